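pipelineDefaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    simulation = list(
      n_reads = 10000L, error_rate = 0.001, contamination_fraction = 0,
      n_taxa = 3L, genome_length = 20000L,
      abundances = NULL,
      delta5 = 0.2, decay = 0.6, delta_base = 0.01),
    qc = list(min_len = 30L, min_q = 20, dust = 7, dedup = TRUE),
    screen = list(min_escore = 7, min_reads = 10, min_rel_abundance = 2e-4,
                  genus_mito_hits_above = 3),
    assign = list(min_mapq = 30, competitor_divergence = 0.15),
    damage = list(n_positions = 30L, terminal_k = c(3L, 5L),
                  gate_reads = 100L),
    sex = list(female_below = 0.016, male_above = 0.077,
               n_reads = 100000L, true_sex = "XY"),
    contamination = list(fraction = 0.05, n_sites = 50L, depth = 100),
    consensus = list(min_depth = 5L, min_gq = 20, recode_ratio = 1 / 9),
    peptides = list(enabled = TRUE, n_psms = 120L, max_score = 0.01,
                    min_psms = 2L, min_unique_peptides = 2L,
                    partial_coverage = 0.05))
}

mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(paste0(path, unknown), collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- mergeConfig(defaults[[k]], user[[k]],
                                   paste0(path, k, "$"))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Every threshold defaults to the pipeline's standard value (QC length
#' 30 / quality 20 / dust 7; E-score 7; genus mito hits > 3; mapq 30;
#' terminal k 3 and 5 with a 100-read gate; Ry thresholds 0.016 / 0.077;
#' consensus depth 5 / GQ 20 / recode 1/9; PSM score 0.01 with >= 2 PSMs,
#' >= 2 unique peptides and 5\% partial coverage). Unknown keys are
#' rejected before any stage runs.
#'
#' @param ... named overrides, possibly nested lists (e.g.
#'   \code{qc = list(min_len = 25)}).
#' @param file optional YAML file of overrides, merged before \code{...}.
#' @return the full configuration list, class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(..., file = NULL) {
  cfg <- pipelineDefaults()
  if (!is.null(file)) cfg <- mergeConfig(cfg, yaml::read_yaml(file))
  user <- list(...)
  if (length(user)) cfg <- mergeConfig(cfg, user)
  structure(cfg, class = c("PipelineConfig", "list"))
}

defaultMixture <- function(sim, seed) {
  ab <- sim$abundances %||% {
    w <- rev(seq_len(sim$n_taxa))
    w / sum(w)
  }
  stopifnot(length(ab) == sim$n_taxa)
  lapply(seq_len(sim$n_taxa), function(i) {
    taxonSpec(sprintf("tax%02d", i),
              sprintf("Simulatus species%02d", i),
              sprintf("Simulatus%02d", (i + 1) %/% 2),
              ab[i],
              setNames(randomReference(sim$genome_length,
                                       seed = subSeed(seed, paste0("ref", i))),
                       sprintf("tax%02d_mt", i)),
              roles = "mitochondrion")
  })
}

stageStep <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full authentication pipeline on simulated data
#'
#' Executes the stages in dependency order — simulate, read QC,
#' taxonomic screening, competitive assignment, damage authentication,
#' sex / contamination / individuality statistics, and (optionally) the
#' peptide-discrimination workflow — and writes a provenance manifest
#' whose counts reconcile every read.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param mixture optional list of \code{\link{taxonSpec}}; by default a
#'   seeded mixture of random mitochondrial genomes is generated.
#' @return list with per-stage results and \code{manifest}; the manifest
#'   (also written to \code{manifest.json} in the output directory)
#'   carries the effective config, per-stage row counts, output
#'   checksums and conservation checks.
#' @export
runPipeline <- function(config = pipelineConfig(), mixture = NULL) {
  cfg <- mergeConfig(pipelineDefaults(), unclass(config))
  seed <- cfg$seed
  outDir <- cfg$out_dir %||% tempfile("sedsift_run_")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "sedsift",
                   version = as.character(utils::packageVersion("sedsift")),
                   config = cfg, counts = list(), checksums = list(),
                   started = format(Sys.time(), usetz = TRUE))

  sim <- cfg$simulation
  mixture <- mixture %||% defaultMixture(sim, seed)

  simOut <- stageStep("simulate", {
    simulateMetagenome(
      mixture,
      dmg = damageModel(sim$delta5, sim$decay, sim$delta_base),
      cfg = simConfig(seed = subSeed(seed, "simulate"),
                      nReads = sim$n_reads, errorRate = sim$error_rate,
                      contaminationFraction = sim$contamination_fraction))
  })
  fastqPath <- file.path(outDir, "reads.fastq")
  writeFastq(simOut$reads, fastqPath)
  manifest$counts$simulated_reads <- length(simOut$reads)
  manifest$counts$truth_rows <- nrow(simOut$truth)

  qcOut <- stageStep("qc", {
    qcFilter(simOut$reads, qcParams(cfg$qc$min_len, cfg$qc$min_q,
                                    cfg$qc$dust, cfg$qc$dedup))
  })
  writeFastq(qcOut$reads, file.path(outDir, "reads.qc.fastq"))
  manifest$counts$qc <- as.list(qcOut$report)

  report <- stageStep("screen", {
    rep <- synthTaxReport(simOut$truth, mixture)
    writeTaxReport(rep, file.path(outDir, "taxreport.tsv"))
    sp <- eScore(rep[rep$rank == "species", , drop = FALSE])
    filtered <- filterTaxa(sp, cfg$screen$min_escore, cfg$screen$min_reads,
                           cfg$screen$min_rel_abundance,
                           total = sum(sp$reads))
    cand <- selectCandidates(sp, cfg$screen$min_escore,
                             cfg$screen$genus_mito_hits_above)
    list(report = rep, filtered = filtered, candidates = cand)
  })
  manifest$counts$screen <- list(
    species_rows = sum(report$report$rank == "species"),
    passing_filters = nrow(report$filtered),
    candidate_species = nrow(report$candidates$candidates))

  assignOut <- stageStep("assign", {
    target <- mixture[[1]]
    refA <- target$sequences
    refB <- divergeReference(refA, cfg$assign$competitor_divergence,
                             seed = subSeed(seed, "competitor"))
    tr <- simOut$truth[simOut$truth$taxon_id == target$taxonId, , drop = FALSE]
    aln <- competitiveAlignments(tr, simOut$reads,
                                 list(target = refA, competitor = refB))
    assignment <- assignReads(aln, cfg$assign$min_mapq,
                              readIds = tr$read_id)
    list(alignments = aln, assignment = assignment,
         genomeLength = sum(nchar(as.character(refA))))
  })
  reasons <- table(factor(assignOut$assignment$reason,
                          levels = c("assigned", "tie", "below_mapq", "no_hit")))
  manifest$counts$assign <- as.list(as.integer(reasons))
  names(manifest$counts$assign) <- names(reasons)

  dmgOut <- stageStep("damage", {
    prof <- misincorporationProfile(simOut$alignments,
                                    cfg$damage$n_positions)
    summaries <- lapply(cfg$damage$terminal_k, function(k) {
      terminalDamage(prof, k, cfg$damage$gate_reads)
    })
    names(summaries) <- paste0("k", cfg$damage$terminal_k)
    list(profile = prof, summaries = summaries)
  })
  manifest$counts$damage <- list(
    alignments_profiled = nReads(dmgOut$profile),
    terminal = lapply(dmgOut$summaries, damageAverage))

  stats <- stageStep("sample-stats", {
    sexCounts <- simulateSexReads(cfg$sex$true_sex, cfg$sex$n_reads,
                                  seed = subSeed(seed, "sex"))
    nX <- sexCounts$count[sexCounts$role == "chrX"]
    nY <- sexCounts$count[sexCounts$role == "chrY"]
    sex <- rySex(sum(nX), sum(nY), cfg$sex$female_below, cfg$sex$male_above)

    ns <- cfg$contamination$n_sites
    geno <- data.frame(chrom = "MT", pos = seq_len(ns) * 100L,
                       ref = rep(DNA_BASES4, length.out = ns),
                       endogenous = rep(DNA_BASES4, length.out = ns),
                       contaminant = rep(c("G", "T", "A", "C"),
                                         length.out = ns),
                       stringsAsFactors = FALSE)
    pu <- simulatePileup(geno, cfg$contamination$depth,
                         cfg$contamination$fraction,
                         seed = subSeed(seed, "pileup"))
    contam <- contaminationRatio(pu$pileup, geno[, c("chrom", "pos")])
    het <- hetScreen(pu$pileup, cfg$consensus$min_depth)
    cons <- consensusCall(pu$pileup, cfg$consensus$min_depth,
                          cfg$consensus$min_gq, cfg$consensus$recode_ratio)
    list(sex = sex, contamination = contam, het = het, consensus = cons)
  })
  manifest$counts$sample_stats <- list(
    sex_call = stats$sex$call, ry = stats$sex$ry,
    contamination = stats$contamination$estimate,
    transversion_het = stats$het$nTransversionHet,
    consensus_emitted = stats$consensus$nEmitted,
    consensus_masked = stats$consensus$nSites - stats$consensus$nEmitted)

  pep <- NULL
  if (isTRUE(cfg$peptides$enabled)) {
    pep <- stageStep("peptides", {
      pair <- synthProteinPair(seed = subSeed(seed, "proteins"))
      psms <- synthPSMTable(pair, cfg$peptides$n_psms,
                            seed = subSeed(seed, "psms"))
      ev <- filterPSMs(psms, cfg$peptides$max_score, cfg$peptides$min_psms)
      matches <- matchPeptides(ev, pair)
      prot <- proteinEvidence(ev, pair, cfg$peptides$min_unique_peptides,
                              cfg$peptides$partial_coverage)
      list(psms = psms, evidence = ev, matches = matches, proteins = prot)
    })
    manifest$counts$peptides <- list(
      psms = nrow(pep$psms), peptides_retained = nrow(pep$evidence),
      diagnostic_peptides = sum(pep$matches$diagnostic),
      proteins_reported = nrow(pep$proteins))
  }

  # conservation checks: every read is accounted for at every boundary
  qcRep <- qcOut$report
  manifest$conservation <- list(
    qc = unname(qcRep$input ==
      qcRep$removed_length + qcRep$removed_quality + qcRep$removed_dust +
      qcRep$removed_duplicate + qcRep$kept),
    truth_matches_fastq = nrow(simOut$truth) == length(simOut$reads),
    report_reads_match = sum(report$report$reads[report$report$rank ==
                                                   "species"]) ==
      nrow(simOut$truth),
    assign_partition = sum(reasons) ==
      length(unique(assignOut$assignment$read_id)))
  if (!all(unlist(manifest$conservation))) {
    stop("pipeline manifest failed count conservation")
  }

  outputs <- list.files(outDir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest$checksums <- as.list(md5sum(outputs))
  names(manifest$checksums) <- basename(outputs)
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  list(outDir = outDir, manifest = manifest, simulation = simOut,
       qc = qcOut, screen = report, assign = assignOut, damage = dmgOut,
       stats = stats, peptides = pep)
}
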