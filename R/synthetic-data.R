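#' Describe one taxon in a simulated metagenomic mixture
#'
#' @param taxonId short stable identifier.
#' @param name species name (used as report taxName).
#' @param genus genus the species belongs to.
#' @param abundance expected fraction of reads drawn from this taxon.
#' @param sequences named \code{\link[Biostrings]{DNAStringSet}} or named
#'   character vector of reference sequences.
#' @param roles per-sequence role, one of \code{"autosome"}, \code{"chrX"},
#'   \code{"chrY"}, \code{"mitochondrion"}, \code{"plastid"}.
#' @return a \code{list} of class \code{"TaxonSpec"}.
#' @export
taxonSpec <- function(taxonId, name, genus, abundance, sequences,
                      roles = "autosome") {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("reference sequences must carry unique names")
  }
  seqs <- as.character(sequences)
  if (any(nchar(seqs) == 0)) stop("empty reference sequence in taxon ", taxonId)
  if (any(grepl("[^ACGT]", seqs))) {
    stop("reference sequences must be over {A,C,G,T} (taxon ", taxonId, ")")
  }
  roles <- rep_len(roles, length(sequences))
  roles <- match.arg(roles,
                     c("autosome", "chrX", "chrY", "mitochondrion", "plastid"),
                     several.ok = TRUE)
  stopifnot(abundance >= 0)
  structure(list(taxonId = taxonId, name = name, genus = genus,
                 abundance = abundance, sequences = sequences, roles = roles),
            class = "TaxonSpec")
}

#' Lognormal fragment-length model for ancient DNA reads
#'
#' @param logMean,logSd parameters of the lognormal on the bp scale.
#' @param minLen,maxLen truncation bounds in bp; draws are clamped.
#' @return a list of class \code{"FragmentModel"}.
#' @export
fragmentModel <- function(logMean = log(55), logSd = 0.35,
                          minLen = 30L, maxLen = 120L) {
  stopifnot(minLen >= 20, maxLen >= minLen)
  structure(list(logMean = logMean, logSd = logSd,
                 minLen = as.integer(minLen), maxLen = as.integer(maxLen)),
            class = "FragmentModel")
}

#' Simulation configuration
#'
#' @param seed master seed; every random stream is derived from it.
#' @param nReads number of reads to emit.
#' @param errorRate per-base sequencing error probability.
#' @param contaminationFraction proportion of reads drawn, undamaged, from
#'   the designated contaminant source.
#' @param qualityModel \code{list(type = "constant", q = 37)} or
#'   \code{list(type = "linear", q5 = , q3 = )} for a position-linear ramp.
#' @return a list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed = 1L, nReads = 1000L, errorRate = 0.001,
                      contaminationFraction = 0,
                      qualityModel = list(type = "constant", q = 37L)) {
  stopifnot(contaminationFraction >= 0, contaminationFraction <= 1,
            errorRate >= 0, errorRate < 1, nReads >= 0)
  structure(list(seed = as.integer(seed), nReads = as.integer(nReads),
                 errorRate = errorRate,
                 contaminationFraction = contaminationFraction,
                 qualityModel = qualityModel),
            class = "SimConfig")
}

#' Random reference sequence helper
#'
#' @param length sequence length in bp.
#' @param seed RNG seed.
#' @param gc GC content of the generated sequence.
#' @return a single uppercase ACGT string.
#' @export
randomReference <- function(length, seed = 1L, gc = 0.42) {
  withSeed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

qualityString <- function(lens, model) {
  if (identical(model$type, "constant")) {
    ch <- intToUtf8(model$q + 33L)
    vapply(lens, function(L) strrep(ch, L), character(1))
  } else if (identical(model$type, "linear")) {
    vapply(lens, function(L) {
      q <- round(seq(model$q5, model$q3, length.out = L))
      intToUtf8(q + 33L, multiple = FALSE)
    }, character(1))
  } else stop("unknown quality model type: ", model$type)
}

# Build an MD tag for a gapless alignment from reference and SAM-oriented
# read characters (equal length). Runs of matches are emitted as lengths,
# mismatches as the reference base.
mdTagGapless <- function(refChars, readChars) {
  mism <- refChars != readChars
  r <- rle(mism)
  out <- character(0)
  pos <- 1L
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) {
      out <- c(out, as.character(r$lengths[i]))
      pos <- pos + r$lengths[i]
    } else {
      for (j in seq_len(r$lengths[i])) {
        if (j > 1L) out <- c(out, "0")
        out <- c(out, refChars[pos])
        pos <- pos + 1L
      }
    }
  }
  if (length(r$lengths) == 0L || r$values[length(r$values)]) out <- c(out, "0")
  if (!length(out) || r$values[1]) out <- c("0", out)
  paste(out, collapse = "")
}

#' Simulate an ancient metagenome with known truth
#'
#' Draws reads from a taxon mixture with lognormal fragment lengths,
#' applies position-decaying terminal deamination (5' C-to-T and, for
#' double-stranded libraries, 3' G-to-A), per-base sequencing error, and an
#' undamaged modern-contaminant admixture. Returns the reads, a lossless
#' truth table and exact-placement alignment records.
#'
#' @param mixture list of \code{\link{taxonSpec}} objects; abundances must
#'   sum to 1 (within 1e-9).
#' @param frag a \code{\link{fragmentModel}}.
#' @param dmg a \code{\link{damageModel}}.
#' @param cfg a \code{\link{simConfig}}.
#' @param contaminant optional \code{taxonSpec} acting as the undamaged
#'   modern contaminant source; required when
#'   \code{cfg$contaminationFraction > 0}.
#' @return list with \code{reads} (a
#'   \code{\link[Biostrings]{QualityScaledDNAStringSet}}), \code{truth}
#'   (data.frame: read_id, taxon_id, seq_id, start, end 0-based half-open,
#'   strand, damaged_positions, is_contaminant) and \code{alignments}
#'   (data.frame of exact placements with cigar, NM and MD).
#' @examples
#' mix <- list(taxonSpec("t1", "Toyus unus", "Toyus", 1,
#'                       c(chr = randomReference(5000, 7))))
#' sim <- simulateMetagenome(mix, cfg = simConfig(seed = 1, nReads = 50))
#' head(sim$truth)
#' @export
simulateMetagenome <- function(mixture, frag = fragmentModel(),
                               dmg = damageModel(), cfg = simConfig(),
                               contaminant = NULL) {
  stopifnot(length(mixture) >= 1)
  ab <- vapply(mixture, `[[`, numeric(1), "abundance")
  if (abs(sum(ab) - 1) > 1e-9) stop("mixture abundances must sum to 1")
  if (cfg$contaminationFraction > 0 && is.null(contaminant)) {
    stop("contaminationFraction > 0 requires a contaminant taxonSpec")
  }
  sources <- mixture
  if (!is.null(contaminant)) sources <- c(sources, list(contaminant))
  for (tx in sources) {
    short <- nchar(as.character(tx$sequences)) < frag$minLen
    if (any(short)) {
      stop("reference sequence ", names(tx$sequences)[which(short)[1]],
           " of taxon ", tx$taxonId, " is shorter than the minimum fragment")
    }
  }
  n <- cfg$nReads
  if (n == 0L) {
    return(list(reads = Biostrings::QualityScaledDNAStringSet(
                  Biostrings::DNAStringSet(), Biostrings::PhredQuality(character())),
                truth = emptyTruth(), alignments = emptyAlignments()))
  }

  # Which reads are contaminant, and how many reads per endogenous taxon.
  isContam <- withSeed(subSeed(cfg$seed, "contamination"), {
    runif(n) < cfg$contaminationFraction
  })
  nEndo <- sum(!isContam)
  counts <- withSeed(subSeed(cfg$seed, "mixture"), {
    as.vector(rmultinom(1, nEndo, ab))
  })

  taxonOf <- character(n)
  taxonOf[!isContam] <- rep(vapply(mixture, `[[`, character(1), "taxonId"), counts)
  if (any(isContam)) taxonOf[isContam] <- contaminant$taxonId
  specOf <- setNames(sources, vapply(sources, `[[`, character(1), "taxonId"))

  # Fragmentation stream: sequence choice, length, start, strand.
  fragDraw <- withSeed(subSeed(cfg$seed, "fragment"), {
    lens <- pmin(pmax(round(rlnorm(n, frag$logMean, frag$logSd)),
                      frag$minLen), frag$maxLen)
    seqId <- character(n)
    start <- integer(n)
    for (tid in unique(taxonOf)) {
      ix <- which(taxonOf == tid)
      sq <- specOf[[tid]]$sequences
      slen <- nchar(as.character(sq))
      pick <- sample.int(length(sq), length(ix), replace = TRUE, prob = slen)
      seqId[ix] <- names(sq)[pick]
      maxLen <- slen[pick]
      lens[ix] <- pmin(lens[ix], maxLen)
      start[ix] <- floor(runif(length(ix)) * (maxLen - lens[ix] + 1))
    }
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    list(lens = as.integer(lens), seqId = seqId, start = as.integer(start),
         strand = strand)
  })
  lens <- fragDraw$lens

  # Extract the (reference-oriented) fragments.
  frags <- character(n)
  for (tid in unique(taxonOf)) {
    sq <- specOf[[tid]]$sequences
    ix <- which(taxonOf == tid)
    frags[ix] <- as.character(Biostrings::subseq(
      sq[fragDraw$seqId[ix]], start = fragDraw$start[ix] + 1L,
      width = lens[ix]))
  }
  reads <- ifelse(fragDraw$strand == "-", revComp(frags), frags)

  # Damage stream: per-base Bernoulli draws on the read orientation.
  flat <- strsplit(reads, NULL)
  bases <- unlist(flat, use.names = FALSE)
  readIx <- rep.int(seq_len(n), lens)
  pos5 <- sequence(lens)
  pos3 <- unlist(lapply(lens, function(L) rev(seq_len(L))), use.names = FALSE)
  dmgFlags <- withSeed(subSeed(cfg$seed, "damage"), {
    u5 <- runif(length(bases))
    u3 <- runif(length(bases))
    ct <- bases == "C" & u5 < damageRate(dmg, pos5) & !isContam[readIx]
    ga <- if (dmg@doubleStranded) {
      bases == "G" & u3 < damageRate(dmg, pos3) & !isContam[readIx]
    } else rep(FALSE, length(bases))
    list(ct = ct, ga = ga)
  })
  bases[dmgFlags$ct] <- "T"
  bases[dmgFlags$ga] <- "A"
  damaged <- dmgFlags$ct | dmgFlags$ga

  # Sequencing error stream.
  if (cfg$errorRate > 0) {
    errFlags <- withSeed(subSeed(cfg$seed, "error"), {
      hit <- runif(length(bases)) < cfg$errorRate
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      list(hit = hit, shift = shift)
    })
    if (any(errFlags$hit)) {
      cur <- match(bases[errFlags$hit], DNA_BASES4)
      bases[errFlags$hit] <- DNA_BASES4[((cur - 1L + errFlags$shift) %% 4L) + 1L]
    }
  }
  readsOut <- pasteByRead(bases, readIx, n)

  dmgPos <- character(n)
  if (any(damaged)) {
    byRead <- split(pos5[damaged], factor(readIx[damaged], levels = seq_len(n)))
    dmgPos <- vapply(byRead, function(p) paste(p, collapse = ","), character(1))
  }

  readId <- sprintf("read_%06d", seq_len(n))
  truth <- data.frame(
    read_id = readId, taxon_id = taxonOf, seq_id = fragDraw$seqId,
    start = fragDraw$start, end = fragDraw$start + lens,
    strand = fragDraw$strand, damaged_positions = dmgPos,
    is_contaminant = isContam, stringsAsFactors = FALSE)

  # Truth alignments: SAM-oriented sequence, NM and MD against the source.
  samSeq <- ifelse(fragDraw$strand == "-", revComp(readsOut), readsOut)
  samChars <- strsplit(samSeq, NULL)
  refChars <- strsplit(frags, NULL)
  nm <- integer(n)
  md <- character(n)
  for (i in seq_len(n)) {
    mism <- samChars[[i]] != refChars[[i]]
    nm[i] <- sum(mism)
    md[i] <- if (nm[i] == 0L) as.character(lens[i]) else
      mdTagGapless(refChars[[i]], samChars[[i]])
  }
  alignments <- data.frame(
    read_id = readId, ref_id = fragDraw$seqId, pos = fragDraw$start,
    strand = fragDraw$strand, cigar = paste0(lens, "M"), mapq = 60L,
    nm = nm, md = md, seq = samSeq, stringsAsFactors = FALSE)

  quals <- qualityString(lens, cfg$qualityModel)
  dna <- Biostrings::DNAStringSet(readsOut)
  names(dna) <- readId
  qs <- Biostrings::PhredQuality(quals)
  reads <- Biostrings::QualityScaledDNAStringSet(dna, qs)

  list(reads = reads, truth = truth, alignments = alignments)
}

emptyTruth <- function() {
  data.frame(read_id = character(), taxon_id = character(),
             seq_id = character(), start = integer(), end = integer(),
             strand = character(), damaged_positions = character(),
             is_contaminant = logical(), stringsAsFactors = FALSE)
}

emptyAlignments <- function() {
  data.frame(read_id = character(), ref_id = character(), pos = integer(),
             strand = character(), cigar = character(), mapq = integer(),
             nm = integer(), md = character(), seq = character(),
             stringsAsFactors = FALSE)
}

#' Stylised chromosome layout for sex-ratio simulations
#'
#' Equal-length X and Y make the expected XY read pattern the "1 X to 1 Y,
#' each at half the autosomal rate per bp" signature that read-ratio sex
#' classification relies on.
#'
#' @param nAutosomes number of autosomes.
#' @param autosomeLength,xLength,yLength lengths in bp.
#' @return data.frame with chrom, length and role columns.
#' @export
defaultSexLayout <- function(nAutosomes = 2L, autosomeLength = 1e6,
                             xLength = 1e6, yLength = 1e6) {
  data.frame(
    chrom = c(paste0("chr", seq_len(nAutosomes)), "chrX", "chrY"),
    length = c(rep(autosomeLength, nAutosomes), xLength, yLength),
    role = c(rep("autosome", nAutosomes), "chrX", "chrY"),
    stringsAsFactors = FALSE)
}

#' Simulate per-chromosome aligned-read counts for a known genetic sex
#'
#' Reads land on each chromosome in proportion to its length times its copy
#' number (autosomes 2; X 2 in XX / 1 in XY; Y 0 in XX / 1 in XY). A noise
#' rate models spurious Y-mapping in females.
#'
#' @param sex \code{"XX"} or \code{"XY"}.
#' @param nReads total aligned reads to distribute.
#' @param layout chromosome table as from \code{\link{defaultSexLayout}};
#'   must include chrX.
#' @param seed RNG seed.
#' @param noise spurious per-bp relative rate applied to chrY in XX
#'   individuals (0 disables it).
#' @return data.frame with chrom, role and count.
#' @export
simulateSexReads <- function(sex = c("XX", "XY"), nReads, layout = defaultSexLayout(),
                             seed = 1L, noise = 0) {
  sex <- match.arg(sex)
  if (nReads <= 0) stop("nReads must be positive")
  if (!"chrX" %in% layout$role) stop("layout must include chrX")
  copy <- ifelse(layout$role == "autosome", 2,
          ifelse(layout$role == "chrX", if (sex == "XX") 2 else 1,
          ifelse(layout$role == "chrY", if (sex == "XX") noise else 1, 0)))
  w <- layout$length * copy
  counts <- withSeed(seed, as.vector(rmultinom(1, nReads, w)))
  data.frame(chrom = layout$chrom, role = layout$role, count = counts,
             stringsAsFactors = FALSE)
}

#' Simulate an allele-depth pileup with known contamination
#'
#' Each site's depth is Poisson; each covering read is endogenous with
#' probability \code{1 - contamination} and carries that haplotype's
#' allele, otherwise the contaminant allele; sequencing error then
#' perturbs bases uniformly.
#'
#' @param genotypes data.frame with columns chrom, pos, ref,
#'   endogenous, contaminant (single-base alleles). Sites where the two
#'   haplotypes differ are the diagnostic sites.
#' @param meanDepth Poisson mean coverage per site.
#' @param contamination contaminant fraction in [0, 1].
#' @param seed RNG seed.
#' @param errorRate per-base sequencing error probability.
#' @return list with \code{pileup} (chrom, pos, ref, A, C, G, T, N) and
#'   \code{truth} (the genotype table plus per-site endogenous depth).
#' @export
simulatePileup <- function(genotypes, meanDepth = 50, contamination = 0,
                           seed = 1L, errorRate = 0) {
  stopifnot(contamination >= 0, contamination <= 1)
  diag <- genotypes$endogenous != genotypes$contaminant
  if (!any(diag)) stop("no diagnostic sites: haplotypes are identical")
  ns <- nrow(genotypes)
  withSeed(seed, {
    depth <- rpois(ns, meanDepth)
    nCont <- rbinom(ns, depth, contamination)
    nEndo <- depth - nCont
    mat <- matrix(0L, nrow = ns, ncol = 5,
                  dimnames = list(NULL, c("A", "C", "G", "T", "N")))
    for (i in seq_len(ns)) {
      mat[i, genotypes$endogenous[i]] <- mat[i, genotypes$endogenous[i]] + nEndo[i]
      mat[i, genotypes$contaminant[i]] <- mat[i, genotypes$contaminant[i]] + nCont[i]
    }
    if (errorRate > 0) {
      for (i in seq_len(ns)) {
        for (b in DNA_BASES4) {
          k <- mat[i, b]
          if (k == 0) next
          nErr <- rbinom(1, k, errorRate)
          if (nErr == 0) next
          mat[i, b] <- mat[i, b] - nErr
          to <- sample(setdiff(DNA_BASES4, b), nErr, replace = TRUE)
          for (t in to) mat[i, t] <- mat[i, t] + 1L
        }
      }
    }
    pileup <- data.frame(chrom = genotypes$chrom, pos = genotypes$pos,
                         ref = genotypes$ref, mat, stringsAsFactors = FALSE)
    truth <- cbind(genotypes,
                   diagnostic = diag, depth = depth, endo_depth = nEndo)
    list(pileup = pileup, truth = truth)
  })
}

#' Emulate a k-mer classification report from simulation truth
#'
#' Per taxon: \code{reads} is the truth count; unique k-mers are the
#' distinct (sequence, offset) k-mer start positions covered by reads,
#' capped by the genome k-mer count; \code{dup} is total k-mer
#' observations over unique; \code{cov} is unique over the genome k-mer
#' count. Species rows are nested under their genus in the emitted
#' hierarchy.
#'
#' @param truth truth table from \code{\link{simulateMetagenome}}.
#' @param mixture the taxon mixture the truth was simulated from (the
#'   contaminant spec may be appended if present in the truth).
#' @param k k-mer length (>= 21).
#' @return data.frame in classification-report form (pct, reads,
#'   tax_reads, unique_kmers, dup, cov, taxid, rank, name, genus,
#'   parent_taxid, depth).
#' @export
synthTaxReport <- function(truth, mixture, k = 31L) {
  stopifnot(k >= 21)
  specs <- setNames(mixture, vapply(mixture, `[[`, character(1), "taxonId"))
  missing <- setdiff(unique(truth$taxon_id), names(specs))
  if (length(missing)) stop("truth contains taxa absent from mixture: ",
                            paste(missing, collapse = ", "))
  total <- nrow(truth)
  rows <- lapply(names(specs), function(tid) {
    tx <- specs[[tid]]
    tr <- truth[truth$taxon_id == tid, , drop = FALSE]
    slen <- setNames(nchar(as.character(tx$sequences)), names(tx$sequences))
    genomeKmers <- sum(pmax(0L, slen - k + 1L))
    if (nrow(tr) == 0) {
      uniq <- 0L; tot <- 0
    } else {
      ok <- (tr$end - tr$start) >= k
      keys <- unlist(lapply(which(ok), function(i) {
        paste(tr$seq_id[i], tr$start[i]:(tr$end[i] - k), sep = ":")
      }))
      uniq <- length(unique(keys))
      tot <- length(keys)
    }
    uniq <- as.integer(min(uniq, genomeKmers))
    data.frame(
      reads = nrow(tr), tax_reads = nrow(tr),
      unique_kmers = uniq,
      dup = if (uniq > 0) tot / uniq else 0,
      cov = if (genomeKmers > 0) uniq / genomeKmers else 0,
      name = tx$name, genus = tx$genus, stringsAsFactors = FALSE)
  })
  species <- do.call(rbind, rows)
  species$rank <- "species"
  # genus rows aggregate their species
  genera <- unique(species$genus)
  gRows <- do.call(rbind, lapply(genera, function(g) {
    sp <- species[species$genus == g, , drop = FALSE]
    data.frame(reads = sum(sp$reads), tax_reads = 0L,
               unique_kmers = sum(sp$unique_kmers),
               dup = if (sum(sp$unique_kmers) > 0)
                 sum(sp$dup * sp$unique_kmers) / sum(sp$unique_kmers) else 0,
               cov = mean(sp$cov), name = g, genus = g, rank = "genus",
               stringsAsFactors = FALSE)
  }))
  out <- NULL
  taxid <- 0L
  for (g in genera) {
    taxid <- taxid + 1L
    gr <- gRows[gRows$name == g, , drop = FALSE]
    gr$taxid <- taxid
    gr$parent_taxid <- NA_integer_
    gr$depth <- 0L
    out <- rbind(out, gr)
    gid <- taxid
    sp <- species[species$genus == g, , drop = FALSE]
    for (i in seq_len(nrow(sp))) {
      taxid <- taxid + 1L
      r <- sp[i, , drop = FALSE]
      r$taxid <- taxid
      r$parent_taxid <- gid
      r$depth <- 1L
      out <- rbind(out, r)
    }
  }
  out$pct <- if (total > 0) 100 * out$reads / total else 0
  rownames(out) <- NULL
  out[, c("pct", "reads", "tax_reads", "unique_kmers", "dup", "cov",
          "taxid", "rank", "name", "genus", "parent_taxid", "depth")]
}

#' Generate a homologous two-species protein pair with diagnostic residues
#'
#' Species B proteins are copies of species A proteins with substitutions
#' at the chosen diagnostic positions; every other residue is identical,
#' so peptides spanning a diagnostic position occur in exactly one
#' species. Substituted residues are chosen to remain distinct under I/L
#' equivalence.
#'
#' @param nProteins homologous protein pairs to generate.
#' @param length protein length (residues).
#' @param nDiagnostic diagnostic residues per protein.
#' @param seed RNG seed.
#' @param speciesA,speciesB species labels for the FASTA headers.
#' @return list with \code{db} (an \code{AAStringSet}, names carrying
#'   \code{species=} and \code{gene=} tags), \code{proteins} (data.frame
#'   acc, species, gene, seq) and \code{diagnostics} (data.frame gene,
#'   pos, residueA, residueB).
#' @export
synthProteinPair <- function(nProteins = 2L, length = 120L, nDiagnostic = 1L,
                             seed = 1L, speciesA = "SpeciesA",
                             speciesB = "SpeciesB") {
  aa <- strsplit("ACDEFGHKMNPQRSTVWY", NULL)[[1]]  # skips I/L for backbones
  withSeed(seed, {
    recs <- list(); diags <- NULL
    for (p in seq_len(nProteins)) {
      gene <- sprintf("PROT%02d", p)
      sa <- sample(aa, length, replace = TRUE)
      sb <- sa
      pos <- sort(sample.int(length, nDiagnostic))
      for (q in pos) {
        sb[q] <- sample(setdiff(aa, sa[q]), 1)
      }
      diags <- rbind(diags, data.frame(gene = gene, pos = pos,
                                       residueA = sa[pos], residueB = sb[pos],
                                       stringsAsFactors = FALSE))
      recs[[paste0(gene, "_A")]] <- list(species = speciesA, gene = gene,
                                         seq = paste(sa, collapse = ""))
      recs[[paste0(gene, "_B")]] <- list(species = speciesB, gene = gene,
                                         seq = paste(sb, collapse = ""))
    }
    proteins <- data.frame(
      acc = names(recs),
      species = vapply(recs, `[[`, character(1), "species"),
      gene = vapply(recs, `[[`, character(1), "gene"),
      seq = vapply(recs, `[[`, character(1), "seq"),
      stringsAsFactors = FALSE, row.names = NULL)
    db <- Biostrings::AAStringSet(proteins$seq)
    names(db) <- sprintf("%s species=%s gene=%s", proteins$acc,
                         proteins$species, proteins$gene)
    list(db = db, proteins = proteins, diagnostics = diags)
  })
}

#' Simulate a peptide-spectrum-match table against a two-species database
#'
#' Peptides are true substrings of the designated source species'
#' proteins; a configurable fraction spans a diagnostic residue. Truth
#' labels (which species' proteome contains each peptide) are computed by
#' exhaustive substring search and retained.
#'
#' @param proteinPair output of \code{\link{synthProteinPair}} (or a list
#'   with the same shape).
#' @param nPsms number of PSM rows to emit.
#' @param seed RNG seed.
#' @param sourceSpecies species the peptides are drawn from.
#' @param diagnosticFraction fraction of distinct peptides forced to span
#'   a diagnostic residue.
#' @param pepLen range of peptide lengths.
#' @param scoreRange search-engine score range (lower is better).
#' @return data.frame with spectrum_id, peptide, modifications, score,
#'   accessions, plus truth columns true_species (comma-joined) and
#'   spans_diagnostic.
#' @export
synthPSMTable <- function(proteinPair, nPsms = 100L, seed = 1L,
                          sourceSpecies = NULL, diagnosticFraction = 0.3,
                          pepLen = c(9L, 25L), scoreRange = c(1e-4, 0.02)) {
  proteins <- proteinPair$proteins
  diags <- proteinPair$diagnostics
  if (is.null(sourceSpecies)) sourceSpecies <- proteins$species[1]
  src <- proteins[proteins$species == sourceSpecies, , drop = FALSE]
  if (nrow(src) == 0) stop("sourceSpecies not present in the database")
  bad <- diags$residueA == diags$residueB
  if (any(bad)) stop("diagnostic position identical in both species (gene ",
                     diags$gene[which(bad)[1]], ")")
  withSeed(seed, {
    nPep <- max(1L, ceiling(nPsms / 3))
    peps <- character(nPep); accs <- character(nPep)
    for (i in seq_len(nPep)) {
      row <- src[sample.int(nrow(src), 1), ]
      L <- sample(seq(pepLen[1], pepLen[2]), 1)
      plen <- nchar(row$seq)
      wantDiag <- runif(1) < diagnosticFraction
      dpos <- diags$pos[diags$gene == row$gene]
      if (wantDiag && length(dpos)) {
        d <- sample(dpos, 1)
        lo <- max(1L, d - L + 1L); hi <- min(d, plen - L + 1L)
        s <- if (hi >= lo) sample(seq(lo, hi), 1) else max(1L, plen - L + 1L)
      } else {
        s <- sample.int(plen - L + 1L, 1)
      }
      peps[i] <- substr(row$seq, s, s + L - 1L)
      accs[i] <- row$acc
    }
    pick <- sample.int(nPep, nPsms, replace = TRUE)
    score <- runif(nPsms, scoreRange[1], scoreRange[2])
    trueSpecies <- vapply(peps, function(p) {
      hit <- vapply(proteins$seq, function(s) grepl(p, s, fixed = TRUE),
                    logical(1))
      paste(sort(unique(proteins$species[hit])), collapse = ",")
    }, character(1), USE.NAMES = FALSE)
    spans <- vapply(seq_len(nPep), function(i) {
      !grepl(",", trueSpecies[i], fixed = TRUE)
    }, logical(1))
    data.frame(
      spectrum_id = sprintf("spec_%05d", seq_len(nPsms)),
      peptide = peps[pick],
      modifications = "",
      score = score,
      accessions = accs[pick],
      true_species = trueSpecies[pick],
      spans_diagnostic = spans[pick],
      stringsAsFactors = FALSE)
  })
}
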