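test_that("zero-damage, zero-error reads are exact substrings of their source", {
  mix <- toyMixture(1)
  sim <- simulateMetagenome(
    mix, dmg = damageModel(delta5 = 0, decay = 0.5, deltaBase = 0),
    cfg = simConfig(seed = 11, nReads = 100, errorRate = 0))
  ref <- as.character(mix[[1]]$sequences[[1]])
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    frag <- substr(ref, tr$start + 1, tr$end)
    read <- as.character(sim$reads)[[tr$read_id]]
    expected <- if (tr$strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
    } else frag
    expect_identical(read, expected)
  }
  expect_true(all(sim$truth$damaged_positions == ""))
  expect_true(all(sim$alignments$nm == 0))
})

test_that("a fixed seed reproduces byte-identical FASTQ, truth and alignments", {
  mix <- toyMixture(2)
  run <- function() simulateMetagenome(mix, cfg = simConfig(seed = 42, nReads = 300))
  s1 <- run(); s2 <- run()
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$alignments, s2$alignments)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeFastq(s1$reads, f1); writeFastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("per-taxon read counts follow the mixture multinomial", {
  mix <- toyMixture(2, abundances = c(0.7, 0.3))
  sim <- simulateMetagenome(mix, cfg = simConfig(seed = 7, nReads = 10000))
  counts <- table(sim$truth$taxon_id)
  probs <- c(tax1 = 0.7, tax2 = 0.3)
  for (tx in names(probs)) {
    p <- probs[[tx]]
    expect_lt(abs(counts[[tx]] - 10000 * p), 3 * sqrt(10000 * p * (1 - p)))
  }
})

test_that("damage lands only on reference C (5') / G (3') and never on contaminants", {
  mix <- toyMixture(1)
  contam <- taxonSpec("modern", "Modernus toy", "Modernus", 1,
                      setNames(randomReference(8000, seed = 555), "modern_chr"))
  sim <- simulateMetagenome(
    mix, dmg = damageModel(delta5 = 0.5, decay = 0.6, deltaBase = 0.02),
    cfg = simConfig(seed = 3, nReads = 2000, errorRate = 0,
                    contaminationFraction = 0.2),
    contaminant = contam)
  expect_true(all(sim$truth$damaged_positions[sim$truth$is_contaminant] == ""))
  refs <- c(as.character(mix[[1]]$sequences), as.character(contam$sequences))
  damagedRows <- which(sim$truth$damaged_positions != "")
  expect_gt(length(damagedRows), 0)
  for (i in damagedRows[seq_len(min(200, length(damagedRows)))]) {
    tr <- sim$truth[i, ]
    frag <- substr(refs[[tr$seq_id]], tr$start + 1, tr$end)
    fragRead <- if (tr$strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
    } else frag
    pos <- as.integer(strsplit(tr$damaged_positions, ",")[[1]])
    orig <- strsplit(fragRead, NULL)[[1]][pos]
    obs <- strsplit(as.character(sim$reads)[[tr$read_id]], NULL)[[1]][pos]
    expect_true(all((orig == "C" & obs == "T") | (orig == "G" & obs == "A")))
  }
})

test_that("a reference shorter than the minimum fragment is refused by name", {
  mix <- list(taxonSpec("t1", "Shortus ref", "Shortus", 1,
                        c(tiny = strrep("ACGT", 5))))
  expect_error(simulateMetagenome(mix, cfg = simConfig(seed = 1, nReads = 10)),
               "tiny")
})

test_that("simulated XY read sets show the 1 X : 1 Y, half-autosome pattern", {
  sx <- simulateSexReads("XY", 100000, seed = 13)
  nX <- sx$count[sx$role == "chrX"]
  nY <- sx$count[sx$role == "chrY"]
  nAuto <- mean(sx$count[sx$role == "autosome"])
  ry <- nY / (nX + nY)
  expect_lt(abs(ry - 0.5), 0.01)
  expect_lt(abs(nX / nAuto - 0.5), 0.05)
  # XX with zero noise places nothing on Y
  xx <- simulateSexReads("XX", 50000, seed = 13, noise = 0)
  expect_identical(xx$count[xx$role == "chrY"], 0L)
  expect_error(simulateSexReads("XY", 0), "positive")
})

test_that("pileup simulation recovers its contamination truth", {
  geno <- data.frame(chrom = "MT", pos = seq_len(50) * 10, ref = "A",
                     endogenous = "A", contaminant = "G",
                     stringsAsFactors = FALSE)
  # c = 0: monoallelic everywhere
  p0 <- simulatePileup(geno, 100, contamination = 0, seed = 5)
  cnt <- as.matrix(p0$pileup[, c("A", "C", "G", "T")])
  expect_true(all(apply(cnt, 1, function(v) sum(v > 0)) == 1))
  # c = 0.10: pooled minority fraction close to truth
  p1 <- simulatePileup(geno, 100, contamination = 0.10, seed = 5)
  est <- contaminationRatio(p1$pileup, geno[, c("chrom", "pos")])
  expect_lt(abs(est$estimate - 0.10), 0.02)
  # c = 1: the pileup is the contaminant haplotype
  p2 <- simulatePileup(geno, 100, contamination = 1, seed = 5)
  expect_true(all(p2$pileup$G > 0 & p2$pileup$A == 0))
  # identical haplotypes are refused
  bad <- geno; bad$contaminant <- bad$endogenous
  expect_error(simulatePileup(bad, 100, 0.1), "diagnostic")
})

test_that("synthetic classification reports obey the k-mer accounting", {
  mix <- toyMixture(1, genomeLength = 5000)
  ref <- as.character(mix[[1]]$sequences[[1]])
  oneRead <- data.frame(read_id = "r1", taxon_id = "tax1", seq_id = "tax1_chr",
                        start = 100L, end = 150L, strand = "+",
                        damaged_positions = "", is_contaminant = FALSE,
                        stringsAsFactors = FALSE)
  rep1 <- synthTaxReport(oneRead, mix, k = 31)
  sp <- rep1[rep1$rank == "species", ]
  expect_lte(sp$unique_kmers, 20)  # 50 - 31 + 1
  # duplicated reads leave unique k-mers unchanged and double dup
  rep2 <- synthTaxReport(rbind(oneRead,
                               transform(oneRead, read_id = "r2")), mix, k = 31)
  sp2 <- rep2[rep2$rank == "species", ]
  expect_identical(sp2$unique_kmers, sp$unique_kmers)
  expect_equal(sp2$dup, 2 * sp$dup)
  # spread reads cover strictly more distinct k-mers than clonal reads,
  # and both match a direct k-mer set oracle
  k <- 31
  spread <- do.call(rbind, lapply(0:9, function(i) {
    transform(oneRead, read_id = sprintf("s%d", i),
              start = 400L * i, end = 400L * i + 50L)
  }))
  clonal <- do.call(rbind, lapply(0:9, function(i) {
    transform(oneRead, read_id = sprintf("c%d", i))
  }))
  kmerOracle <- function(truth) {
    length(unique(unlist(lapply(seq_len(nrow(truth)), function(i) {
      substring(ref, (truth$start[i] + 1):(truth$end[i] - k + 1),
                (truth$start[i] + k):truth$end[i])
    }))))
  }
  us <- synthTaxReport(spread, mix, k)$unique_kmers[2]
  uc <- synthTaxReport(clonal, mix, k)$unique_kmers[2]
  expect_gt(us, uc)
  expect_identical(us, kmerOracle(spread))
  expect_identical(uc, kmerOracle(clonal))
})

test_that("synthetic PSM tables carry exhaustively verified species truth", {
  pair <- synthProteinPair(seed = 21)
  psms <- synthPSMTable(pair, nPsms = 100, seed = 8)
  expect_identical(psms, synthPSMTable(pair, nPsms = 100, seed = 8))
  for (i in seq_len(nrow(psms))) {
    spp <- strsplit(psms$true_species[i], ",")[[1]]
    for (s in c("SpeciesA", "SpeciesB")) {
      expect_identical(speciesContainsOracle(psms$peptide[i], pair$proteins, s,
                                             il = FALSE),
                       s %in% spp)
    }
  }
  expect_setequal(unique(psms$spans_diagnostic),
                  unique(psms$true_species == "SpeciesA"))
  # a diagnostic position identical in both species is a hard error
  broken <- pair
  broken$diagnostics$residueB <- broken$diagnostics$residueA
  expect_error(synthPSMTable(broken, 10, seed = 1), "identical")
})

test_that("read counts are conserved from truth to FASTQ to report", {
  mix <- toyMixture(3, abundances = c(0.5, 0.3, 0.2))
  sim <- simulateMetagenome(mix, cfg = simConfig(seed = 77, nReads = 1500))
  expect_identical(nrow(sim$truth), 1500L)
  expect_identical(length(sim$reads), 1500L)
  rep <- synthTaxReport(sim$truth, mix)
  expect_identical(sum(rep$reads[rep$rank == "species"]), 1500L)
})
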