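test_that("a read identical to its reference has zero substitution frequency", {
  ref <- randomReference(200, seed = 2)
  aln <- makeAlignment(substr(ref, 11, 60), ref, pos = 10L)
  prof <- misincorporationProfile(aln)
  expect_identical(sum(prof@counts), 0L)
  expect_gt(sum(prof@opportunities), 0)
})

test_that("a single 5' C-read-as-T gives frequency 1 with opportunity 1", {
  ref <- paste0("C", strrep("A", 49))
  readSeq <- paste0("T", strrep("A", 49))
  aln <- makeAlignment(readSeq, ref, pos = 0L)
  prof <- misincorporationProfile(aln)
  expect_identical(prof@counts["5p", 1, "C>T"], 1L)
  expect_identical(prof@opportunities["5p", 1, "C"], 1L)
  expect_equal(unname(substitutionFrequency(prof, "5p", "C>T")[1]), 1.0)
})

test_that("position-wise C>T recovery stays inside the 99% binomial envelope", {
  mix <- toyMixture(1, genomeLength = 30000)
  sim <- simulateMetagenome(
    mix, dmg = damageModel(0.2, 0.6, 0.01),
    cfg = simConfig(seed = 5, nReads = 5000, errorRate = 0))
  prof <- misincorporationProfile(sim$alignments)
  model <- damageRate(damageModel(0.2, 0.6, 0.01), 1:10)
  for (i in 1:10) {
    n <- prof@opportunities["5p", i, "C"]
    x <- prof@counts["5p", i, "C>T"]
    ci <- binom.test(x, n, conf.level = 0.99)$conf.int
    expect_gte(model[i], ci[1])
    expect_lte(model[i], ci[2])
  }
})

test_that("MD-tag and reference-FASTA reconstruction agree", {
  mix <- toyMixture(1, genomeLength = 8000)
  sim <- simulateMetagenome(mix, cfg = simConfig(seed = 23, nReads = 300))
  viaMd <- misincorporationProfile(sim$alignments)
  noMd <- sim$alignments
  noMd$md <- NA_character_
  viaRef <- misincorporationProfile(noMd, reference = mix[[1]]$sequences)
  expect_identical(viaMd@counts, viaRef@counts)
  expect_identical(viaMd@opportunities, viaRef@opportunities)
  # with neither MD nor reference the records are skipped, tallied
  skipped <- misincorporationProfile(noMd)
  expect_identical(skipped@nSkipped, nrow(noMd))
  expect_identical(sum(skipped@counts), 0L)
})

test_that("profiles are additive and invariant to reference strand flips", {
  mix <- toyMixture(1, genomeLength = 8000)
  sim <- simulateMetagenome(mix, cfg = simConfig(seed = 29, nReads = 200))
  a <- sim$alignments[1:100, ]; b <- sim$alignments[101:200, ]
  whole <- misincorporationProfile(sim$alignments)
  parts <- misincorporationProfile(a) + misincorporationProfile(b)
  expect_identical(whole@counts, parts@counts)
  expect_identical(whole@opportunities, parts@opportunities)
  # flip the reference: revcomp genome, mirror positions, toggle strands
  ref <- mix[[1]]$sequences
  L <- nchar(as.character(ref[[1]]))
  flippedRef <- Biostrings::reverseComplement(ref)
  aln <- sim$alignments
  aln$md <- NA_character_
  flipped <- aln
  flipped$strand <- ifelse(aln$strand == "+", "-", "+")
  readLen <- nchar(aln$seq)
  flipped$pos <- L - (aln$pos + readLen)
  flipped$seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(aln$seq)))
  p1 <- misincorporationProfile(aln, reference = ref)
  p2 <- misincorporationProfile(flipped, reference = flippedRef)
  expect_identical(p1@counts, p2@counts)
  expect_identical(p1@opportunities, p2@opportunities)
})

test_that("terminal damage is the opportunity-weighted mean with a >100-read gate", {
  prof <- sedsift:::emptyDamageProfile(30)
  # equal opportunities, frequency 0.12 in all six contributing cells
  prof@opportunities["5p", 1:3, "C"] <- 100L
  prof@opportunities["3p", 1:3, "G"] <- 100L
  prof@counts["5p", 1:3, "C>T"] <- 12L
  prof@counts["3p", 1:3, "G>A"] <- 12L
  prof@nReads <- 100L
  td <- terminalDamage(prof, 3)
  expect_equal(damageAverage(td), 0.12)
  expect_false(gatePassed(td))         # exactly 100 reads: gate needs more
  prof@nReads <- 101L
  expect_true(gatePassed(terminalDamage(prof, 3)))
  # unequal opportunities weight the mean
  prof@opportunities["5p", 1, "C"] <- 900L
  prof@counts["5p", 1, "C>T"] <- 90L
  td2 <- terminalDamage(prof, 3)
  expect_equal(damageAverage(td2), (90 + 12 * 5) / (900 + 100 * 5))
  # all-zero opportunities are flagged, not NaN
  expect_warning(td0 <- terminalDamage(sedsift:::emptyDamageProfile(30), 3),
                 "opportunities")
  expect_true(is.na(damageAverage(td0)))
})

test_that("contaminant-only read sets show only the background floor", {
  mix <- toyMixture(1, genomeLength = 20000)
  contam <- taxonSpec("modern", "Modernus toy", "Modernus", 1,
                      setNames(randomReference(20000, seed = 77), "m_chr"))
  sim <- simulateMetagenome(
    mix, dmg = damageModel(0.3, 0.6, 0.01),
    cfg = simConfig(seed = 41, nReads = 4000, errorRate = 0,
                    contaminationFraction = 0.5),
    contaminant = contam)
  contamIds <- sim$truth$read_id[sim$truth$is_contaminant]
  prof <- misincorporationProfile(
    sim$alignments[sim$alignments$read_id %in% contamIds, ])
  td <- terminalDamage(prof, 3)
  # zero model damage and zero error: contaminants are clean
  expect_equal(damageAverage(td), 0)
  endoProf <- misincorporationProfile(
    sim$alignments[!sim$alignments$read_id %in% contamIds, ])
  expect_gt(damageAverage(terminalDamage(endoProf, 3)), 0.1)
})

test_that("descriptive distributions are exact and match the fragment model", {
  one <- makeAlignment(strrep("A", 42), strrep("A", 100))
  d <- readDistributions(one)
  expect_identical(d$length$length, "42")
  expect_identical(d$length$Freq, 1L)
  gc <- readDistributions(makeAlignment("GGCC", strrep("G", 10)))$gc
  expect_equal(gc, 1.0)
  fm <- fragmentModel(logMean = log(55), logSd = 0.3, minLen = 30, maxLen = 150)
  mix <- toyMixture(1, genomeLength = 20000)
  sim <- simulateMetagenome(mix, frag = fm,
                            cfg = simConfig(seed = 3, nReads = 4000))
  lens <- sim$truth$end - sim$truth$start
  # clamped lognormal mean via large-sample oracle
  oracle <- withr::with_seed(1, {
    x <- pmin(pmax(round(rlnorm(2e5, fm$logMean, fm$logSd)), 30), 150)
    mean(x)
  })
  expect_lt(abs(mean(lens) - oracle), 3 * sd(lens) / sqrt(length(lens)))
})

test_that("Welch and ANOVA damage comparisons match closed-form oracles", {
  g <- list(a = c(0.1, 0.12, 0.11), b = c(0.1, 0.12, 0.11))
  same <- compareDamage(g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # hand-computed Welch t on a textbook pair
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6)
  y <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9, 22.1)
  w <- compareDamage(list(x = x, y = y))
  sx <- var(x) / length(x); sy <- var(y) / length(y)
  tManual <- (mean(x) - mean(y)) / sqrt(sx + sy)
  dfManual <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  expect_equal(w$statistic, tManual, tolerance = 1e-6)
  expect_equal(w$df, dfManual, tolerance = 1e-6)
  expect_equal(w$p_value, 2 * pt(-abs(tManual), dfManual), tolerance = 1e-6)
  # three groups: ANOVA with soil-style reference contrasts
  set.seed(2)
  groups <- list(soil = rnorm(10, 0.05, 0.02), gut = rnorm(10, 0.15, 0.02),
                 oral = rnorm(10, 0.12, 0.02))
  av <- compareDamage(groups, referenceGroup = "soil")
  expect_identical(av$test, "anova")
  expect_setequal(av$contrasts$group, c("gut", "oral"))
  fitOracle <- anova(lm(v ~ g, data.frame(
    v = unlist(groups), g = factor(rep(names(groups), each = 10)))))
  expect_equal(av$p_value, fitOracle$`Pr(>F)`[1], tolerance = 1e-12)
  expect_warning(compareDamage(list(a = 1, b = c(1, 2), c = c(2, 3))),
                 "fewer than 2")
})

test_that("deamination-curve power: gut vs soil separates in >=95% of seeds", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    gut <- rnorm(10, 0.15, 0.02)
    soil <- rnorm(10, 0.05, 0.02)
    compareDamage(list(gut = gut, soil = soil))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the damage model is recoverable by weighted least squares", {
  mix <- toyMixture(1, genomeLength = 40000)
  sim <- simulateMetagenome(
    mix, dmg = damageModel(0.2, 0.6, 0.01),
    cfg = simConfig(seed = 61, nReads = 20000, errorRate = 0))
  fit <- fitDamageModel(misincorporationProfile(sim$alignments))
  expect_lt(abs(fit$delta5 - 0.2) / 0.2, 0.10)
  expect_lt(abs(fit$decay - 0.6) / 0.6, 0.10)
})

test_that("indel-bearing CIGAR/MD records are reconstructed correctly", {
  # read ACGTTTACGA aligned with a 2-bp insertion (TT) and a 1-bp deletion
  # against reference ACGTACGCGA: cigar 4M2I3M1D3M is invalid for 10 bp; use
  # a precise small case instead: read = ACG TT ACG, ref = ACGACG + deleted A
  aln <- data.frame(read_id = "r1", ref_id = "c", pos = 0L, strand = "+",
                    cigar = "3M2I3M1D2M", mapq = 60L, nm = 3L,
                    md = "6^A2", seq = "ACGTTACGGT",
                    stringsAsFactors = FALSE)
  prof <- misincorporationProfile(aln, nPositions = 10)
  # aligned columns: ACG (match), ACG (match), GT (match after deletion);
  # insertions contribute nothing, the deletion advances the reference only
  expect_identical(sum(prof@counts), 0L)
  expect_identical(sum(prof@opportunities["5p", , ]), 8L)
})
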