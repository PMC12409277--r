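test_that("Ry classification reproduces the published decision bands", {
  expect_identical(rySex(1000, 1000)$call, "XY")   # the 1/1 male pattern
  expect_identical(rySex(1000, 0)$call, "XX")
  expect_identical(rySex(980, 20)$call, "undetermined")  # 0.016 < 0.02 < 0.077
  expect_error(rySex(0, 0), "positive")
  r <- rySex(980, 20)
  expect_equal(r$ry, 0.02)
  se <- sqrt(0.02 * 0.98 / 1000)
  expect_equal(r$ci95, c(0.02 - 1.96 * se, 0.02 + 1.96 * se))
})

test_that("Ry decision boundaries sit exactly at 0.016 and 0.077", {
  n <- 1e6
  callAt <- function(ry) rySex(n - round(ry * n), round(ry * n))$call
  # binary search the largest Ry still called female
  lo <- 0; hi <- 0.2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (rySex(n * (1 - mid), n * mid)$call == "XX") lo <- mid else hi <- mid
  }
  expect_equal(lo, 0.016, tolerance = 1e-9)
  # and the smallest Ry called male
  lo <- 0; hi <- 0.2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (rySex(n * (1 - mid), n * mid)$call == "XY") hi <- mid else lo <- mid
  }
  expect_equal(hi, 0.077, tolerance = 1e-9)
})

test_that("coverage-ratio sex calls follow the Y-over-X orientation", {
  expect_identical(coverageSex(0.5, 0.5)$call, "XY")  # ratio 1
  expect_identical(coverageSex(1.0, 0.0)$call, "XX")  # ratio 0
  expect_identical(coverageSex(1.0, 0.5)$call, "undetermined")
  expect_error(coverageSex(0, 0.5), "positive")
  # simulated XY read sets classify as XY across seeds
  calls <- vapply(1:20, function(s) {
    sx <- simulateSexReads("XY", 100000, seed = s)
    auto <- sum(sx$count[sx$role == "autosome"]) / (2 * 2e6)
    normX <- (sx$count[sx$role == "chrX"] / 1e6) / auto
    normY <- (sx$count[sx$role == "chrY"] / 1e6) / auto
    coverageSex(normX, normY)$call
  }, character(1))
  expect_true(all(calls == "XY"))
})

test_that("contamination is the pooled minority/(majority+minority) depth ratio", {
  clean <- data.frame(chrom = "MT", pos = 1:5, ref = "A",
                      A = c(50, 40, 60, 55, 45), C = 0, G = 0, T = 0, N = 0)
  est <- contaminationRatio(clean, data.frame(chrom = "MT", pos = 1:5))
  expect_equal(est$estimate, 0)
  one <- data.frame(chrom = "MT", pos = 1, ref = "A",
                    A = 199, C = 0, G = 1, T = 0, N = 0)
  expect_equal(contaminationRatio(one, data.frame(chrom = "MT", pos = 1))$estimate,
               0.005)
  # sites missing from the pileup are skipped and counted
  est2 <- contaminationRatio(one, data.frame(chrom = "MT", pos = c(1, 99)))
  expect_identical(est2$nSitesSkipped, 1L)
  expect_identical(est2$nSitesUsed, 1L)
  expect_error(contaminationRatio(one, one[0, c("chrom", "pos")]), "sites")
  # recovery on simulated truth
  geno <- data.frame(chrom = "MT", pos = seq_len(50) * 7, ref = "C",
                     endogenous = "C", contaminant = "A",
                     stringsAsFactors = FALSE)
  pu <- simulatePileup(geno, 100, contamination = 0.10, seed = 19)
  est3 <- contaminationRatio(pu$pileup, geno[, c("chrom", "pos")])
  expect_lt(abs(est3$estimate - 0.10), 0.02)
  expect_true(est3$ci95[1] <= 0.10 && 0.10 <= est3$ci95[2])
})

test_that("the heterozygosity screen counts only transversion-heterozygous sites", {
  mono <- data.frame(chrom = "MT", pos = 1:20, ref = "A",
                     A = 20, C = 0, G = 0, T = 0, N = 0)
  s1 <- hetScreen(mono)
  expect_identical(s1$nTransversionHet, 0L)
  expect_identical(s1$verdict, "single-individual-consistent")
  trv <- mono; trv$C[1] <- 10  # A/C split at site 1
  s2 <- hetScreen(trv)
  expect_identical(s2$nTransversionHet, 1L)
  expect_identical(s2$verdict, "multiple-or-contaminated")
  # C/T (and G/A) splits are excluded as deamination-type transitions
  trs <- data.frame(chrom = "MT", pos = 1:3, ref = "C",
                    A = c(0, 10, 0), C = c(10, 0, 0), G = c(0, 10, 0),
                    T = c(10, 0, 20), N = 0)
  s3 <- hetScreen(trs)
  expect_identical(s3$nTransversionHet, 0L)
  expect_identical(s3$nTransitionHet, 2L)
  expect_identical(s3$verdict, "single-individual-consistent")
  # depth and minor-fraction floors gate the evidence
  weak <- data.frame(chrom = "MT", pos = 1:2, ref = "A",
                     A = c(3, 96), C = c(1, 4), G = 0, T = 0, N = 0)
  s4 <- hetScreen(weak, minDepth = 5, minMinorFrac = 0.1)
  expect_identical(s4$nSitesConsidered, 1L)  # depth-4 site ignored
  expect_identical(s4$nTransversionHet, 0L)  # 4% minor < 10% floor
  expect_error(hetScreen(mono[0, ]), "empty")
})

test_that("consensus calling masks failures and recodes at exactly 1/9", {
  sites <- data.frame(pos = 1:4, ref = "A",
                      A = c(4, 18, 8, 50), C = c(0, 2, 2, 0),
                      G = 0, T = 0, N = 0)
  out <- consensusCall(sites)
  # depth 4 -> N; 18/2 (exactly 1/9) -> A; 8/2 (1/4) -> N; clean -> A
  expect_identical(out$consensus, c("N", "A", "N", "A"))
  expect_identical(out$nMaskedDepth, 1L)
  expect_identical(out$nMaskedHet, 1L)
  expect_identical(out$nEmitted + out$nMaskedDepth + out$nMaskedGQ +
                     out$nMaskedHet, out$nSites)
  # the recode boundary is exactly minority/majority = 1/9
  probe <- function(minor) {
    s <- data.frame(pos = 1, ref = "A", A = 9000, C = minor, G = 0, T = 0, N = 0)
    consensusCall(s)$consensus == "A"
  }
  expect_true(probe(1000))   # ratio exactly 1/9
  expect_false(probe(1001))  # just above
  # supplied genotype qualities gate sites
  gq <- data.frame(pos = 1:2, ref = "A", A = c(50, 50), C = 0, G = 0, T = 0,
                   N = 0, GQ = c(19, 20))
  outGq <- consensusCall(gq)
  expect_identical(outGq$consensus, c("N", "A"))
  expect_identical(outGq$nMaskedGQ, 1L)
})

test_that("rat-style evidence combines into the single-male verdict", {
  # haploid mitochondrial pileup with zero transversion heterozygosity
  mito <- data.frame(chrom = "MT", pos = 1:100, ref = "A",
                     A = rpois(100, 50) + 5, C = 0, G = 0, T = 0, N = 0)
  het <- hetScreen(mito)
  sx <- simulateSexReads("XY", 50000, seed = 3)
  ry <- rySex(sx$count[sx$role == "chrX"], sx$count[sx$role == "chrY"])
  expect_identical(het$verdict, "single-individual-consistent")
  expect_identical(ry$call, "XY")
})

test_that("contamination estimator is unbiased across simulation levels", {
  for (c0 in c(0.01, 0.05)) {
    geno <- data.frame(chrom = "MT", pos = seq_len(50), ref = "A",
                       endogenous = "A", contaminant = "G",
                       stringsAsFactors = FALSE)
    ests <- vapply(1:60, function(s) {
      pu <- simulatePileup(geno, 100, contamination = c0, seed = s)
      contaminationRatio(pu$pileup, geno[, c("chrom", "pos")])$estimate
    }, numeric(1))
    expect_lt(abs(mean(ests) - c0), 0.005)
  }
})
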