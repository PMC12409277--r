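#' Read-ratio genetic sex classification (Ry)
#'
#' The Ry statistic is the fraction of sex-chromosome-aligned reads
#' hitting the Y chromosome, \eqn{R_y = n_Y / (n_X + n_Y)}. The call is
#' made on the point estimate: strictly below the female threshold is XX,
#' strictly above the male threshold is XY, values in between are
#' undetermined. A normal-approximation 95\% CI is reported alongside.
#'
#' @param nX,nY aligned-read counts on X and Y.
#' @param femaleBelow Ry values strictly below this are called XX.
#' @param maleAbove Ry values strictly above this are called XY.
#' @return list of class \code{"SexResult"}: nX, nY, ry, ci95, call,
#'   method.
#' @examples
#' rySex(980, 20)$call   # "undetermined" (0.016 < 0.02 < 0.077)
#' rySex(1000, 1000)$call # "XY"
#' @export
rySex <- function(nX, nY, femaleBelow = 0.016, maleAbove = 0.077) {
  n <- nX + nY
  if (n <= 0) stop("nX + nY must be positive")
  ry <- nY / n
  se <- sqrt(ry * (1 - ry) / n)
  call <- if (ry < femaleBelow) "XX" else if (ry > maleAbove) "XY"
          else "undetermined"
  structure(list(nX = nX, nY = nY, ry = ry,
                 ci95 = c(ry - 1.96 * se, ry + 1.96 * se),
                 call = call, method = "read-ratio"),
            class = "SexResult")
}

#' Coverage-ratio genetic sex classification
#'
#' Uses autosome-normalized X and Y coverages. The ratio is oriented
#' Y-over-X: an XY individual has X and Y each at roughly half the
#' autosomal rate (ratio near 1), an XX individual has Y near 0.
#'
#' @param normX,normY X and Y coverages normalized by autosomal coverage;
#'   \code{normX} must be positive.
#' @param xxBelow ratios at or below this are called XX.
#' @param xyAbove ratios at or above this are called XY.
#' @return list of class \code{"SexResult"}: ratio, call, method.
#' @export
coverageSex <- function(normX, normY, xxBelow = 0.25, xyAbove = 0.75) {
  if (normX <= 0) stop("normX must be positive")
  r <- normY / normX
  call <- if (r >= xyAbove) "XY" else if (r <= xxBelow) "XX"
          else "undetermined"
  structure(list(ratio = r, call = call, method = "coverage-ratio"),
            class = "SexResult")
}

#' @export
print.SexResult <- function(x, ...) {
  if (x$method == "read-ratio") {
    cat(sprintf("Sex call: %s (Ry = %.4f, nX = %d, nY = %d)\n",
                x$call, x$ry, x$nX, x$nY))
  } else {
    cat(sprintf("Sex call: %s (Y/X coverage ratio = %.3f)\n", x$call, x$ratio))
  }
  invisible(x)
}

siteBaseCounts <- function(pileup) {
  as.matrix(pileup[, c("A", "C", "G", "T"), drop = FALSE])
}

#' Mitochondrial contamination from allele depths
#'
#' At manually annotated diagnostic sites of a haploid (mitochondrial)
#' genome, contamination is estimated as the ratio of minority to
#' (majority + minority) allele depth, pooled across sites. The pooled
#' estimate gets an exact binomial 95\% CI.
#'
#' @param pileup pileup data.frame (chrom, pos, ref, A, C, G, T, N).
#' @param sites data.frame with chrom and pos of the diagnostic sites.
#' @return list of class \code{"ContamEstimate"}: estimate (fraction),
#'   ci95, perSite data.frame, nSitesUsed, nSitesSkipped.
#' @export
contaminationRatio <- function(pileup, sites) {
  if (nrow(sites) == 0) stop("no diagnostic sites supplied")
  key <- paste(pileup$chrom, pileup$pos)
  want <- paste(sites$chrom, sites$pos)
  ix <- match(want, key)
  present <- !is.na(ix)
  cnt <- siteBaseCounts(pileup[ix[present], , drop = FALSE])
  depthOk <- rowSums(cnt) > 0
  cnt <- cnt[depthOk, , drop = FALSE]
  skipped <- sum(!present) + sum(!depthOk)
  if (nrow(cnt) == 0) stop("no diagnostic site has coverage in the pileup")
  sorted <- t(apply(cnt, 1, sort, decreasing = TRUE))
  major <- sorted[, 1]
  minor <- sorted[, 2]
  perSite <- data.frame(
    chrom = sites$chrom[present][depthOk], pos = sites$pos[present][depthOk],
    majority_depth = major, minority_depth = minor,
    minority_fraction = ifelse(major + minor > 0, minor / (major + minor), NA),
    stringsAsFactors = FALSE)
  pooledMinor <- sum(minor)
  pooledTot <- sum(major) + sum(minor)
  ci <- binom.test(pooledMinor, pooledTot)$conf.int
  structure(list(estimate = pooledMinor / pooledTot,
                 ci95 = as.numeric(ci), perSite = perSite,
                 nSitesUsed = nrow(perSite), nSitesSkipped = skipped),
            class = "ContamEstimate")
}

#' @export
print.ContamEstimate <- function(x, ...) {
  cat(sprintf("Contamination: %.3f%% (95%% CI %.3f-%.3f%%) from %d sites\n",
              100 * x$estimate, 100 * x$ci95[1], 100 * x$ci95[2],
              x$nSitesUsed))
  invisible(x)
}

TRANSITION_PAIRS <- list(c("C", "T"), c("G", "A"))

#' Heterozygosity screen for individual count on a haploid genome
#'
#' On a mitochondrial pileup, counts biallelic sites (depth >= minDepth,
#' both alleles above a minor-fraction floor) whose allele pair is a
#' transversion; transition pairs (C/T, G/A) are excluded as potential
#' post-mortem deamination artefacts. Zero transversion-heterozygous
#' sites is consistent with a single individual.
#'
#' @param pileup pileup data.frame over the haploid reference.
#' @param minDepth minimum site depth (inclusive).
#' @param minMinorFrac minimum minor-allele fraction for heterozygous
#'   evidence (guards against single sequencing errors).
#' @return list of class \code{"HetScreen"}: nSitesConsidered,
#'   nTransitionHet, nTransversionHet, hetRate, verdict.
#' @export
hetScreen <- function(pileup, minDepth = 5L, minMinorFrac = 0.1) {
  if (nrow(pileup) == 0) stop("empty pileup")
  cnt <- siteBaseCounts(pileup)
  depth <- rowSums(cnt)
  considered <- depth >= minDepth
  cntC <- cnt[considered, , drop = FALSE]
  depthC <- depth[considered]
  ord <- apply(cntC, 1, order, decreasing = TRUE)
  majorBase <- DNA_BASES4[ord[1, ]]
  minorBase <- DNA_BASES4[ord[2, ]]
  minorCount <- cntC[cbind(seq_len(nrow(cntC)), ord[2, ])]
  isHet <- minorCount / depthC >= minMinorFrac & minorCount > 0
  isTransition <- mapply(function(a, b) {
    any(vapply(TRANSITION_PAIRS, function(p) setequal(c(a, b), p), logical(1)))
  }, majorBase, minorBase)
  nTrv <- sum(isHet & !isTransition)
  nTrs <- sum(isHet & isTransition)
  structure(list(
    nSitesConsidered = sum(considered),
    nTransitionHet = nTrs,
    nTransversionHet = nTrv,
    hetRate = if (sum(considered) > 0) nTrv / sum(considered) else NA_real_,
    verdict = if (nTrv == 0) "single-individual-consistent"
              else "multiple-or-contaminated"),
    class = "HetScreen")
}

#' @export
print.HetScreen <- function(x, ...) {
  cat(sprintf(
    "HetScreen: %d sites, %d transversion-het (%d transition-het excluded) -> %s\n",
    x$nSitesConsidered, x$nTransversionHet, x$nTransitionHet, x$verdict))
  invisible(x)
}

# Symmetric-error genotype quality from allele depths: phred-scaled
# log-likelihood gap between "the majority allele is the true (haploid)
# allele" and "the minority allele is", under a fixed per-read error
# rate. Mixture evidence is judged separately by the allele-ratio rule;
# this model-based stand-in is used only when the caller supplies no
# genotype qualities.
gqFromDepths <- function(major, minor, errorRate = 0.01) {
  n <- major + minor
  llMaj <- dbinom(minor, n, errorRate, log = TRUE)
  llMin <- dbinom(major, n, errorRate, log = TRUE)
  pmax(pmin(round(10 * (llMaj - llMin) / log(10)), 99), 0)
}

#' Filtered consensus calling with N-masking
#'
#' Emits, per site, the majority allele when the site passes depth and
#' genotype-quality filters and is effectively homozygous: heterozygous
#' sites are recoded to the majority allele when the minority:majority
#' allele-depth proportion is at most \code{recodeRatio} (inclusive), and
#' masked to N otherwise. All filter failures become N and are tallied.
#'
#' @param sites data.frame with pos, ref, A, C, G, T and optionally
#'   \code{GQ}; when GQ is absent it is computed from the allele depths
#'   under a symmetric sequencing-error model (see Details in the
#'   vignette; this stand-in is model-based, not a caller's quality).
#' @param minDepth minimum depth (inclusive).
#' @param minGQ minimum genotype quality (inclusive).
#' @param recodeRatio maximum minority/majority depth proportion recoded
#'   as homozygous-majority.
#' @return list of class \code{"ConsensusResult"}: consensus (character
#'   vector of emitted bases, N where masked), sequence (collapsed
#'   string), and tallies nSites, nEmitted, nMaskedDepth, nMaskedGQ,
#'   nMaskedHet.
#' @export
consensusCall <- function(sites, minDepth = 5L, minGQ = 20,
                          recodeRatio = 1 / 9) {
  cnt <- siteBaseCounts(sites)
  depth <- rowSums(cnt)
  ord <- apply(cnt, 1, order, decreasing = TRUE)
  majorBase <- DNA_BASES4[ord[1, ]]
  major <- cnt[cbind(seq_len(nrow(cnt)), ord[1, ])]
  minor <- cnt[cbind(seq_len(nrow(cnt)), ord[2, ])]
  gq <- if (!is.null(sites$GQ)) sites$GQ else gqFromDepths(major, minor)
  failDepth <- depth < minDepth
  failGQ <- !failDepth & gq < minGQ
  ratio <- ifelse(major > 0, minor / major, Inf)
  failHet <- !failDepth & !failGQ & ratio > recodeRatio
  emit <- !(failDepth | failGQ | failHet)
  out <- ifelse(emit, majorBase, "N")
  structure(list(
    consensus = out,
    sequence = paste(out, collapse = ""),
    nSites = nrow(sites),
    nEmitted = sum(emit),
    nMaskedDepth = sum(failDepth),
    nMaskedGQ = sum(failGQ),
    nMaskedHet = sum(failHet)),
    class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf(
    "Consensus over %d sites: %d emitted, %d masked (depth %d, GQ %d, het %d)\n",
    x$nSites, x$nEmitted, x$nSites - x$nEmitted,
    x$nMaskedDepth, x$nMaskedGQ, x$nMaskedHet))
  invisible(x)
}
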