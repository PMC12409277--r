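#' Pseudohaploid calling from pileups at panel sites
#'
#' The standard low-coverage ancient-DNA genotyping: at each biallelic
#' panel site one covering read base is drawn uniformly at random
#' (seeded). A drawn base matching the panel reference allele codes 0,
#' the alternate codes 1; a base matching neither allele, or a site with
#' no coverage, is missing.
#'
#' @param pileup pileup data.frame (chrom, pos, ref, A, C, G, T, N).
#' @param panel data.frame of biallelic sites: chrom, pos, ref, alt.
#' @param seed RNG seed (recorded in the output attributes).
#' @return data.frame with chrom, pos, allele (drawn base or NA) and
#'   code (0 ref / 1 alt / NA).
#' @export
pseudohaploidCall <- function(pileup, panel, seed = 1L) {
  key <- paste(pileup$chrom, pileup$pos)
  ix <- match(paste(panel$chrom, panel$pos), key)
  bases <- c(DNA_BASES4, "N")
  cnt <- as.matrix(pileup[, bases, drop = FALSE])
  allele <- rep(NA_character_, nrow(panel))
  withSeed(seed, {
    for (i in seq_len(nrow(panel))) {
      j <- ix[i]
      if (is.na(j)) next
      depth <- sum(cnt[j, ])
      if (depth == 0) next
      draw <- sample.int(depth, 1)
      allele[i] <- bases[findInterval(draw - 1L, cumsum(cnt[j, ])) + 1L]
    }
  })
  code <- ifelse(is.na(allele), NA_integer_,
          ifelse(allele == panel$ref, 0L,
          ifelse(allele == panel$alt, 1L, NA_integer_)))
  allele[!is.na(allele) & allele != panel$ref & allele != panel$alt] <- NA
  out <- data.frame(chrom = panel$chrom, pos = panel$pos, allele = allele,
                    code = code, stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}

#' Post-imputation genotype filters
#'
#' Retains records whose reference-panel minor allele frequency and
#' maximum genotype probability both meet their (inclusive) thresholds.
#' Records with a missing GP are treated as failing and tallied
#' separately; removal counts per rule are attached as the
#' \code{"removed"} attribute.
#'
#' @param records genotype data.frame with \code{panel_maf} and \code{GP}
#'   columns.
#' @param minMaf minimum panel minor allele frequency (inclusive).
#' @param minGP minimum genotype probability (inclusive).
#' @return the retained records, with attribute \code{removed} (named
#'   counts: maf, gp, missing_gp).
#' @export
imputationFilter <- function(records, minMaf = 0.05, minGP = 0.98) {
  failMaf <- is.na(records$panel_maf) | records$panel_maf < minMaf
  missGp <- is.na(records$GP)
  failGp <- !failMaf & (missGp | records$GP < minGP)
  keep <- !failMaf & !failGp
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- c(maf = sum(failMaf),
                            gp = sum(failGp & !missGp),
                            missing_gp = sum(failGp & missGp))
  out
}

#' Hard-call genotype coding from expected dosage
#'
#' plink-style dosage hard call: the code is the nearest integer in
#' {0, 1, 2} when the dosage lies within \code{threshold} of it
#' (inclusive), otherwise missing.
#'
#' @param ds expected alternate-allele dosage in [0, 2].
#' @param threshold maximum distance to the nearest integer.
#' @return integer vector of codes (NA = missing).
#' @examples
#' dosageCode(c(0.1, 1.05, 1.45)) # 0, 1, NA
#' @export
dosageCode <- function(ds, threshold = 0.1) {
  if (any(!is.na(ds) & (ds < 0 | ds > 2))) {
    stop("dosage outside [0, 2]")
  }
  nearest <- round(ds)
  ifelse(is.na(ds) | abs(ds - nearest) > threshold, NA_integer_,
         as.integer(nearest))
}

#' Genotype concordance over a phenotype-marker panel
#'
#' Compares two samples' hard-called genotype codes over the same marker
#' panel. Discordant markers have differing non-missing codes; by
#' default, pairs with any missing code are excluded from both numerator
#' and denominator (set \code{includeMissing} to count them as
#' discordant).
#'
#' @param codesA,codesB integer code vectors over the same markers (same
#'   length and order; names, when present, must agree).
#' @param includeMissing count called-vs-missing pairs as discordant.
#' @return list of class \code{"ConcordanceResult"}: nMarkers,
#'   nDiscordant, pctConcordant, perMarker data.frame.
#' @examples
#' a <- rep(0L, 109); b <- a; b[1:29] <- 1L
#' phenotypeConcordance(a, b)$pctConcordant  # ~73.4
#' @export
phenotypeConcordance <- function(codesA, codesB, includeMissing = FALSE) {
  if (length(codesA) != length(codesB)) stop("marker panels differ in length")
  if (!is.null(names(codesA)) && !is.null(names(codesB)) &&
      !identical(names(codesA), names(codesB))) {
    if (!length(intersect(names(codesA), names(codesB)))) {
      stop("marker panels are disjoint")
    }
    common <- intersect(names(codesA), names(codesB))
    codesA <- codesA[common]; codesB <- codesB[common]
  }
  bothCalled <- !is.na(codesA) & !is.na(codesB)
  anyMissing <- !bothCalled
  if (includeMissing) {
    used <- rep(TRUE, length(codesA))
    disc <- (bothCalled & codesA != codesB) | (anyMissing & (is.na(codesA) != is.na(codesB)))
  } else {
    used <- bothCalled
    disc <- bothCalled & codesA != codesB
  }
  n <- sum(used)
  nd <- sum(disc[used])
  perMarker <- data.frame(
    marker = names(codesA) %||% seq_along(codesA),
    codeA = codesA, codeB = codesB, used = used,
    discordant = disc, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(nMarkers = n, nDiscordant = nd,
                 pctConcordant = if (n > 0) 100 * (n - nd) / n else NA_real_,
                 perMarker = perMarker),
            class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("Concordance: %.1f%% (%d of %d markers discordant)\n",
              x$pctConcordant, x$nDiscordant, x$nMarkers))
  invisible(x)
}

#' Pairwise mismatch rate of pseudohaploid calls (P0)
#'
#' The raw same-individual / relatedness statistic: the fraction of
#' jointly called panel sites at which two samples' pseudohaploid
#' alleles differ. Optionally normalized by an expected-unrelated
#' baseline.
#'
#' @param callsA,callsB pseudohaploid call data.frames (see
#'   \code{\link{pseudohaploidCall}}) over the same panel, or plain
#'   allele/code vectors.
#' @param baseline optional expected mismatch rate between unrelated
#'   individuals; when given, \code{normalized = p0 / baseline} is
#'   reported.
#' @return list of class \code{"P0Result"}: nOverlap, p0, normalized,
#'   lowConfidence (TRUE when overlap < 100 sites).
#' @export
p0Mismatch <- function(callsA, callsB, baseline = NULL) {
  a <- if (is.data.frame(callsA)) callsA$code else callsA
  b <- if (is.data.frame(callsB)) callsB$code else callsB
  if (length(a) != length(b)) stop("call vectors differ in length")
  both <- !is.na(a) & !is.na(b)
  n <- sum(both)
  p0 <- if (n > 0) mean(a[both] != b[both]) else NA_real_
  structure(list(nOverlap = n, p0 = p0,
                 normalized = if (!is.null(baseline)) p0 / baseline else NA_real_,
                 lowConfidence = n < 100),
            class = "P0Result")
}

#' @export
print.P0Result <- function(x, ...) {
  cat(sprintf("P0 = %.4f over %d shared sites%s\n", x$p0, x$nOverlap,
              if (x$lowConfidence) " (low confidence: < 100 sites)" else ""))
  invisible(x)
}
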