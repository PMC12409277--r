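# Reconstructing reference bases under an alignment and tallying
# position-wise misincorporations in read orientation.

# Expand one CIGAR string into per-op (op, len) vectors.
parseCigar <- function(cigar) {
  runs <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", runs)),
       op = sub("^\\d+", "", runs))
}

# Tokenise an MD tag into match-lengths, mismatch bases and deletions.
parseMd <- function(md) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Z]+|[A-Z]", md))[[1]]
  toks[toks != ""]
}

# Given one SAM record (reference-oriented seq, cigar, MD), return the
# aligned (read, reference) base pair strings: equal length, insertions
# and clipped bases excluded, deletions advancing the reference only.
alignedPairs <- function(seq, cigar, md) {
  cg <- parseCigar(cigar)
  chars <- strsplit(seq, NULL)[[1]]
  readAln <- character(0)
  qpos <- 1L
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; L <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      readAln <- c(readAln, chars[qpos:(qpos + L - 1L)])
      qpos <- qpos + L
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + L
    }
    # D/N/H/P consume no read bases
  }
  refAln <- readAln
  toks <- parseMd(md)
  rpos <- 1L
  for (t in toks) {
    if (grepl("^\\d+$", t)) {
      rpos <- rpos + as.integer(t)
    } else if (startsWith(t, "^")) {
      # deleted reference bases: not present in the read-aligned columns
    } else {
      refAln[rpos] <- t
      rpos <- rpos + 1L
    }
  }
  list(read = readAln, ref = refAln)
}

#' Position-wise misincorporation profile
#'
#' Tallies, in read orientation, all 12 substitution types and the
#' reference-base opportunities at the first \code{nPositions} positions
#' from each fragment end. Minus-strand alignments are
#' reverse-complemented into read orientation before counting. Reference
#' bases are reconstructed from MD tags when present, otherwise sliced
#' from a supplied reference; alignments offering neither are skipped and
#' tallied in \code{nSkipped}.
#'
#' The terminal C-to-T (5') and G-to-A (3') cells of this profile are the
#' classical ancient-DNA deamination signal.
#'
#' @param alignments alignment data.frame (see \code{\link{readSam}}).
#' @param nPositions positions to profile from each end.
#' @param reference optional named \code{DNAStringSet} used when MD tags
#'   are absent.
#' @return a \code{\link{DamageProfile-class}} object.
#' @export
misincorporationProfile <- function(alignments, nPositions = 30L,
                                    reference = NULL) {
  prof <- emptyDamageProfile(nPositions)
  n <- nrow(alignments)
  if (n == 0) return(prof)
  hasMd <- !is.na(alignments$md) & alignments$md != ""
  refSeqOk <- !is.null(reference) & alignments$ref_id %in% names(reference %||% character())
  usable <- hasMd | refSeqOk
  skipped <- sum(!usable)
  aln <- alignments[usable, , drop = FALSE]

  readStr <- character(nrow(aln))
  refStr <- character(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    if (!is.na(aln$md[i]) && aln$md[i] != "") {
      pr <- alignedPairs(aln$seq[i], aln$cigar[i], aln$md[i])
      readStr[i] <- paste(pr$read, collapse = "")
      refStr[i] <- paste(pr$ref, collapse = "")
    } else {
      cg <- parseCigar(aln$cigar[i])
      refLen <- sum(cg$len[cg$op %in% c("M", "=", "X", "D", "N")])
      refSlice <- as.character(Biostrings::subseq(
        reference[[aln$ref_id[i]]], start = aln$pos[i] + 1L, width = refLen))
      pr <- alignedPairsFromRef(aln$seq[i], aln$cigar[i], refSlice)
      readStr[i] <- pr$read
      refStr[i] <- pr$ref
    }
  }
  # rotate minus-strand alignments into read orientation
  minus <- aln$strand == "-"
  if (any(minus)) {
    readStr[minus] <- revComp(readStr[minus])
    refStr[minus] <- revComp(refStr[minus])
  }
  lens <- nchar(readStr)
  readCh <- unlist(strsplit(readStr, NULL), use.names = FALSE)
  refCh <- unlist(strsplit(refStr, NULL), use.names = FALSE)
  pos5 <- sequence(lens)
  pos3 <- unlist(lapply(lens, function(L) rev(seq_len(L))), use.names = FALSE)

  valid <- readCh %in% DNA_BASES4 & refCh %in% DNA_BASES4
  subLab <- ifelse(readCh != refCh, paste0(refCh, ">", readCh), NA)
  for (endIx in 1:2) {
    pos <- if (endIx == 1) pos5 else pos3
    inRange <- valid & pos <= nPositions
    opp <- table(factor(pos[inRange], levels = seq_len(nPositions)),
                 factor(refCh[inRange], levels = DNA_BASES4))
    prof@opportunities[endIx, , ] <- prof@opportunities[endIx, , ] +
      as.integer(opp)
    mism <- inRange & !is.na(subLab)
    if (any(mism)) {
      cnt <- table(factor(pos[mism], levels = seq_len(nPositions)),
                   factor(subLab[mism], levels = SUBSTITUTIONS))
      prof@counts[endIx, , ] <- prof@counts[endIx, , ] + as.integer(cnt)
    }
  }
  prof@nReads <- nrow(aln)
  prof@nSkipped <- as.integer(skipped)
  validObject(prof)
  prof
}

# Reference reconstruction without an MD tag: walk the CIGAR over a
# reference slice.
alignedPairsFromRef <- function(seq, cigar, refSlice) {
  cg <- parseCigar(cigar)
  q <- strsplit(seq, NULL)[[1]]
  r <- strsplit(refSlice, NULL)[[1]]
  readAln <- character(0); refAln <- character(0)
  qpos <- 1L; rpos <- 1L
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; L <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      readAln <- c(readAln, q[qpos:(qpos + L - 1L)])
      refAln <- c(refAln, r[rpos:(rpos + L - 1L)])
      qpos <- qpos + L; rpos <- rpos + L
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + L
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + L
    }
  }
  list(read = paste(readAln, collapse = ""), ref = paste(refAln, collapse = ""))
}

#' Terminal damage summary
#'
#' Opportunity-weighted mean deamination over the outermost \code{k}
#' positions of both ends: the 5' C-to-T and 3' G-to-A cells. The
#' estimate is gated on read support: with \code{nReads <= minReads} the
#' summary is flagged as below the gate.
#'
#' @param profile a \code{\link{DamageProfile-class}}.
#' @param k number of terminal positions to average (commonly 3 or 5).
#' @param minReads gate: more reads than this are required for
#'   \code{gatePassed}.
#' @return a \code{\link{DamageSummary-class}} object.
#' @export
terminalDamage <- function(profile, k = 3L, minReads = 100L) {
  np <- dim(profile@counts)[2]
  stopifnot(k >= 1, k <= np)
  ix <- seq_len(k)
  subs <- sum(profile@counts["5p", ix, "C>T"]) +
    sum(profile@counts["3p", ix, "G>A"])
  opp <- sum(profile@opportunities["5p", ix, "C"]) +
    sum(profile@opportunities["3p", ix, "G"])
  if (opp == 0) {
    warning("no deamination opportunities in the first ", k, " positions")
    avg <- NA_real_
  } else {
    avg <- subs / opp
  }
  new("DamageSummary", average = avg, k = as.integer(k),
      nReads = profile@nReads,
      gatePassed = profile@nReads > minReads,
      substitutions = as.numeric(subs), opportunities = as.numeric(opp))
}

#' Read-set descriptive distributions
#'
#' Exact histograms of aligned read length and edit distance, and the
#' per-read GC content (Ns excluded from the denominator).
#'
#' @param alignments alignment data.frame; \code{seq} and \code{nm} are
#'   used.
#' @return list with \code{length} and \code{edit_distance} count tables
#'   and a numeric \code{gc} vector.
#' @export
readDistributions <- function(alignments) {
  lens <- nchar(alignments$seq)
  freq <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(alignments$seq), baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- ifelse(acgt > 0,
               rowSums(freq[, c("C", "G"), drop = FALSE]) / acgt, NA_real_)
  list(
    length = as.data.frame(table(length = lens), stringsAsFactors = FALSE),
    edit_distance = as.data.frame(table(nm = alignments$nm),
                                  stringsAsFactors = FALSE),
    gc = gc)
}

#' Compare damage levels between groups
#'
#' With two groups, Welch's unequal-variance t-test; with more, a one-way
#' ANOVA plus per-group contrasts against a designated reference group
#' (each contrast a coefficient t-test in the reference-releveled linear
#' model). Groups with fewer than two values are excluded with a
#' warning (no variance estimate).
#'
#' @param groups named list of numeric damage values (e.g. per-species
#'   terminal damage, grouped by inferred source).
#' @param referenceGroup reference level for the ANOVA contrasts;
#'   defaults to the first group.
#' @return list with \code{test} ("welch" or "anova"), \code{statistic},
#'   \code{df}, \code{p_value} and, for ANOVA, a \code{contrasts}
#'   data.frame (group, estimate, p_value vs reference).
#' @export
compareDamage <- function(groups, referenceGroup = NULL) {
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) {
    warning("excluding group(s) with fewer than 2 values: ",
            paste(names(groups)[sizes < 2], collapse = ", "))
    groups <- groups[sizes >= 2]
  }
  if (length(groups) < 2) stop("need at least two groups with >= 2 values")
  if (length(groups) == 2) {
    ht <- t.test(groups[[1]], groups[[2]], var.equal = FALSE)
    return(list(test = "welch", statistic = unname(ht$statistic),
                df = unname(ht$parameter), p_value = ht$p.value))
  }
  referenceGroup <- referenceGroup %||% names(groups)[1]
  stopifnot(referenceGroup %in% names(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  df$group <- stats::relevel(df$group, ref = referenceGroup)
  fit <- lm(value ~ group, data = df)
  an <- anova(fit)
  cf <- summary(fit)$coefficients
  rows <- grepl("^group", rownames(cf))
  contrasts <- data.frame(group = sub("^group", "", rownames(cf)[rows]),
                          estimate = cf[rows, "Estimate"],
                          p_value = cf[rows, "Pr(>|t|)"],
                          row.names = NULL, stringsAsFactors = FALSE)
  list(test = "anova", statistic = an$`F value`[1], df = an$Df[1:2],
       p_value = an$`Pr(>F)`[1], reference = referenceGroup,
       contrasts = contrasts)
}

#' Recover deamination-model parameters from a profile
#'
#' Weighted least squares fit of the geometric decay model
#' \eqn{rate_i = f + (\delta_5 - f)\lambda^{i-1}} to the 5' C-to-T
#' frequencies (weights = opportunity counts) over the given positions.
#'
#' @param profile a \code{\link{DamageProfile-class}}.
#' @param positions positions used in the fit.
#' @return list with delta5, decay and deltaBase estimates.
#' @export
fitDamageModel <- function(profile, positions = 1:10) {
  freq <- substitutionFrequency(profile, "5p", "C>T")[positions]
  w <- profile@opportunities["5p", positions, "C"]
  ok <- is.finite(freq) & w > 0
  if (sum(ok) < 3) stop("not enough informative positions to fit")
  d <- data.frame(i = positions[ok], f = freq[ok], w = w[ok])
  floor0 <- max(min(d$f) * 0.5, 1e-4)
  amp0 <- max(d$f[1] - floor0, 1e-3)
  fit <- nls(f ~ fl + (d5 - fl) * dec^(i - 1), data = d,
             start = list(fl = floor0, d5 = amp0 + floor0, dec = 0.5),
             weights = d$w,
             lower = c(0, 1e-6, 1e-6), upper = c(1, 1, 1),
             algorithm = "port")
  est <- coef(fit)
  list(delta5 = unname(est["d5"]), decay = unname(est["dec"]),
       deltaBase = unname(est["fl"]))
}
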