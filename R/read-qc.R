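#' QC parameter set
#'
#' Defaults follow common ancient-DNA screening practice: discard reads
#' shorter than 30 bp or with mean phred below 20, remove low-complexity
#' reads with a DUST score above 7, then collapse exact duplicates.
#'
#' @param minLen minimum read length in bp.
#' @param minMeanQ minimum mean phred quality.
#' @param dustThreshold maximum DUST score (reads scoring above are removed).
#' @param dedup collapse exact duplicate sequences after filtering.
#' @return a list of class \code{"QCParams"}.
#' @export
qcParams <- function(minLen = 30L, minMeanQ = 20, dustThreshold = 7,
                     dedup = TRUE) {
  stopifnot(minLen >= 1, dustThreshold >= 0, dustThreshold <= 100)
  structure(list(minLen = as.integer(minLen), minMeanQ = minMeanQ,
                 dustThreshold = dustThreshold, dedup = isTRUE(dedup)),
            class = "QCParams")
}

#' DUST low-complexity score
#'
#' Windowed overlapping-triplet statistic: for each 64-bp window (step 32,
#' or the whole read if shorter, with a final window covering the tail),
#' \deqn{score_w = 100 \sum_t c_t (c_t - 1) / 2 \,/\, ((w-3)(w-2)/2)}
#' over triplet counts \eqn{c_t}; the read score is the maximum over
#' windows. A homopolymer scores 100; a read whose triplets are all
#' distinct scores 0.
#'
#' @param seq character vector or \code{DNAStringSet} of read sequences
#'   (length >= 3 each).
#' @param window,step window size and step in bp.
#' @return numeric vector of scores in [0, 100].
#' @examples
#' dustScore(strrep("A", 64))    # 100
#' dustScore(strrep("ACGT", 16)) # periodic repeat, well above 7
#' @export
dustScore <- function(seq, window = 64L, step = 32L) {
  if (!is.character(seq)) seq <- as.character(seq)
  lens <- nchar(seq)
  if (any(lens < 3)) stop("dustScore requires sequences of length >= 3")
  # window starts per read (1-based), always covering the tail
  winOf <- lapply(seq_along(seq), function(i) {
    L <- lens[i]
    if (L <= window) return(data.frame(read = i, start = 1L, w = L))
    starts <- seq(1L, L - window + 1L, by = step)
    if (starts[length(starts)] + window - 1L < L) {
      starts <- c(starts, L - window + 1L)
    }
    data.frame(read = i, start = starts, w = window)
  })
  wins <- do.call(rbind, winOf)
  sub <- substring(seq[wins$read], wins$start, wins$start + wins$w - 1L)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(sub), 3L)
  num <- rowSums(counts * (counts - 1) / 2)
  den <- (wins$w - 3) * (wins$w - 2) / 2
  score <- 100 * num / den
  as.numeric(tapply(score, wins$read, max))
}

#' Filter reads by length, mean quality and complexity
#'
#' Filters are applied in a fixed order (length, then mean quality, then
#' DUST, then optional deduplication) and each removal is attributed to
#' the first violated filter, so the report counts reconcile exactly.
#'
#' @param reads a \code{QualityScaledDNAStringSet} (see
#'   \code{\link{readFastq}}).
#' @param params a \code{\link{qcParams}} object.
#' @return list with \code{reads} (the kept set) and \code{report}
#'   (data.frame of input / per-filter removed / kept counts, class
#'   \code{"QCReport"}).
#' @export
qcFilter <- function(reads, params = qcParams()) {
  n <- length(reads)
  if (n == 0) {
    rep0 <- data.frame(input = 0L, removed_length = 0L, removed_quality = 0L,
                       removed_dust = 0L, removed_duplicate = 0L, kept = 0L)
    class(rep0) <- c("QCReport", "data.frame")
    return(list(reads = reads, report = rep0))
  }
  df <- readsToFrame(reads)
  lens <- nchar(df$seq)
  mq <- meanPhred(df$qual)
  failLen <- lens < params$minLen
  failQ <- !failLen & mq < params$minMeanQ
  # DUST needs length >= 3; anything shorter already failed the length filter
  evalDust <- !failLen & !failQ
  failDust <- rep(FALSE, n)
  if (any(evalDust)) {
    failDust[evalDust] <- dustScore(df$seq[evalDust]) > params$dustThreshold
  }
  keep <- !failLen & !failQ & !failDust
  kept <- df[keep, , drop = FALSE]
  removedDup <- 0L
  if (params$dedup && nrow(kept) > 0) {
    before <- nrow(kept)
    kept <- dedupFrame(kept)
    removedDup <- before - nrow(kept)
  }
  report <- data.frame(
    input = n,
    removed_length = sum(failLen),
    removed_quality = sum(failQ),
    removed_dust = sum(failDust),
    removed_duplicate = removedDup,
    kept = nrow(kept))
  class(report) <- c("QCReport", "data.frame")
  list(reads = frameToReads(kept), report = report)
}

# Deduplicate on exact sequence; the representative is the record with the
# highest mean quality, ties broken by first occurrence.
dedupFrame <- function(df) {
  mq <- meanPhred(df$qual)
  ord <- order(df$seq, -mq, seq_len(nrow(df)))
  sorted <- df[ord, , drop = FALSE]
  first <- !duplicated(sorted$seq)
  out <- sorted[first, , drop = FALSE]
  # restore input order of the surviving records
  out[order(match(out$read_id, df$read_id)), , drop = FALSE]
}

#' Collapse exact duplicate reads
#'
#' One record survives per distinct sequence string; the representative
#' is the copy with the highest mean quality (ties: first occurrence).
#'
#' @param reads a \code{QualityScaledDNAStringSet}.
#' @return the deduplicated \code{QualityScaledDNAStringSet}.
#' @export
dedupReads <- function(reads) {
  if (length(reads) == 0) return(reads)
  frameToReads(dedupFrame(readsToFrame(reads)))
}
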