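#' Competitively assign reads to their best-matching reference
#'
#' Among a read's alignments against several candidate references, the
#' winner is the alignment with minimal edit distance (NM); ties on NM are
#' broken by maximal mapping quality; reads still tied are left
#' unassigned (authentication favours specificity over yield). Winners
#' below the mapping-quality floor are unassigned with reason
#' \code{below_mapq}; reads in \code{readIds} lacking any alignment get
#' \code{no_hit}.
#'
#' @param alignments alignment data.frame (see \code{\link{readSam}});
#'   one row per (read, reference) pair.
#' @param minMapq minimum mapping quality of the winning alignment
#'   (inclusive).
#' @param readIds optional full read-id universe, to report \code{no_hit}
#'   reads.
#' @return data.frame with read_id, ref_id (NA when unassigned) and
#'   reason in \code{assigned / tie / below_mapq / no_hit}; every input
#'   read appears exactly once.
#' @export
assignReads <- function(alignments, minMapq = 30, readIds = NULL) {
  key <- paste(alignments$read_id, alignments$ref_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (read, reference) alignment pairs; deduplicate first")
  }
  ord <- order(alignments$read_id, alignments$nm, -alignments$mapq)
  a <- alignments[ord, , drop = FALSE]
  firstOfRead <- !duplicated(a$read_id)
  best <- a[firstOfRead, , drop = FALSE]
  # a read is tied when its second-ranked alignment matches the best on
  # both nm and mapq
  nxt <- which(firstOfRead) + 1L
  hasNext <- nxt <= nrow(a) & !firstOfRead[pmin(nxt, nrow(a))]
  tied <- rep(FALSE, nrow(best))
  hn <- which(hasNext)
  tied[hn] <- a$nm[nxt[hn]] == best$nm[hn] & a$mapq[nxt[hn]] == best$mapq[hn]
  reason <- ifelse(tied, "tie",
            ifelse(best$mapq < minMapq, "below_mapq", "assigned"))
  out <- data.frame(read_id = best$read_id,
                    ref_id = ifelse(reason == "assigned", best$ref_id, NA),
                    reason = reason, stringsAsFactors = FALSE)
  if (!is.null(readIds)) {
    miss <- setdiff(readIds, out$read_id)
    if (length(miss)) {
      out <- rbind(out, data.frame(read_id = miss, ref_id = NA,
                                   reason = "no_hit", stringsAsFactors = FALSE))
    }
    out <- out[match(readIds, out$read_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

cigarAlignedBases <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, ops), function(runs) {
    n <- as.integer(sub("[A-Z=]$", "", runs))
    op <- sub("^\\d+", "", runs)
    sum(n[op %in% c("M", "=", "X")])
  }, numeric(1))
}

#' Per-taxon mapping statistics
#'
#' The authentication summary for one candidate reference: number of
#' assigned reads, mean edit distance, mean depth of coverage (aligned
#' bases over genome length) and, when a damage summary is supplied, the
#' average terminal deamination.
#'
#' @param assignment output of \code{\link{assignReads}}.
#' @param alignments the alignment records the assignment was computed
#'   from.
#' @param refId reference to summarise.
#' @param genomeLength reference genome length in bp (> 0).
#' @param damageSummary optional \code{\link{DamageSummary-class}} object
#'   (or a plain frequency) for the assigned reads.
#' @return one-row data.frame: ref_id, mapped_reads, av_damage_last3,
#'   av_edit_distance, average_coverage. With zero assigned reads the
#'   statistics are NA (flagged, never NaN-propagated).
#' @export
taxonStats <- function(assignment, alignments, refId, genomeLength,
                       damageSummary = NULL) {
  if (is.null(genomeLength) || genomeLength <= 0) {
    stop("genomeLength must be positive")
  }
  ids <- assignment$read_id[assignment$reason == "assigned" &
                              assignment$ref_id == refId]
  aln <- alignments[alignments$read_id %in% ids &
                      alignments$ref_id == refId, , drop = FALSE]
  dmg <- if (is.null(damageSummary)) NA_real_
         else if (is(damageSummary, "DamageSummary")) damageAverage(damageSummary)
         else as.numeric(damageSummary)
  if (nrow(aln) == 0) {
    return(data.frame(ref_id = refId, mapped_reads = 0L,
                      av_damage_last3 = NA_real_,
                      av_edit_distance = NA_real_,
                      average_coverage = NA_real_,
                      stringsAsFactors = FALSE))
  }
  data.frame(ref_id = refId,
             mapped_reads = nrow(aln),
             av_damage_last3 = dmg,
             av_edit_distance = mean(aln$nm),
             average_coverage = sum(cigarAlignedBases(aln$cigar)) / genomeLength,
             stringsAsFactors = FALSE)
}

#' Score simulated reads against several candidate references
#'
#' Builds the competitive alignment set for simulator output: every read
#' is placed at its truth coordinates on each homologous reference (the
#' references share a coordinate system) and the edit distance is the
#' mismatch count between the fragment-oriented read and that reference's
#' bases.
#'
#' @param truth truth table from \code{\link{simulateMetagenome}}.
#' @param reads the simulated reads.
#' @param references named list of \code{DNAStringSet}s, one per candidate
#'   reference genome; each must contain the sequences named in the truth.
#' @param mapq mapping quality attached to every record.
#' @return alignment data.frame suitable for \code{\link{assignReads}},
#'   with \code{ref_id} set to the reference genome name.
#' @export
competitiveAlignments <- function(truth, reads, references, mapq = 37L) {
  stopifnot(length(references) >= 2, !is.null(names(references)))
  readSeq <- as.character(reads)[truth$read_id]
  samSeq <- ifelse(truth$strand == "-", revComp(readSeq), readSeq)
  samChars <- strsplit(samSeq, NULL)
  out <- lapply(names(references), function(rn) {
    ref <- references[[rn]]
    if (!all(truth$seq_id %in% names(ref))) {
      stop("reference ", rn, " lacks sequences named in the truth table")
    }
    slice <- as.character(Biostrings::subseq(ref[truth$seq_id],
                                             start = truth$start + 1L,
                                             width = truth$end - truth$start))
    refChars <- strsplit(slice, NULL)
    nm <- mapply(function(a, b) sum(a != b), samChars, refChars)
    data.frame(read_id = truth$read_id, ref_id = rn, pos = truth$start,
               strand = truth$strand,
               cigar = paste0(truth$end - truth$start, "M"),
               mapq = as.integer(mapq), nm = as.integer(nm),
               md = NA_character_, seq = samSeq, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mutate a reference genome to a fixed divergence
#'
#' Utility for two-species competitive-mapping simulations: returns a copy
#' of the input sequences with a given per-base substitution divergence.
#'
#' @param sequences named \code{DNAStringSet} or character vector.
#' @param divergence per-base substitution probability.
#' @param seed RNG seed.
#' @return a \code{DNAStringSet} with the same names.
#' @export
divergeReference <- function(sequences, divergence = 0.15, seed = 1L) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  chars <- strsplit(as.character(sequences), NULL)
  withSeed(seed, {
    out <- lapply(chars, function(v) {
      hit <- runif(length(v)) < divergence
      if (any(hit)) {
        cur <- match(v[hit], DNA_BASES4)
        shift <- sample.int(3L, sum(hit), replace = TRUE)
        v[hit] <- DNA_BASES4[((cur - 1L + shift) %% 4L) + 1L]
      }
      paste(v, collapse = "")
    })
    res <- Biostrings::DNAStringSet(unlist(out))
    names(res) <- names(sequences)
    res
  })
}
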