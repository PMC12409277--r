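#' E-score validation statistic for classification-report rows
#'
#' The default strategy is the literal reading "proportion of k-mers per
#' read, per genome coverage": \eqn{E = (unique\_kmers / reads) / cov}.
#' Higher values indicate hits dispersed along the reference genome rather
#' than clonal pileups at one locus. The algebra is pluggable: pass a
#' custom \code{fun(rows)} to swap in another published form without
#' touching the downstream filters.
#'
#' Rows with \code{reads == 0} or \code{cov == 0} are unevaluable: their
#' escore is \code{NA} and \code{escore_evaluable} is \code{FALSE}. They
#' are never silently passed by the filters.
#'
#' @param rows report data.frame (see \code{\link{readTaxReport}}).
#' @param method built-in strategy name; currently
#'   \code{"kmer-read-coverage"}.
#' @param fun optional replacement strategy, a function of the row
#'   data.frame returning a numeric vector.
#' @return \code{rows} with \code{escore} and \code{escore_evaluable}
#'   columns added.
#' @examples
#' r <- data.frame(reads = 10, unique_kmers = 700, cov = 10)
#' eScore(r)$escore  # 7
#' @export
eScore <- function(rows, method = c("kmer-read-coverage"), fun = NULL) {
  if (is.null(fun)) {
    method <- match.arg(method)
    fun <- function(r) (r$unique_kmers / r$reads) / r$cov
  }
  ok <- rows$reads > 0 & rows$cov > 0
  e <- rep(NA_real_, nrow(rows))
  if (any(ok)) e[ok] <- fun(rows[ok, , drop = FALSE])
  rows$escore <- e
  rows$escore_evaluable <- ok
  rows
}

#' Retain report rows passing the validation thresholds
#'
#' A row survives when its E-score, read count and relative abundance all
#' meet their (inclusive) thresholds. Unevaluable rows (no E-score) never
#' survive.
#'
#' @param rows report rows with an \code{escore} column (see
#'   \code{\link{eScore}}).
#' @param minEscore minimum E-score (inclusive).
#' @param minReads minimum clade read count (inclusive).
#' @param minRelAbundance minimum reads / total fraction (inclusive).
#' @param total denominator for relative abundance; defaults to the sum of
#'   \code{rows$reads}.
#' @return the retained rows.
#' @export
filterTaxa <- function(rows, minEscore = 7, minReads = 10,
                       minRelAbundance = 2e-4, total = sum(rows$reads)) {
  if (is.null(rows$escore)) stop("rows carry no escore; run eScore() first")
  keep <- !is.na(rows$escore) & rows$escore >= minEscore &
    rows$reads >= minReads &
    (if (total > 0) rows$reads / total >= minRelAbundance else FALSE)
  rows[keep, , drop = FALSE]
}

#' Select candidate species for competitive mapping
#'
#' Applied to rows screened against a mitochondrial/plastid database: a
#' genus is retained when its summed mitochondrial read hits exceed
#' \code{genusMitoHitsAbove} (strictly more), and within retained genera a
#' species is a candidate when its E-score meets \code{minEscore}
#' (inclusive). Rows lacking a genus are routed to an \code{unplaced}
#' bucket and reported, never dropped silently.
#'
#' @param rows species-rank report rows with \code{genus} and
#'   \code{escore} columns; \code{reads} is the mitochondrial hit count.
#' @param minEscore species-level E-score threshold (inclusive).
#' @param genusMitoHitsAbove genus retained only when summed hits are
#'   strictly greater than this.
#' @return list with \code{candidates}, \code{genusHits} (per-genus sums
#'   and decisions) and \code{unplaced}.
#' @export
selectCandidates <- function(rows, minEscore = 7, genusMitoHitsAbove = 3) {
  if (is.null(rows$escore)) stop("rows carry no escore; run eScore() first")
  hasGenus <- !is.na(rows$genus) & rows$genus != ""
  unplaced <- rows[!hasGenus, , drop = FALSE]
  placed <- rows[hasGenus, , drop = FALSE]
  hits <- aggregate(reads ~ genus, data = placed, FUN = sum)
  names(hits)[2] <- "mito_hits"
  hits$retained <- hits$mito_hits > genusMitoHitsAbove
  keepGenus <- hits$genus[hits$retained]
  cand <- placed[placed$genus %in% keepGenus &
                   !is.na(placed$escore) & placed$escore >= minEscore, ,
                 drop = FALSE]
  list(candidates = cand, genusHits = hits, unplaced = unplaced)
}

#' Merge reports into a joint normalized abundance table
#'
#' Joins a target sample's screened report with reference-sample reports,
#' keeping species with enough reads in at least one reference sample and
#' in the target, dropping species below a pooled relative-abundance
#' floor, then normalizing each sample's retained counts by its library
#' size (retained counts sum to 1 per sample).
#'
#' @param target species-rank rows of the target sample (columns
#'   \code{name}, \code{reads}).
#' @param references named list of reference-sample row data.frames.
#' @param minReadsRef minimum reads in some reference sample (inclusive).
#' @param minReadsTarget minimum reads in the target (inclusive).
#' @param minRel minimum pooled relative abundance (inclusive).
#' @return data.frame with one row per surviving species: name, per-sample
#'   raw counts (\code{reads_*}) and normalized abundances (\code{abund_*}).
#' @export
mergeReports <- function(target, references, minReadsRef = 200,
                         minReadsTarget = 50, minRel = 2e-4) {
  if (length(references) < 2) stop("need at least two reference reports")
  if (is.null(names(references)) || any(names(references) == "")) {
    stop("references must be a named list")
  }
  allNames <- Reduce(union, c(list(target$name),
                              lapply(references, function(r) r$name)))
  countsOf <- function(rows) {
    v <- setNames(rep(0, length(allNames)), allNames)
    v[rows$name] <- rows$reads
    v
  }
  tgt <- countsOf(target)
  refMat <- vapply(references, countsOf, numeric(length(allNames)))
  keep <- apply(refMat, 1, max) >= minReadsRef & tgt >= minReadsTarget
  pooled <- tgt + rowSums(refMat)
  keep <- keep & (pooled / sum(pooled)) >= minRel
  if (!any(keep)) {
    warning("no species survive the merge thresholds; returning empty table")
    return(data.frame(name = character(), stringsAsFactors = FALSE))
  }
  sel <- which(keep)
  norm <- function(v) if (sum(v) > 0) v / sum(v) else v
  out <- data.frame(name = allNames[sel],
                    reads_target = tgt[sel],
                    abund_target = norm(tgt[sel]),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (rn in names(references)) {
    out[[paste0("reads_", rn)]] <- refMat[sel, rn]
    out[[paste0("abund_", rn)]] <- norm(refMat[sel, rn])
  }
  out
}
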