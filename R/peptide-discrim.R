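AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]]

# Collapse isobaric residues: isoleucine and leucine are indistinguishable
# by mass spectrometry.
ilCollapse <- function(x) gsub("I", "L", x, fixed = TRUE)

#' Aggregate and filter peptide-spectrum matches
#'
#' Aggregates PSMs by (modification-stripped) peptide sequence and keeps
#' peptides whose best (lowest) score and spectral count meet the
#' evidence thresholds, both inclusive. Records with malformed peptide
#' strings are rejected with their row numbers.
#'
#' @param psms PSM data.frame: spectrum_id, peptide, score, and
#'   optionally modifications, accessions.
#' @param maxScore maximum (best) search-engine score, lower is better.
#' @param minPsms minimum number of PSMs per peptide.
#' @return data.frame of retained peptide evidence: peptide, psm_count,
#'   best_score, accessions (union, comma-joined); the full unfiltered
#'   aggregation is attached as attribute \code{"all"}.
#' @export
filterPSMs <- function(psms, maxScore = 0.01, minPsms = 2L) {
  bad <- which(!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", psms$peptide))
  if (length(bad)) {
    warning("rejected ", length(bad), " PSM record(s) with malformed peptide",
            " at line(s): ", paste(head(bad, 10), collapse = ", "))
    psms <- psms[-bad, , drop = FALSE]
  }
  if (nrow(psms) == 0) {
    out <- data.frame(peptide = character(), psm_count = integer(),
                      best_score = numeric(), accessions = character(),
                      stringsAsFactors = FALSE)
    attr(out, "all") <- out
    return(out)
  }
  accs <- if (is.null(psms$accessions)) rep("", nrow(psms)) else psms$accessions
  agg <- do.call(rbind, lapply(split(seq_len(nrow(psms)), psms$peptide),
    function(ix) {
      data.frame(
        peptide = psms$peptide[ix[1]],
        psm_count = length(ix),
        best_score = min(psms$score[ix]),
        accessions = paste(sort(unique(unlist(strsplit(accs[ix], ";")))),
                           collapse = ";"),
        stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL
  keep <- agg$best_score <= maxScore & agg$psm_count >= minPsms
  out <- agg[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- agg
  out
}

#' Match peptides against a multi-species protein database
#'
#' A peptide matches a protein when it occurs as an exact substring,
#' with isoleucine and leucine treated as interchangeable by default
#' (they are isobaric). A peptide is species-diagnostic when its matches
#' all fall in exactly one species; for diagnostic peptides the residue
#' positions at which the other species' homolog (same \code{gene} tag)
#' differs are reported in peptide coordinates.
#'
#' @param peptides character vector of peptide sequences (or the output
#'   of \code{\link{filterPSMs}}).
#' @param db protein database as returned by \code{\link{readProteinDb}}
#'   or \code{\link{synthProteinPair}} (needs \code{proteins} with acc,
#'   species, gene, seq).
#' @param ilEquivalent treat I and L as identical during matching.
#' @return data.frame: peptide, species (comma-joined), n_species,
#'   diagnostic, accessions (comma-joined), diagnostic_positions
#'   (comma-joined peptide coordinates, "" when not applicable).
#' @export
matchPeptides <- function(peptides, db, ilEquivalent = TRUE) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  proteins <- db$proteins
  if (is.null(proteins) || nrow(proteins) == 0) stop("empty protein database")
  seqs <- proteins$seq
  pepsM <- if (ilEquivalent) ilCollapse(peptides) else peptides
  seqsM <- if (ilEquivalent) ilCollapse(seqs) else seqs
  res <- lapply(seq_along(peptides), function(i) {
    hit <- which(vapply(seqsM, function(s) grepl(pepsM[i], s, fixed = TRUE),
                        logical(1), USE.NAMES = FALSE))
    spp <- sort(unique(proteins$species[hit]))
    diag <- length(spp) == 1L
    dpos <- ""
    if (diag && !is.null(proteins$gene)) {
      dpos <- diagnosticPositions(pepsM[i], hit[1], proteins, seqsM)
    }
    data.frame(peptide = peptides[i],
               species = paste(spp, collapse = ","),
               n_species = length(spp),
               diagnostic = diag,
               accessions = paste(proteins$acc[hit], collapse = ","),
               diagnostic_positions = dpos,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Peptide-coordinate positions where the homologous protein of another
# species differs from the matched region. Homologs are proteins sharing
# the gene tag; positions are compared at the matched offset (homolog
# pairs are assumed co-linear over the match).
diagnosticPositions <- function(pepM, hitIx, proteins, seqsM) {
  gene <- proteins$gene[hitIx]
  if (is.na(gene)) return("")
  others <- which(proteins$gene == gene &
                    proteins$species != proteins$species[hitIx])
  if (!length(others)) return("")
  start <- regexpr(pepM, seqsM[hitIx], fixed = TRUE)[1]
  if (start < 1) return("")
  pepChars <- strsplit(pepM, NULL)[[1]]
  pos <- integer(0)
  for (o in others) {
    oseq <- seqsM[o]
    if (nchar(oseq) < start + length(pepChars) - 1L) next
    oChars <- strsplit(substr(oseq, start, start + length(pepChars) - 1L),
                       NULL)[[1]]
    pos <- union(pos, which(oChars != pepChars))
  }
  paste(sort(pos), collapse = ",")
}

#' Protein-level evidence from matched peptides
#'
#' For each protein, collects the unique peptides matching it, computes
#' the coverage fraction as the union of matched residue intervals over
#' the protein length, drops proteins with too few unique peptides, and
#' labels proteins reaching the partial-coverage floor.
#'
#' @param peptides retained peptide sequences (or \code{filterPSMs}
#'   output).
#' @param db protein database (see \code{\link{matchPeptides}}).
#' @param minUniquePeptides minimum unique peptides per reported protein.
#' @param partialCoverage coverage fraction at or above which a protein
#'   is labelled partial.
#' @param ilEquivalent treat I and L as identical during matching.
#' @return data.frame: acc, species, n_unique_peptides, coverage,
#'   partial.
#' @export
proteinEvidence <- function(peptides, db, minUniquePeptides = 2L,
                            partialCoverage = 0.05, ilEquivalent = TRUE) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  proteins <- db$proteins
  pepsM <- unique(if (ilEquivalent) ilCollapse(peptides) else peptides)
  seqsM <- if (ilEquivalent) ilCollapse(proteins$seq) else proteins$seq
  rows <- lapply(seq_len(nrow(proteins)), function(j) {
    covered <- IRanges::IRanges()
    nPep <- 0L
    for (p in pepsM) {
      m <- gregexpr(p, seqsM[j], fixed = TRUE)[[1]]
      if (m[1] == -1) next
      nPep <- nPep + 1L
      covered <- c(covered, IRanges::IRanges(start = as.integer(m),
                                             width = nchar(p)))
    }
    cov <- sum(IRanges::width(IRanges::reduce(covered))) / nchar(proteins$seq[j])
    data.frame(acc = proteins$acc[j], species = proteins$species[j],
               n_unique_peptides = nPep, coverage = cov,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_unique_peptides >= minUniquePeptides, , drop = FALSE]
  out$partial <- out$coverage >= partialCoverage
  rownames(out) <- NULL
  out
}

#' Remove blank-derived and listed contaminant peptides
#'
#' Peptides observed in the extraction blank (processed with identical
#' filters) or matching a contaminant accession list are removed;
#' removals are tallied by cause.
#'
#' @param evidence peptide evidence data.frame (see
#'   \code{\link{filterPSMs}}).
#' @param blankEvidence evidence data.frame from the blank, or NULL.
#' @param contaminantAccessions character vector of contaminant protein
#'   accessions, or NULL.
#' @return the cleaned evidence, with attribute \code{removed} (named
#'   counts: blank, contaminant_list).
#' @export
blankSubtract <- function(evidence, blankEvidence = NULL,
                          contaminantAccessions = NULL) {
  inBlank <- if (!is.null(blankEvidence) && nrow(blankEvidence)) {
    ilCollapse(evidence$peptide) %in% ilCollapse(blankEvidence$peptide)
  } else rep(FALSE, nrow(evidence))
  inList <- if (!is.null(contaminantAccessions)) {
    vapply(strsplit(evidence$accessions %||% rep("", nrow(evidence)), "[;,]"),
           function(a) any(a %in% contaminantAccessions), logical(1))
  } else rep(FALSE, nrow(evidence))
  out <- evidence[!(inBlank | inList), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(blank = sum(inBlank),
                            contaminant_list = sum(inList & !inBlank))
  out
}

#' Post-translational modification tally
#'
#' Parses the modifications column (entries like
#' \code{"4:Oxidation;7:Deamidated"}) and reports each modification
#' type's count and its proportion relative to the total number of
#' amino acids across the PSM peptides.
#'
#' @param psms PSM data.frame with peptide and modifications columns.
#' @return data.frame: modification, count, proportion_of_residues.
#' @export
ptmSummary <- function(psms) {
  totalAA <- sum(nchar(psms$peptide))
  mods <- unlist(lapply(strsplit(psms$modifications %||% character(), ";"),
                        function(v) sub("^[0-9]+:", "", v[v != ""])))
  if (!length(mods)) {
    return(data.frame(modification = character(), count = integer(),
                      proportion_of_residues = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(mods)
  data.frame(modification = names(tab), count = as.integer(tab),
             proportion_of_residues = as.integer(tab) / totalAA,
             row.names = NULL, stringsAsFactors = FALSE)
}
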