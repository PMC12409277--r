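# File-format boundaries. FASTQ/FASTA go through Biostrings; SAM reading
# goes through Rsamtools (text SAM is converted to a temporary BAM first);
# SAM writing is a plain serializer for the simulator's truth alignments.

#' Read a FASTQ file
#'
#' @param path FASTQ path (Sanger phred+33).
#' @return a \code{\link[Biostrings]{QualityScaledDNAStringSet}}.
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- Biostrings::PhredQuality(S4Vectors::mcols(x)$qualities)
  S4Vectors::mcols(x) <- NULL
  Biostrings::QualityScaledDNAStringSet(x, q)
}

#' Write reads to FASTQ
#'
#' @param reads a \code{QualityScaledDNAStringSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(reads, path) {
  Biostrings::writeXStringSet(as(reads, "DNAStringSet"), path, format = "fastq",
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

# In-memory view of reads as a data.frame (read_id, seq, qual).
readsToFrame <- function(reads) {
  data.frame(read_id = names(reads),
             seq = as.character(reads),
             qual = as.character(Biostrings::quality(reads)),
             stringsAsFactors = FALSE)
}

frameToReads <- function(df) {
  dna <- Biostrings::DNAStringSet(df$seq)
  names(dna) <- df$read_id
  Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(df$qual))
}

#' Write alignment records as SAM
#'
#' Emits a headerful single-end SAM file with NM and MD tags, suitable for
#' any SAM-consuming tool.
#'
#' @param alignments alignment data.frame (as produced by
#'   \code{\link{simulateMetagenome}}): read_id, ref_id, pos (0-based),
#'   strand, cigar, mapq, nm, md, seq.
#' @param refLengths named vector of reference sequence lengths.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(alignments, refLengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (rn in names(refLengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", rn, as.integer(refLengths[[rn]])), con)
  }
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d\tMD:Z:%s",
                     alignments$read_id, flag, alignments$ref_id,
                     alignments$pos + 1L, alignments$mapq, alignments$cigar,
                     alignments$seq, strrep("I", nchar(alignments$seq)),
                     alignments$nm, alignments$md)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a SAM file into an alignment data.frame
#'
#' The text SAM is converted to a temporary BAM with
#' \code{\link[Rsamtools]{asBam}} and scanned back; unmapped records are
#' dropped.
#'
#' @param path SAM path.
#' @return data.frame with read_id, ref_id, pos (0-based), strand, cigar,
#'   mapq, nm, md, seq.
#' @export
readSam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "mapq", "seq", "flag"),
    tag = c("NM", "MD"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(res$pos)
  data.frame(
    read_id = res$qname[keep],
    ref_id = as.character(res$rname)[keep],
    pos = res$pos[keep] - 1L,
    strand = as.character(res$strand)[keep],
    cigar = res$cigar[keep],
    mapq = res$mapq[keep],
    nm = if (is.null(res$tag$NM)) NA_integer_ else res$tag$NM[keep],
    md = if (is.null(res$tag$MD)) NA_character_ else res$tag$MD[keep],
    seq = as.character(res$seq)[keep],
    stringsAsFactors = FALSE)
}

REPORT_COLS <- c("%", "reads", "taxReads", "kmers", "dup", "cov",
                 "taxID", "rank", "taxName")

#' Read a k-mer classification report
#'
#' Parses the tab-separated report dialect with columns \code{\%, reads,
#' taxReads, kmers, dup, cov, taxID, rank, taxName} and an
#' indentation-encoded hierarchy in taxName (two spaces per level), and
#' reconstructs parent pointers.
#'
#' @param path report path.
#' @return data.frame with pct, reads, tax_reads, unique_kmers, dup, cov,
#'   taxid, rank, name, depth, parent_taxid.
#' @export
readTaxReport <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  missing <- setdiff(REPORT_COLS, names(raw))
  if (length(missing)) {
    stop("report is missing column(s): ", paste(missing, collapse = ", "))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at line ", bad[1] + 1L)
    }
    v
  }
  indent <- nchar(raw$taxName) - nchar(sub("^ +", "", raw$taxName))
  depth <- indent %/% 2L
  taxid <- as.integer(num("taxID"))
  parent <- rep(NA_integer_, nrow(raw))
  stack <- integer(0)
  for (i in seq_len(nrow(raw))) {
    d <- depth[i]
    stack <- stack[seq_len(min(d, length(stack)))]
    parent[i] <- if (d > 0 && length(stack) >= d) stack[d] else NA_integer_
    stack <- c(stack[seq_len(d)], taxid[i])
  }
  data.frame(
    pct = num("%"), reads = num("reads"), tax_reads = num("taxReads"),
    unique_kmers = num("kmers"), dup = num("dup"), cov = num("cov"),
    taxid = taxid, rank = raw$rank, name = sub("^ +", "", raw$taxName),
    depth = depth, parent_taxid = parent, stringsAsFactors = FALSE)
}

#' Write a classification report in the standard column order
#'
#' Inverse of \code{\link{readTaxReport}}: emits \code{\%, reads,
#' taxReads, kmers, dup, cov, taxID, rank, taxName} with the hierarchy
#' re-encoded as two-space indentation of taxName.
#'
#' @param report data.frame as returned by \code{\link{readTaxReport}} or
#'   \code{\link{synthTaxReport}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTaxReport <- function(report, path) {
  depth <- report$depth %||% 0L
  out <- data.frame(
    `%` = report$pct, reads = report$reads, taxReads = report$tax_reads,
    kmers = report$unique_kmers, dup = report$dup, cov = report$cov,
    taxID = report$taxid, rank = report$rank,
    taxName = paste0(strrep("  ", depth), report$name),
    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a species-tagged protein database
#'
#' FASTA headers are expected to carry \code{species=} and optionally
#' \code{gene=} key-value tags.
#'
#' @param path FASTA path.
#' @return list with \code{db} (AAStringSet) and \code{proteins}
#'   (data.frame acc, species, gene, seq).
#' @export
readProteinDb <- function(path) {
  db <- Biostrings::readAAStringSet(path)
  if (length(db) == 0) stop("empty protein database: ", path)
  hdr <- names(db)
  acc <- sub("\\s.*$", "", hdr)
  pick <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    out <- rep(NA_character_, length(hdr))
    out[grepl(paste0(key, "="), hdr)] <- sub(paste0(key, "="), "", m)
    out
  }
  proteins <- data.frame(acc = acc, species = pick("species"),
                         gene = pick("gene"), seq = as.character(db),
                         stringsAsFactors = FALSE, row.names = NULL)
  if (anyNA(proteins$species)) {
    stop("protein FASTA headers must carry species= tags")
  }
  list(db = db, proteins = proteins)
}

#' Write a pileup table as TSV
#'
#' @param pileup data.frame with chrom, pos, ref, A, C, G, T, N.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pileup TSV written by \code{\link{writePileup}}
#'
#' @param path input path.
#' @return the pileup data.frame.
#' @export
readPileup <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
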