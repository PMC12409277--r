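# Shared fixture builders. Everything is generated in code at test time.

toyMixture <- function(nTaxa = 2, abundances = NULL, genomeLength = 8000,
                       seed = 101, genus = NULL) {
  ab <- abundances %||% rep(1 / nTaxa, nTaxa)
  lapply(seq_len(nTaxa), function(i) {
    taxonSpec(sprintf("tax%d", i), sprintf("Toyus species%d", i),
              genus %||% sprintf("Toyus%d", i), ab[i],
              setNames(randomReference(genomeLength, seed = seed + i),
                       sprintf("tax%d_chr", i)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a QualityScaledDNAStringSet from plain vectors.
makeReads <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))  # Q40
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(quals))
}

# One gapless alignment record, MD computed from the reference slice.
makeAlignment <- function(readSeq, refSeq, pos = 0L, strand = "+",
                          readId = "r1", refId = "chr", mapq = 60L) {
  frag <- substr(refSeq, pos + 1, pos + nchar(readSeq))
  samSeq <- readSeq
  a <- strsplit(samSeq, NULL)[[1]]
  b <- strsplit(frag, NULL)[[1]]
  nm <- sum(a != b)
  md <- if (nm == 0) as.character(nchar(readSeq)) else {
    out <- character(0); run <- 0L
    for (i in seq_along(a)) {
      if (a[i] == b[i]) run <- run + 1L
      else { out <- c(out, as.character(run), b[i]); run <- 0L }
    }
    paste(c(out, as.character(run)), collapse = "")
  }
  data.frame(read_id = readId, ref_id = refId, pos = pos, strand = strand,
             cigar = paste0(nchar(readSeq), "M"), mapq = mapq, nm = nm,
             md = md, seq = samSeq, stringsAsFactors = FALSE)
}

# A 64-bp sequence whose 62 overlapping triplets are all distinct (used to
# pin the DUST zero point). Prefer-largest greedy from a homopolymer seed
# traces a de Bruijn sequence, so it never gets stuck before length 66.
distinctTripletSeq <- function(len = 64) {
  stopifnot(len <= 66)
  bases <- c("T", "G", "C", "A")  # prefer-largest order
  s <- "AAA"
  seen <- s
  while (nchar(s) < len) {
    tail2 <- substr(s, nchar(s) - 1, nchar(s))
    for (b in bases) {
      cand <- paste0(tail2, b)
      if (!cand %in% seen) {
        s <- paste0(s, b); seen <- c(seen, cand); break
      }
    }
  }
  s
}

# Independent DUST oracle: direct triplet counting, no windowing shortcuts.
dustOracle <- function(seq, window = 64L, step = 32L) {
  L <- nchar(seq)
  starts <- if (L <= window) 1L else {
    s <- seq(1L, L - window + 1L, by = step)
    if (s[length(s)] + window - 1L < L) s <- c(s, L - window + 1L)
    s
  }
  scores <- vapply(starts, function(st) {
    w <- min(window, L - st + 1L)
    win <- substr(seq, st, st + w - 1L)
    tri <- substring(win, 1:(w - 2), 3:w)
    cnt <- table(tri)
    100 * sum(cnt * (cnt - 1) / 2) / ((w - 3) * (w - 2) / 2)
  }, numeric(1))
  max(scores)
}

# Exhaustive substring oracle for peptide/species containment: enumerates
# every substring of the protein at the peptide's length.
speciesContainsOracle <- function(peptide, proteins, species, il = TRUE) {
  pep <- if (il) gsub("I", "L", peptide) else peptide
  rows <- proteins[proteins$species == species, , drop = FALSE]
  for (s in rows$seq) {
    sq <- if (il) gsub("I", "L", s) else s
    L <- nchar(pep)
    if (nchar(sq) < L) next
    subs <- substring(sq, 1:(nchar(sq) - L + 1), L:nchar(sq))
    if (pep %in% subs) return(TRUE)
  }
  FALSE
}
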