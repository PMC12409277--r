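# Internal helpers shared across modules.

# Derive a reproducible sub-seed for a named random stream from a master
# seed. Each simulation phase (fragmentation, damage, error, contamination)
# draws from its own stream so that toggling one model does not perturb the
# others. Kept strictly below 2^31 - 1.
subSeed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((abs(seed) + h * 104729) %% 2147483629 + 1)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Reverse complement for plain character vectors (ACGTN).
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Collapse a list of per-read character vectors back into strings, keeping
# one entry per read even when a read contributed no characters.
pasteByRead <- function(chars, readIndex, nReads) {
  out <- character(nReads)
  grp <- split(chars, factor(readIndex, levels = seq_len(nReads)))
  out[] <- vapply(grp, paste, character(1), collapse = "")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Phred string <-> integer vectors (Sanger +33 encoding).
phredToInt <- function(qual) {
  lapply(qual, function(s) utf8ToInt(s) - 33L)
}

intToPhred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

meanPhred <- function(qual) {
  vapply(qual, function(s) mean(utf8ToInt(s)) - 33, numeric(1), USE.NAMES = FALSE)
}
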