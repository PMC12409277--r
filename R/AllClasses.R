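SUBSTITUTIONS <- c("A>C", "A>G", "A>T",
                   "C>A", "C>G", "C>T",
                   "G>A", "G>C", "G>T",
                   "T>A", "T>C", "T>G")
DNA_BASES4 <- c("A", "C", "G", "T")

#' Post-mortem deamination model
#'
#' Parameterises position-decaying terminal cytosine deamination: the
#' probability of observing C-to-T at read position \eqn{i} from the 5'
#' end is \eqn{f + (\delta_5 - f)\,\lambda^{i-1}}, where \eqn{f} is a
#' background floor, \eqn{\delta_5} the terminal rate and \eqn{\lambda} a
#' geometric decay. Double-stranded libraries additionally show the
#' symmetric G-to-A pattern at the 3' end with the same magnitudes.
#'
#' @slot delta5 terminal C-to-T probability at 5' position 1.
#' @slot decay per-position geometric decay factor in (0, 1].
#' @slot deltaBase background deamination floor.
#' @slot doubleStranded if \code{TRUE}, apply the symmetric 3' G-to-A model.
#' @export
setClass("DamageModel",
  representation(delta5 = "numeric", decay = "numeric",
                 deltaBase = "numeric", doubleStranded = "logical"),
  prototype(delta5 = 0.2, decay = 0.6, deltaBase = 0.01, doubleStranded = TRUE))

setValidity("DamageModel", function(object) {
  msg <- character()
  if (length(object@delta5) != 1L || length(object@decay) != 1L ||
      length(object@deltaBase) != 1L) {
    msg <- c(msg, "delta5, decay and deltaBase must be scalars")
  }
  if (!(object@deltaBase >= 0 && object@deltaBase <= object@delta5 &&
        object@delta5 <= 1)) {
    msg <- c(msg, "require 0 <= deltaBase <= delta5 <= 1")
  }
  if (!(object@decay > 0 && object@decay <= 1)) {
    msg <- c(msg, "decay must be in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @param delta5,decay,deltaBase,doubleStranded see slot documentation.
#' @return a \code{DamageModel} object.
#' @rdname DamageModel-class
#' @examples
#' m <- damageModel(delta5 = 0.2, decay = 0.6)
#' damageRate(m, 1:5)
#' @export
damageModel <- function(delta5 = 0.2, decay = 0.6, deltaBase = 0.01,
                        doubleStranded = TRUE) {
  new("DamageModel", delta5 = delta5, decay = decay, deltaBase = deltaBase,
      doubleStranded = doubleStranded)
}

#' @rdname DamageModel-class
#' @param model a \code{DamageModel}.
#' @param positions 1-based distances from the read terminus.
#' @export
setGeneric("damageRate", function(model, positions) standardGeneric("damageRate"))

#' @rdname DamageModel-class
#' @export
setMethod("damageRate", "DamageModel", function(model, positions) {
  stopifnot(all(positions >= 1))
  model@deltaBase + (model@delta5 - model@deltaBase) * model@decay^(positions - 1)
})

setMethod("show", "DamageModel", function(object) {
  cat("DamageModel: delta5 =", object@delta5,
      " decay =", object@decay,
      " floor =", object@deltaBase,
      if (object@doubleStranded) " (double-stranded)\n" else " (single-end 5' only)\n")
})

#' Position-wise misincorporation profile
#'
#' Counts of the 12 substitution types and of reference-base opportunities
#' at each of the first \code{nPositions} read positions from either
#' fragment end, in read orientation. This is the evidence object behind
#' terminal-deamination authentication.
#'
#' @slot counts integer array [end (5p/3p), position, substitution].
#' @slot opportunities integer array [end, position, reference base].
#' @slot nReads number of alignments tallied.
#' @slot nSkipped alignments skipped for missing reference information.
#' @export
setClass("DamageProfile",
  representation(counts = "array", opportunities = "array",
                 nReads = "integer", nSkipped = "integer"))

setValidity("DamageProfile", function(object) {
  d1 <- dim(object@counts)
  d2 <- dim(object@opportunities)
  msg <- character()
  if (length(d1) != 3L || d1[1] != 2L || d1[3] != 12L) {
    msg <- c(msg, "counts must be a [2, nPositions, 12] array")
  }
  if (length(d2) != 3L || d2[1] != 2L || d2[3] != 4L) {
    msg <- c(msg, "opportunities must be a [2, nPositions, 4] array")
  }
  if (!length(msg) && d1[2] != d2[2]) {
    msg <- c(msg, "counts and opportunities disagree on nPositions")
  }
  if (any(object@counts < 0) || any(object@opportunities < 0)) {
    msg <- c(msg, "negative cells")
  }
  if (length(msg)) msg else TRUE
})

emptyDamageProfile <- function(nPositions = 30L) {
  nPositions <- as.integer(nPositions)
  counts <- array(0L, dim = c(2L, nPositions, 12L),
                  dimnames = list(end = c("5p", "3p"),
                                  position = seq_len(nPositions),
                                  substitution = SUBSTITUTIONS))
  opp <- array(0L, dim = c(2L, nPositions, 4L),
               dimnames = list(end = c("5p", "3p"),
                               position = seq_len(nPositions),
                               base = DNA_BASES4))
  new("DamageProfile", counts = counts, opportunities = opp,
      nReads = 0L, nSkipped = 0L)
}

#' @rdname DamageProfile-class
#' @param profile a \code{DamageProfile}.
#' @param end \code{"5p"} or \code{"3p"}.
#' @param substitution one of the 12 substitution labels, e.g. \code{"C>T"}.
#' @return \code{substitutionFrequency} returns the per-position frequency
#'   (substitution count / opportunity count); positions without
#'   opportunities are \code{NaN}.
#' @export
setGeneric("substitutionFrequency",
           function(profile, end = "5p", substitution = "C>T")
             standardGeneric("substitutionFrequency"))

#' @rdname DamageProfile-class
#' @export
setMethod("substitutionFrequency", "DamageProfile",
  function(profile, end = "5p", substitution = "C>T") {
    end <- match.arg(end, c("5p", "3p"))
    substitution <- match.arg(substitution, SUBSTITUTIONS)
    from <- substr(substitution, 1, 1)
    profile@counts[end, , substitution] / profile@opportunities[end, , from]
  })

#' @rdname DamageProfile-class
#' @export
setGeneric("nReads", function(profile) standardGeneric("nReads"))

#' @rdname DamageProfile-class
#' @export
setMethod("nReads", "DamageProfile", function(profile) profile@nReads)

#' @rdname DamageProfile-class
#' @param e1,e2 profiles to combine cell-wise.
#' @export
setMethod("+", signature("DamageProfile", "DamageProfile"), function(e1, e2) {
  stopifnot(identical(dim(e1@counts), dim(e2@counts)))
  new("DamageProfile",
      counts = e1@counts + e2@counts,
      opportunities = e1@opportunities + e2@opportunities,
      nReads = e1@nReads + e2@nReads,
      nSkipped = e1@nSkipped + e2@nSkipped)
})

setMethod("show", "DamageProfile", function(object) {
  np <- dim(object@counts)[2]
  f5 <- substitutionFrequency(object, "5p", "C>T")[1]
  f3 <- substitutionFrequency(object, "3p", "G>A")[1]
  cat("DamageProfile over", np, "terminal positions,",
      object@nReads, "alignments\n")
  cat("  5' C>T at position 1:", format(f5, digits = 3),
      "  3' G>A at position 1:", format(f3, digits = 3), "\n")
  if (object@nSkipped > 0) cat("  skipped (no reference info):", object@nSkipped, "\n")
})

#' Terminal damage summary
#'
#' Opportunity-weighted mean deamination frequency over the outermost
#' \code{k} positions of both fragment ends (5' C-to-T and 3' G-to-A
#' cells), with a minimum-read-support gate.
#'
#' @slot average the weighted mean frequency.
#' @slot k number of terminal positions summarised.
#' @slot nReads alignments supporting the profile.
#' @slot gatePassed \code{TRUE} only when more reads than the gate support
#'   the estimate.
#' @slot substitutions total deaminated-base count in the k cells.
#' @slot opportunities total reference C/G opportunity count in the k cells.
#' @export
setClass("DamageSummary",
  representation(average = "numeric", k = "integer", nReads = "integer",
                 gatePassed = "logical", substitutions = "numeric",
                 opportunities = "numeric"))

setMethod("show", "DamageSummary", function(object) {
  cat(sprintf("DamageSummary: mean deamination over last %d bp = %s (%d reads%s)\n",
              object@k,
              format(object@average, digits = 4), object@nReads,
              if (object@gatePassed) "" else "; below read-support gate"))
})

#' @rdname DamageSummary-class
#' @param object a \code{DamageSummary}.
#' @export
setGeneric("gatePassed", function(object) standardGeneric("gatePassed"))

#' @rdname DamageSummary-class
#' @export
setMethod("gatePassed", "DamageSummary", function(object) object@gatePassed)

#' @rdname DamageSummary-class
#' @export
setGeneric("damageAverage", function(object) standardGeneric("damageAverage"))

#' @rdname DamageSummary-class
#' @export
setMethod("damageAverage", "DamageSummary", function(object) object@average)
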