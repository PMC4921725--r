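#' Score a computed alignment against a reference
#'
#' A computed correspondence is correct when its exact (id1, id2) pair is
#' in the reference.  Precision is the number of correct correspondences
#' over the number of computed correspondences, recall the number of
#' correct correspondences over the size of the reference, and the
#' F-measure their harmonic mean \eqn{2PR/(P+R)}.  An empty computed
#' alignment scores precision 0 by convention (pessimistic, keeps F
#' well-defined); an undefined F (P + R = 0) is reported as 0.
#'
#' @param computed,reference \linkS4class{Alignment} objects.
#' @return An \linkS4class{EvalResult}.
#' @examples
#' comp <- alignment(c("a", "b", "c"), c("x", "y", "q"))
#' ref  <- alignment(c("a", "b", "d", "e"), c("x", "y", "w", "v"))
#' scoreAlignment(comp, ref)  # P = 2/3, R = 1/2, F = 4/7
#' @export
scoreAlignment <- function(computed, reference) {
  keys <- function(a) paste(a@id1, a@id2, sep = "\r")
  nCorrect <- length(intersect(keys(computed), keys(reference)))
  nComputed <- length(computed@id1)
  nReference <- length(reference@id1)
  p <- if (nComputed > 0L) nCorrect / nComputed else 0
  r <- if (nReference > 0L) nCorrect / nReference else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  new("EvalResult", precision = p, recall = r, fMeasure = f,
      nCorrect = as.integer(nCorrect), nComputed = as.integer(nComputed),
      nReference = as.integer(nReference))
}

#' @describeIn scoreAlignment Accessors for the evaluation scores.
#' @param x An \code{EvalResult}.
#' @export
precision <- function(x) x@precision

#' @rdname scoreAlignment
#' @export
recall <- function(x) x@recall

#' @rdname scoreAlignment
#' @export
fMeasure <- function(x) x@fMeasure

#' @describeIn scoreAlignment Scores and counts as a one-row data frame.
#' @export
evalTable <- function(x) {
  data.frame(precision = x@precision, recall = x@recall, fMeasure = x@fMeasure,
             nCorrect = x@nCorrect, nComputed = x@nComputed,
             nReference = x@nReference)
}
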