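#' @import methods
NULL

.emptyEdgeMatrix <- function() {
  matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
}

#' Ontology: classes, labels and structural relations
#'
#' An \code{Ontology} holds the named classes of one input ontology together
#' with their human-readable labels and the asserted structural relations
#' used by the matcher: \code{is_a} (subsumption), \code{part_of}
#' (partonomy) and pairwise class disjointness.  Edges are stored as
#' directly asserted pairs; transitive closure is computed on demand by
#' \code{\link{ancestors}}.
#'
#' @slot name Character tag identifying the ontology's role (e.g. "O1").
#' @slot classIds Character vector of unique class identifiers.
#' @slot labels Named list, one character vector of labels per class id.
#'   A class may carry several labels; a class with no labels never yields
#'   match candidates.
#' @slot subEdges Two-column character matrix of direct \code{is_a}
#'   assertions, row \code{(a, b)} meaning a is_a b.
#' @slot partEdges Two-column character matrix of direct \code{part_of}
#'   assertions.
#' @slot disjointPairs Two-column character matrix of unordered disjointness
#'   pairs, stored with the lexicographically smaller id first.
#'
#' @seealso \code{\link{ontology}}, \code{\link{readNativeOntology}},
#'   \code{\link{readOwlOntology}}
#' @exportClass Ontology
setClass("Ontology",
  representation(
    name = "character",
    classIds = "character",
    labels = "list",
    subEdges = "matrix",
    partEdges = "matrix",
    disjointPairs = "matrix"
  ),
  prototype(
    name = "O",
    classIds = character(0),
    labels = list(),
    subEdges = .emptyEdgeMatrix(),
    partEdges = .emptyEdgeMatrix(),
    disjointPairs = .emptyEdgeMatrix()
  )
)

.findCycle <- function(edges, ids) {
  # Kahn's algorithm; returns NULL if acyclic, else the ids on a cycle
  if (nrow(edges) == 0L) return(NULL)
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(edges[, 2L])
  indeg[names(tab)] <- as.integer(tab)
  queue <- ids[indeg == 0L]
  removed <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; removed <- removed + 1L
    heads <- edges[edges[, 1L] == v, 2L]
    for (h in heads) {
      indeg[[h]] <- indeg[[h]] - 1L
      if (indeg[[h]] == 0L) queue <- c(queue, h)
    }
  }
  if (removed == length(ids)) return(NULL)
  sort(names(indeg)[indeg > 0L])
}

setValidity("Ontology", function(object) {
  msgs <- character(0)
  ids <- object@classIds
  if (anyDuplicated(ids)) {
    msgs <- c(msgs, sprintf("duplicate class id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (!setequal(names(object@labels), ids) || length(object@labels) != length(ids)) {
    msgs <- c(msgs, "labels must be a named list with exactly one entry per class id")
  }
  for (slotname in c("subEdges", "partEdges", "disjointPairs")) {
    m <- slot(object, slotname)
    if (ncol(m) != 2L) {
      msgs <- c(msgs, sprintf("%s must have two columns", slotname))
      next
    }
    bad <- setdiff(as.vector(m), ids)
    if (length(bad)) {
      msgs <- c(msgs, sprintf("%s references unknown class id(s): %s",
        slotname, paste(sort(unique(bad)), collapse = ", ")))
    }
  }
  if (nrow(object@disjointPairs) &&
      any(object@disjointPairs[, 1L] == object@disjointPairs[, 2L])) {
    msgs <- c(msgs, "a class cannot be disjoint with itself")
  }
  if (!length(msgs)) {
    for (slotname in c("subEdges", "partEdges")) {
      cyc <- .findCycle(slot(object, slotname), ids)
      if (!is.null(cyc)) {
        msgs <- c(msgs, sprintf("%s contains a cycle involving: %s",
          slotname, paste(cyc, collapse = " -> ")))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Alignment: a set of class correspondences
#'
#' An \code{Alignment} is a set of equivalence correspondences between
#' classes of two ontologies.  Each correspondence carries the identifiers
#' of the two classes and a confidence in [0, 1].  Only the equivalence
#' relation is modelled.  A computed alignment additionally satisfies the
#' one-to-one cardinality invariant (no id appears twice on either side);
#' reference alignments read from files are not required to.
#'
#' @slot id1,id2 Character vectors of class ids (parallel).
#' @slot confidence Numeric vector of confidences in [0, 1].
#'
#' @seealso \code{\link{alignment}}, \code{\link{scoreAlignment}},
#'   \code{\link{readAlignment}}
#' @exportClass Alignment
setClass("Alignment",
  representation(id1 = "character", id2 = "character", confidence = "numeric"),
  prototype(id1 = character(0), id2 = character(0), confidence = numeric(0))
)

setValidity("Alignment", function(object) {
  msgs <- character(0)
  n <- length(object@id1)
  if (length(object@id2) != n || length(object@confidence) != n) {
    msgs <- c(msgs, "id1, id2 and confidence must have equal length")
  } else {
    if (anyDuplicated(paste(object@id1, object@id2, sep = "\r"))) {
      msgs <- c(msgs, "duplicate correspondences")
    }
    if (n && (any(object@confidence < 0) || any(object@confidence > 1))) {
      msgs <- c(msgs, "confidence must lie in [0, 1]")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Matcher configuration
#'
#' Bundles the tunable parameters of the matcher: the candidate-pruning
#' threshold tau, the soft-formula weights, and which formula families are
#' grounded.  Defaults follow the reference setting: tau = 0.8,
#' stability weight -0.01, propagation weight +0.05, all five families
#' enabled.
#'
#' @slot tau Similarity threshold in (0, 1] for candidate generation.
#' @slot wStability Non-positive weight of the stability soft formulas.
#' @slot wPropagation Non-negative weight of the match-propagation soft
#'   formulas.
#' @slot enabled Character vector, subset of
#'   \code{c("prior","cardinality","coherence","stability","propagation")};
#'   "prior" is always included.
#' @slot useTransitiveSubForCoherence Logical; ground coherence constraints
#'   over the transitive is_a closure (default) or direct edges only.
#' @slot useDirectSubForSoft Logical; ground soft formulas over direct
#'   is_a/part_of edges (default) or their transitive closure.
#' @slot inclusiveTau Logical; keep candidates with similarity exactly equal
#'   to tau (default TRUE, so tau = 1 is an exact-label-match mode).
#'
#' @seealso \code{\link{matchConfig}}
#' @exportClass MatchConfig
setClass("MatchConfig",
  representation(
    tau = "numeric",
    wStability = "numeric",
    wPropagation = "numeric",
    enabled = "character",
    useTransitiveSubForCoherence = "logical",
    useDirectSubForSoft = "logical",
    inclusiveTau = "logical"
  ),
  prototype(
    tau = 0.8,
    wStability = -0.01,
    wPropagation = 0.05,
    enabled = c("prior", "cardinality", "coherence", "stability", "propagation"),
    useTransitiveSubForCoherence = TRUE,
    useDirectSubForSoft = TRUE,
    inclusiveTau = TRUE
  )
)

.formulaFamilies <- c("prior", "cardinality", "coherence", "stability", "propagation")

setValidity("MatchConfig", function(object) {
  msgs <- character(0)
  if (length(object@tau) != 1L || is.na(object@tau) ||
      object@tau <= 0 || object@tau > 1) {
    msgs <- c(msgs, "tau must be a single value in (0, 1]")
  }
  if (object@wStability > 0) msgs <- c(msgs, "wStability must be <= 0")
  if (object@wPropagation < 0) msgs <- c(msgs, "wPropagation must be >= 0")
  bad <- setdiff(object@enabled, .formulaFamilies)
  if (length(bad)) {
    msgs <- c(msgs, sprintf("unknown formula family: %s", paste(bad, collapse = ", ")))
  }
  if (!"prior" %in% object@enabled) {
    msgs <- c(msgs, "the prior family must always be enabled")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ground model: variables, hard constraints and weighted soft clauses
#'
#' The result of instantiating the matching formulas over a candidate set.
#' Each candidate correspondence contributes one binary decision variable
#' (its hidden map atom).  The model consists of per-variable prior
#' coefficients (the label similarities sigma), hard at-most-one groups
#' (cardinality), hard pairwise mutual exclusions (coherence), weighted
#' soft conjunctions (stability; reward w < 0 when both variables are
#' selected) and weighted soft implications (propagation; penalty w > 0
#' when the antecedent is selected and the consequent is not).
#'
#' @slot candidates Data frame with columns id1, id2, sigma, label1, label2,
#'   sorted by (id1, id2); row order defines the variable indexing.
#' @slot prior Numeric vector of per-variable objective coefficients.
#' @slot atMostOne List of integer vectors (variable indices); each group is
#'   an at-most-one constraint. Names encode the constrained class
#'   ("row:<id1>" / "col:<id2>").
#' @slot mutex Two-column integer matrix of mutually exclusive variable
#'   pairs (i < j, deduplicated).
#' @slot softConj Data frame (i, j, w) with w <= 0: reward w accrues when
#'   both variables are selected.
#' @slot softImpl Data frame (ant, cons, w) with w >= 0: penalty w accrues
#'   when ant is selected but cons is not.
#' @slot enabled Character vector of the formula families grounded.
#'
#' @seealso \code{\link{groundModel}}, \code{\link{solveMap}}
#' @exportClass GroundModel
setClass("GroundModel",
  representation(
    candidates = "data.frame",
    prior = "numeric",
    atMostOne = "list",
    mutex = "matrix",
    softConj = "data.frame",
    softImpl = "data.frame",
    enabled = "character"
  )
)

setValidity("GroundModel", function(object) {
  msgs <- character(0)
  n <- nrow(object@candidates)
  if (length(object@prior) && length(object@prior) != n) {
    msgs <- c(msgs, "prior must have one coefficient per candidate")
  }
  allIdx <- c(unlist(object@atMostOne, use.names = FALSE),
              as.vector(object@mutex),
              object@softConj$i, object@softConj$j,
              object@softImpl$ant, object@softImpl$cons)
  if (length(allIdx) && (min(allIdx) < 1L || max(allIdx) > n)) {
    msgs <- c(msgs, "constraint references a variable outside 1..n")
  }
  if (nrow(object@mutex) && any(object@mutex[, 1L] == object@mutex[, 2L])) {
    msgs <- c(msgs, "mutual exclusion must pair distinct variables")
  }
  if (nrow(object@softConj) && any(object@softConj$i == object@softConj$j)) {
    msgs <- c(msgs, "soft conjunction references the same variable twice")
  }
  if (nrow(object@softImpl) && any(object@softImpl$ant == object@softImpl$cons)) {
    msgs <- c(msgs, "soft implication references the same variable twice")
  }
  if (length(msgs)) msgs else TRUE
})

#' MAP solution
#'
#' The selected set of map atoms (candidate variables set true) together
#' with the achieved objective value and a solver status.
#'
#' @slot selected Sorted integer vector of selected variable indices.
#' @slot objective Achieved value of the MAP objective (prior terms plus
#'   soft-clause contributions; grounding constants dropped).
#' @slot status One of "optimal" or "time-limit" (best solution found when
#'   the time budget was exhausted before proving optimality).
#'
#' @seealso \code{\link{solveMap}}, \code{\link{bruteForceMap}},
#'   \code{\link{extractAlignment}}
#' @exportClass MapSolution
setClass("MapSolution",
  representation(selected = "integer", objective = "numeric", status = "character"),
  prototype(selected = integer(0), objective = 0, status = "optimal")
)

#' Alignment evaluation result
#'
#' Precision, recall and F-measure of a computed alignment against a
#' reference, with the underlying counts.
#'
#' @slot precision,recall,fMeasure Numeric scores in [0, 1].
#' @slot nCorrect,nComputed,nReference Integer counts.
#' @exportClass EvalResult
setClass("EvalResult",
  representation(
    precision = "numeric", recall = "numeric", fMeasure = "numeric",
    nCorrect = "integer", nComputed = "integer", nReference = "integer"
  )
)
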