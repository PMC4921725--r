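#' Construct an Ontology
#'
#' @param name Character tag for the ontology ("O1"/"O2" role).
#' @param labels Named list mapping each class id to a character vector of
#'   labels (may be empty for unmatchable classes).
#' @param subEdges,partEdges Two-column character matrices (or data frames)
#'   of direct is_a / part_of assertions, child/part first.
#' @param disjointPairs Two-column character matrix of disjoint class pairs;
#'   stored unordered (symmetric).
#' @return A validated \linkS4class{Ontology}.
#' @examples
#' o <- ontology("O1",
#'   labels = list(a = "heart", b = "organ"),
#'   subEdges = rbind(c("a", "b")))
#' nClasses(o)
#' @export
ontology <- function(name, labels = list(), subEdges = NULL, partEdges = NULL,
                     disjointPairs = NULL) {
  asEdge <- function(x) {
    if (is.null(x) || NROW(x) == 0L) return(.emptyEdgeMatrix())
    m <- as.matrix(x)
    storage.mode(m) <- "character"
    dimnames(m) <- list(NULL, c("from", "to"))
    m[!duplicated(m), , drop = FALSE]
  }
  dp <- if (is.null(disjointPairs) || NROW(disjointPairs) == 0L) {
    .emptyEdgeMatrix()
  } else {
    m <- as.matrix(disjointPairs)
    storage.mode(m) <- "character"
    m <- cbind(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
    dimnames(m) <- list(NULL, c("from", "to"))
    m[!duplicated(m), , drop = FALSE]
  }
  labels <- lapply(labels, as.character)
  new("Ontology", name = name, classIds = names(labels), labels = labels,
      subEdges = asEdge(subEdges), partEdges = asEdge(partEdges),
      disjointPairs = dp)
}

#' @rdname ontology
#' @param object,x An \code{Ontology}.
#' @export
nClasses <- function(x) length(x@classIds)

#' @rdname ontology
#' @export
classIds <- function(x) x@classIds

#' @rdname ontology
#' @param id A class id present in \code{x}.
#' @export
classLabels <- function(x, id = NULL) {
  if (is.null(id)) return(x@labels)
  if (!id %in% x@classIds) stop("unknown class id: ", id)
  x@labels[[id]]
}

#' @rdname ontology
#' @export
subEdges <- function(x) x@subEdges

#' @rdname ontology
#' @export
partEdges <- function(x) x@partEdges

#' @rdname ontology
#' @export
disjointPairs <- function(x) x@disjointPairs

setMethod("show", "Ontology", function(object) {
  cat(sprintf("Ontology \"%s\": %d classes, %d is_a, %d part_of, %d disjoint pairs\n",
    object@name, length(object@classIds), nrow(object@subEdges),
    nrow(object@partEdges), nrow(object@disjointPairs)))
})

#' Transitive ancestors under is_a or part_of
#'
#' Classes reachable from \code{id} by following direct edges of the chosen
#' relation; \code{id} itself is excluded.  Used by the coherence grounding,
#' where disjointness propagates to subclasses.
#'
#' @param x An \linkS4class{Ontology}.
#' @param relation "is_a" or "part_of".
#' @param id Class id to start from.
#' @return Character vector of ancestor ids (sorted).
#' @examples
#' o <- ontology("O", labels = list(a = "a", b = "b", c = "c"),
#'   subEdges = rbind(c("a", "b"), c("b", "c")))
#' ancestors(o, "is_a", "a")  # "b" "c"
#' @export
ancestors <- function(x, relation = c("is_a", "part_of"), id) {
  relation <- match.arg(relation)
  if (!id %in% x@classIds) stop("unknown class id: ", id)
  edges <- if (relation == "is_a") x@subEdges else x@partEdges
  adj <- split(edges[, 2L], edges[, 1L])
  seen <- character(0)
  frontier <- adj[[id]]
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- unlist(adj[frontier], use.names = FALSE)
  }
  sort(seen)
}

# Transitive closure of an edge set as a "from\rto" key set (internal).
.closureKeys <- function(edges, ids) {
  if (nrow(edges) == 0L) return(character(0))
  adj <- split(edges[, 2L], edges[, 1L])
  keys <- character(0)
  for (v in unique(edges[, 1L])) {
    seen <- character(0)
    frontier <- adj[[v]]
    while (length(frontier)) {
      frontier <- setdiff(unique(frontier), seen)
      seen <- c(seen, frontier)
      frontier <- unlist(adj[frontier], use.names = FALSE)
    }
    keys <- c(keys, paste(v, seen, sep = "\r"))
  }
  keys
}

#' Construct an Alignment
#'
#' @param id1,id2 Character vectors of corresponding class ids.
#' @param confidence Numeric confidences in [0, 1] (default 1).
#' @return A validated \linkS4class{Alignment}, sorted by (id1, id2).
#' @examples
#' alignment(c("a", "b"), c("x", "y"), c(0.9, 1))
#' @export
alignment <- function(id1 = character(0), id2 = character(0),
                      confidence = rep(1, length(id1))) {
  ord <- order(id1, id2)
  new("Alignment", id1 = as.character(id1)[ord], id2 = as.character(id2)[ord],
      confidence = as.numeric(confidence)[ord])
}

#' @describeIn alignment Number of correspondences.
#' @param x An \code{Alignment}.
#' @export
setMethod("length", "Alignment", function(x) length(x@id1))

#' @describeIn alignment Coerce to a data frame (id1, id2, confidence).
#' @export
alignmentTable <- function(x) {
  data.frame(id1 = x@id1, id2 = x@id2, confidence = x@confidence,
             stringsAsFactors = FALSE)
}

setMethod("show", "Alignment", function(object) {
  cat(sprintf("Alignment with %d correspondence(s)\n", length(object@id1)))
  if (length(object@id1)) {
    print(utils::head(alignmentTable(object), 6L))
    if (length(object@id1) > 6L) cat("...\n")
  }
})

#' Construct a matcher configuration
#'
#' @param tau Candidate-pruning similarity threshold in (0, 1].
#' @param wStability Weight (<= 0) of the stability soft formulas.
#' @param wPropagation Weight (>= 0) of the match-propagation soft formulas.
#' @param setting Convenience alias selecting a formula-family subset:
#'   "prior", "ca", "ca+co", "ca+co+st" or "ca+co+st+mp" (the default, the
#'   full model).  Ignored when \code{enabled} is given.
#' @param enabled Explicit character vector of enabled families (must
#'   include "prior").
#' @param useTransitiveSubForCoherence,useDirectSubForSoft See
#'   \linkS4class{MatchConfig}.
#' @param inclusiveTau Keep candidates with similarity exactly tau.
#' @return A validated \linkS4class{MatchConfig}.
#' @examples
#' matchConfig(tau = 0.8, setting = "ca+co")
#' @export
matchConfig <- function(tau = 0.8, wStability = -0.01, wPropagation = 0.05,
                        setting = "ca+co+st+mp", enabled = NULL,
                        useTransitiveSubForCoherence = TRUE,
                        useDirectSubForSoft = TRUE,
                        inclusiveTau = TRUE) {
  if (is.null(enabled)) enabled <- settingFamilies(setting)
  new("MatchConfig", tau = tau, wStability = wStability,
      wPropagation = wPropagation, enabled = enabled,
      useTransitiveSubForCoherence = useTransitiveSubForCoherence,
      useDirectSubForSoft = useDirectSubForSoft,
      inclusiveTau = inclusiveTau)
}

#' @describeIn matchConfig Expand a setting alias to its formula families.
#' @export
settingFamilies <- function(setting) {
  switch(setting,
    "prior" = "prior",
    "ca" = c("prior", "cardinality"),
    "ca+co" = c("prior", "cardinality", "coherence"),
    "ca+co+st" = c("prior", "cardinality", "coherence", "stability"),
    "ca+co+st+mp" = .formulaFamilies,
    stop("unknown setting: ", setting,
         " (expected one of prior, ca, ca+co, ca+co+st, ca+co+st+mp)"))
}

setMethod("show", "MatchConfig", function(object) {
  cat(sprintf("MatchConfig: tau=%g, wStability=%g, wPropagation=%g\n  families: %s\n",
    object@tau, object@wStability, object@wPropagation,
    paste(object@enabled, collapse = ", ")))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("precision %.4f  recall %.4f  F-measure %.4f  (%d correct / %d computed / %d reference)\n",
    object@precision, object@recall, object@fMeasure,
    object@nCorrect, object@nComputed, object@nReference))
})
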