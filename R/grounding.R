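# Formula grounding: instantiate the matching formulas over the candidate
# set.  Candidates are the only map atoms in the model; pairs pruned by the
# similarity threshold are clamped false, so every grounding is restricted
# to candidate pairs (evidence-only grounding).

.candKey <- function(candidates) paste(candidates$id1, candidates$id2, sep = "\r")

# Edge set as a key environment for O(1) membership tests.
.edgeKeySet <- function(edges, transitive, ids) {
  keys <- if (transitive) .closureKeys(edges, ids)
          else if (nrow(edges)) paste(edges[, 1L], edges[, 2L], sep = "\r")
          else character(0)
  env <- new.env(parent = emptyenv(), size = max(1L, length(keys)))
  for (k in keys) assign(k, TRUE, envir = env)
  env
}

.hasEdge <- function(set, a, b) {
  exists(paste(a, b, sep = "\r"), envir = set, inherits = FALSE)
}

#' Ground the a priori confidence formula
#'
#' One objective term per candidate, with coefficient equal to its label
#' similarity sigma: selecting a candidate contributes sigma to the MAP
#' objective.
#'
#' @param candidates Candidate data frame (see
#'   \code{\link{generateCandidates}}).
#' @return Numeric vector of per-variable coefficients.
#' @export
groundPrior <- function(candidates) {
  as.numeric(candidates$sigma)
}

#' Ground the one-to-one cardinality constraints
#'
#' For each class appearing in more than one candidate on its side, a hard
#' at-most-one constraint over the corresponding variables: a class of one
#' ontology can be equivalent to at most one class of the other.  Groups of
#' size one are omitted (vacuous).
#'
#' @inheritParams groundPrior
#' @return List of integer variable-index vectors, named "row:<id1>" or
#'   "col:<id2>".
#' @export
groundCardinality <- function(candidates) {
  n <- nrow(candidates)
  rows <- split(seq_len(n), candidates$id1)
  cols <- split(seq_len(n), candidates$id2)
  if (length(rows)) names(rows) <- paste0("row:", names(rows))
  if (length(cols)) names(cols) <- paste0("col:", names(cols))
  groups <- c(rows, cols)
  groups[lengths(groups) >= 2L]
}

#' Ground the coherence constraints
#'
#' Hard mutual exclusions forbidding incoherent pairs of correspondences:
#' two classes in a subclass relationship in one ontology must not map to
#' two disjoint classes of the other.  For candidates c = (a1, a2) and
#' d = (b1, b2), c and d are mutually exclusive when a1 is_a b1 and
#' {a2, b2} are disjoint, or {a1, b1} are disjoint and a2 is_a b2.  The
#' subclass test uses the transitive is_a closure when
#' \code{cfg@useTransitiveSubForCoherence} (default; disjointness is
#' inherited by subclasses), else direct edges.
#'
#' @param o1,o2 \linkS4class{Ontology} objects.
#' @param candidates Candidate data frame.
#' @param cfg A \linkS4class{MatchConfig}.
#' @return Two-column integer matrix of mutually exclusive variable pairs
#'   (i < j, deduplicated, sorted).
#' @export
groundCoherence <- function(o1, o2, candidates, cfg = matchConfig()) {
  n <- nrow(candidates)
  out <- list()
  if (n >= 2L) {
    sub1 <- .edgeKeySet(o1@subEdges, cfg@useTransitiveSubForCoherence, o1@classIds)
    sub2 <- .edgeKeySet(o2@subEdges, cfg@useTransitiveSubForCoherence, o2@classIds)
    by1 <- split(seq_len(n), candidates$id1)
    by2 <- split(seq_len(n), candidates$id2)
    # sub in O1, disjoint in O2
    dp2 <- o2@disjointPairs
    for (r in seq_len(nrow(dp2))) {
      for (swap in c(FALSE, TRUE)) {
        x2 <- dp2[r, if (swap) 2L else 1L]; y2 <- dp2[r, if (swap) 1L else 2L]
        for (ci in by2[[x2]]) for (di in by2[[y2]]) {
          if (ci != di && .hasEdge(sub1, candidates$id1[[ci]], candidates$id1[[di]])) {
            out[[length(out) + 1L]] <- c(min(ci, di), max(ci, di))
          }
        }
      }
    }
    # disjoint in O1, sub in O2
    dp1 <- o1@disjointPairs
    for (r in seq_len(nrow(dp1))) {
      for (swap in c(FALSE, TRUE)) {
        x1 <- dp1[r, if (swap) 2L else 1L]; y1 <- dp1[r, if (swap) 1L else 2L]
        for (ci in by1[[x1]]) for (di in by1[[y1]]) {
          if (ci != di && .hasEdge(sub2, candidates$id2[[ci]], candidates$id2[[di]])) {
            out[[length(out) + 1L]] <- c(min(ci, di), max(ci, di))
          }
        }
      }
    }
  }
  m <- if (length(out)) do.call(rbind, out) else matrix(integer(0), ncol = 2L)
  m <- m[!duplicated(m), , drop = FALSE]
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("i", "j"))
  m
}

.emptyConj <- function() data.frame(i = integer(0), j = integer(0), w = numeric(0))
.emptyImpl <- function() data.frame(ant = integer(0), cons = integer(0), w = numeric(0))

#' Ground the stability constraints
#'
#' Weighted soft conjunctions penalizing alignments that introduce new
#' structural knowledge: if a1 is_a b1 but a2 is not a subclass of b2 (or
#' vice versa), selecting both (a1, a2) and (b1, b2) incurs the (negative)
#' stability weight.  Uses direct is_a edges by default
#' (\code{cfg@useDirectSubForSoft}).
#'
#' @inheritParams groundCoherence
#' @return Data frame (i, j, w) of soft conjunctions, w = cfg@wStability.
#' @export
groundStability <- function(o1, o2, candidates, cfg = matchConfig()) {
  stopifnot(cfg@wStability <= 0)
  n <- nrow(candidates)
  if (n < 2L) return(.emptyConj())
  direct <- cfg@useDirectSubForSoft
  sub1 <- .edgeKeySet(o1@subEdges, !direct, o1@classIds)
  sub2 <- .edgeKeySet(o2@subEdges, !direct, o2@classIds)
  sub1keys <- ls(sub1); sub2keys <- ls(sub2)
  by1 <- split(seq_len(n), candidates$id1)
  by2 <- split(seq_len(n), candidates$id2)
  out <- list()
  # a1 is_a b1 but not a2 is_a b2
  for (k in sub1keys) {
    ab <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    for (ci in by1[[ab[[1L]]]]) for (di in by1[[ab[[2L]]]]) {
      if (ci != di && !.hasEdge(sub2, candidates$id2[[ci]], candidates$id2[[di]])) {
        out[[length(out) + 1L]] <- c(ci, di)
      }
    }
  }
  # a2 is_a b2 but not a1 is_a b1
  for (k in sub2keys) {
    ab <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    for (ci in by2[[ab[[1L]]]]) for (di in by2[[ab[[2L]]]]) {
      if (ci != di && !.hasEdge(sub1, candidates$id1[[ci]], candidates$id1[[di]])) {
        out[[length(out) + 1L]] <- c(ci, di)
      }
    }
  }
  if (!length(out)) return(.emptyConj())
  m <- do.call(rbind, out)
  df <- data.frame(i = m[, 1L], j = m[, 2L], w = cfg@wStability)
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Ground the match-propagation formulas
#'
#' Weighted soft implications rewarding structure-consistent alignments: if
#' a1 is_a b1 and a2 is_a b2, then selecting the child pair (a1, a2) while
#' rejecting the parent pair (b1, b2) incurs the (positive) propagation
#' weight as a penalty; the same holds along matching part_of edges.  When
#' both the is_a and part_of conditions hold for a candidate pair, two
#' groundings (hence two penalties) are emitted.
#'
#' @inheritParams groundCoherence
#' @return Data frame (ant, cons, w) of soft implications,
#'   w = cfg@wPropagation.
#' @export
groundPropagation <- function(o1, o2, candidates, cfg = matchConfig()) {
  stopifnot(cfg@wPropagation >= 0)
  n <- nrow(candidates)
  if (n < 2L) return(.emptyImpl())
  direct <- cfg@useDirectSubForSoft
  by1 <- split(seq_len(n), candidates$id1)
  out <- list()
  for (rel in c("sub", "part")) {
    e1 <- if (rel == "sub") o1@subEdges else o1@partEdges
    e2 <- if (rel == "sub") o2@subEdges else o2@partEdges
    set1 <- .edgeKeySet(e1, !direct, o1@classIds)
    set2 <- .edgeKeySet(e2, !direct, o2@classIds)
    for (k in ls(set1)) {
      ab <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      for (ci in by1[[ab[[1L]]]]) for (di in by1[[ab[[2L]]]]) {
        if (ci != di && .hasEdge(set2, candidates$id2[[ci]], candidates$id2[[di]])) {
          out[[length(out) + 1L]] <- c(ci, di)
        }
      }
    }
  }
  if (!length(out)) return(.emptyImpl())
  m <- do.call(rbind, out)
  df <- data.frame(ant = m[, 1L], cons = m[, 2L], w = cfg@wPropagation)
  df <- df[order(df$ant, df$cons), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the full ground model
#'
#' Instantiates the enabled formula families over the candidate set and
#' assembles the \linkS4class{GroundModel}.  Candidates are sorted by
#' (id1, id2) so that variable indexing, and hence the whole model, is
#' deterministic.  Disabled families contribute nothing; the prior family
#' is always present.
#'
#' @inheritParams groundCoherence
#' @return A \linkS4class{GroundModel}.
#' @examples
#' o1 <- ontology("O1", labels = list(a = "heart", b = "organ"),
#'   subEdges = rbind(c("a", "b")))
#' o2 <- ontology("O2", labels = list(x = "heart", y = "organ"),
#'   subEdges = rbind(c("x", "y")))
#' gm <- groundModel(o1, o2, generateCandidates(o1, o2, 0.8))
#' gm
#' @export
groundModel <- function(o1, o2, candidates, cfg = matchConfig()) {
  ord <- order(candidates$id1, candidates$id2)
  candidates <- candidates[ord, , drop = FALSE]
  rownames(candidates) <- NULL
  fam <- cfg@enabled
  new("GroundModel",
    candidates = candidates,
    prior = groundPrior(candidates),
    atMostOne = if ("cardinality" %in% fam) groundCardinality(candidates) else list(),
    mutex = if ("coherence" %in% fam) groundCoherence(o1, o2, candidates, cfg)
            else matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))),
    softConj = if ("stability" %in% fam) groundStability(o1, o2, candidates, cfg)
               else .emptyConj(),
    softImpl = if ("propagation" %in% fam) groundPropagation(o1, o2, candidates, cfg)
               else .emptyImpl(),
    enabled = fam)
}

setMethod("show", "GroundModel", function(object) {
  cat(sprintf(paste0(
    "GroundModel: %d variable(s)\n",
    "  at-most-one groups: %d, mutual exclusions: %d\n",
    "  soft conjunctions: %d, soft implications: %d\n",
    "  families: %s\n"),
    nrow(object@candidates), length(object@atMostOne), nrow(object@mutex),
    nrow(object@softConj), nrow(object@softImpl),
    paste(object@enabled, collapse = ", ")))
})

#' Dump a ground model as text (debugging aid)
#'
#' One line per variable, hard constraint and soft clause; suitable for
#' diffing against an independently produced grounding.
#'
#' @param model A \linkS4class{GroundModel}.
#' @param path Output path, or "" for stdout.
#' @return \code{path}, invisibly.
#' @export
dumpGroundModel <- function(model, path = "") {
  cand <- model@candidates
  lines <- c(
    sprintf("var %d map(%s,%s) sigma=%.6f", seq_len(nrow(cand)),
            cand$id1, cand$id2, cand$sigma),
    vapply(names(model@atMostOne), function(nm) {
      sprintf("atmostone %s: %s", nm,
              paste(model@atMostOne[[nm]], collapse = " "))
    }, character(1)),
    if (nrow(model@mutex)) sprintf("mutex %d %d", model@mutex[, 1L], model@mutex[, 2L]),
    if (nrow(model@softConj)) sprintf("conj %d %d w=%.6f", model@softConj$i,
                                      model@softConj$j, model@softConj$w),
    if (nrow(model@softImpl)) sprintf("impl %d -> %d w=%.6f", model@softImpl$ant,
                                      model@softImpl$cons, model@softImpl$w))
  writeLines(lines, path)
  invisible(path)
}
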