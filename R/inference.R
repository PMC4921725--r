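# MAP inference over a ground model.  The model is a 0-1 program:
#   maximize  sum_i sigma_i x_i  +  sum_{(i,j,w) in conj: w<0} w * x_i x_j
#             - sum_{(a,c,w) in impl: w>0} w * x_a (1 - x_c)
#   s.t.      sum_{i in G} x_i <= 1         for each at-most-one group G
#             x_i + x_j <= 1                for each mutual exclusion
# solved exactly by branch and bound after decomposing the variable
# interaction graph into connected components.  The all-zero assignment is
# always feasible (objective 0), so the program is never infeasible.

#' Objective value of a selection
#'
#' Recomputes the MAP objective for an explicit set of selected variables:
#' the sum of prior coefficients over the selection, plus each soft
#' conjunction's (negative) weight when both its variables are selected,
#' minus each soft implication's (positive) weight when its antecedent is
#' selected but its consequent is not.  Grounding constants are dropped
#' throughout, so the empty selection has objective 0.
#'
#' @param model A \linkS4class{GroundModel}.
#' @param selected Integer vector of selected variable indices.
#' @return A single numeric value.
#' @export
objectiveValue <- function(model, selected) {
  n <- nrow(model@candidates)
  selected <- as.integer(selected)
  if (length(selected) && (min(selected) < 1L || max(selected) > n)) {
    stop("selected references a variable outside 1..", n)
  }
  inSel <- logical(n)
  inSel[selected] <- TRUE
  val <- sum(model@prior[selected])
  if (nrow(model@softConj)) {
    val <- val + sum(model@softConj$w[inSel[model@softConj$i] & inSel[model@softConj$j]])
  }
  if (nrow(model@softImpl)) {
    val <- val - sum(model@softImpl$w[inSel[model@softImpl$ant] & !inSel[model@softImpl$cons]])
  }
  val
}

# Hard-constraint feasibility of a 0/1 selection vector.
.feasible <- function(model, inSel) {
  for (g in model@atMostOne) if (sum(inSel[g]) > 1L) return(FALSE)
  if (nrow(model@mutex) &&
      any(inSel[model@mutex[, 1L]] & inSel[model@mutex[, 2L]])) return(FALSE)
  TRUE
}

# Connected components of the variable interaction graph (shared hard
# constraint or soft clause); singletons solved in closed form.
.components <- function(model) {
  n <- nrow(model@candidates)
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[[v]] != v) {
      parent[[v]] <<- parent[[parent[[v]]]]
      v <- parent[[v]]
    }
    v
  }
  link <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[[rb]] <<- ra
  }
  for (g in model@atMostOne) {
    for (k in seq_along(g)[-1L]) link(g[[1L]], g[[k]])
  }
  if (nrow(model@mutex)) {
    for (r in seq_len(nrow(model@mutex))) link(model@mutex[r, 1L], model@mutex[r, 2L])
  }
  for (r in seq_len(nrow(model@softConj))) {
    link(model@softConj$i[[r]], model@softConj$j[[r]])
  }
  for (r in seq_len(nrow(model@softImpl))) {
    link(model@softImpl$ant[[r]], model@softImpl$cons[[r]])
  }
  split(seq_len(n), vapply(seq_len(n), find, integer(1)))
}

# Exact branch and bound over one component.  Variables are explored in
# decreasing-sigma order, 1-branch first; the admissible upper bound is the
# current partial objective plus the sigma of all undecided variables
# (conjunction weights are <= 0 and implications only penalize, so both can
# be ignored in the bound).
.solveComponent <- function(model, vars, deadline) {
  m <- length(vars)
  ord <- vars[order(-model@prior[vars], vars)]
  sigma <- model@prior[ord]
  suffix <- rev(cumsum(rev(pmax(sigma, 0))))
  pos <- integer(nrow(model@candidates))
  pos[ord] <- seq_len(m)
  # per-position clause lists against earlier-decided positions
  conjAt <- implAt <- groupAt <- mutexAt <- vector("list", m)
  addTo <- function(lst, p, entry) { lst[[p]] <- c(lst[[p]], list(entry)); lst }
  for (r in seq_len(nrow(model@softConj))) {
    pi <- pos[[model@softConj$i[[r]]]]; pj <- pos[[model@softConj$j[[r]]]]
    if (pi == 0L || pj == 0L) next
    hi <- max(pi, pj)
    conjAt <- addTo(conjAt, hi, c(min(pi, pj), model@softConj$w[[r]]))
  }
  for (r in seq_len(nrow(model@softImpl))) {
    pa <- pos[[model@softImpl$ant[[r]]]]; pc <- pos[[model@softImpl$cons[[r]]]]
    if (pa == 0L || pc == 0L) next
    hi <- max(pa, pc)
    implAt <- addTo(implAt, hi, c(pa, pc, model@softImpl$w[[r]]))
  }
  for (g in model@atMostOne) {
    p <- sort(pos[g]); p <- p[p > 0L]
    if (length(p) >= 2L) {
      for (k in seq_along(p)[-1L]) {
        groupAt <- addTo(groupAt, p[[k]], p[seq_len(k - 1L)])
      }
    }
  }
  if (nrow(model@mutex)) {
    for (r in seq_len(nrow(model@mutex))) {
      pi <- pos[[model@mutex[r, 1L]]]; pj <- pos[[model@mutex[r, 2L]]]
      if (pi > 0L && pj > 0L) mutexAt <- addTo(mutexAt, max(pi, pj), min(pi, pj))
    }
  }
  state <- logical(m)
  best <- list(obj = 0, sel = logical(m))
  timedOut <- FALSE
  eps <- 1e-9
  delta <- function(p, value) {
    d <- if (value) sigma[[p]] else 0
    for (e in conjAt[[p]]) {
      if (value && state[[e[[1L]]]]) d <- d + e[[2L]]
    }
    for (e in implAt[[p]]) {
      pa <- e[[1L]]; pc <- e[[2L]]
      if (pa == p) { if (value && !state[[pc]]) d <- d - e[[3L]] }
      else if (!value && state[[pa]]) d <- d - e[[3L]]
    }
    d
  }
  recurse <- function(p, cur) {
    if (timedOut) return()
    if (p > m) {
      if (cur > best$obj + eps) best <<- list(obj = cur, sel = state)
      return()
    }
    if (!is.null(deadline) && p %% 8L == 0L && Sys.time() > deadline) {
      timedOut <<- TRUE
      return()
    }
    rest <- if (p < m) suffix[[p + 1L]] else 0
    if (cur + sigma[[p]] + rest <= best$obj + eps) return()
    # 1-branch, if hard-feasible against decided variables
    ok <- TRUE
    for (g in groupAt[[p]]) if (any(state[g])) { ok <- FALSE; break }
    if (ok) for (q in mutexAt[[p]]) if (state[[q]]) { ok <- FALSE; break }
    if (ok) {
      state[[p]] <<- TRUE
      recurse(p + 1L, cur + delta(p, TRUE))
      state[[p]] <<- FALSE
    }
    if (cur + rest > best$obj + eps) {
      recurse(p + 1L, cur + delta(p, FALSE))
    }
  }
  # evaluate delta for value=FALSE correctly: implications with decided
  # antecedent TRUE and this consequent FALSE fire at decision time, which
  # only works when the antecedent position precedes; implAt stores each
  # clause at the later of its two positions, so exactly one endpoint is
  # undecided when it is applied.
  recurse(1L, 0)
  list(selected = ord[best$sel], timedOut = timedOut)
}

#' Exact MAP inference by branch and bound
#'
#' Solves the 0-1 optimization problem encoded by a
#' \linkS4class{GroundModel}: maximize the prior terms plus soft-clause
#' contributions subject to the hard at-most-one and mutual-exclusion
#' constraints.  The variable interaction graph is decomposed into
#' connected components, each solved exactly by depth-first branch and
#' bound with an admissible prior-sum bound; at typical problem sizes most
#' components are singletons or small conflict clusters, so the search is
#' fast despite worst-case exponential complexity.
#'
#' @param model A \linkS4class{GroundModel}.
#' @param timeLimit Wall-clock budget in seconds (default 300).  If
#'   exhausted, the best solution found so far is returned with status
#'   "time-limit".
#' @return A \linkS4class{MapSolution}; status "optimal" unless the time
#'   limit was hit.
#' @seealso \code{\link{bruteForceMap}} for the exhaustive oracle,
#'   \code{\link{extractAlignment}}.
#' @export
solveMap <- function(model, timeLimit = 300) {
  deadline <- if (is.finite(timeLimit)) Sys.time() + timeLimit else NULL
  selected <- integer(0)
  timedOut <- FALSE
  for (comp in .components(model)) {
    if (length(comp) == 1L) {
      # isolated variable: select iff its prior is positive
      if (model@prior[[comp]] > 0) selected <- c(selected, comp)
    } else {
      res <- .solveComponent(model, comp, deadline)
      selected <- c(selected, res$selected)
      timedOut <- timedOut || res$timedOut
    }
  }
  selected <- sort(selected)
  new("MapSolution", selected = selected,
      objective = objectiveValue(model, selected),
      status = if (timedOut) "time-limit" else "optimal")
}

#' Exhaustive MAP oracle
#'
#' Enumerates every subset of the model's variables, filters by the hard
#' constraints and maximizes the objective.  Ties are broken toward the
#' lexicographically smallest selected-index set.  Refuses models with more
#' than 20 variables.  Intended as an independent correctness oracle for
#' \code{\link{solveMap}} on small instances.
#'
#' @param model A \linkS4class{GroundModel} with at most 20 variables.
#' @return A \linkS4class{MapSolution} with status "optimal".
#' @export
bruteForceMap <- function(model) {
  n <- nrow(model@candidates)
  if (n > 20L) stop("bruteForceMap refuses models with more than 20 variables (got ", n, ")")
  if (n == 0L) return(new("MapSolution", selected = integer(0), objective = 0,
                          status = "optimal"))
  masks <- 0:(2^n - 1L)
  S <- matrix(FALSE, nrow = length(masks), ncol = n)
  for (v in seq_len(n)) S[, v] <- bitwAnd(masks, bitwShiftL(1L, v - 1L)) != 0L
  obj <- as.numeric(S %*% model@prior)
  if (nrow(model@softConj)) {
    for (r in seq_len(nrow(model@softConj))) {
      obj <- obj + model@softConj$w[[r]] *
        (S[, model@softConj$i[[r]]] & S[, model@softConj$j[[r]]])
    }
  }
  if (nrow(model@softImpl)) {
    for (r in seq_len(nrow(model@softImpl))) {
      obj <- obj - model@softImpl$w[[r]] *
        (S[, model@softImpl$ant[[r]]] & !S[, model@softImpl$cons[[r]]])
    }
  }
  feas <- rep(TRUE, length(masks))
  for (g in model@atMostOne) feas <- feas & rowSums(S[, g, drop = FALSE]) <= 1L
  if (nrow(model@mutex)) {
    for (r in seq_len(nrow(model@mutex))) {
      feas <- feas & !(S[, model@mutex[r, 1L]] & S[, model@mutex[r, 2L]])
    }
  }
  obj[!feas] <- -Inf
  bestObj <- max(obj)
  ties <- which(obj >= bestObj - 1e-12)
  # lexicographically smallest selected-index set among ties
  keyOf <- function(row) paste(sprintf("%06d", which(S[row, ])), collapse = ",")
  bestRow <- ties[order(vapply(ties, keyOf, character(1)))][[1L]]
  sel <- which(S[bestRow, ])
  new("MapSolution", selected = as.integer(sel),
      objective = objectiveValue(model, sel), status = "optimal")
}

setMethod("show", "MapSolution", function(object) {
  cat(sprintf("MapSolution (%s): %d selected, objective %.6f\n",
    object@status, length(object@selected), object@objective))
})

#' Extract the alignment from a MAP solution
#'
#' One equivalence correspondence per selected candidate, with confidence
#' equal to the candidate's label similarity sigma; sorted by (id1, id2).
#'
#' @param model The \linkS4class{GroundModel} that was solved.
#' @param sol The corresponding \linkS4class{MapSolution}.
#' @return An \linkS4class{Alignment}.
#' @export
extractAlignment <- function(model, sol) {
  cand <- model@candidates[sol@selected, , drop = FALSE]
  alignment(cand$id1, cand$id2, cand$sigma)
}

#' Export the compiled 0-1 program in LP format
#'
#' Writes the model as a standard LP file (maximization objective with
#' auxiliary product variables for soft conjunctions and penalty variables
#' for soft implications), for solver-independent debugging.  Product
#' variables are declared binary; penalty variables are continuous in
#' [0, 1], which the constraint structure forces to take the correct value
#' at any optimum.
#'
#' @param model A \linkS4class{GroundModel}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
exportLp <- function(model, path) {
  n <- nrow(model@candidates)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  terms <- sprintf("%+.9g x%d", model@prior, seq_len(n))
  nc <- nrow(model@softConj); ni <- nrow(model@softImpl)
  if (nc) terms <- c(terms, sprintf("%+.9g y%d", model@softConj$w, seq_len(nc)))
  if (ni) terms <- c(terms, sprintf("%+.9g p%d", -model@softImpl$w, seq_len(ni)))
  w("Maximize")
  w(" obj: %s", paste(terms, collapse = " "))
  w("Subject To")
  k <- 0L
  for (g in model@atMostOne) {
    k <- k + 1L
    w(" amo%d: %s <= 1", k, paste(sprintf("x%d", g), collapse = " + "))
  }
  if (nrow(model@mutex)) {
    for (r in seq_len(nrow(model@mutex))) {
      w(" mx%d: x%d + x%d <= 1", r, model@mutex[r, 1L], model@mutex[r, 2L])
    }
  }
  if (nc) {
    for (r in seq_len(nc)) {
      i <- model@softConj$i[[r]]; j <- model@softConj$j[[r]]
      w(" cj%da: y%d - x%d - x%d >= -1", r, r, i, j)
    }
  }
  if (ni) {
    for (r in seq_len(ni)) {
      w(" im%d: p%d - x%d + x%d >= 0", r, r,
        model@softImpl$ant[[r]], model@softImpl$cons[[r]])
    }
  }
  w("Bounds")
  if (ni) for (r in seq_len(ni)) w(" 0 <= p%d <= 1", r)
  w("Binary")
  w(" %s", paste(c(sprintf("x%d", seq_len(n)),
                   if (nc) sprintf("y%d", seq_len(nc))), collapse = " "))
  w("End")
  invisible(path)
}
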