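#' Match two ontologies end to end
#'
#' Runs the full pipeline: threshold-pruned candidate generation from label
#' similarity, grounding of the enabled formula families, exact MAP
#' inference, and alignment extraction; optionally scores the result
#' against a reference alignment.
#'
#' @param o1,o2 \linkS4class{Ontology} objects, or paths accepted by
#'   \code{\link{readOntology}}.
#' @param cfg A \linkS4class{MatchConfig}; see \code{\link{matchConfig}}.
#' @param reference Optional \linkS4class{Alignment} (or path) to score
#'   against.
#' @param timeLimit Solver wall-clock budget in seconds.
#' @param verbose Log stage progress to stderr.
#' @return A list (run report) with elements \code{config},
#'   \code{candidates} (data frame), \code{model}
#'   (\linkS4class{GroundModel}), \code{solution}
#'   (\linkS4class{MapSolution}), \code{alignment}
#'   (\linkS4class{Alignment}), \code{counts} (named numeric: candidates,
#'   atMostOne, mutex, softConj, softImpl, aligned), \code{evaluation}
#'   (\linkS4class{EvalResult} or NULL) and \code{timings} (named numeric,
#'   seconds per stage).
#' @examples
#' pair <- generateOntologyPair(nClasses = 25, labelMutationRate = 0,
#'                              dropRate = 0, seed = 3)
#' rep <- matchOntologies(pair$o1, pair$o2, reference = pair$truth)
#' rep$evaluation
#' @export
matchOntologies <- function(o1, o2, cfg = matchConfig(), reference = NULL,
                            timeLimit = 300, verbose = FALSE) {
  if (is.character(o1)) o1 <- readOntology(o1)
  if (is.character(o2)) o2 <- readOntology(o2)
  if (is.character(reference)) reference <- readAlignment(reference)
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() Sys.time()
  timings <- c()
  t0 <- tic()
  cand <- generateCandidates(o1, o2, tau = cfg@tau, inclusive = cfg@inclusiveTau)
  timings[["candidates"]] <- as.numeric(difftime(tic(), t0, units = "secs"))
  say("candidates: %d (tau=%g)", nrow(cand), cfg@tau)
  t0 <- tic()
  model <- groundModel(o1, o2, cand, cfg)
  timings[["grounding"]] <- as.numeric(difftime(tic(), t0, units = "secs"))
  say("ground model: %d amo, %d mutex, %d conj, %d impl",
      length(model@atMostOne), nrow(model@mutex),
      nrow(model@softConj), nrow(model@softImpl))
  t0 <- tic()
  sol <- solveMap(model, timeLimit = timeLimit)
  timings[["inference"]] <- as.numeric(difftime(tic(), t0, units = "secs"))
  say("solution: %s, objective %.6f, %d selected",
      sol@status, sol@objective, length(sol@selected))
  aln <- extractAlignment(model, sol)
  ev <- if (!is.null(reference)) scoreAlignment(aln, reference) else NULL
  list(
    config = cfg,
    candidates = cand,
    model = model,
    solution = sol,
    alignment = aln,
    counts = c(candidates = nrow(cand), atMostOne = length(model@atMostOne),
               mutex = nrow(model@mutex), softConj = nrow(model@softConj),
               softImpl = nrow(model@softImpl), aligned = length(aln@id1)),
    evaluation = ev,
    timings = timings)
}

#' Threshold/setting sweep
#'
#' Runs the matcher for every combination of threshold and formula-family
#' setting and scores each run against the reference alignment.  A failing
#' cell is recorded with NA scores and the sweep continues.
#'
#' @param o1,o2 Ontologies (or paths).
#' @param reference Reference \linkS4class{Alignment} (or path).
#' @param taus Numeric vector of thresholds (default 0.65 to 0.95 by 0.05).
#' @param settings Character vector of setting aliases (default all five:
#'   prior, ca, ca+co, ca+co+st, ca+co+st+mp).
#' @param ... Further arguments to \code{\link{matchConfig}}.
#' @param timeLimit Solver budget per cell in seconds.
#' @return Data frame with one row per (tau, setting): tau, setting,
#'   precision, recall, fMeasure, nAligned.
#' @export
sweepMatch <- function(o1, o2, reference, taus = seq(0.65, 0.95, by = 0.05),
                       settings = c("prior", "ca", "ca+co", "ca+co+st",
                                    "ca+co+st+mp"),
                       ..., timeLimit = 300) {
  if (is.character(o1)) o1 <- readOntology(o1)
  if (is.character(o2)) o2 <- readOntology(o2)
  if (is.character(reference)) reference <- readAlignment(reference)
  rows <- list()
  for (tau in taus) {
    for (setting in settings) {
      row <- tryCatch({
        cfg <- matchConfig(tau = tau, setting = setting, ...)
        rep <- matchOntologies(o1, o2, cfg, reference = reference,
                               timeLimit = timeLimit)
        ev <- rep$evaluation
        data.frame(tau = tau, setting = setting,
                   precision = ev@precision, recall = ev@recall,
                   fMeasure = ev@fMeasure,
                   nAligned = length(rep$alignment@id1))
      }, error = function(e) {
        warning(sprintf("sweep cell tau=%g setting=%s failed: %s",
                        tau, setting, conditionMessage(e)))
        data.frame(tau = tau, setting = setting, precision = NA_real_,
                   recall = NA_real_, fMeasure = NA_real_,
                   nAligned = NA_integer_)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
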