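test_that("objective value matches a naive loop recomputation", {
  empty <- randomGroundModel(4L, seed = 1)
  expect_equal(objectiveValue(empty, integer(0)), 0)
  one <- randomGroundModel(1L, seed = 2)
  expect_equal(objectiveValue(one, 1L), one@prior[[1L]])
  for (seed in 1:20) {
    model <- randomGroundModel(sample(2:10, 1L), seed = seed)
    n <- nrow(model@candidates)
    sel <- which(runif(n) < 0.5)
    expect_equal(objectiveValue(model, sel), naiveObjective(model, sel))
  }
  expect_error(objectiveValue(one, 5L), "outside")
})

test_that("brute-force oracle handles trivial models", {
  m0 <- randomGroundModel(1L, seed = 3)
  m0@prior <- 0.7
  m0@candidates$sigma <- 0.7
  sol <- bruteForceMap(m0)
  expect_equal(sol@selected, 1L)
  expect_equal(sol@objective, 0.7)
  big <- randomGroundModel(10L, seed = 4)
  expect_error({
    big21 <- randomGroundModel(21L, seed = 4); bruteForceMap(big21)
  }, "more than 20")
})

test_that("solver picks the dominant candidate under an at-most-one conflict", {
  cand <- data.frame(id1 = c("a1", "a1"), id2 = c("x2", "y2"),
                     sigma = c(0.9, 0.8), label1 = "l", label2 = "m")
  model <- new("GroundModel", candidates = cand, prior = cand$sigma,
               atMostOne = list(`row:a1` = c(1L, 2L)),
               mutex = matrix(integer(0), ncol = 2L),
               softConj = data.frame(i = integer(0), j = integer(0), w = numeric(0)),
               softImpl = data.frame(ant = integer(0), cons = integer(0), w = numeric(0)),
               enabled = c("prior", "cardinality"))
  sol <- solveMap(model)
  expect_equal(sol@selected, 1L)
  expect_equal(sol@objective, 0.9)
  expect_equal(sol@status, "optimal")
})

test_that("solver respects a mutual exclusion between the only two candidates", {
  cand <- data.frame(id1 = c("a1", "b1"), id2 = c("x2", "y2"),
                     sigma = c(0.9, 0.85), label1 = "l", label2 = "m")
  model <- new("GroundModel", candidates = cand, prior = cand$sigma,
               atMostOne = list(),
               mutex = matrix(c(1L, 2L), ncol = 2L),
               softConj = data.frame(i = integer(0), j = integer(0), w = numeric(0)),
               softImpl = data.frame(ant = integer(0), cons = integer(0), w = numeric(0)),
               enabled = c("prior", "coherence"))
  sol <- solveMap(model)
  expect_equal(sol@selected, 1L)
  expect_equal(sol@objective, 0.9)
})

test_that("branch-and-bound objective equals the exhaustive optimum", {
  for (seed in 1:60) {
    model <- randomGroundModel(sample(2:12, 1L), seed = 1000 + seed)
    got <- solveMap(model)
    want <- bruteForceMap(model)
    expect_equal(got@objective, want@objective, tolerance = 1e-12)
    expect_equal(got@status, "optimal")
    # reported objective is consistent with its own selection
    expect_equal(got@objective, objectiveValue(model, got@selected))
    # and the selection is hard-feasible
    inSel <- logical(nrow(model@candidates)); inSel[got@selected] <- TRUE
    for (g in model@atMostOne) expect_lte(sum(inSel[g]), 1L)
    if (nrow(model@mutex)) {
      expect_false(any(inSel[model@mutex[, 1L]] & inSel[model@mutex[, 2L]]))
    }
  }
})

test_that("with no conflicts and no soft clauses every candidate is selected", {
  model <- randomGroundModel(8L, seed = 77)
  model@atMostOne <- list()
  model@mutex <- matrix(integer(0), ncol = 2L)
  model@softConj <- data.frame(i = integer(0), j = integer(0), w = numeric(0))
  model@softImpl <- data.frame(ant = integer(0), cons = integer(0), w = numeric(0))
  sol <- solveMap(model)
  expect_equal(sol@selected, seq_len(8L))
  expect_equal(sol@objective, sum(model@prior))
})

test_that("weight signs steer the solution as expected", {
  # two structure-violating candidates: a strong conjunction penalty
  # eventually forces dropping the weaker one
  cand <- data.frame(id1 = c("a1", "b1"), id2 = c("x2", "y2"),
                     sigma = c(0.9, 0.7), label1 = "l", label2 = "m")
  mkModel <- function(w) {
    new("GroundModel", candidates = cand, prior = cand$sigma,
        atMostOne = list(), mutex = matrix(integer(0), ncol = 2L),
        softConj = data.frame(i = 1L, j = 2L, w = w),
        softImpl = data.frame(ant = integer(0), cons = integer(0), w = numeric(0)),
        enabled = c("prior", "stability"))
  }
  violations <- vapply(c(-0.01, -0.5, -0.8), function(w) {
    sol <- solveMap(mkModel(w))
    as.integer(length(sol@selected) == 2L)
  }, integer(1))
  expect_true(all(diff(violations) <= 0L))

  # raising the propagation weight never unsatisfies an implication:
  # the consequent competes with a higher-sigma rival under at-most-one,
  # so only a large enough penalty pulls it into the solution
  candP <- data.frame(id1 = c("a1", "b1", "c1"), id2 = c("x2", "y2", "y2"),
                      sigma = c(0.9, 0.66, 0.7), label1 = "l", label2 = "m")
  mkModelP <- function(w) {
    new("GroundModel", candidates = candP, prior = candP$sigma,
        atMostOne = list(`col:y2` = c(2L, 3L)),
        mutex = matrix(integer(0), ncol = 2L),
        softConj = data.frame(i = integer(0), j = integer(0), w = numeric(0)),
        softImpl = data.frame(ant = 1L, cons = 2L, w = w),
        enabled = c("prior", "cardinality", "propagation"))
  }
  satisfied <- vapply(c(0, 0.05, 0.5), function(w) {
    sol <- solveMap(mkModelP(w))
    as.integer(!(1L %in% sol@selected) || (2L %in% sol@selected))
  }, integer(1))
  expect_equal(satisfied[[1L]], 0L)
  expect_equal(satisfied[[3L]], 1L)
  expect_true(all(diff(satisfied) >= 0L))
})

test_that("extracted alignments are one-to-one and carry sigma as confidence", {
  for (seed in c(21, 22, 23)) {
    pair <- generateOntologyPair(nClasses = 40, labelMutationRate = 0.1,
                                 dropRate = 0.1, seed = seed)
    rep <- matchOntologies(pair$o1, pair$o2, matchConfig(tau = 0.7))
    aln <- rep$alignment
    expect_false(anyDuplicated(aln@id1) > 0)
    expect_false(anyDuplicated(aln@id2) > 0)
    # confidences equal the candidate sigmas
    key <- paste(rep$candidates$id1, rep$candidates$id2)
    expect_equal(aln@confidence,
                 rep$candidates$sigma[match(paste(aln@id1, aln@id2), key)])
    # no coherence mutual exclusion violated
    mx <- rep$model@mutex
    if (nrow(mx)) {
      inSel <- logical(nrow(rep$model@candidates))
      inSel[rep$solution@selected] <- TRUE
      expect_false(any(inSel[mx[, 1L]] & inSel[mx[, 2L]]))
    }
  }
})

test_that("empty models solve to the empty alignment with objective zero", {
  oA <- ontology("A", labels = list(a = "heart"))
  oB <- ontology("B", labels = list(x = "zzzz"))
  rep <- matchOntologies(oA, oB, matchConfig(tau = 1.0))
  expect_equal(length(rep$alignment@id1), 0L)
  expect_equal(rep$solution@objective, 0)
})

test_that("LP export writes a well-formed program", {
  model <- randomGroundModel(6L, seed = 9)
  path <- withr::local_tempfile(fileext = ".lp")
  exportLp(model, path)
  lines <- readLines(path)
  expect_true(any(lines == "Maximize"))
  expect_true(any(lines == "Subject To"))
  expect_true(any(lines == "End"))
  expect_equal(sum(grepl("^ amo", lines)), length(model@atMostOne))
  expect_equal(sum(grepl("^ mx", lines)), nrow(model@mutex))
})
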