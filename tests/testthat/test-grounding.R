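cfgDefault <- matchConfig()

test_that("prior grounding is one coefficient per candidate, equal to sigma", {
  cand <- data.frame(id1 = c("a", "b"), id2 = c("x", "y"),
                     sigma = c(0.54, 0.9), label1 = "l", label2 = "m")
  expect_equal(groundPrior(cand), c(0.54, 0.9))
  expect_equal(groundPrior(cand[0, ]), numeric(0))
})

test_that("cardinality grounding emits one at-most-one group per shared class", {
  cand <- data.frame(id1 = c("a1", "a1", "b1"), id2 = c("a2", "b2", "b2"),
                     sigma = 0.9, label1 = "l", label2 = "m")
  groups <- groundCardinality(cand)
  expect_length(groups, 2L)
  expect_setequal(names(groups), c("row:a1", "col:b2"))
  expect_equal(sort(groups[["row:a1"]]), c(1L, 2L))
  expect_equal(sort(groups[["col:b2"]]), c(2L, 3L))
  # all-distinct rows and columns: nothing to constrain
  free <- data.frame(id1 = c("a", "b"), id2 = c("x", "y"),
                     sigma = 0.8, label1 = "l", label2 = "m")
  expect_length(groundCardinality(free), 0L)
  # k candidates sharing one class yield one group of arity k
  shared <- data.frame(id1 = "a", id2 = c("x", "y", "z", "w"),
                       sigma = 0.8, label1 = "l", label2 = "m")
  g <- groundCardinality(shared)
  expect_length(g, 1L)
  expect_length(g[[1L]], 4L)
})

test_that("coherence forbids mapping a subclass pair onto a disjoint pair", {
  o1 <- ontology("O1", labels = list(a1 = "heart", b1 = "organ"),
                 subEdges = rbind(c("a1", "b1")))
  o2 <- ontology("O2", labels = list(a2 = "heart", b2 = "organ"),
                 disjointPairs = rbind(c("a2", "b2")))
  cand <- generateCandidates(o1, o2, 1.0)
  mx <- groundCoherence(o1, o2, cand, cfgDefault)
  expect_equal(nrow(mx), 1L)
  # no disjointness anywhere: no constraints
  o2free <- ontology("O2", labels = list(a2 = "heart", b2 = "organ"))
  expect_equal(nrow(groundCoherence(o1, o2free, cand, cfgDefault)), 0L)
})

test_that("coherence uses the transitive closure when configured", {
  # a1 is_a m1 is_a b1: only the closure links a1 to b1
  o1 <- ontology("O1", labels = list(a1 = "heart", m1 = "mid", b1 = "organ"),
                 subEdges = rbind(c("a1", "m1"), c("m1", "b1")))
  o2 <- ontology("O2", labels = list(a2 = "heart", b2 = "organ"),
                 disjointPairs = rbind(c("a2", "b2")))
  cand <- generateCandidates(o1, o2, 1.0)
  cfgTrans <- matchConfig(useTransitiveSubForCoherence = TRUE)
  cfgDirect <- matchConfig(useTransitiveSubForCoherence = FALSE)
  expect_equal(nrow(groundCoherence(o1, o2, cand, cfgTrans)), 1L)
  expect_equal(nrow(groundCoherence(o1, o2, cand, cfgDirect)), 0L)
})

test_that("stability fires exactly on one-sided subclass structure", {
  o1 <- ontology("O1", labels = list(a1 = "heart", b1 = "organ"),
                 subEdges = rbind(c("a1", "b1")))
  o2 <- ontology("O2", labels = list(a2 = "heart", b2 = "organ"))
  cand <- generateCandidates(o1, o2, 1.0)
  sc <- groundStability(o1, o2, cand, cfgDefault)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$w, -0.01)
  # isomorphic hierarchies: no structural disagreement
  o2iso <- ontology("O2", labels = list(a2 = "heart", b2 = "organ"),
                    subEdges = rbind(c("a2", "b2")))
  expect_equal(nrow(groundStability(o1, o2iso, cand, cfgDefault)), 0L)
})

test_that("propagation rewards structure-consistent pairs along is_a and part_of", {
  o1 <- ontology("O1", labels = list(a1 = "heart", b1 = "organ"),
                 subEdges = rbind(c("a1", "b1")),
                 partEdges = rbind(c("a1", "b1")))
  o2 <- ontology("O2", labels = list(a2 = "heart", b2 = "organ"),
                 subEdges = rbind(c("a2", "b2")),
                 partEdges = rbind(c("a2", "b2")))
  cand <- generateCandidates(o1, o2, 1.0)
  si <- groundPropagation(o1, o2, cand, cfgDefault)
  # both the is_a and the part_of grounding fire for the same ordered pair
  expect_equal(nrow(si), 2L)
  expect_equal(unique(si$w), 0.05)
  expect_equal(unique(paste(si$ant, si$cons)), paste(si$ant[1], si$cons[1]))
  # no edges, no implications
  o1f <- ontology("O1", labels = list(a1 = "heart", b1 = "organ"))
  expect_equal(nrow(groundPropagation(o1f, o2, cand, cfgDefault)), 0L)
})

test_that("groundings agree with quadratic brute-force scans on random instances", {
  for (seed in c(1, 2, 6, 14)) {
    pair <- randomTestPair(seed)
    cand <- generateCandidates(pair$o1, pair$o2, 1.0)
    cand <- cand[order(cand$id1, cand$id2), ]
    rownames(cand) <- NULL
    if (nrow(cand) < 2L) next
    expect_equal(unname(groundCoherence(pair$o1, pair$o2, cand, cfgDefault)),
                 unname(bruteCoherence(pair$o1, pair$o2, cand, cfgDefault)))
    expect_equal(groundStability(pair$o1, pair$o2, cand, cfgDefault),
                 bruteStability(pair$o1, pair$o2, cand, cfgDefault))
    expect_equal(groundPropagation(pair$o1, pair$o2, cand, cfgDefault),
                 brutePropagation(pair$o1, pair$o2, cand, cfgDefault))
  }
})

test_that("ground model honours enabled families and is deterministic", {
  pair <- randomTestPair(3)
  cand <- generateCandidates(pair$o1, pair$o2, 1.0)
  priorOnly <- groundModel(pair$o1, pair$o2, cand,
                           matchConfig(setting = "prior"))
  expect_length(priorOnly@atMostOne, 0L)
  expect_equal(nrow(priorOnly@mutex), 0L)
  expect_equal(nrow(priorOnly@softConj), 0L)
  expect_equal(nrow(priorOnly@softImpl), 0L)
  expect_equal(priorOnly@prior, priorOnly@candidates$sigma)

  full <- groundModel(pair$o1, pair$o2, cand, cfgDefault)
  full2 <- groundModel(pair$o1, pair$o2, cand[sample(nrow(cand)), ], cfgDefault)
  expect_identical(full@candidates, full2@candidates)
  expect_identical(full@softConj, full2@softConj)
  expect_identical(full@softImpl, full2@softImpl)
  expect_identical(full@mutex, full2@mutex)

  # enabling a family never removes another family's clauses
  caCo <- groundModel(pair$o1, pair$o2, cand, matchConfig(setting = "ca+co"))
  expect_identical(caCo@mutex, full@mutex)
  expect_identical(caCo@atMostOne, full@atMostOne)

  # clause-count bounds
  n <- nrow(full@candidates)
  expect_lte(nrow(full@softConj) + nrow(full@softImpl), 3 * n^2)
  expect_lte(nrow(full@mutex), n^2)
})

test_that("weight-sign preconditions are enforced", {
  expect_error(matchConfig(wStability = 0.1), "wStability")
  expect_error(matchConfig(wPropagation = -0.1), "wPropagation")
  expect_error(matchConfig(enabled = c("cardinality")), "prior")
  expect_error(matchConfig(tau = 0), "tau")
})

test_that("ground model dump lists every variable and clause", {
  pair <- randomTestPair(5)
  cand <- generateCandidates(pair$o1, pair$o2, 1.0)
  model <- groundModel(pair$o1, pair$o2, cand, cfgDefault)
  path <- withr::local_tempfile(fileext = ".txt")
  dumpGroundModel(model, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "var ")), nrow(model@candidates))
  expect_equal(sum(startsWith(lines, "mutex ")), nrow(model@mutex))
  expect_equal(sum(startsWith(lines, "conj ")), nrow(model@softConj))
  expect_equal(sum(startsWith(lines, "impl ")), nrow(model@softImpl))
})
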