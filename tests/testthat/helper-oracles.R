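# Independent oracles, kept deliberately naive and separate from the
# package's code paths.

# Full dynamic-programming Levenshtein distance.
dpLevenshtein <- function(s, t) {
  a <- strsplit(s, "")[[1L]]
  b <- strsplit(t, "")[[1L]]
  n <- length(a); m <- length(b)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(
        D[i, j + 1L] + 1L,
        D[i + 1L, j] + 1L,
        D[i, j] + (a[[i]] != b[[j]]))
    }
  }
  D[n + 1L, m + 1L]
}

# Brute-force reachability (BFS from one node over direct edges).
bfsReachable <- function(edges, start) {
  seen <- character(0)
  frontier <- start
  while (length(frontier)) {
    nxt <- edges[edges[, 1L] %in% frontier, 2L]
    frontier <- setdiff(unique(nxt), seen)
    seen <- union(seen, frontier)
  }
  sort(setdiff(seen, start))
}

# Naive objective recomputation with explicit loops.
naiveObjective <- function(model, selected) {
  sel <- model@candidates[selected, ]
  val <- sum(sel$sigma)
  isSel <- function(v) v %in% selected
  sc <- model@softConj
  for (r in seq_len(nrow(sc))) {
    if (isSel(sc$i[[r]]) && isSel(sc$j[[r]])) val <- val + sc$w[[r]]
  }
  si <- model@softImpl
  for (r in seq_len(nrow(si))) {
    if (isSel(si$ant[[r]]) && !isSel(si$cons[[r]])) val <- val - si$w[[r]]
  }
  val
}

# Exhaustive candidate generation via per-pair class similarity.
bruteCandidates <- function(o1, o2, tau) {
  rows <- list()
  for (id1 in classIds(o1)) {
    for (id2 in classIds(o2)) {
      cs <- classSimilarity(classLabels(o1, id1), classLabels(o2, id2))
      if (cs$sigma >= tau - 1e-12) {
        rows[[length(rows) + 1L]] <- data.frame(
          id1 = id1, id2 = id2, sigma = cs$sigma,
          label1 = cs$label1, label2 = cs$label2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      sigma = numeric(0), label1 = character(0),
                      label2 = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$id1, out$id2), ]
  rownames(out) <- NULL
  out
}

# Edge membership helpers over direct edges or transitive closure.
edgePairSet <- function(o, rel = c("is_a", "part_of"), transitive = FALSE) {
  rel <- match.arg(rel)
  edges <- if (rel == "is_a") subEdges(o) else partEdges(o)
  if (!transitive) {
    if (!nrow(edges)) return(character(0))
    return(paste(edges[, 1L], edges[, 2L]))
  }
  keys <- character(0)
  for (id in classIds(o)) {
    anc <- bfsReachable(edges, id)
    keys <- c(keys, paste(id, anc))
  }
  keys
}

disjointSet <- function(o) {
  dp <- disjointPairs(o)
  if (!nrow(dp)) return(character(0))
  c(paste(dp[, 1L], dp[, 2L]), paste(dp[, 2L], dp[, 1L]))
}

# Quadratic brute-force groundings over all ordered candidate pairs.
bruteCoherence <- function(o1, o2, cand, cfg) {
  sub1 <- edgePairSet(o1, "is_a", cfg@useTransitiveSubForCoherence)
  sub2 <- edgePairSet(o2, "is_a", cfg@useTransitiveSubForCoherence)
  dis1 <- disjointSet(o1); dis2 <- disjointSet(o2)
  n <- nrow(cand)
  out <- matrix(integer(0), ncol = 2L)
  for (ci in seq_len(n)) for (di in seq_len(n)) {
    if (ci == di) next
    a1 <- cand$id1[[ci]]; a2 <- cand$id2[[ci]]
    b1 <- cand$id1[[di]]; b2 <- cand$id2[[di]]
    hit <- (paste(a1, b1) %in% sub1 && paste(a2, b2) %in% dis2) ||
           (paste(a1, b1) %in% dis1 && paste(a2, b2) %in% sub2)
    if (hit) out <- rbind(out, c(min(ci, di), max(ci, di)))
  }
  out <- out[!duplicated(out), , drop = FALSE]
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

bruteStability <- function(o1, o2, cand, cfg) {
  sub1 <- edgePairSet(o1, "is_a", !cfg@useDirectSubForSoft)
  sub2 <- edgePairSet(o2, "is_a", !cfg@useDirectSubForSoft)
  n <- nrow(cand)
  rows <- list()
  for (ci in seq_len(n)) for (di in seq_len(n)) {
    if (ci == di) next
    in1 <- paste(cand$id1[[ci]], cand$id1[[di]]) %in% sub1
    in2 <- paste(cand$id2[[ci]], cand$id2[[di]]) %in% sub2
    if (xor(in1, in2)) {
      rows[[length(rows) + 1L]] <- c(ci, di)
    }
  }
  if (!length(rows)) return(data.frame(i = integer(0), j = integer(0), w = numeric(0)))
  m <- do.call(rbind, rows)
  df <- data.frame(i = m[, 1L], j = m[, 2L], w = cfg@wStability)
  df <- df[order(df$i, df$j), ]
  rownames(df) <- NULL
  df
}

brutePropagation <- function(o1, o2, cand, cfg) {
  n <- nrow(cand)
  rows <- list()
  for (rel in c("is_a", "part_of")) {
    e1 <- edgePairSet(o1, rel, !cfg@useDirectSubForSoft)
    e2 <- edgePairSet(o2, rel, !cfg@useDirectSubForSoft)
    for (ci in seq_len(n)) for (di in seq_len(n)) {
      if (ci == di) next
      if (paste(cand$id1[[ci]], cand$id1[[di]]) %in% e1 &&
          paste(cand$id2[[ci]], cand$id2[[di]]) %in% e2) {
        rows[[length(rows) + 1L]] <- c(ci, di)
      }
    }
  }
  if (!length(rows)) return(data.frame(ant = integer(0), cons = integer(0), w = numeric(0)))
  m <- do.call(rbind, rows)
  df <- data.frame(ant = m[, 1L], cons = m[, 2L], w = cfg@wPropagation)
  df <- df[order(df$ant, df$cons), ]
  rownames(df) <- NULL
  df
}

# Random ground model with mixed structural clauses, built directly.
randomGroundModel <- function(nVars, seed) {
  set.seed(seed)
  n <- nVars
  cand <- data.frame(
    id1 = sprintf("a%02d", seq_len(n)),
    id2 = sprintf("b%02d", sample.int(n)),
    sigma = round(runif(n, 0.65, 1), 4L),
    label1 = "l1", label2 = "l2", stringsAsFactors = FALSE)
  cand <- cand[order(cand$id1, cand$id2), ]
  rownames(cand) <- NULL
  pickPair <- function() sort(sample.int(n, 2L))
  amo <- list()
  for (k in seq_len(sample(0:2, 1L))) {
    size <- sample(2:min(4L, n), 1L)
    amo[[length(amo) + 1L]] <- sort(sample.int(n, size))
  }
  if (length(amo)) names(amo) <- paste0("grp:", seq_along(amo))
  nmx <- sample(0:3, 1L)
  mutex <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  if (nmx > 0L && n >= 2L) {
    mutex <- t(replicate(nmx, pickPair()))
    mutex <- mutex[!duplicated(mutex), , drop = FALSE]
    storage.mode(mutex) <- "integer"
    dimnames(mutex) <- list(NULL, c("i", "j"))
  }
  mkConj <- function(k) {
    if (k == 0L || n < 2L) {
      return(data.frame(i = integer(0), j = integer(0), w = numeric(0)))
    }
    m <- t(replicate(k, sample.int(n, 2L)))
    data.frame(i = m[, 1L], j = m[, 2L], w = -0.01)
  }
  mkImpl <- function(k) {
    if (k == 0L || n < 2L) {
      return(data.frame(ant = integer(0), cons = integer(0), w = numeric(0)))
    }
    m <- t(replicate(k, sample.int(n, 2L)))
    data.frame(ant = m[, 1L], cons = m[, 2L], w = 0.05)
  }
  new("GroundModel",
      candidates = cand, prior = cand$sigma,
      atMostOne = amo, mutex = mutex,
      softConj = mkConj(sample(0:4, 1L)),
      softImpl = mkImpl(sample(0:4, 1L)),
      enabled = c("prior", "cardinality", "coherence", "stability", "propagation"))
}

# Small random ontology pair with overlapping vocabulary (for grounding
# oracle tests): candidates arise from shared labels.
randomTestPair <- function(seed, n = 12L) {
  set.seed(seed)
  words <- c("heart", "lung", "liver", "aorta", "vein", "nerve", "bone",
             "gland", "duct", "lobe", "valve", "septum")
  mkOnto <- function(name, prefix) {
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    labels <- stats::setNames(as.list(sample(words, n, replace = TRUE)), ids)
    parent <- c(NA, sample.int(n - 1L, n - 1L, replace = TRUE))
    parent <- ifelse(seq_len(n) > 1L & parent < seq_len(n), parent, NA)
    subIdx <- which(!is.na(parent))
    part <- ifelse(runif(n) < 0.3 & seq_len(n) > 1L,
                   pmax(1L, seq_len(n) - sample.int(3L, n, replace = TRUE)), NA)
    part <- ifelse(!is.na(part) & part < seq_len(n), part, NA)
    partIdx <- which(!is.na(part))
    dis <- NULL
    if (n >= 4L) {
      pr <- replicate(3L, sort(sample.int(n, 2L)))
      dis <- cbind(ids[pr[1L, ]], ids[pr[2L, ]])
      dis <- dis[dis[, 1L] != dis[, 2L], , drop = FALSE]
    }
    ontology(name, labels = labels,
             subEdges = if (length(subIdx)) cbind(ids[subIdx], ids[parent[subIdx]]),
             partEdges = if (length(partIdx)) cbind(ids[partIdx], ids[part[partIdx]]),
             disjointPairs = dis)
  }
  list(o1 = mkOnto("O1", "x"), o2 = mkOnto("O2", "y"))
}
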