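#' Normalize a class label for string comparison
#'
#' Lower-cases the label, replaces underscores and hyphens by spaces,
#' collapses runs of whitespace and strips leading/trailing whitespace.
#' Anatomy ontologies mix conventions ("Vascular_Endothelium" vs
#' "blood vessel endothelium"); edit distance is only meaningful after
#' mapping both onto a common form.
#'
#' @param raw Character vector of raw labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalizeLabel("Vascular_Endothelium")   # "vascular endothelium"
#' normalizeLabel("  Tarsal_Plate ")        # "tarsal plate"
#' @export
normalizeLabel <- function(raw) {
  x <- tolower(raw)
  x <- gsub("[_-]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions transforming \code{s} into \code{t}.  Thin wrapper over
#' \code{utils::adist} with unit costs; vectorized over pairs.
#'
#' @param s,t Character vectors (recycled to a common length).
#' @return Integer vector of distances.
#' @examples
#' levenshteinDistance("kitten", "sitting")  # 3
#' @export
levenshteinDistance <- function(s, t) {
  n <- max(length(s), length(t))
  s <- rep_len(s, n); t <- rep_len(t, n)
  d <- integer(n)
  for (k in seq_len(n)) d[[k]] <- utils::adist(s[[k]], t[[k]])[1L, 1L]
  d
}

#' A priori label similarity
#'
#' The normalized Levenshtein similarity between two labels:
#' \deqn{\sigma = 1 - d(n(l_1), n(l_2)) / \max(|n(l_1)|, |n(l_2)|)}
#' where \code{n} is \code{\link{normalizeLabel}} and \code{d} the
#' Levenshtein distance.  Two empty normalized strings have similarity 1.
#' \code{labelSimilarity("Vascular_Endothelium", "blood vessel endothelium")}
#' is 0.5417 (0.54 to two decimals): the normalized strings are at edit
#' distance 11 and the longer has 24 characters.
#'
#' @param l1,l2 Character vectors of labels (recycled).
#' @return Numeric vector of similarities in [0, 1]; 1 iff the normalized
#'   strings are equal.
#' @examples
#' round(labelSimilarity("Vascular_Endothelium", "blood vessel endothelium"), 2)
#' @export
labelSimilarity <- function(l1, l2) {
  n1 <- normalizeLabel(l1)
  n2 <- normalizeLabel(l2)
  len <- pmax(nchar(n1), nchar(n2))
  d <- levenshteinDistance(n1, n2)
  ifelse(len == 0L, 1, 1 - d / len)
}

#' Best label-pair similarity between two classes
#'
#' Classes may carry several labels; the class-level a priori similarity is
#' the maximum of \code{\link{labelSimilarity}} over the Cartesian product
#' of the two label sets.  Ties are broken by lexicographic order of
#' (label1, label2).  A class with no labels cannot be matched: the result
#' has sigma 0.
#'
#' @param labels1,labels2 Character vectors of labels of the two classes.
#' @return A list with elements \code{sigma}, \code{label1}, \code{label2}.
#' @examples
#' classSimilarity("heart", c("liver", "heart"))  # sigma 1 via ("heart","heart")
#' @export
classSimilarity <- function(labels1, labels2) {
  if (!length(labels1) || !length(labels2)) {
    return(list(sigma = 0, label1 = NA_character_, label2 = NA_character_))
  }
  grid <- expand.grid(label1 = labels1, label2 = labels2,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  sims <- labelSimilarity(grid$label1, grid$label2)
  best <- max(sims)
  hits <- grid[sims >= best - 1e-12, , drop = FALSE]
  hits <- hits[order(hits$label1, hits$label2), , drop = FALSE]
  list(sigma = best, label1 = hits$label1[[1L]], label2 = hits$label2[[1L]])
}

#' Generate threshold-pruned match candidates
#'
#' Computes the class-level a priori similarity for every cross-ontology
#' class pair and keeps pairs at or above the threshold tau (strictly above
#' when \code{inclusive = FALSE}).  Pairs below the threshold are deemed
#' incorrect and never enter the model; their map atoms are implicitly
#' false.
#'
#' @param o1,o2 \linkS4class{Ontology} objects.
#' @param tau Similarity threshold in (0, 1].
#' @param inclusive Keep candidates with sigma exactly tau (default TRUE).
#' @return A data frame with columns \code{id1}, \code{id2}, \code{sigma},
#'   \code{label1}, \code{label2}, sorted by (id1, id2).
#' @examples
#' o1 <- ontology("O1", labels = list(a = "heart"))
#' o2 <- ontology("O2", labels = list(x = "heart", y = "liver"))
#' generateCandidates(o1, o2, tau = 0.8)
#' @export
generateCandidates <- function(o1, o2, tau = 0.8, inclusive = TRUE) {
  stopifnot(tau > 0, tau <= 1)
  empty <- data.frame(id1 = character(0), id2 = character(0),
                      sigma = numeric(0), label1 = character(0),
                      label2 = character(0), stringsAsFactors = FALSE)
  # one row per (class, normalized label)
  tab <- function(o) {
    ids <- rep(o@classIds, lengths(o@labels))
    raw <- unlist(o@labels, use.names = FALSE)
    if (!length(ids)) return(NULL)
    data.frame(id = ids, raw = raw, norm = normalizeLabel(raw),
               len = nchar(normalizeLabel(raw)), stringsAsFactors = FALSE)
  }
  t1 <- tab(o1); t2 <- tab(o2)
  if (is.null(t1) || is.null(t2)) return(empty)
  d <- utils::adist(t1$norm, t2$norm)
  maxlen <- outer(t1$len, t2$len, pmax)
  sim <- ifelse(maxlen == 0L, 1, 1 - d / maxlen)
  keep <- if (inclusive) sim >= tau - 1e-12 else sim > tau + 1e-12
  hit <- which(keep, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  cand <- data.frame(
    id1 = t1$id[hit[, 1L]], id2 = t2$id[hit[, 2L]],
    sigma = sim[hit], label1 = t1$raw[hit[, 1L]], label2 = t2$raw[hit[, 2L]],
    stringsAsFactors = FALSE)
  # per class pair, keep the maximizing label pair (ties: lexicographic)
  cand <- cand[order(cand$id1, cand$id2, -cand$sigma, cand$label1, cand$label2), ]
  cand <- cand[!duplicated(paste(cand$id1, cand$id2, sep = "\r")), ]
  rownames(cand) <- NULL
  cand
}

#' Write a candidate table as TSV (debugging aid)
#'
#' @param candidates Data frame from \code{\link{generateCandidates}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCandidates <- function(candidates, path) {
  out <- candidates
  out$sigma <- sprintf("%.6f", out$sigma)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
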