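# Synthetic ontology pairs with a known ground-truth alignment, so the
# whole matching pipeline is testable without the real benchmark data.

# Anatomy-flavored token vocabulary for label phrases.
.anatomyTokens <- c(
  "artery", "vein", "capillary", "vascular", "endothelium", "epithelium",
  "muscle", "tendon", "ligament", "cartilage", "bone", "marrow", "joint",
  "cranial", "caudal", "dorsal", "ventral", "lateral", "medial", "proximal",
  "distal", "anterior", "posterior", "superior", "inferior", "left", "right",
  "heart", "atrium", "ventricle", "aorta", "pulmonary", "lung", "bronchus",
  "trachea", "larynx", "pharynx", "esophagus", "stomach", "duodenum",
  "jejunum", "ileum", "colon", "rectum", "liver", "gallbladder", "pancreas",
  "spleen", "kidney", "ureter", "bladder", "urethra", "gonad", "ovary",
  "testis", "uterus", "cervix", "prostate", "thyroid", "thymus", "adrenal",
  "pituitary", "brain", "cerebellum", "cortex", "thalamus", "hypothalamus",
  "spinal", "nerve", "ganglion", "plexus", "retina", "cornea", "lens",
  "iris", "sclera", "cochlea", "tympanic", "ossicle", "nasal", "palate",
  "tongue", "gingiva", "dermis", "epidermis", "follicle", "gland", "duct",
  "lobe", "lobule", "septum", "membrane", "mucosa", "serosa", "fascia",
  "sinus", "fossa", "foramen", "canal", "tarsal", "plate", "segment")

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

.titleCase <- function(tokens) {
  paste(vapply(tokens, function(t) {
    paste0(toupper(substring(t, 1L, 1L)), substring(t, 2L))
  }, character(1)), collapse = "_")
}

# Per-character edit perturbation: each position independently mutated with
# probability `rate` by a random substitution, insertion or deletion.
.mutateLabel <- function(label, rate) {
  if (rate <= 0) return(label)
  chars <- strsplit(label, "")[[1L]]
  alphabet <- c(letters, " ")
  out <- character(0)
  for (ch in chars) {
    if (stats::runif(1L) < rate) {
      op <- sample(c("sub", "ins", "del"), 1L)
      if (op == "sub") {
        out <- c(out, sample(alphabet, 1L))
      } else if (op == "ins") {
        out <- c(out, ch, sample(alphabet, 1L))
      }  # del: drop the character
    } else {
      out <- c(out, ch)
    }
  }
  paste(out, collapse = "")
}

#' Generate a synthetic ontology pair with known ground truth
#'
#' Builds a random is_a tree with part_of cross-links and sibling
#' disjointness (disjointness in the first ontology only, mirroring the
#' asymmetry of real anatomy benchmarks where only one side declares
#' disjointWith), then derives the second ontology as a clone with fresh
#' ids, labels perturbed by random character edits, and classes dropped at
#' random.  The ground-truth alignment contains exactly the surviving
#' clone pairs.  Labels are 1-4 token phrases over an anatomy-flavored
#' vocabulary, unique within each ontology; the first ontology uses
#' Title_Case_Underscore style and the clone lowercase spaced style, so
#' label normalization is exercised throughout.
#'
#' @param nClasses Number of classes in the first ontology (>= 1).
#' @param isaBranching Mean number of is_a children per node.
#' @param partOfRate Probability that a class receives a part_of parent.
#' @param disjointSiblingRate Probability that a sibling pair is declared
#'   disjoint (first ontology only).
#' @param labelMutationRate Per-character edit probability for the clone's
#'   labels.
#' @param dropRate Probability that a class is deleted from the clone.
#' @param seed Integer seed; the result is fully reproducible from it and
#'   the caller's RNG state is left untouched.
#' @return A list with elements \code{o1}, \code{o2}
#'   (\linkS4class{Ontology}) and \code{truth} (\linkS4class{Alignment}).
#' @examples
#' pair <- generateOntologyPair(nClasses = 30, seed = 7)
#' pair$o1
#' length(pair$truth@id1)
#' @export
generateOntologyPair <- function(nClasses = 100, isaBranching = 2.5,
                                 partOfRate = 0.3, disjointSiblingRate = 0.15,
                                 labelMutationRate = 0.05, dropRate = 0.05,
                                 seed = 1) {
  stopifnot(nClasses >= 1,
            partOfRate >= 0, partOfRate <= 1,
            disjointSiblingRate >= 0, disjointSiblingRate <= 1,
            labelMutationRate >= 0, labelMutationRate <= 1,
            dropRate >= 0, dropRate <= 1)
  .withSeed(seed, {
    n <- as.integer(nClasses)
    # is_a tree by breadth-first growth with Poisson branching
    parent <- rep(NA_integer_, n)
    if (n > 1L) {
      queue <- 1L
      count <- 1L
      while (count < n) {
        if (!length(queue)) queue <- sample.int(count, 1L)
        v <- queue[[1L]]; queue <- queue[-1L]
        k <- stats::rpois(1L, isaBranching)
        while (k > 0L && count < n) {
          count <- count + 1L
          parent[[count]] <- v
          queue <- c(queue, count)
          k <- k - 1L
        }
      }
    }
    # part_of edges point to a smaller index, keeping the graph acyclic
    partWhole <- rep(NA_integer_, n)
    for (i in seq_len(n)[-1L]) {
      if (stats::runif(1L) < partOfRate) {
        partWhole[[i]] <- sample.int(i - 1L, 1L)
      }
    }
    # sibling disjointness in o1 only
    disjoint <- list()
    if (disjointSiblingRate > 0 && n > 2L) {
      for (p in unique(parent[!is.na(parent)])) {
        sibs <- which(!is.na(parent) & parent == p)
        if (length(sibs) >= 2L) {
          cmb <- utils::combn(sibs, 2L)
          for (k in seq_len(ncol(cmb))) {
            if (stats::runif(1L) < disjointSiblingRate) {
              disjoint[[length(disjoint) + 1L]] <- cmb[, k]
            }
          }
        }
      }
    }
    # unique label phrases
    phrases <- character(n)
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      repeat {
        len <- sample.int(4L, 1L, prob = c(0.2, 0.4, 0.3, 0.1))
        ph <- paste(sample(.anatomyTokens, len, replace = TRUE), collapse = " ")
        if (!exists(ph, envir = seen, inherits = FALSE)) {
          assign(ph, TRUE, envir = seen)
          phrases[[i]] <- ph
          break
        }
      }
    }
    ids1 <- sprintf("A%04d", seq_len(n))
    labels1 <- stats::setNames(
      lapply(phrases, function(p) .titleCase(strsplit(p, " ")[[1L]])), ids1)
    edge1 <- function(child, par, ids) cbind(ids[child], ids[par])
    subIdx <- which(!is.na(parent))
    partIdx <- which(!is.na(partWhole))
    o1 <- ontology("O1", labels = labels1,
      subEdges = if (length(subIdx)) edge1(subIdx, parent[subIdx], ids1),
      partEdges = if (length(partIdx)) edge1(partIdx, partWhole[partIdx], ids1),
      disjointPairs = if (length(disjoint)) {
        m <- do.call(rbind, disjoint)
        cbind(ids1[m[, 1L]], ids1[m[, 2L]])
      })
    # clone: fresh ids, mutated labels, random drops, no disjointness
    keep <- stats::runif(n) >= dropRate
    ids2 <- sprintf("B%04d", seq_len(n))
    labels2 <- stats::setNames(
      lapply(phrases, .mutateLabel, rate = labelMutationRate), ids2)[keep]
    bothKept <- function(idx1, idx2) keep[idx1] & keep[idx2]
    sub2 <- subIdx[bothKept(subIdx, parent[subIdx])]
    part2 <- partIdx[bothKept(partIdx, partWhole[partIdx])]
    o2 <- ontology("O2", labels = labels2,
      subEdges = if (length(sub2)) edge1(sub2, parent[sub2], ids2),
      partEdges = if (length(part2)) edge1(part2, partWhole[part2], ids2))
    truth <- alignment(ids1[keep], ids2[keep])
    list(o1 = o1, o2 = o2, truth = truth)
  })
}

#' Write a synthetic pair to disk in native formats
#'
#' Writes the two ontologies as native-format files and the ground truth
#' as a TSV alignment.
#'
#' @param pair Result of \code{\link{generateOntologyPair}}.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
writeSyntheticPair <- function(pair, dir, prefix = "synth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    o1 = file.path(dir, paste0(prefix, "_o1.txt")),
    o2 = file.path(dir, paste0(prefix, "_o2.txt")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  writeNativeOntology(pair$o1, paths[["o1"]])
  writeNativeOntology(pair$o2, paths[["o2"]])
  writeAlignment(pair$truth, paths[["truth"]], format = "tsv")
  invisible(paths)
}
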