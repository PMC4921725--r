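.rdfNs <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl = "http://www.w3.org/2002/07/owl#"
)
.alignNs <- c(.rdfNs,
  align = "http://knowledgeweb.semanticweb.org/heterogeneity/alignment")

# Reduce an IRI to the class id: fragment after '#', else last path segment.
.iriToId <- function(iri) {
  id <- sub(".*#", "", iri)
  sub(".*/", "", id)
}

#' Read an ontology from the native line-oriented text format
#'
#' The native format is a UTF-8 text file with one statement per line:
#' \preformatted{
#' class <id>\\t<label>[|<label>...]
#' is_a <id> <id>
#' part_of <id> <id>
#' disjoint <id> <id>
#' }
#' \code{#} starts a comment; blank lines are ignored.  Edge statements must
#' reference declared class ids.
#'
#' @param path Path to the file.
#' @param name Ontology name tag (defaults to the file name).
#' @return An \linkS4class{Ontology}.
#' @seealso \code{\link{writeNativeOntology}}, \code{\link{readOwlOntology}}
#' @export
readNativeOntology <- function(path, name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  labels <- list()
  sub <- part <- dis <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    if (!nzchar(trimws(line))) next
    kw <- sub("\\s.*$", "", trimws(line))
    rest <- sub("^\\s*\\S+\\s+", "", trimws(line))
    if (kw == "class") {
      parts <- strsplit(rest, "\t", fixed = TRUE)[[1L]]
      id <- trimws(parts[[1L]])
      if (!nzchar(id)) stop(sprintf("%s:%d: class statement without id", path, i))
      if (id %in% names(labels)) {
        stop(sprintf("%s:%d: duplicate class id '%s'", path, i, id))
      }
      labs <- if (length(parts) > 1L) {
        strsplit(paste(parts[-1L], collapse = "\t"), "|", fixed = TRUE)[[1L]]
      } else character(0)
      labels[[id]] <- labs
    } else if (kw %in% c("is_a", "part_of", "disjoint")) {
      toks <- strsplit(rest, "\\s+")[[1L]]
      if (length(toks) != 2L) {
        stop(sprintf("%s:%d: '%s' statement needs exactly two class ids", path, i, kw))
      }
      e <- list(toks)
      if (kw == "is_a") sub <- c(sub, e)
      else if (kw == "part_of") part <- c(part, e)
      else dis <- c(dis, e)
    } else {
      stop(sprintf("%s:%d: unknown statement '%s'", path, i, kw))
    }
  }
  toMat <- function(l) if (length(l)) do.call(rbind, l) else NULL
  ontology(name, labels = labels, subEdges = toMat(sub),
           partEdges = toMat(part), disjointPairs = toMat(dis))
}

#' Write an ontology in the native text format
#'
#' @param x An \linkS4class{Ontology}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeNativeOntology <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (id in x@classIds) {
    labs <- x@labels[[id]]
    if (length(labs)) {
      writeLines(paste0("class ", id, "\t", paste(labs, collapse = "|")), con)
    } else {
      writeLines(paste0("class ", id), con)
    }
  }
  apply2 <- function(m, kw) {
    if (nrow(m)) writeLines(paste(kw, m[, 1L], m[, 2L]), con)
  }
  apply2(x@subEdges, "is_a")
  apply2(x@partEdges, "part_of")
  apply2(x@disjointPairs, "disjoint")
  invisible(path)
}

#' Read an ontology from an OWL (RDF/XML) file
#'
#' Extracts named classes, their annotation labels, direct named-class
#' \code{rdfs:subClassOf} axioms, \code{part_of} partonomy encoded in the
#' OBO-in-OWL convention (a \code{subClassOf} axiom whose filler is an
#' existential restriction on the part-of property), and disjointness
#' axioms (\code{owl:disjointWith} and \code{owl:AllDisjointClasses}).
#' Anonymous classes, property axioms and individuals are ignored.
#'
#' @param path Path to an RDF/XML OWL file.
#' @param partOfProperty IRI or local name of the partonomy property
#'   (default "part_of"); matched against the full IRI and its fragment.
#' @param labelProperty Local name of the label annotation property
#'   (default "label", i.e. \code{rdfs:label}).
#' @param name Ontology name tag.
#' @return An \linkS4class{Ontology}.  Classes referenced by axioms but not
#'   declared carry an empty label list.
#' @export
readOwlOntology <- function(path, partOfProperty = "part_of",
                            labelProperty = "label", name = basename(path)) {
  doc <- tryCatch(xml2::read_xml(path),
    error = function(e) stop("failed to parse OWL file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  classNodes <- xml2::xml_find_all(doc, "//owl:Class[@rdf:about or @rdf:ID]", .rdfNs)
  labels <- list()
  sub <- part <- dis <- list()
  isPartProp <- function(iri) {
    iri == partOfProperty || .iriToId(iri) == .iriToId(partOfProperty)
  }
  nodeId <- function(node) {
    about <- xml2::xml_attr(node, "about")
    if (is.na(about)) about <- xml2::xml_attr(node, "ID")
    .iriToId(about)
  }
  refId <- function(node) {
    res <- xml2::xml_attr(node, "resource")
    if (!is.na(res)) return(.iriToId(res))
    inner <- xml2::xml_find_first(node, "./owl:Class[@rdf:about]", .rdfNs)
    if (!inherits(inner, "xml_missing")) return(nodeId(inner))
    NA_character_
  }
  for (node in classNodes) {
    id <- nodeId(node)
    labs <- xml2::xml_text(xml2::xml_find_all(
      node, sprintf("./*[local-name()='%s']", labelProperty)))
    labels[[id]] <- unique(c(labels[[id]], labs))
    for (sc in xml2::xml_find_all(node, "./rdfs:subClassOf", .rdfNs)) {
      sup <- refId(sc)
      if (!is.na(sup)) {
        sub <- c(sub, list(c(id, sup)))
        next
      }
      restr <- xml2::xml_find_first(sc, "./owl:Restriction", .rdfNs)
      if (inherits(restr, "xml_missing")) next
      prop <- xml2::xml_attr(
        xml2::xml_find_first(restr, "./owl:onProperty", .rdfNs),
        "resource")
      filler <- xml2::xml_find_first(restr, "./owl:someValuesFrom", .rdfNs)
      if (is.na(prop) || inherits(filler, "xml_missing")) next
      whole <- refId(filler)
      if (!is.na(whole) && isPartProp(prop)) {
        part <- c(part, list(c(id, whole)))
      }
    }
    for (dw in xml2::xml_find_all(node, "./owl:disjointWith", .rdfNs)) {
      other <- refId(dw)
      if (!is.na(other)) dis <- c(dis, list(c(id, other)))
    }
  }
  # owl:AllDisjointClasses blocks: pairwise disjointness over the member list
  for (adc in xml2::xml_find_all(doc, "//owl:AllDisjointClasses", .rdfNs)) {
    members <- xml2::xml_find_all(adc,
      ".//owl:members/*[@rdf:about] | .//owl:members/*[@rdf:resource]", .rdfNs)
    ids <- vapply(members, function(m) {
      a <- xml2::xml_attr(m, "about")
      if (is.na(a)) a <- xml2::xml_attr(m, "resource")
      .iriToId(a)
    }, character(1))
    ids <- unique(ids)
    if (length(ids) >= 2L) {
      cmb <- utils::combn(sort(ids), 2L)
      for (k in seq_len(ncol(cmb))) dis <- c(dis, list(cmb[, k]))
    }
  }
  # classes referenced only inside axioms still count as named classes
  referenced <- unique(unlist(c(sub, part, dis), use.names = FALSE))
  for (id in setdiff(referenced, names(labels))) labels[[id]] <- character(0)
  toMat <- function(l) if (length(l)) do.call(rbind, l) else NULL
  ontology(name, labels = labels, subEdges = toMat(sub),
           partEdges = toMat(part), disjointPairs = toMat(dis))
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write an ontology as OWL (RDF/XML)
#'
#' Serializes classes, labels, is_a axioms, part_of partonomy (as
#' existential restrictions, OBO-in-OWL convention) and pairwise
#' disjointness.  Inverse of \code{\link{readOwlOntology}} up to axiom
#' ordering.
#'
#' @param x An \linkS4class{Ontology}.
#' @param path Output path.
#' @param base Base IRI for class identifiers.
#' @param partOfProperty IRI used for the partonomy property.
#' @return \code{path}, invisibly.
#' @export
writeOwlOntology <- function(x, path, base = "http://example.org/onto#",
                             partOfProperty = "http://example.org/onto#part_of") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<rdf:RDF xmlns:rdf="%s" xmlns:rdfs="%s" xmlns:owl="%s">',
    .rdfNs[["rdf"]], .rdfNs[["rdfs"]], .rdfNs[["owl"]])
  disByFirst <- split(x@disjointPairs[, 2L], x@disjointPairs[, 1L])
  subBy <- split(x@subEdges[, 2L], x@subEdges[, 1L])
  partBy <- split(x@partEdges[, 2L], x@partEdges[, 1L])
  for (id in x@classIds) {
    w('  <owl:Class rdf:about="%s%s">', base, id)
    for (lab in x@labels[[id]]) {
      w('    <rdfs:label>%s</rdfs:label>', .xmlEscape(lab))
    }
    for (sup in subBy[[id]]) {
      w('    <rdfs:subClassOf rdf:resource="%s%s"/>', base, sup)
    }
    for (whole in partBy[[id]]) {
      w('    <rdfs:subClassOf>')
      w('      <owl:Restriction>')
      w('        <owl:onProperty rdf:resource="%s"/>', partOfProperty)
      w('        <owl:someValuesFrom rdf:resource="%s%s"/>', base, whole)
      w('      </owl:Restriction>')
      w('    </rdfs:subClassOf>')
    }
    for (other in disByFirst[[id]]) {
      w('    <owl:disjointWith rdf:resource="%s%s"/>', base, other)
    }
    w('  </owl:Class>')
  }
  w('</rdf:RDF>')
  invisible(path)
}

#' Read an ontology, auto-detecting OWL vs native format
#'
#' @param path Path to an ontology file.
#' @param format "auto" (default; OWL if the file starts with '<'), "owl" or
#'   "native".
#' @param ... Passed to the format-specific reader.
#' @return An \linkS4class{Ontology}.
#' @export
readOntology <- function(path, format = c("auto", "owl", "native"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    head <- readChar(path, 64L, useBytes = TRUE)
  if (!length(head)) head <- ""
    format <- if (grepl("^\\s*<", head)) "owl" else "native"
  }
  if (format == "owl") readOwlOntology(path, ...) else readNativeOntology(path, ...)
}

#' Read an alignment file (OAEI RDF/XML or native TSV)
#'
#' For the OAEI Alignment format, only cells with the equivalence relation
#' ("=") are kept; cells with other relations are dropped with a warning.
#' Entity IRIs are reduced to class ids the same way as the ontology
#' loaders.  The native TSV format has three columns: id1, id2, confidence
#' (no header).
#'
#' @param path Path to the alignment file.
#' @param format "auto" (default), "rdf" or "tsv".
#' @return An \linkS4class{Alignment}.
#' @export
readAlignment <- function(path, format = c("auto", "rdf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    head <- readChar(path, 64L, useBytes = TRUE)
  if (!length(head)) head <- ""
    format <- if (grepl("^\\s*<", head)) "rdf" else "tsv"
  }
  if (format == "tsv") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    if (!length(lines)) return(alignment())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) {
      stop(sprintf("%s:%d: expected at least two tab-separated fields", path, bad[[1L]]))
    }
    id1 <- vapply(parts, `[[`, "", 1L)
    id2 <- vapply(parts, `[[`, "", 2L)
    conf <- vapply(parts, function(p) {
      if (length(p) >= 3L) as.numeric(p[[3L]]) else 1
    }, numeric(1))
    return(alignment(id1, id2, conf))
  }
  doc <- tryCatch(xml2::read_xml(path),
    error = function(e) stop("failed to parse alignment file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  cells <- xml2::xml_find_all(doc, "//*[local-name()='Cell']")
  if (!length(cells)) return(alignment())
  get1 <- function(cell, what) {
    node <- xml2::xml_find_first(cell, sprintf("./*[local-name()='%s']", what))
    if (inherits(node, "xml_missing")) return(NA_character_)
    res <- xml2::xml_attr(node, "resource")
    if (!is.na(res)) res else xml2::xml_text(node)
  }
  id1 <- vapply(cells, function(c) .iriToId(get1(c, "entity1")), character(1))
  id2 <- vapply(cells, function(c) .iriToId(get1(c, "entity2")), character(1))
  rel <- vapply(cells, function(c) trimws(get1(c, "relation")), character(1))
  conf <- vapply(cells, function(c) {
    m <- get1(c, "measure")
    if (is.na(m)) 1 else as.numeric(m)
  }, numeric(1))
  keep <- is.na(rel) | rel == "="
  if (any(!keep)) {
    warning(sum(!keep), " cell(s) with non-equivalence relation ignored")
  }
  alignment(id1[keep], id2[keep], conf[keep])
}

#' Write an alignment (native TSV or OAEI RDF/XML)
#'
#' @param x An \linkS4class{Alignment}.
#' @param path Output path.
#' @param format "tsv" (default) or "rdf".
#' @param base1,base2 Base IRIs prepended to class ids in RDF output.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(x, path, format = c("tsv", "rdf"),
                           base1 = "http://example.org/onto1#",
                           base2 = "http://example.org/onto2#") {
  format <- match.arg(format)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "tsv") {
    if (length(x@id1)) {
      writeLines(sprintf("%s\t%s\t%s", x@id1, x@id2,
                         format(x@confidence, digits = 15L, trim = TRUE)), con)
    }
    return(invisible(path))
  }
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<rdf:RDF xmlns="%s" xmlns:rdf="%s">', .alignNs[["align"]], .rdfNs[["rdf"]])
  w('  <Alignment>')
  w('    <xml>yes</xml><level>0</level><type>11</type>')
  for (k in seq_along(x@id1)) {
    w('    <map><Cell>')
    w('      <entity1 rdf:resource="%s%s"/>', base1, x@id1[[k]])
    w('      <entity2 rdf:resource="%s%s"/>', base2, x@id2[[k]])
    w('      <measure>%s</measure>', format(x@confidence[[k]], digits = 15L))
    w('      <relation>=</relation>')
    w('    </Cell></map>')
  }
  w('  </Alignment>')
  w('</rdf:RDF>')
  invisible(path)
}
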