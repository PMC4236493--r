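# Serializers used by the synthetic generator to emit loadable fixture
# files (OWL RDF/XML and SKOS RDF/XML). Deterministic output: entities are
# written in sorted IRI order.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write an ontology as OWL (RDF/XML)
#'
#' @param o an [ontology()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology_owl <- function(o, path) {
  out <- c(
    '<?xml version="1.0"?>',
    paste0('<rdf:RDF xmlns:rdf="', RDF_NS, '"'),
    paste0('         xmlns:rdfs="', RDFS_NS, '"'),
    paste0('         xmlns:owl="', OWL_NS, '">'))

  lab_of <- split(seq_len(nrow(o$labels)), o$labels$entity)
  com_of <- split(seq_len(nrow(o$comments)), o$comments$entity)

  label_lines <- function(e) {
    idx <- lab_of[[e]]
    if (is.null(idx)) return(character(0))
    vapply(idx, function(i) {
      lang <- o$labels$lang[i]
      attr <- if (nzchar(lang)) sprintf(' xml:lang="%s"', lang) else ""
      sprintf('    <rdfs:label%s>%s</rdfs:label>', attr,
              xml_escape(o$labels$text[i]))
    }, character(1))
  }
  comment_lines <- function(e) {
    idx <- com_of[[e]]
    if (is.null(idx)) return(character(0))
    vapply(idx, function(i)
      sprintf('    <rdfs:comment>%s</rdfs:comment>',
              xml_escape(o$comments$text[i])), character(1))
  }

  dis_of <- NULL
  if (nrow(o$disjointness) > 0L) {
    dis_of <- split(o$disjointness$b, o$disjointness$a)
  }

  for (cpt in sort(o$concepts)) {
    out <- c(out, sprintf('  <owl:Class rdf:about="%s">', xml_escape(cpt)))
    out <- c(out, label_lines(cpt), comment_lines(cpt))
    parents <- sort(o$parents[[cpt]])
    for (p in parents)
      out <- c(out, sprintf('    <rdfs:subClassOf rdf:resource="%s"/>',
                            xml_escape(p)))
    for (d in sort(dis_of[[cpt]]))
      out <- c(out, sprintf('    <owl:disjointWith rdf:resource="%s"/>',
                            xml_escape(d)))
    out <- c(out, '  </owl:Class>')
  }

  prop_lines <- function(p, tag) {
    res <- sprintf('  <%s rdf:about="%s">', tag, xml_escape(p))
    res <- c(res, label_lines(p), comment_lines(p))
    for (d in sort(o$prop_domain[[p]]))
      res <- c(res, sprintf('    <rdfs:domain rdf:resource="%s"/>', xml_escape(d)))
    for (r in sort(o$prop_range[[p]]))
      res <- c(res, sprintf('    <rdfs:range rdf:resource="%s"/>', xml_escape(r)))
    for (s in sort(o$prop_hierarchy$super[o$prop_hierarchy$sub == p]))
      res <- c(res, sprintf('    <rdfs:subPropertyOf rdf:resource="%s"/>',
                            xml_escape(s)))
    if ("functional" %in% o$prop_constraints[[p]])
      res <- c(res, sprintf('    <rdf:type rdf:resource="%sFunctionalProperty"/>',
                            OWL_NS))
    c(res, sprintf('  </%s>', tag))
  }
  for (p in sort(o$obj_properties)) out <- c(out, prop_lines(p, "owl:ObjectProperty"))
  for (p in sort(o$dat_properties)) out <- c(out, prop_lines(p, "owl:DatatypeProperty"))

  out <- c(out, '</rdf:RDF>')
  writeLines(out, path)
  invisible(path)
}

#' Write the concept hierarchy of an ontology as SKOS (RDF/XML)
#'
#' Concepts become `skos:Concept`s; the first label of each concept becomes
#' `skos:prefLabel`, the rest `skos:altLabel`; is-a edges become
#' `skos:broader`. Properties and disjointness have no SKOS rendering and
#' are omitted.
#'
#' @inheritParams write_ontology_owl
#' @export
write_ontology_skos <- function(o, path) {
  out <- c(
    '<?xml version="1.0"?>',
    paste0('<rdf:RDF xmlns:rdf="', RDF_NS, '"'),
    paste0('         xmlns:skos="', SKOS_NS, '">'))
  lab_of <- split(seq_len(nrow(o$labels)), o$labels$entity)
  for (cpt in sort(o$concepts)) {
    out <- c(out, sprintf('  <skos:Concept rdf:about="%s">', xml_escape(cpt)))
    idx <- lab_of[[cpt]]
    for (j in seq_along(idx)) {
      i <- idx[j]
      lang <- o$labels$lang[i]
      attr <- if (nzchar(lang)) sprintf(' xml:lang="%s"', lang) else ""
      tag <- if (j == 1L) "skos:prefLabel" else "skos:altLabel"
      out <- c(out, sprintf('    <%s%s>%s</%s>', tag, attr,
                            xml_escape(o$labels$text[i]), tag))
    }
    for (p in sort(o$parents[[cpt]]))
      out <- c(out, sprintf('    <skos:broader rdf:resource="%s"/>', xml_escape(p)))
    out <- c(out, '  </skos:Concept>')
  }
  out <- c(out, '</rdf:RDF>')
  writeLines(out, path)
  invisible(path)
}
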