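# Front door for reading ontologies in any of the supported formats.

#' Load an ontology file
#'
#' Reads OWL (RDF/XML or Turtle), RDFS, SKOS or OBO 1.4 flat files into the
#' package's [ontology()] model. All named classes/concepts, object and
#' datatype properties, labels (with language tags), is-a/broader edges,
#' domains/ranges, functional flags and explicit disjointness axioms are
#' captured; SKOS prefLabel/altLabel and OBO name/synonym all populate the
#' label table.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"owl"`, `"rdfs"`, `"skos"`, `"obo"`,
#'   `"turtle"`. OWL/RDFS/SKOS share the RDF readers; with `"auto"` the
#'   format is sniffed from the extension and file content.
#' @return an [ontology()] object; empty ontologies load with a warning.
#' @export
load_ontology <- function(path, format = c("auto", "owl", "rdfs", "skos",
                                           "obo", "turtle")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") format <- sniff_format(path)
  o <- switch(format,
    obo = read_obo_ontology(path),
    turtle = graph_to_ontology(turtle_triples(path), iri = path),
    # owl / rdfs / skos serialized as RDF/XML or Turtle
    {
      if (content_is_turtle(path))
        graph_to_ontology(turtle_triples(path), iri = path)
      else
        graph_to_ontology(
          tryCatch(rdfxml_triples(path), error = function(e)
            stop(sprintf("cannot parse '%s' as RDF/XML: %s", path,
                         conditionMessage(e)))),
          iri = path)
    })
  if (length(all_entities(o)) == 0L)
    warning(sprintf("empty ontology loaded from %s", path))
  o
}

sniff_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obo") return("obo")
  if (ext %in% c("ttl", "n3")) return("turtle")
  if (ext %in% c("owl", "rdf", "rdfs", "xml", "skos")) return("owl")
  # content sniffing
  head <- paste(readLines(path, n = 5L, warn = FALSE), collapse = "\n")
  if (grepl("^\\s*format-version:", head)) return("obo")
  if (grepl("@prefix|@base", head)) return("turtle")
  "owl"
}

content_is_turtle <- function(path) {
  head <- paste(readLines(path, n = 5L, warn = FALSE), collapse = "\n")
  !grepl("<\\?xml|<rdf:RDF", head) && grepl("@prefix|@base|\\^\\^|\\ba\\b", head)
}
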