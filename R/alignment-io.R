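# OAEI Alignment format (RDF) reader and writer, plus a TSV export.
# A Cell holds entity1, entity2, relation "=" and a measure in [0, 1].

ALIGN_NS <- "http://knowledgeweb.semanticweb.org/heterogeneity/alignment"

#' Write an alignment in the OAEI Alignment RDF format
#'
#' Cells are written in sorted (e1, e2) order so identical alignments
#' produce byte-identical files.
#'
#' @param alignment data.frame with columns `e1`, `e2`, `score`.
#' @param path output file path.
#' @param onto1,onto2 ontology IRIs recorded in the header.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path, onto1 = "", onto2 = "") {
  al <- alignment[order(alignment$e1, alignment$e2), , drop = FALSE]
  out <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    paste0('<rdf:RDF xmlns="', ALIGN_NS, '#"'),
    paste0('         xmlns:rdf="', RDF_NS, '"'),
    '         xmlns:xsd="http://www.w3.org/2001/XMLSchema#">',
    '  <Alignment>',
    '    <xml>yes</xml>',
    '    <level>0</level>',
    '    <type>11</type>',
    sprintf('    <onto1>%s</onto1>', xml_escape(onto1)),
    sprintf('    <onto2>%s</onto2>', xml_escape(onto2)))
  for (i in seq_len(nrow(al))) {
    out <- c(out,
      '    <map>',
      '      <Cell>',
      sprintf('        <entity1 rdf:resource="%s"/>', xml_escape(al$e1[i])),
      sprintf('        <entity2 rdf:resource="%s"/>', xml_escape(al$e2[i])),
      '        <relation>=</relation>',
      sprintf('        <measure rdf:datatype="http://www.w3.org/2001/XMLSchema#float">%.6f</measure>',
              al$score[i]),
      '      </Cell>',
      '    </map>')
  }
  out <- c(out, '  </Alignment>', '</rdf:RDF>')
  writeLines(out, path)
  invisible(path)
}

#' Read an OAEI Alignment RDF file
#'
#' @param path file path.
#' @return data.frame with columns `e1`, `e2`, `score`.
#' @export
read_alignment <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("cannot parse alignment file %s: %s", path,
                 conditionMessage(e))))
  cells <- xml2::xml_find_all(doc, "//*[local-name() = 'Cell']")
  if (length(cells) == 0L)
    return(data.frame(e1 = character(0), e2 = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  get_res <- function(cell, name) {
    node <- xml2::xml_find_first(cell, paste0("./*[local-name() = '", name, "']"))
    r <- xml2::xml_attr(node, "resource")
    if (is.na(r)) xml2::xml_text(node) else r
  }
  e1 <- vapply(cells, get_res, character(1), name = "entity1")
  e2 <- vapply(cells, get_res, character(1), name = "entity2")
  meas <- vapply(cells, function(cell) {
    node <- xml2::xml_find_first(cell, "./*[local-name() = 'measure']")
    v <- suppressWarnings(as.numeric(xml2::xml_text(node)))
    if (is.na(v)) 1 else v
  }, numeric(1))
  data.frame(e1 = e1, e2 = e2, score = meas, stringsAsFactors = FALSE)
}

#' Write an alignment as TSV
#'
#' @param alignment data.frame with at least `e1`, `e2`, `score`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(alignment, path) {
  al <- alignment[order(alignment$e1, alignment$e2), , drop = FALSE]
  utils::write.table(al, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
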