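# OBO 1.4 flat-file reader. Terms become concepts, typedefs become object
# properties; name and synonym lines both populate the label table.

OBO_BASE <- "http://purl.obolibrary.org/obo/"

obo_iri <- function(id) paste0(OBO_BASE, gsub(":", "_", id))

read_obo_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)          # trailing comments
  lines <- trimws(lines)

  stanza <- ""
  cur <- NULL
  terms <- list()
  typedefs <- list()
  flush <- function() {
    if (is.null(cur)) return()
    if (stanza == "Term") terms[[length(terms) + 1L]] <<- cur
    if (stanza == "Typedef") typedefs[[length(typedefs) + 1L]] <<- cur
  }
  for (line in lines) {
    if (line == "") next
    if (grepl("^\\[.*\\]$", line)) {
      flush()
      stanza <- gsub("^\\[|\\]$", "", line)
      cur <- list(id = NULL, name = NULL, synonyms = character(0),
                  is_a = character(0), is_obsolete = FALSE,
                  relationship = character(0), comment = character(0))
      next
    }
    if (is.null(cur) || !grepl(":", line, fixed = TRUE)) next
    key <- sub(":.*$", "", line)
    val <- trimws(sub("^[^:]+:", "", line))
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "synonym") {
      m <- regmatches(val, regexpr('"[^"]*"', val))
      if (length(m) > 0L) cur$synonyms <- c(cur$synonyms, gsub('"', "", m))
    }
    else if (key == "is_a") cur$is_a <- c(cur$is_a, sub(" .*$", "", val))
    else if (key == "relationship") cur$relationship <- c(cur$relationship, val)
    else if (key == "comment") cur$comment <- c(cur$comment, val)
    else if (key == "is_obsolete" && val == "true") cur$is_obsolete <- TRUE
  }
  flush()

  terms <- Filter(function(t) !is.null(t$id) && !t$is_obsolete, terms)
  typedefs <- Filter(function(t) !is.null(t$id), typedefs)

  concepts <- vapply(terms, function(t) obo_iri(t$id), character(1))
  labels <- list(); isa <- list(); trans <- list(); comments <- list()
  for (t in terms) {
    iri <- obo_iri(t$id)
    texts <- c(t$name, t$synonyms)
    if (length(texts) > 0L)
      labels[[length(labels) + 1L]] <- data.frame(
        entity = iri, text = texts, lang = "", stringsAsFactors = FALSE)
    for (p in t$is_a)
      isa[[length(isa) + 1L]] <- data.frame(
        parent = obo_iri(p), child = iri, stringsAsFactors = FALSE)
    for (r in t$relationship) {
      parts <- strsplit(trimws(r), "[ \t]+")[[1]]
      if (length(parts) >= 2L)
        trans[[length(trans) + 1L]] <- data.frame(
          subject = iri, object = obo_iri(parts[2]), label = parts[1],
          stringsAsFactors = FALSE)
    }
    for (cm in t$comment)
      comments[[length(comments) + 1L]] <- data.frame(
        entity = iri, text = cm, stringsAsFactors = FALSE)
  }

  obj_props <- character(0)
  for (t in typedefs) {
    iri <- obo_iri(t$id)
    obj_props <- c(obj_props, iri)
    texts <- c(t$name, t$synonyms)
    if (length(texts) > 0L)
      labels[[length(labels) + 1L]] <- data.frame(
        entity = iri, text = texts, lang = "", stringsAsFactors = FALSE)
  }

  bindr <- function(lst, proto) if (length(lst) > 0L) do.call(rbind, lst) else proto
  isa_df <- bindr(isa, data.frame(parent = character(0), child = character(0)))
  # is_a targets may be undeclared stubs; declare them as concepts
  concepts <- unique(c(concepts, isa_df$parent, isa_df$child))

  ontology(
    concepts = concepts,
    isa_edges = isa_df,
    obj_properties = obj_props,
    labels = bindr(labels, data.frame(entity = character(0), text = character(0),
                                      lang = character(0))),
    trans_rel = bindr(trans, data.frame(subject = character(0),
                                        object = character(0),
                                        label = character(0))),
    comments = bindr(comments, data.frame(entity = character(0),
                                          text = character(0))),
    iri = OBO_BASE
  )
}
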