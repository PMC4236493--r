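# RDF-based ontology readers (OWL RDF/XML, RDFS, SKOS) built on xml2, plus a
# Turtle-subset reader. Both readers reduce the RDF graph to a triple table
# and share one graph -> ontology assembly step. Anonymous (blank-node)
# classes are skipped: only IRI-named entities are matchable.

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"
SKOS_NS <- "http://www.w3.org/2004/02/skos/core#"
XSD_NS <- "http://www.w3.org/2001/XMLSchema#"

# ---- RDF/XML -> triples -----------------------------------------------------

# Returns data.frame(subject, predicate, object, is_literal, lang).
rdfxml_triples <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_find_first(doc, "/*")
  nsmap <- xml2::xml_ns(doc)
  base <- xml2::xml_attr(root, "base")
  if (is.na(base)) base <- paste0("file://", normalizePath(path, mustWork = FALSE))
  rows <- list()
  bnode_counter <- new.env(); bnode_counter$n <- 0L

  # xml2 matches attributes by local name, which is what we want for
  # rdf:about / rdf:ID / rdf:resource / rdf:nodeID / xml:lang
  node_id <- function(node) {
    about <- xml2::xml_attr(node, "about")
    if (!is.na(about)) return(resolve_iri(about, base))
    id <- xml2::xml_attr(node, "ID")
    if (!is.na(id)) return(paste0(sub("#.*$", "", base), "#", id))
    nodeid <- xml2::xml_attr(node, "nodeID")
    if (!is.na(nodeid)) return(paste0("_:", nodeid))
    bnode_counter$n <- bnode_counter$n + 1L
    paste0("_:genid", bnode_counter$n)
  }

  add <- function(s, p, o, is_literal = FALSE, lang = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = s, predicate = p, object = o,
      is_literal = is_literal, lang = lang, stringsAsFactors = FALSE)
  }

  qname_iri <- function(node) {
    nm <- xml2::xml_name(node, ns = nsmap)
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      uri <- unclass(nsmap)[[parts[1]]]
      if (!is.null(uri)) return(paste0(uri, parts[2]))
    }
    nm
  }

  process_node <- function(node) {
    subj <- node_id(node)
    type_iri <- qname_iri(node)
    if (type_iri != paste0(RDF_NS, "Description"))
      add(subj, paste0(RDF_NS, "type"), type_iri)
    for (child in xml2::xml_children(node)) {
      pred <- qname_iri(child)
      res <- xml2::xml_attr(child, "resource")
      if (!is.na(res)) {
        add(subj, pred, resolve_iri(res, base))
        next
      }
      parse_type <- xml2::xml_attr(child, "parseType")
      kids <- xml2::xml_children(child)
      if (!is.na(parse_type) && parse_type == "Collection") {
        members <- vapply(kids, function(k) {
          m <- node_id(k)
          process_node(k)
          m
        }, character(1))
        # represent the collection as repeated membership triples
        for (m in members) add(subj, pred, m)
        next
      }
      if (length(kids) > 0L) {
        # nested resource description
        inner <- kids[[1]]
        inner_id <- node_id(inner)
        add(subj, pred, inner_id)
        process_node(inner)
        next
      }
      txt <- xml2::xml_text(child)
      lang <- xml2::xml_attr(child, "lang")
      add(subj, pred, txt, is_literal = TRUE,
          lang = if (is.na(lang)) "" else lang)
    }
    invisible(subj)
  }

  for (node in xml2::xml_children(root)) process_node(node)
  if (length(rows) == 0L)
    return(data.frame(subject = character(0), predicate = character(0),
                      object = character(0), is_literal = logical(0),
                      lang = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

resolve_iri <- function(ref, base) {
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*:", ref)) return(ref)  # absolute
  if (startsWith(ref, "#")) return(paste0(sub("#.*$", "", base), ref))
  if (ref == "") return(base)
  paste0(sub("/[^/]*$", "/", base), ref)
}

# ---- Turtle (pragmatic subset) -> triples -----------------------------------

# Supports @prefix/@base, prefixed names, <IRI>, 'a', literal objects with
# optional @lang or ^^datatype, and ';' / ',' predicate-object lists.
turtle_triples <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  toks <- turtle_tokenize(text)
  prefixes <- list()
  base <- ""
  rows <- list()
  add <- function(s, p, o, is_literal = FALSE, lang = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = s, predicate = p, object = o,
      is_literal = is_literal, lang = lang, stringsAsFactors = FALSE)
  }
  expand <- function(tok) {
    if (tok$type == "iri") return(resolve_iri(tok$value, base))
    if (tok$type == "pname") {
      parts <- strsplit(tok$value, ":", fixed = TRUE)[[1]]
      prefix <- if (length(parts) >= 1L) parts[1] else ""
      local <- if (length(parts) >= 2L) paste(parts[-1], collapse = ":") else ""
      ns <- prefixes[[prefix]]
      if (is.null(ns)) stop(sprintf("turtle: undeclared prefix '%s:'", prefix))
      return(paste0(ns, local))
    }
    stop(sprintf("turtle: expected IRI, got %s '%s'", tok$type, tok$value))
  }

  i <- 1L
  n <- length(toks)
  peek <- function() if (i <= n) toks[[i]] else NULL
  nxt <- function() { t <- toks[[i]]; i <<- i + 1L; t }

  while (i <= n) {
    tok <- nxt()
    if (tok$type == "punct" && tok$value == ".") next
    if (tok$type == "pname" && tolower(tok$value) %in% c("@prefix", "@base") ||
        tok$type == "directive") {
      if (tolower(tok$value) == "@prefix") {
        pn <- nxt()   # prefix:
        iri <- nxt()
        prefixes[[sub(":$", "", pn$value)]] <- iri$value
      } else {
        iri <- nxt()
        base <- iri$value
      }
      dot <- nxt()  # '.'
      next
    }
    subj <- expand(tok)
    repeat {
      ptok <- nxt()
      pred <- if (ptok$type == "pname" && ptok$value == "a")
        paste0(RDF_NS, "type") else expand(ptok)
      repeat {
        otok <- nxt()
        if (otok$type == "literal") {
          add(subj, pred, otok$value, is_literal = TRUE, lang = otok$lang)
        } else {
          add(subj, pred, expand(otok))
        }
        sep <- peek()
        if (!is.null(sep) && sep$type == "punct" && sep$value == ",") { nxt(); next }
        break
      }
      sep <- peek()
      if (!is.null(sep) && sep$type == "punct" && sep$value == ";") {
        nxt()
        # allow trailing ';' before '.'
        sep2 <- peek()
        if (!is.null(sep2) && sep2$type == "punct" && sep2$value == ".") { nxt(); break }
        next
      }
      if (!is.null(sep) && sep$type == "punct" && sep$value == ".") { nxt() }
      break
    }
  }
  if (length(rows) == 0L)
    return(data.frame(subject = character(0), predicate = character(0),
                      object = character(0), is_literal = logical(0),
                      lang = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

turtle_tokenize <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, lang = "") {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, lang = lang)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[ \t\r\n]", ch)) { i <- i + 1L; next }
    if (ch == "#") {
      while (i <= n && substr(text, i, i) != "\n") i <- i + 1L
      next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i, n), fixed = TRUE)
      iri <- substr(text, i + 1L, i + j - 2L)
      push("iri", iri)
      i <- i + j
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      val <- character(0)
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") { val <- c(val, substr(text, j + 1L, j + 1L)); j <- j + 2L; next }
        if (cj == "\"") break
        val <- c(val, cj); j <- j + 1L
      }
      j <- j + 1L
      lang <- ""
      if (substr(text, j, j) == "@") {
        m <- regmatches(substr(text, j, n), regexpr("^@[A-Za-z-]+", substr(text, j, n)))
        lang <- sub("^@", "", m)
        j <- j + nchar(m)
      } else if (substr(text, j, j + 1L) == "^^") {
        j <- j + 2L
        rest <- substr(text, j, n)
        if (startsWith(rest, "<")) {
          k <- regexpr(">", rest, fixed = TRUE)
          j <- j + k
        } else {
          m <- regmatches(rest, regexpr("^[A-Za-z0-9_:.-]+", rest))
          j <- j + nchar(m)
        }
      }
      push("literal", paste(val, collapse = ""), lang = lang)
      i <- j
      next
    }
    if (ch %in% c(".", ";", ",")) {
      push("punct", ch)
      i <- i + 1L
      next
    }
    # bare token: pname, 'a', or @directive
    m <- regmatches(substr(text, i, n),
                    regexpr("^[^ \t\r\n<\">;,]+", substr(text, i, n)))
    # trailing '.' of a statement may stick to a pname; split it off
    while (grepl("\\.$", m) && !grepl("^[0-9.]+$", m)) m <- sub("\\.$", "", m)
    push("pname", m)
    i <- i + nchar(m)
    # if we stripped a trailing dot re-detect it on the next loop
    next
  }
  toks
}

# ---- triples -> ontology ----------------------------------------------------

graph_to_ontology <- function(tr, iri = "") {
  p <- function(local, ns = OWL_NS) paste0(ns, local)
  is_res <- !tr$is_literal

  typed <- function(type_iri) unique(tr$subject[tr$predicate == p("type", RDF_NS) &
                                                  tr$object == type_iri])
  named <- function(x) x[!startsWith(x, "_:")]

  classes <- named(unique(c(typed(p("Class")), typed(p("Class", RDFS_NS)),
                            typed(p("Concept", SKOS_NS)))))
  obj_props <- named(typed(p("ObjectProperty")))
  dat_props <- named(typed(p("DatatypeProperty")))
  functional <- named(typed(p("FunctionalProperty")))

  # entities appearing only via subClassOf/broader also count as concepts
  sub_tr <- tr[tr$predicate %in% c(p("subClassOf", RDFS_NS), p("broader", SKOS_NS)) &
                 is_res, , drop = FALSE]
  classes <- unique(c(classes, named(sub_tr$subject), named(sub_tr$object)))
  classes <- setdiff(classes, c(obj_props, dat_props))

  # is-a edges: rdfs:subClassOf child -> parent; skos:broader concept -> parent
  isa <- data.frame(parent = sub_tr$object, child = sub_tr$subject,
                    stringsAsFactors = FALSE)
  isa <- isa[!startsWith(isa$parent, "_:") & !startsWith(isa$child, "_:"), , drop = FALSE]
  # skos:narrower concept -> child
  nar <- tr[tr$predicate == p("narrower", SKOS_NS) & is_res, , drop = FALSE]
  if (nrow(nar) > 0L) {
    isa <- rbind(isa, data.frame(parent = nar$subject, child = nar$object,
                                 stringsAsFactors = FALSE))
    classes <- unique(c(classes, named(nar$subject), named(nar$object)))
  }

  label_preds <- c(p("label", RDFS_NS), p("prefLabel", SKOS_NS),
                   p("altLabel", SKOS_NS))
  lab <- tr[tr$predicate %in% label_preds & tr$is_literal, , drop = FALSE]
  labels <- data.frame(entity = lab$subject, text = lab$object,
                       lang = lab$lang, stringsAsFactors = FALSE)

  com <- tr[tr$predicate == p("comment", RDFS_NS) & tr$is_literal, , drop = FALSE]
  comments <- data.frame(entity = com$subject, text = com$object,
                         stringsAsFactors = FALSE)

  dom <- tr[tr$predicate == p("domain", RDFS_NS) & is_res, , drop = FALSE]
  rng <- tr[tr$predicate == p("range", RDFS_NS) & is_res, , drop = FALSE]
  prop_domain <- split(dom$object, dom$subject)
  prop_range <- split(rng$object, rng$subject)

  subp <- tr[tr$predicate == p("subPropertyOf", RDFS_NS) & is_res, , drop = FALSE]
  prop_hierarchy <- data.frame(super = subp$object, sub = subp$subject,
                               stringsAsFactors = FALSE)

  prop_constraints <- stats::setNames(
    lapply(functional, function(x) "functional"), functional)

  # disjointness: owl:disjointWith plus pairwise members of AllDisjointClasses
  dis <- tr[tr$predicate == p("disjointWith") & is_res, , drop = FALSE]
  disjointness <- data.frame(a = dis$subject, b = dis$object,
                             stringsAsFactors = FALSE)
  adc <- typed(p("AllDisjointClasses"))
  for (node in adc) {
    members <- tr$object[tr$subject == node & tr$predicate == p("members") & is_res]
    members <- named(unique(members))
    if (length(members) >= 2L) {
      pairs <- utils::combn(sort(members), 2L)
      disjointness <- rbind(disjointness,
                            data.frame(a = pairs[1, ], b = pairs[2, ],
                                       stringsAsFactors = FALSE))
    }
  }
  disjointness <- disjointness[!startsWith(disjointness$a, "_:") &
                                 !startsWith(disjointness$b, "_:"), , drop = FALSE]

  # transversal relations from skos:related and object-property declarations
  rel <- tr[tr$predicate == p("related", SKOS_NS) & is_res, , drop = FALSE]
  trans_rel <- data.frame(subject = rel$subject, object = rel$object,
                          label = rep("related", nrow(rel)),
                          stringsAsFactors = FALSE)
  for (op in obj_props) {
    d <- prop_domain[[op]]; r <- prop_range[[op]]
    if (length(d) > 0L && length(r) > 0L) {
      grid <- expand.grid(subject = d, object = r, stringsAsFactors = FALSE)
      grid$label <- local_name(op)
      trans_rel <- rbind(trans_rel, grid)
    }
  }

  attributes <- data.frame(subject = character(0), datatype = character(0),
                           label = character(0), stringsAsFactors = FALSE)
  for (dp in dat_props) {
    d <- prop_domain[[dp]]
    r <- prop_range[[dp]]
    if (length(d) == 0L) d <- NA_character_
    if (length(r) == 0L) r <- NA_character_
    grid <- expand.grid(subject = d, datatype = r, stringsAsFactors = FALSE)
    grid$label <- local_name(dp)
    attributes <- rbind(attributes, grid)
  }

  ontology(concepts = classes,
           isa_edges = isa,
           obj_properties = obj_props,
           dat_properties = dat_props,
           labels = labels,
           trans_rel = trans_rel,
           attributes = attributes,
           prop_hierarchy = prop_hierarchy,
           prop_domain = prop_domain,
           prop_range = prop_range,
           prop_constraints = prop_constraints,
           disjointness = disjointness,
           iri = iri)
}
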