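# The formal ontology model: a 5-tuple of concepts, relations (is-a taxonomy,
# transversal object properties, datatype attributes), a property hierarchy,
# and the multilingual label function, plus disjointness axioms.

#' Construct an ontology object
#'
#' Low-level constructor used by the format readers and the synthetic
#' generator. Validates edge endpoints, breaks is-a cycles (dropping the
#' back-edge seen last in load order, with a warning) and symmetrizes
#' disjointness pairs.
#'
#' @param concepts character vector of concept IRIs.
#' @param isa_edges data.frame with columns `parent`, `child` (both concept
#'   IRIs): the is-a taxonomy, parent subsumes child.
#' @param obj_properties,dat_properties character vectors of property IRIs.
#' @param labels data.frame with columns `entity`, `text`, `lang`.
#' @param trans_rel data.frame `subject`, `object`, `label`: transversal
#'   (object-property) assertions between concepts.
#' @param attributes data.frame `subject`, `datatype`, `label`: datatype
#'   attribute declarations.
#' @param prop_hierarchy data.frame `super`, `sub` over property IRIs.
#' @param prop_domain,prop_range named lists property IRI -> concept IRIs.
#' @param prop_constraints named list property IRI -> character flags
#'   (e.g. `"functional"`).
#' @param disjointness data.frame `a`, `b`: unordered disjoint concept pairs.
#' @param iri ontology base IRI (informational).
#' @param comments data.frame `entity`, `text`: annotation comments.
#' @return an object of class `ontology`.
#' @export
ontology <- function(concepts = character(0),
                     isa_edges = data.frame(parent = character(0), child = character(0)),
                     obj_properties = character(0),
                     dat_properties = character(0),
                     labels = data.frame(entity = character(0), text = character(0), lang = character(0)),
                     trans_rel = data.frame(subject = character(0), object = character(0), label = character(0)),
                     attributes = data.frame(subject = character(0), datatype = character(0), label = character(0)),
                     prop_hierarchy = data.frame(super = character(0), sub = character(0)),
                     prop_domain = list(),
                     prop_range = list(),
                     prop_constraints = list(),
                     disjointness = data.frame(a = character(0), b = character(0)),
                     iri = "",
                     comments = data.frame(entity = character(0), text = character(0))) {
  concepts <- unique(as.character(concepts))
  obj_properties <- unique(as.character(obj_properties))
  dat_properties <- unique(as.character(dat_properties))
  entities <- c(concepts, obj_properties, dat_properties)

  isa_edges <- unique(isa_edges[, c("parent", "child")])
  keep <- isa_edges$parent %in% concepts & isa_edges$child %in% concepts &
    isa_edges$parent != isa_edges$child
  isa_edges <- isa_edges[keep, , drop = FALSE]
  isa_edges <- break_isa_cycles(isa_edges)

  labels <- labels[labels$entity %in% entities & nzchar(labels$text), , drop = FALSE]
  labels <- unique(labels)

  # symmetric storage of disjointness as canonical sorted pairs
  if (nrow(disjointness) > 0L) {
    a <- pmin(disjointness$a, disjointness$b)
    b <- pmax(disjointness$a, disjointness$b)
    disjointness <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
    disjointness <- disjointness[disjointness$a %in% concepts &
                                   disjointness$b %in% concepts &
                                   disjointness$a != disjointness$b, , drop = FALSE]
  }

  children <- split(isa_edges$child, factor(isa_edges$parent, levels = concepts))
  parents <- split(isa_edges$parent, factor(isa_edges$child, levels = concepts))

  obj <- structure(list(
    concepts = concepts,
    obj_properties = obj_properties,
    dat_properties = dat_properties,
    isa_edges = isa_edges,
    children = children,
    parents = parents,
    labels = labels,
    trans_rel = trans_rel,
    attributes = attributes,
    prop_hierarchy = prop_hierarchy,
    prop_domain = prop_domain,
    prop_range = prop_range,
    prop_constraints = prop_constraints,
    disjointness = disjointness,
    iri = iri,
    comments = comments
  ), class = "ontology")
  obj
}

# Drop back-edges closing a cycle, keeping the edge order of loading.
break_isa_cycles <- function(isa_edges) {
  if (nrow(isa_edges) == 0L) return(isa_edges)
  adj <- list()
  keep <- logical(nrow(isa_edges))
  reaches <- function(from, to, adj) {
    # DFS: is `to` reachable from `from`?
    stack <- from
    seen <- character(0)
    while (length(stack) > 0L) {
      cur <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (cur == to) return(TRUE)
      if (cur %in% seen) next
      seen <- c(seen, cur)
      stack <- c(stack, adj[[cur]])
    }
    FALSE
  }
  for (i in seq_len(nrow(isa_edges))) {
    p <- isa_edges$parent[i]; ch <- isa_edges$child[i]
    if (!is.null(adj[[p]]) || !is.null(adj[[ch]])) {
      if (reaches(ch, p, adj)) {
        warning(sprintf("is-a cycle: dropping edge %s -> %s", p, ch))
        next
      }
    }
    keep[i] <- TRUE
    adj[[p]] <- c(adj[[p]], ch)
  }
  isa_edges[keep, , drop = FALSE]
}

all_entities <- function(o) c(o$concepts, o$obj_properties, o$dat_properties)

entity_kind <- function(o, e) {
  if (e %in% o$concepts) "concept"
  else if (e %in% o$obj_properties) "object-property"
  else if (e %in% o$dat_properties) "datatype-property"
  else stop(sprintf("unknown entity: %s", e))
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %s\n", if (nzchar(x$iri)) x$iri else "(anonymous)"))
  cat(sprintf("  concepts: %d  is-a edges: %d\n", length(x$concepts), nrow(x$isa_edges)))
  cat(sprintf("  object properties: %d  datatype properties: %d\n",
              length(x$obj_properties), length(x$dat_properties)))
  cat(sprintf("  labels: %d  disjointness pairs: %d\n",
              nrow(x$labels), nrow(x$disjointness)))
  invisible(x)
}

check_concept <- function(o, concept) {
  if (!(concept %in% o$concepts))
    stop(sprintf("unknown concept: %s", concept))
}

#' Direct descendant concepts
#'
#' The depth-1 children of `concept` under the is-a taxonomy.
#'
#' @param o an [ontology()].
#' @param concept a concept IRI.
#' @return character vector of concept IRIs (possibly empty).
#' @export
descendants <- function(o, concept) {
  check_concept(o, concept)
  sort(unique(o$children[[concept]]))
}

#' Direct ancestor concepts
#'
#' @inheritParams descendants
#' @return character vector of the depth-1 parents of `concept`.
#' @export
ancestors <- function(o, concept) {
  check_concept(o, concept)
  sort(unique(o$parents[[concept]]))
}

#' Sibling concepts
#'
#' Concepts sharing at least one direct parent with `concept`, excluding
#' `concept` itself.
#'
#' @inheritParams descendants
#' @return character vector of concept IRIs.
#' @export
siblings <- function(o, concept) {
  check_concept(o, concept)
  ps <- o$parents[[concept]]
  if (length(ps) == 0L) return(character(0))
  sibs <- unique(unlist(o$children[ps], use.names = FALSE))
  sort(setdiff(sibs, concept))
}

# Depth-limited transitive neighbourhoods. Returns a named integer vector:
# concept IRI -> depth (1 .. k), minimal depth on multiple paths.
walk_k <- function(o, concept, k, direction = c("down", "up")) {
  check_concept(o, concept)
  direction <- match.arg(direction)
  nb <- if (direction == "down") o$children else o$parents
  depth <- integer(0)
  frontier <- concept
  for (d in seq_len(k)) {
    nxt <- unique(unlist(nb[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(names(depth), concept))
    if (length(nxt) == 0L) break
    depth[nxt] <- d
    frontier <- nxt
  }
  if (length(depth) == 0L) return(stats::setNames(integer(0), character(0)))
  depth[order(names(depth))]
}

#' Depth-limited transitive descendants
#'
#' @inheritParams descendants
#' @param k maximum depth (`k = 1` reduces to [descendants()]).
#' @return named integer vector concept IRI -> depth.
#' @export
desc_k <- function(o, concept, k = 2L) walk_k(o, concept, k, "down")

#' Depth-limited transitive ancestors
#'
#' @inheritParams desc_k
#' @return named integer vector concept IRI -> depth.
#' @export
anc_k <- function(o, concept, k = 2L) walk_k(o, concept, k, "up")

# Full transitive closure (used by the criss-cross filter).
transitive_set <- function(o, concept, direction) {
  walk_k(o, concept, length(o$concepts), direction)
}

entity_labels <- function(o, e) {
  o$labels$text[o$labels$entity == e]
}

entity_label_langs <- function(o, e) {
  o$labels[o$labels$entity == e, c("text", "lang"), drop = FALSE]
}

#' Local name of an entity
#'
#' The IRI fragment after `#`, else the segment after the last `/`.
#'
#' @param iri entity IRI.
#' @return local-name string.
#' @export
local_name <- function(iri) {
  frag <- sub("^.*#", "", iri)
  if (identical(frag, iri)) frag <- sub("^.*/", "", iri)
  frag
}

#' Profile a matching task
#'
#' Computes entity counts, the detected language set (untagged labels default
#' to English) and the size category: `"small"` iff both ontologies have
#' fewer than 500 concepts.
#'
#' @param o1,o2 loaded [ontology()] objects.
#' @return an object of class `match_task_profile`.
#' @export
profile_task <- function(o1, o2) {
  langs <- unique(c(o1$labels$lang, o2$labels$lang))
  langs[!nzchar(langs) | is.na(langs)] <- "en"
  langs <- sort(unique(langs))
  if (length(langs) == 0L) langs <- "en"
  small <- length(o1$concepts) < 500L && length(o2$concepts) < 500L
  structure(list(
    n_concepts_1 = length(o1$concepts),
    n_concepts_2 = length(o2$concepts),
    n_properties_1 = length(o1$obj_properties) + length(o1$dat_properties),
    n_properties_2 = length(o2$obj_properties) + length(o2$dat_properties),
    languages = langs,
    size_category = if (small) "small" else "large",
    level = "entity"
  ), class = "match_task_profile")
}

#' @export
print.match_task_profile <- function(x, ...) {
  cat(sprintf("<match task> %d vs %d concepts (%s), %d vs %d properties, languages: %s\n",
              x$n_concepts_1, x$n_concepts_2, x$size_category,
              x$n_properties_1, x$n_properties_2,
              paste(x$languages, collapse = ", ")))
  invisible(x)
}
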