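# Virtual documents: the fielded bag of normalized terminological
# information describing one entity. The direct document (dVD) carries the
# entity's own description; the extended document (eVD) adds ancestor labels
# and local names (for concepts) or super-property local names.
#
# Field schema (generated dynamically -- only features the entity holds
# produce fields):
#   concepts:  uri, directNameC, directLabelC<LANG> per language, comments
#   datatype properties: uri, directNameP, dRange, domainLabelsDP, propertyType
#   object properties:   uri, directNameP, domainLabelsOP, rangeLabelsOP
#   extended only: supLabels, supLocalNames (concepts); supLocalNames (props)

#' Build the virtual document of an entity
#'
#' @param o an [ontology()].
#' @param e entity IRI (concept or property).
#' @param extended build the extended document (ancestor-derived fields)?
#' @param cfg a [normalizer_config()].
#' @param mode `"exact"` stores each label as its set of concatenated
#'   permuted-stemmed forms (single terms); `"relaxed"` stores token streams.
#' @return an object of class `virtual_document` with elements `entity_id`,
#'   `kind`, `fields` (named list of term vectors) and `extended`.
#' @export
build_virtual_document <- function(o, e, extended = FALSE,
                                   cfg = normalizer_config(),
                                   mode = c("exact", "relaxed")) {
  mode <- match.arg(mode)
  kind <- entity_kind(o, e)
  fields <- list(uri = e)

  label_terms <- function(text) {
    if (mode == "exact") exact_forms(text, cfg)
    else normalize_label(text, cfg)
  }
  labels_to_terms <- function(texts) {
    terms <- unlist(lapply(texts, label_terms), use.names = FALSE)
    unique(terms)
  }

  lab <- entity_label_langs(o, e)
  lname <- local_name(e)

  if (kind == "concept") {
    # local name: lowercased concatenation of its words, unstemmed
    toks <- split_label_words(lname)
    if (length(toks) > 0L)
      fields$directNameC <- concatenate_tokens(toks)
    if (nrow(lab) > 0L) {
      langs <- ifelse(nzchar(lab$lang), lab$lang, cfg$language)
      for (lg in sort(unique(langs))) {
        terms <- labels_to_terms(lab$text[langs == lg])
        if (length(terms) > 0L)
          fields[[paste0("directLabelC", toupper(lg))]] <- terms
      }
    }
    cm <- o$comments$text[o$comments$entity == e]
    if (length(cm) > 0L) {
      terms <- unique(unlist(lapply(cm, normalize_label, cfg = cfg),
                             use.names = FALSE))
      if (length(terms) > 0L) fields$comments <- terms
    }
    if (extended) {
      anc <- ancestors(o, e)
      if (length(anc) > 0L) {
        sup_lab <- labels_to_terms(unlist(lapply(anc, entity_labels, o = o),
                                          use.names = FALSE))
        if (length(sup_lab) > 0L) fields$supLabels <- sup_lab
        sup_ln <- unique(unlist(lapply(anc, function(a) {
          t <- split_label_words(local_name(a))
          if (length(t) == 0L) character(0) else concatenate_tokens(t)
        }), use.names = FALSE))
        if (length(sup_ln) > 0L) fields$supLocalNames <- sup_ln
      }
    }
  } else {
    # property local name is normalized (stemmed) and concatenated
    toks <- normalize_label(lname, cfg)
    if (length(toks) > 0L)
      fields$directNameP <- concatenate_tokens(toks)
    if (nrow(lab) > 0L) {
      terms <- labels_to_terms(lab$text)
      if (length(terms) > 0L) fields$directLabelP <- terms
    }
    dom <- o$prop_domain[[e]]
    dom_terms <- unique(unlist(lapply(dom, function(d) {
      txt <- entity_labels(o, d)
      if (length(txt) == 0L) txt <- local_name(d)
      unlist(lapply(txt, normalize_label, cfg = cfg, stem = FALSE),
             use.names = FALSE)
    }), use.names = FALSE))
    rng <- o$prop_range[[e]]
    if (kind == "datatype-property") {
      if (length(dom_terms) > 0L) fields$domainLabelsDP <- dom_terms
      rng_terms <- unique(unlist(lapply(rng, function(r) {
        if (startsWith(r, XSD_NS)) c("xsd", sub("^.*#", "", r))
        else normalize_label(local_name(r), cfg, stem = FALSE)
      }), use.names = FALSE))
      if (length(rng_terms) > 0L) fields$dRange <- rng_terms
      if ("functional" %in% o$prop_constraints[[e]])
        fields$propertyType <- "function"
    } else {
      if (length(dom_terms) > 0L) fields$domainLabelsOP <- dom_terms
      rng_terms <- unique(unlist(lapply(rng, function(r) {
        txt <- entity_labels(o, r)
        if (length(txt) == 0L) txt <- local_name(r)
        unlist(lapply(txt, normalize_label, cfg = cfg, stem = FALSE),
               use.names = FALSE)
      }), use.names = FALSE))
      if (length(rng_terms) > 0L) fields$rangeLabelsOP <- rng_terms
    }
    if (extended) {
      sups <- o$prop_hierarchy$super[o$prop_hierarchy$sub == e]
      if (length(sups) > 0L) {
        sup_ln <- unique(vapply(sups, function(s) {
          t <- normalize_label(local_name(s), cfg)
          concatenate_tokens(t)
        }, character(1)))
        sup_ln <- sup_ln[nzchar(sup_ln)]
        if (length(sup_ln) > 0L) fields$supLocalNames <- sup_ln
      }
    }
  }

  if (length(fields) == 1L && nrow(lab) == 0L)
    warning(sprintf("entity %s has no label and no usable local name; document has uri field only", e))

  structure(list(entity_id = e, kind = kind, fields = fields,
                 extended = isTRUE(extended)),
            class = "virtual_document")
}

#' @export
print.virtual_document <- function(x, ...) {
  cat(sprintf("<virtual document> %s (%s%s)\n", x$entity_id, x$kind,
              if (x$extended) ", extended" else ""))
  for (f in names(x$fields))
    cat(sprintf("  %s: %s\n", f, paste(x$fields[[f]], collapse = " | ")))
  invisible(x)
}

# Flat normalized text of an entity for the contextual feature vectors:
# the entity's own normalized labels plus those of its direct ancestors
# (no property fields), joined in deterministic order.
entity_context_text <- function(o, e, cfg = normalizer_config()) {
  own <- sort(unique(unlist(lapply(entity_labels(o, e), normalize_label,
                                   cfg = cfg), use.names = FALSE)))
  if (length(own) == 0L) own <- normalize_label(local_name(e), cfg)
  anc <- ancestors(o, e)
  sup <- sort(unique(unlist(lapply(unlist(lapply(anc, entity_labels, o = o),
                                          use.names = FALSE),
                                   normalize_label, cfg = cfg),
                            use.names = FALSE)))
  paste(c(own, sup), collapse = " ")
}
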