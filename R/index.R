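# Fielded inverted index over virtual documents, with a Lucene-style tf-idf
# scoring function:
#
#   score(q, e) = coord(q, e) * queryNorm(q) *
#                 sum_t tf(t, e) * idf(t)^2 * boost(field(t)) * norm(t, e)
#
# with tf = sqrt(term frequency), idf(t) = 1 + ln(N / (1 + entityFreq(t))),
# norm(t, e) = 1 / sqrt(field length), coord = matched / total query terms,
# queryNorm = 1 / sqrt(sum idf^2). Deterministic: postings and result order
# are fixed by entity IRI.

DEFAULT_BOOSTS <- c(uri = 0.5)

field_boost <- function(boosts, field) {
  if (is.null(boosts) || !(field %in% names(boosts))) return(1.0)
  as.numeric(boosts[[field]])
}

#' Index an ontology's virtual documents
#'
#' Builds one document per entity (concepts plus object/datatype properties)
#' and a fielded inverted index over their terms.
#'
#' @param o an [ontology()].
#' @param cfg a [normalizer_config()].
#' @param mode `"exact"` (concatenated permuted-stemmed label forms as single
#'   terms) or `"relaxed"` (token streams).
#' @param extended index extended virtual documents (ancestor fields)?
#' @param with_context additionally index sibling / descendant / ancestor
#'   label fields (`ctxSiblings`, `ctxDescendants`, `ctxAncestors`).
#' @param entities restrict indexing to these entity IRIs (default: all).
#' @param boosts named numeric vector of per-field boosts; unnamed fields
#'   default to 1 (`uri` defaults to 0.5).
#' @return an object of class `inverted_index`.
#' @export
index_ontology <- function(o, cfg = normalizer_config(),
                           mode = c("exact", "relaxed"),
                           extended = FALSE, with_context = FALSE,
                           entities = NULL, boosts = DEFAULT_BOOSTS) {
  mode <- match.arg(mode)
  if (is.null(entities)) entities <- all_entities(o)
  entities <- sort(entities)

  docs <- vector("list", length(entities))
  names(docs) <- entities
  postings <- new.env(parent = emptyenv())
  field_len <- new.env(parent = emptyenv())

  ctx_fields <- function(e) {
    if (!(e %in% o$concepts)) return(list())
    grab <- function(set) {
      terms <- unlist(lapply(set, function(x) {
        unlist(lapply(entity_labels(o, x), normalize_label, cfg = cfg),
               use.names = FALSE)
      }), use.names = FALSE)
      unique(terms)
    }
    out <- list()
    sb <- grab(siblings(o, e)); if (length(sb) > 0L) out$ctxSiblings <- sb
    ds <- grab(descendants(o, e)); if (length(ds) > 0L) out$ctxDescendants <- ds
    an <- grab(ancestors(o, e)); if (length(an) > 0L) out$ctxAncestors <- an
    out
  }

  for (e in entities) {
    vd <- suppressWarnings(
      build_virtual_document(o, e, extended = extended, cfg = cfg, mode = mode))
    if (with_context) vd$fields <- c(vd$fields, ctx_fields(e))
    docs[[e]] <- vd
    for (f in names(vd$fields)) {
      terms <- vd$fields[[f]]
      tf <- table(terms)
      assign(paste0(f, "\x1f", e), length(terms), envir = field_len)
      for (t in names(tf)) {
        key <- paste0(f, "\x1f", t)
        plist <- if (exists(key, envir = postings, inherits = FALSE))
          get(key, envir = postings) else integer(0)
        plist[e] <- as.integer(tf[[t]])
        assign(key, plist, envir = postings)
      }
    }
  }

  structure(list(docs = docs, postings = postings, field_len = field_len,
                 doc_count = length(entities), mode = mode,
                 extended = extended, with_context = with_context,
                 boosts = boosts, cfg = cfg),
            class = "inverted_index")
}

#' @export
print.inverted_index <- function(x, ...) {
  cat(sprintf("<inverted index> %d documents, %d postings, mode=%s\n",
              x$doc_count, length(ls(x$postings)), x$mode))
  invisible(x)
}

index_idf <- function(idx, field, term) {
  key <- paste0(field, "\x1f", term)
  ef <- if (exists(key, envir = idx$postings, inherits = FALSE))
    length(get(key, envir = idx$postings)) else 0L
  1 + log(idx$doc_count / (1 + ef))
}

# Score every entity matching at least one query term. Returns a named
# numeric vector (entity -> score) plus attribute "matched" (term counts).
score_query <- function(idx, query_vd) {
  qterms <- list()
  for (f in names(query_vd$fields)) {
    for (t in unique(query_vd$fields[[f]])) {
      qterms[[length(qterms) + 1L]] <- c(field = f, term = t)
    }
  }
  n_q <- length(qterms)
  if (n_q == 0L) return(numeric(0))

  idfs <- vapply(qterms, function(qt) index_idf(idx, qt[["field"]], qt[["term"]]),
                 numeric(1))
  query_norm <- 1 / sqrt(sum(idfs^2))

  acc <- new.env(parent = emptyenv())
  matched <- new.env(parent = emptyenv())
  for (k in seq_len(n_q)) {
    f <- qterms[[k]][["field"]]; t <- qterms[[k]][["term"]]
    key <- paste0(f, "\x1f", t)
    if (!exists(key, envir = idx$postings, inherits = FALSE)) next
    plist <- get(key, envir = idx$postings)
    idf <- idfs[k]
    boost <- field_boost(idx$boosts, f)
    for (e in names(plist)) {
      flen <- get(paste0(f, "\x1f", e), envir = idx$field_len)
      contrib <- sqrt(plist[[e]]) * idf^2 * boost / sqrt(flen)
      prev <- if (exists(e, envir = acc, inherits = FALSE)) get(e, envir = acc) else 0
      assign(e, prev + contrib, envir = acc)
      mprev <- if (exists(e, envir = matched, inherits = FALSE)) get(e, envir = matched) else 0L
      assign(e, mprev + 1L, envir = matched)
    }
  }
  ents <- ls(acc)
  if (length(ents) == 0L) return(numeric(0))
  scores <- vapply(ents, function(e) {
    coord <- get(e, envir = matched) / n_q
    coord * query_norm * get(e, envir = acc)
  }, numeric(1))
  scores
}

#' Lucene-style tf-idf score of one entity for a query document
#'
#' @param query a `virtual_document` (passed through the same filters as the
#'   index).
#' @param e indexed entity IRI.
#' @param idx an [index_ontology()] result.
#' @return non-negative score; 0 if `e` is absent or shares no term.
#' @export
tfidf_cosine <- function(query, e, idx) {
  s <- score_query(idx, query)
  if (e %in% names(s)) unname(s[e]) else 0
}

#' Search an index with a virtual-document query
#'
#' @param idx an [index_ontology()] result.
#' @param query a `virtual_document`.
#' @param k number of hits to return (fewer if fewer entities score > 0).
#' @return data.frame with columns `entity_id`, `score`, sorted by score
#'   descending, ties broken by entity IRI.
#' @export
search_index <- function(idx, query, k = 5L) {
  stopifnot(k >= 1L)
  s <- score_query(idx, query)
  s <- s[s > 0]
  if (length(s) == 0L)
    return(data.frame(entity_id = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  ord <- order(-s, names(s))
  top <- utils::head(ord, k)
  data.frame(entity_id = names(s)[top], score = unname(s[top]),
             stringsAsFactors = FALSE)
}
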