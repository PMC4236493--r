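# Candidate mapping generation: two-way exact search with Best-k selection
# and engine-score pre-filtering, the Sim_lex threshold filter producing
# M_exact and M_prop, the extended (relaxed eVD) search over residual
# concepts, and the synonym-lexicon bridge.

#' Lexical stage configuration
#'
#' @param best_k keep the Best-k hits of each directed query (default 3).
#' @param max_score engine-score pre-filter threshold on this package's
#'   scoring scale (default 0.1).
#' @param theta Sim_lex acceptance threshold (default 0.75).
#' @param theta_syn score floor for synonym-bridged pairs (defaults to
#'   `theta`).
#' @param weights a [lex_weights()] object.
#' @param require_both keep a pair only if it appears in *both* directed
#'   Best-k lists (the strict two-way intersection); set `FALSE` for the
#'   one-directional behaviour used by the light profile.
#' @return an object of class `lexical_config`.
#' @export
lexical_config <- function(best_k = 3L, max_score = 0.1, theta = 0.75,
                           theta_syn = theta, weights = lex_weights(),
                           require_both = TRUE) {
  stopifnot(best_k >= 1L, theta >= 0, theta <= 1)
  structure(list(best_k = as.integer(best_k), max_score = max_score,
                 theta = theta, theta_syn = theta_syn, weights = weights,
                 require_both = isTRUE(require_both)),
            class = "lexical_config")
}

empty_pairs <- function() {
  data.frame(e1 = character(0), e2 = character(0), engine_score = numeric(0),
             stringsAsFactors = FALSE)
}

empty_triples <- function() {
  data.frame(e1 = character(0), e2 = character(0), score = numeric(0),
             provenance = character(0), engine_score = numeric(0),
             sim_lex = numeric(0), stringsAsFactors = FALSE)
}

entities_of_kind <- function(o, kind) {
  switch(kind,
         concept = o$concepts,
         object = o$obj_properties,
         datatype = o$dat_properties)
}

# Directed search: every entity of `ents` queried against idx; returns
# data.frame(e_query, e_hit, score) restricted to Best-k and score >= max_score.
directed_search <- function(ents, o, idx, cfg, lex_cfg, extended = FALSE,
                            mode = idx$mode, restrict_to = NULL) {
  rows <- vector("list", length(ents))
  for (i in seq_along(ents)) {
    e <- ents[i]
    q <- suppressWarnings(
      build_virtual_document(o, e, extended = extended, cfg = cfg, mode = mode))
    hits <- search_index(idx, q, k = lex_cfg$best_k)
    hits <- hits[hits$score >= lex_cfg$max_score, , drop = FALSE]
    if (!is.null(restrict_to))
      hits <- hits[hits$entity_id %in% restrict_to, , drop = FALSE]
    if (nrow(hits) > 0L)
      rows[[i]] <- data.frame(e_query = e, e_hit = hits$entity_id,
                              score = hits$score, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(e_query = character(0), e_hit = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Two-way index search
#'
#' Queries every entity of `o1` against `i2` and every entity of `o2`
#' against `i1`, keeps the Best-k hits per query with engine score at least
#' `max_score`, and intersects the two directed result sets. Each surviving
#' unordered pair carries the mean of its two directed engine scores (or the
#' single available score when `require_both = FALSE`).
#'
#' @param o1,o2 ontologies.
#' @param i1,i2 their indexes (built with the same config).
#' @param lex_cfg a [lexical_config()].
#' @param kind `"concept"`, `"object"` or `"datatype"` entities.
#' @param cfg the [normalizer_config()] shared with indexing.
#' @return data.frame `e1`, `e2`, `engine_score`.
#' @export
two_way_search <- function(o1, o2, i1, i2, lex_cfg = lexical_config(),
                           kind = "concept", cfg = normalizer_config()) {
  ents1 <- entities_of_kind(o1, kind)
  ents2 <- entities_of_kind(o2, kind)
  allowed2 <- entities_of_kind(o2, kind)
  d12 <- directed_search(ents1, o1, i2, cfg, lex_cfg, restrict_to = allowed2)
  d21 <- directed_search(ents2, o2, i1, cfg, lex_cfg, restrict_to = ents1)
  key12 <- paste(d12$e_query, d12$e_hit, sep = "\x1f")
  key21 <- paste(d21$e_hit, d21$e_query, sep = "\x1f")
  if (lex_cfg$require_both) {
    common <- intersect(key12, key21)
    if (length(common) == 0L) return(empty_pairs())
    s12 <- d12$score[match(common, key12)]
    s21 <- d21$score[match(common, key21)]
    parts <- strsplit(common, "\x1f", fixed = TRUE)
    out <- data.frame(e1 = vapply(parts, `[`, character(1), 1L),
                      e2 = vapply(parts, `[`, character(1), 2L),
                      engine_score = (s12 + s21) / 2,
                      stringsAsFactors = FALSE)
  } else {
    keys <- union(key12, key21)
    if (length(keys) == 0L) return(empty_pairs())
    s12 <- d12$score[match(keys, key12)]
    s21 <- d21$score[match(keys, key21)]
    sc <- rowMeans(cbind(s12, s21), na.rm = TRUE)
    parts <- strsplit(keys, "\x1f", fixed = TRUE)
    out <- data.frame(e1 = vapply(parts, `[`, character(1), 1L),
                      e2 = vapply(parts, `[`, character(1), 2L),
                      engine_score = sc, stringsAsFactors = FALSE)
  }
  out[order(out$e1, out$e2), , drop = FALSE]
}

# Sim_lex label variants of an entity: normalized pre-stem label strings
# including permutation-enriched forms; falls back to the local name.
simlex_labels <- function(o, e, cfg) {
  texts <- entity_labels(o, e)
  if (length(texts) == 0L) texts <- local_name(e)
  unique(unlist(lapply(texts, label_variants, cfg = cfg), use.names = FALSE))
}

pair_sim_lex <- function(o1, o2, e1, e2, cfg, weights) {
  l1 <- simlex_labels(o1, e1, cfg)
  l2 <- simlex_labels(o2, e2, cfg)
  if (length(l1) == 0L || length(l2) == 0L) return(0)
  lexical_similarity(l1, l2, weights)
}

#' Filter scored pairs into M_exact
#'
#' Retains the pairs whose lexical similarity `Sim_lex` reaches the theta
#' threshold; the triple score is `Sim_lex`, provenance `"exact"`.
#'
#' @param pairs output of [two_way_search()].
#' @param o1,o2 ontologies.
#' @param lex_cfg a [lexical_config()].
#' @param cfg normalizer config.
#' @param provenance provenance tag for the produced triples.
#' @return mapping-triple data.frame (`e1`, `e2`, `score`, `provenance`,
#'   `engine_score`, `sim_lex`).
#' @export
build_m_exact <- function(pairs, o1, o2, lex_cfg = lexical_config(),
                          cfg = normalizer_config(), provenance = "exact") {
  if (nrow(pairs) == 0L) return(empty_triples())
  sims <- vapply(seq_len(nrow(pairs)), function(i) {
    pair_sim_lex(o1, o2, pairs$e1[i], pairs$e2[i], cfg, lex_cfg$weights)
  }, numeric(1))
  keep <- sims >= lex_cfg$theta
  if (!any(keep)) return(empty_triples())
  out <- data.frame(e1 = pairs$e1[keep], e2 = pairs$e2[keep],
                    score = sims[keep], provenance = provenance,
                    engine_score = pairs$engine_score[keep],
                    sim_lex = sims[keep], stringsAsFactors = FALSE)
  out[order(out$e1, out$e2), , drop = FALSE]
}

#' Match properties (M_prop)
#'
#' The two-way + theta pipeline restricted to object-object and
#' datatype-datatype property pairs.
#'
#' @inheritParams two_way_search
#' @return mapping-triple data.frame with provenance `"prop"`.
#' @export
match_properties <- function(o1, o2, i1, i2, lex_cfg = lexical_config(),
                             cfg = normalizer_config()) {
  res <- empty_triples()
  for (kind in c("object", "datatype")) {
    pairs <- two_way_search(o1, o2, i1, i2, lex_cfg, kind = kind, cfg = cfg)
    res <- rbind(res, build_m_exact(pairs, o1, o2, lex_cfg, cfg,
                                    provenance = "prop"))
  }
  res[order(res$e1, res$e2), , drop = FALSE]
}

#' Extended search over residual concepts
#'
#' Repeats the two-way search for concepts left unmatched by the exact
#' stage, using extended virtual documents (ancestor fields included) in
#' relaxed token mode, followed by the same theta filter.
#'
#' @param residual1,residual2 unmatched concept IRIs of each side.
#' @param o1,o2 ontologies.
#' @param lex_cfg a [lexical_config()].
#' @param cfg normalizer config.
#' @return mapping-triple data.frame with provenance `"extended"`.
#' @export
extended_search <- function(residual1, residual2, o1, o2,
                            lex_cfg = lexical_config(),
                            cfg = normalizer_config()) {
  if (length(residual1) == 0L || length(residual2) == 0L)
    return(empty_triples())
  i1 <- index_ontology(o1, cfg, mode = "relaxed", extended = TRUE,
                       entities = residual1)
  i2 <- index_ontology(o2, cfg, mode = "relaxed", extended = TRUE,
                       entities = residual2)
  d12 <- directed_search(residual1, o1, i2, cfg, lex_cfg, extended = TRUE,
                         mode = "relaxed", restrict_to = residual2)
  d21 <- directed_search(residual2, o2, i1, cfg, lex_cfg, extended = TRUE,
                         mode = "relaxed", restrict_to = residual1)
  key12 <- paste(d12$e_query, d12$e_hit, sep = "\x1f")
  key21 <- paste(d21$e_hit, d21$e_query, sep = "\x1f")
  common <- if (lex_cfg$require_both) intersect(key12, key21) else union(key12, key21)
  if (length(common) == 0L) return(empty_triples())
  s12 <- d12$score[match(common, key12)]
  s21 <- d21$score[match(common, key21)]
  parts <- strsplit(common, "\x1f", fixed = TRUE)
  pairs <- data.frame(e1 = vapply(parts, `[`, character(1), 1L),
                      e2 = vapply(parts, `[`, character(1), 2L),
                      engine_score = rowMeans(cbind(s12, s21), na.rm = TRUE),
                      stringsAsFactors = FALSE)
  build_m_exact(pairs, o1, o2, lex_cfg, cfg, provenance = "extended")
}

#' Read a synonym lexicon
#'
#' A lexicon is a TSV file with columns `term`, `synonym` holding normalized
#' (lowercased, space-separated) forms; entries are used in both directions
#' but substitution is single-hop.
#'
#' @param path TSV file path.
#' @return a named list term -> character vector of synonyms.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("term", "synonym") %in% names(df)))
  lexicon_from_frame(df)
}

lexicon_from_frame <- function(df) {
  both <- rbind(data.frame(term = df$term, synonym = df$synonym,
                           stringsAsFactors = FALSE),
                data.frame(term = df$synonym, synonym = df$term,
                           stringsAsFactors = FALSE))
  both <- unique(both[both$term != both$synonym, , drop = FALSE])
  split(both$synonym, both$term)
}

# All single-hop substitutions of a normalized label string under the
# lexicon: whole-phrase replacement plus single whole-word replacement.
expand_label <- function(norm_label, lexicon) {
  out <- character(0)
  phrase <- lexicon[[norm_label]]
  if (!is.null(phrase)) out <- c(out, phrase)
  toks <- strsplit(norm_label, " ", fixed = TRUE)[[1]]
  for (i in seq_along(toks)) {
    subs <- lexicon[[toks[i]]]
    for (s in subs) {
      repl <- toks
      repl[i] <- s
      out <- c(out, paste(repl, collapse = " "))
    }
  }
  unique(out)
}

# Exact-form set of a normalized (pre-stem) label string.
forms_of_norm_label <- function(norm_label, cfg) {
  toks <- strsplit(norm_label, " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return(character(0))
  perms <- permute_tokens(toks, cfg$max_permuted_words)
  unique(vapply(perms, function(p) {
    if (cfg$stem && cfg$language == "en") p <- porter_stem(p)
    concatenate_tokens(p)
  }, character(1)))
}

#' Bridge residual concepts through a synonym lexicon
#'
#' For each residual concept, every label is expanded by single-hop lexicon
#' substitution; a pair is proposed when an expanded label of one side
#' equals (as an exact permuted-stemmed form) a label of the other side.
#' The triple score is `Sim_lex` on the original labels, floored at
#' `theta_syn`; provenance `"extended"`.
#'
#' @param residual1,residual2 unmatched concept IRIs.
#' @param o1,o2 ontologies.
#' @param lexicon a [read_lexicon()] result; `NULL` skips the stage with a
#'   warning.
#' @param lex_cfg a [lexical_config()].
#' @param cfg normalizer config.
#' @return mapping-triple data.frame with provenance `"extended"`.
#' @export
synonym_bridge <- function(residual1, residual2, o1, o2, lexicon,
                           lex_cfg = lexical_config(),
                           cfg = normalizer_config()) {
  if (is.null(lexicon)) {
    warning("no synonym lexicon supplied; synonym bridging skipped")
    return(empty_triples())
  }
  if (length(residual1) == 0L || length(residual2) == 0L)
    return(empty_triples())

  norm_labels <- function(o, e) {
    texts <- entity_labels(o, e)
    if (length(texts) == 0L) texts <- local_name(e)
    unique(vapply(texts, function(t)
      paste(normalize_label(t, cfg, stem = FALSE), collapse = " "),
      character(1), USE.NAMES = FALSE))
  }

  # form -> entities lookup for each side's residuals
  form_map <- function(o, residual) {
    m <- new.env(parent = emptyenv())
    for (e in residual) {
      for (lab in norm_labels(o, e)) {
        for (f in forms_of_norm_label(lab, cfg)) {
          cur <- if (exists(f, envir = m, inherits = FALSE))
            get(f, envir = m) else character(0)
          assign(f, unique(c(cur, e)), envir = m)
        }
      }
    }
    m
  }
  map1 <- form_map(o1, residual1)
  map2 <- form_map(o2, residual2)

  propose <- new.env(parent = emptyenv())
  bridge_side <- function(o, residual, other_map, flip) {
    for (e in residual) {
      for (lab in norm_labels(o, e)) {
        for (exp_lab in expand_label(lab, lexicon)) {
          for (f in forms_of_norm_label(exp_lab, cfg)) {
            if (exists(f, envir = other_map, inherits = FALSE)) {
              for (other in get(f, envir = other_map)) {
                key <- if (flip) paste(other, e, sep = "\x1f")
                       else paste(e, other, sep = "\x1f")
                assign(key, TRUE, envir = propose)
              }
            }
          }
        }
      }
    }
  }
  bridge_side(o1, residual1, map2, flip = FALSE)
  bridge_side(o2, residual2, map1, flip = TRUE)

  keys <- sort(ls(propose))
  if (length(keys) == 0L) return(empty_triples())
  parts <- strsplit(keys, "\x1f", fixed = TRUE)
  e1 <- vapply(parts, `[`, character(1), 1L)
  e2 <- vapply(parts, `[`, character(1), 2L)
  sims <- vapply(seq_along(e1), function(i)
    pair_sim_lex(o1, o2, e1[i], e2[i], cfg, lex_cfg$weights), numeric(1))
  data.frame(e1 = e1, e2 = e2,
             score = pmax(sims, lex_cfg$theta_syn),
             provenance = "extended", engine_score = NA_real_,
             sim_lex = sims, stringsAsFactors = FALSE)
}
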