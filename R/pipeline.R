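# Pipeline orchestration: load -> profile -> index -> lexical -> extended ->
# contextual -> post-process, with the full and light (lt) profiles.

#' Matching configuration
#'
#' @param normalizer a [normalizer_config()].
#' @param lexical a [lexical_config()].
#' @param phi structural gate for the contextual stage (default 0.5).
#' @param neg_per_pos negatives per positive in contextual training.
#' @param depth_limit neighbourhood depth for contextual scores.
#' @param min_positives minimum anchors required to run the contextual stage.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param cardinality `"one-to-one"` or `"one-to-many"` final selection.
#' @param profile `"full"` or `"lt"` (light: index the larger ontology only,
#'   concepts only, Levenshtein candidate selection, 1:n output).
#' @param properties,extended,contextual,enrich stage switches.
#' @return an object of class `match_config`.
#' @export
match_config <- function(normalizer = normalizer_config(),
                         lexical = lexical_config(),
                         phi = 0.5, neg_per_pos = 2L, depth_limit = 2L,
                         min_positives = 10L, seed = 1L,
                         cardinality = c("one-to-one", "one-to-many"),
                         profile = c("full", "lt"),
                         properties = TRUE, extended = TRUE,
                         contextual = TRUE, enrich = TRUE) {
  structure(list(normalizer = normalizer, lexical = lexical, phi = phi,
                 neg_per_pos = as.integer(neg_per_pos),
                 depth_limit = as.integer(depth_limit),
                 min_positives = as.integer(min_positives),
                 seed = as.integer(seed),
                 cardinality = match.arg(cardinality),
                 profile = match.arg(profile),
                 properties = isTRUE(properties),
                 extended = isTRUE(extended),
                 contextual = isTRUE(contextual),
                 enrich = isTRUE(enrich)),
            class = "match_config")
}

#' Read a matching configuration from YAML
#'
#' Recognized keys mirror the [match_config()] arguments, with nested
#' `normalizer.*` (language, max_permuted_words), `lexical.*` (best_k,
#' max_score, theta, theta_syn, require_both) and `simlex.*` (alpha, beta,
#' gamma) blocks.
#'
#' @param path YAML file path.
#' @return a [match_config()].
#' @export
read_match_config <- function(path) {
  y <- yaml::read_yaml(path)
  norm <- do.call(normalizer_config, y$normalizer %||% list())
  lw <- do.call(lex_weights, y$simlex %||% list())
  lex_args <- y$lexical %||% list()
  lex_args$weights <- lw
  lex <- do.call(lexical_config, lex_args)
  top <- y[setdiff(names(y), c("normalizer", "lexical", "simlex"))]
  do.call(match_config, c(list(normalizer = norm, lexical = lex), top))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_ontology <- function(x) {
  if (inherits(x, "ontology")) x else load_ontology(x)
}

dedupe_against <- function(new_triples, existing) {
  if (nrow(new_triples) == 0L) return(new_triples)
  keys <- pair_key(existing$e1, existing$e2)
  out <- new_triples[!(pair_key(new_triples$e1, new_triples$e2) %in% keys), ,
                     drop = FALSE]
  out[!duplicated(pair_key(out$e1, out$e2)), , drop = FALSE]
}

#' Match two ontologies
#'
#' Runs the full matching pipeline and returns an `ontology_alignment`
#' object holding the per-stage candidate sets (`m_exact`, `m_prop`,
#' `m_extended`, `m_context`), the filtered and greedily selected `final`
#' alignment, the task profile, the trained contextual model (if any) and,
#' when a reference is supplied, an evaluation report.
#'
#' @param source,target ontologies: [ontology()] objects or file paths.
#' @param config a [match_config()].
#' @param lexicon optional synonym lexicon ([read_lexicon()] result, a
#'   data.frame with `term`/`synonym` columns, or a TSV path).
#' @param reference optional reference alignment (data.frame with `e1`,
#'   `e2`, or an OAEI Alignment RDF path) for evaluation.
#' @return an object of class `ontology_alignment`.
#' @export
match_ontologies <- function(source, target, config = match_config(),
                             lexicon = NULL, reference = NULL) {
  t0 <- proc.time()[["elapsed"]]
  o1 <- as_ontology(source)
  o2 <- as_ontology(target)
  if (is.character(lexicon)) lexicon <- read_lexicon(lexicon)
  if (is.data.frame(lexicon)) lexicon <- lexicon_from_frame(lexicon)
  if (is.character(reference)) reference <- read_alignment(reference)

  prof <- profile_task(o1, o2)
  cfg <- config$normalizer
  lex_cfg <- config$lexical
  timings <- c(load = proc.time()[["elapsed"]] - t0)

  if (config$profile == "lt") {
    res <- match_lt(o1, o2, cfg, lex_cfg)
    res$profile <- prof
    res$config <- config
    res$timings <- c(timings, res$timings)
    res$reference <- reference
    if (!is.null(reference))
      res$evaluation <- evaluate_alignment(res$final, reference)
    return(res)
  }

  t1 <- proc.time()[["elapsed"]]
  i1 <- index_ontology(o1, cfg, mode = "exact")
  i2 <- index_ontology(o2, cfg, mode = "exact")
  timings["index"] <- proc.time()[["elapsed"]] - t1

  t1 <- proc.time()[["elapsed"]]
  pairs <- two_way_search(o1, o2, i1, i2, lex_cfg, kind = "concept", cfg = cfg)
  m_exact <- build_m_exact(pairs, o1, o2, lex_cfg, cfg)
  timings["lexical"] <- proc.time()[["elapsed"]] - t1

  t1 <- proc.time()[["elapsed"]]
  m_prop <- if (config$properties)
    match_properties(o1, o2, i1, i2, lex_cfg, cfg) else empty_triples()
  timings["properties"] <- proc.time()[["elapsed"]] - t1

  t1 <- proc.time()[["elapsed"]]
  m_extended <- empty_triples()
  if (config$extended) {
    residual1 <- setdiff(o1$concepts, m_exact$e1)
    residual2 <- setdiff(o2$concepts, m_exact$e2)
    ext <- extended_search(residual1, residual2, o1, o2, lex_cfg, cfg)
    syn <- if (is.null(lexicon)) empty_triples() else
      synonym_bridge(residual1, residual2, o1, o2, lexicon, lex_cfg, cfg)
    m_extended <- rbind(ext, dedupe_against(syn, ext))
    m_extended <- dedupe_against(m_extended, rbind(m_exact, m_prop))
    m_extended <- m_extended[order(m_extended$e1, m_extended$e2), , drop = FALSE]
  }
  timings["extended"] <- proc.time()[["elapsed"]] - t1

  t1 <- proc.time()[["elapsed"]]
  m_context <- empty_triples()
  context_model <- NULL
  if (config$contextual && nrow(m_exact) >= config$min_positives) {
    concept_anchors <- m_exact[m_exact$e1 %in% o1$concepts &
                                 m_exact$e2 %in% o2$concepts, , drop = FALSE]
    pcc <- suppressWarnings(generate_pcc(concept_anchors, o1, o2))
    training <- build_training_set(concept_anchors, o1, o2,
                                   neg_per_pos = config$neg_per_pos,
                                   seed = config$seed + 101L,
                                   depth_limit = config$depth_limit,
                                   cfg = cfg,
                                   min_positives = config$min_positives)
    context_model <- train_classifier(training, seed = config$seed + 202L)
    m_context <- classify_pcc(pcc, phi = config$phi, model = context_model,
                              m_exact = concept_anchors, o1 = o1, o2 = o2,
                              depth_limit = config$depth_limit, cfg = cfg)
    m_context <- dedupe_against(m_context, rbind(m_exact, m_prop, m_extended))
  }
  timings["contextual"] <- proc.time()[["elapsed"]] - t1

  t1 <- proc.time()[["elapsed"]]
  m_candidate <- rbind(m_exact, m_prop, m_extended, m_context)
  filtered <- disjointness_filter(m_candidate, m_exact, o1, o2)
  filtered <- crisscross_filter(filtered, m_exact, o1, o2)
  if (config$enrich) {
    adds <- enrich_candidates(filtered, o1, o2, theta = lex_cfg$theta,
                              cfg = cfg, weights = lex_cfg$weights)
    if (nrow(adds) > 0L) {
      adds$enriched <- NULL
      filtered <- rbind(filtered, adds)
    }
  }
  final <- greedy_select(filtered, mode = config$cardinality)
  timings["postprocess"] <- proc.time()[["elapsed"]] - t1

  out <- structure(list(
    o1 = o1, o2 = o2, profile = prof, config = config,
    m_exact = m_exact, m_prop = m_prop, m_extended = m_extended,
    m_context = m_context, m_candidate = m_candidate,
    final = final, context_model = context_model,
    reference = reference, timings = timings), class = "ontology_alignment")
  if (!is.null(reference))
    out$evaluation <- evaluate_alignment(final, reference)
  out
}

# Light profile: index only the larger ontology, query with the smaller,
# concepts only, candidates chosen by Levenshtein similarity of local
# names, 1:n output.
match_lt <- function(o1, o2, cfg, lex_cfg) {
  t1 <- proc.time()[["elapsed"]]
  swap <- length(o2$concepts) < length(o1$concepts)
  big <- if (swap) o1 else o2
  small <- if (swap) o2 else o1
  idx <- index_ontology(big, cfg, mode = "exact", entities = big$concepts)
  timings <- c(index = proc.time()[["elapsed"]] - t1)

  t1 <- proc.time()[["elapsed"]]
  rows <- list()
  for (e in small$concepts) {
    q <- suppressWarnings(build_virtual_document(small, e, cfg = cfg,
                                                 mode = "exact"))
    hits <- search_index(idx, q, k = lex_cfg$best_k)
    hits <- hits[hits$score >= lex_cfg$max_score, , drop = FALSE]
    if (nrow(hits) == 0L) next
    lev <- vapply(hits$entity_id, function(h)
      levenshtein_sim(tolower(local_name(e)), tolower(local_name(h))),
      numeric(1))
    best <- lev == max(lev)
    for (h in which(best)) {
      rows[[length(rows) + 1L]] <- data.frame(
        e1 = if (swap) hits$entity_id[h] else e,
        e2 = if (swap) e else hits$entity_id[h],
        score = unname(lev[h]), provenance = "exact",
        engine_score = hits$score[h], sim_lex = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  m_exact <- if (length(rows) > 0L) do.call(rbind, rows) else empty_triples()
  m_exact <- m_exact[order(m_exact$e1, m_exact$e2), , drop = FALSE]
  timings["lexical"] <- proc.time()[["elapsed"]] - t1
  final <- greedy_select(m_exact, mode = "one-to-many")
  structure(list(o1 = o1, o2 = o2,
                 m_exact = m_exact, m_prop = empty_triples(),
                 m_extended = empty_triples(), m_context = empty_triples(),
                 m_candidate = m_exact, final = final,
                 context_model = NULL, timings = timings),
            class = "ontology_alignment")
}

#' @export
print.ontology_alignment <- function(x, ...) {
  cat("<ontology alignment>\n")
  cat(sprintf("  profile: %s, cardinality: %s\n",
              x$config$profile %||% "full",
              x$config$cardinality %||% "one-to-many"))
  cat(sprintf("  M_exact: %d  M_prop: %d  M_extended: %d  M_context: %d\n",
              nrow(x$m_exact), nrow(x$m_prop), nrow(x$m_extended),
              nrow(x$m_context)))
  cat(sprintf("  final mappings: %d\n", nrow(x$final)))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}

#' @export
summary.ontology_alignment <- function(object, ...) {
  print(object)
  cat("  provenance of final mappings:\n")
  tab <- table(object$final$provenance)
  for (p in names(tab)) cat(sprintf("    %s: %d\n", p, tab[[p]]))
  cat("  stage timings (s):\n")
  for (t in names(object$timings))
    cat(sprintf("    %s: %.2f\n", t, object$timings[[t]]))
  invisible(object)
}

#' Run a matching task end to end and write its outputs
#'
#' Executes [match_ontologies()] and writes the final alignment in the OAEI
#' Alignment RDF format, a TSV export, and a JSON run report (configuration
#' echo, per-stage candidate counts, timings, and the evaluation when a
#' reference is given).
#'
#' @param source,target ontology file paths (or loaded ontologies).
#' @param output path of the alignment RDF to write; the TSV and report
#'   paths are derived from it (`.tsv`, `.report.json`).
#' @param config a [match_config()] or a YAML config path.
#' @param lexicon optional synonym lexicon (TSV path or object).
#' @param reference optional reference alignment (path or data.frame).
#' @return the `ontology_alignment`, invisibly.
#' @export
run_match <- function(source, target, output, config = match_config(),
                      lexicon = NULL, reference = NULL) {
  if (is.character(config)) config <- read_match_config(config)
  res <- match_ontologies(source, target, config = config,
                          lexicon = lexicon, reference = reference)
  write_alignment(res$final, output,
                  onto1 = res$o1$iri, onto2 = res$o2$iri)
  write_alignment_tsv(res$final, paste0(tools::file_path_sans_ext(output), ".tsv"))
  report <- list(
    config = list(
      profile = config$profile, cardinality = config$cardinality,
      theta = config$lexical$theta, best_k = config$lexical$best_k,
      max_score = config$lexical$max_score, phi = config$phi,
      neg_per_pos = config$neg_per_pos, depth_limit = config$depth_limit,
      seed = config$seed,
      simlex = unclass(config$lexical$weights),
      stages = list(properties = config$properties,
                    extended = config$extended,
                    contextual = config$contextual,
                    enrich = config$enrich)),
    profile = unclass(res$profile),
    stages = list(m_exact = nrow(res$m_exact), m_prop = nrow(res$m_prop),
                  m_extended = nrow(res$m_extended),
                  m_context = nrow(res$m_context),
                  final = nrow(res$final)),
    provenance = as.list(table(res$final$provenance)),
    timings = as.list(res$timings))
  if (!is.null(res$evaluation)) report$evaluation <- unclass(res$evaluation)
  jsonlite::write_json(report, paste0(tools::file_path_sans_ext(output), ".report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
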