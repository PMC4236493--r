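# Post-processing: union of the candidate sets, sub-concept enrichment, the
# two trivial consistency filters (disjointness and criss-cross), greedy
# best-candidate selection, and P/R/F evaluation.

PROVENANCE_RANK <- c(exact = 1L, prop = 2L, extended = 3L, context = 4L)

#' Enrich candidates with lexically matching sub-concept pairs
#'
#' For each mapped concept pair `(c1, c2)`, any unmapped direct-child pair
#' `(x, y)` with `Sim_lex(x, y) >= theta` is added (best-first per child)
#' with provenance `"context"` and an `enriched` flag.
#'
#' @param candidates mapping-triple data.frame (all stages combined).
#' @param o1,o2 ontologies.
#' @param theta Sim_lex acceptance threshold.
#' @param cfg normalizer config.
#' @param weights [lex_weights()] for Sim_lex.
#' @return data.frame of added triples (possibly empty).
#' @export
enrich_candidates <- function(candidates, o1, o2, theta = 0.75,
                              cfg = normalizer_config(), weights = lex_weights()) {
  added <- empty_triples()
  if (nrow(candidates) == 0L) return(added)
  mapped_keys <- pair_key(candidates$e1, candidates$e2)
  mapped1 <- unique(candidates$e1)
  mapped2 <- unique(candidates$e2)
  conc <- candidates$e1 %in% o1$concepts & candidates$e2 %in% o2$concepts
  for (i in which(conc)) {
    kids1 <- setdiff(descendants(o1, candidates$e1[i]), mapped1)
    kids2 <- setdiff(descendants(o2, candidates$e2[i]), mapped2)
    if (length(kids1) == 0L || length(kids2) == 0L) next
    scored <- list()
    for (x in kids1) for (y in kids2) {
      s <- pair_sim_lex(o1, o2, x, y, cfg, weights)
      if (s >= theta)
        scored[[length(scored) + 1L]] <- data.frame(
          e1 = x, e2 = y, score = s, stringsAsFactors = FALSE)
    }
    if (length(scored) == 0L) next
    sc <- do.call(rbind, scored)
    sc <- sc[order(-sc$score, sc$e1, sc$e2), , drop = FALSE]
    used1 <- character(0); used2 <- character(0)
    for (j in seq_len(nrow(sc))) {
      if (sc$e1[j] %in% used1 || sc$e2[j] %in% used2) next
      if (pair_key(sc$e1[j], sc$e2[j]) %in% mapped_keys) next
      added <- rbind(added, data.frame(
        e1 = sc$e1[j], e2 = sc$e2[j], score = sc$score[j],
        provenance = "context", engine_score = NA_real_,
        sim_lex = sc$score[j], stringsAsFactors = FALSE))
      used1 <- c(used1, sc$e1[j]); used2 <- c(used2, sc$e2[j])
      mapped_keys <- c(mapped_keys, pair_key(sc$e1[j], sc$e2[j]))
    }
  }
  if (nrow(added) > 0L) added$enriched <- TRUE
  added
}

#' Remove candidates that pair disjoint concepts with an anchored partner
#'
#' If `c1` and `c2` are declared disjoint in one ontology and `(c1, c3)` is
#' an anchor in `m_exact`, every candidate `(c2, c3)` is discarded;
#' symmetric across both ontologies.
#'
#' @param candidates mapping-triple data.frame.
#' @param m_exact anchor triples.
#' @param o1,o2 ontologies.
#' @return the filtered candidates (never adds rows).
#' @export
disjointness_filter <- function(candidates, m_exact, o1, o2) {
  if (nrow(candidates) == 0L || nrow(m_exact) == 0L) return(candidates)
  drop <- rep(FALSE, nrow(candidates))

  both_orders <- function(d)
    rbind(d, data.frame(a = d$b, b = d$a, stringsAsFactors = FALSE))

  if (nrow(o1$disjointness) > 0L) {
    dis1 <- both_orders(o1$disjointness)
    # anchors keyed by their o1 concept: c1 -> c3 partners
    anchor_of <- split(m_exact$e2, m_exact$e1)
    for (i in seq_len(nrow(dis1))) {
      c1 <- dis1$a[i]; c2 <- dis1$b[i]
      partners <- anchor_of[[c1]]
      if (is.null(partners)) next
      drop <- drop | (candidates$e1 == c2 & candidates$e2 %in% partners)
    }
  }
  if (nrow(o2$disjointness) > 0L) {
    dis2 <- both_orders(o2$disjointness)
    anchor_of <- split(m_exact$e1, m_exact$e2)
    for (i in seq_len(nrow(dis2))) {
      c1 <- dis2$a[i]; c2 <- dis2$b[i]
      partners <- anchor_of[[c1]]
      if (is.null(partners)) next
      drop <- drop | (candidates$e2 == c2 & candidates$e1 %in% partners)
    }
  }
  candidates[!drop, , drop = FALSE]
}

#' Remove criss-cross candidates conflicting with anchors
#'
#' For each anchor `(c1, c2)` in `m_exact`, discard candidates pairing `c1`
#' with a (transitive) ancestor or descendant of `c2`, and candidates
#' pairing a (transitive) ancestor or descendant of `c1` with `c2`. Anchor
#' triples themselves are exempt: they define the constraint.
#'
#' @inheritParams disjointness_filter
#' @return the filtered candidates.
#' @export
crisscross_filter <- function(candidates, m_exact, o1, o2) {
  if (nrow(candidates) == 0L || nrow(m_exact) == 0L) return(candidates)
  anchor_keys <- pair_key(m_exact$e1, m_exact$e2)
  cand_keys <- pair_key(candidates$e1, candidates$e2)
  exempt <- cand_keys %in% anchor_keys & candidates$provenance == "exact"
  drop <- rep(FALSE, nrow(candidates))
  anchors <- m_exact[m_exact$e1 %in% o1$concepts & m_exact$e2 %in% o2$concepts, ,
                     drop = FALSE]
  for (i in seq_len(nrow(anchors))) {
    c1 <- anchors$e1[i]; c2 <- anchors$e2[i]
    ud2 <- c(names(transitive_set(o2, c2, "up")),
             names(transitive_set(o2, c2, "down")))
    ud1 <- c(names(transitive_set(o1, c1, "up")),
             names(transitive_set(o1, c1, "down")))
    drop <- drop | (candidates$e1 == c1 & candidates$e2 %in% ud2)
    drop <- drop | (candidates$e2 == c2 & candidates$e1 %in% ud1)
  }
  candidates[!(drop & !exempt), , drop = FALSE]
}

#' Greedy best-candidate selection
#'
#' Candidates are sorted by score descending (ties: provenance rank
#' exact > prop > extended > context, then IRI pair); under one-to-one
#' cardinality a triple is accepted only if neither endpoint is already
#' used, under one-to-many all distinct pairs are accepted.
#'
#' @param candidates mapping-triple data.frame.
#' @param mode `"one-to-one"` or `"one-to-many"`.
#' @return the selected triples.
#' @export
greedy_select <- function(candidates, mode = c("one-to-one", "one-to-many")) {
  mode <- match.arg(mode)
  if (nrow(candidates) == 0L) return(candidates)
  rank <- PROVENANCE_RANK[candidates$provenance]
  ord <- order(-candidates$score, rank, candidates$e1, candidates$e2)
  cand <- candidates[ord, , drop = FALSE]
  cand <- cand[!duplicated(pair_key(cand$e1, cand$e2)), , drop = FALSE]
  if (mode == "one-to-many") {
    rownames(cand) <- NULL
    return(cand)
  }
  used1 <- new.env(parent = emptyenv())
  used2 <- new.env(parent = emptyenv())
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (exists(cand$e1[i], envir = used1, inherits = FALSE)) next
    if (exists(cand$e2[i], envir = used2, inherits = FALSE)) next
    keep[i] <- TRUE
    assign(cand$e1[i], TRUE, envir = used1)
    assign(cand$e2[i], TRUE, envir = used2)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate an alignment against a reference
#'
#' Precision `|RM n CM| / |RM|`, recall `|RM n CM| / |CM|` and F-measure
#' `2PR / (P + R)` over unordered entity-pair identity; zero denominators
#' yield 0 with a warning.
#'
#' @param returned data.frame with columns `e1`, `e2` (the system mappings).
#' @param reference data.frame with columns `e1`, `e2` (correct mappings).
#' @return an object of class `evaluation_report`: precision, recall,
#'   f_measure, n_returned, n_reference, n_correct.
#' @export
evaluate_alignment <- function(returned, reference) {
  rm_keys <- unique(pair_key(returned$e1, returned$e2))
  cm_keys <- unique(pair_key(reference$e1, reference$e2))
  n_correct <- length(intersect(rm_keys, cm_keys))
  precision <- if (length(rm_keys) == 0L) {
    warning("no returned mappings; precision = 0")
    0
  } else n_correct / length(rm_keys)
  recall <- if (length(cm_keys) == 0L) {
    warning("empty reference; recall = 0")
    0
  } else n_correct / length(cm_keys)
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f_measure = f,
                 n_returned = length(rm_keys), n_reference = length(cm_keys),
                 n_correct = n_correct),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F = %.4f  (%d returned, %d reference, %d correct)\n",
              x$precision, x$recall, x$f_measure,
              x$n_returned, x$n_reference, x$n_correct))
  invisible(x)
}
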