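# Contextual similarity stage: candidate pairs are drawn from the
# neighbourhood (ancestors x ancestors, descendants x descendants,
# siblings x siblings) of the high-precision anchor pairs in M_exact,
# gated by a depth-weighted structural score, featurized with five string
# metrics over ancestor-augmented label text, and classified by a decision
# tree trained on auto-labelled examples.

#' Generate possible context candidate pairs (pcc)
#'
#' For every anchor pair `(a, b)` in `m_exact`, all cross pairs among
#' `ancestors(a) x ancestors(b)`, `descendants(a) x descendants(b)` and
#' `siblings(a) x siblings(b)` whose members are not already mapped,
#' deduplicated.
#'
#' @param m_exact mapping-triple data.frame of anchors.
#' @param o1,o2 ontologies.
#' @return data.frame `e1`, `e2` of unmapped candidate pairs.
#' @export
generate_pcc <- function(m_exact, o1, o2) {
  if (nrow(m_exact) == 0L) {
    warning("empty M_exact: contextual stage degenerate")
    return(data.frame(e1 = character(0), e2 = character(0),
                      stringsAsFactors = FALSE))
  }
  mapped1 <- unique(m_exact$e1)
  mapped2 <- unique(m_exact$e2)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(m_exact))) {
    a <- m_exact$e1[i]; b <- m_exact$e2[i]
    if (!(a %in% o1$concepts) || !(b %in% o2$concepts)) next
    sets <- list(
      list(setdiff(ancestors(o1, a), mapped1), setdiff(ancestors(o2, b), mapped2)),
      list(setdiff(descendants(o1, a), mapped1), setdiff(descendants(o2, b), mapped2)),
      list(setdiff(siblings(o1, a), mapped1), setdiff(siblings(o2, b), mapped2)))
    for (s in sets) {
      if (length(s[[1]]) == 0L || length(s[[2]]) == 0L) next
      for (x in s[[1]]) for (y in s[[2]])
        assign(paste(x, y, sep = "\x1f"), TRUE, envir = seen)
    }
  }
  keys <- sort(ls(seen))
  if (length(keys) == 0L)
    return(data.frame(e1 = character(0), e2 = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keys, "\x1f", fixed = TRUE)
  data.frame(e1 = vapply(parts, `[`, character(1), 1L),
             e2 = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Structural context scores of a concept pair
#'
#' `score_sub` accumulates, over anchor pairs `(x, y)` in `m_exact` with `x`
#' a descendant of `c1` and `y` a descendant of `c2` (within `depth_limit`),
#' the weight `1 / max(depth(x), depth(y))`, so direct-child evidence counts
#' 1 and deeper evidence counts less. `score_sup` mirrors this over
#' ancestors; `score_sib` counts matched sibling pairs with weight 1.
#'
#' @param c1,c2 concept IRIs.
#' @param m_exact anchor triples.
#' @param o1,o2 ontologies.
#' @param depth_limit neighbourhood depth (default 2).
#' @return list with `score_sub`, `score_sup`, `score_sib`, `total`.
#' @export
context_scores <- function(c1, c2, m_exact, o1, o2, depth_limit = 2L) {
  stopifnot(depth_limit >= 1L)
  anchor_keys <- paste(m_exact$e1, m_exact$e2, sep = "\x1f")

  directional <- function(dir) {
    d1 <- walk_k(o1, c1, depth_limit, dir)
    d2 <- walk_k(o2, c2, depth_limit, dir)
    if (length(d1) == 0L || length(d2) == 0L) return(0)
    total <- 0
    hit <- m_exact$e1 %in% names(d1) & m_exact$e2 %in% names(d2)
    for (i in which(hit)) {
      dep <- max(d1[[m_exact$e1[i]]], d2[[m_exact$e2[i]]])
      total <- total + 1 / dep
    }
    total
  }
  score_sub <- directional("down")
  score_sup <- directional("up")

  s1 <- siblings(o1, c1); s2 <- siblings(o2, c2)
  score_sib <- if (length(s1) == 0L || length(s2) == 0L) 0 else
    sum(m_exact$e1 %in% s1 & m_exact$e2 %in% s2)

  list(score_sub = score_sub, score_sup = score_sup, score_sib = score_sib,
       total = score_sub + score_sup + score_sib)
}

# Five-metric feature vector between the context texts of a pair.
context_features <- function(text1, text2) {
  c(qgram = qgram_sim(text1, text2),
    levenshtein = levenshtein_sim(text1, text2),
    block_distance = block_distance_sim(text1, text2),
    jaccard = jaccard_words(text1, text2),
    monge_elkan = monge_elkan(text1, text2))
}

context_text_cache <- function(o, cfg) {
  cache <- new.env(parent = emptyenv())
  function(e) {
    if (exists(e, envir = cache, inherits = FALSE))
      return(get(e, envir = cache))
    txt <- entity_context_text(o, e, cfg)
    assign(e, txt, envir = cache)
    txt
  }
}

#' Build the contextual training set
#'
#' Every anchor pair of `m_exact` yields one `"yes"` feature vector; for
#' each anchor `(c1, c2)`, `neg_per_pos` `"no"` vectors are built from
#' `(c1, d)` with `d` sampled uniformly (seeded) from the ancestors and
#' descendants of `c2` within the depth limit -- a concept cannot be mapped
#' both to a concept and to its ancestor or descendant. Anchors lacking
#' neighbours contribute fewer negatives.
#'
#' @param m_exact anchor triples (at least `min_positives` rows).
#' @param o1,o2 ontologies.
#' @param neg_per_pos negatives drawn per positive (default 2).
#' @param seed integer seed for the negative sampling.
#' @param depth_limit neighbourhood depth (default 2).
#' @param cfg normalizer config.
#' @param min_positives minimum usable anchors (default 10).
#' @return data.frame of five feature columns plus a `label` factor
#'   (`"yes"`/`"no"`), or `NULL` when there are too few positives.
#' @export
build_training_set <- function(m_exact, o1, o2, neg_per_pos = 2L, seed = 1L,
                               depth_limit = 2L, cfg = normalizer_config(),
                               min_positives = 10L) {
  anchors <- m_exact[m_exact$e1 %in% o1$concepts & m_exact$e2 %in% o2$concepts, ,
                     drop = FALSE]
  if (nrow(anchors) < min_positives) return(NULL)
  text1 <- context_text_cache(o1, cfg)
  text2 <- context_text_cache(o2, cfg)

  rows <- vector("list", nrow(anchors) * (1L + neg_per_pos))
  k <- 0L
  with_seed(seed, {
    for (i in seq_len(nrow(anchors))) {
      c1 <- anchors$e1[i]; c2 <- anchors$e2[i]
      k <- k + 1L
      rows[[k]] <- c(context_features(text1(c1), text2(c2)), label = "yes")
      nbr <- unique(c(names(desc_k(o2, c2, depth_limit)),
                      names(anc_k(o2, c2, depth_limit))))
      if (length(nbr) == 0L) next
      take <- sample(nbr, min(neg_per_pos, length(nbr)))
      for (d in take) {
        k <- k + 1L
        rows[[k]] <- c(context_features(text1(c1), text2(d)), label = "no")
      }
    }
  })
  rows <- rows[seq_len(k)]
  feat <- as.data.frame(do.call(rbind, lapply(rows, function(r) r[1:5])),
                        stringsAsFactors = FALSE)
  names(feat) <- c("qgram", "levenshtein", "block_distance", "jaccard",
                   "monge_elkan")
  feat[] <- lapply(feat, as.numeric)
  feat$label <- factor(vapply(rows, `[[`, character(1), "label"),
                       levels = c("no", "yes"))
  feat
}

#' Train the contextual decision tree
#'
#' Fits a classification tree on the five string-similarity features.
#' Training requires both classes; the training accuracy is attached to the
#' result.
#'
#' @param training output of [build_training_set()].
#' @param seed integer seed (tree fitting itself is deterministic; the seed
#'   guards any tie-breaking randomness).
#' @return an object of class `context_model` wrapping the `rpart` fit, or
#'   `NULL` for a single-class training set.
#' @export
train_classifier <- function(training, seed = 1L) {
  if (is.null(training) || length(unique(training$label)) < 2L) return(NULL)
  fit <- with_seed(seed, rpart::rpart(
    label ~ qgram + levenshtein + block_distance + jaccard + monge_elkan,
    data = training, method = "class",
    control = rpart::rpart.control(minsplit = 5L, cp = 0.005, xval = 0L)))
  pred <- predict(fit, training, type = "prob")[, "yes"]
  acc <- mean((pred > 0.5) == (training$label == "yes"))
  structure(list(fit = fit, training_accuracy = acc,
                 n_training = nrow(training)),
            class = "context_model")
}

#' @export
print.context_model <- function(x, ...) {
  cat(sprintf("<context model> decision tree, %d training rows, accuracy %.3f\n",
              x$n_training, x$training_accuracy))
  print(x$fit)
  invisible(x)
}

#' Classify context candidates into M_context
#'
#' Pairs whose structural context score exceeds `phi` are featurized and
#' classified; predictions `"yes"` (leaf probability strictly above 0.5 --
#' a tied leaf predicts `"no"`) become mapping triples with provenance
#' `"context"` and the leaf confidence as score.
#'
#' @param pcc output of [generate_pcc()].
#' @param phi structural score gate (default 0.5).
#' @param model a [train_classifier()] result.
#' @param m_exact anchor triples.
#' @param o1,o2 ontologies.
#' @param depth_limit neighbourhood depth for the structural scores.
#' @param cfg normalizer config.
#' @return mapping-triple data.frame with provenance `"context"`.
#' @export
classify_pcc <- function(pcc, phi = 0.5, model = NULL, m_exact, o1, o2,
                         depth_limit = 2L, cfg = normalizer_config()) {
  if (is.null(model) || nrow(pcc) == 0L) return(empty_triples())
  totals <- vapply(seq_len(nrow(pcc)), function(i) {
    context_scores(pcc$e1[i], pcc$e2[i], m_exact, o1, o2, depth_limit)$total
  }, numeric(1))
  gated <- pcc[totals > phi, , drop = FALSE]
  if (nrow(gated) == 0L) return(empty_triples())
  text1 <- context_text_cache(o1, cfg)
  text2 <- context_text_cache(o2, cfg)
  feats <- as.data.frame(t(vapply(seq_len(nrow(gated)), function(i)
    context_features(text1(gated$e1[i]), text2(gated$e2[i])), numeric(5))))
  names(feats) <- c("qgram", "levenshtein", "block_distance", "jaccard",
                    "monge_elkan")
  prob_yes <- predict(model$fit, feats, type = "prob")[, "yes"]
  keep <- prob_yes > 0.5
  data.frame(e1 = gated$e1[keep], e2 = gated$e2[keep],
             score = unname(prob_yes[keep]), provenance = "context",
             engine_score = NA_real_, sim_lex = NA_real_,
             stringsAsFactors = FALSE)
}
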