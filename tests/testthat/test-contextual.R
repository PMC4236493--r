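cfg <- normalizer_config()

# mirrored taxonomies with one anchor and named neighbours
ctx_fixture <- function() {
  #        root
  #       /    \
  #   anchor    aunt
  #   /    \
  # kid1  kid2    (kid2 has child grandkid)
  labels <- c("root organ", "anchor part", "aunt part", "kid one",
              "kid two", "grand kid")
  parent <- c(0, 1, 1, 2, 2, 5)
  list(o1 = make_taxonomy(labels, parent, ns = NS1),
       o2 = make_taxonomy(labels, parent, ns = NS2))
}

anchor_df <- function(...) {
  keys <- list(...)
  data.frame(e1 = paste0(NS1, vapply(keys, `[`, character(1), 1)),
             e2 = paste0(NS2, vapply(keys, `[`, character(1), 2)),
             score = 1, provenance = "exact", engine_score = NA_real_,
             sim_lex = 1, stringsAsFactors = FALSE)
}

test_that("pcc gathers unmapped neighbour cross pairs and deduplicates", {
  fx <- ctx_fixture()
  m <- anchor_df(c("anchor_part", "anchor_part"))
  pcc <- generate_pcc(m, fx$o1, fx$o2)
  keys <- paste(pcc$e1, pcc$e2)
  # children cross pairs present
  expect_true(paste(paste0(NS1, "kid_one"), paste0(NS2, "kid_one")) %in% keys)
  expect_true(paste(paste0(NS1, "kid_one"), paste0(NS2, "kid_two")) %in% keys)
  # ancestors and siblings too
  expect_true(paste(paste0(NS1, "root_organ"), paste0(NS2, "root_organ")) %in% keys)
  expect_true(paste(paste0(NS1, "aunt_part"), paste0(NS2, "aunt_part")) %in% keys)
  # no duplicates, and no anchor members
  expect_equal(anyDuplicated(keys), 0)
  expect_false(any(pcc$e1 == paste0(NS1, "anchor_part")))
  # pcc never intersects M_exact
  expect_false(any(keys %in% paste(m$e1, m$e2)))

  # anchors whose neighbours are all mapped contribute nothing
  m_all <- anchor_df(c("anchor_part", "anchor_part"),
                     c("root_organ", "root_organ"),
                     c("aunt_part", "aunt_part"),
                     c("kid_one", "kid_one"), c("kid_two", "kid_two"))
  pcc2 <- generate_pcc(m_all[1, ], fx$o1, fx$o2)
  # with only the anchor given, neighbours unmapped -> nonempty; with all
  # mapped, empty
  pcc3 <- generate_pcc(m_all, fx$o1, fx$o2)
  keys3 <- paste(pcc3$e1, pcc3$e2)
  expect_false(any(keys3 %in% paste(m_all$e1, m_all$e2)))
  expect_true(nrow(pcc2) > nrow(pcc3))

  expect_warning(empty <- generate_pcc(m[0, ], fx$o1, fx$o2), "degenerate")
  expect_equal(nrow(empty), 0)
})

test_that("context scores weight matched neighbours by depth", {
  fx <- ctx_fixture()
  # no surrounding matches -> 0
  none <- context_scores(paste0(NS1, "kid_one"), paste0(NS2, "kid_one"),
                         anchor_df(c("aunt_part", "aunt_part")),
                         fx$o1, fx$o2, 2)
  expect_equal(none$total, 0)
  # matched direct-child pair -> score_sub = 1
  sub1 <- context_scores(paste0(NS1, "anchor_part"), paste0(NS2, "anchor_part"),
                         anchor_df(c("kid_one", "kid_one")),
                         fx$o1, fx$o2, 2)
  expect_equal(sub1$score_sub, 1)
  expect_equal(sub1$total, 1)
  # matched depth-2 descendant pair (grand kid under anchor) -> 0.5
  sub2 <- context_scores(paste0(NS1, "anchor_part"), paste0(NS2, "anchor_part"),
                         anchor_df(c("grand_kid", "grand_kid")),
                         fx$o1, fx$o2, 2)
  expect_equal(sub2$score_sub, 0.5)
  # matched parent -> score_sup = 1; matched sibling -> score_sib = 1
  up <- context_scores(paste0(NS1, "kid_one"), paste0(NS2, "kid_one"),
                       anchor_df(c("anchor_part", "anchor_part")),
                       fx$o1, fx$o2, 2)
  expect_equal(up$score_sup, 1)
  sib <- context_scores(paste0(NS1, "kid_one"), paste0(NS2, "kid_one"),
                        anchor_df(c("kid_two", "kid_two")),
                        fx$o1, fx$o2, 2)
  expect_equal(sib$score_sib, 1)
})

test_that("training sets follow the negative-generation rule and the seed", {
  set.seed(3)
  n <- 40
  labels <- paste(random_words(n), random_words(n))
  parent <- c(0, vapply(2:n, function(i) sample(i - 1, 1), integer(1)))
  o1 <- make_taxonomy(labels, parent, ns = NS1)
  o2 <- make_taxonomy(labels, parent, ns = NS2)
  m <- data.frame(e1 = o1$concepts, e2 = o2$concepts, score = 1,
                  provenance = "exact", engine_score = NA_real_, sim_lex = 1)
  tr1 <- build_training_set(m, o1, o2, neg_per_pos = 2, seed = 42, cfg = cfg)
  tr2 <- build_training_set(m, o1, o2, neg_per_pos = 2, seed = 42, cfg = cfg)
  expect_identical(tr1, tr2)
  tr3 <- build_training_set(m, o1, o2, neg_per_pos = 2, seed = 43, cfg = cfg)
  expect_false(identical(tr1, tr3))
  expect_equal(sum(tr1$label == "yes"), n)
  expect_lte(sum(tr1$label == "no"), 2 * n)
  # a concept with no ancestors or descendants contributes no negatives
  o_flat1 <- make_taxonomy("alone", 0, ns = NS1)
  o_flat2 <- make_taxonomy("alone", 0, ns = NS2)
  m_flat <- data.frame(e1 = o_flat1$concepts, e2 = o_flat2$concepts,
                       score = 1, provenance = "exact",
                       engine_score = NA_real_, sim_lex = 1)
  tr_flat <- build_training_set(m_flat, o_flat1, o_flat2, min_positives = 1,
                                cfg = cfg)
  expect_equal(sum(tr_flat$label == "no"), 0)
  # too few positives aborts
  expect_null(build_training_set(m[1:3, ], o1, o2, min_positives = 10,
                                 cfg = cfg))
})

test_that("negatives pair an anchor with hierarchy neighbours of its partner", {
  # anchor (c1, c2) with c2's only neighbour its parent p
  o1 <- make_taxonomy(c("p label", "c label"), c(0, 1), ns = NS1)
  o2 <- make_taxonomy(c("p label", "c label"), c(0, 1), ns = NS2)
  m <- data.frame(e1 = paste0(NS1, "c_label"), e2 = paste0(NS2, "c_label"),
                  score = 1, provenance = "exact", engine_score = NA_real_,
                  sim_lex = 1)
  tr <- build_training_set(m, o1, o2, neg_per_pos = 2, seed = 1,
                           min_positives = 1, cfg = cfg)
  expect_equal(sum(tr$label == "no"), 1)  # only the parent is available
})

test_that("the decision tree separates clean classes and survives noise", {
  yes <- data.frame(qgram = 1, levenshtein = 1, block_distance = 1,
                    jaccard = 1, monge_elkan = 1)
  no <- data.frame(qgram = 0, levenshtein = 0, block_distance = 0,
                   jaccard = 0, monge_elkan = 0)
  training <- rbind(yes[rep(1, 20), ], no[rep(1, 20), ])
  training$label <- factor(rep(c("yes", "no"), each = 20),
                           levels = c("no", "yes"))
  model <- train_classifier(training, seed = 1)
  expect_equal(model$training_accuracy, 1)
  # contradictory duplicated rows: accuracy < 1, no crash
  contra <- training
  contra$label <- factor(rep(c("yes", "no"), 20), levels = c("no", "yes"))
  model2 <- train_classifier(contra, seed = 1)
  expect_lt(model2$training_accuracy, 1)
  # single-class training aborts
  expect_null(train_classifier(training[training$label == "yes", ], seed = 1))
})

test_that("the tree recovers a planted threshold rule on held-out data", {
  set.seed(10)
  n <- 200
  gen <- function(n) {
    d <- data.frame(qgram = runif(n), levenshtein = runif(n),
                    block_distance = runif(n), jaccard = runif(n),
                    monge_elkan = runif(n))
    d$label <- factor(ifelse(d$jaccard > 0.55 & d$qgram > 0.3, "yes", "no"),
                      levels = c("no", "yes"))
    d
  }
  train <- gen(n); test <- gen(100)
  model <- train_classifier(train, seed = 1)
  pred <- predict(model$fit, test, type = "prob")[, "yes"] > 0.5
  expect_gte(mean(pred == (test$label == "yes")), 0.95)
})

test_that("classification gates on the structural score and excludes mapped pairs", {
  fx <- ctx_fixture()
  m <- anchor_df(c("anchor_part", "anchor_part"),
                 c("grand_kid", "grand_kid"),
                 c("root_organ", "root_organ"))
  # force a permissive model trained on clean separable data
  yes <- data.frame(qgram = c(1, .9), levenshtein = c(1, .9),
                    block_distance = c(1, .9), jaccard = c(1, .9),
                    monge_elkan = c(1, .9))
  no <- yes * 0
  training <- rbind(yes[rep(1:2, 10), ], no[rep(1:2, 10), ])
  training$label <- factor(rep(c("yes", "no"), each = 20),
                           levels = c("no", "yes"))
  model <- train_classifier(training, seed = 1)
  pcc <- suppressWarnings(generate_pcc(m, fx$o1, fx$o2))
  got <- classify_pcc(pcc, phi = 0.5, model = model, m_exact = m,
                      o1 = fx$o1, o2 = fx$o2, cfg = cfg)
  keys <- paste(got$e1, got$e2)
  # kid pairs sit between matched parent and matched child: s > phi, and
  # their context texts are identical -> classified yes
  expect_true(paste(paste0(NS1, "kid_two"), paste0(NS2, "kid_two")) %in% keys)
  expect_true(all(got$provenance == "context"))
  expect_false(any(keys %in% paste(m$e1, m$e2)))
  # a high phi gates everything out
  none <- classify_pcc(pcc, phi = 1e6, model = model, m_exact = m,
                       o1 = fx$o1, o2 = fx$o2, cfg = cfg)
  expect_equal(nrow(none), 0)
})

test_that("repeated runs with fixed seeds give identical M_context", {
  pair <- generate_pair(generator_spec(seed = 19, n_concepts = 80,
                                       p_opaque = 0.15))
  r1 <- match_ontologies(pair$o1, pair$o2, match_config(seed = 5))
  r2 <- match_ontologies(pair$o1, pair$o2, match_config(seed = 5))
  expect_identical(r1$m_context, r2$m_context)
  expect_identical(r1$final, r2$final)
  # M_context never overlaps the earlier candidate sets
  prior <- paste(c(r1$m_exact$e1, r1$m_extended$e1),
                 c(r1$m_exact$e2, r1$m_extended$e2))
  expect_false(any(paste(r1$m_context$e1, r1$m_context$e2) %in% prior))
})
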