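cfg <- normalizer_config()
lex_cfg <- lexical_config()

two_onto <- function(labels1, labels2, parent1 = NULL, parent2 = NULL) {
  if (is.null(parent1)) parent1 <- c(0, rep(1, length(labels1) - 1))
  if (is.null(parent2)) parent2 <- c(0, rep(1, length(labels2) - 1))
  list(o1 = make_taxonomy(labels1, parent1, ns = NS1),
       o2 = make_taxonomy(labels2, parent2, ns = NS2))
}

exact_indexes <- function(o1, o2) {
  list(i1 = index_ontology(o1, cfg, mode = "exact"),
       i2 = index_ontology(o2, cfg, mode = "exact"))
}

test_that("two-way search keeps pairs found from both directions only", {
  os <- two_onto(c("body", "heart", "lung"), c("soma", "heart", "kidney"))
  ix <- exact_indexes(os$o1, os$o2)
  pairs <- two_way_search(os$o1, os$o2, ix$i1, ix$i2, lex_cfg, cfg = cfg)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$e1, paste0(NS1, "heart"))
  expect_equal(pairs$e2, paste0(NS2, "heart"))
  # label present on one side only yields nothing
  os2 <- two_onto(c("body", "spleen"), c("soma", "kidney"))
  ix2 <- exact_indexes(os2$o1, os2$o2)
  expect_equal(nrow(two_way_search(os2$o1, os2$o2, ix2$i1, ix2$i2, lex_cfg,
                                   cfg = cfg)), 0)
})

test_that("a pair ranked below Best-k in one direction is excluded", {
  # o2 has many entities sharing the query's label tokens so that the true
  # partner of "alpha" falls outside Best-1 in one direction
  o1 <- make_taxonomy(c("root x", "alpha beta"), c(0, 1), ns = NS1)
  o2 <- make_taxonomy(c("root x", "alpha beta", "alpha beta extra"),
                      c(0, 1, 1), ns = NS2)
  i1 <- index_ontology(o1, cfg, mode = "exact")
  i2 <- index_ontology(o2, cfg, mode = "exact")
  strict <- lexical_config(best_k = 1, max_score = 0)
  pairs <- two_way_search(o1, o2, i1, i2, strict, cfg = cfg)
  # exhaustive check: every reported pair is in the top-1 of both directions
  for (i in seq_len(nrow(pairs))) {
    q1 <- build_virtual_document(o1, pairs$e1[i], cfg = cfg, mode = "exact")
    expect_equal(search_index(i2, q1, 1)$entity_id, pairs$e2[i])
    q2 <- build_virtual_document(o2, pairs$e2[i], cfg = cfg, mode = "exact")
    expect_equal(search_index(i1, q2, 1)$entity_id, pairs$e1[i])
  }
})

test_that("the theta filter on Sim_lex is strict and assigns Sim_lex as score", {
  os <- two_onto(c("organ", "left lung"), c("organ", "left lungs"))
  ix <- exact_indexes(os$o1, os$o2)
  pairs <- two_way_search(os$o1, os$o2, ix$i1, ix$i2,
                          lexical_config(max_score = 0), cfg = cfg)
  m_all <- build_m_exact(pairs, os$o1, os$o2, lexical_config(theta = 0),
                         cfg = cfg)
  expect_true(all(m_all$score == m_all$sim_lex))
  expect_true(all(m_all$provenance == "exact"))
  identical_pair <- m_all[m_all$e1 == paste0(NS1, "organ"), ]
  expect_equal(identical_pair$score, 1)
  # raising theta just above a pair's Sim_lex drops exactly that pair
  lungs <- m_all[m_all$e1 == paste0(NS1, "left_lung"), ]
  expect_equal(nrow(lungs), 1)
  m_cut <- build_m_exact(pairs, os$o1, os$o2,
                         lexical_config(theta = lungs$sim_lex + 1e-6),
                         cfg = cfg)
  expect_false(paste0(NS1, "left_lung") %in% m_cut$e1)
  m_keep <- build_m_exact(pairs, os$o1, os$o2,
                          lexical_config(theta = lungs$sim_lex), cfg = cfg)
  expect_true(paste0(NS1, "left_lung") %in% m_keep$e1)
})

test_that("theta filtering agrees with an exhaustive Sim_lex oracle", {
  set.seed(61)
  labels1 <- paste(random_words(10), random_words(10))
  labels2 <- c(labels1[1:5], paste(random_words(5), random_words(5)))
  os <- two_onto(labels1, labels2)
  ix <- exact_indexes(os$o1, os$o2)
  pairs <- two_way_search(os$o1, os$o2, ix$i1, ix$i2,
                          lexical_config(max_score = 0), cfg = cfg)
  theta <- 0.8
  m <- build_m_exact(pairs, os$o1, os$o2, lexical_config(theta = theta),
                     cfg = cfg)
  for (i in seq_len(nrow(pairs))) {
    sim <- lexical_similarity(
      ontomatch:::simlex_labels(os$o1, pairs$e1[i], cfg),
      ontomatch:::simlex_labels(os$o2, pairs$e2[i], cfg))
    in_m <- paste(pairs$e1[i], pairs$e2[i]) %in% paste(m$e1, m$e2)
    expect_equal(in_m, sim >= theta)
  }
})

test_that("property matching respects kind compatibility", {
  iri1 <- function(x) paste0(NS1, x); iri2 <- function(x) paste0(NS2, x)
  mk <- function(ns, iri) ontology(
    concepts = iri("Thing"),
    obj_properties = iri("Has_part"),
    dat_properties = iri("Has_note"),
    labels = data.frame(entity = c(iri("Thing"), iri("Has_part"), iri("Has_note")),
                        text = c("thing", "has part", "has note"), lang = ""),
    prop_domain = stats::setNames(list(iri("Thing"), iri("Thing")),
                                  c(iri("Has_part"), iri("Has_note"))),
    prop_range = stats::setNames(
      list(iri("Thing"), "http://www.w3.org/2001/XMLSchema#string"),
      c(iri("Has_part"), iri("Has_note"))),
    iri = ns)
  o1 <- mk(NS1, iri1); o2 <- mk(NS2, iri2)
  i1 <- index_ontology(o1, cfg, mode = "exact")
  i2 <- index_ontology(o2, cfg, mode = "exact")
  m_prop <- match_properties(o1, o2, i1, i2, lexical_config(max_score = 0),
                             cfg = cfg)
  keys <- paste(m_prop$e1, m_prop$e2)
  expect_true(paste(iri1("Has_part"), iri2("Has_part")) %in% keys)
  expect_true(paste(iri1("Has_note"), iri2("Has_note")) %in% keys)
  # same-name object vs datatype property never pairs
  expect_false(paste(iri1("Has_part"), iri2("Has_note")) %in% keys)
  expect_false(paste(iri1("Has_note"), iri2("Has_part")) %in% keys)
})

test_that("extended search finds residual concepts through ancestor fields", {
  # same labels but also concepts only matchable via parents
  o1 <- make_taxonomy(c("organ", "left lung"), c(0, 1), ns = NS1)
  o2 <- make_taxonomy(c("organ", "left lung"), c(0, 1), ns = NS2)
  ext <- extended_search(o1$concepts, o2$concepts, o1, o2,
                         lexical_config(max_score = 0), cfg)
  keys <- paste(ext$e1, ext$e2)
  expect_true(paste(paste0(NS1, "left_lung"), paste0(NS2, "left_lung")) %in% keys)
  expect_true(all(ext$provenance == "extended"))
  # already-matched (non-residual) concepts are never re-proposed
  ext2 <- extended_search(character(0), o2$concepts, o1, o2,
                          lexical_config(max_score = 0), cfg)
  expect_equal(nrow(ext2), 0)
})

test_that("the synonym bridge proposes lexicon-linked pairs, one hop only", {
  o1 <- make_taxonomy(c("disease", "heart attack"), c(0, 1), ns = NS1)
  o2 <- make_taxonomy(c("disease", "myocardial infarction"), c(0, 1), ns = NS2)
  lexicon <- ontomatch:::lexicon_from_frame(data.frame(
    term = "heart attack", synonym = "myocardial infarction"))
  res <- synonym_bridge(paste0(NS1, "heart_attack"),
                        paste0(NS2, "myocardial_infarction"),
                        o1, o2, lexicon, lex_cfg, cfg)
  expect_equal(nrow(res), 1)
  expect_equal(res$e1, paste0(NS1, "heart_attack"))
  expect_gte(res$score, lex_cfg$theta_syn)

  # no overlapping lexicon entries -> nothing
  lex_none <- ontomatch:::lexicon_from_frame(data.frame(
    term = "renal calculus", synonym = "kidney stone"))
  expect_equal(nrow(synonym_bridge(paste0(NS1, "heart_attack"),
                                   paste0(NS2, "myocardial_infarction"),
                                   o1, o2, lex_none, lex_cfg, cfg)), 0)

  # chains (a -> b, b -> c) are not followed
  o3 <- make_taxonomy(c("disease", "cardiac event"), c(0, 1), ns = NS2)
  lex_chain <- ontomatch:::lexicon_from_frame(data.frame(
    term = c("heart attack", "myocardial infarction"),
    synonym = c("myocardial infarction", "cardiac event")))
  res_chain <- synonym_bridge(paste0(NS1, "heart_attack"),
                              paste0(NS2, "cardiac_event"),
                              o1, o3, lex_chain, lex_cfg, cfg)
  expect_equal(nrow(res_chain), 0)

  expect_warning(
    none <- synonym_bridge(paste0(NS1, "heart_attack"),
                           paste0(NS2, "myocardial_infarction"),
                           o1, o2, NULL, lex_cfg, cfg),
    "skipped")
  expect_equal(nrow(none), 0)
})

test_that("swapping the input order flips but preserves M_exact pairs", {
  set.seed(71)
  labels1 <- paste(random_words(12), random_words(12))
  labels2 <- c(labels1[1:8], paste(random_words(4), random_words(4)))
  os <- two_onto(labels1, labels2)
  ix <- exact_indexes(os$o1, os$o2)
  m_ab <- build_m_exact(two_way_search(os$o1, os$o2, ix$i1, ix$i2, lex_cfg,
                                       cfg = cfg), os$o1, os$o2, lex_cfg, cfg)
  m_ba <- build_m_exact(two_way_search(os$o2, os$o1, ix$i2, ix$i1, lex_cfg,
                                       cfg = cfg), os$o2, os$o1, lex_cfg, cfg)
  expect_setequal(paste(m_ab$e1, m_ab$e2), paste(m_ba$e2, m_ba$e1))
})

test_that("unique shared labels give an exact M_exact (P = R = 1)", {
  set.seed(83)
  shared <- unique(paste(random_words(20), random_words(20)))
  os <- two_onto(shared, shared)
  ix <- exact_indexes(os$o1, os$o2)
  m <- build_m_exact(two_way_search(os$o1, os$o2, ix$i1, ix$i2, lex_cfg,
                                    cfg = cfg), os$o1, os$o2, lex_cfg, cfg)
  ref <- data.frame(e1 = os$o1$concepts, e2 = os$o2$concepts)
  ev <- evaluate_alignment(m, ref)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
})
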