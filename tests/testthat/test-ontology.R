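cfg <- normalizer_config()

owl_fixture <- function() {
  # A subClassOf B; C standalone
  o <- ontology(
    concepts = paste0(NS1, c("A", "B", "C")),
    isa_edges = data.frame(parent = paste0(NS1, "B"), child = paste0(NS1, "A")),
    labels = data.frame(entity = paste0(NS1, c("A", "B", "C")),
                        text = c("heart", "body part", "cell"), lang = "en"),
    iri = NS1)
  path <- tempfile(fileext = ".owl")
  write_ontology_owl(o, path)
  path
}

test_that("OWL loading captures classes, edges and labels", {
  o <- load_ontology(owl_fixture())
  expect_length(o$concepts, 3)
  expect_equal(nrow(o$isa_edges), 1)
  expect_equal(o$isa_edges$parent, paste0(NS1, "B"))
  expect_equal(o$isa_edges$child, paste0(NS1, "A"))
  expect_error(load_ontology(tempfile()), "not found")
})

test_that("SKOS prefLabel/altLabel populate the label table with languages", {
  path <- tempfile(fileext = ".rdf")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:skos="http://www.w3.org/2004/02/skos/core#">',
    '  <skos:Concept rdf:about="http://test.org/a#Heart">',
    '    <skos:prefLabel xml:lang="en">heart</skos:prefLabel>',
    '    <skos:altLabel xml:lang="la">cor</skos:altLabel>',
    '  </skos:Concept>',
    '</rdf:RDF>'), path)
  o <- load_ontology(path)
  lab <- o$labels[o$labels$entity == paste0(NS1, "Heart"), ]
  expect_setequal(paste(lab$text, lab$lang), c("heart en", "cor la"))
})

test_that("OBO terms, synonyms, is_a and obsolescence load as checked against obonet", {
  path <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.4", "ontology: test", "",
    "[Term]", "id: TST:0000001", "name: foramen",
    'synonym: "opening" EXACT []', "",
    "[Term]", "id: TST:0000002", "name: vertebral foramen",
    "is_a: TST:0000001 ! foramen", "",
    "[Term]", "id: TST:0000003", "name: obsolete thing",
    "is_obsolete: true", "",
    "[Typedef]", "id: TST:9000001", "name: part of"), path)
  o <- load_ontology(path)
  # obonet on the same fixture: 2 live terms, edge 0000002 -is_a-> 0000001
  expect_length(o$concepts, 2)
  t1 <- "http://purl.obolibrary.org/obo/TST_0000001"
  expect_setequal(o$labels$text[o$labels$entity == t1], c("foramen", "opening"))
  expect_equal(o$isa_edges$parent, t1)
  expect_length(o$obj_properties, 1)
})

test_that("OWL and SKOS serializations of a fixture load equivalently", {
  labels <- c("root organ", "left lung", "right lung", "lung lobe")
  o <- make_taxonomy(labels, c(0, 1, 1, 2))
  p_owl <- tempfile(fileext = ".owl"); write_ontology_owl(o, p_owl)
  p_skos <- tempfile(fileext = ".rdf"); write_ontology_skos(o, p_skos)
  a <- load_ontology(p_owl); b <- load_ontology(p_skos)
  expect_equal(length(a$concepts), length(b$concepts))
  expect_setequal(a$concepts, b$concepts)
  expect_equal(sort(a$labels$text), sort(b$labels$text))
  expect_equal(a$isa_edges[order(a$isa_edges$child), ],
               b$isa_edges[order(b$isa_edges$child), ],
               ignore_attr = TRUE)
})

test_that("is-a cycles are broken by dropping the last-loaded back-edge", {
  expect_warning(
    o <- ontology(concepts = paste0(NS1, c("A", "B")),
                  isa_edges = data.frame(parent = paste0(NS1, c("A", "B")),
                                         child = paste0(NS1, c("B", "A")))),
    "cycle")
  expect_equal(nrow(o$isa_edges), 1)
  expect_equal(o$isa_edges$parent, paste0(NS1, "A"))
})

test_that("descendants / ancestors / siblings follow their definitions", {
  # root -> mid -> leaf; root -> other
  o <- make_taxonomy(c("root", "mid", "leaf", "other"), c(0, 1, 2, 1))
  iri <- function(x) paste0(NS1, x)
  expect_equal(descendants(o, iri("root")), sort(iri(c("mid", "other"))))
  expect_equal(descendants(o, iri("leaf")), character(0))
  expect_equal(ancestors(o, iri("leaf")), iri("mid"))
  expect_equal(ancestors(o, iri("root")), character(0))
  expect_equal(siblings(o, iri("mid")), iri("other"))
  expect_equal(siblings(o, iri("leaf")), character(0))
  expect_error(descendants(o, "nope"), "unknown concept")
  # depth-limited transitive variants
  expect_equal(names(desc_k(o, iri("root"), 2)),
               sort(iri(c("leaf", "mid", "other"))))
  expect_equal(unname(desc_k(o, iri("root"), 2)[iri("leaf")]), 2L)
  expect_equal(names(anc_k(o, iri("leaf"), 2)), sort(iri(c("mid", "root"))))
})

test_that("multi-parent concepts union their parents' child sets", {
  # c under p1 and p2; p1 children {c, x}; p2 children {c, y}
  iri <- function(x) paste0(NS1, x)
  o <- ontology(
    concepts = iri(c("r", "p1", "p2", "c", "x", "y")),
    isa_edges = data.frame(
      parent = iri(c("r", "r", "p1", "p2", "p1", "p2")),
      child = iri(c("p1", "p2", "c", "c", "x", "y"))))
  expect_setequal(ancestors(o, iri("c")), iri(c("p1", "p2")))
  expect_setequal(siblings(o, iri("c")), iri(c("x", "y")))
})

test_that("descendant/ancestor duality and sibling symmetry hold on random DAGs", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    labels <- paste("concept", seq_len(n))
    parent <- c(0, vapply(2:n, function(i) sample(i - 1, 1), integer(1)))
    o <- make_taxonomy(labels, parent)
    # add some extra multi-parent edges (still acyclic: parent index < child)
    extra <- data.frame(
      parent = o$concepts[vapply(1:8, function(i) sample(n - 1, 1), integer(1))],
      child = NA_character_)
    extra$child <- vapply(match(extra$parent, o$concepts), function(p)
      o$concepts[sample((p + 1):n, 1)], character(1))
    o <- ontology(concepts = o$concepts,
                  isa_edges = rbind(o$isa_edges, extra),
                  labels = o$labels, iri = o$iri)
    for (a in sample(o$concepts, 10)) {
      for (b in descendants(o, a))
        expect_true(a %in% ancestors(o, b))
      for (b in ancestors(o, a))
        expect_true(a %in% descendants(o, b))
      for (s in siblings(o, a))
        expect_true(a %in% siblings(o, s))
    }
  }
})

test_that("task profiling applies the 500-concept rule and language union", {
  o_small <- make_taxonomy(paste("c", 1:300), c(0, rep(1, 299)))
  o_mid <- make_taxonomy(paste("d", 1:400), c(0, rep(1, 399)), ns = NS2)
  expect_equal(profile_task(o_small, o_mid)$size_category, "small")
  o_big <- make_taxonomy(paste("e", 1:600), c(0, rep(1, 599)), ns = NS2)
  expect_equal(profile_task(o_small, o_big)$size_category, "large")
  o_fr <- ontology(concepts = paste0(NS2, "X"),
                   labels = data.frame(entity = paste0(NS2, "X"),
                                       text = "coeur", lang = "fr"))
  expect_setequal(profile_task(o_small, o_fr)$languages, c("en", "fr"))
})

test_that("virtual documents follow the fielded schema", {
  iri <- function(x) paste0(NS1, x)
  o <- ontology(
    concepts = iri(c("Thoracic_vertebral_foramen", "Bone")),
    isa_edges = data.frame(parent = iri("Bone"),
                           child = iri("Thoracic_vertebral_foramen")),
    labels = data.frame(
      entity = iri(c("Thoracic_vertebral_foramen", "Bone")),
      text = c("thoracic vertebral foramen", "bone"), lang = "en"),
    dat_properties = iri("Outdated_meaning"),
    prop_domain = stats::setNames(list(iri("Bone")), iri("Outdated_meaning")),
    prop_range = stats::setNames(
      list("http://www.w3.org/2001/XMLSchema#string"), iri("Outdated_meaning")),
    prop_constraints = stats::setNames(list("functional"), iri("Outdated_meaning")))

  vd <- build_virtual_document(o, iri("Thoracic_vertebral_foramen"),
                               cfg = cfg, mode = "exact")
  expect_equal(vd$kind, "concept")
  expect_equal(vd$fields$directNameC, "thoracicvertebralforamen")
  expect_setequal(vd$fields$directLabelCEN,
                  c("thoracvertebrforamen", "thoracforamenvertebr",
                    "vertebrthoracforamen", "vertebrforamenthorac",
                    "foramenthoracvertebr", "foramenvertebrthorac"))
  expect_false("supLabels" %in% names(vd$fields))

  dp <- build_virtual_document(o, iri("Outdated_meaning"), cfg = cfg)
  expect_equal(dp$kind, "datatype-property")
  expect_equal(dp$fields$directNameP, "outdatmean")
  expect_setequal(dp$fields$dRange, c("xsd", "string"))
  expect_equal(dp$fields$propertyType, "function")
  expect_equal(dp$fields$domainLabelsDP, "bone")

  evd <- build_virtual_document(o, iri("Thoracic_vertebral_foramen"),
                                extended = TRUE, cfg = cfg)
  expect_true("bone" %in% evd$fields$supLabels)
  expect_true("bone" %in% evd$fields$supLocalNames)
})

test_that("the extended document restricted to direct fields equals the direct one", {
  set.seed(8)
  labels <- paste(random_words(15), random_words(15))
  o <- make_taxonomy(labels, c(0, vapply(2:15, function(i) sample(i - 1, 1),
                                         integer(1))))
  for (e in o$concepts) {
    dvd <- build_virtual_document(o, e, extended = FALSE, cfg = cfg)
    evd <- build_virtual_document(o, e, extended = TRUE, cfg = cfg)
    expect_equal(evd$fields[names(dvd$fields)], dvd$fields)
    expect_true(all(setdiff(names(evd$fields), names(dvd$fields)) %in%
                      c("supLabels", "supLocalNames")))
  }
})

test_that("an unlabeled, unnamed entity yields a uri-only document with warning", {
  o <- ontology(concepts = "http://test.org/a#")
  expect_warning(vd <- build_virtual_document(o, "http://test.org/a#"),
                 "uri field only")
  expect_equal(names(vd$fields), "uri")
})
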