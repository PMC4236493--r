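# Synthetic ontology-pair generator. Emulates the label structure of
# UMLS-annotated biomedical ontologies: multi-word labels, word-order
# permutations between synonymous labels, synonym replacements backed by an
# emitted lexicon, opaque (code-like) labels, is-a hierarchies, object and
# datatype properties, and optional sibling disjointness. The second
# ontology is a perturbed copy of the first; the surviving copy pairs form
# the reference alignment.

GEN_NS1 <- "http://example.org/onto1#"
GEN_NS2 <- "http://example.org/onto2#"

# Pronounceable pseudo-word pool, deterministic in the RNG state.
make_word_pool <- function(n_words) {
  onsets <- c("b", "c", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r",
              "s", "t", "v", "z", "br", "cr", "dr", "gl", "pl", "st", "tr",
              "ch", "th", "ph", "sc", "sp")
  vowels <- c("a", "e", "i", "o", "u", "ae", "ia", "io", "ou")
  codas <- c("", "", "", "n", "r", "s", "l", "x", "m", "st", "nt")
  pool <- character(0)
  while (length(pool) < n_words) {
    k <- sample(2:3, 1L)
    w <- paste(vapply(seq_len(k), function(i)
      paste0(sample(onsets, 1L), sample(vowels, 1L),
             if (i == k) sample(codas, 1L) else ""), character(1)),
      collapse = "")
    if (nchar(w) >= 4L && !(w %in% pool)) pool <- c(pool, w)
  }
  pool
}

random_opaque_token <- function() {
  paste(sample(letters, sample(8:12, 1L), replace = TRUE), collapse = "")
}

#' Specify a synthetic ontology pair
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param n_concepts number of concepts in the first ontology (>= 2).
#' @param branching maximum children per concept while growing the is-a tree.
#' @param n_pool size of the pseudo-word pool labels are drawn from.
#' @param p_permute,p_synonym,p_opaque per-concept probabilities that the
#'   copied label is word-permuted, replaced through the emitted synonym
#'   lexicon, or replaced by an opaque code-like token; their sum must be
#'   at most 1 (the remainder keeps the label unchanged).
#' @param p_unmatched fraction of concepts deleted from the second ontology.
#' @param n_properties total number of properties (split between object and
#'   datatype).
#' @param p_disjoint_siblings probability that a parent with at least two
#'   children declares its children pairwise disjoint.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n_concepts = 300L, branching = 3L,
                           n_pool = 900L, p_permute = 0.15, p_synonym = 0.1,
                           p_opaque = 0.1, p_unmatched = 0.1,
                           n_properties = 10L, p_disjoint_siblings = 0.05) {
  stopifnot(n_concepts >= 2L, branching >= 1L,
            p_permute >= 0, p_synonym >= 0, p_opaque >= 0, p_unmatched >= 0,
            p_permute + p_synonym + p_opaque <= 1, p_unmatched <= 1)
  structure(list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
                 branching = as.integer(branching), n_pool = as.integer(n_pool),
                 p_permute = p_permute, p_synonym = p_synonym,
                 p_opaque = p_opaque, p_unmatched = p_unmatched,
                 n_properties = as.integer(n_properties),
                 p_disjoint_siblings = p_disjoint_siblings),
            class = "generator_spec")
}

title_case <- function(words) {
  paste(vapply(words, function(w)
    paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w))), character(1)),
    collapse = "_")
}

#' Generate a synthetic ontology pair with reference alignment
#'
#' Builds a random is-a tree with multi-word labels; the second ontology is
#' a namespace-shifted copy whose labels are perturbed per
#' [generator_spec()] and from which a fraction of concepts is deleted
#' (children are re-attached to the nearest surviving ancestor). Properties
#' are copied unchanged. The emitted synonym lexicon links every
#' synonym-replaced label to its original, in normalized form.
#'
#' @param spec a [generator_spec()].
#' @return list with elements `o1`, `o2` ([ontology()] objects), `reference`
#'   (data.frame `e1`, `e2` over surviving entities), `lexicon` (data.frame
#'   `term`, `synonym`) and `spec`.
#' @export
generate_pair <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, generate_pair_impl(spec))
}

generate_pair_impl <- function(spec) {
  n <- spec$n_concepts
  pool <- make_word_pool(spec$n_pool)
  cfg <- normalizer_config()

  # labels: unique 2-3 word combinations
  labels1 <- character(n)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    repeat {
      words <- sample(pool, sample(2:3, 1L))
      lab <- paste(words, collapse = " ")
      if (!exists(lab, envir = seen, inherits = FALSE)) {
        assign(lab, TRUE, envir = seen)
        labels1[i] <- lab
        break
      }
    }
  }
  iri1 <- paste0(GEN_NS1, vapply(strsplit(labels1, " ", fixed = TRUE),
                                 title_case, character(1)))

  # random is-a tree capped at `branching` children per node
  parent_idx <- integer(n)           # 0 = root
  child_count <- integer(n)
  for (i in 2:n) {
    open <- which(child_count[seq_len(i - 1L)] < spec$branching)
    if (length(open) == 0L) open <- seq_len(i - 1L)
    p <- if (length(open) == 1L) open else sample(open, 1L)
    parent_idx[i] <- p
    child_count[p] <- child_count[p] + 1L
  }
  isa1 <- data.frame(parent = iri1[parent_idx[-1L]], child = iri1[-1L],
                     stringsAsFactors = FALSE)

  # sibling disjointness
  disjoint <- data.frame(a = character(0), b = character(0),
                         stringsAsFactors = FALSE)
  for (p in which(child_count >= 2L)) {
    if (stats::runif(1) < spec$p_disjoint_siblings) {
      kids <- iri1[which(parent_idx == p)]
      pairs <- utils::combn(sort(kids), 2L)
      disjoint <- rbind(disjoint, data.frame(a = pairs[1, ], b = pairs[2, ],
                                             stringsAsFactors = FALSE))
    }
  }

  # properties: half object, half datatype
  n_obj <- spec$n_properties %/% 2L
  n_dat <- spec$n_properties - n_obj
  prop_label <- function() paste("has", paste(sample(pool, 2L), collapse = " "))
  mk_props <- function(count, prefix) {
    labs <- character(count)
    for (i in seq_len(count)) {
      repeat {
        l <- prop_label()
        if (!(l %in% labs)) { labs[i] <- l; break }
      }
    }
    labs
  }
  obj_labels <- mk_props(n_obj)
  dat_labels <- mk_props(n_dat)
  obj_iri1 <- paste0(GEN_NS1, vapply(strsplit(obj_labels, " ", fixed = TRUE),
                                     title_case, character(1)))
  dat_iri1 <- paste0(GEN_NS1, vapply(strsplit(dat_labels, " ", fixed = TRUE),
                                     title_case, character(1)))
  prop_domain <- list(); prop_range <- list(); prop_constraints <- list()
  for (i in seq_along(obj_iri1)) {
    prop_domain[[obj_iri1[i]]] <- iri1[sample(n, 1L)]
    prop_range[[obj_iri1[i]]] <- iri1[sample(n, 1L)]
  }
  for (i in seq_along(dat_iri1)) {
    prop_domain[[dat_iri1[i]]] <- iri1[sample(n, 1L)]
    prop_range[[dat_iri1[i]]] <- paste0(XSD_NS, sample(c("string", "integer"), 1L))
    if (stats::runif(1) < 0.5) prop_constraints[[dat_iri1[i]]] <- "functional"
  }

  labels_df <- function(iris, labs, lang = "en")
    data.frame(entity = iris, text = labs, lang = lang, stringsAsFactors = FALSE)

  o1 <- ontology(
    concepts = iri1,
    isa_edges = isa1,
    obj_properties = obj_iri1,
    dat_properties = dat_iri1,
    labels = rbind(labels_df(iri1, labels1),
                   labels_df(obj_iri1, obj_labels, lang = ""),
                   labels_df(dat_iri1, dat_labels, lang = "")),
    prop_domain = prop_domain, prop_range = prop_range,
    prop_constraints = prop_constraints,
    disjointness = disjoint,
    iri = GEN_NS1)

  # ---- perturbed copy -------------------------------------------------------
  labels2 <- labels1
  lexicon <- data.frame(term = character(0), synonym = character(0),
                        stringsAsFactors = FALSE)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    words <- strsplit(labels1[i], " ", fixed = TRUE)[[1]]
    if (u[i] < spec$p_permute) {
      if (length(words) >= 2L) {
        repeat {
          perm <- sample(words)
          if (!identical(perm, words)) break
        }
        labels2[i] <- paste(perm, collapse = " ")
      }
    } else if (u[i] < spec$p_permute + spec$p_synonym) {
      repeat {
        syn_words <- sample(pool, sample(2:3, 1L))
        syn <- paste(syn_words, collapse = " ")
        if (!exists(syn, envir = seen, inherits = FALSE)) {
          assign(syn, TRUE, envir = seen)
          break
        }
      }
      labels2[i] <- syn
      lexicon <- rbind(lexicon, data.frame(
        term = paste(normalize_label(labels1[i], cfg, stem = FALSE), collapse = " "),
        synonym = paste(normalize_label(syn, cfg, stem = FALSE), collapse = " "),
        stringsAsFactors = FALSE))
    } else if (u[i] < spec$p_permute + spec$p_synonym + spec$p_opaque) {
      labels2[i] <- random_opaque_token()
    }
  }
  iri2 <- paste0(GEN_NS2, vapply(strsplit(labels2, " ", fixed = TRUE),
                                 title_case, character(1)))
  # opaque relabelling may collide with itself across concepts; uniquify
  dup <- duplicated(iri2)
  while (any(dup)) {
    for (i in which(dup)) {
      labels2[i] <- random_opaque_token()
      iri2[i] <- paste0(GEN_NS2, title_case(labels2[i]))
    }
    dup <- duplicated(iri2)
  }

  # deletion: children re-attach to the nearest surviving ancestor
  deleted <- rep(FALSE, n)
  if (spec$p_unmatched > 0 && n > 1L) {
    n_del <- round(spec$p_unmatched * n)
    # never delete the root so re-attachment always finds an ancestor
    if (n_del > 0L)
      deleted[sample(2:n, min(n_del, n - 1L))] <- TRUE
  }
  surviving <- which(!deleted)
  eff_parent <- function(i) {
    p <- parent_idx[i]
    while (p != 0L && deleted[p]) p <- parent_idx[p]
    p
  }
  isa2 <- list()
  for (i in surviving) {
    p <- eff_parent(i)
    if (p != 0L)
      isa2[[length(isa2) + 1L]] <- data.frame(parent = iri2[p], child = iri2[i],
                                              stringsAsFactors = FALSE)
  }
  isa2 <- if (length(isa2) > 0L) do.call(rbind, isa2) else
    data.frame(parent = character(0), child = character(0))

  obj_iri2 <- sub(GEN_NS1, GEN_NS2, obj_iri1, fixed = TRUE)
  dat_iri2 <- sub(GEN_NS1, GEN_NS2, dat_iri1, fixed = TRUE)
  remap_concept <- function(x) {
    i <- match(x, iri1)
    out <- iri2[i]
    out[deleted[i]] <- NA_character_
    out
  }
  prop_domain2 <- list(); prop_range2 <- list(); prop_constraints2 <- list()
  for (i in seq_along(obj_iri1)) {
    d <- remap_concept(prop_domain[[obj_iri1[i]]])
    r <- remap_concept(prop_range[[obj_iri1[i]]])
    if (!is.na(d)) prop_domain2[[obj_iri2[i]]] <- d
    if (!is.na(r)) prop_range2[[obj_iri2[i]]] <- r
  }
  for (i in seq_along(dat_iri1)) {
    d <- remap_concept(prop_domain[[dat_iri1[i]]])
    if (!is.na(d)) prop_domain2[[dat_iri2[i]]] <- d
    prop_range2[[dat_iri2[i]]] <- prop_range[[dat_iri1[i]]]
    if (!is.null(prop_constraints[[dat_iri1[i]]]))
      prop_constraints2[[dat_iri2[i]]] <- prop_constraints[[dat_iri1[i]]]
  }

  dis2 <- disjoint
  if (nrow(dis2) > 0L) {
    dis2$a <- remap_concept(dis2$a)
    dis2$b <- remap_concept(dis2$b)
    dis2 <- dis2[!is.na(dis2$a) & !is.na(dis2$b), , drop = FALSE]
  }

  o2 <- ontology(
    concepts = iri2[surviving],
    isa_edges = isa2,
    obj_properties = obj_iri2,
    dat_properties = dat_iri2,
    labels = rbind(labels_df(iri2[surviving], labels2[surviving]),
                   labels_df(obj_iri2, obj_labels, lang = ""),
                   labels_df(dat_iri2, dat_labels, lang = "")),
    prop_domain = prop_domain2, prop_range = prop_range2,
    prop_constraints = prop_constraints2,
    disjointness = dis2,
    iri = GEN_NS2)

  reference <- data.frame(
    e1 = c(iri1[surviving], obj_iri1, dat_iri1),
    e2 = c(iri2[surviving], obj_iri2, dat_iri2),
    stringsAsFactors = FALSE)
  reference <- reference[order(reference$e1), , drop = FALSE]
  rownames(reference) <- NULL

  list(o1 = o1, o2 = o2, reference = reference, lexicon = lexicon, spec = spec)
}

#' Write a generated pair to disk
#'
#' Emits `onto1.owl`, `onto2.owl`, `reference.rdf` (OAEI Alignment format)
#' and `lexicon.tsv` into `dir`.
#'
#' @param pair a [generate_pair()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_generated_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ontology_owl(pair$o1, file.path(dir, "onto1.owl"))
  write_ontology_owl(pair$o2, file.path(dir, "onto2.owl"))
  ref <- pair$reference
  ref$score <- 1
  write_alignment(ref, file.path(dir, "reference.rdf"),
                  onto1 = pair$o1$iri, onto2 = pair$o2$iri)
  utils::write.table(pair$lexicon, file.path(dir, "lexicon.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
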