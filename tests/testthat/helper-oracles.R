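# Independent brute-force oracles and fixture builders shared by the tests.
# Oracles deliberately use different code paths from the package
# implementations they check.

# -- Levenshtein distance by plain dynamic programming (not utils::adist) ----
oracle_lev_dist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  d <- matrix(0L, na + 1L, nb + 1L)
  d[, 1] <- 0:na; d[1, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    cost <- if (ca[i] == cb[j]) 0L else 1L
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
  }
  d[na + 1L, nb + 1L]
}

oracle_lev_sim <- function(a, b) {
  if (nchar(a) == 0 && nchar(b) == 0) return(1)
  1 - oracle_lev_dist(a, b) / max(nchar(a), nchar(b))
}

# -- q-gram Dice by direct enumeration ---------------------------------------
oracle_qgrams <- function(s, q, pad) {
  if (pad && q > 1) s <- paste0(strrep("#", q - 1), s, strrep("#", q - 1))
  n <- nchar(s)
  if (n < q) return(character(0))
  vapply(1:(n - q + 1), function(i) substr(s, i, i + q - 1), character(1))
}

oracle_qgram_sim <- function(a, b, q = 3, pad = TRUE) {
  ga <- oracle_qgrams(a, q, pad); gb <- oracle_qgrams(b, q, pad)
  if (length(ga) == 0 && length(gb) == 0) return(1)
  if (length(ga) == 0 || length(gb) == 0) return(0)
  common <- 0
  gb_left <- gb
  for (g in ga) {
    hit <- match(g, gb_left)
    if (!is.na(hit)) { common <- common + 1; gb_left <- gb_left[-hit] }
  }
  2 * common / (length(ga) + length(gb))
}

# -- word-set / token-vector oracles -----------------------------------------
oracle_tokens <- function(s) {
  t <- strsplit(tolower(gsub("[^A-Za-z0-9]+", " ", s)), " +")[[1]]
  t[nzchar(t)]
}

oracle_jaccard <- function(a, b) {
  ta <- unique(oracle_tokens(a)); tb <- unique(oracle_tokens(b))
  if (length(ta) == 0 && length(tb) == 0) return(1)
  if (length(union(ta, tb)) == 0) return(1)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

oracle_monge_elkan <- function(a, b) {
  ta <- oracle_tokens(a); tb <- oracle_tokens(b)
  if (length(ta) == 0 && length(tb) == 0) return(1)
  if (length(ta) == 0 || length(tb) == 0) return(0)
  dir_me <- function(x, y) mean(vapply(x, function(xi)
    max(vapply(y, function(yi) oracle_lev_sim(xi, yi), numeric(1))), numeric(1)))
  (dir_me(ta, tb) + dir_me(tb, ta)) / 2
}

oracle_block_distance <- function(a, b) {
  ta <- oracle_tokens(a); tb <- oracle_tokens(b)
  if (length(ta) == 0 && length(tb) == 0) return(1)
  if (length(ta) == 0 || length(tb) == 0) return(0)
  vocab <- unique(c(ta, tb))
  va <- vapply(vocab, function(v) sum(ta == v), numeric(1))
  vb <- vapply(vocab, function(v) sum(tb == v), numeric(1))
  1 - sum(abs(va - vb)) / (length(ta) + length(tb))
}

# -- ISub: independent transcription of the published measure ----------------
# (commonality via repeated longest-common-substring removal, difference via
# the Hamacher parameterized triangular norm with p = 0.6, Winkler prefix
# bonus), rescaled to [0, 1].
oracle_isub <- function(s1, s2) {
  a <- tolower(s1); b <- tolower(s2)
  if (a == b) return(1)
  if (a > b) { tmp <- a; a <- b; b <- tmp }   # canonical order, as pinned
  la <- nchar(a); lb <- nchar(b)
  if (la == 0 || lb == 0) return(0)   # rescaled native -1
  longest_common <- function(x, y) {
    best <- c(0L, 0L, 0L)
    for (i in seq_len(nchar(x))) {
      for (j in seq_len(nchar(y))) {
        k <- 0L
        while (i + k <= nchar(x) && j + k <= nchar(y) &&
               substr(x, i + k, i + k) == substr(y, j + k, j + k)) k <- k + 1L
        if (k > best[3]) best <- c(i, j, k)
      }
    }
    best
  }
  total <- 0L
  x <- a; y <- b
  repeat {
    m <- longest_common(x, y)
    if (m[3] < 2L) break
    total <- total + m[3]
    x <- paste0(substr(x, 1, m[1] - 1), substr(x, m[1] + m[3], nchar(x)))
    y <- paste0(substr(y, 1, m[2] - 1), substr(y, m[2] + m[3], nchar(y)))
  }
  comm <- 2 * total / (la + lb)
  u1 <- nchar(x) / la; u2 <- nchar(y) / lb
  p <- 0.6
  den <- p + (1 - p) * (u1 + u2 - u1 * u2)
  diff <- if (den == 0) 0 else u1 * u2 / den
  pref <- 0L
  while (pref < min(4L, la, lb) &&
         substr(a, pref + 1, pref + 1) == substr(b, pref + 1, pref + 1))
    pref <- pref + 1L
  ((comm - diff + pref * 0.1 * (1 - comm)) + 1) / 2
}

# -- dense tf-idf scorer: linear-algebra route over the full term space ------
# Recomputes the fielded Lucene-style score for every document of an index
# from dense matrices, independently of the postings accumulation.
oracle_dense_scores <- function(idx, query_vd) {
  qterms <- list()
  for (f in names(query_vd$fields))
    for (t in unique(query_vd$fields[[f]]))
      qterms[[length(qterms) + 1L]] <- c(f = f, t = t)
  if (length(qterms) == 0) return(numeric(0))
  docs <- idx$docs
  ents <- names(docs)
  N <- idx$doc_count
  # entity frequency of each query (field, term)
  ef <- vapply(qterms, function(qt) {
    sum(vapply(ents, function(e) {
      terms <- docs[[e]]$fields[[qt[["f"]]]]
      !is.null(terms) && qt[["t"]] %in% terms
    }, logical(1)))
  }, numeric(1))
  idf <- 1 + log(N / (1 + ef))
  qnorm <- 1 / sqrt(sum(idf^2))
  boosts <- idx$boosts
  scores <- vapply(ents, function(e) {
    contrib <- 0; matched <- 0L
    for (k in seq_along(qterms)) {
      f <- qterms[[k]][["f"]]; t <- qterms[[k]][["t"]]
      terms <- docs[[e]]$fields[[f]]
      if (is.null(terms)) next
      tf <- sum(terms == t)
      if (tf == 0) next
      matched <- matched + 1L
      b <- if (f %in% names(boosts)) boosts[[f]] else 1
      contrib <- contrib + sqrt(tf) * idf[k]^2 * b / sqrt(length(terms))
    }
    if (matched == 0L) return(0)
    (matched / length(qterms)) * qnorm * contrib
  }, numeric(1))
  scores[scores > 0]
}

# -- fixture builders --------------------------------------------------------
NS1 <- "http://test.org/a#"
NS2 <- "http://test.org/b#"

# quick concept-only ontology from label vector + parent index vector (0=root)
make_taxonomy <- function(labels, parent, ns = NS1, extra = list()) {
  iri <- paste0(ns, gsub(" ", "_", labels))
  isa <- data.frame(parent = iri[parent[parent != 0]],
                    child = iri[which(parent != 0)],
                    stringsAsFactors = FALSE)
  args <- c(list(
    concepts = iri,
    isa_edges = isa,
    labels = data.frame(entity = iri, text = labels, lang = "en",
                        stringsAsFactors = FALSE),
    iri = ns), extra)
  do.call(ontology, args)
}

random_words <- function(n, len = 3:8) {
  vapply(seq_len(n), function(i)
    paste(sample(letters, sample(len, 1), replace = TRUE), collapse = ""),
    character(1))
}

random_string <- function(maxlen = 15, alphabet = c(letters[1:8], " ")) {
  n <- sample(0:maxlen, 1)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
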