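# String similarity ensemble used for candidate scoring and the contextual
# feature vectors. All metrics are symmetric-on-identity and lie in [0, 1].

#' Levenshtein similarity
#'
#' `1 - dist(a, b) / max(nchar(a), nchar(b))`, where `dist` is the classic
#' single-character edit distance; two empty strings are identical (1).
#'
#' @param a,b strings.
#' @return similarity in `[0, 1]`.
#' @export
levenshtein_sim <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L && nb == 0L) return(1)
  d <- utils::adist(a, b)[1, 1]
  1 - d / max(na, nb)
}

# q-grams of a string with boundary padding (q-1 '#' on each side when
# padded); returns a character vector (multiset).
qgrams_of <- function(s, q = 3L, pad = TRUE) {
  if (pad && q > 1L) {
    padding <- strrep("#", q - 1L)
    s <- paste0(padding, s, padding)
  }
  n <- nchar(s)
  if (n < q) return(character(0))
  substring(s, seq_len(n - q + 1L), seq_len(n - q + 1L) + q - 1L)
}

#' Q-gram similarity (Dice coefficient over padded q-gram multisets)
#'
#' @param a,b strings.
#' @param q gram size (default 3).
#' @param pad pad the string boundaries with `q - 1` marker characters.
#' @return `2 * |common grams| / (|grams(a)| + |grams(b)|)` in `[0, 1]`.
#' @export
qgram_sim <- function(a, b, q = 3L, pad = TRUE) {
  ga <- qgrams_of(a, q, pad)
  gb <- qgrams_of(b, q, pad)
  if (length(ga) == 0L && length(gb) == 0L) return(1)
  if (length(ga) == 0L || length(gb) == 0L) return(0)
  ta <- table(ga); tb <- table(gb)
  shared <- intersect(names(ta), names(tb))
  common <- sum(pmin(ta[shared], tb[shared]))
  2 * common / (length(ga) + length(gb))
}

# Longest common substring of two character strings; returns list(start1,
# start2, len). Dynamic programming over the suffix table.
lcs_substring <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(ca); nb <- length(cb)
  best_len <- 0L; best_i <- 0L; best_j <- 0L
  if (na == 0L || nb == 0L)
    return(list(start1 = 0L, start2 = 0L, len = 0L))
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    match_j <- which(cb == ca[i])
    for (j in match_j) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best_len) {
        best_len <- cur[j]; best_i <- i - cur[j] + 1L; best_j <- j - cur[j] + 1L
      }
    }
    prev <- cur
  }
  list(start1 = best_i, start2 = best_j, len = best_len)
}

# ISub (Stoilos, Stamou & Kollias 2005): similarity tuned for ontology
# entity names. Native range [-1, 1]: commonality - difference + Winkler
# improvement. Commonality iteratively strips longest common substrings;
# difference follows the Hamacher product with p = 0.6.
isub_native <- function(a, b) {
  a <- tolower(a); b <- tolower(b)
  if (a == b) return(1)   # identity is maximal regardless of length
  # the greedy substring removal is order-dependent on ties; canonical
  # argument order makes the measure symmetric
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L || lb == 0L) return(-1)

  common <- 0L
  s1 <- a; s2 <- b
  repeat {
    m <- lcs_substring(s1, s2)
    if (m$len < 2L) break   # substrings of length 1 carry no commonality
    common <- common + m$len
    s1 <- paste0(substr(s1, 1L, m$start1 - 1L),
                 substr(s1, m$start1 + m$len, nchar(s1)))
    s2 <- paste0(substr(s2, 1L, m$start2 - 1L),
                 substr(s2, m$start2 + m$len, nchar(s2)))
  }
  comm <- 2 * common / (la + lb)

  u1 <- nchar(s1) / la      # unmatched fraction of a
  u2 <- nchar(s2) / lb
  p <- 0.6
  denom <- p + (1 - p) * (u1 + u2 - u1 * u2)
  diff <- if (denom == 0) 0 else (u1 * u2) / denom

  # Winkler prefix improvement on the original strings
  maxpref <- min(4L, la, lb)
  L <- 0L
  while (L < maxpref &&
         substr(a, L + 1L, L + 1L) == substr(b, L + 1L, L + 1L)) L <- L + 1L
  winkler <- L * 0.1 * (1 - comm)

  comm - diff + winkler
}

#' ISub string similarity
#'
#' The entity-name similarity of Stoilos et al., rescaled from its native
#' `[-1, 1]` range to `[0, 1]` by `(x + 1) / 2`.
#'
#' @param a,b strings.
#' @return similarity in `[0, 1]`.
#' @export
isub_sim <- function(a, b) {
  (isub_native(a, b) + 1) / 2
}

simple_word_tokens <- function(s) {
  toks <- strsplit(trimws(tolower(gsub("[^a-z0-9]+", " ", tolower(s)))), " +")[[1]]
  toks[nzchar(toks)]
}

#' Word-level Jaccard similarity
#'
#' Number of distinct words two strings share divided by the total number of
#' distinct words; two empty strings give 1.
#'
#' @param a,b strings.
#' @return similarity in `[0, 1]`.
#' @export
jaccard_words <- function(a, b) {
  ta <- unique(simple_word_tokens(a))
  tb <- unique(simple_word_tokens(b))
  if (length(ta) == 0L && length(tb) == 0L) return(1)
  u <- length(union(ta, tb))
  if (u == 0L) return(1)
  length(intersect(ta, tb)) / u
}

#' Monge-Elkan similarity (two-way)
#'
#' The directional Monge-Elkan score is the mean over the tokens of `a` of
#' the best inner similarity against the tokens of `b` (inner similarity:
#' [levenshtein_sim()]); the returned value is the mean of the two
#' directions, making the measure symmetric.
#'
#' @param a,b strings.
#' @return similarity in `[0, 1]`.
#' @export
monge_elkan <- function(a, b) {
  ta <- simple_word_tokens(a)
  tb <- simple_word_tokens(b)
  if (length(ta) == 0L && length(tb) == 0L) return(1)
  if (length(ta) == 0L || length(tb) == 0L) return(0)
  d <- utils::adist(ta, tb)
  ml <- outer(nchar(ta), nchar(tb), pmax)
  sims <- 1 - d / ml
  (mean(apply(sims, 1L, max)) + mean(apply(sims, 2L, max))) / 2
}

#' Block (L1) distance similarity over token-count vectors
#'
#' Token-count vectors are built over the union vocabulary of both strings;
#' similarity is `1 - L1 / (total tokens of a + total tokens of b)`.
#'
#' @param a,b strings.
#' @return similarity in `[0, 1]`.
#' @export
block_distance_sim <- function(a, b) {
  ta <- simple_word_tokens(a)
  tb <- simple_word_tokens(b)
  if (length(ta) == 0L && length(tb) == 0L) return(1)
  if (length(ta) == 0L || length(tb) == 0L) return(0)
  vocab <- union(ta, tb)
  va <- tabulate(match(ta, vocab), nbins = length(vocab))
  vb <- tabulate(match(tb, vocab), nbins = length(vocab))
  l1 <- sum(abs(va - vb))
  1 - l1 / (length(ta) + length(tb))
}

#' Lexical similarity weights
#'
#' Weights for the ISub, q-gram and Levenshtein components of
#' [lexical_similarity()]; they must sum to 1.
#'
#' @param alpha,beta,gamma component weights in `[0, 1]`.
#' @return an object of class `lex_weights`.
#' @export
lex_weights <- function(alpha = 0.4, beta = 0.3, gamma = 0.3) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0,
            abs(alpha + beta + gamma - 1) < 1e-9)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "lex_weights")
}

#' Weighted lexical similarity between two entities' label sets
#'
#' `Sim_lex = alpha * ISub + beta * QGram + gamma * Levenshtein`, each
#' component evaluated as the maximum over all cross pairs of the two label
#' sets (normalized label strings).
#'
#' @param labels1,labels2 character vectors of (normalized) label strings.
#' @param w a [lex_weights()] object.
#' @return `Sim_lex` in `[0, 1]`; 0 (with a warning) if either set is empty.
#' @export
lexical_similarity <- function(labels1, labels2, w = lex_weights()) {
  labels1 <- unique(labels1[nzchar(labels1)])
  labels2 <- unique(labels2[nzchar(labels2)])
  if (length(labels1) == 0L || length(labels2) == 0L) {
    warning("empty label set; Sim_lex = 0")
    return(0)
  }
  # identical cross pair short-circuits every component at its maximum
  if (length(intersect(labels1, labels2)) > 0L) return(1)
  best_isub <- 0; best_qgram <- 0; best_lev <- 0
  for (x in labels1) {
    for (y in labels2) {
      best_isub <- max(best_isub, isub_sim(x, y))
      best_qgram <- max(best_qgram, qgram_sim(x, y))
      best_lev <- max(best_lev, levenshtein_sim(x, y))
    }
  }
  w$alpha * best_isub + w$beta * best_qgram + w$gamma * best_lev
}
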