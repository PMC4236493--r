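# Label normalization: the filter chain applied to every label both at
# indexing time and at query time, plus permutation enrichment and the
# exact-mode concatenation.

ONES <- c("zero", "one", "two", "three", "four", "five", "six", "seven",
          "eight", "nine", "ten", "eleven", "twelve", "thirteen", "fourteen",
          "fifteen", "sixteen", "seventeen", "eighteen", "nineteen")
TENS <- c("twenty", "thirty", "forty", "fifty", "sixty", "seventy",
          "eighty", "ninety")

# Spell out an integer 0..999 as English word tokens ("21" -> twenty, one).
number_words <- function(n) {
  n <- as.integer(n)
  if (n < 0L || n > 999L) return(as.character(n))
  out <- character(0)
  if (n >= 100L) {
    out <- c(out, ONES[n %/% 100L + 1L], "hundred")
    n <- n %% 100L
    if (n == 0L) return(out)
  }
  if (n < 20L) return(c(out, ONES[n + 1L]))
  out <- c(out, TENS[n %/% 10L - 1L])
  if (n %% 10L > 0L) out <- c(out, ONES[n %% 10L + 1L])
  out
}

default_stopwords <- function(language = "en") {
  path <- system.file("extdata", "stopwords", paste0(language, ".txt"),
                      package = "ontomatch")
  if (!nzchar(path) || !file.exists(path)) return(character(0))
  readLines(path, warn = FALSE)
}

#' Create a normalizer configuration
#'
#' Bundles the language, stopword list, stemming and number-conversion flags
#' and the permutation window used by [normalize_label()] and the indexer.
#'
#' @param language language tag; only `"en"` ships a stopword list and the
#'   Porter stemmer, other languages fall back to no stopwords / no stemming.
#' @param stopwords character vector; defaults to the bundled list for
#'   `language`.
#' @param stem stem tokens after all other filters?
#' @param number_to_words spell standalone integer tokens 0-999 as words
#'   (`"9"` becomes `"nine"`), so that e.g. "T9 Vertebra" and
#'   "Ninth thoracic vertebra" share stemmable material.
#' @param max_permuted_words permutation window: orderings are generated for
#'   the first `max_permuted_words` tokens of a label (default 4).
#' @return an object of class `normalizer_config`.
#' @export
normalizer_config <- function(language = "en",
                              stopwords = default_stopwords(language),
                              stem = TRUE,
                              number_to_words = TRUE,
                              max_permuted_words = 4L) {
  stopifnot(max_permuted_words >= 1L)
  structure(list(language = language,
                 stopwords = stopwords,
                 stem = isTRUE(stem),
                 number_to_words = isTRUE(number_to_words),
                 max_permuted_words = as.integer(max_permuted_words)),
            class = "normalizer_config")
}

# Split camelCase and underscores, keep alphanumerics only.
split_label_words <- function(label) {
  s <- gsub("([a-z])([A-Z])", "\\1 \\2", label)
  s <- gsub("([A-Za-z])([0-9])", "\\1 \\2", s)
  s <- gsub("([0-9])([A-Za-z])", "\\1 \\2", s)
  s <- tolower(s)
  s <- gsub("[^a-z0-9]+", " ", s)
  strsplit(trimws(s), " +")[[1]]
}

#' Normalize a label to a token list
#'
#' Ordered pipeline: split camelCase/underscores, lowercase, replace
#' non-alphanumeric runs with spaces, tokenize, remove stopwords, spell out
#' digit tokens, stem. The result may be empty (an all-stopword label).
#'
#' @param label a single string.
#' @param cfg a [normalizer_config()].
#' @param stem override the config's stemming flag (used for pre-stem forms).
#' @return character vector of normalized tokens.
#' @examples
#' cfg <- normalizer_config()
#' normalize_label("Thoracic_vertebral_foramen", cfg)
#' @export
normalize_label <- function(label, cfg = normalizer_config(), stem = cfg$stem) {
  stopifnot(is.character(label), length(label) == 1L)
  toks <- split_label_words(label)
  if (length(toks) == 0L) return(character(0))
  toks <- toks[!(toks %in% cfg$stopwords)]
  if (length(toks) == 0L) return(character(0))
  if (cfg$number_to_words) {
    is_num <- grepl("^[0-9]+$", toks)
    if (any(is_num)) {
      toks <- unlist(lapply(seq_along(toks), function(i) {
        if (is_num[i]) number_words(toks[i]) else toks[i]
      }), use.names = FALSE)
    }
  }
  if (stem && cfg$language == "en") {
    toks <- porter_stem(toks)
    # a stem may itself be a stopword ("nos" -> "no"); re-filter so the
    # pipeline is idempotent on its own output
    toks <- toks[!(toks %in% cfg$stopwords)]
  }
  toks
}

#' All orderings of the leading tokens of a label
#'
#' Generates every ordering of the first `min(length(tokens), max_words)`
#' tokens, each followed by the remaining tokens in their original order.
#' The original ordering is always included; the result has
#' `factorial(min(length(tokens), max_words))` elements.
#'
#' @param tokens non-empty character vector.
#' @param max_words permutation window (default 4).
#' @return list of character vectors.
#' @export
permute_tokens <- function(tokens, max_words = 4L) {
  stopifnot(length(tokens) >= 1L)
  head_n <- min(length(tokens), max_words)
  tail_toks <- if (head_n < length(tokens)) tokens[(head_n + 1L):length(tokens)] else character(0)
  perms <- permutations_of(head_n)
  lapply(perms, function(p) c(tokens[p], tail_toks))
}

# All permutations of 1..n as a list of index vectors, deterministic order.
permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

#' Concatenate tokens into a single exact-form term
#'
#' @param tokens character vector.
#' @return a single string: tokens joined with no separator; empty input
#'   yields the empty string.
#' @examples
#' concatenate_tokens(c("thoracic", "vertebral", "foramen"))
#' @export
concatenate_tokens <- function(tokens) {
  paste(tokens, collapse = "")
}

# Exact-mode vocabulary of one label: the set of concatenated permuted forms.
# Permutation is applied before stemming (and after stopword/symbol removal),
# so the forms are permutations of the *unstemmed* tokens, stemmed afterwards
# when stemming is on.
exact_forms <- function(label, cfg = normalizer_config()) {
  toks <- normalize_label(label, cfg, stem = FALSE)
  if (length(toks) == 0L) return(character(0))
  perms <- permute_tokens(toks, cfg$max_permuted_words)
  forms <- vapply(perms, function(p) {
    if (cfg$stem && cfg$language == "en") p <- porter_stem(p)
    concatenate_tokens(p)
  }, character(1))
  sort(unique(forms))
}

# Pre-stem normalized label strings including permuted variants; these are the
# strings Sim_lex is evaluated on.
label_variants <- function(label, cfg = normalizer_config()) {
  toks <- normalize_label(label, cfg, stem = FALSE)
  if (length(toks) == 0L) return(character(0))
  perms <- permute_tokens(toks, cfg$max_permuted_words)
  sort(unique(vapply(perms, paste, character(1), collapse = " ")))
}
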