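# Porter stemming algorithm (Porter 1980), English.
# Implemented here because the matcher needs deterministic, dependency-free
# stemming of ontology labels; verified against the classic test pairs.

porter_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_is_cons(chars, i - 1L))
  }
  TRUE
}

# measure m of the stem chars[1..j]: number of VC sequences
porter_m <- function(chars, j) {
  if (j < 1L) return(0L)
  types <- vapply(seq_len(j), function(i) porter_is_cons(chars, i), logical(1))
  # collapse runs
  runs <- rle(types)$values
  # count transitions V -> C
  m <- 0L
  seen_vowel <- FALSE
  for (cons in runs) {
    if (!cons) seen_vowel <- TRUE
    else if (seen_vowel) { m <- m + 1L; seen_vowel <- FALSE }
  }
  m
}

porter_has_vowel <- function(chars, j) {
  if (j < 1L) return(FALSE)
  any(!vapply(seq_len(j), function(i) porter_is_cons(chars, i), logical(1)))
}

porter_ends_double_cons <- function(chars, j) {
  j >= 2L && chars[j] == chars[j - 1L] && porter_is_cons(chars, j)
}

# *o: stem ends cvc where final c is not w, x or y
porter_cvc <- function(chars, j) {
  if (j < 3L) return(FALSE)
  if (!porter_is_cons(chars, j) || porter_is_cons(chars, j - 1L) ||
      !porter_is_cons(chars, j - 2L)) return(FALSE)
  !(chars[j] %in% c("w", "x", "y"))
}

porter_stem_word <- function(word) {
  if (nchar(word) <= 2L) return(word)
  w <- strsplit(word, "", fixed = TRUE)[[1]]

  ends <- function(suffix) {
    s <- strsplit(suffix, "", fixed = TRUE)[[1]]
    ls <- length(s); lw <- length(w)
    lw > ls && identical(w[(lw - ls + 1L):lw], s)
  }
  stem_len <- function(suffix) length(w) - nchar(suffix)
  replace_suffix <- function(suffix, repl) {
    k <- stem_len(suffix)
    w <<- c(w[seq_len(k)], if (nzchar(repl)) strsplit(repl, "", fixed = TRUE)[[1]])
  }

  # Step 1a
  if (ends("sses")) replace_suffix("sses", "ss")
  else if (ends("ies")) replace_suffix("ies", "i")
  else if (ends("ss")) NULL
  else if (ends("s")) replace_suffix("s", "")

  # Step 1b
  step1b_extra <- FALSE
  if (ends("eed")) {
    if (porter_m(w, stem_len("eed")) > 0L) replace_suffix("eed", "ee")
  } else if (ends("ed") && porter_has_vowel(w, stem_len("ed"))) {
    replace_suffix("ed", ""); step1b_extra <- TRUE
  } else if (ends("ing") && porter_has_vowel(w, stem_len("ing"))) {
    replace_suffix("ing", ""); step1b_extra <- TRUE
  }
  if (step1b_extra) {
    if (ends("at")) replace_suffix("at", "ate")
    else if (ends("bl")) replace_suffix("bl", "ble")
    else if (ends("iz")) replace_suffix("iz", "ize")
    else if (porter_ends_double_cons(w, length(w)) &&
             !(w[length(w)] %in% c("l", "s", "z"))) w <- w[-length(w)]
    else if (porter_m(w, length(w)) == 1L && porter_cvc(w, length(w)))
      w <- c(w, "e")
  }

  # Step 1c
  if (ends("y") && porter_has_vowel(w, stem_len("y"))) replace_suffix("y", "i")

  # Step 2 (m > 0)
  step2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
             izer = "ize", abli = "able", alli = "al", entli = "ent",
             eli = "e", ousli = "ous", ization = "ize", ation = "ate",
             ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
             ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")
  for (suf in names(step2)) {
    if (ends(suf)) {
      if (porter_m(w, stem_len(suf)) > 0L) replace_suffix(suf, step2[[suf]])
      break
    }
  }

  # Step 3 (m > 0)
  step3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
             ical = "ic", ful = "", ness = "")
  for (suf in names(step3)) {
    if (ends(suf)) {
      if (porter_m(w, stem_len(suf)) > 0L) replace_suffix(suf, step3[[suf]])
      break
    }
  }

  # Step 4 (m > 1)
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")
  for (suf in step4) {
    if (ends(suf)) {
      k <- stem_len(suf)
      if (suf == "ion") {
        if (k >= 1L && w[k] %in% c("s", "t") && porter_m(w, k) > 1L)
          replace_suffix(suf, "")
      } else if (porter_m(w, k) > 1L) replace_suffix(suf, "")
      break
    }
  }

  # Step 5a
  if (w[length(w)] == "e") {
    k <- length(w) - 1L
    m <- porter_m(w, k)
    if (m > 1L || (m == 1L && !porter_cvc(w, k))) w <- w[-length(w)]
  }
  # Step 5b
  if (porter_m(w, length(w)) > 1L && porter_ends_double_cons(w, length(w)) &&
      w[length(w)] == "l") w <- w[-length(w)]

  paste(w, collapse = "")
}

#' Stem English words with the Porter algorithm
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems.
#' @examples
#' porter_stem(c("thoracic", "vertebral", "foramen"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem_word, character(1), USE.NAMES = FALSE)
}
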