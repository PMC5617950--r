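#' Porter stemming
#'
#' Deterministic suffix-stripping stemmer implementing the classic Porter
#' (1980) algorithm, with one extension for medical vocabulary: a terminal
#' "-is" is removed when the remaining stem has measure > 1, so that
#' Greek/Latin singular/plural pairs such as "metastasis"/"metastases",
#' "diagnosis"/"diagnoses" and "stenosis"/"stenoses" conflate to a single
#' stem. Without that rule the classic algorithm leaves "metastasi" and
#' "metastas" distinct, which splits the document frequency of what
#' radiologists use as one term.
#'
#' Words of length <= 2 are returned unchanged, as in the original
#' algorithm. Input is expected to be lowercase alphabetic; the function is
#' vectorised and caches repeated words.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("metastases", "metastasis"))   # both "metastas"
#' porter_stem(c("hypoattenuating", "hypoattenuated"))
#' porter_stem(c("recurrent", "recurrence"))
#' @export
porter_stem <- function(words) {
  if (!is.character(words)) stop("`words` must be a character vector")
  u <- unique(words)
  stems <- vapply(u, .porter1, character(1), USE.NAMES = FALSE)
  stems[match(words, u)]
}

# -- letter classification -------------------------------------------------
# A consonant is a letter other than a,e,i,o,u and other than y preceded by
# a consonant; so y is a vowel iff the preceding letter is a consonant.
.vowel_mask <- function(chars) {
  n <- length(chars)
  v <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      v[i] <- TRUE
    } else if (ch == "y") {
      v[i] <- if (i == 1L) FALSE else !v[i - 1L]
    }
  }
  v
}

# measure m: number of VC sequences in [C](VC)^m[V]
.measure <- function(s) {
  if (!nzchar(s)) return(0L)
  v <- .vowel_mask(strsplit(s, "", fixed = TRUE)[[1]])
  runs <- rle(v)$values  # alternating vowel/consonant runs
  if (length(runs) < 2L) return(0L)
  m <- 0L
  for (i in seq_len(length(runs) - 1L)) {
    if (runs[i] && !runs[i + 1L]) m <- m + 1L
  }
  m
}

.has_vowel <- function(s) {
  if (!nzchar(s)) return(FALSE)
  any(.vowel_mask(strsplit(s, "", fixed = TRUE)[[1]]))
}

.ends_double_cons <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(FALSE)
  a <- substr(s, n - 1L, n - 1L)
  b <- substr(s, n, n)
  if (a != b) return(FALSE)
  v <- .vowel_mask(strsplit(s, "", fixed = TRUE)[[1]])
  !v[n]
}

# *o: stem ends cvc where the final c is not w, x or y
.ends_cvc <- function(s) {
  n <- nchar(s)
  if (n < 3L) return(FALSE)
  v <- .vowel_mask(strsplit(s, "", fixed = TRUE)[[1]])
  last <- substr(s, n, n)
  !v[n - 2L] && v[n - 1L] && !v[n] && !(last %in% c("w", "x", "y"))
}

.ends <- function(w, suf) {
  nw <- nchar(w); ns <- nchar(suf)
  nw > ns && substr(w, nw - ns + 1L, nw) == suf
}

.chop <- function(w, n) substr(w, 1L, nchar(w) - n)

.porter1 <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # medical extension: terminal -is (metastasis, diagnosis, stenosis, ...)
  if (.ends(w, "is") && .measure(.chop(w, 2L)) > 1L) {
    w <- .chop(w, 2L)
  } else {
    # step 1a
    if (.ends(w, "sses")) {
      w <- .chop(w, 2L)
    } else if (.ends(w, "ies")) {
      w <- .chop(w, 2L)
    } else if (!.ends(w, "ss") && .ends(w, "s")) {
      w <- .chop(w, 1L)
    }
  }

  # step 1b
  if (.ends(w, "eed")) {
    if (.measure(.chop(w, 3L)) > 0L) w <- .chop(w, 1L)
  } else {
    flag <- FALSE
    if (.ends(w, "ed") && .has_vowel(.chop(w, 2L))) {
      w <- .chop(w, 2L); flag <- TRUE
    } else if (.ends(w, "ing") && .has_vowel(.chop(w, 3L))) {
      w <- .chop(w, 3L); flag <- TRUE
    }
    if (flag) {
      if (.ends(w, "at") || .ends(w, "bl") || .ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (.ends_double_cons(w) &&
                 !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
        w <- .chop(w, 1L)
      } else if (.measure(w) == 1L && .ends_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c
  if (.ends(w, "y") && .has_vowel(.chop(w, 1L))) {
    w <- paste0(.chop(w, 1L), "i")
  }

  # step 2 (condition m > 0), longest matching suffix wins
  step2 <- c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  )
  w <- .apply_rules(w, step2, min_m = 1L)

  # step 3 (condition m > 0)
  step3 <- c(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  )
  w <- .apply_rules(w, step3, min_m = 1L)

  # step 4 (condition m > 1); "ion" only after s or t
  step4 <- c(
    "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
    "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
  )
  sufs <- step4[order(-nchar(step4))]
  for (suf in sufs) {
    if (.ends(w, suf)) {
      stem <- .chop(w, nchar(suf))
      ok <- .measure(stem) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (.ends(w, "e")) {
    stem <- .chop(w, 1L)
    m <- .measure(stem)
    if (m > 1L || (m == 1L && !.ends_cvc(stem))) w <- stem
  }
  # step 5b
  if (.measure(w) > 1L && .ends_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- .chop(w, 1L)
  }
  w
}

# longest matching suffix; if it matches but the measure condition fails,
# the word is left alone (Porter's rule-block semantics)
.apply_rules <- function(w, rules, min_m) {
  sufs <- names(rules)[order(-nchar(names(rules)))]
  for (suf in sufs) {
    if (.ends(w, suf)) {
      stem <- .chop(w, nchar(suf))
      if (.measure(stem) >= min_m) w <- paste0(stem, rules[[suf]])
      break
    }
  }
  w
}
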