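#' Negation-tagging configuration
#'
#' Settings for the proximity-based negation tagger: a lexicon of negation
#' cue phrases, a scope window (number of word tokens after a cue that are
#' marked negated), and scope terminators (punctuation or conjunctions that
#' cut a negation scope short).
#'
#' Cues may be multi-word phrases ("free of", "negative for"); they are
#' matched against consecutive tokens, longest phrase first. A new cue
#' inside an open scope restarts the window. Punctuation tokens that are
#' not terminators are transparent: they neither consume window positions
#' nor emit terms.
#'
#' @param cues character vector of lowercase cue phrases.
#' @param window positive integer; number of word tokens after a cue that
#'   fall inside the negation scope.
#' @param terminators character vector of tokens that end a scope
#'   (punctuation marks and/or words).
#' @return an object of class `negation_config`.
#' @examples
#' cfg <- negation_config()
#' tag_negation(tokenize("No discrete mass."), cfg)
#' @export
negation_config <- function(cues = c("no", "not", "without", "absent",
                                     "free of", "negative for"),
                            window = 3L,
                            terminators = c(".", ";", ":", "!", "?",
                                            "but", "however")) {
  if (!is.character(cues) || length(cues) == 0L || any(!nzchar(cues)))
    stop("`cues` must be a non-empty character vector of non-empty phrases")
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("`window` must be >= 1")
  if (!is.character(terminators)) stop("`terminators` must be character")
  cue_tokens <- strsplit(tolower(cues), " +")
  cue_tokens <- cue_tokens[order(-lengths(cue_tokens))]
  structure(
    list(cues = tolower(cues), cue_tokens = cue_tokens,
         window = window, terminators = tolower(terminators)),
    class = "negation_config"
  )
}

.PUNCT_TOKENS <- c(".", ";", ":", "!", "?", ",")

#' Tokenize report text
#'
#' Lowercases the text and splits it into word tokens in document order.
#' Sentence punctuation (`. ; : ! ? ,`) is preserved as sentinel tokens so
#' the negation tagger can terminate scopes at clause boundaries. Tokens
#' containing digits (measurements, dates, series labels such as "t2") and
#' tokens shorter than two characters are dropped.
#'
#' @param text a single character string (may be empty or `NA`).
#' @return character vector of tokens; empty for empty input.
#' @examples
#' tokenize("No discrete mass.")   # "no" "discrete" "mass" "."
#' tokenize("T2 lesion x 3")       # "lesion"
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop("`text` must be a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  m <- gregexpr("[a-z0-9]+|[.;:!?,]", x, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  toks <- regmatches(x, list(m))[[1]]
  is_punct <- toks %in% .PUNCT_TOKENS
  keep <- is_punct | (!grepl("[0-9]", toks) & nchar(toks) >= 2L)
  toks[keep]
}

# negation scan on raw tokens; returns surface forms + negation flags,
# leaving stemming to the caller (so a corpus can stem unique surfaces once)
.tag_raw <- function(tokens, config) {
  n <- length(tokens)
  surface <- character(n)
  negated <- logical(n)
  k <- 0L
  remaining <- 0L
  i <- 1L
  cue_tokens <- config$cue_tokens
  terminators <- config$terminators
  while (i <= n) {
    matched <- 0L
    for (ct in cue_tokens) {
      len <- length(ct)
      if (i + len - 1L <= n && all(tokens[i:(i + len - 1L)] == ct)) {
        matched <- len
        break
      }
    }
    if (matched > 0L) {
      remaining <- config$window
      i <- i + matched
      next
    }
    tok <- tokens[i]
    if (tok %in% terminators) {
      remaining <- 0L
      i <- i + 1L
      next
    }
    if (tok %in% .PUNCT_TOKENS) {  # transparent punctuation
      i <- i + 1L
      next
    }
    k <- k + 1L
    surface[k] <- tok
    negated[k] <- remaining > 0L
    if (remaining > 0L) remaining <- remaining - 1L
    i <- i + 1L
  }
  list(surface = surface[seq_len(k)], negated = negated[seq_len(k)])
}

.term_display <- function(surface, negated) {
  ifelse(negated, paste0("[no] ", surface), surface)
}

.term_key <- function(stem, negated) {
  ifelse(negated, paste0("[no] ", stem), stem)
}

#' Tag tokens with negation context and stem them
#'
#' Applies the proximity negation check to a token stream from
#' [tokenize()]: a word token is negated iff it lies within
#' `config$window` word tokens after a negation cue, with the scope cut
#' short by any terminator or restarted by a new cue. Cues and terminators
#' emit no term. Each remaining word token becomes a term with its Porter
#' stem, negation flag, surface form and display string
#' (`"[no] <surface>"` when negated).
#'
#' @param tokens character vector from [tokenize()] (sentinels intact).
#' @param config a [negation_config()].
#' @return data.frame with columns `stem`, `negated`, `surface`,
#'   `display`, `key` in document order (one row per word token).
#' @export
tag_negation <- function(tokens, config = negation_config()) {
  stopifnot(inherits(config, "negation_config"))
  raw <- .tag_raw(tokens, config)
  stems <- porter_stem(raw$surface)
  data.frame(
    stem = stems,
    negated = raw$negated,
    surface = raw$surface,
    display = .term_display(raw$surface, raw$negated),
    key = .term_key(stems, raw$negated),
    stringsAsFactors = FALSE
  )
}

#' Distinct term set of one report
#'
#' Runs tokenize -> negation tagging -> stemming and reduces the result to
#' the report's distinct term set (presence, not multiplicity): downstream
#' counting is document frequency. A negated and a plain occurrence of the
#' same stem are distinct terms and may co-occur in one report. The first
#' surface form encountered for a term is kept for display.
#'
#' @param report either a character string of report text or a list/row
#'   with a `text` field.
#' @param config a [negation_config()].
#' @return data.frame with columns `stem`, `negated`, `surface`,
#'   `display`, `key`; one row per distinct term.
#' @examples
#' process_report("No discrete mass but discrete calcification.")
#' @export
process_report <- function(report, config = negation_config()) {
  text <- if (is.character(report)) report else report$text
  terms <- tag_negation(tokenize(text), config)
  terms[!duplicated(terms$key), , drop = FALSE]
}

#' Process every report of a corpus
#'
#' Applies [process_report()] to each report with a shared
#' [negation_config()], stemming unique surface forms once for speed, and
#' gathers per-cohort vocabulary statistics.
#'
#' @param corpus a `report_corpus`.
#' @param config a [negation_config()].
#' @return list with elements `term_sets` (one data.frame per report, as
#'   [process_report()]), `cohorts` (character vector), and `stats`, a
#'   data.frame with per-cohort distinct-term and word-token-instance
#'   counts.
#' @export
process_corpus <- function(corpus, config = negation_config()) {
  stopifnot(inherits(corpus, "report_corpus"))
  texts <- corpus$reports$text
  cohorts <- corpus$reports$cohort
  raws <- lapply(texts, function(tx) .tag_raw(tokenize(tx), config))
  all_surface <- unique(unlist(lapply(raws, `[[`, "surface"), use.names = FALSE))
  stem_map <- porter_stem(all_surface)
  names(stem_map) <- all_surface
  term_sets <- lapply(raws, function(r) {
    stems <- unname(stem_map[r$surface])
    d <- data.frame(
      stem = stems,
      negated = r$negated,
      surface = r$surface,
      display = .term_display(r$surface, r$negated),
      key = .term_key(stems, r$negated),
      stringsAsFactors = FALSE
    )
    d[!duplicated(d$key), , drop = FALSE]
  })
  token_counts <- vapply(raws, function(r) length(r$surface), integer(1))
  stats <- do.call(rbind, lapply(c("MUTANT", "WILDTYPE"), function(ch) {
    sel <- cohorts == ch
    data.frame(
      cohort = ch,
      n_reports = sum(sel),
      token_instances = sum(token_counts[sel]),
      distinct_terms = length(unique(unlist(
        lapply(term_sets[sel], `[[`, "key"), use.names = FALSE))),
      stringsAsFactors = FALSE
    )
  }))
  list(term_sets = term_sets, cohorts = cohorts, stats = stats)
}
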