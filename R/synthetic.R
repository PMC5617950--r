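# run code under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Planted marker term
#'
#' A marker is a surface word planted in synthetic reports with a
#' cohort-specific report-level inclusion probability: each MUTANT report
#' contains it with probability `q_mut`, each WILDTYPE report with
#' `q_wt` (Bernoulli per report — presence/absence is what the
#' document-frequency analysis sees). With `negated = TRUE` the word is
#' planted inside a "no <word> ..." phrase so the negation tagger must
#' recover it as the `"[no] <stem>"` term.
#'
#' @param word alphabetic surface word.
#' @param q_mut,q_wt inclusion probabilities in `[0, 1]`.
#' @param negated logical; plant in negated context.
#' @return object of class `marker_spec`.
#' @export
marker_spec <- function(word, q_mut, q_wt, negated = FALSE) {
  if (!is.character(word) || length(word) != 1L ||
      !grepl("^[a-z]+$", word))
    stop("marker `word` must be a single lowercase alphabetic string")
  for (q in list(q_mut = q_mut, q_wt = q_wt))
    if (!is.numeric(q) || q < 0 || q > 1)
      stop("marker inclusion probabilities must lie in [0, 1]")
  structure(list(word = word, q_mut = q_mut, q_wt = q_wt,
                 negated = isTRUE(negated)),
            class = "marker_spec")
}

#' Default marker panel
#'
#' Three markers emulating cohort-differential radiology descriptors: a
#' strongly and a moderately MUTANT-enriched plain descriptor
#' ("innumerable", "confluent": tumour-burden language) and a
#' WILDTYPE-enriched negated descriptor ("no discrete ..."). Analytic
#' posteriors under balanced cohorts: 0.75, ~0.676 and 0.25.
#'
#' @return list of [marker_spec()] objects.
#' @export
default_markers <- function() {
  list(
    marker_spec("innumerable", q_mut = 0.30, q_wt = 0.10),
    marker_spec("confluent", q_mut = 0.25, q_wt = 0.12),
    marker_spec("discrete", q_mut = 0.10, q_wt = 0.30, negated = TRUE)
  )
}

#' Synthetic corpus specification
#'
#' Generative parameters for a two-cohort corpus of short free-text
#' reports: cohort sizes, the planted markers, a background vocabulary of
#' pronounceable nonsense words (consonant-vowel syllables, guaranteeing
#' zero stem collision with real marker words), the mean number of
#' background words per report (Poisson), sentence templates with `{w}`
#' (marker word) and `{bg}` (fresh random background word) slots, and the
#' RNG seed. Template filler is drawn from the background vocabulary
#' rather than fixed words so that no template co-word inherits a marker's
#' cohort differential, and the default negated template closes the
#' negation scope right after the marker (`"no {w}; ..."`) so background
#' filler is never spuriously negation-tagged.
#'
#' @param n_mut,n_wt positive cohort sizes (reports).
#' @param markers list of [marker_spec()]; at least one.
#' @param vocab_size background vocabulary size; must be at least
#'   `bg_words_mean`.
#' @param bg_words_mean positive mean background words per report.
#' @param templates named list with `plain`, `negated`, `background`
#'   template strings.
#' @param seed integer RNG seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_mut = 2000L, n_wt = 2000L,
                           markers = default_markers(),
                           vocab_size = 500L, bg_words_mean = 40L,
                           templates = list(
                             plain = "{w} {bg} {bg}.",
                             negated = "no {w}; {bg} {bg}.",
                             background = "{bg} {bg} {bg} {bg} {bg} {bg}."
                           ),
                           seed = 101L) {
  n_mut <- as.integer(n_mut); n_wt <- as.integer(n_wt)
  if (is.na(n_mut) || n_mut < 1L) stop("invalid field `n_mut`: must be >= 1")
  if (is.na(n_wt) || n_wt < 1L) stop("invalid field `n_wt`: must be >= 1")
  if (!is.list(markers) || length(markers) == 0L)
    stop("invalid field `markers`: at least one marker is required")
  markers <- lapply(markers, function(m) {
    if (inherits(m, "marker_spec")) m else do.call(marker_spec, m)
  })
  vocab_size <- as.integer(vocab_size)
  if (is.na(vocab_size) || vocab_size < 1L)
    stop("invalid field `vocab_size`: must be >= 1")
  if (!is.numeric(bg_words_mean) || bg_words_mean < 1)
    stop("invalid field `bg_words_mean`: must be >= 1")
  if (vocab_size < bg_words_mean)
    stop("invalid field `vocab_size`: must be >= `bg_words_mean`")
  if (!all(c("plain", "negated", "background") %in% names(templates)))
    stop("invalid field `templates`: need `plain`, `negated`, `background`")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("invalid field `seed`: must be an integer")
  structure(list(n_mut = n_mut, n_wt = n_wt, markers = markers,
                 vocab_size = vocab_size, bg_words_mean = bg_words_mean,
                 templates = templates, seed = seed),
            class = "synthetic_spec")
}

#' Analytic naive Bayes posterior of a planted marker
#'
#' The population image of the per-term Bayes posterior under the
#' generator: `q_mut * rho / (q_mut * rho + q_wt * (1 - rho))`, where
#' `rho` is the MUTANT cohort prior. Equals 0.5 for a null marker
#' (`q_mut = q_wt`) under balanced cohorts.
#'
#' @param q_mut,q_wt report-level inclusion probabilities; not both zero.
#' @param rho MUTANT prior in (0, 1).
#' @return posterior in `[0, 1]`; vectorised.
#' @examples
#' analytic_posterior(0.3, 0.1, 0.5)   # 0.75
#' @export
analytic_posterior <- function(q_mut, q_wt, rho = 0.5) {
  if (any(rho <= 0 | rho >= 1)) stop("`rho` must lie strictly in (0, 1)")
  if (any(q_mut < 0 | q_mut > 1 | q_wt < 0 | q_wt > 1))
    stop("inclusion probabilities must lie in [0, 1]")
  if (any(q_mut == 0 & q_wt == 0))
    stop("analytic posterior undefined when both probabilities are zero")
  num <- q_mut * rho
  num / (num + q_wt * (1 - rho))
}

# pronounceable CV-syllable nonsense vocabulary with unique Porter stems,
# disjoint from the given stems
.make_vocab <- function(n, forbidden_stems) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vows <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(cons, vows, paste0))
  words <- character(0)
  stems <- character(0)
  while (length(words) < n) {
    need <- (n - length(words)) * 2L + 10L
    cand <- vapply(seq_len(need), function(i)
      paste0(sample(syll, 3L, replace = TRUE), collapse = ""), character(1))
    cand <- setdiff(unique(cand), words)
    st <- porter_stem(cand)
    ok <- !(st %in% c(stems, forbidden_stems)) & !duplicated(st)
    words <- c(words, cand[ok])
    stems <- c(stems, st[ok])
  }
  words[seq_len(n)]
}

.fill_template <- function(template, word, vocab) {
  out <- template
  if (grepl("{w}", out, fixed = TRUE))
    out <- gsub("{w}", word, out, fixed = TRUE)
  while (grepl("{bg}", out, fixed = TRUE))
    out <- sub("{bg}", sample(vocab, 1L), out, fixed = TRUE)
  out
}

#' Generate a labelled synthetic corpus with known ground truth
#'
#' Draws `n_mut + n_wt` reports. Each report contains a Poisson number of
#' background sentences filled with uniform draws from the nonsense
#' vocabulary, plus, independently for every marker, one marker sentence
#' with its cohort's inclusion probability (negated markers embedded as
#' "no <word> ..." phrases). Marker sentences are shuffled uniformly into
#' the report. Fully reproducible from `spec$seed` via a single RNG
#' stream; the generator algorithm is recorded in the ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional directory; when given, the corpus is written via
#'   [write_corpus()] together with `ground_truth.json`.
#' @return list with `corpus` (a `report_corpus`) and `ground_truth`, a
#'   data.frame with one row per marker: `word`, `key`, `negated`,
#'   `q_mut`, `q_wt`, `posterior` (analytic, with the empirical prior
#'   `rho = n_mut / (n_mut + n_wt)`).
#' @export
generate_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  marker_words <- vapply(spec$markers, `[[`, character(1), "word")
  marker_neg <- vapply(spec$markers, `[[`, logical(1), "negated")
  marker_stems <- porter_stem(marker_words)
  rho <- spec$n_mut / (spec$n_mut + spec$n_wt)

  res <- .with_seed(spec$seed, {
    vocab <- .make_vocab(spec$vocab_size, marker_stems)
    n_total <- spec$n_mut + spec$n_wt
    cohorts <- rep(c("MUTANT", "WILDTYPE"), c(spec$n_mut, spec$n_wt))
    texts <- character(n_total)
    for (i in seq_len(n_total)) {
      mut <- cohorts[i] == "MUTANT"
      n_bg <- max(1L, as.integer(round(stats::rpois(1L, spec$bg_words_mean) / 6)))
      sentences <- vapply(seq_len(n_bg), function(j)
        .fill_template(spec$templates$background, "", vocab), character(1))
      for (k in seq_along(spec$markers)) {
        m <- spec$markers[[k]]
        q <- if (mut) m$q_mut else m$q_wt
        if (stats::runif(1L) < q) {
          tpl <- if (m$negated) spec$templates$negated else spec$templates$plain
          sentences <- c(sentences, .fill_template(tpl, m$word, vocab))
        }
      }
      texts[i] <- paste(sample(sentences), collapse = " ")
    }
    list(vocab = vocab, cohorts = cohorts, texts = texts)
  })

  idx_mut <- seq_len(spec$n_mut)
  idx_wt <- seq_len(spec$n_wt)
  reports <- data.frame(
    report_id = c(sprintf("MUT%05d", idx_mut), sprintf("WT%05d", idx_wt)),
    patient_id = c(sprintf("PM%05d", ceiling(idx_mut / 2)),
                   sprintf("PW%05d", ceiling(idx_wt / 2))),
    cohort = res$cohorts,
    text = res$texts,
    stringsAsFactors = FALSE
  )
  corpus <- report_corpus(reports)
  ground_truth <- data.frame(
    word = marker_words,
    key = .term_key(marker_stems, marker_neg),
    negated = marker_neg,
    q_mut = vapply(spec$markers, `[[`, numeric(1), "q_mut"),
    q_wt = vapply(spec$markers, `[[`, numeric(1), "q_wt"),
    posterior = analytic_posterior(
      vapply(spec$markers, `[[`, numeric(1), "q_mut"),
      vapply(spec$markers, `[[`, numeric(1), "q_wt"), rho),
    stringsAsFactors = FALSE
  )
  attr(ground_truth, "rho") <- rho
  attr(ground_truth, "rng") <- RNGkind()[1]
  attr(ground_truth, "seed") <- spec$seed
  if (!is.null(dir)) {
    write_corpus(corpus, dir)
    gt <- c(as.list(ground_truth), list(rho = rho, rng = RNGkind()[1],
                                        seed = spec$seed))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(corpus = corpus, ground_truth = ground_truth)
}
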