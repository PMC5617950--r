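#' Per-cohort document-frequency table
#'
#' Counts, for every distinct term, the number of reports per cohort whose
#' distinct-term set contains it (document frequency — multiplicity within
#' a report is irrelevant). The canonical display string of a term is the
#' most frequent surface form mapped to its stem (ties broken
#' lexicographically), prefixed with `"[no] "` when negated.
#'
#' @param term_sets list of per-report term data.frames as produced by
#'   [process_report()] / [process_corpus()].
#' @param cohorts character vector of cohort labels, one per report.
#' @return data.frame of class `cohort_term_table` with columns `key`,
#'   `stem`, `negated`, `display`, `df_mut`, `df_wt`, sorted by `key`;
#'   attributes `n_mut`, `n_wt` hold the report totals.
#' @export
build_term_table <- function(term_sets, cohorts) {
  if (length(term_sets) != length(cohorts))
    stop("`term_sets` and `cohorts` must have the same length")
  bad <- setdiff(unique(cohorts), .COHORTS)
  if (length(bad)) stop("unknown cohort label: ", paste(bad, collapse = ", "))
  n_mut <- sum(cohorts == "MUTANT")
  n_wt <- sum(cohorts == "WILDTYPE")
  if (n_mut == 0L || n_wt == 0L)
    stop("both cohorts must be non-empty (frequencies are undefined for N = 0)")

  lens <- vapply(term_sets, nrow, integer(1))
  key <- unlist(lapply(term_sets, `[[`, "key"), use.names = FALSE)
  stem <- unlist(lapply(term_sets, `[[`, "stem"), use.names = FALSE)
  negated <- unlist(lapply(term_sets, `[[`, "negated"), use.names = FALSE)
  surface <- unlist(lapply(term_sets, `[[`, "surface"), use.names = FALSE)
  cohort_row <- rep(cohorts, lens)

  kf <- factor(key)
  df_mut <- as.integer(table(kf[cohort_row == "MUTANT"]))
  df_wt <- as.integer(table(kf[cohort_row == "WILDTYPE"]))

  # modal surface per term (each report contributes one surface per term)
  disp <- vapply(split(surface, kf), function(s) {
    tab <- sort(table(s), decreasing = TRUE)
    best <- names(tab)[tab == tab[1]]
    sort(best)[1]
  }, character(1))

  first <- !duplicated(key)
  meta <- data.frame(key = key[first], stem = stem[first],
                     negated = negated[first], stringsAsFactors = FALSE)
  meta <- meta[order(meta$key), , drop = FALSE]
  stopifnot(identical(meta$key, levels(kf)))

  out <- data.frame(
    key = levels(kf),
    stem = meta$stem,
    negated = meta$negated,
    display = .term_display(unname(disp), meta$negated),
    df_mut = df_mut,
    df_wt = df_wt,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_mut") <- n_mut
  attr(out, "n_wt") <- n_wt
  class(out) <- c("cohort_term_table", "data.frame")
  out
}

#' Report frequency of a term
#'
#' The fraction of a cohort's reports containing a term: `df / N`,
#' unsmoothed (smoothing is applied only inside Bayes scoring, so reported
#' frequencies keep their direct counting definition).
#'
#' @param df document frequency (integer, `0 <= df <= n`).
#' @param n positive cohort report total.
#' @return frequency in `[0, 1]`; vectorised.
#' @export
report_frequency <- function(df, n) {
  if (any(n <= 0)) stop("`n` must be positive")
  if (any(df < 0) || any(df > n)) stop("`df` must satisfy 0 <= df <= n")
  df / n
}

#' Symmetric percent difference between two frequencies
#'
#' `100 * |a - b| / ((a + b) / 2)` by default — the mean-relative
#' (symmetric) form; `method = "max"` gives the max-relative variant
#' `100 * |a - b| / max(a, b)` for sensitivity analysis. Undefined (an
#' error) when both frequencies are zero.
#'
#' @param f_a,f_b frequencies in `[0, 1]`; vectorised.
#' @param method `"mean"` (default) or `"max"`.
#' @return percent difference `>= 0`.
#' @examples
#' percent_difference(0.3, 0.1)   # 100
#' @export
percent_difference <- function(f_a, f_b, method = c("mean", "max")) {
  method <- match.arg(method)
  if (any(f_a < 0 | f_a > 1 | f_b < 0 | f_b > 1))
    stop("frequencies must lie in [0, 1]")
  if (any(f_a == 0 & f_b == 0))
    stop("percent difference is undefined when both frequencies are zero")
  denom <- switch(method, mean = (f_a + f_b) / 2, max = pmax(f_a, f_b))
  100 * abs(f_a - f_b) / denom
}

#' Rank scored terms
#'
#' Filters to terms seen in at least `min_df` reports overall
#' (`df_mut + df_wt >= min_df`; suppresses one-off typo terms) and sorts
#' descending by the chosen metric — absolute posterior difference
#' `|p_mut - p_wt|` or percent frequency difference. Ties are broken by
#' higher total document frequency, then lexicographic stem (and plain
#' before negated).
#'
#' @param scores a scored term table from [score_all_terms()].
#' @param min_df non-negative integer.
#' @param metric `"abs_posterior_diff"` or `"pct_diff"`.
#' @return the filtered, ordered score data.frame (possibly zero rows).
#' @export
rank_terms <- function(scores, min_df = 5L,
                       metric = c("abs_posterior_diff", "pct_diff")) {
  metric <- match.arg(metric)
  min_df <- as.integer(min_df)
  if (is.na(min_df) || min_df < 0L) stop("`min_df` must be >= 0")
  if (metric == "abs_posterior_diff" && is.null(scores$p_mut))
    stop("`scores` must carry posteriors; run score_all_terms() first")
  total <- scores$df_mut + scores$df_wt
  keep <- total >= min_df
  s <- scores[keep, , drop = FALSE]
  total <- total[keep]
  val <- switch(metric,
                abs_posterior_diff = abs(s$p_mut - s$p_wt),
                pct_diff = s$pct_diff)
  ord <- order(-val, -total, s$stem, s$negated)
  out <- s[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
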