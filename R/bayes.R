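#' Naive Bayes scoring configuration
#'
#' Controls the per-term posterior computation: the cohort prior and the
#' add-alpha (Laplace) smoothing applied to document frequencies before
#' they enter Bayes' rule. With `prior_mode = "empirical"` the MUTANT
#' prior is `N_mut / (N_mut + N_wt)`; `"fixed"` uses `prior_mut` (the
#' spam-filter convention is a fixed 0.5).
#'
#' @param prior_mode `"empirical"` (default) or `"fixed"`.
#' @param prior_mut MUTANT-cohort prior in (0, 1); used when
#'   `prior_mode = "fixed"`.
#' @param alpha smoothing pseudo-count, `>= 0`. `alpha = 0` reproduces raw
#'   frequencies but is rejected for terms absent from (or present in all
#'   of) a cohort, where the posterior would be degenerate.
#' @return an object of class `bayes_config`.
#' @export
bayes_config <- function(prior_mode = c("empirical", "fixed"),
                         prior_mut = 0.5, alpha = 1) {
  prior_mode <- match.arg(prior_mode)
  if (prior_mode == "fixed" &&
      (!is.numeric(prior_mut) || prior_mut <= 0 || prior_mut >= 1))
    stop("fixed `prior_mut` must lie strictly in (0, 1)")
  if (!is.numeric(alpha) || alpha < 0) stop("`alpha` must be >= 0")
  structure(list(prior_mode = prior_mode, prior_mut = prior_mut,
                 alpha = alpha),
            class = "bayes_config")
}

#' Smoothed per-cohort term likelihood
#'
#' `(df + alpha) / (N + 2 * alpha)`: the probability that a report of the
#' cohort contains the term, with an add-alpha pseudo-count guarding the
#' zero-frequency case (Bayes' rule is undefined when both cohort
#' likelihoods are zero).
#'
#' @param df document frequency, `0 <= df <= n`; vectorised.
#' @param n positive cohort report total.
#' @param alpha pseudo-count `>= 0`; must be `> 0` when `df` is 0 or `n`.
#' @return likelihood strictly inside (0, 1) whenever `alpha > 0`.
#' @export
smoothed_likelihood <- function(df, n, alpha = 1) {
  if (any(n <= 0)) stop("`n` must be positive")
  if (any(df < 0) || any(df > n)) stop("`df` must satisfy 0 <= df <= n")
  if (any(alpha < 0)) stop("`alpha` must be >= 0")
  if (any(alpha == 0 & (df == 0 | df == n)))
    stop("zero likelihood requires smoothing: alpha must be > 0 when df is 0 or n")
  (df + alpha) / (n + 2 * alpha)
}

#' Per-term posterior probability of the MUTANT cohort
#'
#' Bayes' rule applied to a single term's presence:
#' `p = lik_mut * prior / (lik_mut * prior + lik_wt * (1 - prior))`,
#' the probability that a report containing the term comes from the
#' MUTANT cohort. The WILDTYPE posterior is the complement.
#'
#' @param lik_mut,lik_wt per-cohort term likelihoods in (0, 1); vectorised.
#' @param prior_mut MUTANT prior in (0, 1).
#' @return posterior in (0, 1).
#' @examples
#' term_posterior(0.30, 0.10, 0.5)   # 0.75
#' @export
term_posterior <- function(lik_mut, lik_wt, prior_mut) {
  if (any(lik_mut <= 0 | lik_mut >= 1) || any(lik_wt <= 0 | lik_wt >= 1))
    stop("likelihoods must lie strictly in (0, 1)")
  if (any(prior_mut <= 0 | prior_mut >= 1))
    stop("`prior_mut` must lie strictly in (0, 1)")
  num <- lik_mut * prior_mut
  num / (num + lik_wt * (1 - prior_mut))
}

#' Score every term of a document-frequency table
#'
#' Adds to the table: unsmoothed report frequencies `f_mut`, `f_wt`, the
#' symmetric percent difference `pct_diff`, and the naive Bayes posteriors
#' `p_mut`, `p_wt = 1 - p_mut` computed from smoothed likelihoods and the
#' configured prior.
#'
#' @param table a `cohort_term_table` from [build_term_table()].
#' @param config a [bayes_config()].
#' @return data.frame of class `term_scores`; attributes `n_mut`, `n_wt`,
#'   `prior_mut`, `alpha` record the scoring conditions.
#' @export
score_all_terms <- function(table, config = bayes_config()) {
  stopifnot(inherits(table, "cohort_term_table"))
  if (!nrow(table)) stop("term table is empty")
  n_mut <- attr(table, "n_mut")
  n_wt <- attr(table, "n_wt")
  prior <- switch(config$prior_mode,
                  empirical = n_mut / (n_mut + n_wt),
                  fixed = config$prior_mut)
  lik_mut <- smoothed_likelihood(table$df_mut, n_mut, config$alpha)
  lik_wt <- smoothed_likelihood(table$df_wt, n_wt, config$alpha)
  p_mut <- term_posterior(lik_mut, lik_wt, prior)
  out <- as.data.frame(table)
  out$f_mut <- report_frequency(table$df_mut, n_mut)
  out$f_wt <- report_frequency(table$df_wt, n_wt)
  out$pct_diff <- percent_difference(out$f_mut, out$f_wt)
  out$p_mut <- p_mut
  out$p_wt <- 1 - p_mut
  attr(out, "n_mut") <- n_mut
  attr(out, "n_wt") <- n_wt
  attr(out, "prior_mut") <- prior
  attr(out, "alpha") <- config$alpha
  class(out) <- c("term_scores", "data.frame")
  out
}

#' Select predictor term sets for both cohorts
#'
#' The MUTANT predictor set is the top `k_mut` terms by absolute posterior
#' difference `|p_mut - p_wt|` among terms with `p_mut` strictly above the
#' threshold; the WILDTYPE set is analogous with `p_wt`. A term with
#' posterior exactly at the threshold joins neither set. Since
#' `p_wt = 1 - p_mut`, ranking by `|p_mut - p_wt|` is ranking by distance
#' from 0.5. Sets may be smaller than `k` when too few terms qualify.
#'
#' @param scores a `term_scores` data.frame (typically [rank_terms()]
#'   output).
#' @param k_mut,k_wt non-negative set sizes (defaults mirror a 6-term
#'   mutant and 4-term wild-type predictor panel).
#' @param threshold posterior selection threshold, default 0.5; strict.
#' @return list with elements `mutant` and `wildtype`, each of class
#'   `predictor_set`: list(cohort, threshold, k, terms) where `terms` is
#'   the ordered score data.frame of members.
#' @export
select_predictors <- function(scores, k_mut = 6L, k_wt = 4L, threshold = 0.5) {
  if (is.null(scores$p_mut)) stop("`scores` must carry posteriors")
  if (k_mut < 0L || k_wt < 0L) stop("`k_mut` and `k_wt` must be >= 0")
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  pick <- function(cohort, k) {
    own <- if (cohort == "MUTANT") scores$p_mut else scores$p_wt
    elig <- scores[own > threshold, , drop = FALSE]
    total <- elig$df_mut + elig$df_wt
    ord <- order(-abs(elig$p_mut - elig$p_wt), -total, elig$stem, elig$negated)
    terms <- utils::head(elig[ord, , drop = FALSE], k)
    rownames(terms) <- NULL
    structure(list(cohort = cohort, threshold = threshold,
                   k = nrow(terms), terms = terms),
              class = "predictor_set")
  }
  list(mutant = pick("MUTANT", k_mut), wildtype = pick("WILDTYPE", k_wt))
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("<predictor_set> %s: %d term(s), posterior > %.2f\n",
              x$cohort, x$k, x$threshold))
  if (x$k) {
    own <- if (x$cohort == "MUTANT") x$terms$p_mut else x$terms$p_wt
    for (i in seq_len(x$k))
      cat(sprintf("  %-24s p_own = %.3f\n", x$terms$display[i], own[i]))
  }
  invisible(x)
}
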