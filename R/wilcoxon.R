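#' Wilcoxon signed-rank test with exact small-sample null
#'
#' Paired nonparametric test. Zero differences are dropped (the classic
#' Wilcoxon convention), absolute differences are ranked with midranks for
#' ties, and the reported statistic is the smaller of the two signed-rank
#' sums. For `n_used <= exact_cutoff` the p-value is exact: the null
#' distribution of the positive-rank sum `W+` over all `2^n` equiprobable
#' sign assignments is built by convolution over the (possibly tied)
#' ranks, which equals full sign enumeration. Beyond the cutoff a normal
#' approximation with tie correction and continuity correction is used.
#' All-zero differences give `p = 1` with `n_used = 0`.
#'
#' @param x,y paired numeric samples of equal length.
#' @param alternative `"two_sided"` (default), `"greater"` (x tends to
#'   exceed y) or `"less"`.
#' @param exact_cutoff largest `n_used` for which the exact null is used.
#' @return object of class `wilcoxon_result`: list with `n_used`,
#'   `statistic` (min of the two rank sums), `w_plus`, `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`), `alternative`.
#' @examples
#' wilcoxon_signed_rank(1:5, rep(0, 5), alternative = "greater")  # p = 1/32
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two_sided", "greater", "less"),
                                 exact_cutoff = 25L) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 1L) stop("`x` and `y` must contain at least one pair")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(n_used = 0L, statistic = 0, w_plus = 0,
                          p_value = 1, method = "exact",
                          alternative = alternative),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- n * (n + 1) / 2 - w_plus
  statistic <- min(w_plus, w_minus)

  if (n <= exact_cutoff) {
    # exact null of W+ on a half-integer grid (midranks may be .5)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(total + 1L - ri)])
      f <- 0.5 * (f + shifted)
    }
    obs2 <- as.integer(round(2 * w_plus))
    p_ge <- sum(f[(obs2 + 1L):(total + 1L)])
    p_le <- sum(f[seq_len(obs2 + 1L)])
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two_sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    p <- switch(alternative,
      greater = stats::pnorm((w_plus - mu - 0.5) / sigma, lower.tail = FALSE),
      less = stats::pnorm((w_plus - mu + 0.5) / sigma),
      two_sided = {
        cc <- sign(w_plus - mu) * 0.5
        z <- (w_plus - mu - cc) / sigma
        min(1, 2 * stats::pnorm(-abs(z)))
      })
    method <- "normal_approx"
  }
  structure(list(n_used = n, statistic = statistic, w_plus = w_plus,
                 p_value = p, method = method, alternative = alternative),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank: n_used = %d, statistic = %g, p = %.5g (%s, %s)\n",
    x$n_used, x$statistic, x$p_value, x$method, x$alternative))
  invisible(x)
}

#' Evaluate a predictor term set at the group level
#'
#' Feeds the per-term paired posteriors (own cohort vs other cohort) of a
#' predictor set to the signed-rank test and summarises the group by its
#' mean posteriors — the data behind a bar-plot comparison of mean
#' cohort probabilities for a term panel. Because the two posteriors of a
#' term are complements, all pair differences share one sign by
#' construction, so the exact p-value is driven by the set size; the test
#' is reported as a descriptive group-level summary.
#'
#' @param scores a `term_scores` data.frame containing every set member.
#' @param set a `predictor_set` from [select_predictors()]; must be
#'   non-empty.
#' @param alternative passed to [wilcoxon_signed_rank()].
#' @return object of class `group_evaluation`: list with `label`,
#'   `n_terms`, `mean_own`, `mean_other`, `wilcoxon`.
#' @export
evaluate_predictor_group <- function(scores, set,
                                     alternative = c("two_sided", "greater",
                                                     "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(set, "predictor_set"))
  if (set$k == 0L) stop("predictor set is empty")
  if (!all(set$terms$key %in% scores$key))
    stop("predictor set contains terms absent from `scores`")
  idx <- match(set$terms$key, scores$key)
  p_mut <- scores$p_mut[idx]
  own <- if (set$cohort == "MUTANT") p_mut else 1 - p_mut
  other <- 1 - own
  wres <- wilcoxon_signed_rank(own, other, alternative = alternative)
  structure(list(label = set$cohort, n_terms = set$k,
                 mean_own = mean(own), mean_other = mean(other),
                 wilcoxon = wres),
            class = "group_evaluation")
}

#' @export
print.group_evaluation <- function(x, ...) {
  cat(sprintf(
    "<group_evaluation> %s predictors (n = %d): mean own = %.3f, mean other = %.3f, p = %.4g\n",
    x$label, x$n_terms, x$mean_own, x$mean_other, x$wilcoxon$p_value))
  invisible(x)
}
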