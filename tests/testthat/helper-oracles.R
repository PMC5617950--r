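# Independent oracles and small fixture builders shared across tests.

# brute-force signed-rank p-value by full 2^n enumeration of sign patterns
enum_signrank_p <- function(x, y, alternative = "two_sided") {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1L), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1L))) > 0
    sum(r[signs])
  }, numeric(1))
  eps <- 1e-9
  p_ge <- mean(ws >= obs - eps)
  p_le <- mean(ws <= obs + eps)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

# quadratic recount: re-scan every report for every term
brute_recount <- function(term_sets, cohorts) {
  keys <- sort(unique(unlist(lapply(term_sets, `[[`, "key"),
                            use.names = FALSE)))
  df_mut <- integer(length(keys))
  df_wt <- integer(length(keys))
  for (i in seq_along(keys)) {
    has <- vapply(term_sets, function(s) keys[i] %in% s$key, logical(1))
    df_mut[i] <- sum(has & cohorts == "MUTANT")
    df_wt[i] <- sum(has & cohorts == "WILDTYPE")
  }
  data.frame(key = keys, df_mut = df_mut, df_wt = df_wt,
             stringsAsFactors = FALSE)
}

# direct arithmetic evaluation of the per-term Bayes posterior
direct_posterior <- function(df_mut, df_wt, n_mut, n_wt, alpha, prior) {
  lm <- (df_mut + alpha) / (n_mut + 2 * alpha)
  lw <- (df_wt + alpha) / (n_wt + 2 * alpha)
  lm * prior / (lm * prior + lw * (1 - prior))
}

# in-memory corpus from parallel vectors of texts and cohorts
make_corpus <- function(texts, cohorts, patients = NULL) {
  n <- length(texts)
  report_corpus(data.frame(
    report_id = sprintf("R%03d", seq_len(n)),
    patient_id = if (is.null(patients)) sprintf("P%03d", seq_len(n)) else patients,
    cohort = cohorts,
    text = texts,
    stringsAsFactors = FALSE
  ))
}

# random document-frequency table for scoring tests
random_term_table <- function(n_terms, n_mut, n_wt) {
  sets_keys <- sprintf("term%02d", seq_len(n_terms))
  tbl <- data.frame(
    key = sets_keys, stem = sets_keys,
    negated = FALSE, display = sets_keys,
    df_mut = sample(0:n_mut, n_terms, replace = TRUE),
    df_wt = sample(0:n_wt, n_terms, replace = TRUE),
    stringsAsFactors = FALSE
  )
  # the table contract requires every term to occur at least once
  zero <- tbl$df_mut == 0 & tbl$df_wt == 0
  tbl$df_mut[zero] <- 1L
  attr(tbl, "n_mut") <- n_mut
  attr(tbl, "n_wt") <- n_wt
  class(tbl) <- c("cohort_term_table", "data.frame")
  tbl
}
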