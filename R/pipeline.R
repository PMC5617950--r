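#' Pipeline run configuration
#'
#' Bundles every stage's settings: input paths (or a synthetic spec),
#' exclusion rules, negation tagging, Bayes scoring, ranking and predictor
#' selection parameters, the signed-rank alternative and the run seed.
#'
#' @param out_dir output directory for the run artifacts.
#' @param manifest,reports_dir input corpus location (may be `NULL` when a
#'   corpus object or synthetic spec is supplied instead).
#' @param exclusion an [exclusion_rules()].
#' @param negation a [negation_config()].
#' @param bayes a [bayes_config()].
#' @param min_df minimum total document frequency for ranked terms.
#' @param k_mut,k_wt predictor set sizes.
#' @param threshold posterior selection threshold (strict).
#' @param alternative signed-rank alternative hypothesis.
#' @param synthetic optional [synthetic_spec()].
#' @param seed integer seed; overrides `synthetic$seed` when supplied.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       manifest = NULL, reports_dir = NULL,
                       exclusion = exclusion_rules(),
                       negation = negation_config(),
                       bayes = bayes_config(),
                       min_df = 5L, k_mut = 6L, k_wt = 4L, threshold = 0.5,
                       alternative = c("two_sided", "greater", "less"),
                       synthetic = NULL, seed = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(exclusion, "exclusion_rules"),
            inherits(negation, "negation_config"),
            inherits(bayes, "bayes_config"))
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_spec"))
  if (!is.null(seed) && !is.null(synthetic)) synthetic$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, manifest = manifest,
                 reports_dir = reports_dir, exclusion = exclusion,
                 negation = negation, bayes = bayes,
                 min_df = as.integer(min_df), k_mut = as.integer(k_mut),
                 k_wt = as.integer(k_wt), threshold = threshold,
                 alternative = alternative, synthetic = synthetic,
                 seed = if (is.null(seed)) synthetic$seed else as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' The file mirrors the [run_config()] arguments; nested sections
#' `exclusion`, `negation`, `bayes` and `synthetic` (with a `markers`
#' list) are mapped onto their constructors, so every invariant is
#' checked. YAML is a superset of JSON, so either format works.
#'
#' @param path config file path.
#' @param out_dir,seed optional overrides of the file's values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  args <- list(
    out_dir = if (!is.null(out_dir)) out_dir else raw$out_dir,
    manifest = raw$manifest,
    reports_dir = raw$reports_dir
  )
  if (is.null(args$out_dir)) stop("config must provide `out_dir`")
  if (!is.null(raw$exclusion))
    args$exclusion <- do.call(exclusion_rules, raw$exclusion)
  if (!is.null(raw$negation)) {
    neg <- raw$negation
    neg$cues <- unlist(neg$cues)
    neg$terminators <- unlist(neg$terminators)
    neg <- neg[!vapply(neg, is.null, logical(1))]
    args$negation <- do.call(negation_config, neg)
  }
  if (!is.null(raw$bayes)) args$bayes <- do.call(bayes_config, raw$bayes)
  for (fld in c("min_df", "k_mut", "k_wt", "threshold", "alternative"))
    if (!is.null(raw[[fld]])) args[[fld]] <- raw[[fld]]
  if (!is.null(raw$synthetic)) {
    syn <- raw$synthetic
    if (!is.null(syn$markers))
      syn$markers <- lapply(syn$markers, function(m) do.call(marker_spec, m))
    if (!is.null(syn$templates)) syn$templates <- as.list(syn$templates)
    args$synthetic <- do.call(synthetic_spec, syn)
  }
  if (!is.null(seed)) args$seed <- as.integer(seed)
  else if (!is.null(raw$seed)) args$seed <- as.integer(raw$seed)
  do.call(run_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  path
}

# analysis settings only: filesystem paths are omitted so that identical
# configurations produce byte-identical artifacts in any directory
.config_echo <- function(config) {
  list(
    exclusion = unclass(config$exclusion),
    negation = unclass(config$negation)[c("cues", "window", "terminators")],
    bayes = unclass(config$bayes),
    min_df = config$min_df, k_mut = config$k_mut, k_wt = config$k_wt,
    threshold = config$threshold, alternative = config$alternative,
    seed = config$seed,
    synthetic = if (is.null(config$synthetic)) NULL else {
      s <- unclass(config$synthetic)
      s$markers <- lapply(s$markers, unclass)
      s
    }
  )
}

.group_eval_record <- function(ev) {
  list(cohort = ev$label, n_terms = ev$n_terms,
       mean_own = ev$mean_own, mean_other = ev$mean_other,
       statistic = ev$wilcoxon$statistic, n_used = ev$wilcoxon$n_used,
       p_value = ev$wilcoxon$p_value, method = ev$wilcoxon$method,
       alternative = ev$wilcoxon$alternative)
}

#' Run the full term-mining pipeline
#'
#' Executes filter -> tokenize/stem/negation-tag -> document-frequency
#' table -> Bayes scoring -> ranking -> predictor selection -> group
#' evaluation, and writes five artifacts to `config$out_dir`:
#' `term_table.csv`, `term_scores.csv` (ranked, min_df-filtered),
#' `predictor_sets.json`, `group_evaluation.json` and
#' `run_summary.json`. Deterministic given the config (and seed, when the
#' corpus is synthetic). Any stage error aborts with the stage name and
#' removes partial outputs.
#'
#' @param config a [run_config()].
#' @param corpus optional pre-loaded `report_corpus`; when `NULL` the
#'   corpus is loaded from `config$manifest` / `config$reports_dir`.
#' @param quiet suppress stage log messages.
#' @return invisibly, a list of class `pipeline_result` with `summary`,
#'   `scores` (full scored table), `ranked`, `predictor_sets`,
#'   `evaluations` and `files`.
#' @export
run_pipeline <- function(config, corpus = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(config$out_dir,
                     c("term_table.csv", "term_scores.csv",
                       "predictor_sets.json", "group_evaluation.json",
                       "run_summary.json"))
  names(files) <- c("term_table", "term_scores", "predictor_sets",
                    "group_evaluation", "run_summary")
  ok <- FALSE
  on.exit(if (!ok) unlink(files))
  say <- function(...) if (!quiet) message(sprintf(...))

  corpus <- .stage("ingest", {
    if (is.null(corpus)) {
      if (is.null(config$manifest) || is.null(config$reports_dir))
        stop("no corpus supplied and no manifest/reports_dir configured")
      load_corpus(config$manifest, config$reports_dir)
    } else corpus
  })
  say("ingest: %d reports (%d MUTANT, %d WILDTYPE)",
      nrow(corpus$reports), corpus$n_mut, corpus$n_wt)

  filtered <- .stage("filter", filter_reports(corpus, config$exclusion,
                                              quiet = TRUE))
  excl_log <- attr(filtered, "exclusion_log")
  say("filter: %d -> %d reports", nrow(corpus$reports), nrow(filtered$reports))

  processed <- .stage("process", process_corpus(filtered, config$negation))
  say("process: %d distinct terms overall",
      length(unique(unlist(lapply(processed$term_sets, `[[`, "key"),
                           use.names = FALSE))))

  table <- .stage("table", build_term_table(processed$term_sets,
                                            processed$cohorts))
  scores <- .stage("score", score_all_terms(table, config$bayes))
  ranked <- .stage("rank", rank_terms(scores, min_df = config$min_df,
                                      metric = "abs_posterior_diff"))
  say("rank: %d of %d terms pass min_df = %d", nrow(ranked), nrow(scores),
      config$min_df)

  sets <- .stage("select", select_predictors(ranked, k_mut = config$k_mut,
                                             k_wt = config$k_wt,
                                             threshold = config$threshold))
  say("select: %d MUTANT, %d WILDTYPE predictor term(s)",
      sets$mutant$k, sets$wildtype$k)

  evals <- .stage("evaluate", {
    out <- list()
    for (nm in c("mutant", "wildtype"))
      if (sets[[nm]]$k > 0L)
        out[[nm]] <- evaluate_predictor_group(scores, sets[[nm]],
                                              alternative = config$alternative)
    out
  })

  summary <- list(
    tool = "radbayes", version = as.character(utils::packageVersion("radbayes")),
    reports = list(
      ingested = list(mutant = corpus$n_mut, wildtype = corpus$n_wt),
      analyzed = list(mutant = filtered$n_mut, wildtype = filtered$n_wt),
      excluded = nrow(corpus$reports) - nrow(filtered$reports),
      exclusion_log = excl_log
    ),
    vocabulary = processed$stats,
    top_terms = utils::head(ranked$display, 10L),
    predictor_sets = lapply(sets, function(s)
      list(cohort = s$cohort, k = s$k, terms = s$terms$display)),
    group_evaluations = lapply(evals, .group_eval_record),
    config = .config_echo(config)
  )

  .stage("write", {
    tbl <- as.data.frame(scores)
    tbl <- tbl[, c("display", "negated", "df_mut", "df_wt")]
    tbl$n_mut <- attr(scores, "n_mut")
    tbl$n_wt <- attr(scores, "n_wt")
    tbl$f_mut <- scores$f_mut
    tbl$f_wt <- scores$f_wt
    utils::write.csv(tbl, files["term_table"], row.names = FALSE)
    rk <- as.data.frame(ranked)
    rk$n_mut <- attr(scores, "n_mut")
    rk$n_wt <- attr(scores, "n_wt")
    cols <- c("display", "negated", "df_mut", "df_wt", "n_mut", "n_wt",
              "f_mut", "f_wt", "pct_diff", "p_mut", "p_wt")
    utils::write.csv(rk[, cols], files["term_scores"], row.names = FALSE)
    .write_json(lapply(sets, function(s) list(
      cohort = s$cohort, threshold = s$threshold, k = s$k,
      terms = s$terms[, c("display", "p_mut", "p_wt", "f_mut", "f_wt")]
    )), files["predictor_sets"])
    .write_json(lapply(evals, .group_eval_record), files["group_evaluation"])
    .write_json(summary, files["run_summary"])
  })
  ok <- TRUE
  invisible(structure(
    list(summary = summary, scores = scores, ranked = ranked,
         predictor_sets = sets, evaluations = evals, files = files),
    class = "pipeline_result"))
}

#' Generate a synthetic corpus, analyze it, and measure recovery
#'
#' Runs [generate_corpus()] on `config$synthetic`, feeds the corpus
#' through [run_pipeline()], and compares each planted marker's estimated
#' posterior against its analytic ground truth, writing
#' `ground_truth.json` and `recovery_report.json` (per-marker absolute
#' error) beside the pipeline artifacts.
#'
#' @param config a [run_config()] with a non-`NULL` `synthetic` spec.
#' @param quiet suppress stage log messages.
#' @return invisibly, list of class `simulation_result` with `result`
#'   (the `pipeline_result`), `ground_truth` and `recovery` (data.frame
#'   with `posterior_hat` and `abs_error` per marker).
#' @export
simulate_and_run <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$synthetic))
    stop("`config$synthetic` must be a synthetic_spec")
  gen <- .stage("simulate", generate_corpus(config$synthetic))
  res <- run_pipeline(config, corpus = gen$corpus, quiet = quiet)
  gt <- gen$ground_truth
  idx <- match(gt$key, res$scores$key)
  recovery <- data.frame(
    word = gt$word, key = gt$key,
    q_mut = gt$q_mut, q_wt = gt$q_wt,
    posterior = gt$posterior,
    posterior_hat = res$scores$p_mut[idx],
    stringsAsFactors = FALSE
  )
  recovery$abs_error <- abs(recovery$posterior_hat - recovery$posterior)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_json(gt, file.path(config$out_dir, "ground_truth.json"))
  .write_json(list(markers = recovery,
                   max_abs_error = max(recovery$abs_error, na.rm = TRUE)),
              file.path(config$out_dir, "recovery_report.json"))
  if (!quiet)
    message(sprintf("recovery: max |posterior error| = %.4f",
                    max(recovery$abs_error, na.rm = TRUE)))
  invisible(structure(list(result = res, ground_truth = gt,
                           recovery = recovery),
                      class = "simulation_result"))
}

#' Demo configuration
#'
#' A ready-to-run [run_config()] over the default synthetic study
#' conditions: 2,000 reports per cohort, the [default_markers()] panel,
#' 500 background words, add-one smoothing with empirical priors.
#'
#' @param out_dir output directory.
#' @param seed RNG seed for the generator.
#' @return a `run_config`.
#' @export
demo_config <- function(out_dir = tempfile("radbayes_demo_"), seed = 101L) {
  run_config(out_dir = out_dir,
             synthetic = synthetic_spec(seed = as.integer(seed)),
             seed = as.integer(seed))
}
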