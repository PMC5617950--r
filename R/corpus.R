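#' @keywords internal
.COHORTS <- c("MUTANT", "WILDTYPE")

#' Construct a labelled report corpus
#'
#' A corpus holds one free-text radiology report per row together with its
#' patient and cohort label (`MUTANT` or `WILDTYPE`). Reports, not
#' patients, are the counting unit of the document-frequency analysis;
#' `patient_id` is retained for the cohort-consistency check (all of a
#' patient's reports must carry the same label).
#'
#' @param reports data.frame with character columns `report_id`,
#'   `patient_id`, `cohort`, `text`.
#' @return an object of class `report_corpus`: list with `reports` (the
#'   validated data.frame) and cohort counts `n_mut`, `n_wt`.
#' @export
report_corpus <- function(reports) {
  req <- c("report_id", "patient_id", "cohort", "text")
  missing_cols <- setdiff(req, names(reports))
  if (length(missing_cols))
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  reports <- as.data.frame(reports[, req], stringsAsFactors = FALSE)
  for (cl in req) reports[[cl]] <- as.character(reports[[cl]])
  dup <- reports$report_id[duplicated(reports$report_id)]
  if (length(dup))
    stop("duplicate report_id: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(reports$cohort), .COHORTS)
  if (length(bad))
    stop("unknown cohort label: ", paste(bad, collapse = ", "),
         " (expected MUTANT or WILDTYPE)")
  if (nrow(reports)) {
    mixed <- tapply(reports$cohort, reports$patient_id,
                    function(x) length(unique(x)) > 1L)
    if (any(mixed))
      stop("patient(s) with reports in both cohorts: ",
           paste(names(mixed)[mixed], collapse = ", "))
  }
  rownames(reports) <- NULL
  structure(
    list(reports = reports,
         n_mut = sum(reports$cohort == "MUTANT"),
         n_wt = sum(reports$cohort == "WILDTYPE")),
    class = "report_corpus"
  )
}

#' @export
print.report_corpus <- function(x, ...) {
  cat(sprintf("<report_corpus> %d reports (%d MUTANT, %d WILDTYPE), %d patients\n",
              nrow(x$reports), x$n_mut, x$n_wt,
              length(unique(x$reports$patient_id))))
  invisible(x)
}

# read a whole file as UTF-8, replacing undecodable bytes
.read_text_utf8 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  out <- iconv(txt, from = "UTF-8", to = "UTF-8", sub = "�")
  if (is.na(out)) out <- iconv(txt, from = "latin1", to = "UTF-8")
  out
}

.sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Load a report corpus from a manifest and a directory of text files
#'
#' The manifest is a header-bearing comma- or tab-separated table with
#' columns `report_id`, `patient_id`, `cohort`; the delimiter is sniffed
#' from the header line. Each report's text is read from
#' `<reports_dir>/<report_id>.txt` as UTF-8 with replacement of
#' undecodable bytes.
#'
#' @param manifest_path path to the manifest file.
#' @param reports_dir directory containing one `<report_id>.txt` per row.
#' @return a [report_corpus()].
#' @export
load_corpus <- function(manifest_path, reports_dir) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  if (!dir.exists(reports_dir)) stop("reports directory not found: ", reports_dir)
  delim <- .sniff_delim(manifest_path)
  man <- utils::read.table(manifest_path, header = TRUE, sep = delim,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  req <- c("report_id", "patient_id", "cohort")
  missing_cols <- setdiff(req, names(man))
  if (length(missing_cols))
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  dup <- man$report_id[duplicated(man$report_id)]
  if (length(dup))
    stop("duplicate report_id: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(man$cohort), .COHORTS)
  if (length(bad))
    stop("unknown cohort label: ", paste(bad, collapse = ", "))
  paths <- file.path(reports_dir, paste0(man$report_id, ".txt"))
  absent <- !file.exists(paths)
  if (any(absent))
    stop("report file not found for report_id: ",
         paste(man$report_id[absent], collapse = ", "))
  man$text <- vapply(paths, .read_text_utf8, character(1), USE.NAMES = FALSE)
  report_corpus(man)
}

#' Write a corpus back to a manifest plus text files
#'
#' Emits the same layout [load_corpus()] reads: `manifest.csv` (columns
#' `report_id`, `patient_id`, `cohort`) and one `<report_id>.txt` per
#' report, UTF-8, byte-exact (so load -> write -> load round-trips).
#'
#' @param corpus a `report_corpus`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "report_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- corpus$reports[, c("report_id", "patient_id", "cohort")]
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest_path, row.names = FALSE, quote = FALSE)
  for (i in seq_len(nrow(corpus$reports))) {
    path <- file.path(dir, paste0(corpus$reports$report_id[i], ".txt"))
    con <- file(path, open = "wb")
    writeBin(charToRaw(enc2utf8(corpus$reports$text[i])), con)
    close(con)
  }
  invisible(manifest_path)
}

#' Exclusion rules for clinically irrelevant reports
#'
#' Reports whose text contains any of the case-insensitive substring
#' patterns (billing statements, scheduling notes, ...) or whose text is
#' shorter than `min_chars` characters are excluded from analysis.
#'
#' @param patterns character vector of case-insensitive substrings.
#' @param min_chars non-negative integer; minimum report length in
#'   characters (guards against empty/placeholder documents).
#' @return an object of class `exclusion_rules`.
#' @export
exclusion_rules <- function(patterns = c("billing", "charges", "scheduling"),
                            min_chars = 50L) {
  if (length(patterns) && (!is.character(patterns) || any(!nzchar(patterns))))
    stop("`patterns` must be non-empty strings")
  min_chars <- as.integer(min_chars)
  if (is.na(min_chars) || min_chars < 0L) stop("`min_chars` must be >= 0")
  structure(list(patterns = patterns, min_chars = min_chars),
            class = "exclusion_rules")
}

#' Filter clinically irrelevant reports from a corpus
#'
#' Returns a new corpus excluding every report matching an exclusion
#' pattern (case-insensitive substring) or shorter than the minimum
#' length. Cohort counts are recomputed. The number excluded per rule is
#' attached as attribute `"exclusion_log"` and reported via `message()`.
#' An empty result corpus is legal. The operation is idempotent.
#'
#' @param corpus a `report_corpus`.
#' @param rules an [exclusion_rules()].
#' @param quiet suppress the per-rule messages.
#' @return the filtered `report_corpus` with an `exclusion_log` attribute
#'   (data.frame `rule`, `n_excluded`).
#' @export
filter_reports <- function(corpus, rules = exclusion_rules(), quiet = FALSE) {
  stopifnot(inherits(corpus, "report_corpus"), inherits(rules, "exclusion_rules"))
  txt <- tolower(corpus$reports$text)
  hit <- matrix(FALSE, nrow = length(txt), ncol = length(rules$patterns))
  for (j in seq_along(rules$patterns))
    hit[, j] <- grepl(tolower(rules$patterns[j]), txt, fixed = TRUE)
  short <- nchar(corpus$reports$text) < rules$min_chars
  drop <- short | (if (ncol(hit)) rowSums(hit) > 0L else FALSE)
  log <- data.frame(
    rule = c(rules$patterns, sprintf("min_chars<%d", rules$min_chars)),
    n_excluded = c(if (ncol(hit)) colSums(hit) else integer(0), sum(short)),
    stringsAsFactors = FALSE
  )
  if (!quiet) {
    for (i in seq_len(nrow(log)))
      message(sprintf("filter_reports: rule '%s' matched %d report(s)",
                      log$rule[i], log$n_excluded[i]))
    message(sprintf("filter_reports: excluded %d of %d reports",
                    sum(drop), length(drop)))
  }
  out <- report_corpus(corpus$reports[!drop, , drop = FALSE])
  attr(out, "exclusion_log") <- log
  out
}
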