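#' Read a CLD table from TSV/CSV
#'
#' Reads a two-column (or mapped) chain-length-distribution export as
#' produced by FACE/HPAEC/SEC software.  DP must be strictly increasing
#' positive integers (duplicates rejected); rows with DP < 1 are dropped
#' with a warning; gaps in DP are allowed and recorded in the `gaps`
#' attribute.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"csv"` (default guessed from the extension).
#' @param dp_col,abundance_col column names (or 1-based indices) holding DP
#'   and abundance.
#' @return A [cld()] with attributes `gaps` (missing DP values inside the
#'   observed span) and `source` (the path).
#' @export
read_cld_table <- function(path, dialect = NULL, dp_col = 1,
                           abundance_col = 2) {
  if (!file.exists(path))
    abort_validation(sprintf("file not found: %s", path))
  if (is.null(dialect))
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  dialect <- match.arg(dialect, c("tsv", "csv"))
  df <- utils::read.table(path, header = TRUE,
                          sep = if (dialect == "tsv") "\t" else ",",
                          comment.char = "#", check.names = FALSE)
  if (nrow(df) == 0) abort_validation("empty table")
  pick <- function(col) {
    if (is.numeric(col)) {
      if (col > ncol(df)) abort_validation("column index out of range")
      df[[col]]
    } else {
      if (!col %in% names(df))
        abort_validation(sprintf("column '%s' not found", col))
      df[[col]]
    }
  }
  dp <- pick(dp_col)
  ab <- pick(abundance_col)
  if (!is.numeric(dp) || !is.numeric(ab))
    abort_validation("DP and abundance columns must be numeric")
  bad_dp <- which(dp < 1 | dp != round(dp))
  if (length(bad_dp) > 0) {
    warning(sprintf("dropping %d row(s) with DP < 1 or non-integer DP (rows %s)",
                    length(bad_dp), paste(bad_dp, collapse = ", ")))
    dp <- dp[-bad_dp]; ab <- ab[-bad_dp]
  }
  if (length(dp) == 0) abort_validation("no valid rows after DP filtering")
  neg <- which(ab < 0)
  if (length(neg) > 0)
    abort_validation(sprintf("negative abundance in row %s",
                             paste(neg, collapse = ", ")))
  if (any(diff(dp) <= 0))
    abort_validation("DP column must be strictly increasing (no duplicates)")
  out <- cld(dp, ab, norm = "raw")
  attr(out, "gaps") <- setdiff(seq(min(dp), max(dp)), dp)
  attr(out, "source") <- path
  out
}

#' Write a CLD table
#'
#' @param x a [cld()].
#' @param path output file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_cld_table <- function(x, path, dialect = c("tsv", "csv")) {
  stopifnot(inherits(x, "cld"))
  dialect <- match.arg(dialect)
  utils::write.table(as.data.frame(x), path, sep = if (dialect == "tsv")
    "\t" else ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fit result
#'
#' Writes the full parameter report as JSON and the per-DP decomposition
#' (observed, SL model, TL model, composed) as TSV.
#'
#' @param fit a `fit_result` from [fit_cld()].
#' @param json_path,tsv_path output paths (`NULL` skips either).
#' @param seed optional seed to embed in the report.
#' @return Invisibly, the report list written to JSON.
#' @export
write_fit_result <- function(fit, json_path = NULL, tsv_path = NULL,
                             seed = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  set_rec <- function(s) list(label = s$label, beta = s$beta,
                              x0 = s$constraints$x0,
                              xmin = s$constraints$xmin)
  rep <- list(
    package = "amylocld",
    version = as.character(utils::packageVersion("amylocld")),
    seed = seed,
    model = fit$cfg$model,
    objective_scale = fit$cfg$objective_scale,
    sl_range = fit$sl$range,
    tl_start = fit$tl_start_used,
    tl_end = fit$cfg$tl_end,
    xmax = fit$cfg$xmax,
    sl = list(sets = lapply(fit$sl$sets, set_rec),
              gamma = if (inherits(fit$sl, "range_fit")) fit$sl$gamma
                      else fit$sl$gammas,
              sse = fit$sse_sl),
    h_ii_over_i = fit$h_ii_over_i,
    tl = if (is.null(fit$tl)) NULL else
      list(sets = lapply(fit$tl$sets, set_rec), gamma = fit$tl$gamma,
           sse = fit$sse_tl),
    h_iii_over_i = fit$h_iii_over_i,
    parameters = as.list(fit_parameters(fit)))
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(tsv_path))
    utils::write.table(fit$residuals, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(rep)
}
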