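#' Write pipeline results to a directory
#'
#' Emits deterministic plain-text artifacts: the tidy per-cell CSV, a
#' per-alpha summary CSV and JSON summary, and (optionally) base-graphics
#' figures. Re-running produces byte-identical CSVs.
#'
#' @param x a \code{performance_curve}, \code{null_comparison} or
#'   \code{stratified_readout}.
#' @param out_dir output directory (created if needed).
#' @param figures also write PNG figures.
#' @param ... unused.
#' @return invisibly, the vector of files written.
#' @export
report <- function(x, out_dir, figures = FALSE, ...) UseMethod("report")

write_csv_det <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  path
}

ensure_dir <- function(out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_connrc("cannot create output directory %s", out_dir,
                class = "connrc_io_error")
}

#' @export
report.performance_curve <- function(x, out_dir, figures = FALSE, ...) {
  ensure_dir(out_dir)
  files <- c(write_csv_det(as.data.frame(x), file.path(out_dir, "cells.csv")),
             write_csv_det(summary(x), file.path(out_dir, "summary.csv")))
  jpath <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary(x), jpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  files <- c(files, jpath)
  if (figures) {
    fpath <- file.path(out_dir, "performance_curve.png")
    grDevices::png(fpath, width = 800, height = 600)
    plot(x)
    grDevices::dev.off()
    files <- c(files, fpath)
  }
  invisible(files)
}

#' @export
report.null_comparison <- function(x, out_dir, figures = FALSE, ...) {
  ensure_dir(out_dir)
  files <- write_csv_det(
    data.frame(replicate = seq_along(x$null_values), value = x$null_values),
    file.path(out_dir, "null_values.csv"))
  jpath <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(list(metric = x$metric, statistic = x$statistic,
                            alpha_at = x$alpha_at,
                            alternative = x$alternative,
                            empirical_value = x$empirical_value,
                            null_mean = mean(x$null_values),
                            n_nulls = length(x$null_values),
                            p_value = x$p_value),
                       jpath, auto_unbox = TRUE, digits = NA)
  files <- c(files, jpath,
             report(x$empirical_curve, file.path(out_dir, "empirical"),
                    figures = figures))
  if (figures) {
    fpath <- file.path(out_dir, "null_histogram.png")
    grDevices::png(fpath, width = 800, height = 600)
    plot(x)
    grDevices::dev.off()
    files <- c(files, fpath)
  }
  invisible(files)
}

#' @export
report.stratified_readout <- function(x, out_dir, figures = FALSE, ...) {
  ensure_dir(out_dir)
  files <- write_csv_det(x$table, file.path(out_dir, "module_cells.csv"))
  jpath <- file.path(out_dir, "anova.json")
  a <- x$anova
  a$F <- if (is.finite(a$F)) a$F else "Inf"
  jsonlite::write_json(a, jpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, jpath))
}
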