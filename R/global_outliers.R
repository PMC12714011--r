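# Tissue-wide baseline: median +/- n MAD thresholds over all spots, and the
# global-vs-local comparison summaries.

#' Global median ± n·MAD outlier flags
#'
#' The conventional tissue-wide rule: a spot is flagged when its metric
#' value falls beyond `n_mads` median absolute deviations from the global
#' median (strict inequalities). The MAD is unscaled by default; set
#' `mad_scaled = TRUE` to multiply it by the 1.4826 normal-consistency
#' constant, as some upstream ecosystems do.
#'
#' A consequence worth knowing: for strongly right-skewed non-negative
#' metrics (raw total counts, typically), the lower threshold
#' `median - n_mads * MAD` can fall below every observed value, so the
#' lower tail flags nothing — one reason to analyze log totals instead.
#'
#' @param values finite numeric vector (all spots of a tissue)
#' @param direction `"lower"`, `"higher"` or `"both"`
#' @param n_mads positive number of MADs (default 3)
#' @param mad_scaled multiply MAD by 1.4826 (default `FALSE`)
#' @return logical vector of flags
#' @examples
#' global_mad_outliers(c(1:9, 100), direction = "higher")
#' @export
global_mad_outliers <- function(values, direction = "lower", n_mads = 3,
                                mad_scaled = FALSE) {
  direction <- match_direction(direction)
  check_scalar_number(n_mads, "n_mads", lower = 0, strict = TRUE)
  if (length(values) == 0L) {
    stop_value_error("global_mad_outliers() needs a non-empty vector")
  }
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop_value_error("global_mad_outliers() needs finite numeric values")
  }
  med <- stats::median(values)
  m <- stats::median(abs(values - med))
  if (mad_scaled) m <- m * 1.4826
  lo <- values < med - n_mads * m
  hi <- values > med + n_mads * m
  switch(direction, lower = lo, higher = hi, both = lo | hi)
}

#' Default metric rows for the global-vs-local comparison
#'
#' The four standard rows: raw total counts (lower tail), log total counts
#' (lower; materialized as an explicit `sum_log` column so its z/flag
#' columns do not collide with the raw row's), detected genes (lower,
#' scored on the log scale), and mitochondrial percentage (higher tail,
#' raw).
#'
#' @return data.frame with columns `metric`, `direction`, `log`
#' @export
qc_comparison_metrics <- function() {
  data.frame(
    metric = c("sum", "sum_log", "detected", "subsets_mito_percent"),
    direction = c("lower", "lower", "lower", "higher"),
    log = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Compare global and local outlier calls
#'
#' Runs, per metric row, both the tissue-wide median ± n·MAD rule and the
#' neighbourhood-aware local call, and summarizes where they disagree:
#'
#' * a per-metric table of flagged counts and percentages for both methods,
#'   plus an `any_metric` union row;
#' * two per-spot discrepancy masks — `global_only` (flagged by the global
#'   rule on some metric but by no local call) and `local_only` — also
#'   added to `obs` as `global_only_outliers` / `local_only_outliers`;
#' * per metric × method × flag-group summaries (n, median, quartiles) of
#'   the local z-scores, the numbers behind violin-style stratification
#'   plots.
#'
#' A row with `metric = "sum_log"` is materialized on demand via
#' [log1p_column()]. The global rule is always applied to the metric
#' column's own values; the local call log-transforms when the row's `log`
#' is `TRUE`.
#'
#' @param ds a `SpatialQCDataset` with QC metric columns (see
#'   [compute_qc_metrics()])
#' @param metrics data.frame like [qc_comparison_metrics()]
#' @param n_mads,mad_scaled global threshold parameters
#' @param n_neighbors,cutoff,sample_key,workers local call parameters
#' @return an object of class `qc_comparison`: list with `table`,
#'   `global_only`, `local_only`, `z_summary`, and the updated `dataset`
#' @export
compare_global_local <- function(ds, metrics = qc_comparison_metrics(),
                                 n_mads = 3, mad_scaled = FALSE,
                                 n_neighbors = 36L, cutoff = 3.0,
                                 sample_key = "sample_id", workers = 1L) {
  stopifnot(inherits(ds, "SpatialQCDataset"))
  metrics <- as.data.frame(metrics)
  if (!all(c("metric", "direction") %in% colnames(metrics))) {
    stop_value_error("`metrics` needs columns metric and direction")
  }
  if (is.null(metrics$log)) metrics$log <- FALSE

  if ("sum_log" %in% metrics$metric && !"sum_log" %in% colnames(ds$obs) &&
      "sum" %in% colnames(ds$obs)) {
    ds <- log1p_column(ds, "sum")
  }
  missing <- setdiff(metrics$metric, colnames(ds$obs))
  if (length(missing)) {
    stop_key_error(sprintf("metric column(s) not found in obs: %s",
                           paste(missing, collapse = ", ")))
  }

  n <- n_spots(ds)
  global_flags <- matrix(FALSE, n, nrow(metrics))
  local_flags <- matrix(FALSE, n, nrow(metrics))
  z_summary <- NULL
  rows <- NULL

  for (r in seq_len(nrow(metrics))) {
    metric <- metrics$metric[r]
    direction <- match_direction(metrics$direction[r])
    gflag <- global_mad_outliers(ds$obs[[metric]], direction = direction,
                                 n_mads = n_mads, mad_scaled = mad_scaled)
    ds <- local_outliers(ds, metric = metric, direction = direction,
                         n_neighbors = n_neighbors, sample_key = sample_key,
                         log = isTRUE(metrics$log[r]), cutoff = cutoff,
                         workers = workers)
    schema <- obs_column_schema(metric)
    lflag <- ds$obs[[schema[["flag"]]]]
    z <- ds$obs[[schema[["z"]]]]
    global_flags[, r] <- gflag
    local_flags[, r] <- lflag
    rows <- rbind(rows, data.frame(
      metric = metric, direction = direction, n_spots = n,
      global_n = sum(gflag), global_pct = 100 * mean(gflag),
      local_n = sum(lflag), local_pct = 100 * mean(lflag),
      stringsAsFactors = FALSE))
    for (method in c("global", "local")) {
      f <- if (method == "global") gflag else lflag
      for (grp in c(FALSE, TRUE)) {
        zz <- z[f == grp]
        z_summary <- rbind(z_summary, data.frame(
          metric = metric, method = method, flagged = grp,
          n = length(zz),
          z_median = if (length(zz)) stats::median(zz) else NA_real_,
          z_q1 = if (length(zz)) unname(stats::quantile(zz, 0.25)) else NA_real_,
          z_q3 = if (length(zz)) unname(stats::quantile(zz, 0.75)) else NA_real_,
          stringsAsFactors = FALSE))
      }
    }
  }

  any_global <- rowSums(global_flags) > 0
  any_local <- rowSums(local_flags) > 0
  rows <- rbind(rows, data.frame(
    metric = "any_metric", direction = "union", n_spots = n,
    global_n = sum(any_global), global_pct = 100 * mean(any_global),
    local_n = sum(any_local), local_pct = 100 * mean(any_local),
    stringsAsFactors = FALSE))

  global_only <- any_global & !any_local
  local_only <- any_local & !any_global
  ds <- set_obs_column(ds, "global_only_outliers", global_only)
  ds <- set_obs_column(ds, "local_only_outliers", local_only)

  structure(list(table = rows, global_only = global_only,
                 local_only = local_only, z_summary = z_summary,
                 dataset = ds),
            class = "qc_comparison")
}

#' @method print qc_comparison
#' @export
print.qc_comparison <- function(x, ...) {
  cat("Global vs local QC outlier comparison\n")
  tab <- x$table
  tab$global_pct <- sprintf("%.2f%%", tab$global_pct)
  tab$local_pct <- sprintf("%.2f%%", tab$local_pct)
  print(tab, row.names = FALSE)
  cat(sprintf("discrepancy: %d global-only, %d local-only spot(s)\n",
              sum(x$global_only), sum(x$local_only)))
  invisible(x)
}

#' Export a comparison table to CSV
#' @param cmp a `qc_comparison`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_comparison_table <- function(cmp, path) {
  stopifnot(inherits(cmp, "qc_comparison"))
  ok <- tryCatch({ utils::write.csv(cmp$table, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io_error(sprintf("cannot write comparison table to '%s'", path))
  invisible(path)
}
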