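# Spatial QC plots: metric-coloured spot maps with outlier highlighting,
# single figures or multipage PDF reports (one page per sample).

metric_colors <- function(values, colors) {
  if (length(colors) < 2L) {
    stop_value_error("`colors` needs at least two anchors")
  }
  rng <- range(values)
  scaled <- if (diff(rng) > 0) (values - rng[1L]) / diff(rng) else
    rep(0, length(values))
  ramp <- grDevices::colorRamp(colors)
  m <- ramp(scaled)
  grDevices::rgb(m[, 1L], m[, 2L], m[, 3L], maxColorValue = 255)
}

plot_sample_panel <- function(ds, sample, metric, outlier_col, colors,
                              point_size) {
  sel <- which(resolve_sample_ids(ds, ds$sample_name) == sample)
  x <- ds$coords[sel, 1L]
  y <- ds$coords[sel, 2L]
  vals <- ds$obs[[metric]][sel]
  cols <- metric_colors(vals, colors)
  # inverted y-axis: conventional tissue orientation (origin top-left)
  plot(x, y, col = cols, pch = 16, cex = point_size / 2, asp = 1,
       ylim = rev(range(y)), xlab = "x", ylab = "y",
       main = sprintf("%s - %s", sample, metric))
  if (!is.null(outlier_col)) {
    flagged <- which(as.logical(ds$obs[[outlier_col]][sel]))
    if (length(flagged)) {
      graphics::points(x[flagged], y[flagged], col = "red", pch = 1,
                       cex = point_size / 2 + 0.4, lwd = 1.5)
    }
  }
}

check_plot_inputs <- function(ds, metric, outlier_col, point_size) {
  stopifnot(inherits(ds, "SpatialQCDataset"))
  check_scalar_number(point_size, "point_size", lower = 0, strict = TRUE)
  if (!metric %in% colnames(ds$obs)) {
    stop_key_error(sprintf("metric column '%s' not found in obs", metric))
  }
  if (!is.null(outlier_col) && !outlier_col %in% colnames(ds$obs)) {
    stop_key_error(sprintf("outlier column '%s' not found in obs", outlier_col))
  }
}

#' Spatial plot of a QC metric with outliers ringed
#'
#' Scatter of one sample's spots at their spatial coordinates, coloured by
#' a continuous ramp over the metric (default white-to-black, so
#' zero-count spots sit at the white floor of the ramp), equal aspect
#' ratio, inverted y-axis (conventional tissue orientation), flagged
#' outliers ringed in red.
#'
#' @param ds a `SpatialQCDataset`
#' @param sample sample label to plot
#' @param metric obs column providing the colour scale
#' @param outlier_col logical obs column of flags (or `NULL` for none)
#' @param colors two or more colour anchors for the ramp
#' @param point_size point size (plotting `cex` is `point_size / 2`)
#' @param file optional PNG path; when given the figure is written there
#'   instead of the active device
#' @param width,height device size in inches when `file` is used
#' @return `file` (or `NULL`), invisibly
#' @export
plot_qc_metric <- function(ds, sample, metric, outlier_col = NULL,
                           colors = c("white", "black"), point_size = 2.0,
                           file = NULL, width = 5, height = 5) {
  check_plot_inputs(ds, metric, outlier_col, point_size)
  samples <- unique(resolve_sample_ids(ds, ds$sample_name))
  if (!sample %in% samples) {
    stop_value_error(sprintf(
      "sample '%s' not present (available: %s)", sample,
      paste(samples, collapse = ", ")))
  }
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height, units = "in",
                   res = 150)
    on.exit(grDevices::dev.off())
  }
  plot_sample_panel(ds, sample, metric, outlier_col, colors, point_size)
  invisible(file)
}

#' Multipage PDF QC report
#'
#' One page per sample, each page a [plot_qc_metric()]-style panel of the
#' chosen metric with outliers ringed in red.
#'
#' @param ds a `SpatialQCDataset`
#' @param metric obs column providing the colour scale
#' @param outlier_col logical obs column of flags (or `NULL`)
#' @param fname output PDF path
#' @param colors,point_size style, as in [plot_qc_metric()]
#' @param width,height page size in inches (default 5 x 5)
#' @return `fname`, invisibly
#' @export
plot_qc_pdf <- function(ds, metric, outlier_col = NULL, fname,
                        colors = c("white", "black"), point_size = 2.0,
                        width = 5, height = 5) {
  check_plot_inputs(ds, metric, outlier_col, point_size)
  ok <- tryCatch({
    grDevices::pdf(fname, width = width, height = height, onefile = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io_error(sprintf("cannot open PDF device at '%s'", fname))
  on.exit(grDevices::dev.off())
  for (sample in unique(resolve_sample_ids(ds, ds$sample_name))) {
    plot_sample_panel(ds, sample, metric, outlier_col, colors, point_size)
  }
  invisible(fname)
}
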