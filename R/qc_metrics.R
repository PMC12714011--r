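#' Compute standard per-spot QC metrics
#'
#' Adds the three conventional spot-level QC metrics to `obs`:
#'
#' * `sum` — total UMI counts (library size) of the spot,
#' * `detected` — number of genes with a nonzero count,
#' * `subsets_mito_percent` — percentage of counts on mitochondrially
#'   encoded genes, identified by a gene-name prefix (default `"MT-"`,
#'   case-sensitive). Spots with zero total counts get 0 (not `NaN`):
#'   downstream robust z-scores require finite inputs, and 0 is the neutral
#'   value consistent with the degenerate-neighbourhood rule.
#'
#' Existing columns with these names are overwritten with a warning.
#'
#' @param ds a `SpatialQCDataset`
#' @param mito_prefix gene-name prefix marking mitochondrial genes
#' @return the dataset with the three obs columns added
#' @examples
#' ds <- generate_tissue(synthetic_tissue_spec(n_rows = 8, n_cols = 8,
#'                                             seed = 1))$dataset
#' ds <- compute_qc_metrics(ds)
#' head(ds$obs)
#' @export
compute_qc_metrics <- function(ds, mito_prefix = "MT-") {
  stopifnot(inherits(ds, "SpatialQCDataset"))
  clobbered <- intersect(c("sum", "detected", "subsets_mito_percent"),
                         colnames(ds$obs))
  if (length(clobbered)) {
    warning(sprintf("overwriting existing obs column(s): %s",
                    paste(clobbered, collapse = ", ")), call. = FALSE)
  }
  total <- Matrix::rowSums(ds$counts)
  detected <- Matrix::rowSums(ds$counts > 0)
  is_mito <- startsWith(ds$gene_names, mito_prefix)
  mito <- if (any(is_mito)) {
    Matrix::rowSums(ds$counts[, is_mito, drop = FALSE])
  } else rep(0, n_spots(ds))
  pct <- ifelse(total > 0, 100 * mito / total, 0)

  ds <- set_obs_column(ds, "sum", as.numeric(total))
  ds <- set_obs_column(ds, "detected", as.numeric(detected))
  ds <- set_obs_column(ds, "subsets_mito_percent", as.numeric(pct))
  ds
}

#' Add a log(1+x) column for a QC metric
#'
#' Writes natural `log(1 + x)` of `obs[[metric]]` into `"{metric}_log"`,
#' damping the heavy right tail of count metrics before robust scoring. If
#' the log column already exists it is left untouched, so a preprocessing
#' pipeline that ran earlier keeps authority over the values.
#'
#' @param ds a `SpatialQCDataset`
#' @param metric name of an existing obs column (finite values, all >= -1)
#' @return the dataset, with the log column present
#' @export
log1p_column <- function(ds, metric) {
  schema <- obs_column_schema(metric)
  if (!metric %in% colnames(ds$obs)) {
    stop_key_error(sprintf("metric column '%s' not found in obs", metric))
  }
  if (schema[["log"]] %in% colnames(ds$obs)) {
    return(ds)
  }
  x <- ds$obs[[metric]]
  if (!is.numeric(x) || !all(is.finite(x)) || any(x < -1)) {
    stop_value_error(sprintf(
      "metric column '%s' must be finite and >= -1 for log(1+x)", metric))
  }
  set_obs_column(ds, schema[["log"]], log1p(x))
}
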