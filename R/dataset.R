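#' Construct a spatial QC dataset
#'
#' The single container every spotscreen stage operates on: a sparse
#' spots-by-genes count matrix, 2D spatial coordinates, per-spot sample
#' labels, and a per-spot annotation table (`obs`) that accumulates QC
#' metric, z-score and outlier-flag columns. All components are row-aligned:
#' row i of `counts`, `coords`, `sample_ids` and `obs` refers to
#' `spot_ids[i]`, and adding columns to `obs` never reorders rows.
#'
#' @param counts spots-by-genes count matrix (coerced to a sparse
#'   `dgCMatrix`); non-negative.
#' @param coords numeric matrix/data.frame with one row per spot and two
#'   columns of finite spatial coordinates, in the units of the source
#'   platform (pixels, or array rows/cols, or lattice units).
#' @param spot_ids unique character spot identifiers (barcodes). Defaults to
#'   rownames of `counts` or `spot_1..n`.
#' @param gene_ids,gene_names character gene identifiers/symbols; default to
#'   colnames of `counts`. `gene_names` falls back to `gene_ids`.
#' @param sample_ids character vector of per-spot sample labels, or a single
#'   label recycled to all spots, or `NULL` when unknown (metric-only
#'   workflows still load; [local_outliers()] will then demand a sample
#'   column in `obs`).
#' @param obs per-spot annotation `data.frame` (or `NULL` for empty).
#' @param coord_name,sample_name names under which the coordinate slot and
#'   sample column are known (defaults `"spatial"` and `"sample_id"`),
#'   retained so keyed lookups in downstream calls can be validated.
#'
#' @return An object of class `SpatialQCDataset`.
#' @examples
#' counts <- matrix(rpois(30, 5), nrow = 6,
#'                  dimnames = list(paste0("s", 1:6), paste0("g", 1:5)))
#' ds <- spatial_qc_dataset(counts, coords = cbind(x = 1:6, y = rep(1, 6)),
#'                          sample_ids = "A")
#' ds
#' @export
spatial_qc_dataset <- function(counts, coords, spot_ids = NULL,
                               gene_ids = NULL, gene_names = NULL,
                               sample_ids = NULL, obs = NULL,
                               coord_name = "spatial",
                               sample_name = "sample_id") {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  n_spots <- nrow(counts)
  n_genes <- ncol(counts)
  if (any(counts@x < 0)) stop_value_error("counts must be non-negative")

  if (is.null(spot_ids)) spot_ids <- rownames(counts)
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(n_spots))
  spot_ids <- as.character(spot_ids)
  if (length(spot_ids) != n_spots) {
    stop_value_error("spot_ids length must equal nrow(counts)")
  }
  if (anyDuplicated(spot_ids)) stop_value_error("spot_ids must be unique")

  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(n_genes))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != n_genes) {
    stop_value_error("gene_ids length must equal ncol(counts)")
  }
  if (is.null(gene_names)) gene_names <- gene_ids
  gene_names <- as.character(gene_names)
  if (length(gene_names) != n_genes) {
    stop_value_error("gene_names length must equal ncol(counts)")
  }

  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != n_spots || ncol(coords) != 2L) {
    stop_value_error("coords must be an n_spots x 2 matrix")
  }
  if (!all(is.finite(coords))) stop_value_error("coords must be finite")
  colnames(coords) <- c("x", "y")
  rownames(coords) <- spot_ids

  if (!is.null(sample_ids)) {
    sample_ids <- as.character(sample_ids)
    if (length(sample_ids) == 1L) sample_ids <- rep(sample_ids, n_spots)
    if (length(sample_ids) != n_spots) {
      stop_value_error("sample_ids must have one label per spot")
    }
  }

  if (is.null(obs)) {
    obs <- data.frame(row.names = spot_ids)
  } else {
    obs <- as.data.frame(obs)
    if (nrow(obs) != n_spots) {
      stop_value_error("obs must have one row per spot")
    }
    rownames(obs) <- spot_ids
  }

  dimnames(counts) <- list(spot_ids, gene_ids)
  structure(
    list(counts = counts, spot_ids = spot_ids,
         gene_ids = gene_ids, gene_names = gene_names,
         coords = coords, sample_ids = sample_ids, obs = obs,
         coord_name = coord_name, sample_name = sample_name),
    class = "SpatialQCDataset")
}

#' Number of spots / genes in a dataset
#' @param ds a `SpatialQCDataset`
#' @return integer count
#' @export
n_spots <- function(ds) length(ds$spot_ids)

#' @rdname n_spots
#' @export
n_genes <- function(ds) length(ds$gene_ids)

#' @export
dim.SpatialQCDataset <- function(x) c(n_spots(x), n_genes(x))

#' @method print SpatialQCDataset
#' @export
print.SpatialQCDataset <- function(x, ...) {
  ns <- if (is.null(x$sample_ids)) "<none>" else
    paste(unique(x$sample_ids), collapse = ", ")
  cat(sprintf("SpatialQCDataset: %d spots x %d genes\n", n_spots(x), n_genes(x)))
  cat(sprintf("  samples: %s\n", ns))
  cat(sprintf("  obs columns: %s\n",
              if (ncol(x$obs)) paste(colnames(x$obs), collapse = ", ") else "<none>"))
  invisible(x)
}

#' @export
`[.SpatialQCDataset` <- function(x, i, ...) {
  idx <- seq_len(n_spots(x))[i]
  spatial_qc_dataset(
    counts = x$counts[idx, , drop = FALSE],
    coords = x$coords[idx, , drop = FALSE],
    spot_ids = x$spot_ids[idx],
    gene_ids = x$gene_ids, gene_names = x$gene_names,
    sample_ids = if (is.null(x$sample_ids)) NULL else x$sample_ids[idx],
    obs = x$obs[idx, , drop = FALSE],
    coord_name = x$coord_name, sample_name = x$sample_name)
}

# set/overwrite an obs column preserving row order
set_obs_column <- function(ds, name, values) {
  stopifnot(length(values) == n_spots(ds))
  ds$obs[[name]] <- values
  ds
}

# fetch per-spot sample labels; `sample_key` may name an obs column or the
# dataset's canonical sample slot. Raises a key error when neither exists.
resolve_sample_ids <- function(ds, sample_key) {
  if (!is.null(sample_key) && sample_key %in% colnames(ds$obs)) {
    return(as.character(ds$obs[[sample_key]]))
  }
  if (!is.null(ds$sample_ids) &&
      (is.null(sample_key) || identical(sample_key, ds$sample_name))) {
    return(ds$sample_ids)
  }
  stop_key_error(sprintf(
    "sample column '%s' not found in the dataset (no obs column of that name%s)",
    sample_key,
    if (is.null(ds$sample_ids)) " and no per-spot sample labels loaded" else
      sprintf(" and the dataset's sample slot is named '%s'", ds$sample_name)))
}

#' Derived obs column names for a QC metric
#'
#' The column-naming contract: for a metric `m`, the log-transformed values
#' live in `m_log`, the robust local z-scores in `m_z`, and the boolean
#' outlier flags in `m_outliers`. No other naming is permitted; every stage
#' derives names through this helper.
#'
#' @param metric metric column name.
#' @return named character vector with entries `metric`, `log`, `z`, `flag`.
#' @examples obs_column_schema("detected")
#' @export
obs_column_schema <- function(metric) {
  if (!is.character(metric) || length(metric) != 1L || !nzchar(metric)) {
    stop_value_error("`metric` must be a non-empty string")
  }
  c(metric = metric,
    log = paste0(metric, "_log"),
    z = paste0(metric, "_z"),
    flag = paste0(metric, "_outliers"))
}

#' Export the per-spot annotation table to CSV
#'
#' Writes one row per spot — spot id, sample label, the two coordinates, and
#' every `obs` column (QC metrics, z-scores, outlier flags) — preserving row
#' order.
#'
#' @param ds a `SpatialQCDataset`
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_obs_table <- function(ds, path) {
  tab <- data.frame(spot_id = ds$spot_ids,
                    sample_id = if (is.null(ds$sample_ids)) NA_character_ else ds$sample_ids,
                    x = ds$coords[, 1L], y = ds$coords[, 2L],
                    check.names = FALSE)
  if (ncol(ds$obs)) tab <- cbind(tab, ds$obs)
  rownames(tab) <- NULL
  ok <- tryCatch({ utils::write.csv(tab, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) {
    stop_io_error(sprintf("cannot write obs table to '%s'", path))
  }
  invisible(path)
}
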