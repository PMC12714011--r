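# 10x-style directory I/O: matrix.mtx[.gz] + features.tsv[.gz] +
# barcodes.tsv[.gz] and a tissue-positions CSV (headered
# `tissue_positions.csv` or headerless `tissue_positions_list.csv`; both
# dialects exist in the wild and are auto-detected from the first row).

find_tenx_file <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  NULL
}

read_lines_maybe_gz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

# positions table normalized to: barcode, in_tissue, array_row, array_col,
# pxl_row, pxl_col
read_positions_file <- function(path) {
  if (!file.exists(path)) {
    stop_io_error(sprintf("positions file '%s' not found", path))
  }
  first <- read_lines_maybe_gz(path)[1L]
  has_header <- grepl("barcode", first, ignore.case = TRUE) ||
    grepl("in_tissue", first, ignore.case = TRUE)
  pos <- utils::read.csv(if (grepl("\\.gz$", path)) gzfile(path) else path,
                         header = has_header, stringsAsFactors = FALSE)
  if (ncol(pos) < 6L) {
    stop_io_error(sprintf(
      "positions file '%s' must have 6 columns (barcode, in_tissue, array_row, array_col, pxl_row, pxl_col); found %d",
      path, ncol(pos)))
  }
  pos <- pos[, 1:6]
  names(pos) <- c("barcode", "in_tissue", "array_row", "array_col",
                  "pxl_row", "pxl_col")
  pos$barcode <- as.character(pos$barcode)
  pos
}

#' Read a 10x-style matrix directory with tissue positions
#'
#' Loads a sparse gene-barcode matrix triplet (`matrix.mtx[.gz]`,
#' `features.tsv[.gz]`, `barcodes.tsv[.gz]`) together with a
#' tissue-positions CSV, joins them by barcode, drops spots flagged as not
#' in tissue, and returns a [spatial_qc_dataset()] whose coordinates are the
#' pixel columns of the positions file. Barcodes present in only one of the
#' two inputs are dropped with a warning; a disjoint barcode set is an
#' error.
#'
#' @param path directory containing the matrix triplet.
#' @param positions_file tissue-positions CSV; defaults to
#'   `tissue_positions.csv` / `tissue_positions_list.csv` inside `path`.
#' @param sample_id single sample label assigned to every spot
#'   (default `"sample01"`).
#' @param keep_not_in_tissue keep spots whose in-tissue flag is 0
#'   (default `FALSE`: reported spot counts conventionally refer to
#'   in-tissue spots).
#' @return a `SpatialQCDataset`
#' @export
read_tenx_dir <- function(path, positions_file = NULL, sample_id = "sample01",
                          keep_not_in_tissue = FALSE) {
  if (!dir.exists(path)) {
    stop_io_error(sprintf("10x directory '%s' does not exist", path))
  }
  mtx <- find_tenx_file(path, "matrix.mtx")
  feat <- find_tenx_file(path, c("features.tsv", "genes.tsv"))
  bc <- find_tenx_file(path, "barcodes.tsv")
  if (is.null(mtx) || is.null(feat) || is.null(bc)) {
    stop_io_error(sprintf(
      "'%s' is missing one of matrix.mtx[.gz], features.tsv[.gz], barcodes.tsv[.gz]",
      path))
  }
  if (is.null(positions_file)) {
    positions_file <- find_tenx_file(path, c("tissue_positions",
                                             "tissue_positions.csv",
                                             "tissue_positions_list.csv"))
    if (is.null(positions_file)) {
      stop_io_error(sprintf("no tissue positions file found in '%s'", path))
    }
  }

  m <- Matrix::readMM(mtx)            # genes x barcodes, 10x convention
  barcodes <- read_lines_maybe_gz(bc)
  features <- utils::read.delim(if (grepl("\\.gz$", feat)) gzfile(feat) else feat,
                                header = FALSE, stringsAsFactors = FALSE)
  if (nrow(m) != nrow(features) || ncol(m) != length(barcodes)) {
    stop_io_error(sprintf(
      "matrix is %d x %d but features/barcodes have %d/%d entries",
      nrow(m), ncol(m), nrow(features), length(barcodes)))
  }
  gene_ids <- as.character(features[[1L]])
  gene_names <- if (ncol(features) >= 2L) as.character(features[[2L]]) else gene_ids

  pos <- read_positions_file(positions_file)
  common <- intersect(barcodes, pos$barcode)
  if (length(common) == 0L) {
    stop_io_error("barcode sets of matrix and positions file are disjoint")
  }
  n_drop_m <- sum(!barcodes %in% common)
  n_drop_p <- sum(!pos$barcode %in% common)
  if (n_drop_m > 0L) {
    warning(sprintf("%d matrix barcode(s) missing from positions file; dropped",
                    n_drop_m), call. = FALSE)
  }
  if (n_drop_p > 0L) {
    warning(sprintf("%d positions barcode(s) missing from matrix; ignored",
                    n_drop_p), call. = FALSE)
  }

  # keyed join: keep matrix barcode order for the intersection
  keep <- barcodes[barcodes %in% common]
  pos <- pos[match(keep, pos$barcode), , drop = FALSE]
  if (!keep_not_in_tissue) {
    in_tissue <- pos$in_tissue != 0
    keep <- keep[in_tissue]
    pos <- pos[in_tissue, , drop = FALSE]
  }
  if (length(keep) == 0L) {
    stop_io_error("no in-tissue spots remain after joining with positions")
  }

  counts <- Matrix::t(m[, match(keep, barcodes), drop = FALSE])
  spatial_qc_dataset(
    counts = counts,
    coords = cbind(pos$pxl_col, pos$pxl_row),
    spot_ids = keep, gene_ids = gene_ids, gene_names = gene_names,
    sample_ids = sample_id)
}

#' Write a dataset as a 10x-style matrix directory
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` and a headered
#' `tissue_positions.csv` (all uncompressed) so that reader code paths can be
#' exercised end-to-end on generated data. Coordinates are written into the
#' pixel columns; array row/col are filled with the coordinate ranks.
#'
#' @param ds a `SpatialQCDataset`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_tenx_dir <- function(ds, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop_io_error(sprintf("cannot create directory '%s'", dir))
  Matrix::writeMM(Matrix::t(ds$counts), file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(ds$gene_ids, ds$gene_names, "Gene Expression"),
    file.path(dir, "features.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(ds$spot_ids, file.path(dir, "barcodes.tsv"))
  pos <- data.frame(barcode = ds$spot_ids, in_tissue = 1L,
                    array_row = rank(ds$coords[, 2L], ties.method = "min"),
                    array_col = rank(ds$coords[, 1L], ties.method = "min"),
                    pxl_row_in_fullres = ds$coords[, 2L],
                    pxl_col_in_fullres = ds$coords[, 1L])
  utils::write.csv(pos, file.path(dir, "tissue_positions.csv"), row.names = FALSE)
  invisible(dir)
}
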