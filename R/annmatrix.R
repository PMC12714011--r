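# h5ad-style annotated-matrix I/O via rhdf5.
#
# On-disk layout follows the anndata HDF5 encoding (encoding-type attributes,
# CSR/CSC sparse X groups, encoded obs/var dataframes, obsm slots), so files
# written here open in the python ecosystem and vice versa. HDF5 is
# row-major while R is column-major: every 2-D dataset is transposed at the
# boundary.

h5_write_attr <- function(obj, name, value) {
  rhdf5::h5writeAttribute(value, obj, name,
                          variableLengthString = is.character(value),
                          asScalar = is.character(value) && length(value) == 1L)
}

h5_write_encoded <- function(fid, path, values, encoding) {
  if (is.character(values)) {
    rhdf5::h5write(values, fid, path, variableLengthString = TRUE,
                   encoding = "UTF-8")
  } else {
    rhdf5::h5write(values, fid, path)
  }
  ds <- rhdf5::H5Dopen(fid, path)
  on.exit(rhdf5::H5Dclose(ds))
  h5_write_attr(ds, "encoding-type", encoding)
  h5_write_attr(ds, "encoding-version", "0.2.0")
}

h5_write_dict_group <- function(fid, path) {
  rhdf5::h5createGroup(fid, path)
  g <- rhdf5::H5Gopen(fid, path)
  on.exit(rhdf5::H5Gclose(g))
  h5_write_attr(g, "encoding-type", "dict")
  h5_write_attr(g, "encoding-version", "0.1.0")
}

h5_write_dataframe <- function(fid, path, index, columns) {
  rhdf5::h5createGroup(fid, path)
  g <- rhdf5::H5Gopen(fid, path)
  on.exit(rhdf5::H5Gclose(g))
  h5_write_attr(g, "encoding-type", "dataframe")
  h5_write_attr(g, "encoding-version", "0.2.0")
  h5_write_attr(g, "_index", "_index")
  if (length(columns)) {
    rhdf5::h5writeAttribute(names(columns), g, "column-order",
                            variableLengthString = TRUE)
  }
  h5_write_encoded(fid, paste0(path, "/_index"), index, "string-array")
  for (nm in names(columns)) {
    col <- columns[[nm]]
    if (is.factor(col)) col <- as.character(col)
    enc <- if (is.character(col)) "string-array" else "array"
    h5_write_encoded(fid, paste0(path, "/", nm), col, enc)
  }
}

#' Write a dataset as an h5ad-style annotated matrix
#'
#' Serializes counts (CSR sparse), the `obs` table (including the sample
#' label column), gene metadata and coordinates (under
#' `obsm/<coord_name>`) in the anndata HDF5 encoding, readable from the
#' python ecosystem.
#'
#' @param ds a `SpatialQCDataset`
#' @param path output `.h5ad` path (overwritten if present)
#' @return `path`, invisibly
#' @export
write_annmatrix <- function(ds, path) {
  if (file.exists(path) && unlink(path) != 0L) {
    stop_io_error(sprintf("cannot overwrite '%s'", path))
  }
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) stop_io_error(sprintf("cannot create '%s'", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  fid <- rhdf5::H5Fopen(path)
  h5_write_attr(fid, "encoding-type", "anndata")
  h5_write_attr(fid, "encoding-version", "0.1.0")

  # CSR over spots: column-compressed slots of t(counts) are exactly the
  # row-compressed slots of counts
  tc <- methods::as(Matrix::t(ds$counts), "CsparseMatrix")
  rhdf5::h5createGroup(fid, "X")
  gX <- rhdf5::H5Gopen(fid, "X")
  h5_write_attr(gX, "encoding-type", "csr_matrix")
  h5_write_attr(gX, "encoding-version", "0.1.0")
  rhdf5::h5writeAttribute(as.integer(c(n_spots(ds), n_genes(ds))), gX, "shape")
  rhdf5::H5Gclose(gX)
  rhdf5::h5write(as.double(tc@x), fid, "X/data")
  rhdf5::h5write(as.integer(tc@i), fid, "X/indices")
  rhdf5::h5write(as.integer(tc@p), fid, "X/indptr")

  obs_cols <- as.list(ds$obs)
  if (!is.null(ds$sample_ids) && !ds$sample_name %in% names(obs_cols)) {
    obs_cols <- c(setNames(list(ds$sample_ids), ds$sample_name), obs_cols)
  }
  h5_write_dataframe(fid, "obs", ds$spot_ids, obs_cols)
  h5_write_dataframe(fid, "var", ds$gene_ids,
                     list(gene_name = ds$gene_names))

  h5_write_dict_group(fid, "obsm")
  h5_write_encoded(fid, paste0("obsm/", ds$coord_name),
                   t(unname(ds$coords)), "array")
  for (g in c("uns", "obsp", "varm", "varp", "layers")) {
    h5_write_dict_group(fid, g)
  }
  rhdf5::H5Fclose(fid)
  invisible(path)
}

h5ad_read_strings <- function(path, name) {
  v <- rhdf5::h5read(path, name)
  as.character(v)
}

h5ad_read_column <- function(path, name) {
  attrs <- rhdf5::h5readAttributes(path, name)
  enc <- attrs[["encoding-type"]]
  if (!is.null(enc) && enc == "categorical") {
    cats <- as.character(rhdf5::h5read(path, paste0(name, "/categories")))
    codes <- as.integer(rhdf5::h5read(path, paste0(name, "/codes")))
    out <- rep(NA_character_, length(codes))
    ok <- codes >= 0L
    out[ok] <- cats[codes[ok] + 1L]
    return(out)
  }
  v <- rhdf5::h5read(path, name)
  if (is.factor(v)) {
    # rhdf5 surfaces HDF5 bool/enum datasets as factors
    if (all(levels(v) %in% c("FALSE", "TRUE"))) return(as.logical(as.character(v)))
    return(as.character(v))
  }
  if (is.raw(v)) return(as.logical(as.integer(v)))
  if (is.array(v)) v <- as.vector(v)
  v
}

h5ad_read_dataframe <- function(path, name, objects) {
  attrs <- rhdf5::h5readAttributes(path, name)
  index_name <- if (!is.null(attrs[["_index"]])) attrs[["_index"]] else "_index"
  index <- h5ad_read_strings(path, paste0(name, "/", index_name))
  cols <- as.character(attrs[["column-order"]])
  present <- objects$name[objects$group == paste0("/", name)]
  cols <- cols[cols %in% present]
  out <- data.frame(row.names = index)
  for (nm in cols) {
    out[[nm]] <- h5ad_read_column(path, paste0(name, "/", nm))
  }
  out
}

h5ad_read_X <- function(path, attrs, n_obs_hint = NULL) {
  enc <- attrs[["encoding-type"]]
  if (!is.null(enc) && enc %in% c("csr_matrix", "csc_matrix")) {
    shape <- as.integer(attrs[["shape"]])
    data <- as.double(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    if (enc == "csr_matrix") {
      # csr(n_obs, n_var) slots == csc slots of the transposed matrix
      m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                dims = rev(shape))
      return(Matrix::t(m))
    }
    Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data, dims = shape)
  } else {
    m <- rhdf5::h5read(path, "X")      # dense: HDF5 (n_obs, n_var) -> R transposed
    Matrix::t(methods::as(m, "CsparseMatrix"))
  }
}

#' Read an h5ad-style annotated matrix
#'
#' Loads counts, the per-spot `obs` table, gene metadata and a 2-column
#' coordinate slot from an anndata-encoded HDF5 file (sparse CSR/CSC or
#' dense `X`; plain, boolean, string and categorical obs columns).
#'
#' If the sample column named by `sample_key` is absent the dataset still
#' loads with unset sample labels — the check is deferred to
#' [local_outliers()] so metric-only workflows work. A missing or
#' non-2-column coordinate slot is an error.
#'
#' @param path `.h5ad` file
#' @param coord_key name of the coordinate slot under `obsm`
#'   (default `"spatial"`)
#' @param sample_key name of the per-spot sample label column in `obs`
#'   (default `"sample_id"`)
#' @return a `SpatialQCDataset`
#' @export
read_annmatrix <- function(path, coord_key = "spatial",
                           sample_key = "sample_id") {
  if (!file.exists(path)) {
    stop_io_error(sprintf("file '%s' does not exist", path))
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  objects <- tryCatch(rhdf5::h5ls(path), error = function(e) {
    stop_io_error(sprintf("'%s' is not a readable HDF5 file: %s",
                          path, conditionMessage(e)))
  })
  root <- objects$name[objects$group == "/"]
  if (!all(c("X", "obs", "obsm") %in% root)) {
    stop_io_error(sprintf(
      "'%s' lacks the X/obs/obsm structure of an annotated matrix", path))
  }

  coord_path <- paste0("obsm/", coord_key)
  obsm_names <- objects$name[objects$group == "/obsm"]
  if (!coord_key %in% obsm_names) {
    stop_io_error(sprintf("coordinate slot 'obsm/%s' not found", coord_key))
  }
  coords <- rhdf5::h5read(path, coord_path)
  coords <- t(coords)                   # HDF5 (n, d) arrives as R (d, n)
  if (ncol(coords) != 2L) {
    stop_io_error(sprintf(
      "coordinate slot 'obsm/%s' must have 2 columns; found %d",
      coord_key, ncol(coords)))
  }

  x_attrs <- rhdf5::h5readAttributes(path, "X")
  counts <- h5ad_read_X(path, x_attrs)
  obs <- h5ad_read_dataframe(path, "obs", objects)
  var <- h5ad_read_dataframe(path, "var", objects)

  sample_ids <- NULL
  if (sample_key %in% colnames(obs)) {
    sample_ids <- as.character(obs[[sample_key]])
    obs[[sample_key]] <- NULL
  }
  gene_names <- if ("gene_name" %in% colnames(var)) {
    as.character(var$gene_name)
  } else rownames(var)

  spatial_qc_dataset(
    counts = counts, coords = coords, spot_ids = rownames(obs),
    gene_ids = rownames(var), gene_names = gene_names,
    sample_ids = sample_ids, obs = obs,
    coord_name = coord_key, sample_name = sample_key)
}
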