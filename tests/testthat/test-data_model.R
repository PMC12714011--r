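test_that("dataset constructor enforces row alignment and uniqueness", {
  ds <- toy_dataset(n = 5)
  expect_s3_class(ds, "SpatialQCDataset")
  expect_equal(dim(ds), c(5L, 4L))
  expect_identical(rownames(ds$obs), ds$spot_ids)
  expect_identical(rownames(ds$coords), ds$spot_ids)

  expect_value_error(spatial_qc_dataset(matrix(1, 2, 2), coords = cbind(1, 1)))
  expect_value_error(spatial_qc_dataset(matrix(1, 2, 2),
                                        coords = cbind(c(1, 2), c(1, NA))))
  expect_value_error(spatial_qc_dataset(matrix(-1, 2, 2),
                                        coords = cbind(1:2, 1:2)))
  expect_value_error(spatial_qc_dataset(matrix(1, 2, 2),
                                        coords = cbind(1:2, 1:2),
                                        spot_ids = c("a", "a")))
})

test_that("adding obs columns never reorders rows; subsetting stays aligned", {
  ds <- toy_dataset(n = 6)
  ds <- compute_qc_metrics(ds)
  before <- rownames(ds$obs)
  ds$obs$extra <- rnorm(6)
  expect_identical(rownames(ds$obs), before)

  sub <- ds[c(5, 2)]
  expect_identical(sub$spot_ids, ds$spot_ids[c(5, 2)])
  expect_identical(sub$obs$sum, ds$obs$sum[c(5, 2)])
  expect_identical(unname(sub$coords[, 1]), unname(ds$coords[c(5, 2), 1]))
})

test_that("obs column schema derives the only permitted names", {
  s <- obs_column_schema("detected")
  expect_identical(unname(s["z"]), "detected_z")
  expect_identical(unname(s["flag"]), "detected_outliers")
  expect_identical(unname(s["log"]), "detected_log")
  expect_value_error(obs_column_schema(""))
})

test_that("obs table export preserves order, headers and flag values", {
  ds <- compute_qc_metrics(toy_dataset(n = 5))
  ds <- local_outliers(ds, metric = "sum", n_neighbors = 2, log = FALSE)
  csv <- tempfile(fileext = ".csv")
  write_obs_table(ds, csv)
  tab <- read.csv(csv)
  expect_identical(tab$spot_id, ds$spot_ids)
  expect_true(all(c("sum_z", "sum_outliers") %in% colnames(tab)))
  expect_identical(tab$sum_outliers, ds$obs$sum_outliers)

  # empty obs: id/sample/coordinate columns only
  csv2 <- tempfile(fileext = ".csv")
  write_obs_table(toy_dataset(n = 3), csv2)
  expect_identical(colnames(read.csv(csv2)), c("spot_id", "sample_id", "x", "y"))

  expect_io_error(write_obs_table(ds, file.path(tempdir(), "no/such/dir.csv")))
})

make_tenx_fixture <- function(dir, barcodes, in_tissue = NULL,
                              shuffle_positions = FALSE,
                              drop_from_positions = character(0)) {
  n <- length(barcodes)
  counts <- matrix(seq_len(n * 3), nrow = n)
  ds <- spatial_qc_dataset(counts, coords = cbind(seq_len(n) * 10, rep(7, n)),
                           spot_ids = barcodes, sample_ids = "A")
  write_tenx_dir(ds, dir)
  pos <- read.csv(file.path(dir, "tissue_positions.csv"))
  if (!is.null(in_tissue)) pos$in_tissue <- in_tissue
  if (shuffle_positions) pos <- pos[rev(seq_len(nrow(pos))), ]
  pos <- pos[!pos$barcode %in% drop_from_positions, ]
  write.csv(pos, file.path(dir, "tissue_positions.csv"), row.names = FALSE)
  ds
}

test_that("10x reader filters by in-tissue flag and joins by barcode", {
  dir <- tempfile("tenx")
  make_tenx_fixture(dir, c("AAA", "BBB", "CCC"), in_tissue = c(1, 0, 1))
  ds <- read_tenx_dir(dir)
  expect_equal(n_spots(ds), 2L)
  expect_identical(ds$spot_ids, c("AAA", "CCC"))

  # positions in a different row order: coords realigned by keyed join
  dir2 <- tempfile("tenx")
  orig <- make_tenx_fixture(dir2, c("AAA", "BBB", "CCC"),
                            shuffle_positions = TRUE)
  ds2 <- read_tenx_dir(dir2)
  expect_identical(ds2$spot_ids, orig$spot_ids)
  expect_equal(unname(ds2$coords), unname(orig$coords))
})

test_that("10x reader drops barcodes missing from positions with a warning", {
  dir <- tempfile("tenx")
  make_tenx_fixture(dir, c("AAA", "BBB", "CCC", "DDD"),
                    drop_from_positions = "CCC")
  expect_warning(ds <- read_tenx_dir(dir), "missing from positions")
  expect_identical(ds$spot_ids, c("AAA", "BBB", "DDD"))
})

test_that("10x reader error paths: missing files, disjoint barcodes", {
  expect_io_error(read_tenx_dir(tempfile("nope")))

  dir <- tempfile("tenx")
  make_tenx_fixture(dir, c("AAA", "BBB"))
  file.remove(file.path(dir, "features.tsv"))
  expect_io_error(read_tenx_dir(dir))

  dir3 <- tempfile("tenx")
  make_tenx_fixture(dir3, c("AAA", "BBB"))
  pos <- read.csv(file.path(dir3, "tissue_positions.csv"))
  pos$barcode <- c("XXX", "YYY")
  write.csv(pos, file.path(dir3, "tissue_positions.csv"), row.names = FALSE)
  expect_io_error(read_tenx_dir(dir3))
})

test_that("headerless positions dialect is auto-detected", {
  dir <- tempfile("tenx")
  orig <- make_tenx_fixture(dir, c("AAA", "BBB", "CCC"))
  pos <- read.csv(file.path(dir, "tissue_positions.csv"))
  file.remove(file.path(dir, "tissue_positions.csv"))
  write.table(pos, file.path(dir, "tissue_positions_list.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  ds <- read_tenx_dir(dir)
  expect_identical(ds$spot_ids, orig$spot_ids)
  expect_equal(unname(ds$coords), unname(orig$coords))
})

test_that("reading never modifies counts (round trip through 10x dir)", {
  set.seed(11)
  counts <- matrix(rpois(60, 4), nrow = 10)
  ds <- spatial_qc_dataset(counts, coords = cbind(1:10, 1:10),
                           sample_ids = "A")
  dir <- tempfile("tenx")
  write_tenx_dir(ds, dir)
  back <- read_tenx_dir(dir)
  expect_equal(as.matrix(back$counts), as.matrix(ds$counts),
               ignore_attr = TRUE)
})
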