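test_that("neighbourhood MAD on hand-computed vectors", {
  expect_equal(neighborhood_mad(c(1, 2, 3, 4, 5)), 1)
  expect_equal(neighborhood_mad(rep(4.2, 3)), 0)
  expect_equal(neighborhood_mad(c(1:9, 100)), 2.5)
  expect_value_error(neighborhood_mad(numeric(0)))
  expect_value_error(neighborhood_mad(c(1, NA)))
})

test_that("robust local z on hand-computed neighbourhoods", {
  # line of 6 spots; spot 6 far away so spots 1..5 are its 5 neighbours
  coords <- cbind(c(1, 2, 3, 4, 5, 100), 0)
  values <- c(1, 2, 3, 4, 5, 10)
  g <- knn_within_sample(coords, "A", k = 5)
  z <- robust_local_zscores(values, g)
  expect_equal(z[6], 0.6745 * (10 - 3) / 1, tolerance = 1e-12)
  expect_equal(z[6], 4.7215, tolerance = 1e-4)

  # constant neighbourhood: z = 0 whatever the focal value
  zc <- robust_local_zscores(c(rep(7, 5), 1000), g)
  expect_identical(zc[6], 0)

  # focal value at the neighbourhood median: zero numerator
  z0 <- robust_local_zscores(c(1, 2, 3, 4, 5, 3), g)
  expect_identical(z0[6], 0)

  expect_value_error(robust_local_zscores(1:3, g))   # misaligned
})

test_that("directional flags use strict inequalities", {
  z <- c(4.72, -3.0, -3.5, 3.0, 0)
  expect_identical(flag_outliers(z, "higher", 3),
                   c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(flag_outliers(z, "lower", 3),
                   c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(flag_outliers(z, "both", 3),
                   c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_value_error(flag_outliers(z, "sideways", 3))
  expect_value_error(flag_outliers(z, "both", 0))
})

test_that("a single dead spot amid uniformly high tissue is flagged exactly", {
  # near-uniform background (small striped variation keeps the
  # neighbourhood MAD positive; an exactly constant background would fall
  # under the degenerate rule and score everything 0)
  ds <- grid_dataset(n_side = 20, value = 100)
  dead <- 20 * 10 + 10                     # interior spot
  counts <- as.matrix(ds$counts) + seq_len(400) %% 3
  counts[dead, ] <- 0
  ds <- spatial_qc_dataset(counts, coords = ds$coords, sample_ids = "A")
  ds <- compute_qc_metrics(ds)
  ds <- local_outliers(ds, metric = "sum", direction = "lower",
                       n_neighbors = 36)
  expect_identical(which(ds$obs$sum_outliers), as.integer(dead))
  # brute-force confirmation of its z-score
  z_oracle <- oracle_local_z(log1p(ds$obs$sum), ds$coords,
                             rep("A", n_spots(ds)), k = 36)
  expect_equal(ds$obs$sum_z, z_oracle, tolerance = 1e-12)
})

test_that("local_outliers validates keys and parameters as specified", {
  ds <- compute_qc_metrics(toy_dataset(n = 10))
  expect_key_error(local_outliers(ds, metric = "not_there"))
  expect_key_error(local_outliers(ds, metric = "sum", coord_key = "umap"))
  expect_key_error(local_outliers(ds, metric = "sum", sample_key = "absent"))
  expect_value_error(local_outliers(ds, metric = "sum",
                                    direction = "sideways"))
  expect_value_error(local_outliers(ds, metric = "sum", cutoff = -1))
  expect_value_error(local_outliers(ds, metric = "sum", n_neighbors = 0))
})

test_that("log handling: column naming, persistence, stale-column rule", {
  ds <- compute_qc_metrics(toy_dataset(n = 12))
  ds <- local_outliers(ds, metric = "sum", n_neighbors = 4, log = TRUE)
  expect_true(all(c("sum_log", "sum_z", "sum_outliers") %in%
                    colnames(ds$obs)))
  expect_equal(ds$obs$sum_log, log1p(ds$obs$sum))
  expect_type(ds$obs$sum_z, "double")
  expect_type(ds$obs$sum_outliers, "logical")

  # a pre-existing log column is scored as-is (with a notice), not rebuilt
  ds2 <- compute_qc_metrics(toy_dataset(n = 12))
  ds2$obs$sum_log <- rev(log1p(ds2$obs$sum))
  expect_message(
    ds2 <- local_outliers(ds2, metric = "sum", n_neighbors = 4, log = TRUE),
    "no overwrite")
  expect_identical(ds2$obs$sum_log, rev(log1p(ds2$obs$sum)))
  g <- knn_within_sample(ds2$coords, ds2$sample_ids, k = 4)
  expect_equal(ds2$obs$sum_z, robust_local_zscores(ds2$obs$sum_log, g))
})

test_that("re-running is idempotent", {
  ds <- compute_qc_metrics(toy_dataset(n = 15))
  a <- local_outliers(ds, metric = "sum", n_neighbors = 5)
  b <- local_outliers(a, metric = "sum", n_neighbors = 5)
  expect_identical(a$obs$sum_z, b$obs$sum_z)
  expect_identical(a$obs$sum_outliers, b$obs$sum_outliers)
})

test_that("singleton-sample spots score zero and are never flagged", {
  coords <- rbind(cbind(1:8, 0), c(50, 50))
  counts <- matrix(c(rep(10, 8), 0), ncol = 1) %*% t(rep(1, 3))
  ds <- spatial_qc_dataset(counts, coords = coords,
                           sample_ids = c(rep("A", 8), "lonely"))
  ds <- compute_qc_metrics(ds)
  suppressWarnings(expect_warning(
    ds <- local_outliers(ds, metric = "sum", direction = "both",
                         n_neighbors = 3),
    "single spot"))
  expect_identical(ds$obs$sum_z[9], 0)
  expect_false(ds$obs$sum_outliers[9])
})

test_that("z-scores are shift- and scale-invariant within neighbourhoods", {
  dat <- random_qc_values(n = 150, n_samples = 1, seed = 13)
  g <- knn_within_sample(dat$coords, dat$sample_ids, k = 10)
  z0 <- robust_local_zscores(dat$values, g)
  expect_equal(robust_local_zscores(dat$values + 17.3, g), z0,
               tolerance = 1e-9)
  expect_equal(robust_local_zscores(dat$values * 4.2, g), z0,
               tolerance = 1e-9)
})

test_that("permuting spot order permutes z-scores and flags identically", {
  set.seed(31)
  dat <- random_qc_values(n = 120, n_samples = 2, seed = 17)
  counts <- matrix(rpois(120 * 3, 5), nrow = 120)
  ds <- spatial_qc_dataset(counts, coords = dat$coords,
                           sample_ids = dat$sample_ids)
  ds <- compute_qc_metrics(ds)
  ds <- local_outliers(ds, metric = "sum", direction = "both",
                       n_neighbors = 8, cutoff = 1.5)

  perm <- sample(120)
  dsp <- spatial_qc_dataset(counts[perm, ], coords = dat$coords[perm, ],
                            sample_ids = dat$sample_ids[perm])
  dsp <- compute_qc_metrics(dsp)
  dsp <- local_outliers(dsp, metric = "sum", direction = "both",
                        n_neighbors = 8, cutoff = 1.5)
  expect_equal(dsp$obs$sum_z, ds$obs$sum_z[perm], tolerance = 1e-12)
  expect_identical(dsp$obs$sum_outliers, ds$obs$sum_outliers[perm])
})

test_that("concatenated samples score exactly as the samples alone", {
  d1 <- random_qc_values(n = 60, n_samples = 1, seed = 41)
  d2 <- random_qc_values(n = 70, n_samples = 1, seed = 42)
  coords <- rbind(d1$coords, d2$coords)
  samples <- c(rep("s1", 60), rep("s2", 70))
  values <- c(d1$values, d2$values)

  z_cat <- robust_local_zscores(values,
                                knn_within_sample(coords, samples, k = 9))
  z1 <- robust_local_zscores(d1$values,
                             knn_within_sample(d1$coords, "s1", k = 9))
  z2 <- robust_local_zscores(d2$values,
                             knn_within_sample(d2$coords, "s2", k = 9))
  expect_equal(z_cat, c(z1, z2), tolerance = 1e-15)
})

test_that("worker count leaves local_outliers output unchanged", {
  dat <- random_qc_values(n = 150, n_samples = 3, seed = 55)
  counts <- matrix(rpois(150 * 2, 6), nrow = 150)
  base <- NULL
  for (w in c(1, 2, 4)) {
    ds <- spatial_qc_dataset(counts, coords = dat$coords,
                             sample_ids = dat$sample_ids)
    ds <- compute_qc_metrics(ds)
    ds <- local_outliers(ds, metric = "sum", n_neighbors = 7, workers = w)
    if (is.null(base)) base <- ds$obs else expect_identical(ds$obs, base)
  }
})
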