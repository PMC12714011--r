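# Shared fixture builders and independent oracles. The oracles deliberately
# take different code paths from the package internals (stats::dist, full
# matrices, literal formula transcription) so agreement is informative.

# tiny dataset on a line or grid with hand-settable obs columns
toy_dataset <- function(n = 6, sample_ids = "A", coords = NULL,
                        counts = NULL, n_genes = 4) {
  if (is.null(coords)) coords <- cbind(seq_len(n), rep(0, n))
  if (is.null(counts)) {
    counts <- matrix(seq_len(n * n_genes) %% 7, nrow = n)
  }
  spatial_qc_dataset(counts, coords = coords, sample_ids = sample_ids)
}

grid_dataset <- function(n_side = 10, value = 100, sample_ids = "A") {
  coords <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side)))
  n <- nrow(coords)
  counts <- matrix(value, nrow = n, ncol = 3)
  spatial_qc_dataset(counts, coords = coords, sample_ids = sample_ids)
}

# independent kNN oracle: full distance matrix via stats::dist, per-spot
# ordering by (distance, global index), per-sample restriction
oracle_knn <- function(coords, sample_ids, k) {
  d <- as.matrix(stats::dist(coords))
  lapply(seq_len(nrow(coords)), function(i) {
    same <- which(sample_ids == sample_ids[i])
    same <- setdiff(same, i)
    if (length(same) == 0L) return(integer(0))
    ord <- same[order(d[i, same], same)]
    ord[seq_len(min(k, length(ord)))]
  })
}

# literal robust local z-score: 0.6745 * (x_i - median(N)) / MAD(N),
# degenerate MAD or non-finite result -> 0
oracle_local_z <- function(values, coords, sample_ids, k) {
  nb <- oracle_knn(coords, sample_ids, k)
  vapply(seq_along(values), function(i) {
    if (length(nb[[i]]) == 0L) return(0)
    xj <- values[nb[[i]]]
    m <- median(xj)
    s <- median(abs(xj - m))
    z <- 0.6745 * (values[i] - m) / s
    if (!is.finite(z)) 0 else z
  }, numeric(1))
}

# random multi-sample dataset with continuous coordinates (tie-free)
random_qc_values <- function(n, n_samples, seed) {
  set.seed(seed)
  list(coords = cbind(runif(n, 0, 100), runif(n, 0, 100)),
       sample_ids = sample(paste0("s", seq_len(n_samples)), n, replace = TRUE),
       values = rlnorm(n, meanlog = 5, sdlog = 1))
}

# page count of an uncompressed R pdf() file: page objects carry
# "/Type /Page", the page-tree root "/Type /Pages"
count_pdf_pages <- function(path) {
  txt <- readLines(path, warn = FALSE)
  sum(grepl("/Type /Page$|/Type /Page[^s]", txt, useBytes = TRUE))
}

expect_value_error <- function(expr) {
  testthat::expect_error(expr, class = "spotscreen_value_error")
}
expect_key_error <- function(expr) {
  testthat::expect_error(expr, class = "spotscreen_key_error")
}
expect_io_error <- function(expr) {
  testthat::expect_error(expr, class = "spotscreen_io_error")
}
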