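# Synthetic Visium-like tissues with known ground truth, so every stage of
# the pipeline is testable without downloads.

#' Specify a synthetic tissue
#'
#' Describes a lattice of capture spots with an overdispersed count
#' baseline and optional injected artifacts.
#'
#' Geometry: `"hex"` places odd rows offset by half a spacing with row
#' pitch sqrt(3)/2, so each interior spot has 6 equidistant neighbours at
#' distance 1 (Visium-style); `"square"` is a unit square lattice
#' (HD-bin-style).
#'
#' Baseline: per-spot total UMI counts are negative binomial with mean
#' `total_mean` and variance `total_dispersion * total_mean` — dispersion
#' is the variance-to-mean ratio (Fano factor), 1 being Poisson. Spot
#' totals pool thousands of genes, so homogeneous tissue sits close to
#' Poisson with modest inflation; regional structure is modelled by
#' artifacts, not baseline noise. Totals are allocated to genes by
#' multinomial draws: a binomial share (per-spot beta-distributed
#' mitochondrial fraction, mean `mito_mean_percent`%) goes uniformly to the
#' `ceiling(mito_gene_fraction * n_genes)` MT-prefixed genes, the rest
#' uniformly over a per-spot active subset of the remaining genes (each
#' active with probability `detected_fraction`), so mitochondrial
#' percentage and detected genes are internally consistent with the counts.
#'
#' Artifacts (list of `list(kind, center = c(row, col), radius, effect)`):
#' * `micro_tear` / `low_region` — counts of spots within Euclidean
#'   `radius` (lattice spacings) of the center are binomially thinned to a
#'   fraction `effect` of their expectation (tears: small radius, severe
#'   effect like 0.05; regions: large radius, mild effect like 0.5);
#' * `mito_spike` — the spots' target mitochondrial fraction is raised by
#'   `effect` percentage points.
#'
#' @param grid `"hex"` or `"square"`
#' @param n_rows,n_cols lattice size (per sample)
#' @param total_mean,total_dispersion negative-binomial baseline of spot
#'   totals (defaults 4000 and 2)
#' @param detected_fraction mean fraction of non-mitochondrial genes active
#'   per spot (default 0.6)
#' @param mito_mean_percent,mito_concentration beta baseline of the
#'   per-spot mitochondrial fraction: mean in percent (default 2.5) and
#'   concentration (default 100)
#' @param artifacts list of artifact definitions (see Details)
#' @param n_genes gene count (default 300)
#' @param mito_gene_fraction fraction of genes that are MT-prefixed
#'   (default 0.05)
#' @param n_samples number of independent sections sharing the lattice and
#'   artifact layout (default 1)
#' @param seed RNG seed consumed by [generate_tissue()]
#' @return an object of class `SyntheticTissueSpec`
#' @export
synthetic_tissue_spec <- function(grid = c("hex", "square"),
                                  n_rows = 60L, n_cols = 60L,
                                  total_mean = 4000, total_dispersion = 2,
                                  detected_fraction = 0.6,
                                  mito_mean_percent = 2.5,
                                  mito_concentration = 100,
                                  artifacts = list(),
                                  n_genes = 300L,
                                  mito_gene_fraction = 0.05,
                                  n_samples = 1L,
                                  seed = 1L) {
  grid <- match.arg(grid)
  check_scalar_number(n_rows, "n_rows", lower = 1, strict = FALSE)
  check_scalar_number(n_cols, "n_cols", lower = 1, strict = FALSE)
  check_scalar_number(total_mean, "total_mean", lower = 0, strict = TRUE)
  check_scalar_number(total_dispersion, "total_dispersion", lower = 1)
  check_scalar_number(detected_fraction, "detected_fraction", lower = 0, strict = TRUE)
  check_scalar_number(mito_mean_percent, "mito_mean_percent", lower = 0)
  check_scalar_number(n_genes, "n_genes", lower = 2)
  check_scalar_number(n_samples, "n_samples", lower = 1)
  if (mito_gene_fraction < 0 || mito_gene_fraction >= 1) {
    stop_value_error("`mito_gene_fraction` must be in [0, 1)")
  }
  structure(list(grid = grid, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 total_mean = total_mean, total_dispersion = total_dispersion,
                 detected_fraction = detected_fraction,
                 mito_mean_percent = mito_mean_percent,
                 mito_concentration = mito_concentration,
                 artifacts = artifacts, n_genes = as.integer(n_genes),
                 mito_gene_fraction = mito_gene_fraction,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "SyntheticTissueSpec")
}

#' @method print SyntheticTissueSpec
#' @export
print.SyntheticTissueSpec <- function(x, ...) {
  cat(sprintf(
    "SyntheticTissueSpec: %s %dx%d, %d sample(s), %d genes, %d artifact(s)\n",
    x$grid, x$n_rows, x$n_cols, x$n_samples, x$n_genes, length(x$artifacts)))
  invisible(x)
}

lattice_coords <- function(grid, n_rows, n_cols) {
  row <- rep(seq_len(n_rows), each = n_cols) - 1L
  col <- rep(seq_len(n_cols), times = n_rows) - 1L
  if (grid == "hex") {
    cbind(x = col + 0.5 * (row %% 2), y = row * sqrt(3) / 2)
  } else {
    cbind(x = as.numeric(col), y = as.numeric(row))
  }
}

artifact_mask <- function(spec, coords, artifact) {
  for (field in c("kind", "center", "radius", "effect")) {
    if (is.null(artifact[[field]])) {
      stop_value_error(sprintf("artifact is missing field '%s'", field))
    }
  }
  if (!artifact$kind %in% c("micro_tear", "low_region", "mito_spike")) {
    stop_value_error(sprintf("unknown artifact kind '%s'", artifact$kind))
  }
  ctr <- artifact$center
  if (length(ctr) != 2L || any(ctr < 1) ||
      ctr[1L] > spec$n_rows || ctr[2L] > spec$n_cols) {
    stop_value_error(sprintf(
      "artifact center (%s) outside the %dx%d grid",
      paste(ctr, collapse = ", "), spec$n_rows, spec$n_cols))
  }
  check_scalar_number(artifact$radius, "radius", lower = 0)
  center_idx <- (as.integer(ctr[1L]) - 1L) * spec$n_cols + as.integer(ctr[2L])
  d <- sqrt((coords[, 1L] - coords[center_idx, 1L])^2 +
              (coords[, 2L] - coords[center_idx, 2L])^2)
  d <= artifact$radius + 1e-9
}

rnbinom_fano <- function(n, mean, dispersion) {
  if (dispersion <= 1) {
    stats::rpois(n, lambda = mean)
  } else {
    stats::rnbinom(n, mu = mean, size = mean / (dispersion - 1))
  }
}

#' Generate a synthetic tissue with ground truth
#'
#' Draws a [spatial_qc_dataset()] from a [synthetic_tissue_spec()]
#' (deterministically for a fixed `spec$seed`) together with per-artifact
#' ground-truth masks. For `low_region` artifacts an additional
#' `low_region_interior` mask marks region spots at least 3.5 lattice
#' spacings from the region edge — spots whose default 36-neighbourhood
#' (three hexagonal rings) lies entirely inside the region.
#'
#' @param spec a `SyntheticTissueSpec`
#' @return list with `dataset` (obs empty of QC columns) and `truth`, a
#'   list of logical masks over all spots: one per artifact
#'   (`artifact_1`, ...), per-kind unions (`micro_tear`, `low_region`,
#'   `low_region_interior`, `mito_spike`) and `any`
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "SyntheticTissueSpec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  coords1 <- lattice_coords(spec$grid, spec$n_rows, spec$n_cols)
  n_per <- nrow(coords1)
  masks1 <- lapply(spec$artifacts, function(a) artifact_mask(spec, coords1, a))

  n_mito <- if (spec$mito_gene_fraction > 0) {
    max(1L, as.integer(ceiling(spec$mito_gene_fraction * spec$n_genes)))
  } else 0L
  gene_ids <- c(if (n_mito) paste0("MT-G", seq_len(n_mito)),
                paste0("G", seq_len(spec$n_genes - n_mito)))
  is_mito <- startsWith(gene_ids, "MT-")
  n_other <- spec$n_genes - n_mito

  sample_labels <- sprintf("sample%02d", seq_len(spec$n_samples))
  all_counts_i <- list(); all_counts_j <- list(); all_counts_x <- list()
  spot_ids <- character(0)
  offset <- 0L

  p_base <- spec$mito_mean_percent / 100
  shape1 <- max(p_base * spec$mito_concentration, 1e-6)
  shape2 <- max((1 - p_base) * spec$mito_concentration, 1e-6)

  for (s in seq_len(spec$n_samples)) {
    totals <- rnbinom_fano(n_per, spec$total_mean, spec$total_dispersion)
    p_mito <- if (p_base > 0) stats::rbeta(n_per, shape1, shape2) else rep(0, n_per)

    for (a in seq_along(spec$artifacts)) {
      art <- spec$artifacts[[a]]
      m <- masks1[[a]]
      if (art$kind %in% c("micro_tear", "low_region")) {
        if (art$effect < 0 || art$effect > 1) {
          stop_value_error("thinning artifact `effect` must be in [0, 1]")
        }
        totals[m] <- stats::rbinom(sum(m), size = totals[m], prob = art$effect)
      } else if (art$kind == "mito_spike") {
        p_mito[m] <- pmin(1, p_mito[m] + art$effect / 100)
      }
    }

    mito_counts <- if (n_mito) stats::rbinom(n_per, totals, p_mito) else
      rep(0L, n_per)
    other_counts <- totals - mito_counts

    for (i in seq_len(n_per)) {
      gi <- integer(0); xi <- integer(0)
      if (mito_counts[i] > 0) {
        draw <- stats::rmultinom(1, mito_counts[i], rep(1, n_mito))[, 1L]
        keep <- draw > 0
        gi <- which(is_mito)[keep]; xi <- draw[keep]
      }
      if (other_counts[i] > 0 && n_other > 0) {
        active <- which(stats::runif(n_other) < spec$detected_fraction)
        if (length(active) == 0L) active <- sample.int(n_other, 1L)
        draw <- stats::rmultinom(1, other_counts[i], rep(1, length(active)))[, 1L]
        keep <- draw > 0
        gi <- c(gi, which(!is_mito)[active[keep]]); xi <- c(xi, draw[keep])
      }
      if (length(gi)) {
        all_counts_i[[length(all_counts_i) + 1L]] <- rep(offset + i, length(gi))
        all_counts_j[[length(all_counts_j) + 1L]] <- gi
        all_counts_x[[length(all_counts_x) + 1L]] <- xi
      }
    }
    spot_ids <- c(spot_ids, sprintf("%s_spot%05d", sample_labels[s],
                                    seq_len(n_per)))
    offset <- offset + n_per
  }

  n_total <- n_per * spec$n_samples
  counts <- Matrix::sparseMatrix(
    i = unlist(all_counts_i), j = unlist(all_counts_j),
    x = as.numeric(unlist(all_counts_x)),
    dims = c(n_total, spec$n_genes))

  ds <- spatial_qc_dataset(
    counts = counts,
    coords = coords1[rep(seq_len(n_per), spec$n_samples), , drop = FALSE],
    spot_ids = spot_ids, gene_ids = gene_ids, gene_names = gene_ids,
    sample_ids = rep(sample_labels, each = n_per))

  rep_mask <- function(m) rep(m, spec$n_samples)
  truth <- list()
  for (a in seq_along(spec$artifacts)) {
    truth[[sprintf("artifact_%d", a)]] <- rep_mask(masks1[[a]])
  }
  for (kind in c("micro_tear", "low_region", "mito_spike")) {
    of_kind <- vapply(spec$artifacts, function(a) a$kind == kind, logical(1))
    truth[[kind]] <- if (any(of_kind)) {
      rep_mask(Reduce(`|`, masks1[of_kind]))
    } else rep(FALSE, n_total)
  }
  interior <- rep(FALSE, n_per)
  for (a in seq_along(spec$artifacts)) {
    art <- spec$artifacts[[a]]
    if (art$kind == "low_region") {
      shrunk <- art; shrunk$radius <- max(art$radius - 3.5, 0)
      interior <- interior | artifact_mask(spec, coords1, shrunk)
    }
  }
  truth$low_region_interior <- rep_mask(interior)
  truth$any <- Reduce(`|`, truth[c("micro_tear", "low_region", "mito_spike")])

  list(dataset = ds, truth = truth)
}

#' Monte-Carlo false-flag rate on artifact-free tissue
#'
#' Generates `n_reps` homogeneous tissues from `spec` (which must carry an
#' empty artifact list), runs the local outlier call on the chosen metric,
#' and returns the mean flagged fraction — an estimate of the
#' false-positive rate of the cutoff under the null of no artifacts.
#'
#' @param spec artifact-free `SyntheticTissueSpec`
#' @param n_reps number of replicate tissues (default 3)
#' @param seed base seed; replicate r uses `seed + r - 1`
#' @param metric,direction,n_neighbors,cutoff,log local call parameters
#'   (defaults: total counts, both tails, k 36, cutoff 3, log scale)
#' @return mean flagged fraction across replicates
#' @export
null_flag_rate <- function(spec, n_reps = 3L, seed = 1L, metric = "sum",
                           direction = "both", n_neighbors = 36L,
                           cutoff = 3.0, log = TRUE) {
  stopifnot(inherits(spec, "SyntheticTissueSpec"))
  if (length(spec$artifacts)) {
    stop_value_error("null_flag_rate() needs a spec with no artifacts")
  }
  check_scalar_number(n_reps, "n_reps", lower = 1)
  rates <- vapply(seq_len(n_reps), function(r) {
    spec$seed <- as.integer(seed) + r - 1L
    ds <- compute_qc_metrics(generate_tissue(spec)$dataset)
    ds <- local_outliers(ds, metric = metric, direction = direction,
                         n_neighbors = n_neighbors, log = log,
                         cutoff = cutoff)
    mean(ds$obs[[obs_column_schema(metric)[["flag"]]]])
  }, numeric(1))
  mean(rates)
}
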