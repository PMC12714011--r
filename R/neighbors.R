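#' Per-sample k-nearest spatial neighbours
#'
#' Builds, for every spot, the ordered list of its `k` nearest neighbours by
#' Euclidean distance in the supplied coordinate frame, restricted to spots
#' of the same sample (tissue sections are independent; neighbourhoods never
#' cross a section boundary). The spot itself is excluded from its own
#' neighbourhood. Ties at equal distance are broken by ascending global spot
#' index, which makes the result deterministic and independent of the worker
#' count. When a sample has fewer than `k + 1` spots, `k` is clamped to
#' `n_sample - 1` with a warning; a singleton sample yields an empty
#' neighbour list (also warned).
#'
#' The search is an exact per-sample all-pairs scan. Spot counts in the
#' regimes this package targets (thousands of spots per section) keep that
#' comfortably fast, and exactness is what makes the deterministic tie-break
#' contract checkable.
#'
#' @param coords numeric matrix (n x 2) of finite spatial coordinates
#' @param sample_ids character vector of per-spot sample labels (a single
#'   value is recycled)
#' @param k requested neighbourhood size (>= 1); default 36, a hexagonal
#'   three-ring neighbourhood on Visium-style grids
#' @param workers number of parallel workers used to process samples; the
#'   result is identical for any value
#' @return an object of class `NeighborGraph`: list with `neighbor_indices`
#'   (per-spot integer vectors of global indices, nearest first),
#'   `k_requested`, and `effective_k` (named per-sample vector)
#' @examples
#' g <- knn_within_sample(cbind(0:4, 0), rep("A", 5), k = 2)
#' g$neighbor_indices[[1]]
#' @export
knn_within_sample <- function(coords, sample_ids, k = 36L, workers = 1L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L || !all(is.finite(coords))) {
    stop_value_error("coords must be a finite n x 2 matrix")
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 1) {
    stop_value_error(sprintf("`k` must be an integer >= 1 (got %s)",
                             deparse(k)[1L]))
  }
  k <- as.integer(k)
  if (length(sample_ids) == 1L) sample_ids <- rep(sample_ids, nrow(coords))
  if (length(sample_ids) != nrow(coords)) {
    stop_value_error("sample_ids must have one label per coordinate row")
  }
  check_scalar_number(workers, "workers", lower = 1)

  idx_by_sample <- split(seq_len(nrow(coords)), sample_ids)
  singletons <- names(idx_by_sample)[lengths(idx_by_sample) == 1L]
  if (length(singletons)) {
    warning(sprintf(
      "sample(s) with a single spot get empty neighbour lists: %s",
      paste(singletons, collapse = ", ")), call. = FALSE)
  }
  clamped <- names(idx_by_sample)[lengths(idx_by_sample) > 1L &
                                    lengths(idx_by_sample) <= k]
  if (length(clamped)) {
    warning(sprintf(
      "k = %d exceeds sample size; clamped to n - 1 for sample(s): %s",
      k, paste(clamped, collapse = ", ")), call. = FALSE)
  }

  per_sample <- function(global_idx) {
    n_s <- length(global_idx)
    if (n_s == 1L) return(list(integer(0)))
    k_s <- min(k, n_s - 1L)
    xs <- coords[global_idx, 1L]
    ys <- coords[global_idx, 2L]
    lapply(seq_len(n_s), function(j) {
      d2 <- (xs - xs[j])^2 + (ys - ys[j])^2
      d2[j] <- Inf                       # exclude self
      ord <- order(d2, global_idx)       # tie-break: ascending global index
      global_idx[ord[seq_len(k_s)]]
    })
  }

  workers <- as.integer(workers)
  results <- if (workers > 1L && length(idx_by_sample) > 1L &&
                 .Platform$OS.type == "unix") {
    parallel::mclapply(idx_by_sample, per_sample, mc.cores = workers)
  } else {
    lapply(idx_by_sample, per_sample)
  }

  neighbor_indices <- vector("list", nrow(coords))
  for (s in names(idx_by_sample)) {
    neighbor_indices[idx_by_sample[[s]]] <- results[[s]]
  }
  effective_k <- vapply(idx_by_sample, function(ii) {
    max(min(k, length(ii) - 1L), 0L)
  }, integer(1))

  structure(list(neighbor_indices = neighbor_indices,
                 k_requested = k,
                 sample_ids = as.character(sample_ids),
                 effective_k = effective_k),
            class = "NeighborGraph")
}

#' @method print NeighborGraph
#' @export
print.NeighborGraph <- function(x, ...) {
  cat(sprintf("NeighborGraph: %d spots, k = %d, %d sample(s)\n",
              length(x$neighbor_indices), x$k_requested,
              length(x$effective_k)))
  invisible(x)
}

#' Serialize a neighbour graph to an edge table
#'
#' Debugging helper: two-column data frame (`from`, `to`) of directed
#' nearest-neighbour edges, optionally written to CSV.
#'
#' @param graph a `NeighborGraph`
#' @param path optional CSV output path
#' @return the edge data frame (invisibly when `path` is given)
#' @export
neighbor_edges <- function(graph, path = NULL) {
  from <- rep(seq_along(graph$neighbor_indices),
              lengths(graph$neighbor_indices))
  edges <- data.frame(from = from,
                      to = unlist(graph$neighbor_indices, use.names = FALSE))
  if (!is.null(path)) {
    utils::write.csv(edges, path, row.names = FALSE)
    return(invisible(edges))
  }
  edges
}
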