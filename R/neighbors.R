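#' k-nearest-neighbor graph
#'
#' Exact Euclidean kNN by full pairwise search, with ties broken by cell
#' index for determinism and the cell itself excluded.
#'
#' @param x Numeric matrix (cells x features).
#' @param k Number of neighbors, `0 < k < nrow(x)`.
#' @param mode Label recording which space the graph was built in.
#' @return An object of class `"neighbor_graph"`: list with `indices`
#'   (cells x k integer matrix), `k` and `mode`.
#' @export
knn_graph <- function(x, k, mode = "embedding") {
  x <- as.matrix(x)
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (k >= nrow(x)) stop("`k` must be smaller than the number of cells",
                         call. = FALSE)
  idx <- knn_brute_cpp(x, as.integer(k))
  structure(list(indices = idx, k = as.integer(k), mode = mode),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d cells, k = %d, mode = %s\n",
              nrow(x$indices), x$k, x$mode))
  invisible(x)
}

# min-max scale a vector to [0, 1]; constant vectors map to 0
minmax <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}

#' Gene-specific kNN in the phase plane
#'
#' Nearest neighbors in a gene's (u, s) phase portrait after min-max
#' scaling each coordinate to `[0, 1]`, which makes the graph invariant to
#' separate affine rescaling of u and s.
#'
#' @param u,s Per-cell abundances.
#' @param k Number of neighbors.
#' @return A `"neighbor_graph"` with mode `"phase_gene"`.
#' @export
knn_phase <- function(u, s, k) {
  stopifnot(length(u) == length(s))
  knn_graph(cbind(minmax(u), minmax(s)), k, mode = "phase_gene")
}

#' Gene-shared kNN on a feature matrix
#'
#' Nearest neighbors in a shared space: the spliced matrix, the
#' concatenated spliced+unspliced matrix, or a supplied low-dimensional
#' embedding.
#'
#' @param x Cells x features matrix.
#' @param k Number of neighbors.
#' @param mode One of `"shared_spliced"`, `"shared_spliced_unspliced"`,
#'   `"embedding"`.
#' @return A `"neighbor_graph"`.
#' @export
knn_shared <- function(x, k,
                       mode = c("shared_spliced", "shared_spliced_unspliced",
                                "embedding")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (ncol(x) < 1) stop("`x` needs at least one feature", call. = FALSE)
  knn_graph(x, k, mode = mode)
}

#' First-moment smoothing over a neighbor graph
#'
#' Replaces each cell's value by the mean over the cell and its neighbors,
#' the standard first-moment noise reduction for spliced/unspliced counts.
#'
#' @param x Cells x genes matrix (or a vector, treated as one column).
#' @param graph A `"neighbor_graph"` built on the same cells.
#' @return The smoothed matrix (or vector).
#' @export
smooth_first_moment <- function(x, graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  if (nrow(m) != nrow(graph$indices)) {
    stop("graph was built on a different number of cells", call. = FALSE)
  }
  acc <- m
  for (l in seq_len(graph$k)) acc <- acc + m[graph$indices[, l], , drop = FALSE]
  out <- acc / (graph$k + 1)
  if (vec) drop(out) else out
}

#' Density-normalizing grid downsampling of a phase portrait
#'
#' Overlays a uniform grid on the min-max-scaled (u, s) plane and keeps,
#' per occupied grid box, the cell closest to the box center. Training on
#' the downsampled set equalizes the cell density along the manifold so
#' that neighbor displacements trace the trajectory instead of local
#' density fluctuations.
#'
#' @param u,s Per-cell abundances.
#' @param grid Two integers: grid resolution in u and s.
#' @return Sorted integer indices of the retained cells.
#' @export
downsample_grid <- function(u, s, grid = c(40, 40)) {
  stopifnot(length(u) == length(s), length(grid) == 2, all(grid >= 1))
  un <- minmax(u); sn <- minmax(s)
  gu <- pmin(floor(un * grid[1]), grid[1] - 1)
  gs <- pmin(floor(sn * grid[2]), grid[2] - 1)
  bin <- gu * grid[2] + gs
  d2 <- (un - (gu + 0.5) / grid[1])^2 + (sn - (gs + 0.5) / grid[2])^2
  ord <- order(bin, d2, seq_along(bin))
  sort(ord[!duplicated(bin[ord])])
}
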