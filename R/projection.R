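#' Correlation-based transition probabilities between neighboring cells
#'
#' For each cell `j` and neighbor `j'`, the probability that `j`
#' transitions to `j'` applies an exponential kernel to the Pearson
#' correlation (across genes) between `j`'s high-dimensional velocity and
#' the expression displacement `delta_jj' = s_j' - s_j`:
#' `P_jj' ~ exp(corr(v_j, delta_jj') / sigma)`, row-normalized over the
#' neighbor set. A cell with an all-zero velocity (or a constant
#' displacement) gets a uniform row.
#'
#' @param velocity Cells x genes matrix of (spliced) velocities.
#' @param expression Cells x genes spliced expression matrix.
#' @param graph A `"neighbor_graph"` defining each cell's neighbor set.
#' @param sigma Kernel width (default 0.05).
#' @return An object of class `"transition_matrix"`: list with `probs`
#'   (cells x k, rows summing to 1), `indices` (the neighbor sets), and
#'   `sigma`.
#' @export
transition_matrix <- function(velocity, expression, graph, sigma = 0.05) {
  stopifnot(inherits(graph, "neighbor_graph"), sigma > 0)
  velocity <- as.matrix(velocity)
  expression <- as.matrix(expression)
  stopifnot(all(dim(velocity) == dim(expression)),
            nrow(velocity) == nrow(graph$indices))
  n <- nrow(velocity); k <- graph$k
  probs <- matrix(0, n, k)
  for (i in seq_len(n)) {
    j <- graph$indices[i, ]
    delta <- expression[j, , drop = FALSE] -
      matrix(expression[i, ], k, ncol(expression), byrow = TRUE)
    v <- velocity[i, ]
    if (stats::sd(v) == 0) {
      probs[i, ] <- 1 / k
      next
    }
    cc <- apply(delta, 1, function(d) {
      if (stats::sd(d) == 0) 0 else cor(v, d)
    })
    w <- exp(cc / sigma)
    probs[i, ] <- w / sum(w)
  }
  structure(list(probs = probs, indices = graph$indices, sigma = sigma),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d cells, %d neighbors, sigma = %g\n",
              nrow(x$probs), ncol(x$probs), x$sigma))
  invisible(x)
}

#' Project high-dimensional velocities onto a 2-D embedding
#'
#' The embedding velocity of cell `j` is the probability-weighted mean of
#' unit displacement vectors toward its neighbors, centered by the uniform
#' distribution: `v~_j = sum_j' (P_jj' - 1/|N|) theta^_jj'`, where
#' `theta^_jj'` is the unit vector from `j` to `j'` in the embedding.
#' Under a uniform transition row the projected velocity is exactly zero.
#' Coincident cells contribute a zero unit vector.
#'
#' @param tm A `"transition_matrix"`.
#' @param coords Cells x 2 embedding coordinates.
#' @return An object of class `"embedding_velocity"`: list with `coords`
#'   and `vel2d` (both cells x 2).
#' @export
project_velocity <- function(tm, coords) {
  stopifnot(inherits(tm, "transition_matrix"))
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) == nrow(tm$probs),
            all(is.finite(coords)))
  n <- nrow(coords); k <- ncol(tm$probs)
  vel <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    j <- tm$indices[i, ]
    disp <- coords[j, , drop = FALSE] -
      matrix(coords[i, ], k, 2, byrow = TRUE)
    len <- sqrt(rowSums(disp^2))
    unit <- disp / ifelse(len < 1e-12, Inf, len)  # coincident -> zero vector
    w <- tm$probs[i, ] - 1 / k
    vel[i, ] <- colSums(unit * w)
  }
  structure(list(coords = coords, vel2d = vel), class = "embedding_velocity")
}

#' @export
print.embedding_velocity <- function(x, ...) {
  cat(sprintf("embedding_velocity: %d cells\n", nrow(x$coords)))
  invisible(x)
}
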