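#' Meta-cell grid over an embedding
#'
#' Bins the embedding bounding box into a uniform rectangular grid; each
#' occupied bin ("meta cell") carries the mean projected velocity of its
#' cells, smoothing abrupt vector flows before streamline tracing. Empty
#' bins carry zero velocity.
#'
#' @param emb An `"embedding_velocity"` (from [project_velocity()]), or a
#'   list with `coords` and `vel2d`.
#' @param grid_shape Two integers `(nx, ny)`.
#' @return An object of class `"metacell_grid"`: list with `grid_shape`,
#'   `origin`, `bin_size`, `cell_bin` (per-cell bin index), and `vel`
#'   (nx*ny x 2 matrix of bin velocities).
#' @export
build_grid <- function(emb, grid_shape = c(30, 30)) {
  coords <- as.matrix(emb$coords); vel <- as.matrix(emb$vel2d)
  stopifnot(ncol(coords) == 2, nrow(coords) >= 1, all(grid_shape >= 1))
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  if (any(hi - lo == 0)) {
    stop("degenerate bounding box: all cells coincide along an axis",
         call. = FALSE)
  }
  bin_size <- (hi - lo) / grid_shape
  bx <- pmin(floor((coords[, 1] - lo[1]) / bin_size[1]), grid_shape[1] - 1)
  by <- pmin(floor((coords[, 2] - lo[2]) / bin_size[2]), grid_shape[2] - 1)
  cell_bin <- as.integer(bx * grid_shape[2] + by + 1)
  nbin <- prod(grid_shape)
  vx <- rowsum(vel[, 1], cell_bin)
  vy <- rowsum(vel[, 2], cell_bin)
  cnt <- as.numeric(table(factor(cell_bin, levels = seq_len(nbin))))
  binvel <- matrix(0, nbin, 2)
  occupied <- as.integer(rownames(vx))
  binvel[occupied, 1] <- vx / cnt[occupied]
  binvel[occupied, 2] <- vy / cnt[occupied]
  structure(list(grid_shape = as.integer(grid_shape), origin = lo,
                 bin_size = bin_size, cell_bin = cell_bin, vel = binvel),
            class = "metacell_grid")
}

# bin index of arbitrary positions; NA outside the grid
grid_bin <- function(grid, pos) {
  gx <- floor((pos[, 1] - grid$origin[1]) / grid$bin_size[1])
  gy <- floor((pos[, 2] - grid$origin[2]) / grid$bin_size[2])
  ok <- gx >= 0 & gx < grid$grid_shape[1] & gy >= 0 & gy < grid$grid_shape[2]
  out <- rep(NA_integer_, nrow(pos))
  out[ok] <- as.integer(gx[ok] * grid$grid_shape[2] + gy[ok] + 1)
  out
}

#' Trace stochastic velocity streamlines
#'
#' From every cell, `n_repeats` trajectories follow the meta-cell velocity
#' field: each step moves by the current bin's velocity rotated by an
#' independent Gaussian swaying angle `N(0, sway_sd)`, times `dt`. A
#' trajectory stops after `n_steps` steps, on leaving the grid, or in a
#' zero-velocity bin.
#'
#' @param grid A `"metacell_grid"`.
#' @param dt Step duration.
#' @param n_steps Maximum steps per trajectory.
#' @param n_repeats Trajectories per starting cell.
#' @param sway_sd Standard deviation of the swaying angle (radians,
#'   default `pi/6`); draws are not truncated.
#' @param starts Optional matrix of starting positions (default: the cell
#'   positions implied by the grid is not stored, so pass the embedding
#'   coordinates used to build the grid).
#' @param seed Integer seed; traced positions are bit-reproducible.
#' @return An object of class `"trajectory_pool"`: list with `paths` (list
#'   of step-position matrices), `cell` and `repeat_id` per path, and `dt`.
#' @export
trace_trajectories <- function(grid, starts, dt = 1, n_steps = 500,
                               n_repeats = 10, sway_sd = pi / 6, seed = 1) {
  stopifnot(inherits(grid, "metacell_grid"), dt > 0, n_steps >= 1,
            n_repeats >= 1)
  starts <- as.matrix(starts)
  n <- nrow(starts)
  set.seed(seed)
  npath <- n * n_repeats
  pos <- starts[rep(seq_len(n), each = n_repeats), , drop = FALSE]
  alive <- rep(TRUE, npath)
  hist <- vector("list", npath)
  for (p in seq_len(npath)) hist[[p]] <- pos[p, ]
  for (step in seq_len(n_steps)) {
    if (!any(alive)) break
    ai <- which(alive)
    b <- grid_bin(grid, pos[ai, , drop = FALSE])
    v <- matrix(0, length(ai), 2)
    v[!is.na(b), ] <- grid$vel[b[!is.na(b)], , drop = FALSE]
    speed <- sqrt(rowSums(v^2))
    stopnow <- is.na(b) | speed < 1e-12
    theta <- rnorm(length(ai), 0, sway_sd)
    ct <- cos(theta); st <- sin(theta)
    vr <- cbind(ct * v[, 1] - st * v[, 2], st * v[, 1] + ct * v[, 2])
    newpos <- pos[ai, , drop = FALSE] + vr * dt
    for (ii in seq_along(ai)) {
      p <- ai[ii]
      if (stopnow[ii]) {
        alive[p] <- FALSE
      } else {
        pos[p, ] <- newpos[ii, ]
        hist[[p]] <- rbind(hist[[p]], newpos[ii, ])
      }
    }
  }
  paths <- lapply(hist, function(h) {
    m <- matrix(h, ncol = 2)
    colnames(m) <- c("x", "y")
    m
  })
  structure(list(paths = paths,
                 cell = rep(seq_len(n), each = n_repeats),
                 repeat_id = rep(seq_len(n_repeats), n),
                 dt = dt),
            class = "trajectory_pool")
}

#' @export
print.trajectory_pool <- function(x, ...) {
  cat(sprintf("trajectory_pool: %d paths from %d cells\n",
              length(x$paths), max(x$cell)))
  invisible(x)
}

traverse_length <- function(path) {
  if (nrow(path) < 2) return(0)
  sum(sqrt(rowSums(diff(path)^2)))
}

# mean distance from each point of the shorter path to the nearest point of
# the longer one; paths are subsampled for tractability
path_similarity <- function(a, b, max_pts = 60) {
  if (nrow(a) > nrow(b)) { tmp <- a; a <- b; b <- tmp }
  sub <- function(m) {
    if (nrow(m) <= max_pts) m else m[round(seq(1, nrow(m), length.out = max_pts)), , drop = FALSE]
  }
  a <- sub(a); b <- sub(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  mean(sqrt(pmax(apply(d2, 1, min), 0)))
}

#' Select long trajectories from a pool
#'
#' Greedy selection of the pool's dominant paths: iteratively pick the
#' trajectory with the largest traverse length (accumulated step distance)
#' and eliminate all trajectories within `similarity_cutoff` of it (mean
#' closest-point distance), until the pool is exhausted or `n_path`
#' trajectories are selected. Stagnating paths -- net displacement below
#' `min_straightness` of the traversed distance, typically paths trapped in
#' a noisy vortex of the meta-cell field -- are excluded beforehand, since
#' their accumulated length does not reflect progress along the manifold.
#'
#' @param pool A `"trajectory_pool"`.
#' @param similarity_cutoff Elimination radius; defaults to one grid-cell
#'   diagonal when `grid` is supplied, otherwise 5% of the pool's spatial
#'   extent.
#' @param n_path Maximum number of long trajectories (default unlimited).
#' @param grid Optional `"metacell_grid"` used for the default cutoff.
#' @param min_straightness Minimum net-displacement to traverse-length
#'   ratio for a path to be eligible.
#' @return An object of class `"long_trajectories"`: list with `paths`,
#'   `pool_index`, `lengths`, `cutoff`, `dt`.
#' @export
select_long_trajectories <- function(pool, similarity_cutoff = NULL,
                                     n_path = Inf, grid = NULL,
                                     min_straightness = 0.3) {
  stopifnot(inherits(pool, "trajectory_pool"), length(pool$paths) >= 1)
  if (is.null(similarity_cutoff)) {
    similarity_cutoff <- if (!is.null(grid)) {
      sqrt(sum(grid$bin_size^2))
    } else {
      all_pts <- do.call(rbind, pool$paths)
      0.05 * sqrt(sum(apply(all_pts, 2, function(z) diff(range(z)))^2))
    }
  }
  lens <- vapply(pool$paths, traverse_length, numeric(1))
  net <- vapply(pool$paths, function(p) {
    sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  }, numeric(1))
  eligible <- lens == 0 | net >= min_straightness * lens
  if (!any(eligible)) eligible <- rep(TRUE, length(lens))
  remaining <- order(lens, decreasing = TRUE)
  remaining <- remaining[eligible[remaining]]
  chosen <- integer(0)
  while (length(remaining) > 0 && length(chosen) < n_path) {
    top <- remaining[1]
    chosen <- c(chosen, top)
    keep <- vapply(remaining, function(i) {
      path_similarity(pool$paths[[i]], pool$paths[[top]]) > similarity_cutoff
    }, logical(1))
    remaining <- remaining[keep]
  }
  structure(list(paths = pool$paths[chosen], pool_index = chosen,
                 lengths = lens[chosen], cutoff = similarity_cutoff,
                 dt = pool$dt),
            class = "long_trajectories")
}

#' @export
print.long_trajectories <- function(x, ...) {
  cat(sprintf("long_trajectories: %d selected (cutoff %.3g)\n",
              length(x$paths), x$cutoff))
  invisible(x)
}

#' Assign cells to long trajectories and read off raw pseudotime
#'
#' A cell's cluster is the long trajectory on or around which the majority
#' of its traced repeats terminate (within the elimination radius); its
#' raw time is the time coordinate (step index times `dt`) of the closest
#' point of that trajectory to the cell's position. Cells none of whose
#' repeats reach a long trajectory are assigned to the nearest one and
#' flagged.
#'
#' @param coords Cells x 2 embedding positions (the trace starts).
#' @param long_set A `"long_trajectories"`.
#' @param pool The `"trajectory_pool"` the selection came from.
#' @return A data frame with columns `cell`, `cluster`, `raw_time`,
#'   `flagged`.
#' @export
assign_pseudotime <- function(coords, long_set, pool) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  m <- length(long_set$paths)
  radius <- long_set$cutoff
  ends <- t(vapply(pool$paths, function(p) p[nrow(p), ], numeric(2)))
  # nearest long trajectory (and distance) for every path endpoint
  end_near <- vapply(seq_len(m), function(k) {
    p <- long_set$paths[[k]]
    d2 <- outer(rowSums(ends^2), rowSums(p^2), "+") - 2 * tcrossprod(ends, p)
    sqrt(pmax(apply(d2, 1, min), 0))
  }, numeric(nrow(ends)))
  end_near <- matrix(end_near, nrow = nrow(ends))

  cluster <- integer(n); flagged <- logical(n); raw_time <- numeric(n)
  for (i in seq_len(n)) {
    mine <- which(pool$cell == i)
    hits <- apply(end_near[mine, , drop = FALSE], 1, function(d) {
      j <- which.min(d)
      if (d[j] <= radius) j else NA_integer_
    })
    hits <- hits[!is.na(hits)]
    if (length(hits) > 0) {
      tab <- table(hits)
      cluster[i] <- as.integer(names(tab)[which.max(tab)])
    } else {
      # no repeat terminates near any long trajectory: nearest one wins
      d <- vapply(seq_len(m), function(k) {
        p <- long_set$paths[[k]]
        min(sqrt(rowSums((p - matrix(coords[i, ], nrow(p), 2, byrow = TRUE))^2)))
      }, numeric(1))
      cluster[i] <- which.min(d)
      flagged[i] <- TRUE
    }
    p <- long_set$paths[[cluster[i]]]
    d2 <- rowSums((p - matrix(coords[i, ], nrow(p), 2, byrow = TRUE))^2)
    raw_time[i] <- (which.min(d2) - 1) * long_set$dt
  }
  data.frame(cell = seq_len(n), cluster = cluster, raw_time = raw_time,
             flagged = flagged)
}

#' Merge trajectory time zones into one pseudotime
#'
#' Cells assigned to different long trajectories carry only relative
#' ("time zone") times. Overlapping cells -- mutual nearest neighbors in
#' the embedding belonging to different clusters -- are assumed to share
#' the same time, giving a shift estimate `dt_lm = median(t_l - t_m)` per
#' cluster pair. The cluster graph must be a forest: each tree is
#' traversed from its lowest-id node, accumulating shifts; a cycle aborts
#' with the advice to reduce `n_path`. All times are finally min-max
#' rescaled to `[0, 1]`.
#'
#' @param assignment Data frame from [assign_pseudotime()].
#' @param coords Cells x 2 embedding positions.
#' @param k Neighbors for the mutual-kNN overlap detection.
#' @return `assignment` with an added `pseudotime` column in `[0, 1]`.
#' @export
adjust_time_zones <- function(assignment, coords, k = 10) {
  coords <- as.matrix(coords)
  n <- nrow(assignment)
  clusters <- sort(unique(assignment$cluster))
  if (length(clusters) > 1 && n > k) {
    g <- knn_graph(coords, k, mode = "embedding")
    edges <- list()
    for (i in seq_len(n)) {
      for (j in g$indices[i, ]) {
        if (i < j && i %in% g$indices[j, ] &&
            assignment$cluster[i] != assignment$cluster[j]) {
          edges[[length(edges) + 1]] <- c(i, j)
        }
      }
    }
    shifts <- list()
    if (length(edges) > 0) {
      em <- do.call(rbind, edges)
      cl <- cbind(assignment$cluster[em[, 1]], assignment$cluster[em[, 2]])
      swap <- cl[, 1] > cl[, 2]
      em[swap, ] <- em[swap, 2:1]; cl[swap, ] <- cl[swap, 2:1]
      key <- paste(cl[, 1], cl[, 2])
      for (kk in unique(key)) {
        sel <- key == kk
        # dt_lm = t_l - t_m over overlapping cells: cluster m needs + dt_lm
        dlm <- median(assignment$raw_time[em[sel, 1]] -
                      assignment$raw_time[em[sel, 2]])
        shifts[[kk]] <- c(cl[sel, 1][1], cl[sel, 2][1], dlm)
      }
    }
    tau <- setNames(rep(0, length(clusters)), clusters)
    if (length(shifts) > 0) {
      es <- do.call(rbind, shifts)
      ig <- igraph::graph_from_data_frame(
        data.frame(from = as.character(es[, 1]), to = as.character(es[, 2])),
        directed = FALSE,
        vertices = data.frame(name = as.character(clusters)))
      n_comp <- igraph::components(ig)$no
      if (igraph::ecount(ig) > igraph::vcount(ig) - n_comp) {
        stop("cycle in the time-zone graph; the time adjustment fails. ",
             "We suggest reducing the n_path parameter.", call. = FALSE)
      }
      # per tree, traverse from the lowest-id node accumulating shifts
      comp <- igraph::components(ig)$membership
      for (tree in unique(comp)) {
        nodes <- as.integer(names(comp)[comp == tree])
        visited <- setNames(logical(length(nodes)), nodes)
        queue <- min(nodes)
        visited[as.character(queue)] <- TRUE
        while (length(queue) > 0) {
          o <- queue[1]; queue <- queue[-1]
          for (r in seq_len(nrow(es))) {
            l <- es[r, 1]; m <- es[r, 2]; dlm <- es[r, 3]
            if (l == o && !visited[as.character(m)]) {
              tau[as.character(m)] <- tau[as.character(o)] + dlm
              visited[as.character(m)] <- TRUE
              queue <- c(queue, m)
            } else if (m == o && !visited[as.character(l)]) {
              tau[as.character(l)] <- tau[as.character(o)] - dlm
              visited[as.character(l)] <- TRUE
              queue <- c(queue, l)
            }
          }
        }
      }
    }
    adjusted <- assignment$raw_time + tau[as.character(assignment$cluster)]
  } else {
    adjusted <- assignment$raw_time
  }
  rng <- range(adjusted)
  assignment$pseudotime <- if (diff(rng) == 0) rep(0, n) else {
    (adjusted - rng[1]) / diff(rng)
  }
  assignment
}

#' Gene-shared pseudotime from projected velocities
#'
#' The full pipeline: meta-cell grid, stochastic streamline tracing from
#' every cell, greedy long-trajectory selection, per-cell time assignment,
#' and graph-based merging of the trajectory time zones into a single
#' pseudotime in `[0, 1]`.
#'
#' @param emb An `"embedding_velocity"`.
#' @param grid_shape Meta-cell grid resolution.
#' @param dt,n_steps,n_repeats,sway_sd Tracing parameters (see
#'   [trace_trajectories()]); `dt = NULL` (default) scales the step so a
#'   fast meta cell advances about half a grid cell per step.
#' @param similarity_cutoff,n_path Selection parameters (see
#'   [select_long_trajectories()]).
#' @param overlap_k Neighbors for time-zone overlap detection.
#' @param seed Integer seed.
#' @return A data frame with columns `cell`, `cluster`, `raw_time`,
#'   `flagged`, `pseudotime`; the long trajectories are attached as
#'   attribute `"long_trajectories"`.
#' @export
estimate_pseudotime <- function(emb, grid_shape = c(30, 30), dt = NULL,
                                n_steps = 500, n_repeats = 10,
                                sway_sd = pi / 6, similarity_cutoff = NULL,
                                n_path = Inf, overlap_k = 10, seed = 1) {
  grid <- build_grid(emb, grid_shape)
  if (is.null(dt)) {
    speeds <- sqrt(rowSums(grid$vel^2))
    fast <- stats::quantile(speeds[speeds > 0], 0.9)
    dt <- if (length(fast) == 0 || fast == 0) 1 else {
      0.5 * mean(grid$bin_size) / fast
    }
  }
  pool <- trace_trajectories(grid, emb$coords, dt = dt, n_steps = n_steps,
                             n_repeats = n_repeats, sway_sd = sway_sd,
                             seed = seed)
  long_set <- select_long_trajectories(pool, similarity_cutoff, n_path, grid)
  assignment <- assign_pseudotime(emb$coords, long_set, pool)
  out <- adjust_time_zones(assignment, emb$coords, k = overlap_k)
  attr(out, "long_trajectories") <- long_set
  out
}
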