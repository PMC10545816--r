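emb_of <- function(coords, vel) list(coords = coords, vel2d = vel)

test_that("meta-cell grid averages enclosed velocities", {
  emb <- emb_of(rbind(c(0.5, 0.4), c(1.5, 0.6)), rbind(c(1, 0), c(0, 2)))
  grid <- build_grid(emb, c(2, 1))
  expect_equal(grid$vel[1, ], c(1, 0))
  expect_equal(grid$vel[2, ], c(0, 2))
  # opposite velocities in one bin cancel
  emb2 <- emb_of(rbind(c(0.2, 0.2), c(0.3, 0.3), c(5, 5)),
                 rbind(c(1, 1), c(-1, -1), c(1, 0)))
  g2 <- build_grid(emb2, c(2, 2))
  b <- relayvelo:::grid_bin(g2, matrix(c(0.25, 0.25), 1, 2))
  expect_equal(g2$vel[b, ], c(0, 0))
  expect_error(build_grid(emb_of(rbind(c(1, 1), c(1, 2)),
                                 matrix(0, 2, 2)), c(3, 3)), "degenerate")
})

test_that("grid bin means match brute-force averaging", {
  set.seed(5)
  coords <- matrix(runif(200), 100, 2)
  vel <- matrix(rnorm(200), 100, 2)
  grid <- build_grid(emb_of(coords, vel), c(5, 5))
  bins <- grid$cell_bin
  for (b in unique(bins)) {
    expect_equal(grid$vel[b, ], colMeans(vel[bins == b, , drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("tracing follows the field and stops appropriately", {
  # zero field: every trajectory is a single point
  emb0 <- emb_of(matrix(runif(20), 10, 2), matrix(0, 10, 2))
  grid0 <- build_grid(emb0, c(3, 3))
  pool0 <- trace_trajectories(grid0, emb0$coords, n_repeats = 2, seed = 1)
  expect_true(all(vapply(pool0$paths, nrow, integer(1)) == 1))
  # constant field, no sway: straight path with known traverse length
  coords <- rbind(c(0, 0), c(10, 10))
  vel <- rbind(c(0.5, 0), c(0.5, 0))
  grid <- build_grid(emb_of(coords, vel), c(1, 1))
  pool <- trace_trajectories(grid, matrix(c(0, 5), 1, 2), dt = 1,
                             n_steps = 12, n_repeats = 1, sway_sd = 0,
                             seed = 2)
  p <- pool$paths[[1]]
  expect_equal(unique(p[, "y"]), 5)
  # capped by n_steps: length = n_steps * |v| * dt
  expect_equal(relayvelo:::traverse_length(p), 12 * 0.5 * 1, tolerance = 1e-12)
  expect_identical(nrow(p), 13L)
  # seeded reproducibility is bit-exact
  grid_r <- build_grid(emb_of(matrix(runif(40), 20, 2),
                              matrix(rnorm(40, 0, 0.2), 20, 2)), c(4, 4))
  a <- trace_trajectories(grid_r, grid_r$origin + t(matrix(c(0.3, 0.3))),
                          n_steps = 50, n_repeats = 3, seed = 7)
  b <- trace_trajectories(grid_r, grid_r$origin + t(matrix(c(0.3, 0.3))),
                          n_steps = 50, n_repeats = 3, seed = 7)
  expect_identical(a$paths, b$paths)
})

make_path <- function(x0, y0, dx, dy, n) {
  cbind(x = x0 + dx * (0:(n - 1)), y = y0 + dy * (0:(n - 1)))
}

test_that("long-trajectory selection is greedy with elimination", {
  mk_pool <- function(paths) {
    structure(list(paths = paths, cell = seq_along(paths),
                   repeat_id = rep(1L, length(paths)), dt = 1),
              class = "trajectory_pool")
  }
  one <- mk_pool(list(make_path(0, 0, 1, 0, 5)))
  expect_length(select_long_trajectories(one, 0.5)$paths, 1)
  # two identical trajectories: exactly one survives
  two <- mk_pool(list(make_path(0, 0, 1, 0, 5), make_path(0, 0, 1, 0, 5)))
  expect_length(select_long_trajectories(two, 0.5)$paths, 1)
  # two well-separated straight paths plus jittered copies: exactly two
  set.seed(3)
  base1 <- make_path(0, 0, 1, 0, 20)
  base2 <- make_path(0, 50, 1, 0, 18)
  jitter_path <- function(p) p + matrix(rnorm(length(p), 0, 0.05), nrow(p), 2)
  pool <- mk_pool(c(list(base1, base2),
                    lapply(1:5, function(i) jitter_path(base1)),
                    lapply(1:5, function(i) jitter_path(base2))))
  sel <- select_long_trajectories(pool, similarity_cutoff = 2)
  expect_length(sel$paths, 2)
})

test_that("pseudotime assignment reads times off the nearest trajectory", {
  long_path <- make_path(0, 0, 1, 0, 11)           # times 0..10
  pool <- structure(list(paths = rep(list(long_path), 4),
                         cell = 1:4, repeat_id = rep(1L, 4), dt = 1),
                    class = "trajectory_pool")
  long_set <- structure(list(paths = list(long_path), pool_index = 1L,
                             lengths = 10, cutoff = 1, dt = 1),
                        class = "long_trajectories")
  coords <- rbind(c(0, 0.1), c(3.4, -0.2), c(7.1, 0.3), c(10, 0))
  asg <- assign_pseudotime(coords, long_set, pool)
  expect_equal(asg$raw_time, c(0, 3, 7, 10))
  expect_true(all(diff(asg$raw_time) > 0))  # monotone along the path
  expect_equal(asg$cluster, rep(1L, 4))
})

test_that("two-branch fixtures keep their branch membership", {
  b1 <- make_path(0, 0, 1, 0, 10)
  b2 <- make_path(0, 20, 1, 0, 10)
  # each cell's traced paths terminate on its own branch
  paths <- c(rep(list(b1), 3), rep(list(b2), 3))
  pool <- structure(list(paths = paths, cell = c(1, 1, 1, 2, 2, 2),
                         repeat_id = rep(1:3, 2), dt = 1),
                    class = "trajectory_pool")
  long_set <- structure(list(paths = list(b1, b2), pool_index = 1:2,
                             lengths = c(9, 9), cutoff = 1, dt = 1),
                        class = "long_trajectories")
  coords <- rbind(c(5, 0.5), c(5, 19.5))
  asg <- assign_pseudotime(coords, long_set, pool)
  expect_equal(asg$cluster, c(1L, 2L))
  expect_false(any(asg$flagged))
})

test_that("time zones merge by a rigid shift and rescale to [0, 1]", {
  # one cluster: rescaling only, order preserved
  one <- data.frame(cell = 1:4, cluster = 1L, raw_time = c(2, 4, 6, 10),
                    flagged = FALSE)
  out1 <- adjust_time_zones(one, matrix(runif(8), 4, 2), k = 2)
  expect_equal(out1$pseudotime, c(0, 0.25, 0.5, 1))
  # two clusters overlapping in space with shift 5
  set.seed(8)
  n <- 30
  coords <- rbind(cbind(runif(n), runif(n)), cbind(runif(n), runif(n)))
  asg <- data.frame(cell = 1:(2 * n), cluster = rep(c(1L, 2L), each = n),
                    raw_time = c(runif(n, 5, 6), runif(n, 0, 1)),
                    flagged = FALSE)
  out <- adjust_time_zones(asg, coords, k = 10)
  # cluster 2 is shifted up by ~5 so the merged times coincide
  expect_lt(abs(median(out$pseudotime[asg$cluster == 1]) -
                median(out$pseudotime[asg$cluster == 2])), 0.15)
  # order preserved within each cluster (rigid shift)
  for (cl in 1:2) {
    sel <- asg$cluster == cl
    expect_identical(order(out$pseudotime[sel]), order(asg$raw_time[sel]))
  }
  expect_equal(range(out$pseudotime), c(0, 1))
})

test_that("a cyclic time-zone graph aborts with the n_path advice", {
  set.seed(9)
  n <- 20
  coords <- do.call(rbind, lapply(1:3, function(i) cbind(runif(n), runif(n))))
  asg <- data.frame(cell = 1:(3 * n), cluster = rep(1:3, each = n),
                    raw_time = runif(3 * n), flagged = FALSE)
  expect_error(adjust_time_zones(asg, coords, k = 10), "n_path")
})

test_that("pseudotime recovers the flow order of an analytic field", {
  # open C-shaped flow: cells along a quarter circle, field tangent
  set.seed(10)
  n <- 300
  t0 <- sort(runif(n))
  theta <- t0 * pi / 2
  coords <- cbind(cos(theta), sin(theta)) +
    matrix(rnorm(2 * n, 0, 0.02), n, 2)
  vel <- cbind(-sin(theta), cos(theta))
  pt <- estimate_pseudotime(emb_of(coords, vel), grid_shape = c(12, 12),
                            n_repeats = 4, n_steps = 200, n_path = 2,
                            seed = 5)
  expect_true(all(pt$pseudotime >= 0 & pt$pseudotime <= 1))
  expect_gt(cor(t0, pt$pseudotime, method = "spearman"), 0.8)
})
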