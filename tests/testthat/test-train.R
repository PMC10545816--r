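test_that("relay loss matches parallel/anti-parallel geometry", {
  # two cells in the (u, s) plane; each is the other's only neighbor
  g <- structure(list(indices = matrix(c(2L, 1L), 2, 1), k = 1L,
                      mode = "phase_gene"), class = "neighbor_graph")
  # cell A at (u,s)=(1,1), cell B at (2,1). A's velocity (-0.25, 0) points
  # away from B (anti-parallel, cosine -1); B's velocity (-0.5, 0) points
  # exactly at A (parallel, cosine 1).
  out <- relay_loss(u = c(1, 2), s = c(1, 1), alpha = c(0, 0),
                    beta = c(0.5, 0.5), gamma = c(0.5, 1), g, dt = 0.5)
  expect_equal(out$per_cell_loss[1], 2)  # anti-parallel
  expect_equal(out$per_cell_loss[2], 0)  # parallel
  expect_equal(out$total_loss, sum(out$per_cell_loss))
})

test_that("relay loss equals exhaustive enumeration on a 5-cell fixture", {
  set.seed(8)
  u <- runif(5); s <- runif(5)
  alpha <- runif(5); beta <- runif(5); gamma <- runif(5)
  idx <- knn_oracle(cbind(u, s), 3)
  g <- structure(list(indices = idx, k = 3L, mode = "phase_gene"),
                 class = "neighbor_graph")
  out <- relay_loss(u, s, alpha, beta, gamma, g, dt = 0.5)
  oracle <- relay_loss_oracle(u, s, alpha, beta, gamma, idx, dt = 0.5)
  expect_equal(out$total_loss, oracle$total)
  expect_equal(out$per_cell_loss, oracle$per_cell)
})

test_that("duplicated cells contribute cosine 0, never NaN", {
  g <- structure(list(indices = matrix(c(2L, 1L), 2, 1), k = 1L,
                      mode = "phase_gene"), class = "neighbor_graph")
  out <- relay_loss(u = c(1, 1), s = c(1, 1), alpha = c(0.9, 0.9),
                    beta = c(0.1, 0.1), gamma = c(0.1, 0.1), g)
  expect_false(anyNA(out$per_cell_loss))
  expect_equal(out$per_cell_loss, c(1, 1))  # zero displacement -> cos 0
})

test_that("rate predictions are sigmoid-bounded and deterministic", {
  gene <- make_mono_gene(n = 200, seed = 4)
  cfg <- train_config(seed = 4, max_epochs = 30)
  fit <- train_gene(gene$u, gene$s, cfg)
  expect_true(all(fit$rates >= 0 & fit$rates <= 1))
  r <- predict_rates(fit$net, c(0.3, 0.3, 0.8), c(0.2, 0.2, 0.9))
  expect_identical(r[1, ], r[2, ], ignore_attr = TRUE)
  expect_equal(r$alpha[1], r$alpha[2])
  expect_warning(predict_rates(fit$net, 2, 0.5), "scale")
})

test_that("velocity from rates is the Euler displacement", {
  a <- 0.6; b <- 0.3; g <- 0.2
  v0 <- velocity_from_rates(a / b, a / g, a, b, g, dt = 0.5)
  expect_equal(v0$du, 0); expect_equal(v0$ds, 0)
  set.seed(5)
  u <- runif(10); s <- runif(10)
  al <- runif(10); be <- runif(10); ga <- runif(10)
  v1 <- velocity_from_rates(u, s, al, be, ga, dt = 0.4)
  v2 <- velocity_from_rates(u, s, al, be, ga, dt = 0.8)
  expect_equal(2 * v1$du, v2$du)
  st <- extrapolate_state(u, s, al, be, ga, dt = 0.4)
  expect_equal(v1$du, st$u_next - u)
  expect_equal(v1$ds, st$s_next - s)
})

test_that("training a mono-kinetic gene separates the two alpha phases", {
  gene <- make_mono_gene(n = 600, alpha = 2, beta = 2, gamma = 1, seed = 2)
  fit <- train_gene(gene$u, gene$s, train_config(seed = 2))
  a_ind <- mean(fit$rates$alpha[gene$induction])
  a_rep <- mean(fit$rates$alpha[!gene$induction])
  expect_gt(a_ind, 0.3)
  expect_lt(a_rep, 0.15)
  # and the direction field is mostly right
  cs <- cosine_similarity(as.matrix(fit$velocity),
                          cbind(gene$du, gene$ds))
  expect_gt(mean(cs > 0.7), 0.85)
})

test_that("training is reproducible and scale-invariant", {
  gene <- make_mono_gene(n = 300, seed = 6)
  cfg <- train_config(seed = 11, max_epochs = 60)
  f1 <- train_gene(gene$u, gene$s, cfg)
  f2 <- train_gene(gene$u, gene$s, cfg)
  expect_identical(f1$rates, f2$rates)
  expect_identical(f1$loss_history, f2$loss_history)
  # multiplying raw u and s by positive constants leaves rates unchanged
  # (power-of-two factors keep the max-scaled inputs bitwise identical)
  f3 <- train_gene(8 * gene$u, 0.25 * gene$s, cfg)
  expect_equal(f1$rates, f3$rates, tolerance = 1e-12)
})

test_that("best checkpoint objective is non-increasing and loss matches relay_loss", {
  gene <- make_mono_gene(n = 300, seed = 9)
  fit <- train_gene(gene$u, gene$s, train_config(seed = 9, max_epochs = 80))
  best_so_far <- cummin(fit$loss_history$objective)
  expect_true(all(diff(best_so_far) <= 0))
  expect_true(all(fit$loss_history$loss >= 0 & fit$loss_history$loss <= 2))
  # the reported loss equals an independent R evaluation of the relay loss
  # on the training cells at the returned rates
  keep <- fit$train_index
  us <- fit$smoothed$u / fit$scale["u_max"]
  ss <- fit$smoothed$s / fit$scale["s_max"]
  g <- knn_phase(us[keep], ss[keep], min(5, length(keep) - 1))
  rl <- relay_loss(us[keep], ss[keep], fit$rates$alpha[keep],
                   fit$rates$beta[keep], fit$rates$gamma[keep], g, dt = 0.5)
  expect_equal(fit$loss, rl$total_loss / length(keep), tolerance = 1e-10)
})

test_that("gene ranking is ascending with lexicographic ties", {
  expect_identical(rank_genes_by_loss(c(b = 0.5, a = 0.1))$gene, c("a", "b"))
  expect_identical(rank_genes_by_loss(c(z = 0.3, k = 0.3))$gene, c("k", "z"))
  # a pattern-less shuffled gene ranks below a clean kinetic gene
  gene <- make_mono_gene(n = 400, seed = 10)
  set.seed(10)
  u2 <- sample(gene$u)  # destroys the phase-portrait structure
  vr <- train_dataset(cbind(clean = gene$u, shuffled = u2),
                      cbind(clean = gene$s, shuffled = gene$s),
                      train_config(seed = 3, max_epochs = 80))
  rk <- rank_genes_by_loss(vr)
  expect_identical(rk$gene[1], "clean")
})

test_that("per-gene results are independent of the worker count", {
  gene <- make_mono_gene(n = 250, seed = 12)
  u <- cbind(g1 = gene$u, g2 = gene$u + 0.1)
  s <- cbind(g1 = gene$s, g2 = gene$s)
  cfg <- train_config(seed = 7, max_epochs = 40)
  r1 <- train_dataset(u, s, cfg, jobs = 1)
  r2 <- train_dataset(u, s, cfg, jobs = 2)
  expect_identical(r1$alpha, r2$alpha)
  expect_identical(r1$loss, r2$loss)
  # and of which other genes are trained
  r3 <- train_dataset(u, s, cfg, genes = "g2")
  expect_identical(r1$gamma[, "g2"], r3$gamma[, "g2"])
})
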