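spec_small <- function(regime, n_cells = 80, n_genes = 3, ...) {
  regime_spec(regime, n_cells = n_cells, n_genes = n_genes, ...)
}

test_that("regime rate draws respect the stated uniform bounds", {
  for (i in 1:5) {
    g <- simulate_gene(spec_small("transcriptional_boost", n_genes = 5), i)
    pre <- g$group == 1L
    expect_true(all(g$alpha[pre] >= 1.6 & g$alpha[pre] <= 2.4))
    expect_true(all(g$alpha[!pre] >= 4 & g$alpha[!pre] <= 6))
    expect_true(all(g$beta >= 1.8 & g$beta <= 2.2))
    expect_true(all(g$gamma >= 0.9 & g$gamma <= 1.1))
  }
  g <- simulate_gene(spec_small("multi_backward"), 1)
  expect_true(all(g$alpha == 0))
  g <- simulate_gene(spec_small("multi_forward"), 2)
  l1 <- g$group == 1L
  expect_true(all(g$alpha[l1] >= 0.8 & g$alpha[l1] <= 1.2))
  expect_true(all(g$gamma[!l1] >= 4 & g$gamma[!l1] <= 6))
})

test_that("mono-kinetic transcription takes exactly two values per gene", {
  g <- simulate_gene(spec_small("mono_kinetic"), 1)
  vals <- sort(unique(g$alpha))
  expect_length(vals, 2)
  expect_identical(vals[1], 0)
  expect_true(vals[2] >= 1.6 && vals[2] <= 2.4)
})

test_that("noiseless simulation matches the closed form piecewise", {
  for (regime in c("mono_kinetic", "multi_forward", "multi_backward")) {
    spec <- spec_small(regime, noise_sd = 0)
    g <- simulate_gene(spec, 1)
    rates <- relayvelo:::sim_rates(spec, 1)
    for (cell in c(1, 20, 50, 80)) {
      grp <- g$group[cell]
      if (regime == "mono_kinetic" && grp == 2L) {
        span1 <- spec$span / min(rates$beta[1], rates$gamma[1])
        sw <- closed_form_constant_rates(0, 0, rates$alpha[1], rates$beta[1],
                                         rates$gamma[1], span1)
        cf <- closed_form_constant_rates(sw$u, sw$s, 0, rates$beta[2],
                                         rates$gamma[2], g$time[cell] - span1)
      } else if (regime == "multi_backward") {
        cf <- closed_form_constant_rates(rates$start[grp, 1],
                                         rates$start[grp, 2], 0,
                                         rates$beta[grp], rates$gamma[grp],
                                         g$time[cell])
      } else {
        cf <- closed_form_constant_rates(0, 0, rates$alpha[grp],
                                         rates$beta[grp], rates$gamma[grp],
                                         g$time[cell])
      }
      expect_equal(g$u[cell], cf$u, tolerance = 1e-5)
      expect_equal(g$s[cell], cf$s, tolerance = 1e-5)
    }
  }
})

test_that("ground-truth velocities satisfy the kinetics exactly", {
  ds <- generate_dataset(spec_small("transcriptional_boost"))
  v <- instantaneous_velocity(pmax(ds$u_true, 0), pmax(ds$s_true, 0),
                              ds$true_alpha, ds$true_beta, ds$true_gamma)
  expect_equal(as.vector(ds$velocity_u), v$du)
  expect_equal(as.vector(ds$velocity_s), v$ds)
})

test_that("identical specs give bit-identical datasets", {
  a <- generate_dataset(spec_small("multi_forward", seed = 9))
  b <- generate_dataset(spec_small("multi_forward", seed = 9))
  expect_identical(a$u, b$u)
  expect_identical(a$velocity_s, b$velocity_s)
  c <- generate_dataset(spec_small("multi_forward", seed = 10))
  expect_false(identical(a$u, c$u))
})

test_that("lineage downsampling reproduces the requested ratio", {
  spec <- regime_spec("transcriptional_boost", n_cells = 2000, n_genes = 1,
                      lineage_sampling_ratio = 0.4, seed = 2)
  ds <- generate_dataset(spec)
  n_pre <- sum(ds$obs$group == 1L)
  n_post <- sum(ds$obs$group == 2L)
  expect_equal(n_post / n_pre, 0.4, tolerance = 0.05)
  full <- generate_dataset(regime_spec("transcriptional_boost",
                                       n_cells = 2000, n_genes = 1, seed = 2))
  expect_lt(nrow(ds$u), nrow(full$u))
})

test_that("dataset shapes and noise clipping hold", {
  ds <- generate_dataset(spec_small("mono_kinetic", n_cells = 60, n_genes = 4))
  expect_identical(dim(ds$u), c(60L, 4L))
  expect_true(all(ds$u >= 0) && all(ds$s >= 0))
  expect_identical(rownames(ds$u), ds$obs$cell_id)
})

test_that("Poisson dropout behaves like the Poisson zero mass", {
  z <- apply_dropout(rep(0, 10), rep(0, 10), n_neighbors = 50, seed = 1)
  expect_true(all(z$u_counts == 0))
  expect_identical(z$dropout_ratio, 1)
  lam <- 1.3
  d <- apply_dropout(rep(lam, 40), rep(lam, 40), n_neighbors = 200, seed = 2)
  expect_equal(mean(d$u_counts == 0), exp(-lam), tolerance = 0.02)
  expect_equal(d$u_smooth, rep(lam, 40), tolerance = 0.1)
  expect_error(apply_dropout(-1, 1), "non-negative")
})

test_that("the dropout grid search lands in the target band", {
  for (target in c(0.5, 0.7)) {
    combos <- dropout_rate_grid(target, tol = 0.03)
    expect_gt(nrow(combos), 0)
    expect_true(all(abs(combos$expected_dropout - target) <= 0.03))
    expect_true(all(combos$alpha >= 0.1 & combos$alpha <= 1))
  }
})

test_that("simulated dropout datasets realize the expected zero fraction", {
  dd <- simulate_dropout_dataset(n_genes = 6, n_cells = 300, target = 0.6,
                                 seed = 3)
  expect_equal(dd$dropout_ratio, 0.6, tolerance = 0.03)
  expect_true(all(dd$u >= 0))
})
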