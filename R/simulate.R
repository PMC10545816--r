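#' Specify a simulation regime
#'
#' Defines one of the four benchmark kinetic regimes:
#' \describe{
#'   \item{`mono_kinetic`}{two-step transcription: an induction phase with
#'     `alpha ~ U(1.6, 2.4)` followed by repression with `alpha = 0`;
#'     `beta ~ U(1.8, 2.2)` and `gamma ~ U(0.9, 1.1)` shared by all cells of
#'     a gene.}
#'   \item{`transcriptional_boost`}{`alpha ~ U(1.6, 2.4)` before the boost
#'     and `U(4, 6)` after; `beta ~ U(1.8, 2.2)`, `gamma ~ U(0.9, 1.1)`.}
#'   \item{`multi_forward`}{two lineages induced from the origin; lineage 1
#'     has `alpha ~ U(0.8, 1.2)`, `beta ~ U(0.4, 0.6)`,
#'     `gamma ~ U(0.2, 0.3)`; lineage 2 has `alpha ~ U(4, 6)`,
#'     `beta ~ U(0.8, 1.2)`, `gamma ~ U(4, 6)`.}
#'   \item{`multi_backward`}{`alpha = 0` in all cells,
#'     `beta, gamma ~ U(0.9, 1.1)` per lineage; lineage 1 starts near
#'     `(s = 1.3, u = 0.2)` and lineage 2 near `(s = 1, u = 1)`, both
#'     decaying.}
#' }
#'
#' Rates are drawn once per gene (per stage or lineage); cells are placed
#' uniformly in integration time along each stage/lineage, with the stage
#' switch at the midpoint of the time span. Each stage or lineage spans
#' `span` time constants of its slowest rate (`span / min(beta, gamma)`),
#' long enough to approach the fixed point without accumulating a dominant
#' steady-state pile. Gaussian noise with standard deviation
#' `noise_sd * range` is added per gene and clipped at zero.
#'
#' @param regime One of `"mono_kinetic"`, `"transcriptional_boost"`,
#'   `"multi_forward"`, `"multi_backward"`.
#' @param n_cells Number of cells (>= 2).
#' @param n_genes Number of genes (>= 1).
#' @param noise_sd Gaussian expression noise, as a fraction of each gene's
#'   dynamic range.
#' @param lineage_sampling_ratio In (0, 1]: fraction retained of the
#'   post-switch stage (two-stage regimes) or of lineage 1 (branching
#'   regimes), relative to the other group, to emulate imbalanced sampling.
#' @param seed Integer seed; identical specs give bit-identical datasets.
#' @param span Stage/lineage duration in time constants of the slowest rate.
#' @return An object of class `"regime_spec"`.
#' @export
regime_spec <- function(regime = c("mono_kinetic", "transcriptional_boost",
                                   "multi_forward", "multi_backward"),
                        n_cells = 2000, n_genes = 100, noise_sd = 0.05,
                        lineage_sampling_ratio = 1, seed = 1, span = 2) {
  regime <- match.arg(regime)
  stopifnot(n_cells >= 2, n_genes >= 1, noise_sd >= 0,
            lineage_sampling_ratio > 0, lineage_sampling_ratio <= 1,
            span > 0)
  structure(list(regime = regime, n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes), noise_sd = noise_sd,
                 lineage_sampling_ratio = lineage_sampling_ratio,
                 seed = as.integer(seed), span = span),
            class = "regime_spec")
}

#' @export
print.regime_spec <- function(x, ...) {
  cat(sprintf("regime_spec: %s, %d cells x %d genes, noise %.3g, ratio %.2g, seed %d\n",
              x$regime, x$n_cells, x$n_genes, x$noise_sd,
              x$lineage_sampling_ratio, x$seed))
  invisible(x)
}

# dataset-level cell draws shared by all genes: a developmental clock
# t_frac in [0, 1] and a lineage assignment (used by branching regimes).
sim_cells <- function(spec) {
  set.seed(gene_seed(spec$seed, "cells"))
  data.frame(
    cell_id = sprintf("cell_%04d", seq_len(spec$n_cells)),
    t_frac = runif(spec$n_cells),
    lineage = sample(c(1L, 2L), spec$n_cells, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# per-gene, per-group (stage or lineage) rate draws
sim_rates <- function(spec, gene_index) {
  set.seed(gene_seed(spec$seed, paste0("gene_", gene_index)))
  switch(spec$regime,
    mono_kinetic = list(
      alpha = c(runif(1, 1.6, 2.4), 0),
      beta = rep(runif(1, 1.8, 2.2), 2),
      gamma = rep(runif(1, 0.9, 1.1), 2)),
    transcriptional_boost = list(
      alpha = c(runif(1, 1.6, 2.4), runif(1, 4, 6)),
      beta = rep(runif(1, 1.8, 2.2), 2),
      gamma = rep(runif(1, 0.9, 1.1), 2)),
    multi_forward = list(
      alpha = c(runif(1, 0.8, 1.2), runif(1, 4, 6)),
      beta = c(runif(1, 0.4, 0.6), runif(1, 0.8, 1.2)),
      gamma = c(runif(1, 0.2, 0.3), runif(1, 4, 6))),
    multi_backward = list(
      alpha = c(0, 0),
      beta = runif(2, 0.9, 1.1),
      gamma = runif(2, 0.9, 1.1),
      start = rbind(pmax(c(0.2, 1.3) + rnorm(2, 0, 0.05), 0),
                    pmax(c(1.0, 1.0) + rnorm(2, 0, 0.05), 0)))
  )
}

# integrate the constant-rate kinetics with an adaptive Runge-Kutta scheme
# (deSolve ode45, rtol = atol = 1e-6) and evaluate at the requested times
integrate_stage <- function(y0, alpha, beta, gamma, times) {
  grid <- sort(unique(c(0, times)))
  deriv <- function(t, y, p) {
    list(c(alpha - beta * y[1], beta * y[1] - gamma * y[2]))
  }
  out <- deSolve::ode(y = c(u = y0[1], s = y0[2]), times = grid,
                      func = deriv, parms = NULL, method = "ode45",
                      rtol = 1e-6, atol = 1e-6)
  idx <- match(times, grid)
  cbind(u = out[idx, "u"], s = out[idx, "s"])
}

#' Simulate one gene of a kinetic regime
#'
#' Integrates the kinetics from `(u, s) = (0, 0)` (or the lineage start
#' points for the backward regime) with an adaptive Runge-Kutta scheme and
#' returns the per-cell noiseless and noisy abundances, the true rates, and
#' the ground-truth velocity (the instantaneous kinetics evaluated at the
#' noiseless state).
#'
#' @param spec A [regime_spec()].
#' @param gene_index Integer gene index in `1:spec$n_genes`.
#' @return A list with per-cell vectors `u`, `s` (noisy), `u_true`, `s_true`,
#'   `alpha`, `beta`, `gamma`, `du`, `ds`, `time`, and the group label
#'   `group` (stage or lineage index).
#' @export
simulate_gene <- function(spec, gene_index = 1L) {
  stopifnot(inherits(spec, "regime_spec"),
            gene_index >= 1, gene_index <= spec$n_genes)
  cells <- sim_cells(spec)
  rates <- sim_rates(spec, gene_index)
  n <- spec$n_cells
  two_stage <- spec$regime %in% c("mono_kinetic", "transcriptional_boost")

  us <- matrix(0, n, 2)
  tt <- numeric(n)
  if (two_stage) {
    group <- ifelse(cells$t_frac < 0.5, 1L, 2L)
    span1 <- spec$span / min(rates$beta[1], rates$gamma[1])
    span2 <- spec$span / min(rates$beta[2], rates$gamma[2])
    t1 <- 2 * cells$t_frac[group == 1L] * span1
    t2 <- (2 * cells$t_frac[group == 2L] - 1) * span2
    us[group == 1L, ] <- integrate_stage(c(0, 0), rates$alpha[1],
                                         rates$beta[1], rates$gamma[1], t1)
    switch_state <- integrate_stage(c(0, 0), rates$alpha[1], rates$beta[1],
                                    rates$gamma[1], span1)
    us[group == 2L, ] <- integrate_stage(as.numeric(switch_state),
                                         rates$alpha[2], rates$beta[2],
                                         rates$gamma[2], t2)
    tt[group == 1L] <- t1
    tt[group == 2L] <- span1 + t2
  } else {
    group <- cells$lineage
    for (L in 1:2) {
      idx <- which(group == L)
      spanL <- spec$span / min(rates$beta[L], rates$gamma[L])
      tL <- cells$t_frac[idx] * spanL
      y0 <- if (spec$regime == "multi_backward") {
        c(rates$start[L, 1], rates$start[L, 2])  # (u, s) start of lineage L
      } else {
        c(0, 0)
      }
      us[idx, ] <- integrate_stage(y0, rates$alpha[L], rates$beta[L],
                                   rates$gamma[L], tL)
      tt[idx] <- tL
    }
  }

  alpha <- rates$alpha[group]
  beta <- rates$beta[group]
  gamma <- rates$gamma[group]
  vel <- instantaneous_velocity(pmax(us[, 1], 0), pmax(us[, 2], 0),
                                alpha, beta, gamma)

  set.seed(gene_seed(spec$seed, paste0("noise_", gene_index)))
  u <- us[, 1]; s <- us[, 2]
  if (spec$noise_sd > 0) {
    u <- u + rnorm(n, 0, spec$noise_sd * max(diff(range(u)), 1e-12))
    s <- s + rnorm(n, 0, spec$noise_sd * max(diff(range(s)), 1e-12))
  }
  list(u = pmax(u, 0), s = pmax(s, 0), u_true = us[, 1], s_true = us[, 2],
       alpha = alpha, beta = beta, gamma = gamma,
       du = vel$du, ds = vel$ds, time = tt, group = group,
       cell_id = cells$cell_id)
}

#' Generate a full simulated dataset
#'
#' Stacks [simulate_gene()] across genes with independent rate draws but a
#' shared developmental clock (cell `j` sits at the same time fraction in
#' every gene). `lineage_sampling_ratio < 1` then discards a random subset
#' of the post-switch cells (two-stage regimes) or lineage-1 cells
#' (branching regimes) so that their count is `ratio` times the other
#' group's, emulating imbalanced lineage capture.
#'
#' @param spec A [regime_spec()].
#' @return An object of class `"simulated_dataset"`: a list with cells x
#'   genes matrices `u`, `s`, `u_true`, `s_true`, `true_alpha`, `true_beta`,
#'   `true_gamma`, `velocity_u`, `velocity_s`, a per-cell data frame `obs`
#'   (`cell_id`, `time`, `group`), and `gene_names`.
#' @examples
#' ds <- generate_dataset(regime_spec("multi_backward", n_cells = 60, n_genes = 2))
#' dim(ds$u)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "regime_spec"))
  genes <- lapply(seq_len(spec$n_genes), function(i) simulate_gene(spec, i))
  gene_names <- sprintf("gene_%04d", seq_len(spec$n_genes))
  grab <- function(field) {
    m <- vapply(genes, `[[`, numeric(spec$n_cells), field)
    dimnames(m) <- list(genes[[1]]$cell_id, gene_names)
    m
  }
  ds <- list(u = grab("u"), s = grab("s"),
             u_true = grab("u_true"), s_true = grab("s_true"),
             true_alpha = grab("alpha"), true_beta = grab("beta"),
             true_gamma = grab("gamma"),
             velocity_u = grab("du"), velocity_s = grab("ds"),
             obs = data.frame(cell_id = genes[[1]]$cell_id,
                              time = genes[[1]]$time,
                              group = genes[[1]]$group,
                              stringsAsFactors = FALSE),
             gene_names = gene_names, spec = spec)

  ratio <- spec$lineage_sampling_ratio
  if (ratio < 1) {
    # group 2 is the reference: boost keeps all pre-boost cells and
    # downsamples post-boost; branching regimes downsample lineage 1
    if (spec$regime %in% c("mono_kinetic", "transcriptional_boost")) {
      target_group <- 2L; reference <- 1L
    } else {
      target_group <- 1L; reference <- 2L
    }
    idx_t <- which(ds$obs$group == target_group)
    idx_r <- which(ds$obs$group == reference)
    n_keep <- min(length(idx_t), round(ratio * length(idx_r)))
    set.seed(gene_seed(spec$seed, "sampling"))
    keep <- sort(c(idx_r, sample(idx_t, n_keep)))
    for (f in c("u", "s", "u_true", "s_true", "true_alpha", "true_beta",
                "true_gamma", "velocity_u", "velocity_s")) {
      ds[[f]] <- ds[[f]][keep, , drop = FALSE]
    }
    ds$obs <- ds$obs[keep, , drop = FALSE]
    rownames(ds$obs) <- NULL
  }
  class(ds) <- "simulated_dataset"
  ds
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %s, %d cells x %d genes\n",
              x$spec$regime, nrow(x$u), ncol(x$u)))
  invisible(x)
}

#' Poisson technical dropout around latent abundances
#'
#' Emulates zero-inflated raw counts: for each cell, `n_neighbors`
#' pseudo-cells are drawn as `Poisson(u)` and `Poisson(s)` around the
#' latent means. The dataset-level dropout ratio is the fraction of zero
#' entries among all drawn counts.
#'
#' @param u_mean,s_mean Non-negative latent abundances, one per cell.
#' @param n_neighbors Number of pseudo-cells per cell (default 200).
#' @param seed Integer seed.
#' @return A list with `u_counts`, `s_counts` (cells x `n_neighbors`
#'   integer matrices), `u_smooth`, `s_smooth` (pseudo-cell means, the
#'   first-moment recovery of the latent state), and `dropout_ratio`.
#' @export
apply_dropout <- function(u_mean, s_mean, n_neighbors = 200, seed = 1) {
  if (any(u_mean < 0) || any(s_mean < 0)) {
    stop("latent means must be non-negative", call. = FALSE)
  }
  n <- length(u_mean)
  stopifnot(length(s_mean) == n, n_neighbors >= 1)
  set.seed(seed)
  uc <- matrix(rpois(n * n_neighbors, rep(u_mean, n_neighbors)), nrow = n)
  sc <- matrix(rpois(n * n_neighbors, rep(s_mean, n_neighbors)), nrow = n)
  list(u_counts = uc, s_counts = sc,
       u_smooth = rowMeans(uc), s_smooth = rowMeans(sc),
       dropout_ratio = mean(c(uc, sc) == 0))
}

#' Grid-search kinetic rates for a target dropout ratio
#'
#' Scans `(alpha, beta, gamma)` over `[0.1, 1.0]` in steps of 0.1 and keeps
#' the combinations whose expected zero fraction, for a trajectory started
#' at `(0, 0)` and sampled uniformly in time, falls within
#' `target +/- tol`. The expectation uses the Poisson zero mass
#' `exp(-lambda)` averaged along the closed-form trajectory.
#'
#' @param target Target dropout ratio (e.g. 0.5, 0.6, 0.7).
#' @param tol Half-width of the accepted band (default 0.03).
#' @param span Trajectory duration in time constants of the slowest rate.
#' @param step Grid step for the rates.
#' @return A data frame with columns `alpha`, `beta`, `gamma`,
#'   `expected_dropout`.
#' @export
dropout_rate_grid <- function(target, tol = 0.03, span = 2, step = 0.1) {
  vals <- seq(0.1, 1.0, by = step)
  grid <- expand.grid(alpha = vals, beta = vals, gamma = vals)
  tfrac <- seq(0.005, 0.995, length.out = 100)
  expd <- vapply(seq_len(nrow(grid)), function(i) {
    a <- grid$alpha[i]; b <- grid$beta[i]; g <- grid$gamma[i]
    tt <- tfrac * span / min(b, g)
    st <- closed_form_constant_rates(0, 0, a, b, g, tt)
    mean(c(exp(-st$u), exp(-st$s)))
  }, numeric(1))
  keep <- abs(expd - target) <= tol
  out <- grid[keep, , drop = FALSE]
  out$expected_dropout <- expd[keep]
  rownames(out) <- NULL
  out
}

#' Simulate a dropout benchmark dataset
#'
#' Generates constant-rate genes whose rates are sampled from the
#' [dropout_rate_grid()] combinations matching the target dropout band,
#' draws Poisson pseudo-cell counts around the latent trajectory, and
#' returns the first-moment (pseudo-cell mean) recovered abundances used
#' for training.
#'
#' @param n_genes,n_cells Dataset dimensions.
#' @param target Target dropout ratio.
#' @param tol Band half-width.
#' @param n_neighbors Pseudo-cells per cell.
#' @param seed Integer seed.
#' @param span Trajectory duration in slowest-rate time constants.
#' @return A list with matrices `u`, `s` (smoothed), `u_true`, `s_true`,
#'   `true_alpha`, `true_beta`, `true_gamma`, `velocity_u`, `velocity_s`,
#'   the realized `dropout_ratio`, and `gene_names`.
#' @export
simulate_dropout_dataset <- function(n_genes = 30, n_cells = 1000,
                                     target = 0.6, tol = 0.03,
                                     n_neighbors = 200, seed = 1, span = 2) {
  combos <- dropout_rate_grid(target, tol, span)
  if (nrow(combos) == 0) stop("no rate combination matches the dropout band")
  set.seed(gene_seed(seed, "dropout_combos"))
  pick <- combos[sample(nrow(combos), n_genes, replace = nrow(combos) < n_genes), ]
  set.seed(gene_seed(seed, "dropout_times"))
  tfrac <- runif(n_cells)
  gene_names <- sprintf("gene_%04d", seq_len(n_genes))
  mats <- c("u", "s", "u_true", "s_true", "true_alpha", "true_beta",
            "true_gamma", "velocity_u", "velocity_s")
  out <- setNames(lapply(mats, function(f) {
    matrix(0, n_cells, n_genes,
           dimnames = list(sprintf("cell_%04d", seq_len(n_cells)), gene_names))
  }), mats)
  zero_n <- 0; tot_n <- 0
  for (i in seq_len(n_genes)) {
    a <- pick$alpha[i]; b <- pick$beta[i]; g <- pick$gamma[i]
    tt <- tfrac * span / min(b, g)
    st <- integrate_stage(c(0, 0), a, b, g, tt)
    dr <- apply_dropout(pmax(st[, 1], 0), pmax(st[, 2], 0), n_neighbors,
                        seed = gene_seed(seed, paste0("dropout_", i)))
    vel <- instantaneous_velocity(pmax(st[, 1], 0), pmax(st[, 2], 0), a, b, g)
    out$u[, i] <- dr$u_smooth; out$s[, i] <- dr$s_smooth
    out$u_true[, i] <- st[, 1]; out$s_true[, i] <- st[, 2]
    out$true_alpha[, i] <- a; out$true_beta[, i] <- b; out$true_gamma[, i] <- g
    out$velocity_u[, i] <- vel$du; out$velocity_s[, i] <- vel$ds
    zero_n <- zero_n + sum(dr$u_counts == 0) + sum(dr$s_counts == 0)
    tot_n <- tot_n + 2 * length(dr$u_counts)
  }
  out$dropout_ratio <- zero_n / tot_n
  out$gene_names <- gene_names
  out
}

#' Write a simulated dataset to CSV files
#'
#' One file per layer (`u.csv`, `s.csv`, `alpha.csv`, `beta.csv`,
#' `gamma.csv`, `velocity_u.csv`, `velocity_s.csv`) plus `obs.csv` with the
#' per-cell metadata. Matrices are cells x genes with a `cell_id` column.
#'
#' @param ds A `"simulated_dataset"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset_csv <- function(ds, dir) {
  stopifnot(inherits(ds, "simulated_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  put <- function(m, name) {
    df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
    write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  }
  put(ds$u, "u"); put(ds$s, "s")
  put(ds$true_alpha, "alpha"); put(ds$true_beta, "beta")
  put(ds$true_gamma, "gamma")
  put(ds$velocity_u, "velocity_u"); put(ds$velocity_s, "velocity_s")
  write.csv(ds$obs, file.path(dir, "obs.csv"), row.names = FALSE)
  invisible(dir)
}
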