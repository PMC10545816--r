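#' Cosine similarity of two-dimensional vectors
#'
#' Row-wise cosine similarity between two sets of 2-vectors; zero-length
#' vectors have similarity 0 by convention.
#'
#' @param a,b Length-2 vectors or matrices with two columns.
#' @return Numeric vector of similarities in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 2), c(3, 4))  # 11 / (sqrt(5) * 5)
#' @export
cosine_similarity <- function(a, b) {
  a <- if (is.null(dim(a))) matrix(a, ncol = 2) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(b, ncol = 2) else as.matrix(b)
  stopifnot(ncol(a) == 2, ncol(b) == 2, nrow(a) == nrow(b))
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2)) * sqrt(rowSums(b^2))
  ifelse(den < 1e-24, 0, num / den)
}

#' Velocity error rate
#'
#' The percentage of cells whose predicted velocity has cosine similarity
#' below `cutoff` with the ground-truth velocity.
#'
#' @param pred,truth Cells x 2 matrices of (du, ds) velocities.
#' @param cutoff Cosine cutoff (default 0.7).
#' @return Percentage in `[0, 100]`.
#' @export
error_rate <- function(pred, truth, cutoff = 0.7) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (nrow(pred) == 0) stop("empty input", call. = FALSE)
  cs <- cosine_similarity(pred, truth)
  100 * mean(cs < cutoff)
}

#' Squared Pearson correlation between predicted and true quantities
#'
#' @param pred,truth Numeric vectors of matched values.
#' @return Squared Pearson correlation, or `NA` if either vector is
#'   constant (reported as missing rather than fabricated).
#' @export
recovery_r2 <- function(pred, truth) {
  ok <- complete.cases(pred, truth)
  pred <- pred[ok]; truth <- truth[ok]
  if (length(pred) < 3 || stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    return(NA_real_)
  }
  cor(pred, truth)^2
}

#' Per-gene rate-ratio readout from a trained model
#'
#' Pools the cell-specific predicted rates of one gene into per-phase
#' scalar ratios comparable to a simulation's ground truth. Because the
#' relay loss constrains only the direction of the velocity, a ratio is
#' identifiable where the fitted kinetics declare the corresponding
#' reaction balanced: `alpha/beta` is read at the fitted u-nullcline
#' (where `du = 0`, so `alpha/beta = u`), `gamma/beta` at the fitted
#' s-nullcline (`gamma/beta = u/s`). Ratios are rescaled to the input
#' units through the gene's max-scaling factors (`alpha/beta` by `u_max`,
#' `gamma/beta` by `u_max/s_max`, `alpha/gamma` by `s_max`). For phases
#' whose nullcline is not crossed at high expression (e.g. a repression
#' phase with `alpha ~ 0`), the plain phase mean is used.
#'
#' @param fit A `"train_result"`.
#' @param phase Optional factor/vector splitting cells into kinetic phases
#'   (e.g. induction/repression); ratios are reported per phase.
#' @param balance_frac Fraction of eligible cells nearest the nullcline
#'   used for the balance readout.
#' @return A data frame with one row per phase and columns `phase`,
#'   `alpha_over_beta`, `gamma_over_beta`, `alpha_over_gamma`.
#' @export
pooled_ratios <- function(fit, phase = NULL, balance_frac = 0.1) {
  stopifnot(inherits(fit, "train_result"))
  r <- fit$rates
  up <- fit$smoothed$u / fit$scale["u_max"]
  sp <- fit$smoothed$s / fit$scale["s_max"]
  vu <- r$alpha - r$beta * up
  vs <- r$beta * up - r$gamma * sp
  if (is.null(phase)) phase <- rep("all", nrow(r))
  mu <- unname(fit$scale["u_max"]); ms <- unname(fit$scale["s_max"])

  balance_mean <- function(ratio, resid, coord, idx) {
    hi <- idx[coord[idx] >= 0.5]
    if (length(hi) < 5) return(mean(ratio[idx]))
    bal <- hi[order(abs(resid[hi]))]
    bal <- bal[seq_len(max(5, round(balance_frac * length(hi))))]
    mean(ratio[bal])
  }
  out <- lapply(unique(phase), function(ph) {
    idx <- which(phase == ph)
    ab_raw <- r$alpha[idx] / r$beta[idx]
    # the u-nullcline is crossed at high u only when the phase is inducing;
    # otherwise the phase mean (near zero for repression) is the readout
    ab <- if (mean(r$alpha[idx]) > 0.25 && any(up[idx] >= 0.5)) {
      balance_mean(r$alpha / r$beta, vu, up, idx)
    } else {
      mean(ab_raw)
    }
    gb <- balance_mean(r$gamma / r$beta, vs, sp, idx)
    # alpha/gamma has its own balance locus (the fixed point, where both
    # fluxes vanish): read alpha-hat/gamma-hat there
    ag <- if (mean(r$alpha[idx]) > 0.25 && any(sp[idx] >= 0.5)) {
      balance_mean(r$alpha / r$gamma, abs(vu) + abs(vs), sp, idx)
    } else {
      mean(r$alpha[idx] / r$gamma[idx])
    }
    data.frame(phase = ph,
               alpha_over_beta = ab * mu,
               gamma_over_beta = gb * mu / ms,
               alpha_over_gamma = ag * ms,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Epoch at which a loss history converged
#'
#' The first checkpoint epoch after which the loss never improves by more
#' than `threshold` times its total decrease. A flat history converges at
#' the first checkpoint.
#'
#' @param epochs,losses Checkpoint epochs and loss values (as in a
#'   `"train_result"`'s `loss_history`).
#' @param threshold Fraction of the total decrease regarded as negligible.
#' @return The convergence epoch (integer).
#' @export
convergence_epoch <- function(epochs, losses, threshold = 0.01) {
  stopifnot(length(epochs) == length(losses), length(epochs) >= 2)
  running_min <- cummin(losses)
  total <- running_min[1] - running_min[length(running_min)]
  if (total <= 0) return(as.integer(epochs[1]))
  # remaining achievable improvement after each checkpoint
  remaining <- running_min - running_min[length(running_min)]
  idx <- which(remaining <= threshold * total)[1]
  as.integer(epochs[idx])
}

#' Benchmark a velocity result against simulated ground truth
#'
#' Computes per-gene error rates (cosine cutoff) of the predicted versus
#' true velocity fields, in the input units.
#'
#' @param result A `"velocity_result"`.
#' @param ds The `"simulated_dataset"` (or dropout dataset list) it was
#'   trained on.
#' @param cutoff Cosine cutoff.
#' @return Named numeric vector of per-gene error rates (percent).
#' @export
benchmark_error_rates <- function(result, ds, cutoff = 0.7) {
  vapply(seq_along(result$gene_names), function(i) {
    error_rate(cbind(result$velocity_u[, i], result$velocity_s[, i]),
               cbind(ds$velocity_u[, i], ds$velocity_s[, i]), cutoff)
  }, numeric(1)) |> setNames(result$gene_names)
}

#' Rate-ratio recovery table for a simulated benchmark
#'
#' Joins each gene's pooled predicted ratios (see [pooled_ratios()]) with
#' the simulation's ground truth. `alpha/beta` is reported per kinetic
#' phase (cells grouped by their true transcription rate being positive or
#' zero) because the two-step benchmark draws one true value per phase;
#' `gamma/beta` and `alpha/gamma` are reported once per gene.
#'
#' @param result A `"velocity_result"`.
#' @param ds The simulated dataset it was trained on (a
#'   `"simulated_dataset"` or the list from [simulate_dropout_dataset()]).
#' @param split_phases Group cells into induction/repression phases by the
#'   sign of the true transcription rate.
#' @return A data frame with one row per gene and phase: `gene`, `phase`,
#'   `ab_pred`, `ab_true`, `gb_pred`, `gb_true`, `ag_pred`, `ag_true`.
#' @export
benchmark_recovery <- function(result, ds, split_phases = TRUE) {
  rows <- lapply(seq_along(result$gene_names), function(i) {
    fit <- result$fits[[i]]
    a <- ds$true_alpha[, i]; b <- ds$true_beta[, i]; g <- ds$true_gamma[, i]
    phase <- if (split_phases) {
      ifelse(a > 0, "induction", "repression")
    } else {
      rep("all", length(a))
    }
    pr <- pooled_ratios(fit, phase)
    whole <- pooled_ratios(fit)
    do.call(rbind, lapply(seq_len(nrow(pr)), function(r) {
      sel <- phase == pr$phase[r]
      data.frame(gene = result$gene_names[i], phase = pr$phase[r],
                 ab_pred = pr$alpha_over_beta[r],
                 ab_true = mean(a[sel] / b[sel]),
                 gb_pred = whole$gamma_over_beta,
                 gb_true = mean(g[sel] / b[sel]),
                 ag_pred = whole$alpha_over_gamma,
                 ag_true = mean(a[sel] / g[sel]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
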