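#' Instantaneous RNA velocity under first-order kinetics
#'
#' The reaction kinetics of a single gene couple the unspliced abundance
#' `u` and the spliced abundance `s` through the transcription rate `alpha`,
#' the splicing rate `beta` and the degradation rate `gamma`:
#' `du/dt = alpha - beta * u` and `ds/dt = beta * u - gamma * s`.
#'
#' All arguments are recycled to a common length, so the function evaluates
#' the velocity of many cells at once.
#'
#' @param u,s Non-negative unspliced and spliced abundances.
#' @param alpha,beta,gamma Reaction rates (unitless; only ratios and the
#'   direction of the velocity vector are identifiable from snapshot data).
#' @return A list with numeric components `du` and `ds`.
#' @examples
#' instantaneous_velocity(1, 1, alpha = 2, beta = 1, gamma = 1)
#' @export
instantaneous_velocity <- function(u, s, alpha, beta, gamma) {
  n <- max(length(u), length(s), length(alpha), length(beta), length(gamma))
  u <- rep_len(u, n); s <- rep_len(s, n)
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n); gamma <- rep_len(gamma, n)
  stopifnot_finite(u = u, s = s, alpha = alpha, beta = beta, gamma = gamma)
  if (any(u < 0) || any(s < 0)) {
    stop("`u` and `s` must be non-negative abundances", call. = FALSE)
  }
  list(du = alpha - beta * u, ds = beta * u - gamma * s)
}

#' Extrapolate the expression state by one Euler step
#'
#' Advances `(u, s)` by `dt` under the discretized kinetics:
#' `u(t + dt) = u + dt * (alpha - beta * u)` and
#' `s(t + dt) = s + dt * (beta * u - gamma * s)`. The raw Euler step is
#' returned without clipping at zero: the relay loss uses only the direction
#' of the displacement, and clipping would bias its angle.
#'
#' @inheritParams instantaneous_velocity
#' @param dt Positive time increment (default 0.5, the extrapolation step
#'   used throughout the package).
#' @return A list with components `u_next` and `s_next`.
#' @examples
#' extrapolate_state(1, 1, alpha = 2, beta = 1, gamma = 1, dt = 0.5)
#' @export
extrapolate_state <- function(u, s, alpha, beta, gamma, dt = 0.5) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  v <- instantaneous_velocity(u, s, alpha, beta, gamma)
  list(u_next = u + dt * v$du, s_next = s + dt * v$ds)
}

#' Closed-form solution of the kinetics at constant rates
#'
#' Exact solution of the two-species linear system for constant
#' `(alpha, beta, gamma)`, used as the simulator's independent oracle. For
#' `beta != gamma`,
#' `u(t) = alpha/beta + (u0 - alpha/beta) exp(-beta t)` and
#' `s(t)` combines `exp(-beta t)` and `exp(-gamma t)` modes; the degenerate
#' `beta == gamma` case is handled analytically through the `t exp(-beta t)`
#' secular term rather than by perturbing the rates. As `t` grows the
#' solution converges to the fixed point `(alpha/beta, alpha/gamma)`.
#'
#' @param u0,s0 Initial abundances.
#' @param alpha Transcription rate (>= 0).
#' @param beta,gamma Positive splicing and degradation rates.
#' @param t Non-negative time (vectorized).
#' @return A list with numeric components `u` and `s`, one entry per `t`.
#' @examples
#' closed_form_constant_rates(0, 0, alpha = 0.5, beta = 0.5, gamma = 0.5, t = 50)
#' @export
closed_form_constant_rates <- function(u0, s0, alpha, beta, gamma, t) {
  stopifnot_finite(u0 = u0, s0 = s0, alpha = alpha, beta = beta,
                   gamma = gamma, t = t)
  if (length(beta) != 1L || length(gamma) != 1L || length(alpha) != 1L) {
    stop("rates must be scalars", call. = FALSE)
  }
  if (beta <= 0 || gamma <= 0) {
    stop("`beta` and `gamma` must be positive", call. = FALSE)
  }
  ustar <- alpha / beta
  sstar <- alpha / gamma
  eb <- exp(-beta * t)
  eg <- exp(-gamma * t)
  u <- ustar + (u0 - ustar) * eb
  if (abs(beta - gamma) < 1e-8 * max(beta, gamma)) {
    s <- sstar + (s0 - sstar) * eg + beta * (u0 - ustar) * t * eg
  } else {
    c1 <- beta * (u0 - ustar) / (gamma - beta)
    s <- sstar + c1 * eb + (s0 - sstar - c1) * eg
  }
  list(u = u, s = s)
}

# shared validation helper: every element of every argument must be finite
stopifnot_finite <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
      stop(sprintf("`%s` must be finite numeric", nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}
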