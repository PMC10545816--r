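# Shared fixtures, all generated in code.

# a quick two-phase (induction then repression) gene via the closed form,
# for trainer tests that do not need the full simulator
make_mono_gene <- function(n = 400, alpha = 2, beta = 2, gamma = 1,
                           span = 2, noise = 0.05, seed = 1) {
  set.seed(seed)
  half <- span / min(beta, gamma)
  tt <- runif(n, 0, 2 * half)
  pre <- tt < half
  sw <- closed_form_constant_rates(0, 0, alpha, beta, gamma, half)
  u <- s <- numeric(n)
  st1 <- closed_form_constant_rates(0, 0, alpha, beta, gamma, tt[pre])
  u[pre] <- st1$u; s[pre] <- st1$s
  st2 <- closed_form_constant_rates(sw$u, sw$s, 0, beta, gamma, tt[!pre] - half)
  u[!pre] <- st2$u; s[!pre] <- st2$s
  a_cell <- ifelse(pre, alpha, 0)
  v <- instantaneous_velocity(u, s, a_cell, beta, gamma)
  list(u = pmax(u + rnorm(n, 0, noise * diff(range(u))), 0),
       s = pmax(s + rnorm(n, 0, noise * diff(range(s))), 0),
       u_true = u, s_true = s, alpha = a_cell, beta = beta, gamma = gamma,
       du = v$du, ds = v$ds, induction = pre, time = tt)
}

# independent brute-force kNN oracle (double loop, tie-break by index)
knn_oracle <- function(x, k) {
  n <- nrow(x)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(x) - x[i, ])^2))
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  }, integer(k)))
}

# independent relay-loss oracle: literal enumeration of all neighbor pairs
relay_loss_oracle <- function(u, s, alpha, beta, gamma, idx, dt) {
  per <- numeric(length(u))
  for (i in seq_along(u)) {
    vu <- dt * (alpha[i] - beta[i] * u[i])
    vs <- dt * (beta[i] * u[i] - gamma[i] * s[i])
    nv <- sqrt(vu^2 + vs^2)
    if (nv < 1e-12) { per[i] <- 1; next }
    best <- -Inf
    for (j in idx[i, ]) {
      du <- u[j] - u[i]; ds <- s[j] - s[i]
      nd <- sqrt(du^2 + ds^2)
      cs <- if (nd < 1e-12) 0 else (vu * du + vs * ds) / (nv * nd)
      best <- max(best, cs)
    }
    per[i] <- 1 - best
  }
  list(total = sum(per), per_cell = per)
}

# reference min-max scaling used by oracles
minmax_ref <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}
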