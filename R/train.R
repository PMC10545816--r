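#' Training configuration for the per-gene velocity network
#'
#' Hyperparameters of the relay velocity learner. The network is a fully
#' connected 2-100-100-3 map from a cell's scaled `(u, s)` to
#' `(alpha, beta, gamma)`, with leaky-ReLU hidden activations and a sigmoid
#' squashing the rates into `[0, 1]`. It is trained with Adam
#' (learning rate 0.001, L2 weight decay 0.004) on the summed per-cell
#' relay loss; each epoch samples a `permutation_ratio` fraction of the
#' cells for the gradient step while checkpoints evaluate the loss on all
#' cells.
#'
#' @param hidden Hidden layer width (both layers).
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 penalty coefficient.
#' @param dt Extrapolation time step of the discretized kinetics.
#' @param n_neighbors Neighbor candidates per cell in the relay loss,
#'   built in the gene's phase plane on the (downsampled) training cells.
#' @param permutation_ratio Fraction of training cells sampled per epoch.
#' @param check_every Epochs between checkpoints (full-data loss, early
#'   stopping bookkeeping).
#' @param patience Checkpoints without improvement before stopping.
#' @param max_epochs Epoch budget.
#' @param early_stop Logical; disable to record the full loss history.
#' @param smooth_k Neighbors for first-moment smoothing of the phase
#'   portrait before training (0 disables smoothing).
#' @param downsample Grid resolution for density-normalizing downsampling
#'   of the training cells (`NULL` disables it).
#' @param orient Logical; constrain the relay's neighbor candidates by the
#'   steady-state orientation of the phase portrait (see
#'   [orientation_labels()]). Without the constraint the cosine loss cannot
#'   distinguish the two orientations of flow along a one-dimensional
#'   manifold.
#' @param deadband Half-width of the unconstrained band around the
#'   balance line, as a fraction of the largest residual.
#' @param leaky_slope Negative-side slope of the leaky-ReLU.
#' @param seed Integer seed; per-gene seeds are derived from it and the
#'   gene name so results do not depend on the worker count.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(hidden = 100, learning_rate = 0.001,
                         weight_decay = 0.004, dt = 0.5, n_neighbors = 5,
                         permutation_ratio = 0.125, check_every = 10,
                         patience = 5, max_epochs = 200, early_stop = TRUE,
                         smooth_k = 100, downsample = c(40, 40),
                         orient = TRUE, deadband = 0.05,
                         leaky_slope = 0.01, seed = 1) {
  stopifnot(permutation_ratio > 0, permutation_ratio <= 1, patience >= 1,
            check_every >= 1, dt > 0, max_epochs >= 1, n_neighbors >= 1)
  structure(list(hidden = as.integer(hidden), learning_rate = learning_rate,
                 weight_decay = weight_decay, dt = dt,
                 n_neighbors = as.integer(n_neighbors),
                 permutation_ratio = permutation_ratio,
                 check_every = as.integer(check_every),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 early_stop = isTRUE(early_stop),
                 smooth_k = as.integer(smooth_k),
                 downsample = if (is.null(downsample)) NULL else as.integer(downsample),
                 orient = isTRUE(orient), deadband = deadband,
                 leaky_slope = leaky_slope, seed = as.integer(seed)),
            class = "train_config")
}

#' Steady-state orientation of a phase portrait
#'
#' The relay cosine loss constrains the predicted velocity to point toward
#' an observed neighbor, but along a one-dimensional manifold both
#' orientations admit equally good neighbors, so the loss alone cannot
#' decide the arrow of time. This function assigns each cell the classic
#' steady-state orientation: a balance line `u = gamma0 * s` through the
#' origin is fitted to the spliced-extreme cells, cells with unspliced
#' excess above the line are inducing (`+1`, both `u` and `s` increasing)
#' and cells below are repressing (`-1`, both decreasing); cells within
#' `deadband` of the line are unconstrained (`0`).
#'
#' Portraits without an induction arm (no cells above the balance chord
#' through the u-maximal cell) are pure down-regulation; all their cells
#' are labelled `-1`.
#'
#' @param u,s Per-cell abundances (smoothed; any common scaling).
#' @param quantile Spliced quantile defining the extreme cells used to fit
#'   the balance line.
#' @param deadband Unconstrained band half-width, as a fraction of the
#'   largest residual.
#' @param induction_min Minimum fraction of cells with unspliced excess
#'   above the chord for the portrait to count as having an induction arm.
#' @return Integer vector of labels in `{-1, 0, 1}`.
#' @export
orientation_labels <- function(u, s, quantile = 0.95, deadband = 0.05,
                               induction_min = 0.02) {
  stopifnot(length(u) == length(s), length(u) >= 2)
  iu <- which.max(u)
  chord <- u[iu] / max(s[iu], 1e-12)
  above <- u > chord * s + deadband * max(u)
  if (mean(above) < induction_min) {
    r <- u - chord * s
    return(as.integer(ifelse(abs(r) < deadband * max(abs(r)), 0L, -1L)))
  }
  ext <- s >= stats::quantile(s, quantile)
  g0 <- sum(u[ext] * s[ext]) / sum(s[ext]^2)
  r <- u - g0 * s
  as.integer(ifelse(abs(r) < deadband * max(abs(r)), 0L,
                    ifelse(r > 0, 1L, -1L)))
}

#' Relay cosine loss of a rate assignment
#'
#' The per-cell loss is `1 - max_j' cos(v_j, v_jj')`, where `v_j` is the
#' displacement predicted by one Euler step of the kinetics at cell `j`'s
#' rates and `v_jj'` is the observed displacement from cell `j` to neighbor
#' `j'`; the total loss is the sum over cells. The cosine of a zero-length
#' vector is defined as 0, so duplicated cells never produce NaN.
#'
#' @param u,s Per-cell abundances (same scaling as used for the rates).
#' @param alpha,beta,gamma Per-cell rates.
#' @param graph A `"neighbor_graph"` on the same cells with at least one
#'   neighbor per cell.
#' @param dt Extrapolation step.
#' @return A list with `total_loss` (sum over cells) and `per_cell_loss`.
#' @export
relay_loss <- function(u, s, alpha, beta, gamma, graph, dt = 0.5) {
  stopifnot(inherits(graph, "neighbor_graph"))
  n <- length(u)
  if (graph$k < 1) stop("graph must have at least one neighbor per cell",
                        call. = FALSE)
  v <- instantaneous_velocity(u, s, alpha, beta, gamma)
  vu <- dt * v$du; vs <- dt * v$ds
  per_cell <- vapply(seq_len(n), function(i) {
    j <- graph$indices[i, ]
    du <- u[j] - u[i]; ds <- s[j] - s[i]
    nd <- sqrt(du^2 + ds^2)
    nv <- sqrt(vu[i]^2 + vs[i]^2)
    if (nv < 1e-12) return(1)
    cs <- ifelse(nd < 1e-12, 0, (vu[i] * du + vs[i] * ds) / (nv * nd))
    1 - max(cs)
  }, numeric(1))
  list(total_loss = sum(per_cell), per_cell_loss = per_cell)
}

#' Apply a trained network to scaled abundances
#'
#' Evaluates the rate map cell-wise; the sigmoid output layer keeps every
#' rate in `[0, 1]`. Inputs are expected on the per-gene max scaling used
#' in training; a warning is emitted if they exceed it.
#'
#' @param net Network object from a [train_gene()] result (`$net`).
#' @param u,s Scaled abundances in `[0, 1]`.
#' @return A data frame with columns `alpha`, `beta`, `gamma`.
#' @export
predict_rates <- function(net, u, s) {
  stopifnot(length(u) == length(s))
  if (max(u, s) > 1 + 1e-6) {
    warning("inputs exceed the [0, 1] training scale; ",
            "rates assume max-scaled abundances")
  }
  r <- mlp_rates_cpp(net, as.numeric(u), as.numeric(s))
  data.frame(alpha = r[, 1], beta = r[, 2], gamma = r[, 3])
}

#' Velocity implied by predicted rates
#'
#' One Euler displacement `(dt * (alpha - beta u), dt * (beta u - gamma s))`
#' on whatever scale `u`, `s` and the rates share.
#'
#' @inheritParams relay_loss
#' @return A data frame with columns `du` and `ds`.
#' @export
velocity_from_rates <- function(u, s, alpha, beta, gamma, dt = 0.5) {
  v <- instantaneous_velocity(u, s, alpha, beta, gamma)
  data.frame(du = dt * v$du, ds = dt * v$ds)
}

#' Train the velocity network for one gene
#'
#' The full per-gene procedure: first-moment smoothing of the phase
#' portrait, per-gene max scaling of `u` and `s` to `[0, 1]`,
#' density-normalizing grid downsampling of the training cells,
#' steady-state orientation labelling, and minimization of the relay
#' cosine loss with Adam and checkpointed early stopping. Rates and
#' velocities are then predicted for every cell (not only the training
#' subset); velocities are reported both on the scaled coordinates and
#' unscaled back to the input units.
#'
#' @param u,s Raw per-cell abundances for the gene.
#' @param config A [train_config()].
#' @param cell_ids Optional cell identifiers.
#' @param gene Optional gene name (used for messages).
#' @return An object of class `"train_result"`: list with per-cell `rates`
#'   (data frame `alpha`, `beta`, `gamma`, on the scaled coordinates),
#'   `velocity` (`du`, `ds` in input units), `loss` (mean per-cell relay
#'   loss at the best checkpoint), `loss_history` (data frame with the
#'   checkpoint `epoch`, the relay `loss` of Eq.-style unmasked form, and
#'   the orientation-constrained training `objective`), `converged_epoch`,
#'   `stopped_epoch`, `scale` (`u_max`,
#'   `s_max`), `net`, `train_index`, `orientation`, and `diverged`.
#' @export
train_gene <- function(u, s, config = train_config(), cell_ids = NULL,
                       gene = NULL) {
  stopifnot(inherits(config, "train_config"), length(u) == length(s))
  stopifnot_finite(u = u, s = s)
  n <- length(u)
  if (n < 2 * config$n_neighbors) {
    stop("need at least 2 * n_neighbors cells to train", call. = FALSE)
  }
  set.seed(config$seed)

  if (config$smooth_k > 0) {
    g_sm <- knn_phase(u, s, min(config$smooth_k, n - 1))
    u <- smooth_first_moment(u, g_sm)
    s <- smooth_first_moment(s, g_sm)
  }
  u_max <- max(u); s_max <- max(s)
  if (u_max <= 0 || s_max <= 0) {
    stop("gene has no expression to fit", call. = FALSE)
  }
  us <- u / u_max; ss <- s / s_max

  keep <- if (is.null(config$downsample)) seq_len(n) else {
    downsample_grid(us, ss, config$downsample)
  }
  uk <- us[keep]; sk <- ss[keep]
  # permutation_ratio counts cells of the full dataset; the per-epoch
  # sample cannot exceed the (downsampled) training set
  batch_ratio <- min(1, config$permutation_ratio * n / length(keep))
  k <- min(config$n_neighbors, length(keep) - 1)
  graph <- knn_phase(uk, sk, k)
  orient <- if (config$orient) {
    orientation_labels(uk, sk, deadband = config$deadband)
  } else {
    integer(length(keep))
  }

  fit <- train_gene_cpp(uk, sk, graph$indices, config$dt,
                        config$learning_rate, config$weight_decay,
                        config$hidden, config$leaky_slope,
                        batch_ratio, config$check_every,
                        config$patience, config$max_epochs,
                        config$early_stop, orient,
                        if (config$orient) config$max_epochs else 0L)

  rates_all <- predict_rates(fit$net, us, ss)
  v_scaled <- velocity_from_rates(us, ss, rates_all$alpha, rates_all$beta,
                                  rates_all$gamma, config$dt)
  structure(list(
    rates = rates_all,
    velocity = data.frame(du = v_scaled$du * u_max, ds = v_scaled$ds * s_max),
    velocity_scaled = v_scaled,
    loss = fit$loss,
    loss_history = data.frame(epoch = fit$epochs, loss = fit$relay_losses,
                              objective = fit$losses),
    converged_epoch = fit$best_epoch,
    stopped_epoch = fit$stopped_epoch,
    scale = c(u_max = u_max, s_max = s_max),
    smoothed = data.frame(u = u, s = s),
    net = fit$net,
    train_index = keep,
    orientation = orient,
    cell_ids = cell_ids,
    gene = gene,
    diverged = isTRUE(fit$diverged)
  ), class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("train_result%s: %d cells, loss %.4f, best epoch %d, stopped %d\n",
              if (is.null(x$gene)) "" else paste0(" [", x$gene, "]"),
              nrow(x$rates), x$loss, x$converged_epoch, x$stopped_epoch))
  invisible(x)
}

#' Train velocity networks for every gene of a dataset
#'
#' Runs [train_gene()] per gene, optionally in parallel. Each gene's seed
#' is derived from the global seed and the gene name, so results are
#' independent of the worker count and of which other genes are trained.
#'
#' @param u,s Cells x genes matrices (or a `"simulated_dataset"` passed as
#'   `u`, in which case its layers are used).
#' @param config A [train_config()].
#' @param genes Optional subset of gene names (or indices) to train.
#' @param jobs Number of parallel workers (forked; use 1 on Windows).
#' @return An object of class `"velocity_result"`: list of per-gene
#'   `"train_result"`s plus assembled matrices `velocity_u`, `velocity_s`
#'   (input units), `alpha`, `beta`, `gamma` (scaled units), `loss` per
#'   gene, and `gene_names`.
#' @export
train_dataset <- function(u, s = NULL, config = train_config(),
                          genes = NULL, jobs = 1) {
  if (inherits(u, "simulated_dataset")) {
    s <- u$s; u <- u$u
  }
  u <- as.matrix(u); s <- as.matrix(s)
  stopifnot(all(dim(u) == dim(s)))
  gene_names <- colnames(u)
  if (is.null(gene_names)) gene_names <- sprintf("gene_%04d", seq_len(ncol(u)))
  if (!is.null(genes)) {
    pick <- if (is.numeric(genes)) genes else match(genes, gene_names)
    if (anyNA(pick)) stop("unknown gene name(s)", call. = FALSE)
    u <- u[, pick, drop = FALSE]; s <- s[, pick, drop = FALSE]
    gene_names <- gene_names[pick]
  }
  cell_ids <- rownames(u)
  run_one <- function(i) {
    cfg <- config
    cfg$seed <- gene_seed(config$seed, gene_names[i])
    train_gene(u[, i], s[, i], cfg, cell_ids = cell_ids, gene = gene_names[i])
  }
  fits <- if (jobs > 1) {
    parallel::mclapply(seq_along(gene_names), run_one, mc.cores = jobs)
  } else {
    lapply(seq_along(gene_names), run_one)
  }
  bad <- vapply(fits, function(f) inherits(f, "try-error") || f$diverged,
                logical(1))
  if (any(bad)) {
    warning(sprintf("%d gene(s) flagged as diverged", sum(bad)))
  }
  grab <- function(fn) {
    m <- vapply(fits, fn, numeric(nrow(u)))
    dimnames(m) <- list(cell_ids, gene_names)
    m
  }
  structure(list(
    fits = fits,
    velocity_u = grab(function(f) f$velocity$du),
    velocity_s = grab(function(f) f$velocity$ds),
    alpha = grab(function(f) f$rates$alpha),
    beta = grab(function(f) f$rates$beta),
    gamma = grab(function(f) f$rates$gamma),
    loss = setNames(vapply(fits, `[[`, numeric(1), "loss"), gene_names),
    gene_names = gene_names,
    config = config
  ), class = "velocity_result")
}

#' @export
print.velocity_result <- function(x, ...) {
  cat(sprintf("velocity_result: %d genes x %d cells, median loss %.4f\n",
              length(x$gene_names), nrow(x$velocity_s), median(x$loss)))
  invisible(x)
}

#' Rank genes by their minimized relay loss
#'
#' A small loss indicates a phase portrait well explained by the kinetics;
#' pattern-less genes rank last. Ties are broken lexicographically by gene
#' name.
#'
#' @param result A `"velocity_result"` (or a named numeric vector of
#'   losses).
#' @return A data frame with columns `gene` and `loss`, ascending by loss.
#' @export
rank_genes_by_loss <- function(result) {
  loss <- if (inherits(result, "velocity_result")) result$loss else result
  if (is.null(names(loss))) stop("losses must be named by gene", call. = FALSE)
  ord <- order(loss, names(loss))
  data.frame(gene = names(loss)[ord], loss = unname(loss[ord]),
             stringsAsFactors = FALSE)
}
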