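#' Run the full velocity pipeline
#'
#' Executes the stages in order -- per-gene rate/velocity inference,
#' projection of the high-dimensional velocity onto a 2-D embedding, and
#' gene-shared pseudotime -- writing each stage's CSV table plus a
#' provenance JSON (package version, configuration, its hash, seed) to
#' `out_dir`. The run is deterministic given the input, configuration and
#' seed, and identical for any number of workers.
#'
#' The embedding is taken from `input$obs` (columns `embedding_1`,
#' `embedding_2`) when present; otherwise each cell's mean scaled spliced
#' and unspliced abundances serve as a surrogate portrait-like embedding,
#' which is adequate for simulated regimes where all genes share one clock.
#'
#' @param input A `"simulated_dataset"`, the list returned by
#'   [read_container()], or any list with `u` and `s` matrices (cells x
#'   genes) and optionally `obs`.
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return A list with `velocity` (`"velocity_result"`), `embedding`
#'   (`"embedding_velocity"`), `pseudotime` (data frame), and `provenance`.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  u <- as.matrix(input$u); s <- as.matrix(input$s)
  if (is.null(rownames(u))) {
    rownames(u) <- rownames(s) <- sprintf("cell_%04d", seq_len(nrow(u)))
  }

  tc <- as_train_config(config)
  vr <- train_dataset(u, s, tc, jobs = config$jobs)

  coords <- NULL
  if (!is.null(input$obs) &&
      all(c("embedding_1", "embedding_2") %in% names(input$obs))) {
    coords <- as.matrix(input$obs[, c("embedding_1", "embedding_2")])
  }
  if (is.null(coords)) {
    scale_cols <- function(m) sweep(m, 2, pmax(apply(m, 2, max), 1e-12), "/")
    coords <- cbind(rowMeans(scale_cols(s)), rowMeans(scale_cols(u)))
    colnames(coords) <- c("embedding_1", "embedding_2")
  }

  feat <- switch(config$neighbor_mode,
                 shared_spliced = s,
                 shared_spliced_unspliced = cbind(s, u),
                 embedding = coords,
                 stop("unknown neighbor_mode", call. = FALSE))
  k <- min(config$projection_k, nrow(u) - 1)
  graph <- knn_shared(feat, k, mode = config$neighbor_mode)
  # the kernel correlates velocities with first-moment-smoothed expression
  # displacements; raw displacements are noise-dominated at local scales
  smooth_g <- knn_shared(cbind(s, u), min(config$smooth_k, nrow(u) - 1),
                         mode = "shared_spliced_unspliced")
  s_smooth <- smooth_first_moment(s, smooth_g)
  tm <- transition_matrix(vr$velocity_s, s_smooth, graph, sigma = config$sigma)
  emb <- project_velocity(tm, coords)

  pt <- estimate_pseudotime(emb, grid_shape = config$grid_shape,
                            n_steps = config$n_steps,
                            n_repeats = config$n_repeats,
                            sway_sd = config$sway_sd,
                            n_path = config$n_path,
                            overlap_k = config$overlap_k,
                            seed = gene_seed(config$seed, "pseudotime"))
  pt$cell_id <- rownames(u)[pt$cell]

  provenance <- list(
    package = "relayvelo",
    version = as.character(utils::packageVersion("relayvelo")),
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    stamp <- provenance$config_hash
    vel_df <- data.frame(cell_id = rownames(u),
                         round_trip_hash = stamp,
                         vr$velocity_s, check.names = FALSE)
    write.csv(vel_df, file.path(out_dir, "velocity_s.csv"), row.names = FALSE)
    rates_long <- data.frame(
      cell_id = rep(rownames(u), times = length(vr$gene_names)),
      gene = rep(vr$gene_names, each = nrow(u)),
      alpha = as.vector(vr$alpha), beta = as.vector(vr$beta),
      gamma = as.vector(vr$gamma),
      du = as.vector(vr$velocity_u), ds = as.vector(vr$velocity_s),
      loss = rep(unname(vr$loss), each = nrow(u)),
      config_hash = stamp)
    write.csv(rates_long, file.path(out_dir, "rates.csv"), row.names = FALSE)
    proj_df <- data.frame(cell_id = rownames(u), x = emb$coords[, 1],
                          y = emb$coords[, 2], vx = emb$vel2d[, 1],
                          vy = emb$vel2d[, 2], config_hash = stamp)
    write.csv(proj_df, file.path(out_dir, "projection.csv"), row.names = FALSE)
    pt_out <- pt
    pt_out$config_hash <- stamp
    write.csv(pt_out, file.path(out_dir, "pseudotime.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(provenance, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "provenance.json"))
  }

  list(velocity = vr, embedding = emb, pseudotime = pt,
       provenance = provenance)
}
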