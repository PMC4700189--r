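# Config-driven experiment runner: named presets reproduce the package's
# reference experiments end to end (network construction, dynamics,
# analysis, artifact files, manifest).  Networks and trajectories are
# serialized as plain text (TSV matrices + JSON sidecars) so every run is
# diff-able and round-trippable.

#' Named experiment presets
#'
#' Returns the configuration list for a named experiment, or all of them.
#' Presets: `fig3` (d = 0 perceptron noise robustness), `fig4_6` (ring
#' traversal and its analysis statistics), `fig7_8` (critical marker
#' load), `fig9` (single-ring SOM), `fig10` (two-ring SOM selection),
#' `fig11` (LIF sliding bump), `fig12` (asymmetric LIF travelling wave).
#'
#' @param name Preset name, or `NULL` for the full list.
#' @return A config list (fields depend on the experiment) with `seed`
#'   unset; pass through [run_experiment()].
#' @export
experiment_presets <- function(name = NULL) {
  presets <- list(
    fig3 = list(experiment = "fig3", R = 100, N = 300, M = 100, L = 20,
                etas = seq(0, 1, 0.025), n_trials = 20),
    fig4_6 = list(experiment = "fig4_6", N = 300, k = 3, Delta = 80,
                  delta = 12, sigma = 3, dtheta = 0.1, tau = 200,
                  theta0 = 0, sweeps = 16000, max_dt = 8000),
    fig7_8 = list(experiment = "fig7_8", N = 300, Delta = 80, delta = 12,
                  sigma = 3, k_range = 6:8, seeds = 1:3,
                  dtheta = 0.1, tau = 200, theta0 = 0),
    fig9 = list(experiment = "fig9", N = 300, R = 300, delta = 12,
                sigma = 3, n_steps = 20000, eta_learn = 0.05,
                n_test = 1000),
    fig10 = list(experiment = "fig10", N = 300, R = 300, delta = 12,
                 sigma = 10, n_steps = 20000, eta_learn = 0.05,
                 n_test = 1000),
    fig11 = list(experiment = "fig11", N = 600, k = 2, Delta = 200,
                 delta = 30, duration = 3, mode = "symmetric"),
    fig12 = list(experiment = "fig12", N = 600, k = 2, Delta = 200,
                 delta = 30, duration = 3, mode = "asymmetric",
                 w_exc = 12, w_inh = 0.6))
  if (is.null(name)) presets
  else if (name %in% names(presets)) presets[[name]]
  else stop_arg_("unknown preset: ", name)
}

write_matrix_ <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  path
}

read_matrix_ <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Write a network to plain-text files
#'
#' Writes `<prefix>_weights.tsv` (dense weight matrix) and
#' `<prefix>.json` (parameters, mode, and invariant-check summary).
#'
#' @param net A `connection_matrix`.
#' @param prefix Path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "connection_matrix"))
  wfile <- paste0(prefix, "_weights.tsv")
  write_matrix_(net$weights, wfile)
  W <- net$weights
  side <- list(N = nrow(W), sigma = net$sigma, mode = net$mode,
               meta = net$meta,
               checks = list(
                 zero_diagonal = all(diag(W) == 0),
                 symmetric = isTRUE(all.equal(W, t(W))),
                 value_set = all(W %in% c(1, 0, -net$sigma))))
  jfile <- paste0(prefix, ".json")
  jsonlite::write_json(side, jfile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(wfile, jfile))
}

#' Read a network written by [write_network()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `connection_matrix`.
#' @export
read_network <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  W <- unname(read_matrix_(paste0(prefix, "_weights.tsv")))
  storage.mode(W) <- "double"
  new_connection_matrix_(W, as.numeric(side$sigma), side$mode,
                         as.list(side$meta))
}

#' Write a binary trajectory to plain text
#'
#' States go to `<prefix>_states.tsv` (one sweep per row) and the
#' parameter snapshot to `<prefix>.json`.
#'
#' @param traj A `binary_trajectory`.
#' @param prefix Path prefix.
#' @return Files written, invisibly.
#' @export
write_trajectory <- function(traj, prefix) {
  stopifnot(inherits(traj, "binary_trajectory"))
  sfile <- paste0(prefix, "_states.tsv")
  write_matrix_(traj$states, sfile)
  jfile <- paste0(prefix, ".json")
  jsonlite::write_json(list(params = traj$params, seed = traj$seed,
                            sweeps = nrow(traj$states) - 1L,
                            N = ncol(traj$states)),
                       jfile, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(sfile, jfile))
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `binary_trajectory`.
#' @export
read_trajectory <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  S <- unname(read_matrix_(paste0(prefix, "_states.tsv")))
  storage.mode(S) <- "integer"
  structure(list(states = S, thresholds = NULL,
                 params = as.list(side$params),
                 seed = side$seed),
            class = "binary_trajectory")
}

png_ok_ <- function() isTRUE(capabilities("png"))

save_raster_png_ <- function(mat, path, xlab, ylab, main) {
  if (!png_ok_()) return(NULL)
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  graphics::image(t(mat), useRaster = TRUE, xlab = xlab, ylab = ylab,
                  main = main, col = grDevices::hcl.colors(64, "viridis"))
  path
}

#' Run a named experiment end to end
#'
#' Executes the preset (or custom config) pipeline, writes all artifacts
#' under `out_dir` and returns (and writes) a run manifest with the config
#' snapshot, per-file checksums and timing.  Re-running with the same
#' config and seed reproduces identical payloads.
#'
#' @param config A preset name, or a config list as returned by
#'   [experiment_presets()] (field `experiment` selects the pipeline;
#'   `custom` runs construction + optional dynamics from the remaining
#'   fields).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (mandatory).
#' @param figures Also emit PNG figures when the device is available.
#' @return The manifest list, invisibly; also written to
#'   `manifest.json`.
#' @export
run_experiment <- function(config, out_dir, seed, figures = FALSE) {
  if (is.character(config)) config <- experiment_presets(config)
  if (missing(seed) || is.null(seed)) stop_arg_("a seed is mandatory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  cfg <- config
  cfg$seed <- as.integer(seed)
  files <- character(0)
  results <- switch(
    cfg$experiment,
    fig3 = run_fig3_(cfg, out_dir, figures),
    fig4_6 = run_fig4_6_(cfg, out_dir, figures),
    fig7_8 = run_fig7_8_(cfg, out_dir),
    fig9 = run_fig9_(cfg, out_dir, two_ring = FALSE),
    fig10 = run_fig9_(cfg, out_dir, two_ring = TRUE),
    fig11 = run_lif_(cfg, out_dir, figures),
    fig12 = run_lif_(cfg, out_dir, figures),
    custom = run_custom_(cfg, out_dir),
    stop_arg_("unknown experiment: ", cfg$experiment))
  files <- results$files
  manifest <- list(config = cfg,
                   package_version = as.character(utils::packageVersion("mmbann")),
                   wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")),
                   estimates = results$estimates,
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(f) list(
                                    exists = file.exists(f),
                                    md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the full ring-traversal experiment and its analysis
#'
#' Builds a ring network, runs threshold-accommodation dynamics over
#' several activity cycles, and computes the traversal statistics
#' (period, slope, state count, plateau, mean activity).  Marker
#' realizations whose weight disorder traps the bump (no full-ring
#' traversal; see [traverses_full_ring()]) are discarded and rebuilt
#' with a fresh construction seed, up to `max_realizations` times; the
#' number discarded is reported.
#'
#' @param N,k,Delta,delta,sigma Network construction parameters.
#' @param dtheta,tau,theta0 Accommodation parameters.
#' @param sweeps Run length.  Must allow at least one full circulation
#'   (roughly `5 * k * N` sweeps at the typical traversal speed of ~0.2
#'   states/sweep) or the traversal gate rejects every realization; the
#'   default covers 3+ periods of the reference configuration.
#' @param max_dt Largest offset of the distance curve (beyond the
#'   expected period).
#' @param seed Integer seed; realization seeds derive from it.
#' @param max_realizations Construction attempts before giving up.
#' @return List with `estimates` (T_net, min_depth, slope, M_prime,
#'   L_bar, D, D_pre, D_theory, n_discarded), and the `assignment`,
#'   `net`, `candidates`, `traj` and `curve` of the traversing run.
#' @export
ring_traversal_experiment <- function(N = 300, k = 3, Delta = 80,
                                      delta = 12, sigma = 3, dtheta = 0.1,
                                      tau = 200, theta0 = 0,
                                      sweeps = 16000, max_dt = 8000,
                                      seed = 1, max_realizations = 6) {
  for (try in seq_len(max_realizations) - 1L) {
    s <- seed + 7919L * try
    a <- build_ring_marker_assignment(N, k, Delta, seed = s)
    net <- connect_ring_attractor(a, delta, sigma)
    L <- measure_bump_width(net, seed = s)
    cand <- candidate_state_set(a, L_c = L)
    traj <- run_accommodation_dynamics(net, sweeps = sweeps,
                                       dtheta = dtheta, tau = tau,
                                       theta0 = theta0,
                                       init = cand$indicator[, 1], L = L,
                                       seed = s + 1L)
    if (traverses_full_ring(traj, cand)$ok) break
    if (try == max_realizations - 1L)
      stop_arg_("no marker realization traversed the full ring in ",
                max_realizations, " attempts")
  }
  curve <- mean_distance_curve(traj, max_dt)
  per <- estimate_period(curve)
  slope <- estimate_slope(curve)
  Lbar <- mean_activity(traj)
  plat <- plateau_distance(curve, slope, Delta, per$period)
  est <- list(T_net = per$period, min_depth = per$depth, slope = slope,
              M_prime = estimate_state_count(per$period, slope),
              L_bar = Lbar, D = plat$D, D_pre = plat$pre,
              D_theory = theoretical_plateau_distance(Lbar, k, a$M),
              n_discarded = try)
  list(estimates = est, assignment = a, net = net, candidates = cand,
       traj = traj, curve = curve)
}

run_fig4_6_ <- function(cfg, out_dir, figures = FALSE) {
  res <- ring_traversal_experiment(cfg$N, cfg$k, cfg$Delta, cfg$delta,
                                   cfg$sigma, cfg$dtheta, cfg$tau,
                                   cfg$theta0, cfg$sweeps, cfg$max_dt,
                                   seed = cfg$seed)
  net <- res$net
  traj <- res$traj
  cand <- res$candidates
  curve <- res$curve
  est <- res$estimates
  files <- c(write_network(net, file.path(out_dir, "net")),
             write_trajectory(traj, file.path(out_dir, "traj")))
  utils::write.csv(curve, file.path(out_dir, "distance_curve.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(out_dir, "distance_curve.csv"))
  jsonlite::write_json(est, file.path(out_dir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(out_dir, "estimates.json"))
  cr <- candidate_state_raster(traj, cand)
  utils::write.csv(data.frame(sweep = seq_along(cr$argmin) - 1L,
                              index = cr$argmin, min_dist = cr$min_dist),
                   file.path(out_dir, "candidate_argmin.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(out_dir, "candidate_argmin.csv"))
  if (figures) {
    nshow <- min(nrow(traj$states), 4000L)
    lp <- lplot(traj$states[seq_len(nshow), ], min(cfg$max_dt, nshow - 1L))
    f <- save_raster_png_(lp$distance[seq(1, nrow(lp$distance), by = 4), ],
                          file.path(out_dir, "lplot.png"), "dt", "t",
                          "L-plot")
    if (!is.null(f)) files <- c(files, f)
  }
  list(files = files, estimates = est)
}

run_fig3_ <- function(cfg, out_dir, figures = FALSE) {
  pm <- build_point_marker_assignment(cfg$N, cfg$M, cfg$L, seed = cfg$seed)
  net <- connect_point_attractor(pm)
  withr::local_seed(cfg$seed + 1L)
  W0 <- matrix(runif(cfg$R * cfg$N, -0.1, 0.1), cfg$R, cfg$N)
  inputs <- select_input_vectors(net, W0, cfg$M, cfg$L, seed = cfg$seed + 2L)
  fit <- train_modified_perceptron(net, inputs, W0)
  # the unconnected baseline scores against its own top-L responses, and
  # its training is a no-op (initial state always equals final state)
  inputs_base <- inputs
  inputs_base$targets <- apply(crossprod(W0, inputs$X), 2,
                               initial_state_top_l, L = cfg$L)
  base_fit <- train_modified_perceptron(NULL, inputs_base, W0)
  conds <- list(
    attractor_after = list(net = net, W = fit$W, inp = inputs),
    attractor_before = list(net = net, W = W0, inp = inputs),
    unconnected_after = list(net = NULL, W = base_fit$W, inp = inputs_base),
    unconnected_before = list(net = NULL, W = W0, inp = inputs_base))
  curves <- lapply(seq_along(conds), function(i) {
    cd <- conds[[i]]
    cv <- noise_tolerance_curve(cd$net, cd$W, cd$inp, etas = cfg$etas,
                                n_trials = cfg$n_trials,
                                seed = cfg$seed + 10L + i)
    cv$condition <- names(conds)[i]
    cv
  })
  curves <- do.call(rbind, curves)
  utils::write.csv(curves, file.path(out_dir, "noise_curves.csv"),
                   row.names = FALSE)
  after <- curves[curves$condition == "attractor_after", ]
  base <- curves[curves$condition == "unconnected_before", ]
  over <- which(after$error >= 0.05)
  eta_tol <- if (length(over)) after$eta[min(over)] - diff(after$eta[1:2])
             else max(after$eta)
  est <- list(passes = fit$passes, converged = fit$converged,
              n_resampled = inputs$n_resampled,
              eta_tolerance = eta_tol,
              net_err_at_0.5 = after$error[which.min(abs(after$eta - 0.5))],
              base_err_at_0.5 = base$error[which.min(abs(base$eta - 0.5))])
  jsonlite::write_json(est, file.path(out_dir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = file.path(out_dir, c("noise_curves.csv", "estimates.json")),
       estimates = est)
}

run_fig7_8_ <- function(cfg, out_dir) {
  res <- empirical_kc(cfg$N, cfg$Delta, cfg$delta, cfg$sigma,
                      k_range = cfg$k_range, seeds = cfg$seeds + cfg$seed,
                      dtheta = cfg$dtheta, tau = cfg$tau, theta0 = cfg$theta0)
  utils::write.csv(res$detail, file.path(out_dir, "kc_scan.csv"),
                   row.names = FALSE)
  est <- list(k_c = res$k_c,
              k_c_formula = c(critical_k_formula(cfg$N, cfg$delta, 1),
                              critical_k_formula(cfg$N, cfg$delta, 2)))
  jsonlite::write_json(est, file.path(out_dir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = file.path(out_dir, c("kc_scan.csv", "estimates.json")),
       estimates = est)
}

run_fig9_ <- function(cfg, out_dir, two_ring = FALSE) {
  if (two_ring) {
    exp <- two_ring_som_experiment(cfg$N, cfg$R, cfg$delta, cfg$sigma,
                                   n_steps = cfg$n_steps,
                                   eta_learn = cfg$eta_learn,
                                   n_test = cfg$n_test, seed = cfg$seed)
    est <- list(winner = exp$winner, margin = exp$margin,
                assoc1 = exp$metrics1$circular_association,
                assoc2 = exp$metrics2$circular_association)
    mapping <- exp$metrics1$mapping
    W <- exp$state$W
  } else {
    ring <- build_ring_marker_assignment(cfg$N, 1, 0, seed = cfg$seed)
    net <- connect_ring_attractor(ring, cfg$delta, cfg$sigma)
    receptors <- receptor_array(cfg$R, width = 0.06)
    state <- train_som(net, receptors, n_steps = cfg$n_steps,
                       eta_learn = cfg$eta_learn, seed = cfg$seed + 1L)
    ev <- evaluate_mapping(state, cfg$n_test, ring = ring)
    est <- list(circular_association = ev$circular_association,
                adjacency_fraction = ev$adjacency_fraction,
                coverage = ev$coverage,
                relax_within_6 = mean(state$relax_sweeps_log <= 6))
    mapping <- ev$mapping
    W <- state$W
  }
  utils::write.csv(mapping, file.path(out_dir, "mapping.csv"),
                   row.names = FALSE)
  write_matrix_(W, file.path(out_dir, "W.tsv"))
  jsonlite::write_json(est, file.path(out_dir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = file.path(out_dir, c("mapping.csv", "W.tsv",
                                    "estimates.json")),
       estimates = est)
}

run_lif_ <- function(cfg, out_dir, figures = FALSE) {
  a <- build_ring_marker_assignment(cfg$N, cfg$k, cfg$Delta, seed = cfg$seed)
  net <- connect_ring_attractor(a, cfg$delta, sigma = 0, mode = cfg$mode,
                                window = if (cfg$mode == "asymmetric")
                                  cfg$delta %/% 2 else NULL)
  cand <- candidate_state_set(a, cfg$delta)
  params <- lif_params(w_exc = cfg$w_exc %||% 5, w_inh = cfg$w_inh %||% 1)
  rec <- simulate_lif(net, params, duration = cfg$duration,
                      seed = cfg$seed + 1L,
                      init_bump = which(cand$indicator[, 1] == 1L))
  sns <- sns_projection(rec, a, cfg$delta)
  spikes <- data.frame(
    neuron = rep(seq_len(rec$N), lengths(rec$spikes)),
    time = unlist(rec$spikes))
  utils::write.csv(spikes, file.path(out_dir, "spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(time = sns$times, peak = sns$peak),
                   file.path(out_dir, "sns_peak.csv"), row.names = FALSE)
  files <- file.path(out_dir, c("spikes.csv", "sns_peak.csv"))
  if (figures) {
    f <- save_raster_png_(sns$raster, file.path(out_dir, "sns_raster.png"),
                          "time", "SNS index", "SNS raster")
    if (!is.null(f)) files <- c(files, f)
  }
  est <- list(n_spikes = nrow(spikes),
              peak_range = length(unique(sns$peak)))
  jsonlite::write_json(est, file.path(out_dir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = c(files, file.path(out_dir, "estimates.json")),
       estimates = est)
}

run_custom_ <- function(cfg, out_dir) {
  a <- build_ring_marker_assignment(cfg$N, cfg$k, cfg$Delta, seed = cfg$seed)
  net <- connect_ring_attractor(a, cfg$delta, cfg$sigma)
  files <- write_network(net, file.path(out_dir, "net"))
  est <- list(N = cfg$N, M = a$M)
  if (!is.null(cfg$sweeps) && cfg$sweeps > 0) {
    L <- measure_bump_width(net, seed = cfg$seed)
    cand <- candidate_state_set(a, L)
    traj <- run_accommodation_dynamics(net, sweeps = cfg$sweeps,
                                       dtheta = cfg$dtheta %||% 0.1,
                                       tau = cfg$tau %||% 200,
                                       theta0 = cfg$theta0 %||% 0,
                                       init = cand$indicator[, 1], L = L,
                                       seed = cfg$seed + 1L)
    files <- c(files, write_trajectory(traj, file.path(out_dir, "traj")))
    est$L_bar <- mean_activity(traj)
  }
  jsonlite::write_json(est, file.path(out_dir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = c(files, file.path(out_dir, "estimates.json")),
       estimates = est)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an experiment config from a YAML file
#'
#' The file must define at least `experiment`; missing fields are filled
#' from the matching preset.
#'
#' @param path YAML file path.
#' @return A config list suitable for [run_experiment()].
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$experiment)) stop_arg_("config lacks `experiment`")
  if (cfg$experiment != "custom") {
    base <- experiment_presets(cfg$experiment)
    cfg <- utils::modifyList(base, cfg)
  }
  cfg
}

#' Deterministic small fixtures with oracle-verifiable structure
#'
#' Emits tiny instances used for verification: networks small enough for
#' exhaustive stable-state enumeration, ideal single-load rings, planted
#' jump series and a hand-built monotone mapping.
#'
#' @param name One of `"ring-k1-n10"`, `"points-n6-m2-l3"`, `"empty"`,
#'   `"planted-jumps"`, `"ideal-mapping"`.
#' @return A list with the fixture objects (contents depend on the name).
#' @export
make_fixture <- function(name) {
  switch(
    name,
    "ring-k1-n10" = {
      a <- build_ring_marker_assignment(10, 1, 0, seed = 42)
      net <- connect_ring_attractor(a, delta = 2, sigma = 1)
      list(assignment = a, net = net,
           candidates = candidate_state_set(a, 2))
    },
    "points-n6-m2-l3" = {
      a <- build_point_marker_assignment(6, 2, 3, seed = 42)
      net <- connect_point_attractor(a, sigma = 1)
      list(assignment = a, net = net)
    },
    "empty" = {
      W <- matrix(0, 8, 8)
      list(net = new_connection_matrix_(W, 0, "symmetric",
                                        list(kind = "empty")))
    },
    "planted-jumps" = {
      idx <- c(1:40, 61:100, 81:120 %% 100 + 1)
      list(series = idx, M = 100, jumps_at = c(40L, 80L))
    },
    "ideal-mapping" = {
      n <- 100; M <- 50
      phi <- (seq_len(n) - 1) / n
      idx <- floor(phi * M) + 1
      list(phi = phi, index = idx, M = M)
    },
    stop_arg_("unknown fixture: ", name))
}
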