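# Binary (McCulloch-Pitts) network dynamics.  A network state is a 0/1
# vector of length N; updates are asynchronous: a uniformly random neuron
# is set to 1 iff its net input exceeds its threshold (strict), and one
# sweep is N such micro-updates.  Symmetric zero-diagonal networks relax
# to fixed points; with threshold accommodation the activity instead
# slides along chains of attractor states ("artificial dynamics").

as_weights_ <- function(net) {
  W <- weight_matrix(net)
  if (!is.double(W)) storage.mode(W) <- "double"
  W
}

check_state_ <- function(v, N) {
  if (length(v) != N || !all(v %in% c(0, 1)))
    stop_arg_("state must be a 0/1 vector of length N")
  as.integer(v)
}

#' Relax a binary network to a fixed point
#'
#' Repeats sweeps of N asynchronous micro-updates (uniformly random neuron,
#' activation rule `v_i <- 1` iff `sum_j T_ij v_j > theta_i`) until a full
#' sweep changes nothing and no neuron is left inconsistent, or
#' `max_sweeps` is reached.
#'
#' @param net A `connection_matrix` or plain numeric weight matrix.
#' @param state Initial 0/1 state vector.
#' @param theta Threshold(s), scalar or length-N vector (default 0).
#' @param max_sweeps Sweep budget (>= 1).
#' @param seed Optional integer seed for the update order.
#' @return List with `state` (0/1 integer vector), `sweeps` used and a
#'   logical `converged` flag.
#' @export
async_relax <- function(net, state, theta = 0, max_sweeps = 100, seed = NULL) {
  W <- as_weights_(net)
  N <- nrow(W)
  if (max_sweeps < 1) stop_arg_("max_sweeps must be >= 1")
  v <- check_state_(state, N)
  theta <- rep_len(as.double(theta), N)
  local_seed_(seed)
  cpp_async_relax(W, v, theta, as.integer(max_sweeps))
}

#' Hopfield energy of a binary state
#'
#' `E = -0.5 * v' T v + theta' v`, defined for symmetric zero-diagonal
#' networks; along any asynchronous trajectory of such a network the energy
#' is non-increasing, which is why relaxation terminates.
#'
#' @inheritParams async_relax
#' @param v A 0/1 state vector.
#' @return The scalar energy.
#' @export
hopfield_energy <- function(net, theta, v) {
  W <- as_weights_(net)
  if (!isTRUE(all.equal(W, t(W))))
    stop_arg_("energy is undefined for asymmetric connections")
  if (any(diag(W) != 0)) stop_arg_("diagonal must be zero")
  N <- nrow(W)
  v <- check_state_(v, N)
  theta <- rep_len(as.double(theta), N)
  drop(-0.5 * crossprod(v, W %*% v) + sum(theta * v))
}

#' Run threshold-accommodation ("artificial") dynamics
#'
#' Each neuron carries a fatigue threshold equal to `theta0 + dtheta`
#' times the number of sweeps it was active among the last `tau` sweeps
#' (a sliding-window integral of its recent activity).  Active neurons
#' fatigue, so the bump of activity slides from the current attractor
#' state to an adjacent one and circulates around closed chains of states
#' indefinitely.  Two update schemes are provided:
#'
#' * `"rank"` (default): per sweep the `L` neurons with the largest
#'   fatigue-corrected net input `h_i - theta_i` are active
#'   (winner-take-L, the same fixed-activity rule used in the point
#'   -attractor experiments).  Deterministic given the network; robust
#'   against pinning by weight disorder, hence the scheme used for the
#'   ring-traversal experiments.
#' * `"async"`: N asynchronous micro-updates per sweep with rule
#'   `v_i <- 1` iff `h_i > theta_i`, as in [async_relax()].
#'
#' @inheritParams async_relax
#' @param sweeps Number of sweeps to simulate (>= 1).
#' @param dtheta Threshold increment per active sweep (>= 0).
#' @param tau Activity-integration window in sweeps (> 0).
#' @param theta0 Baseline threshold.
#' @param init Initial 0/1 state (e.g. a candidate bump state).
#' @param update Update scheme, `"rank"` or `"async"`.
#' @param L Activity level for the rank scheme (default: the number of
#'   active neurons in `init`; see [measure_bump_width()] for a principled
#'   choice).
#' @param score_noise Standard deviation of the Gaussian jitter added to
#'   the rank scores each sweep (membrane noise).  A small amount keeps
#'   reflecting weight-disorder defects from trapping the bump between
#'   two sites forever; 0 makes the rank scheme fully deterministic.
#' @param record_thresholds Also record the threshold trajectory.
#' @return A `binary_trajectory`: list with `states` ((sweeps + 1) x N 0/1
#'   matrix, first row the initial state), optional `thresholds`, `params`
#'   and `seed`.
#' @export
run_accommodation_dynamics <- function(net, sweeps, dtheta = 0.1, tau = 200,
                                       theta0 = 0, init, seed = NULL,
                                       update = c("rank", "async"),
                                       L = NULL, score_noise = 0,
                                       record_thresholds = FALSE) {
  update <- match.arg(update)
  W <- as_weights_(net)
  N <- nrow(W)
  if (sweeps < 1) stop_arg_("sweeps must be >= 1")
  if (tau <= 0 || dtheta < 0) stop_arg_("need tau > 0 and dtheta >= 0")
  v <- check_state_(init, N)
  local_seed_(seed)
  if (update == "rank") {
    if (is.null(L)) L <- sum(v)
    if (L < 1 || L > N) stop_arg_("L must be in 1..N")
    res <- cpp_rank_accommodation_run(W, v, as.integer(L),
                                      as.integer(sweeps), dtheta,
                                      as.integer(tau), theta0, score_noise,
                                      record_thresholds)
  } else {
    res <- cpp_accommodation_run(W, v, as.integer(sweeps), dtheta,
                                 as.integer(tau), theta0,
                                 record_thresholds)
  }
  structure(list(states = res$states, thresholds = res$thresholds,
                 params = list(dtheta = dtheta, tau = tau, theta0 = theta0,
                               update = update, L = L),
                 seed = seed),
            class = "binary_trajectory")
}

#' Measure the natural bump width of a ring network
#'
#' Relaxes the network (static thresholds) from several random states and
#' returns the median number of active neurons of the resulting attractor
#' states — the activity level the network itself selects, used as the
#' `L` of the rank dynamics and as the candidate-state window length.
#'
#' @inheritParams async_relax
#' @param n_probe Number of random starts.
#' @param init_active Active neurons in each random start (default N/20).
#' @param seed Optional integer seed.
#' @return Integer bump width (median over probes).
#' @export
measure_bump_width <- function(net, n_probe = 12, init_active = NULL,
                               seed = NULL) {
  W <- as_weights_(net)
  N <- nrow(W)
  if (is.null(init_active)) init_active <- max(3L, round(N / 20))
  local_seed_(seed)
  widths <- vapply(seq_len(n_probe), function(i) {
    v0 <- integer(N)
    v0[sample.int(N, init_active)] <- 1L
    sum(async_relax(net, v0, theta = 0, max_sweeps = 60)$state)
  }, 0L)
  as.integer(round(stats::median(widths)))
}

#' @export
print.binary_trajectory <- function(x, ...) {
  cat(sprintf("<binary_trajectory> %d sweeps x %d neurons, mean activity %.2f\n",
              nrow(x$states) - 1L, ncol(x$states), mean(rowSums(x$states))))
  invisible(x)
}

#' Mean number of active neurons along a trajectory
#'
#' @param traj A `binary_trajectory` (or 0/1 state matrix).
#' @return Mean of the per-sweep active-neuron counts.
#' @export
mean_activity <- function(traj) {
  mean(rowSums(trajectory_states_(traj)))
}

trajectory_states_ <- function(traj) {
  if (inherits(traj, "binary_trajectory")) traj$states
  else if (is.matrix(traj)) traj
  else stop_arg_("expected a binary_trajectory or state matrix")
}

#' Initial state from an external drive: excite the top L neurons
#'
#' The `L` neurons receiving maximum drive are set active; ties are broken
#' towards the lowest neuron index (fixed for reproducibility).
#'
#' @param drive Length-N numeric drive vector.
#' @param L Number of neurons to excite, `1 <= L <= N`.
#' @return 0/1 integer vector with exactly `L` ones.
#' @export
initial_state_top_l <- function(drive, L) {
  N <- length(drive)
  if (L < 1 || L > N) stop_arg_("L must be in 1..N")
  v <- integer(N)
  v[order(-drive)[seq_len(L)]] <- 1L   # order() is stable: lowest index wins
  v
}

#' Enumerate all stable states of a small network by brute force
#'
#' Checks every one of the `2^N` binary states for the fixed-point
#' condition `v_i == (sum_j T_ij v_j > theta_i)`.  Intended for networks
#' with N <= 20 as ground truth in verification.
#'
#' @inheritParams async_relax
#' @return 0/1 integer matrix, one stable state per row.
#' @export
enumerate_stable_states <- function(net, theta = 0) {
  W <- as_weights_(net)
  N <- nrow(W)
  if (N > 20) stop_arg_("brute-force enumeration limited to N <= 20")
  theta <- rep_len(as.double(theta), N)
  S <- as.matrix(expand.grid(rep(list(0:1), N)))
  colnames(S) <- NULL
  H <- S %*% t(W)
  stable <- rowSums((H > rep(theta, each = nrow(S))) != S) == 0
  S[stable, , drop = FALSE]
}
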