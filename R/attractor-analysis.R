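# Analysis statistics for attractor trajectories.  The central surface is
# the Hamming distance between network states at different times: the
# L-plot resolves it by (t, dt), the mean distance curve averages over t.
# For a ring of attractor states traversed smoothly, the curve rises
# linearly (2 bits per state passed), saturates near twice the bump size,
# and dips back to ~0 after one full period T_net; hence
# T_net * slope = 2 * (number of states) and M' = T_net * slope / 2.

gram_ <- function(S) {
  if (!is.double(S)) storage.mode(S) <- "double"
  tcrossprod(S)
}

#' L-plot: Hamming distances between states at time offsets
#'
#' Entry `(t, dt)` is the Hamming distance between the network state at
#' sweep `t` and at `t + dt`, for `dt` in `-max_dt..max_dt` (NA where the
#' offset leaves the trajectory).  Periodic activity shows up as horizontal
#' near-zero stripes at multiples of the period.
#'
#' @param traj A `binary_trajectory` or 0/1 state matrix (rows = sweeps).
#' @param max_dt Largest offset; must be smaller than the trajectory
#'   length.
#' @return Object of class `lplot`: list with `distance` (n_t x
#'   (2 max_dt + 1) matrix), `t` and `dt` axes.
#' @export
lplot <- function(traj, max_dt) {
  S <- trajectory_states_(traj)
  nt <- nrow(S)
  if (max_dt >= nt) stop_arg_("max_dt must be smaller than the trajectory length")
  G <- gram_(S)
  act <- diag(G)
  dts <- -max_dt:max_dt
  D <- matrix(NA_real_, nt, length(dts))
  for (j in seq_along(dts)) {
    dt <- dts[j]
    t1 <- seq_len(nt)
    keep <- t1 + dt >= 1 & t1 + dt <= nt
    t1 <- t1[keep]
    D[keep, j] <- act[t1] + act[t1 + dt] - 2 * G[cbind(t1, t1 + dt)]
  }
  structure(list(distance = D, t = seq_len(nt) - 1L, dt = dts),
            class = "lplot")
}

#' Mean Hamming-distance curve over time offsets
#'
#' `r(dt)` is the Hamming distance between states `dt` sweeps apart,
#' averaged over the trajectory (equivalently the column means of the
#' L-plot).  Computed via per-neuron FFT autocorrelations, so long runs
#' stay cheap; the result is exact (binary counts, rounded to integers
#' before averaging).
#'
#' @inheritParams lplot
#' @return Object of class `distance_curve`: data frame with columns `dt`
#'   (0..max_dt), `r` and `n` (samples per offset).
#' @export
mean_distance_curve <- function(traj, max_dt) {
  S <- trajectory_states_(traj)
  nt <- nrow(S)
  if (max_dt >= nt) stop_arg_("max_dt must be smaller than the trajectory length")
  m <- stats::nextn(2L * nt, 2)
  pow <- numeric(m)
  for (i in seq_len(ncol(S))) {
    x <- c(as.numeric(S[, i]), numeric(m - nt))
    pow <- pow + Mod(stats::fft(x))^2
  }
  cross <- round(Re(stats::fft(pow, inverse = TRUE)) / m)[seq_len(max_dt + 1)]
  act <- rowSums(S)
  P <- cumsum(act)
  total <- P[nt]
  dts <- 0:max_dt
  n <- nt - dts
  lead_sum <- total - c(0, P[seq_len(max_dt)])
  lag_sum <- P[n]
  r <- (lag_sum + lead_sum - 2 * cross) / n
  structure(data.frame(dt = dts, r = r, n = n),
            class = c("distance_curve", "data.frame"))
}

#' Estimate the activity period from a distance curve
#'
#' Locates the deepest local minimum of `r(dt)` beyond `min_lag` and
#' refines it by parabolic interpolation through the three surrounding
#' points.  The minimum is generally not zero: traversal of the ring of
#' states is noisy, so successive cycles do not repeat exactly.
#'
#' @param curve A `distance_curve`.
#' @param min_lag Smallest lag considered (default 50 sweeps).
#' @return List with `period` (fractional sweeps), `depth` (curve value at
#'   the minimum) and `index` (discrete argmin).
#' @export
estimate_period <- function(curve, min_lag = 50) {
  r <- curve$r
  dt <- curve$dt
  i <- which(dt > min_lag & dt < max(dt))
  if (!length(i)) stop_arg_("no admissible lags beyond min_lag")
  loc <- i[r[i] < r[i - 1] & r[i] <= r[i + 1]]
  if (!length(loc)) stop_arg_("no local minimum found beyond min_lag")
  j <- loc[which.min(r[loc])]
  num <- r[j - 1] - r[j + 1]
  den <- r[j - 1] - 2 * r[j] + r[j + 1]
  shift <- if (den > 0) 0.5 * num / den else 0
  list(period = dt[j] + shift, depth = r[j], index = dt[j])
}

#' Small-offset slope of the distance curve
#'
#' Least-squares slope of `r` against `dt` over `[fit_lo, fit_hi]`, where
#' the curve is linear: each attractor state passed changes 2 bits, so the
#' slope equals twice the traversal speed in states per sweep.
#'
#' @param curve A `distance_curve`.
#' @param fit_lo,fit_hi Fit range in sweeps (default 1..10).
#' @return The slope `dr/d(dt)`.
#' @export
estimate_slope <- function(curve, fit_lo = 1, fit_hi = 10) {
  sel <- curve$dt >= fit_lo & curve$dt <= fit_hi
  if (sum(sel) < 2) stop_arg_("fewer than 2 points in the fit range")
  unname(coef(lm(r ~ dt, data = curve[sel, ]))[2])
}

#' Count attractor states from period and slope
#'
#' `M' = T_net * slope / 2`: over one period the summed state-to-state
#' distance is `T_net * slope`, and adjacent attractor states differ in 2
#' bits, so half that is the number of distinct states attended per cycle.
#'
#' @param period Activity period in sweeps.
#' @param slope Small-offset slope of the distance curve.
#' @return The (fractional) state count `M'`.
#' @export
estimate_state_count <- function(period, slope) {
  if (period <= 0 || slope <= 0) stop_arg_("period and slope must be positive")
  period * slope / 2
}

#' Post-drop plateau level of the distance curve
#'
#' After the linear rise the curve saturates near `2 * L_eff`; once the
#' activity has passed about `Delta` states, overlaps through the
#' reference neurons' other markers pull the distance down to a lower
#' plateau `D`.  This measures the mean of `r` over the window from
#' `Delta * 2 / slope` plus a safety margin up to half the period, and
#' also reports the pre-drop plateau.
#'
#' @param curve A `distance_curve`.
#' @param slope Small-offset slope (from [estimate_slope()]).
#' @param Delta Minimum intra-neuron marker distance of the generating
#'   assignment.
#' @param period Activity period in sweeps (from [estimate_period()]).
#' @param margin Fraction of the period added after the drop point and
#'   kept clear of the period minimum (default 0.1).
#' @return List with `D` (post-drop plateau), `pre` (pre-drop plateau
#'   level) and the averaging `window`.
#' @export
plateau_distance <- function(curve, slope, Delta, period, margin = 0.1) {
  drop_at <- Delta * 2 / slope
  lo <- drop_at + margin * period
  hi <- period / 2
  sel <- curve$dt >= lo & curve$dt <= hi
  if (!any(sel)) stop_arg_("empty post-drop window")
  pre_sel <- curve$dt >= drop_at * 0.5 & curve$dt <= drop_at * 0.9
  list(D = mean(curve$r[sel]),
       pre = if (any(pre_sel)) mean(curve$r[pre_sel]) else NA_real_,
       window = c(lo, hi))
}

#' Theoretical post-drop plateau level
#'
#' For a bump of `L` active neurons on a ring of `M` markers with `k`
#' markers per neuron, the expected post-drop plateau is
#' `D = 2 L (1 - (k - 1) L / M)`: each of a neuron's `k - 1` other markers
#' gives it a chance `L / M` of also lying under the displaced bump.
#'
#' @param L Bump size (active neurons per state).
#' @param r_overlap Markers per neuron (`k`).
#' @param M Ring size.
#' @return The plateau level in Hamming units.
#' @examples
#' theoretical_plateau_distance(15, 3, 900)  # 29
#' @export
theoretical_plateau_distance <- function(L, r_overlap, M) {
  if (M <= 0) stop_arg_("M must be positive")
  2 * L * (1 - (r_overlap - 1) * L / M)
}

#' Candidate bump states of a ring assignment
#'
#' Candidate state `i` activates the neurons owning markers
#' `i, i+1, ..., i + L_c - 1` (mod M).  When `Delta >= L_c` the window
#' cannot hit one neuron twice, so each candidate has exactly `L_c`
#' distinct neurons.
#'
#' @param assignment A `ring_marker_assignment`.
#' @param L_c Window length in markers.
#' @return Object of class `candidate_state_set`: list with `indicator`
#'   (N x M 0/1 matrix, one candidate per column), `L_c` and `M`.
#' @export
candidate_state_set <- function(assignment, L_c) {
  stopifnot(inherits(assignment, "ring_marker_assignment"))
  M <- assignment$M
  owner <- assignment$owner
  C <- matrix(0L, assignment$N, M)
  for (i in seq_len(M)) {
    w <- ((i - 1L) + 0:(L_c - 1L)) %% M + 1L
    C[unique(owner[w]), i] <- 1L
  }
  structure(list(indicator = C, L_c = as.integer(L_c), M = M),
            class = "candidate_state_set")
}

#' Distance raster between a trajectory and the candidate states
#'
#' `raster[t, i]` is the Hamming distance between the network state at
#' sweep `t` and candidate state `i`; the per-sweep argmin traces which
#' candidate the activity currently occupies.
#'
#' @param traj A `binary_trajectory` or state matrix.
#' @param candidates A `candidate_state_set`.
#' @return List with `raster` (time x M), `argmin` (per-sweep best
#'   candidate index, ties to the lowest index) and `min_dist`.
#' @export
candidate_state_raster <- function(traj, candidates) {
  S <- trajectory_states_(traj)
  C <- candidates$indicator
  if (ncol(S) != nrow(C)) stop_arg_("trajectory and candidates disagree in N")
  if (!is.double(S)) storage.mode(S) <- "double"
  ov <- S %*% C
  D <- sweep(-2 * ov, 1, rowSums(S), "+")
  D <- sweep(D, 2, colSums(C), "+")
  idx <- max.col(-D, ties.method = "first")
  list(raster = D, argmin = idx, min_dist = D[cbind(seq_len(nrow(D)), idx)])
}

#' Check whether a trajectory traverses the full ring of candidate states
#'
#' The weight disorder of ring networks occasionally contains a defect
#' strong enough to reflect the travelling bump, trapping the activity in
#' a bouncing segment; traversal statistics (period, slope, state count,
#' plateau) are only meaningful for runs that circulate.  This gate
#' computes the ring span of the smooth drift (leaps above
#' `2 * candidates$L_c` excluded) and the leap count.
#'
#' @param traj A `binary_trajectory` or state matrix.
#' @param candidates The ring's `candidate_state_set`.
#' @return List with `ok` (span covers the ring), `span` (states) and
#'   `n_jumps`.
#' @export
traverses_full_ring <- function(traj, candidates) {
  M <- candidates$M
  idx <- candidate_state_raster(traj, candidates)$argmin
  step <- ring_diff_(idx[-length(idx)], idx[-1], M)
  thr <- 2 * candidates$L_c
  jumps <- sum(abs(step) > thr)
  step[abs(step) > thr] <- 0
  span <- diff(range(cumsum(step)))
  list(ok = span >= M, span = span, n_jumps = jumps)
}

ring_diff_ <- function(a, b, M) {
  # signed ring displacement from a to b in (-M/2, M/2]
  d <- (b - a) %% M
  ifelse(d > M / 2, d - M, d)
}

#' Detect jumps in a best-matching-candidate series
#'
#' A jump is a change of the best-matching candidate index exceeding
#' `jump_threshold` in ring metric between consecutive sweeps.  For each
#' jump the drift direction before and after (sign of the summed
#' displacement over `dir_window` sweeps) is compared: above the critical
#' marker load each leap reverses the direction of wave propagation.
#'
#' @param argmin_series Integer series of candidate indices (1..M).
#' @param M Ring size.
#' @param jump_threshold Ring distance counting as a jump (default
#'   `2 * L_c` is the conventional choice).
#' @param dir_window Sweeps used to estimate drift direction around a jump.
#' @return Data frame with columns `time`, `size` and `direction_flip`.
#' @export
detect_jumps <- function(argmin_series, M, jump_threshold, dir_window = 20) {
  s <- as.integer(argmin_series)
  n <- length(s)
  if (n < 2) return(data.frame(time = integer(), size = numeric(),
                               direction_flip = logical()))
  step <- ring_diff_(s[-n], s[-1], M)
  at <- which(abs(step) > jump_threshold)
  flips <- vapply(at, function(j) {
    pre <- step[max(1, j - dir_window):max(1, j - 1)]
    post <- step[min(n - 1, j + 1):min(n - 1, j + dir_window)]
    pre <- pre[abs(pre) <= jump_threshold]
    post <- post[abs(post) <= jump_threshold]
    if (!length(pre) || !length(post)) return(NA)
    sign(sum(pre)) != sign(sum(post)) && sum(post) != 0 && sum(pre) != 0
  }, NA)
  data.frame(time = at, size = abs(step[at]), direction_flip = flips)
}

#' Empirical critical marker load k_c
#'
#' For each `k` in `k_range`, builds ring networks, runs accommodation
#' dynamics and checks (majority over seeds) that the activity traverses
#' all `k * N` candidate indices with zero jumps.  Returns the largest
#' such `k`: beyond it the activity leaps between distant attractor
#' states instead of sliding.
#'
#' @param N Neurons.
#' @param Delta Minimum intra-neuron marker distance.
#' @param delta Excitation radius.
#' @param sigma Inhibition magnitude.
#' @param k_range Integer vector of marker loads to test.
#' @param seeds Integer vector of seeds (majority vote across them); each
#'   seed draws an independent network realization.
#' @param dtheta,tau,theta0 Accommodation parameters.
#' @param sweeps Run length per k; default `ceiling(8 * k * N)` sweeps,
#'   comfortably more than one traversal cycle at the typical speed.
#' @param L_c Candidate window length; by default measured per network
#'   with [measure_bump_width()].
#' @return List with `k_c`, and `detail` (data frame per k x seed: ring
#'   span traversed, jump count, direction flips, smooth flag).
#' @export
empirical_kc <- function(N, Delta, delta, sigma, k_range, seeds = 1:3,
                         dtheta = 0.1, tau = 200, theta0 = 0,
                         sweeps = NULL, L_c = NULL) {
  rows <- list()
  for (k in k_range) {
    M <- k * N
    ns <- if (is.null(sweeps)) ceiling(8 * M) else sweeps
    for (s in seeds) {
      a <- build_ring_marker_assignment(N, k, Delta, seed = s * 1000L + k)
      net <- connect_ring_attractor(a, delta, sigma)
      L <- if (is.null(L_c)) measure_bump_width(net, seed = s) else L_c
      cand <- candidate_state_set(a, L)
      traj <- run_accommodation_dynamics(net, sweeps = ns, dtheta = dtheta,
                                         tau = tau, theta0 = theta0,
                                         init = cand$indicator[, 1], L = L,
                                         seed = s * 1000L + k)
      idx <- candidate_state_raster(traj, cand)$argmin
      jumps <- detect_jumps(idx, M, jump_threshold = 2 * L)
      step <- ring_diff_(idx[-length(idx)], idx[-1], M)
      step[abs(step) > 2 * L] <- 0     # span of the smooth drift only
      span <- diff(range(cumsum(step)))
      rows[[length(rows) + 1L]] <-
        data.frame(k = k, seed = s, L = L, span = span,
                   n_jumps = nrow(jumps),
                   n_flips = sum(jumps$direction_flip, na.rm = TRUE),
                   smooth = span >= M && nrow(jumps) == 0)
    }
  }
  detail <- do.call(rbind, rows)
  by_k <- vapply(split(detail$smooth, detail$k),
                 function(x) mean(x) > 0.5, NA)
  ks <- as.integer(names(by_k))
  k_c <- if (any(by_k)) max(ks[by_k]) else NA_integer_
  list(k_c = k_c, detail = detail)
}

#' Theoretical critical marker load
#'
#' `k_c = N / (2 * delta * correction)`: each marker links a neuron to the
#' ~2 delta neurons of its ring neighbourhood, and the network supports
#' smooth traversal while the per-neuron connection load stays below N.
#' The correction factor lies in [1, 2] for bump sizes >= 20 and N up to
#' 1e5.
#'
#' @param N Neurons.
#' @param delta Excitation radius.
#' @param correction Correction factor in [1, 2] (warning outside).
#' @return The critical marker load (real).
#' @export
critical_k_formula <- function(N, delta, correction = 1) {
  if (correction < 1 || correction > 2)
    warning("correction factor outside [1, 2]")
  N / (2 * delta * correction)
}

#' Verify the bump-attractor property of candidate states
#'
#' Checks, for every candidate state: (a) that it is a fixed point of the
#' asynchronous dynamics under a static threshold placed midway between
#' the weakest in-bump drive and the strongest out-of-bump drive of the
#' ideal state, and (b) that adjacent candidate states differ in Hamming
#' distance at most 2 (the connectedness criterion for a bump attractor).
#'
#' @param net A `connection_matrix` or weight matrix.
#' @param candidates A `candidate_state_set`.
#' @param theta Optional fixed threshold (scalar); by default the midway
#'   rule above, per candidate.
#' @return List with `all_stable`, `all_connected`, `stable` and
#'   `adjacent_distance` vectors, and indices of `failures`.
#' @export
verify_bump_attractor <- function(net, candidates, theta = NULL) {
  W <- as_weights_(net)
  C <- candidates$indicator
  M <- ncol(C)
  H <- W %*% C
  stable <- logical(M)
  for (i in seq_len(M)) {
    act <- C[, i] == 1
    th <- if (is.null(theta)) (min(H[act, i]) + max(H[!act, i])) / 2
          else theta
    stable[i] <- all(H[act, i] > th) && all(H[!act, i] <= th)
  }
  adj <- vapply(seq_len(M), function(i) {
    j <- if (i == M) 1L else i + 1L
    sum(abs(C[, i] - C[, j]))
  }, 0)
  list(all_stable = all(stable),
       all_connected = all(adj <= 2),
       stable = stable, adjacent_distance = adj,
       failures = which(!stable))
}

#' Dimensionality bound for attractor grids
#'
#' A d-dimensional grid of `l` elements per dimension embedded as bump
#' attractor states requires `l^d <= N^2 / L`, i.e.
#' `d <= log(N^2 / L) / log(l)`.  Optionally also checks the connection
#' -load constraint `(2 delta)^d * k < N`.
#'
#' @param N Neurons.
#' @param l Grid elements per dimension (> 1).
#' @param L Active neurons per state.
#' @param delta,k Optional: excitation radius and marker load for the
#'   companion connection-load check.
#' @return Integer bound `floor(log(N^2 / L) / log(l))`; attribute
#'   `load_ok` when `delta` and `k` are given.
#' @examples
#' dimension_bound(1e4, 10, 10)    # 7
#' dimension_bound(1e4, 100, 100)  # 3
#' @export
dimension_bound <- function(N, l, L, delta = NULL, k = NULL) {
  if (l <= 1) stop_arg_("l must exceed 1")
  d <- floor(log(N^2 / L) / log(l) + 1e-9)
  if (!is.null(delta) && !is.null(k))
    attr(d, "load_ok") <- (2 * delta)^d * k < N
  d
}
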