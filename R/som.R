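# Self-organizing mapping of a cyclic stimulus onto a ring attractor.
# R receptors with circular-Gaussian tuning read a cyclic variable phi in
# [0, 1); their activation drives a ring-attractor network through an
# R x N weight matrix W.  Each learning step excites the most-driven
# neurons (after one relay through the recurrent excitation, which acts
# as a bump-matched filter), relaxes the network to an attractor state V
# with the receptors switched off, and pulls the active neurons' weight
# columns towards the input:
#   W[, j] <- W[, j] + eta * (X - W[, j])   for V_j = 1.
# The attractor supplies the Kohonen neighbourhood: one bump covers ~L
# adjacent candidate states, so neighbouring ring positions acquire
# similar receptive fields.  Global ordering is helped by annealing the
# receptor tuning width from broad to its final value over training
# (coarse-to-fine), the package's counterpart of Kohonen's shrinking
# neighbourhood; residual fold defects can survive, visible as
# deflections in the learned map.

#' Receptor array with circular-Gaussian tuning
#'
#' `R` broadly tuned receptors with preferred values evenly spaced on the
#' cyclic domain [0, 1) and bell-shaped (circular Gaussian) tuning curves.
#'
#' @param R Number of receptors (>= 2).
#' @param width Tuning width as a fraction of the circle (default 0.1,
#'   broad tuning).
#' @param gain Peak activation.
#' @return Object of class `receptor_array`.
#' @export
receptor_array <- function(R, width = 0.1, gain = 1) {
  if (R < 2 || width <= 0) stop_arg_("need R >= 2 and width > 0")
  structure(list(R = as.integer(R), preferred = (seq_len(R) - 1) / R,
                 width = width, gain = gain),
            class = "receptor_array")
}

circ_dist_ <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

#' Receptor activation for a stimulus value
#'
#' @param phi Cyclic stimulus value (reduced mod 1).
#' @param receptors A `receptor_array`.
#' @param width Optional tuning-width override (used by the annealing
#'   schedule during training).
#' @return Length-R activation vector
#'   `gain * exp(-d(phi, pref)^2 / (2 width^2))` with circular distance d.
#' @export
receptor_activation <- function(phi, receptors, width = NULL) {
  if (is.null(width)) width <- receptors$width
  d <- circ_dist_(phi %% 1, receptors$preferred)
  receptors$gain * exp(-d^2 / (2 * width^2))
}

#' @export
print.som_state <- function(x, ...) {
  cat(sprintf("<som_state> R = %d receptors -> N = %d neurons, %d steps\n",
              nrow(x$W), ncol(x$W), x$step))
  invisible(x)
}

#' Initialise a SOM state
#'
#' @param net Ring-attractor `connection_matrix`.
#' @param receptors A `receptor_array`.
#' @param eta_learn Learning rate in (0, 1].
#' @param W0 Initial R x N weights (default uniform random in [0, 1]).
#' @param L_init Activity level used to seed the network from the readout
#'   drive (default: the measured bump width of `net`).
#' @param update `"masked"` (default) updates only the active neurons'
#'   columns; `"full"` applies the literal full-matrix update, under
#'   which the silent neurons' columns decay.
#' @param seed Optional integer seed (for `W0`).
#' @return A `som_state`.
#' @export
som_initialize <- function(net, receptors, eta_learn = 0.05, W0 = NULL,
                           L_init = NULL, update = c("masked", "full"),
                           seed = NULL) {
  update <- match.arg(update)
  if (eta_learn <= 0 || eta_learn > 1) stop_arg_("eta_learn must be in (0, 1]")
  local_seed_(seed)
  W <- weight_matrix(net)
  N <- nrow(W)
  if (is.null(L_init)) L_init <- measure_bump_width(net)
  if (is.null(W0)) W0 <- matrix(runif(receptors$R * N), receptors$R, N)
  structure(list(W = W0, net = net, exc = (W > 0) * 1,
                 receptors = receptors, L_init = L_init,
                 eta_learn = eta_learn, update = update, step = 0L,
                 relax_sweeps_log = integer(0)),
            class = "som_state")
}

som_winner_init_ <- function(state, X) {
  drive <- drop(crossprod(state$W, X))
  # one relay through the recurrent excitation: a bump-matched smoothing
  initial_state_top_l(drop(state$exc %*% drive) + drive, state$L_init)
}

#' One SOM learning step
#'
#' Computes the receptor activation for `phi`, excites the `L_init`
#' most-driven neurons (drive smoothed by one pass through the recurrent
#' excitation), relaxes the network for up to `relax_sweeps` sweeps with
#' the receptors switched off, then runs `smear_sweeps` sweeps of
#' threshold-accommodation dynamics from the attractor state.  The
#' update weights each neuron's column by its time-averaged activity
#' over that short drift, so the bump and its immediate neighbours on
#' the chain of attractor states are trained together — the attractor
#' supplies the Kohonen neighbourhood.
#'
#' @param state A `som_state`.
#' @param phi Stimulus value in [0, 1).
#' @param relax_sweeps Relaxation budget in sweeps (default 20; stability
#'   is typically reached in 3-6).
#' @param width Optional tuning-width override for this step.
#' @param smear_sweeps Accommodation sweeps defining the neighbourhood
#'   (0 restricts the update to the attractor state itself).
#' @return The updated `som_state`.
#' @export
som_step <- function(state, phi, relax_sweeps = 20, width = NULL,
                     smear_sweeps = 20) {
  X <- receptor_activation(phi, state$receptors, width = width)
  init <- som_winner_init_(state, X)
  rel <- async_relax(state$net, init, theta = 0, max_sweeps = relax_sweeps)
  V <- rel$state
  eta <- state$eta_learn
  if (state$update == "full") {
    state$W <- state$W + eta * (tcrossprod(X, V) - state$W)
  } else {
    vbar <- as.numeric(V)
    if (smear_sweeps > 0 && sum(V) > 0) {
      traj <- run_accommodation_dynamics(state$net, sweeps = smear_sweeps,
                                         init = V, L = sum(V),
                                         update = "rank")
      vbar <- colMeans(traj$states)
    }
    state$W <- state$W +
      eta * (outer(X, vbar) - state$W * rep(vbar, each = nrow(state$W)))
  }
  state$step <- state$step + 1L
  state$relax_sweeps_log <- c(state$relax_sweeps_log, rel$sweeps)
  state
}

#' Train a SOM on uniformly random stimuli
#'
#' Runs [som_step()] `n_steps` times with independent uniform `phi`.  The
#' receptor tuning width is annealed from `width_start` down to the
#' array's final width with time constant `anneal_frac * n_steps`
#' (coarse-to-fine ordering); relaxation sweep counts are logged.
#'
#' @inheritParams som_initialize
#' @param n_steps Number of learning steps.
#' @param seed Optional integer seed.
#' @param relax_sweeps Relaxation budget per step.
#' @param width_start Initial (broad) tuning width as a fraction of the
#'   circle; `NULL` disables annealing.
#' @param anneal_frac Annealing time constant as a fraction of `n_steps`.
#' @return The trained `som_state` (field `relax_sweeps_log` holds the
#'   per-step relaxation sweep counts).
#' @export
train_som <- function(net, receptors, n_steps = 20000, eta_learn = 0.05,
                      seed = NULL, W0 = NULL, L_init = NULL,
                      update = c("masked", "full"), relax_sweeps = 20,
                      width_start = 0.25, anneal_frac = 0.25) {
  update <- match.arg(update)
  local_seed_(seed)
  state <- som_initialize(net, receptors, eta_learn, W0, L_init, update)
  w_final <- receptors$width
  t_anneal <- anneal_frac * n_steps
  relax_counts <- integer(n_steps)
  for (s in seq_len(n_steps)) {
    wd <- if (is.null(width_start)) NULL
          else w_final + (width_start - w_final) * exp(-s / t_anneal)
    state$relax_sweeps_log <- integer(0)
    state <- som_step(state, runif(1), relax_sweeps, width = wd)
    relax_counts[s] <- state$relax_sweeps_log[1]
  }
  state$step <- n_steps
  state$relax_sweeps_log <- relax_counts
  state
}

# Fisher-Lee circular-circular correlation, computed in O(n) via the
# angular sum expansions.
circular_correlation <- function(alpha, beta) {
  A <- sum(cos(alpha) * cos(beta)); B <- sum(sin(alpha) * sin(beta))
  C <- sum(cos(alpha) * sin(beta)); D <- sum(sin(alpha) * cos(beta))
  num <- 2 * (A * B - C * D)
  d1 <- length(alpha)^2 - sum(cos(2 * alpha))^2 - sum(sin(2 * alpha))^2
  d2 <- length(beta)^2 - sum(cos(2 * beta))^2 - sum(sin(2 * beta))^2
  2 * num / sqrt(d1 * d2)
}

#' Evaluate the stimulus-to-attractor mapping
#'
#' Sweeps `n_test` evenly spaced stimulus values through the trained
#' system, records the converged attractor's ring position (best-matching
#' candidate index) and scores: `circular_association` (absolute
#' circular-circular correlation between phi and ring position),
#' `adjacency_fraction` (share of consecutive phi pairs whose indices
#' move by at most the expected grid step, with a floor of ring distance
#' 2) and `coverage` (fraction of candidate indices reached).
#'
#' @param state A trained `som_state`.
#' @param n_test Number of evenly spaced test stimuli (default 1000).
#' @param candidates A `candidate_state_set` for the network's ring; by
#'   default built from `ring` when supplied.
#' @param ring Optional `ring_marker_assignment` used to build candidates.
#' @param relax_sweeps Relaxation budget per test stimulus.
#' @return List with the three metrics and `mapping` (data frame `phi`,
#'   `index`, `min_dist`).
#' @export
evaluate_mapping <- function(state, n_test = 1000, candidates = NULL,
                             ring = NULL, relax_sweeps = 20) {
  if (is.null(candidates)) {
    if (is.null(ring)) stop_arg_("supply `candidates` or `ring`")
    candidates <- candidate_state_set(ring, state$L_init)
  }
  phis <- (seq_len(n_test) - 1) / n_test
  N <- ncol(state$W)
  states <- matrix(0L, n_test, N)
  for (i in seq_len(n_test)) {
    X <- receptor_activation(phis[i], state$receptors)
    init <- som_winner_init_(state, X)
    states[i, ] <- async_relax(state$net, init, theta = 0,
                               max_sweeps = relax_sweeps)$state
  }
  cr <- candidate_state_raster(states, candidates)
  M <- candidates$M
  idx <- cr$argmin
  assoc <- abs(circular_correlation(2 * pi * phis, 2 * pi * idx / M))
  exp_step <- M / n_test
  steps <- abs(ring_diff_(idx[-n_test], idx[-1], M))
  adjacency <- mean(steps <= pmax(2, 2 * exp_step))
  coverage <- length(unique(idx)) / M
  list(circular_association = assoc, adjacency_fraction = adjacency,
       coverage = coverage,
       mapping = data.frame(phi = phis, index = idx, min_dist = cr$min_dist))
}

#' Two-ring SOM selection experiment
#'
#' Builds a network carrying two independent full ring attractors, trains
#' the SOM, and evaluates the mapping against the candidate states of
#' each ring separately.  Learning "selects" exactly one ring: the
#' mapping is far more continuous in that ring's enumeration than in the
#' other's, and which ring wins depends on the random initial conditions.
#'
#' @param N Neurons (= markers per ring).
#' @param R Receptors.
#' @param delta Excitation radius.
#' @param sigma Inhibition magnitude (the two-ring networks of interest
#'   use strong inhibition; default 10).
#' @param n_steps,eta_learn,relax_sweeps Training parameters.
#' @param n_test Test stimuli for the evaluation sweep.
#' @param seed Optional integer seed.
#' @return List with `winner` (1 or 2), `margin` (difference in circular
#'   association), `metrics1`, `metrics2`, the trained `state` and the
#'   `rings`.
#' @export
two_ring_som_experiment <- function(N, R, delta, sigma = 10,
                                    n_steps = 20000, eta_learn = 0.05,
                                    relax_sweeps = 20, n_test = 1000,
                                    seed = NULL) {
  local_seed_(seed)
  two <- build_two_ring_network(N, delta, sigma)
  receptors <- receptor_array(R, width = 0.06)
  state <- train_som(two$net, receptors, n_steps = n_steps,
                     eta_learn = eta_learn, relax_sweeps = relax_sweeps)
  L_c <- state$L_init
  ev1 <- evaluate_mapping(state, n_test,
                          candidates = candidate_state_set(two$ring1, L_c),
                          relax_sweeps = relax_sweeps)
  ev2 <- evaluate_mapping(state, n_test,
                          candidates = candidate_state_set(two$ring2, L_c),
                          relax_sweeps = relax_sweeps)
  m1 <- ev1$circular_association
  m2 <- ev2$circular_association
  list(winner = if (m1 >= m2) 1L else 2L, margin = abs(m1 - m2),
       metrics1 = ev1, metrics2 = ev2, state = state, rings = two)
}
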