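# Readout learning for d = 0 (isolated point attractor) networks.  Input
# vectors X in [-1, 1]^R drive the network through an R x N weight matrix
# W; in phase 1 the L most-driven neurons are excited, in phase 2 the
# network relaxes to an attractor state under winner-take-L dynamics.
# The modified two-phase perceptron rule moves W until phase 1 directly
# reproduces each input's attractor, which is what makes the readout
# noise-robust.

#' Winner-take-L relaxation for d = 0 networks
#'
#' Keeps the activity level fixed at `L` and greedily exchanges the
#' weakest active neuron for the strongest inactive one while the
#' exchange raises the summed within-set drive.  The descent is monotone
#' (no oscillations) and concentrates the activity on the marker class
#' best represented in the initial state, whose L member neurons form the
#' attractor.  This is the externally constrained relaxation used with
#' d = 0 networks, where recurrent inhibition is optional.
#'
#' @inheritParams async_relax
#' @param L Activity level (number of active neurons).
#' @param max_swaps Exchange budget.
#' @return List with `state`, `swaps` performed, `converged`.
#' @export
relax_winner_take_l <- function(net, state, L, max_swaps = 2000) {
  W <- as_weights_(net)
  v <- check_state_(state, nrow(W))
  if (sum(v) != L) stop_arg_("initial state must have exactly L active neurons")
  res <- cpp_wtl_relax(W, v, as.integer(L), as.integer(max_swaps))
  list(state = res$state, swaps = res$swaps,
       converged = res$swaps < max_swaps)
}

#' Classic Rosenblatt perceptron update
#'
#' Single-unit rule: with output `O = w . X` and teacher sign `y` in
#' {-1, +1}, `w` is unchanged when `sign(O) == y` and becomes `w + X y`
#' otherwise.
#'
#' @param w Length-R weight vector.
#' @param X Length-R input vector.
#' @param y Teacher sign, -1 or +1.
#' @return Updated weight vector.
#' @export
rosenblatt_update <- function(w, X, y) {
  if (!(length(y) == 1 && y %in% c(-1, 1)))
    stop_arg_("y must be -1 or +1")
  if (sign(sum(w * X)) == y) w else w + X * y
}

phase1_state_ <- function(W, X, L) initial_state_top_l(drop(crossprod(W, X)), L)

two_phase_ <- function(net, W, X, L) {
  init <- phase1_state_(W, X, L)
  final <- if (is.null(net)) init
           else relax_winner_take_l(net, init, L)$state
  list(init = init, final = final)
}

#' Select input vectors mapping to distinct attractors
#'
#' Draws random vectors in `[-1, 1]^R` and keeps those whose two-phase
#' response (top-L excitation then winner-take-L relaxation) lands on a
#' previously unoccupied attractor state, resampling on collisions.
#'
#' @param net The d = 0 `connection_matrix`.
#' @param W0 Initial R x N readout weights.
#' @param n_inputs Number of input vectors (= attractors to occupy).
#' @param L Activity level.
#' @param seed Optional integer seed.
#' @param max_resample Total draw budget.
#' @return Object of class `input_vector_set`: list with `X` (R x
#'   n_inputs matrix), `targets` (N x n_inputs 0/1 matrix of assigned
#'   attractor states), `L`, and `n_resampled`.
#' @export
select_input_vectors <- function(net, W0, n_inputs, L, seed = NULL,
                                 max_resample = 200 * n_inputs) {
  local_seed_(seed)
  R <- nrow(W0)
  X <- matrix(NA_real_, R, n_inputs)
  targets <- matrix(NA_integer_, ncol(W0), n_inputs)
  keys <- character(0)
  got <- 0L
  for (draw in seq_len(max_resample)) {
    x <- runif(R, -1, 1)
    v <- two_phase_(net, W0, x, L)$final
    key <- paste(which(v == 1L), collapse = ",")
    if (!(key %in% keys)) {
      got <- got + 1L
      X[, got] <- x
      targets[, got] <- v
      keys <- c(keys, key)
      if (got == n_inputs)
        return(structure(list(X = X, targets = targets, L = L,
                              n_resampled = draw - n_inputs),
                         class = "input_vector_set"))
    }
  }
  stop_arg_("could not occupy ", n_inputs, " distinct attractors in ",
            max_resample, " draws")
}

#' Train the modified two-phase perceptron
#'
#' For each input: phase 1 excites the top-L neurons of the readout
#' drive; phase 2 is the attractor state the input was assigned when it
#' was selected (the state its phase-2 relaxation produced then — fixing
#' it makes the procedure a per-neuron perceptron and keeps the
#' input-to-attractor map stable during learning).  Neurons whose state
#' flips 0 -> 1 between the phases get `X` added to their readout column;
#' 1 -> 0 flips get `X` subtracted.  Passes over the full input set
#' repeat until `W` stops changing or `max_passes` is reached.
#'
#' @param net The d = 0 network (`NULL` for the unconnected baseline; its
#'   assigned states equal the initial phase-1 states, so no update ever
#'   occurs and the baseline is unaffected by learning).
#' @param inputs An `input_vector_set`.
#' @param W0 Initial R x N readout weights.
#' @param max_passes Pass budget.
#' @return List with `W`, `passes` and `converged` (`FALSE` flags pass
#'   budget exhaustion, not an error).
#' @export
train_modified_perceptron <- function(net, inputs, W0, max_passes = 50) {
  W <- W0
  L <- inputs$L
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    for (t in seq_len(ncol(inputs$X))) {
      x <- inputs$X[, t]
      init <- phase1_state_(W, x, L)
      final <- inputs$targets[, t]
      up <- final == 1L & init == 0L
      dn <- final == 0L & init == 1L
      if (any(up)) { W[, up] <- W[, up] + x; changed <- TRUE }
      if (any(dn)) { W[, dn] <- W[, dn] - x; changed <- TRUE }
    }
    if (!changed)
      return(list(W = W, passes = pass, converged = TRUE))
  }
  list(W = W, passes = max_passes, converged = FALSE)
}

#' Mean output error under input noise
#'
#' Perturbs each input by a uniform noise vector with coordinates in
#' `[-eta, eta]`, runs phase 1 (and phase 2 when a network is given; with
#' `net = NULL` the unconnected baseline just excites the L most-driven
#' neurons) and scores the Hamming distance between the reached state and
#' the input's assigned attractor state.
#'
#' @param net The d = 0 network, or `NULL` for the unconnected baseline.
#' @param W Trained R x N readout weights.
#' @param inputs An `input_vector_set` carrying the assigned targets.
#' @param eta Noise amplitude in [0, 1].
#' @param n_trials Noise draws per input.
#' @param seed Optional integer seed.
#' @param normalize Divide by `2 L` (mismatched bits over the maximal
#'   disjoint-state distance); `FALSE` gives absolute Hamming distance.
#' @return Mean error over inputs x trials.
#' @export
noise_response_error <- function(net, W, inputs, eta, n_trials = 20,
                                 seed = NULL, normalize = TRUE) {
  if (eta < 0 || eta > 1) stop_arg_("eta must be in [0, 1]")
  local_seed_(seed)
  L <- inputs$L
  n_in <- ncol(inputs$X)
  R <- nrow(inputs$X)
  total <- 0
  Wm <- if (is.null(net)) NULL else as_weights_(net)
  for (trial in seq_len(n_trials)) {
    Xn <- inputs$X + matrix(runif(R * n_in, -eta, eta), R, n_in)
    Dr <- crossprod(W, Xn)                      # N x n_in drives
    V <- apply(Dr, 2, initial_state_top_l, L = L)
    if (!is.null(Wm))
      for (t in seq_len(n_in))
        V[, t] <- cpp_wtl_relax(Wm, V[, t], L, 2000L)$state
    total <- total + sum(abs(V - inputs$targets))
  }
  err <- total / (n_trials * n_in)
  if (normalize) err / (2 * L) else err
}

#' Noise-tolerance curve
#'
#' Convenience sweep of [noise_response_error()] over a grid of noise
#' amplitudes.
#'
#' @inheritParams noise_response_error
#' @param etas Noise amplitudes (default 0..1 in steps of 0.025).
#' @return Data frame with columns `eta` and `error`.
#' @export
noise_tolerance_curve <- function(net, W, inputs, etas = seq(0, 1, 0.025),
                                  n_trials = 20, seed = NULL,
                                  normalize = TRUE) {
  local_seed_(seed)
  err <- vapply(etas, function(e)
    noise_response_error(net, W, inputs, e, n_trials, seed = NULL,
                         normalize = normalize), 0)
  data.frame(eta = etas, error = err)
}
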