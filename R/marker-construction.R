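# Construction of model molecular-marker sets and the innate connection
# matrices they induce.  Two marker geometries are supported:
#   * point markers: M classes of L interchangeable markers each (d = 0
#     isolated attractor points);
#   * ring markers: M = k * N markers ordered on a ring, distance
#     min(|i - j|, M - |i - j|) (d = 1 bump attractors).
# Neuron, marker and class identifiers are 1-based throughout.

#' Ring distance between two markers
#'
#' Markers are ordered on a ring of size `M`; the distance between markers
#' `i` and `j` is `min(|i - j|, M - |i - j|)`.
#'
#' @param i,j Marker identifiers in `1..M` (vectorised, recycled).
#' @param M Ring size (total number of markers).
#' @return Integer vector of ring distances, each in `0..floor(M/2)`.
#' @examples
#' marker_ring_distance(5, 5, 900)    # 0
#' marker_ring_distance(1, 900, 900)  # 1 (wrap-around)
#' marker_ring_distance(11, 251, 900) # 240
#' @export
marker_ring_distance <- function(i, j, M) {
  if (M < 1) stop_arg_("`M` must be a positive integer")
  if (any(i < 1L | i > M) || any(j < 1L | j > M))
    stop_arg_("marker identifiers must lie in 1..M")
  a <- abs(i - j)
  as.integer(pmin(a, M - a))
}

#' Distribute point markers over neurons
#'
#' Places `M * L` marker instances (`M` classes, `L` instances per class)
#' randomly over `N` neurons such that each class occupies `L` distinct
#' neurons, no neuron holds two markers of the same class, and per-neuron
#' marker counts are as even as possible (`floor(q)` or `ceiling(q)` with
#' `q = M * L / N`).
#'
#' @param N Number of neurons.
#' @param M Number of marker classes.
#' @param L Instances per class.
#' @param seed Optional integer seed; the construction is deterministic
#'   given the seed.
#' @param max_attempts Global restarts before giving up.
#' @return An object of class `point_marker_assignment`: a list with fields
#'   `N`, `M`, `L`, `q` and `classes` (per-neuron integer vectors of class
#'   identifiers).
#' @examples
#' a <- build_point_marker_assignment(N = 12, M = 4, L = 3, seed = 1)
#' range(lengths(a$classes))
#' @export
build_point_marker_assignment <- function(N, M, L, seed = NULL,
                                          max_attempts = 1000) {
  if (L > N)
    stop_arg_("infeasible: L > N (a class cannot occupy L distinct neurons)")
  if (N < 1 || M < 1 || L < 1) stop_arg_("N, M, L must be positive")
  local_seed_(seed)
  q <- M * L / N
  cap_hi <- ceiling(q)
  n_hi <- M * L - N * floor(q)          # neurons holding ceiling(q) markers
  for (attempt in seq_len(max_attempts)) {
    caps <- rep(floor(q), N)
    if (n_hi > 0) caps[sample.int(N, n_hi)] <- cap_hi
    rem <- caps
    classes <- vector("list", N)
    ok <- TRUE
    for (cls in sample.int(M)) {
      open <- which(rem > 0L)
      if (length(open) < L) { ok <- FALSE; break }
      # favour fuller remaining capacity so the exact degree sequence fills
      ord <- open[order(-rem[open], runif(length(open)))]
      chosen <- ord[seq_len(L)]
      rem[chosen] <- rem[chosen] - 1L
      for (n in chosen) classes[[n]] <- c(classes[[n]], cls)
    }
    if (ok && all(rem == 0L)) {
      out <- structure(
        list(N = as.integer(N), M = as.integer(M), L = as.integer(L),
             q = q, classes = lapply(classes, function(x) sort(as.integer(x)))),
        class = c("point_marker_assignment", "mmbann_assignment"))
      validate_point_assignment(out)
      return(out)
    }
  }
  stop_arg_("point-marker construction failed after ", max_attempts,
            " attempts")
}

#' Validate a point-marker assignment
#'
#' Checks the defining invariants: each class occupies exactly `L` distinct
#' neurons, no neuron repeats a class, per-neuron counts differ by at most
#' one, and the total number of instances is `M * L`.
#'
#' @param x A `point_marker_assignment`.
#' @return `TRUE` invisibly; errors if an invariant is violated.
#' @export
validate_point_assignment <- function(x) {
  stopifnot(inherits(x, "point_marker_assignment"))
  counts <- lengths(x$classes)
  if (sum(counts) != x$M * x$L)
    stop_arg_("total marker instances != M * L")
  if (max(counts) - min(counts) > 1L)
    stop_arg_("per-neuron marker counts differ by more than 1")
  if (any(vapply(x$classes, anyDuplicated, 0L) > 0L))
    stop_arg_("a neuron holds two markers of one class")
  tab <- tabulate(unlist(x$classes), nbins = x$M)
  if (any(tab != x$L))
    stop_arg_("a class does not appear in exactly L neurons")
  invisible(TRUE)
}

#' Distribute ring markers over neurons
#'
#' Places the `M = k * N` ring-ordered markers one at a time into random
#' neurons, subject to: every neuron owns exactly `k` markers, and any two
#' markers within one neuron are at ring distance strictly greater than
#' `Delta`.  On a dead end the whole placement restarts (up to
#' `max_attempts` times).
#'
#' @param N Number of neurons.
#' @param k Markers per neuron (`M = k * N`).
#' @param Delta Minimum intra-neuron ring distance (strict: distances must
#'   exceed `Delta`).
#' @param seed Optional integer seed.
#' @param max_attempts Global restarts before giving up.
#' @return An object of class `ring_marker_assignment`: a list with fields
#'   `N`, `k`, `M`, `Delta`, `owner` (marker -> neuron) and `per_neuron`
#'   (neuron -> ordered marker identifiers).
#' @examples
#' a <- build_ring_marker_assignment(N = 30, k = 2, Delta = 10, seed = 1)
#' a$M
#' @export
build_ring_marker_assignment <- function(N, k, Delta, seed = NULL,
                                         max_attempts = 1000) {
  if (N < 1 || k < 1 || Delta < 0) stop_arg_("invalid N, k or Delta")
  M <- as.integer(k * N)
  if (k >= 2 && M < k * (Delta + 1))
    stop_arg_("infeasible: a neuron cannot hold ", k,
              " markers pairwise more than ", Delta, " apart on a ring of ", M)
  local_seed_(seed)
  for (attempt in seq_len(max_attempts)) {
    mk <- matrix(NA_integer_, nrow = N, ncol = k)  # markers held per neuron
    load <- integer(N)
    owner <- integer(M)
    ok <- TRUE
    for (m in sample.int(M)) {
      open <- which(load < k)
      if (k > 1L && length(open)) {
        sub <- mk[open, , drop = FALSE]
        d <- abs(sub - m)
        d <- pmin(d, M - d)
        bad <- rowSums(!is.na(sub) & d <= Delta) > 0L
        open <- open[!bad]
      }
      if (!length(open)) { ok <- FALSE; break }
      n <- if (length(open) == 1L) open else open[sample.int(length(open), 1L)]
      load[n] <- load[n] + 1L
      mk[n, load[n]] <- m
      owner[m] <- n
    }
    if (ok) {
      per_neuron <- lapply(seq_len(N), function(n) sort(mk[n, seq_len(load[n])]))
      out <- structure(
        list(N = as.integer(N), k = as.integer(k), M = M,
             Delta = Delta, owner = owner, per_neuron = per_neuron),
        class = c("ring_marker_assignment", "mmbann_assignment"))
      validate_ring_assignment(out)
      return(out)
    }
  }
  stop_arg_("ring-marker construction failed after ", max_attempts,
            " restarts")
}

#' Validate a ring-marker assignment
#'
#' Checks: each marker owned by exactly one neuron, each neuron owns
#' exactly `k` markers, intra-neuron ring distances all exceed `Delta`.
#'
#' @param x A `ring_marker_assignment`.
#' @return `TRUE` invisibly; errors if an invariant is violated.
#' @export
validate_ring_assignment <- function(x) {
  stopifnot(inherits(x, "ring_marker_assignment"))
  if (length(x$owner) != x$M || anyNA(x$owner))
    stop_arg_("owner map does not cover every marker")
  if (any(lengths(x$per_neuron) != x$k))
    stop_arg_("a neuron does not own exactly k markers")
  if (sum(lengths(x$per_neuron)) != x$M)
    stop_arg_("per-neuron counts do not sum to M")
  for (n in seq_len(x$N)) {
    ms <- x$per_neuron[[n]]
    if (any(x$owner[ms] != n)) stop_arg_("owner map inconsistent")
    if (length(ms) > 1L) {
      d <- marker_ring_distance(rep(ms, each = length(ms)), rep(ms,
                                length(ms)), x$M)
      d <- matrix(d, length(ms))
      if (any(d[upper.tri(d)] <= x$Delta))
        stop_arg_("intra-neuron marker distance <= Delta")
    }
  }
  invisible(TRUE)
}

new_connection_matrix_ <- function(W, sigma, mode, meta = list()) {
  structure(list(weights = W, sigma = sigma, mode = mode, meta = meta),
            class = "connection_matrix")
}

#' @export
print.connection_matrix <- function(x, ...) {
  cat(sprintf("<connection_matrix> N = %d, mode = %s, sigma = %g\n",
              nrow(x$weights), x$mode, x$sigma))
  invisible(x)
}

#' @export
print.mmbann_assignment <- function(x, ...) {
  if (inherits(x, "ring_marker_assignment"))
    cat(sprintf("<ring_marker_assignment> N = %d, k = %d, M = %d, Delta = %g\n",
                x$N, x$k, x$M, x$Delta))
  else
    cat(sprintf("<point_marker_assignment> N = %d, M = %d classes, L = %d, q = %.3g\n",
                x$N, x$M, x$L, x$q))
  invisible(x)
}

#' Extract the weight matrix of a network
#'
#' @param x A `connection_matrix` (or a plain numeric matrix, returned
#'   as-is).
#' @return The `N x N` numeric weight matrix.
#' @export
weight_matrix <- function(x) {
  if (inherits(x, "connection_matrix")) x$weights
  else if (is.matrix(x)) x
  else stop_arg_("not a connection matrix")
}

#' Connect a point-marker network (d = 0)
#'
#' Neurons sharing at least one marker class are coupled with weight `+1`;
#' all other off-diagonal pairs get `-sigma` (default 0: the d = 0 network
#' is stabilised externally by winner-take-L dynamics, so inhibition is
#' optional).  The diagonal is zero and the matrix symmetric.
#'
#' @param assignment A `point_marker_assignment`.
#' @param sigma Inhibitory magnitude for non-sharing pairs (>= 0).
#' @return A `connection_matrix` (mode `"symmetric"`).
#' @export
connect_point_attractor <- function(assignment, sigma = 0) {
  stopifnot(inherits(assignment, "point_marker_assignment"))
  N <- assignment$N
  B <- matrix(0, N, assignment$M)
  for (n in seq_len(N)) B[n, assignment$classes[[n]]] <- 1
  share <- tcrossprod(B) > 0
  W <- ifelse(share, 1, -sigma)
  diag(W) <- 0
  new_connection_matrix_(W, sigma, "symmetric",
                         list(kind = "point", M = assignment$M,
                              L = assignment$L))
}

#' Connect a ring-marker network (d = 1)
#'
#' Symmetric mode: neurons are coupled `+1` when some pair of their markers
#' is at ring distance strictly less than `delta`, else `-sigma`.
#' Asymmetric mode (dynamic attractor): neuron `j` excites neuron `i` only
#' when a marker of `i` trails a marker of `j` by `1..window` ring steps
#' (excitation runs from higher to lower marker order); all other
#' off-diagonal entries are `-sigma`.
#'
#' @param assignment A `ring_marker_assignment`.
#' @param delta Excitation radius (strict `<` rule); must satisfy
#'   `0 < delta <= Delta` so one neuron's own markers never bridge distinct
#'   bump neighbourhoods.
#' @param sigma Inhibitory magnitude.
#' @param mode `"symmetric"` or `"asymmetric"`.
#' @param window Forward window for asymmetric mode (the ring-step range of
#'   excitation; conventionally about half the bump width).
#' @return A `connection_matrix`.
#' @export
connect_ring_attractor <- function(assignment, delta, sigma,
                                   mode = c("symmetric", "asymmetric"),
                                   window = NULL) {
  stopifnot(inherits(assignment, "ring_marker_assignment"))
  mode <- match.arg(mode)
  if (assignment$k > 1L && delta >= assignment$Delta)
    stop_arg_("delta must be smaller than Delta (bump neighbourhoods would merge)")
  if (delta <= 0) stop_arg_("delta must be positive")
  N <- assignment$N
  M <- assignment$M
  owner <- assignment$owner
  E <- matrix(FALSE, N, N)
  if (mode == "symmetric") {
    for (o in seq_len(max(0L, as.integer(ceiling(delta)) - 1L))) {
      if (o >= delta) break
      a <- owner
      b <- owner[c((o + 1):M, seq_len(o))]   # marker m + o (mod M)
      E[cbind(a, b)] <- TRUE
      E[cbind(b, a)] <- TRUE
    }
    # distance 0 pairs are same-marker (same neuron): excluded by diag zero
  } else {
    if (is.null(window)) stop_arg_("asymmetric mode requires `window`")
    for (o in seq_len(window)) {
      pre <- owner[c((o + 1):M, seq_len(o))]  # holds marker m + o (higher)
      post <- owner                           # holds marker m (lower)
      E[cbind(post, pre)] <- TRUE             # row = target, col = source
    }
  }
  W <- ifelse(E, 1, -sigma)
  diag(W) <- 0
  new_connection_matrix_(W, sigma, mode,
                         list(kind = "ring", delta = delta,
                              Delta = assignment$Delta, k = assignment$k,
                              M = M, window = window))
}

#' Build a network carrying two independent marker rings
#'
#' Each neuron receives one marker from each of two independent rings of
#' `N` markers (two independent random permutations).  Neurons are coupled
#' `+1` when either ring places a pair of their markers at distance less
#' than `delta`, else `-sigma`.  The network then contains two superposed
#' full ring attractors, recoverable by re-ordering neurons along either
#' ring.
#'
#' @param N Number of neurons (= markers per ring).
#' @param delta Excitation radius.
#' @param sigma Inhibitory magnitude.
#' @param seed Optional integer seed.
#' @return A list with elements `net` (a `connection_matrix`), `ring1` and
#'   `ring2` (the two `ring_marker_assignment`s).
#' @export
build_two_ring_network <- function(N, delta, sigma, seed = NULL) {
  local_seed_(seed)
  r1 <- build_ring_marker_assignment(N, k = 1, Delta = 0)
  r2 <- build_ring_marker_assignment(N, k = 1, Delta = 0)
  n1 <- connect_ring_attractor(r1, delta, sigma)
  n2 <- connect_ring_attractor(r2, delta, sigma)
  E <- (n1$weights > 0) | (n2$weights > 0)
  W <- ifelse(E, 1, -sigma)
  diag(W) <- 0
  net <- new_connection_matrix_(W, sigma, "symmetric",
                                list(kind = "two_ring", delta = delta, N = N))
  list(net = net, ring1 = r1, ring2 = r2)
}
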