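# Brute-force reference implementations used as independent oracles.

# pairwise class-intersection check for d = 0 connectivity
oracle_connect_point <- function(assignment, sigma = 0) {
  N <- assignment$N
  W <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    shared <- length(intersect(assignment$classes[[i]],
                               assignment$classes[[j]])) > 0
    W[i, j] <- if (shared) 1 else -sigma
  }
  W
}

# all-marker-pairs check for d = 1 connectivity
oracle_connect_ring <- function(assignment, delta, sigma,
                                mode = "symmetric", window = NULL) {
  N <- assignment$N
  M <- assignment$M
  W <- matrix(-sigma, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    hit <- FALSE
    for (a in assignment$per_neuron[[i]]) {
      for (b in assignment$per_neuron[[j]]) {
        if (mode == "symmetric") {
          if (marker_ring_distance(a, b, M) < delta) hit <- TRUE
        } else {
          # excitation from j onto i when j's marker leads i's by 1..window
          if (((b - a) %% M) %in% seq_len(window)) hit <- TRUE
        }
      }
    }
    W[i, j] <- if (hit) 1 else -sigma
  }
  diag(W) <- 0
  W
}

# direct double-loop Hamming distances
oracle_pair_distances <- function(S) {
  nt <- nrow(S)
  D <- matrix(0, nt, nt)
  for (a in seq_len(nt)) for (b in seq_len(nt))
    D[a, b] <- sum(S[a, ] != S[b, ])
  D
}

# a small random symmetric zero-diagonal integer network
random_symmetric_net <- function(N, seed) {
  set.seed(seed)
  W <- matrix(sample(c(-1, 0, 1), N * N, replace = TRUE,
                     prob = c(0.3, 0.4, 0.3)), N, N)
  W <- W + t(W)
  diag(W) <- 0
  W
}

# permute a ring assignment's neurons by `p` (new id of old neuron i is p[i])
permute_ring_assignment <- function(a, p) {
  out <- a
  out$owner <- p[a$owner]
  out$per_neuron <- vector("list", a$N)
  for (i in seq_len(a$N)) out$per_neuron[[p[i]]] <- a$per_neuron[[i]]
  out
}
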