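test_that("fixed points are returned unchanged by asynchronous relaxation", {
  fx <- make_fixture("ring-k1-n10")
  stable <- enumerate_stable_states(fx$net, theta = 0)
  expect_gt(nrow(stable), 0)
  for (r in seq_len(min(5, nrow(stable)))) {
    res <- async_relax(fx$net, stable[r, ], theta = 0, seed = r)
    expect_identical(res$state, as.integer(stable[r, ]))
    expect_true(res$converged)
    expect_lte(res$sweeps, 2)
  }
})

test_that("relaxation endpoints agree with exhaustive stable-state enumeration", {
  W <- random_symmetric_net(10, seed = 4)
  stable <- enumerate_stable_states(W, theta = 0)
  keys <- apply(stable, 1, paste, collapse = "")
  set.seed(9)
  for (i in 1:12) {
    v0 <- sample(0:1, 10, replace = TRUE)
    res <- async_relax(W, v0, theta = 0, max_sweeps = 200, seed = i)
    expect_true(res$converged)
    expect_true(paste(res$state, collapse = "") %in% keys)
  }
})

test_that("a marker-class state is an attractor of the d = 0 network", {
  fx <- make_fixture("points-n6-m2-l3")
  a <- fx$assignment
  for (cls in 1:2) {
    v <- as.integer(vapply(seq_len(6),
                           function(n) cls %in% a$classes[[n]], NA))
    # stays fixed under winner-take-L relaxation at the class's own size
    res <- relax_winner_take_l(fx$net, v, L = 3)
    expect_identical(res$state, v)
    # and under asynchronous relaxation with a mid-gap threshold
    h <- drop(weight_matrix(fx$net) %*% v)
    th <- (min(h[v == 1]) + max(h[v == 0])) / 2
    expect_identical(async_relax(fx$net, v, theta = th, seed = 1)$state, v)
  }
})

test_that("states one bit away from a class state relax back to it", {
  fx <- make_fixture("points-n6-m2-l3")
  a <- fx$assignment
  v <- as.integer(vapply(seq_len(6), function(n) 1L %in% a$classes[[n]], NA))
  set.seed(21)
  for (flip in which(v == 1)) {
    u <- v
    u[flip] <- 0L
    u[sample(which(v == 0), 1)] <- 1L   # keep the activity level at L
    res <- relax_winner_take_l(fx$net, u, L = 3)
    expect_identical(res$state, v)
  }
})

test_that("Hopfield energy behaves as defined and never increases", {
  W <- random_symmetric_net(10, seed = 6)
  expect_identical(hopfield_energy(W, 0, rep(0L, 10)), 0)
  th <- runif(10)
  v1 <- integer(10); v1[3] <- 1L
  expect_equal(hopfield_energy(W, th, v1), th[3])
  # sweep-by-sweep monotonicity along asynchronous trajectories
  set.seed(2)
  for (trial in 1:5) {
    v <- sample(0:1, 10, replace = TRUE)
    e <- hopfield_energy(W, 0, v)
    for (s in 1:30) {
      v <- async_relax(W, v, theta = 0, max_sweeps = 1, seed = trial * 100 + s)$state
      e2 <- hopfield_energy(W, 0, v)
      expect_lte(e2, e + 1e-12)
      e <- e2
    }
  }
  Wa <- matrix(rnorm(16), 4); diag(Wa) <- 0
  expect_error(hopfield_energy(Wa, 0, rep(0L, 4)), "asymmetric")
})

test_that("top-L initial states pick maxima with stable tie-breaks", {
  expect_identical(initial_state_top_l(runif(7), 7), rep(1L, 7))
  expect_identical(initial_state_top_l(rep(1, 6), 3),
                   c(1L, 1L, 1L, 0L, 0L, 0L))
  set.seed(3)
  drive <- rnorm(50)
  v <- initial_state_top_l(drive, 12)
  expect_identical(which(v == 1L), sort(order(drive, decreasing = TRUE)[1:12]))
  expect_error(initial_state_top_l(drive, 0), "1..N")
})

test_that("accommodation with dtheta = 0 reduces to static relaxation", {
  fx <- make_fixture("ring-k1-n10")
  cand <- fx$candidates
  init <- cand$indicator[, 1]
  traj <- run_accommodation_dynamics(fx$net, sweeps = 30, dtheta = 0,
                                     init = init, L = sum(init), seed = 1)
  expect_true(all(apply(traj$states, 1, identical, y = traj$states[1, ])))
})

test_that("a k = 1 ring is traversed monotonically and completely", {
  a <- build_ring_marker_assignment(N = 50, k = 1, Delta = 0, seed = 4)
  net <- connect_ring_attractor(a, delta = 6, sigma = 3)
  L <- measure_bump_width(net, seed = 1)
  cand <- candidate_state_set(a, L)
  traj <- run_accommodation_dynamics(net, sweeps = 600, init = cand$indicator[, 1],
                                     L = L, seed = 2)
  idx <- candidate_state_raster(traj, cand)$argmin
  step <- mmbann:::ring_diff_(idx[-length(idx)], idx[-1], 50)
  expect_true(all(abs(step) <= L))            # no jumps
  # after the start-up transient the drift direction is fixed
  moving <- step[-(1:100)]
  moving <- moving[moving != 0]
  expect_gt(length(moving), 20)
  expect_gte(max(mean(moving > 0), mean(moving < 0)), 0.9)
  expect_identical(sort(unique(idx)), 1:50)   # visits every candidate
})

test_that("accommodation never halts in one state on a ring network", {
  a <- build_ring_marker_assignment(N = 60, k = 2, Delta = 20, seed = 8)
  net <- connect_ring_attractor(a, delta = 5, sigma = 3)
  L <- measure_bump_width(net, seed = 1)
  cand <- candidate_state_set(a, L)
  traj <- run_accommodation_dynamics(net, sweeps = 1500, init = cand$indicator[, 1],
                                     L = L, seed = 3)
  idx <- candidate_state_raster(traj, cand)$argmin
  expect_gt(length(unique(idx)), a$M / 2)
})

test_that("the measured bump width reflects the excitation radius", {
  a <- build_ring_marker_assignment(N = 300, k = 1, Delta = 0, seed = 5)
  net <- connect_ring_attractor(a, delta = 12, sigma = 3)
  L <- measure_bump_width(net, seed = 2)
  expect_gte(L, 12)
  expect_lte(L, 19)
})
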