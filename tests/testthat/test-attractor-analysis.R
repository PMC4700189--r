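test_that("L-plots and distance curves match the pairwise oracle", {
  set.seed(1)
  S <- matrix(sample(0:1, 20 * 10, replace = TRUE), 20, 10)
  D <- oracle_pair_distances(S)
  lp <- lplot(S, max_dt = 8)
  for (t in 1:20) for (j in seq_along(lp$dt)) {
    t2 <- t + lp$dt[j]
    if (t2 >= 1 && t2 <= 20) expect_identical(lp$distance[t, j], D[t, t2])
  }
  curve <- mean_distance_curve(S, 8)
  for (dt in 0:8) {
    t1 <- seq_len(20 - dt)
    expect_equal(curve$r[dt + 1], mean(D[cbind(t1, t1 + dt)]))
  }
  expect_error(lplot(S, 20), "smaller")
})

test_that("degenerate trajectories give degenerate distance statistics", {
  S <- matrix(rep(c(0, 1, 1, 0, 0), each = 12), 12, 5)
  expect_true(all(na.omit(as.vector(lplot(S, 5)$distance)) == 0))
  expect_true(all(mean_distance_curve(S, 5)$r == 0))
  # alternating two states at Hamming distance 4
  a <- c(1, 1, 1, 1, 0, 0); b <- c(0, 0, 0, 0, 1, 1)
  S2 <- matrix(rep(c(a, b), 8), ncol = 6, byrow = TRUE)
  lp <- lplot(S2, 4)
  expect_setequal(unique(na.omit(as.vector(lp$distance))), c(0, 6))
  cv <- mean_distance_curve(S2, 4)
  expect_equal(cv$r, c(0, 6, 0, 6, 0))
})

test_that("period estimation recovers known periods", {
  base <- matrix(0L, 7, 10)
  for (i in 1:7) base[i, ((i - 1) %% 10) + 1] <- 1L
  S <- base[rep(1:7, 12), ]
  cv <- mean_distance_curve(S, 40)
  expect_equal(estimate_period(cv, min_lag = 3)$period, 7, tolerance = 1e-6)
  # noisy sinusoid-shaped curve with period 50
  set.seed(2)
  dt <- 0:200
  r <- 10 * (1 - cos(2 * pi * dt / 50)) + rnorm(201, sd = 0.3)
  r[1] <- 0
  cv2 <- structure(data.frame(dt = dt, r = r, n = 200 - dt),
                   class = c("distance_curve", "data.frame"))
  expect_equal(estimate_period(cv2, min_lag = 10)$period, 50, tolerance = 1)
  flat <- structure(data.frame(dt = 0:60, r = 0:60, n = 60),
                    class = c("distance_curve", "data.frame"))
  expect_error(estimate_period(flat), "minimum")
})

test_that("slope estimation is a least-squares fit on the early rise", {
  cv <- structure(data.frame(dt = 0:30, r = 2 * (0:30), n = 30),
                  class = c("distance_curve", "data.frame"))
  expect_equal(estimate_slope(cv), 2)
  set.seed(3)
  cv2 <- cv
  cv2$r <- 0.5 * cv$dt + rnorm(31, sd = 0.05)
  expect_equal(estimate_slope(cv2, 1, 20), 0.5, tolerance = 0.02)
  expect_error(estimate_slope(cv, 5, 5.5), "fewer")
})

test_that("state counting combines period and slope", {
  expect_equal(estimate_state_count(1225, 1.47), 900.375)
  expect_equal(estimate_state_count(300, 2), 300)
  expect_error(estimate_state_count(-1, 2), "positive")
})

test_that("plateau distance averages the post-drop window", {
  # synthetic curve: rise to 30, then a plateau at 29 after the drop
  dt <- 0:500
  r <- pmin(2 * dt, 30)
  r[dt > 170] <- 29
  cv <- structure(data.frame(dt = dt, r = r, n = 500 - dt),
                  class = c("distance_curve", "data.frame"))
  pl <- plateau_distance(cv, slope = 2, Delta = 80, period = 900)
  sel <- dt >= 80 * 2 / 2 + 90 & dt <= 450
  expect_equal(pl$D, mean(r[sel]))
  expect_error(plateau_distance(cv, 2, 80, period = 100), "empty")
})

test_that("the theoretical plateau follows the overlap formula", {
  expect_equal(theoretical_plateau_distance(15, 1, 900), 30)
  expect_equal(theoretical_plateau_distance(15, 3, 900), 29)
  expect_equal(theoretical_plateau_distance(15, 3, 90), 20)
  expect_error(theoretical_plateau_distance(15, 3, 0), "positive")
})

test_that("candidate-state rasters match a brute-force distance computation", {
  a <- build_ring_marker_assignment(N = 12, k = 1, Delta = 0, seed = 6)
  cand <- candidate_state_set(a, L_c = 3)
  expect_true(all(colSums(cand$indicator) == 3))
  set.seed(7)
  S <- matrix(sample(0:1, 5 * 12, replace = TRUE), 5, 12)
  cr <- candidate_state_raster(S, cand)
  for (t in 1:5) for (i in 1:12)
    expect_equal(cr$raster[t, i], sum(S[t, ] != cand$indicator[, i]))
  # a state equal to candidate i has distance zero there
  cr2 <- candidate_state_raster(matrix(cand$indicator[, 4], 1), cand)
  expect_equal(cr2$raster[1, 4], 0)
  expect_identical(cr2$argmin, 4L)
  # the empty state is at distance L_c from every candidate
  cr3 <- candidate_state_raster(matrix(0L, 1, 12), cand)
  expect_true(all(cr3$raster == 3))
})

test_that("jump detection recovers planted leaps and direction flips", {
  expect_identical(nrow(detect_jumps(rep(1:100, 3), 100, 10)), 0L)
  fx <- make_fixture("planted-jumps")
  j <- detect_jumps(fx$series, fx$M, jump_threshold = 10)
  expect_identical(j$time, fx$jumps_at)
  # a leap joining two opposite-direction ramps flips the drift direction
  s <- c(1:50, 250, 249:200)
  j2 <- detect_jumps(s, 300, 20)
  expect_identical(nrow(j2), 1L)
  expect_true(j2$direction_flip[1])
})

test_that("the critical-load formula brackets with its correction factor", {
  expect_equal(critical_k_formula(300, 12, 1), 12.5)
  expect_equal(critical_k_formula(300, 12, 2), 6.25)
  expect_warning(critical_k_formula(300, 12, 3), "correction")
})

test_that("bump verification certifies ideal rings and rejects random nets", {
  fx <- make_fixture("ring-k1-n10")
  rep1 <- verify_bump_attractor(fx$net, fx$candidates)
  expect_true(rep1$all_stable)
  expect_true(rep1$all_connected)
  expect_true(all(rep1$adjacent_distance == 2))
  set.seed(8)
  Wr <- matrix(rnorm(100), 10); diag(Wr) <- 0
  rep2 <- verify_bump_attractor(Wr, fx$candidates)
  expect_false(rep2$all_stable)
})

test_that("the dimension bound matches its closed form and monotonicities", {
  expect_identical(as.integer(dimension_bound(1e4, 10, 10)), 7L)
  expect_identical(as.integer(dimension_bound(1e4, 100, 100)), 3L)
  expect_identical(as.integer(dimension_bound(100, 100^2 / 4, 4)), 1L)
  # monotone: non-increasing in l and L, non-decreasing in N
  ls <- c(5, 10, 50, 100); Ls <- c(5, 20, 80); Ns <- c(1e3, 1e4, 1e5)
  for (L in Ls) for (N in Ns)
    expect_true(all(diff(vapply(ls, function(l)
      as.numeric(dimension_bound(N, l, L)), 0)) <= 0))
  for (l in ls) for (L in Ls)
    expect_true(all(diff(vapply(Ns, function(N)
      as.numeric(dimension_bound(N, l, L)), 0)) >= 0))
  d <- dimension_bound(300, 10, 15, delta = 12, k = 3)
  expect_false(attr(d, "load_ok"))   # (24)^d * 3 handily exceeds 300
  expect_error(dimension_bound(100, 1, 10), "exceed")
})
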