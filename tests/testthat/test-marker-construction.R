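test_that("marker ring distance follows the circular metric", {
  expect_identical(marker_ring_distance(5, 5, 900), 0L)
  expect_identical(marker_ring_distance(1, 900, 900), 1L)
  expect_identical(marker_ring_distance(11, 251, 900), 240L)
  # symmetry and range over a grid
  i <- rep(1:30, each = 30); j <- rep(1:30, 30)
  d <- marker_ring_distance(i, j, 30)
  expect_identical(d, marker_ring_distance(j, i, 30))
  expect_true(all(d >= 0 & d <= 15))
  expect_error(marker_ring_distance(0, 5, 900), "1..M")
  expect_error(marker_ring_distance(5, 901, 900), "1..M")
})

test_that("point-marker assignments satisfy their invariants", {
  a <- build_point_marker_assignment(N = 300, M = 100, L = 20, seed = 7)
  expect_true(validate_point_assignment(a))
  # q = 2000/300 is fractional: counts must split between 6 and 7
  expect_setequal(unique(lengths(a$classes)), c(6L, 7L))
  b <- build_point_marker_assignment(N = 4, M = 2, L = 2, seed = 1)
  expect_true(all(lengths(b$classes) == 1L))
  expect_error(build_point_marker_assignment(N = 3, M = 1, L = 4),
               "infeasible")
})

test_that("point-marker construction is deterministic given the seed", {
  a <- build_point_marker_assignment(60, 10, 6, seed = 42)
  b <- build_point_marker_assignment(60, 10, 6, seed = 42)
  expect_identical(a, b)
})

test_that("ring-marker assignments satisfy their invariants", {
  a <- build_ring_marker_assignment(N = 300, k = 3, Delta = 80, seed = 7)
  expect_identical(a$M, 900L)
  expect_true(validate_ring_assignment(a))
  # k = 1 with no distance constraint is a bijection markers -> neurons
  b <- build_ring_marker_assignment(N = 10, k = 1, Delta = 0, seed = 1)
  expect_setequal(b$owner, 1:10)
  # on a ring of M = 8 the maximum distance is 4, never > Delta = 4
  expect_error(build_ring_marker_assignment(N = 4, k = 2, Delta = 4),
               "infeasible")
})

test_that("marker assignments pass invariants over many random draws", {
  for (s in 1:25) {
    a <- build_ring_marker_assignment(N = 30, k = 2, Delta = 8, seed = s)
    expect_true(validate_ring_assignment(a))
    p <- build_point_marker_assignment(N = 24, M = 8, L = 5, seed = s)
    expect_true(validate_point_assignment(p))
  }
})

test_that("point-attractor connectivity matches the brute-force oracle", {
  a <- build_point_marker_assignment(N = 6, M = 2, L = 3, seed = 3)
  for (sigma in c(0, 1)) {
    net <- connect_point_attractor(a, sigma = sigma)
    expect_equal(net$weights, oracle_connect_point(a, sigma))
    expect_identical(diag(net$weights), rep(0, 6))
    expect_equal(net$weights, t(net$weights))
  }
})

test_that("ring-attractor connectivity matches the brute-force oracle", {
  a <- build_ring_marker_assignment(N = 12, k = 2, Delta = 6, seed = 5)
  net <- connect_ring_attractor(a, delta = 3, sigma = 2)
  expect_equal(net$weights, oracle_connect_ring(a, 3, 2))
  expect_true(all(net$weights %in% c(1, -2, 0)))
  # asymmetric mode against the forward-window oracle
  anet <- connect_ring_attractor(a, delta = 3, sigma = 2,
                                 mode = "asymmetric", window = 4)
  expect_equal(anet$weights,
               oracle_connect_ring(a, 3, 2, "asymmetric", window = 4))
  expect_error(connect_ring_attractor(a, delta = 6, sigma = 2), "Delta")
})

test_that("a k = 1 ring with delta = 2 couples each neuron to its marker neighbours", {
  a <- build_ring_marker_assignment(N = 10, k = 1, Delta = 0, seed = 2)
  net <- connect_ring_attractor(a, delta = 2, sigma = 1)
  for (m in 1:10) {
    nb <- a$owner[c((m %% 10) + 1, ((m - 2) %% 10) + 1)]
    exc <- which(net$weights[, a$owner[m]] > 0)
    expect_setequal(exc, nb)
  }
})

test_that("connectivity is equivariant under neuron relabeling", {
  a <- build_ring_marker_assignment(N = 10, k = 2, Delta = 4, seed = 9)
  net <- connect_ring_attractor(a, delta = 2, sigma = 3)
  set.seed(1)
  p <- sample(10)
  ap <- permute_ring_assignment(a, p)
  netp <- connect_ring_attractor(ap, delta = 2, sigma = 3)
  P <- diag(10)[p, ]   # row i of P W P' is old neuron p^-1(i)...
  expect_equal(netp$weights[p, p], net$weights)
})

test_that("two-ring networks use the union excitation rule", {
  two <- build_two_ring_network(N = 10, delta = 2, sigma = 4, seed = 11)
  n1 <- connect_ring_attractor(two$ring1, 2, 4)
  n2 <- connect_ring_attractor(two$ring2, 2, 4)
  manual <- ifelse((n1$weights > 0) | (n2$weights > 0), 1, -4)
  diag(manual) <- 0
  expect_equal(two$net$weights, manual)
  expect_true(validate_ring_assignment(two$ring1))
  expect_true(validate_ring_assignment(two$ring2))
  # the two rings are (almost surely) different enumerations
  expect_false(identical(two$ring1$owner, two$ring2$owner))
})
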