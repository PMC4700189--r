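test_that("receptor tuning is circular, peaked and translation invariant", {
  rec <- receptor_array(40, width = 0.08)
  x <- receptor_activation(0.2, rec)
  expect_identical(which.max(x), which.min(circ_dist <- abs(rec$preferred - 0.2)))
  expect_equal(max(x), rec$gain)
  # half-circle rotation of the stimulus rotates the pattern (even R)
  x2 <- receptor_activation(0.7, rec)
  expect_equal(x2, x[c(21:40, 1:20)], tolerance = 1e-12)
  # summed drive is translation invariant for broad enough tuning
  sums <- vapply(seq(0, 0.99, 0.01),
                 function(p) sum(receptor_activation(p, rec)), 0)
  expect_lt(diff(range(sums)) / mean(sums), 0.01)
  # phi is cyclic
  expect_equal(receptor_activation(1.3, rec), receptor_activation(0.3, rec))
  expect_error(receptor_array(1), "R >= 2")
})

small_som_net <- function(seed = 4) {
  ring <- build_ring_marker_assignment(60, 1, 0, seed = seed)
  list(ring = ring, net = connect_ring_attractor(ring, 5, 3))
}

test_that("a single SOM step follows the weight-update rule", {
  fx <- small_som_net()
  rec <- receptor_array(30, width = 0.1)
  st <- som_initialize(fx$net, rec, eta_learn = 0.2, seed = 1)
  # eta (effectively) zero: weights unchanged
  st0 <- st; st0$eta_learn <- 1e-12
  out0 <- som_step(st0, 0.3, smear_sweeps = 0)
  expect_equal(out0$W, st$W, tolerance = 1e-9)
  # full-matrix variant: W + eta (X V' - W), pure decay where V = 0
  stf <- som_initialize(fx$net, rec, eta_learn = 0.2, update = "full",
                        seed = 1)
  out <- som_step(stf, 0.3)
  X <- receptor_activation(0.3, rec)
  # silent neurons' columns must have decayed by exactly (1 - eta)
  silent <- which(colSums(abs(out$W - 0.8 * stf$W)) < 1e-9)
  expect_gt(length(silent), 30)
  # masked variant with no smear: only active columns move, towards X
  stm <- som_initialize(fx$net, rec, eta_learn = 0.2, seed = 1)
  outm <- som_step(stm, 0.3, smear_sweeps = 0)
  moved <- which(colSums(abs(outm$W - stm$W)) > 1e-12)
  for (j in moved)
    expect_equal(outm$W[, j], stm$W[, j] + 0.2 * (X - stm$W[, j]))
  expect_equal(length(moved), stm$L_init, tolerance = 3)
})

test_that("weights remain bounded during training", {
  fx <- small_som_net()
  rec <- receptor_array(30, width = 0.1)
  st <- train_som(fx$net, rec, n_steps = 300, eta_learn = 0.3, seed = 2)
  expect_true(all(st$W >= -1e-9))
  expect_true(all(st$W <= max(1, rec$gain) + 1e-9))
})

test_that("the circular correlation is exact on reference mappings", {
  fx <- make_fixture("ideal-mapping")
  a <- 2 * pi * fx$phi
  b <- 2 * pi * fx$index / fx$M
  expect_gt(abs(mmbann:::circular_correlation(a, b)), 0.99)
  # reversed mapping: same strength, opposite sign
  expect_lt(mmbann:::circular_correlation(a, -b), -0.99)
  set.seed(3)
  expect_lt(abs(mmbann:::circular_correlation(a, sample(b))), 0.25)
})

test_that("relaxation inside SOM steps stabilizes within a few sweeps", {
  fx <- small_som_net()
  rec <- receptor_array(60, width = 0.08)
  st <- train_som(fx$net, rec, n_steps = 250, eta_learn = 0.05, seed = 5)
  expect_gte(mean(st$relax_sweeps_log <= 6), 0.9)
})

test_that("training organizes a scaled-down stimulus map", {
  fx <- small_som_net()
  rec <- receptor_array(60, width = 0.08)
  st <- train_som(fx$net, rec, n_steps = 4000, eta_learn = 0.05, seed = 7)
  ev <- evaluate_mapping(st, n_test = 300, ring = fx$ring)
  # an untrained readout shows no association
  st0 <- som_initialize(fx$net, rec, seed = 8)
  ev0 <- evaluate_mapping(st0, n_test = 300, ring = fx$ring)
  expect_gt(ev$adjacency_fraction, 0.8)
  expect_gt(ev$circular_association, ev0$circular_association)
  expect_gt(ev$coverage, ev0$coverage / 2)  # trained map keeps broad coverage
})

test_that("the two-ring experiment reports a selected ring and margin", {
  exp2 <- two_ring_som_experiment(N = 60, R = 60, delta = 5, sigma = 10,
                                  n_steps = 3000, n_test = 200, seed = 9)
  expect_true(exp2$winner %in% c(1L, 2L))
  expect_gte(exp2$margin, 0)
  win <- if (exp2$winner == 1) exp2$metrics1 else exp2$metrics2
  lose <- if (exp2$winner == 1) exp2$metrics2 else exp2$metrics1
  expect_gte(win$circular_association, lose$circular_association)
})
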