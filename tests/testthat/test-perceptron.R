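test_that("the classic Rosenblatt update follows its rule", {
  w <- c(1, -2, 0.5)
  X <- c(0.2, 0.1, -0.3)
  expect_identical(rosenblatt_update(w, X, sign(sum(w * X))), w)
  y <- -sign(sum(w * X))
  expect_equal(rosenblatt_update(w, X, y), w + X * y)
  expect_identical(rosenblatt_update(w, rep(0, 3), 1), w + 0)
  expect_error(rosenblatt_update(w, X, 0), "-1 or \\+1")
})

test_that("the classic rule converges on a separable fixture", {
  set.seed(4)
  R <- 12
  w_true <- rnorm(R)
  X <- matrix(runif(40 * R, -1, 1), R, 40)
  y <- sign(drop(crossprod(X, w_true)) + 0.3)  # margin keeps it separable
  keep <- y != 0
  X <- X[, keep]; y <- y[keep]
  w <- rnorm(R, sd = 0.01)
  for (pass in 1:200) {
    w_old <- w
    for (t in seq_along(y)) w <- rosenblatt_update(w, X[, t], y[t])
    if (identical(w, w_old)) break
  }
  expect_lt(pass, 200)
  expect_identical(sign(drop(crossprod(X, w))), y)
})

small_perceptron_fixture <- function(seed = 13) {
  pm <- build_point_marker_assignment(N = 60, M = 12, L = 5, seed = seed)
  net <- connect_point_attractor(pm)
  set.seed(seed + 1)
  W0 <- matrix(runif(20 * 60, -0.1, 0.1), 20, 60)
  inputs <- select_input_vectors(net, W0, n_inputs = 12, L = 5,
                                 seed = seed + 2)
  list(net = net, W0 = W0, inputs = inputs)
}

test_that("input selection occupies pairwise distinct attractors", {
  fx <- small_perceptron_fixture()
  keys <- apply(fx$inputs$targets, 2, paste, collapse = "")
  expect_identical(length(unique(keys)), 12L)
  expect_true(all(colSums(fx$inputs$targets) == 5))
  one <- select_input_vectors(fx$net, fx$W0, n_inputs = 1, L = 5, seed = 3)
  expect_identical(ncol(one$X), 1L)
})

test_that("a single mismatched input updates the readout columns by +/- X", {
  fx <- small_perceptron_fixture()
  inp <- fx$inputs
  inp$X <- inp$X[, 1, drop = FALSE]
  inp$targets <- inp$targets[, 1, drop = FALSE]
  W <- fx$W0
  init <- initial_state_top_l(drop(crossprod(W, inp$X[, 1])), 5)
  fit <- train_modified_perceptron(fx$net, inp, W, max_passes = 1)
  up <- inp$targets[, 1] == 1L & init == 0L
  dn <- inp$targets[, 1] == 0L & init == 1L
  expected <- W
  expected[, up] <- expected[, up] + inp$X[, 1]
  expected[, dn] <- expected[, dn] - inp$X[, 1]
  expect_equal(fit$W, expected)
})

test_that("training converges and reproduces every assigned attractor", {
  fx <- small_perceptron_fixture()
  fit <- train_modified_perceptron(fx$net, fx$inputs, fx$W0)
  expect_true(fit$converged)
  expect_lt(fit$passes, 50)
  for (t in 1:12) {
    init <- initial_state_top_l(drop(crossprod(fit$W, fx$inputs$X[, t])), 5)
    fin <- relax_winner_take_l(fx$net, init, 5)$state
    expect_identical(fin, fx$inputs$targets[, t])
  }
  expect_equal(noise_response_error(fx$net, fit$W, fx$inputs, eta = 0,
                                    n_trials = 2, seed = 1), 0)
})

test_that("an already-consistent readout trains in one silent pass", {
  fx <- small_perceptron_fixture()
  fit <- train_modified_perceptron(fx$net, fx$inputs, fx$W0)
  again <- train_modified_perceptron(fx$net, fx$inputs, fit$W)
  expect_identical(again$passes, 1L)
  expect_identical(again$W, fit$W)
})

test_that("the unconnected baseline is unchanged by training and degrades with noise", {
  fx <- small_perceptron_fixture()
  base_inputs <- fx$inputs
  base_inputs$targets <- apply(crossprod(fx$W0, fx$inputs$X), 2,
                               initial_state_top_l, L = 5)
  fit <- train_modified_perceptron(NULL, base_inputs, fx$W0)
  expect_identical(fit$W, fx$W0)
  expect_identical(fit$passes, 1L)
  errs <- vapply(c(0, 0.2, 0.4, 0.7, 1), function(e)
    noise_response_error(NULL, fx$W0, base_inputs, e, n_trials = 12,
                         seed = 5), 0)
  expect_equal(errs[1], 0)
  expect_true(all(diff(errs) > 0))
})

test_that("the trained attractor readout resists far more noise than the baseline", {
  fx <- small_perceptron_fixture()
  fit <- train_modified_perceptron(fx$net, fx$inputs, fx$W0)
  base_inputs <- fx$inputs
  base_inputs$targets <- apply(crossprod(fx$W0, fx$inputs$X), 2,
                               initial_state_top_l, L = 5)
  e_net <- noise_response_error(fx$net, fit$W, fx$inputs, 0.4,
                                n_trials = 12, seed = 6)
  e_base <- noise_response_error(NULL, fx$W0, base_inputs, 0.4,
                                 n_trials = 12, seed = 6)
  expect_gt(e_base, 3 * max(e_net, 0.01))
  expect_error(noise_response_error(fx$net, fit$W, fx$inputs, 1.2), "eta")
})
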