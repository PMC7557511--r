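test_that("initialization is seeded and produces the production shapes", {
  net <- init_network(c(12, 16, 2), seed = 41)
  expect_equal(dim(net$W1), c(16, 12))
  expect_equal(dim(net$W2), c(2, 16))
  expect_length(net$b1, 16)
  expect_length(net$b2, 2)
  expect_identical(net, init_network(c(12, 16, 2), seed = 41))
  other <- init_network(c(12, 16, 2), seed = 42)
  expect_gt(max(abs(net$W1 - other$W1)), 0)
})

test_that("the forward pass is the log-sigmoid composition", {
  # all-zero parameters: every activation is sigmoid(0) = 1/2
  net <- init_network(c(3, 4, 2), seed = 1)
  net$W1[] <- 0; net$W2[] <- 0; net$b1[] <- 0; net$b2[] <- 0
  fw <- forward(net, matrix(rnorm(6), 2, 3))
  expect_true(all(fw$hidden == 0.5) && all(fw$output == 0.5))

  # outputs stay inside (0, 1) even for extreme finite inputs
  net2 <- init_network(c(2, 3, 2), seed = 2)
  fw2 <- forward(net2, matrix(c(1e3, -1e3, 0, 1e-8), 2, 2))
  expect_true(all(fw2$output > 0 & fw2$output < 1))
  expect_error(forward(net2, matrix(c(NA, 1), 1, 2)), "non-finite")
  expect_error(forward(net2, matrix(1, 1, 3)), "expects")

  # pencil-and-paper 2-1-1 oracle:
  # x = (0.5, -1), W1 = (0.3, 0.2), b1 = 0.1, W2 = 0.5, b2 = -0.2
  net3 <- init_network(c(2, 1, 1), seed = 3)
  net3$W1 <- matrix(c(0.3, 0.2), 1, 2)
  net3$b1 <- 0.1
  net3$W2 <- matrix(0.5, 1, 1)
  net3$b2 <- -0.2
  fw3 <- forward(net3, c(0.5, -1))
  expect_equal(as.numeric(fw3$hidden), 0.512497396484210, tolerance = 1e-14)
  expect_equal(as.numeric(fw3$output), 0.514058468104893, tolerance = 1e-14)
})

test_that("the batch objective is the half-sum of squared residuals", {
  net <- init_network(c(2, 2, 2), seed = 5)
  X <- matrix(rnorm(10), 5, 2)
  # outputs equal targets -> E = 0
  Y_exact <- forward(net, X)$output
  expect_equal(mse_error(net, X, Y_exact)$E, 0)
  # one sample with residual (0.5, 0.5) -> E = 0.25
  y_off <- Y_exact[1, ] - 0.5
  expect_equal(mse_error(net, X[1, , drop = FALSE],
                         matrix(y_off, 1))$E, 0.25)
  # random batch against a direct summation
  set.seed(6)
  Y <- matrix(runif(10), 5, 2)
  O <- forward(net, X)$output
  expect_equal(mse_error(net, X, Y)$E, 0.5 * sum((O - Y)^2), tolerance = 1e-12)
  expect_error(mse_error(net, X, Y[1:2, ]), "differ")
})

test_that("the back-propagated Jacobian matches finite differences", {
  for (s in 1:10) {
    prob <- random_problem(layout = c(3, 4, 2), n = 5, seed = 100 + s)
    jac <- jacobian(prob$net, prob$X, prob$Y)
    g_bp <- as.vector(crossprod(jac$J, jac$e))
    g_fd <- fd_gradient(prob$net, prob$X, prob$Y)
    expect_lt(max(abs(g_bp - g_fd)) / max(abs(g_fd)), 1e-5)
  }
  # zero residuals -> zero gradient
  net <- init_network(c(2, 3, 2), seed = 7)
  X <- matrix(rnorm(8), 4, 2)
  jac0 <- jacobian(net, X, forward(net, X)$output)
  expect_equal(max(abs(crossprod(jac0$J, jac0$e))), 0)
})

test_that("with identity activations the Jacobian is the design matrix", {
  # freeze the first layer to the identity map; the output unit is then the
  # linear model o = w'x + b whose residual Jacobian w.r.t. (w, b) is (X, 1)
  # (the classical least-squares Jacobian up to the residual sign convention
  # e = o - y = -(y - o))
  d <- 3; n <- 6
  net <- init_network(c(d, d, 1), seed = 8, activation = "identity")
  net$W1 <- diag(d); net$b1 <- numeric(d)
  set.seed(9)
  X <- matrix(rnorm(n * d), n, d)
  Y <- matrix(rnorm(n), n, 1)
  jac <- jacobian(net, X, Y)
  w2_cols <- d * d + d + seq_len(d)
  b2_col <- d * d + d + d + 1
  expect_equal(unname(jac$J[, w2_cols]), unname(X), tolerance = 1e-12)
  expect_equal(unname(jac$J[, b2_col]), rep(1, n), tolerance = 1e-12)
})

test_that("the damped step interpolates gradient descent and Gauss-Newton", {
  # full-rank linear least-squares problem posed directly as (J, e)
  set.seed(10)
  J <- cbind(1, matrix(rnorm(40), 20, 2))
  beta <- c(0.5, -1, 2)
  y <- J %*% c(1, 1, 1)
  e <- as.vector(J %*% beta - y)
  net <- init_network(c(2, 1, 1), seed = 1)  # only carries the param count

  expect_equal(lm_update(net, J, numeric(20), mu = 1), rep(0, 3))

  mu_big <- 1e8
  expect_equal(lm_update(net, J, e, mu_big),
               as.vector(-crossprod(J, e) / mu_big), tolerance = 1e-6)

  gn <- as.vector(-solve(crossprod(J), crossprod(J, e)))
  expect_equal(lm_update(net, J, e, mu = 1e-12), gn, tolerance = 1e-6)
  # and that step lands exactly on the least-squares optimum
  expect_equal(beta + gn, as.vector(qr.solve(J, y)), tolerance = 1e-8)
  expect_error(lm_update(net, J, e, mu = 0), "mu must be")
})

test_that("LM training solves XOR and always decreases the accepted error", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  Y <- matrix(c(0, 1, 1, 0), 4, 1)
  solved <- 0
  for (s in 1:10) {
    net <- init_network(c(2, 2, 1), seed = 2000 + s)
    fit <- train_lmbp(net, X, Y, training_config(max_epochs = 200, goal = 1e-4))
    if (fit$E_final < 1e-3) solved <- solved + 1
    acc <- fit$trace[fit$trace$accepted, "E"]
    expect_true(all(diff(acc) < 0))  # accepted steps strictly decrease E
  }
  expect_gte(solved, 9)
})

test_that("an already-converged network stops immediately", {
  net <- init_network(c(2, 2, 2), seed = 11)
  X <- matrix(rnorm(8), 4, 2)
  Y <- forward(net, X)$output  # E = 0 at the start
  fit <- train_lmbp(net, X, Y)
  expect_equal(fit$termination, "goal")
  expect_identical(fit$net$W1, net$W1)
  expect_equal(fit$E_final, 0)
})

test_that("LM training is byte-stable across identical runs", {
  prob <- random_problem(layout = c(4, 3, 2), n = 30, seed = 55)
  cfg <- training_config(max_epochs = 40)
  a <- train_lmbp(prob$net, prob$X, prob$Y, cfg)
  b <- train_lmbp(prob$net, prob$X, prob$Y, cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(a$net, b$net)
  expect_identical(a$E_final, b$E_final)
})

test_that("Adam is deterministic, idles at zero gradient, and trails LM", {
  # zero-gradient start: residuals all zero -> weights unchanged
  net <- init_network(c(2, 3, 2), seed = 12)
  X <- matrix(rnorm(8), 4, 2)
  Y0 <- forward(net, X)$output
  fit0 <- train_adam(net, X, Y0, training_config(max_epochs = 5))
  expect_equal(fit0$net$W1, net$W1)

  prob <- random_problem(layout = c(4, 6, 2), n = 40, seed = 77)
  cfg <- training_config(max_epochs = 100)
  a1 <- train_adam(prob$net, prob$X, prob$Y, cfg)
  a2 <- train_adam(prob$net, prob$X, prob$Y, cfg)
  expect_identical(a1$net, a2$net)

  # equal epoch budget: the second-order trainer reaches an error at least
  # as low as first-order Adam on this batch problem
  lm <- train_lmbp(prob$net, prob$X, prob$Y, cfg)
  expect_lte(lm$E_final, a1$E_final)
})

test_that("the label codec is bijective and predictions decode correctly", {
  expect_identical(decode_outputs(c(0.9, 0.1)), "left_smirking")
  expect_identical(decode_outputs(c(0.1, 0.2)), "furrowing_brow")
  expect_identical(decode_outputs(c(0.2, 0.8)), "raising_brow")
  expect_identical(decode_outputs(c(0.7, 0.6)), "right_smirking")
  for (a in action_classes()) {
    expect_identical(decode_outputs(encode_actions(a)), a)
  }
  expect_equal(dim(unique(encode_actions(action_classes()))), c(4, 2))
  expect_error(encode_actions("scowling"), "unknown facial action")
})
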