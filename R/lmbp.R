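#' Network layout and initialization
#'
#' The classifier is a fully connected feed-forward network with one hidden
#' layer and log-sigmoid activations on both the hidden and output layers:
#' `f(s) = 1 / (1 + exp(-s))` with net input `s = W x + b`. The production
#' layout is 12-16-2: 12 band-energy inputs, 16 hidden units, 2 output units
#' whose thresholded bits encode the four actions (see [encode_actions()]).
#'
#' Weights are drawn uniformly from `[-0.5, 0.5] / sqrt(fan_in)` and biases
#' uniformly from `[-0.5, 0.5]` (nonzero bias draws break the hidden-unit
#' symmetry that otherwise traps small nets in saddle points).
#' `activation = "identity"` replaces the sigmoids by the
#' identity (used to check the Jacobian against the closed-form linear
#' least-squares case).
#'
#' @param layout Integer vector `c(inputs, hidden, outputs)`.
#' @param seed Integer seed; the draw is deterministic under it.
#' @param activation `"logsig"` (default) or `"identity"`.
#' @return An object of class `lmbp_network` with weight matrices `W1`
#'   (hidden x inputs), `W2` (outputs x hidden) and bias vectors `b1`, `b2`.
#' @export
init_network <- function(layout = c(12, 16, 2), seed = 1,
                         activation = c("logsig", "identity")) {
  activation <- match.arg(activation)
  stopifnot(length(layout) == 3, all(layout >= 1))
  set.seed(as.integer(seed))
  d <- layout[1]; h <- layout[2]; k <- layout[3]
  structure(
    list(
      W1 = matrix(stats::runif(h * d, -0.5, 0.5) / sqrt(d), h, d),
      b1 = stats::runif(h, -0.5, 0.5),
      W2 = matrix(stats::runif(k * h, -0.5, 0.5) / sqrt(h), k, h),
      b2 = stats::runif(k, -0.5, 0.5),
      layout = as.integer(layout), activation = activation
    ),
    class = "lmbp_network"
  )
}

act_fun <- function(s, activation) {
  if (activation == "logsig") 1 / (1 + exp(-s)) else s
}
act_deriv <- function(a, activation) {
  if (activation == "logsig") a * (1 - a) else rep(1, length(a))
}

#' Forward pass
#'
#' @param net `lmbp_network`.
#' @param X Numeric matrix (samples x inputs) or a single input vector.
#' @return List with `output` (samples x outputs) and `hidden` (samples x
#'   hidden units), both activations. With log-sigmoid units every activation
#'   lies in the open interval (0, 1).
#' @export
forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != net$layout[1]) {
    stop("input has ", ncol(X), " features; network expects ", net$layout[1],
         call. = FALSE)
  }
  if (!all(is.finite(X))) stop("non-finite values in input", call. = FALSE)
  H <- act_fun(X %*% t(net$W1) + rep(net$b1, each = nrow(X)), net$activation)
  O <- act_fun(H %*% t(net$W2) + rep(net$b2, each = nrow(X)), net$activation)
  list(output = O, hidden = H)
}

#' Batch mean-squared-error objective
#'
#' The training objective is `E(Q) = 1/2 * sum_m ||P_m - Y_m||^2`, the
#' half-sum of squared residuals between the network outputs `P_m` and the
#' encoded targets `Y_m` over the whole batch.
#'
#' @param net `lmbp_network`.
#' @param X Feature matrix (samples x inputs).
#' @param Y Target matrix (samples x outputs).
#' @return List with `E` (scalar), `per_sample` (vector of per-sample
#'   half-sums) and `residuals` (samples x outputs matrix `output - target`).
#' @export
mse_error <- function(net, X, Y) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = NROW(X))
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ", call. = FALSE)
  R <- forward(net, X)$output - Y
  list(E = 0.5 * sum(R^2), per_sample = 0.5 * rowSums(R^2), residuals = R)
}

# Parameter vector order: vec(W1) column-major, b1, vec(W2) column-major, b2.
pack_params <- function(net) {
  c(as.vector(net$W1), net$b1, as.vector(net$W2), net$b2)
}

unpack_params <- function(net, q) {
  d <- net$layout[1]; h <- net$layout[2]; k <- net$layout[3]
  i <- 0
  net$W1 <- matrix(q[i + seq_len(h * d)], h, d); i <- i + h * d
  net$b1 <- q[i + seq_len(h)];                   i <- i + h
  net$W2 <- matrix(q[i + seq_len(k * h)], k, h); i <- i + k * h
  net$b2 <- q[i + seq_len(k)]
  net
}

n_params <- function(net) {
  d <- net$layout[1]; h <- net$layout[2]; k <- net$layout[3]
  h * d + h + k * h + k
}

#' Residual Jacobian by back-propagation
#'
#' Computes the Jacobian `J[r, p] = d e_r / d Q_p` of the stacked residual
#' vector `e` (sample-major: the outputs of sample 1, then sample 2, ...)
#' with respect to the packed parameter vector `Q` (`vec(W1)` column-major,
#' `b1`, `vec(W2)`, `b2`). The gradient of the objective is then
#' `grad E = J' e` and the damped normal matrix `J'J + mu I` drives the LM
#' update.
#'
#' @param net `lmbp_network`.
#' @param X,Y Feature and target matrices.
#' @return List with `J` (residuals x parameters), `e` (stacked residual
#'   vector) and `E` (objective value).
#' @export
jacobian <- function(net, X, Y) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = nrow(X))
  fw <- forward(net, X)
  H <- fw$hidden; O <- fw$output
  n <- nrow(X); d <- net$layout[1]; h <- net$layout[2]; k <- net$layout[3]
  R <- O - Y
  if (!all(is.finite(R))) stop("non-finite residuals", call. = FALSE)
  dO <- matrix(act_deriv(O, net$activation), n, k)   # d out / d net input
  dH <- matrix(act_deriv(H, net$activation), n, h)
  J <- matrix(0, n * k, n_params(net))
  c_w1 <- seq_len(h * d)
  c_b1 <- h * d + seq_len(h)
  c_w2 <- h * d + h + seq_len(k * h)
  c_b2 <- h * d + h + k * h + seq_len(k)
  for (kk in seq_len(k)) {
    rows <- (seq_len(n) - 1) * k + kk
    # output layer: d e_k / d W2[kk, j] = dO_k * H_j ; d e_k / d b2[kk] = dO_k
    W2block <- dO[, kk] * H                       # n x h
    # W2 is k x h, column-major: param index of W2[kk, j] is (j-1)*k + kk
    J[rows, c_w2[(seq_len(h) - 1) * k + kk]] <- W2block
    J[rows, c_b2[kk]] <- dO[, kk]
    # hidden layer: delta_j = dO_k * W2[kk, j] * dH_j
    Delta <- dO[, kk] * (dH * rep(net$W2[kk, ], each = n))  # n x h
    # W1 is h x d, column-major: param index of W1[j, i] is (i-1)*h + j
    for (ii in seq_len(d)) {
      J[rows, c_w1[(ii - 1) * h + seq_len(h)]] <- Delta * X[, ii]
    }
    J[rows, c_b1] <- Delta
  }
  list(J = J, e = as.vector(t(R)), E = 0.5 * sum(R^2))
}

#' Damped Gauss-Newton (Levenberg-Marquardt) step
#'
#' Solves `(J'J + mu I) dq = -J' e` for the parameter correction. The
#' damping `mu` blends the Gauss-Newton step (`mu -> 0`) with a scaled
#' gradient-descent step `-(1/mu) J' e` (`mu -> infinity`).
#'
#' @param net `lmbp_network` (used for the parameter count only).
#' @param J Residual Jacobian.
#' @param e Stacked residual vector.
#' @param mu Damping parameter (> 0).
#' @return Numeric correction vector `dq` in packed-parameter order.
#' @export
lm_update <- function(net, J, e, mu) {
  if (mu <= 0) stop("mu must be > 0", call. = FALSE)
  A <- crossprod(J)
  diag(A) <- diag(A) + mu
  g <- crossprod(J, e)
  dq <- tryCatch({
    U <- chol(A)
    -backsolve(U, forwardsolve(t(U), g))
  }, error = function(err) NULL)
  if (is.null(dq)) {
    dq <- tryCatch(-solve(A, g), error = function(err) {
      stop("damped normal equations are singular (mu = ", mu, ")",
           call. = FALSE)
    })
  }
  as.vector(dq)
}

#' Training configuration
#'
#' @param mu_init Initial damping `mu` (default 1e-3).
#' @param mu_increase,mu_decrease Factors applied to `mu` on a rejected /
#'   accepted step (classical Marquardt schedule: x10 and x0.1).
#' @param epsilon Stop when the accepted update norm `||dq||` falls below
#'   this (default 1e-6).
#' @param goal Stop when `E(Q)` falls to or below this (default 0).
#' @param max_epochs Epoch budget (default 1000).
#' @param mu_max Declare divergence when `mu` exceeds this (default 1e10).
#' @param mu_min Floor under `mu` (default 1e-10): repeated accepted steps
#'   otherwise shrink the damping until the normal equations of a
#'   rank-deficient Jacobian (e.g. saturated sigmoids on separable data)
#'   become numerically singular.
#' @param learning_rate Adam step size (used by [train_adam()] only).
#' @return List of class `training_config`.
#' @export
training_config <- function(mu_init = 1e-3, mu_increase = 10,
                            mu_decrease = 0.1, epsilon = 1e-6, goal = 0,
                            max_epochs = 1000, mu_max = 1e10, mu_min = 1e-10,
                            learning_rate = 0.01) {
  stopifnot(mu_init > 0, mu_increase > 1, mu_decrease > 0, mu_decrease < 1,
            epsilon > 0, max_epochs >= 1, mu_min > 0, mu_max > mu_min)
  structure(list(mu_init = mu_init, mu_increase = mu_increase,
                 mu_decrease = mu_decrease, epsilon = epsilon, goal = goal,
                 max_epochs = max_epochs, mu_max = mu_max, mu_min = mu_min,
                 learning_rate = learning_rate),
            class = "training_config")
}

#' Levenberg-Marquardt batch training
#'
#' Full-batch damped Gauss-Newton training of the feed-forward network. Each
#' epoch computes the residual Jacobian once and then proposes corrections:
#' a step that decreases `E(Q)` is accepted and relaxes the damping
#' (`mu <- mu * mu_decrease`); a step that does not is rejected and the
#' damping is raised (`mu <- mu * mu_increase`) before retrying, so every
#' accepted step strictly decreases the objective. Training stops when the
#' accepted update norm drops below `epsilon`, the objective reaches `goal`,
#' the epoch budget is exhausted, or `mu` overflows `mu_max` (divergence).
#'
#' @param net `lmbp_network` starting point.
#' @param X Feature matrix (samples x inputs); z-scored features recommended.
#' @param Y Encoded target matrix (samples x outputs).
#' @param config `training_config`.
#' @return List with `net` (trained network) and `trace` (data frame: epoch,
#'   `E` after the epoch, `mu`, update norm, accepted flag) plus
#'   `termination` reason.
#' @export
train_lmbp <- function(net, X, Y, config = training_config()) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = NROW(X))
  E_cur <- mse_error(net, X, Y)$E
  mu <- config$mu_init
  trace <- vector("list", config$max_epochs)
  termination <- "max_epochs"
  n_done <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    if (E_cur <= config$goal) { termination <- "goal"; break }
    jac <- jacobian(net, X, Y)
    q <- pack_params(net)
    accepted <- FALSE
    dq <- numeric(n_params(net))
    while (!accepted) {
      dq <- lm_update(net, jac$J, jac$e, mu)
      cand <- unpack_params(net, q + dq)
      E_new <- mse_error(cand, X, Y)$E
      if (is.finite(E_new) && E_new < E_cur) {
        net <- cand
        E_cur <- E_new
        mu <- max(mu * config$mu_decrease, config$mu_min)
        accepted <- TRUE
      } else if (sqrt(sum(dq^2)) < config$epsilon) {
        # the damped step has shrunk below the tolerance without improving
        break
      } else {
        mu <- mu * config$mu_increase
        if (mu > config$mu_max) break
      }
    }
    n_done <- epoch
    trace[[epoch]] <- data.frame(epoch = epoch, E = E_cur, mu = mu,
                                 dq_norm = sqrt(sum(dq^2)),
                                 accepted = accepted)
    if (!accepted) {
      termination <- if (mu > config$mu_max) "mu_overflow" else "step_tolerance"
      break
    }
    if (sqrt(sum(dq^2)) < config$epsilon) { termination <- "step_tolerance"; break }
    if (E_cur <= config$goal) { termination <- "goal"; break }
  }
  if (E_cur <= config$goal) termination <- "goal"
  list(net = net, trace = do.call(rbind, trace[seq_len(n_done)]),
       termination = termination, E_final = E_cur, epochs = n_done)
}

# Gradient of E(Q) by plain back-propagation (no Jacobian materialization).
grad_mse <- function(net, X, Y) {
  fw <- forward(net, X)
  H <- fw$hidden; O <- fw$output
  n <- nrow(X)
  R <- O - Y
  D2 <- R * matrix(act_deriv(O, net$activation), n, net$layout[3])
  gW2 <- t(D2) %*% H
  gb2 <- colSums(D2)
  D1 <- (D2 %*% net$W2) * matrix(act_deriv(H, net$activation), n, net$layout[2])
  gW1 <- t(D1) %*% X
  gb1 <- colSums(D1)
  c(as.vector(gW1), gb1, as.vector(gW2), gb2)
}

#' Adam baseline trainer
#'
#' Trains the same network and objective with full-batch Adam (first/second
#' moment estimates with bias correction; beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8; step size from `config$learning_rate`). Serves as the
#' first-order comparison against the LM trainer. Deterministic given the
#' initial network.
#'
#' @inheritParams train_lmbp
#' @return Same structure as [train_lmbp()].
#' @export
train_adam <- function(net, X, Y, config = training_config()) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = NROW(X))
  np <- n_params(net)
  m <- numeric(np); v <- numeric(np)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  q <- pack_params(net)
  trace <- vector("list", config$max_epochs)
  termination <- "max_epochs"
  E_cur <- mse_error(net, X, Y)$E
  n_done <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    if (E_cur <= config$goal) { termination <- "goal"; break }
    g <- grad_mse(net, X, Y)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^epoch)
    vhat <- v / (1 - beta2^epoch)
    dq <- -config$learning_rate * mhat / (sqrt(vhat) + eps)
    q <- q + dq
    net <- unpack_params(net, q)
    E_cur <- mse_error(net, X, Y)$E
    n_done <- epoch
    trace[[epoch]] <- data.frame(epoch = epoch, E = E_cur, mu = NA_real_,
                                 dq_norm = sqrt(sum(dq^2)), accepted = TRUE)
    if (sqrt(sum(dq^2)) < config$epsilon) { termination <- "step_tolerance"; break }
  }
  if (E_cur <= config$goal) termination <- "goal"
  list(net = net, trace = do.call(rbind, trace[seq_len(n_done)]),
       termination = termination, E_final = E_cur, epochs = n_done)
}
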