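#' Create a NeuralUCB agent
#'
#' One-hidden-layer ReLU network shared across actions; the action is
#' encoded by placing the context in the a-th input block (zeros
#' elsewhere), so the input width is \code{k * d}. Exploration follows the
#' diagonal confidence approximation: Z accumulates elementwise squared
#' network gradients, starting at \eqn{\lambda}, and the bonus for action a
#' is \eqn{\nu \sqrt{g_a^T \mathrm{diag}(Z)^{-1} g_a / m}}. After each
#' observed reward the network is trained by full-batch gradient descent on
#' the squared error over the replay of all observed (x, a, r) triples, up
#' to \code{stepBudget} steps with early stop at loss \code{tol}.
#'
#' @param d context dimension.
#' @param k number of actions.
#' @param m hidden width (the printed grid is 16...512; any positive
#'   integer is accepted).
#' @param nu exploration scale.
#' @param lambda ridge initialisation of Z (> 0).
#' @param lr learning rate; 0 freezes the network (Z still accumulates).
#' @param seed integer seed for the random weight initialisation.
#' @param stepBudget maximum gradient steps per trial (default 100).
#' @param tol early-stopping training loss (default 1e-3).
#' @return a [NeuralUCBAgent-class].
#' @export
NeuralUCB <- function(d, k = 2L, m = 32L, nu = 1, lambda = 1e-2,
                      lr = 0.02, seed = 1L, stepBudget = 100L, tol = 1e-3) {
  stopifnot(d >= 1, k >= 1, m >= 1, lambda > 0, lr >= 0, nu >= 0)
  d <- as.integer(d); k <- as.integer(k); m <- as.integer(m)
  p0 <- k * d
  set.seed(seed)
  st <- new.env(parent = emptyenv())
  st$W1 <- matrix(stats::rnorm(m * p0, 0, sqrt(2 / p0)), m, p0)
  st$b1 <- numeric(m)
  st$w2 <- stats::rnorm(m, 0, sqrt(1 / m))
  st$b2 <- 0
  st$ZW1 <- matrix(lambda, m, p0)
  st$Zb1 <- rep(lambda, m)
  st$Zw2 <- rep(lambda, m)
  st$Zb2 <- lambda
  st$X <- matrix(0, 0, p0)      # replay: embedded contexts
  st$r <- numeric(0)
  st$tol <- tol
  new("NeuralUCBAgent", state = st, d = d, k = k, m = m,
      nu = nu, lambda = lambda, lr = lr, stepBudget = as.integer(stepBudget))
}

# embed context x into the a-th input block
.nucbEmbed <- function(x, a, d, k) {
  z <- numeric(k * d)
  z[seq((a - 1L) * d + 1L, a * d)] <- x
  z
}

# forward pass + gradient of the scalar output w.r.t. all parameters,
# exploiting that z is nonzero only in block a.
.nucbForwardGrad <- function(st, x, a, d) {
  cols <- seq((a - 1L) * d + 1L, a * d)
  h <- drop(st$W1[, cols, drop = FALSE] %*% x) + st$b1
  act <- pmax(h, 0)
  f <- sum(st$w2 * act) + st$b2
  dh <- st$w2 * (h > 0)                  # d f / d h
  list(f = f, cols = cols,
       gW1blk = outer(dh, x),            # m x d block of dW1
       gb1 = dh, gw2 = act, gb2 = 1)
}

#' @rdname ucbScores
#' @export
setMethod("ucbScores", "NeuralUCBAgent", function(agent, x) {
  x <- as.numeric(x)
  if (length(x) != agent@d) stop("context has length ", length(x),
                                 ", expected ", agent@d)
  if (!all(is.finite(x))) stop("non-finite context vector")
  st <- agent@state
  vapply(seq_len(agent@k), function(a) {
    fg <- .nucbForwardGrad(st, x, a, agent@d)
    if (!is.finite(fg$f)) stop("non-finite network output")
    q <- sum(fg$gW1blk^2 / st$ZW1[, fg$cols, drop = FALSE]) +
      sum(fg$gb1^2 / st$Zb1) + sum(fg$gw2^2 / st$Zw2) + fg$gb2^2 / st$Zb2
    fg$f + agent@nu * sqrt(q / agent@m)
  }, numeric(1))
})

#' @rdname updateAgent
#' @export
setMethod("updateAgent", "NeuralUCBAgent", function(agent, x, action, reward) {
  x <- as.numeric(x)
  stopifnot(length(x) == agent@d, all(is.finite(x)),
            action >= 1, action <= agent@k, reward >= 0, reward <= 1)
  st <- agent@state
  fg <- .nucbForwardGrad(st, x, action, agent@d)
  st$ZW1[, fg$cols] <- st$ZW1[, fg$cols] + fg$gW1blk^2
  st$Zb1 <- st$Zb1 + fg$gb1^2
  st$Zw2 <- st$Zw2 + fg$gw2^2
  st$Zb2 <- st$Zb2 + fg$gb2^2
  st$X <- rbind(st$X, .nucbEmbed(x, action, agent@d, agent@k))
  st$r <- c(st$r, reward)
  if (agent@lr > 0) .nucbTrain(st, agent@lr, agent@stepBudget, st$tol)
  invisible(agent)
})

# full-batch gradient descent on mean squared error over the replay buffer
.nucbTrain <- function(st, lr, steps, tol) {
  n <- length(st$r)
  for (s in seq_len(steps)) {
    H <- st$X %*% t(st$W1)
    H <- sweep(H, 2, st$b1, "+")
    act <- pmax(H, 0)
    pred <- drop(act %*% st$w2) + st$b2
    resid <- pred - st$r
    loss <- mean(resid^2)
    if (!is.finite(loss))
      stop("NeuralUCB training diverged (loss is not finite); ",
           "use a smaller learning rate")
    if (loss < tol) break
    dpred <- 2 * resid / n
    dact <- outer(dpred, st$w2) * (H > 0)
    st$w2 <- st$w2 - lr * drop(crossprod(act, dpred))
    st$b2 <- st$b2 - lr * sum(dpred)
    st$W1 <- st$W1 - lr * crossprod(dact, st$X)
    st$b1 <- st$b1 - lr * colSums(dact)
  }
  invisible(NULL)
}

#' @rdname agentState
#' @export
setMethod("agentState", "NeuralUCBAgent", function(agent) {
  st <- agent@state
  list(W1 = st$W1 + 0, b1 = st$b1 + 0, w2 = st$w2 + 0, b2 = st$b2,
       ZW1 = st$ZW1 + 0, Zb1 = st$Zb1 + 0, Zw2 = st$Zw2 + 0, Zb2 = st$Zb2,
       nReplay = length(st$r), m = agent@m, nu = agent@nu,
       lambda = agent@lambda, lr = agent@lr, d = agent@d, k = agent@k)
})

setMethod("show", "NeuralUCBAgent", function(object) {
  cat(sprintf(
    "NeuralUCBAgent: d = %d, k = %d, m = %d, nu = %g, lambda = %g, lr = %g, replay = %d\n",
    object@d, object@k, object@m, object@nu, object@lambda, object@lr,
    length(object@state$r)))
})
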