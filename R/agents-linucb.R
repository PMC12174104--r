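#' @useDynLib errpBandit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Create a LinUCB agent
#'
#' Disjoint-arm LinUCB with unit ridge initialisation: for every action
#' \eqn{A_a = I_d}, \eqn{b_a = 0}, so the initial score of any context x is
#' \eqn{\alpha \sqrt{x^T x}} for all actions. The printed search grid for
#' the exploration weight is \code{c(0.01, 0.1, 1, 2, 4, 10)}
#' (see [defaultLinUCBGrid()]).
#'
#' @param d context dimension (>= 1).
#' @param k number of actions (>= 1).
#' @param alpha exploration weight (>= 0), default 1.
#' @return a [LinUCBAgent-class].
#' @examples
#' ag <- LinUCB(d = 2, k = 2, alpha = 1)
#' ucbScores(ag, c(1, 0))          # both actions: alpha * sqrt(x'x)
#' @export
LinUCB <- function(d, k = 2L, alpha = 1) {
  stopifnot(d >= 1, k >= 1, alpha >= 0)
  d <- as.integer(d); k <- as.integer(k)
  st <- new.env(parent = emptyenv())
  st$A <- lapply(seq_len(k), function(a) diag(d))
  st$Ainv <- lapply(seq_len(k), function(a) diag(d))
  st$b <- lapply(seq_len(k), function(a) numeric(d))
  st$theta <- lapply(seq_len(k), function(a) numeric(d))
  st$u <- lapply(seq_len(k), function(a) numeric(d))   # Ainv x buffers
  st$lastX <- NULL
  # contexts whose outer products are not yet folded into A (deferred to a
  # BLAS-3 flush; Ainv/b/theta are always current)
  st$pendingX <- lapply(seq_len(k), function(a) list())
  st$count <- integer(k)
  st$resolveEvery <- 256L
  new("LinUCBAgent", state = st, d = d, k = k, alpha = alpha)
}

# fold pending rank-1 terms into A (crossprod uses BLAS-3)
.linucbFlushA <- function(st, a) {
  if (length(st$pendingX[[a]]) == 0L) return(invisible(NULL))
  X <- do.call(cbind, st$pendingX[[a]])
  st$A[[a]] <- st$A[[a]] + tcrossprod(X)
  st$pendingX[[a]] <- list()
  invisible(NULL)
}

#' @rdname ucbScores
#' @export
setMethod("ucbScores", "LinUCBAgent", function(agent, x) {
  x <- as.numeric(x)
  if (length(x) != agent@d) stop("context has length ", length(x),
                                 ", expected ", agent@d)
  if (!all(is.finite(x))) stop("non-finite context vector")
  st <- agent@state
  out <- vapply(seq_len(agent@k), function(a)
    .linucbScoreCpp(st$Ainv[[a]], st$theta[[a]], x, agent@alpha, st$u[[a]]),
    numeric(1))
  st$lastX <- x
  out
})

#' @rdname updateAgent
#' @export
setMethod("updateAgent", "LinUCBAgent", function(agent, x, action, reward) {
  x <- as.numeric(x)
  stopifnot(length(x) == agent@d, all(is.finite(x)),
            action >= 1, action <= agent@k, reward >= 0, reward <= 1)
  st <- agent@state
  if (!identical(st$lastX, x))   # u buffer stale: recompute Ainv x
    .linucbScoreCpp(st$Ainv[[action]], st$theta[[action]], x, 0,
                    st$u[[action]])
  .linucbRank1Cpp(st$Ainv[[action]], st$b[[action]], st$theta[[action]],
                  x, st$u[[action]], reward)
  st$pendingX[[action]][[length(st$pendingX[[action]]) + 1L]] <- x
  st$count[action] <- st$count[action] + 1L
  st$lastX <- NULL
  if (st$count[action] %% st$resolveEvery == 0L) {
    # periodic full re-solve for numerical hygiene
    .linucbFlushA(st, action)
    st$Ainv[[action]] <- chol2inv(chol(st$A[[action]]))
    st$theta[[action]] <- drop(st$Ainv[[action]] %*% st$b[[action]])
  }
  invisible(agent)
})

#' @rdname agentState
#' @export
setMethod("agentState", "LinUCBAgent", function(agent) {
  st <- agent@state
  for (a in seq_len(agent@k)) .linucbFlushA(st, a)
  list(A = lapply(st$A, function(m) m + 0),
       Ainv = lapply(st$Ainv, function(m) m + 0),
       b = lapply(st$b, function(v) v + 0),
       theta = lapply(st$theta, function(v) v + 0),
       count = st$count + 0L, alpha = agent@alpha, d = agent@d, k = agent@k)
})

setMethod("show", "LinUCBAgent", function(object) {
  cat(sprintf("LinUCBAgent: d = %d, k = %d, alpha = %g, updates = %s\n",
              object@d, object@k, object@alpha,
              paste(object@state$count, collapse = "/")))
})

#' Pick the action with the highest score
#'
#' Argmax with explicit tie handling: the default \code{"first"} rule takes
#' the lowest index among tied maxima (deterministic); \code{"random"}
#' draws uniformly among them using the current RNG stream, so runs remain
#' reproducible under a fixed seed.
#'
#' @param scores numeric vector of per-action scores (length >= 1).
#' @param tieRule \code{"first"} or \code{"random"}.
#' @return the selected action index (1-based).
#' @export
selectAction <- function(scores, tieRule = c("first", "random")) {
  tieRule <- match.arg(tieRule)
  stopifnot(length(scores) >= 1)
  top <- which(scores == max(scores))
  if (tieRule == "first" || length(top) == 1L) top[1L]
  else top[sample.int(length(top), 1L)]
}

#' Hyperparameter grids used for agent search
#'
#' The exploration-weight grid for LinUCB and the hidden-size /
#' \eqn{\nu} / \eqn{\lambda} / learning-rate grids for NeuralUCB.
#'
#' @return a named list of grid values.
#' @export
defaultLinUCBGrid <- function() list(alpha = c(0.01, 0.1, 1, 2, 4, 10))

#' @rdname defaultLinUCBGrid
#' @export
defaultNeuralUCBGrid <- function() list(
  m = c(16L, 32L, 64L, 128L, 256L, 512L),
  nu = c(0.1, 1, 10),
  lambda = 10^-(1:4),
  lr = sort(c(2 * 10^-(1:4), 5 * 10^-(1:4)))
)
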