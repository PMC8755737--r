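#' L1-regularized linear regression by coordinate descent
#'
#' Minimizes `(1/m) * sum((y - w0 - X W)^2) + (lambda/m) * |W|_1` with an
#' unpenalized intercept, by cyclic coordinate descent with soft
#' thresholding. The objective is the luminance-decoder loss; dividing by 2
#' maps it onto the conventional lasso `(1/2m) RSS + (lambda/2m) |W|_1`, so
#' the soft-threshold level per coordinate is `lambda / (2m)`.
#'
#' @param X `m x N` predictor matrix.
#' @param y length-m response.
#' @param lambda regularization strength, `>= 0` (on the `lambda/m` scale of
#'   the decoder loss).
#' @param tol convergence tolerance on the objective change.
#' @param max_sweeps sweep cap.
#' @return list with `w` (N-vector), `w0`, `lambda`, `objective`,
#'   `n_sweeps`, `converged`.
#' @export
lasso_cd <- function(X, y, lambda, tol = 1e-8, max_sweeps = 10000L) {
  X <- as.matrix(X)
  m <- nrow(X); N <- ncol(X)
  stopifnot(length(y) == m, lambda >= 0, m >= 2)
  lg <- lambda / (2 * m)                      # soft-threshold level
  z <- colSums(X^2) / m
  w <- numeric(N)
  w0 <- mean(y)
  r <- y - w0                                 # residual y - w0 - Xw
  obj <- function() mean(r^2) + (lambda / m) * sum(abs(w))
  soft <- function(a, t) sign(a) * max(abs(a) - t, 0)
  last <- obj()
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    for (j in seq_len(N)) {
      if (z[j] == 0) next
      rho <- sum(X[, j] * r) / m + z[j] * w[j]
      wj_new <- soft(rho, lg) / z[j]
      if (wj_new != w[j]) {
        r <- r - X[, j] * (wj_new - w[j])
        w[j] <- wj_new
      }
    }
    w0_new <- w0 + mean(r)
    r <- r - (w0_new - w0)
    w0 <- w0_new
    cur <- obj()
    if (abs(last - cur) < tol) { converged <- TRUE; break }
    last <- cur
  }
  list(w = w, w0 = w0, lambda = lambda, objective = obj(),
       n_sweeps = sweeps, converged = converged)
}

## Closed-form 1-D lasso solution (unit design scaling handled internally):
## the soft-thresholded least-squares coefficient. Used as an oracle in tests.
soft_threshold <- function(a, t) sign(a) * pmax(abs(a) - t, 0)

#' L1-regularized logistic regression by proximal gradient
#'
#' Minimizes the penalized negative log-likelihood
#' `-(1/m) * sum(y log p + (1-y) log(1-p)) + (lambda/(2m)) * |W|_1` with
#' `p = 1 / (1 + exp(-(w0 + X W)))` and an unpenalized intercept, by FISTA
#' with a Lipschitz step.
#'
#' @param X `m x N` predictor matrix.
#' @param y length-m 0/1 labels (1 = edge).
#' @param lambda regularization strength on the `lambda/2m` scale of the
#'   location-decoder loss.
#' @param tol objective-change tolerance.
#' @param max_iter iteration cap.
#' @return list with `w`, `w0`, `lambda`, `objective`, `n_iter`,
#'   `converged`.
#' @export
logistic_lasso <- function(X, y, lambda, tol = 1e-8, max_iter = 20000L) {
  X <- as.matrix(X)
  m <- nrow(X); N <- ncol(X)
  stopifnot(length(y) == m, all(y %in% c(0, 1)), lambda >= 0)
  if (length(unique(y)) < 2L) stop("single-class input: both locations required")
  lg <- lambda / (2 * m)
  X1 <- cbind(1, X)
  L <- (norm(X1, "2")^2) / (4 * m)
  if (L == 0) L <- 1
  step <- 1 / L
  nll <- function(beta) {
    eta <- drop(X1 %*% beta)
    ## numerically stable -loglik/m
    mean((1 - y) * eta + log1p(exp(-eta)))
  }
  pen <- function(beta) lg * sum(abs(beta[-1]))
  grad <- function(beta) {
    p <- 1 / (1 + exp(-drop(X1 %*% beta)))
    drop(crossprod(X1, p - y)) / m
  }
  beta <- numeric(N + 1L)
  zv <- beta; tk <- 1
  last <- nll(beta) + pen(beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- grad(zv)
    bnew <- zv - step * g
    bnew[-1] <- soft_threshold(bnew[-1], step * lg)
    tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zv <- bnew + ((tk - 1) / tnew) * (bnew - beta)
    beta <- bnew; tk <- tnew
    if (it %% 10L == 0L) {
      cur <- nll(beta) + pen(beta)
      if (abs(last - cur) < tol) { converged <- TRUE; break }
      last <- cur
    }
  }
  list(w = beta[-1], w0 = beta[1], lambda = lambda,
       objective = nll(beta) + pen(beta), n_iter = it, converged = converged)
}
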