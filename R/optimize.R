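# Penalized Bernoulli likelihood objective and the l1 solver / path.

#' Per-sample Bernoulli negative log-likelihood
#'
#' `(1/n) * sum(-y * f + log(1 + exp(f)))`, evaluated stably for large `|f|`
#' via `log1p(exp(-|f|)) + max(f, 0)`.
#'
#' @param y 0/1 responses.
#' @param f linear-predictor values, same length.
#' @return scalar.
#' @examples
#' negLogLik(c(1, 0, 1), c(0, 0, 0))  # log(2)
#' @export
negLogLik <- function(y, f) {
  stopifnot(length(y) == length(f))
  mean(-y * f + pmax(f, 0) + log1p(exp(-abs(f))))
}

#' Per-column penalty weights for a pattern design
#'
#' Encodes both penalty conventions in one vector: the constant column gets
#' weight 0; in the single-penalty problem every other column gets `lambda`;
#' in the two-penalty problem main-effect columns get `lambda1` and
#' interaction columns (order 2 and 3) get `lambda2`.
#'
#' @param design a [PatternDesign].
#' @param lambda single penalty value, or
#' @param lambda1,lambda2 the two-penalty pair (overrides `lambda`).
#' @return numeric vector of per-column penalties.
#' @export
penaltyWeights <- function(design, lambda = NULL, lambda1 = NULL,
                           lambda2 = NULL) {
  ord <- design@order
  w <- numeric(length(ord))
  if (!is.null(lambda1) || !is.null(lambda2)) {
    w[ord == 1L] <- lambda1
    w[ord >= 2L] <- lambda2
  } else {
    w[ord >= 1L] <- lambda
  }
  w
}

#' Penalized objective value
#'
#' The negative log-likelihood plus the weighted l1 penalty
#' `sum(pen * abs(coef))`; with equal weights on all non-constant columns
#' this is the single-penalty pattern-search objective, with separate
#' main/interaction weights the two-penalty one.
#'
#' @param coef coefficients over all design columns.
#' @param design a [PatternDesign].
#' @param y 0/1 responses.
#' @param penalty per-column penalties (see [penaltyWeights()]).
#' @return scalar.
#' @export
objectiveValue <- function(coef, design, y, penalty) {
  f <- as.numeric(design@design %*% coef)
  negLogLik(y, f) + sum(penalty * abs(coef))
}

#' Smallest penalty with an intercept-only solution
#'
#' The entry point of the regularization path: the maximum over penalized
#' columns of `|(1/n) * sum_i B_l(x_i) (y_i - ybar)|`. At any penalty at or
#' above this value the all-zero (intercept-only) fit is stationary.
#'
#' @param design a [PatternDesign].
#' @param y 0/1 responses.
#' @param columns optional column subset over which to take the maximum
#'   (used for the per-block path endpoints of the two-penalty grid).
#' @return scalar; carries attribute `degenerate = TRUE` when `y` is all 0
#'   or all 1.
#' @export
lambdaMax <- function(design, y, columns = NULL) {
  ybar <- mean(y)
  d <- design@design
  sc <- abs(plps_col_inner(d@p, d@i, nrow(d), y - ybar))
  keep <- design@order > 0L
  if (!is.null(columns)) {
    keep <- keep & seq_along(sc) %in% columns
  }
  out <- if (any(keep)) max(sc[keep]) else 0
  if (ybar == 0 || ybar == 1) attr(out, "degenerate") <- TRUE
  out
}

.fitFromSolve <- function(sol, lambda, pen, design, y) {
  new("PenalizedFit", coef = as.numeric(sol$coef), lambda = lambda,
      penalty = pen, f = as.numeric(sol$f),
      objective = negLogLik(y, sol$f) + sum(pen * abs(sol$coef)),
      converged = isTRUE(sol$converged))
}

#' Solve the l1-penalized logistic problem at fixed penalties
#'
#' Cyclic coordinate descent on the quadratic majorization of the Bernoulli
#' negative log-likelihood (curvature bound 1/4), with active-set iteration
#' and full KKT sweeps; the intercept (constant column) is never penalized.
#' The problem is convex, so the returned fit is the global minimizer up to
#' the stationarity tolerance.
#'
#' @param design a [PatternDesign] (must include the constant column).
#' @param y 0/1 responses.
#' @param penalty per-column penalties from [penaltyWeights()].
#' @param warmStart optional [PenalizedFit] used to initialize.
#' @param tol KKT stationarity tolerance (default 1e-6).
#' @param maxit maximum number of coordinate sweeps (default 1e4).
#' @param lambda value(s) recorded in the returned fit (defaults to the
#'   distinct nonzero penalties).
#' @return a [PenalizedFit].
#' @export
solveL1Logistic <- function(design, y, penalty, warmStart = NULL,
                            tol = 1e-6, maxit = 10000, lambda = NULL) {
  d <- design@design
  n <- nrow(d)
  stopifnot(length(y) == n, length(penalty) == ncol(d), all(penalty >= 0))
  m <- ncol(d)
  if (is.null(warmStart)) {
    cinit <- numeric(m)
    finit <- numeric(n)
  } else {
    cinit <- warmStart@coef
    finit <- as.numeric(d %*% cinit)
  }
  sol <- plps_cd_solve(d@p, d@i, n, as.numeric(y), penalty, cinit, finit,
                       tol, as.integer(maxit))
  if (!isTRUE(sol$converged))
    stop(sprintf("l1 solver did not converge in %d sweeps (KKT residual %.2e)",
                 as.integer(maxit), sol$maxviol))
  if (is.null(lambda)) {
    lambda <- unique(penalty[penalty > 0])
    if (length(lambda) == 0) lambda <- 0
    if (length(lambda) > 2) lambda <- max(lambda)
  }
  .fitFromSolve(sol, lambda, penalty, design, y)
}

#' Geometric penalty grid
#'
#' @param lmax path entry point, typically [lambdaMax()].
#' @param nlambda number of grid points (default 50).
#' @param minRatio ratio of the smallest to largest value (default 1e-3).
#' @return decreasing numeric vector.
#' @export
lambdaGrid <- function(lmax, nlambda = 50, minRatio = 1e-3) {
  if (lmax <= 0) return(rep(0, nlambda))
  exp(seq(log(lmax), log(lmax * minRatio), length.out = nlambda))
}

#' Solve the regularization path
#'
#' One fit per penalty value on a descending grid, each warm-started from
#' the previous solution. The descent is stopped early once the active set
#' exceeds `dfmax` (saturated fits that no BGACV-family criterion selects).
#'
#' @param design a [PatternDesign].
#' @param y 0/1 responses.
#' @param lambdas decreasing penalty values.
#' @param dfmax active-set cap truncating the path (default Inf).
#' @inheritParams solveL1Logistic
#' @return list of [PenalizedFit] objects (possibly shorter than `lambdas`).
#' @export
solvePath <- function(design, y, lambdas, dfmax = Inf, tol = 1e-6,
                      maxit = 10000) {
  stopifnot(!is.unsorted(rev(lambdas)))
  fits <- vector("list", length(lambdas))
  warm <- NULL
  used <- 0L
  for (h in seq_along(lambdas)) {
    pen <- penaltyWeights(design, lambda = lambdas[h])
    fit <- tryCatch(
      solveL1Logistic(design, y, pen, warmStart = warm, tol = tol,
                      maxit = maxit, lambda = lambdas[h]),
      error = function(e)
        stop(sprintf("path failed at lambda index %d (%.4g): %s",
                     h, lambdas[h], conditionMessage(e))))
    used <- used + 1L
    fits[[used]] <- fit
    warm <- fit
    if (length(activeSet(fit)) > dfmax) break
  }
  fits[seq_len(used)]
}

#' Fitted success probabilities
#'
#' `1 / (1 + exp(-f(x)))` for each row of a binary matrix, where `f` is a
#' selected pattern model's logit.
#'
#' @param model a [SelectedModel].
#' @param X 0/1 matrix (or [BinaryDataset]) with the same variable indexing
#'   the model was fit on.
#' @return numeric vector of probabilities.
#' @export
predictProb <- function(model, X) {
  if (is(X, "BinaryDataset")) X <- X@X
  X <- as.matrix(X)
  f <- rep(model@intercept, nrow(X))
  for (h in seq_along(model@patterns)) {
    v <- model@patterns[[h]]
    b <- if (length(v) == 1L) X[, v] else apply(X[, v, drop = FALSE], 1, prod)
    f <- f + model@coefficients[h] * b
  }
  plogis(f)
}
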