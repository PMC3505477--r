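# GACV/BGACV tuning scores and the balanced two-penalty criteria.

# counts of nonzero coefficients by pattern order; s includes the intercept
.activeCounts <- function(coef, order) {
  nz <- coef != 0 & order > 0L
  nb <- c(sum(nz & order == 1L), sum(nz & order == 2L), sum(nz & order == 3L))
  list(nb = as.integer(nb), s = as.integer(sum(nz) + 1L))
}

.bgacvCore <- function(y, f, nb, s, stringent = TRUE, balance = 1) {
  n <- length(y)
  obs <- negLogLik(y, f)
  phi <- if (stringent) log(n) / 2 else 1
  optimism <- if (s >= n) Inf else phi * s / n
  new("TuningScore", obs = obs, optimism = optimism, stringency = phi,
      balance = balance, score = (obs + optimism) * balance,
      nb = nb, s = as.integer(s))
}

#' GACV / BGACV score of a penalized fit
#'
#' Comparative model-selection score: the observed per-sample negative
#' log-likelihood plus the optimism term `phi * s / n`, where `s` is the
#' active-set size including the intercept. `phi = 1` gives GACV (the
#' AIC-correspondence scale, `AIC / 2n`); BGACV uses `phi = log(n)/2` (the
#' `BIC / 2n` scale), making it the more stringent criterion — the
#' difference mirrors that between BIC and AIC. A saturated fit
#' (`s >= n`) scores `Inf`.
#'
#' @param fit a [PenalizedFit].
#' @param design the [PatternDesign] it was fit on.
#' @param y 0/1 responses.
#' @param stringent `TRUE` for BGACV (default), `FALSE` for GACV.
#' @return a [TuningScore].
#' @export
bgacv <- function(fit, design, y, stringent = TRUE) {
  ac <- .activeCounts(fit@coef, design@order)
  .bgacvCore(y, fit@f, ac$nb, ac$s, stringent = stringent)
}

#' Balance factor of the BGACV2 criterion
#'
#' `1 + 0.5 * |nb1 - nb2| / (nb1 + nb2)` with the convention that the factor
#' is 1 when no coefficient is active; always in `[1, 1.5]`.
#'
#' @param nb1 number of nonzero main-effect coefficients.
#' @param nb2 number of nonzero size-2 pattern coefficients.
#' @return scalar factor.
#' @export
balanceFactor2 <- function(nb1, nb2) {
  tot <- nb1 + nb2
  if (tot == 0) 1 else 1 + 0.5 * abs(nb1 - nb2) / tot
}

#' Balance factor of the BGACV3 criterion
#'
#' `1 + 0.5 * (|nb1 - na| + |nb2 - na| + |nb3 - na|) / (nb1 + nb2 + nb3)`
#' with `na = (nb1 + nb2 + nb3) / 3`; equals 1 exactly when the three counts
#' are equal (or all zero) and is always below 2.
#'
#' @param nb1,nb2,nb3 counts of nonzero main-effect, size-2 and size-3
#'   pattern coefficients.
#' @return scalar factor.
#' @export
balanceFactor3 <- function(nb1, nb2, nb3) {
  tot <- nb1 + nb2 + nb3
  if (tot == 0) return(1)
  na <- tot / 3
  1 + 0.5 * (abs(nb1 - na) + abs(nb2 - na) + abs(nb3 - na)) / tot
}

#' Balanced BGACV2 criterion for the two-penalty problem
#'
#' BGACV multiplied by [balanceFactor2()], penalizing disparity between the
#' numbers of selected main effects and size-2 patterns; used to choose
#' `(lambda1, lambda2)` in the order-2 aggregation stage.
#'
#' @inheritParams bgacv
#' @return a [TuningScore].
#' @export
bgacv2 <- function(fit, design, y) {
  ac <- .activeCounts(fit@coef, design@order)
  .bgacvCore(y, fit@f, ac$nb, ac$s,
             balance = balanceFactor2(ac$nb[1], ac$nb[2]))
}

#' Balanced BGACV3 criterion for the order-3 two-penalty problem
#'
#' BGACV multiplied by [balanceFactor3()], penalizing disparity among the
#' counts of selected mains, size-2 and size-3 patterns.
#'
#' @inheritParams bgacv
#' @return a [TuningScore].
#' @export
bgacv3 <- function(fit, design, y) {
  ac <- .activeCounts(fit@coef, design@order)
  .bgacvCore(y, fit@f, ac$nb, ac$s,
             balance = balanceFactor3(ac$nb[1], ac$nb[2], ac$nb[3]))
}

.criterionFun <- function(criterion) {
  switch(criterion,
         bgacv = function(fit, design, y) bgacv(fit, design, y, TRUE),
         gacv = function(fit, design, y) bgacv(fit, design, y, FALSE),
         bgacv2 = bgacv2,
         bgacv3 = bgacv3,
         stop("unknown criterion: ", criterion))
}

#' Select the penalty along a single-penalty path
#'
#' Minimizes the criterion over the path; ties go to the larger penalty
#' (sparser model). If every score is infinite the sparsest fit is returned
#' with a warning.
#'
#' @param path list of [PenalizedFit] objects in decreasing-penalty order.
#' @param design the [PatternDesign] used.
#' @param y 0/1 responses.
#' @param criterion `"bgacv"` (default) or `"gacv"`.
#' @return list with `fit`, `score` (a [TuningScore]), `index` and the
#'   numeric vector `scores`.
#' @export
selectLambda <- function(path, design, y, criterion = "bgacv") {
  stopifnot(length(path) >= 1)
  fun <- .criterionFun(criterion)
  scores <- lapply(path, fun, design = design, y = y)
  vals <- vapply(scores, function(s) s@score, numeric(1))
  if (all(!is.finite(vals))) {
    warning("all criterion scores are infinite; returning the sparsest fit")
    idx <- 1L
  } else {
    idx <- which.min(vals)  # first minimum = largest penalty on ties
  }
  list(fit = path[[idx]], score = scores[[idx]], index = idx, scores = vals)
}

#' Select the penalty pair on a two-penalty grid
#'
#' Minimizes a balanced criterion over converged `(lambda1, lambda2)` fits;
#' ties go to the larger `lambda1 + lambda2`, then the larger `lambda2`.
#'
#' @param fits list of two-penalty [PenalizedFit] objects (each with
#'   `lambda = c(lambda1, lambda2)`).
#' @param design the [PatternDesign] used.
#' @param y 0/1 responses.
#' @param criterion `"bgacv2"` (default), `"bgacv3"`, or a plain criterion
#'   (`"bgacv"`, `"gacv"`) for unbalanced selection on the grid.
#' @return as [selectLambda()].
#' @export
selectLambdaPair <- function(fits, design, y, criterion = "bgacv2") {
  stopifnot(length(fits) >= 1)
  fun <- .criterionFun(criterion)
  scores <- lapply(fits, fun, design = design, y = y)
  vals <- vapply(scores, function(s) s@score, numeric(1))
  l1 <- vapply(fits, function(f) f@lambda[1], numeric(1))
  l2 <- vapply(fits, function(f) f@lambda[2], numeric(1))
  if (all(!is.finite(vals))) {
    warning("all criterion scores are infinite; returning the sparsest fit")
    idx <- order(-(l1 + l2), -l2)[1]
  } else {
    ord <- order(vals, -(l1 + l2), -l2)
    idx <- ord[1]
  }
  list(fit = fits[[idx]], score = scores[[idx]], index = idx, scores = vals)
}
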