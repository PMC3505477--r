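# One complete LASSO-Patternsearch pass: penalized screening with BGACV
# selection, unpenalized logistic refit, backward elimination.

#' LASSO screening step
#'
#' Solves the single-penalty regularization path on a pattern design and
#' returns the active patterns of the criterion-selected fit (constant
#' excluded).
#'
#' @param design a [PatternDesign] including the constant column.
#' @param y 0/1 responses.
#' @param criterion `"bgacv"` (default) or `"gacv"`.
#' @param nlambda,minRatio geometric path grid (defaults 50 points over 3
#'   decades below [lambdaMax()]).
#' @param dfmax active-set cap truncating the path.
#' @param tol,maxit solver controls.
#' @return list of surviving patterns; attribute `"selection"` carries the
#'   [selectLambda()] result.
#' @export
screenLasso <- function(design, y, criterion = "bgacv", nlambda = 50,
                        minRatio = 1e-3, dfmax = 150, tol = 1e-6,
                        maxit = 10000) {
  lmax <- lambdaMax(design, y)
  if (isTRUE(attr(lmax, "degenerate")) || lmax <= 0) {
    out <- list()
    attr(out, "selection") <- NULL
    return(out)
  }
  grid <- lambdaGrid(as.numeric(lmax), nlambda, minRatio)
  path <- solvePath(design, y, grid, dfmax = dfmax, tol = tol, maxit = maxit)
  sel <- selectLambda(path, design, y, criterion)
  act <- activeSet(sel$fit)
  out <- design@patterns[act]
  attr(out, "selection") <- sel
  out
}

# standard errors from the weighted least-squares normal equations of the MLE
.glmSe <- function(Xd, prob) {
  w <- prob * (1 - prob)
  info <- crossprod(Xd * sqrt(w))
  tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, ncol(Xd)))
}

#' Unpenalized logistic refit on a set of patterns
#'
#' Maximum-likelihood logistic regression on the pattern design (intercept
#' plus one column per pattern). Linear predictors are capped at
#' `+/- etaCap` when computing probabilities and criterion scores; a fit
#' whose predictors exceed `etaCap / 2` (odds beyond ~3e6 under the
#' default) is flagged as quasi-complete separation.
#'
#' @param data a [BinaryDataset].
#' @param patterns list of patterns (no constant; must be distinct and fewer
#'   than `nSamples(data)`).
#' @param provenance character tag stored in the model.
#' @param etaCap linear-predictor cap (default 30).
#' @return a [SelectedModel] scored by BGACV.
#' @export
fitParametric <- function(data, patterns, provenance = "lps", etaCap = 30) {
  y <- data@y
  n <- length(y)
  keys <- vapply(patterns, patternKey, character(1))
  if (anyDuplicated(keys)) stop("duplicate patterns in refit")
  if (length(patterns) >= n) stop("more patterns than samples in refit")
  des <- buildDesign(data, c(list(integer(0)), patterns))
  Xd <- as.matrix(des@design)
  fit <- suppressWarnings(glm.fit(Xd, y, family = binomial()))
  cf <- fit$coefficients
  if (anyNA(cf)) {  # collinear columns: drop the offending patterns, refit
    bad <- which(is.na(cf)) - 1L
    return(fitParametric(data, patterns[-bad], provenance, etaCap))
  }
  eta <- as.numeric(Xd %*% cf)
  quasi <- any(abs(eta) > etaCap / 2)
  etaC <- pmin(pmax(eta, -etaCap), etaCap)
  prob <- plogis(etaC)
  ords <- vapply(patterns, length, integer(1))
  nb <- c(sum(ords == 1L), sum(ords == 2L), sum(ords == 3L))
  score <- .bgacvCore(y, etaC, as.integer(nb), 1L + length(patterns))
  se <- .glmSe(Xd, prob)
  stats <- data.frame(term = c("(Intercept)", keys),
                      order = c(0L, ords),
                      estimate = cf,
                      se = se,
                      z = cf / se,
                      row.names = NULL)
  new("SelectedModel", patterns = patterns, intercept = cf[1],
      coefficients = if (length(patterns)) cf[-1] else numeric(0),
      stats = stats, provenance = provenance, score = score@score,
      quasiSeparated = quasi)
}

#' Backward elimination under a tuning criterion
#'
#' Greedily deletes, one at a time, the pattern whose removal gives the
#' lowest criterion score (refitting the MLE after each deletion), stopping
#' when no single deletion lowers the current score. Score ties are resolved
#' by removing the higher-order term, then the lexicographically later
#' pattern label.
#'
#' @param model a fitted [SelectedModel].
#' @param data the [BinaryDataset] it was fit on.
#' @param etaCap linear-predictor cap passed to the refits.
#' @return the pruned [SelectedModel].
#' @export
backwardEliminate <- function(model, data, etaCap = 30) {
  current <- model
  repeat {
    m <- length(current@patterns)
    if (m == 0L) break
    cands <- vector("list", m)
    vals <- numeric(m)
    for (h in seq_len(m)) {
      cands[[h]] <- fitParametric(data, current@patterns[-h],
                                  provenance = current@provenance,
                                  etaCap = etaCap)
      vals[h] <- cands[[h]]@score
    }
    best <- min(vals)
    if (!(best < current@score)) break
    tied <- which(vals <= best + 1e-12)
    ords <- vapply(current@patterns[tied], length, integer(1))
    labs <- vapply(current@patterns[tied], patternKey, character(1))
    pick <- tied[order(-ords, -xtfrm(labs))][1]
    current <- cands[[pick]]
  }
  current
}

#' One complete LASSO-Patternsearch pass
#'
#' [screenLasso()] on the given candidate patterns, an unpenalized logistic
#' refit on the survivors, and [backwardEliminate()] under BGACV. If
#' screening retains at least `nSamples - 1` patterns, only the largest
#' (absolute) penalized coefficients are refit.
#'
#' @param data a [BinaryDataset].
#' @param patterns candidate pattern list (a constant basis is added if
#'   absent).
#' @param criterion screening criterion, `"bgacv"` (default) or `"gacv"`.
#' @param config a [plpsConfig()] list of solver/path controls.
#' @param provenance character tag for the returned model.
#' @return a [SelectedModel].
#' @export
runLps <- function(data, patterns, criterion = "bgacv",
                   config = plpsConfig(), provenance = "lps") {
  if (!any(vapply(patterns, length, integer(1)) == 0L))
    patterns <- c(list(integer(0)), patterns)
  design <- buildDesign(data, patterns)
  surv <- screenLasso(design, data@y, criterion = criterion,
                      nlambda = config$nlambda, minRatio = config$minRatio,
                      dfmax = config$dfmax, tol = config$tol,
                      maxit = config$maxit)
  sel <- attr(surv, "selection")
  attributes(surv) <- NULL
  n <- nSamples(data)
  if (length(surv) >= n - 1L) {  # rare: keep the strongest penalized terms
    cf <- abs(sel$fit@coef[activeSet(sel$fit)])
    surv <- surv[order(-cf)][seq_len(n %/% 2L)]
  }
  model <- fitParametric(data, surv, provenance = provenance,
                         etaCap = config$etaCap)
  backwardEliminate(model, data, etaCap = config$etaCap)
}
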