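# Two-stage pipeline: parallelizable screening over partition subproblems,
# survivor union, aggregation with separate main/interaction penalties.

#' Pipeline configuration
#'
#' Controls for the two-stage pattern search. Defaults follow the standard
#' workstation setting: partitions of `g = 200` variables for order 2 and
#' `g = 35` for order 3; a 50-point single-penalty path over three decades;
#' a 12 x 12 geometric `(lambda1, lambda2)` grid over three decades below
#' each block's own path entry point; KKT tolerance 1e-6 with at most 1e4
#' coordinate sweeps.
#'
#' @param order highest interaction order, 2 or 3.
#' @param g partition size (default 200 for order 2, 35 for order 3).
#' @param nlambda,minRatio single-penalty path grid.
#' @param nlambda2,minRatio2 per-axis two-penalty grid.
#' @param dfmax active-set cap truncating penalized paths.
#' @param tol,maxit coordinate-descent controls.
#' @param etaCap linear-predictor cap for unpenalized refits.
#' @param cap materialization cap on patterns per subproblem.
#' @return named list of settings.
#' @export
plpsConfig <- function(order = 2, g = NULL, nlambda = 50, minRatio = 1e-3,
                       nlambda2 = 12, minRatio2 = 1e-3, dfmax = 150,
                       tol = 1e-6, maxit = 10000, etaCap = 30, cap = 5e6) {
  order <- as.integer(order)
  stopifnot(order %in% c(2L, 3L))
  if (is.null(g)) g <- if (order == 2L) 200L else 35L
  stopifnot(g >= 1)
  list(order = order, g = as.integer(g), nlambda = nlambda,
       minRatio = minRatio, nlambda2 = nlambda2, minRatio2 = minRatio2,
       dfmax = dfmax, tol = tol, maxit = maxit, etaCap = etaCap, cap = cap)
}

#' Screening stage: one LPS pass per subproblem
#'
#' Partitions the variables, enumerates the subproblems of the requested
#' order and runs a full LPS pass (penalized path, BGACV selection,
#' parametric refit, backward elimination) on each subproblem's pattern
#' list. Subproblems are pure functions of the data and their spec, so the
#' merged result is independent of execution order.
#'
#' @param data a [BinaryDataset].
#' @param config a [plpsConfig()].
#' @return a [ScreeningResult].
#' @export
runScreeningStage <- function(data, config = plpsConfig()) {
  scheme <- makePartition(nVariables(data), config$g)
  specs <- enumerateSubproblems(scheme, config$order)
  models <- vector("list", length(specs))
  names(models) <- vapply(specs, subproblemId, character(1))
  for (h in seq_along(specs)) {
    pats <- patternsForSubproblem(specs[[h]], scheme)
    if (length(pats) > config$cap)
      stop(sprintf("subproblem %s: %d patterns exceed cap %g",
                   names(models)[h], length(pats), config$cap))
    models[[h]] <- tryCatch(
      runLps(data, pats, criterion = "bgacv", config = config,
             provenance = names(models)[h]),
      error = function(e)
        stop(sprintf("screening subproblem %s failed: %s",
                     names(models)[h], conditionMessage(e))))
  }
  allPats <- do.call(c, c(lapply(models, patternList), list()))
  keys <- vapply(allPats, patternKey, character(1))
  surv <- allPats[!duplicated(keys)]
  surv <- surv[order(vapply(surv, length, integer(1)),
                     vapply(surv, patternKey, character(1)))]
  names(surv) <- NULL
  new("ScreeningResult", models = models, survivors = surv,
      pStar = aggregateVariables(surv))
}

#' Unique variables appearing in surviving patterns
#'
#' @param survivors list of patterns.
#' @return sorted integer vector (the aggregation-stage variable set).
#' @export
aggregateVariables <- function(survivors) {
  sort(unique(as.integer(unlist(survivors, use.names = FALSE))))
}

# candidate patterns of the aggregation stage: constant + mains + all
# interactions up to `order` among the surviving variables
.aggregationPatterns <- function(vars, order) {
  out <- c(list(integer(0)), as.list(vars))
  if (order >= 2L && length(vars) >= 2L) out <- c(out, .pairsWithin(vars))
  if (order >= 3L && length(vars) >= 3L) {
    m <- combn(vars, 3L)
    out <- c(out, lapply(seq_len(ncol(m)), function(j) m[, j]))
  }
  out
}

#' Aggregation stage: two-penalty LPS on the surviving variables
#'
#' Builds the design of all patterns up to the configured order over the
#' `pStar` variables, solves the two-penalty problem over a geometric
#' `(lambda1, lambda2)` grid (one penalty for mains, one shared by all
#' interactions), selects the pair by BGACV2 (order 2) or BGACV3 (order 3),
#' then refits the survivors unpenalized and backward-eliminates under
#' BGACV.
#'
#' @param data a [BinaryDataset].
#' @param pStar integer vector of variables surviving screening.
#' @param config a [plpsConfig()].
#' @return a [SelectedModel] with provenance `"aggregation"`.
#' @export
runAggregationStage <- function(data, pStar, config = plpsConfig()) {
  y <- data@y
  n <- nSamples(data)
  if (length(pStar) == 0L)
    return(fitParametric(data, list(), provenance = "aggregation",
                         etaCap = config$etaCap))
  if (length(pStar) >= n)
    warning("more surviving variables than samples; penalized fit proceeds")
  design <- buildDesign(data, .aggregationPatterns(pStar, config$order))
  mainCols <- which(design@order == 1L)
  intCols <- which(design@order >= 2L)
  l1max <- as.numeric(lambdaMax(design, y, columns = mainCols))
  if (isTRUE(attr(lambdaMax(design, y), "degenerate")) || l1max <= 0)
    return(fitParametric(data, list(), provenance = "aggregation",
                         etaCap = config$etaCap))
  grid1 <- lambdaGrid(l1max, config$nlambda2, config$minRatio2)
  haveInt <- length(intCols) > 0L
  if (haveInt) {
    l2max <- as.numeric(lambdaMax(design, y, columns = intCols))
    grid2 <- lambdaGrid(l2max, config$nlambda2, config$minRatio2)
  } else {
    grid2 <- NA_real_
  }
  fits <- vector("list", length(grid1) * length(grid2))
  h <- 0L
  rowStart <- NULL
  for (i in seq_along(grid1)) {
    warm <- rowStart
    for (j in seq_along(grid2)) {
      l2 <- if (haveInt) grid2[j] else grid1[i]
      pen <- penaltyWeights(design, lambda1 = grid1[i], lambda2 = l2)
      fit <- solveL1Logistic(design, y, pen, warmStart = warm,
                             tol = config$tol, maxit = config$maxit,
                             lambda = c(grid1[i], l2))
      h <- h + 1L
      fits[[h]] <- fit
      warm <- fit
      if (j == 1L) rowStart <- fit
      if (length(activeSet(fit)) > config$dfmax) break
    }
  }
  fits <- fits[seq_len(h)]
  # with no interaction candidates there is nothing to balance: the factor
  # would only punish mains-only models, so fall back to plain BGACV
  crit <- if (!haveInt) "bgacv"
          else if (config$order == 3L) "bgacv3" else "bgacv2"
  sel <- selectLambdaPair(fits, design, y, criterion = crit)
  surv <- design@patterns[activeSet(sel$fit)]
  if (length(surv) >= n - 1L) {
    cf <- abs(sel$fit@coef[activeSet(sel$fit)])
    surv <- surv[order(-cf)][seq_len(n %/% 2L)]
  }
  model <- fitParametric(data, surv, provenance = "aggregation",
                         etaCap = config$etaCap)
  backwardEliminate(model, data, etaCap = config$etaCap)
}

#' Run the full two-stage partitioned pattern search
#'
#' [runScreeningStage()], [aggregateVariables()] and
#' [runAggregationStage()] composed; with a single partition (`g >= p`) the
#' procedure degenerates to one LPS pass over all patterns followed by the
#' aggregation pass on its survivors.
#'
#' @param data a [BinaryDataset].
#' @param config a [plpsConfig()].
#' @return the final [SelectedModel]; the [ScreeningResult] is attached as
#'   attribute `"screening"`.
#' @export
runPlps <- function(data, config = plpsConfig()) {
  screening <- runScreeningStage(data, config)
  model <- runAggregationStage(data, screening@pStar, config)
  attr(model, "screening") <- screening
  model
}

#' Write / read a survivors file
#'
#' Plain-text exchange format used to split screening and aggregation
#' across machines: one pattern label per line (`X50`, `X150*X250`, ...).
#'
#' @param survivors list of patterns.
#' @param path file path.
#' @return `readSurvivors` returns a list of patterns.
#' @export
writeSurvivors <- function(survivors, path) {
  writeLines(vapply(survivors, patternKey, character(1)), path)
  invisible(path)
}

#' @rdname writeSurvivors
#' @export
readSurvivors <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], parsePatternKey)
}
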