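# Evaluation: selection-count tables, prevalence filter, AUC, stratified
# cross-validation.

#' Pattern and variable selection counts over replicated models
#'
#' For each true pattern, the pattern count is the number of replicates
#' whose final model contains exactly that pattern; for each variable in a
#' true pattern, the variable count is the number of replicates in which it
#' appears anywhere in the model (as a main effect or inside any
#' interaction). Every selected pattern not in the truth set counts toward
#' the false-pattern total (pattern instances, summed over replicates).
#'
#' @param models list of [SelectedModel] objects (`NULL` entries — failed
#'   replicates — are skipped).
#' @param truth list of true patterns.
#' @return list with `patternCounts` and `variableCounts` (named integer
#'   vectors), `falseTotal`, and `reps` (number of non-`NULL` models).
#' @export
countPatterns <- function(models, truth) {
  models <- models[!vapply(models, is.null, logical(1))]
  reps <- length(models)
  stopifnot(reps >= 1)
  truthKeys <- vapply(truth, patternKey, character(1))
  truthVars <- sort(unique(unlist(truth)))
  patternCounts <- setNames(integer(length(truthKeys)), truthKeys)
  variableCounts <- setNames(integer(length(truthVars)),
                             paste0("X", truthVars))
  falseTotal <- 0L
  for (m in models) {
    keys <- vapply(m@patterns, patternKey, character(1))
    patternCounts <- patternCounts + as.integer(truthKeys %in% keys)
    vars <- unique(unlist(m@patterns))
    variableCounts <- variableCounts + as.integer(truthVars %in% vars)
    falseTotal <- falseTotal + sum(!keys %in% truthKeys)
  }
  list(patternCounts = patternCounts, variableCounts = variableCounts,
       falseTotal = falseTotal, reps = reps)
}

#' Drop variables with extreme prevalence
#'
#' Keeps variables whose expression rate lies in `[low, high]`; variables
#' expressed in fewer than 10% or more than 90% of the samples are removed
#' under the defaults (boundaries inclusive).
#'
#' @param X 0/1 matrix or [BinaryDataset].
#' @param low,high prevalence bounds (defaults 0.10 and 0.90).
#' @return integer vector of kept column indices.
#' @export
prevalenceFilter <- function(X, low = 0.10, high = 0.90) {
  if (is(X, "BinaryDataset")) X <- X@X
  m <- colMeans(X)
  which(m >= low & m <= high)
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank statistic with midrank tie correction.
#'
#' @param scores numeric predictions, higher = more case-like.
#' @param labels 0/1 outcomes.
#' @return scalar in `[0, 1]`.
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold labels: within each class, shuffle and deal round-robin
.stratifiedFolds <- function(y, folds) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Model-complexity summary of one model
#'
#' `nGene` = unique variables, `nPara` = non-intercept coefficients, `q` =
#' highest pattern order present (0 for the intercept-only model), `total` =
#' their sum.
#'
#' @param model a [SelectedModel].
#' @return named numeric vector.
#' @export
modelComplexity <- function(model) {
  ords <- vapply(model@patterns, length, integer(1))
  c(nGene = length(unique(unlist(model@patterns))),
    nPara = length(model@patterns),
    q = if (length(ords)) max(ords) else 0L,
    total = length(unique(unlist(model@patterns))) + length(model@patterns) +
      (if (length(ords)) max(ords) else 0L))
}

#' Stratified k-fold cross-validation of the pipeline
#'
#' Response-stratified folds; per fold the two-stage search runs on the
#' training split and the held-out split is scored by AUC, with model
#' complexity (`nGene`, `nPara`, `q`, `total`) recorded. The summary is the
#' fold average of each measure.
#'
#' @param data a [BinaryDataset].
#' @param config a [plpsConfig()].
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list with `summary` (named fold-average vector incl. `auc`),
#'   `folds` (per-fold data.frame), `models` (per-fold [SelectedModel]s)
#'   and `seed`.
#' @export
crossValidate <- function(data, config = plpsConfig(), folds = 5, seed = 1) {
  y <- data@y
  n <- nSamples(data)
  stopifnot(n >= folds)
  set.seed(seed)
  fold <- .stratifiedFolds(y, folds)
  if (any(tabulate(fold, folds) == 0L) ||
      any(vapply(seq_len(folds), function(k) length(unique(y[fold != k])),
                 integer(1)) < 2L))
    stop("degenerate folds: a training split lost a response class")
  perFold <- vector("list", folds)
  models <- vector("list", folds)
  for (k in seq_len(folds)) {
    train <- BinaryDataset(data@X[fold != k, , drop = FALSE], y[fold != k])
    test <- fold == k
    model <- runPlps(train, config)
    models[[k]] <- model
    prob <- predictProb(model, data@X[test, , drop = FALSE])
    cmplx <- modelComplexity(model)
    auc <- if (length(unique(y[test])) == 2L) aucScore(prob, y[test])
           else NA_real_
    perFold[[k]] <- data.frame(fold = k, t(cmplx), auc = auc)
  }
  tab <- do.call(rbind, perFold)
  list(summary = colMeans(tab[, -1], na.rm = TRUE), folds = tab,
       models = models, seed = seed)
}
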