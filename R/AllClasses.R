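#' Binary predictor data with a dichotomous response
#'
#' Container for a subjects-by-variables 0/1 predictor matrix and a 0/1
#' response, the input of every pattern-search fit. Variable names are the
#' column names of `X`; unnamed matrices get labels `X1..Xp` matching the
#' conventional notation for dichotomized predictors.
#'
#' @slot X numeric matrix, entries 0/1, one row per subject.
#' @slot y integer vector of 0/1 responses, length `nrow(X)`.
#'
#' @examples
#' d <- BinaryDataset(matrix(rbinom(40, 1, 0.5), 10, 4), rbinom(10, 1, 0.5))
#' d
#' @aliases BinaryDataset-class
#' @export
setClass("BinaryDataset", slots = c(X = "matrix", y = "integer"))

setValidity("BinaryDataset", function(object) {
  X <- object@X; y <- object@y
  if (nrow(X) < 1L || ncol(X) < 1L) return("X must have >= 1 row and column")
  if (length(y) != nrow(X)) return("length(y) must equal nrow(X)")
  if (anyNA(X) || !all(X == 0 | X == 1)) return("X entries must be 0/1")
  if (anyNA(y) || !all(y %in% c(0L, 1L))) return("y entries must be 0/1")
  nm <- colnames(X)
  if (is.null(nm) || anyDuplicated(nm)) return("X needs unique column names")
  TRUE
})

#' @param X numeric/integer matrix with 0/1 entries.
#' @param y 0/1 response vector.
#' @rdname BinaryDataset-class
#' @export
BinaryDataset <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  new("BinaryDataset", X = X, y = as.integer(y))
}

#' Partition scheme over the predictor variables
#'
#' Contiguous blocks of `g` variables (the last possibly smaller) used to
#' define the screening-stage subproblems.
#'
#' @slot p integer, number of variables.
#' @slot g integer, nominal partition size.
#' @slot k integer, number of partitions, `ceiling(p / g)`.
#' @slot assign integer vector of length `p`, partition label of each variable.
#' @aliases PartitionScheme-class
#' @export
setClass("PartitionScheme",
         slots = c(p = "integer", g = "integer", k = "integer",
                   assign = "integer"))

setValidity("PartitionScheme", function(object) {
  if (length(object@assign) != object@p) return("assign must have length p")
  sz <- tabulate(object@assign, object@k)
  if (any(sz == 0L)) return("every partition must be non-empty")
  if (any(sz[-object@k] != object@g)) return("non-final partitions must have size g")
  if (sz[object@k] > object@g) return("final partition larger than g")
  TRUE
})

#' Pattern design matrix
#'
#' Sparse binary design whose columns are pattern basis functions: the
#' constant basis, main effects, and products of 2-3 predictors. Column
#' `l` at row `i` is the product of the pattern's variables for subject `i`.
#'
#' @slot patterns list of sorted integer vectors of variable indices
#'   (length 0 = constant basis).
#' @slot design `dgCMatrix` of 0/1 values, one column per pattern.
#' @slot order integer vector, number of variables in each pattern.
#' @slot p integer, number of variables in the originating dataset.
#' @aliases PatternDesign-class
#' @export
setClass("PatternDesign",
         slots = c(patterns = "list", design = "ANY", order = "integer",
                   p = "integer"))

setValidity("PatternDesign", function(object) {
  if (length(object@patterns) != ncol(object@design))
    return("one design column per pattern required")
  if (sum(object@order == 0L) != 1L)
    return("exactly one constant column required")
  TRUE
})

#' One penalized logistic fit
#'
#' Solution of the l1-penalized Bernoulli likelihood problem at a fixed
#' penalty, with coefficients aligned to the columns of a [PatternDesign].
#'
#' @slot coef numeric vector over all design columns (the constant column's
#'   coefficient is the intercept).
#' @slot lambda numeric, the penalty value(s) used (length 1, or 2 as
#'   `c(lambda1, lambda2)` in the two-penalty problem).
#' @slot penalty numeric vector of effective per-column penalties.
#' @slot f numeric vector of linear-predictor values at the solution.
#' @slot objective numeric, penalized objective at the solution.
#' @slot converged logical.
#' @aliases PenalizedFit-class
#' @export
setClass("PenalizedFit",
         slots = c(coef = "numeric", lambda = "numeric", penalty = "numeric",
                   f = "numeric", objective = "numeric", converged = "logical"))

#' Final selected pattern model
#'
#' Patterns surviving selection together with unpenalized maximum-likelihood
#' coefficients; the output of [runLps()], [runPlps()] and
#' [backwardEliminate()].
#'
#' @slot patterns list of integer vectors (no constant pattern; eliminated
#'   terms removed).
#' @slot intercept numeric.
#' @slot coefficients numeric, one per pattern.
#' @slot stats data.frame with per-term label, order, coefficient, standard
#'   error and z value.
#' @slot provenance character, e.g. a subproblem id or "aggregation".
#' @slot score numeric, tuning-criterion value of the model.
#' @slot quasiSeparated logical, `TRUE` when the refit hit the linear
#'   predictor cap (quasi-complete separation).
#' @aliases SelectedModel-class
#' @export
setClass("SelectedModel",
         slots = c(patterns = "list", intercept = "numeric",
                   coefficients = "numeric", stats = "data.frame",
                   provenance = "character", score = "numeric",
                   quasiSeparated = "logical"))

setValidity("SelectedModel", function(object) {
  if (length(object@patterns) != length(object@coefficients))
    return("one coefficient per pattern required")
  keys <- vapply(object@patterns, patternKey, character(1))
  if (anyDuplicated(keys)) return("duplicate patterns")
  if (any(object@coefficients == 0)) return("coefficients must be nonzero")
  TRUE
})

#' Tuning-criterion score
#'
#' GACV/BGACV-family score of one fit: the observed negative log-likelihood
#' plus an optimism (model-complexity) term, optionally multiplied by a
#' balance factor penalizing disparity between the counts of selected main
#' effects and interactions.
#'
#' @slot obs numeric, per-sample negative log-likelihood at the fit.
#' @slot optimism numeric, complexity term (already scaled by the stringency
#'   factor).
#' @slot stringency numeric, 1 for GACV, `log(n)/2` for BGACV.
#' @slot balance numeric, balance factor (1 for plain GACV/BGACV).
#' @slot score numeric, `(obs + optimism) * balance`.
#' @slot nb integer vector `c(nb1, nb2, nb3)`: counts of nonzero main-effect,
#'   size-2 and size-3 coefficients.
#' @slot s integer, active-set size including the intercept.
#' @aliases TuningScore-class
#' @export
setClass("TuningScore",
         slots = c(obs = "numeric", optimism = "numeric",
                   stringency = "numeric", balance = "numeric",
                   score = "numeric", nb = "integer", s = "integer"))

#' Screening-stage result
#'
#' @slot models list of per-subproblem [SelectedModel] objects.
#' @slot survivors list of unique patterns surviving any subproblem.
#' @slot pStar integer vector: the unique variables appearing in any
#'   surviving pattern.
#' @aliases ScreeningResult-class
#' @export
setClass("ScreeningResult",
         slots = c(models = "list", survivors = "list", pStar = "integer"))

#' Simulation scenario
#'
#' Covariate law (iid Bernoulli(0.5) blocks and/or banded-latent thresholded
#' Gaussian blocks) plus a sparse logit: an intercept and signed weights on a
#' list of patterns.
#'
#' @slot n,p integer sample size and variable count.
#' @slot blocks list of blocks, each `list(from, to, law, rho1, rho2)` with
#'   `law` one of `"iid"`, `"banded"`.
#' @slot intercept numeric.
#' @slot patterns list of integer vectors (the true patterns).
#' @slot weights numeric, one signed weight per pattern.
#' @slot name character label.
#' @aliases SimulationScenario-class
#' @export
setClass("SimulationScenario",
         slots = c(n = "integer", p = "integer", blocks = "list",
                   intercept = "numeric", patterns = "list",
                   weights = "numeric", name = "character"))

setValidity("SimulationScenario", function(object) {
  if (length(object@patterns) != length(object@weights))
    return("one weight per pattern required")
  if (!all(is.finite(object@weights))) return("weights must be finite")
  for (b in object@blocks)
    if (b$law == "banded" && abs(b$rho1) >= 1) return("|rho1| must be < 1")
  TRUE
})
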