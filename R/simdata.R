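# Synthetic-data generators: iid Bernoulli and banded-latent thresholded
# Gaussian covariate laws, sparse pattern logits, replicated runs.

#' Construct a simulation scenario
#'
#' @param n,p sample size and variable count.
#' @param blocks list of covariate blocks, each `list(from, to, law, rho1,
#'   rho2)`; `law = "iid"` draws Bernoulli(0.5), `law = "banded"` thresholds
#'   latent Gaussians with lag-1/lag-2 correlations `rho1`/`rho2` at zero.
#' @param intercept logit intercept.
#' @param patterns list of true patterns (integer variable index vectors).
#' @param weights signed logit weights, one per pattern.
#' @param name label.
#' @return a [SimulationScenario].
#' @export
simulationScenario <- function(n, p, blocks, intercept, patterns, weights,
                               name = "custom") {
  new("SimulationScenario", n = as.integer(n), p = as.integer(p),
      blocks = blocks, intercept = intercept, patterns = patterns,
      weights = weights, name = name)
}

#' The four standard simulation designs
#'
#' Exact sample sizes, covariate laws and logits of the four benchmark
#' scenarios:
#' 1. n = 700, p = 400 iid Bernoulli(0.5);
#'    `f = -2 + 1.5 X50 + 1.5 X150 X250 + 1.5 X251 X252`.
#' 2. n = 1000, p = 8000, latent lag correlations (2/3, 1/3);
#'    `f = -4 + 2 X500 + 3 X5000 + 2 X1000 X3000 + 3 X7000 X7002`.
#' 3. n = 1000, p = 500, same law as 2;
#'    `f = -4 + 2 X100 + 3 X200 + 2 X300 X400 + 3 X150 X450 X451`
#'    (order-3 design).
#' 4. n = 700, p = 400; variables 1-200 with lag correlations (2/3, 1/3),
#'    201-400 with (-1/3, -1/6);
#'    `f = -1 + 2.5 (X1 - X3 + X10 - X201 + X220 - X230)
#'         + 3 (X100 X102 - X300 X302 + X50 X250)`.
#'
#' @param example scenario id, 1-4.
#' @return a [SimulationScenario].
#' @examples
#' makeScenario(1)
#' @export
makeScenario <- function(example) {
  stopifnot(length(example) == 1L, example %in% 1:4)
  bandPos <- function(from, to) list(from = from, to = to, law = "banded",
                                     rho1 = 2 / 3, rho2 = 1 / 3)
  switch(as.character(example),
    "1" = simulationScenario(
      700, 400,
      list(list(from = 1, to = 400, law = "iid", rho1 = 0, rho2 = 0)),
      intercept = -2,
      patterns = list(50L, c(150L, 250L), c(251L, 252L)),
      weights = c(1.5, 1.5, 1.5), name = "example1"),
    "2" = simulationScenario(
      1000, 8000, list(bandPos(1, 8000)),
      intercept = -4,
      patterns = list(500L, 5000L, c(1000L, 3000L), c(7000L, 7002L)),
      weights = c(2, 3, 2, 3), name = "example2"),
    "3" = simulationScenario(
      1000, 500, list(bandPos(1, 500)),
      intercept = -4,
      patterns = list(100L, 200L, c(300L, 400L), c(150L, 450L, 451L)),
      weights = c(2, 3, 2, 3), name = "example3"),
    "4" = simulationScenario(
      700, 400,
      list(bandPos(1, 200),
           list(from = 201, to = 400, law = "banded",
                rho1 = -1 / 3, rho2 = -1 / 6)),
      intercept = -1,
      patterns = list(1L, 3L, 10L, 201L, 220L, 230L,
                      c(100L, 102L), c(300L, 302L), c(50L, 250L)),
      weights = c(2.5, -2.5, 2.5, -2.5, 2.5, -2.5, 3, -3, 3),
      name = "example4"))
}

# upper-triangular factor of the banded latent correlation matrix; a 1e-8
# ridge keeps the boundary-singular negative band factorizable
.bandFactor <- function(m, rho1, rho2, ridge = 1e-8) {
  diags <- list(rep(1 + ridge, m))
  ks <- 0L
  if (m >= 2) { diags <- c(diags, list(rep(rho1, m - 1))); ks <- c(ks, 1L) }
  if (m >= 3) { diags <- c(diags, list(rep(rho2, m - 2))); ks <- c(ks, 2L) }
  sigma <- Matrix::bandSparse(m, k = ks, diagonals = diags, symmetric = TRUE)
  tryCatch(Matrix::chol(sigma),
           error = function(e)
             stop(sprintf("banded block (rho1=%.3f, rho2=%.3f) is not positive semidefinite: %s",
                          rho1, rho2, conditionMessage(e))))
}

#' Generate the binary covariate matrix of a scenario
#'
#' iid blocks are Bernoulli(0.5) draws; banded blocks draw latent Gaussians
#' with the block's lag-1/lag-2 correlation profile (zero beyond lag 2) and
#' threshold them at zero, giving marginal Bernoulli(0.5) columns with
#' binary correlation `(2/pi) * asin(rho)` at each lag.
#'
#' @param scenario a [SimulationScenario].
#' @param seed optional integer seed.
#' @param n optional override of the scenario sample size.
#' @return n x p matrix of 0/1 values with columns `X1..Xp`.
#' @export
genCovariates <- function(scenario, seed = NULL, n = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- scenario@n
  X <- matrix(0, n, scenario@p)
  for (b in scenario@blocks) {
    cols <- b$from:b$to
    m <- length(cols)
    if (b$law == "iid") {
      X[, cols] <- matrix(rbinom(n * m, 1, 0.5), n, m)
    } else {
      R <- .bandFactor(m, b$rho1, b$rho2)
      Z <- matrix(rnorm(n * m), n, m)
      X[, cols] <- (as.matrix(Z %*% R) > 0) + 0
    }
  }
  colnames(X) <- paste0("X", seq_len(scenario@p))
  X
}

#' Generate Bernoulli responses from a sparse pattern logit
#'
#' `y_i ~ Bernoulli(plogis(f(x_i)))` with
#' `f(x) = intercept + sum_h weights[h] * prod(X[, patterns[[h]]])`.
#'
#' @param X 0/1 covariate matrix.
#' @param intercept logit intercept.
#' @param patterns list of integer variable index vectors.
#' @param weights signed weights, one per pattern.
#' @param seed optional integer seed.
#' @return integer 0/1 vector of length `nrow(X)`.
#' @export
genResponse <- function(X, intercept, patterns, weights, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- rep(intercept, nrow(X))
  for (h in seq_along(patterns)) {
    v <- patterns[[h]]
    b <- if (length(v) == 1L) X[, v] else apply(X[, v, drop = FALSE], 1, prod)
    f <- f + weights[h] * b
  }
  as.integer(rbinom(nrow(X), 1, plogis(f)))
}

#' One simulated dataset of a scenario
#'
#' Covariates use `seed`, responses `seed + 1e6` (the replicate seed
#' protocol of [runReplicates()]).
#'
#' @param scenario a [SimulationScenario].
#' @param seed integer seed.
#' @param n optional sample-size override.
#' @return a [BinaryDataset].
#' @export
genDataset <- function(scenario, seed, n = NULL) {
  X <- genCovariates(scenario, seed = seed, n = n)
  y <- genResponse(X, scenario@intercept, scenario@patterns,
                   scenario@weights, seed = seed + 1000000L)
  BinaryDataset(X, y)
}

#' Replicated simulation runs of the two-stage pipeline
#'
#' Replicate `r` draws covariates with seed `baseSeed + r` and responses
#' with seed `baseSeed + 1e6 + r`, then runs [runPlps()]. Per-replicate
#' failures are recorded, not fatal.
#'
#' @param scenario a [SimulationScenario].
#' @param config a [plpsConfig()].
#' @param reps number of replicates (>= 1).
#' @param baseSeed integer base seed.
#' @param n optional sample-size override.
#' @return list with `models` (list of [SelectedModel] or `NULL`), `errors`
#'   (character, `NA` on success) and `seeds` (data.frame of the seeds
#'   used).
#' @export
runReplicates <- function(scenario, config = plpsConfig(), reps, baseSeed = 1,
                          n = NULL) {
  stopifnot(reps >= 1)
  models <- vector("list", reps)
  errors <- rep(NA_character_, reps)
  seeds <- data.frame(replicate = seq_len(reps),
                      covariateSeed = baseSeed + seq_len(reps),
                      responseSeed = baseSeed + 1000000L + seq_len(reps))
  for (r in seq_len(reps)) {
    data <- genDataset(scenario, seed = baseSeed + r, n = n)
    models[[r]] <- tryCatch(runPlps(data, config), error = function(e) {
      errors[r] <<- conditionMessage(e)
      NULL
    })
  }
  list(models = models, errors = errors, seeds = seeds)
}
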