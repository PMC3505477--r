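# Shared fixtures: small binary datasets and random solver instances,
# always built in code under explicit seeds.

toyDataset <- function(n = 60, p = 6, seed = 1, intercept = -0.5,
                       patterns = list(), weights = numeric(0)) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.5), n, p)
  colnames(X) <- paste0("X", seq_len(p))
  f <- rep(intercept, n)
  for (h in seq_along(patterns)) {
    v <- patterns[[h]]
    b <- if (length(v) == 1) X[, v] else apply(X[, v, drop = FALSE], 1, prod)
    f <- f + weights[h] * b
  }
  y <- rbinom(n, 1, plogis(f))
  # keep both classes represented in tiny draws
  while (sum(y) < 3) y[sample(which(y == 0), 1)] <- 1L
  while (sum(1 - y) < 3) y[sample(which(y == 1), 1)] <- 0L
  BinaryDataset(X, y)
}

# random penalized instance within the oracle-checkable regime
randomInstance <- function(seed) {
  set.seed(seed)
  n <- sample(20:60, 1)
  p <- sample(2:5, 1)
  d <- toyDataset(n, p, seed = seed + 1000,
                  intercept = runif(1, -1, 0.5),
                  patterns = list(1L), weights = runif(1, -1.5, 1.5))
  des <- buildDesign(d, enumerateAllPatterns(p, 2))  # N_B <= 16
  lmax <- as.numeric(lambdaMax(des, response(d)))
  list(data = d, design = des, lambda = runif(1, 0.05, 0.9) * max(lmax, 0.05))
}

# penalized objective of arbitrary coefficients, independent scalar route
objectiveByHand <- function(coefs, designMat, y, pen) {
  f <- as.numeric(designMat %*% coefs)
  mean(-y * f + log1p(exp(f))) + sum(pen * abs(coefs))
}
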