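test_that("negative log-likelihood matches closed forms and scalar summation", {
  expect_equal(negLogLik(c(1, 0, 1), rep(0, 3)), log(2))
  expect_lt(negLogLik(c(1, 0), c(50, -50)), 1e-20)
  y <- c(1, 1, 0); f <- c(1, -1, 0.5)
  byhand <- sum(-y * f + log(1 + exp(f))) / 3
  expect_equal(negLogLik(y, f), byhand)
  # stable at extreme linear predictors
  expect_true(is.finite(negLogLik(c(1, 0), c(1000, -1000))))
})

test_that("objective adds the weighted l1 term and collapses penalties", {
  d <- toyDataset(40, 4, seed = 3)
  des <- buildDesign(d, enumerateAllPatterns(4, 2))
  y <- response(d)
  cf <- numeric(length(des@patterns))
  expect_equal(objectiveValue(cf, des, y, penaltyWeights(des, lambda = 0.3)),
               negLogLik(y, rep(0, 40)))
  cf[1] <- 0.4; cf[2] <- 0.5; cf[3] <- -0.2
  pen1 <- penaltyWeights(des, lambda = 0.1)
  pen2 <- penaltyWeights(des, lambda1 = 0.1, lambda2 = 0.1)
  expect_equal(pen1, pen2)
  expect_equal(objectiveValue(cf, des, y, pen1),
               objectiveByHand(cf, des@design, y, pen1))
  expect_equal(objectiveValue(cf, des, y, pen1) -
                 objectiveValue(cf, des, y, penaltyWeights(des, lambda = 0)),
               0.1 * 0.7)
})

test_that("lambda_max is the zero-solution stationarity threshold", {
  d <- toyDataset(80, 5, seed = 7)
  y <- response(d)
  # plant a column identical to y: it attains the max score
  X <- predictors(d); X[, 3] <- y
  d2 <- BinaryDataset(X, y)
  des <- buildDesign(d2, enumerateAllPatterns(5, 1))
  lmax <- as.numeric(lambdaMax(des, y))
  sc <- abs(plps:::plps_col_inner(des@design@p, des@design@i, 80, y - mean(y)))
  expect_equal(lmax, sc[1 + 3])  # column of pattern X3 (constant first)
  # solving just above lambda_max returns the empty active set
  fit <- solveL1Logistic(des, y, penaltyWeights(des, lambda = 1.01 * lmax))
  expect_length(activeSet(fit), 0L)
  expect_equal(plogis(fit@coef[des@order == 0L]), mean(y), tolerance = 1e-6)
  # orthogonal noise columns, large n: threshold near 0
  set.seed(42)
  Xn <- matrix(rbinom(5000 * 4, 1, 0.5), 5000, 4)
  colnames(Xn) <- paste0("X", 1:4)
  yn <- rbinom(5000, 1, 0.5)
  dn <- BinaryDataset(Xn, yn)
  desn <- buildDesign(dn, enumerateAllPatterns(4, 1))
  expect_lt(as.numeric(lambdaMax(desn, yn)), 0.02)
  # degenerate response flagged
  expect_true(isTRUE(attr(lambdaMax(des, rep(1L, 80)), "degenerate")))
})

test_that("solver reaches the global optimum of small convex instances", {
  skip_if_not_installed("glmnet")
  for (seed in 1:12) {
    inst <- randomInstance(seed)
    des <- inst$design; y <- response(inst$data)
    pen <- penaltyWeights(des, lambda = inst$lambda)
    fit <- solveL1Logistic(des, y, pen)
    expect_true(fit@converged)
    Xg <- as.matrix(des@design[, -1, drop = FALSE])
    g <- suppressWarnings(
      glmnet::glmnet(Xg, y, family = "binomial", lambda = inst$lambda,
                     standardize = FALSE, thresh = 1e-14, maxit = 1e7))
    cg <- c(as.numeric(g$a0), as.numeric(g$beta))
    oracleObj <- negLogLik(y, cbind(1, Xg) %*% cg) +
      inst$lambda * sum(abs(cg[-1]))
    expect_lt(fit@objective, oracleObj + 1e-6)
  }
})

test_that("unpenalized solve matches the generic MLE", {
  d <- toyDataset(50, 3, seed = 5, intercept = -0.3,
                  patterns = list(1L), weights = 1)
  des <- buildDesign(d, enumerateAllPatterns(3, 1))
  y <- response(d)
  fit <- solveL1Logistic(des, y, penaltyWeights(des, lambda = 0), tol = 1e-8)
  ml <- suppressWarnings(glm.fit(as.matrix(des@design), y,
                                 family = binomial()))
  expect_equal(fit@coef, unname(ml$coefficients), tolerance = 1e-4)
})

test_that("two-penalty solution with equal penalties matches single penalty", {
  d <- toyDataset(60, 5, seed = 9, patterns = list(2L, c(3L, 4L)),
                  weights = c(1, 1.2))
  des <- buildDesign(d, enumerateAllPatterns(5, 2))
  y <- response(d)
  lam <- 0.05
  f1 <- solveL1Logistic(des, y, penaltyWeights(des, lambda = lam), tol = 1e-10)
  f2 <- solveL1Logistic(des, y,
                        penaltyWeights(des, lambda1 = lam, lambda2 = lam),
                        tol = 1e-10)
  expect_equal(f1@coef, f2@coef, tolerance = 1e-6)
})

test_that("objective is convex along random segments", {
  d <- toyDataset(40, 4, seed = 13)
  des <- buildDesign(d, enumerateAllPatterns(4, 2))
  y <- response(d)
  pen <- penaltyWeights(des, lambda = 0.08)
  set.seed(99)
  for (r in 1:20) {
    a <- rnorm(length(des@patterns), sd = 0.5)
    b <- rnorm(length(des@patterns), sd = 0.5)
    mid <- objectiveValue((a + b) / 2, des, y, pen)
    expect_lte(mid, (objectiveValue(a, des, y, pen) +
                       objectiveValue(b, des, y, pen)) / 2 + 1e-12)
  }
})

test_that("path fits warm-start consistently and coefficients vanish at lambda_max", {
  d <- toyDataset(70, 5, seed = 21, patterns = list(1L), weights = 1.3)
  des <- buildDesign(d, enumerateAllPatterns(5, 2))
  y <- response(d)
  lmax <- as.numeric(lambdaMax(des, y))
  # grid above lambda_max: all intercept-only
  above <- solvePath(des, y, c(2 * lmax, lmax * 1.0000001))
  expect_true(all(vapply(above, function(f) length(activeSet(f)) == 0L, NA)))
  # path fit equals cold-start fit at every grid point
  grid <- lambdaGrid(lmax, 8, 0.05)
  path <- solvePath(des, y, grid, tol = 1e-8)
  for (h in seq_along(path)) {
    cold <- solveL1Logistic(des, y, penaltyWeights(des, lambda = grid[h]),
                            tol = 1e-8)
    expect_equal(path[[h]]@coef, cold@coef, tolerance = 1e-5)
  }
  # singleton grid behaves as a single solve
  single <- solvePath(des, y, grid[3], tol = 1e-8)
  expect_equal(single[[1]]@coef, path[[3]]@coef, tolerance = 1e-6)
})

test_that("fitted probabilities follow the logistic link and monotonicity", {
  m <- new("SelectedModel", patterns = list(2L), intercept = 0,
           coefficients = 1.5, stats = data.frame(), provenance = "test",
           score = 0, quasiSeparated = FALSE)
  X0 <- matrix(0, 1, 3); X1 <- X0; X1[1, 2] <- 1
  expect_equal(predictProb(m, X0), 0.5)
  expect_equal(predictProb(m, X1), plogis(1.5))
  expect_gt(predictProb(m, X1), predictProb(m, X0))
  # intercept-only model with a strongly negative logit
  m0 <- new("SelectedModel", patterns = list(), intercept = -8.15,
            coefficients = numeric(0), stats = data.frame(),
            provenance = "test", score = 0, quasiSeparated = FALSE)
  expect_equal(predictProb(m0, X0), 1 / (1 + exp(8.15)))
})
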