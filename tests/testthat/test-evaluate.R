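mkModel <- function(patterns, coefs = rep(1, length(patterns)),
                    intercept = -1) {
  new("SelectedModel", patterns = patterns, intercept = intercept,
      coefficients = coefs, stats = data.frame(), provenance = "test",
      score = 0, quasiSeparated = FALSE)
}

test_that("pattern and variable counts follow the table conventions", {
  truth <- list(50L, c(150L, 250L), c(251L, 252L))
  perfect <- replicate(4, mkModel(truth), simplify = FALSE)
  rep1 <- countPatterns(perfect, truth)
  expect_true(all(rep1$patternCounts == 4L))
  expect_true(all(rep1$variableCounts == 4L))
  expect_equal(rep1$falseTotal, 0L)

  # X50*X99 counts the variable X50 but not the pattern X50, and is false
  models <- list(mkModel(list(c(50L, 99L))))
  rep2 <- countPatterns(models, truth)
  expect_equal(unname(rep2$patternCounts["X50"]), 0L)
  expect_equal(unname(rep2$variableCounts["X50"]), 1L)
  expect_equal(rep2$falseTotal, 1L)

  # brute-force recount over an arbitrary toy batch
  batch <- list(
    mkModel(list(50L, c(150L, 250L))),
    mkModel(list(c(251L, 252L), 7L, c(1L, 2L))),
    NULL,
    mkModel(list(50L, 50L * 2L)),
    mkModel(list())
  )
  got <- countPatterns(batch, truth)
  live <- batch[!vapply(batch, is.null, NA)]
  for (tk in names(got$patternCounts)) {
    brute <- sum(vapply(live, function(m)
      tk %in% vapply(m@patterns, patternKey, ""), NA))
    expect_equal(unname(got$patternCounts[tk]), brute)
  }
  bruteFalse <- sum(vapply(live, function(m) {
    keys <- vapply(m@patterns, patternKey, "")
    sum(!keys %in% vapply(truth, patternKey, ""))
  }, 0L))
  expect_equal(got$falseTotal, bruteFalse)
  expect_equal(got$reps, 4L)
})

test_that("prevalence filter keeps the inclusive 10-90% band", {
  X <- cbind(a = rep(c(1, rep(0, 19)), 5),   # mean 0.05 -> removed
             b = rep(c(1, rep(0, 9)), 10),   # mean 0.10 -> kept
             c = rep(c(1, 0), 50),           # mean 0.50 -> kept
             d = rep(1, 100),                # all ones  -> removed
             e = rep(c(rep(1, 9), 0), 10))   # mean 0.90 -> kept
  expect_equal(prevalenceFilter(X), c(b = 2L, c = 3L, e = 5L))
})

test_that("AUC matches hand enumeration, oracle and invariances", {
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(10)
  big <- aucScore(runif(4000), rbinom(4000, 1, 0.5))
  expect_equal(big, 0.5, tolerance = 0.05)
  # 6-point toy with one tie, Mann-Whitney by hand:
  # scores (case): 0.7, 0.5, 0.3 ; (control): 0.5, 0.2, 0.1
  # pairs: 0.7 beats 3; 0.5 beats 2 ties 1 (0.5); 0.3 beats 2 -> (3+2.5+2)/9
  sc <- c(0.7, 0.5, 0.3, 0.5, 0.2, 0.1)
  lb <- c(1, 1, 1, 0, 0, 0)
  expect_equal(aucScore(sc, lb), 7.5 / 9)
  skip_if_not_installed("pROC")
  oracle <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                           direction = "<")))
  expect_equal(aucScore(sc, lb), oracle)
  # invariant under strictly monotone transforms
  expect_equal(aucScore(exp(3 * sc), lb), aucScore(sc, lb))
  expect_error(aucScore(sc, rep(1, 6)), "both classes")
})

test_that("model complexity summary follows the counting convention", {
  m <- mkModel(list(1L, c(2L, 3L)))
  cx <- modelComplexity(m)
  expect_equal(unname(cx["nGene"]), 3)
  expect_equal(unname(cx["nPara"]), 2)
  expect_equal(unname(cx["q"]), 2)
  expect_equal(unname(cx["total"]), 7)
  expect_equal(unname(modelComplexity(mkModel(list()))["total"]), 0)
})

test_that("cross-validation is stratified, seeded and sane on both laws", {
  sc <- simulationScenario(300, 12,
    list(list(from = 1, to = 12, law = "iid", rho1 = 0, rho2 = 0)),
    intercept = -0.5, patterns = list(), weights = numeric(0), name = "null")
  d <- genDataset(sc, seed = 3)
  cfg <- plpsConfig(order = 2, g = 12, nlambda = 25)
  cvNull <- crossValidate(d, cfg, folds = 5, seed = 11)
  # fold assignment partitions the samples with near-balanced case rates
  expect_equal(sum(cvNull$folds$fold %in% 1:5), 5L)
  expect_gte(cvNull$summary["auc"], 0.3)
  expect_lte(cvNull$summary["auc"], 0.7)
  # deterministic given the seed
  cvNull2 <- crossValidate(d, cfg, folds = 5, seed = 11)
  expect_equal(cvNull$summary, cvNull2$summary)

  scSig <- simulationScenario(400, 12,
    list(list(from = 1, to = 12, law = "iid", rho1 = 0, rho2 = 0)),
    intercept = -1, patterns = list(3L, c(5L, 7L)), weights = c(2, 2.5),
    name = "signal")
  dS <- genDataset(scSig, seed = 5)
  cvS <- crossValidate(dS, cfg, folds = 5, seed = 11)
  expect_gt(cvS$summary["auc"], 0.7)
})

test_that("fold labels partition and stratify the response", {
  set.seed(2)
  y <- rbinom(200, 1, 0.3)
  f <- plps:::.stratifiedFolds(y, 5)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 200L)
  perFold <- vapply(1:5, function(k) sum(y[f == k]), 0L)
  expect_lte(max(perFold) - min(perFold), 1L)
})

test_that("dataset files round-trip and non-binary entries are located", {
  d <- toyDataset(30, 4, seed = 17)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDataset(d, path)
  d2 <- readDataset(path, "y")
  expect_equal(predictors(d2), predictors(d))
  expect_equal(response(d2), response(d))
  # corrupt one entry
  lines <- readLines(path)
  lines[3] <- sub("^(\\S*\t\\S*\t)\\S*", "\\12", lines[3])
  writeLines(lines, path)
  expect_error(readDataset(path, "y"), "row 2")
  expect_error(readDataset("nope.tsv", "y"), "no such file")
})

test_that("model JSON serialization is faithful for an interaction-rich model", {
  # structure mirroring a five-pair classifier with repeated genes
  m <- mkModel(list(c(3L, 9L), c(12L, 40L), c(17L, 21L), c(5L, 33L),
                    c(40L, 44L)),
               coefs = c(3.58, 1.93, 3.29, 3.75, 2.34), intercept = -8.15)
  path <- withr::local_tempfile(fileext = ".json")
  writeModel(m, path, tuning = list(criterion = "bgacv2",
                                    lambdas = c(0.02, 0.005)))
  m2 <- readModel(path)
  expect_equal(patternList(m2), patternList(m))
  expect_identical(m2@coefficients, m@coefficients)
  expect_identical(m2@intercept, m@intercept)
  # truth files round-trip a scenario's logit
  scn <- makeScenario(4)
  tpath <- withr::local_tempfile(fileext = ".json")
  writeTruth(scn, tpath)
  tr <- readTruth(tpath)
  expect_equal(tr$intercept, -1)
  expect_equal(tr$patterns, scn@patterns)
  expect_equal(tr$weights, scn@weights)
})
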