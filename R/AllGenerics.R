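#' @name accessors
#' @title Accessors for plps classes
#' @description Small accessor generics: sample/variable counts, variable
#'   names, response vector, pattern lists and active sets.
#' @param object a plps object.
#' @param ... unused.
NULL

#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nVariables", function(object) standardGeneric("nVariables"))
#' @rdname accessors
#' @export
setGeneric("variableNames", function(object) standardGeneric("variableNames"))
#' @rdname accessors
#' @export
setGeneric("response", function(object) standardGeneric("response"))
#' @rdname accessors
#' @export
setGeneric("predictors", function(object) standardGeneric("predictors"))
#' @rdname accessors
#' @export
setGeneric("patternList", function(object) standardGeneric("patternList"))
#' @rdname accessors
#' @export
setGeneric("activeSet", function(object, ...) standardGeneric("activeSet"))
#' @rdname accessors
#' @export
setGeneric("survivors", function(object) standardGeneric("survivors"))
#' @rdname accessors
#' @export
setGeneric("pStar", function(object) standardGeneric("pStar"))

setMethod("nSamples", "BinaryDataset", function(object) nrow(object@X))
setMethod("nVariables", "BinaryDataset", function(object) ncol(object@X))
setMethod("variableNames", "BinaryDataset", function(object) colnames(object@X))
setMethod("response", "BinaryDataset", function(object) object@y)
setMethod("predictors", "BinaryDataset", function(object) object@X)

setMethod("nVariables", "PartitionScheme", function(object) object@p)
setMethod("patternList", "PatternDesign", function(object) object@patterns)
setMethod("nSamples", "PatternDesign", function(object) nrow(object@design))
setMethod("patternList", "SelectedModel", function(object) object@patterns)
setMethod("patternList", "ScreeningResult", function(object) object@survivors)
setMethod("survivors", "ScreeningResult", function(object) object@survivors)
setMethod("pStar", "ScreeningResult", function(object) object@pStar)

#' @rdname accessors
#' @export
setMethod("activeSet", "PenalizedFit", function(object, ...) {
  which(object@coef != 0 & object@penalty > 0)
})

#' @describeIn SelectedModel-class model coefficients, intercept first.
#' @param object a `SelectedModel`.
#' @export
setMethod("coef", "SelectedModel", function(object) {
  cf <- c(object@intercept, object@coefficients)
  names(cf) <- c("(Intercept)",
                 vapply(object@patterns, patternKey, character(1)))
  cf
})

setMethod("show", "BinaryDataset", function(object) {
  cat(sprintf("BinaryDataset: %d subjects x %d binary variables, case rate %.3f\n",
              nSamples(object), nVariables(object), mean(object@y)))
})

setMethod("show", "PartitionScheme", function(object) {
  cat(sprintf("PartitionScheme: p = %d variables in k = %d partitions of size g = %d%s\n",
              object@p, object@k, object@g,
              if (object@p %% object@g) sprintf(" (last: %d)", object@p - (object@k - 1L) * object@g) else ""))
})

setMethod("show", "PatternDesign", function(object) {
  tab <- table(factor(object@order, levels = 0:3))
  cat(sprintf("PatternDesign: %d x %d (constant %d, mains %d, pairs %d, triples %d)\n",
              nrow(object@design), length(object@patterns),
              tab[1], tab[2], tab[3], tab[4]))
})

setMethod("show", "PenalizedFit", function(object) {
  cat(sprintf("PenalizedFit: lambda = %s, %d active terms, objective %.6f%s\n",
              paste(signif(object@lambda, 4), collapse = "/"),
              length(activeSet(object)), object@objective,
              if (object@converged) "" else " (NOT converged)"))
})

setMethod("show", "SelectedModel", function(object) {
  cat(sprintf("SelectedModel (%s): %d pattern(s)\n", object@provenance,
              length(object@patterns)))
  terms <- sprintf("%+.3f*%s", object@coefficients,
                   vapply(object@patterns, patternKey, character(1)))
  cat("  f =", sprintf("%.3f", object@intercept),
      if (length(terms)) paste(terms, collapse = " "), "\n")
  if (object@quasiSeparated) cat("  note: quasi-separation flagged in refit\n")
})

setMethod("show", "TuningScore", function(object) {
  cat(sprintf("TuningScore: %.5f = (obs %.5f + optimism %.5f) x balance %.4f; nb = (%s), s = %d\n",
              object@score, object@obs, object@optimism, object@balance,
              paste(object@nb, collapse = ","), object@s))
})

setMethod("show", "ScreeningResult", function(object) {
  cat(sprintf("ScreeningResult: %d subproblems, %d surviving patterns, |p*| = %d\n",
              length(object@models), length(object@survivors),
              length(object@pStar)))
})

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf("SimulationScenario '%s': n = %d, p = %d, %d true pattern(s)\n",
              object@name, object@n, object@p, length(object@patterns)))
})
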