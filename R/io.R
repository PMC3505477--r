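# Dataset / model / truth file I/O.

#' Read a binary dataset from TSV or CSV
#'
#' Expects a header row of variable names and one row per subject; the
#' response is either a named column of the file or a separate
#' single-column file. Any non-0/1 entry is rejected with its coordinates.
#'
#' @param path dataset file; comma-separated when the extension is `.csv`,
#'   tab-separated otherwise.
#' @param response name of the response column, or the path of a
#'   single-column response file.
#' @return a [BinaryDataset].
#' @export
readDataset <- function(path, response) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, check.names = FALSE)
  if (response %in% colnames(tab)) {
    y <- tab[[response]]
    tab <- tab[setdiff(colnames(tab), response)]
  } else if (file.exists(response)) {
    y <- scan(response, quiet = TRUE)
  } else {
    stop("response column/file not found: ", response)
  }
  X <- as.matrix(tab)
  bad <- which(!(X == 0 | X == 1) | is.na(X), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-binary entry '%s' at row %d, column '%s'",
                 X[bad[1, 1], bad[1, 2]], bad[1, 1],
                 colnames(X)[bad[1, 2]]))
  }
  if (any(!(y == 0 | y == 1) | is.na(y)))
    stop("non-binary response value at row ",
         which(!(y == 0 | y == 1) | is.na(y))[1])
  BinaryDataset(X, y)
}

#' Write a dataset as TSV
#'
#' @param data a [BinaryDataset].
#' @param path output path; the response is written as column `y`.
#' @export
writeDataset <- function(data, path) {
  tab <- cbind(data.frame(y = data@y), as.data.frame(data@X))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize a selected model as JSON
#'
#' Terms are stored as variable label lists with coefficients at 17
#' significant digits, so a write/read round trip reproduces the model
#' exactly.
#'
#' @param model a [SelectedModel].
#' @param path JSON file path.
#' @param tuning optional list recorded under `tuning` (criterion, lambdas).
#' @return `readModel` returns a [SelectedModel].
#' @export
writeModel <- function(model, path, tuning = NULL) {
  obj <- list(
    order = if (length(model@patterns))
      max(vapply(model@patterns, length, integer(1))) else 0L,
    intercept = model@intercept,
    terms = lapply(seq_along(model@patterns), function(h) {
      list(variables = paste0("X", model@patterns[[h]]),
           coefficient = model@coefficients[h])
    }),
    tuning = if (is.null(tuning)) list(criterion = "bgacv", score = model@score)
             else tuning,
    provenance = model@provenance,
    quasiSeparated = model@quasiSeparated)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 17,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  patterns <- lapply(obj$terms, function(t)
    sort(as.integer(sub("^X", "", unlist(t$variables)))))
  cf <- vapply(obj$terms, function(t) as.numeric(t$coefficient), numeric(1))
  keys <- vapply(patterns, patternKey, character(1))
  ords <- vapply(patterns, length, integer(1))
  stats <- data.frame(term = c("(Intercept)", keys),
                      order = c(0L, ords),
                      estimate = c(obj$intercept, cf),
                      se = NA_real_, z = NA_real_, row.names = NULL)
  new("SelectedModel", patterns = patterns,
      intercept = as.numeric(obj$intercept), coefficients = cf,
      stats = stats,
      provenance = as.character(obj$provenance %||% "file"),
      score = as.numeric(obj$tuning$score %||% NA_real_),
      quasiSeparated = isTRUE(obj$quasiSeparated))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a simulation truth file
#'
#' JSON description of a scenario's logit: intercept plus signed weights on
#' variable-label patterns.
#'
#' @param scenario a [SimulationScenario].
#' @param path JSON file path.
#' @return `readTruth` returns `list(intercept, patterns, weights)`.
#' @export
writeTruth <- function(scenario, path) {
  obj <- list(intercept = scenario@intercept,
              terms = lapply(seq_along(scenario@patterns), function(h)
                list(variables = paste0("X", scenario@patterns[[h]]),
                     weight = scenario@weights[h])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 17,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  list(intercept = as.numeric(obj$intercept),
       patterns = lapply(obj$terms, function(t)
         sort(as.integer(sub("^X", "", unlist(t$variables))))),
       weights = vapply(obj$terms, function(t) as.numeric(t$weight),
                        numeric(1)))
}
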