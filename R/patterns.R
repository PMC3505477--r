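# Partition scheme, screening subproblems, pattern enumeration and
# design-matrix assembly.

#' Canonical label of a pattern
#'
#' Patterns are sorted integer vectors of 1-based variable indices; the
#' constant basis is the empty vector. Labels follow the usual notation:
#' `"X50"`, `"X150*X250"`, `"1"` for the constant.
#'
#' @param pattern sorted integer vector of variable indices (possibly empty).
#' @return character label.
#' @export
patternKey <- function(pattern) {
  if (length(pattern) == 0L) return("1")
  paste0("X", pattern, collapse = "*")
}

#' Parse a pattern label back into variable indices
#'
#' @param key label such as `"X150*X250"`; `"1"` gives the constant pattern.
#' @return sorted integer vector.
#' @export
parsePatternKey <- function(key) {
  if (identical(key, "1")) return(integer(0))
  sort(as.integer(sub("^X", "", strsplit(key, "*", fixed = TRUE)[[1]])))
}

#' Divide p variables into contiguous partitions of size g
#'
#' @param p number of variables.
#' @param g partition size; the last partition may be smaller when `g` does
#'   not divide `p`.
#' @return a [PartitionScheme].
#' @examples
#' makePartition(400, 200)
#' @export
makePartition <- function(p, g) {
  p <- as.integer(p); g <- as.integer(g)
  if (length(p) != 1L || length(g) != 1L || is.na(p) || is.na(g) ||
      p <= 0L || g <= 0L)
    stop("p and g must be positive integers")
  g <- min(g, p)
  k <- as.integer(ceiling(p / g))
  new("PartitionScheme", p = p, g = g, k = k,
      assign = as.integer((seq_len(p) - 1L) %/% g + 1L))
}

partitionMembers <- function(scheme, s) which(scheme@assign == s)

#' Enumerate the screening-stage subproblems of a partition scheme
#'
#' For order 2 there are `choose(k, 2)` cross-pair subproblems (all
#' interactions between two partitions plus both partitions' main effects)
#' and `k` within subproblems (mains plus within-partition pairs). For order
#' 3 there is one subproblem per size-3 multiset of partition labels, tagged
#' by its label-equality type.
#'
#' @param scheme a [PartitionScheme].
#' @param order 2 or 3.
#' @return list of subproblem specs, each `list(order, type, labels)`, in
#'   lexicographic label order.
#' @examples
#' length(enumerateSubproblems(makePartition(1000, 200), 2))  # 10 + 5
#' @export
enumerateSubproblems <- function(scheme, order = 2) {
  order <- as.integer(order)
  stopifnot(order %in% c(2L, 3L))
  k <- scheme@k
  specs <- list()
  if (order == 2L) {
    for (s1 in seq_len(k)) for (s2 in s1:k) {
      specs[[length(specs) + 1L]] <- list(
        order = 2L,
        type = if (s1 == s2) "within" else "cross-pair",
        labels = c(s1, s2))
    }
  } else {
    for (s1 in seq_len(k)) for (s2 in s1:k) for (s3 in s2:k) {
      eq <- paste0("s1", if (s1 == s2) "=" else "<",
                   "s2", if (s2 == s3) "=" else "<", "s3")
      specs[[length(specs) + 1L]] <- list(order = 3L, type = eq,
                                          labels = c(s1, s2, s3))
    }
  }
  specs
}

subproblemId <- function(spec) {
  paste0("q", spec$order, ":", paste(spec$labels, collapse = "-"))
}

# all pairs within a variable set, as a list of sorted 2-vectors
.pairsWithin <- function(v) {
  if (length(v) < 2L) return(list())
  m <- combn(v, 2L)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

.crossPairs <- function(a, b) {
  out <- vector("list", length(a) * length(b))
  h <- 0L
  for (t1 in a) for (t2 in b) {
    h <- h + 1L
    out[[h]] <- sort(c(t1, t2))
  }
  out
}

#' Patterns belonging to one screening subproblem
#'
#' Order 2: a cross-pair subproblem over partitions (s1, s2) holds the
#' constant basis, the 2g main effects of both partitions and the g^2 cross
#' products (g^2 + 2g + 1 patterns); a within subproblem holds the constant,
#' g mains and choose(g, 2) within-partition pairs (1 + g(g+1)/2 patterns).
#' Order 3: each subproblem holds the size-3 products whose sorted partition
#' labels equal its label multiset; main effects and within-partition pairs
#' are placed in the (s,s,s) subproblem of their partition, and a cross pair
#' with labels a < b in the (a,a,b) subproblem, so that every variable subset
#' of size 1-3 is a candidate exactly once across the enumeration.
#'
#' @param spec one element of [enumerateSubproblems()].
#' @param scheme the [PartitionScheme] used to create it.
#' @return list of patterns (the constant basis first).
#' @export
patternsForSubproblem <- function(spec, scheme) {
  lab <- spec$labels
  mem <- lapply(lab, partitionMembers, scheme = scheme)
  out <- list(integer(0))
  if (spec$order == 2L) {
    if (spec$type == "within") {
      v <- mem[[1]]
      out <- c(out, as.list(v), .pairsWithin(v))
    } else {
      out <- c(out, as.list(mem[[1]]), as.list(mem[[2]]),
               .crossPairs(mem[[1]], mem[[2]]))
    }
  } else {
    s1 <- lab[1]; s2 <- lab[2]; s3 <- lab[3]
    if (spec$type == "s1=s2=s3") {
      v <- mem[[1]]
      tri <- if (length(v) >= 3L) {
        m <- combn(v, 3L); lapply(seq_len(ncol(m)), function(j) m[, j])
      } else list()
      out <- c(out, as.list(v), .pairsWithin(v), tri)
    } else if (spec$type == "s1=s2<s3") {
      a <- mem[[1]]; b <- mem[[3]]
      tri <- list()
      if (length(a) >= 2L) {
        pm <- combn(a, 2L)
        for (j in seq_len(ncol(pm))) for (t3 in b)
          tri[[length(tri) + 1L]] <- sort(c(pm[, j], t3))
      }
      out <- c(out, .crossPairs(a, b), tri)
    } else if (spec$type == "s1<s2=s3") {
      a <- mem[[1]]; b <- mem[[2]]
      tri <- list()
      if (length(b) >= 2L) {
        pm <- combn(b, 2L)
        for (t1 in a) for (j in seq_len(ncol(pm)))
          tri[[length(tri) + 1L]] <- sort(c(t1, pm[, j]))
      }
      out <- c(out, tri)
    } else {
      tri <- list()
      for (t1 in mem[[1]]) for (t2 in mem[[2]]) for (t3 in mem[[3]])
        tri[[length(tri) + 1L]] <- sort(c(t1, t2, t3))
      out <- c(out, tri)
    }
  }
  out
}

#' Number of patterns up to a given order
#'
#' `sum(choose(p, 0:order))`, the column count of the full design including
#' the constant basis; for order 2 this equals `1 + p*(p+1)/2`.
#'
#' @param p number of variables.
#' @param order highest pattern order, 1-3.
#' @return scalar count.
#' @examples
#' patternCount(2000, 2)  # 2001001
#' @export
patternCount <- function(p, order = 2) {
  stopifnot(p >= 1, order %in% 1:3)
  sum(choose(p, 0:order))
}

#' Enumerate all patterns up to a given order
#'
#' The full (unpartitioned) candidate set: `sum(choose(p, 0:order))`
#' patterns; for order 2 this is `1 + p(p+1)/2`.
#'
#' @param p number of variables.
#' @param order highest pattern order, 1-3.
#' @param cap refuse materialization when the count exceeds this many
#'   patterns (default 5e6).
#' @return list of patterns (constant first, then mains, pairs, triples).
#' @export
enumerateAllPatterns <- function(p, order = 2, cap = 5e6) {
  p <- as.integer(p); order <- as.integer(order)
  stopifnot(p >= 1L, order %in% 1:3)
  count <- sum(choose(p, 0:order))
  if (count > cap)
    stop(sprintf("pattern count %.0f exceeds materialization cap %.0f",
                 count, cap))
  out <- c(list(integer(0)), as.list(seq_len(p)))
  if (order >= 2L && p >= 2L) out <- c(out, .pairsWithin(seq_len(p)))
  if (order >= 3L && p >= 3L) {
    m <- combn(seq_len(p), 3L)
    out <- c(out, lapply(seq_len(ncol(m)), function(j) m[, j]))
  }
  out
}

#' Build the sparse pattern design matrix
#'
#' Column `l` at row `i` equals the product of pattern `l`'s variables for
#' subject `i` (all ones for the constant basis).
#'
#' @param data a [BinaryDataset] (or a 0/1 matrix).
#' @param patterns list of patterns.
#' @return a [PatternDesign] holding a sparse `dgCMatrix`.
#' @export
buildDesign <- function(data, patterns) {
  X <- if (is(data, "BinaryDataset")) data@X else as.matrix(data)
  p <- ncol(X)
  idx <- unlist(patterns, use.names = FALSE)
  if (length(idx) && (min(idx) < 1L || max(idx) > p))
    stop("pattern variable index out of range")
  Xi <- X; storage.mode(Xi) <- "integer"
  csc <- plps_build_design_csc(Xi, patterns)
  m <- new("dgCMatrix", p = csc$p, i = csc$i,
           x = rep(1, length(csc$i)), Dim = c(nrow(X), length(patterns)))
  new("PatternDesign", patterns = patterns, design = m,
      order = vapply(patterns, length, integer(1)), p = as.integer(p))
}

#' Check that a partition scheme covers every candidate pattern
#'
#' Enumerates all subproblems' pattern lists and counts, for every variable
#' subset of size 1..order, how many subproblems list it. For order 2, pairs
#' must be covered exactly once and mains at least once; for order 3, subsets
#' of every size are covered exactly once under the placement used by
#' [patternsForSubproblem()]. Intended as a validation tool at small `p`
#' (it materializes all `choose(p, order)` subsets).
#'
#' @param scheme a [PartitionScheme].
#' @param order 2 or 3.
#' @return list with `ok` (logical), `mainMultiplicity` (named integer
#'   vector) and `violations` (character vector of mis-covered subsets).
#' @export
verifyCoverage <- function(scheme, order = 2) {
  order <- as.integer(order)
  specs <- enumerateSubproblems(scheme, order)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (spec in specs) {
    for (pat in patternsForSubproblem(spec, scheme)) {
      if (length(pat) == 0L) next
      key <- patternKey(pat)
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  p <- scheme@p
  violations <- character(0)
  mains <- integer(p)
  for (j in seq_len(p)) {
    key <- patternKey(j)
    mains[j] <- if (is.null(counts[[key]])) 0L else counts[[key]]
    want <- if (order == 2L) mains[j] >= 1L else mains[j] == 1L
    if (!want) violations <- c(violations, key)
  }
  names(mains) <- paste0("X", seq_len(p))
  checkExact <- function(subsets) {
    for (j in seq_len(ncol(subsets))) {
      key <- patternKey(subsets[, j])
      cnt <- if (is.null(counts[[key]])) 0L else counts[[key]]
      if (cnt != 1L) violations <<- c(violations, key)
    }
  }
  if (p >= 2L) checkExact(combn(seq_len(p), 2L))
  if (order == 3L && p >= 3L) checkExact(combn(seq_len(p), 3L))
  list(ok = length(violations) == 0L, mainMultiplicity = mains,
       violations = violations)
}
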