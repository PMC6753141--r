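#' Ratio combination set
#'
#' A ratio combination set assigns to each of the 10 finger pairs a distinct
#' denominator pair, such that every pair appears exactly once as numerator
#' and exactly once as denominator and never divides itself -- i.e. the
#' denominators form a fixed-point-free permutation (derangement) of the
#' pairs. One record's ratiometric feature vector is then the 10 ratio
#' spectra, 25 frequencies each: 250 elements, the same count as the raw
#' spectra.
#'
#' @param num,den character vectors of 10 pair labels (`"a-b"`), the
#'   numerator and denominator of each combination, in order.
#' @return An object of class `ratio_combination`: a data frame with columns
#'   `num` and `den`.
#' @seealso [published_combination()], [select_combinations()]
#' @export
ratio_combination <- function(num, den) {
  fp <- finger_pairs()
  num <- as.character(num)
  den <- as.character(den)
  if (length(num) != nrow(fp) || length(den) != nrow(fp))
    stop("need exactly ", nrow(fp), " numerator/denominator pairs",
         call. = FALSE)
  if (!all(num %in% fp$label) || !all(den %in% fp$label))
    stop("unknown pair label; use \"a-b\" with 1 <= a < b <= 5",
         call. = FALSE)
  if (anyDuplicated(num) || anyDuplicated(den))
    stop("each pair must appear exactly once as numerator and once as denominator",
         call. = FALSE)
  if (any(num == den))
    stop("a pair may not be divided by itself (derangement required)",
         call. = FALSE)
  structure(data.frame(num = num, den = den, stringsAsFactors = FALSE),
            class = c("ratio_combination", "data.frame"))
}

#' @export
print.ratio_combination <- function(x, ...) {
  cat("Ratio combination set (numerator / denominator):\n")
  cat(paste0("  pair(", sub("-", ",", x$num), ") / pair(",
             sub("-", ",", x$den), ")", collapse = "\n"), "\n")
  invisible(x)
}

#' The published 10-combination ratio set
#'
#' The fixed set of 10 numerator/denominator assignments reported with the
#' method and reused for all subjects: (1,2)/(4,5), (1,3)/(1,2), (1,5)/(1,3),
#' (1,4)/(1,5), (2,3)/(1,4), (2,5)/(2,3), (2,4)/(2,5), (3,5)/(2,4),
#' (3,4)/(3,5), (4,5)/(3,4). The induced permutation is a single 10-cycle.
#'
#' @return A [ratio_combination()].
#' @export
published_combination <- function() {
  ratio_combination(
    num = c("1-2", "1-3", "1-5", "1-4", "2-3", "2-5", "2-4", "3-5", "3-4", "4-5"),
    den = c("4-5", "1-2", "1-3", "1-5", "1-4", "2-3", "2-5", "2-4", "3-5", "3-4"))
}

check_record_matrix <- function(spectra) {
  fp <- finger_pairs()
  if (!is.matrix(spectra) || is.null(rownames(spectra)))
    stop("record spectra must be a matrix with pair-label rownames",
         call. = FALSE)
  if (!setequal(rownames(spectra), fp$label))
    stop("record must contain all 10 finger pairs on one grid", call. = FALSE)
  if (any(!is.finite(spectra)) || any(spectra <= 0))
    stop("impedance magnitudes must be finite and > 0", call. = FALSE)
  spectra[fp$label, , drop = FALSE]
}

#' Ratiometric feature vector of one record
#'
#' Divides, element-wise at each frequency, the magnitude spectrum of each
#' combination's numerator pair by that of its denominator pair, both taken
#' from the same placement. Any multiplicative factor common to all pairs of
#' the record (session drift, temperature) cancels exactly.
#'
#' @param spectra one record's spectra: a numeric matrix, 10 pair rows
#'   (rownames `"a-b"`) by frequencies.
#' @param combos a [ratio_combination()], default [published_combination()].
#' @return Numeric feature vector of length `10 * ncol(spectra)` (250 on the
#'   default grid), combinations in `combos` order, frequencies ascending
#'   within each; names `"num/den_<col>"`.
#' @export
ratiometric_transform <- function(spectra, combos = published_combination()) {
  spectra <- check_record_matrix(spectra)
  if (!inherits(combos, "ratio_combination"))
    stop("'combos' must be a ratio_combination", call. = FALSE)
  ratio <- spectra[combos$num, , drop = FALSE] /
    spectra[combos$den, , drop = FALSE]
  cn <- colnames(spectra)
  if (is.null(cn)) cn <- seq_len(ncol(spectra))
  out <- as.vector(t(ratio))
  names(out) <- as.vector(t(outer(paste0(combos$num, "/", combos$den), cn,
                                  paste, sep = "_")))
  out
}

#' Raw feature vector of one record
#'
#' Concatenates the 10 raw magnitude spectra in canonical pair order
#' (lexicographic `(a, b)`), frequencies ascending within each pair.
#'
#' @inheritParams ratiometric_transform
#' @return Numeric vector of length `10 * ncol(spectra)`, names
#'   `"a-b_<col>"`.
#' @export
raw_features <- function(spectra) {
  spectra <- check_record_matrix(spectra)
  cn <- colnames(spectra)
  if (is.null(cn)) cn <- seq_len(ncol(spectra))
  out <- as.vector(t(spectra))
  names(out) <- as.vector(t(outer(rownames(spectra), cn, paste, sep = "_")))
  out
}

#' Feature matrix of a whole dataset
#'
#' @param ds a `spectra_dataset`.
#' @param kind `"raw"` or `"ratiometric"`.
#' @param combos combination set for `kind = "ratiometric"`.
#' @return Numeric matrix, one row per record, 250 columns on the default
#'   grid, with attribute `kind`.
#' @export
featurize <- function(ds, kind = c("ratiometric", "raw"),
                      combos = published_combination()) {
  kind <- match.arg(kind)
  n <- n_records(ds)
  out <- matrix(0, n, nrow(ds$pairs) * length(ds$grid))
  for (i in seq_len(n)) {
    v <- if (kind == "raw") raw_features(record_spectra(ds, i))
         else ratiometric_transform(record_spectra(ds, i), combos)
    if (i == 1L) colnames(out) <- names(v)
    out[i, ] <- v
  }
  attr(out, "kind") <- kind
  out
}

# ---- combination selection -------------------------------------------------

# all derangements of 1..n as a matrix (rows = derangements), lexicographic
# row order; brute-force oracle path, practical for n <= 7
all_derangements <- function(n) {
  rec <- function(chosen, remaining) {
    d <- length(chosen) + 1L
    if (d > n) return(matrix(chosen, nrow = 1L))
    do.call(rbind, lapply(remaining[remaining != d], function(q) {
      rec(c(chosen, q), setdiff(remaining, q))
    }))
  }
  rec(integer(0), seq_len(n))  # DFS in ascending order => lexicographic rows
}

# exact min-cost derangement by depth-first branch-and-bound.
# cost: n x n matrix; entry [p, q] is the cost of assigning denominator q to
# numerator p; the diagonal is forbidden. Returns the assignment sigma
# (sigma[p] = q) minimizing sum_p cost[p, sigma[p]]; among ties, the
# lexicographically smallest sigma (guaranteed because the search tries
# denominators in ascending order and only replaces the incumbent on strict
# improvement).
min_cost_derangement <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, n >= 2L)
  cost <- as.matrix(cost)
  diag(cost) <- Inf
  best <- Inf
  best_sigma <- NULL
  sigma <- integer(n)
  used <- logical(n)

  lower_bound <- function(d) {
    # sum over remaining numerators of their cheapest available denominator
    if (d > n) return(0)
    lb <- 0
    for (p in d:n) {
      avail <- cost[p, !used]
      m <- min(avail)
      if (!is.finite(m)) return(Inf)
      lb <- lb + m
    }
    lb
  }

  search <- function(d, acc) {
    if (d > n) {
      if (acc < best) {
        best <<- acc
        best_sigma <<- sigma[seq_len(n)]
      }
      return(invisible())
    }
    if (acc + lower_bound(d) >= best) return(invisible())
    for (q in seq_len(n)) {  # ascending denominator index
      if (used[q] || q == d) next
      step <- cost[d, q]
      if (!is.finite(step) || acc + step >= best) next
      sigma[d] <<- q
      used[q] <<- TRUE
      search(d + 1L, acc + step)
      used[q] <<- FALSE
    }
    invisible()
  }
  search(1L, 0)
  if (is.null(best_sigma)) stop("no feasible derangement", call. = FALSE)
  list(sigma = best_sigma, objective = best)
}

# brute-force companion for tests: exhaustive enumeration, same tie-break.
# The objective accumulates left-to-right in double precision, the same
# convention as the branch-and-bound path, so exact ties (e.g. a reversed
# cycle under a symmetric cost) resolve identically.
min_cost_derangement_bruteforce <- function(cost) {
  n <- nrow(cost)
  der <- all_derangements(n)
  obj <- apply(der, 1L, function(sg) {
    acc <- 0
    for (p in seq_len(n)) acc <- acc + cost[p, sg[p]]
    acc
  })
  i <- which(obj == min(obj))[1L]
  list(sigma = der[i, ], objective = obj[i])
}

#' Select balanced ratio combinations from training data
#'
#' Chooses the denominator for each finger pair so that the resulting
#' ratiometric features have balanced scales: with `M_p` the mean of
#' `log |Z_p(f)|` over all training records and frequencies, it finds the
#' fixed-point-free permutation `sigma` minimizing
#' `sum_p (M_p - M_sigma(p))^2` -- the squared deviation of each log-ratio
#' feature's scale from the set average, which is zero by the telescoping
#' property. The optimum is found exactly by branch-and-bound over the
#' ~1.33 million derangements of 10 pairs; ties are broken by lexicographic
#' order of the assignment list.
#'
#' @param training a `spectra_dataset` of training records (>= 1 record).
#' @return A [ratio_combination()] with numerators in canonical pair order,
#'   plus attribute `objective` (the minimized sum of squares).
#' @export
select_combinations <- function(training) {
  if (!inherits(training, "spectra_dataset") || n_records(training) < 1L)
    stop("'training' must be a non-empty spectra_dataset", call. = FALSE)
  # M_p: mean log-magnitude per pair over records and frequencies
  m <- apply(log(training$spectra), 2L, mean)
  cost <- outer(m, m, function(x, y) (x - y)^2)
  sol <- min_cost_derangement(cost)
  fp <- finger_pairs()
  out <- ratio_combination(num = fp$label, den = fp$label[sol$sigma])
  attr(out, "objective") <- sol$objective
  out
}
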