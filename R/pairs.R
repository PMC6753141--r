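#' Canonical finger pairs
#'
#' Five fingertip electrodes (numbered 1 = thumb to 5 = index-side, in hand
#' order) yield `choose(5, 2) = 10` measurable finger pairs. The canonical
#' ordering used everywhere in this package is lexicographic in `(a, b)`.
#'
#' @return A data frame with columns `a`, `b` (integer finger indices,
#'   `a < b`) and `label` (`"a-b"`), 10 rows.
#' @examples
#' finger_pairs()
#' @export
finger_pairs <- function() {
  cmb <- utils::combn(5L, 2L)
  data.frame(a = cmb[1L, ], b = cmb[2L, ],
             label = paste0(cmb[1L, ], "-", cmb[2L, ]),
             stringsAsFactors = FALSE)
}

pair_label <- function(a, b) paste0(a, "-", b)

# canonical index (1..10) of pair (a, b); errors on invalid pairs
pair_index <- function(a, b) {
  fp <- finger_pairs()
  idx <- match(pair_label(a, b), fp$label)
  if (any(is.na(idx)))
    stop("invalid finger pair: must have 1 <= a < b <= 5", call. = FALSE)
  idx
}
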