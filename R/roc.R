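#' ROC, EER and AUC from genuine/impostor scores
#'
#' Open-set verification view of a multiclass score matrix: the score a
#' sample assigns to its true class is a genuine score; every score it
#' assigns to another enrolled class is an impostor score. Sweeping the
#' acceptance threshold `theta` over the pooled score set gives
#' `FAR(theta)` (fraction of impostor scores `>= theta`, non-increasing) and
#' `FRR(theta)` (fraction of genuine scores `< theta`, non-decreasing). The
#' equal error rate is the FAR = FRR crossing (linear interpolation between
#' the two bracketing thresholds) and the AUC the trapezoidal area under
#' `(FAR, 1 - FRR)`.
#'
#' @param genuine,impostor numeric score vectors (higher = more confident);
#'   both non-empty. Alternatively pass a `scored_predictions` object plus
#'   `true` labels to [scores_to_genuine_impostor()] first.
#' @return An object of class `roc_result`: list with `thresholds`, `far`,
#'   `frr` (rates in \[0, 1\]), `eer_pct` (percent) and `auc`.
#' @export
roc_from_scores <- function(genuine, impostor) {
  genuine <- as.numeric(genuine)
  impostor <- as.numeric(impostor)
  if (length(genuine) == 0L || length(impostor) == 0L)
    stop("need at least one genuine and one impostor score", call. = FALSE)
  if (any(!is.finite(c(genuine, impostor))))
    stop("scores must be finite", call. = FALSE)

  th <- c(-Inf, sort(unique(c(genuine, impostor))), Inf)
  far <- vapply(th, function(t) mean(impostor >= t), numeric(1))
  frr <- vapply(th, function(t) mean(genuine < t), numeric(1))

  # EER: first threshold where FRR >= FAR, interpolated against the previous
  i <- which(frr >= far)[1L]
  if (i == 1L) {
    eer <- far[1L]
  } else {
    d1 <- far[i - 1L] - frr[i - 1L]
    d2 <- far[i] - frr[i]
    lam <- if (d1 == d2) 0 else d1 / (d1 - d2)
    eer <- far[i - 1L] + lam * (far[i] - far[i - 1L])
  }

  # AUC: trapezoid over (FPR = FAR, TPR = 1 - FRR), sorted by FPR
  fpr <- rev(far)
  tpr <- rev(1 - frr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)

  structure(list(thresholds = th, far = far, frr = frr,
                 eer_pct = 100 * eer, auc = auc,
                 n_genuine = length(genuine), n_impostor = length(impostor)),
            class = "roc_result")
}

#' Split a score matrix into genuine and impostor scores
#'
#' @param scores `n x n_class` score matrix with class column names.
#' @param true true class label per row.
#' @return List with `genuine` and `impostor` numeric vectors.
#' @export
scores_to_genuine_impostor <- function(scores, true) {
  true <- as.character(true)
  if (length(true) != nrow(scores))
    stop("one true label per score row required", call. = FALSE)
  col <- match(true, colnames(scores))
  if (any(is.na(col)))
    stop("true labels not all among enrolled classes", call. = FALSE)
  sel <- matrix(FALSE, nrow(scores), ncol(scores))
  sel[cbind(seq_len(nrow(scores)), col)] <- TRUE
  list(genuine = scores[sel], impostor = scores[!sel])
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d genuine / %d impostor scores\n",
              x$n_genuine, x$n_impostor))
  cat(sprintf("  EER = %.4f %%   AUC = %.4f\n", x$eer_pct, x$auc))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(rev(x$far), rev(1 - x$frr), type = "l",
       xlab = "False acceptance rate", ylab = "1 - false rejection rate",
       main = sprintf("ROC (EER %.2f%%, AUC %.4f)", x$eer_pct, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
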