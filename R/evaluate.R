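#' Leave-one-session-out folds
#'
#' One fold per (subject, session): that subject's records from that session
#' form the validation set ("one session of a person on a day"), everything
#' else trains. Folds cover every record exactly once as validation, so
#' cross-day generalization is what is measured.
#'
#' @param ds a `spectra_dataset`; every subject must have at least two
#'   sessions.
#' @return List of folds, each `list(subject, session, train, val)` with
#'   integer record indices.
#' @export
loso_split <- function(ds) {
  if (!inherits(ds, "spectra_dataset"))
    stop("'ds' must be a spectra_dataset", call. = FALSE)
  meta <- ds$meta
  ses_per_subj <- tapply(meta$session_id, meta$subject_id,
                         function(s) length(unique(s)))
  bad <- names(ses_per_subj)[ses_per_subj < 2L]
  if (length(bad))
    stop("subjects with a single session cannot be cross-validated: ",
         paste(bad, collapse = ", "), call. = FALSE)
  combos <- unique(meta[, c("subject_id", "session_id")])
  combos <- combos[order(combos$subject_id, combos$session_id), , drop = FALSE]
  lapply(seq_len(nrow(combos)), function(i) {
    val <- which(meta$subject_id == combos$subject_id[i] &
                   meta$session_id == combos$session_id[i])
    list(subject = combos$subject_id[i], session = combos$session_id[i],
         train = setdiff(seq_len(nrow(meta)), val), val = val)
  })
}

#' LOSO-CV identification benchmark
#'
#' Runs the full open-set identification protocol on a dataset: features
#' (raw or ratiometric), leave-one-session-out folds, one classifier fit per
#' fold, pooled genuine/impostor scores across folds for the threshold
#' sweep. Accuracy is top-score identification without a threshold; EER and
#' AUC come from [roc_from_scores()] on the pooled scores.
#'
#' @param ds a `spectra_dataset`.
#' @param feature_kind `"ratiometric"` or `"raw"`.
#' @param spec a [classifier_spec()].
#' @param combos combination set for ratiometric features.
#' @param seed integer seed passed to stochastic classifiers.
#' @param unknown_subject optional subject id withheld from enrolment
#'   entirely: that subject's records never train, and their scores against
#'   the enrolled classes join the impostor pool, emulating attempts by an
#'   unregistered attacker. Default `NULL` (closed impostor pool).
#' @return Object of class `identify_eval`: list with `accuracy_pct`,
#'   `error_pct`, `roc` (a `roc_result`), `confusion` (table,
#'   rows = true subject), `feature_kind`, `classifier`, `n_folds`.
#' @export
evaluate <- function(ds, feature_kind = c("ratiometric", "raw"),
                     spec = classifier_spec("knn"),
                     combos = published_combination(), seed = 1,
                     unknown_subject = NULL) {
  feature_kind <- match.arg(feature_kind)
  x_all <- featurize(ds, feature_kind, combos)
  unknown_idx <- integer(0)
  if (!is.null(unknown_subject)) {
    unknown_idx <- which(ds$meta$subject_id == unknown_subject)
    if (length(unknown_idx) == 0L)
      stop("unknown_subject not present in the dataset", call. = FALSE)
    keep <- setdiff(seq_len(nrow(ds$meta)), unknown_idx)
    ds <- new_spectra_dataset(ds$meta[keep, , drop = FALSE],
                              ds$spectra[keep, , , drop = FALSE],
                              ds$grid, ds$pairs)
    x <- x_all[keep, , drop = FALSE]
  } else {
    x <- x_all
  }
  y <- ds$meta$subject_id
  folds <- loso_split(ds)

  true_all <- character(0)
  pred_all <- character(0)
  genuine <- numeric(0)
  impostor <- numeric(0)
  for (f in folds) {
    sp <- fit_predict(spec, x[f$train, , drop = FALSE], y[f$train],
                      x[f$val, , drop = FALSE], seed = seed)
    gi <- scores_to_genuine_impostor(sp$scores, y[f$val])
    genuine <- c(genuine, gi$genuine)
    impostor <- c(impostor, gi$impostor)
    true_all <- c(true_all, y[f$val])
    pred_all <- c(pred_all, sp$predicted)
  }
  if (length(unknown_idx)) {
    # unregistered attacker: every score an unenrolled probe attains
    # against an enrolled class is an impostor score
    sp <- fit_predict(spec, x, y, x_all[unknown_idx, , drop = FALSE],
                      seed = seed)
    impostor <- c(impostor, as.vector(sp$scores))
  }
  lev <- sort(unique(y))
  confusion <- table(true = factor(true_all, lev),
                     predicted = factor(pred_all, lev))
  acc <- 100 * mean(true_all == pred_all)
  structure(list(accuracy_pct = acc, error_pct = 100 - acc,
                 roc = roc_from_scores(genuine, impostor),
                 confusion = confusion,
                 feature_kind = feature_kind, classifier = spec$family,
                 n_folds = length(folds)),
            class = "identify_eval")
}

#' @export
print.identify_eval <- function(x, ...) {
  cat(sprintf("LOSO-CV identification: %s features, %s (%d folds)\n",
              x$feature_kind, x$classifier, x$n_folds))
  cat(sprintf("  accuracy = %.2f %%   EER = %.4f %%   AUC = %.4f\n",
              x$accuracy_pct, x$roc$eer_pct, x$roc$auc))
  invisible(x)
}

#' @export
summary.identify_eval <- function(object, ...) {
  print(object)
  cat("\nConfusion matrix (rows = true subject):\n")
  print(object$confusion)
  invisible(object)
}

#' Finger-pair classification within one subject
#'
#' The within-subject reproducibility demonstration: can the 10 finger pairs
#' (or, in ratiometric mode, the 10 ratio combinations) of a single subject
#' be told apart across sessions? Each raw sample is one pair's 25-point
#' magnitude spectrum labelled by the pair; each ratiometric sample is one
#' combination's 25-point ratio curve labelled by the combination. Accuracy
#' is leave-one-session-out.
#'
#' @param ds a single-subject `spectra_dataset` with >= 2 sessions.
#' @param feature_kind `"ratiometric"` or `"raw"`.
#' @param spec a [classifier_spec()].
#' @param combos combination set for ratiometric mode.
#' @param seed integer seed for stochastic classifiers.
#' @return Accuracy in percent.
#' @export
finger_pair_classification <- function(ds,
                                       feature_kind = c("ratiometric", "raw"),
                                       spec = classifier_spec("knn"),
                                       combos = published_combination(),
                                       seed = 1) {
  feature_kind <- match.arg(feature_kind)
  if (length(unique(ds$meta$subject_id)) != 1L)
    stop("finger-pair classification expects a single-subject dataset",
         call. = FALSE)
  n <- n_records(ds)
  # explode each record into 10 curve samples
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    m <- record_spectra(ds, i)
    if (feature_kind == "ratiometric") {
      v <- ratiometric_transform(m, combos)
      curves <- matrix(v, nrow = nrow(combos), byrow = TRUE)
      labels <- paste0(combos$num, "/", combos$den)
    } else {
      curves <- m
      labels <- rownames(m)
    }
    samples[[i]] <- list(x = curves, y = labels,
                         session = ds$meta$session_id[i])
  }
  x <- do.call(rbind, lapply(samples, `[[`, "x"))
  y <- unlist(lapply(samples, `[[`, "y"))
  ses <- rep(vapply(samples, `[[`, character(1), "session"),
             each = nrow(samples[[1L]]$x))
  sessions <- unique(ses)
  if (length(sessions) < 2L)
    stop("need at least two sessions", call. = FALSE)
  correct <- 0L
  total <- 0L
  for (s in sessions) {
    val <- ses == s
    sp <- fit_predict(spec, x[!val, , drop = FALSE], y[!val],
                      x[val, , drop = FALSE], seed = seed)
    correct <- correct + sum(sp$predicted == y[val])
    total <- total + sum(val)
  }
  100 * correct / total
}
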