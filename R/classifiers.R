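#' Classifier specification
#'
#' The four discriminative families benchmarked by the method, with the
#' published hyperparameters as defaults: SVMs with box constraint `C = 1`
#' and kernel scale 16 (features are divided by the kernel scale before the
#' kernel, MATLAB-style; the quadratic kernel is `(1 + u.v)^2` on the scaled
#' features), 1-nearest-neighbour with Euclidean distance, and bagged
#' decision trees (30 trees, Gini splits, at most 2165 splits per tree).
#'
#' @param family one of `"linear-svm"`, `"quadratic-svm"`, `"knn"`,
#'   `"bagged-trees"`.
#' @param box_constraint SVM cost parameter C.
#' @param kernel_scale SVM kernel scale.
#' @param k_neighbors number of neighbours for KNN.
#' @param n_trees,max_splits bagged-tree ensemble size and per-tree split cap.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("knn", "linear-svm", "quadratic-svm",
                                       "bagged-trees"),
                            box_constraint = 1.0, kernel_scale = 16,
                            k_neighbors = 1L, n_trees = 30L,
                            max_splits = 2165L) {
  family <- match.arg(family)
  if (box_constraint <= 0 || kernel_scale <= 0 || k_neighbors < 1 ||
      n_trees < 1 || max_splits < 1)
    stop("classifier hyperparameters must be positive", call. = FALSE)
  structure(list(family = family, box_constraint = box_constraint,
                 kernel_scale = kernel_scale,
                 k_neighbors = as.integer(k_neighbors),
                 n_trees = as.integer(n_trees),
                 max_splits = as.integer(max_splits)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("Classifier:", x$family, "\n")
  invisible(x)
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Train a classifier and score validation samples
#'
#' Fits the specified model on the training features and returns, for every
#' validation sample, a per-class confidence score in `[0, 1]` summing to 1
#' across classes, suitable for an acceptance-threshold sweep. Calibration
#' per family: SVMs turn each one-vs-one decision value into a soft vote
#' through a sigmoid (pairwise coupling) and normalize the per-class soft
#' vote totals; 1-NN uses `exp(-d_c)` over the distance
#' `d_c` to each class's nearest training sample, normalized (raw k=1 votes
#' are 0/1 and cannot be swept); bagged trees use ensemble class vote
#' fractions.
#'
#' @param spec a [classifier_spec()].
#' @param x_train,y_train training feature matrix and class labels.
#' @param x_val validation feature matrix (same columns).
#' @param seed integer seed (bagged trees bootstrap).
#' @return A list of class `scored_predictions`: `true` is absent (the
#'   caller knows the labels), `scores` is a `n_val x n_class` matrix with
#'   class column names, `predicted` the top-scoring class per row.
#' @export
fit_predict <- function(spec, x_train, y_train, x_val, seed = 1) {
  if (!inherits(spec, "classifier_spec"))
    stop("'spec' must be a classifier_spec", call. = FALSE)
  x_train <- as.matrix(x_train)
  x_val <- as.matrix(x_val)
  if (ncol(x_train) != ncol(x_val))
    stop("train and validation features differ in dimension", call. = FALSE)
  y_train <- factor(y_train)
  if (nlevels(y_train) < 2L)
    stop("training data must contain at least two classes", call. = FALSE)
  classes <- levels(y_train)

  scores <- switch(spec$family,
    "knn" = {
      # per-class distance to the nearest training sample, softmax of -d
      d <- matrix(Inf, nrow(x_val), length(classes),
                  dimnames = list(NULL, classes))
      for (cl in classes) {
        xt <- x_train[y_train == cl, , drop = FALSE]
        d2 <- outer(rowSums(x_val^2), rowSums(xt^2), "+") -
          2 * x_val %*% t(xt)
        d2[d2 < 0] <- 0  # numerical guard
        dd <- sqrt(d2)
        k <- min(spec$k_neighbors, ncol(dd))
        d[, cl] <- apply(dd, 1L, function(r) mean(sort(r)[seq_len(k)]))
      }
      softmax_rows(-d)
    },
    "linear-svm" = ,
    "quadratic-svm" = {
      # standardize on training statistics (the MATLAB SVM-learner default,
      # under which a kernel scale of 16 ~ sqrt(250) is the usual
      # heuristic), then divide by the kernel scale
      mu <- colMeans(x_train)
      sg <- apply(x_train, 2L, stats::sd)
      sg[sg == 0] <- 1
      sc <- spec$kernel_scale
      std <- function(m) sweep(sweep(m, 2L, mu), 2L, sg, "/") / sc
      xt <- std(x_train)
      fit <- if (spec$family == "linear-svm")
        e1071::svm(xt, y_train, kernel = "linear",
                   cost = spec$box_constraint, scale = FALSE)
      else
        e1071::svm(xt, y_train, kernel = "polynomial", degree = 2,
                   gamma = 1, coef0 = 1, cost = spec$box_constraint,
                   scale = FALSE)
      pr <- attr(stats::predict(fit, std(x_val), decision.values = TRUE),
                 "decision.values")
      # pairwise coupling: each one-vs-one decision value becomes a soft
      # vote through a sigmoid (raw margins are not comparable across
      # duels); per-class soft-vote totals are normalized to sum to 1
      agg <- matrix(0, nrow(x_val), length(classes),
                    dimnames = list(NULL, classes))
      duel <- strsplit(colnames(pr), "/", fixed = TRUE)
      for (j in seq_along(duel)) {
        sv <- 1 / (1 + exp(-pr[, j]))
        agg[, duel[[j]][1L]] <- agg[, duel[[j]][1L]] + sv
        agg[, duel[[j]][2L]] <- agg[, duel[[j]][2L]] + (1 - sv)
      }
      agg / rowSums(agg)
    },
    "bagged-trees" = {
      set.seed(seed)
      maxn <- min(spec$max_splits + 1L, nrow(x_train))
      fit <- randomForest::randomForest(
        x = x_train, y = y_train, ntree = spec$n_trees,
        mtry = ncol(x_train), maxnodes = maxn)
      p <- stats::predict(fit, x_val, type = "prob")
      p[, classes, drop = FALSE]
    })

  structure(list(scores = scores,
                 predicted = classes[max.col(scores, ties.method = "first")]),
            class = "scored_predictions")
}
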