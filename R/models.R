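# Penetration classifiers: random-forest and extremely-randomized-trees
# ensembles (ranger backends) with randomized hyperparameter search scored
# by cross-validated ROC-AUC, plus the full metric suite (precision,
# recall, F1, accuracy, MCC, confusion matrix) computed from the confusion
# counts and a rank-based ROC-AUC.

#' Hyperparameter search space for the tree ensembles
#'
#' @param kind `"rf"` (random forest) or `"et"` (extremely randomized
#'   trees).
#' @param max_depth Integer range (min, max) for tree depth; default 1-20.
#' @param n_estimators Integer range (min, max) for the number of trees;
#'   default 50-500.
#' @param n_search_draws Number of random parameter settings drawn.
#' @param cv_folds Folds for the cross-validated ROC-AUC score (default 5).
#' @param seed Integer seed controlling draws, folds and tree fitting.
#' @return A `bbb_tree_space` list.
#' @export
tree_search_space <- function(kind = c("rf", "et"), max_depth = c(1L, 20L),
                              n_estimators = c(50L, 500L),
                              n_search_draws = 20L, cv_folds = 5L, seed = 1L) {
  kind <- match.arg(kind)
  if (length(max_depth) != 2L || max_depth[1L] > max_depth[2L]) {
    stop_config("tree_search_space(): max_depth must be an increasing pair")
  }
  if (length(n_estimators) != 2L || n_estimators[1L] > n_estimators[2L]) {
    stop_config("tree_search_space(): n_estimators must be an increasing pair")
  }
  if (cv_folds < 2L) stop_config("tree_search_space(): cv_folds must be >= 2")
  structure(list(
    kind = kind, max_depth = as.integer(max_depth),
    n_estimators = as.integer(n_estimators),
    n_search_draws = as.integer(n_search_draws),
    cv_folds = as.integer(cv_folds), seed = as.integer(seed)
  ), class = "bbb_tree_space")
}

ranger_fit <- function(x, y, kind, depth, trees, seed, class_weights = NULL) {
  args <- list(
    x = as.data.frame(x), y = factor(y, levels = c(0L, 1L)),
    num.trees = trees, max.depth = depth, probability = TRUE,
    seed = seed, num.threads = 1L, verbose = FALSE
  )
  if (kind == "et") {
    args$splitrule <- "extratrees"
    args$num.random.splits <- 1L
    args$replace <- FALSE
    args$sample.fraction <- 1
  }
  if (!is.null(class_weights)) args$class.weights <- class_weights
  do.call(ranger::ranger, args)
}

kfold_indices <- function(n, k, seed) {
  perm <- with_seed(seed, sample.int(n))
  split(perm, rep(seq_len(k), length.out = n))
}

#' Rank-based ROC-AUC
#'
#' Area under the ROC curve computed from the probability ranking
#' (Mann-Whitney statistic, ties resolved by average rank).
#'
#' @param labels Binary 0/1 labels.
#' @param probs Predicted probabilities of label 1.
#' @return AUC in \[0, 1\]; `NA` (with a warning) when only one class is
#'   present.
#' @export
roc_auc <- function(labels, probs) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warn("roc_auc(): only one class present; AUC undefined")
    return(NA_real_)
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Randomized hyperparameter search and final fit for a tree ensemble
#'
#' Draws `n_search_draws` (depth, trees) settings uniformly from the
#' space, scores each by mean k-fold cross-validated ROC-AUC on the
#' training data, and refits the best setting on all of it.  Deterministic
#' under the space's seed.
#'
#' @param x Training feature matrix (binary fingerprint rows).
#' @param labels Binary 0/1 training labels (both classes required).
#' @param space A [tree_search_space()].
#' @param class_weights Optional per-class weights, e.g.
#'   `c("0" = 3, "1" = 1)`, passed to the ensemble as an alternative to
#'   oversampling.
#' @return A `bbb_model` with the fitted ensemble, `best_params`, and the
#'   per-draw search results (`cv_results`).
#' @export
search_and_train_tree <- function(x, labels, space = tree_search_space(),
                                  class_weights = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop_config("search_and_train_tree(): training labels contain a single class")
  }
  x <- as.matrix(x)
  draws <- with_seed(derive_seed(space$seed, "draws"), tibble::tibble(
    max_depth = sample(space$max_depth[1L]:space$max_depth[2L],
      space$n_search_draws,
      replace = TRUE
    ),
    n_estimators = sample(space$n_estimators[1L]:space$n_estimators[2L],
      space$n_search_draws,
      replace = TRUE
    )
  ))
  folds <- kfold_indices(nrow(x), space$cv_folds, derive_seed(space$seed, "folds"))
  draws$cv_roc_auc <- vapply(seq_len(nrow(draws)), function(i) {
    aucs <- vapply(folds, function(hold) {
      tr <- setdiff(seq_len(nrow(x)), hold)
      if (length(unique(labels[tr])) < 2L || length(unique(labels[hold])) < 2L) {
        return(NA_real_)
      }
      fit <- ranger_fit(x[tr, , drop = FALSE], labels[tr], space$kind,
        draws$max_depth[i], draws$n_estimators[i],
        seed = derive_seed(space$seed, paste0("fit", i)),
        class_weights = class_weights
      )
      p <- predict(fit, data = as.data.frame(x[hold, , drop = FALSE]),
        num.threads = 1L
      )$predictions[, "1"]
      suppressWarnings(roc_auc(labels[hold], p))
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(draws$cv_roc_auc)
  fit <- ranger_fit(x, labels, space$kind, draws$max_depth[best],
    draws$n_estimators[best],
    seed = derive_seed(space$seed, "final"), class_weights = class_weights
  )
  structure(list(
    kind = space$kind, fit = fit,
    best_params = list(
      max_depth = draws$max_depth[best], n_estimators = draws$n_estimators[best]
    ),
    cv_results = draws, seed = space$seed
  ), class = "bbb_model")
}

#' Predicted probability of penetration (label 1)
#'
#' @param model A fitted model (`bbb_model`, `bbb_drn`, or a plain function
#'   mapping a feature matrix to a probability vector, useful as a black
#'   box in tests).
#' @param x Feature matrix.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, x) UseMethod("predict_proba")

#' @export
predict_proba.bbb_model <- function(model, x) {
  p <- predict(model$fit, data = as.data.frame(as.matrix(x)), num.threads = 1L)
  p$predictions[, "1"]
}

#' @export
predict_proba.function <- function(model, x) {
  as.numeric(model(as.matrix(x)))
}

#' @export
print.bbb_model <- function(x, ...) {
  cat(sprintf(
    "<bbb_model> %s ensemble: depth %d, %d trees (cv ROC-AUC %.3f over %d draws)\n",
    toupper(x$kind), x$best_params$max_depth, x$best_params$n_estimators,
    max(x$cv_results$cv_roc_auc, na.rm = TRUE), nrow(x$cv_results)
  ))
  invisible(x)
}

#' @rdname search_and_train_tree
#' @param x,object A `bbb_model`.
#' @param ... Unused.
#' @export
tidy.bbb_model <- function(x, ...) x$cv_results

#' @rdname search_and_train_tree
#' @export
glance.bbb_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, max_depth = x$best_params$max_depth,
    n_estimators = x$best_params$n_estimators,
    cv_roc_auc = max(x$cv_results$cv_roc_auc, na.rm = TRUE)
  )
}

confusion_counts <- function(labels, pred) {
  m <- matrix(0L, 2L, 2L, dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  for (i in seq_along(labels)) {
    m[labels[i] + 1L, pred[i] + 1L] <- m[labels[i] + 1L, pred[i] + 1L] + 1L
  }
  m
}

metrics_from_confusion <- function(confusion) {
  tn <- confusion["0", "0"]; fp <- confusion["0", "1"]
  fn <- confusion["1", "0"]; tp <- confusion["1", "1"]
  div <- function(num, den) if (den == 0) 0 else num / den
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  accuracy <- div(tp + tn, tp + tn + fp + fn)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  list(precision = precision, recall = recall, f1 = f1, accuracy = accuracy, mcc = mcc)
}

#' Evaluate a classifier on a labelled dataset
#'
#' Hard labels are taken at probability threshold 0.5; precision, recall,
#' F1, accuracy and the Matthews correlation coefficient come from the
#' resulting confusion matrix, ROC-AUC from the probability ranking.
#'
#' @param model A fitted model accepted by [predict_proba()].
#' @param x Feature matrix.
#' @param labels Binary 0/1 labels.
#' @param threshold Hard-label probability threshold (default 0.5).
#' @return A `bbb_metrics` object (also a plain list): `roc_auc`,
#'   `precision`, `recall`, `f1`, `accuracy`, `mcc`, `confusion`
#'   (2x2 matrix, rows = true class, columns = predicted class), `n`.
#' @export
evaluate <- function(model, x, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  probs <- predict_proba(model, x)
  pred <- as.integer(probs >= threshold)
  confusion <- confusion_counts(labels, pred)
  m <- metrics_from_confusion(confusion)
  structure(c(
    list(roc_auc = suppressWarnings(roc_auc(labels, probs))),
    m,
    list(confusion = confusion, n = length(labels), threshold = threshold)
  ), class = "bbb_metrics")
}

#' @export
print.bbb_metrics <- function(x, ...) {
  cat(sprintf(
    "<bbb_metrics> n=%d  ROC-AUC %.3f | precision %.3f recall %.3f F1 %.3f | accuracy %.3f MCC %.3f\n",
    x$n, x$roc_auc, x$precision, x$recall, x$f1, x$accuracy, x$mcc
  ))
  print(x$confusion)
  invisible(x)
}

#' @rdname evaluate
#' @param x,object A `bbb_metrics` object.
#' @param ... Unused.
#' @export
tidy.bbb_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("roc_auc", "precision", "recall", "f1", "accuracy", "mcc"),
    value = c(x$roc_auc, x$precision, x$recall, x$f1, x$accuracy, x$mcc)
  )
}

#' @rdname evaluate
#' @export
glance.bbb_metrics <- function(x, ...) {
  tibble::tibble(
    roc_auc = x$roc_auc, precision = x$precision, recall = x$recall,
    f1 = x$f1, accuracy = x$accuracy, mcc = x$mcc, n = x$n
  )
}

#' @rdname evaluate
#' @export
autoplot.bbb_metrics <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(c("0", "1"))) +
    ggplot2::labs(title = "Confusion matrix", x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Nested cross-validation
#'
#' Outer k-fold evaluation with the randomized hyperparameter search (and
#' optional minority oversampling) confined to each outer-training fold,
#' giving a less biased performance estimate than reusing one CV loop for
#' both tuning and assessment.
#'
#' @param x Feature matrix.
#' @param labels Binary 0/1 labels.
#' @param space A [tree_search_space()]; its `cv_folds` is overridden by
#'   `inner_folds`.
#' @param inner_folds Folds for the hyperparameter search (default 5).
#' @param outer_folds Folds for the outer evaluation loop (default 10).
#' @param resample If `TRUE` (default), each outer-training fold is
#'   class-balanced by oversampling before the search; outer validation
#'   folds are never resampled.
#' @return A tibble with one row per evaluated outer fold: fold id, chosen
#'   hyperparameters, and all validation metrics.  Folds whose validation
#'   part lacks a class are skipped with a warning.
#' @export
nested_cv <- function(x, labels, space = tree_search_space(),
                      inner_folds = 5L, outer_folds = 10L, resample = TRUE) {
  labels <- as.integer(labels)
  x <- as.matrix(x)
  if (nrow(x) < outer_folds) stop_config("nested_cv(): fewer rows than outer folds")
  folds <- kfold_indices(nrow(x), outer_folds, derive_seed(space$seed, "outer"))
  rows <- list()
  for (k in seq_along(folds)) {
    hold <- folds[[k]]
    tr <- setdiff(seq_len(nrow(x)), hold)
    if (length(unique(labels[hold])) < 2L || length(unique(labels[tr])) < 2L) {
      warn(sprintf("nested_cv(): outer fold %d lacks a class; skipped", k))
      next
    }
    xtr <- x[tr, , drop = FALSE]
    ytr <- labels[tr]
    if (resample) {
      rs <- resample_balanced(xtr, ytr, seed = derive_seed(space$seed, paste0("rs", k)))
      xtr <- rs$x; ytr <- rs$labels
    }
    sp <- space
    sp$cv_folds <- as.integer(inner_folds)
    sp$seed <- derive_seed(space$seed, paste0("inner", k))
    model <- search_and_train_tree(xtr, ytr, sp)
    met <- evaluate(model, x[hold, , drop = FALSE], labels[hold])
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(
        fold = k, n_validation = length(hold),
        max_depth = model$best_params$max_depth,
        n_estimators = model$best_params$n_estimators
      ),
      glance(met)
    )
  }
  dplyr::bind_rows(rows)
}

#' Confidently predicted penetrating molecules
#'
#' Validation-set molecules that truly penetrate (label 1) and whose
#' predicted penetration probability reaches the threshold: the candidates
#' subsequently explained and mined for substructure alerts.
#'
#' @param model A fitted model accepted by [predict_proba()].
#' @param x Validation feature matrix.
#' @param labels Binary 0/1 validation labels.
#' @param prob_threshold Probability cut-off in (0, 1); default 0.8.
#' @return Integer vector of row indices (possibly empty).
#' @export
select_confident_positives <- function(model, x, labels, prob_threshold = 0.8) {
  if (!is.numeric(prob_threshold) || prob_threshold <= 0 || prob_threshold >= 1) {
    stop_config("select_confident_positives(): prob_threshold must lie in (0, 1)")
  }
  labels <- as.integer(labels)
  probs <- predict_proba(model, x)
  which(labels == 1L & probs >= prob_threshold)
}
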