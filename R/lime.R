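# Perturbation-based local linear surrogate for binary fingerprint
# features (classification mode), written from scratch.  One instance at a
# time: draw perturbed copies of the molecule's fingerprint from the
# training marginals, weight them by an exponential proximity kernel on
# the match/mismatch encoding, fit a weighted ridge regression of the
# black box's label-1 probability, and keep the K largest-magnitude
# coefficients as per-bit contribution weights.

#' Per-feature training marginals for the perturbation sampler
#'
#' @param x Binary training feature matrix.
#' @return A `bbb_lime_stats` list: `freq` (empirical frequency of value 1
#'   per feature) and `d` (feature count).
#' @export
fit_training_stats <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop_config("fit_training_stats(): empty training matrix")
  structure(list(freq = colMeans(x), d = ncol(x)), class = "bbb_lime_stats")
}

#' Explainer configuration
#'
#' @param n_samples Number of perturbed samples per explanation
#'   (default 5000; the first sample is the instance itself).
#' @param n_features Maximum number K of features retained in an
#'   explanation (default 100).
#' @param kernel_width Proximity-kernel width; default `0.75 * sqrt(d)`,
#'   the convention of the explainer family this reproduces (resolved when
#'   the feature count is known).
#' @param top_labels Number of labels explained; fixed to 1 here (the
#'   surrogate regresses the probability of label 1 only).
#' @param ridge Ridge penalty of the surrogate fit (default 1; set to 0
#'   for the exact unpenalized limit used in recovery tests).
#' @param seed Integer seed; explanations are deterministic under it.
#' @return A `bbb_explainer_config` list.
#' @export
explainer_config <- function(n_samples = 5000L, n_features = 100L,
                             kernel_width = NULL, top_labels = 1L,
                             ridge = 1.0, seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 10L) {
    stop_config("explainer_config(): n_samples must be >= 10")
  }
  if (n_features < 1L) stop_config("explainer_config(): n_features must be >= 1")
  if (!is.null(kernel_width) && kernel_width <= 0) {
    stop_config("explainer_config(): kernel_width must be positive")
  }
  if (!identical(as.integer(top_labels), 1L)) {
    stop_config("explainer_config(): only top_labels = 1 is supported")
  }
  structure(list(
    n_samples = n_samples, n_features = as.integer(n_features),
    kernel_width = kernel_width, top_labels = 1L,
    ridge = ridge, seed = as.integer(seed)
  ), class = "bbb_explainer_config")
}

resolve_kernel_width <- function(config, d) {
  config$kernel_width %||% (0.75 * sqrt(d))
}

#' Draw perturbed copies of one instance
#'
#' Sample 1 is the instance itself.  In samples 2..n every feature is
#' drawn independently from its training marginal (Bernoulli of the
#' training frequency).  The interpretable encoding marks agreement with
#' the instance: `zp = 1` where the sample equals the instance, else 0.
#'
#' @param x Binary feature vector of the instance.
#' @param stats A [fit_training_stats()] object.
#' @param n_samples Number of rows to draw.
#' @param seed Integer seed.
#' @return A list with `z` (raw samples, n x d) and `zp` (interpretable
#'   match/mismatch encoding, n x d).
#' @export
sample_perturbations <- function(x, stats, n_samples = 5000L, seed = 1L) {
  stopifnot(inherits(stats, "bbb_lime_stats"))
  x <- as.numeric(x)
  d <- stats$d
  if (length(x) != d) stop_config("sample_perturbations(): instance length != d")
  n <- as.integer(n_samples)
  z <- with_seed(seed, {
    u <- matrix(runif((n - 1L) * d), n - 1L, d)
    (u < matrix(stats$freq, n - 1L, d, byrow = TRUE)) * 1
  })
  z <- rbind(matrix(x, 1L, d), z)
  zp <- 1 * (z == matrix(x, n, d, byrow = TRUE))
  list(z = z, zp = zp)
}

#' Proximity-kernel sample weights
#'
#' The distance of a perturbed sample is the Euclidean distance between
#' its match/mismatch encoding and the all-ones vector, i.e. the square
#' root of the mismatch count; the weight is `exp(-D^2 / sigma^2)`.  The
#' self-sample (no mismatches) has weight 1 and weights decrease strictly
#' with every additional mismatch.
#'
#' @param zp Interpretable encoding matrix from [sample_perturbations()].
#' @param sigma Kernel width (> 0).
#' @return Numeric vector of per-sample weights in (0, 1].
#' @export
kernel_weights <- function(zp, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop_config("kernel_weights(): sigma must be > 0")
  d2 <- rowSums(zp == 0)
  exp(-d2 / sigma^2)
}

weighted_ridge <- function(zp, y, w, ridge) {
  X <- cbind(1, zp)
  sw <- sqrt(w)
  Xw <- X * sw
  A <- crossprod(Xw)
  diag(A)[-1L] <- diag(A)[-1L] + ridge
  b <- crossprod(Xw, y * sw)
  beta <- tryCatch(solve(A, b), error = function(e) {
    stop_config(
      "fit_local_surrogate(): degenerate perturbation sample (singular design); increase n_samples"
    )
  })
  drop(beta)
}

#' Fit the local linear surrogate
#'
#' Two-stage fit: (1) weighted ridge regression of the black-box label-1
#' probability on all interpretable features; (2) keep the K coefficients
#' of largest magnitude and refit the weighted ridge on that subset.  The
#' refit coefficients are the explanation weights; the weighted R-squared
#' of the refit is the local fit quality.
#'
#' @param zp Interpretable encoding matrix (first row = self-sample).
#' @param probs Black-box probabilities of label 1 on the raw samples.
#' @param weights Kernel weights from [kernel_weights()].
#' @param n_features Maximum number K of retained features.
#' @param ridge Ridge penalty (0 gives exact weighted least squares).
#' @return A `bbb_explanation` object: `$weights` (tibble `bit`, `weight`,
#'   0-based feature indices, sorted by absolute weight), `$intercept`,
#'   `$local_fit_score`.
#' @export
fit_local_surrogate <- function(zp, probs, weights, n_features = 100L, ridge = 1.0) {
  zp <- as.matrix(zp)
  d <- ncol(zp)
  if (n_features > d) n_features <- d
  beta_full <- weighted_ridge(zp, probs, weights, ridge)
  coef_full <- beta_full[-1L]
  keep <- order(abs(coef_full), decreasing = TRUE)[seq_len(n_features)]
  keep <- sort(keep)
  beta <- weighted_ridge(zp[, keep, drop = FALSE], probs, weights, ridge)
  intercept <- beta[[1L]]
  coefs <- beta[-1L]
  fitted <- intercept + zp[, keep, drop = FALSE] %*% coefs
  wmean <- sum(weights * probs) / sum(weights)
  ss_tot <- sum(weights * (probs - wmean)^2)
  ss_res <- sum(weights * (probs - fitted)^2)
  r2 <- if (ss_tot <= 0) 1 else 1 - ss_res / ss_tot
  o <- order(abs(coefs), decreasing = TRUE)
  new_bbb_explanation(
    weights = tibble::tibble(bit = keep[o] - 1L, weight = coefs[o]),
    intercept = intercept, local_fit_score = r2
  )
}

new_bbb_explanation <- function(weights, intercept, local_fit_score,
                                predicted_probability = NA_real_,
                                instance_id = NA_character_) {
  structure(list(
    instance_id = instance_id, weights = weights, intercept = intercept,
    local_fit_score = local_fit_score,
    predicted_probability = predicted_probability
  ), class = "bbb_explanation")
}

#' Explain one prediction
#'
#' End-to-end local explanation of the label-1 probability for one
#' instance: perturbation sampling from the training marginals, proximity
#' kernel, weighted ridge surrogate, K-feature selection.  Deterministic
#' under the configuration seed.
#'
#' @param model A fitted model accepted by [predict_proba()].
#' @param x Binary feature vector of the instance to explain.
#' @param stats A [fit_training_stats()] object.
#' @param config An [explainer_config()].
#' @param instance_id Optional identifier carried into the result.
#' @return A `bbb_explanation`: per-bit signed weights (0-based bit
#'   indices, sorted by magnitude, at most `n_features` entries),
#'   intercept, local fit quality, and the black box's probability for the
#'   instance.
#' @export
explain_instance <- function(model, x, stats, config = explainer_config(),
                             instance_id = NA_character_) {
  stopifnot(inherits(stats, "bbb_lime_stats"))
  sm <- sample_perturbations(x, stats, config$n_samples, config$seed)
  sigma <- resolve_kernel_width(config, stats$d)
  w <- kernel_weights(sm$zp, sigma)
  probs <- predict_proba(model, sm$z)
  expl <- fit_local_surrogate(sm$zp, probs, w, config$n_features, config$ridge)
  expl$predicted_probability <- probs[[1L]]
  expl$instance_id <- instance_id
  expl
}

#' Explanation weights as a map
#'
#' @param explanation A `bbb_explanation`.
#' @return A named numeric vector mapping feature index (0-based, as
#'   names) to signed weight; lossless round trip with the weight list.
#' @export
as_weight_map <- function(explanation) {
  stopifnot(inherits(explanation, "bbb_explanation"))
  setNames(explanation$weights$weight, explanation$weights$bit)
}

#' @export
print.bbb_explanation <- function(x, ...) {
  cat(sprintf(
    "<bbb_explanation>%s p(penetrating)=%.3f, intercept %.3f, local R2 %.3f, %d weights\n",
    if (is.na(x$instance_id)) "" else paste0(" ", x$instance_id),
    x$predicted_probability, x$intercept, x$local_fit_score, nrow(x$weights)
  ))
  print(head(x$weights, 5))
  invisible(x)
}

#' @rdname explain_instance
#' @param x,object A `bbb_explanation`.
#' @param ... Unused.
#' @export
tidy.bbb_explanation <- function(x, ...) x$weights

#' @rdname explain_instance
#' @export
glance.bbb_explanation <- function(x, ...) {
  tibble::tibble(
    instance_id = x$instance_id,
    predicted_probability = x$predicted_probability,
    intercept = x$intercept, local_fit_score = x$local_fit_score,
    n_weights = nrow(x$weights)
  )
}

#' @rdname explain_instance
#' @param top_n Number of weights shown by the plot.
#' @export
autoplot.bbb_explanation <- function(object, top_n = 15L, ...) {
  df <- head(object$weights, top_n)
  df$bit <- factor(df$bit, levels = rev(df$bit))
  ggplot2::ggplot(df, ggplot2::aes(.data$weight, .data$bit, fill = .data$weight > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f0e")) +
    ggplot2::labs(
      x = "contribution weight (label 1)", y = "fingerprint bit",
      title = sprintf(
        "p = %.2f, local R2 = %.2f",
        object$predicted_probability, object$local_fit_score
      )
    )
}
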