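test_that("training marginals are plain column means", {
  x <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 1), c(0, 0, 1))
  st <- fit_training_stats(x)
  expect_equal(st$freq, c(0.5, 0.5, 0.5))
  expect_equal(st$d, 3L)
  expect_equal(fit_training_stats(matrix(1, 4, 2))$freq, c(1, 1))
})

test_that("perturbation sampling follows the training marginals", {
  x <- c(1, 0, 1, 0, 1)
  st <- structure(list(freq = c(1, 0, 0.5, 0.2, 0.8), d = 5L), class = "bbb_lime_stats")
  sm <- sample_perturbations(x, st, n_samples = 5000, seed = 2)
  # sample 0 is the instance itself; its interpretable row is all ones
  expect_equal(sm$z[1, ], x)
  expect_equal(sm$zp[1, ], rep(1, 5))
  # degenerate marginals are deterministic
  expect_true(all(sm$z[, 1] == 1))
  expect_true(all(sm$z[, 2] == 0))
  # column means approach the marginals (binomial +-3 SE at n = 5000)
  for (j in 3:5) {
    se <- sqrt(st$freq[j] * (1 - st$freq[j]) / 5000)
    expect_lt(abs(mean(sm$z[-1, j]) - st$freq[j]), 3 * se + 1e-9)
  }
  # reproducible
  expect_identical(sm, sample_perturbations(x, st, 5000, seed = 2))
})

test_that("kernel weights decay monotonically with mismatch count", {
  zp <- rbind(rep(1, 4), c(0, 1, 1, 1), c(0, 0, 1, 1), c(0, 0, 0, 1))
  sigma <- 0.75 * 2
  w <- kernel_weights(zp, sigma)
  expect_equal(w[1], 1)
  expect_equal(w[2], exp(-1 / 2.25))
  expect_true(all(diff(w) < 0))
  expect_error(kernel_weights(zp, 0), class = "bbbalert_config_error")
})

test_that("the unpenalized surrogate recovers enumerable linear black boxes exactly", {
  # worked case: d = 3, f = 0.1 + 0.2 z1 + 0.3 z2 on the full design
  z <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(z) <- NULL
  y <- 0.1 + 0.2 * z[, 1] + 0.3 * z[, 2]
  w <- kernel_weights(z, 0.75 * sqrt(3)) # x = all-ones, so zp == z
  ex <- fit_local_surrogate(z, y, w, n_features = 3, ridge = 0)
  wm <- as_weight_map(ex)
  expect_equal(unname(wm[as.character(0:2)]), c(0.2, 0.3, 0), tolerance = 1e-8)
  expect_equal(ex$intercept, 0.1, tolerance = 1e-8)
  expect_equal(ex$local_fit_score, 1, tolerance = 1e-8)
  # sweep d <= 10 with random coefficients against truth and an
  # independent weighted-least-squares oracle
  set.seed(31)
  for (d in c(2L, 4L, 7L, 10L)) {
    z <- as.matrix(expand.grid(rep(list(0:1), d)))
    colnames(z) <- NULL
    beta <- round(runif(d, -0.5, 0.5), 3)
    beta[sample(d, max(0L, d - 3L))] <- 0
    y <- 0.4 + drop(z %*% beta)
    w <- kernel_weights(z, 0.75 * sqrt(d))
    ex <- fit_local_surrogate(z, y, w, n_features = d, ridge = 0)
    wm <- as_weight_map(ex)
    got <- unname(wm[as.character(0:(d - 1))])
    expect_equal(got, beta, tolerance = 1e-8)
    orc <- wls_oracle(z, y, w)
    expect_equal(ex$intercept, orc[1], tolerance = 1e-8)
    expect_equal(got, orc[-1], tolerance = 1e-8)
  }
})

test_that("a constant black box yields null weights and the constant intercept", {
  set.seed(5)
  zp <- matrix(rbinom(200 * 6, 1, 0.5), 200, 6)
  ex <- fit_local_surrogate(zp, rep(0.7, 200), rep(1, 200), n_features = 6, ridge = 1)
  expect_true(all(abs(ex$weights$weight) < 1e-8))
  expect_equal(ex$intercept, 0.7, tolerance = 1e-6)
})

test_that("explanations are capped at K features and sorted by magnitude", {
  set.seed(6)
  zp <- matrix(rbinom(300 * 12, 1, 0.5), 300, 12)
  y <- 0.2 + 0.3 * zp[, 1] - 0.2 * zp[, 2] + 0.1 * zp[, 3]
  ex <- fit_local_surrogate(zp, y, rep(1, 300), n_features = 4, ridge = 0)
  expect_lte(nrow(ex$weights), 4L)
  expect_true(all(diff(abs(ex$weights$weight)) <= 1e-12))
  expect_true(all(ex$weights$bit %in% 0:11))
  expect_false(anyDuplicated(ex$weights$bit) > 0)
  # degenerate design errors out with advice
  expect_error(
    fit_local_surrogate(matrix(1, 20, 3), rep(0.5, 20), rep(1, 20), 3, ridge = 0),
    "n_samples"
  )
})

test_that("explain_instance is seed-deterministic and finds planted logits", {
  d <- 20L
  beta <- c(2, -1.5, 1, rep(0, d - 3))
  blackbox <- function(x) stats::plogis(-0.2 + drop(as.matrix(x) %*% beta))
  set.seed(77)
  xtrain <- matrix(rbinom(400 * d, 1, 0.5), 400, d)
  st <- fit_training_stats(xtrain)
  cfg <- explainer_config(n_samples = 800, n_features = d, seed = 4)
  x0 <- rep(1L, d)
  e1 <- explain_instance(blackbox, x0, st, cfg, instance_id = "m1")
  e2 <- explain_instance(blackbox, x0, st, cfg, instance_id = "m1")
  expect_identical(e1$weights, e2$weights)
  expect_equal(e1$predicted_probability, blackbox(matrix(x0, 1)))
  # planted-coefficient recovery: the 3 truly nonzero features rank in the
  # top 5 by |weight| in >= 90% of seeds
  hits <- vapply(1:20, function(s) {
    e <- explain_instance(blackbox, x0, st,
      explainer_config(n_samples = 800, n_features = d, seed = s)
    )
    top5 <- e$weights$bit[1:5]
    all(c(0L, 1L, 2L) %in% top5)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # weight-map round trip is lossless
  wm <- as_weight_map(e1)
  expect_equal(length(wm), nrow(e1$weights))
  expect_equal(unname(wm[as.character(e1$weights$bit)]), e1$weights$weight)
  empty <- bbbalert:::new_bbb_explanation(
    tibble::tibble(bit = integer(0), weight = numeric(0)), 0, 0
  )
  expect_length(as_weight_map(empty), 0L)
  expect_s3_class(ggplot2::autoplot(e1), "ggplot")
})

test_that("default configuration mirrors the documented conventions", {
  cfg <- explainer_config()
  expect_equal(cfg$n_samples, 5000L)
  expect_equal(cfg$n_features, 100L)
  expect_equal(cfg$top_labels, 1L)
  expect_equal(bbbalert:::resolve_kernel_width(cfg, 1024), 0.75 * 32)
  expect_error(explainer_config(n_samples = 5), class = "bbbalert_config_error")
  expect_error(explainer_config(top_labels = 2), class = "bbbalert_config_error")
  expect_error(explainer_config(kernel_width = -1), class = "bbbalert_config_error")
})

test_that("top fragments are stable across kernel widths on the molecule library", {
  fx <- get_small_run()
  i <- fx$candidates[1]
  x0 <- fx$xva[i, ]
  d <- length(x0)
  stable <- vapply(1:5, function(s) {
    tops <- lapply(c(0.5, 0.75, 1.0), function(mult) {
      e <- explain_instance(fx$model, x0, fx$stats, explainer_config(
        n_samples = 600, kernel_width = mult * sqrt(d), seed = s
      ))
      sort(e$weights$bit[1:5])
    })
    identical(tops[[1]], tops[[2]]) && identical(tops[[2]], tops[[3]])
  }, logical(1))
  expect_gte(sum(stable), 4L)
})
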