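test_that("metrics agree with direct formula evaluation on random confusion matrices", {
  set.seed(42)
  for (k in 1:200) {
    tp <- sample(0:30, 1); tn <- sample(0:30, 1)
    fp <- sample(0:30, 1); fn <- sample(0:30, 1)
    if (tp + tn + fp + fn == 0) next
    rz <- realize_confusion(tp, tn, fp, fn)
    met <- evaluate(function(x) rz$probs, matrix(0, length(rz$labels), 1), rz$labels)
    orc <- oracle_metrics(tp, tn, fp, fn)
    for (nm in names(orc)) {
      expect_equal(met[[nm]], orc[[nm]], tolerance = 1e-12)
    }
    expect_identical(unname(met$confusion["1", "1"]), tp)
    expect_identical(unname(met$confusion["0", "0"]), tn)
    expect_identical(unname(met$confusion["0", "1"]), fp)
    expect_identical(unname(met$confusion["1", "0"]), fn)
    expect_equal(sum(met$confusion), length(rz$labels))
  }
})

test_that("the worked confusion example evaluates to the printed values", {
  rz <- realize_confusion(tp = 3, tn = 2, fp = 1, fn = 1)
  met <- evaluate(function(x) rz$probs, matrix(0, 7, 1), rz$labels)
  expect_equal(met$precision, 0.75)
  expect_equal(met$recall, 0.75)
  expect_equal(met$accuracy, 5 / 7)
  expect_equal(met$mcc, 5 / 12)
  # perfect prediction pins every score at its best value
  perfect <- evaluate(function(x) c(0.9, 0.9, 0.1), matrix(0, 3, 1), c(1, 1, 0))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$roc_auc, 1)
})

test_that("rank-based ROC-AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (k in 1:50) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2) # rounding forces ties
    ref <- as.numeric(suppressMessages(pROC::auc(y, p, direction = "<")))
    expect_equal(roc_auc(y, p), ref, tolerance = 1e-12)
  }
  expect_warning(a <- roc_auc(c(1, 1), c(0.2, 0.8)))
  expect_true(is.na(a))
})

test_that("MCC of label-permuted predictions is centred on zero", {
  set.seed(11)
  y <- rbinom(120, 1, 0.6)
  p <- runif(120)
  mccs <- replicate(100, {
    evaluate(function(x) sample(p), matrix(0, 120, 1), y)$mcc
  })
  expect_lt(abs(mean(mccs)), 0.1)
  expect_true(all(mccs >= -1 & mccs <= 1))
})

test_that("both tree backends separate a linearly separable toy set", {
  fx <- make_separable_xy(seed = 3)
  for (kind in c("rf", "et")) {
    sp <- tree_search_space(kind = kind, n_search_draws = 4, cv_folds = 3, seed = 5)
    m <- search_and_train_tree(fx$x, fx$y, sp)
    expect_true(m$best_params$max_depth >= 1 && m$best_params$max_depth <= 20)
    expect_true(m$best_params$n_estimators >= 50 && m$best_params$n_estimators <= 500)
    met <- evaluate(m, fx$x, fx$y)
    expect_equal(met$roc_auc, 1.0)
    # deterministic under the seed
    m2 <- search_and_train_tree(fx$x, fx$y, sp)
    expect_identical(m$best_params, m2$best_params)
    expect_equal(predict_proba(m, fx$x), predict_proba(m2, fx$x))
  }
  expect_error(
    search_and_train_tree(fx$x, rep(1L, nrow(fx$x)), tree_search_space()),
    class = "bbbalert_config_error"
  )
})

test_that("confident-positive selection honours both the label and the threshold", {
  probs <- c(0.79, 0.90, 0.85, 0.99)
  labels <- c(1, 0, 1, 1)
  idx <- select_confident_positives(function(x) probs, matrix(0, 4, 1), labels, 0.8)
  expect_identical(idx, c(3L, 4L)) # 0.79/1 below threshold, 0.90/0 wrong label
  expect_error(
    select_confident_positives(function(x) probs, matrix(0, 4, 1), labels, 1.2),
    class = "bbbalert_config_error"
  )
})

test_that("nested cross-validation partitions the data and stays clean on separable data", {
  fx <- make_separable_xy(n = 80, seed = 9)
  sp <- tree_search_space(kind = "rf", n_search_draws = 2, seed = 2)
  res <- nested_cv(fx$x, fx$y, sp, inner_folds = 3, outer_folds = 5, resample = TRUE)
  expect_equal(sum(res$n_validation), 80L)
  expect_equal(sort(unique(res$fold)), seq_len(5))
  # outer validation scores: separable data is solved in every fold
  expect_true(all(res$roc_auc == 1.0))
  expect_true(all(res$max_depth >= 1 & res$max_depth <= 20))
  expect_error(nested_cv(fx$x[1:4, ], fx$y[1:4], sp), class = "bbbalert_config_error")
})

test_that("model and metrics expose broom-style views", {
  fx <- make_separable_xy(seed = 1)
  m <- search_and_train_tree(fx$x, fx$y,
    tree_search_space(n_search_draws = 2, cv_folds = 3, seed = 1)
  )
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(nrow(tidy(m)), 2L)
  expect_named(glance(m), c("kind", "max_depth", "n_estimators", "cv_roc_auc"))
  met <- evaluate(m, fx$x, fx$y)
  expect_equal(nrow(tidy(met)), 6L)
  expect_s3_class(ggplot2::autoplot(met), "ggplot")
})
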