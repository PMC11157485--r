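test_that("fingerprint rows are binary with the configured length", {
  fps <- compute_fingerprints(data.frame(smiles = c("CCO", "c1ccncc1", "CC(=O)O")))
  expect_equal(dim(fps$matrix), c(3L, 1024L))
  expect_true(all(fps$matrix %in% c(0L, 1L)))
  expect_error(
    compute_fingerprints(data.frame(smiles = "zzz$")),
    class = "bbbalert_config_error"
  )
  expect_error(fp_config(n_bits = 1), class = "bbbalert_config_error")
  expect_error(fp_config(radius = -1), class = "bbbalert_config_error")
})

test_that("symmetric molecules set the environment-enumeration bit counts", {
  # expected counts were frozen from an independent circular-fingerprint
  # reference on the same fixtures (ethane 2; benzene 3; methanol 3;
  # pyrrole 8)
  fps <- compute_fingerprints(data.frame(smiles = c("CC", "c1ccccc1", "CO", "c1cc[nH]c1")))
  expect_equal(unname(rowSums(fps$matrix)), c(2, 3, 3, 8))
  # benzene: one bit per radius, all six atoms listed as centers
  env <- fps$env[[2]]
  expect_equal(length(unique(vapply(env, function(e) e$bit, integer(1)))), 3L)
  by_radius <- split(env, vapply(env, function(e) e$radius, integer(1)))
  expect_equal(
    unname(vapply(by_radius, function(es) sum(lengths(lapply(es, `[[`, "centers")))
    , integer(1))),
    c(6L, 6L, 6L)
  )
})

test_that("fingerprinting is a pure function and the registry is sound", {
  smis <- c("CCN1CCCC1", "CC(=O)Oc1ccccc1", "FC(F)(F)CCO")
  a <- compute_fingerprints(data.frame(smiles = smis))
  b <- compute_fingerprints(data.frame(smiles = smis))
  expect_identical(a$matrix, b$matrix)
  for (i in seq_along(smis)) {
    bits <- vapply(a$env[[i]], function(e) e$bit, integer(1))
    expect_true(all(a$matrix[i, bits + 1L] == 1L))
    radii <- vapply(a$env[[i]], function(e) e$radius, integer(1))
    expect_true(all(radii >= 0L & radii <= a$config$radius))
  }
})

test_that("bits resolve to substructure fragments of their parents", {
  fps <- compute_fingerprints(data.frame(smiles = c("CC", "c1ccccc1", "CCN1CCCC1")))
  # ethane radius-0 environment is a bare carbon
  b0 <- fps$env[[1]][[1]]$bit
  fr <- bit_to_fragments(fps, 1, b0)
  expect_true(all(fr$fragment_smiles == "C"))
  # a bit set by several distinct environments returns several fragments
  env2 <- fps$env[[2]]
  r1bit <- env2[[which(vapply(env2, function(e) e$radius, integer(1)) == 1L)[1]]]$bit
  fr2 <- bit_to_fragments(fps, 2, r1bit)
  expect_equal(nrow(fr2), 6L) # six symmetric benzene environments
  expect_equal(length(unique(fr2$fragment_smiles)), 1L)
  # substructure soundness on an aliphatic molecule: every fragment matches
  # its parent by SMARTS search
  env3 <- fps$env[[3]]
  for (e in env3[vapply(env3, function(x) x$radius, integer(1)) > 0]) {
    fr3 <- bit_to_fragments(fps, 3, e$bit)
    for (fs in fr3$fragment_smiles) {
      expect_gt(bbbalert:::smarts_match_counts("CCN1CCCC1", fs), 0)
    }
  }
  # a bit that is not set yields no fragments
  unset <- setdiff(0:1023, vapply(env3, function(e) e$bit, integer(1)))[1]
  expect_equal(nrow(bit_to_fragments(fps, 3, unset)), 0L)
})

test_that("random splits are reproducible, disjoint and exhaustive", {
  s <- split_dataset(10, 0.8, seed = 3)
  expect_equal(length(s$train), 8L)
  expect_equal(length(s$validation), 2L)
  expect_length(intersect(s$train, s$validation), 0L)
  expect_setequal(c(s$train, s$validation), 1:10)
  expect_identical(s, split_dataset(10, 0.8, seed = 3))
  expect_false(identical(s$train, split_dataset(10, 0.8, seed = 4)$train))
  expect_error(split_dataset(10, 1.2), class = "bbbalert_config_error")
  expect_error(split_dataset(1, 0.8), class = "bbbalert_config_error")
})

test_that("minority oversampling balances classes with exact copies", {
  x <- matrix(seq_len(16), ncol = 4)
  rs <- resample_balanced(x, c(1, 1, 1, 0), seed = 1)
  expect_equal(unname(table(rs$labels)), c(3L, 3L) ,ignore_attr = TRUE)
  expect_equal(as.vector(table(factor(rs$labels, levels = 0:1))), c(3L, 3L))
  # every synthetic row is a copy of an input minority row
  extra <- rs$index[-(1:4)]
  expect_true(all(extra == 4L))
  expect_identical(rs$x[5, ], x[4, ])
  # balanced input unchanged
  rb <- resample_balanced(x, c(0, 0, 1, 1), seed = 1)
  expect_identical(rb$x, x)
  expect_error(resample_balanced(x, c(1, 1, 1, 1)), class = "bbbalert_config_error")
})

test_that("explained-variance curve matches closed-form spectra", {
  # two orthogonal (anti-correlated-free) unit-ish features: eigenvalues
  # are equal, so the curve is (0.5, 1.0) and 2 components reach 95%
  x <- cbind(c(1, 0, 1, 0), c(0, 1, 1, 0))
  ev <- cumulative_explained_variance(x)
  expect_equal(ev$curve, c(0.5, 1.0), tolerance = 1e-12)
  expect_equal(ev$n_components, 2L)
  # one informative feature among constants
  x2 <- cbind(c(1, 0, 1, 0), 1, 1)
  ev2 <- cumulative_explained_variance(x2)
  expect_equal(ev2$n_components, 1L)
  # invariants: nondecreasing, within [0,1], ends at 1
  set.seed(9)
  x3 <- matrix(rbinom(300, 1, 0.3), 30)
  ev3 <- cumulative_explained_variance(x3)
  expect_true(all(diff(ev3$curve) >= -1e-9))
  expect_true(all(ev3$curve >= -1e-9 & ev3$curve <= 1 + 1e-9))
  expect_equal(ev3$curve[length(ev3$curve)], 1, tolerance = 1e-9)
  expect_error(
    cumulative_explained_variance(matrix(1, 4, 3)),
    class = "bbbalert_config_error"
  )
  expect_s3_class(ggplot2::autoplot(ev3), "ggplot")
})
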