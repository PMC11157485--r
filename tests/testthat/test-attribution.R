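make_expl <- function(id, bits, weights, prob = 0.9) {
  bbbalert:::new_bbb_explanation(
    weights = tibble::tibble(bit = as.integer(bits), weight = weights)[
      order(abs(weights), decreasing = TRUE),
    ],
    intercept = 0, local_fit_score = 1,
    predicted_probability = prob, instance_id = id
  )
}

test_that("the sign-sum rule compares positive against negative weight mass", {
  expect_identical(
    classify_by_weight_sums(make_expl("a", 1:3, c(0.3, 0.2, -0.1))),
    "penetrating"
  )
  expect_identical(
    classify_by_weight_sums(make_expl("a", 1:2, c(-0.4, -0.1))),
    "nonpenetrating"
  )
  # exact tie falls to nonpenetrating
  expect_identical(
    classify_by_weight_sums(make_expl("a", 1:2, c(0.2, -0.2))),
    "nonpenetrating"
  )
  expect_error(
    classify_by_weight_sums(make_expl("a", integer(0), numeric(0))),
    class = "bbbalert_config_error"
  )
})

test_that("weight filtering is inclusive at the cut and drops negatives", {
  ex <- make_expl("a", 0:3, c(0.10, 0.099, -0.5, 0.4))
  kept <- filter_weights(ex, 0.1)
  expect_setequal(kept$bit, c(0L, 3L))
  expect_true(all(kept$weight >= 0.1))
  expect_equal(nrow(filter_weights(make_expl("a", 1, -0.2), 0.1)), 0L)
  expect_error(filter_weights(ex, -0.1), class = "bbbalert_config_error")
})

test_that("fragments aggregate additively across molecules", {
  fps <- compute_fingerprints(data.frame(smiles = c("CCOC", "CCOC"), num = c("m1", "m2")),
    id_col = "num"
  )
  # pick a bit carried by exactly one environment of the molecule
  env1 <- fps$env[[1]]
  bits1 <- vapply(env1, function(e) e$bit, integer(1))
  centers1 <- vapply(env1, function(e) length(e$centers), integer(1))
  once <- bits1[centers1 == 1L & !(bits1 %in% bits1[duplicated(bits1)])]
  bit <- once[[1]]
  expl <- list(
    make_expl("m1", bit, 0.2),
    make_expl("m2", bit, 0.2)
  )
  tab <- aggregate_fragments(expl, fps, min_weight = 0.1)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$occurrence_count, 2L)
  expect_equal(tab$total_weight, 0.4)
  calls <- attr(tab, "classifications")
  expect_equal(calls$call, rep("penetrating", 2))
})

test_that("a bit carried by several environments credits each fragment fully", {
  fps <- compute_fingerprints(data.frame(smiles = "c1ccccc1", num = "benz"), id_col = "num")
  env <- fps$env[[1]]
  r1 <- env[vapply(env, function(e) e$radius, integer(1)) == 1L]
  bit <- r1[[1]]$bit # six distinct radius-1 environments, one shared bit
  tab <- aggregate_fragments(list(make_expl("benz", bit, 0.2)), fps, min_weight = 0.1)
  expect_equal(sum(tab$occurrence_count), 6L)
  expect_equal(sum(tab$total_weight), 6 * 0.2, tolerance = 1e-12)
})

test_that("weights are conserved into the table on multiplicity-one fixtures", {
  fps <- compute_fingerprints(data.frame(smiles = "CCOCCl", num = "m1"), id_col = "num")
  env <- fps$env[[1]]
  ones <- Filter(function(e) length(e$centers) == 1L, env)
  bits <- vapply(ones, function(e) e$bit, integer(1))
  bits <- bits[!bits %in% bits[duplicated(bits)]][1:4] # bits with exactly one environment
  wts <- c(0.15, 0.2, 0.25, 0.3)
  tab <- aggregate_fragments(list(make_expl("m1", bits, wts)), fps, min_weight = 0.1)
  expect_equal(sum(tab$total_weight), sum(wts), tolerance = 1e-12)
  expect_equal(sum(tab$occurrence_count), 4L)
})

test_that("retained bits without an environment become unmapped diagnostics", {
  fps <- compute_fingerprints(data.frame(smiles = "CCO", num = "m1"), id_col = "num")
  set_bits <- vapply(fps$env[[1]], function(e) e$bit, integer(1))
  missing_bit <- setdiff(0:1023, set_bits)[1]
  tab <- aggregate_fragments(
    list(make_expl("m1", missing_bit, 0.5)), fps, min_weight = 0.1
  )
  expect_equal(nrow(tab), 0L)
  um <- attr(tab, "unmapped")
  expect_equal(nrow(um), 1L)
  expect_equal(um$bit, missing_bit)
  expect_error(
    aggregate_fragments(list(make_expl("ghost", 1, 0.5)), fps),
    class = "bbbalert_config_error"
  )
})

test_that("raising the filter never increases a fragment's count or weight", {
  fx <- get_small_run()
  i <- fx$candidates[seq_len(min(3, length(fx$candidates)))]
  expl <- lapply(i, function(k) {
    explain_instance(fx$model, fx$xva[k, ], fx$stats,
      explainer_config(n_samples = 500, seed = k),
      instance_id = fx$fps$ids[fx$split$validation[k]]
    )
  })
  lo <- aggregate_fragments(expl, fx$fps, min_weight = 0.02)
  hi <- aggregate_fragments(expl, fx$fps, min_weight = 0.1)
  # a stricter filter can only shrink the table
  expect_gt(nrow(lo), 0L)
  expect_lte(nrow(hi), nrow(lo))
  expect_lte(sum(hi$total_weight), sum(lo$total_weight) + 1e-12)
  expect_true(all(hi$fragment_smiles %in% lo$fragment_smiles))
  for (j in seq_len(nrow(hi))) {
    match_row <- lo[lo$fragment_smiles == hi$fragment_smiles[j], ]
    expect_equal(nrow(match_row), 1L)
    expect_lte(hi$occurrence_count[j], match_row$occurrence_count)
    expect_lte(hi$total_weight[j], match_row$total_weight + 1e-12)
  }
})

test_that("top_fragments ranks by weight with count and SMILES tie-breaks", {
  tab <- tibble::tibble(
    fragment_smiles = c("CC", "CN", "CO", "CF"),
    occurrence_count = c(1L, 5L, 2L, 2L),
    total_weight = c(0.9, 0.5, 0.5, 0.5)
  )
  top <- top_fragments(tab, 10)
  expect_equal(nrow(top), 4L)
  expect_identical(top$fragment_smiles, c("CC", "CN", "CF", "CO"))
  expect_equal(nrow(top_fragments(tab, 2)), 2L)
  expect_error(top_fragments(tab, 0), class = "bbbalert_config_error")
})

test_that("highlight rendering writes one SVG per molecule", {
  fps <- compute_fingerprints(
    data.frame(smiles = c("CCN1CCCC1", "CCO"), num = c("m1", "m2")),
    id_col = "num"
  )
  env1 <- fps$env[[1]]
  ring_env <- env1[vapply(env1, function(e) e$radius, integer(1)) == 2L][[1]]
  frag <- bit_to_fragments(fps, "m1", ring_env$bit)$fragment_smiles[1]
  dir <- tempfile("svg")
  expect_warning(
    out <- render_highlights(fps, c("m1", "m2"), c(frag, "C1CNCCN1"), dir),
    "matched no molecule"
  )
  expect_equal(nrow(out), 2L)
  expect_true(all(file.exists(out$path)))
  expect_gt(out$n_highlighted_atoms[out$molecule == "m1"], 0L)
  expect_equal(out$n_highlighted_atoms[out$molecule == "m2"], 0L)
  svg <- readLines(out$path[1])
  expect_true(any(grepl("<svg", svg)))
})
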