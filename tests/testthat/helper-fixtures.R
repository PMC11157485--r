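# Shared fixtures and independent oracles, all built in code.

# A raw BBBP-dialect table with known injected defects: returns the table
# plus the exact counts a correct curation pass must report.
make_corrupt_table <- function(seed = 1L, n_clean = 30L) {
  base <- generate_library(library_spec(
    n_molecules = n_clean, label_noise = 0, seed = seed
  ))
  # curate once so the clean base is structure-unique and consistently
  # labelled before defects are injected
  clean <- curate(base,
    smiles_col = "smiles", label_col = "label",
    id_col = "record_id", name_col = "name"
  )$records
  rows <- data.frame(
    num = clean$record_id, name = clean$name, p_np = clean$label,
    smiles = clean$smiles, stringsAsFactors = FALSE
  )
  set.seed(seed + 1000L)
  # duplicates (consistent labels): exact copies of existing records
  n_dup <- sample(2:5, 1)
  dup_idx <- sample(nrow(rows), n_dup)
  dup_rows <- rows[dup_idx, ]
  dup_rows$num <- paste0("dup", seq_len(n_dup))
  # conflicting labels: one structure duplicated with the opposite label
  conf_idx <- sample(setdiff(seq_len(nrow(rows)), dup_idx), 1)
  conf_row <- rows[conf_idx, ]
  conf_row$num <- "conflict1"
  conf_row$p_np <- 1 - conf_row$p_np
  # tetravalent neutral nitrogen (repairable) and one hopeless string
  bad_n <- data.frame(
    num = c("badn1", "badn2"), name = c("badn1", "badn2"), p_np = c(1, 0),
    smiles = c("CC[N](C)(C)CC", "CN(C)(C)C"), stringsAsFactors = FALSE
  )
  garbage <- data.frame(
    num = "junk1", name = "junk1", p_np = 1,
    smiles = "C1CC(", stringsAsFactors = FALSE
  )
  tab <- rbind(rows, dup_rows, conf_row, bad_n, garbage)
  tab <- tab[sample(nrow(tab)), ]
  list(
    table = tab,
    n_input = nrow(tab),
    n_nitrogen_fixed = 2L,
    n_unparseable_dropped = 1L,
    n_duplicates_removed = n_dup,
    # the conflicting structure removes both of its records
    n_inconsistent_records_removed = 2L
  )
}

# Linearly separable toy feature set: class decided by one bit, plus noise
# bits.  Any consistent tree ensemble separates it.
make_separable_xy <- function(n = 60L, d = 24L, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rbinom(n * d, 1, 0.3), n, d)
  x[, 1L] <- y
  x[, 2L] <- 1L - y
  list(x = x, y = y)
}

# Independent weighted-least-squares oracle (base lm machinery, a code
# path disjoint from the package's closed-form ridge solver).
wls_oracle <- function(zp, y, w) {
  fit <- stats::lm.wfit(cbind(1, zp), y, w)
  unname(fit$coefficients)
}

# Independent confusion-matrix metric formulas, written straight from the
# definitions.
oracle_metrics <- function(tp, tn, fp, fn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / (tp + tn + fp + fn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(precision = precision, recall = recall, f1 = f1, accuracy = accuracy, mcc = mcc)
}

# Build labels and a deterministic probability vector realizing the given
# confusion counts at threshold 0.5.
realize_confusion <- function(tp, tn, fp, fn) {
  labels <- c(rep(1L, tp), rep(0L, tn), rep(0L, fp), rep(1L, fn))
  probs <- c(rep(0.9, tp), rep(0.1, tn), rep(0.9, fp), rep(0.1, fn))
  list(labels = labels, probs = probs)
}

# Black-box "model" wrapping a fixed per-row probability lookup keyed by
# row identity is impractical; instead tests use plain functions of the
# feature matrix, which predict_proba() accepts directly.

expect_identical_tables <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}

# One small trained end-to-end fixture, built lazily and shared across
# test files (the suite runs in a single session).
.fixture_cache <- new.env(parent = emptyenv())
get_small_run <- function() {
  if (!is.null(.fixture_cache$run)) return(.fixture_cache$run)
  lib <- generate_library(library_spec(n_molecules = 250, seed = 42))
  cur <- curate(lib,
    smiles_col = "smiles", label_col = "label",
    id_col = "record_id", name_col = "name"
  )
  fps <- compute_fingerprints(cur)
  sp <- split_dataset(nrow(fps$matrix), 0.8, seed = 7)
  xtr <- fps$matrix[sp$train, , drop = FALSE]
  ytr <- cur$records$label[sp$train]
  rs <- resample_balanced(xtr, ytr, seed = 3)
  model <- search_and_train_tree(rs$x, rs$labels,
    tree_search_space(kind = "rf", n_search_draws = 3, cv_folds = 3, seed = 5)
  )
  xva <- fps$matrix[sp$validation, , drop = FALSE]
  yva <- cur$records$label[sp$validation]
  cand <- select_confident_positives(model, xva, yva, 0.8)
  if (length(cand) == 0L) { # fall back to the most confident true positive
    probs <- predict_proba(model, xva)
    pos <- which(yva == 1L)
    cand <- pos[which.max(probs[pos])]
  }
  .fixture_cache$run <- list(
    lib = lib, cur = cur, fps = fps, split = sp,
    stats = fit_training_stats(rs$x), model = model,
    xva = xva, yva = yva, candidates = cand
  )
  .fixture_cache$run
}
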