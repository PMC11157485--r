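# One seeded, configured, logged run of the whole analysis:
# curate -> fingerprint -> split -> (resample) -> train -> evaluate ->
# explain confident positives -> aggregate fragments.  A single global
# seed fans out to stable per-stage seeds, so a rerun with the same
# configuration reproduces every deterministic artifact bit for bit.

#' Pipeline configuration
#'
#' @param input Path to a BBBP-dialect CSV, or a data frame of records.
#'   Exactly one of `input` and `synthetic` must be given.
#' @param synthetic A [library_spec()] for a generated library.
#' @param model `"rf"`, `"et"` or `"drn"`.
#' @param fp A [fp_config()].
#' @param train_fraction Train share of the random split (default 0.8).
#' @param imbalance How to counter class imbalance during training:
#'   `"oversample"` (default) duplicates minority training rows to
#'   balance; `"weights"` passes inverse-frequency class weights to the
#'   tree ensemble instead; `"none"` does neither.  Validation data is
#'   never touched.
#' @param resample Deprecated alias: `FALSE` maps to
#'   `imbalance = "none"`.
#' @param n_search_draws,cv_folds Hyperparameter-search budget.
#' @param explainer An [explainer_config()] (its seed is overridden by a
#'   per-molecule derived seed).
#' @param attribution An [attribution_config()].
#' @param max_explained Cap on the number of confident positives explained
#'   per run (highest predicted probability first; default 50).
#' @param seed Global integer seed.
#' @param out_dir Optional output directory for artifacts.
#' @return A `bbb_pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            model = c("rf", "et", "drn"),
                            fp = fp_config(), train_fraction = 0.8,
                            imbalance = c("oversample", "weights", "none"),
                            resample = TRUE, n_search_draws = 20L,
                            cv_folds = 5L,
                            explainer = explainer_config(),
                            attribution = attribution_config(),
                            max_explained = 50L, seed = 1L, out_dir = NULL) {
  model <- match.arg(model)
  imbalance <- match.arg(imbalance)
  if (isFALSE(resample) && imbalance == "oversample") imbalance <- "none"
  if (is.null(input) == is.null(synthetic)) {
    stop_config("pipeline_config(): give exactly one of 'input' or 'synthetic'")
  }
  if (!is.null(input) && is.character(input) && !file.exists(input)) {
    stop_config("pipeline_config(): input file '%s' does not exist", input)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "bbb_library_spec"))
  structure(list(
    input = input, synthetic = synthetic, model = model, fp = fp,
    train_fraction = train_fraction, imbalance = imbalance,
    n_search_draws = as.integer(n_search_draws), cv_folds = as.integer(cv_folds),
    explainer = explainer, attribution = attribution,
    max_explained = as.integer(max_explained),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "bbb_pipeline_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", hash_ints(utf8ToInt(as.character(json))))
}

#' Run the full explanation pipeline
#'
#' Executes every stage in order on one dataset with one model backend.
#' Any stage failure aborts with an error naming the stage.  With the same
#' configuration and seed, reruns reproduce all artifacts (tree backends).
#'
#' @param config A [pipeline_config()].
#' @return A `bbb_run` report: curation report, best hyperparameters,
#'   train/validation metrics, the attribution table, per-stage log, the
#'   configuration echo and its content hash.  When `config$out_dir` is
#'   set, artifacts (curated CSV, metrics JSON, attribution CSV, run log,
#'   JSON report) are written there via [write_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bbb_pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- sprintf("[%s] %s", stage, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = "bbbalert_stage_error"
      )
    })
  }

  raw <- stage("load", {
    if (!is.null(config$synthetic)) {
      spec <- config$synthetic
      spec$seed <- derive_seed(config$seed, "simulate")
      generate_library(spec)
    } else if (is.character(config$input)) {
      read_bbbp_csv(config$input)
    } else {
      tibble::as_tibble(config$input)
    }
  })
  note("load", "n_input=%d", nrow(raw))

  curated <- stage("curate", {
    if (!is.null(config$synthetic)) {
      curate(raw, smiles_col = "smiles", label_col = "label",
        id_col = "record_id", name_col = "name"
      )
    } else {
      curate(raw)
    }
  })
  note("curate", "n_in=%d n_out=%d", curated$report$n_input, curated$report$n_output)

  fps <- stage("featurize", compute_fingerprints(curated, config$fp))
  note("featurize", "n=%d bits=%d", nrow(fps$matrix), ncol(fps$matrix))

  split <- stage("split", split_dataset(
    nrow(fps$matrix), config$train_fraction, derive_seed(config$seed, "split")
  ))
  note("split", "train=%d validation=%d", length(split$train), length(split$validation))

  xtr <- fps$matrix[split$train, , drop = FALSE]
  ytr <- curated$records$label[split$train]
  xva <- fps$matrix[split$validation, , drop = FALSE]
  yva <- curated$records$label[split$validation]

  class_weights <- NULL
  if (config$imbalance == "oversample") {
    rs <- stage("resample", resample_balanced(xtr, ytr, derive_seed(config$seed, "resample")))
    xtr_fit <- rs$x; ytr_fit <- rs$labels
    note("resample", "n_in=%d n_out=%d", length(ytr), length(ytr_fit))
  } else {
    xtr_fit <- xtr; ytr_fit <- ytr
    if (config$imbalance == "weights") {
      tab <- table(factor(ytr, levels = c(0L, 1L)))
      class_weights <- stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
      note("resample", "class_weights 0=%.3f 1=%.3f", class_weights[["0"]], class_weights[["1"]])
    }
  }

  model <- stage("train", {
    if (config$model == "drn") {
      train_residual_network(xtr_fit, ytr_fit, drn_search_space(
        n_search_draws = config$n_search_draws, cv_folds = config$cv_folds,
        seed = derive_seed(config$seed, "train")
      ))
    } else {
      search_and_train_tree(xtr_fit, ytr_fit, tree_search_space(
        kind = config$model, n_search_draws = config$n_search_draws,
        cv_folds = config$cv_folds, seed = derive_seed(config$seed, "train")
      ), class_weights = class_weights)
    }
  })
  note("train", "model=%s params=%s", config$model,
    paste(names(model$best_params), unlist(model$best_params), sep = "=", collapse = " ")
  )

  metrics <- stage("evaluate", list(
    training = evaluate(model, xtr, ytr),
    validation = evaluate(model, xva, yva)
  ))
  note("evaluate", "validation ROC-AUC=%.3f MCC=%.3f",
    metrics$validation$roc_auc, metrics$validation$mcc
  )

  stats <- fit_training_stats(xtr_fit)
  candidates <- stage("select", select_confident_positives(
    model, xva, yva, config$attribution$prob_threshold
  ))
  n_confident <- length(candidates)
  if (n_confident > config$max_explained) {
    probs <- predict_proba(model, xva[candidates, , drop = FALSE])
    candidates <- candidates[order(probs, decreasing = TRUE)][seq_len(config$max_explained)]
  }
  note("select", "confident_positives=%d explained=%d", n_confident, length(candidates))

  explanations <- stage("explain", {
    lapply(candidates, function(i) {
      id <- fps$ids[split$validation[i]]
      cfg <- config$explainer
      cfg$seed <- derive_seed(config$seed, paste0("explain_", id))
      explain_instance(model, xva[i, ], stats, cfg, instance_id = id)
    })
  })
  note("explain", "n_explained=%d", length(explanations))

  attribution <- stage("attribute", aggregate_fragments(
    explanations, fps, config$attribution$min_weight
  ))
  note("attribute", "n_fragments=%d", nrow(attribution))

  run <- structure(list(
    config = config, config_hash = config_hash(config),
    curation = curated$report,
    best_params = model$best_params,
    metrics = metrics,
    split = split,
    model = model,
    fingerprints = fps,
    curated = curated,
    explanations = explanations,
    attribution = attribution,
    top = top_fragments(attribution, config$attribution$top_n),
    log = unlist(log),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "bbb_run")
  if (!is.null(config$out_dir)) run <- write_report(run, config$out_dir)
  run
}

#' Write run artifacts and a machine-readable report
#'
#' @param run A `bbb_run` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The run, with `$paths` recording every artifact written.
#' @export
write_report <- function(run, dir) {
  stopifnot(inherits(run, "bbb_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    curated_csv = file.path(dir, "curated.csv"),
    curation_report = file.path(dir, "curation_report.json"),
    metrics = file.path(dir, "metrics.json"),
    attribution_csv = file.path(dir, "attribution.csv"),
    log = file.path(dir, "run.log"),
    report = file.path(dir, "report.json"),
    summary = file.path(dir, "summary.txt")
  )
  write_curated(run$curated, paths$curated_csv, paths$curation_report)
  jsonlite::write_json(
    list(
      training = unclass(glance(run$metrics$training)),
      validation = unclass(glance(run$metrics$validation)),
      confusion_validation = run$metrics$validation$confusion
    ),
    paths$metrics, auto_unbox = FALSE, digits = NA
  )
  write.csv(as.data.frame(run$attribution), paths$attribution_csv, row.names = FALSE)
  writeLines(run$log, paths$log)
  jsonlite::write_json(list(
    config_hash = run$config_hash,
    seed = run$config$seed,
    model = run$config$model,
    curation = run$curation,
    best_params = run$best_params,
    validation = unclass(glance(run$metrics$validation)),
    n_explained = length(run$explanations),
    classifications = attr(run$attribution, "classifications"),
    unmapped_bits = attr(run$attribution, "unmapped"),
    artifacts = lapply(paths, normalizePath, mustWork = FALSE),
    timestamp = run$timestamp
  ), paths$report, auto_unbox = TRUE, digits = NA)
  top <- run$top
  writeLines(c(
    sprintf("bbbalert run %s (model %s, seed %d)", run$config_hash,
      run$config$model, run$config$seed
    ),
    sprintf("validation ROC-AUC %.3f, MCC %.3f",
      run$metrics$validation$roc_auc, run$metrics$validation$mcc
    ),
    sprintf("%d explained molecules, %d fragments", length(run$explanations),
      nrow(run$attribution)
    ),
    "top fragments:",
    sprintf(
      "  %-30s count %3d  total weight %8.3f",
      top$fragment_smiles, top$occurrence_count, top$total_weight
    )
  ), paths$summary)
  run$paths <- paths
  run
}

#' @export
print.bbb_run <- function(x, ...) {
  cat(sprintf(
    "<bbb_run> %s model, seed %d, hash %s\n", x$config$model, x$config$seed,
    x$config_hash
  ))
  cat(sprintf(
    "  validation: ROC-AUC %.3f | MCC %.3f | accuracy %.3f\n",
    x$metrics$validation$roc_auc, x$metrics$validation$mcc,
    x$metrics$validation$accuracy
  ))
  cat(sprintf(
    "  %d explained molecules -> %d fragments\n",
    length(x$explanations), nrow(x$attribution)
  ))
  print(head(x$top, 5))
  invisible(x)
}

#' Planted-alert recovery study
#'
#' Runs the full pipeline once per seed on a synthetic library with a
#' planted alert and checks, for each run, whether the planted fragment
#' (or a super-fragment containing it, by substructure match) appears
#' among the top-ranked rows of the attribution table.
#'
#' @param seeds Integer vector of global pipeline seeds (one run each).
#' @param spec The [library_spec()] shared by all runs (per-run randomness
#'   comes from the pipeline seed).
#' @param model,n_search_draws,max_explained,n_samples Pipeline settings
#'   for the study runs (see [pipeline_config()]).
#' @param top_n How deep into the ranked table to look (default 3).
#' @return A tibble with one row per seed: `recovered`, the validation
#'   ROC-AUC and MCC, the fragment count, and the top fragment.
#' @export
alert_recovery_study <- function(seeds, spec = library_spec(), model = "rf",
                                 n_search_draws = 4L, max_explained = 8L,
                                 n_samples = 2000L, top_n = 3L) {
  purrr::map_dfr(seeds, function(s) {
    cfg <- pipeline_config(
      synthetic = spec, model = model, n_search_draws = n_search_draws,
      cv_folds = 5L, max_explained = max_explained,
      explainer = explainer_config(n_samples = n_samples), seed = s
    )
    run <- run_pipeline(cfg)
    top <- top_fragments(run$attribution, top_n)
    hit <- nrow(top) > 0L && any(vapply(spec$alert_fragments, function(al) {
      any(smarts_match_counts(top$fragment_smiles, al) > 0L)
    }, logical(1)))
    tibble::tibble(
      seed = s, recovered = hit,
      validation_roc_auc = run$metrics$validation$roc_auc,
      validation_mcc = run$metrics$validation$mcc,
      n_fragments = nrow(run$attribution),
      top_fragment = if (nrow(top) > 0L) top$fragment_smiles[[1L]] else NA_character_
    )
  })
}

#' @rdname run_pipeline
#' @param x A `bbb_run`.
#' @param ... Unused.
#' @export
tidy.bbb_run <- function(x, ...) tibble::as_tibble(x$attribution)

#' @rdname run_pipeline
#' @export
glance.bbb_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      model = x$config$model, seed = x$config$seed,
      n_curated = x$curation$n_output, n_explained = length(x$explanations),
      n_fragments = nrow(x$attribution)
    ),
    glance(x$metrics$validation)
  )
}
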