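# Folded binary extended-connectivity (circular, Morgan-style) fingerprints
# with a per-bit atom-environment registry.  The registry is the bridge from
# model features back to chemistry: every set bit knows which circular atom
# environments (center atom + radius) produced it, and each environment can
# be rendered as a substructure SMILES.

.ATOMIC_NUMBER <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Na = 11L, Si = 14L,
  P = 15L, S = 16L, Cl = 17L, K = 19L, Ca = 20L, As = 33L, Se = 34L,
  Br = 35L, I = 53L, Li = 3L
)

#' Fingerprint configuration
#'
#' @param n_bits Folded fingerprint length (default 1024).
#' @param radius Maximum circular-environment radius in bond hops
#'   (default 2, the ECFP4 convention).
#' @return A `bbb_fp_config` list.
#' @export
fp_config <- function(n_bits = 1024L, radius = 2L) {
  n_bits <- as.integer(n_bits); radius <- as.integer(radius)
  if (is.na(n_bits) || n_bits < 2L) stop_config("fp_config(): n_bits must be >= 2")
  if (is.na(radius) || radius < 0L) stop_config("fp_config(): radius must be >= 0")
  structure(list(n_bits = n_bits, radius = radius), class = "bbb_fp_config")
}

# Circular environments of one molecule.  Returns a list of environment
# records: bit, id (unfolded), radius, centers (atom indices sharing the
# same bond set), atoms (atom set of the environment).  Environments with
# identical bond sets are merged (first occurrence wins, extra centers are
# appended); an environment that stops growing contributes nothing new.
ecfp_environments <- function(g, n_bits, radius) {
  if (g$n == 0L) return(list())
  z <- .ATOMIC_NUMBER[g$elem]
  z[is.na(z)] <- 0L
  ids <- vapply(seq_len(g$n), function(a) {
    hash_ints(c(
      z[a], length(g$adj[[a]]),
      if (is.na(g$nH[a])) 0L else g$nH[a],
      g$charge[a] + 8L, as.integer(g$arom[a]),
      as.integer(any(g$bond_ring[g$badj[[a]]]))
    ))
  }, integer(1))
  envs <- list()
  by_bondset <- new.env(parent = emptyenv())
  for (a in seq_len(g$n)) {
    envs[[length(envs) + 1L]] <- list(
      bit = ids[a] %% n_bits, id = ids[a], radius = 0L, centers = a, atoms = a
    )
  }
  # one BFS per atom to the maximum radius; per-radius atom and bond sets
  # are then slices of the same distance vector
  dists <- lapply(seq_len(g$n), function(a) bfs_within(g, a, radius))
  n_prev_bonds <- rep(-1L, g$n)
  ids_prev <- ids
  r <- 1L
  while (r <= radius) {
    ids_new <- ids_prev
    round_envs <- list()
    for (a in seq_len(g$n)) {
      nb <- g$adj[[a]]
      if (length(nb) == 0L) next
      bk <- g$badj[[a]]
      codes <- ifelse(g$bond_arom[bk], 4L, g$bond_order[bk])
      o <- order(codes, ids_prev[nb])
      id <- hash_ints(c(r, ids_prev[a], rbind(codes[o], ids_prev[nb][o])))
      ids_new[a] <- id
      d <- dists[[a]]
      da <- d[g$bond_a]; db <- d[g$bond_b]
      bset <- which(!is.na(da) & !is.na(db) & da <= r & db <= r & pmin(da, db) <= r - 1L)
      if (length(bset) == n_prev_bonds[a]) next # no growth: dead end
      round_envs[[length(round_envs) + 1L]] <- list(
        atom = a, id = id, bonds = bset,
        atoms = which(!is.na(d) & d <= r)
      )
      n_prev_bonds[a] <- length(bset)
    }
    for (e in round_envs) {
      key <- paste(e$bonds, collapse = ",")
      hit <- get0(key, envir = by_bondset, inherits = FALSE)
      if (is.null(hit)) {
        envs[[length(envs) + 1L]] <- list(
          bit = e$id %% n_bits, id = e$id, radius = r,
          centers = e$atom, atoms = e$atoms
        )
        assign(key, length(envs), envir = by_bondset)
      } else {
        envs[[hit]]$centers <- c(envs[[hit]]$centers, e$atom)
      }
    }
    ids_prev <- ids_new
    r <- r + 1L
  }
  envs
}

#' Compute circular fingerprints with an atom-environment registry
#'
#' Hashes all circular atom environments of radius `0..radius` and folds
#' them into an `n_bits`-long binary vector per molecule.  Alongside the
#' matrix, a registry records for every set bit the environments (center
#' atom, radius, atom set) that produced it, so bits can later be resolved
#' back to substructures with [bit_to_fragments()].  Fingerprinting is a
#' pure function of the SMILES and the configuration.
#'
#' @param dataset A `bbb_curated` object or a data frame with a SMILES
#'   column; all SMILES must parse.
#' @param config A [fp_config()].
#' @param smiles_col,id_col Column names used when `dataset` is a plain
#'   data frame (an `id_col` absent from the data falls back to row order).
#' @return A `bbb_fingerprints` object: `$matrix` (binary integer matrix,
#'   rows named by molecule id), `$env` (per-molecule environment registry),
#'   `$graphs` (parsed molecular graphs), `$ids`, `$config`.
#' @examples
#' fps <- compute_fingerprints(data.frame(smiles = c("CCO", "c1ccccc1")))
#' dim(fps$matrix)
#' @export
compute_fingerprints <- function(dataset, config = fp_config(),
                                 smiles_col = "smiles", id_col = "record_id") {
  graphs <- NULL
  if (inherits(dataset, "bbb_curated")) {
    if (!is.null(dataset$graphs) && length(dataset$graphs) == nrow(dataset$records)) {
      graphs <- dataset$graphs # parsed once during curation
    }
    dataset <- dataset$records
  }
  dataset <- tibble::as_tibble(dataset)
  if (smiles_col %notin% names(dataset)) {
    stop_config("compute_fingerprints(): no '%s' column", smiles_col)
  }
  smiles <- as.character(dataset[[smiles_col]])
  ids <- if (id_col %in% names(dataset)) {
    as.character(dataset[[id_col]])
  } else {
    as.character(seq_along(smiles))
  }
  if (is.null(graphs)) graphs <- parse_mol_graphs(smiles)
  bad <- which(vapply(graphs, is.null, logical(1)))
  if (length(bad) > 0L) {
    stop_config(
      "compute_fingerprints(): unparseable SMILES for record(s) %s",
      paste(head(ids[bad], 5L), collapse = ", ")
    )
  }
  n <- length(smiles)
  mat <- matrix(0L, nrow = n, ncol = config$n_bits, dimnames = list(ids, NULL))
  env <- vector("list", n)
  for (i in seq_len(n)) {
    es <- ecfp_environments(graphs[[i]], config$n_bits, config$radius)
    if (length(es) > 0L) {
      mat[i, vapply(es, function(e) e$bit, integer(1)) + 1L] <- 1L
    }
    env[[i]] <- es
  }
  names(env) <- ids
  names(graphs) <- ids
  structure(
    list(matrix = mat, env = env, graphs = graphs, ids = ids, config = config),
    class = "bbb_fingerprints"
  )
}

#' @export
print.bbb_fingerprints <- function(x, ...) {
  cat(sprintf(
    "<bbb_fingerprints> %d molecules x %d bits (radius %d), density %.3f\n",
    nrow(x$matrix), ncol(x$matrix), x$config$radius, mean(x$matrix)
  ))
  invisible(x)
}

#' Resolve a fingerprint bit to its substructure fragments
#'
#' Looks up every distinct circular environment of `molecule` that set
#' `bit` (a bit can be set by several environments when hashed ids collide
#' under folding) and extracts each as the submolecule induced by the atoms
#' within the environment radius of its center atom.  Fragment SMILES are
#' canonicalized so identical chemistry aggregates across molecules.
#'
#' @param fps A `bbb_fingerprints` object.
#' @param molecule Molecule id (rowname) or row index.
#' @param bit Bit index, 0-based (as reported in explanations).
#' @return A tibble with columns `fragment_smiles`, `center_atom`,
#'   `radius`, `n_centers`, `atoms` (list column of parent atom indices);
#'   zero rows when the bit is not set for the molecule.
#' @export
bit_to_fragments <- function(fps, molecule, bit) {
  stopifnot(inherits(fps, "bbb_fingerprints"))
  i <- if (is.character(molecule)) match(molecule, fps$ids) else as.integer(molecule)
  if (is.na(i) || i < 1L || i > length(fps$ids)) {
    stop_config("bit_to_fragments(): unknown molecule '%s'", as.character(molecule))
  }
  es <- fps$env[[i]]
  es <- es[vapply(es, function(e) e$bit == bit, logical(1))]
  if (length(es) == 0L) {
    return(tibble::tibble(
      fragment_smiles = character(0), center_atom = integer(0),
      radius = integer(0), n_centers = integer(0), atoms = list()
    ))
  }
  g <- fps$graphs[[i]]
  raw <- vapply(es, function(e) {
    write_fragment_smiles(induced_subgraph(g, e$atoms))
  }, character(1))
  tibble::tibble(
    fragment_smiles = canonical_fragment_keys(raw),
    center_atom = vapply(es, function(e) e$centers[[1L]], integer(1)),
    radius = vapply(es, function(e) e$radius, integer(1)),
    n_centers = vapply(es, function(e) length(e$centers), integer(1)),
    atoms = lapply(es, function(e) e$atoms)
  )
}

#' Serialize fingerprints and the environment registry
#'
#' Writes the binary matrix as a compressed R array (`matrix.rds`), the
#' molecule-id index as plain text, and the per-bit environment registry
#' (with canonical fragment SMILES) as JSON.
#'
#' @param fps A `bbb_fingerprints` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fingerprints <- function(fps, dir) {
  stopifnot(inherits(fps, "bbb_fingerprints"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(fps$matrix, file.path(dir, "matrix.rds"), compress = "gzip")
  writeLines(fps$ids, file.path(dir, "molecule_ids.txt"))
  env_json <- lapply(seq_along(fps$ids), function(i) {
    g <- fps$graphs[[i]]
    lapply(fps$env[[i]], function(e) {
      list(
        bit = e$bit, radius = e$radius, centers = e$centers,
        fragment_smiles = canonical_fragment_keys(
          write_fragment_smiles(induced_subgraph(g, e$atoms))
        )
      )
    })
  })
  names(env_json) <- fps$ids
  jsonlite::write_json(
    list(config = unclass(fps$config), environments = env_json),
    file.path(dir, "environment_map.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}

#' Random train/validation split
#'
#' Uniform random 80/20-style split by permutation under a fixed seed; no
#' stratification (class balance is handled downstream by resampling).
#'
#' @param n Number of records, or an object with rows.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed; the split is reproducible.
#' @return A `bbb_split` list with `train`, `validation` index vectors.
#' @export
split_dataset <- function(n, train_fraction = 0.8, seed = 1L) {
  if (inherits(n, "bbb_curated")) n <- nrow(n$records)
  if (inherits(n, "bbb_fingerprints")) n <- nrow(n$matrix)
  if (is.data.frame(n) || is.matrix(n)) n <- nrow(n)
  n <- as.integer(n)
  if (n < 2L) stop_config("split_dataset(): need at least 2 records")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_config("split_dataset(): train_fraction must lie in (0, 1)")
  }
  n_train <- as.integer(round(train_fraction * n))
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- with_seed(seed, sample.int(n))
  structure(list(
    train = sort(perm[seq_len(n_train)]),
    validation = sort(perm[(n_train + 1L):n]),
    train_fraction = train_fraction, seed = as.integer(seed)
  ), class = "bbb_split")
}

#' Oversample the minority class to balance a training set
#'
#' Randomly duplicates minority-class rows (with replacement) until both
#' classes have equal counts.  Only ever applied to training data.
#'
#' @param x Feature matrix (rows are samples).
#' @param labels Binary 0/1 labels aligned to rows of `x`.
#' @param seed Integer seed.
#' @return A list with `x`, `labels`, and `index` (source row of every
#'   output row; synthetic rows are exact copies of input rows).
#' @export
resample_balanced <- function(x, labels, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(nrow(x) == length(labels))
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab == 0L)) stop_config("resample_balanced(): both classes must be present")
  if (tab[[1L]] == tab[[2L]]) {
    return(list(x = x, labels = labels, index = seq_along(labels)))
  }
  minority <- as.integer(names(tab)[which.min(tab)])
  n_extra <- abs(tab[[1L]] - tab[[2L]])
  pool <- which(labels == minority)
  extra <- pool[with_seed(seed, sample.int(length(pool), n_extra, replace = TRUE))]
  index <- c(seq_along(labels), extra)
  list(x = x[index, , drop = FALSE], labels = labels[index], index = index)
}

#' Cumulative explained variance of the fingerprint matrix
#'
#' Principal-component spectrum of the column-centered binary matrix: how
#' many components are needed to cover a given fraction (default 95%) of
#' the total variance, an audit of the effective dimensionality of the
#' folded fingerprint.
#'
#' @param x A `bbb_fingerprints` object or a numeric matrix with at least
#'   two rows.
#' @param threshold Cumulative-variance threshold in (0, 1].
#' @return A `bbb_evr` list: `curve` (nondecreasing cumulative proportions,
#'   ending at 1), `n_components` (smallest count reaching `threshold`),
#'   `threshold`.
#' @export
cumulative_explained_variance <- function(x, threshold = 0.95) {
  if (inherits(x, "bbb_fingerprints")) x <- x$matrix
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_config("cumulative_explained_variance(): need >= 2 rows")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop_config("cumulative_explained_variance(): threshold must lie in (0, 1]")
  }
  vars <- apply(x, 2L, stats::var)
  if (all(vars < .Machine$double.eps)) {
    stop_config("cumulative_explained_variance(): matrix has zero total variance")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  curve <- cumsum(ev) / sum(ev)
  curve[length(curve)] <- 1 # guard against last-ulp drift
  structure(list(
    curve = curve,
    n_components = which(curve >= threshold)[1L],
    threshold = threshold
  ), class = "bbb_evr")
}

#' @export
print.bbb_evr <- function(x, ...) {
  cat(sprintf(
    "<bbb_evr> %d components reach %.0f%% cumulative explained variance (of %d)\n",
    x$n_components, 100 * x$threshold, length(x$curve)
  ))
  invisible(x)
}

#' @rdname cumulative_explained_variance
#' @param object A `bbb_evr` object.
#' @param ... Unused.
#' @export
autoplot.bbb_evr <- function(object, ...) {
  df <- tibble::tibble(
    component = seq_along(object$curve),
    cumulative = object$curve
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$cumulative)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(xintercept = object$n_components, linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "principal component", y = "cumulative explained variance",
      title = sprintf("%d components cover %.0f%%", object$n_components, 100 * object$threshold)
    )
}
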