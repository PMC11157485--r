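#' Repair neutral tetravalent nitrogen atoms in SMILES strings
#'
#' A nitrogen written with four bonds must carry a +1 formal charge to be
#' valid chemistry; several public BBB permeability records write it
#' uncharged, which strict SMILES parsers reject.  This adds the missing
#' charge (bond-order sum of exactly 4 on a neutral N) and leaves every
#' other atom untouched.  Strings with no such nitrogen are returned
#' verbatim; strings OpenBabel cannot read at all are also returned
#' verbatim so that downstream curation can count them as unparseable.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of the same length; repaired entries are
#'   rewritten in canonical form, all others are returned unchanged.
#' @examples
#' fix_tetravalent_nitrogen(c("CN(C)(C)C", "CCO"))
#' @export
fix_tetravalent_nitrogen <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- smiles
  graphs <- parse_mol_graphs(smiles)
  needs <- vapply(graphs, function(g) {
    !is.null(g) && any(g$elem == "N" & g$charge == 0L & g$order_sum == 4L)
  }, logical(1))
  if (!any(needs)) return(out)
  fixed <- lapply(which(needs), function(i) {
    g <- graphs[[i]]
    g$charge[g$elem == "N" & g$charge == 0L & g$order_sum == 4L] <- 1L
    g
  })
  rewritten <- graphs_to_smiles_batch(fixed)
  ok <- !is.na(rewritten)
  out[which(needs)[ok]] <- rewritten[ok]
  out
}

# Single-atom counter-ions stripped before keying (canonical forms).
.COUNTER_IONS <- c("[Na+]", "[K+]", "[Li+]", "[Cl-]", "[Br-]", "[I-]", "[F-]")

#' Canonical structure key for duplicate detection
#'
#' Maps a SMILES string to a canonical key such that (a) the protonated
#' carboxylic acid, its carboxylate anion and its simple alkali/halide salt
#' all share one key (the neutral acid form, the physiologically sensible
#' representation), and (b) any two spellings of the same molecule share
#' one key.  The key is the OpenBabel canonical SMILES of the largest
#' organic component after stripping single-atom counter-ions
#' (Na+, K+, Li+, Cl-, Br-, I-, F-) and neutralizing carboxylate oxygens.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict If `TRUE` (default), unparseable input is an error; if
#'   `FALSE`, it yields `NA` so callers can count failures.
#' @return Character vector of canonical keys.
#' @examples
#' canonical_key(c("CC(=O)O", "CC(=O)[O-]", "CC(=O)[O-].[Na+]"))
#' @export
canonical_key <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0L) return(character(0))
  graphs <- parse_mol_graphs(smiles)
  bad <- vapply(graphs, is.null, logical(1))
  if (strict && any(bad)) {
    stop_config(
      "canonical_key(): unparseable SMILES at position(s) %s",
      paste(utils::head(which(bad), 5L), collapse = ", ")
    )
  }
  # fast path: single-component, no negative charge -> plain canonicalization
  needs_surgery <- vapply(graphs, function(g) {
    if (is.null(g)) return(FALSE)
    any(g$charge < 0L) || max(graph_components(g)) > 1L
  }, logical(1))
  keys <- rep(NA_character_, n)
  plain <- which(!bad & !needs_surgery)
  if (length(plain) > 0L) keys[plain] <- ob_canonical(smiles[plain])
  surg <- which(needs_surgery)
  if (length(surg) > 0L) {
    pruned <- lapply(surg, function(i) prune_to_parent(graphs[[i]]))
    keys[surg] <- graphs_to_smiles_batch(pruned)
  }
  keys
}

# Largest organic component with carboxylates neutralized: the "parent"
# structure used as the deduplication key.
prune_to_parent <- function(g) {
  comp <- graph_components(g)
  sizes <- tabulate(comp)
  drop_comp <- integer(0)
  if (max(comp) > 1L) {
    # strip single-atom counter ions, then keep the largest component
    # (ties: first), preferring carbon-containing components
    for (ci in seq_len(max(comp))) {
      atoms <- which(comp == ci)
      if (length(atoms) == 1L &&
        paste0("[", g$elem[atoms],
          if (g$charge[atoms] > 0L) "+" else if (g$charge[atoms] < 0L) "-" else "",
          "]"
        ) %in% .COUNTER_IONS) {
        drop_comp <- c(drop_comp, ci)
      }
    }
    remaining <- setdiff(seq_len(max(comp)), drop_comp)
    has_c <- vapply(remaining, function(ci) any(g$elem[comp == ci] == "C"), logical(1))
    pool <- if (any(has_c)) remaining[has_c] else remaining
    keep <- pool[which.max(sizes[pool])]
  } else {
    keep <- 1L
  }
  atoms <- which(comp == keep)
  sub <- induced_subgraph(g, atoms)
  sub$x <- g$x[atoms]; sub$y <- g$y[atoms]
  # neutralize carboxylate: O(-) singly bonded to a C that carries C=O
  for (a in which(sub$elem == "O" & sub$charge == -1L & lengths(sub$adj) == 1L)) {
    cb <- sub$adj[[a]][1L]
    if (sub$elem[cb] != "C") next
    has_carbonyl <- any(vapply(seq_along(sub$badj[[cb]]), function(j) {
      k <- sub$badj[[cb]][j]
      other <- if (sub$bond_a[k] == cb) sub$bond_b[k] else sub$bond_a[k]
      sub$bond_order[k] == 2L && sub$elem[other] == "O"
    }, logical(1)))
    if (has_carbonyl) sub$charge[a] <- 0L
  }
  sub
}

#' Group records by canonical key and resolve duplicates
#'
#' Records sharing a canonical structure key are collapsed: a group with a
#' single label keeps its first occurrence (file order) and the rest count
#' as duplicates; a group whose members disagree on the label is removed
#' entirely and counted as inconsistent, mirroring how conflicting
#' penetrant/non-penetrant annotations of one compound are handled.
#'
#' @param records A data frame with columns `record_id`, `name`, `smiles`,
#'   `label` and `key` (see [canonical_key()]).
#' @return A `bbb_curated` object: `$records` (tibble, deduplicated, file
#'   order) and `$report` (named list of curation counts).
#' @export
deduplicate <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("record_id", "name", "smiles", "label", "key")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L) {
    stop_config("deduplicate(): missing column(s): %s", paste(missing, collapse = ", "))
  }
  n <- nrow(records)
  if (n == 0L) {
    return(new_bbb_curated(records, list(
      n_input = 0L, n_nitrogen_fixed = 0L, n_unparseable_dropped = 0L,
      n_duplicates_removed = 0L, n_triplicate_groups = 0L,
      n_inconsistent_records_removed = 0L, n_output = 0L
    )))
  }
  records$.row <- seq_len(n)
  grp <- split(records, records$key)
  keep_rows <- integer(0)
  n_dup <- 0L
  n_tri <- 0L
  n_inc <- 0L
  for (gdf in grp) {
    if (length(unique(gdf$label)) > 1L) {
      n_inc <- n_inc + nrow(gdf)
    } else {
      keep_rows <- c(keep_rows, gdf$.row[1L])
      n_dup <- n_dup + nrow(gdf) - 1L
      if (nrow(gdf) >= 3L) n_tri <- n_tri + 1L
    }
  }
  keep_rows <- sort(keep_rows)
  out <- records[keep_rows, setdiff(names(records), ".row")]
  res <- new_bbb_curated(out, list(
    n_input = n, n_nitrogen_fixed = 0L, n_unparseable_dropped = 0L,
    n_duplicates_removed = n_dup, n_triplicate_groups = n_tri,
    n_inconsistent_records_removed = n_inc, n_output = nrow(out)
  ))
  res$kept_rows <- keep_rows
  res
}

new_bbb_curated <- function(records, report) {
  structure(list(records = tibble::as_tibble(records), report = report),
    class = "bbb_curated"
  )
}

#' Curate a labelled SMILES table
#'
#' Full curation pass over a BBBP-dialect molecule table: repair neutral
#' tetravalent nitrogens, drop records that remain unparseable or
#' valence-invalid, assign canonical structure keys, and collapse
#' duplicate / inconsistently labelled structures.  The operation is
#' deterministic and idempotent: curating an already-curated table changes
#' nothing.
#'
#' @param table Data frame of raw records, or a `bbb_curated` object.
#' @param smiles_col,label_col,id_col,name_col Column names in `table`
#'   (defaults follow the BBBP CSV dialect: `smiles`, `p_np`, `num`, `name`).
#' @return A `bbb_curated` object with `$records` (tibble with columns
#'   `record_id`, `name`, `smiles`, `label`, `key`) and `$report` (named
#'   list of counts; see Details).
#' @details The report fields satisfy the conservation identity
#'   `n_output = n_input - n_unparseable_dropped - n_duplicates_removed -
#'   n_inconsistent_records_removed`.  `n_nitrogen_fixed` counts records
#'   whose SMILES was rewritten by [fix_tetravalent_nitrogen()];
#'   `n_triplicate_groups` counts label-consistent key groups of three or
#'   more records.
#' @examples
#' t <- data.frame(
#'   num = 1:3, name = c("a", "b", "c"),
#'   p_np = c(1, 1, 0), smiles = c("CCO", "OCC", "c1ccccc1")
#' )
#' curate(t)$report$n_duplicates_removed
#' @export
curate <- function(table, smiles_col = "smiles", label_col = "p_np",
                   id_col = "num", name_col = "name") {
  pre_parsed <- NULL
  if (inherits(table, "bbb_curated")) {
    pre_parsed <- table$graphs
    table <- table$records
    smiles_col <- "smiles"; label_col <- "label"
    id_col <- "record_id"; name_col <- "name"
  } else {
    pre_parsed <- attr(table, "graphs")
  }
  table <- tibble::as_tibble(table)
  if (!is.null(pre_parsed) &&
    (length(pre_parsed) != nrow(table) ||
      !all(vapply(pre_parsed, inherits, logical(1), "mol_graph")))) {
    pre_parsed <- NULL
  }
  for (col in c(smiles_col, label_col)) {
    if (col %notin% names(table)) {
      stop_config("curate(): required column '%s' is missing", col)
    }
  }
  n_input <- nrow(table)
  records <- tibble::tibble(
    record_id = if (id_col %in% names(table)) {
      as.character(table[[id_col]])
    } else {
      as.character(seq_len(n_input))
    },
    name = if (name_col %in% names(table)) {
      as.character(table[[name_col]])
    } else {
      as.character(seq_len(n_input))
    },
    smiles = as.character(table[[smiles_col]]),
    label = as.integer(table[[label_col]])
  )
  if (n_input > 0L && !all(records$label %in% c(0L, 1L))) {
    stop_config("curate(): labels must be 0/1 in column '%s'", label_col)
  }
  if (n_input == 0L) {
    return(deduplicate(tibble::tibble(
      record_id = character(0), name = character(0), smiles = character(0),
      label = integer(0), key = character(0)
    )))
  }
  # one parse per record; the graphs drive repair, validity check, keying,
  # and are handed on to the fingerprinter
  graphs <- pre_parsed %||% parse_mol_graphs(records$smiles)
  needs_fix <- vapply(graphs, function(g) {
    !is.null(g) && any(g$elem == "N" & g$charge == 0L & g$order_sum == 4L)
  }, logical(1))
  n_fixed <- 0L
  if (any(needs_fix)) {
    for (i in which(needs_fix)) {
      g <- graphs[[i]]
      g$charge[g$elem == "N" & g$charge == 0L & g$order_sum == 4L] <- 1L
      g$nH <- vapply(seq_len(g$n), function(a) {
        atom_hydrogens(g$elem[a], g$charge[a], g$order_sum[a])
      }, integer(1))
      graphs[[i]] <- g
    }
    rewritten <- graphs_to_smiles_batch(graphs[needs_fix])
    ok <- !is.na(rewritten)
    records$smiles[which(needs_fix)[ok]] <- rewritten[ok]
    n_fixed <- sum(ok)
  }
  valid <- vapply(graphs, function(g) !is.null(g) && graph_is_valid(g), logical(1))
  n_unparseable <- sum(!valid)
  records <- records[valid, , drop = FALSE]
  graphs <- graphs[valid]
  # canonical key: largest neutralized organic component (graph surgery
  # only where needed), canonical SMILES in one batched conversion
  needs_surgery <- vapply(graphs, function(g) {
    any(g$charge < 0L) || max(graph_components(g)) > 1L
  }, logical(1))
  key_graphs <- graphs
  for (i in which(needs_surgery)) key_graphs[[i]] <- prune_to_parent(graphs[[i]])
  records$key <- graphs_to_smiles_batch(key_graphs)
  still_bad <- is.na(records$key)
  if (any(still_bad)) { # defensive; a parsed graph should always round-trip
    n_unparseable <- n_unparseable + sum(still_bad)
    records <- records[!still_bad, , drop = FALSE]
    graphs <- graphs[!still_bad]
  }
  out <- deduplicate(records)
  out$report$n_input <- n_input
  out$report$n_nitrogen_fixed <- n_fixed
  out$report$n_unparseable_dropped <- n_unparseable
  out$graphs <- setNames(graphs[out$kept_rows], out$records$record_id)
  out
}

#' Read a BBBP-dialect CSV
#'
#' @param path CSV file with a header row and columns `num`, `name`,
#'   `p_np`, `smiles` (extra columns are kept).
#' @return A tibble.
#' @export
read_bbbp_csv <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE, comment.char = ""))
}

#' Write a curated dataset back to the BBBP CSV dialect plus a JSON report
#'
#' @param x A `bbb_curated` object.
#' @param csv_path Output CSV path (columns `num`, `name`, `p_np`, `smiles`).
#' @param report_path Optional path for the curation report as JSON.
#' @return `csv_path`, invisibly.
#' @export
write_curated <- function(x, csv_path, report_path = NULL) {
  stopifnot(inherits(x, "bbb_curated"))
  df <- data.frame(
    num = x$records$record_id, name = x$records$name,
    p_np = x$records$label, smiles = x$records$smiles
  )
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(x$report, report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(csv_path)
}

#' @export
print.bbb_curated <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<bbb_curated> %d records (from %d input)\n", r$n_output, r$n_input
  ))
  cat(sprintf(
    "  nitrogen-fixed %d | unparseable %d | duplicates %d | triplicate groups %d | inconsistent %d\n",
    r$n_nitrogen_fixed, r$n_unparseable_dropped, r$n_duplicates_removed,
    r$n_triplicate_groups, r$n_inconsistent_records_removed
  ))
  print(x$records, n = 5)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname curate
#' @param x A `bbb_curated` object.
#' @param ... Unused.
#' @export
tidy.bbb_curated <- function(x, ...) x$records

#' @rdname curate
#' @export
glance.bbb_curated <- function(x, ...) tibble::as_tibble(x$report)
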