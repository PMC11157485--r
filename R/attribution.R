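# From per-instance explanations to the headline output: a filtered,
# ranked table of substructures with occurrence counts and total
# contribution weights, plus the sign-sum penetration call per molecule.

#' Attribution configuration
#'
#' @param prob_threshold Probability cut-off used when selecting which
#'   correctly predicted penetrating molecules to explain (default 0.8).
#' @param min_weight Minimum (inclusive) explanation weight a bit must
#'   reach to be retained (default 0.1); negative and small positive
#'   weights are discarded as unimportant for penetration.
#' @param top_n Number of top-ranked fragments reported (default 10).
#' @return A `bbb_attr_config` list.
#' @export
attribution_config <- function(prob_threshold = 0.8, min_weight = 0.1, top_n = 10L) {
  if (prob_threshold <= 0 || prob_threshold >= 1) {
    stop_config("attribution_config(): prob_threshold must lie in (0, 1)")
  }
  if (min_weight < 0) stop_config("attribution_config(): min_weight must be >= 0")
  if (top_n < 1L) stop_config("attribution_config(): top_n must be >= 1")
  structure(list(
    prob_threshold = prob_threshold, min_weight = min_weight,
    top_n = as.integer(top_n)
  ), class = "bbb_attr_config")
}

#' Sign-sum penetration call from an explanation
#'
#' A molecule is called "penetrating" when the sum of its positive
#' explanation weights exceeds the magnitude sum of its negative weights;
#' ties fall to "nonpenetrating" (conservative default).
#'
#' @param explanation A `bbb_explanation` with a non-empty weight list.
#' @return `"penetrating"` or `"nonpenetrating"`.
#' @export
classify_by_weight_sums <- function(explanation) {
  stopifnot(inherits(explanation, "bbb_explanation"))
  w <- explanation$weights$weight
  if (length(w) == 0L) {
    stop_config("classify_by_weight_sums(): explanation has no weights")
  }
  if (sum(w[w > 0]) > sum(abs(w[w < 0]))) "penetrating" else "nonpenetrating"
}

#' Filter explanation weights
#'
#' Keeps (bit, weight) pairs with `weight >= min_weight` (inclusive, so
#' the documented 0.1 cut keeps a weight of exactly 0.1); all negative
#' weights are removed.
#'
#' @param explanation A `bbb_explanation`.
#' @param min_weight Inclusive lower bound (>= 0).
#' @return Tibble with columns `bit`, `weight` (possibly empty).
#' @export
filter_weights <- function(explanation, min_weight = 0.1) {
  stopifnot(inherits(explanation, "bbb_explanation"))
  if (min_weight < 0) stop_config("filter_weights(): min_weight must be >= 0")
  dplyr::filter(explanation$weights, .data$weight >= min_weight)
}

#' Aggregate explained bits into a ranked substructure table
#'
#' For every explained molecule, weights are filtered at `min_weight`,
#' each retained bit is resolved to the circular-environment fragment(s)
#' that set it in that molecule (a folded bit can carry several
#' environments; each is credited with the full bit weight and one
#' occurrence), and fragments are merged across molecules by canonical
#' fragment SMILES.  Retained bits with no environment in their molecule
#' (bits the surrogate weighted although the molecule does not set them)
#' are recorded as "unmapped" diagnostics, not credited.
#'
#' @param explanations List of `bbb_explanation` objects whose
#'   `instance_id`s are molecule ids of `fps`.
#' @param fps The `bbb_fingerprints` of the explained molecules.
#' @param min_weight Inclusive weight filter (default 0.1).
#' @return A `bbb_attribution`: tibble with `fragment_smiles`,
#'   `occurrence_count`, `total_weight`, sorted by total weight
#'   (descending), with diagnostics in `attr(, "unmapped")` and the
#'   per-molecule sign-sum calls in `attr(, "classifications")`.
#' @export
aggregate_fragments <- function(explanations, fps, min_weight = 0.1) {
  stopifnot(inherits(fps, "bbb_fingerprints"))
  if (inherits(explanations, "bbb_explanation")) explanations <- list(explanations)
  frag_rows <- list()
  unmapped <- list()
  calls <- list()
  for (expl in explanations) {
    stopifnot(inherits(expl, "bbb_explanation"))
    mid <- expl$instance_id
    i <- match(mid, fps$ids)
    if (is.na(i)) {
      stop_config("aggregate_fragments(): no environment map for molecule '%s'", mid)
    }
    calls[[length(calls) + 1L]] <- tibble::tibble(
      molecule = mid,
      predicted_probability = expl$predicted_probability,
      call = classify_by_weight_sums(expl)
    )
    kept <- filter_weights(expl, min_weight)
    if (nrow(kept) == 0L) next
    g <- fps$graphs[[i]]
    envs <- fps$env[[i]]
    env_bits <- vapply(envs, function(e) e$bit, integer(1))
    for (j in seq_len(nrow(kept))) {
      hits <- which(env_bits == kept$bit[j])
      if (length(hits) == 0L) {
        unmapped[[length(unmapped) + 1L]] <- tibble::tibble(
          molecule = mid, bit = kept$bit[j], weight = kept$weight[j]
        )
        next
      }
      for (h in hits) {
        frag_rows[[length(frag_rows) + 1L]] <- tibble::tibble(
          molecule = mid, bit = kept$bit[j], weight = kept$weight[j],
          raw = write_fragment_smiles(induced_subgraph(g, envs[[h]]$atoms))
        )
      }
    }
  }
  if (length(frag_rows) == 0L) {
    tab <- tibble::tibble(
      fragment_smiles = character(0), occurrence_count = integer(0),
      total_weight = numeric(0)
    )
  } else {
    rows <- dplyr::bind_rows(frag_rows)
    rows$fragment_smiles <- canonical_fragment_keys(rows$raw)
    tab <- rows |>
      dplyr::group_by(.data$fragment_smiles) |>
      dplyr::summarise(
        occurrence_count = dplyr::n(),
        total_weight = sum(.data$weight),
        .groups = "drop"
      ) |>
      dplyr::arrange(
        dplyr::desc(.data$total_weight),
        dplyr::desc(.data$occurrence_count), .data$fragment_smiles
      )
  }
  structure(tab,
    class = c("bbb_attribution", class(tab)),
    unmapped = dplyr::bind_rows(unmapped),
    classifications = dplyr::bind_rows(calls),
    min_weight = min_weight
  )
}

#' Top-ranked fragments
#'
#' @param table A `bbb_attribution` (or any data frame with
#'   `total_weight`, `occurrence_count`, `fragment_smiles`).
#' @param top_n Number of rows returned (default 10); ties in total weight
#'   fall to the higher occurrence count, then lexicographic SMILES.
#' @return The first `min(top_n, nrow)` rows, re-ranked.
#' @export
top_fragments <- function(table, top_n = 10L) {
  if (top_n < 1L) stop_config("top_fragments(): top_n must be >= 1")
  out <- dplyr::arrange(
    tibble::as_tibble(table),
    dplyr::desc(.data$total_weight),
    dplyr::desc(.data$occurrence_count), .data$fragment_smiles
  )
  head(out, top_n)
}

#' @export
print.bbb_attribution <- function(x, ...) {
  cat(sprintf(
    "<bbb_attribution> %d fragments (weight filter >= %.3g), %d unmapped bit(s)\n",
    nrow(x), attr(x, "min_weight"), nrow(attr(x, "unmapped") %||% tibble::tibble())
  ))
  NextMethod()
}

#' @rdname aggregate_fragments
#' @param object A `bbb_attribution`.
#' @param top_n Fragments shown.
#' @param ... Unused.
#' @export
autoplot.bbb_attribution <- function(object, top_n = 10L, ...) {
  df <- top_fragments(object, top_n)
  df$fragment_smiles <- factor(df$fragment_smiles, levels = rev(df$fragment_smiles))
  ggplot2::ggplot(df, ggplot2::aes(.data$total_weight, .data$fragment_smiles)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_text(ggplot2::aes(label = .data$occurrence_count), hjust = -0.3, size = 3) +
    ggplot2::labs(
      x = "total contribution weight", y = NULL,
      title = "Substructures driving predicted BBB penetration",
      subtitle = "bar label: occurrence count"
    )
}

#' Render molecules with their alert substructures highlighted
#'
#' Writes one SVG drawing per molecule, highlighting the atoms of every
#' fingerprint environment whose canonical fragment SMILES appears in
#' `fragments`.  Purely presentational.
#'
#' @param fps A `bbb_fingerprints` object (provides 2D coordinates and the
#'   environment registry).
#' @param molecules Molecule ids to draw.
#' @param fragments Character vector of canonical fragment SMILES to
#'   highlight (e.g. `top_fragments(tab)$fragment_smiles`).
#' @param dir Output directory (created if needed).
#' @return Tibble with `molecule`, `path`, `n_highlighted_atoms`,
#'   invisibly.  Fragments that match no molecule produce a warning;
#'   molecules without a match are drawn plain.
#' @export
render_highlights <- function(fps, molecules, fragments, dir) {
  stopifnot(inherits(fps, "bbb_fingerprints"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  matched_any <- setNames(rep(FALSE, length(fragments)), fragments)
  out <- list()
  for (mid in molecules) {
    i <- match(mid, fps$ids)
    if (is.na(mid) || is.na(i)) stop_config("render_highlights(): unknown molecule '%s'", mid)
    g <- fps$graphs[[i]]
    envs <- fps$env[[i]]
    hl <- integer(0)
    if (length(envs) > 0L && length(fragments) > 0L) {
      keys <- canonical_fragment_keys(vapply(envs, function(e) {
        write_fragment_smiles(induced_subgraph(g, e$atoms))
      }, character(1)))
      hit <- keys %in% fragments
      matched_any[keys[hit]] <- TRUE
      hl <- sort(unique(unlist(lapply(envs[hit], function(e) e$atoms))))
    }
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", mid), ".svg"))
    writeLines(molecule_svg(g, highlight = hl, title = mid), path)
    out[[length(out) + 1L]] <- tibble::tibble(
      molecule = mid, path = path, n_highlighted_atoms = length(hl)
    )
  }
  miss <- names(matched_any)[!matched_any]
  if (length(miss) > 0L) {
    warn(sprintf(
      "render_highlights(): %d fragment(s) matched no molecule: %s",
      length(miss), paste(head(miss, 3L), collapse = ", ")
    ))
  }
  invisible(dplyr::bind_rows(out))
}

# Minimal 2D structure drawing as SVG text (lines for bonds, haloed
# circles for highlighted atoms, element labels for heteroatoms).
molecule_svg <- function(g, highlight = integer(0), title = "", px = 360) {
  if (g$n == 0L) {
    return(sprintf("<svg xmlns='http://www.w3.org/2000/svg' width='%d' height='%d'/>", px, px))
  }
  xr <- range(g$x); yr <- range(g$y)
  span <- max(xr[2] - xr[1], yr[2] - yr[1], 1e-6)
  pad <- 30
  sc <- (px - 2 * pad) / span
  X <- pad + (g$x - xr[1]) * sc
  Y <- pad + (yr[2] - g$y) * sc
  parts <- c(
    sprintf(
      "<svg xmlns='http://www.w3.org/2000/svg' width='%d' height='%d' viewBox='0 0 %d %d'>",
      px, px, px, px
    ),
    sprintf("<title>%s</title>", title),
    sprintf("<rect width='%d' height='%d' fill='white'/>", px, px)
  )
  for (a in highlight) {
    parts <- c(parts, sprintf(
      "<circle cx='%.1f' cy='%.1f' r='%.1f' fill='#fdae61' fill-opacity='0.6'/>",
      X[a], Y[a], max(8, sc * 0.35)
    ))
  }
  for (k in seq_along(g$bond_a)) {
    a <- g$bond_a[k]; b <- g$bond_b[k]
    w <- if (g$bond_order[k] >= 2L && !g$bond_arom[k]) 3.2 else 1.6
    dash <- if (g$bond_arom[k]) " stroke-dasharray='none'" else ""
    parts <- c(parts, sprintf(
      "<line x1='%.1f' y1='%.1f' x2='%.1f' y2='%.1f' stroke='black' stroke-width='%.1f'%s/>",
      X[a], Y[a], X[b], Y[b], w, dash
    ))
  }
  for (a in seq_len(g$n)) {
    if (g$elem[a] == "C" && g$charge[a] == 0L) next
    lab <- g$elem[a]
    if (g$charge[a] > 0L) lab <- paste0(lab, "+")
    if (g$charge[a] < 0L) lab <- paste0(lab, "-")
    parts <- c(parts, sprintf(
      paste0(
        "<circle cx='%.1f' cy='%.1f' r='9' fill='white'/>",
        "<text x='%.1f' y='%.1f' font-size='12' text-anchor='middle' ",
        "dominant-baseline='central' fill='#1a55a0'>%s</text>"
      ),
      X[a], Y[a], X[a], Y[a], lab
    ))
  }
  c(parts, "</svg>")
}
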