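# Seeded synthetic inputs with known ground truth: (1) a SMILES library
# assembled from scaffolds and substituents in which a planted "alert"
# substructure (noisily) determines the penetration label, emulating the
# size and imbalance character of the public BBB penetration benchmark;
# (2) binary feature tables with a known linear logit, the oracle for the
# surrogate explainer.

.DEFAULT_SCAFFOLDS <- c(
  "c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCOC1", "c1ccc2ccccc2c1", "C1CCCC1"
)
# The substituent pool deliberately includes acyclic nitrogen groups
# (tertiary amine, nitrile, acetamide): they appear in penetrants and
# non-penetrants alike, so generic nitrogen environments carry no signal
# and only the alert ring's own environments separate the classes --
# mirroring how nitrogen is ubiquitous in the real benchmark.
.DEFAULT_SUBSTITUENTS <- c(
  "C", "CC", "CO", "CCO", "CC(C)C", "C(F)(F)F", "CCl", "COC", "CC=O",
  "c1ccccc1", "CN(C)C", "C#N", "CNC(C)=O"
)

#' Specification of the synthetic molecule library
#'
#' @param scaffold_smiles Ring systems molecules are built on.
#' @param substituent_smiles Side chains attached at random C-H positions.
#' @param alert_fragments SMILES of the planted alert substructure(s);
#'   default azetidine, the kind of compact basic nitrogen heterocycle that
#'   recurs among known brain-penetrant drugs.  The four-membered ring is
#'   chosen deliberately: its doubly-N-adjacent methylene is the smallest
#'   amine-ring feature whose radius-2 circular environment is unique
#'   (tree-unfolded environments cannot tell 5- from 6-membered ring
#'   amines apart at radius 2), and that environment's induced fragment is
#'   exactly the full ring, so the planted alert is recoverable verbatim
#'   from the attribution table.
#' @param decoy_fragments Counterfactual ring amines (default piperidine)
#'   planted, through the same spacer, in molecules that do not carry the
#'   alert.  With the decoy in place both classes share every generic
#'   nitrogen environment (the ring N itself, its radius-1 surroundings),
#'   so only the alert ring's own radius-2 geometry separates penetrants
#'   from non-penetrants -- the situation a substructure explainer is
#'   meant to resolve.  Set to `character(0)` for a decoy-free library.
#' @param decoy_prevalence Probability that an alert-free molecule
#'   receives a decoy (default 1).
#' @param n_molecules Library size (default 2000, the scale of the public
#'   benchmark).
#' @param alert_prevalence Fraction of assembled molecules carrying an
#'   alert before imbalance adjustment.
#' @param label_noise Probability of flipping a label (must be < 0.5).
#' @param imbalance Target positive (penetrating) fraction of the final
#'   library; default 0.76 mimics the benchmark's skew.
#' @param seed Integer seed; generation is a pure function of this spec.
#' @return A `bbb_library_spec` list.
#' @export
library_spec <- function(scaffold_smiles = .DEFAULT_SCAFFOLDS,
                         substituent_smiles = .DEFAULT_SUBSTITUENTS,
                         alert_fragments = "C1CNC1",
                         decoy_fragments = "C1CCNCC1",
                         decoy_prevalence = 1.0,
                         n_molecules = 2000L,
                         alert_prevalence = 0.76,
                         label_noise = 0.05,
                         imbalance = 0.76,
                         seed = 1L) {
  if (label_noise < 0 || label_noise >= 0.5) {
    stop_config("library_spec(): label_noise must lie in [0, 0.5)")
  }
  if (alert_prevalence <= 0 || alert_prevalence >= 1) {
    stop_config("library_spec(): alert_prevalence must lie in (0, 1)")
  }
  if (imbalance <= 0 || imbalance >= 1) {
    stop_config("library_spec(): imbalance must lie in (0, 1)")
  }
  if (decoy_prevalence < 0 || decoy_prevalence > 1) {
    stop_config("library_spec(): decoy_prevalence must lie in [0, 1]")
  }
  blocks <- c(scaffold_smiles, substituent_smiles, alert_fragments, decoy_fragments)
  parsed <- ob_canonical(blocks)
  if (anyNA(parsed)) {
    stop_config(
      "library_spec(): unparseable building block(s): %s",
      paste(blocks[is.na(parsed)], collapse = ", ")
    )
  }
  structure(list(
    scaffold_smiles = scaffold_smiles,
    substituent_smiles = substituent_smiles,
    alert_fragments = alert_fragments,
    decoy_fragments = decoy_fragments,
    decoy_prevalence = decoy_prevalence,
    n_molecules = as.integer(n_molecules),
    alert_prevalence = alert_prevalence,
    label_noise = label_noise,
    imbalance = imbalance,
    seed = as.integer(seed)
  ), class = "bbb_library_spec")
}

# Join two molecular graphs with a single bond between atoms a1 (of g1)
# and a2 (of g2).  The new bond is a bridge, so ring membership, aromatic
# flags and hydrogen counts carry over without recomputation (each
# attachment atom gives up one hydrogen).
merge_attach <- function(g1, a1, g2, a2) {
  off <- g1$n
  moff <- length(g1$bond_a)
  b2 <- a2 + off
  g <- list(
    n = g1$n + g2$n,
    elem = c(g1$elem, g2$elem),
    charge = c(g1$charge, g2$charge),
    x = c(g1$x, g2$x + max(g1$x) + 3), y = c(g1$y, g2$y),
    bond_a = c(g1$bond_a, g2$bond_a + off, a1),
    bond_b = c(g1$bond_b, g2$bond_b + off, b2),
    bond_order = c(g1$bond_order, g2$bond_order, 1L),
    bond_arom = c(g1$bond_arom, g2$bond_arom, FALSE),
    bond_ring = c(g1$bond_ring, g2$bond_ring, FALSE),
    adj = c(g1$adj, lapply(g2$adj, function(v) v + off)),
    badj = c(g1$badj, lapply(g2$badj, function(v) v + moff)),
    arom = c(g1$arom, g2$arom),
    order_sum = c(g1$order_sum, g2$order_sum),
    nH = c(g1$nH, g2$nH),
    smiles = NA_character_
  )
  k <- length(g$bond_a)
  g$adj[[a1]] <- c(g$adj[[a1]], b2)
  g$adj[[b2]] <- c(g$adj[[b2]], a1)
  g$badj[[a1]] <- c(g$badj[[a1]], k)
  g$badj[[b2]] <- c(g$badj[[b2]], k)
  g$order_sum[c(a1, b2)] <- g$order_sum[c(a1, b2)] + 1L
  g$nH[c(a1, b2)] <- pmax(0L, g$nH[c(a1, b2)] - 1L)
  class(g) <- "mol_graph"
  g
}

attachment_points <- function(g, carbon_only = TRUE) {
  ok <- !is.na(g$nH) & g$nH >= 1L
  if (carbon_only) ok <- ok & g$elem == "C"
  which(ok)
}

#' Generate the synthetic molecule library
#'
#' Molecules are assembled by attaching one or two random substituents to
#' a random scaffold; a seeded fraction additionally carries one alert
#' fragment, attached through an ethyl spacer so the alert core sits as a
#' terminal group whose circular environments are identical across
#' molecules.  The label is 1 exactly when an alert substructure matches
#' (verified by SMARTS search, so accidental matches are labelled
#' consistently), then flipped independently with probability
#' `label_noise`.  The library is finally subsampled to `n_molecules`
#' records at the target positive fraction.
#'
#' @param spec A [library_spec()].
#' @return A tibble of molecule records (`record_id`, `name`, `smiles`,
#'   `label`) with ground-truth columns `has_alert` (pre-noise SMARTS
#'   truth) and `true_label`; the spec is attached as `attr(, "spec")`.
#' @export
generate_library <- function(spec = library_spec()) {
  stopifnot(inherits(spec, "bbb_library_spec"))
  scaf <- parse_mol_graphs(spec$scaffold_smiles)
  subs <- parse_mol_graphs(spec$substituent_smiles)
  alert <- parse_mol_graphs(spec$alert_fragments)
  decoy <- parse_mol_graphs(spec$decoy_fragments)
  linker <- parse_mol_graphs("CC")[[1L]]
  # size the assembly pool so both classes can reach the target imbalance
  # after label noise, with a safety margin
  p_lab <- spec$alert_prevalence * (1 - spec$label_noise) +
    (1 - spec$alert_prevalence) * spec$label_noise
  n_pos_target <- round(spec$imbalance * spec$n_molecules)
  n_neg_target <- spec$n_molecules - n_pos_target
  n_pool <- as.integer(ceiling(
    1.15 * max(n_pos_target / p_lab, n_neg_target / (1 - p_lab))
  )) + 30L
  graphs <- vector("list", n_pool)
  planted <- logical(n_pool)
  with_seed(derive_seed(spec$seed, "assemble"), {
    for (i in seq_len(n_pool)) {
      want_alert <- runif(1) < spec$alert_prevalence
      want_decoy <- length(decoy) > 0L && !want_alert &&
        runif(1) < spec$decoy_prevalence
      g <- NULL
      for (try in 1:10) { # retry cap for combinations without open valence
        g <- scaf[[sample.int(length(scaf), 1L)]]
        ok <- TRUE
        for (s in seq_len(1L + (runif(1) < 0.5))) {
          pts <- attachment_points(g)
          if (length(pts) == 0L) { ok <- FALSE; break }
          sub <- subs[[sample.int(length(subs), 1L)]]
          spts <- attachment_points(sub)
          if (length(spts) == 0L) { ok <- FALSE; break }
          g <- merge_attach(g, pts[sample.int(length(pts), 1L)],
            sub, spts[sample.int(length(spts), 1L)]
          )
        }
        # terminal groups go on through an ethyl spacer, N-alkylated when
        # the group carries an amine N-H (the natural linkage), so their
        # circular environments are identical across the library
        attach_terminal <- function(g, grp) {
          pts <- attachment_points(g)
          if (length(pts) == 0L) return(NULL)
          apts <- which(grp$elem == "N" & !is.na(grp$nH) & grp$nH >= 1L)
          if (length(apts) == 0L) apts <- attachment_points(grp, carbon_only = FALSE)
          if (length(apts) == 0L) return(NULL)
          g <- merge_attach(g, pts[sample.int(length(pts), 1L)], linker, 1L)
          merge_attach(g, g$n, grp, apts[[1L]])
        }
        if (ok && want_decoy) {
          g <- attach_terminal(g, decoy[[sample.int(length(decoy), 1L)]])
          if (is.null(g)) ok <- FALSE
        }
        if (ok && want_alert) {
          g <- attach_terminal(g, alert[[sample.int(length(alert), 1L)]])
          if (is.null(g)) ok <- FALSE
        }
        if (ok) break
        g <- NULL
      }
      graphs[[i]] <- g # NULL when every retry failed; dropped below
      planted[i] <- want_alert
    }
  })
  keep <- !vapply(graphs, is.null, logical(1))
  graphs <- graphs[keep]
  planted <- planted[keep]
  smiles <- graphs_to_smiles_batch(graphs)
  ok <- !is.na(smiles)
  smiles <- smiles[ok]
  planted <- planted[ok]
  # ground truth by substructure match, not by construction flag
  has_alert <- rep(FALSE, length(smiles))
  for (al in spec$alert_fragments) {
    has_alert <- has_alert | smarts_match_counts(smiles, al, assume_parseable = TRUE) > 0L
  }
  true_label <- as.integer(has_alert)
  label <- with_seed(
    derive_seed(spec$seed, "noise"),
    as.integer(xor(true_label == 1L, runif(length(true_label)) < spec$label_noise))
  )
  # subsample to the target class balance at the requested size
  n_pos <- as.integer(round(spec$imbalance * spec$n_molecules))
  n_neg <- spec$n_molecules - n_pos
  pos <- which(label == 1L)
  neg <- which(label == 0L)
  if (length(pos) < n_pos || length(neg) < n_neg) {
    n_pos <- min(n_pos, length(pos))
    n_neg <- min(spec$n_molecules - n_pos, length(neg))
  }
  sel <- with_seed(derive_seed(spec$seed, "subsample"), {
    sort(c(
      pos[sample.int(length(pos), n_pos)],
      neg[sample.int(length(neg), n_neg)]
    ))
  })
  out <- tibble::tibble(
    record_id = sprintf("M%05d", seq_along(sel)),
    name = sprintf("synthetic-%05d", seq_along(sel)),
    smiles = smiles[sel],
    label = label[sel],
    has_alert = has_alert[sel],
    true_label = true_label[sel]
  )
  attr(out, "spec") <- spec
  # parsed graphs ride along so downstream curation/featurization can skip
  # re-parsing what this generator just built
  attr(out, "graphs") <- graphs[sel]
  out
}

#' Write a synthetic library in the BBBP CSV dialect
#'
#' @param library A tibble from [generate_library()].
#' @param csv_path Output CSV (columns `num`, `name`, `p_np`, `smiles`).
#' @param truth_path Optional JSON with per-molecule ground truth and the
#'   generating spec.
#' @return `csv_path`, invisibly.
#' @export
write_library <- function(library, csv_path, truth_path = NULL) {
  write.csv(data.frame(
    num = library$record_id, name = library$name,
    p_np = library$label, smiles = library$smiles
  ), csv_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    spec <- attr(library, "spec")
    jsonlite::write_json(list(
      spec = unclass(spec),
      truth = data.frame(
        record_id = library$record_id, has_alert = library$has_alert,
        true_label = library$true_label
      )
    ), truth_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(csv_path)
}

#' Specification of a synthetic binary feature table with linear logit
#'
#' @param n Number of samples.
#' @param d Number of binary features.
#' @param coefficients Length-`d` logit coefficient vector (mostly zeros).
#' @param intercept Logit intercept.
#' @param seed Integer seed.
#' @return A `bbb_binary_spec` list.
#' @export
binary_table_spec <- function(n = 1000L, d = 30L,
                              coefficients = c(2, -1.5, 1, rep(0, d - 3L)),
                              intercept = 0, seed = 1L) {
  if (length(coefficients) != d) {
    stop_config("binary_table_spec(): coefficients must have length d")
  }
  structure(list(
    n = as.integer(n), d = as.integer(d),
    coefficients = as.numeric(coefficients), intercept = as.numeric(intercept),
    seed = as.integer(seed)
  ), class = "bbb_binary_spec")
}

#' Generate a binary table with known logistic ground truth
#'
#' Features are iid Bernoulli(0.5); the label is drawn from
#' `plogis(intercept + x %*% coefficients)`.
#'
#' @param spec A [binary_table_spec()].
#' @return A list with `x` (n x d 0/1 matrix), `labels`, `probabilities`,
#'   and the `spec`.
#' @export
generate_binary_table <- function(spec = binary_table_spec()) {
  stopifnot(inherits(spec, "bbb_binary_spec"))
  with_seed(spec$seed, {
    x <- matrix(as.integer(runif(spec$n * spec$d) < 0.5), spec$n, spec$d)
    p <- stats::plogis(spec$intercept + drop(x %*% spec$coefficients))
    labels <- as.integer(runif(spec$n) < p)
    list(x = x, labels = labels, probabilities = p, spec = spec)
  })
}
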