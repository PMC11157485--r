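# Internal molecular-graph layer.
#
# SMILES parsing, canonicalization and SMARTS matching are delegated to
# OpenBabel through ChemmineR/ChemmineOB.  OpenBabel is deliberately lenient
# about valence (it will parse a neutral tetravalent nitrogen), so validity
# of a structure is decided here by an explicit allowed-valence table: an
# atom whose bond-order sum cannot be completed to an allowed valence with
# implicit hydrogens marks the molecule invalid.  SDF output is kekulized;
# aromatic bond flags are recovered from a mol2 conversion of the same
# SMILES (atom order is preserved by both conversions).

# ---- OpenBabel wrappers ------------------------------------------------

ob_convert <- function(from, to, text) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, text)),
    error = function(e) ""
  )
  out
}

# Batch canonical SMILES.  Returns NA for strings OpenBabel cannot parse.
# OpenBabel aborts a multi-molecule conversion at the first bad record, so
# unconverted tails are retried (the stubborn head record one at a time).
ob_canonical <- function(smiles) {
  n <- length(smiles)
  res <- rep(NA_character_, n)
  if (n == 0L) return(res)
  tags <- sprintf("t%07d", seq_len(n))
  fill_from <- function(out, idx) {
    if (!nzchar(out)) return(invisible())
    lines <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]])
    for (ln in lines[nzchar(lines)]) {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      if (length(parts) >= 2L) {
        i <- match(parts[[length(parts)]], tags[idx])
        if (!is.na(i)) res[idx[i]] <<- parts[[1L]]
      }
    }
  }
  todo <- seq_len(n)
  repeat {
    if (length(todo) == 0L) break
    fill_from(
      ob_convert("SMI", "CAN", paste(smiles[todo], tags[todo], collapse = "\n")),
      todo
    )
    todo <- todo[is.na(res[todo])]
    if (length(todo) == 0L) break
    # the head of the remainder is the record the batch stopped on: try it
    # alone (it may simply be unparseable), then continue with the rest
    fill_from(ob_convert("SMI", "CAN", paste(smiles[todo[1L]], tags[todo[1L]])), todo[1L])
    todo <- todo[-1L]
  }
  res
}

# ---- valence model -----------------------------------------------------

.VALENCES <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L,
  Se = c(2L, 4L, 6L), As = c(3L, 5L)
)

allowed_valences <- function(elem, charge) {
  base <- .VALENCES[[elem]]
  if (is.null(base)) return(NULL) # metals etc.: no implicit-H model, never flagged
  if (charge == 0L) return(base)
  if (elem %in% c("N", "P", "As", "O", "S", "Se")) return(pmax(base + charge, 0L))
  if (elem %in% c("C", "Si", "B")) return(pmax(base - abs(charge), 0L))
  base
}

# Implicit hydrogen count per atom from kekulized bond orders; NA when the
# bond-order sum exceeds every allowed valence (a valence defect).
atom_hydrogens <- function(elem, charge, order_sum) {
  av <- allowed_valences(elem, charge)
  if (is.null(av)) return(0L)
  ok <- av[av >= order_sum]
  if (length(ok) == 0L) return(NA_integer_)
  as.integer(min(ok) - order_sum)
}

# ---- construction ------------------------------------------------------

decode_mdl_charge <- function(code) {
  ifelse(code %in% 1:3, 4L - as.integer(code),
    ifelse(code %in% 5:7, 4L - as.integer(code), 0L)
  )
}

# Aromatic bond pairs from one mol2 block: matrix with columns a, b.
# OpenBabel marks delocalized non-ring bonds (e.g. carboxylate C-O) "ar"
# too; callers intersect with ring membership.
mol2_ar_bonds <- function(block_lines) {
  i <- grep("^@<TRIPOS>BOND", block_lines)
  if (length(i) == 0L || i[1L] >= length(block_lines)) {
    return(matrix(integer(0), ncol = 2))
  }
  rows <- list()
  for (j in seq(i[1L] + 1L, length(block_lines))) {
    ln <- trimws(block_lines[[j]])
    if (!nzchar(ln)) next
    if (grepl("^@<TRIPOS>", ln)) break
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) >= 4L && parts[[4L]] == "ar") {
      rows[[length(rows) + 1L]] <- as.integer(parts[2:3])
    }
  }
  if (length(rows) == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, rows)
}

# Bonds that lie on a cycle: bond (a,b) is a ring bond iff b stays reachable
# from a with the bond removed.
ring_bond_flags <- function(n, bond_a, bond_b) {
  m <- length(bond_a)
  flags <- logical(m)
  if (m == 0L) return(flags)
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[bond_a[k]]] <- c(adj[[bond_a[k]]], k)
    adj[[bond_b[k]]] <- c(adj[[bond_b[k]]], k)
  }
  for (k in seq_len(m)) {
    src <- bond_a[k]; dst <- bond_b[k]
    seen <- logical(n); seen[src] <- TRUE
    queue <- src
    found <- FALSE
    while (length(queue) > 0L && !found) {
      a <- queue[[1L]]; queue <- queue[-1L]
      for (bk in adj[[a]]) {
        if (bk == k) next
        nb <- if (bond_a[bk] == a) bond_b[bk] else bond_a[bk]
        if (nb == dst) { found <- TRUE; break }
        if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
      }
    }
    flags[k] <- found
  }
  flags
}

new_mol_graph <- function(elem, charge, x, y, bond_a, bond_b, bond_order,
                          bond_arom, smiles = NA_character_) {
  n <- length(elem)
  m <- length(bond_a)
  ring <- ring_bond_flags(n, bond_a, bond_b)
  bond_arom <- bond_arom & ring
  adj <- vector("list", n)
  badj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[bond_a[k]]] <- c(adj[[bond_a[k]]], bond_b[k])
    adj[[bond_b[k]]] <- c(adj[[bond_b[k]]], bond_a[k])
    badj[[bond_a[k]]] <- c(badj[[bond_a[k]]], k)
    badj[[bond_b[k]]] <- c(badj[[bond_b[k]]], k)
  }
  arom_atom <- logical(n)
  if (any(bond_arom)) {
    arom_atom[unique(c(bond_a[bond_arom], bond_b[bond_arom]))] <- TRUE
  }
  os <- vapply(seq_len(n), function(a) {
    if (length(badj[[a]]) == 0L) 0L else sum(bond_order[badj[[a]]])
  }, integer(1))
  nH <- vapply(seq_len(n), function(a) atom_hydrogens(elem[a], charge[a], os[a]),
    integer(1)
  )
  structure(list(
    n = n, elem = elem, charge = as.integer(charge), x = x, y = y,
    bond_a = bond_a, bond_b = bond_b, bond_order = as.integer(bond_order),
    bond_arom = bond_arom, bond_ring = ring,
    adj = adj, badj = badj, arom = arom_atom, order_sum = os, nH = nH,
    smiles = smiles
  ), class = "mol_graph")
}

graph_is_valid <- function(g) !anyNA(g$nH)

# Parse a vector of SMILES into mol_graph objects (NULL where OpenBabel
# fails outright).  Lenient: valence defects yield a graph with NA
# hydrogen counts, flagged by graph_is_valid().  With
# `assume_parseable = TRUE` (internal fast path for machine-generated
# SMILES) the pre-screening conversion is skipped.
parse_mol_graphs <- function(smiles, assume_parseable = FALSE) {
  n <- length(smiles)
  graphs <- vector("list", n)
  if (n == 0L) return(graphs)
  if (assume_parseable) {
    ok <- seq_len(n)
  } else {
    can <- ob_canonical(smiles)
    ok <- which(!is.na(can))
  }
  if (length(ok) == 0L) return(graphs)
  named <- smiles[ok]
  names(named) <- sprintf("t%07d", ok)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(named)),
    error = function(e) NULL
  )
  if (is.null(sdf)) { # rare: fall back to one-at-a-time, full screening
    for (i in ok) {
      g <- tryCatch(parse_mol_graphs(smiles[i])[[1L]], error = function(e) NULL)
      graphs[[i]] <- g
    }
    return(graphs)
  }
  mol2 <- ob_convert("SMI", "MOL2", paste(smiles[ok], names(named), collapse = "\n"))
  mol2_blocks <- list()
  if (nzchar(mol2)) {
    lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
    starts <- grep("^@<TRIPOS>MOLECULE", lines)
    ends <- c(starts[-1L] - 1L, length(lines))
    for (s in seq_along(starts)) {
      blk <- lines[starts[s]:ends[s]]
      tag <- trimws(blk[[2L]])
      mol2_blocks[[tag]] <- blk
    }
  }
  if (length(sdf) != length(ok)) { # silent drop: realign one at a time
    for (i in ok) {
      graphs[[i]] <- tryCatch(parse_mol_graphs(smiles[i])[[1L]],
        error = function(e) NULL
      )
    }
    return(graphs)
  }
  abs <- ChemmineR::atomblock(sdf)
  bbs <- ChemmineR::bondblock(sdf)
  for (s in seq_along(ok)) {
    i <- ok[s]
    ab <- abs[[s]]
    bb <- bbs[[s]]
    elem <- sub("_.*$", "", rownames(ab))
    chg <- if ("C6" %in% colnames(ab)) decode_mdl_charge(ab[, "C6"]) else rep(0L, nrow(ab))
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = if (length(bb) > 0L) 1L else 0L)
    if (nrow(bb) == 0L || ncol(bb) < 3L) {
      ba <- integer(0); bbnd <- integer(0); bo <- integer(0)
    } else {
      ba <- as.integer(bb[, 1L]); bbnd <- as.integer(bb[, 2L]); bo <- as.integer(bb[, 3L])
    }
    arom <- rep(FALSE, length(ba))
    blk <- mol2_blocks[[names(named)[s]]]
    if (!is.null(blk)) {
      arp <- mol2_ar_bonds(blk)
      if (nrow(arp) > 0L) {
        key <- paste(pmin(ba, bbnd), pmax(ba, bbnd))
        akey <- paste(pmin(arp[, 1L], arp[, 2L]), pmax(arp[, 1L], arp[, 2L]))
        arom <- key %in% akey
      }
    }
    graphs[[i]] <- new_mol_graph(
      elem = elem, charge = chg, x = ab[, 1L], y = ab[, 2L],
      bond_a = ba, bond_b = bbnd, bond_order = bo, bond_arom = arom,
      smiles = smiles[i]
    )
  }
  graphs
}

# ---- serialization back to SMILES --------------------------------------

graph_to_molblock <- function(g, title = "") {
  hdr <- c(title, " bbbalert", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", g$n, length(g$bond_a))
  atoms <- vapply(seq_len(g$n), function(a) {
    sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      g$x[a] %||% 0, g$y[a] %||% 0, 0, g$elem[a]
    )
  }, character(1))
  bonds <- vapply(seq_along(g$bond_a), function(k) {
    sprintf("%3d%3d%3d  0  0  0  0", g$bond_a[k], g$bond_b[k], g$bond_order[k])
  }, character(1))
  chg_lines <- character(0)
  charged <- which(g$charge != 0L)
  if (length(charged) > 0L) {
    for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
      chg_lines <- c(chg_lines, paste0(
        "M  CHG", sprintf("%3d", length(grp)),
        paste0(vapply(grp, function(a) sprintf("%4d%4d", a, g$charge[a]), character(1)),
          collapse = ""
        )
      ))
    }
  }
  paste(c(hdr, counts, atoms, bonds, chg_lines, "M  END", "$$$$"), collapse = "\n")
}

graph_to_smiles <- function(g) {
  out <- ob_convert("MOL", "CAN", graph_to_molblock(g))
  out <- trimws(strsplit(out, "[ \t\n]+")[[1]])
  out <- out[nzchar(out)]
  if (length(out) == 0L) NA_character_ else out[[1L]]
}

# Canonical SMILES for many graphs in one OpenBabel round trip.
graphs_to_smiles_batch <- function(graphs) {
  n <- length(graphs)
  res <- rep(NA_character_, n)
  if (n == 0L) return(res)
  tags <- sprintf("g%07d", seq_len(n))
  sdf <- paste(vapply(seq_len(n), function(i) graph_to_molblock(graphs[[i]], tags[i]),
    character(1)
  ), collapse = "\n")
  out <- ob_convert("SDF", "CAN", sdf)
  if (!nzchar(out)) {
    return(vapply(graphs, graph_to_smiles, character(1)))
  }
  lines <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]])
  for (ln in lines[nzchar(lines)]) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) >= 2L) {
      i <- match(parts[[length(parts)]], tags)
      if (!is.na(i)) res[i] <- parts[[1L]]
    }
  }
  miss <- which(is.na(res))
  for (i in miss) res[i] <- graph_to_smiles(graphs[[i]])
  res
}

# Connected components: integer membership vector.
graph_components <- function(g) {
  comp <- rep(NA_integer_, g$n)
  cur <- 0L
  for (start in seq_len(g$n)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0L) {
      a <- queue[[1L]]; queue <- queue[-1L]
      for (nb in g$adj[[a]]) {
        if (is.na(comp[nb])) { comp[nb] <- cur; queue <- c(queue, nb) }
      }
    }
  }
  comp
}

# ---- subgraphs and fragments -------------------------------------------

# BFS distances from a center, capped at `radius` bond hops.
bfs_within <- function(g, center, radius) {
  dist <- rep(NA_integer_, g$n)
  dist[center] <- 0L
  queue <- center
  while (length(queue) > 0L) {
    a <- queue[[1L]]; queue <- queue[-1L]
    if (dist[a] >= radius) next
    for (nb in g$adj[[a]]) {
      if (is.na(dist[nb])) {
        dist[nb] <- dist[a] + 1L
        queue <- c(queue, nb)
      }
    }
  }
  dist
}

# Bond indices within `radius` hops of `center` (the circular environment).
env_bonds <- function(g, center, radius) {
  if (radius == 0L || length(g$bond_a) == 0L) return(integer(0))
  dist <- bfs_within(g, center, radius)
  keep <- which(!is.na(dist))
  inset <- logical(g$n); inset[keep] <- TRUE
  which(inset[g$bond_a] & inset[g$bond_b] &
    (pmin(dist[g$bond_a], dist[g$bond_b], na.rm = FALSE) <= radius - 1L))
}

# Induced subgraph on an atom set; keeps parent bookkeeping needed to write
# fragment SMILES (dangling valences become implicit hydrogens).
induced_subgraph <- function(g, atoms) {
  atoms <- sort(unique(atoms))
  remap <- rep(NA_integer_, g$n)
  remap[atoms] <- seq_along(atoms)
  keep <- which(!is.na(remap[g$bond_a]) & !is.na(remap[g$bond_b]))
  sub <- list(
    n = length(atoms),
    elem = g$elem[atoms],
    charge = g$charge[atoms],
    arom = g$arom[atoms],
    bond_a = remap[g$bond_a[keep]],
    bond_b = remap[g$bond_b[keep]],
    bond_order = g$bond_order[keep],
    bond_arom = g$bond_arom[keep],
    parent_atoms = atoms
  )
  sub$adj <- vector("list", sub$n)
  sub$badj <- vector("list", sub$n)
  for (k in seq_along(sub$bond_a)) {
    sub$adj[[sub$bond_a[k]]] <- c(sub$adj[[sub$bond_a[k]]], sub$bond_b[k])
    sub$adj[[sub$bond_b[k]]] <- c(sub$adj[[sub$bond_b[k]]], sub$bond_a[k])
    sub$badj[[sub$bond_a[k]]] <- c(sub$badj[[sub$bond_a[k]]], k)
    sub$badj[[sub$bond_b[k]]] <- c(sub$badj[[sub$bond_b[k]]], k)
  }
  os <- vapply(seq_len(sub$n), function(a) {
    if (length(sub$badj[[a]]) == 0L) 0L else sum(sub$bond_order[sub$badj[[a]]])
  }, integer(1))
  # dangling valence (bonds cut by the fragment boundary) becomes hydrogen
  sub$nH <- pmax(0L, g$nH[atoms] + g$order_sum[atoms] - os)
  sub
}

# Canonical atom ranks for a fragment: Weisfeiler-Lehman colour refinement
# with deterministic tie-breaking, so isomorphic fragments from different
# molecules order identically.
frag_canonical_ranks <- function(sub) {
  color <- match(
    paste(sub$elem, sub$arom, sub$charge, lengths(sub$adj)),
    sort(unique(paste(sub$elem, sub$arom, sub$charge, lengths(sub$adj))))
  )
  refine <- function(color) {
    repeat {
      sig <- vapply(seq_len(sub$n), function(a) {
        nb <- sub$adj[[a]]
        bk <- sub$badj[[a]]
        if (length(nb) == 0L) return(paste0(color[a], "|"))
        codes <- ifelse(sub$bond_arom[bk], 4L, sub$bond_order[bk])
        paste0(color[a], "|", paste(sort(paste0(codes, ":", color[nb])), collapse = ","))
      }, character(1))
      new <- match(sig, sort(unique(sig)))
      if (length(unique(new)) == length(unique(color))) return(new)
      color <- new
    }
  }
  color <- refine(color)
  while (length(unique(color)) < sub$n) {
    tab <- table(color)
    dup <- as.integer(names(tab)[tab > 1L])
    cls <- min(dup)
    a <- which(color == cls)[1L]
    color <- color * 2L
    color[a] <- color[a] - 1L
    color <- refine(match(color, sort(unique(color))))
  }
  color
}

frag_atom_token <- function(sub, a) {
  sym <- sub$elem[a]
  arom <- sub$arom[a]
  organic <- sym %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
  if (arom) sym <- tolower(sym)
  needs_bracket <- sub$charge[a] != 0L || !organic ||
    (arom && sub$elem[a] == "N" && sub$nH[a] > 0L)
  if (!needs_bracket) return(sym)
  h <- sub$nH[a]
  hs <- if (h <= 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ch <- sub$charge[a]
  cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-" else sprintf("%+d", ch)
  paste0("[", sym, hs, cs, "]")
}

frag_bond_token <- function(sub, k, from, to) {
  if (sub$bond_arom[k]) return("")
  o <- sub$bond_order[k]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  if (sub$arom[from] && sub$arom[to]) return("-") # explicit single between aromatics
  ""
}

# Deterministic (canonical up to WL power) SMILES for a fragment subgraph.
write_fragment_smiles <- function(sub) {
  if (sub$n == 0L) return("")
  rank <- frag_canonical_ranks(sub)
  root <- which.min(rank)
  visited <- logical(sub$n)
  used_bond <- logical(length(sub$bond_a))
  ring_digit <- list() # per atom: character vector of digit tokens (with bond symbol)
  next_digit <- 0L
  order_nb <- function(a) {
    nb <- sub$adj[[a]]; bk <- sub$badj[[a]]
    o <- order(rank[nb])
    list(nb = nb[o], bk = bk[o])
  }
  # pass 1: spanning tree + ring-closure digit assignment
  tree_children <- vector("list", sub$n)
  walk <- function(a) {
    visited[a] <<- TRUE
    nbs <- order_nb(a)
    for (j in seq_along(nbs$nb)) {
      b <- nbs$nb[j]; k <- nbs$bk[j]
      if (used_bond[k]) next
      if (!visited[b]) {
        used_bond[k] <<- TRUE
        tree_children[[a]] <<- c(tree_children[[a]], list(c(b, k)))
        walk(b)
      } else {
        used_bond[k] <<- TRUE
        next_digit <<- next_digit + 1L
        d <- if (next_digit < 10L) as.character(next_digit) else paste0("%", next_digit)
        sym <- frag_bond_token(sub, k, a, b)
        ring_digit[[as.character(a)]] <<- c(ring_digit[[as.character(a)]] %||% character(0), paste0(sym, d))
        ring_digit[[as.character(b)]] <<- c(ring_digit[[as.character(b)]] %||% character(0), d)
      }
    }
  }
  walk(root)
  emit <- function(a) {
    tok <- paste0(
      frag_atom_token(sub, a),
      paste(ring_digit[[as.character(a)]] %||% character(0), collapse = "")
    )
    kids <- tree_children[[a]]
    if (length(kids) == 0L) return(tok)
    parts <- vapply(kids, function(bk) {
      paste0(frag_bond_token(sub, bk[2L], a, bk[1L]), emit(bk[1L]))
    }, character(1))
    if (length(parts) > 1L) {
      tok <- paste0(tok, paste0("(", parts[-length(parts)], ")", collapse = ""))
    }
    paste0(tok, parts[[length(parts)]])
  }
  emit(root)
}

# Canonical fragment key: OpenBabel canonical SMILES for fully aliphatic
# fragments (guaranteed to re-parse as written).  Fragments carrying
# aromatic atoms may be partial ring systems that no longer kekulize, so
# they keep the deterministic writer form instead.
canonical_fragment_keys <- function(frag_smiles) {
  uniq <- unique(frag_smiles)
  bare <- gsub("Cl|Br|\\[[^]]*\\]", "", uniq)
  aromatic <- grepl("[a-z]", bare)
  keys <- uniq
  if (any(!aromatic)) {
    can <- ob_canonical(uniq[!aromatic])
    keys[!aromatic] <- ifelse(is.na(can) | !nzchar(can), uniq[!aromatic], can)
  }
  keys[match(frag_smiles, uniq)]
}

# ---- SMARTS ------------------------------------------------------------

# Count SMARTS matches per SMILES (0 for unparseable input).
smarts_match_counts <- function(smiles, smarts, assume_parseable = FALSE) {
  n <- length(smiles)
  res <- integer(n)
  if (assume_parseable) {
    ok <- seq_len(n)
  } else {
    can <- ob_canonical(smiles)
    ok <- which(!is.na(can))
  }
  if (length(ok) == 0L) return(res)
  named <- smiles[ok]
  names(named) <- sprintf("q%06d", seq_along(ok))
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(named)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) != length(ok)) {
    if (assume_parseable) return(smarts_match_counts(smiles, smarts, FALSE))
    return(res)
  }
  hits <- tryCatch(
    suppressWarnings(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE)),
    error = function(e) rep(0L, length(ok))
  )
  res[ok] <- as.integer(hits)
  res
}
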