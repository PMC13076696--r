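# Molecular graphs (heavy atoms, kekule bond orders, hydrogen counts, formal
# charges) recovered from explicit-hydrogen molblocks, and a seeded random-DFS
# SMILES writer built on them. The writer emits kekule SMILES; round-tripping
# through canonicalization is enforced by the caller.

.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Parse molecules into heavy-atom graphs
#'
#' One backend round trip for the whole batch. Each graph is a list with
#' `element` (character), `h` (hydrogen counts), `charge` (formal charges),
#' and `bonds` (matrix with columns a1, a2, order over heavy-atom indices;
#' kekule orders).
#'
#' @param smiles Character vector of valid SMILES.
#' @return List of graphs, aligned with the input.
#' @keywords internal
parse_mol_graphs <- function(smiles) {
  txt <- ob_sdf_text(smiles, explicit_h = TRUE)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  sdf <- ChemmineR::read.SDFset(lines)
  if (length(sdf) != length(smiles)) {
    stop("SDF conversion dropped molecules (", length(sdf), "/", length(smiles), ")")
  }
  # per-molecule M CHG lines, in block order
  block_id <- cumsum(c(1L, utils::head(lines, -1) == "$$$$"))
  chg_by_block <- split(grep("^M  CHG", lines, value = TRUE),
                        block_id[grepl("^M  CHG", lines)])

  lapply(seq_along(smiles), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    bb <- ChemmineR::bondblock(sdf[[i]])
    element <- sub("_[0-9]+$", "", rownames(ab))
    n_all <- length(element)

    charge <- integer(n_all)
    for (ln in chg_by_block[[as.character(i)]]) {
      fields <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      for (e in seq_len(fields[1])) {
        charge[fields[2 * e]] <- fields[2 * e + 1]
      }
    }

    heavy <- which(element != "H")
    idx_map <- integer(n_all)
    idx_map[heavy] <- seq_along(heavy)

    b1 <- as.integer(bb[, 1]); b2 <- as.integer(bb[, 2]); bo <- as.integer(bb[, 3])
    h <- integer(length(heavy))
    keep <- logical(length(b1))
    for (k in seq_along(b1)) {
      e1 <- element[b1[k]]; e2 <- element[b2[k]]
      if (e1 == "H" && e2 == "H") next
      if (e1 == "H") { h[idx_map[b2[k]]] <- h[idx_map[b2[k]]] + 1L; next }
      if (e2 == "H") { h[idx_map[b1[k]]] <- h[idx_map[b1[k]]] + 1L; next }
      keep[k] <- TRUE
    }
    bonds <- cbind(a1 = idx_map[b1[keep]], a2 = idx_map[b2[keep]], order = bo[keep])
    list(element = element[heavy], h = h, charge = charge[heavy], bonds = bonds)
  })
}

#' @rdname parse_mol_graphs
#' @keywords internal
parse_mol_graph <- function(smiles) {
  parse_mol_graphs(smiles[1])[[1]]
}

# SMILES atom spelling: bare organic-subset symbol when the hydrogen count
# matches the default implicit valence, bracket form otherwise.
.atom_spelling <- function(element, h, charge, bond_order_sum) {
  if (charge == 0L && element %in% names(.default_valences)) {
    vals <- .default_valences[[element]]
    v <- vals[vals >= bond_order_sum]
    implicit <- if (length(v)) v[1] - bond_order_sum else 0L
    if (h == implicit) return(element)
  }
  hpart <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  cpart <- if (charge == 0L) "" else if (charge == 1L) "+" else if (charge == -1L) "-" else
    sprintf("%+d", charge)
  paste0("[", element, hpart, cpart, "]")
}

.bond_symbol <- function(order) c("", "=", "#")[order]

# One random depth-first SMILES spelling for a parsed graph; consumes the
# current R RNG stream. Two passes per connected component: (1) a randomized
# iterative DFS fixing the spanning tree, child order, and ring-closure
# (non-tree) edges; (2) recursive emission with branches in parentheses and
# paired ring-closure digits.
.random_dfs_smiles <- function(g) {
  n <- length(g$element)
  nb <- vector("list", n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds[k, 1]; b <- g$bonds[k, 2]; o <- g$bonds[k, 3]
      nb[[a]] <- rbind(nb[[a]], c(b, o))
      nb[[b]] <- rbind(nb[[b]], c(a, o))
    }
  }
  bosum <- vapply(seq_len(n), function(i) {
    if (is.null(nb[[i]])) 0 else sum(nb[[i]][, 2])
  }, numeric(1))

  visited <- logical(n)
  components <- character(0)

  while (any(!visited)) {
    remaining <- which(!visited)
    root <- if (length(remaining) == 1L) remaining else sample(remaining, 1L)

    parent <- rep(NA_integer_, n)
    porder <- integer(n)
    order_children <- vector("list", n)
    in_tree <- logical(n)
    ring_edges <- NULL

    st <- list(c(root, 0L, 0L)) # atom, parent, bond order
    while (length(st)) {
      top <- st[[length(st)]]
      st[[length(st)]] <- NULL
      a <- top[1]; p <- top[2]; o <- top[3]
      if (in_tree[a]) {
        if (p > 0L) ring_edges <- rbind(ring_edges, c(p, a, o))
        next
      }
      in_tree[a] <- TRUE
      parent[a] <- p
      porder[a] <- o
      nbr <- nb[[a]]
      if (!is.null(nbr)) {
        for (k in sample.int(nrow(nbr), nrow(nbr))) {
          b <- nbr[k, 1]; bo <- nbr[k, 2]
          if (b == p) next
          if (in_tree[b]) {
            ring_edges <- rbind(ring_edges, c(a, b, bo))
          } else {
            order_children[[a]] <- c(order_children[[a]], b)
            st[[length(st) + 1L]] <- c(b, a, bo)
          }
        }
      }
    }

    ring_list <- vector("list", n)
    if (!is.null(ring_edges)) {
      key <- paste(pmin(ring_edges[, 1], ring_edges[, 2]),
                   pmax(ring_edges[, 1], ring_edges[, 2]))
      ring_edges <- ring_edges[!duplicated(key), , drop = FALSE]
      # emission (preorder) positions, for label reuse by interval scheduling
      pos <- integer(n)
      cnt <- 0L
      walk <- function(a) {
        cnt <<- cnt + 1L
        pos[a] <<- cnt
        for (b in order_children[[a]]) {
          if (!is.na(parent[b]) && parent[b] == a) walk(b)
        }
      }
      walk(root)
      starts <- pmin(pos[ring_edges[, 1]], pos[ring_edges[, 2]])
      ends <- pmax(pos[ring_edges[, 1]], pos[ring_edges[, 2]])
      ord <- order(starts, ends)
      lab_end <- integer(99) # per label, position where it was last closed
      for (k in ord) {
        lab <- which(lab_end < starts[k])[1] # smallest reusable label
        if (is.na(lab)) stop("ring-closure labels exhausted")
        lab_end[lab] <- ends[k]
        a <- ring_edges[k, 1]; b <- ring_edges[k, 2]; o <- ring_edges[k, 3]
        ring_list[[a]] <- rbind(ring_list[[a]], c(lab, o))
        ring_list[[b]] <- rbind(ring_list[[b]], c(lab, o))
      }
    }

    ring_digit <- function(lab, order) {
      d <- if (lab > 9L) paste0("%", sprintf("%02d", lab)) else as.character(lab)
      paste0(.bond_symbol(order), d)
    }
    write_atom <- function(a) {
      s <- .atom_spelling(g$element[a], g$h[a], g$charge[a], bosum[a])
      rl <- ring_list[[a]]
      if (!is.null(rl)) {
        for (k in seq_len(nrow(rl))) s <- paste0(s, ring_digit(rl[k, 1], rl[k, 2]))
      }
      kids <- order_children[[a]]
      kids <- kids[parent[kids] == a] # drop atoms reached first via another path
      if (length(kids)) {
        for (k in seq_along(kids)) {
          child <- paste0(.bond_symbol(porder[kids[k]]), write_atom(kids[k]))
          s <- if (k < length(kids)) paste0(s, "(", child, ")") else paste0(s, child)
        }
      }
      s
    }
    components <- c(components, write_atom(root))
    visited <- visited | in_tree
  }
  paste(components, collapse = ".")
}

#' Seed-reproducible randomized SMILES
#'
#' Emits `n` alternative (non-canonical, kekule) SMILES spellings of a
#' molecule by random depth-first traversal of its heavy-atom graph. Every
#' output is verified to canonicalize back to the canonical form of the input;
#' a failure to round-trip is an error, not a silent substitution.
#'
#' @param smiles A single valid (ideally standardized) SMILES string.
#' @param n Number of spellings to draw.
#' @param seed Optional integer seed; when NULL the current RNG stream is
#'   used (so callers may manage seeding themselves).
#' @return Character vector of length `n`.
#' @export
randomize_smiles <- function(smiles, n = 1, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  g <- parse_mol_graph(smiles)
  out <- vapply(seq_len(n), function(i) .random_dfs_smiles(g), character(1))
  can_in <- ob_convert_smiles(smiles)
  can_out <- ob_convert_smiles(out)
  bad <- is.na(can_out) | can_out != can_in
  if (any(bad)) {
    stop("randomized SMILES failed round-trip for: ", smiles,
         " -> ", out[which(bad)[1]])
  }
  out
}

# Batch helper: one random spelling per pre-parsed graph (shared RNG stream);
# used by the randomized training variant every epoch. Round-trip is not
# re-verified here (inputs were standardized and the writer is
# round-trip-tested); verifying every epoch would dominate the epoch cost.
.randomize_each <- function(graphs) {
  vapply(graphs, .random_dfs_smiles, character(1))
}

#' Ring sizes of a molecule
#'
#' Smallest-set ring perception on the heavy-atom graph.
#'
#' @param smiles A single valid SMILES string.
#' @return Integer vector of ring sizes (possibly empty).
#' @export
ring_sizes <- function(smiles) {
  sdf <- ChemmineR::read.SDFset(strsplit(ob_sdf_text(smiles), "\n")[[1]])
  r <- tryCatch(ChemmineR::rings(sdf[[1]], inner = TRUE), error = function(e) NULL)
  if (is.null(r) || !length(r)) return(integer(0))
  unname(vapply(r, length, integer(1)))
}

#' Aromatic and aliphatic ring counts
#'
#' @param smiles Character vector of valid SMILES.
#' @return Data frame with columns `aromatic` and `aliphatic`.
#' @export
ring_counts <- function(smiles) {
  sdf <- ChemmineR::read.SDFset(strsplit(ob_sdf_text(smiles), "\n")[[1]])
  arom <- integer(length(smiles)); alip <- integer(length(smiles))
  for (i in seq_along(smiles)) {
    r <- tryCatch(ChemmineR::rings(sdf[[i]], inner = TRUE, arom = TRUE),
                  error = function(e) NULL)
    if (is.null(r) || !length(r$RINGS)) next
    arom[i] <- sum(r$AROMATIC)
    alip[i] <- sum(!r$AROMATIC)
  }
  data.frame(aromatic = arom, aliphatic = alip)
}

#' Murcko scaffold of a molecule
#'
#' Ring systems plus the linkers connecting them, with all substituents
#' removed: iteratively prunes non-ring atoms of degree one from the
#' heavy-atom graph and returns the canonical SMILES of what remains.
#'
#' @param smiles A single valid SMILES string.
#' @return Canonical scaffold SMILES, or NA for acyclic molecules.
#' @export
murcko_scaffold <- function(smiles) {
  g <- parse_mol_graph(smiles)
  n <- length(g$element)
  if (!nrow(g$bonds)) return(NA_character_)
  keep <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    for (k in seq_len(nrow(g$bonds))) {
      if (keep[g$bonds[k, 1]] && keep[g$bonds[k, 2]]) {
        deg[g$bonds[k, 1]] <- deg[g$bonds[k, 1]] + 1L
        deg[g$bonds[k, 2]] <- deg[g$bonds[k, 2]] + 1L
      }
    }
    prune <- keep & deg <= 1L
    if (!any(prune)) break
    keep[prune] <- FALSE
    if (!any(keep)) return(NA_character_) # acyclic: everything pruned away
  }
  remap <- cumsum(keep)
  m <- g$bonds[keep[g$bonds[, 1]] & keep[g$bonds[, 2]], , drop = FALSE]
  sub <- list(
    element = g$element[keep],
    charge = g$charge[keep],
    bonds = cbind(a1 = remap[m[, 1]], a2 = remap[m[, 2]], order = m[, 3])
  )
  # hydrogen counts on cut atoms changed; rebuild all as implicit defaults
  bosum <- integer(sum(keep))
  for (k in seq_len(nrow(sub$bonds))) {
    bosum[sub$bonds[k, 1]] <- bosum[sub$bonds[k, 1]] + sub$bonds[k, 3]
    bosum[sub$bonds[k, 2]] <- bosum[sub$bonds[k, 2]] + sub$bonds[k, 3]
  }
  sub$h <- integer(sum(keep))
  for (i in seq_len(sum(keep))) {
    vals <- .default_valences[[sub$element[i]]]
    if (!is.null(vals) && sub$charge[i] == 0L) {
      v <- vals[vals >= bosum[i]]
      sub$h[i] <- if (length(v)) as.integer(v[1] - bosum[i]) else 0L
    }
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(0L)
  ob_convert_smiles(.random_dfs_smiles(sub))
}
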