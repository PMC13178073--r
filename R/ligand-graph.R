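## Ligand graphs: small-molecule connection tables read from SDF V2000.
## Implicit hydrogens come from standard valences, ring membership from
## cycle detection, and aromaticity from SDF aromatic bond flags or Kekule
## alternation in 6-rings.

BASE_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                  S = 2, Cl = 1, Br = 1, I = 1)

#' Ligand graph constructor
#'
#' @param elements element symbols per node.
#' @param formal_charges integer formal charges per node.
#' @param bonds data.frame with columns `a`, `b` (1-based node indices) and
#'   `order` (1, 2, 3, or 4 for an SDF aromatic flag).
#' @return object of class `ligand_graph` with per-node implicit-H counts,
#'   ring membership and aromaticity filled in.
#' @export
ligand_graph <- function(elements, formal_charges = 0L, bonds) {
  n <- length(elements)
  formal_charges <- rep_len(as.integer(formal_charges), n)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) && !all(bonds$order %in% c(1, 2, 3, 4)))
    stop("bond orders must be in {1, 2, 3, 4(aromatic)}")
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, rbind(bonds$a, bonds$b))
  if (igraph::components(g)$no != 1 && n > 1)
    stop("ligand graph must be connected")

  ## ring membership: an atom lies on a cycle iff it touches a non-bridge edge
  in_ring <- rep(FALSE, n)
  if (nrow(bonds)) {
    bridge_ids <- as.integer(igraph::bridges(g))
    cyclic <- setdiff(seq_len(nrow(bonds)), bridge_ids)
    in_ring[unique(c(bonds$a[cyclic], bonds$b[cyclic]))] <- TRUE
  }

  ## aromaticity: SDF flag 4, or Kekule 1-2 alternation around a 6-ring
  aromatic_bond <- if (nrow(bonds)) bonds$order == 4 else logical(0)
  if (nrow(bonds)) {
    for (ring in six_rings(bonds, n)) {
      e_idx <- ring_edge_indices(ring, bonds)
      orders <- bonds$order[e_idx]
      if (all(orders %in% c(1, 2)) && all(abs(diff(c(orders, orders[1]))) == 1))
        aromatic_bond[e_idx] <- TRUE
    }
  }
  aromatic_atom <- rep(FALSE, n)
  if (any(aromatic_bond))
    aromatic_atom[unique(c(bonds$a[aromatic_bond], bonds$b[aromatic_bond]))] <- TRUE

  ## implicit hydrogens by standard valence (aromatic bonds count 1.5)
  order_val <- if (nrow(bonds)) ifelse(aromatic_bond, 1.5, pmin(bonds$order, 3)) else numeric(0)
  bond_sum <- rep(0, n)
  for (k in seq_len(nrow(bonds))) {
    bond_sum[bonds$a[k]] <- bond_sum[bonds$a[k]] + order_val[k]
    bond_sum[bonds$b[k]] <- bond_sum[bonds$b[k]] + order_val[k]
  }
  base <- BASE_VALENCE[elements]
  base[is.na(base)] <- 0
  n_h <- pmax(0L, as.integer(round(base + formal_charges - bond_sum)))
  heavy_degree <- rep(0L, n)
  if (nrow(bonds)) {
    tab <- table(factor(c(bonds$a, bonds$b), levels = seq_len(n)))
    heavy_degree <- as.integer(tab)
  }

  structure(list(
    atoms = data.frame(element = as.character(elements),
                       formal_charge = formal_charges,
                       heavy_degree = heavy_degree, n_h = n_h,
                       in_ring = in_ring, aromatic = aromatic_atom,
                       stringsAsFactors = FALSE),
    bonds = data.frame(a = as.integer(bonds$a), b = as.integer(bonds$b),
                       order = as.integer(bonds$order),
                       aromatic = aromatic_bond)
  ), class = "ligand_graph")
}

## all simple 6-cycles (as ordered vertex vectors), deduplicated
six_rings <- function(bonds, n) {
  adj <- lapply(seq_len(n), function(i)
    sort(unique(c(bonds$b[bonds$a == i], bonds$a[bonds$b == i]))))
  rings <- list()
  seen <- character(0)
  path <- integer(6)
  walk <- function(depth, v, start) {
    path[depth] <<- v
    if (depth == 6) {
      if (start %in% adj[[v]]) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) { seen <<- c(seen, key); rings[[length(rings) + 1]] <<- path }
      }
      return()
    }
    for (w in adj[[v]])
      if (w > start && !(w %in% path[seq_len(depth)])) walk(depth + 1L, w, start)
  }
  for (s in seq_len(n)) walk(1L, s, s)
  rings
}

ring_edge_indices <- function(ring, bonds) {
  pairs <- cbind(ring, c(ring[-1], ring[1]))
  vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    which((bonds$a == i & bonds$b == j) | (bonds$a == j & bonds$b == i))[1]
  }, 0L)
}

#' @export
print.ligand_graph <- function(x, ...) {
  cat(sprintf("<ligand_graph> %d heavy atoms, %d bonds, %d ring atoms\n",
              nrow(x$atoms), nrow(x$bonds), sum(x$atoms$in_ring)))
  invisible(x)
}

#' Read a small-molecule structure from an SDF V2000 file
#'
#' Elements, formal charges and bond orders come from the connection table
#' (parsed with ChemmineR); implicit hydrogens are assigned by standard
#' valence, ring membership by cycle detection, and aromaticity from bond
#' flags or Kekule alternation in 6-rings.
#'
#' @param path SDF file path (first record is read).
#' @return a [ligand_graph()].
#' @export
read_sdf <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("malformed SDF: fewer than 4 header lines")
  counts <- lines[4]
  if (grepl("V3000", counts)) stop("V3000 SDF files are not supported")
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || is.na(n_bonds) || n_atoms < 1)
    stop("malformed SDF counts line: ", counts)

  if (n_bonds > 0) {
    sdf <- ChemmineR::read.SDFset(path)[[1]]
    ab <- ChemmineR::atomblock(sdf)
    elements <- sub("_[0-9]+$", "", rownames(ab))
    if (nrow(ab) != n_atoms) stop("atom block does not match counts line")
    bb <- ChemmineR::bondblock(sdf)
    bonds <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  } else {
    ## bond-free molecules (single-atom) fail ChemmineR's validity check;
    ## take elements from the fixed-width atom block directly
    elements <- trimws(substr(lines[4 + seq_len(n_atoms)], 32, 34))
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0))
  }

  ## formal charges from M  CHG property lines (override the atom block)
  charges <- rep(0L, n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substring(ln, 7)), "[[:space:]]+")[[1]])
    k <- toks[1]
    for (m in seq_len(k)) charges[toks[2 * m]] <- toks[2 * m + 1]
  }
  ligand_graph(elements, charges, bonds)
}
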