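## Circular (Morgan/ECFP-style) fingerprints over ligand graphs, and the
## Tanimoto index between them. Hashing is a stable 32-bit polynomial mix of
## sorted (bond order, neighbor identifier) tuples, so fingerprints are
## reproducible across platforms. Chirality is ignored (default ECFP
## behavior); aromatic bonds use a dedicated bond code.

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                   S = 16, Cl = 17, Br = 35, I = 53)

HASH_MOD <- 2147483647  # 2^31 - 1

## stable polynomial hash of an integer vector into [0, 2^31-2]
mix_hash <- function(values) {
  h <- 17
  for (v in values) {
    h <- (h * 1000003 + (as.numeric(v) %% HASH_MOD)) %% HASH_MOD
  }
  as.integer(h)
}

#' Morgan (ECFP-style) circular fingerprint of a ligand graph
#'
#' Initial atom identifiers hash the invariant tuple (atomic number, heavy
#' degree, attached hydrogens, formal charge, ring flag); each iteration
#' rehashes an atom's identifier together with its sorted
#' (bond code, neighbor identifier) pairs, up to the given radius.
#' Environments covering an identical bond set are deduplicated (keeping the
#' first, as in standard ECFP); surviving identifiers are folded modulo
#' `n_bits` into a bitset and also kept as an identifier count multiset.
#'
#' @param graph a [ligand_graph()].
#' @param radius neighborhood radius (default 2, the ECFP4-equivalent).
#' @param n_bits folded bitset length (default 2048).
#' @return object of class `fingerprint_profile` with elements `bits`
#'   (sorted 1-based positions of set bits), `counts` (named identifier
#'   multiset), `n_bits`, `radius`, `n_on`.
#' @export
morgan_fingerprint <- function(graph, radius = 2L, n_bits = 2048L) {
  stopifnot(inherits(graph, "ligand_graph"), radius >= 0, n_bits >= 1)
  at <- graph$atoms
  bd <- graph$bonds
  n <- nrow(at)
  if (n > 1) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, rbind(bd$a, bd$b))
    if (igraph::components(g)$no != 1) stop("fingerprint requires a connected graph")
    dist <- igraph::distances(g)
  } else {
    dist <- matrix(0, 1, 1)
  }

  znum <- ATOMIC_NUMBER[at$element]
  znum[is.na(znum)] <- 0
  ids <- vapply(seq_len(n), function(i)
    mix_hash(c(znum[i], at$heavy_degree[i], at$n_h[i],
               at$formal_charge[i], as.integer(at$in_ring[i]))), 0L)

  bond_code <- if (nrow(bd)) ifelse(bd$aromatic, 4L, bd$order) else integer(0)
  nbrs <- lapply(seq_len(n), function(i) {
    k <- which(bd$a == i | bd$b == i)
    j <- ifelse(bd$a[k] == i, bd$b[k], bd$a[k])
    list(atom = j, code = bond_code[k], edge = k)
  })

  features <- data.frame(id = ids, radius = 0L, atom = seq_len(n))
  seen_envs <- character(0)
  keep <- rep(TRUE, n)
  if (radius >= 1) {
    for (r in seq_len(radius)) {
      new_ids <- ids
      for (i in seq_len(n)) {
        nb <- nbrs[[i]]
        if (!length(nb$atom)) next
        ord <- order(nb$code, ids[nb$atom])
        tuple <- c(r, ids[i], rbind(nb$code[ord], ids[nb$atom[ord]]))
        new_ids[i] <- mix_hash(tuple)
      }
      ids <- new_ids
      for (i in seq_len(n)) {
        if (!length(nbrs[[i]]$atom)) { keep <- c(keep, FALSE); next }
        env_edges <- which(pmin(dist[i, bd$a], dist[i, bd$b]) <= r - 1)
        key <- paste(env_edges, collapse = ",")
        fresh <- !(key %in% seen_envs)
        if (fresh) seen_envs <- c(seen_envs, key)
        keep <- c(keep, fresh)
      }
      features <- rbind(features,
                        data.frame(id = ids, radius = r, atom = seq_len(n)))
    }
  }
  kept <- features[keep, ]
  counts <- table(kept$id)
  bit_pos <- sort(unique(kept$id %% as.integer(n_bits) + 1L))
  structure(list(bits = bit_pos,
                 counts = setNames(as.integer(counts), names(counts)),
                 n_bits = as.integer(n_bits), radius = as.integer(radius),
                 n_on = length(bit_pos)),
            class = "fingerprint_profile")
}

#' @export
print.fingerprint_profile <- function(x, ...) {
  cat(sprintf("<fingerprint_profile> radius %d, %d/%d bits on, %d environments\n",
              x$radius, x$n_on, x$n_bits, sum(x$counts)))
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' In `"counts"` mode (default) the index is the multiset Tanimoto
#' sum(min)/sum(max) over environment-identifier counts, the convention under
#' which radius-2 Morgan similarities of close triterpenoid analogues fall in
#' the 0.4-0.8 range; `"bits"` mode is |a AND b| / |a OR b| on the folded
#' bitsets. Both fingerprints must share radius and bit length. Two empty
#' fingerprints score 1.0 with attribute `both_empty = TRUE`.
#'
#' @param a,b [morgan_fingerprint()] profiles.
#' @param on `"counts"` or `"bits"`.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b, on = c("counts", "bits")) {
  on <- match.arg(on)
  stopifnot(inherits(a, "fingerprint_profile"), inherits(b, "fingerprint_profile"))
  if (a$n_bits != b$n_bits || a$radius != b$radius)
    stop("fingerprints have mismatched parameters (radius/bit length)")
  if (on == "bits") {
    inter <- length(intersect(a$bits, b$bits))
    uni <- length(union(a$bits, b$bits))
  } else {
    keys <- union(names(a$counts), names(b$counts))
    ca <- ifelse(keys %in% names(a$counts), a$counts[keys], 0L)
    cb <- ifelse(keys %in% names(b$counts), b$counts[keys], 0L)
    ca[is.na(ca)] <- 0L; cb[is.na(cb)] <- 0L
    inter <- sum(pmin(ca, cb))
    uni <- sum(pmax(ca, cb))
  }
  if (uni == 0) return(structure(1.0, both_empty = TRUE))
  as.numeric(inter) / uni
}

#' Pairwise Tanimoto similarity matrix for a set of SDF files
#'
#' @param paths named character vector of SDF paths (names label the matrix).
#' @param radius,n_bits fingerprint parameters.
#' @param on `"counts"` or `"bits"` (see [tanimoto()]).
#' @return symmetric numeric matrix of similarities.
#' @export
similarity_matrix <- function(paths, radius = 2L, n_bits = 2048L,
                              on = c("counts", "bits")) {
  on <- match.arg(on)
  labels <- if (is.null(names(paths))) basename(paths) else names(paths)
  fps <- lapply(paths, function(p) morgan_fingerprint(read_sdf(p), radius, n_bits))
  m <- diag(1, length(fps))
  dimnames(m) <- list(labels, labels)
  for (i in seq_along(fps)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- tanimoto(fps[[i]], fps[[j]], on = on)
  }
  m
}
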