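# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (path enumeration, double loops, Floyd-Warshall) so the
# package implementations are checked against a different route.

# Floyd-Warshall shortest paths on the tree graph -> tip-to-tip distances
oracle_cophenetic <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  d <- matrix(Inf, nn, nn)
  diag(d) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    d[i, j] <- d[j, i] <- tree$edge.length[e]
  }
  for (k in seq_len(nn)) {
    for (i in seq_len(nn)) {
      for (j in seq_len(nn)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  out <- d[seq_len(ntip), seq_len(ntip)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# brute-force double loops
oracle_mpd <- function(dm, present) {
  idx <- match(present, colnames(dm))
  tot <- 0; np <- 0
  for (i in seq_along(idx)) {
    for (j in seq_along(idx)) {
      if (j > i) { tot <- tot + dm[idx[i], idx[j]]; np <- np + 1 }
    }
  }
  tot / np
}

oracle_mntd <- function(dm, present) {
  idx <- match(present, colnames(dm))
  mean(vapply(seq_along(idx), function(i) {
    min(dm[idx[i], idx[-i]])
  }, numeric(1)))
}

# PD via root-path enumeration: union of edges on each present tip's path to
# the root; the edges shared by every path form the MRCA-to-root spine
oracle_pd <- function(tree, present, include_root = TRUE) {
  ntip <- length(tree$tip.label)
  parent_edge <- integer(ntip + tree$Nnode)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  paths <- lapply(match(present, tree$tip.label), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  })
  edges <- unique(unlist(paths))
  if (!include_root) {
    spine <- Reduce(intersect, paths)
    edges <- setdiff(edges, spine)
  }
  sum(tree$edge.length[edges])
}

# random tree with fresh labels (ape::rtree is independent of simulate_tree)
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

# minimal RMS distance between two configurations after centering and
# optimal orthogonal rotation/reflection (no scaling)
procrustes_rms <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  rot <- s$u %*% t(s$v)
  sqrt(mean((yc %*% rot - xc)^2))
}

# deep two-clade tree: two star-like clades of `m` tips hanging far apart
two_clade_tree <- function(m = 5, gap = 10) {
  left <- paste(sprintf("L%d:1", seq_len(m)), collapse = ",")
  right <- paste(sprintf("R%d:1", seq_len(m)), collapse = ",")
  parse_newick(sprintf("((%s):%g,(%s):%g);", left, gap / 2, right, gap / 2))
}

# small community over given species
comm_fixture <- function(rows, species, habitat = NULL) {
  inc <- do.call(rbind, rows)
  dimnames(inc) <- list(names(rows), species)
  community_matrix(inc, habitat = habitat)
}
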