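# Observed per-site phylogenetic alpha metrics: Faith's PD, mean pairwise
# distance (MPD) and mean nearest taxon distance (MNTD). All are
# incidence-based (unweighted).

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting the species present
#' at a site. With `include_root = TRUE` (default) the path from the species'
#' MRCA up to the tree root is included, so the PD of the whole species pool
#' equals the total tree length.
#'
#' @param tree a `phylo` object.
#' @param present character vector of species present (subset of tip labels).
#' @param include_root include the MRCA-to-root path (default `TRUE`).
#' @return numeric PD in branch-length units.
#' @export
pd_faith <- function(tree, present, include_root = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  present <- unique(normalize_names(present))
  if (length(present) == 0) stop("empty species set")
  idx <- match(.name_key(present), .name_key(tree$tip.label))
  if (anyNA(idx)) {
    stop("species not in tree: ", .quote_names(present[is.na(idx)]))
  }
  k <- length(idx)
  ntip <- length(tree$tip.label)
  # count present descendants below each edge (postorder accumulation)
  tree <- ape::reorder.phylo(tree, "postorder")
  npres <- integer(ntip + tree$Nnode)
  npres[idx] <- 1L
  for (e in seq_len(nrow(tree$edge))) {
    npres[tree$edge[e, 1]] <- npres[tree$edge[e, 1]] + npres[tree$edge[e, 2]]
  }
  below <- npres[tree$edge[, 2]]
  spanned <- below >= 1L & below < k
  pd <- sum(tree$edge.length[spanned])
  if (include_root) pd <- pd + sum(tree$edge.length[below == k])
  pd
}

#' Mean pairwise phylogenetic distance
#'
#' Mean cophenetic distance over all unordered pairs of species present.
#' Undefined (returns `NA`) for fewer than two species.
#'
#' @param dm cophenetic distance matrix (see [cophenetic_matrix()]).
#' @param present character vector of species present.
#' @return numeric MPD, or `NA_real_` when `|present| < 2`.
#' @export
mpd <- function(dm, present) {
  idx <- .present_idx(dm, present)
  if (length(idx) < 2) return(NA_real_)
  d <- dm[idx, idx]
  sum(d) / (length(idx) * (length(idx) - 1))
}

#' Mean nearest taxon distance
#'
#' Mean, over the species present, of the distance to the nearest other
#' species present. Undefined (`NA`) for fewer than two species.
#'
#' @inheritParams mpd
#' @return numeric MNTD, or `NA_real_` when `|present| < 2`.
#' @export
mntd <- function(dm, present) {
  idx <- .present_idx(dm, present)
  if (length(idx) < 2) return(NA_real_)
  d <- dm[idx, idx]
  diag(d) <- Inf
  mean(d[cbind(seq_along(idx), max.col(-d, ties.method = "first"))])
}

.present_idx <- function(dm, present) {
  present <- unique(normalize_names(present))
  idx <- match(.name_key(present), .name_key(colnames(dm)))
  if (anyNA(idx)) {
    stop("species not in distance matrix: ", .quote_names(present[is.na(idx)]))
  }
  idx
}

#' Per-site alpha metrics table
#'
#' @param tree pruned `phylo` covering all community species.
#' @param cm a [community_matrix()].
#' @param dm optional precomputed [cophenetic_matrix()] of `tree`.
#' @param include_root see [pd_faith()].
#' @return data.frame with columns `site_id`, `SR`, `PD`, `MPD_obs`,
#'   `MNTD_obs` (the latter two `NA` for sites with a single species).
#' @export
site_metrics <- function(tree, cm, dm = NULL, include_root = TRUE) {
  stopifnot(inherits(cm, "comm_matrix"))
  if (is.null(dm)) dm <- cophenetic_matrix(tree)
  res <- lapply(cm$site_ids, function(s) {
    sp <- cm$species[cm$incidence[s, ] == 1L]
    data.frame(site_id = s, SR = length(sp),
               PD = pd_faith(tree, sp, include_root = include_root),
               MPD_obs = mpd(dm, sp), MNTD_obs = mntd(dm, sp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
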