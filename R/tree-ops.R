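# Tree input/output, megatree pruning with genus-level grafting, and
# patristic (cophenetic) distances. Trees are ape "phylo" objects throughout;
# the functions here add the validation the pipeline relies on: unique tip
# labels, non-negative branch lengths, a single root.

#' Parse a Newick string into a validated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the pipeline assumes: balanced parentheses, unique tip labels and
#' non-negative branch lengths. The tree is treated as rooted at the
#' outermost node.
#'
#' @param text a Newick string (must end with `;`).
#' @return an object of class `phylo`.
#' @seealso [read_newick()] for reading from a file, [write_newick()].
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' sum(tr$edge.length)  # 5
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("newick parse error: unbalanced ')' at position ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("newick parse error: ", depth, " unclosed '(' at end of input")
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("newick parse error: input is not a tree")
  validate_tree(tree)
}

#' @rdname parse_newick
#' @param path path to a Newick file.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path, digits = 15) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

# enforce PhyloTree invariants on an ape phylo object
validate_tree <- function(tree) {
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate tip labels: ", .quote_names(dup))
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths")
  }
  neg <- which(tree$edge.length < 0)
  if (length(neg) > 0) {
    stop("negative branch length on edge ", neg[1], " (",
         tree$edge.length[neg[1]], ")")
  }
  tree
}

#' Prune a phylogeny to a set of taxa, optionally grafting missing species
#'
#' Reduces a (mega)tree to the species observed in a study. Names are matched
#' case-insensitively after replacing spaces with underscores. Species absent
#' from the tree can be grafted at genus level: a missing binomial whose genus
#' (first underscore-separated token) has at least one tip in the tree is
#' attached as a polytomy child of the most recent common ancestor (MRCA) of
#' its congeners, with pendant branch length equal to the mean path length
#' from that MRCA to the existing congener tips. If the genus has exactly one
#' tip the new species is attached at that tip's parent with the congener's
#' own pendant length (keeping both at the same depth). Missing species with
#' no congeners are dropped and reported.
#'
#' Degree-2 internal nodes created by pruning are collapsed with branch
#' lengths summed, so tip-to-tip path lengths among retained taxa are
#' conserved. Retained tips are relabelled to the query spelling.
#'
#' @param tree a `phylo` megatree (validated as in [parse_newick()]).
#' @param taxa character vector of species names to keep.
#' @param graft_missing logical; graft species absent from the tree (default
#'   `FALSE`).
#' @return a list with components `tree` (the pruned `phylo`) and `report`
#'   (data.frame with columns `name`, `status` in `kept`/`grafted`/`dropped`).
#' @export
prune_to_taxa <- function(tree, taxa, graft_missing = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- unique(normalize_names(taxa))
  if (length(taxa) == 0) stop("no resolvable taxa: empty taxon set")
  keys <- .name_key(taxa)
  status <- rep("dropped", length(taxa))
  names(status) <- taxa

  tip_keys <- .name_key(tree$tip.label)
  status[keys %in% tip_keys] <- "kept"

  if (graft_missing) {
    for (i in which(!(keys %in% .name_key(tree$tip.label)))) {
      genus <- .name_key(sub("_.*$", "", taxa[i]))
      cong <- which(.name_key(sub("_.*$", "", tree$tip.label)) == genus)
      if (length(cong) == 0) next
      tree <- .graft_tip(tree, cong, taxa[i])
      status[i] <- "grafted"
    }
  }

  tip_keys <- .name_key(tree$tip.label)
  keep_idx <- match(keys, tip_keys)
  found <- !is.na(keep_idx)
  if (!any(found)) {
    stop("no resolvable taxa: none of ", .quote_names(taxa),
         " match the tree", if (!graft_missing) " (grafting disabled)")
  }
  pruned <- .keep_tips(tree, tree$tip.label[keep_idx[found]])
  # relabel to the query spelling
  pruned$tip.label <- taxa[found][match(.name_key(pruned$tip.label),
                                        keys[found])]
  list(tree = validate_tree(pruned),
       report = data.frame(name = taxa, status = unname(status),
                           stringsAsFactors = FALSE))
}

# attach `label` near the congener tips `cong` (tip indices); polytomy child
# of their MRCA with pendant length = mean MRCA->congener path.
.graft_tip <- function(tree, cong, label) {
  depths <- ape::node.depth.edgelength(tree)
  if (length(cong) == 1L) {
    node <- tree$edge[tree$edge[, 2] == cong, 1]
    len <- tree$edge.length[tree$edge[, 2] == cong]
  } else {
    node <- ape::getMRCA(tree, cong)
    len <- mean(depths[cong] - depths[node])
  }
  .add_tip_at_node(tree, node, label, len)
}

# insert a new tip as a child of internal node `node` (no new internal node)
.add_tip_at_node <- function(tree, node, label, length) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  edge[edge > ntip] <- edge[edge > ntip] + 1L
  node <- if (node > ntip) node + 1L else node
  tree$edge <- rbind(edge, c(node, ntip + 1L))
  storage.mode(tree$edge) <- "integer"
  tree$edge.length <- c(tree$edge.length, length)
  tree$tip.label <- c(tree$tip.label, label)
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

# keep.tip that also handles the single-tip case (depth preserved)
.keep_tips <- function(tree, tips) {
  if (length(tips) == 1L) {
    i <- match(tips, tree$tip.label)
    depth <- ape::node.depth.edgelength(tree)[i]
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          edge.length = depth, Nnode = 1L,
                          tip.label = tips),
                     class = "phylo", order = "cladewise"))
  }
  ape::keep.tip(tree, tips)
}

#' Patristic (cophenetic) distance matrix
#'
#' Pairwise tip-to-tip distances: the sum of branch lengths along the unique
#' path between each pair of tips, in the same units as the branch lengths.
#'
#' @param tree a `phylo` object with at least 2 tips.
#' @return a symmetric numeric matrix with zero diagonal, rows/columns in
#'   `tree$tip.label` order.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) {
    stop("cophenetic_matrix needs a tree with >= 2 tips")
  }
  m <- stats::cophenetic(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Write a pruning/grafting report as CSV
#'
#' @param report the `report` data.frame from [prune_to_taxa()].
#' @param path output CSV path.
#' @export
write_prune_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
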