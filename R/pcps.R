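# Phylogenetic fuzzy weighting and principal coordinates of phylogenetic
# structure (PCPS). Each species' incidence is redistributed across all
# species in proportion to phylogenetic similarity s = 1 - d/d_max, giving a
# row-stochastic species x species matrix Q; matrix P = row-normalized
# incidence %*% Q describes the phylogeny-weighted composition of each site.
# PCPS axes are the principal coordinates of dissimilarities among rows of P;
# the first axis captures the dominant gradient in phylogenetic composition.

#' Phylogenetic fuzzy weights Q
#'
#' @param dm cophenetic distance matrix with at least 2 species and a
#'   positive maximum distance.
#' @return species x species matrix `Q` with rows summing to 1;
#'   `q_jk = s_jk / sum_m s_jm` where `s_jk = 1 - d_jk / d_max`.
#' @export
fuzzy_weights <- function(dm) {
  dm <- as.matrix(dm)
  if (ncol(dm) < 2) stop("fuzzy_weights needs >= 2 species")
  dmax <- max(dm)
  if (dmax <= 0) stop("all pairwise distances are zero; weighting undefined")
  s <- 1 - dm / dmax
  s / rowSums(s)
}

#' Phylogeny-weighted species composition P
#'
#' @param cm a [community_matrix()].
#' @param fw fuzzy weight matrix from [fuzzy_weights()]; its species must
#'   match the community's (order may differ).
#' @return sites x species matrix `P = W' Q` where `W'` is the row-normalized
#'   incidence; rows sum to 1.
#' @export
matrix_p <- function(cm, fw) {
  stopifnot(inherits(cm, "comm_matrix"))
  sp_cm <- .name_key(cm$species)
  sp_fw <- .name_key(colnames(fw))
  if (!setequal(sp_cm, sp_fw)) {
    stop("species mismatch between community and weights: ",
         .quote_names(c(setdiff(sp_cm, sp_fw), setdiff(sp_fw, sp_cm))))
  }
  fw <- fw[match(sp_cm, sp_fw), match(sp_cm, sp_fw)]
  w <- cm$incidence / rowSums(cm$incidence)
  p <- w %*% fw
  dimnames(p) <- list(cm$site_ids, cm$species)
  p
}

#' Principal coordinates of phylogenetic structure
#'
#' Principal coordinates analysis of dissimilarities among the rows of `P`.
#' The default dissimilarity is the square root of Bray-Curtis (rows of P are
#' compositional; the square root makes the matrix closer to Euclidean);
#' plain Euclidean distance is available as an option. Axes with
#' non-positive eigenvalues are discarded. Axis signs are canonicalized so
#' the site with the lexicographically smallest id scores non-negatively.
#'
#' @param p matrix from [matrix_p()] (needs >= 3 sites).
#' @param distance `"sqrt_bray"` (default) or `"euclidean"`.
#' @return object of class `pcps_result`: list with `P`, `eigenvalues`,
#'   `percent` (share of positive eigenvalues, summing to 100),
#'   `site_scores` (sites x axes, axis a = eigenvector * sqrt(lambda_a)).
#' @export
pcps_ordination <- function(p, distance = c("sqrt_bray", "euclidean")) {
  distance <- match.arg(distance)
  if (nrow(p) < 3) stop("PCPS needs >= 3 sites")
  d <- switch(distance,
    sqrt_bray = sqrt(as.matrix(vegan::vegdist(p, method = "bray"))),
    euclidean = as.matrix(stats::dist(p))
  )
  if (max(d) == 0) stop("degenerate ordination: all sites identical")
  n <- nrow(d)
  a <- -0.5 * d^2
  g <- a - rowMeans(a)[row(a)] - colMeans(a)[col(a)] + mean(a)
  eig <- eigen(g, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  lambda <- eig$values[pos]
  scores <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda), sum(pos))
  rownames(scores) <- rownames(p)
  colnames(scores) <- paste0("PCPS", seq_len(ncol(scores)))
  # canonical sign: first site (lexicographic) with a nonzero score is >= 0
  ord <- order(rownames(p))
  for (ax in seq_len(ncol(scores))) {
    v <- scores[ord, ax]
    nz <- which(abs(v) > 1e-12)
    if (length(nz) > 0 && v[nz[1]] < 0) scores[, ax] <- -scores[, ax]
  }
  structure(list(P = p, eigenvalues = lambda,
                 percent = 100 * lambda / sum(lambda),
                 site_scores = scores, distance = distance),
            class = "pcps_result")
}

#' @export
print.pcps_result <- function(x, ...) {
  cat("PCPS ordination:", nrow(x$site_scores), "sites,",
      length(x$eigenvalues), "positive axes (", x$distance, ")\n")
  k <- min(4, length(x$eigenvalues))
  cat("Axis % variation:",
      paste(sprintf("%s=%.1f%%", colnames(x$site_scores)[1:k],
                    x$percent[1:k]), collapse = ", "), "\n")
  invisible(x)
}

#' Species scores and clade centroids on the PCPS axes
#'
#' A species' score on an axis is the P-weighted average of the site scores
#' (weights: the species' column of P); a clade centroid is the unweighted
#' mean of its member species' scores — the quantities behind spider plots of
#' species around their clade centroids.
#'
#' @param res a [pcps_ordination()] result.
#' @param clade_map optional data.frame with columns `species`, `clade`
#'   (e.g. eudicots / monocots / magnoliids / other).
#' @return list with `species_scores` (species x axes) and, when `clade_map`
#'   is given, `clade_centroids` (clade x axes) and the `clade` assignment
#'   used. Species with zero column mass in P are excluded with a message.
#' @export
species_and_clade_scores <- function(res, clade_map = NULL) {
  stopifnot(inherits(res, "pcps_result"))
  p <- res$P
  mass <- colSums(p)
  zero <- mass == 0
  if (any(zero)) {
    message("species with zero mass in P excluded: ",
            .quote_names(colnames(p)[zero]))
  }
  pw <- p[, !zero, drop = FALSE]
  sp_scores <- crossprod(pw, res$site_scores) / colSums(pw)
  out <- list(species_scores = sp_scores)
  if (!is.null(clade_map)) {
    stopifnot(all(c("species", "clade") %in% names(clade_map)))
    clade <- clade_map$clade[match(.name_key(rownames(sp_scores)),
                                   .name_key(clade_map$species))]
    if (anyNA(clade)) {
      stop("species missing from clade map: ",
           .quote_names(rownames(sp_scores)[is.na(clade)]))
    }
    cent <- do.call(rbind, lapply(split(seq_len(nrow(sp_scores)), clade),
                                  function(i) colMeans(sp_scores[i, , drop = FALSE])))
    out$clade_centroids <- cent
    out$clade <- clade
  }
  out
}
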