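# Richness-preserving null model and the standardized structure indices.
#
# The null keeps each site's species richness and draws that many species
# uniformly (equal probability, without replacement within a draw) from the
# species pool, 999 times by default. NRI/NTI are the negated standardized
# effect sizes of observed MPD/MNTD against the null ensemble:
#
#   NRI = -(MPD_obs - mean(MPD_null)) / SD(MPD_null)
#   NTI = -(MNTD_obs - mean(MNTD_null)) / SD(MNTD_null)
#
# so positive values indicate phylogenetic clustering (species more closely
# related than expected), negative values overdispersion.

#' Draw null communities from the species pool
#'
#' @param pool character vector, the species pool.
#' @param richness number of species per draw (site richness).
#' @param n_null number of draws (default 999).
#' @param seed integer seed; the same seed reproduces the same draw sequence.
#' @return list of `n_null` character vectors, each of length `richness`.
#' @export
draw_null <- function(pool, richness, n_null = 999, seed = 1) {
  if (richness > length(pool)) {
    stop("richness (", richness, ") exceeds pool size (", length(pool), ")")
  }
  if (richness < 2) return(NULL)  # SES undefined below 2 species
  with_seed(seed, {
    lapply(seq_len(n_null), function(i) pool[sample.int(length(pool), richness)])
  })
}

# Null MPD and MNTD distributions for one site: `n_null` uniform draws of
# `richness` species from the pool (columns of `dm` indexed by `pool_idx`),
# the SAME draws feeding both metrics. Call inside with_seed().
.null_metrics <- function(dm, pool_idx, richness, n_null) {
  np <- length(pool_idx)
  mpd_null <- numeric(n_null)
  mntd_null <- numeric(n_null)
  denom <- richness * (richness - 1)
  for (i in seq_len(n_null)) {
    idx <- pool_idx[sample.int(np, richness)]
    d <- dm[idx, idx]
    mpd_null[i] <- sum(d) / denom
    diag(d) <- Inf
    mntd_null[i] <- mean(d[cbind(seq_len(richness),
                                 max.col(-d, ties.method = "first"))])
  }
  list(mpd = mpd_null, mntd = mntd_null)
}

#' Standardized effect size index and null quantile
#'
#' @param obs observed metric value.
#' @param null_values numeric vector of null metric values.
#' @return list with `index` (negated SES, positive = clustered), `quantile`
#'   (rank position of `obs` in the null distribution, in (0,1), midranked
#'   over ties). Both `NA` when the null SD is zero (degenerate, e.g. the
#'   community equals the pool) or `obs` is `NA`.
#' @export
ses_index <- function(obs, null_values) {
  if (is.na(obs) || is.null(null_values)) {
    return(list(index = NA_real_, quantile = NA_real_))
  }
  s <- sd(null_values)
  if (!is.finite(s) || s == 0) {
    message("null SD is zero; SES undefined")
    return(list(index = NA_real_, quantile = NA_real_))
  }
  n <- length(null_values)
  list(index = -(obs - mean(null_values)) / s,
       quantile = (sum(null_values < obs) + 0.5 * sum(null_values == obs) + 1) /
         (n + 1))
}

#' Classify phylogenetic structure
#'
#' One-tailed at `alpha` in the direction of the observed sign: a clustered
#' site (index > 0, observed distance small) is significant when its null
#' quantile is at most `alpha`; an overdispersed site (index <= 0; an exact
#' zero tie-breaks to overdispersed) when the quantile is at least
#' `1 - alpha`.
#'
#' @param index NRI or NTI value.
#' @param quantile null quantile from [ses_index()].
#' @param alpha one-tailed significance level (default 0.05).
#' @return one of `"clustered_sig"`, `"clustered_ns"`, `"overdispersed_sig"`,
#'   `"overdispersed_ns"`, `"undefined"`.
#' @export
classify <- function(index, quantile, alpha = 0.05) {
  if (is.na(index)) return("undefined")
  if (index > 0) {
    if (quantile <= alpha) "clustered_sig" else "clustered_ns"
  } else {
    if (quantile >= 1 - alpha) "overdispersed_sig" else "overdispersed_ns"
  }
}

#' Per-site SES table (PD, NRI, NTI, classes)
#'
#' Runs the full per-site computation: observed metrics, a per-site null
#' ensemble (seeded as `site_seed(seed, site_id)` so results do not depend on
#' processing order), indices, quantiles and structure classes. Sites with a
#' single species get `NA` indices and class `"undefined"`.
#'
#' @param tree pruned `phylo` covering all community species.
#' @param cm a [community_matrix()].
#' @param n_null number of null draws per site (default 999).
#' @param seed global seed (default 1).
#' @param alpha one-tailed significance level (default 0.05).
#' @param include_root see [pd_faith()].
#' @param dm optional precomputed [cophenetic_matrix()].
#' @return data.frame with one row per site: `site_id`, `habitat`, `SR`,
#'   `PD`, `MPD_obs`, `MNTD_obs`, `NRI`, `NTI`, `quantile_mpd`,
#'   `quantile_mntd`, `class_nri`, `class_nti`.
#' @export
ses_table <- function(tree, cm, n_null = 999, seed = 1, alpha = 0.05,
                      include_root = TRUE, dm = NULL) {
  stopifnot(inherits(cm, "comm_matrix"))
  if (is.null(dm)) dm <- cophenetic_matrix(tree)
  pool <- species_pool(cm)
  pool_idx <- .present_idx(dm, pool)
  obs <- site_metrics(tree, cm, dm = dm, include_root = include_root)
  n <- nrow(obs)
  out <- data.frame(
    site_id = obs$site_id,
    habitat = if (is.null(cm$habitat)) NA_character_
              else unname(cm$habitat[obs$site_id]),
    obs[, c("SR", "PD", "MPD_obs", "MNTD_obs")],
    NRI = NA_real_, NTI = NA_real_,
    quantile_mpd = NA_real_, quantile_mntd = NA_real_,
    class_nri = "undefined", class_nti = "undefined",
    stringsAsFactors = FALSE
  )
  skipped <- character(0)
  for (i in seq_len(n)) {
    k <- obs$SR[i]
    if (k < 2) {
      skipped <- c(skipped, obs$site_id[i])
      next
    }
    nulls <- with_seed(site_seed(seed, obs$site_id[i]),
                       .null_metrics(dm, pool_idx, k, n_null))
    r1 <- ses_index(obs$MPD_obs[i], nulls$mpd)
    r2 <- ses_index(obs$MNTD_obs[i], nulls$mntd)
    out$NRI[i] <- r1$index
    out$NTI[i] <- r2$index
    out$quantile_mpd[i] <- r1$quantile
    out$quantile_mntd[i] <- r2$quantile
    out$class_nri[i] <- classify(r1$index, r1$quantile, alpha)
    out$class_nti[i] <- classify(r2$index, r2$quantile, alpha)
  }
  if (length(skipped) > 0) {
    message("sites with richness < 2 excluded from SES: ",
            .quote_names(skipped))
  }
  out
}

#' Tally phylogenetic structure by habitat
#'
#' Counts (and percentages, to 2 decimals) of sites with negative/positive
#' NRI and NTI, and of those significant one-tailed at the level used when
#' building the SES table, per habitat plus an `Overall` row. Sites with
#' undefined indices are excluded with a message.
#'
#' @param ses data.frame from [ses_table()] (needs a `habitat` column).
#' @return data.frame with one row per habitat plus `Overall`; columns
#'   `habitat`, `n_sites`, then count and `_pct` columns for
#'   `nri_neg`, `nri_neg_sig`, `nri_pos`, `nri_pos_sig` and the `nti_*`
#'   equivalents.
#' @export
tabulate_structure <- function(ses) {
  bad <- is.na(ses$NRI) | is.na(ses$NTI)
  if (any(bad)) {
    message(sum(bad), " site(s) with undefined indices excluded from tally")
    ses <- ses[!bad, , drop = FALSE]
  }
  if (nrow(ses) == 0) stop("no sites with defined indices")
  one_group <- function(df, label) {
    n <- nrow(df)
    cnt <- c(
      nri_neg = sum(!(df$NRI > 0)),
      nri_neg_sig = sum(df$class_nri == "overdispersed_sig"),
      nri_pos = sum(df$NRI > 0),
      nri_pos_sig = sum(df$class_nri == "clustered_sig"),
      nti_neg = sum(!(df$NTI > 0)),
      nti_neg_sig = sum(df$class_nti == "overdispersed_sig"),
      nti_pos = sum(df$NTI > 0),
      nti_pos_sig = sum(df$class_nti == "clustered_sig")
    )
    row <- data.frame(habitat = label, n_sites = n)
    for (nm in names(cnt)) {
      row[[nm]] <- cnt[[nm]]
      row[[paste0(nm, "_pct")]] <- round(100 * cnt[[nm]] / n, 2)
    }
    row
  }
  groups <- split(ses, ses$habitat)
  rows <- lapply(names(groups), function(h) one_group(groups[[h]], h))
  do.call(rbind, c(rows, list(one_group(ses, "Overall"))))
}
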