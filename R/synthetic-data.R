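# Synthetic two-habitat data generator. Emulates the statistical structure
# the analysis assumes: a species pool on a pure-birth phylogeny, a
# species-poor habitat assembled with phylogenetic clustering (desert
# analogue) and a species-rich habitat assembled with overdispersion (alpine
# analogue), plus habitat-correlated environmental covariates. Environmental
# variables are drawn independently of assembly given habitat, so their
# correlation with the structure indices arises through habitat alone —
# mimicking a confounded observational design.

#' Synthetic dataset configuration
#'
#' Defaults reproduce the shape of the motivating field study: a 285-species
#' pool, 20 desert and 41 alpine sites, mean richness 12.35 and 33.39
#' species per site, clustering strength +3 (desert) and -3 (alpine).
#'
#' @param seed integer seed.
#' @param n_pool species-pool size (default 285).
#' @param birth_rate pure-birth speciation rate (default 1; branch lengths
#'   are in units of 1/rate).
#' @param n_desert,n_alpine site counts (defaults 20, 41).
#' @param richness_desert,richness_alpine mean per-site richness (defaults
#'   12.35, 33.39; per-site richness is 2 + Poisson(mean - 2)).
#' @param lambda_desert,lambda_alpine assembly strength: positive clusters,
#'   negative overdisperses, 0 is the uniform null (defaults +3, -3).
#' @param desert_affinity probability that a desert site is seeded from the
#'   affinity clade (largest pseudo-clade; default 0.9), emulating the
#'   eudicot-dominated desert communities.
#' @param env per-habitat `c(mean, sd)` for MAT (deg C), MAP (mm), SWC (%),
#'   coverage (%), Anomaly1 and Anomaly2 (deg C); Anomaly2 is larger in the
#'   alpine habitat. Anomaly3 is derived as Anomaly2 - Anomaly1 plus small
#'   noise (the periods satisfy MH-LGM = (cur-LGM) - (cur-MH)).
#' @return list of class `synth_config`.
#' @export
synthetic_config <- function(seed = 1, n_pool = 285, birth_rate = 1,
                             n_desert = 20, n_alpine = 41,
                             richness_desert = 12.35,
                             richness_alpine = 33.39,
                             lambda_desert = 3, lambda_alpine = -3,
                             desert_affinity = 0.9,
                             env = NULL) {
  if (n_pool < 10) stop("n_pool must be >= 10")
  if (richness_desert >= n_pool || richness_alpine >= n_pool) {
    stop("mean richness must be below the pool size")
  }
  if (!is.finite(lambda_desert) || !is.finite(lambda_alpine)) {
    stop("assembly strengths must be finite")
  }
  default_env <- list(
    desert = list(MAT = c(7.5, 1.2), MAP = c(150, 30), SWC = c(6, 2),
                  coverage = c(25, 8), Anomaly1 = c(0.4, 0.15),
                  Anomaly2 = c(4.5, 0.5)),
    alpine = list(MAT = c(1.0, 1.5), MAP = c(420, 60), SWC = c(20, 5),
                  coverage = c(60, 12), Anomaly1 = c(0.6, 0.15),
                  Anomaly2 = c(6.2, 0.6))
  )
  structure(list(seed = seed, n_pool = n_pool, birth_rate = birth_rate,
                 n_desert = n_desert, n_alpine = n_alpine,
                 richness_desert = richness_desert,
                 richness_alpine = richness_alpine,
                 lambda_desert = lambda_desert,
                 lambda_alpine = lambda_alpine,
                 desert_affinity = desert_affinity,
                 env = if (is.null(env)) default_env else env),
            class = "synth_config")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Starts from two lineages at the root; while `k` lineages are alive the
#' waiting time to the next speciation is exponential with rate
#' `k * birth_rate` and a uniformly chosen lineage splits; a final waiting
#' period at `n_pool` lineages separates the last split from the present.
#' Expected depth is `sum_{k=2..n} 1/(k * birth_rate)`.
#'
#' @param n_pool number of tips (>= 2).
#' @param birth_rate speciation rate (default 1).
#' @param seed integer seed; the same seed gives an identical tree.
#' @return a `phylo` with tips `sp0001 ...`.
#' @export
simulate_tree <- function(n_pool, birth_rate = 1, seed = 1) {
  stopifnot(n_pool >= 2, birth_rate > 0)
  with_seed(seed, {
    root <- n_pool + 1L
    parent <- c(root, root)       # per active lineage
    birth <- c(0, 0)
    time <- 0
    next_node <- root + 1L
    edges <- matrix(0L, 0, 2)
    lens <- numeric(0)
    while (length(parent) < n_pool) {
      k <- length(parent)
      time <- time + rexp(1, k * birth_rate)
      i <- sample.int(k, 1)
      edges <- rbind(edges, c(parent[i], next_node))
      lens <- c(lens, time - birth[i])
      parent <- c(parent[-i], next_node, next_node)
      birth <- c(birth[-i], time, time)
      next_node <- next_node + 1L
    }
    time <- time + rexp(1, n_pool * birth_rate)
    edges <- rbind(edges, cbind(parent, seq_len(n_pool)))
    lens <- c(lens, time - birth)
    tree <- structure(list(edge = edges, edge.length = lens,
                           Nnode = n_pool - 1L,
                           tip.label = sprintf("sp%04d", seq_len(n_pool))),
                      class = "phylo")
    storage.mode(tree$edge) <- "integer"
    ape::reorder.phylo(tree, "cladewise")
  })
}

#' Assemble one community with phylogenetic structure
#'
#' Sequential kernel: the first species is uniform (or a supplied seed
#' species); each subsequent species `j` joins with probability proportional
#' to `exp(-lambda * mean cophenetic distance from j to the current
#' members)`, without replacement, until `richness` members. `lambda > 0`
#' favours relatives (clustering), `lambda < 0` favours distant species
#' (overdispersion), `lambda = 0` reduces to the uniform richness null.
#'
#' @param tree a `phylo`, or pass a precomputed distance matrix via `dm`.
#' @param richness community size, between 2 and the pool size.
#' @param lambda assembly strength.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param dm optional [cophenetic_matrix()] (avoids recomputation in loops).
#' @param start optional species name to seed the community with.
#' @return character vector of `richness` species names.
#' @export
assemble_site <- function(tree, richness, lambda, seed = NULL, dm = NULL,
                          start = NULL) {
  if (is.null(dm)) dm <- cophenetic_matrix(tree)
  n <- ncol(dm)
  if (richness < 2 || richness > n) {
    stop("richness must be in [2, ", n, "]")
  }
  run <- function() {
    members <- if (is.null(start)) sample.int(n, 1) else {
      m <- match(.name_key(start), .name_key(colnames(dm)))
      if (is.na(m)) stop("start species not in pool: ", start)
      m
    }
    while (length(members) < richness) {
      outsiders <- setdiff(seq_len(n), members)
      mbar <- colMeans(dm[members, outsiders, drop = FALSE])
      lw <- -lambda * mbar
      w <- exp(lw - max(lw))
      members <- c(members, outsiders[sample.int(length(outsiders), 1,
                                                 prob = w)])
    }
    colnames(dm)[members]
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# assign tips to 3 pseudo-clades by the deepest splits: start from the root's
# child subtrees and keep splitting the largest until 3 groups exist
.pseudo_clades <- function(tree, labels = c("eudicots", "monocots",
                                            "magnoliids")) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  groups <- lapply(kids[[as.character(ntip + 1L)]], tips_under)
  roots <- kids[[as.character(ntip + 1L)]]
  while (length(groups) < length(labels)) {
    sizes <- vapply(groups, length, integer(1))
    splittable <- which(roots > ntip & sizes > 1)
    if (length(splittable) == 0) break
    i <- splittable[which.max(sizes[splittable])]
    sub <- kids[[as.character(roots[i])]]
    groups <- c(groups[-i], lapply(sub, tips_under))
    roots <- c(roots[-i], sub)
  }
  ord <- order(vapply(groups, length, integer(1)), decreasing = TRUE)
  clade <- character(ntip)
  for (j in seq_along(ord)) {
    lab <- if (j <= length(labels)) labels[j] else "other"
    clade[groups[[ord[j]]]] <- lab
  }
  data.frame(species = tree$tip.label, clade = clade,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic two-habitat dataset
#'
#' @param cfg a [synthetic_config()].
#' @return list with `tree` (`phylo`), `community` ([community_matrix()]),
#'   `env` (data.frame as in [read_env()]), `clade_map` (species/clade
#'   data.frame) and `manifest` (seed + configuration echo). Per-site
#'   richness is `2 + Poisson(mean - 2)`; the rare species never picked by
#'   assembly are each added to one random alpine site so the observed pool
#'   equals the full `n_pool` (documented generator property).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  tree <- simulate_tree(cfg$n_pool, cfg$birth_rate, seed = cfg$seed)
  dm <- cophenetic_matrix(tree)
  clade_map <- .pseudo_clades(tree)
  affinity_clade <- clade_map$species[clade_map$clade == "eudicots"]
  with_seed(site_seed(cfg$seed, "assembly"), {
    n_sites <- cfg$n_desert + cfg$n_alpine
    site_ids <- c(sprintf("d%02d", seq_len(cfg$n_desert)),
                  sprintf("a%02d", seq_len(cfg$n_alpine)))
    habitat <- rep(c("desert", "alpine"), c(cfg$n_desert, cfg$n_alpine))
    inc <- matrix(0L, n_sites, cfg$n_pool,
                  dimnames = list(site_ids, tree$tip.label))
    for (i in seq_len(n_sites)) {
      desert <- habitat[i] == "desert"
      mean_k <- if (desert) cfg$richness_desert else cfg$richness_alpine
      k <- 2 + rpois(1, max(mean_k - 2, 0))
      k <- min(k, cfg$n_pool)
      lam <- if (desert) cfg$lambda_desert else cfg$lambda_alpine
      start <- NULL
      if (desert && runif(1) < cfg$desert_affinity) {
        start <- sample(affinity_clade, 1)
      }
      sp <- assemble_site(tree, k, lam, seed = NULL, dm = dm, start = start)
      inc[i, sp] <- 1L
    }
    # guarantee full pool coverage: park never-drawn species in random
    # alpine sites (the richer habitat), one site each
    missing <- which(colSums(inc) == 0)
    for (j in missing) {
      inc[sample(which(habitat == "alpine"), 1), j] <- 1L
    }
    env <- .generate_env(cfg, site_ids, habitat)
    community <- community_matrix(inc, habitat = habitat)
    list(tree = tree, community = community, env = env,
         clade_map = clade_map,
         manifest = list(seed = cfg$seed, config = unclass(cfg)))
  })
}

.generate_env <- function(cfg, site_ids, habitat) {
  draw <- function(var) {
    vapply(habitat, function(h) {
      ms <- cfg$env[[h]][[var]]
      rnorm(1, ms[1], ms[2])
    }, numeric(1), USE.NAMES = FALSE)
  }
  a1 <- draw("Anomaly1")
  a2 <- draw("Anomaly2")
  data.frame(site_id = site_ids, habitat = habitat,
             MAT = draw("MAT"), MAP = draw("MAP"), SWC = draw("SWC"),
             coverage = draw("coverage"),
             Anomaly1 = a1, Anomaly2 = a2,
             Anomaly3 = a2 - a1 + rnorm(length(a1), 0, 0.1),
             stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to disk
#'
#' Writes `tree.nwk`, `community.csv`, `env.csv`, `clades.csv` and
#' `manifest.json` (seed + configuration echo) into `dir`.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  write_community(dataset$community, file.path(dir, "community.csv"))
  write.csv(dataset$env, file.path(dir, "env.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(dataset$clade_map, file.path(dir, "clades.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a clade map CSV (species, clade)
#'
#' @param path CSV with columns `species`, `clade`.
#' @return data.frame.
#' @export
read_clade_map <- function(path) {
  if (!file.exists(path)) stop("clade map not found: ", path)
  cm <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "clade") %in% names(cm))) {
    stop("clade map needs columns 'species' and 'clade'")
  }
  cm$species <- normalize_names(cm$species)
  cm
}
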