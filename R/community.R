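# Site-by-species incidence data model. The canonical representation is
# presence/absence: the study design records species composition per site
# (union of subplots), not abundance, so any nonzero input value is coerced
# to 1.

#' Construct a community matrix
#'
#' @param incidence numeric matrix, sites x species, with dimnames; nonzero
#'   entries are coerced to 1 (a warning reports how many were coerced).
#' @param habitat optional per-site habitat labels (length = number of sites),
#'   e.g. `"desert"` / `"alpine"`.
#' @return an object of class `comm_matrix`: a list with elements `incidence`
#'   (0/1 integer matrix), `site_ids`, `species`, `habitat`.
#' @details Invariants enforced: every site holds at least one species and
#'   every species occurs at least once; site ids and species names unique.
#' @export
community_matrix <- function(incidence, habitat = NULL) {
  incidence <- as.matrix(incidence)
  if (is.null(rownames(incidence)) || is.null(colnames(incidence))) {
    stop("incidence matrix needs site row names and species column names")
  }
  if (anyDuplicated(rownames(incidence))) {
    stop("duplicate site ids: ",
         .quote_names(unique(rownames(incidence)[duplicated(rownames(incidence))])))
  }
  colnames(incidence) <- normalize_names(colnames(incidence))
  if (anyDuplicated(colnames(incidence))) {
    stop("duplicate species columns: ",
         .quote_names(unique(colnames(incidence)[duplicated(colnames(incidence))])))
  }
  if (any(is.na(incidence))) stop("incidence matrix contains NA")
  n_coerced <- sum(incidence != 0 & incidence != 1)
  if (n_coerced > 0) {
    warning(n_coerced, " non-binary incidence entr",
            if (n_coerced == 1) "y" else "ies", " coerced to 1")
  }
  storage.mode(incidence) <- "integer"
  incidence[incidence != 0L] <- 1L
  empty_sites <- rownames(incidence)[rowSums(incidence) == 0]
  if (length(empty_sites) > 0) {
    stop("empty site: ", .quote_names(empty_sites))
  }
  empty_sp <- colSums(incidence) == 0
  if (any(empty_sp)) {
    warning("dropping species with no occurrences: ",
            .quote_names(colnames(incidence)[empty_sp]))
    incidence <- incidence[, !empty_sp, drop = FALSE]
  }
  if (!is.null(habitat)) {
    if (length(habitat) != nrow(incidence)) {
      stop("habitat must have one label per site")
    }
    habitat <- as.character(habitat)
    names(habitat) <- rownames(incidence)
  }
  structure(list(incidence = incidence,
                 site_ids = rownames(incidence),
                 species = colnames(incidence),
                 habitat = habitat),
            class = "comm_matrix")
}

#' @export
print.comm_matrix <- function(x, ...) {
  cat("Community matrix:", nrow(x$incidence), "sites x",
      ncol(x$incidence), "species\n")
  if (!is.null(x$habitat)) {
    tab <- table(x$habitat)
    cat("Habitats:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("Richness per site:", paste(range(rowSums(x$incidence)), collapse = "-"),
      "(min-max)\n")
  invisible(x)
}

#' Read a community matrix from CSV
#'
#' Two layouts are accepted. Wide: first column the site id, one column per
#' species (0/1 entries; nonzero coerced to 1 with a warning), and an optional
#' `habitat` column. Long: columns `site`, `species` (one row per occurrence)
#' plus optional `habitat`, pivoted to incidence.
#'
#' @param path CSV path (UTF-8, comma-separated).
#' @param habitat_col name of the habitat column, if present (default
#'   `"habitat"`).
#' @return a [community_matrix()].
#' @export
read_community <- function(path, habitat_col = "habitat") {
  if (!file.exists(path)) stop("community file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("community CSV needs at least 2 columns")
  if (anyDuplicated(names(df))) {
    stop("duplicate species columns: ",
         .quote_names(unique(names(df)[duplicated(names(df))])))
  }
  long <- all(c("site", "species") %in% names(df))
  if (long) {
    hab <- NULL
    if (habitat_col %in% names(df)) {
      hab_map <- unique(df[, c("site", habitat_col)])
      if (anyDuplicated(hab_map$site)) {
        stop("conflicting habitat labels for a site in long-format input")
      }
      hab <- hab_map[[habitat_col]]
      names(hab) <- hab_map$site
    }
    sites <- unique(as.character(df$site))
    species <- unique(normalize_names(df$species))
    inc <- matrix(0L, length(sites), length(species),
                  dimnames = list(sites, species))
    inc[cbind(as.character(df$site), normalize_names(df$species))] <- 1L
    return(community_matrix(inc, habitat = if (!is.null(hab)) hab[sites]))
  }
  site_ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  habitat <- NULL
  if (habitat_col %in% names(df)) {
    habitat <- df[[habitat_col]]
    df <- df[, setdiff(names(df), habitat_col), drop = FALSE]
  }
  inc <- as.matrix(df)
  if (!is.numeric(inc)) stop("non-numeric incidence entries in ", path)
  rownames(inc) <- site_ids
  community_matrix(inc, habitat = habitat)
}

#' Write a community matrix to CSV (wide layout)
#'
#' @param cm a [community_matrix()].
#' @param path output path.
#' @export
write_community <- function(cm, path) {
  df <- data.frame(site = cm$site_ids, check.names = FALSE)
  if (!is.null(cm$habitat)) df$habitat <- unname(cm$habitat)
  df <- cbind(df, as.data.frame(cm$incidence, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Union of subplot communities
#'
#' Combines per-subplot incidence tables for the same sites into the per-site
#' species composition (elementwise OR), the way several subplots per
#' sampling site are merged into one community.
#'
#' @param subplots list of [community_matrix()] objects over identical site
#'   id sets (species sets may differ).
#' @return a [community_matrix()] whose species set is the union.
#' @export
union_subplots <- function(subplots) {
  stopifnot(is.list(subplots), length(subplots) >= 1)
  sites <- sort(subplots[[1]]$site_ids)
  for (s in subplots) {
    if (!identical(sort(s$site_ids), sites)) {
      stop("mismatched site ids across subplots")
    }
  }
  species <- sort(unique(unlist(lapply(subplots, `[[`, "species"))))
  inc <- matrix(0L, length(sites), length(species),
                dimnames = list(sites, species))
  for (s in subplots) {
    inc[s$site_ids, s$species] <-
      pmax(inc[s$site_ids, s$species], s$incidence)
  }
  habitat <- subplots[[1]]$habitat
  community_matrix(inc, habitat = if (!is.null(habitat)) habitat[sites])
}

#' Species pool
#'
#' The pool from which null communities are drawn: all species observed
#' across all sampling sites.
#'
#' @param cm a [community_matrix()].
#' @return character vector of species names.
#' @export
species_pool <- function(cm) {
  stopifnot(inherits(cm, "comm_matrix"))
  cm$species[colSums(cm$incidence) >= 1]
}
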