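# End-to-end orchestration: read tree/community/environment inputs, run the
# alpha metrics, null model, PCPS and statistical layer, and write the
# publication-style output tables. A stage failure aborts with the stage name
# and removes partial outputs.

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; quotes around
#' values are stripped; numeric and true/false values are coerced.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^["\']|["\']$', "", val)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) as.logical(toupper(val))
      else val
  }
  cfg
}

# defaults mirroring the study: 999 nulls, alpha 0.05, pool = union of sites
.default_run_config <- function() {
  list(n_null = 999, alpha = 0.05, seed = 1, distance = "sqrt_bray",
       include_root = TRUE, graft_missing = FALSE,
       varpart_response = "PD",
       varpart_predictors = "Anomaly1,Anomaly2,Anomaly3")
}

.fmt_df <- function(df, digits = 6) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  }
  df
}

.write_table <- function(df, path, written) {
  write.csv(.fmt_df(df), path, row.names = FALSE, quote = FALSE)
  c(written, path)
}

#' Run the full analysis pipeline
#'
#' Stages: input validation and tree pruning; per-site PD/NRI/NTI with the
#' richness null; structure tally by habitat; correlation table; variation
#' partitioning of the configured response on the three MAT anomalies; PCPS
#' ordination with species and clade-centroid scores; Wilcoxon habitat
#' contrasts on PD, NRI, NTI and the first PCPS axis.
#'
#' @param config named list or path to a [read_config()] file. Required
#'   keys: `tree`, `community`, `env`, `outdir`; optional: `clades`,
#'   `n_null` (999), `alpha` (0.05), `seed` (1), `distance`
#'   (`"sqrt_bray"`), `include_root` (TRUE), `graft_missing` (FALSE).
#' @return invisible list of the in-memory results (`ses`, `table1`,
#'   `table2`, `varpart`, `pcps`, `contrasts`, `outputs`). Writes
#'   `metrics.csv`, `table1.csv`, `table2.csv`, `varpart.csv`,
#'   `contrasts.csv`, `prune_report.csv`, `run.log` and a `pcps/`
#'   subdirectory into `outdir`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- modifyList(.default_run_config(), config)
  for (key in c("tree", "community", "env", "outdir")) {
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
  }
  for (key in c("tree", "community", "env")) {
    if (!file.exists(cfg[[key]])) {
      stop("input path does not exist: ", cfg[[key]], " (", key, ")")
    }
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(cfg$outdir, "pcps"), showWarnings = FALSE)
  written <- character(0)
  stage <- "setup"
  result <- tryCatch({
    stage <- "inputs"
    tree <- read_newick(cfg$tree)
    comm <- read_community(cfg$community)
    env <- read_env(cfg$env)
    clades <- if (!is.null(cfg$clades)) read_clade_map(cfg$clades)

    stage <- "prune"
    pr <- prune_to_taxa(tree, comm$species,
                        graft_missing = isTRUE(cfg$graft_missing))
    unresolved <- pr$report$name[pr$report$status == "dropped"]
    if (length(unresolved) > 0) {
      stop("species absent from the tree",
           if (!isTRUE(cfg$graft_missing)) " (grafting disabled)", ": ",
           .quote_names(unresolved))
    }
    tree <- pr$tree
    written <- .write_table(pr$report,
                            file.path(cfg$outdir, "prune_report.csv"), written)

    stage <- "metrics"
    dm <- cophenetic_matrix(tree)
    ses <- ses_table(tree, comm, n_null = cfg$n_null, seed = cfg$seed,
                     alpha = cfg$alpha, include_root = isTRUE(cfg$include_root),
                     dm = dm)

    stage <- "pcps"
    p <- matrix_p(comm, fuzzy_weights(dm))
    ord <- pcps_ordination(p, distance = cfg$distance)
    sc <- species_and_clade_scores(ord, clade_map = clades)
    ses$PCPS1 <- ord$site_scores[ses$site_id, 1]
    written <- .write_table(as.data.frame(ord$P) |>
                              (\(d) cbind(site_id = rownames(ord$P), d))(),
                            file.path(cfg$outdir, "pcps", "matrix_p.csv"),
                            written)
    written <- .write_table(
      data.frame(axis = seq_along(ord$eigenvalues),
                 eigenvalue = ord$eigenvalues, percent = ord$percent),
      file.path(cfg$outdir, "pcps", "eigenvalues.csv"), written)
    written <- .write_table(
      cbind(site_id = rownames(ord$site_scores),
            as.data.frame(ord$site_scores)),
      file.path(cfg$outdir, "pcps", "site_scores.csv"), written)
    written <- .write_table(
      cbind(species = rownames(sc$species_scores),
            clade = if (is.null(clades)) NA else sc$clade,
            as.data.frame(sc$species_scores)),
      file.path(cfg$outdir, "pcps", "species_scores.csv"), written)
    if (!is.null(clades)) {
      written <- .write_table(
        cbind(clade = rownames(sc$clade_centroids),
              as.data.frame(sc$clade_centroids)),
        file.path(cfg$outdir, "pcps", "clade_centroids.csv"), written)
    }

    stage <- "tables"
    written <- .write_table(ses, file.path(cfg$outdir, "metrics.csv"), written)
    tab1 <- tabulate_structure(ses)
    written <- .write_table(tab1, file.path(cfg$outdir, "table1.csv"), written)
    tab2 <- correlation_table(ses, env)
    written <- .write_table(cbind(index = rownames(tab2), tab2),
                            file.path(cfg$outdir, "table2.csv"), written)

    stage <- "varpart"
    preds <- trimws(strsplit(cfg$varpart_predictors, ",")[[1]])
    env_m <- env[match(ses$site_id, env$site_id), , drop = FALSE]
    resp <- if (cfg$varpart_response %in% names(ses)) {
      ses[[cfg$varpart_response]]
    } else env_m[[cfg$varpart_response]]
    vp <- varpart3(resp, env_m[[preds[1]]], env_m[[preds[2]]],
                   env_m[[preds[3]]])
    vp_df <- data.frame(fraction = names(vp$fractions),
                        value = unname(vp$fractions))
    written <- .write_table(vp_df, file.path(cfg$outdir, "varpart.csv"),
                            written)

    stage <- "contrasts"
    contr_df <- merge(ses, env_m[, c("site_id",
                                     setdiff(names(env_m),
                                             c("habitat", names(ses))))],
                      by = "site_id")
    contrasts <- habitat_contrasts(contr_df,
                                   c("PD", "NRI", "NTI", "PCPS1"))
    written <- .write_table(contrasts,
                            file.path(cfg$outdir, "contrasts.csv"), written)

    stage <- "log"
    log_lines <- c(
      paste("shrubphylo", as.character(utils::packageVersion("shrubphylo"))),
      paste("R", getRversion()),
      paste("seed", cfg$seed),
      paste("n_null", cfg$n_null),
      paste("alpha", cfg$alpha, "(one-tailed per direction)"),
      "null_model richness (uniform draws from the site-union species pool)",
      paste("pcoa_distance", cfg$distance),
      paste("include_root", isTRUE(cfg$include_root)),
      paste("graft_missing", isTRUE(cfg$graft_missing))
    )
    writeLines(log_lines, file.path(cfg$outdir, "run.log"))
    written <- c(written, file.path(cfg$outdir, "run.log"))

    list(ses = ses, table1 = tab1, table2 = tab2, varpart = vp,
         pcps = ord, clade_scores = sc, contrasts = contrasts,
         outputs = written)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
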