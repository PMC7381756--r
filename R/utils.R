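# Internal helpers shared across modules.

#' Normalize taxon names
#'
#' Canonical form used for matching community species to tree tips: spaces
#' become underscores and matching elsewhere is case-insensitive. The original
#' spelling (with underscores) is preserved for output.
#'
#' @param x character vector of names.
#' @return character vector with spaces replaced by underscores.
#' @export
normalize_names <- function(x) {
  gsub("[ ]+", "_", trimws(x))
}

# case-insensitive key for matching
.name_key <- function(x) tolower(normalize_names(x))

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Derive a per-site RNG seed
#'
#' Combines a global seed with a site identifier so each site's null draws are
#' reproducible independently of processing order. The result is always in
#' `[0, 2^31 - 2]` (a valid R integer seed).
#'
#' @param global_seed integer scalar.
#' @param site_id character scalar.
#' @return integer seed.
#' @export
site_seed <- function(global_seed, site_id) {
  p <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(as.character(site_id))) {
    h <- (h * 31 + code) %% p
  }
  as.integer((h + (as.numeric(global_seed) %% p) * 2654435) %% p)
}

# single-quote a vector for error messages
.quote_names <- function(x, max = 10) {
  x <- as.character(x)
  if (length(x) > max) x <- c(x[seq_len(max)], "...")
  paste(sQuote(x, q = FALSE), collapse = ", ")
}
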