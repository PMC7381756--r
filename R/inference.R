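# Statistical layer: habitat contrasts (Wilcoxon rank-sum), one-sample t
# tests of NRI/NTI against 0, Pearson correlations with environmental
# variables, and three-predictor variation partitioning of PD by the MAT
# anomalies. All tests are implemented from their definitions; the test
# suite checks them against the stats/vegan reference implementations.

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p by enumeration of all rank assignments when the combined sample
#' size is at most 16 and there are no ties; otherwise a normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return list with `U` (Mann-Whitney U for `x`), `p` (two-sided),
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  m <- length(x); n <- length(y); N <- m + n
  comb <- c(x, y)
  if (length(unique(comb)) == 1L) {
    message("all values identical; Wilcoxon p = 1")
    return(list(U = m * n / 2, p = 1, method = "degenerate"))
  }
  r <- rank(comb)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(comb))
  if (N <= 16 && !ties) {
    # exact null distribution of U over all choose(N, m) rank assignments
    us <- combn(N, m, FUN = sum) - m * (m + 1) / 2
    p <- min(1, 2 * min(mean(us <= U), mean(us >= U)))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- m * n / 2
  tie_tab <- table(comb)
  sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' One-sample Student's t test
#'
#' Used to test whether mean NRI or NTI differs from 0 within a habitat.
#'
#' @param values numeric vector, `n >= 2`, nonzero variance.
#' @param mu0 null mean (default 0).
#' @return list with `t`, `df`, `p` (two-sided), `mean`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  n <- length(values)
  if (n < 2) stop("one_sample_t needs n >= 2")
  s <- sd(values)
  if (s == 0) stop("zero variance; t test undefined")
  t <- (mean(values) - mu0) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), df = n - 1),
       mean = mean(values))
}

#' Pearson correlation with significance stars
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero variance.
#' @return list with `r`, `p` (two-sided, via `t = r sqrt((n-2)/(1-r^2))`),
#'   `stars` (`"***"` p < .001, `"**"` p < .01, `"*"` p < .05, else `"ns"`).
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("pearson_cor needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input; correlation undefined")
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(r = r, p = p, stars = stars, n = n)
}

#' Variation partitioning among three predictors
#'
#' Ordinary least squares of `y` on every non-empty subset of
#' `{x1, x2, x3}`; explained variation of subset S is the adjusted R-squared
#' `1 - (1 - R^2)(n - 1)/(n - |S| - 1)` (raw R-squared with
#' `adjusted = FALSE`). Unique and shared fractions follow by
#' inclusion-exclusion; negative fractions (a known property of adjusted
#' R-squared partitioning) are reported as-is.
#'
#' @param y response (e.g. per-site PD).
#' @param x1,x2,x3 predictors (e.g. the three MAT anomalies).
#' @param adjusted use adjusted R-squared (default `TRUE`).
#' @return list with `r2` (named vector for the 7 subsets), `fractions`
#'   (named vector: `unique_x1..3`, `shared_x1x2`, `shared_x1x3`,
#'   `shared_x2x3`, `shared_all`, `residual`); the 7 non-residual fractions
#'   sum to `r2["x1x2x3"]`.
#' @export
varpart3 <- function(y, x1, x2, x3, adjusted = TRUE) {
  n <- length(y)
  stopifnot(length(x1) == n, length(x2) == n, length(x3) == n)
  if (n <= 5) stop("varpart3 needs n > 5")
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  if (qr(cbind(1, X))$rank < 4) {
    cors <- abs(cor(X))
    pair <- which(cors > 1 - 1e-10 & upper.tri(cors), arr.ind = TRUE)
    nm <- if (nrow(pair) > 0) {
      paste(colnames(X)[pair[1, 2]], "and", colnames(X)[pair[1, 1]])
    } else "a predictor combination"
    stop("rank-deficient full model: ", nm, " are collinear")
  }
  r2_of <- function(cols) {
    fit <- lm(y ~ X[, cols, drop = FALSE])
    s <- summary(fit)
    if (adjusted) s$adj.r.squared else s$r.squared
  }
  subsets <- list(x1 = 1, x2 = 2, x3 = 3, x1x2 = c(1, 2), x1x3 = c(1, 3),
                  x2x3 = c(2, 3), x1x2x3 = 1:3)
  r2 <- vapply(subsets, r2_of, numeric(1))
  a <- r2[["x1x2x3"]] - r2[["x2x3"]]
  b <- r2[["x1x2x3"]] - r2[["x1x3"]]
  c_ <- r2[["x1x2x3"]] - r2[["x1x2"]]
  d <- r2[["x1x2x3"]] - r2[["x3"]] - a - b     # shared x1 & x2 only
  f <- r2[["x1x2x3"]] - r2[["x2"]] - a - c_    # shared x1 & x3 only
  e <- r2[["x1x2x3"]] - r2[["x1"]] - b - c_    # shared x2 & x3 only
  g <- r2[["x1x2x3"]] - (a + b + c_ + d + e + f)
  fractions <- c(unique_x1 = a, unique_x2 = b, unique_x3 = c_,
                 shared_x1x2 = d, shared_x1x3 = f, shared_x2x3 = e,
                 shared_all = g, residual = 1 - r2[["x1x2x3"]])
  list(r2 = r2, fractions = fractions, adjusted = adjusted, n = n)
}

#' Correlation table of diversity/structure vs environment
#'
#' One row per response (PD, NRI, NTI), one column per environmental
#' variable, each cell formatted `"r stars"` (r to 2 decimals). Numeric r and
#' p matrices are attached as attributes `r` and `p`.
#'
#' @param ses data.frame from [ses_table()].
#' @param env environment table with a `site_id` column and the predictor
#'   columns.
#' @param responses columns of `ses` to correlate (default PD, NRI, NTI).
#' @param predictors columns of `env` (default Anomaly2, MAT, MAP, SWC, SR,
#'   coverage; SR is taken from `ses`).
#' @return data.frame of formatted cells.
#' @export
correlation_table <- function(ses, env,
                              responses = c("PD", "NRI", "NTI"),
                              predictors = c("Anomaly2", "MAT", "MAP", "SWC",
                                             "SR", "coverage")) {
  env <- env[match(ses$site_id, env$site_id), , drop = FALSE]
  rmat <- matrix(NA_real_, length(responses), length(predictors),
                 dimnames = list(responses, predictors))
  pmat <- rmat
  cells <- matrix("", length(responses), length(predictors),
                  dimnames = list(responses, predictors))
  for (resp in responses) {
    for (pred in predictors) {
      xv <- if (pred %in% names(ses)) ses[[pred]] else env[[pred]]
      res <- pearson_cor(ses[[resp]], xv)
      rmat[resp, pred] <- res$r
      pmat[resp, pred] <- res$p
      cells[resp, pred] <- sprintf("%.2f %s", res$r, res$stars)
    }
  }
  out <- as.data.frame(cells, stringsAsFactors = FALSE)
  attr(out, "r") <- rmat
  attr(out, "p") <- pmat
  out
}

#' Habitat contrasts by Wilcoxon rank-sum
#'
#' @param df data.frame with a `habitat` column (exactly 2 levels).
#' @param vars columns of `df` to contrast.
#' @return data.frame: `variable`, group mean columns, `U`, `p`.
#' @export
habitat_contrasts <- function(df, vars) {
  habs <- sort(unique(df$habitat))
  if (length(habs) != 2) stop("habitat_contrasts needs exactly 2 habitats")
  rows <- lapply(vars, function(v) {
    x <- df[[v]][df$habitat == habs[1]]
    y <- df[[v]][df$habitat == habs[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    w <- wilcoxon_rank_sum(x, y)
    out <- data.frame(variable = v, m1 = mean(x), m2 = mean(y),
                      U = w$U, p = w$p, stringsAsFactors = FALSE)
    names(out)[2:3] <- paste0("mean_", habs)
    out
  })
  do.call(rbind, rows)
}

#' Read a site-level environment table
#'
#' @param path CSV with columns `site_id`, optional `habitat`, `MAT` (deg C),
#'   `MAP` (mm), `SWC`, `coverage` (%), `Anomaly1` (current minus
#'   mid-Holocene MAT), `Anomaly2` (current minus LGM MAT), `Anomaly3`
#'   (mid-Holocene minus LGM MAT).
#' @return data.frame, one row per site.
#' @export
read_env <- function(path) {
  if (!file.exists(path)) stop("environment file not found: ", path)
  env <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "MAT", "MAP", "SWC", "coverage",
            "Anomaly1", "Anomaly2", "Anomaly3")
  miss <- setdiff(need, names(env))
  if (length(miss) > 0) {
    stop("environment table missing columns: ", .quote_names(miss))
  }
  if (anyDuplicated(env$site_id)) stop("duplicate site_id in environment table")
  env$site_id <- as.character(env$site_id)
  env
}
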