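test_that("wilcoxon exact p matches full enumeration and wilcox.test", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$U, 0)
  expect_equal(w$p, 0.1)          # 2/20 assignments as extreme
  expect_equal(w$method, "exact")

  set.seed(2)
  for (rep in 1:15) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    x <- rnorm(m); y <- rnorm(n)
    mine <- wilcoxon_rank_sum(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("wilcoxon handles ties, identity and large shifted samples", {
  x <- c(1, 2, 3)
  expect_gt(wilcoxon_rank_sum(x, x)$p, 0.95)  # same multiset
  expect_message(deg <- wilcoxon_rank_sum(rep(2, 4), rep(2, 3)),
                 "identical")
  expect_equal(deg$p, 1)

  set.seed(8)
  big <- wilcoxon_rank_sum(rnorm(200), rnorm(200) + 2)
  expect_lt(big$p, 1e-10)
  expect_equal(big$method, "normal")

  # tie-corrected normal path agrees with wilcox.test's correction
  set.seed(9)
  x <- sample(1:5, 30, replace = TRUE)
  y <- sample(2:6, 25, replace = TRUE)
  mine <- wilcoxon_rank_sum(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("normal approximation is close to exact for n >= 12 per group", {
  set.seed(4)
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(12) + runif(1, -1, 1)
    approx_p <- wilcoxon_rank_sum(x, y)$p   # N = 24 > 16 -> normal path
    u <- sum(rank(c(x, y))[1:12]) - 12 * 13 / 2
    exact_p <- min(1, 2 * min(stats::pwilcox(u, 12, 12),
                              1 - stats::pwilcox(u - 1, 12, 12)))
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})

test_that("one_sample_t matches the closed form and t.test", {
  sym <- c(-2, -1, 0, 1, 2)
  r <- one_sample_t(sym)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r2 <- one_sample_t(c(1, 2, 3))
  expect_equal(r2$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r2$p, 0.07418, tolerance = 1e-3)
  ref <- stats::t.test(c(1, 2, 3), mu = 0)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-12)

  expect_error(one_sample_t(5), "n >= 2")
  expect_error(one_sample_t(c(2, 2, 2)), "zero variance")
})

test_that("pearson_cor matches hand values, cor.test and the star legend", {
  expect_equal(pearson_cor(1:5, 2 * (1:5))$r, 1)
  r <- pearson_cor(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$r, 0.5, tolerance = 1e-12)

  set.seed(6)
  x <- rnorm(40); y <- x + rnorm(40)
  mine <- pearson_cor(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$r, pearson_cor(y, x)$r)  # symmetry
  expect_true(abs(mine$r) <= 1)

  expect_equal(pearson_cor(1:30, (1:30) + rnorm(30, sd = 0.01))$stars, "***")
  expect_equal(pearson_cor(rnorm(10), rnorm(10))$stars %in%
                 c("ns", "*", "**", "***"), TRUE)
  expect_error(pearson_cor(rep(1, 5), 1:5), "constant input")
})

test_that("varpart3 recovers a pure predictor and sums exactly", {
  set.seed(12)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  # y = x1 exactly: lm warns about the perfect fit, which is the point here
  vp <- suppressWarnings(varpart3(x1, x1, x2, x3))
  expect_gt(vp$fractions[["unique_x1"]], 0.95)
  others <- vp$fractions[setdiff(names(vp$fractions),
                                 c("unique_x1", "residual"))]
  expect_true(all(abs(others) < 0.05))

  y <- rnorm(n)
  vp2 <- varpart3(y, x1, x2, x3)
  expect_equal(sum(vp2$fractions[setdiff(names(vp2$fractions), "residual")]),
               vp2$r2[["x1x2x3"]], tolerance = 1e-10)
  expect_equal(vp2$fractions[["residual"]], 1 - vp2$r2[["x1x2x3"]],
               tolerance = 1e-12)
})

test_that("varpart3 is invariant to affine predictor rescaling", {
  set.seed(13)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- x1 + 0.5 * x2 + rnorm(n)
  a <- varpart3(y, x1, x2, x3)
  b <- varpart3(y, 10 * x1 - 3, -0.2 * x2 + 7, x3 / 5)
  expect_equal(a$fractions, b$fractions, tolerance = 1e-9)
})

test_that("varpart3 matches vegan::varpart on shared data", {
  set.seed(14)
  n <- 80
  x1 <- rnorm(n); x2 <- x1 + rnorm(n); x3 <- rnorm(n)
  y <- x1 + x3 + rnorm(n)
  mine <- varpart3(y, x1, x2, x3)
  ref <- vegan::varpart(y, ~x1, ~x2, ~x3,
                        data = data.frame(x1, x2, x3))$part
  indfract <- ref$indfract$Adj.R.square
  # vegan order: [a] unique X1, [b] unique X2, [c] unique X3, [d] X1&X2,
  # [e] X2&X3, [f] X1&X3, [g] all, [h] residual
  expect_equal(unname(mine$fractions),
               indfract[c(1, 2, 3, 4, 6, 5, 7, 8)], tolerance = 1e-8)
})

test_that("varpart3 rejects degenerate designs", {
  set.seed(15)
  x <- rnorm(30)
  expect_error(varpart3(rnorm(30), x, x, rnorm(30)),
               "collinear")
  expect_error(varpart3(rnorm(4), rnorm(4), rnorm(4), rnorm(4)), "n > 5")
})

test_that("correlation_table formats r with stars per the legend", {
  set.seed(16)
  n <- 50
  ses <- data.frame(site_id = paste0("s", 1:n), SR = rpois(n, 20) + 2,
                    PD = rnorm(n, 50, 5), NRI = rnorm(n), NTI = rnorm(n))
  ses$PD <- ses$PD + 2 * ses$SR  # strong PD~SR correlation
  env <- data.frame(site_id = ses$site_id, Anomaly2 = rnorm(n),
                    MAT = rnorm(n), MAP = rnorm(n), SWC = rnorm(n),
                    coverage = rnorm(n))
  tab <- correlation_table(ses, env)
  expect_equal(rownames(tab), c("PD", "NRI", "NTI"))
  expect_equal(colnames(tab),
               c("Anomaly2", "MAT", "MAP", "SWC", "SR", "coverage"))
  expect_match(tab["PD", "SR"], "\\*\\*\\*$")
  r <- attr(tab, "r")
  expect_equal(r["PD", "SR"], pearson_cor(ses$PD, ses$SR)$r)
  expect_true(all(grepl("^-?\\d+\\.\\d{2} (\\*{1,3}|ns)$", unlist(tab))))
})

test_that("habitat_contrasts runs Wilcoxon per variable", {
  set.seed(17)
  df <- data.frame(habitat = rep(c("alpine", "desert"), c(12, 10)),
                   PD = c(rnorm(12, 80, 5), rnorm(10, 15, 5)),
                   NRI = c(rnorm(12, -1), rnorm(10, 3)))
  ct <- habitat_contrasts(df, c("PD", "NRI"))
  expect_equal(ct$variable, c("PD", "NRI"))
  expect_lt(ct$p[ct$variable == "PD"], 0.001)
  expect_gt(ct$mean_desert[ct$variable == "NRI"],
            ct$mean_alpine[ct$variable == "NRI"])
})
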