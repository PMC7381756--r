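# six-species, two deep clades; used across the PCPS tests
clade_tree <- two_clade_tree(m = 3, gap = 10)
clade_dm <- cophenetic_matrix(clade_tree)

test_that("fuzzy_weights follows the similarity formula and is row-stochastic", {
  # equidistant star: every off-diagonal distance equals d_max -> Q = I
  star <- cophenetic_matrix(parse_newick("(A:1,B:1,C:1);"))
  expect_equal(fuzzy_weights(star), diag(3), ignore_attr = TRUE)

  # two species at d = 0 plus one at d_max
  tr0 <- parse_newick("((A:0,B:0):1,C:1);")
  q <- fuzzy_weights(cophenetic_matrix(tr0))
  expect_equal(unname(q["A", ]), c(0.5, 0.5, 0))

  for (seed in 1:5) {
    dm <- cophenetic_matrix(random_tree(8, seed))
    q <- fuzzy_weights(dm)
    expect_equal(unname(rowSums(q)), rep(1, 8), tolerance = 1e-12)
    expect_true(all(q >= 0 & q <= 1))
    expect_true(all(diag(q) >= apply(q, 1, max) - 1e-12))
  }

  expect_error(fuzzy_weights(matrix(0, 2, 2)), "distances are zero")
})

test_that("matrix_p is the row-normalized incidence times Q", {
  star_tree <- parse_newick("(A:1,B:1,C:1);")
  cm <- comm_fixture(list(s1 = c(1L, 1L, 0L), s2 = c(0L, 0L, 1L),
                          s3 = c(1L, 1L, 1L)), c("A", "B", "C"))
  q <- fuzzy_weights(cophenetic_matrix(star_tree))  # identity
  p <- matrix_p(cm, q)
  w <- cm$incidence / rowSums(cm$incidence)
  expect_equal(p, w, ignore_attr = TRUE)           # Q = I -> P = W'
  expect_equal(unname(p["s2", ]), unname(q["C", ]))  # single-species site

  # clade-pure site concentrates mass on its clade's columns
  cm2 <- comm_fixture(list(s1 = c(1L, 1L, 1L, 0L, 0L, 0L),
                           s2 = c(0L, 0L, 0L, 1L, 1L, 1L),
                           s3 = c(1L, 0L, 1L, 0L, 1L, 0L)),
                      clade_tree$tip.label)
  p2 <- matrix_p(cm2, fuzzy_weights(clade_dm))
  left_cols <- grepl("^L", colnames(p2))
  expect_gt(sum(p2["s1", left_cols]), 0.5)
  expect_gt(sum(p2["s2", !left_cols]), 0.5)
  expect_equal(unname(rowSums(p2)), rep(1, 3), tolerance = 1e-12)

  bad <- comm_fixture(list(s1 = c(1L, 1L)), c("A", "Zz"))
  expect_error(matrix_p(bad, q), "species mismatch.*zz")
})

test_that("pcoa separates two composition groups and reports percentages", {
  cm <- comm_fixture(list(s1 = c(1L, 1L, 1L, 0L, 0L, 0L),
                          s2 = c(1L, 1L, 1L, 0L, 0L, 0L),
                          s3 = c(0L, 0L, 0L, 1L, 1L, 1L),
                          s4 = c(0L, 0L, 0L, 1L, 1L, 1L)),
                     clade_tree$tip.label)
  p <- matrix_p(cm, fuzzy_weights(clade_dm))
  ord <- pcps_ordination(p)
  z <- ord$site_scores[, 1]
  expect_lt(max(abs(z["s1"] - z["s2"]), abs(z["s3"] - z["s4"])), 1e-9)
  expect_gt(abs(z["s1"] - z["s3"]), 0.1)
  expect_equal(sum(ord$percent), 100, tolerance = 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))  # non-increasing

  same <- matrix(rep(c(0.5, 0.5, 0, 0, 0, 0), 3), 3, 6, byrow = TRUE,
                 dimnames = list(paste0("s", 1:3), clade_tree$tip.label))
  expect_error(pcps_ordination(same), "degenerate ordination")
})

test_that("pcoa with Euclidean distance recovers a planted configuration", {
  set.seed(42)
  x <- matrix(rnorm(20), 10, 2,
              dimnames = list(sprintf("s%02d", 1:10), c("d1", "d2")))
  ord <- pcps_ordination(x, distance = "euclidean")
  expect_gte(ncol(ord$site_scores), 2)
  expect_lt(procrustes_rms(x, ord$site_scores[, 1:2]), 1e-8)
})

test_that("ordination is invariant under site reordering", {
  set.seed(3)
  cm <- comm_fixture(
    lapply(setNames(1:6, paste0("s", 1:6)),
           function(i) as.integer(runif(6) < 0.6 | c(TRUE, rep(FALSE, 5)))),
    clade_tree$tip.label)
  p <- matrix_p(cm, fuzzy_weights(clade_dm))
  ord1 <- pcps_ordination(p)
  perm <- sample(nrow(p))
  ord2 <- pcps_ordination(p[perm, ])
  expect_equal(ord2$site_scores[rownames(ord1$site_scores), 1:2],
               ord1$site_scores[, 1:2], tolerance = 1e-8)
})

test_that("species scores are P-weighted site means; centroids are clade means", {
  star_tree <- parse_newick("(A:1,B:1,C:1);")
  cm <- comm_fixture(list(s1 = c(1L, 0L, 0L), s2 = c(0L, 1L, 0L),
                          s3 = c(0L, 0L, 1L)), c("A", "B", "C"))
  p <- matrix_p(cm, fuzzy_weights(cophenetic_matrix(star_tree)))
  ord <- pcps_ordination(p)
  sc <- species_and_clade_scores(
    ord, clade_map = data.frame(species = c("A", "B", "C"),
                                clade = c("one", "one", "two")))
  # species in exactly one site with Q = I: species score = site score
  expect_equal(unname(sc$species_scores["A", ]),
               unname(ord$site_scores["s1", ]))
  # one-species clade: centroid = that species' score
  expect_equal(unname(sc$clade_centroids["two", ]),
               unname(sc$species_scores["C", ]))
  expect_equal(unname(sc$clade_centroids["one", ]),
               unname(colMeans(sc$species_scores[c("A", "B"), ])))
})

test_that("clade centroids oppose on axis 1 for a two-clade fixture", {
  cm <- comm_fixture(list(s1 = c(1L, 1L, 1L, 0L, 0L, 0L),
                          s2 = c(1L, 1L, 0L, 0L, 0L, 1L),
                          s3 = c(0L, 0L, 0L, 1L, 1L, 1L),
                          s4 = c(0L, 1L, 0L, 1L, 1L, 1L)),
                     clade_tree$tip.label)
  p <- matrix_p(cm, fuzzy_weights(clade_dm))
  ord <- pcps_ordination(p)
  sc <- species_and_clade_scores(
    ord, clade_map = data.frame(species = clade_tree$tip.label,
                                clade = rep(c("left", "right"), each = 3)))
  expect_lt(prod(sc$clade_centroids[, 1]), 0)
})

test_that("axis 1 separates phylogenetically disjoint habitats", {
  big <- two_clade_tree(m = 12, gap = 12)
  dm <- cophenetic_matrix(big)
  set.seed(10)
  rows <- list()
  habitat <- character(0)
  for (i in 1:8) {
    inc <- integer(24)
    inc[sample(1:12, 5)] <- 1L        # left clade only
    rows[[sprintf("d%02d", i)]] <- inc
    habitat <- c(habitat, "desert")
  }
  for (i in 1:8) {
    inc <- integer(24)
    inc[sample(13:24, 5)] <- 1L       # right clade only
    rows[[sprintf("a%02d", i)]] <- inc
    habitat <- c(habitat, "alpine")
  }
  cm <- comm_fixture(rows, big$tip.label, habitat = habitat)
  p <- matrix_p(cm, fuzzy_weights(dm))
  ord <- pcps_ordination(p)
  r <- cor(ord$site_scores[cm$site_ids, 1], as.numeric(habitat == "desert"))
  expect_gt(abs(r), 0.9)
})
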