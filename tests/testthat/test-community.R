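test_that("read filter keeps exactly the rows at or above threshold", {
  props <- matrix(0.2, 1, 5, dimnames = list("a", sym_genera()))
  m <- make_genus_table(props, n_per_cat = 3, depth = 1000, seed = 1)
  x <- as.matrix(m[sym_genera()])
  m[1, sym_genera()] <- round(x[1, ] * 999 / 1000)
  m[1, "Symbiodinium"] <- m[1, "Symbiodinium"] + (999 - sum(m[1, sym_genera()]))
  m[3, sym_genera()] <- x[3, ] * 5
  expect_equal(suppressMessages(filter_min_reads(m))$sample_id, m$sample_id[2:3])
  expect_identical(filter_min_reads(m, 0), m)
  m0 <- m
  m0[sym_genera()] <- 0L
  expect_error(filter_min_reads(m0), "below")
})

test_that("percentage conversion normalises rows to 100", {
  m <- data.frame(sample_id = c("a", "b", "c"), category = "x", species_code = "x",
                  Symbiodinium = c(50L, 720L, 0L), Breviolum = c(50L, 0L, 0L),
                  Cladocopium = c(0L, 180L, 400L), Durusdinium = c(0L, 90L, 0L),
                  Fugacium = c(0L, 10L, 0L))
  p <- to_percent(m)
  expect_equal(as.numeric(p[1, sym_genera()]), c(50, 50, 0, 0, 0))
  expect_equal(as.numeric(p[2, sym_genera()]), c(72, 0, 18, 9, 1))
  expect_equal(as.numeric(p[3, sym_genera()]), c(0, 0, 100, 0, 0))
  expect_true(all(abs(rowSums(p[sym_genera()]) - 100) < 1e-6))
  m[3, sym_genera()] <- 0L
  expect_error(to_percent(m), "zero-read")
})

test_that("Bray-Curtis matches its definition and vegan", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 5)), 1)
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(20)
  for (i in 1:25) {
    a <- stats::rpois(5, 10); b <- stats::rpois(5, 10)
    if (sum(a) + sum(b) == 0) next
    bc <- bray_curtis(a, b)
    expect_equal(bc, bray_curtis(b, a))
    expect_gte(bc, 0); expect_lte(bc, 1)
    if (bc == 0) expect_equal(a, b)
  }
  skip_if_not_installed("vegan")
  props <- matrix(rep(c(0.7, 0.05, 0.1, 0.1, 0.05), 2), 2, 5, byrow = TRUE,
                  dimnames = list(c("a", "b"), sym_genera()))
  props["b", ] <- c(0.1, 0.1, 0.6, 0.1, 0.1)
  m <- make_genus_table(props, n_per_cat = 4, seed = 21)
  d <- bray_curtis_matrix(m)
  expect_equal(max(abs(d - as.matrix(vegan::vegdist(m[sym_genera()])))), 0,
               tolerance = 1e-12)
})

test_that("PERMANOVA statistics match the brute-force oracle and vegan", {
  props <- matrix(c(0.7, 0.05, 0.1, 0.1, 0.05,
                    0.1, 0.1, 0.6, 0.1, 0.1,
                    0.2, 0.2, 0.2, 0.2, 0.2), 3, 5, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), sym_genera()))
  m <- to_percent(make_genus_table(props, n_per_cat = 5, seed = 22))
  d <- bray_curtis_matrix(m)
  res <- permanova(d, m$category, n_permutations = 99, seed = 1)
  oracle <- brute_permanova_stats(d, m$category)
  expect_equal(res$pseudo_F, oracle$pseudo_F)
  expect_equal(res$R_squared, oracle$R_squared)
  expect_equal(res$df_between, 2)
  expect_gte(res$p_value, 1 / 100)
  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(as.dist(d) ~ category, data = m, permutations = 99)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(res$R_squared, ad$R2[1], tolerance = 1e-10)
})

test_that("well-separated clusters give the minimal p and R2 near 1", {
  xy <- rbind(matrix(stats::rnorm(24, 0, 0.01), 12, 2),
              matrix(stats::rnorm(24, 100, 0.01), 12, 2))
  d <- euclid_dist(xy)
  res <- permanova(d, rep(c("a", "b"), each = 12), n_permutations = 999, seed = 2)
  expect_equal(res$p_value, 1 / 1000)
  expect_gt(res$R_squared, 0.9)
})

test_that("permutation p agrees with exhaustive enumeration at n = 6", {
  set.seed(23)
  xy <- matrix(stats::rnorm(12), 6, 2)
  xy[4:6, 1] <- xy[4:6, 1] + 1.5
  d <- euclid_dist(xy)
  groups <- rep(c("a", "b"), each = 3)
  f_obs <- brute_permanova_stats(d, groups)$pseudo_F
  combos <- utils::combn(6, 3)
  fs <- apply(combos, 2, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    brute_permanova_stats(d, g)$pseudo_F
  })
  p_exact <- mean(fs >= f_obs - 1e-12)
  res <- permanova(d, groups, n_permutations = 1999, seed = 3)
  expect_lt(abs(res$p_value - p_exact), 1 / 500 + 3 * sqrt(p_exact * (1 - p_exact) / 2000))
  # p is invariant to relabeling categories and stable across seeds
  res2 <- permanova(d, rep(c("B", "A"), each = 3), n_permutations = 1999, seed = 99)
  expect_lt(abs(res2$p_value - res$p_value), 0.05)
  expect_error(permanova(d, c("a", rep("b", 5)), 99, 1), "singleton")
})

test_that("pairwise PERMANOVA covers all pairs with a monotone BH adjustment", {
  props <- matrix(c(0.7, 0.05, 0.1, 0.1, 0.05,
                    0.1, 0.1, 0.6, 0.1, 0.1,
                    0.2, 0.2, 0.2, 0.2, 0.2,
                    0.05, 0.6, 0.1, 0.2, 0.05), 4, 5, byrow = TRUE,
                  dimnames = list(letters[1:4], sym_genera()))
  m <- to_percent(make_genus_table(props, n_per_cat = 5, seed = 24))
  d <- bray_curtis_matrix(m)
  pw <- pairwise_permanova(d, m$category, n_permutations = 99, seed = 4)
  expect_equal(nrow(pw), 4 * 3 / 2)
  expect_true(all(pw$p_adjusted >= pw$p_value))
  # step-up property: adjusted values are monotone in the raw ordering
  o <- order(pw$p_value)
  expect_true(all(diff(pw$p_adjusted[o]) >= -1e-12))
  # identical raw p values adjust to a common value equal to the raw p
  expect_equal(stats::p.adjust(rep(0.02, 3), "BH"), rep(0.02, 3))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  lt <- significance_letters(pw)
  expect_length(lt, 4)
})

test_that("dispersion test matches betadisper with centroid distances", {
  set.seed(25)
  xy <- rbind(matrix(stats::rnorm(24, 0, 1), 12, 2),
              matrix(stats::rnorm(24, 5, 1), 12, 2))
  d <- euclid_dist(xy)
  groups <- rep(c("a", "b"), each = 12)
  res <- dispersion_test(d, groups, n_permutations = 199, seed = 5)
  # identical (translated) point clouds: no dispersion difference
  expect_gt(res$p_value, 0.05)
  expect_error(dispersion_test(d[c(1, 13), c(1, 13)], c("a", "b"), 99, 1), "groups")
  skip_if_not_installed("vegan")
  bd <- vegan::betadisper(stats::as.dist(d), groups, type = "centroid")
  expect_equal(res$distances, unname(bd$distances), tolerance = 1e-10)
  expect_equal(res$F, stats::anova(bd)$`F value`[1], tolerance = 1e-10)
})

test_that("a diffuse group is detected against a tight one", {
  hits <- 0
  for (i in 1:40) {
    set.seed(400 + i)
    xy <- rbind(matrix(stats::rnorm(40, 0, 0.1), 20, 2),
                matrix(stats::rnorm(40, 0, 1.0), 20, 2))
    res <- dispersion_test(euclid_dist(xy), rep(c("t", "d"), each = 20),
                           n_permutations = 0)
    if (res$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.9)
})

test_that("balanced subsampling is exact, deterministic and validated", {
  props <- matrix(0.2, 2, 5, dimnames = list(c("a", "b"), sym_genera()))
  m <- make_genus_table(props, n_per_cat = 6, seed = 26)
  s1 <- balanced_subsample(m, 3, seed = 7)
  s2 <- balanced_subsample(m, 3, seed = 7)
  expect_identical(s1, s2)
  expect_equal(as.integer(table(s1$category)), c(3L, 3L))
  ids <- c("a_1", "a_3", "b_2")
  sf <- balanced_subsample(m, fixed_ids = ids)
  expect_equal(sf$sample_id, ids[order(match(ids, m$sample_id))])
  expect_identical(balanced_subsample(m, 6, seed = 1), m)
  expect_error(balanced_subsample(m, 7, seed = 1), "too small")
  expect_error(balanced_subsample(m, fixed_ids = "nope"), "not present")
})

test_that("rarefaction closed form matches resampling and handles edges", {
  counts <- c(90, 10, 0, 0, 0)
  expect_equal(rarefaction_curve(counts, sum(counts))$expected_richness, 2)
  expect_equal(rarefaction_curve(counts, 1)$expected_richness, 1)
  # Monte-Carlo cross-check at depth 10
  set.seed(27)
  pool <- rep(seq_along(counts), counts)
  draws <- replicate(10000, length(unique(sample(pool, 10))))
  closed <- rarefaction_curve(counts, 10)$expected_richness
  expect_lt(abs(closed - mean(draws)), 0.02)
  expect_error(rarefaction_curve(counts, 101), "exceeds")
})
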