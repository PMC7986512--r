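test_that("generators are deterministic given a seed", {
  prof <- default_guild_profiles()
  a <- generate_cell_count_samples(prof["water"], n_per_guild = 5, seed = 3)
  b <- generate_cell_count_samples(prof["water"], n_per_guild = 5, seed = 3)
  expect_identical(a, b)
  ga <- generate_genus_counts(prof, n_per_guild = 4, seed = 3)
  gb <- generate_genus_counts(prof, n_per_guild = 4, seed = 3)
  expect_identical(ga, gb)
  fa <- generate_field_observations(default_species_params(), n_follows = 10, seed = 3)
  fb <- generate_field_observations(default_species_params(), n_follows = 10, seed = 3)
  expect_identical(fa, fb)
  expect_identical(child_seeds(5, 4), child_seeds(5, 4))
})

test_that("zero true density yields all-zero replicate counts", {
  prof <- guild_profile("empty", -Inf, 0, 0.5, rep(1, 5))
  out <- generate_cell_count_samples(list(prof), n_per_guild = 10, seed = 2)
  counts <- unlist(lapply(out$samples, function(s) c(s$live_counts, s$dead_counts)))
  expect_true(all(counts == 0))
  expect_true(all(out$truth$true_live_per_ml == 0))
})

test_that("replicate counts are Poisson at density x dilution fraction x chamber volume", {
  # constant-density guild; 1250 samples x 8 replicates = 10,000 replicate draws
  prof <- guild_profile("g", 6, 0, 1, rep(1, 5))
  out <- generate_cell_count_samples(list(prof), n_per_guild = 1250, seed = 4)
  obs <- vapply(out$samples, function(s) mean(s$live_counts), numeric(1))
  expected <- vapply(out$samples, function(s)
    1e6 / dilution_factor(s$prep) * s$counted_volume_ml, numeric(1))
  ratio <- sum(obs) / sum(expected)
  # Monte-Carlo SE of the pooled ratio: Poisson, so var = total expected count
  se <- sqrt(sum(expected) * 8) / (sum(expected) * 8)
  expect_lt(abs(ratio - 1), 3 * se)
})

test_that("obligate and water guild densities span >= 6 orders of magnitude", {
  profs <- list(guild_profile("obligate", 6.5, 0.3, 0.7, rep(1, 5)),
                guild_profile("water", -0.6, 0.3, 0.5, rep(1, 5)))
  out <- generate_cell_count_samples(profs, n_per_guild = 20, seed = 5)
  dens <- density_table(out$samples)
  m <- tapply(dens$live_per_ml, dens$guild, mean)
  expect_lte(m[["water"]], m[["obligate"]] * 1e-6)
})

test_that("genus counts follow the Dirichlet-multinomial law", {
  # degenerate concentration: everything lands in Cladocopium
  prof <- guild_profile("c", 6, 0.5, 0.7,
                        c(1e-8, 1e-8, 1, 1e-8, 1e-8))
  g <- generate_genus_counts(list(prof), n_per_guild = 20,
                             depth_range = c(2000, 2000), seed = 6)
  x <- as.matrix(g$counts[sym_genera()])
  expect_true(all(x[, setdiff(sym_genera(), "Cladocopium")] == 0))
  expect_true(all(rowSums(x) == 2000))

  # symmetric concentration: each genus averages 20% relative abundance
  prof <- guild_profile("s", 6, 0.5, 0.7, rep(1, 5))
  g <- generate_genus_counts(list(prof), n_per_guild = 500,
                             depth_range = c(10000, 10000), seed = 7)
  rel <- as.matrix(g$counts[sym_genera()]) / 10000
  expect_true(all(abs(colMeans(rel) - 0.2) < 0.02))

  # default obligate profile sits in the Cladocopium-dominated band
  g <- generate_genus_counts(default_guild_profiles()["obligate_corallivore"],
                             n_per_guild = 200, depth_range = c(5000, 5000), seed = 8)
  rel <- as.matrix(g$counts[sym_genera()])
  clado <- mean(rel[, "Cladocopium"] / rowSums(rel))
  expect_gt(clado, 0.72)
  expect_lt(clado, 0.98)

  # truth proportions sum to 1
  expect_true(all(abs(rowSums(g$truth[sym_genera()]) - 1) < 1e-9))
  # a below-filter library is emitted when the depth range allows it
  g2 <- generate_genus_counts(default_guild_profiles(), n_per_guild = 6,
                              depth_range = c(600, 20000), seed = 9)
  expect_true(any(rowSums(g2$counts[sym_genera()]) < 1000))
  expect_error(generate_genus_counts(list(), 5), "empty")
})

test_that("field observations recover the egestion rate and feed the dispersal module", {
  sp0 <- list(A = list(egestion_rate_per_h = 0, pellet_length_mean_cm = 2,
                       pellet_length_sd_cm = 0.5, pellet_linear_density_mean_g_cm = 0.05,
                       pellet_linear_density_sd_g_cm = 0.01,
                       fish_density_mean_per_250m2 = 10))
  f0 <- generate_field_observations(sp0, n_follows = 50, seed = 10)
  expect_true(all(f0$follows$events == 0))
  expect_equal(egestion_constant(f0$follows), 0)

  sp <- sp0
  sp$A$egestion_rate_per_h <- 1.5
  f <- generate_field_observations(sp, n_follows = 1000, follow_duration_min = 60,
                                   seed = 11)
  rate <- sum(f$follows$events) / (sum(f$follows$duration_min) / 60)
  se <- sqrt(sum(f$follows$events)) / 1000  # Poisson SE of the pooled rate
  expect_lt(abs(rate - 1.5), 3 * se)

  # schema round-trip: three species accepted by the dispersal module end-to-end
  f3 <- generate_field_observations(default_species_params(), n_follows = 20, seed = 12)
  for (sp_name in names(default_species_params())) {
    g <- egestion_constant(f3$follows[f3$follows$species == sp_name, ])
    pel <- f3$pellets[f3$pellets$species == sp_name, ]
    tr <- f3$transects[f3$transects$species == sp_name, ]
    est <- bootstrap_dispersal(bootstrap_inputs(
      sp_name, g, pel$length_cm, pellet_linear_density(pel$length_cm, pel$weight_g),
      C = c(1e6, 2e6), F_ = lter_density_convert(tr$count_per_250m2)),
      iterations = 50, seed = 13)
    expect_s3_class(est, "dispersal_estimate")
    expect_true(est$ci_low <= est$mean_T && est$mean_T <= est$ci_high)
  }
})

test_that("coral cover points follow their zone's Bernoulli law", {
  all_live <- generate_coral_cover(c(fore = 1, back = 1), c(fore = 3, back = 3),
                                   points_per_transect = 20, seed = 14)
  tc <- transect_cover(all_live)
  expect_true(all(tc$percent_cover == 100))

  big <- generate_coral_cover(c(fore = 0.45, back = 0.15),
                              c(fore = 1000, back = 1000),
                              points_per_transect = 50, seed = 15)
  tc <- transect_cover(big)
  zm <- tapply(tc$percent_cover, tc$zone, mean)
  expect_lt(abs(zm[["fore"]] - 45), 1)
  expect_lt(abs(zm[["back"]] - 15), 1)
  expect_error(generate_coral_cover(c(fore = 1.2)), "\\[0, 1\\]")
})

test_that("default-cover zones are separated by the cover ANOVA at large n", {
  pts <- generate_coral_cover(n_transects_by_zone = c(fore = 60, back = 60), seed = 16)
  tc <- transect_cover(pts)
  res <- coral_cover_anova(tc$percent_cover, tc$zone)
  expect_lt(res$anova$p_value, 1e-6)
})
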