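# The pipeline entry point binding the modules together. Each command reads
# the standard delimited schemas from the input directory, runs one stage,
# and writes plain CSV outputs plus a run log (seed, config hash, versions)
# sufficient to replay the run exactly.

pipeline_files <- list(
  cell_counts = "cell_counts.csv", genus_counts = "genus_counts.csv",
  follows = "follows.csv", cover = "cover.csv", contacts = "contacts.csv",
  culture = "culture_wells.csv", bootstrap = "bootstrap_inputs.csv",
  truth = "truth.yaml")

log_run <- function(cfg, out_dir, command) {
  cfg_path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  lines <- c(sprintf("command: %s", command),
             sprintf("seed: %d", cfg$seed),
             sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))),
             sprintf("r_version: %s", R.version.string),
             sprintf("package_version: %s",
                     as.character(utils::packageVersion("symdisp"))),
             sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(lines, file.path(out_dir, sprintf("run_log_%s.txt", command)))
}

species_guild_map <- c(CHOR = "obligate_corallivore", CHRE = "obligate_corallivore",
                       CHCI = "facultative_corallivore")

#' Run one stage of the dispersal-quantification pipeline
#'
#' Commands:
#' \describe{
#'   \item{simulate}{Write a complete synthetic dataset (cell counts, genus
#'     counts, follows, cover, contacts, culture wells, bootstrap inputs)
#'     plus a ground-truth sidecar (`truth.yaml`) to the input directory.}
#'   \item{densities}{Cell counts -> per-sample density table and per-group
#'     summary.}
#'   \item{community}{Genus counts -> filtered percentages, Bray-Curtis
#'     distance matrix, overall and pairwise PERMANOVA, dispersion test,
#'     rarefaction table.}
#'   \item{dispersal}{Bootstrap inputs (+ follows for g) -> per-species
#'     dispersal estimates and raw draws.}
#'   \item{stats}{Density table + cover + culture + contacts -> univariate
#'     test tables and prevalence summaries.}
#'   \item{report}{Combine the stage outputs into one human-readable
#'     summary.}
#' }
#'
#' @param command One of simulate, densities, community, dispersal, stats,
#'   report.
#' @param config A config list / YAML path for [read_run_config()].
#' @return (Invisibly) a named list of the objects computed by the stage.
#' @export
run_pipeline <- function(command = c("simulate", "densities", "community",
                                     "dispersal", "stats", "report"),
                         config = NULL) {
  command <- match.arg(command)
  cfg <- read_run_config(config)
  in_dir <- cfg$paths$input_dir
  out_dir <- cfg$paths$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(command,
    simulate = pipeline_simulate(cfg, in_dir),
    densities = pipeline_densities(cfg, in_dir, out_dir),
    community = pipeline_community(cfg, in_dir, out_dir),
    dispersal = pipeline_dispersal(cfg, in_dir, out_dir),
    stats = pipeline_stats(cfg, in_dir, out_dir),
    report = pipeline_report(cfg, out_dir))
  log_run(cfg, out_dir, command)
  invisible(res)
}

pipeline_simulate <- function(cfg, in_dir) {
  dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- child_seeds(cfg$seed, 7)
  profiles <- default_guild_profiles()
  count_profiles <- profiles[setdiff(names(profiles), "coral")]
  cc <- generate_cell_count_samples(count_profiles,
                                    n_per_guild = cfg$simulate$n_per_guild,
                                    chamber_volume_ml = cfg$hemocytometer$counted_volume_ml,
                                    seed = seeds[1])
  write_cell_counts(cc$samples, file.path(in_dir, pipeline_files$cell_counts))
  gc <- generate_genus_counts(profiles, n_per_guild = cfg$simulate$n_genus_per_guild,
                              seed = seeds[2])
  utils::write.csv(gc$counts, file.path(in_dir, pipeline_files$genus_counts),
                   row.names = FALSE)
  fo <- generate_field_observations(default_species_params(),
                                    n_follows = cfg$simulate$n_follows,
                                    n_transects = cfg$simulate$n_transects,
                                    seed = seeds[3])
  utils::write.csv(fo$follows, file.path(in_dir, pipeline_files$follows),
                   row.names = FALSE)
  cov <- generate_coral_cover(seed = seeds[4])
  utils::write.csv(cov, file.path(in_dir, pipeline_files$cover), row.names = FALSE)
  con <- generate_fecal_contacts(seed = seeds[5])
  utils::write.csv(con, file.path(in_dir, pipeline_files$contacts), row.names = FALSE)
  cw <- generate_culture_wells(seed = seeds[6])
  utils::write.csv(cw, file.path(in_dir, pipeline_files$culture), row.names = FALSE)

  # bootstrap inputs: C per species from the matching guild's per-gram
  # densities, S and W from the synthetic pellets, F from the transects
  dens <- density_table(cc$samples)
  inputs <- lapply(names(species_guild_map), function(sp) {
    guild <- species_guild_map[[sp]]
    C <- dens$live_per_g[dens$guild == guild & !is.na(dens$live_per_g)]
    pel <- fo$pellets[fo$pellets$species == sp, ]
    tr <- fo$transects[fo$transects$species == sp, ]
    list(species = sp, zone = tr$zone[1], g = NA_real_,
         S = pel$length_cm,
         W = pellet_linear_density(pel$length_cm, pel$weight_g),
         C = C, F = lter_density_convert(tr$count_per_250m2))
  })
  names(inputs) <- names(species_guild_map)
  write_bootstrap_inputs(inputs, file.path(in_dir, pipeline_files$bootstrap))

  truth <- list(seed = cfg$seed,
                cell_density = split(cc$truth[setdiff(names(cc$truth), "seed")],
                                     seq_len(nrow(cc$truth))),
                egestion_rates = stats::setNames(
                  lapply(default_species_params(), `[[`, "egestion_rate_per_h"),
                  names(default_species_params())))
  yaml::write_yaml(truth, file.path(in_dir, pipeline_files$truth))
  list(samples = cc$samples, genus_counts = gc$counts, field = fo,
       cover = cov, contacts = con, culture = cw, bootstrap_inputs = inputs)
}

pipeline_densities <- function(cfg, in_dir, out_dir) {
  cc <- read_cell_counts(file.path(in_dir, pipeline_files$cell_counts))
  dens <- if (isTRUE(attr(cc, "precomputed"))) cc else density_table(cc)
  summ <- summarize_guild_densities(dens, group = "guild")
  utils::write.csv(dens, file.path(out_dir, "density_table.csv"), row.names = FALSE)
  utils::write.csv(summ, file.path(out_dir, "density_summary.csv"), row.names = FALSE)
  list(densities = dens, summary = summ)
}

pipeline_community <- function(cfg, in_dir, out_dir) {
  m <- read_genus_counts(file.path(in_dir, pipeline_files$genus_counts))
  m <- filter_min_reads(m, cfg$community$threshold_reads)
  # a balanced design cannot exceed the smallest retained category
  n_cat <- min(cfg$community$n_per_category, min(table(m$category)))
  if (n_cat < cfg$community$n_per_category)
    message("reducing n_per_category to ", n_cat,
            " (smallest category after read filtering)")
  sub <- balanced_subsample(m, n_cat, seed = cfg$seed,
                            fixed_ids = cfg$community$fixed_ids)
  ab <- if (isTRUE(cfg$community$use_percent)) to_percent(sub) else sub
  d <- bray_curtis_matrix(ab)
  seeds <- child_seeds(cfg$seed, 3)
  ov <- permanova(d, sub$category, cfg$community$permutations, seeds[1])
  pw <- pairwise_permanova(d, sub$category, cfg$community$permutations, seeds[2])
  disp <- dispersion_test(d, sub$category, cfg$community$permutations, seeds[3])
  rar <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    tot <- sum(as.numeric(m[i, SYM_GENERA]))
    depths <- unique(pmin(tot, c(10, 50, 100, 500, 1000, 5000, tot)))
    cbind(sample_id = m$sample_id[i],
          rarefaction_curve(as.numeric(m[i, SYM_GENERA]), depths))
  }))
  utils::write.csv(as.data.frame(d), file.path(out_dir, "bray_curtis.csv"))
  ov_df <- data.frame(df = ov$df_between, pseudo_F = ov$pseudo_F,
                      R_squared = ov$R_squared, p_value = ov$p_value,
                      n_permutations = ov$n_permutations)
  utils::write.csv(ov_df, file.path(out_dir, "permanova_overall.csv"), row.names = FALSE)
  utils::write.csv(pw, file.path(out_dir, "permanova_pairwise.csv"), row.names = FALSE)
  disp_df <- data.frame(group = names(disp$group_means),
                        mean_centroid_distance = as.numeric(disp$group_means))
  disp_df$F <- disp$F; disp_df$p_value <- disp$p_value
  disp_df$p_permutation <- disp$p_permutation
  utils::write.csv(disp_df, file.path(out_dir, "dispersion.csv"), row.names = FALSE)
  utils::write.csv(rar, file.path(out_dir, "rarefaction.csv"), row.names = FALSE)
  list(distance = d, overall = ov, pairwise = pw, dispersion = disp,
       rarefaction = rar,
       letters = significance_letters(pw))
}

pipeline_dispersal <- function(cfg, in_dir, out_dir) {
  raw <- read_bootstrap_inputs(file.path(in_dir, pipeline_files$bootstrap))
  follows_path <- file.path(in_dir, pipeline_files$follows)
  follows <- if (file.exists(follows_path)) read_follows(follows_path) else NULL
  seeds <- child_seeds(cfg$seed, length(raw))
  ests <- lapply(seq_along(raw), function(i) {
    b <- raw[[i]]
    g <- b$g
    if (is.na(g)) {
      if (is.null(follows) || !b$species %in% follows$species)
        stop_invalid("no g_constant and no follows for species '%s'", b$species)
      g <- egestion_constant(follows[follows$species == b$species, ],
                             cfg$active_hours)
    }
    bootstrap_dispersal(bootstrap_inputs(b$species, g, b$S, b$W, b$C, b$F),
                        iterations = cfg$bootstrap$iterations, seed = seeds[i],
                        ci_level = cfg$bootstrap$ci_level,
                        scheme = cfg$bootstrap$scheme)
  })
  names(ests) <- vapply(ests, `[[`, "", "species")
  tab <- do.call(rbind, lapply(ests, function(e)
    data.frame(species = e$species, g = e$g, mean_T = e$mean_T,
               ci_low = e$ci_low, ci_high = e$ci_high,
               half_width = e$half_width, iterations = e$iterations,
               seed = e$seed, stringsAsFactors = FALSE)))
  utils::write.csv(tab, file.path(out_dir, "dispersal_estimates.csv"),
                   row.names = FALSE)
  draws <- do.call(rbind, lapply(ests, function(e)
    data.frame(species = e$species, draw = seq_along(e$draws), T = e$draws)))
  utils::write.csv(draws, file.path(out_dir, "dispersal_draws.csv"),
                   row.names = FALSE)
  list(estimates = ests, table = tab)
}

pipeline_stats <- function(cfg, in_dir, out_dir) {
  dens_path <- file.path(out_dir, "density_table.csv")
  if (!file.exists(dens_path))
    pipeline_densities(cfg, in_dir, out_dir)
  dens <- utils::read.csv(dens_path, stringsAsFactors = FALSE)
  kw_live <- kruskal_wallis(dens$live_per_ml, dens$species_or_type)
  kw_dead <- kruskal_wallis(dens$dead_per_ml, dens$species_or_type)
  dn <- dunn_test(dens$live_per_ml, dens$species_or_type)
  out_flags <- outlier_screen(dens$live_per_ml, dens$guild)
  cov <- read_cover(file.path(in_dir, pipeline_files$cover))
  ct <- transect_cover(cov)
  an <- coral_cover_anova(ct$percent_cover, ct$zone)
  cw <- utils::read.csv(file.path(in_dir, pipeline_files$culture),
                        stringsAsFactors = FALSE)
  cult <- culture_summary(cw)
  con <- read_contacts(file.path(in_dir, pipeline_files$contacts))
  contact <- fecal_contact_summary(con)
  kw_df <- data.frame(test = c("kruskal_wallis_live", "kruskal_wallis_dead"),
                      statistic = c(kw_live$statistic, kw_dead$statistic),
                      df = c(kw_live$df, kw_dead$df),
                      p_value = c(kw_live$p_value, kw_dead$p_value))
  an_df <- data.frame(test = c("anova_cover", "shapiro_residuals", "levene"),
                      statistic = c(an$anova$statistic, an$shapiro$statistic,
                                    an$levene$statistic),
                      df1 = c(an$anova$df[1], NA, an$levene$df[1]),
                      df2 = c(an$anova$df[2], NA, an$levene$df[2]),
                      p_value = c(an$anova$p_value, an$shapiro$p_value,
                                  an$levene$p_value))
  utils::write.csv(kw_df, file.path(out_dir, "kruskal_wallis.csv"), row.names = FALSE)
  utils::write.csv(dn, file.path(out_dir, "dunn_pairwise.csv"), row.names = FALSE)
  utils::write.csv(out_flags, file.path(out_dir, "outliers.csv"), row.names = FALSE)
  utils::write.csv(an_df, file.path(out_dir, "cover_anova.csv"), row.names = FALSE)
  utils::write.csv(cult, file.path(out_dir, "culture_summary.csv"), row.names = FALSE)
  utils::write.csv(contact, file.path(out_dir, "contact_summary.csv"), row.names = FALSE)
  list(kruskal_wallis = list(live = kw_live, dead = kw_dead), dunn = dn,
       outliers = out_flags, cover_anova = an, culture = cult,
       contacts = contact, cover_transects = ct)
}

pipeline_report <- function(cfg, out_dir) {
  grab <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  lines <- c("Symbiodiniaceae dispersal pipeline report", "")
  ds <- grab("density_summary.csv")
  if (!is.null(ds)) {
    lines <- c(lines, "Live cell densities per group (cells/ml source):",
               utils::capture.output(print(ds)), "")
  }
  ov <- grab("permanova_overall.csv")
  if (!is.null(ov))
    lines <- c(lines, sprintf(
      "Genus-level community PERMANOVA: df = %d, F = %.2f, R2 = %.2f, p = %.4g",
      ov$df, ov$pseudo_F, ov$R_squared, ov$p_value), "")
  de <- grab("dispersal_estimates.csv")
  if (!is.null(de)) {
    lines <- c(lines, "Reef-scale dispersal estimates (cells per 100 m2 per day):",
               utils::capture.output(print(de)), "")
  }
  kw <- grab("kruskal_wallis.csv")
  if (!is.null(kw))
    lines <- c(lines, utils::capture.output(print(kw)), "")
  cs <- grab("contact_summary.csv")
  if (!is.null(cs))
    lines <- c(lines, "Fecal contact with live coral:",
               utils::capture.output(print(cs)), "")
  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path)
  list(report_path = path, lines = lines)
}
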