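# Synthetic-data generators with known ground truth.
#
# Every input the pipeline consumes can be generated here with its true
# parameters recorded, so density recovery, community separation and
# bootstrap coverage are all testable without field data. One global seed
# fans out to per-generator child streams via child_seeds().

#' Generate hemocytometer cell-count samples with known true densities
#'
#' For each guild, true live density per ml of source is zero with the
#' guild's zero-inflation probability and otherwise lognormal
#' (10^Normal(log10 mean, log10 sd)). Dead density follows from the guild's
#' live fraction (dead = live x (1 - f) / f). Sample volumes and masses are
#' drawn uniformly over the ranges observed in the study (42-234 ul; 22-170
#' mg); fixative volume is 750 ul. Each technical replicate count is Poisson
#' with mean = true density / dilution factor x counted chamber volume,
#' split live/dead.
#'
#' @param profiles List of [guild_profile()] objects.
#' @param n_per_guild Samples per guild (>= 1).
#' @param chamber_volume_ml Counted grid volume per replicate, ml (> 0).
#' @param n_replicates Technical replicates per sample (study design: 8).
#' @param seed Integer seed.
#' @return List with `samples` (list of [cell_count_sample()]) and `truth`
#'   (data frame: sample_id, guild, true_live_per_ml, true_dead_per_ml, seed).
#' @export
generate_cell_count_samples <- function(profiles, n_per_guild = 12,
                                        chamber_volume_ml = 1e-4,
                                        n_replicates = 8, seed = 1) {
  if (length(profiles) == 0) stop_invalid("empty profile list")
  check_number(n_per_guild, "n_per_guild", lower = 1, integer = TRUE)
  if (!is.numeric(chamber_volume_ml) || chamber_volume_ml <= 0)
    stop_invalid("chamber_volume_ml must be > 0")
  set.seed(seed)
  samples <- list()
  truth <- list()
  for (pr in profiles) {
    for (i in seq_len(n_per_guild)) {
      zero <- stats::runif(1) < pr$zero_prob
      live <- if (zero || !is.finite(pr$log10_mean_live_density)) 0 else
        10^stats::rnorm(1, pr$log10_mean_live_density, pr$log10_sd)
      f <- pr$live_fraction
      dead <- if (f > 0 && f < 1) live * (1 - f) / f else if (f == 1) 0 else {
        # all-dead guild: dead density reuses the lognormal law directly
        if (zero) 0 else 10^stats::rnorm(1, pr$log10_mean_live_density, pr$log10_sd)
      }
      sv <- stats::runif(1, 42, 234)
      prep <- if (pr$source_type == "feces")
        sample_prep(sv, 750, 0, stats::runif(1, 22, 170), "feces")
      else sample_prep(sv, 750, 0, NA_real_, pr$source_type)
      df <- dilution_factor(prep)
      lam_live <- live / df * chamber_volume_ml
      lam_dead <- dead / df * chamber_volume_ml
      sid <- sprintf("%s_%02d", pr$guild_name, i)
      samples[[sid]] <- cell_count_sample(
        sid, pr$guild_name, pr$guild_name,
        live_counts = stats::rpois(n_replicates, lam_live),
        dead_counts = stats::rpois(n_replicates, lam_dead),
        counted_volume_ml = chamber_volume_ml, prep = prep)
      truth[[sid]] <- data.frame(sample_id = sid, guild = pr$guild_name,
                                 true_live_per_ml = live,
                                 true_dead_per_ml = dead,
                                 stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  truth$seed <- seed
  list(samples = unname(samples), truth = truth)
}

#' Generate a genus-level ITS2 read count matrix
#'
#' Per-sample genus proportions are Dirichlet with the guild's concentration
#' vector; reads are multinomial at a depth drawn log-uniformly in
#' `depth_range`. When `min_reads < 1000` at least one sample below the
#' 1000-read filter threshold is emitted so downstream filtering is
#' exercised.
#'
#' @param profiles List of [guild_profile()] objects.
#' @param n_per_guild Samples per guild.
#' @param depth_range `c(min_reads, max_reads)`; defaults 600-20000 so a few
#'   libraries fall under the 1000-read filter, as in the study.
#' @param seed Integer seed.
#' @return List with `counts` (data frame: sample_id, category, species_code,
#'   five genus columns) and `truth` (data frame of true proportions, plus
#'   seed).
#' @export
generate_genus_counts <- function(profiles, n_per_guild = 14,
                                  depth_range = c(600, 20000), seed = 1) {
  if (length(profiles) == 0) stop_invalid("empty profile list")
  check_number(n_per_guild, "n_per_guild", lower = 1, integer = TRUE)
  if (depth_range[1] < 0 || depth_range[2] < depth_range[1])
    stop_invalid("need 0 <= min_reads <= max_reads")
  set.seed(seed)
  rows <- list(); truths <- list()
  for (pr in profiles) {
    p <- rdirichlet(n_per_guild, pr$genus_concentration)
    depth <- round(exp(stats::runif(n_per_guild, log(max(depth_range[1], 1)),
                                    log(max(depth_range[2], 1)))))
    for (i in seq_len(n_per_guild)) {
      reads <- as.vector(stats::rmultinom(1, depth[i], p[i, ]))
      sid <- sprintf("%s_%02d", pr$guild_name, i)
      cnt <- as.data.frame(as.list(stats::setNames(reads, SYM_GENERA)))
      rows[[sid]] <- cbind(data.frame(sample_id = sid, category = pr$guild_name,
                                      species_code = pr$guild_name,
                                      stringsAsFactors = FALSE), cnt)
      truths[[sid]] <- cbind(data.frame(sample_id = sid, category = pr$guild_name,
                                        stringsAsFactors = FALSE),
                             as.data.frame(as.list(stats::setNames(p[i, ], SYM_GENERA))))
    }
  }
  counts <- do.call(rbind, rows)
  # guarantee one below-filter library when the range allows it
  if (depth_range[1] < 1000 && all(rowSums(counts[SYM_GENERA]) >= 1000)) {
    shallow <- max(1, depth_range[1])
    pr1 <- profiles[[1]]
    p1 <- rdirichlet(1, pr1$genus_concentration)
    counts[1, SYM_GENERA] <- as.vector(stats::rmultinom(1, shallow, p1[1, ]))
  }
  truth <- do.call(rbind, truths)
  rownames(counts) <- rownames(truth) <- NULL
  truth$seed <- seed
  list(counts = counts, truth = truth)
}

#' Generate timed fish-follow, pellet and transect observations
#'
#' Egestion events per follow are Poisson(rate x duration); pellet lengths
#' and linear densities are truncated-normal above zero; transect counts are
#' Poisson at the species' mean density per 250 m^2 belt transect.
#'
#' @param species_params Named list; one entry per species, each a list with
#'   `egestion_rate_per_h`, `pellet_length_mean_cm`, `pellet_length_sd_cm`,
#'   `pellet_linear_density_mean_g_cm`, `pellet_linear_density_sd_g_cm`,
#'   `fish_density_mean_per_250m2`, and optionally `zone`.
#' @param n_follows Follows per species.
#' @param follow_duration_min Duration of each follow, minutes.
#' @param n_pellets Pellet length/weight measurements per species.
#' @param n_transects Belt transects per species.
#' @param seed Integer seed.
#' @return List of data frames: `follows` (species, follow_id, duration_min,
#'   events), `pellets` (species, length_cm, weight_g), `transects` (species,
#'   zone, transect_id, count_per_250m2), and `truth` (the input parameters,
#'   flattened, plus seed).
#' @export
generate_field_observations <- function(species_params, n_follows = 40,
                                        follow_duration_min = 7.9,
                                        n_pellets = 4, n_transects = 4,
                                        seed = 1) {
  if (length(species_params) == 0) stop_invalid("empty species_params")
  for (sp in names(species_params)) {
    q <- species_params[[sp]]
    if (q$egestion_rate_per_h < 0 || q$fish_density_mean_per_250m2 < 0)
      stop_invalid("rates and densities must be >= 0 (species %s)", sp)
  }
  check_number(n_follows, "n_follows", lower = 1, integer = TRUE)
  set.seed(seed)
  follows <- pellets <- transects <- list()
  for (sp in names(species_params)) {
    q <- species_params[[sp]]
    ev <- stats::rpois(n_follows, q$egestion_rate_per_h * follow_duration_min / 60)
    follows[[sp]] <- data.frame(species = sp, follow_id = seq_len(n_follows),
                                duration_min = follow_duration_min, events = ev,
                                stringsAsFactors = FALSE)
    len <- rtruncnorm_pos(n_pellets, q$pellet_length_mean_cm, q$pellet_length_sd_cm,
                          lower = 1e-3)
    wpc <- rtruncnorm_pos(n_pellets, q$pellet_linear_density_mean_g_cm,
                          q$pellet_linear_density_sd_g_cm, lower = 1e-4)
    pellets[[sp]] <- data.frame(species = sp, length_cm = len,
                                weight_g = wpc * len, stringsAsFactors = FALSE)
    transects[[sp]] <- data.frame(species = sp,
                                  zone = if (is.null(q$zone)) "fore" else q$zone,
                                  transect_id = seq_len(n_transects),
                                  count_per_250m2 = stats::rpois(n_transects, q$fish_density_mean_per_250m2),
                                  stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, lapply(names(species_params), function(sp) {
    q <- species_params[[sp]]
    data.frame(species = sp,
               egestion_rate_per_h = q$egestion_rate_per_h,
               pellet_length_mean_cm = q$pellet_length_mean_cm,
               pellet_linear_density_mean_g_cm = q$pellet_linear_density_mean_g_cm,
               fish_density_mean_per_250m2 = q$fish_density_mean_per_250m2,
               stringsAsFactors = FALSE)
  }))
  truth$seed <- seed
  out <- list(follows = do.call(rbind, follows),
              pellets = do.call(rbind, pellets),
              transects = do.call(rbind, transects),
              truth = truth)
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  out
}

#' Default per-species field parameters for the three focal corallivores
#'
#' Magnitudes chosen so the synthetic reef reproduces the study's structure:
#' the two obligate corallivores (fore reef) are several-fold denser than the
#' facultative corallivore (back reef), egest slightly larger, denser pellets
#' at somewhat higher rates, and their feces carry orders of magnitude more
#' live cells (that part comes from the guild density profiles).
#'
#' @return Named list suitable for [generate_field_observations()].
#' @export
default_species_params <- function() {
  list(
    CHOR = list(egestion_rate_per_h = 1.6, pellet_length_mean_cm = 1.8,
                pellet_length_sd_cm = 0.4, pellet_linear_density_mean_g_cm = 0.06,
                pellet_linear_density_sd_g_cm = 0.015,
                fish_density_mean_per_250m2 = 15, zone = "fore"),
    CHRE = list(egestion_rate_per_h = 1.4, pellet_length_mean_cm = 2.0,
                pellet_length_sd_cm = 0.5, pellet_linear_density_mean_g_cm = 0.07,
                pellet_linear_density_sd_g_cm = 0.02,
                fish_density_mean_per_250m2 = 19, zone = "fore"),
    CHCI = list(egestion_rate_per_h = 1.2, pellet_length_mean_cm = 1.2,
                pellet_length_sd_cm = 0.3, pellet_linear_density_mean_g_cm = 0.04,
                pellet_linear_density_sd_g_cm = 0.01,
                fish_density_mean_per_250m2 = 3, zone = "back")
  )
}

#' Generate coral-cover point-transect records
#'
#' Each meter mark along a transect is an independent Bernoulli draw: live
#' coral with the zone's probability, "other" otherwise.
#'
#' @param p_live_by_zone Named vector of live-cover probabilities per zone;
#'   defaults to the observed mean covers (fore 0.448, back 0.1533).
#' @param n_transects_by_zone Named integer vector of transects per zone;
#'   defaults to the study design (fore 5, back 12).
#' @param points_per_transect Meter marks per transect (50 m transect).
#' @param seed Integer seed.
#' @return Data frame: zone, transect_id, point, live_coral (0/1).
#' @export
generate_coral_cover <- function(p_live_by_zone = c(fore = 0.448, back = 0.1533),
                                 n_transects_by_zone = c(fore = 5, back = 12),
                                 points_per_transect = 50, seed = 1) {
  if (any(p_live_by_zone < 0 | p_live_by_zone > 1))
    stop_invalid("cover probabilities must be in [0, 1]")
  set.seed(seed)
  out <- list()
  for (z in names(p_live_by_zone)) {
    nt <- n_transects_by_zone[[z]]
    for (t in seq_len(nt)) {
      out[[paste(z, t)]] <- data.frame(
        zone = z, transect_id = sprintf("%s_%02d", z, t),
        point = seq_len(points_per_transect),
        live_coral = as.integer(stats::runif(points_per_transect) < p_live_by_zone[[z]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate fecal-contact observations per reef zone
#'
#' Each observed egestion contacts live coral with its zone's probability;
#' defaults reproduce the observed contact frequencies (fore 20/22, back
#' 3/30 — roughly the zones' live coral covers amplified by fish positioning
#' over coral).
#'
#' @param p_contact_by_zone Named contact probabilities per zone.
#' @param n_by_zone Named counts of observed egestions per zone.
#' @param seed Integer seed.
#' @return Data frame: zone, contacted_live_coral (0/1).
#' @export
generate_fecal_contacts <- function(p_contact_by_zone = c(fore = 20 / 22, back = 3 / 30),
                                    n_by_zone = c(fore = 22, back = 30),
                                    seed = 1) {
  if (any(p_contact_by_zone < 0 | p_contact_by_zone > 1))
    stop_invalid("contact probabilities must be in [0, 1]")
  set.seed(seed)
  out <- do.call(rbind, lapply(names(p_contact_by_zone), function(z) {
    n <- n_by_zone[[z]]
    data.frame(zone = z,
               contacted_live_coral = as.integer(stats::runif(n) < p_contact_by_zone[[z]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate culture-well outcomes per guild
#'
#' Each sample is culture-competent with its guild's probability; competent
#' samples get a positive well count drawn Binomial(n_wells, within-sample
#' well rate) conditioned to be >= 1. Default competence probabilities
#' reproduce the observed culture positivity (obligate 54%, facultative 11%,
#' grazer 38%).
#'
#' @param p_positive_by_guild Named per-guild probabilities that a sample
#'   yields at least one positive well.
#' @param n_samples_by_guild Named sample counts per guild.
#' @param n_wells Replicate wells per sample (study design: 24).
#' @param well_rate Per-well positivity rate within a competent sample.
#' @param seed Integer seed.
#' @return Data frame: sample_id, guild, n_wells, n_positive_wells.
#' @export
generate_culture_wells <- function(p_positive_by_guild = c(obligate_corallivore = 0.54,
                                                           facultative_corallivore = 0.11,
                                                           grazer_detritivore = 0.38),
                                   n_samples_by_guild = c(obligate_corallivore = 35,
                                                          facultative_corallivore = 18,
                                                          grazer_detritivore = 8),
                                   n_wells = 24, well_rate = 0.2, seed = 1) {
  if (any(p_positive_by_guild < 0 | p_positive_by_guild > 1))
    stop_invalid("probabilities must be in [0, 1]")
  set.seed(seed)
  out <- do.call(rbind, lapply(names(p_positive_by_guild), function(g) {
    n <- n_samples_by_guild[[g]]
    competent <- stats::runif(n) < p_positive_by_guild[[g]]
    pos <- integer(n)
    for (i in which(competent)) {
      repeat {
        k <- stats::rbinom(1, n_wells, well_rate)
        if (k >= 1) { pos[i] <- k; break }
      }
    }
    data.frame(sample_id = sprintf("%s_cult_%02d", g, seq_len(n)), guild = g,
               n_wells = n_wells, n_positive_wells = pos,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-transect percent live coral cover
#'
#' @param points Data frame from [generate_coral_cover()] or [read_cover()].
#' @return Data frame: zone, transect_id, n_points, percent_cover.
#' @export
transect_cover <- function(points) {
  out <- do.call(rbind, lapply(split(points, points$transect_id), function(d) {
    data.frame(zone = d$zone[1], transect_id = d$transect_id[1],
               n_points = nrow(d),
               percent_cover = 100 * mean(d$live_coral > 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
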