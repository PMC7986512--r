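# Hemocytometer-based live/dead Symbiodiniaceae density estimation.
#
# The measurement chain: a fecal (or sediment/water) sample is fixed in
# formalin, stained with trypan blue, and loaded on a Neubauer hemocytometer.
# Eight technical replicate grids are counted; live (unstained) and dead
# (blue) cells are tallied separately. Densities per ml of the ORIGINAL
# source material are recovered by multiplying the suspension concentration
# by the dilution factor (total preserved volume / sample volume), and per
# gram of feces via the sample's measured volume and mass.

#' Sample preparation record
#'
#' @param sample_volume_ul Fecal/filtrate volume added to the preservation
#'   mix, microlitres (> 0).
#' @param fixative_volume_ul Fixative volume, microlitres (>= 0).
#' @param stain_volume_ul Stain volume, microlitres (>= 0; the trypan blue
#'   volume is rarely recorded, so the default is 0).
#' @param sample_mass_mg Fecal sample mass in milligrams; required when
#'   `source_type = "feces"`, must be absent (`NA`) otherwise.
#' @param source_type One of `"feces"`, `"sediment"`, `"water"`.
#' @return An object of class `sample_prep`.
#' @export
sample_prep <- function(sample_volume_ul, fixative_volume_ul = 750,
                        stain_volume_ul = 0, sample_mass_mg = NA_real_,
                        source_type = "feces") {
  check_number(sample_volume_ul, "sample_volume_ul", lower = 0)
  if (sample_volume_ul <= 0) stop_invalid("sample_volume_ul must be > 0")
  check_number(fixative_volume_ul, "fixative_volume_ul", lower = 0)
  check_number(stain_volume_ul, "stain_volume_ul", lower = 0)
  if (!source_type %in% c("feces", "sediment", "water"))
    stop_invalid("unknown source_type '%s'", source_type)
  if (source_type == "feces") {
    if (is.na(sample_mass_mg) || sample_mass_mg <= 0)
      stop_invalid("fecal samples require a positive sample_mass_mg")
  } else if (!is.na(sample_mass_mg)) {
    stop_invalid("sample_mass_mg must be absent for %s samples", source_type)
  }
  structure(list(sample_volume_ul = sample_volume_ul,
                 fixative_volume_ul = fixative_volume_ul,
                 stain_volume_ul = stain_volume_ul,
                 sample_mass_mg = sample_mass_mg,
                 source_type = source_type),
            class = "sample_prep")
}

#' One biological sample's hemocytometer counts
#'
#' @param sample_id Label.
#' @param species_or_type Species code or sample-type label.
#' @param guild Guild/category label.
#' @param live_counts,dead_counts Non-negative integer vectors, one entry per
#'   technical replicate (the study design uses 8).
#' @param counted_volume_ml Suspension volume represented by one counted grid
#'   region, ml; identical across replicates. Default `1e-4` ml = one Neubauer
#'   large square (1 mm x 1 mm x 0.1 mm).
#' @param prep A [sample_prep()].
#' @return An object of class `cell_count_sample`.
#' @export
cell_count_sample <- function(sample_id, species_or_type, guild,
                              live_counts, dead_counts,
                              counted_volume_ml = 1e-4, prep) {
  if (length(live_counts) < 1 || length(live_counts) != length(dead_counts))
    stop_invalid("need >= 1 replicate with paired live and dead counts")
  if (any(live_counts < 0) || any(dead_counts < 0) ||
      any(live_counts != round(live_counts)) || any(dead_counts != round(dead_counts)))
    stop_invalid("replicate counts must be non-negative integers")
  check_number(counted_volume_ml, "counted_volume_ml", lower = 0)
  if (counted_volume_ml <= 0) stop_invalid("counted_volume_ml must be > 0")
  if (!inherits(prep, "sample_prep")) stop_invalid("prep must be a sample_prep")
  structure(list(sample_id = sample_id, species_or_type = species_or_type,
                 guild = guild,
                 live_counts = as.numeric(live_counts),
                 dead_counts = as.numeric(dead_counts),
                 counted_volume_ml = counted_volume_ml, prep = prep),
            class = "cell_count_sample")
}

#' Mean replicate concentration in the counting suspension
#'
#' Averages count / counted_volume over the technical replicates (replicates
#' are averaged, never summed), separately for live and dead cells.
#'
#' @param sample A [cell_count_sample()].
#' @return Named numeric `c(live = , dead = )`, cells per ml of suspension.
#' @export
replicate_mean_concentration <- function(sample) {
  if (!inherits(sample, "cell_count_sample"))
    stop_invalid("input must be a cell_count_sample")
  if (length(sample$live_counts) == 0) stop_invalid("no replicates")
  c(live = mean(sample$live_counts) / sample$counted_volume_ml,
    dead = mean(sample$dead_counts) / sample$counted_volume_ml)
}

#' Dilution factor of a preserved sample
#'
#' (sample + fixative + stain volume) / sample volume; >= 1 by construction.
#'
#' @param prep A [sample_prep()].
#' @return Dimensionless dilution factor.
#' @export
dilution_factor <- function(prep) {
  if (!inherits(prep, "sample_prep")) stop_invalid("prep must be a sample_prep")
  with(prep, (sample_volume_ul + fixative_volume_ul + stain_volume_ul) / sample_volume_ul)
}

#' Convert suspension concentration to source-material density
#'
#' Divides the suspension concentration by the fraction of sample in the
#' summed volume of fixative, stain and sample — i.e. multiplies by the
#' dilution factor. The result is cells per ml of the original source
#' material (feces, sediment or water).
#'
#' @param concentration Cells per ml of suspension (>= 0).
#' @param prep A [sample_prep()].
#' @return Cells per ml of source.
#' @export
to_source_density <- function(concentration, prep) {
  if (any(concentration < 0)) stop_invalid("concentration must be >= 0")
  concentration * dilution_factor(prep)
}

#' Convert a per-ml source density to cells per gram of feces
#'
#' density per ml x (sample volume in ml) / (sample mass in g). Only defined
#' for fecal samples, whose volume and mass were both measured.
#'
#' @param density_per_ml_source Cells per ml of source (>= 0).
#' @param prep A [sample_prep()] with `source_type = "feces"`.
#' @return Cells per gram of feces.
#' @export
to_per_gram <- function(density_per_ml_source, prep) {
  if (!inherits(prep, "sample_prep")) stop_invalid("prep must be a sample_prep")
  if (prep$source_type != "feces" || is.na(prep$sample_mass_mg))
    stop_invalid("per-gram densities require a fecal sample with a mass")
  if (any(density_per_ml_source < 0)) stop_invalid("density must be >= 0")
  density_per_ml_source * (prep$sample_volume_ul / 1000) / (prep$sample_mass_mg / 1000)
}

#' Full density result for one sample
#'
#' Runs the whole chain: replicate mean concentration, dilution correction to
#' source density, and (for feces) per-gram conversion.
#'
#' @param sample A [cell_count_sample()].
#' @return A one-row data frame: sample_id, species_or_type, guild,
#'   live_per_ml, dead_per_ml, live_per_g (NA for non-fecal samples),
#'   dilution_factor.
#' @export
sample_density <- function(sample) {
  conc <- replicate_mean_concentration(sample)
  live_ml <- to_source_density(conc[["live"]], sample$prep)
  dead_ml <- to_source_density(conc[["dead"]], sample$prep)
  live_g <- if (sample$prep$source_type == "feces")
    to_per_gram(live_ml, sample$prep) else NA_real_
  data.frame(sample_id = sample$sample_id,
             species_or_type = sample$species_or_type,
             guild = sample$guild,
             live_per_ml = live_ml, dead_per_ml = dead_ml,
             live_per_g = live_g,
             dilution_factor = dilution_factor(sample$prep),
             stringsAsFactors = FALSE)
}

#' Density table for a list of samples
#'
#' @param samples List of [cell_count_sample()] objects.
#' @return Data frame, one row per sample (see [sample_density()]).
#' @export
density_table <- function(samples) {
  if (length(samples) == 0) stop_invalid("no samples")
  do.call(rbind, lapply(samples, sample_density))
}

#' Summarise live/dead densities per group
#'
#' Non-detections contribute zeros, never missing values, so that group means
#' are not inflated by excluding below-detection samples. The detection
#' fraction is the proportion of samples with live density > 0, reported both
#' raw and rounded to the nearest integer percent.
#'
#' @param densities Data frame with at least `live_per_ml`, `dead_per_ml` and
#'   a grouping column.
#' @param group Name of the grouping column (default `"species_or_type"`).
#' @return Data frame with one row per group: n, mean/SE of live and dead
#'   density, detection_fraction and detection_pct. Groups present as factor
#'   levels but empty are omitted with a warning.
#' @export
summarize_guild_densities <- function(densities, group = "species_or_type") {
  if (!group %in% names(densities)) stop_invalid("no column '%s'", group)
  g <- densities[[group]]
  if (is.factor(g)) {
    empty <- setdiff(levels(g), unique(as.character(g)))
    if (length(empty))
      warning("omitting empty group(s): ", paste(empty, collapse = ", "))
  }
  g <- as.character(g)
  if (anyNA(densities$live_per_ml) || anyNA(densities$dead_per_ml))
    stop_invalid("densities must be numeric with non-detections entered as 0, not NA")
  out <- do.call(rbind, lapply(split(densities, g), function(d) {
    data.frame(group = d[[group]][1],
               n = nrow(d),
               mean_live_per_ml = mean(d$live_per_ml),
               se_live_per_ml = se_mean(d$live_per_ml),
               mean_dead_per_ml = mean(d$dead_per_ml),
               se_dead_per_ml = se_mean(d$dead_per_ml),
               detection_fraction = mean(d$live_per_ml > 0),
               detection_pct = round(100 * mean(d$live_per_ml > 0)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
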