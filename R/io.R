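# Delimited-file readers and writers. CSV is the primary dialect; TSV is
# accepted on read (auto-detected from the header line). All column units
# are encoded in column names (_ml, _ul, _mg, _cm) so the dispersal module's
# unit audit is enforceable at the file boundary.

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_invalid("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
}

# Apply an optional old-name -> new-name mapping before schema validation.
apply_column_map <- function(df, column_map) {
  if (is.null(column_map)) return(df)
  for (old in names(column_map))
    names(df)[names(df) == old] <- column_map[[old]]
  df
}

#' Read hemocytometer cell counts
#'
#' Long format, one row per technical replicate: sample_id, species_code,
#' guild, replicate, live_count, dead_count, counted_volume_ml,
#' sample_volume_ul, fixative_volume_ul, stain_volume_ul, sample_mass_mg
#' (empty for sediment/water), source_type. A pre-computed density dialect
#' with columns `Live` and `Dead` (cells per ml source) is also accepted and
#' returned as a data frame flagged `precomputed`; it can be passed straight
#' to [summarize_guild_densities()].
#'
#' @param path CSV/TSV file.
#' @param column_map Optional named character vector renaming file columns
#'   on ingest (names = file columns, values = schema columns).
#' @return List of [cell_count_sample()] objects, or (for the pre-computed
#'   dialect) a data frame with attribute `precomputed = TRUE`.
#' @export
read_cell_counts <- function(path, column_map = NULL) {
  df <- apply_column_map(read_delim_auto(path), column_map)
  if (all(c("Live", "Dead") %in% names(df))) {
    out <- data.frame(sample_id = df$sample_id,
                      species_or_type = df$species_code, guild = df$guild,
                      live_per_ml = as.numeric(df$Live),
                      dead_per_ml = as.numeric(df$Dead),
                      stringsAsFactors = FALSE)
    attr(out, "precomputed") <- TRUE
    return(out)
  }
  schema <- c("sample_id", "species_code", "guild", "replicate", "live_count",
              "dead_count", "counted_volume_ml", "sample_volume_ul",
              "fixative_volume_ul", "stain_volume_ul", "sample_mass_mg",
              "source_type")
  require_columns(df, schema, path)
  if (nrow(df) == 0) return(list())
  samples <- lapply(split(seq_len(nrow(df)), df$sample_id), function(idx) {
    d <- df[idx, ]
    d <- d[order(d$replicate), ]
    tryCatch({
      mass <- d$sample_mass_mg[1]
      prep <- sample_prep(d$sample_volume_ul[1], d$fixative_volume_ul[1],
                          d$stain_volume_ul[1],
                          if (is.na(mass)) NA_real_ else mass,
                          d$source_type[1])
      if (length(unique(d$counted_volume_ml)) != 1)
        stop_invalid("counted_volume_ml differs across replicates")
      cell_count_sample(d$sample_id[1], d$species_code[1], d$guild[1],
                        d$live_count, d$dead_count, d$counted_volume_ml[1], prep)
    }, error = function(e) {
      stop_invalid("%s: sample '%s' (rows %s): %s", path, d$sample_id[1],
                   paste(range(idx + 1), collapse = "-"), conditionMessage(e))
    })
  })
  unname(samples[unique(df$sample_id)])
}

#' Write cell-count samples to the long CSV schema
#'
#' @param samples List of [cell_count_sample()] objects.
#' @param path Output CSV.
#' @export
write_cell_counts <- function(samples, path) {
  rows <- do.call(rbind, lapply(samples, function(s) {
    n <- length(s$live_counts)
    data.frame(sample_id = s$sample_id, species_code = s$species_or_type,
               guild = s$guild, replicate = seq_len(n),
               live_count = s$live_counts, dead_count = s$dead_counts,
               counted_volume_ml = s$counted_volume_ml,
               sample_volume_ul = s$prep$sample_volume_ul,
               fixative_volume_ul = s$prep$fixative_volume_ul,
               stain_volume_ul = s$prep$stain_volume_ul,
               sample_mass_mg = s$prep$sample_mass_mg,
               source_type = s$prep$source_type, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a genus-level ITS2 count table
#'
#' Columns: sample_id, category, species_code, plus the five genus columns
#' in any order (normalised to the canonical order on read). Unknown genus
#' columns are rejected.
#'
#' @inheritParams read_cell_counts
#' @return Data frame in canonical column order.
#' @export
read_genus_counts <- function(path, column_map = NULL) {
  df <- apply_column_map(read_delim_auto(path), column_map)
  require_columns(df, c("sample_id", "category", "species_code"), path)
  meta <- c("sample_id", "category", "species_code")
  extra <- setdiff(names(df), c(meta, SYM_GENERA))
  if (length(extra))
    stop_invalid("%s: unknown genus column(s): %s — expected %s", path,
                 paste(extra, collapse = ", "), paste(SYM_GENERA, collapse = ", "))
  require_columns(df, SYM_GENERA, path)
  out <- df[c(meta, SYM_GENERA)]
  x <- genus_matrix(out)
  if (any(x != round(x))) stop_invalid("%s: read counts must be integers", path)
  if (anyDuplicated(out$sample_id)) stop_invalid("%s: duplicate sample_id", path)
  out
}

#' Read per-species bootstrap inputs
#'
#' Long format mirroring the deposited source-data sheet: columns species,
#' zone, variable, value, where variable is one of `Live_g_sample` (C, cells
#' per g), `Wet_weight` (W, g per cm), `Fish_density` (F, fish per 100 m^2)
#' and `Pellet_length` (S, cm). A species-specific `g` (egestions per day)
#' may be supplied as variable `g_constant`, or computed separately from
#' follows via [egestion_constant()].
#'
#' @inheritParams read_cell_counts
#' @return Named list (per species) of lists with vectors S, W, C, F and
#'   optional g; pass to [bootstrap_inputs()].
#' @export
read_bootstrap_inputs <- function(path, column_map = NULL) {
  df <- apply_column_map(read_delim_auto(path), column_map)
  require_columns(df, c("species", "variable", "value"), path)
  known <- c("Live_g_sample", "Wet_weight", "Fish_density", "Pellet_length",
             "g_constant")
  bad <- setdiff(unique(df$variable), known)
  if (length(bad))
    stop_invalid("%s: unknown variable(s): %s", path, paste(bad, collapse = ", "))
  needed <- setdiff(known, "g_constant")
  lapply(split(df, df$species), function(d) {
    missing <- setdiff(needed, unique(d$variable))
    if (length(missing))
      stop_invalid("%s: species '%s' missing variable(s): %s", path,
                   d$species[1], paste(missing, collapse = ", "))
    val <- function(v) as.numeric(d$value[d$variable == v])
    g <- if ("g_constant" %in% d$variable) val("g_constant")[1] else NA_real_
    list(species = d$species[1],
         zone = if ("zone" %in% names(d)) d$zone[1] else NA_character_,
         g = g, S = val("Pellet_length"), W = val("Wet_weight"),
         C = val("Live_g_sample"), F = val("Fish_density"))
  })
}

#' Write bootstrap inputs in the long schema read by [read_bootstrap_inputs()]
#'
#' @param inputs_list Named list as returned by [read_bootstrap_inputs()].
#' @param path Output CSV.
#' @export
write_bootstrap_inputs <- function(inputs_list, path) {
  rows <- do.call(rbind, lapply(inputs_list, function(b) {
    long <- rbind(
      data.frame(variable = "Pellet_length", value = b$S),
      data.frame(variable = "Wet_weight", value = b$W),
      data.frame(variable = "Live_g_sample", value = b$C),
      data.frame(variable = "Fish_density", value = b$F),
      if (!is.null(b$g) && !is.na(b$g))
        data.frame(variable = "g_constant", value = b$g))
    cbind(data.frame(species = b$species,
                     zone = if (is.null(b$zone)) NA_character_ else b$zone,
                     stringsAsFactors = FALSE), long)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read coral-cover point records
#'
#' Columns: zone, transect_id, point, live_coral (0/1).
#'
#' @inheritParams read_cell_counts
#' @return Data frame.
#' @export
read_cover <- function(path, column_map = NULL) {
  df <- apply_column_map(read_delim_auto(path), column_map)
  require_columns(df, c("zone", "transect_id", "point", "live_coral"), path)
  if (any(!df$live_coral %in% c(0, 1)))
    stop_invalid("%s: live_coral must be 0/1", path)
  df
}

#' Read timed fish-follow records
#'
#' Columns: species, follow_id, duration_min, events.
#'
#' @inheritParams read_cell_counts
#' @return Data frame.
#' @export
read_follows <- function(path, column_map = NULL) {
  df <- apply_column_map(read_delim_auto(path), column_map)
  require_columns(df, c("species", "follow_id", "duration_min", "events"), path)
  if (any(df$duration_min <= 0)) stop_invalid("%s: durations must be > 0", path)
  if (any(df$events < 0)) stop_invalid("%s: events must be >= 0", path)
  df
}

#' Read fecal-contact records
#'
#' Columns: zone, contacted_live_coral (0/1 or TRUE/FALSE).
#'
#' @inheritParams read_cell_counts
#' @return Data frame.
#' @export
read_contacts <- function(path, column_map = NULL) {
  df <- apply_column_map(read_delim_auto(path), column_map)
  require_columns(df, c("zone", "contacted_live_coral"), path)
  df
}
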