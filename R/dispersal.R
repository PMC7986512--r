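# Reef-scale bootstrap estimation of live Symbiodiniaceae dispersal,
# T = g * S * W * C * F:
#   g  egestions per (8-hour) day, a fixed species constant
#   S  fecal pellet length, cm
#   W  fecal linear density, g per cm
#   C  live Symbiodiniaceae cells per g of feces
#   F  fish per 100 m^2
# so T has units cells per 100 m^2 per day.

BOOT_VECTOR_UNITS <- c(S = "cm", W = "g/cm", C = "cells/g", F = "fish/100m2")

#' Species egestion constant from timed fish follows
#'
#' Pooled rate: total observed egestion events divided by total observation
#' hours, scaled by the assumed daily activity window (8 h, matching the
#' 09:00-17:00 observation frame).
#'
#' @param follows Data frame with `duration_min` (> 0) and `events` (>= 0)
#'   columns, one row per follow.
#' @param active_hours Hours per day the species is assumed active.
#' @return g, egestions per day.
#' @export
egestion_constant <- function(follows, active_hours = 8) {
  if (!all(c("duration_min", "events") %in% names(follows)))
    stop_invalid("follows needs 'duration_min' and 'events' columns")
  if (any(follows$duration_min <= 0)) stop_invalid("durations must be > 0")
  if (any(follows$events < 0)) stop_invalid("event counts must be >= 0")
  tot_h <- sum(follows$duration_min) / 60
  if (tot_h <= 0) stop_invalid("zero total observation time")
  check_number(active_hours, "active_hours", lower = 0)
  sum(follows$events) / tot_h * active_hours
}

#' Convert a 250 m^2 belt-transect fish count to fish per 100 m^2
#'
#' The long-term monitoring belt transects are 5 x 50 m = 250 m^2; counts
#' are multiplied by 0.4.
#'
#' @param count_per_250m2 Non-negative count(s).
#' @return Fish per 100 m^2.
#' @export
lter_density_convert <- function(count_per_250m2) {
  if (any(count_per_250m2 < 0)) stop_invalid("counts must be >= 0")
  count_per_250m2 * 0.4
}

#' Fecal linear density from paired pellet lengths and weights
#'
#' @param lengths_cm Positive lengths.
#' @param weights_g Positive weights, same length.
#' @return Per-specimen W = weight / length, g per cm.
#' @export
pellet_linear_density <- function(lengths_cm, weights_g) {
  if (length(lengths_cm) != length(weights_g))
    stop_invalid("lengths and weights must be paired")
  if (any(lengths_cm <= 0)) stop_invalid("pellet lengths must be > 0")
  if (any(weights_g < 0)) stop_invalid("weights must be >= 0")
  weights_g / lengths_cm
}

#' Assemble the five inputs of the dispersal estimator
#'
#' Carries the unit bookkeeping for the product T = gSWCF; the constructor
#' refuses empty or negative inputs and records each vector's unit so
#' mismatched inputs are caught at the boundary.
#'
#' @param species Species label.
#' @param g Egestions per day (fixed species constant, not resampled).
#' @param S Pellet lengths, cm.
#' @param W Fecal linear densities, g per cm.
#' @param C Live cells per g of feces.
#' @param F_ Fish per 100 m^2 (transect densities). Named `F_` to avoid the
#'   base-R `F` binding.
#' @param units Named character vector of units for S, W, C, F; defaults to
#'   the canonical units and must match them.
#' @return An object of class `bootstrap_inputs`.
#' @export
bootstrap_inputs <- function(species, g, S, W, C, F_,
                             units = BOOT_VECTOR_UNITS) {
  check_number(g, "g", lower = 0)
  vecs <- list(S = S, W = W, C = C, F = F_)
  for (nm in names(vecs)) {
    v <- vecs[[nm]]
    if (length(v) == 0) stop_invalid("input vector '%s' is empty", nm)
    if (any(!is.finite(v)) || any(v < 0))
      stop_invalid("input vector '%s' must be finite and >= 0", nm)
  }
  if (!identical(units[names(BOOT_VECTOR_UNITS)], BOOT_VECTOR_UNITS))
    stop_invalid("unit mismatch: expected %s",
                 paste(sprintf("%s [%s]", names(BOOT_VECTOR_UNITS), BOOT_VECTOR_UNITS),
                       collapse = ", "))
  structure(c(list(species = species, g = g), vecs, list(units = units)),
            class = "bootstrap_inputs")
}

#' Bootstrap the reef-scale dispersal estimate T = gSWCF
#'
#' Default scheme (`"resample-means"`): each iteration independently
#' resamples S, W, C and F with replacement at their original sizes, takes
#' each vector's mean, and computes `T = g * mean(S) * mean(W) * mean(C) *
#' mean(F)` — the natural bootstrap of a product of sample means. The
#' alternative scheme (`"single-draw"`) draws one value per variable per
#' iteration. g is a fixed species constant and is never resampled.
#'
#' The confidence interval is the percentile interval of the draws at
#' `ci_level`; the symmetric `half_width = (ci_high - ci_low) / 2` is also
#' reported, along with a normal-theory interval (mean +/- z * sd of draws)
#' for comparison.
#'
#' @param inputs A [bootstrap_inputs()].
#' @param iterations Bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @param ci_level Coverage of the percentile interval (default 0.95).
#' @param scheme `"resample-means"` (default) or `"single-draw"`.
#' @return An object of class `dispersal_estimate` with the draws, their
#'   mean, percentile and normal CIs, and metadata.
#' @export
bootstrap_dispersal <- function(inputs, iterations = 1000, seed = 1,
                                ci_level = 0.95,
                                scheme = c("resample-means", "single-draw")) {
  if (!inherits(inputs, "bootstrap_inputs"))
    stop_invalid("inputs must be a bootstrap_inputs object")
  check_number(iterations, "iterations", lower = 1, integer = TRUE)
  check_number(ci_level, "ci_level", lower = 0, upper = 1)
  scheme <- match.arg(scheme)
  set.seed(seed)
  draw_one <- if (scheme == "resample-means") {
    function(v) mean(v[sample.int(length(v), replace = TRUE)])
  } else {
    function(v) v[sample.int(length(v), 1)]
  }
  draws <- vapply(seq_len(iterations), function(i) {
    inputs$g * draw_one(inputs$S) * draw_one(inputs$W) *
      draw_one(inputs$C) * draw_one(inputs$F)
  }, numeric(1))
  alpha <- 1 - ci_level
  ci <- unname(stats::quantile(draws, c(alpha / 2, 1 - alpha / 2), type = 7))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(species = inputs$species, g = inputs$g,
                 mean_T = mean(draws),
                 ci_low = ci[1], ci_high = ci[2],
                 half_width = (ci[2] - ci[1]) / 2,
                 normal_ci = c(mean(draws) - z * stats::sd(draws),
                               mean(draws) + z * stats::sd(draws)),
                 ci_level = ci_level, iterations = iterations,
                 seed = seed, scheme = scheme, draws = draws),
            class = "dispersal_estimate")
}

#' @export
print.dispersal_estimate <- function(x, ...) {
  cat(sprintf("Reef-scale dispersal estimate, T = gSWCF (%s)\n", x$species))
  cat(sprintf("  mean T = %.4g cells per 100 m2 per day\n", x$mean_T))
  cat(sprintf("  %d%% percentile CI [%.4g, %.4g] (half-width %.3g)\n",
              round(100 * x$ci_level), x$ci_low, x$ci_high, x$half_width))
  cat(sprintf("  g = %.4g egestions/day; %d bootstrap iterations (%s), seed %d\n",
              x$g, x$iterations, x$scheme, x$seed))
  invisible(x)
}

#' @export
summary.dispersal_estimate <- function(object, ...) {
  q <- stats::quantile(object$draws, c(0.025, 0.25, 0.5, 0.75, 0.975))
  out <- list(species = object$species, mean_T = object$mean_T,
              quantiles = q, sd = stats::sd(object$draws),
              ci = c(object$ci_low, object$ci_high),
              normal_ci = object$normal_ci,
              iterations = object$iterations)
  class(out) <- "summary.dispersal_estimate"
  out
}

#' @export
print.summary.dispersal_estimate <- function(x, ...) {
  cat(sprintf("Bootstrap distribution of T for %s (%d draws)\n",
              x$species, x$iterations))
  cat(sprintf("  mean %.4g, sd %.4g\n", x$mean_T, x$sd))
  print(signif(x$quantiles, 4))
  invisible(x)
}

#' @export
plot.dispersal_estimate <- function(x, ...) {
  graphics::hist(x$draws, breaks = 30,
                 main = sprintf("Bootstrap draws of T (%s)", x$species),
                 xlab = "cells per 100 m2 per day", ...)
  graphics::abline(v = c(x$ci_low, x$mean_T, x$ci_high),
                   lty = c(2, 1, 2), col = "red3")
  invisible(x)
}

#' Summarise how often egested feces contacted live coral, per reef zone
#'
#' @param contacts Data frame with `zone` and logical/0-1
#'   `contacted_live_coral` columns, one row per observed egestion.
#' @return Data frame per zone: n, n_contacting, percent (unrounded) and
#'   percent_rounded. Zones present as factor levels but empty are omitted
#'   with a warning.
#' @export
fecal_contact_summary <- function(contacts) {
  if (!all(c("zone", "contacted_live_coral") %in% names(contacts)))
    stop_invalid("contacts needs 'zone' and 'contacted_live_coral' columns")
  z <- contacts$zone
  if (is.factor(z)) {
    empty <- setdiff(levels(z), unique(as.character(z)))
    if (length(empty))
      warning("omitting empty zone(s): ", paste(empty, collapse = ", "))
  }
  out <- do.call(rbind, lapply(split(contacts, as.character(z)), function(d) {
    hit <- sum(as.logical(d$contacted_live_coral))
    data.frame(zone = as.character(d$zone[1]), n = nrow(d), n_contacting = hit,
               percent = 100 * hit / nrow(d),
               percent_rounded = round(100 * hit / nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
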