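# Univariate field statistics: Kruskal-Wallis with Dunn post-hoc tests
# (Bonferroni), coral-cover ANOVA with normality and homogeneity checks,
# culture-positivity summaries and a boxplot-rule outlier screen.

check_grouped <- function(values, group) {
  if (length(values) != length(group)) stop_invalid("values and group must be paired")
  if (any(!is.finite(values))) stop_invalid("values must be finite")
  tab <- table(as.character(group))
  if (length(tab) < 2) stop_invalid("need >= 2 groups")
  invisible(tab)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with df = k - 1 and a chi-squared reference
#' distribution (via [stats::kruskal.test()]). Non-detections should enter
#' as zeros, matching the density pipeline's zero-entry rule.
#'
#' @param values Numeric measurements.
#' @param group Per-value labels.
#' @return List: statistic (H), df, p_value, method.
#' @export
kruskal_wallis <- function(values, group) {
  tab <- check_grouped(values, group)
  if (length(unique(values)) == 1)  # degenerate: all identical, H = 0
    return(list(statistic = 0, df = length(tab) - 1, p_value = 1,
                method = "Kruskal-Wallis"))
  kt <- stats::kruskal.test(values, factor(as.character(group)))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = unname(kt$p.value), method = "Kruskal-Wallis")
}

#' Dunn's post-hoc test for pairwise group comparisons
#'
#' Standard Dunn (1964) z statistics from mean-rank differences with the
#' tie-corrected pooled variance
#' `sigma2_ij = (N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j)`,
#' two-sided normal p-values, and Bonferroni adjustment
#' `p_adj = min(1, p * k(k-1)/2)` by default.
#'
#' @param values Numeric measurements.
#' @param group Per-value labels.
#' @param correction `"bonferroni"` (default), `"BH"` or `"none"` — passed to
#'   [stats::p.adjust()].
#' @return Data frame: group1, group2, z, p_value, p_adjusted.
#' @export
dunn_test <- function(values, group, correction = "bonferroni") {
  check_grouped(values, group)
  group <- as.character(group)
  n_tot <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  base_var <- n_tot * (n_tot + 1) / 12 - tie_term
  mean_rank <- tapply(r, group, mean)
  n_g <- tapply(r, group, length)
  gl <- sort(unique(group))
  pairs <- utils::combn(gl, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt(base_var * (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    z <- if (se == 0) 0 else (mean_rank[[g1]] - mean_rank[[g2]]) / se
    data.frame(group1 = g1, group2 = g2, z = z,
               p_value = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = correction)
  out
}

#' One-way coral-cover ANOVA with assumption checks
#'
#' Reports the F-test between reef zones together with a Shapiro-Wilk test
#' on the ANOVA residuals and Levene's test (median- or mean-centred) for
#' homogeneity of variance — all three together, as the assumptions should
#' be read alongside the test.
#'
#' @param cover Percent-cover values, one per transect.
#' @param zone Per-transect zone labels (>= 2 zones, >= 2 transects each).
#' @param levene_center `"median"` (default, robust) or `"mean"`.
#' @return List: anova (statistic F, df = c(between, within), p_value),
#'   shapiro (statistic W, p_value), levene (statistic F, df, p_value).
#' @export
coral_cover_anova <- function(cover, zone, levene_center = c("median", "mean")) {
  tab <- check_grouped(cover, zone)
  if (any(tab < 2))
    stop_invalid("each zone needs >= 2 transects (got %s)",
                 paste(sprintf("%s: %d", names(tab), tab), collapse = ", "))
  levene_center <- match.arg(levene_center)
  zf <- factor(as.character(zone))
  fit <- stats::aov(cover ~ zf)
  an <- summary(fit)[[1]]
  sh <- stats::shapiro.test(stats::residuals(fit))
  lv <- car::leveneTest(cover ~ zf, center = if (levene_center == "median")
    stats::median else mean)
  list(anova = list(statistic = an$`F value`[1],
                    df = c(an$Df[1], an$Df[2]),
                    p_value = an$`Pr(>F)`[1], method = "one-way ANOVA"),
       shapiro = list(statistic = unname(sh$statistic), p_value = sh$p.value),
       levene = list(statistic = lv$`F value`[1],
                     df = c(lv$Df[1], lv$Df[2]), p_value = lv$`Pr(>F)`[1]))
}

#' Per-guild culture positivity
#'
#' A sample is culture-positive iff at least one of its replicate wells
#' contained intact cells after the incubation period.
#'
#' @param wells Data frame with `guild`, `n_wells` (>= 1) and
#'   `n_positive_wells` columns, one row per sample.
#' @return Data frame per guild: n_samples, n_positive, fraction, percent
#'   (rounded to integer).
#' @export
culture_summary <- function(wells) {
  if (!all(c("guild", "n_wells", "n_positive_wells") %in% names(wells)))
    stop_invalid("wells needs 'guild', 'n_wells', 'n_positive_wells'")
  if (any(wells$n_wells < 1)) stop_invalid("each sample needs >= 1 well")
  if (any(wells$n_positive_wells < 0 | wells$n_positive_wells > wells$n_wells))
    stop_invalid("n_positive_wells must be in [0, n_wells]")
  out <- do.call(rbind, lapply(split(wells, wells$guild), function(d) {
    pos <- sum(d$n_positive_wells >= 1)
    data.frame(guild = d$guild[1], n_samples = nrow(d), n_positive = pos,
               fraction = pos / nrow(d), percent = round(100 * pos / nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Boxplot-rule outlier screen
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` per group (type-7
#' quartiles). Flagged values are reported, never removed — the field study
#' retained its one flagged value after inspection.
#'
#' @param values Numeric measurements.
#' @param group Per-value labels; groups with fewer than 4 values are not
#'   screened.
#' @return Data frame of flagged observations: group, index (position in the
#'   input), value.
#' @export
outlier_screen <- function(values, group) {
  if (length(values) != length(group)) stop_invalid("values and group must be paired")
  group <- as.character(group)
  idx_all <- seq_along(values)
  rows <- lapply(split(idx_all, group), function(idx) {
    if (length(idx) < 4) return(NULL)
    x <- values[idx]
    q <- stats::quantile(x, c(0.25, 0.75), type = 7)
    iqr <- q[2] - q[1]
    bad <- x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
    if (!any(bad)) return(NULL)
    data.frame(group = group[idx[bad]], index = idx[bad], value = x[bad],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(), index = integer(), value = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
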