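# Genus-level Symbiodiniaceae community analysis: read filtering, percentage
# conversion, Bray-Curtis distances, PERMANOVA (overall and pairwise with
# Benjamini-Hochberg correction), homogeneity-of-dispersion testing on a
# principal-coordinates embedding, balanced random subsampling and
# rarefaction curves.

genus_matrix <- function(m) {
  missing <- setdiff(SYM_GENERA, names(m))
  if (length(missing))
    stop_invalid("missing genus column(s): %s", paste(missing, collapse = ", "))
  x <- as.matrix(m[SYM_GENERA])
  if (any(x < 0)) stop_invalid("negative read counts")
  rownames(x) <- m$sample_id
  x
}

#' Discard samples below a read-depth threshold
#'
#' Retains exactly the samples whose total genus-level read count is at or
#' above `threshold` (the study discards libraries with < 1000 reads —
#' strict inequality).
#'
#' @param m Genus count data frame (sample_id, category, species_code + the
#'   five genus columns).
#' @param threshold Minimum retained row sum (default 1000).
#' @return Filtered data frame; discarded sample_ids are reported via
#'   `message()`.
#' @export
filter_min_reads <- function(m, threshold = 1000) {
  check_number(threshold, "threshold", lower = 0)
  depth <- rowSums(genus_matrix(m))
  keep <- depth >= threshold
  if (!any(keep)) stop_invalid("all samples fall below the %s-read threshold", threshold)
  if (any(!keep))
    message("discarded ", sum(!keep), " sample(s) below ", threshold, " reads: ",
            paste(m$sample_id[!keep], collapse = ", "))
  m[keep, , drop = FALSE]
}

#' Convert genus counts to row percentages
#'
#' @param m Genus count data frame with positive row sums (filter first).
#' @return Same shape, genus columns as percentages summing to 100 per row.
#' @export
to_percent <- function(m) {
  x <- genus_matrix(m)
  rs <- rowSums(x)
  if (any(rs <= 0))
    stop_invalid("zero-read sample(s): %s (apply filter_min_reads first)",
                 paste(m$sample_id[rs <= 0], collapse = ", "))
  m[SYM_GENERA] <- 100 * x / rs
  m
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' BC = sum |a_i - b_i| / sum (a_i + b_i), in `[0, 1]`.
#'
#' @param a,b Non-negative numeric vectors of equal length, not both all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("vectors differ in length")
  if (any(a < 0) || any(b < 0)) stop_invalid("abundances must be >= 0")
  tot <- sum(a + b)
  if (tot == 0) stop_invalid("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(a - b)) / tot
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param m Genus abundance data frame (counts or percentages).
#' @return A symmetric matrix with zero diagonal, labelled by sample_id.
#' @export
bray_curtis_matrix <- function(m) {
  x <- genus_matrix(m)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- bray_curtis(x[i, ], x[j, ])
  d
}

check_dist <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12))
    stop_invalid("d must be a symmetric distance matrix with zero diagonal")
  d
}

# Within-group sum of squared distances for a label vector, from d^2.
# SS_w = sum over groups of (sum_{i<j in g} d_ij^2) / n_g, computed via
# indicator vectors so label permutations are cheap.
ss_within <- function(d2, groups) {
  s <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    s <- s + sum(d2[idx, idx]) / (2 * sum(idx))
  }
  s
}

#' Permutational multivariate analysis of variance on a distance matrix
#'
#' One-way PERMANOVA. Total sum of squares is `sum(d^2) / N` over unordered
#' pairs; within-group SS is the analogous per-group quantity; the pseudo-F
#' statistic is `(SS_between / df_between) / (SS_within / df_within)` with
#' `df_between = k - 1`, `df_within = N - k`. The p-value is the add-one
#' permutation estimate `(1 + #{F_perm >= F_obs}) / (1 + n_permutations)`
#' under random relabelling, so it is never 0 and never below
#' `1 / (n_permutations + 1)`. Ties count as exceedances (conservative).
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param groups Per-sample labels (>= 2 groups, each with >= 2 samples).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `permanova_result`: df_between, df_within,
#'   ss_between, ss_within, ss_total, pseudo_F, R_squared, p_value,
#'   n_permutations.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- check_dist(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop_invalid("groups length must match d")
  tab <- table(groups)
  if (length(tab) < 2) stop_invalid("need >= 2 groups")
  if (any(tab < 2)) stop_invalid("singleton group(s): %s",
                                 paste(names(tab)[tab < 2], collapse = ", "))
  check_number(n_permutations, "n_permutations", lower = 1, integer = TRUE)
  n <- nrow(d); k <- length(tab)
  d2 <- d^2
  ss_tot <- sum(d2) / (2 * n)
  ss_w <- ss_within(d2, groups)
  ss_b <- ss_tot - ss_w
  df_b <- k - 1; df_w <- n - k
  f_obs <- (ss_b / df_b) / (ss_w / df_w)
  set.seed(seed)
  exceed <- 0L
  for (p in seq_len(n_permutations)) {
    gp <- groups[sample.int(n)]
    ssw_p <- ss_within(d2, gp)
    f_p <- ((ss_tot - ssw_p) / df_b) / (ssw_p / df_w)
    if (f_p >= f_obs) exceed <- exceed + 1L
  }
  structure(list(df_between = df_b, df_within = df_w,
                 ss_between = ss_b, ss_within = ss_w, ss_total = ss_tot,
                 pseudo_F = f_obs, R_squared = ss_b / ss_tot,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (one-way, distance-based)\n")
  cat(sprintf("  df = %d, pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$df_between, x$pseudo_F, x$R_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA with Benjamini-Hochberg correction
#'
#' Runs [permanova()] on every unordered pair of group labels and adjusts the
#' p-values with the BH step-up procedure. Pairs whose sub-design is invalid
#' (e.g. a singleton group) are reported with NA statistics and excluded from
#' the adjustment family.
#'
#' @inheritParams permanova
#' @return Data frame with one row per pair: group1, group2, df_between,
#'   pseudo_F, R_squared, p_value, p_adjusted.
#' @export
pairwise_permanova <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- check_dist(d)
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  pairs <- utils::combn(gl, 2)
  seeds <- child_seeds(seed, ncol(pairs))
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    idx <- groups %in% c(g1, g2)
    res <- tryCatch(permanova(d[idx, idx, drop = FALSE], groups[idx],
                              n_permutations, seeds[i]),
                    error = function(e) NULL)
    if (is.null(res))
      data.frame(group1 = g1, group2 = g2, df_between = NA_integer_,
                 pseudo_F = NA_real_, R_squared = NA_real_, p_value = NA_real_,
                 stringsAsFactors = FALSE)
    else
      data.frame(group1 = g1, group2 = g2, df_between = res$df_between,
                 pseudo_F = res$pseudo_F, R_squared = res$R_squared,
                 p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Significance letters from a pairwise comparison table
#'
#' Heuristic grouping: build the graph whose edges connect pairs that are NOT
#' significantly different (adjusted p >= alpha) and assign one letter per
#' connected component. Groups sharing a letter are statistically
#' indistinguishable at alpha under this (coarse) rule.
#'
#' @param pairwise Data frame from [pairwise_permanova()] (needs group1,
#'   group2, p_adjusted).
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letters per group.
#' @export
significance_letters <- function(pairwise, alpha = 0.05) {
  gl <- sort(unique(c(pairwise$group1, pairwise$group2)))
  comp <- stats::setNames(seq_along(gl), gl)
  for (i in seq_len(nrow(pairwise))) {
    p <- pairwise$p_adjusted[i]
    if (!is.na(p) && p >= alpha) {
      a <- comp[[pairwise$group1[i]]]; b <- comp[[pairwise$group2[i]]]
      comp[comp == max(a, b)] <- min(a, b)
    }
  }
  stats::setNames(letters[match(comp, sort(unique(comp)))], gl)
}

# Principal-coordinates embedding keeping negative-eigenvalue axes under the
# imaginary-distance convention. Eigenvalues below 1e-8 x the largest (in
# magnitude) are dropped as numerical noise.
pcoa_embed <- function(d) {
  d <- check_dist(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  keep <- abs(e$values) > 1e-8 * max(abs(e$values))
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  coords <- sweep(vecs, 2, sqrt(abs(vals)), `*`)
  list(coords = coords, eigenvalues = vals)
}

#' Test homogeneity of multivariate dispersion among groups
#'
#' The distance matrix is embedded by principal-coordinates decomposition
#' (axes with negative eigenvalues are retained on the imaginary-distance
#' convention); each sample's distance to its group centroid is computed as
#' `sqrt(max(0, d_real^2 - d_imag^2))`; and group differences in those
#' distances are tested by a one-way F-test, with an optional permutation
#' p-value obtained by permuting group labels of the centroid distances.
#'
#' @param d Symmetric distance matrix.
#' @param groups Per-sample labels (>= 2 groups, each >= 2 samples).
#' @param n_permutations Permutations for the permutation p (0 = parametric
#'   F-test only).
#' @param seed Integer seed.
#' @return List: `distances` (per-sample centroid distance), `group_means`,
#'   `F`, `df`, `p_value` (parametric), `p_permutation` (NA when
#'   `n_permutations = 0`).
#' @export
dispersion_test <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- check_dist(d)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop_invalid("dispersion test needs >= 2 groups with >= 2 samples each")
  emb <- pcoa_embed(d)
  pos <- emb$eigenvalues > 0
  z <- numeric(nrow(d))
  for (g in unique(groups)) {
    idx <- groups == g
    cen <- colMeans(emb$coords[idx, , drop = FALSE])
    dif <- sweep(emb$coords[idx, , drop = FALSE], 2, cen)
    d2_real <- rowSums(dif[, pos, drop = FALSE]^2)
    d2_imag <- rowSums(dif[, !pos, drop = FALSE]^2)
    z[idx] <- sqrt(pmax(0, d2_real - d2_imag))
  }
  fit <- stats::aov(z ~ factor(groups))
  an <- summary(fit)[[1]]
  f_obs <- an$`F value`[1]
  p_perm <- NA_real_
  if (n_permutations > 0) {
    set.seed(seed)
    exceed <- 0L
    for (i in seq_len(n_permutations)) {
      gp <- groups[sample.int(length(groups))]
      anp <- summary(stats::aov(z ~ factor(gp)))[[1]]
      if (anp$`F value`[1] >= f_obs) exceed <- exceed + 1L
    }
    p_perm <- (1 + exceed) / (1 + n_permutations)
  }
  list(distances = z,
       group_means = tapply(z, groups, mean),
       F = f_obs, df = c(an$Df[1], an$Df[2]),
       p_value = an$`Pr(>F)`[1], p_permutation = p_perm)
}

#' Balanced random subsample of a genus count table
#'
#' PERMANOVA is sensitive to heterogeneous dispersion combined with an
#' unbalanced design, so the study drew the same number of samples (12) from
#' each category before testing. Selection is seeded random sampling per
#' category, or exactly the provided `fixed_ids` (order-stable with respect
#' to the input table).
#'
#' @param m Genus count data frame with a `category` column.
#' @param n_per_category Samples to keep per category (default 12).
#' @param seed Integer seed.
#' @param fixed_ids Optional character vector of sample_ids to select
#'   verbatim instead of sampling.
#' @return Subsampled data frame.
#' @export
balanced_subsample <- function(m, n_per_category = 12, seed = 1,
                               fixed_ids = NULL) {
  if (!is.null(fixed_ids)) {
    missing <- setdiff(fixed_ids, m$sample_id)
    if (length(missing))
      stop_invalid("fixed_ids not present: %s", paste(missing, collapse = ", "))
    return(m[m$sample_id %in% fixed_ids, , drop = FALSE])
  }
  check_number(n_per_category, "n_per_category", lower = 1, integer = TRUE)
  tab <- table(m$category)
  small <- names(tab)[tab < n_per_category]
  if (length(small))
    stop_invalid("category too small for n = %d: %s", n_per_category,
                 paste(small, collapse = ", "))
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(m)), m$category), function(idx) {
    sort(sample(idx, n_per_category))
  }))
  m[sort(keep), , drop = FALSE]
}

#' Expected rarefaction curve for one sample
#'
#' Closed-form hypergeometric expectation of genus richness at each depth:
#' `E[S(n)] = sum_g (1 - C(N - N_g, n) / C(N, n))` where `N` is the total
#' read count and `N_g` the count of genus g. Computed with log-binomials
#' for stability.
#'
#' @param counts Non-negative integer vector of one sample's genus counts.
#' @param depths Subsample depths, each `<= sum(counts)`.
#' @return Data frame: depth, expected_richness.
#' @export
rarefaction_curve <- function(counts, depths) {
  if (any(counts < 0)) stop_invalid("counts must be >= 0")
  n_tot <- sum(counts)
  if (any(depths > n_tot))
    stop_invalid("depth exceeds total reads (%d)", n_tot)
  if (any(depths < 0)) stop_invalid("depths must be >= 0")
  er <- vapply(depths, function(n) {
    sum(vapply(counts[counts > 0], function(ng) {
      if (n_tot - ng < n) return(1)
      1 - exp(lchoose(n_tot - ng, n) - lchoose(n_tot, n))
    }, numeric(1)))
  }, numeric(1))
  data.frame(depth = depths, expected_richness = er)
}
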