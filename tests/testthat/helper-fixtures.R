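# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

make_prep <- function(sv = 100, fx = 750, st = 0, mass = 73,
                      type = "feces") {
  sample_prep(sv, fx, st, if (type == "feces") mass else NA_real_, type)
}

make_sample <- function(live = rep(0, 8), dead = rep(0, 8), vol = 1e-4,
                        prep = make_prep(), id = "s1", guild = "obligate_corallivore") {
  cell_count_sample(id, guild, guild, live, dead, vol, prep)
}

# A small genus table: k categories x n samples, counts multinomial at the
# given per-category proportion rows.
make_genus_table <- function(props, n_per_cat = 5, depth = 5000, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cat in rownames(props)) {
    for (i in seq_len(n_per_cat)) {
      reads <- as.vector(stats::rmultinom(1, depth, props[cat, ]))
      rows[[paste(cat, i)]] <- cbind(
        data.frame(sample_id = sprintf("%s_%d", cat, i), category = cat,
                   species_code = cat, stringsAsFactors = FALSE),
        as.data.frame(as.list(stats::setNames(reads, sym_genera()))))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Euclidean distance matrix from a coordinate matrix (independent of the
# package's distance code).
euclid_dist <- function(xy) {
  as.matrix(stats::dist(xy))
}

# Independent brute-force PERMANOVA statistics straight from the distance
# matrix definition, O(N^2) double loop; used as the oracle for the package's
# implementation.
brute_permanova_stats <- function(d, groups) {
  n <- nrow(d)
  ss_tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_tot <- ss_tot + d[i, j]^2
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]^2
    ss_w <- ss_w + s / length(idx)
  }
  k <- length(unique(groups))
  f <- ((ss_tot - ss_w) / (k - 1)) / (ss_w / (n - k))
  list(pseudo_F = f, R_squared = (ss_tot - ss_w) / ss_tot)
}
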