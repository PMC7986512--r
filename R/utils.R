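#' @keywords internal
"_PACKAGE"

# Canonical Symbiodiniaceae genus order used throughout the package.
SYM_GENERA <- c("Symbiodinium", "Breviolum", "Cladocopium", "Durusdinium", "Fugacium")

#' Canonical Symbiodiniaceae genus order
#'
#' The five genera tracked by the genus-level community analyses, in the fixed
#' column order every reader and generator normalises to.
#'
#' @return Character vector of length 5.
#' @export
sym_genera <- function() SYM_GENERA

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE, integer = FALSE) {
  if (length(x) != 1 || (!allow_na && is.na(x)) || (!is.na(x) && !is.numeric(x)))
    stop_invalid("'%s' must be a single number", name)
  if (!is.na(x)) {
    if (x < lower || x > upper)
      stop_invalid("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
    if (integer && x != round(x))
      stop_invalid("'%s' must be a whole number, got %s", name, x)
  }
  invisible(x)
}

#' Derive per-generator child seeds from one global seed
#'
#' One global seed fans out deterministically to the package's independent
#' random processes: child k is drawn by seeding R's RNG with the global seed
#' and taking the k-th value of `sample.int(.Machine$integer.max, n)`. The
#' scheme guarantees that generators consuming different children are
#' independent streams, and that the whole fan-out is reproducible
#' byte-for-byte from the single global seed.
#'
#' @param seed Global integer seed.
#' @param n Number of child seeds required.
#' @return Integer vector of `n` seeds, each in `[1, 2^31 - 1]`.
#' @export
child_seeds <- function(seed, n) {
  check_number(seed, "seed", integer = TRUE)
  check_number(n, "n", lower = 1, integer = TRUE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

# Standard error of the mean; 0 for a single value (degenerate group).
se_mean <- function(x) {
  if (length(x) <= 1) return(0)
  stats::sd(x) / sqrt(length(x))
}

# Truncated-normal draws on (lower, Inf) via inverse-CDF; vectorised over n.
rtruncnorm_pos <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(max(mean, lower), n))
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(u, mean, sd)
}

# Dirichlet draws via normalised gammas; alpha strictly positive.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sw <- rowSums(x)
  # all-zero rows can occur for tiny alpha; fall back to the mean simplex
  bad <- sw == 0
  if (any(bad)) {
    x[bad, ] <- matrix(alpha / sum(alpha), sum(bad), k, byrow = TRUE)
    sw[bad] <- 1
  }
  x / sw
}
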