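#' Moore-Rayleigh statistic for weighted circular data
#'
#' Rank-weighted extension of the Rayleigh test: the vector magnitudes are
#' replaced by their ranks (average ranks under ties) and the length of the
#' rank-weighted resultant is normalized by `n^(3/2)`,
#' `R* = sqrt((sum r_i cos(theta_i))^2 + (sum r_i sin(theta_i))^2) / n^1.5`.
#' Large values indicate that the vectors share a common direction.
#'
#' @param angles numeric vector of angles in radians, length n >= 2.
#' @param magnitudes non-negative weights, same length as `angles`.
#' @return the statistic `R*` (non-negative scalar).
#' @export
moore_rayleigh_stat <- function(angles, magnitudes) {
  n <- length(angles)
  if (n < 2) stop("need at least 2 vectors")
  if (length(magnitudes) != n) stop("angles and magnitudes differ in length")
  if (any(magnitudes < 0)) stop("magnitudes must be non-negative")
  r <- rank(magnitudes)
  sqrt(sum(r * cos(angles))^2 + sum(r * sin(angles))^2) / n^1.5
}

# Monte-Carlo null table of R* for a given rank vector, cached per
# (ranks, n_mc, seed). Under the null hypothesis the angles are independent
# and uniform, and the null distribution of R* conditional on the observed
# magnitudes depends only on their rank vector; for untied magnitudes this is
# the usual ranks 1..n null.
.mr_cache <- new.env(parent = emptyenv())

mr_null_table <- function(ranks, n_mc = 100000L, seed = 20240713L) {
  key <- paste(c(format(n_mc), format(seed), format(sort(ranks))),
               collapse = "|")
  tab <- .mr_cache[[key]]
  if (!is.null(tab)) return(tab)
  n <- length(ranks)
  # local RNG without disturbing the caller's stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  th <- matrix(stats::runif(n * n_mc, 0, 2 * pi), nrow = n)
  s <- sqrt(as.vector(crossprod(cos(th), ranks))^2 +
            as.vector(crossprod(sin(th), ranks))^2) / n^1.5
  tab <- sort(s)
  .mr_cache[[key]] <- tab
  tab
}

#' Monte-Carlo p-value for the Moore-Rayleigh statistic
#'
#' The null distribution (independent uniform angles carrying the observed
#' rank weights; ranks 1..n when magnitudes are untied) is sampled by
#' Monte-Carlo with a fixed seed and cached per sample size, and
#' `p = (1 + #(null R* >= observed)) / (1 + n_mc)`, so `p` lies in (0, 1].
#'
#' @param R_star observed statistic (scalar or vector).
#' @param n sample size (number of vectors), n >= 2.
#' @param n_mc number of null draws (default 100000).
#' @param seed seed for the cached null table.
#' @param ranks optional rank vector of the observed magnitudes; defaults to
#'   `1:n` (untied magnitudes).
#' @return p-value(s) in (0, 1].
#' @export
moore_rayleigh_pvalue <- function(R_star, n, n_mc = 100000L,
                                  seed = 20240713L, ranks = NULL) {
  if (n < 2) stop("need at least 2 vectors")
  n_mc <- as.integer(n_mc)
  if (is.na(n_mc) || n_mc < 1) stop("invalid n_mc")
  if (is.null(ranks)) ranks <- seq_len(n)
  stopifnot(length(ranks) == n)
  tab <- mr_null_table(ranks, n_mc, seed)
  n_lt <- findInterval(R_star, tab, left.open = TRUE)  # null draws < observed
  (1 + (n_mc - n_lt)) / (1 + n_mc)
}

#' Moore-Rayleigh test
#'
#' Convenience wrapper computing the statistic and its Monte-Carlo p-value.
#'
#' @inheritParams moore_rayleigh_stat
#' @inheritParams moore_rayleigh_pvalue
#' @return list with `statistic`, `p_value`, `n`.
#' @export
moore_rayleigh_test <- function(angles, magnitudes, n_mc = 100000L,
                                seed = 20240713L) {
  s <- moore_rayleigh_stat(angles, magnitudes)
  n <- length(angles)
  p <- moore_rayleigh_pvalue(s, n, n_mc, seed, ranks = rank(magnitudes))
  list(statistic = s, p_value = p, n = n)
}

#' Weighted circular mean
#'
#' Argument of the weighted resultant `sum(w * exp(i * angle * 2*pi/period))`
#' mapped back to `[0, period)`. For data with a period other than `2*pi`
#' (e.g. orientations, period 180), angles are rescaled to the full circle,
#' averaged, and rescaled back.
#'
#' @param angles numeric vector (same units as `period`).
#' @param weights non-negative weights, at least one positive; defaults to
#'   equal weights.
#' @param period the angular period (default `2*pi`).
#' @return mean angle in `[0, period)`, or `NaN` (with a warning) when the
#'   resultant vanishes (e.g. antipodal inputs).
#' @export
circular_mean <- function(angles, weights = NULL, period = 2 * pi) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  stopifnot(length(weights) == length(angles), all(weights >= 0))
  if (!any(weights > 0)) stop("all weights are zero")
  z <- sum(weights * exp(1i * angles * 2 * pi / period))
  if (Mod(z) / sum(weights) < 1e-9) {
    warning("circular mean undefined: resultant vector is (numerically) zero")
    return(NaN)
  }
  wrap_period(Arg(z) * period / (2 * pi), period)
}
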