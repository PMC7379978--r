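#' Expected richness under sample-based rarefaction
#'
#' Analytic (hypergeometric) expectation of the number of taxa observed in a
#' random subset of `n` of the `m` pellets, drawn without replacement:
#' \deqn{E[S(n)] = \sum_t \left[1 - \binom{m - m_t}{n} / \binom{m}{n}\right]}
#' with `m_t` the incidence count of taxon t. This equals the exhaustive mean
#' over all `choose(m, n)` pellet subsets.
#'
#' @param x an [incidence_matrix].
#' @param n number of pellets, `1 <= n <= m`.
#' @return expected observed richness (numeric scalar).
#' @export
expected_richness <- function(x, n) {
  ic <- incidence_counts(x)
  if (n < 1 || n > ic$m) stop("n must be in [1, m]")
  sum(1 - choose(ic$m - ic$m_t, n) / choose(ic$m, n))
}

#' Chao2 incidence-based richness estimator
#'
#' \eqn{\hat S = S_{obs} + \frac{m-1}{m}\frac{Q_1^2}{2 Q_2}} when `Q2 > 0`,
#' and the bias-corrected fallback
#' \eqn{S_{obs} + \frac{m-1}{m}\frac{Q_1 (Q_1 - 1)}{2 (Q_2 + 1)}} when
#' `Q2 = 0`. Always `>= S_obs`.
#'
#' @param S_obs observed richness.
#' @param Q1 number of taxa occurring in exactly one sampling unit.
#' @param Q2 number occurring in exactly two.
#' @param m number of sampling units.
#' @return estimated richness.
#' @export
chao2 <- function(S_obs, Q1, Q2, m) {
  stopifnot(m >= 1)
  if (Q2 > 0) S_obs + (m - 1) / m * Q1^2 / (2 * Q2)
  else S_obs + (m - 1) / m * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
}

.chao2_of_matrix <- function(mat) {
  ic <- incidence_counts(mat)
  chao2(ic$S_obs, ic$Q1, ic$Q2, ic$m)
}

#' Mean Chao2 of pellet subsamples
#'
#' Chao2 of a subsample has no simple closed form, so the curve is built by
#' seeded resampling: the mean of [chao2] over `reps` subsamples of `n`
#' pellets drawn without replacement. At `n = m` the full-matrix Chao2 is
#' returned exactly (no resampling).
#'
#' @param x an [incidence_matrix].
#' @param n subsample size, `1 <= n <= m`.
#' @param reps number of subsamples (default 200).
#' @param seed integer seed.
#' @return mean Chao2 estimate at `n` pellets.
#' @export
chao2_curve <- function(x, n, reps = 200L, seed = 1L) {
  mat <- if (inherits(x, "incidence_matrix")) x$mat else x
  m <- nrow(mat)
  if (n < 1 || n > m) stop("n must be in [1, m]")
  stopifnot(reps >= 1)
  if (n == m) return(.chao2_of_matrix(mat))
  set.seed(as.integer(seed))
  mean(vapply(seq_len(reps), function(b) {
    .chao2_of_matrix(mat[sample.int(m, n), , drop = FALSE])
  }, numeric(1)))
}

#' Mean accumulation curve across individuals
#'
#' For each pellet count `n` (1 up to the smallest `m` across individuals),
#' computes the across-individual mean and standard error of the analytic
#' rarefaction expectation and of the resampled Chao2 estimate. SE is the
#' sample SD divided by `sqrt(I)`; with a single individual SE is 0 by
#' convention.
#'
#' @param mats list of [incidence_matrix] (e.g. from [collapse_pcrs]).
#' @param reps Chao2 resampling replicates per (individual, n).
#' @param seed integer seed for the Chao2 resampling stream.
#' @return data frame of class `accumulation_curve` with columns `n`,
#'   `mean_obs`, `se_obs`, `mean_chao2`, `se_chao2`.
#' @export
mean_curve <- function(mats, reps = 200L, seed = 1L) {
  stopifnot(length(mats) >= 1)
  I <- length(mats)
  m_min <- min(vapply(mats, function(x) x$m, numeric(1)))
  set.seed(as.integer(seed))
  se <- function(v) if (I == 1L) 0 else stats::sd(v) / sqrt(I)
  rows <- lapply(seq_len(m_min), function(n) {
    obs <- vapply(mats, expected_richness, numeric(1), n = n)
    ch <- vapply(mats, function(x) {
      mat <- x$mat
      if (n == x$m) return(.chao2_of_matrix(mat))
      # draws come from the one stream seeded above, not per-call reseeding
      mean(vapply(seq_len(reps), function(b)
        .chao2_of_matrix(mat[sample.int(x$m, n), , drop = FALSE]), numeric(1)))
    }, numeric(1))
    data.frame(n = n, mean_obs = mean(obs), se_obs = se(obs),
               mean_chao2 = mean(ch), se_chao2 = se(ch))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' Pellets needed to recover a fraction of the full-sample richness
#'
#' Smallest `n` with `mean_obs(n) >= fraction * mean_obs(m)`.
#'
#' @param curve an `accumulation_curve` (from [mean_curve]).
#' @param fraction target fraction in `(0, 1]`, e.g. 0.80.
#' @return smallest pellet count `n`.
#' @export
pellets_for_fraction <- function(curve, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  target <- fraction * curve$mean_obs[nrow(curve)]
  curve$n[which(curve$mean_obs >= target)[1]]
}
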