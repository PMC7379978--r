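#' Frequency-of-occurrence descriptors
#'
#' After PCR collapse, computes per taxon:
#' * `fo_tot` — fraction of individuals in which the taxon was detected in at
#'   least one of their pellets;
#' * `fo_pel` — mean, over the individuals in which it was detected, of the
#'   fraction of that individual's pellets containing it (`NA` when
#'   `fo_tot = 0`);
#' * `fo_pool` — fraction of individuals whose pool sample detects it
#'   (`NA` when no pools are supplied);
#' * `fo_pellet_overall` — fraction of all pellets (across individuals)
#'   containing it.
#'
#' @param cube a [detection_cube].
#' @param pools optional [pool_block].
#' @param mode,seed PCR collapse convention, see [collapse_pcrs]. The same
#'   convention (and stream) is applied to the pools.
#' @return data frame with one row per taxon.
#' @export
fo_table <- function(cube, pools = NULL, mode = c("union", "single_random"),
                     seed = NULL) {
  mode <- match.arg(mode)
  mats <- collapse_pcrs(cube, mode, seed)
  fo <- fo_from_matrices(mats)
  fo$fo_pool <- NA_real_
  if (!is.null(pools)) {
    pm <- collapse_pools(pools, mode,
                         seed = if (is.null(seed)) NULL else seed + 1L)
    fo$fo_pool <- colMeans(pm[, fo$taxon, drop = FALSE])
  }
  fo[, c("taxon", "fo_tot", "fo_pel", "fo_pool", "fo_pellet_overall")]
}

#' FO descriptors from collapsed incidence matrices
#'
#' @param mats list of [incidence_matrix].
#' @return data frame with `taxon`, `fo_tot`, `fo_pel`, `fo_pellet_overall`.
#' @export
fo_from_matrices <- function(mats) {
  taxa <- colnames(mats[[1]]$mat)
  I <- length(mats)
  counts <- vapply(mats, function(x) colSums(x$mat), numeric(length(taxa)))
  ms <- vapply(mats, function(x) x$m, numeric(1))
  counts <- matrix(counts, nrow = length(taxa))  # taxa x individuals
  det <- counts > 0
  fo_tot <- rowMeans(det)
  frac <- sweep(counts, 2, ms, "/")
  fo_pel <- vapply(seq_along(taxa), function(t) {
    d <- det[t, ]
    if (!any(d)) NA_real_ else mean(frac[t, d])
  }, numeric(1))
  data.frame(taxon = taxa, fo_tot = fo_tot, fo_pel = fo_pel,
             fo_pellet_overall = rowSums(counts) / sum(ms),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Resample the FO of one taxon at reduced pellet sample size
#'
#' For each of `reps` replicates: from every individual, draw `n` pellets
#' with replacement from its `m` analysed pellets, mark the individual
#' positive if any drawn pellet contains the taxon, and estimate FO as the
#' fraction of positive individuals. Input is the PCR-collapsed
#' representation (one detection layer per pellet).
#'
#' @param mats list of [incidence_matrix].
#' @param taxon taxon id (column name).
#' @param n pellets drawn per individual (with replacement; `n >= 1`).
#' @param reps number of replicates.
#' @param seed integer seed.
#' @return numeric vector of `reps` FO estimates.
#' @export
resample_fo <- function(mats, taxon, n, reps = 10000L, seed = 1L) {
  stopifnot(n >= 1, reps >= 1)
  set.seed(as.integer(seed))
  I <- length(mats)
  pos <- matrix(0, reps, I)
  for (i in seq_len(I)) {
    p <- mats[[i]]$mat[, taxon]
    draws <- matrix(sample.int(mats[[i]]$m, reps * n, replace = TRUE), reps, n)
    pos[, i] <- as.numeric(rowSums(matrix(p[draws], reps, n)) > 0)
  }
  rowMeans(pos)
}

#' FO estimation-error curves over pellet sample sizes
#'
#' The Monte-Carlo procedure behind the replication-error analysis: for each
#' `n` in `n_range` and each replicate, every individual contributes `n`
#' pellets drawn with replacement (one shared draw per individual and
#' replicate, applied to all taxa), FO is re-estimated, and the error against
#' the full-sample FO (`fo_m`, from all `m` pellets) is recorded.
#' `absolute` error is `fo_m - fo_hat`; `relative` divides by `fo_m`.
#' Taxa with `fo_m = 0` are excluded.
#'
#' @param mats list of [incidence_matrix] (PCR-collapsed).
#' @param taxa taxa to include; default all taxa with full-sample FO > 0.
#' @param n_range vector of pellet counts (default `1:(m - 1)`).
#' @param reps Monte-Carlo replicates per `n` (default 10000).
#' @param seed integer seed.
#' @param error_kind `"relative"` (default) or `"absolute"`.
#' @return data frame of class `error_curve` with columns `taxon`, `n`,
#'   `mean_fo`, `mean_error`, `sd_error`; attribute `error_kind`.
#' @export
error_curve <- function(mats, taxa = NULL, n_range = NULL, reps = 10000L,
                        seed = 1L, error_kind = c("relative", "absolute")) {
  error_kind <- match.arg(error_kind)
  stopifnot(reps >= 1)
  I <- length(mats)
  fo_full <- fo_from_matrices(mats)
  if (is.null(taxa)) taxa <- fo_full$taxon[fo_full$fo_tot > 0]
  fo_m <- fo_full$fo_tot[match(taxa, fo_full$taxon)]
  if (any(fo_m == 0)) stop("error_curve requires taxa with full-sample FO > 0")
  if (is.null(n_range)) n_range <- seq_len(min(vapply(mats, `[[`, 0, "m")) - 1L)
  set.seed(as.integer(seed))
  Tt <- length(taxa)
  sub <- lapply(mats, function(x) x$mat[, taxa, drop = FALSE] * 1)

  out <- vector("list", length(n_range))
  for (ni in seq_along(n_range)) {
    n <- n_range[ni]
    det_count <- matrix(0, reps, Tt)  # positive individuals per rep x taxon
    for (i in seq_len(I)) {
      m <- mats[[i]]$m
      draws <- matrix(sample.int(m, reps * n, replace = TRUE), reps, n)
      H <- matrix(0, reps, m)  # was pellet j drawn in replicate r?
      for (k in seq_len(n)) H[cbind(seq_len(reps), draws[, k])] <- 1
      det_count <- det_count + ((H %*% sub[[i]]) > 0)
    }
    fo_hat <- det_count / I
    err <- sweep(-fo_hat, 2, fo_m, "+")
    if (error_kind == "relative") err <- sweep(err, 2, fo_m, "/")
    out[[ni]] <- data.frame(
      taxon = taxa, n = n,
      mean_fo = colMeans(fo_hat),
      mean_error = colMeans(err),
      sd_error = apply(err, 2, stats::sd),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  res <- do.call(rbind, out)
  attr(res, "error_kind") <- error_kind
  class(res) <- c("error_curve", "data.frame")
  res
}

#' Error of pool-based FO estimates
#'
#' Per-taxon error of the pool estimate against the full separate-pellet
#' estimate: relative `(fo_tot - fo_pool) / fo_tot` (default) or absolute
#' difference. Restricted to taxa with `fo_tot > 0`.
#'
#' @param fo an FO table from [fo_table] (must include `fo_pool`).
#' @param error_kind `"relative"` or `"absolute"`.
#' @return data frame with `taxon`, `error`.
#' @export
pool_error <- function(fo, error_kind = c("relative", "absolute")) {
  error_kind <- match.arg(error_kind)
  stopifnot("fo_pool" %in% names(fo))
  fo <- fo[fo$fo_tot > 0 & !is.na(fo$fo_pool), , drop = FALSE]
  e <- fo$fo_tot - fo$fo_pool
  if (error_kind == "relative") e <- e / fo$fo_tot
  data.frame(taxon = fo$taxon, error = e, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Classical paired t test
#'
#' Two-sided paired t on the differences `x - y`, `df = length(x) - 1`.
#' All-zero differences return `t = 0, p = 1`; zero-variance differences
#' with nonzero mean are an error (t undefined).
#'
#' @param x,y numeric vectors of equal length `>= 2`.
#' @return list with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1))
    stop("zero-variance nonzero differences: t statistic undefined")
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

#' Clopper-Pearson interval for a full-sample FO estimate
#'
#' Exact binomial confidence band for `fo * I` positive individuals out of
#' `I`, used to shade the FO convergence plots.
#'
#' @param fo full-sample FO estimate.
#' @param I number of individuals.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
fo_confint <- function(fo, I, level = 0.95) {
  x <- round(fo * I)
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, I - x + 1)
  hi <- if (x == I) 1 else stats::qbeta(1 - a, x + 1, I - x)
  c(lower = lo, upper = hi)
}
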