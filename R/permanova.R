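# Nested three-level PERMANOVA on the PCR-level presence/absence matrix,
# using squared Euclidean distance on the raw 0/1 data (equivalently, the
# Gower-centred distance-matrix formulation by the McArdle-Anderson identity).

.expand_means <- function(Y, g) {
  gm <- rowsum(Y, g) / as.vector(table(g)[levels(g)])
  gm[as.integer(g), , drop = FALSE]
}

#' Nested sums of squares (individual / pellet / PCR)
#'
#' Partitions the total sum of squares of the unit x taxon 0/1 matrix into
#' among-individual, among-pellet-within-individual and
#' among-PCR-within-pellet components:
#' \deqn{SS_{ind} = \sum_{u} \|\bar y_i - \bar y\|^2,\quad
#'       SS_{pel} = \sum_{u} \|\bar y_{ij} - \bar y_i\|^2,\quad
#'       SS_{pcr} = \sum_{u} \|y_{ijk} - \bar y_{ij}\|^2}
#' (sums over units u). In this fully nested design the PCR term is the
#' deepest and the residual row has 0 df and 0 SS (saturated model).
#'
#' @param Y numeric units x taxa matrix (0/1 detections).
#' @param labels data frame with columns `individual`, `pellet`, `pcr`
#'   (pellet ids need not be globally unique; nesting is enforced by
#'   crossing with the individual).
#' @return data frame of class `permanova_table` with rows `individual`,
#'   `individual:pellet`, `individual:pellet:PCR`, `residual`, `total` and
#'   columns `df`, `SS`, `MS`, `R2`.
#' @export
nested_ss <- function(Y, labels) {
  stopifnot(nrow(Y) == nrow(labels))
  Y <- as.matrix(Y) * 1
  N <- nrow(Y)
  ind <- factor(labels$individual)
  pel <- factor(paste(labels$individual, labels$pellet, sep = "\r"))
  gm <- matrix(colMeans(Y), N, ncol(Y), byrow = TRUE)
  mi <- .expand_means(Y, ind)
  mij <- .expand_means(Y, pel)
  ss_ind <- sum((mi - gm)^2)
  ss_pel <- sum((mij - mi)^2)
  ss_pcr <- sum((Y - mij)^2)
  ss_tot <- sum((Y - gm)^2)
  df_ind <- nlevels(ind) - 1L
  df_pel <- nlevels(pel) - nlevels(ind)
  df_pcr <- N - nlevels(pel)
  df_res <- (N - 1L) - df_ind - df_pel - df_pcr  # always 0 here
  tab <- data.frame(
    term = c("individual", "individual:pellet", "individual:pellet:PCR",
             "residual", "total"),
    df = c(df_ind, df_pel, df_pcr, df_res, N - 1L),
    SS = c(ss_ind, ss_pel, ss_pcr, 0, ss_tot),
    stringsAsFactors = FALSE
  )
  tab$MS <- ifelse(tab$df > 0, tab$SS / tab$df, NA_real_)
  tab$MS[tab$term == "total"] <- NA_real_
  tab$R2 <- ifelse(tab$term %in% c("total"), NA_real_,
                   if (ss_tot > 0) tab$SS / ss_tot else NA_real_)
  class(tab) <- c("permanova_table", "data.frame")
  tab
}

#' Pseudo-F statistics for the nested table
#'
#' `next_nested` (default): each term's MS is tested against the MS of the
#' next term down the hierarchy (`F_ind = MS_ind / MS_pel`,
#' `F_pel = MS_pel / MS_pcr`); the deepest term has no denominator when the
#' residual has 0 df and its F is `NA`. `residual`: every term over the
#' residual MS, only defined when residual df > 0.
#'
#' @param tab a `permanova_table` from [nested_ss].
#' @param f_scheme `"next_nested"` or `"residual"`.
#' @return the table with an `F` column added.
#' @export
pseudo_f <- function(tab, f_scheme = c("next_nested", "residual")) {
  f_scheme <- match.arg(f_scheme)
  ms <- stats::setNames(tab$MS, tab$term)
  F <- rep(NA_real_, nrow(tab))
  div <- function(a, b) {
    if (is.na(b)) return(NA_real_)
    if (b == 0) { warning("zero denominator MS; F infinite"); return(Inf) }
    a / b
  }
  if (f_scheme == "next_nested") {
    F[tab$term == "individual"] <- div(ms["individual"], ms["individual:pellet"])
    F[tab$term == "individual:pellet"] <-
      div(ms["individual:pellet"], ms["individual:pellet:PCR"])
    # deepest term: no next-nested denominator in a saturated design
  } else {
    if (tab$df[tab$term == "residual"] > 0) {
      mres <- ms["residual"]
      for (tm in c("individual", "individual:pellet", "individual:pellet:PCR"))
        F[tab$term == tm] <- div(ms[tm], mres)
    } else {
      warning("residual df = 0: no residual-scheme F available")
    }
  }
  tab$F <- F
  tab
}

# SS of the three nested terms only (fast path used inside the RRPP loop).
.nested_ss_terms <- function(Y, ind, pel) {
  mi <- .expand_means(Y, ind)
  mij <- .expand_means(Y, pel)
  gm <- matrix(colMeans(Y), nrow(Y), ncol(Y), byrow = TRUE)
  c(ind = sum((mi - gm)^2), pel = sum((mij - mi)^2), pcr = sum((Y - mij)^2))
}

#' Nested PERMANOVA with RRPP significance
#'
#' For each term in hierarchical sequence, residuals of the reduced model
#' (all shallower terms) are permuted across units B times (randomized
#' residual permutation procedure), the term's statistic is recomputed on
#' each permuted dataset, and `p = (1 + #\{F* >= F_obs\}) / (1 + B)` (ties
#' count as exceedances). The statistic is the `next_nested` pseudo-F where
#' defined; for the deepest (PCR) term in the saturated design the MS itself
#' is used descriptively — its observed value is an upper bound over
#' permutations, so that p is degenerate at `1/(B+1)` (see the methods
#' vignette).
#'
#' @inheritParams nested_ss
#' @param B number of permutations (default 999).
#' @param seed integer seed.
#' @param f_scheme passed to [pseudo_f].
#' @return `permanova_table` with `F` and `p_perm` columns; attributes `B`
#'   and `f_scheme`.
#' @export
rrpp_test <- function(Y, labels, B = 999L, seed = 1L,
                      f_scheme = c("next_nested", "residual")) {
  f_scheme <- match.arg(f_scheme)
  stopifnot(B >= 1)
  Y <- as.matrix(Y) * 1
  N <- nrow(Y)
  ind <- factor(labels$individual)
  pel <- factor(paste(labels$individual, labels$pellet, sep = "\r"))
  tab <- pseudo_f(nested_ss(Y, labels), f_scheme)
  if (f_scheme == "residual" && tab$df[tab$term == "residual"] == 0) {
    # no residual-scheme statistic exists in the saturated design
    tab$p_perm <- NA_real_
    attr(tab, "B") <- B
    attr(tab, "f_scheme") <- f_scheme
    return(tab)
  }
  obs <- .nested_ss_terms(Y, ind, pel)
  df <- c(ind = nlevels(ind) - 1L, pel = nlevels(pel) - nlevels(ind),
          pcr = N - nlevels(pel))
  ms_obs <- obs / df
  f_obs <- c(ind = ms_obs[["ind"]] / ms_obs[["pel"]],
             pel = ms_obs[["pel"]] / ms_obs[["pcr"]],
             pcr = ms_obs[["pcr"]])

  gm <- matrix(colMeans(Y), N, ncol(Y), byrow = TRUE)
  fit_ind <- .expand_means(Y, ind)
  fit_pel <- .expand_means(Y, pel)
  res0 <- Y - gm       # reduced model for the individual term: intercept
  res1 <- Y - fit_ind  # reduced model for the pellet term
  res2 <- Y - fit_pel  # reduced model for the PCR term

  set.seed(as.integer(seed))
  exceed <- c(ind = 0L, pel = 0L, pcr = 0L)
  for (b in seq_len(B)) {
    pr <- sample.int(N)
    s <- .nested_ss_terms(gm + res0[pr, , drop = FALSE], ind, pel)
    if ((s[["ind"]] / df[["ind"]]) / (s[["pel"]] / df[["pel"]]) >= f_obs[["ind"]])
      exceed[["ind"]] <- exceed[["ind"]] + 1L
    pr <- sample.int(N)
    s <- .nested_ss_terms(fit_ind + res1[pr, , drop = FALSE], ind, pel)
    if ((s[["pel"]] / df[["pel"]]) / (s[["pcr"]] / df[["pcr"]]) >= f_obs[["pel"]])
      exceed[["pel"]] <- exceed[["pel"]] + 1L
    pr <- sample.int(N)
    s <- .nested_ss_terms(fit_pel + res2[pr, , drop = FALSE], ind, pel)
    if (s[["pcr"]] / df[["pcr"]] >= f_obs[["pcr"]])
      exceed[["pcr"]] <- exceed[["pcr"]] + 1L
  }
  p <- (1 + exceed) / (1 + B)
  tab$p_perm <- NA_real_
  tab$p_perm[tab$term == "individual"] <- p[["ind"]]
  tab$p_perm[tab$term == "individual:pellet"] <- p[["pel"]]
  tab$p_perm[tab$term == "individual:pellet:PCR"] <- p[["pcr"]]
  attr(tab, "B") <- B
  attr(tab, "f_scheme") <- f_scheme
  tab
}

#' One-factor PERMANOVA (pools vs separate pellets)
#'
#' Squared-Euclidean one-way PERMANOVA with raw-unit permutation of group
#' labels; `F = (SS_b / (g - 1)) / (SS_w / (N - g))`, `R2 = SS_b / SS_tot`.
#'
#' @param Y numeric units x taxa matrix.
#' @param group factor-like vector of group labels (two or more groups,
#'   each of size >= 2).
#' @param B permutations (default 999).
#' @param seed integer seed.
#' @return list with `F`, `R2`, `p`, `df`.
#' @export
two_group_permanova <- function(Y, group, B = 999L, seed = 1L) {
  Y <- as.matrix(Y) * 1
  g <- factor(group)
  if (any(table(g) < 2)) stop("each group must have at least 2 units")
  N <- nrow(Y)
  k <- nlevels(g)
  stat <- function(gg) {
    mg <- .expand_means(Y, gg)
    gm <- matrix(colMeans(Y), N, ncol(Y), byrow = TRUE)
    ssb <- sum((mg - gm)^2)
    ssw <- sum((Y - mg)^2)
    if (ssw == 0) {
      warning("zero within-group SS; F undefined")
      return(c(NA_real_, if (ssb > 0) 1 else NA_real_))
    }
    c((ssb / (k - 1)) / (ssw / (N - k)), ssb / (ssb + ssw))
  }
  o <- stat(g)
  if (is.na(o[1]))
    return(list(F = o[1], R2 = o[2], p = NA_real_, df = c(k - 1L, N - k)))
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(B)) {
    s <- stat(g[sample.int(N)])
    if (!is.na(s[1]) && s[1] >= o[1]) exceed <- exceed + 1L
  }
  list(F = o[1], R2 = o[2], p = (1 + exceed) / (1 + B),
       df = c(k - 1L, N - k))
}
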