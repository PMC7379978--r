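rand_units <- function(N_ind = 3, J = 3, K = 2, T = 6, seed = 1, p = 0.4) {
  set.seed(seed)
  labels <- expand.grid(pcr = sprintf("k%d", 1:K),
                        pellet = sprintf("p%d", 1:J),
                        individual = sprintf("b%d", 1:N_ind),
                        stringsAsFactors = FALSE)[, 3:1]
  Y <- matrix(as.numeric(stats::runif(nrow(labels) * T) < p), nrow(labels), T)
  list(Y = Y, labels = labels)
}

# distance-only oracle: within-group SS of grouping g from squared pairwise
# Euclidean distances, Sum_g (1/n_g) Sum_{i<j in g} d^2_ij
ss_within_from_dist <- function(Y, g) {
  d2 <- as.matrix(stats::dist(Y))^2
  sum(vapply(split(seq_len(nrow(Y)), g), function(ix) {
    sum(d2[ix, ix]) / (2 * length(ix))
  }, numeric(1)))
}

test_that("nested_ss reproduces the hand-computed toy decomposition", {
  # 2 individuals x 2 pellets x 1 PCR, 1 taxon, values (1,1 | 0,0)
  Y <- matrix(c(1, 1, 0, 0), 4, 1)
  labels <- data.frame(individual = c("a", "a", "b", "b"),
                       pellet = c("p1", "p2", "p1", "p2"),
                       pcr = "k1")
  tab <- nested_ss(Y, labels)
  expect_equal(tab$SS[tab$term == "individual"], 1)
  expect_equal(tab$SS[tab$term == "individual:pellet"], 0)
  expect_equal(tab$SS[tab$term == "total"], 1)
  expect_equal(tab$R2[tab$term == "individual"], 1)
  expect_equal(tab$df[1:3], c(1, 2, 0))
})

test_that("SS decomposition is additive and matches the distance oracle", {
  for (s in 1:6) {
    u <- rand_units(seed = 600 + s)
    tab <- nested_ss(u$Y, u$labels)
    ss <- stats::setNames(tab$SS, tab$term)
    expect_equal(ss[["individual"]] + ss[["individual:pellet"]] +
                   ss[["individual:pellet:PCR"]], ss[["total"]],
                 tolerance = 1e-10)
    expect_equal(sum(tab$df[1:4]), nrow(u$Y) - 1)

    ind <- u$labels$individual
    pel <- paste(ind, u$labels$pellet)
    n <- nrow(u$Y)
    ss_tot_d <- sum(as.matrix(stats::dist(u$Y))^2) / (2 * n)
    expect_equal(ss[["total"]], ss_tot_d, tolerance = 1e-8)
    within_ind <- ss_within_from_dist(u$Y, ind)   # = SS_pel + SS_pcr
    within_pel <- ss_within_from_dist(u$Y, pel)   # = SS_pcr
    expect_equal(ss[["individual"]], ss_tot_d - within_ind, tolerance = 1e-8)
    expect_equal(ss[["individual:pellet"]], within_ind - within_pel,
                 tolerance = 1e-8)
    expect_equal(ss[["individual:pellet:PCR"]], within_pel, tolerance = 1e-8)
  }
})

test_that("pseudo_f forms the next-nested ratios and flags the saturated case", {
  tab <- data.frame(
    term = c("individual", "individual:pellet", "individual:pellet:PCR",
             "residual", "total"),
    df = c(2, 4, 8, 0, 14), SS = c(16, 8, 8, 0, 32),
    MS = c(8, 2, 1, NA, NA), R2 = c(0.5, 0.25, 0.25, 0, NA))
  out <- pseudo_f(tab, "next_nested")
  expect_equal(out$F[out$term == "individual"], 4)
  expect_equal(out$F[out$term == "individual:pellet"], 2)
  expect_true(is.na(out$F[out$term == "individual:pellet:PCR"]))

  eq <- tab; eq$MS[1:2] <- c(2, 2)
  expect_equal(pseudo_f(eq)$F[1], 1)

  expect_warning(res <- pseudo_f(tab, "residual"), "residual df = 0")
  expect_true(all(is.na(res$F[1:3])))
})

test_that("rrpp_test saturates under a large injected individual effect", {
  u <- rand_units(N_ind = 4, J = 3, K = 2, T = 5, seed = 10)
  shift <- matrix(5 * as.integer(factor(u$labels$individual)),
                  nrow(u$Y), ncol(u$Y))
  Y <- u$Y + shift
  B <- 199
  tab <- rrpp_test(Y, u$labels, B = B, seed = 3)
  expect_equal(tab$p_perm[tab$term == "individual"], 1 / (B + 1))
})

test_that("rrpp_test is invariant to unit reordering and seed-reproducible", {
  u <- rand_units(seed = 20)
  t1 <- rrpp_test(u$Y, u$labels, B = 49, seed = 5)
  perm <- sample(nrow(u$Y))
  t2 <- rrpp_test(u$Y[perm, ], u$labels[perm, ], B = 49, seed = 5)
  expect_equal(t1$SS, t2$SS, tolerance = 1e-10)
  expect_equal(t1$F, t2$F, tolerance = 1e-10)
  expect_identical(rrpp_test(u$Y, u$labels, B = 49, seed = 5),
                   rrpp_test(u$Y, u$labels, B = 49, seed = 5))
})

test_that("residual scheme on a saturated design returns no p-values", {
  u <- rand_units(seed = 30)
  expect_warning(tab <- rrpp_test(u$Y, u$labels, B = 19, seed = 1,
                                  f_scheme = "residual"),
                 "residual df = 0")
  expect_true(all(is.na(tab$p_perm)))
})

test_that("two-group PERMANOVA handles degenerate and clean cases", {
  # disjoint constant profiles: all variation is between groups
  Y <- rbind(matrix(1, 3, 4), matrix(0, 3, 4))
  g <- rep(c("pool", "pellet"), each = 3)
  expect_warning(res <- two_group_permanova(Y, g, B = 19, seed = 1),
                 "F undefined")
  expect_equal(res$R2, 1)
  expect_true(is.na(res$F))
  expect_true(is.na(res$p))

  expect_error(two_group_permanova(Y, c("a", rep("b", 5)), B = 9, seed = 1),
               "at least 2")

  set.seed(77)
  Y <- matrix(as.numeric(stats::runif(30 * 8) < 0.4), 30, 8)
  g <- rep(c("pool", "pellet"), each = 15)
  res <- two_group_permanova(Y, g, B = 99, seed = 2)
  # McArdle-Anderson identity against the distance-only computation
  n <- nrow(Y)
  ss_tot <- sum(as.matrix(stats::dist(Y))^2) / (2 * n)
  ss_w <- ss_within_from_dist(Y, g)
  expect_equal(res$R2, (ss_tot - ss_w) / ss_tot, tolerance = 1e-10)
  expect_equal(res$F, ((ss_tot - ss_w) / 1) / (ss_w / (n - 2)),
               tolerance = 1e-10)
})

test_that("two-group PERMANOVA agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(123)
  Y <- matrix(as.numeric(stats::runif(24 * 6) < 0.5), 24, 6)
  Y[1:12, 1:2] <- 1  # mild group signal
  g <- rep(c("A", "B"), each = 12)
  res <- two_group_permanova(Y, g, B = 199, seed = 4)
  ref <- vegan::adonis2(stats::dist(Y) ~ g, data = data.frame(g = g),
                        permutations = 199)
  expect_equal(res$F, ref$F[1], tolerance = 1e-8)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-8)
})
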