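make_two_bat_cube <- function() {
  # 2 bats x 15 pellets x 1 PCR x 2 taxa; taxon tA in 3 pellets of b01 only,
  # taxon tB everywhere
  dn <- list(individual = c("b01", "b02"), pellet = sprintf("p%02d", 1:15),
             pcr = "k1", taxon = c("tA", "tB"))
  det <- array(FALSE, c(2, 15, 1, 2), dimnames = dn)
  det["b01", 1:3, "k1", "tA"] <- TRUE
  det[, , , "tB"] <- TRUE
  detection_cube(det, array(TRUE, c(2, 15, 1), dimnames = dn[1:3]))
}

test_that("fo_table reproduces hand-counted descriptors", {
  fo <- fo_table(make_two_bat_cube(), mode = "union")
  a <- fo[fo$taxon == "tA", ]
  expect_equal(a$fo_tot, 0.5)
  expect_equal(a$fo_pel, 0.2)
  expect_equal(a$fo_pellet_overall, 0.1)
  b <- fo[fo$taxon == "tB", ]
  expect_equal(unlist(b[c("fo_tot", "fo_pel", "fo_pellet_overall")]),
               c(fo_tot = 1, fo_pel = 1, fo_pellet_overall = 1))
})

test_that("fo_table handles absent taxa and pool detections", {
  cube <- make_two_bat_cube()
  cube$detected[, , , "tA"] <- FALSE
  pdet <- array(FALSE, c(2, 1, 2),
                dimnames = list(individual = c("b01", "b02"), pcr = "k1",
                                taxon = c("tA", "tB")))
  pdet[, , "tB"] <- TRUE
  pools <- pool_block(pdet, matrix(TRUE, 2, 1,
                                   dimnames = list(c("b01", "b02"), "k1")))
  fo <- fo_table(cube, pools, mode = "union")
  a <- fo[fo$taxon == "tA", ]
  expect_equal(a$fo_tot, 0)
  expect_true(is.na(a$fo_pel))
  expect_equal(fo$fo_pool, c(0, 1))
})

test_that("resample_fo is exact for ubiquitous taxa and matches the binomial oracle", {
  mats <- collapse_pcrs(make_two_bat_cube(), "union")
  # tB in every pellet of every bat: every replicate returns FOtot = 1
  expect_true(all(resample_fo(mats, "tB", n = 1, reps = 200, seed = 1) == 1))
  expect_true(all(resample_fo(mats, "tB", n = 7, reps = 200, seed = 1) == 1))

  # one bat, taxon in 5/15 pellets, n = 1: P(detect) = 1/3
  v <- resample_fo(mats["b01"], "tA", n = 1, reps = 10000, seed = 2)
  # (tA sits in 3/15 pellets of b01 -> P = 0.2); also test a 5/15 matrix
  expect_equal(mean(v), 0.2, tolerance = 3 * sqrt(0.2 * 0.8 / 10000) / 0.2)
  m5 <- im_from(cbind(c(rep(1, 5), rep(0, 10))), id = "b01")
  colnames(m5$mat) <- "tA"
  v5 <- resample_fo(list(m5), "tA", n = 1, reps = 10000, seed = 3)
  expect_equal(mean(v5), 1 / 3, tolerance = 3 * sqrt((1 / 3) * (2 / 3) / 10000) * 3)

  # large n converges to FOtot
  v <- resample_fo(mats, "tA", n = 500, reps = 500, seed = 4)
  expect_equal(mean(v), 0.5, tolerance = 1e-6)
})

test_that("error_curve matches closed forms and is seed-deterministic", {
  mats <- collapse_pcrs(make_two_bat_cube(), "union")
  err <- error_curve(mats, reps = 3000, seed = 5)
  # tB has within-individual frequency 1 -> zero error at every n
  expect_true(all(err$mean_error[err$taxon == "tB"] == 0))
  expect_true(all(err$sd_error[err$taxon == "tB"] == 0))

  # single-bat cube with m_t = 5, m = 15, n = 2: relative e_2 = 4/9
  m5 <- im_from(cbind(tA = c(rep(1, 5), rep(0, 10))), id = "b01")
  e <- error_curve(list(m5), taxa = "tA", n_range = 2, reps = 20000, seed = 6)
  p2 <- 1 - (10 / 15)^2
  mc_se <- sqrt(p2 * (1 - p2) / 20000)
  expect_equal(e$mean_error, 4 / 9, tolerance = 3 * mc_se / (4 / 9))

  expect_identical(error_curve(mats, reps = 100, seed = 9),
                   error_curve(mats, reps = 100, seed = 9))
  expect_error(error_curve(mats, taxa = "tA", n_range = 1, reps = 10, seed = 1,
                           error_kind = "absolute"), NA)
})

test_that("relative errors never exceed 1 and absolute/relative agree", {
  sim <- generate_dataset(synth_params(I = 8, J = 6, K = 1, T = 30, seed = 44))
  mats <- collapse_pcrs(sim$cube, "union")
  rel <- error_curve(mats, reps = 400, seed = 1, error_kind = "relative")
  abs_ <- error_curve(mats, reps = 400, seed = 1, error_kind = "absolute")
  expect_true(all(rel$mean_error <= 1 + 1e-12))
  fo <- fo_from_matrices(mats)
  fom <- fo$fo_tot[match(rel$taxon, fo$taxon)]
  expect_equal(rel$mean_error * fom, abs_$mean_error, tolerance = 1e-12)
})

test_that("pool_error behaves at its fixed points", {
  fo <- data.frame(taxon = c("a", "b", "c"), fo_tot = c(0.5, 0.4, 0),
                   fo_pel = c(0.3, 0.2, NA), fo_pool = c(0.5, 0, 0))
  pe <- pool_error(fo)
  expect_equal(pe$error[pe$taxon == "a"], 0)
  expect_equal(pe$error[pe$taxon == "b"], 1)
  expect_false("c" %in% pe$taxon)  # FOtot = 0 excluded
  pa <- pool_error(fo, "absolute")
  expect_equal(pa$error, c(0, 0.4))
})

test_that("paired_t reproduces classical values", {
  y <- c(4.2, 1.1, 7.3, 2.2)
  expect_equal(paired_t(y, y), list(t = 0, df = 3, p = 1))

  x <- c(1, 2, 3)
  res <- paired_t(x + c(5, 5, 5), c(5, 5, 5))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  ref <- stats::t.test(x + c(5, 5, 5), c(5, 5, 5), paired = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)

  a <- c(1, 3, 2, 5); b <- c(0, 4, 1, 2)
  expect_equal(paired_t(a, b)$t, -paired_t(b, a)$t)
  expect_error(paired_t(c(1, 2), c(0, 1)), "zero-variance")
})
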