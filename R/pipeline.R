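#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. All randomness is
#' driven by stage seeds derived deterministically from the single `seed`
#' field, so a config reproduces its outputs byte-for-byte.
#'
#' @param input path to a long-format detection CSV, or `NULL` to simulate.
#' @param synth a [synth_params] used when `input` is `NULL`.
#' @param collapse PCR collapse mode (`"single_random"` by default: the one
#'   random PCR per pellet convention).
#' @param reps_accum Chao2 resampling replicates per (individual, n).
#' @param reps_fo Monte-Carlo replicates of the FO subsampling procedure.
#' @param perms RRPP permutations.
#' @param error_kind `"relative"` or `"absolute"` FO error.
#' @param filter_threshold per-PCR relative-abundance filter (applied only
#'   when the input file carries read counts).
#' @param seed master integer seed.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synth = synth_params(),
                            collapse = c("single_random", "union"),
                            reps_accum = 200L, reps_fo = 10000L,
                            perms = 999L,
                            error_kind = c("relative", "absolute"),
                            filter_threshold = 0.01, seed = 1L,
                            out_dir = "dietrep_out") {
  structure(list(input = input, synth = synth,
                 collapse = match.arg(collapse),
                 reps_accum = as.integer(reps_accum),
                 reps_fo = as.integer(reps_fo), perms = as.integer(perms),
                 error_kind = match.arg(error_kind),
                 filter_threshold = filter_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# Stage seeds: deterministic small offsets from the master seed, kept well
# below .Machine$integer.max.
.stage_seed <- function(seed, stage) (as.integer(seed) %% 100000L) * 13L + stage

#' Run the full replication-effects pipeline
#'
#' Simulate (or ingest and filter) the detection data, collapse PCRs, then
#' compute: the mean accumulation curve (observed + Chao2) with the
#' pellets-for-80%/95% summaries; the FO table and the pellet-subsampling
#' error curves; the pool error comparison and paired t test of pool vs
#' separate-pellet richness; the three-level nested PERMANOVA with RRPP; the
#' pools-vs-pellets one-factor PERMANOVA; the beta regression of FO error
#' rates; and the pool-detection logistic fit. Writes `curve.csv`, `fo.csv`,
#' `errors.csv`, `anova.csv`, `fit.json` and `report.md` into
#' `config$out_dir`.
#'
#' @param config a [pipeline_config].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all result objects.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  if (is.null(config$input)) {
    say("stage simulate: seed %d", config$synth$seed)
    sim <- generate_dataset(config$synth)
    cube <- sim$cube; pools <- sim$pools; truth <- sim$truth
  } else {
    say("stage ingest: %s", config$input)
    dat <- read_long_table(config$input,
                           filter_threshold = config$filter_threshold)
    cube <- dat$cube; pools <- dat$pools; truth <- NULL
  }

  collapse_seed <- .stage_seed(seed, 1L)
  say("stage collapse: mode=%s seed=%d", config$collapse, collapse_seed)
  mats <- collapse_pcrs(cube, config$collapse, seed = collapse_seed)

  say("stage accumulate: reps=%d", config$reps_accum)
  curve <- mean_curve(mats, reps = config$reps_accum,
                      seed = .stage_seed(seed, 2L))
  n80 <- pellets_for_fraction(curve, 0.80)
  n95 <- pellets_for_fraction(curve, 0.95)
  utils::write.csv(curve, file.path(config$out_dir, "curve.csv"),
                   row.names = FALSE)

  say("stage fo")
  fo <- fo_table(cube, pools, mode = config$collapse, seed = collapse_seed)
  utils::write.csv(fo, file.path(config$out_dir, "fo.csv"), row.names = FALSE)

  say("stage fo-error: reps=%d kind=%s", config$reps_fo, config$error_kind)
  errors <- error_curve(mats, reps = config$reps_fo,
                        seed = .stage_seed(seed, 3L),
                        error_kind = config$error_kind)
  utils::write.csv(errors, file.path(config$out_dir, "errors.csv"),
                   row.names = FALSE)

  # pool comparisons (when pools are present)
  pool_cmp <- NULL
  if (!is.null(pools)) {
    pm <- collapse_pools(pools, config$collapse, seed = collapse_seed + 1L)
    rich_sep <- vapply(mats, function(x) sum(colSums(x$mat) > 0), numeric(1))
    rich_pool <- rowSums(pm)
    tt <- paired_t(rich_sep, rich_pool)
    perr <- pool_error(fo, config$error_kind)
    e14 <- errors[errors$n == max(errors$n), ]
    cmp_t <- tryCatch(
      paired_t(e14$mean_error[match(perr$taxon, e14$taxon)], perr$error),
      error = function(e) NULL)
    # two-group composition test on collapsed units: all pellets + all pools
    Yp <- do.call(rbind, lapply(mats, function(x) x$mat * 1))
    Yq <- pm[, colnames(Yp), drop = FALSE] * 1
    tg <- two_group_permanova(rbind(Yp, Yq),
                              c(rep("pellet", nrow(Yp)), rep("pool", nrow(Yq))),
                              B = config$perms, seed = .stage_seed(seed, 4L))
    pool_cmp <- list(richness_t = tt, rich_sep = rich_sep,
                     rich_pool = rich_pool, pool_errors = perr,
                     error14_vs_pool_t = cmp_t, two_group = tg)
  }

  say("stage permanova: B=%d", config$perms)
  units <- cube_to_units(cube)
  anova <- rrpp_test(units$Y, units$labels, B = config$perms,
                     seed = .stage_seed(seed, 5L))
  utils::write.csv(as.data.frame(anova),
                   file.path(config$out_dir, "anova.csv"), row.names = FALSE)

  say("stage betareg")
  des <- beta_design(errors, fo, clip = "zero")
  bfit <- fit_betareg(des$X, des$y)

  pool_fit <- NULL
  if (!is.null(pools)) {
    pm <- collapse_pools(pools, config$collapse, seed = collapse_seed + 1L)
    pd <- .pool_detection_data(mats, pm)
    pool_fit <- tryCatch(fit_pool_detection(pd$detected, pd$fopel),
                         error = function(e) { say("pool logistic: %s",
                                                   conditionMessage(e)); NULL })
  }

  fit_json <- list(
    betareg = list(coefficients = as.list(bfit$coefficients),
                   se = as.list(bfit$se), phi = bfit$phi,
                   loglik = bfit$loglik, pseudo_r2 = bfit$pseudo_r2,
                   converged = bfit$converged),
    pool_logistic = if (!is.null(pool_fit))
      list(coefficients = as.list(pool_fit$coefficients),
           se = as.list(pool_fit$se), z = as.list(pool_fit$z))
  )
  jsonlite::write_json(fit_json, file.path(config$out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  res <- list(cube = cube, pools = pools, truth = truth, mats = mats,
              curve = curve, n80 = n80, n95 = n95, fo = fo, errors = errors,
              anova = anova, betareg = bfit, pool_fit = pool_fit,
              pool_cmp = pool_cmp, config = config)
  .write_report(res, file.path(config$out_dir, "report.md"))
  say("done: outputs in %s", config$out_dir)
  invisible(res)
}

# Per-(individual, taxon) pool detection flags for pairs where the taxon was
# detected in that individual's separate pellets.
.pool_detection_data <- function(mats, pool_matrix) {
  rows <- lapply(seq_along(mats), function(i) {
    cnt <- colSums(mats[[i]]$mat)
    keep <- cnt > 0
    data.frame(individual = mats[[i]]$individual_id,
               taxon = names(cnt)[keep],
               fopel = cnt[keep] / mats[[i]]$m,
               detected = as.numeric(pool_matrix[i, names(cnt)[keep]]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

.write_report <- function(res, path) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c(
    "# dietrep pipeline report", "",
    sprintf("- master seed: %d", res$config$seed),
    sprintf("- collapse: %s; FO reps: %d; RRPP permutations: %d",
            res$config$collapse, res$config$reps_fo, res$config$perms), "",
    "## Diet diversity accumulation",
    sprintf("- mean observed richness at m pellets: %s",
            fmt(res$curve$mean_obs[nrow(res$curve)])),
    sprintf("- pellets for 80%% / 95%% of full-sample richness: %d / %d",
            res$n80, res$n95), "",
    "## Nested PERMANOVA (RRPP)", "",
    paste(utils::capture.output(print(as.data.frame(res$anova))),
          collapse = "\n"), "",
    "## FO error",
    sprintf("- mean %s error at n=1: %s; at n=%d: %s",
            res$config$error_kind,
            fmt(mean(res$errors$mean_error[res$errors$n == 1])),
            max(res$errors$n),
            fmt(mean(res$errors$mean_error[res$errors$n == max(res$errors$n)]))),
    "",
    "## Beta regression of FO error rates",
    sprintf("- pseudo R2: %s; phi: %s; converged: %s",
            fmt(res$betareg$pseudo_r2, 4), fmt(res$betareg$phi, 2),
            res$betareg$converged), ""
  )
  if (!is.null(res$pool_cmp)) {
    tt <- res$pool_cmp$richness_t
    lines <- c(lines,
      "## Pools vs separate pellets",
      sprintf("- mean richness: pools %s vs separate %s (paired t = %s, df = %d, p = %.2g)",
              fmt(mean(res$pool_cmp$rich_pool), 1),
              fmt(mean(res$pool_cmp$rich_sep), 1),
              fmt(tt$t, 2), tt$df, tt$p),
      sprintf("- mean pool error: %s (vs %s at n = %d separate pellets)",
              fmt(mean(res$pool_cmp$pool_errors$error)),
              fmt(mean(res$errors$mean_error[res$errors$n == max(res$errors$n)])),
              max(res$errors$n)),
      sprintf("- two-group PERMANOVA pools vs pellets: F = %s, R2 = %s, p = %.2g",
              fmt(res$pool_cmp$two_group$F, 2),
              fmt(res$pool_cmp$two_group$R2, 4), res$pool_cmp$two_group$p),
      "")
  }
  if (!is.null(res$pool_fit)) {
    lines <- c(lines,
      "## Pool detection logistic",
      sprintf("- slope (fopel): %s (SE %s, z = %s)",
              fmt(res$pool_fit$coefficients[["fopel"]], 3),
              fmt(res$pool_fit$se[["fopel"]], 3),
              fmt(res$pool_fit$z[["fopel"]], 2)), "")
  }
  writeLines(lines, path)
  invisible(path)
}
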