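#' Parameters of the hierarchical detection simulator
#'
#' The generator emulates a nested faecal-pellet metabarcoding design: `I`
#' individuals, `J` pellets per individual plus one `J`-pellet pool per
#' individual, and `K` PCR replicates per pellet/pool (defaults 20 x 15 x 3,
#' i.e. 960 PCR-level sampling units). Diet heterogeneity is produced by a
#' taxon-specific population consumption probability `q_t` (drawn once from
#' `Beta(0.4, 2.5)` when not supplied) and an individual-by-taxon
#' within-individual pellet frequency `r_it ~ Beta(r_shape[1], r_shape[2])`
#' for consumed taxa. PCR detection given pellet presence is near-perfect
#' (`d_pcr`, default 0.97), so replicate PCRs are almost identical. Pool PCRs
#' detect a consumed taxon with probability
#' `plogis(pool_alpha + pool_beta * r_it)`, so pools preferentially recover
#' taxa that are frequent within an individual.
#'
#' @param I,J,K,T design dimensions (individuals, pellets, PCRs, taxa).
#' @param q optional length-`T` vector of per-taxon consumption
#'   probabilities; drawn from `Beta(0.4, 2.5)` when `NULL`.
#' @param r_shape length-2 shape vector of the Beta distribution of `r_it`.
#' @param d_pcr per-PCR detection probability given presence in the pellet.
#' @param fp_pcr per-PCR false-positive probability given absence.
#' @param pool_alpha,pool_beta intercept and slope of the pool-detection
#'   logistic on `r_it` (the slope default mirrors the magnitude estimated
#'   from real pool data, ~6).
#' @param seed integer seed; the generator uses one global RNG stream.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(I = 20L, J = 15L, K = 3L, T = 150L, q = NULL,
                         r_shape = c(1.2, 3.0), d_pcr = 0.97, fp_pcr = 0,
                         pool_alpha = -3.0, pool_beta = 6.0, seed = 1L) {
  stopifnot(I >= 1, J >= 1, K >= 1, T >= 1)
  stopifnot(d_pcr >= 0, d_pcr <= 1, fp_pcr >= 0, fp_pcr <= 1)
  stopifnot(length(r_shape) == 2, all(r_shape > 0), is.finite(pool_beta))
  if (!is.null(q)) stopifnot(length(q) == T, all(q >= 0), all(q <= 1))
  structure(list(I = as.integer(I), J = as.integer(J), K = as.integer(K),
                 T = as.integer(T), q = q, r_shape = r_shape, d_pcr = d_pcr,
                 fp_pcr = fp_pcr, pool_alpha = pool_alpha,
                 pool_beta = pool_beta, seed = as.integer(seed)),
            class = "synth_params")
}

#' Generate a synthetic hierarchical detection dataset
#'
#' Draw order (one seeded RNG stream, so datasets are bit-reproducible):
#' taxon consumption probabilities `q` (if not supplied), then consumption
#' indicators `consumed_it`, then within-individual frequencies `r_it`
#' (a full I x T block is drawn and zeroed where not consumed), then pellet
#' presences, pellet-PCR detections and pool-PCR detections.
#'
#' @param params a [synth_params] object.
#' @return list with `cube` ([detection_cube]), `pools` ([pool_block]) and
#'   `truth` (class `synth_truth`: `consumed`, `r`, `q`, plus realized
#'   `fo_tot`/`fo_pel` per taxon).
#' @export
generate_dataset <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)
  q <- if (is.null(p$q)) stats::rbeta(p$T, 0.4, 2.5) else p$q

  consumed <- matrix(stats::rbinom(p$I * p$T, 1L, rep(q, each = p$I)),
                     p$I, p$T) == 1L
  r <- matrix(stats::rbeta(p$I * p$T, p$r_shape[1], p$r_shape[2]), p$I, p$T)
  r[!consumed] <- 0

  inds <- sprintf("bat%02d", seq_len(p$I))
  pellets <- sprintf("p%02d", seq_len(p$J))
  pcrs <- sprintf("pcr%d", seq_len(p$K))
  taxa <- sprintf("taxon%03d", seq_len(p$T))

  # pellet presence: presence[i, j, t] ~ Bern(r_it), expanded along pellet axis
  prob_pres <- aperm(array(r, c(p$I, p$T, p$J)), c(1, 3, 2))
  presence <- array(stats::rbinom(length(prob_pres), 1L, as.vector(prob_pres)),
                    dim(prob_pres)) == 1L

  pres4 <- aperm(array(presence, c(p$I, p$J, p$T, p$K)), c(1, 2, 4, 3))
  prob_det <- p$d_pcr * pres4 + p$fp_pcr * (1 - pres4)
  detected <- array(stats::rbinom(length(prob_det), 1L, as.vector(prob_det)),
                    dim(prob_det),
                    dimnames = list(individual = inds, pellet = pellets,
                                    pcr = pcrs, taxon = taxa)) == 1L
  mask <- array(TRUE, c(p$I, p$J, p$K),
                dimnames = list(individual = inds, pellet = pellets, pcr = pcrs))
  cube <- detection_cube(detected, mask)

  p_pool <- stats::plogis(p$pool_alpha + p$pool_beta * r) * consumed
  pool3 <- aperm(array(p_pool, c(p$I, p$T, p$K)), c(1, 3, 2))
  pdet <- array(stats::rbinom(length(pool3), 1L, as.vector(pool3)), dim(pool3),
                dimnames = list(individual = inds, pcr = pcrs, taxon = taxa)) == 1L
  pmask <- matrix(TRUE, p$I, p$K, dimnames = list(inds, pcrs))
  pools <- pool_block(pdet, pmask)

  fo_tot <- colMeans(consumed)
  fo_pel <- vapply(seq_len(p$T), function(t) {
    ci <- consumed[, t]
    if (!any(ci)) NA_real_ else mean(r[ci, t])
  }, numeric(1))
  truth <- structure(list(consumed = consumed, r = r, q = q,
                          fo_tot = fo_tot, fo_pel = fo_pel, taxa = taxa),
                     class = "synth_truth")
  list(cube = cube, pools = pools, truth = truth)
}

#' Ground-truth frequency-of-occurrence table
#'
#' `fo_tot(t)` is the fraction of individuals that consumed taxon t;
#' `fo_pel(t)` the mean within-individual pellet frequency over consuming
#' individuals (`NA` for taxa consumed by nobody).
#'
#' @param truth a `synth_truth` object from [generate_dataset].
#' @return data frame with columns `taxon`, `fo_tot`, `fo_pel`.
#' @export
truth_fo <- function(truth) {
  stopifnot(inherits(truth, "synth_truth"))
  data.frame(taxon = truth$taxa, fo_tot = truth$fo_tot,
             fo_pel = truth$fo_pel, stringsAsFactors = FALSE)
}
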