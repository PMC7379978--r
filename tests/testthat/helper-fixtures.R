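# In-code fixtures: small randomly filled cubes and incidence matrices.

rand_cube <- function(I = 3, J = 4, K = 2, T = 5, p = 0.3, seed = 1) {
  set.seed(seed)
  dn <- list(individual = sprintf("b%02d", 1:I),
             pellet = sprintf("p%02d", 1:J),
             pcr = sprintf("k%d", 1:K),
             taxon = sprintf("t%02d", 1:T))
  det <- array(stats::runif(I * J * K * T) < p, c(I, J, K, T), dimnames = dn)
  mask <- array(TRUE, c(I, J, K), dimnames = dn[1:3])
  detection_cube(det, mask)
}

rand_im <- function(m = 5, T = 6, p = 0.4, seed = 1, id = "b01") {
  set.seed(seed)
  mat <- matrix(stats::runif(m * T) < p, m, T,
                dimnames = list(sprintf("p%02d", 1:m), sprintf("t%02d", 1:T)))
  incidence_matrix(id, mat)
}

im_from <- function(mat, id = "b01") {
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("t%02d", seq_len(ncol(mat)))
  incidence_matrix(id, mat == 1)
}

# exhaustive mean observed richness over all choose(m, n) pellet subsets
exhaustive_richness <- function(mat, n) {
  subs <- utils::combn(nrow(mat), n)
  mean(apply(subs, 2, function(ix) sum(colSums(mat[ix, , drop = FALSE]) > 0)))
}
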