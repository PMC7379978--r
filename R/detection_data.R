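#' @keywords internal
"_PACKAGE"

# Default column-name schema for long-format detection tables.
.default_schema <- c(
  individual = "individual", unit = "unit", unit_kind = "unit_kind",
  pcr = "pcr", taxon = "taxon", detected = "detected", reads = "reads"
)

#' Construct a detection cube
#'
#' A detection cube is the central container of the package: a boolean
#' incidence tensor indexed (individual, pellet, PCR, taxon) together with a
#' presence mask marking which (individual, pellet, PCR) sampling units exist.
#' Ragged designs (unequal pellets or PCRs per individual) are represented by
#' the mask; cells of absent units are explicit `FALSE` and never consumed by
#' downstream estimators.
#'
#' @param detected logical 4-d array with `dimnames` `individual`, `pellet`,
#'   `pcr`, `taxon`.
#' @param mask logical 3-d array over (individual, pellet, pcr); `TRUE` where
#'   the sampling unit was actually assayed.
#' @return An object of class `detection_cube`.
#' @export
detection_cube <- function(detected, mask) {
  stopifnot(is.array(detected), length(dim(detected)) == 4L, is.logical(detected))
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  stopifnot(all(dim(mask) == dim(detected)[1:3]))
  if (anyDuplicated(dimnames(detected)[[4]]))
    stop("duplicated taxon ids in cube")
  structure(list(detected = detected, mask = mask), class = "detection_cube")
}

#' Construct a pool block
#'
#' Pool samples (many pellets mixed before extraction) have the same axes as a
#' [detection_cube] minus the pellet axis: one pool per individual, with K PCR
#' replicates.
#'
#' @param detected logical 3-d array (individual, pcr, taxon).
#' @param mask logical matrix (individual, pcr).
#' @return An object of class `pool_block`.
#' @export
pool_block <- function(detected, mask) {
  stopifnot(is.array(detected), length(dim(detected)) == 3L, is.logical(detected))
  stopifnot(is.matrix(mask), all(dim(mask) == dim(detected)[1:2]))
  structure(list(detected = detected, mask = mask), class = "pool_block")
}

#' @export
print.detection_cube <- function(x, ...) {
  d <- dim(x$detected)
  cat(sprintf(
    "detection_cube: %d individuals x %d pellets x %d PCRs x %d taxa (%d units present)\n",
    d[1], d[2], d[3], d[4], sum(x$mask)))
  invisible(x)
}

#' @export
print.pool_block <- function(x, ...) {
  d <- dim(x$detected)
  cat(sprintf("pool_block: %d pools x %d PCRs x %d taxa\n", d[1], d[2], d[3]))
  invisible(x)
}

.resolve_schema <- function(schema) {
  s <- .default_schema
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), names(s))
    if (length(bad)) stop("unknown schema fields: ", paste(bad, collapse = ", "))
    s[names(schema)] <- schema
  }
  s
}

#' Read a long-format detection table
#'
#' Reads a delimited text file (comma-separated by default, tab for `.tsv`)
#' with one row per (individual, unit, PCR, taxon) cell and either a 0/1
#' `detected` column or a non-negative `reads` column, and assembles the
#' [detection_cube] (rows with `unit_kind == "pellet"`) and [pool_block]
#' (rows with `unit_kind == "pool"`). Axis orderings are stable and sorted.
#' When reads are supplied, detection is `reads > 0`; the relative-abundance
#' filter is applied separately (see [apply_relative_abundance_filter]) on the
#' record table before cube construction.
#'
#' @param path file path.
#' @param schema optional named character vector remapping the standard column
#'   names (`individual`, `unit`, `unit_kind`, `pcr`, `taxon`, `detected`,
#'   `reads`) to the file's columns.
#' @param filter_threshold if non-`NULL` and a reads column is present, the
#'   per-PCR relative-abundance filter is applied at this threshold first.
#' @return list with elements `cube` ([detection_cube]) and `pools`
#'   ([pool_block] or `NULL` when the file has no pool rows).
#' @export
read_long_table <- function(path, schema = NULL, filter_threshold = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  records_to_cube(df, schema = schema, filter_threshold = filter_threshold)
}

#' Assemble a detection cube from a record data frame
#'
#' @param records data frame of long-format records (see [read_long_table]).
#' @inheritParams read_long_table
#' @return list(cube, pools) as for [read_long_table].
#' @export
records_to_cube <- function(records, schema = NULL, filter_threshold = NULL) {
  s <- .resolve_schema(schema)
  need <- s[c("individual", "unit", "unit_kind", "pcr", "taxon")]
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  has_det <- s[["detected"]] %in% names(records)
  has_reads <- s[["reads"]] %in% names(records)
  if (!has_det && !has_reads)
    stop("need either a detected or a reads column")

  df <- data.frame(
    individual = as.character(records[[s[["individual"]]]]),
    unit = as.character(records[[s[["unit"]]]]),
    unit_kind = as.character(records[[s[["unit_kind"]]]]),
    pcr = as.character(records[[s[["pcr"]]]]),
    taxon = as.character(records[[s[["taxon"]]]]),
    stringsAsFactors = FALSE
  )
  bad_kind <- setdiff(unique(df$unit_kind), c("pellet", "pool"))
  if (length(bad_kind))
    stop("unknown unit_kind: ", paste(bad_kind, collapse = ", "))

  key <- paste(df$individual, df$unit, df$pcr, df$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    k <- strsplit(key[duplicated(key)][1], "\r", fixed = TRUE)[[1]]
    stop(sprintf("duplicate key row: individual=%s unit=%s pcr=%s taxon=%s",
                 k[1], k[2], k[3], k[4]))
  }

  if (has_reads) {
    reads <- as.numeric(records[[s[["reads"]]]])
    if (any(is.na(reads)) || any(reads < 0)) stop("reads must be non-negative")
    df$reads <- reads
    if (!is.null(filter_threshold))
      df <- apply_relative_abundance_filter(df, filter_threshold)
    df$detected <- df$reads > 0
  } else {
    det <- records[[s[["detected"]]]]
    if (!all(det %in% c(0, 1, TRUE, FALSE)))
      stop("detected column must be 0/1")
    df$detected <- as.logical(det)
  }

  taxa <- sort(unique(df$taxon))
  pel <- df[df$unit_kind == "pellet", , drop = FALSE]
  poo <- df[df$unit_kind == "pool", , drop = FALSE]

  inds <- sort(unique(df$individual))
  units <- sort(unique(pel$unit))
  pcrs <- sort(unique(df$pcr))
  I <- length(inds); J <- length(units); K <- length(pcrs); Tt <- length(taxa)

  detected <- array(FALSE, c(I, J, K, Tt),
                    dimnames = list(individual = inds, pellet = units,
                                    pcr = pcrs, taxon = taxa))
  mask <- array(FALSE, c(I, J, K),
                dimnames = list(individual = inds, pellet = units, pcr = pcrs))
  if (nrow(pel)) {
    i <- match(pel$individual, inds); j <- match(pel$unit, units)
    k <- match(pel$pcr, pcrs); t <- match(pel$taxon, taxa)
    mask[cbind(i, j, k)] <- TRUE
    detected[cbind(i, j, k, t)] <- pel$detected
  }
  cube <- detection_cube(detected, mask)

  pools <- NULL
  if (nrow(poo)) {
    per_ind <- tapply(poo$unit, poo$individual, function(u) length(unique(u)))
    if (any(per_ind > 1))
      stop("more than one pool unit for individual: ",
           paste(names(per_ind)[per_ind > 1], collapse = ", "))
    pdet <- array(FALSE, c(I, K, Tt),
                  dimnames = list(individual = inds, pcr = pcrs, taxon = taxa))
    pmask <- matrix(FALSE, I, K, dimnames = list(inds, pcrs))
    i <- match(poo$individual, inds); k <- match(poo$pcr, pcrs)
    t <- match(poo$taxon, taxa)
    pmask[cbind(i, k)] <- TRUE
    pdet[cbind(i, k, t)] <- poo$detected
    pools <- pool_block(pdet, pmask)
  }
  list(cube = cube, pools = pools)
}

#' Write a cube (and optional pools) as a long-format CSV
#'
#' Writes every cell of every present sampling unit, so that
#' `read_long_table(write_long_table(x))` round-trips exactly (taxa never
#' detected anywhere are preserved because all cells are written).
#'
#' @param cube a [detection_cube].
#' @param path output file path (`.tsv` for tab-separated).
#' @param pools optional [pool_block].
#' @return `path`, invisibly.
#' @export
write_long_table <- function(cube, path, pools = NULL) {
  dn <- dimnames(cube$detected)
  idx <- which(cube$mask, arr.ind = TRUE)
  Tt <- length(dn$taxon)
  rows <- NULL
  if (nrow(idx)) {
    rep_idx <- idx[rep(seq_len(nrow(idx)), each = Tt), , drop = FALSE]
    t <- rep(seq_len(Tt), times = nrow(idx))
    rows <- data.frame(
      individual = dn$individual[rep_idx[, 1]],
      unit = dn$pellet[rep_idx[, 2]],
      unit_kind = "pellet",
      pcr = dn$pcr[rep_idx[, 3]],
      taxon = dn$taxon[t],
      detected = as.integer(cube$detected[cbind(rep_idx, t)]),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(pools)) {
    pdn <- dimnames(pools$detected)
    pidx <- which(pools$mask, arr.ind = TRUE)
    if (nrow(pidx)) {
      rep_idx <- pidx[rep(seq_len(nrow(pidx)), each = Tt), , drop = FALSE]
      t <- rep(seq_len(Tt), times = nrow(pidx))
      prows <- data.frame(
        individual = pdn$individual[rep_idx[, 1]],
        unit = "pool",
        unit_kind = "pool",
        pcr = pdn$pcr[rep_idx[, 2]],
        taxon = pdn$taxon[t],
        detected = as.integer(pools$detected[cbind(rep_idx, t)]),
        stringsAsFactors = FALSE
      )
      rows <- rbind(rows, prows)
    }
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-PCR relative-abundance read filter
#'
#' Within each PCR (each (individual, unit, pcr) combination), a record is
#' kept iff its reads are at least `threshold` of that PCR's total reads.
#' PCRs with zero total reads are dropped entirely. This is the tabular
#' analogue of discarding haplotypes below 1% of a PCR's reads; it is
#' idempotent because surviving proportions are only renormalised upward.
#'
#' @param records data frame with columns `individual`, `unit`, `pcr`,
#'   `taxon`, `reads` (plus any others, preserved).
#' @param threshold fraction in `[0, 1)`; default 0.01.
#' @return the filtered record data frame.
#' @export
apply_relative_abundance_filter <- function(records, threshold = 0.01) {
  stopifnot(is.data.frame(records), "reads" %in% names(records))
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop("threshold must be in [0, 1)")
  if (any(records$reads < 0)) stop("reads must be non-negative")
  grp <- paste(records$individual, records$unit, records$pcr, sep = "\r")
  tot <- stats::ave(records$reads, grp, FUN = sum)
  keep <- tot > 0 & records$reads / tot >= threshold & records$reads > 0
  if (threshold == 0) keep <- records$reads > 0
  records[keep, , drop = FALSE]
}

#' Per-individual incidence matrix
#'
#' @param individual_id id string.
#' @param mat logical pellets x taxa matrix (rows = sampling units after PCR
#'   collapse).
#' @return object of class `incidence_matrix` with fields `individual_id`,
#'   `mat` and `m` (number of pellets).
#' @export
incidence_matrix <- function(individual_id, mat) {
  stopifnot(is.matrix(mat), is.logical(mat))
  structure(list(individual_id = individual_id, mat = mat, m = nrow(mat)),
            class = "incidence_matrix")
}

#' Collapse PCR replicates into pellet-level incidence matrices
#'
#' Two conventions are supported. `union` marks a taxon present in a pellet if
#' any of its PCRs detected it. `single_random` reproduces the study-design
#' convention of selecting one random PCR replicate per pellet: detection is
#' copied from one seeded, uniformly chosen PCR among those present for that
#' pellet.
#'
#' @param cube a [detection_cube].
#' @param mode `"union"` or `"single_random"`.
#' @param seed integer; required (and used) only for `single_random`.
#' @return named list of [incidence_matrix] objects, one per individual, in
#'   cube order. Pellets with no assayed PCR are dropped from the matrix.
#' @export
collapse_pcrs <- function(cube, mode = c("union", "single_random"), seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "single_random") {
    if (is.null(seed)) stop("single_random collapse requires a seed")
    set.seed(as.integer(seed))
  }
  dn <- dimnames(cube$detected)
  I <- dim(cube$detected)[1]
  out <- vector("list", I)
  names(out) <- dn$individual
  for (i in seq_len(I)) {
    pj <- which(apply(cube$mask[i, , , drop = FALSE], 2, any))
    mat <- matrix(FALSE, length(pj), length(dn$taxon),
                  dimnames = list(dn$pellet[pj], dn$taxon))
    for (r in seq_along(pj)) {
      j <- pj[r]
      ks <- which(cube$mask[i, j, ])
      if (mode == "union") {
        mat[r, ] <- apply(cube$detected[i, j, ks, , drop = FALSE], 4, any)
      } else {
        k <- if (length(ks) == 1L) ks else ks[sample.int(length(ks), 1L)]
        mat[r, ] <- cube$detected[i, j, k, ]
      }
    }
    out[[i]] <- incidence_matrix(dn$individual[i], mat)
  }
  out
}

#' Collapse pool PCR replicates
#'
#' Same selection machinery as [collapse_pcrs], applied to the pool block:
#' returns one detection vector per individual's pool.
#'
#' @inheritParams collapse_pcrs
#' @param pools a [pool_block].
#' @return logical individuals x taxa matrix.
#' @export
collapse_pools <- function(pools, mode = c("union", "single_random"), seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "single_random") {
    if (is.null(seed)) stop("single_random collapse requires a seed")
    set.seed(as.integer(seed))
  }
  dn <- dimnames(pools$detected)
  I <- dim(pools$detected)[1]
  out <- matrix(FALSE, I, length(dn$taxon), dimnames = dn[c(1, 3)])
  for (i in seq_len(I)) {
    ks <- which(pools$mask[i, ])
    if (!length(ks)) next
    if (mode == "union") {
      out[i, ] <- apply(pools$detected[i, ks, , drop = FALSE], 3, any)
    } else {
      k <- if (length(ks) == 1L) ks else ks[sample.int(length(ks), 1L)]
      out[i, ] <- pools$detected[i, k, ]
    }
  }
  out
}

#' Incidence frequency counts
#'
#' Computes, from one individual's pellet x taxon incidence matrix, the
#' per-taxon incidence counts `m_t` (number of pellets containing taxon t)
#' and the summary counts consumed by the Chao2 estimator: observed richness
#' `S_obs`, uniques `Q1` (taxa in exactly one pellet) and duplicates `Q2`
#' (taxa in exactly two).
#'
#' @param x an [incidence_matrix] (or a plain logical matrix).
#' @return list with `m_t`, `S_obs`, `Q1`, `Q2`, `m`.
#' @export
incidence_counts <- function(x) {
  mat <- if (inherits(x, "incidence_matrix")) x$mat else x
  m_t <- colSums(mat)
  list(m_t = m_t,
       S_obs = sum(m_t > 0),
       Q1 = sum(m_t == 1),
       Q2 = sum(m_t == 2),
       m = nrow(mat))
}

# Flatten the PCR-level cube to a unit x taxon 0/1 matrix plus nested labels
# (one row per present (individual, pellet, pcr) unit), the input shape the
# PERMANOVA functions consume.

#' Flatten a detection cube to PCR-level units
#'
#' @param cube a [detection_cube].
#' @return list with `Y` (numeric 0/1 units x taxa matrix) and `labels`
#'   (data frame with columns `individual`, `pellet`, `pcr`).
#' @export
cube_to_units <- function(cube) {
  dn <- dimnames(cube$detected)
  idx <- which(cube$mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  Tt <- length(dn$taxon)
  Y <- matrix(0, nrow(idx), Tt, dimnames = list(NULL, dn$taxon))
  for (r in seq_len(nrow(idx)))
    Y[r, ] <- as.numeric(cube$detected[idx[r, 1], idx[r, 2], idx[r, 3], ])
  labels <- data.frame(
    individual = dn$individual[idx[, 1]],
    pellet = dn$pellet[idx[, 2]],
    pcr = dn$pcr[idx[, 3]],
    stringsAsFactors = FALSE
  )
  list(Y = Y, labels = labels)
}
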