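# Base-stacking detection and the per-base stacking factor q_stacking,
# plus the pairwise-RMSD ensemble comparison.

ring_atoms_of <- function(base) {
  if (base %in% c("A", "G")) c("N9", "C8", "N7", "C5", "C4", "C6", "N1",
                               "C2", "N3")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
}

base_ring_geometry <- function(conf) {
  n <- n_residues(conf)
  bases <- strsplit(conf$sequence, "")[[1]]
  centers <- matrix(NA_real_, n, 3)
  normals <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    rows <- vapply(ring_atoms_of(bases[i]),
                   function(a) atom_row(conf, i, a), integer(1))
    if (any(rows == 0L)) next  # undefined marker stays NA
    X <- conf$coords[rows, , drop = FALSE]
    ctr <- colMeans(X)
    sv <- svd(sweep(X, 2, ctr))
    centers[i, ] <- ctr
    normals[i, ] <- sv$v[, 3]
  }
  list(centers = centers, normals = normals)
}

#' Detect stacked base pairs and consecutive stacking runs
#'
#' Two bases are stacked iff (i) their ring-center distance is <= `d_max`,
#' (ii) the lateral offset of each center in the other's base plane is
#' < `rho_max`, (iii) the absolute offset along each base normal lies in
#' `[z_min, z_max]`, and (iv) the angle between the ring normals is
#' < `angle_max` degrees. Runs are maximal sets of consecutively stacked
#' bases (pairs i, i+1).
#'
#' @param conf an `rna_conformation`.
#' @param d_max,rho_max,z_min,z_max,angle_max criterion thresholds
#'   (defaults 5.0, 2.5, 2.0, 5.0 Angstrom and 40 degrees).
#' @return object of class `stack_record`: `pairs` (two-column matrix of
#'   stacked base indices), `runs` (list of integer vectors of
#'   consecutively stacked bases), `n_stacked` (per-base run length, 0 if
#'   unstacked), `undefined` (bases with missing ring atoms).
#' @export
detect_stacks <- function(conf, d_max = 5.0, rho_max = 2.5, z_min = 2.0,
                          z_max = 5.0, angle_max = 40) {
  n <- n_residues(conf)
  geo <- base_ring_geometry(conf)
  undefined <- which(is.na(geo$centers[, 1]))
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (i %in% undefined || j %in% undefined) next
    v <- geo$centers[j, ] - geo$centers[i, ]
    d <- sqrt(sum(v^2))
    if (d > d_max) next
    zi <- abs(sum(geo$normals[i, ] * v))
    zj <- abs(sum(geo$normals[j, ] * v))
    if (zi < z_min || zi > z_max || zj < z_min || zj > z_max) next
    rhoi <- sqrt(max(0, d^2 - zi^2))
    rhoj <- sqrt(max(0, d^2 - zj^2))
    if (rhoi >= rho_max || rhoj >= rho_max) next
    cosang <- abs(sum(geo$normals[i, ] * geo$normals[j, ]))
    if (acos(pmin(1, cosang)) * 180 / pi >= angle_max) next
    pairs <- rbind(pairs, c(i, j))
  }
  consec <- rep(FALSE, max(n - 1, 0))
  if (nrow(pairs))
    for (k in seq_len(nrow(pairs)))
      if (pairs[k, 2] == pairs[k, 1] + 1) consec[pairs[k, 1]] <- TRUE
  runs <- list()
  i <- 1
  while (i <= n - 1) {
    if (consec[i]) {
      j <- i
      while (j <= n - 1 && consec[j]) j <- j + 1
      runs[[length(runs) + 1]] <- i:j
      i <- j + 1
    } else i <- i + 1
  }
  n_stacked <- rep(0L, n)
  for (r in runs) n_stacked[r] <- length(r)
  structure(list(pairs = pairs, runs = runs, n_stacked = n_stacked,
                 undefined = undefined, n = n),
            class = "stack_record")
}

#' @export
print.stack_record <- function(x, ...) {
  cat("<stack_record> ", nrow(x$pairs), " stacked pairs, ",
      length(x$runs), " consecutive runs over ", x$n, " bases\n", sep = "")
  invisible(x)
}

#' Per-base stacking factor
#'
#' With c = n/(n-1) for a chain of n bases: unstacked bases score 0; bases
#' in a consecutive run of 2 score 0.25 c, of 3 score 0.5 c, and of
#' n_stacked >= 4 score c - c/(n_stacked - 1).
#'
#' @param record a `stack_record` from [detect_stacks()].
#' @param n chain length (defaults to the record's).
#' @return numeric vector of per-base factors in [0, c].
#' @export
q_stacking <- function(record, n = record$n) {
  if (n < 2) stop("q_stacking undefined for n < 2 (c = n/(n-1))")
  cc <- n / (n - 1)
  ns <- record$n_stacked
  out <- numeric(length(ns))
  out[ns == 2] <- 0.25 * cc
  out[ns == 3] <- 0.5 * cc
  big <- ns >= 4
  out[big] <- cc - cc / (ns[big] - 1)
  out
}

#' Sample pairwise heavy-atom RMSDs between (or within) ensembles
#'
#' RMSD after optimal (unweighted) superposition of all heavy atoms, for
#' `n_pairs` random cross-pairs. With `ensB` identical to `ensA`
#' (within-ensemble mode), self-pairs are excluded.
#'
#' @param ensA,ensB `hcg_ensemble`s with identical sequences and atom
#'   inventories.
#' @param n_pairs number of sampled pairs.
#' @param seed RNG seed.
#' @param exhaustive if TRUE, all cross-pairs are evaluated instead.
#' @return numeric vector of RMSD values, Angstrom.
#' @export
pairwise_rmsd_distribution <- function(ensA, ensB = ensA, n_pairs = 1000,
                                       seed = 1, exhaustive = FALSE) {
  if (!identical(ensA$sequence, ensB$sequence) ||
        !identical(ensA$atoms$name, ensB$atoms$name))
    stop("ensembles have mismatched sequences or atom inventories")
  nA <- n_members(ensA); nB <- n_members(ensB)
  within <- identical(ensA$coords, ensB$coords) && nA > 1
  if (exhaustive) {
    ij <- expand.grid(i = seq_len(nA), j = seq_len(nB))
    if (within) ij <- ij[ij$i != ij$j, ]
  } else {
    ij <- with_seed(seed, {
      i <- sample.int(nA, n_pairs, replace = TRUE)
      j <- sample.int(nB, n_pairs, replace = TRUE)
      if (within) {
        while (any(i == j))
          j[i == j] <- sample.int(nB, sum(i == j), replace = TRUE)
      }
      data.frame(i = i, j = j)
    })
  }
  vapply(seq_len(nrow(ij)), function(k) {
    weighted_superposition(ensA$coords[[ij$i[k]]],
                           ensB$coords[[ij$j[k]]])$wrmsd
  }, numeric(1))
}
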