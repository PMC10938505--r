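# Elementary 3D geometry: dihedrals, internal-coordinate atom placement,
# weighted rigid-body superposition (Kabsch), clash counting.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Dihedral angle of four points
#'
#' Standard IUPAC signed torsion in degrees, in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  b2u <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2u[3] - n1[3] * b2u[2],
          n1[3] * b2u[1] - n1[1] * b2u[3],
          n1[1] * b2u[2] - n1[2] * b2u[1])
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  -rad2deg(ang)
}

# NeRF placement: given positions a-b-c, place d with bond |c-d|, angle
# b-c-d and torsion a-b-c-d (degrees). Inverse of dihedral_angle().
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("degenerate reference frame in atom placement")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Weighted rigid-body superposition (weighted Kabsch)
#'
#' Finds the proper rotation and translation minimizing the weighted sum of
#' squared deviations between `mobile` and `target` point sets.
#'
#' @param mobile,target n x 3 coordinate matrices (Angstrom), n >= 3.
#' @param weights positive per-point weights (default uniform).
#' @return list with `rotation` (3x3, det = +1), `translation` (3-vector)
#'   and `wrmsd`, the weighted RMSD sqrt(sum w d^2 / sum w) after the fit.
#'   The fitted mobile points are `mobile %*% t(rotation) + translation`.
#' @export
weighted_superposition <- function(mobile, target,
                                   weights = rep(1, nrow(mobile))) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (nrow(mobile) != nrow(target))
    stop("mismatched point counts: ", nrow(mobile), " vs ", nrow(target))
  if (nrow(mobile) < 3) stop("need at least 3 points for superposition")
  if (any(weights <= 0) || length(weights) != nrow(mobile))
    stop("weights must be positive, one per point")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  M <- sweep(mobile, 2, cm)
  T <- sweep(target, 2, ct)
  H <- crossprod(M * w, T)  # 3x3 weighted covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10)
    stop("degenerate point set (rank < 2): cannot determine rotation")
  s <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, s))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- ct - as.vector(R %*% cm)
  fitted <- tcrossprod(mobile, R)
  fitted <- sweep(fitted, 2, tr, "+")
  d2 <- rowSums((fitted - target)^2)
  list(rotation = R, translation = tr, wrmsd = sqrt(sum(w * d2)))
}

# Apply rigid transform from weighted_superposition() to an n x 3 matrix.
apply_transform <- function(coords, fit) {
  sweep(tcrossprod(coords, fit$rotation), 2, fit$translation, "+")
}

#' Count steric clashes between two heavy-atom sets
#'
#' A clash is an inter-set pair at distance strictly below `cutoff`.
#' Uses a cell-list neighbor search equivalent to the all-pairs count.
#' Atoms listed in `excluded1`/`excluded2` (row indices) are skipped.
#'
#' @param atoms1,atoms2 n x 3 coordinate matrices (heavy atoms, Angstrom).
#' @param cutoff clash distance in Angstrom (default 2.0).
#' @param excluded1,excluded2 integer row indices to drop before counting.
#' @return integer clash count.
#' @export
detect_clashes <- function(atoms1, atoms2, cutoff = 2.0,
                           excluded1 = integer(), excluded2 = integer()) {
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- as.matrix(atoms1)
  b <- as.matrix(atoms2)
  if (length(excluded1)) a <- a[-excluded1, , drop = FALSE]
  if (length(excluded2)) b <- b[-excluded2, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) return(0L)
  .clash_count_cpp(a, b, cutoff)
}

# Seed-scoped RNG: runs expr with a local seed and restores global state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Deterministic substream seed below 2^31 for (seed, level, slot) triples.
derive_seed <- function(seed, level, slot) {
  as.integer((as.double(seed) * 48271 + level * 1000003 + slot * 7919) %%
               2147483629)
}
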