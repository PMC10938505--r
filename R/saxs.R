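# SAXS forward model: Debye-formula intensities with tabulated atomic form
# factors, Guinier analysis, ensemble averaging, and the scale/offset fit
# against experimental profiles with reduced chi-squared.
#
# q is carried in nm^-1 throughout (coordinates in Angstrom; the conversion
# is internal). Experimental profiles are 3-column text (q, I, sigma).

#' Construct a scattering profile
#'
#' @param q scattering vector grid, nm^-1, strictly increasing, >= 0.
#' @param I intensities (arbitrary units).
#' @param sigma standard errors (same units as I), or NULL for computed
#'   profiles.
#' @return object of class `scattering_profile`.
#' @export
scattering_profile <- function(q, I, sigma = NULL) {
  if (length(q) != length(I)) stop("q and I lengths differ")
  if (any(q < 0) || any(diff(q) <= 0)) stop("q must be increasing and >= 0")
  if (!is.null(sigma)) {
    if (length(sigma) != length(q)) stop("sigma length differs")
    if (any(sigma <= 0)) stop("sigma must be positive where present")
  }
  structure(list(q = as.numeric(q), I = as.numeric(I), sigma = sigma),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat("<scattering_profile> ", length(x$q), " points, q in [",
      min(x$q), ", ", max(x$q), "] nm^-1",
      if (!is.null(x$sigma)) " (with errors)", "\n", sep = "")
  invisible(x)
}

#' Read a 3-column SAXS profile (q, I, sigma)
#'
#' Whitespace-separated text; '#' comments. A 2-column file is read
#' without errors.
#' @param path input file; q in nm^-1 unless `q_unit = "A^-1"` (then
#'   converted).
#' @param q_unit "nm^-1" (default) or "A^-1".
#' @return a `scattering_profile`.
#' @export
read_saxs_profile <- function(path, q_unit = c("nm^-1", "A^-1")) {
  q_unit <- match.arg(q_unit)
  tab <- utils::read.table(path, comment.char = "#")
  q <- tab[[1]]
  if (q_unit == "A^-1") q <- q * 10
  sigma <- if (ncol(tab) >= 3) tab[[3]] else NULL
  if (!is.null(sigma) && all(is.na(sigma))) sigma <- NULL
  scattering_profile(q, tab[[2]], sigma)
}

#' Write a SAXS profile as 3-column text
#' @param profile a `scattering_profile`.
#' @param path output file.
#' @export
write_saxs_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q[nm^-1] I sigma", con)
  sg <- if (is.null(profile$sigma)) rep(NA, length(profile$q))
        else profile$sigma
  writeLines(sprintf("%.8g %.10g %.10g", profile$q, profile$I, sg), con)
  invisible(path)
}

# 4-Gaussian atomic form factor parameterizations (international tables),
# f(s) = sum a_i exp(-b_i s^2) + c with s = q/(4 pi), q in A^-1
.FF <- list(
  C = list(a = c(2.3100, 1.0200, 1.5886, 0.8650),
           b = c(20.8439, 10.2075, 0.5687, 51.6512), c = 0.2156),
  N = list(a = c(12.2126, 3.1322, 2.0125, 1.1663),
           b = c(0.0057, 9.8933, 28.9975, 0.5826), c = -11.529),
  O = list(a = c(3.0485, 2.2868, 1.5463, 0.8670),
           b = c(13.2771, 5.7011, 0.3239, 32.9089), c = 0.2508),
  P = list(a = c(6.4345, 4.1791, 1.7800, 1.4908),
           b = c(1.9067, 27.1570, 0.5260, 68.1645), c = 1.1149)
)

form_factor <- function(element, q_A) {
  p <- .FF[[element]]
  if (is.null(p)) p <- .FF[["C"]]  # fallback for exotic elements
  s2 <- (q_A / (4 * pi))^2
  vapply(s2, function(x) sum(p$a * exp(-p$b * x)) + p$c, numeric(1))
}

#' Debye-formula scattering intensity of one conformation
#'
#' I(q) = sum_a sum_b f_a(q) f_b(q) sinc(q r_ab), exact double sum over
#' heavy atoms. In "point" mode all form factors are 1 (useful for tests:
#' then I(0) = N^2 and the Guinier limit returns the plain coordinate
#' radius of gyration).
#'
#' @param conf an `rna_conformation` (or bare coordinate matrix in point
#'   mode).
#' @param q_grid q values, nm^-1.
#' @param mode "form_factor" (tabulated C/N/O/P factors) or "point".
#' @return a `scattering_profile`.
#' @export
debye_intensity <- function(conf, q_grid, mode = c("form_factor", "point")) {
  mode <- match.arg(mode)
  if (inherits(conf, "rna_conformation")) {
    X <- conf$coords
    elements <- conf$atoms$element
  } else {
    X <- as.matrix(conf)
    elements <- rep("C", nrow(X))
  }
  if (nrow(X) < 1) stop("empty conformation")
  if (any(q_grid < 0)) stop("negative q")
  q_A <- q_grid / 10  # nm^-1 -> A^-1, matching Angstrom coordinates
  if (mode == "point") {
    F <- matrix(1, nrow(X), length(q_A))
  } else {
    F <- matrix(0, nrow(X), length(q_A))
    for (el in unique(elements)) {
      rows <- elements == el
      F[rows, ] <- matrix(form_factor(el, q_A), sum(rows), length(q_A),
                          byrow = TRUE)
    }
  }
  scattering_profile(q_grid, .debye_sum_cpp(X, F, q_A))
}

#' Per-member Debye profiles of an ensemble
#'
#' @param ens an `hcg_ensemble`.
#' @param q_grid q values, nm^-1.
#' @param mode see [debye_intensity()].
#' @return matrix n_members x n_q of intensities.
#' @export
ensemble_intensities <- function(ens, q_grid,
                                 mode = c("form_factor", "point")) {
  mode <- match.arg(mode)
  out <- matrix(0, n_members(ens), length(q_grid))
  for (i in seq_len(n_members(ens)))
    out[i, ] <- debye_intensity(ensemble_member(ens, i), q_grid, mode)$I
  out
}

#' Guinier radius of gyration from the low-q limit
#'
#' R_G = sqrt(-3 * slope) with the slope of ln I versus q^2 evaluated as a
#' numerical first difference on the two smallest q points (optionally a
#' low-q linear fit over `n_points` for noisy data).
#'
#' @param profile a `scattering_profile` (q in nm^-1).
#' @param n_points number of low-q points (default 2 = first difference).
#' @return R_G in Angstrom.
#' @export
guinier_rg <- function(profile, n_points = 2) {
  if (length(profile$q) < n_points || n_points < 2)
    stop("need at least two low-q points")
  q <- profile$q[seq_len(n_points)]
  I <- profile$I[seq_len(n_points)]
  if (any(I <= 0)) stop("nonpositive intensity in the Guinier window")
  if (n_points == 2) {
    slope <- (log(I[2]) - log(I[1])) / (q[2]^2 - q[1]^2)
  } else {
    slope <- stats::coef(stats::lm(log(I) ~ I(q^2)))[2]
  }
  if (slope > 0) stop("positive Guinier slope: R_G undefined")
  sqrt(-3 * slope) * 10  # nm -> Angstrom
}

#' Weighted ensemble average of scattering profiles
#'
#' @param profiles list of `scattering_profile`s on one common q grid, or
#'   a matrix n_members x n_q.
#' @param weights normalized member weights (default uniform).
#' @param q q grid (required if `profiles` is a matrix).
#' @return a `scattering_profile`.
#' @export
ensemble_average_intensity <- function(profiles, weights = NULL, q = NULL) {
  if (is.matrix(profiles)) {
    M <- profiles
    if (is.null(q)) stop("q grid required with matrix input")
  } else {
    q <- profiles[[1]]$q
    for (p in profiles)
      if (!isTRUE(all.equal(p$q, q))) stop("q grid mismatch across profiles")
    M <- do.call(rbind, lapply(profiles, `[[`, "I"))
  }
  if (is.null(weights)) weights <- rep(1 / nrow(M), nrow(M))
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must be normalized")
  scattering_profile(q, as.vector(crossprod(M, weights)))
}

#' Root-mean-square radius of gyration of an ensemble
#'
#' sqrt(sum_i w_i R_G,i^2), the ensemble statistic matched by the Guinier
#' analysis of the averaged intensity.
#'
#' @param rg_values per-member R_G values (Angstrom).
#' @param weights normalized weights (default uniform).
#' @return RMS R_G in Angstrom.
#' @export
rms_rg <- function(rg_values, weights = rep(1 / length(rg_values),
                                            length(rg_values))) {
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must be normalized")
  sqrt(sum(weights * rg_values^2))
}

#' Least-squares scale and offset between computed and measured intensity
#'
#' Fits I_exp(q) = a * I_sim(q) + b by error-weighted linear regression
#' (closed form).
#'
#' @param I_sim computed profile (`scattering_profile` or numeric vector).
#' @param exp experimental `scattering_profile` with errors.
#' @return named vector c(a, b).
#' @export
fit_scale_offset <- function(I_sim, exp) {
  x <- if (inherits(I_sim, "scattering_profile")) I_sim$I else I_sim
  if (length(x) != length(exp$I)) stop("profile length mismatch")
  if (is.null(exp$sigma)) stop("experimental profile needs errors")
  w <- 1 / exp$sigma^2
  y <- exp$I
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  den <- sw * sxx - sx^2
  if (abs(den) < 1e-12 * sw * max(sxx, 1))
    stop("singular fit: computed intensity is constant")
  a <- (sw * sxy - sx * sy) / den
  b <- (sy - a * sx) / sw
  c(a = a, b = b)
}

#' Reduced chi-squared of a scale/offset fit
#'
#' (1/M) sum_j ((I_j - a I_sim,j - b) / sigma_j)^2 over the M data points.
#'
#' @param I_sim computed profile or numeric vector.
#' @param exp experimental `scattering_profile` with errors.
#' @param a,b scale and offset (default from [fit_scale_offset()]).
#' @return dimensionless reduced chi-squared.
#' @export
reduced_chi2 <- function(I_sim, exp, a = NULL, b = NULL) {
  x <- if (inherits(I_sim, "scattering_profile")) I_sim$I else I_sim
  if (is.null(exp$sigma) || any(exp$sigma <= 0))
    stop("experimental profile needs positive errors")
  if (is.null(a) || is.null(b)) {
    ab <- fit_scale_offset(x, exp)
    a <- ab[["a"]]; b <- ab[["b"]]
  }
  mean(((exp$I - a * x - b) / exp$sigma)^2)
}
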