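# Forster transfer efficiency forward models. Three treatments of the
# orientation factor kappa^2: model 1 fixes kappa^2 = 2/3 (fast isotropic
# dye rotation), model 2 additionally averages the interdye distance over
# attached dye conformers before applying model 1 (fast linker dynamics),
# model 3 evaluates r and kappa^2 explicitly per conformation (slow dyes).

#' FRET parameters
#'
#' @param R0 Forster radius in nm (defined at kappa^2 = 2/3; default 5.4).
#' @param tauD donor fluorescence lifetime in ns, in the absence of the
#'   acceptor (default 4).
#' @param kappa2_fixed orientation factor used by models 1-2 (default 2/3).
#' @return object of class `fret_params`.
#' @export
fret_params <- function(R0 = 5.4, tauD = 4, kappa2_fixed = 2 / 3) {
  if (R0 <= 0 || tauD <= 0) stop("R0 and tauD must be positive")
  structure(list(R0 = R0, tauD = tauD, kappa2_fixed = kappa2_fixed),
            class = "fret_params")
}

#' FRET efficiency, model 1 (fixed kappa^2 = 2/3)
#'
#' E = 1 / (1 + (r/R0)^6).
#'
#' @param r interdye distance(s), nm.
#' @param p a [fret_params()].
#' @return efficiency in [0, 1], vectorized over `r`.
#' @export
fret_model1 <- function(r, p = fret_params()) {
  if (any(r <= 0)) stop("r must be positive")
  1 / (1 + (r / p$R0)^6)
}

#' FRET efficiency, model 2 (linker-averaged distance)
#'
#' Averages the interdye distance over the accepted dye-pair placements of
#' one chain, then applies model 1 at the mean distance.
#'
#' @param placements result of [remap_dye_pair()] for one chain, or a
#'   numeric vector of interdye distances (nm).
#' @param p a [fret_params()].
#' @return efficiency (scalar).
#' @export
fret_model2 <- function(placements, p = fret_params()) {
  r <- if (is.numeric(placements)) placements else placements$distances
  if (length(r) < 1)
    stop("no accepted dye placements: efficiency undefined (chain weight 0)")
  fret_model1(mean(r), p)
}

#' Orientation factor kappa^2
#'
#' kappa^2 = (muD.muA - 3 (muD.rhat)(muA.rhat))^2, in [0, 4].
#'
#' @param muD,muA unit vectors along the donor/acceptor transition dipoles.
#' @param rhat unit vector along the interdye axis.
#' @return kappa^2.
#' @export
kappa2 <- function(muD, muA, rhat) {
  for (v in list(muD, muA, rhat))
    if (abs(sqrt(sum(v^2)) - 1) > 1e-6)
      stop("kappa2 inputs must be unit vectors (tolerance 1e-6)")
  (sum(muD * muA) - 3 * sum(muD * rhat) * sum(muA * rhat))^2
}

#' FRET efficiency, model 3 (explicit kappa^2, slow dyes)
#'
#' The transfer rate is k_ET = (3 kappa^2 / 2) tauD^-1 (R0/r)^6 and
#' E = k_ET / (k_ET + tauD^-1) = 1 / (1 + (2/(3 kappa^2)) (r/R0)^6).
#' With kappa^2 = 2/3 this reduces exactly to model 1 (R0 is defined at
#' the isotropic average).
#'
#' @param r interdye distance(s), nm.
#' @param k2 orientation factor(s), >= 0; k2 = 0 gives E = 0.
#' @param p a [fret_params()].
#' @return efficiency in [0, 1], vectorized.
#' @export
fret_model3 <- function(r, k2, p = fret_params()) {
  if (any(r <= 0)) stop("r must be positive")
  if (any(k2 < 0)) stop("kappa^2 must be >= 0")
  n <- max(length(r), length(k2))
  r <- rep_len(r, n)
  k2 <- rep_len(k2, n)
  out <- numeric(n)
  nz <- k2 > 0
  out[nz] <- 1 / (1 + (2 / (3 * k2[nz])) * (r[nz] / p$R0)^6)
  out
}
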