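# Forward models: Debye SAXS, Guinier, scale/offset fits, FRET models,
# stacking factors, pairwise RMSD distributions.

test_that("debye_intensity: self-term, closed form, brute-force oracle", {
  one <- debye_intensity(matrix(c(0, 0, 0), 1, 3), c(0.1, 1, 2),
                         mode = "point")
  expect_equal(one$I, c(1, 1, 1))

  d <- 7.3  # Angstrom
  two <- debye_intensity(rbind(c(0, 0, 0), c(d, 0, 0)),
                         seq(0.1, 3, length.out = 20), mode = "point")
  qA <- two$q / 10
  expect_equal(two$I, 2 + 2 * sin(qA * d) / (qA * d), tolerance = 1e-12)

  set.seed(8)
  X <- matrix(rnorm(150, 0, 8), 50, 3)
  q <- seq(0.05, 3, length.out = 25)
  p <- debye_intensity(X, q, mode = "point")
  D <- as.matrix(dist(X))
  oracle <- vapply(q / 10, function(qa) {
    s <- 0
    for (i in 1:50) for (j in 1:50) {
      x <- qa * D[i, j]
      s <- s + if (x < 1e-12) 1 else sin(x) / x
    }
    s
  }, numeric(1))
  expect_equal(p$I, oracle, tolerance = 1e-10)
})

test_that("debye_intensity invariances and form-factor normalization", {
  q <- seq(0.05, 2, length.out = 15)
  p0 <- debye_intensity(ideal_a4, q)
  R <- random_rotation()
  conf_r <- ideal_a4
  conf_r$coords <- sweep(tcrossprod(ideal_a4$coords, R), 2, c(5, 5, 5), "+")
  expect_equal(debye_intensity(conf_r, q)$I, p0$I, tolerance = 1e-9)
  expect_true(all(p0$I > 0))
  expect_equal(which.max(debye_intensity(ideal_a4, c(0, q))$I), 1L)
  # f(0) equals the electron count
  expect_equal(rnahcg:::form_factor("C", 0), 6, tolerance = 0.01)
  expect_equal(rnahcg:::form_factor("N", 0), 7, tolerance = 0.01)
  expect_equal(rnahcg:::form_factor("O", 0), 8, tolerance = 0.01)
  expect_equal(rnahcg:::form_factor("P", 0), 15, tolerance = 0.01)
})

test_that("guinier_rg: exact Guinier input, flat profile, Debye consistency", {
  qg <- seq(0.005, 0.1, length.out = 30)
  prof <- scattering_profile(qg, 50 * exp(-qg^2 * 4 / 3))  # Rg = 2 nm
  expect_equal(guinier_rg(prof), 20, tolerance = 0.1)  # Angstrom
  flat <- scattering_profile(qg, rep(3, 30))
  expect_equal(guinier_rg(flat), 0)
  neg <- scattering_profile(qg, exp(+qg^2))
  expect_error(guinier_rg(neg), "positive Guinier slope")
  pd <- debye_intensity(ideal_a30, seq(0.01, 0.1, length.out = 10),
                        mode = "point")
  expect_equal(guinier_rg(pd), radius_of_gyration(ideal_a30),
               tolerance = 0.02 * radius_of_gyration(ideal_a30))
})

test_that("guinier-limit consistency holds for random rigid bodies", {
  set.seed(17)
  for (k in 1:20) {
    X <- matrix(rnorm(3 * 40, 0, runif(1, 3, 15)), 40, 3)
    pd <- debye_intensity(X, seq(0.005, 0.05, length.out = 5),
                          mode = "point")
    rg <- radius_of_gyration(X)
    expect_equal(guinier_rg(pd), rg, tolerance = 0.02 * rg)
  }
})

test_that("ensemble averaging and rms_rg arithmetic", {
  q <- seq(0.1, 1, length.out = 5)
  p1 <- scattering_profile(q, rep(1, 5))
  p3 <- scattering_profile(q, rep(3, 5))
  expect_equal(ensemble_average_intensity(list(p1))$I, p1$I)
  expect_equal(ensemble_average_intensity(list(p1, p3), c(1, 0))$I, p1$I)
  expect_equal(ensemble_average_intensity(list(p1, p3), c(0.5, 0.5))$I,
               rep(2, 5))
  p_bad <- scattering_profile(q + 0.01, rep(1, 5))
  expect_error(ensemble_average_intensity(list(p1, p_bad)), "mismatch")

  expect_equal(rms_rg(rep(15, 7)), 15)
  expect_equal(rms_rg(c(10, 20)), sqrt(250))
  expect_equal(rms_rg(c(10, 20), c(1, 0)), 10)
})

test_that("fit_scale_offset: exact and statistical recovery", {
  q <- seq(0.05, 2, length.out = 60)
  Isim <- debye_intensity(ideal_a4, q)$I
  exp1 <- scattering_profile(q, 2 * Isim + 5, sigma = rep(1, 60))
  expect_equal(fit_scale_offset(Isim, exp1), c(a = 2, b = 5),
               tolerance = 1e-9)
  exp2 <- scattering_profile(q, Isim, sigma = rep(1, 60))
  expect_equal(fit_scale_offset(Isim, exp2), c(a = 1, b = 0),
               tolerance = 1e-9)
  expect_equal(reduced_chi2(Isim, exp1), 0, tolerance = 1e-18)

  # noisy recovery within 3 standard errors (weighted regression theory)
  set.seed(4)
  sig <- 0.02 * (1.7 * Isim + 0.3)
  for (k in 1:5) {
    y <- 1.7 * Isim + 0.3 + rnorm(60, 0, sig)
    expn <- scattering_profile(q, y, sigma = sig)
    ab <- fit_scale_offset(Isim, expn)
    w <- 1 / sig^2
    xb <- sum(w * Isim) / sum(w)
    se_a <- 1 / sqrt(sum(w * (Isim - xb)^2))
    se_b <- sqrt(sum(w * Isim^2) / (sum(w) * sum(w * (Isim - xb)^2)))
    expect_lt(abs(ab[["a"]] - 1.7), 3 * se_a)
    expect_lt(abs(ab[["b"]] - 0.3), 3 * se_b)
  }
  expect_error(fit_scale_offset(rep(2, 60), exp1), "singular")
})

test_that("reduced_chi2: alternating residuals and sampling bound", {
  q <- seq(0.1, 1, length.out = 10)
  Isim <- seq(10, 1, length.out = 10)
  y <- Isim + c(1, -1) * 0.5
  expp <- scattering_profile(q, y, sigma = rep(0.5, 10))
  expect_equal(reduced_chi2(Isim, expp, a = 1, b = 0), 1.0)
  set.seed(12)
  M <- 500
  qM <- seq(0.01, 2, length.out = M)
  IsimM <- 100 * exp(-qM^2)
  sig <- rep(2, M)
  yM <- IsimM + rnorm(M, 0, 2)
  expM <- scattering_profile(qM, yM, sigma = sig)
  expect_lt(abs(reduced_chi2(IsimM, expM, a = 1, b = 0) - 1),
            3 * sqrt(2 / M))
  expect_error(reduced_chi2(IsimM, scattering_profile(qM, yM)), "errors")
})

test_that("FRET models: fixed points, limits, exact consistency", {
  p <- fret_params()
  expect_equal(p$R0, 5.4)
  expect_equal(p$tauD, 4)
  expect_equal(fret_model1(p$R0), 0.5)
  expect_equal(fret_model1(1e-6), 1, tolerance = 1e-9)
  expect_equal(fret_model1(1e4), 0, tolerance = 1e-12)
  expect_equal(fret_model1(2 * p$R0), 1 / 65)

  r <- seq(0.1, 20, length.out = 200)
  expect_equal(fret_model3(r, 2 / 3), fret_model1(r), tolerance = 1e-12)
  expect_equal(fret_model3(r, 0), rep(0, 200))
  expect_equal(fret_model3(p$R0, 4 / 3), 2 / 3)

  expect_equal(fret_model2(c(5.4 - 0.3, 5.4 + 0.3)), 0.5)
  rs <- seq(3, 7, length.out = 20)
  expect_equal(fret_model2(rs), fret_model1(mean(rs)))
  expect_equal(fret_model2(6.1), fret_model1(6.1))
  expect_error(fret_model2(numeric(0)), "undefined")
})

test_that("kappa2: analytic orientations and unit-vector validation", {
  z <- c(0, 0, 1); x <- c(1, 0, 0)
  expect_equal(kappa2(z, z, z), 4)
  expect_equal(kappa2(x, x, z), 1)
  expect_equal(kappa2(x, c(0, 1, 0), z), 0)
  expect_error(kappa2(2 * z, z, z), "unit")
})

test_that("mean efficiency decreases under global distance scale-up", {
  set.seed(3)
  r <- runif(50, 2, 9)
  e0 <- mean(fret_model1(r))
  for (s in c(1.1, 1.5, 2)) expect_lt(mean(fret_model1(s * r)), e0)
})

test_that("detect_stacks: helix, separated bases, coplanar side-by-side", {
  st <- detect_stacks(ideal_a10)
  expect_equal(nrow(st$pairs), 9)
  expect_length(st$runs, 1)
  expect_equal(st$n_stacked, rep(10L, 10))

  apart <- build_ideal_aform("AA")
  r2 <- which(apart$atoms$residue_index == 2)
  apart$coords[r2, ] <- apart$coords[r2, ] + 15
  expect_equal(nrow(detect_stacks(apart)$pairs), 0)

  # coplanar side-by-side (paired-like, not stacked): shift residue 2's
  # base into residue 1's base plane
  side <- build_ideal_aform("AA")
  geo <- rnahcg:::base_ring_geometry(side)
  n1 <- geo$normals[1, ]
  v <- geo$centers[2, ] - geo$centers[1, ]
  target <- geo$centers[1, ] + (v - sum(v * n1) * n1) /
    sqrt(sum((v - sum(v * n1) * n1)^2)) * 4.0
  r2 <- which(side$atoms$residue_index == 2)
  side$coords[r2, ] <- sweep(side$coords[r2, ], 2,
                             geo$centers[2, ] - target)
  st2 <- detect_stacks(side)
  expect_equal(nrow(st2$pairs), 0)  # fails the axis-offset window
})

test_that("q_stacking piecewise formulas are exact", {
  st30 <- detect_stacks(ideal_a30)
  qs <- q_stacking(st30)
  cc <- 30 / 29
  expect_equal(qs, rep(cc - cc / 29, 30))

  st2 <- detect_stacks(build_ideal_aform("AA"))
  expect_equal(q_stacking(st2, n = 30), rep(0.25 * cc, 2))
  st3 <- detect_stacks(build_ideal_aform("AAA"))
  expect_equal(q_stacking(st3, n = 30), rep(0.5 * cc, 3))

  apart <- build_ideal_aform("AA")
  r2 <- which(apart$atoms$residue_index == 2)
  apart$coords[r2, ] <- apart$coords[r2, ] + 20
  expect_equal(q_stacking(detect_stacks(apart), n = 30), c(0, 0))
  expect_error(q_stacking(st2, n = 1), "n < 2")
  expect_true(all(qs >= 0 & qs <= cc))
})

test_that("pairwise_rmsd_distribution: zeros, rotation, exhaustive oracle", {
  one <- ens_small
  one$coords <- one$coords[1]
  one$weights <- 1
  expect_equal(pairwise_rmsd_distribution(one, one, n_pairs = 5),
               rep(0, 5), tolerance = 1e-8)

  rot <- one
  R <- random_rotation()
  rot$coords <- list(sweep(tcrossprod(one$coords[[1]], R), 2, c(1, 2, 3),
                           "+"))
  expect_equal(pairwise_rmsd_distribution(one, rot, n_pairs = 5),
               rep(0, 5), tolerance = 1e-8)

  five <- ens_small
  five$coords <- five$coords[1:5]
  vals <- pairwise_rmsd_distribution(five, five, exhaustive = TRUE)
  oracle <- c()
  for (i in 1:5) for (j in 1:5) if (i != j)
    oracle <- c(oracle, weighted_superposition(five$coords[[i]],
                                               five$coords[[j]])$wrmsd)
  expect_equal(sort(vals), sort(oracle), tolerance = 1e-10)
})

test_that("SAXS profile text round trip", {
  q <- seq(0.05, 2, length.out = 12)
  p <- scattering_profile(q, 10 * exp(-q^2), sigma = rep(0.1, 12))
  tmp <- tempfile(fileext = ".dat")
  write_saxs_profile(p, tmp)
  p2 <- read_saxs_profile(tmp)
  expect_equal(p2$q, p$q, tolerance = 1e-6)
  expect_equal(p2$I, p$I, tolerance = 1e-8)
  expect_equal(p2$sigma, p$sigma, tolerance = 1e-8)
  # A^-1 flag converts
  p3 <- read_saxs_profile(tmp, q_unit = "A^-1")
  expect_equal(p3$q, p$q * 10, tolerance = 1e-5)
})
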