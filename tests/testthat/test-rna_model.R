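# Core geometry: weighted superposition, junction alignment spec, clash
# detection, torsions, size metrics.

test_that("weighted_superposition handles identity and exact recovery", {
  X <- ideal_a4$coords[1:20, ]
  fit <- weighted_superposition(X, X, runif(20, 0.5, 2))
  expect_equal(fit$wrmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-8)

  set.seed(5)
  for (k in 1:10) {
    R <- random_rotation()
    tr <- rnorm(3, 0, 5)
    Y <- sweep(tcrossprod(X, R), 2, tr, "+")
    fit <- weighted_superposition(X, Y)
    expect_lt(fit$wrmsd, 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
    expect_equal(apply_transform(X, fit), Y, tolerance = 1e-8)
  }
})

test_that("weighted_superposition matches a brute-force Euler-angle oracle", {
  # unit square vs square with one corner displaced by 0.4 A
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  tgt <- sq
  tgt[3, ] <- tgt[3, ] + c(0.4, 0, 0)
  fit <- weighted_superposition(sq, tgt)
  euler_R <- function(a, b, c) {
    Rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                            c(0, 0, 1))
    Ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0),
                            c(-sin(t), 0, cos(t)))
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  wrmsd_of <- function(par) {
    R <- euler_R(par[1], par[2], par[3])
    M <- sweep(sq, 2, colMeans(sq))
    T <- sweep(tgt, 2, colMeans(tgt))
    sqrt(mean(rowSums((tcrossprod(M, R) - T)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf
  for (a in grid) for (b in grid) for (c in grid) {
    v <- wrmsd_of(c(a, b, c))
    if (v < best) { best <- v; best_par <- c(a, b, c) }
  }
  ref <- optim(best_par, wrmsd_of, control = list(reltol = 1e-14))
  expect_equal(fit$wrmsd, ref$value, tolerance = 1e-6)
})

test_that("wrmsd is invariant to rigid pre-transformations", {
  set.seed(11)
  X <- matrix(rnorm(36), 12, 3)
  Y <- matrix(rnorm(36), 12, 3)
  w <- runif(12, 0.5, 3)
  ref <- weighted_superposition(X, Y, w)$wrmsd
  for (k in 1:10) {
    R <- random_rotation()
    tr <- rnorm(3, 0, 10)
    Xr <- sweep(tcrossprod(X, R), 2, tr, "+")
    expect_equal(weighted_superposition(Xr, Y, w)$wrmsd, ref,
                 tolerance = 1e-8)
    R2 <- random_rotation()
    Yr <- sweep(tcrossprod(Y, R2), 2, rnorm(3), "+")
    expect_equal(weighted_superposition(X, Yr, w)$wrmsd, ref,
                 tolerance = 1e-8)
  }
})

test_that("superposition errors on degenerate or mismatched input", {
  collinear <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(weighted_superposition(collinear, collinear + 1),
               "degenerate|rank")
  expect_error(weighted_superposition(matrix(rnorm(12), 4, 3),
                                      matrix(rnorm(15), 5, 3)),
               "mismatched")
  expect_error(weighted_superposition(matrix(rnorm(6), 2, 3),
                                      matrix(rnorm(6), 2, 3)), "3 points")
})

test_that("junction_alignment_spec pairs and weights follow the overlap rule", {
  sp <- junction_alignment_spec(ideal_a4, ideal_a4)
  expect_length(sp$idx1, 14)  # 3 backbone + 10 adenine base atoms + C1'
  expect_equal(sp$weights, c(2, 2, 2, rep(1, 11)))
  expect_equal(sp$rmsd_cutoff, 0.64)
  expect_equal(sp$atom_names[1:3], c("O3'", "P", "O5'"))

  u4 <- build_ideal_aform("UUUU")
  spu <- junction_alignment_spec(u4, u4)
  expect_length(spu$idx1, 12)  # 3 backbone + 8 uracil base atoms + C1'

  g4 <- build_ideal_aform("GGGG")
  expect_error(junction_alignment_spec(g4, ideal_a4),
               "sequence incompatibility")
})

test_that("detect_clashes is strict, symmetric, and matches brute force", {
  a <- matrix(c(0, 0, 0), 1, 3)
  expect_equal(detect_clashes(a, matrix(c(1.99, 0, 0), 1, 3), 2.0), 1L)
  expect_equal(detect_clashes(a, matrix(c(2.00, 0, 0), 1, 3), 2.0), 0L)
  X <- ideal_a4$coords
  expect_equal(detect_clashes(X, X, 2.0,
                              excluded1 = seq_len(nrow(X))), 0L)
  set.seed(3)
  for (k in 1:10) {
    P <- matrix(runif(600, 0, 20), 200, 3)
    A <- P[1:100, ]; B <- P[101:200, ]
    D <- sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B))
    expect_equal(detect_clashes(A, B, 2.0), sum(D < 2.0))
    expect_equal(detect_clashes(B, A, 2.0), detect_clashes(A, B, 2.0))
  }
})

test_that("dihedral_angle matches an independent oracle and the 60-degree case", {
  set.seed(21)
  for (k in 1:25) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-10)
  }
  # constructed 60-degree geometry
  p1 <- c(1, 0, 0); p2 <- c(0, 0, 0); p3 <- c(0, 1.5, 0)
  p4 <- p3 + c(cos(pi / 3), 0, -sin(pi / 3))
  expect_equal(dihedral_angle(p1, p2, p3, p4),
               oracle_dihedral(p1, p2, p3, p4), tolerance = 1e-10)
  expect_equal(abs(dihedral_angle(p1, p2, p3, p4)), 60, tolerance = 1e-8)
})

test_that("backbone torsions of the ideal helix equal the template values", {
  tt <- backbone_torsions(ideal_a10)
  tmpl <- aform_torsions()
  for (i in 3:8)
    for (ang in names(tmpl))
      expect_equal(wrap180(tt[[ang]][i] - tmpl[[ang]]), 0, tolerance = 1e-6)
  # terminal residues yield NA where atoms are missing, no error
  expect_true(is.na(tt$alpha[1]))
  expect_true(is.na(tt$epsilon[nrow(tt)]))
})

test_that("torsions are rigid-motion invariant and negate under reflection", {
  set.seed(31)
  tt0 <- backbone_torsions(ideal_a4)
  R <- random_rotation()
  conf_r <- ideal_a4
  conf_r$coords <- sweep(tcrossprod(ideal_a4$coords, R), 2, c(3, -2, 7), "+")
  expect_equal(backbone_torsions(conf_r), tt0, tolerance = 1e-8)
  conf_m <- ideal_a4
  conf_m$coords[, 1] <- -conf_m$coords[, 1]
  tt_m <- backbone_torsions(conf_m)
  for (ang in c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                "chi")) {
    ok <- !is.na(tt0[[ang]])
    expect_equal(wrap180(tt_m[[ang]][ok] + tt0[[ang]][ok]),
                 rep(0, sum(ok)), tolerance = 1e-8)
  }
})

test_that("radius_of_gyration analytic cases and rigid invariance", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  cube <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  expect_equal(radius_of_gyration(cube), sqrt(3))
  R <- random_rotation()
  expect_equal(radius_of_gyration(sweep(tcrossprod(ideal_a30$coords, R),
                                        2, c(9, 9, 9), "+")),
               radius_of_gyration(ideal_a30), tolerance = 1e-9)
  expect_error(radius_of_gyration(matrix(numeric(0), 0, 3)), "empty")
})

test_that("end_to_end_distance analytic cases and helix closed form", {
  conf <- build_ideal_aform("AA")
  i5 <- which(conf$atoms$residue_index == 1 & conf$atoms$name == "O5'")
  i3 <- which(conf$atoms$residue_index == 2 & conf$atoms$name == "O3'")
  conf$coords[i5, ] <- c(0, 0, 0)
  conf$coords[i3, ] <- c(3, 4, 0)
  expect_equal(end_to_end_distance(conf), 5.0)
  conf$coords[i3, ] <- conf$coords[i5, ]
  expect_equal(end_to_end_distance(conf), 0)

  # 40-mer: propagate O3'(1) with the screw transform as the analytic path
  conf40 <- build_ideal_aform(strrep("A", 40))
  hp <- aform_helix_params()
  o3 <- conf40$coords[which(conf40$atoms$residue_index == 1 &
                              conf40$atoms$name == "O3'"), ]
  p <- o3
  for (k in 1:39) p <- as.vector(hp$rotation %*% p) + hp$translation
  o5 <- conf40$coords[which(conf40$atoms$residue_index == 1 &
                              conf40$atoms$name == "O5'"), ]
  expect_equal(end_to_end_distance(conf40), sqrt(sum((p - o5)^2)),
               tolerance = 1e-6)
})
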