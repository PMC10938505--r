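# HCG engine: merging, level growth, hierarchical ensembles, mixed
# structured/disordered assembly, post-hoc validation.

test_that("attempt_merge joins ideal tetramers covalently", {
  m <- attempt_merge(ideal_a4, ideal_a4)
  expect_s3_class(m, "rna_conformation")
  expect_equal(n_residues(m), 6)
  validate_conformation(m)
  d <- sqrt(sum((rnahcg:::atom_xyz(m, 3, "O3'") -
                   rnahcg:::atom_xyz(m, 4, "P"))^2))
  expect_lt(d, 1.8)
})

test_that("attempt_merge rejects on rmsd and on clash with reasons", {
  # distort the overlap region beyond any rigid fit
  bad <- ideal_a4
  rows <- which(bad$atoms$residue_index == 2 &
                  !(bad$atoms$name %in% c("P", "OP1", "OP2")))
  bad$coords[rows, ] <- bad$coords[rows, ] +
    outer(seq_along(rows) %% 2 * 4 - 2, c(1, 0, 0))
  rej <- attempt_merge(ideal_a4, bad)
  expect_s3_class(rej, "hcg_rejection")
  expect_equal(rej$reason, "rmsd")

  # alignment region intact, but downstream atoms fold back onto piece1
  clashy <- ideal_a4
  r4 <- which(clashy$atoms$residue_index == 4)
  r1 <- which(clashy$atoms$residue_index == 1)
  n_copy <- min(length(r4), length(r1))
  clashy$coords[r4[seq_len(n_copy)], ] <-
    clashy$coords[r1[seq_len(n_copy)], ] + 0.2
  rej2 <- attempt_merge(ideal_a4, clashy)
  expect_s3_class(rej2, "hcg_rejection")
  expect_equal(rej2$reason, "clash")

  # precondition violation is an error, not a stochastic rejection
  expect_error(attempt_merge(ideal_a4, build_ideal_aform("GGGG")),
               "incompatibility")
})

test_that("grow_level: degenerate pools, determinism, unit acceptance", {
  cfg <- growth_config(n_chains = 5, seed = 2)
  out <- grow_level(list(ideal_a4), list(ideal_a4), 5, cfg)
  expect_length(out, 5)
  for (m in out) expect_equal(m$coords, out[[1]]$coords)
  expect_equal(attr(out, "acceptance_rate"), 1.0)

  lib <- synth_fragment_library("AAAA", 30, noise = 6, seed = 5)
  a <- grow_level(lib, lib, 20, cfg, seed = 11)
  b <- grow_level(lib, lib, 20, cfg, seed = 11)
  expect_identical(lapply(a, `[[`, "coords"), lapply(b, `[[`, "coords"))
})

test_that("grow_ensemble respects sequence, size, weights and determinism", {
  expect_equal(ens_small$sequence, strrep("A", 30))
  expect_equal(n_members(ens_small), 60)
  expect_equal(sum(ens_small$weights), 1, tolerance = 1e-12)
  expect_equal(ens_small$weights, rep(1 / 60, 60))
  ens_b <- grow_ensemble(plan_a30, list(AAAA = lib_small),
                         growth_config(n_chains = 60, seed = 7))
  expect_identical(ens_small$coords, ens_b$coords)

  ph <- plan_tiling("UCAAUC", "heteropolymer")
  libs <- synth_plan_libraries(ph, n_conformers = 40, seed = 3, noise = 6,
                               unstack_prob = 0.05)
  ensh <- grow_ensemble(ph, libs, growth_config(n_chains = 15, seed = 4))
  expect_equal(ensh$sequence, "UCAAUC")
  for (i in 1:15) validate_conformation(ensemble_member(ensh, i))

  expect_error(grow_ensemble(ph, libs["GUCA"], growth_config()),
               "no library")
})

test_that("every member passes global clash and continuity validation", {
  v <- validate_ensemble(ens_small)
  expect_equal(sum(v$clashes), 0L)
  expect_equal(sum(v$discontinuities), 0L)
})

test_that("growth is exchangeable under conformer permutation + reseed", {
  set.seed(33)
  perm <- sample(seq_len(n_conformers(lib_small)))
  lib_p <- lib_small
  lib_p$coords <- lib_small$coords[perm]
  ens_p <- grow_ensemble(plan_a30, list(AAAA = lib_p),
                         growth_config(n_chains = 60, seed = 19))
  rg_a <- vapply(seq_len(60), function(i)
    radius_of_gyration(ensemble_member(ens_small, i)), numeric(1))
  rg_b <- vapply(seq_len(60), function(i)
    radius_of_gyration(ensemble_member(ens_p, i)), numeric(1))
  expect_gt(suppressWarnings(ks.test(rg_a, rg_b)$p.value), 0.01)
})

test_that("homopolymer and heteropolymer tilings of poly-A agree", {
  # mirrors the reported near-identity of rGA3-grown and rA4-grown poly-A
  seq20 <- strrep("A", 20)
  p_homo <- plan_tiling(seq20, "homopolymer")
  p_het <- plan_tiling(seq20, "heteropolymer")
  lib_g <- synth_fragment_library("GAAA", 120, noise = 8,
                                  unstack_prob = 0.1, seed = 42)
  ens_homo <- grow_ensemble(p_homo, list(AAAA = lib_small),
                            growth_config(n_chains = 80, seed = 5))
  ens_het <- grow_ensemble(p_het, list(GAAA = lib_g),
                           growth_config(n_chains = 80, seed = 6))
  expect_equal(ens_het$sequence, seq20)
  rg_a <- vapply(seq_len(80), function(i)
    radius_of_gyration(ensemble_member(ens_homo, i)), numeric(1))
  rg_b <- vapply(seq_len(80), function(i)
    radius_of_gyration(ensemble_member(ens_het, i)), numeric(1))
  expect_gt(suppressWarnings(ks.test(rg_a, rg_b)$p.value), 0.01)
})

test_that("growth failure is loud and labeled", {
  # a clash-guaranteed pool: piece2 copies that fold back onto piece1
  clashy <- ideal_a4
  r4 <- which(clashy$atoms$residue_index == 4)
  r1 <- which(clashy$atoms$residue_index == 1)
  n_copy <- min(length(r4), length(r1))
  clashy$coords[r4[seq_len(n_copy)], ] <-
    clashy$coords[r1[seq_len(n_copy)], ] + 0.2
  cfg <- growth_config(n_chains = 2, max_attempts = 10, seed = 1)
  expect_error(grow_level(list(ideal_a4), list(clashy), 2, cfg),
               "growth failure")
})

test_that("assemble_mixed keeps structured segments internally rigid", {
  # structured segment: a kinked 6-mer, single conformer
  kink_t <- as.data.frame(as.list(aform_torsions()))[rep(1, 6), ]
  kink_t$gamma[3] <- kink_t$gamma[3] + 100  # sharp kink
  raw <- rnahcg:::build_chain_internal("AAGGAA", kink_t)
  hairpin <- new_fragment_library("AAGGAA", raw$atoms, list(raw$coords))

  plan6 <- plan_tiling(strrep("A", 6), "homopolymer")
  libs <- list(AAAA = lib_small)
  segments <- list(
    list(type = "flexible", plan = plan6, libraries = libs),
    list(type = "structured", library = hairpin),
    list(type = "flexible", plan = plan6, libraries = libs))
  cfg <- growth_config(rmsd_cutoff = 1.0, n_chains = 10, seed = 8)
  ens <- assemble_mixed(segments, cfg)
  expect_equal(ens$sequence, paste0(strrep("A", 5), "AGGA", strrep("A", 5)))
  expect_equal(n_members(ens), 10)
  # structured contribution occupies chain residues 6..9: compare with
  # source conformer residues 2..5 after optimal superposition
  src_rows <- which(raw$atoms$residue_index %in% 2:5)
  for (i in 1:10) {
    m <- ensemble_member(ens, i)
    rows <- which(m$atoms$residue_index %in% 6:9)
    fit <- weighted_superposition(m$coords[rows, ], raw$coords[src_rows, ])
    expect_lt(fit$wrmsd, 1e-6)
    validate_conformation(m)
  }
})

test_that("all-structured input with single conformers is deterministic", {
  t6 <- as.data.frame(as.list(aform_torsions()))[rep(1, 6), ]
  raw1 <- rnahcg:::build_chain_internal("AAAAAA", t6)
  s1 <- new_fragment_library("AAAAAA", raw1$atoms, list(raw1$coords))
  segs <- list(list(type = "structured", library = s1),
               list(type = "structured", library = s1))
  cfg <- growth_config(rmsd_cutoff = 1.0, n_chains = 3, seed = 1)
  ens <- assemble_mixed(segs, cfg)
  expect_equal(n_members(ens), 3)
  expect_equal(nchar(ens$sequence), 10)
  for (i in 2:3) expect_equal(ens$coords[[i]], ens$coords[[1]])
})
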