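# Shared fixtures, built once per test run. Sizes are desk-scale; the
# full-scale run lives in test-acceptance.R.

ideal_a4 <- build_ideal_aform("AAAA")
ideal_a10 <- build_ideal_aform(strrep("A", 10))
ideal_a30 <- build_ideal_aform(strrep("A", 30))

plan_a30 <- plan_tiling(strrep("A", 30), "homopolymer")

# single-conformer ideal library (degenerate growth fixtures)
lib_ideal_a4 <- synth_fragment_library("AAAA", 1, noise = 0,
                                       unstack_prob = 0, seed = 1)

# small noisy library + ensemble reused across files
lib_small <- synth_fragment_library("AAAA", 120, noise = 8,
                                    unstack_prob = 0.1, seed = 42)
ens_small <- grow_ensemble(plan_a30, list(AAAA = lib_small),
                           growth_config(n_chains = 60, seed = 7))

# independent (praxeolitic) dihedral oracle, reimplemented here so the
# package's NeRF/dihedral code is never its own reference
oracle_dihedral <- function(p0, p1, p2, p3) {
  b0 <- p0 - p1
  b1 <- p2 - p1
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p3 - p2
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  atan2(y, x) * 180 / pi
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_res)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# wrap angular differences into (-180, 180]
wrap180 <- function(x) ((x + 180) %% 360) - 180
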