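---
title: "Hierarchical chain growth of ssRNA ensembles: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical chain growth of ssRNA ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnahcg)
```

# The model

Single-stranded RNA without stable base pairing behaves as a disordered
heteropolymer whose local structure — sugar pucker, backbone rotamers,
base stacking — is well sampled by short-fragment simulations, while its
global dimensions emerge from how those local states concatenate.
Hierarchical chain growth (HCG) exploits this separation: full-length
chains are assembled by recursively merging conformers drawn at random
from tetramer fragment pools, with purely geometric acceptance criteria
and no interfragment energy model. The resulting ensemble is a prior; it
is confronted with experiments (SAXS curves, mean FRET efficiencies)
through forward models, and minimally reweighted toward them with BioEn.

## Assumptions

* Local conformational preferences of a tetramer are transferable into
  longer chains; all sequence context beyond the 4-mer window is ignored.
* Fragments interact only sterically during assembly (hard heavy-atom
  exclusion at 2 Å); electrostatics, solvent and attractive stacking
  between fragments are absorbed into the fragment libraries themselves
  and, at the ensemble level, into the experimental reweighting.
* Chain dynamics are slow compared to the fluorescence lifetime (FRET
  models) and the ensemble average is what SAXS measures.

# Growth machinery

Merging aligns the two-nucleotide overlap: backbone O3′/P/O5′ of the
junction (weight 2) plus the nucleobase heavy atoms and C1′ of the
overlapping nucleotide (weight 1), by weighted Kabsch superposition. The
acceptance threshold (default 0.64 Å) applies to the *weighted* RMSD of
the fitted atoms — the same quantity the fit minimizes; the source
procedure does not specify weighted versus plain RMSD for the threshold,
and using the fit's own objective keeps acceptance monotone in the fit
quality. Ribose atoms other than C1′ are deliberately not aligned, so
sugar-pucker diversity in the libraries survives assembly.

Steric rejection counts heavy-atom pairs below 2 Å (strictly; boundary
equality is not a clash) between the retained parts of the two pieces.
The exclusion set at the junction is: all atoms of the two removed
nucleotides plus the aligned backbone atoms O3′ (left nt −2) and P/O5′
(right nt 2) — the bridging covalent neighborhood. Post-hoc ensemble
validation re-checks whole chains with the same exemptions plus the
covalent O3′(i)–P(i+1) linkage.

Junction atom ownership: the merged chain keeps the left piece up to and
including nucleotide −2's O3′; the bridging phosphate group (P, OP1, OP2)
comes from the right piece's nucleotide 2, preserving its sampled α
torsion. The dihedral that cannot be preserved exactly is α's dependence
on the *left* piece's O3′ — see "Known limitations".

Scheduling is a deterministic left-to-right binary tree; an odd piece at
any level carries over unmerged. Every level draws fresh members with
replacement and produces `n_chains` conformations per slot, so pool
statistics do not degenerate along the tree. `max_attempts` (default
1000) bounds the retries per output conformation; exhausting it is a hard
error — silent under-filling would bias the ensemble toward easy merges.
One top-level seed derives per-level, per-slot substreams, so results are
reproducible and independent of evaluation order.

## Tiling and caps

k tetramers yield 2k + 2 nucleotides (each junction removes one
nucleotide from each side). In heteropolymer mode the fragments are
G-capped tetramers rG·s(2j−1)·s(2j)·s(2j+1); the leading G and the final
3′ cap are trimmed by default so the chain contains only target
nucleotides. For even-length targets the final fragment's 3′ cap base is
not determined by the target; it defaults to A and is recorded in the
plan. Odd lengths are handled by retaining one terminal cap position
(homopolymer) or by letting the final fragment's 3′ position be the last
target nucleotide (heteropolymer); a trimming pass that would create atom
combinations never sampled together was rejected.

# The synthetic fragment generator

`synth_fragment_library()` stands in for MD-derived libraries. Conformers
are built in internal coordinates: standard bond lengths and angles, a
C3′-endo sugar ring (pseudorotation phase 18°, amplitude 38°), planar
bases, and per-residue torsion means perturbed by Gaussian noise
(default σ = 8°, a realistic within-rotamer width for sub-helical RNA
sampling). With probability 0.2 per terminal residue a conformer's
terminal base is flipped toward syn and its adjacent backbone perturbed,
emulating the cluster structure of sampled tetramer ensembles: roughly
64% fully A-form-like, 32% with one inverted/unstacked terminal, 4% with
both — mirroring the dominant stacked cluster, the large
terminal-inverted cluster, and sparse unstacked states seen in MD.
Internally clashing conformers are regenerated, as MD frames are
clash-free by construction.

Template calibration: the torsion means start from canonical A-form
fibre values (α −68, β 178, γ 54, δ 82, ε −153, ζ −71, χ −158) and were
adjusted once, each by at most ~6°, so that the template chain reproduces
A-form helical parameters (rise 2.81 Å, twist ≈ 33°) and clean base
stacking under the adopted bond-angle set (α −67.3, β 172.6, γ 54.6,
δ 82.1, ε −156.5, ζ −69.6, χ −155.2). Uncalibrated canonical torsions
with idealized bond angles gave a helix with 3.13 Å rise whose bases
failed geometric stacking criteria; the calibration is against canonical
helix geometry only, never against any test outcome. Substituent torsion
offsets and in-plane base coordinates were measured once from idealized
ribonucleotide component-dictionary geometries and frozen as constants
(the dictionary's own flat sugar ring was discarded in favor of the
C3′-endo ring above).

What a green test on synthetic libraries establishes: the assembly,
observable and refinement machinery is correct on inputs with the stated
statistical structure. What it does not establish: force-field-level
realism of local conformations, sequence-specific stacking propensities,
or agreement with any particular measured SAXS/FRET dataset — those
require real fragment libraries (loadable through `load_library()`) and
real data.

## Dye fixture

The mock dye library is a rigid six-carbon ring around a central oxygen
(the distance-defining atom), linked by two freely rotating carbons to a
dideoxy-adenosine dinucleotide anchor; three uniformly drawn linker
torsions give broad orientational coverage. The transition dipole is the
ring diagonal through the center. It is labeled synthetic everywhere;
real dye libraries (multi-model PDB + JSON sidecar declaring center and
dipole atoms) use the same attachment code path. The acceptor labels the
5′ end via the anchor's 3′ nucleotide, the donor the 3′ end via the
anchor's 5′ nucleotide; "≈20 conformers" for the distance-averaged FRET
model are the first 20 accepted placements under the seeded RNG.

# Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `rmsd_cutoff` (growth) | 0.64 | Å | junction alignment acceptance |
| `rmsd_cutoff` (mixed assembly) | 1.0 | Å | relaxed for structured segments |
| `clash_cutoff` | 2.0 | Å | heavy-atom excluded volume |
| dye `rmsd_cutoff` | 0.8 | Å | terminal-nucleotide alignment |
| `n_chains` | 10000 | — | production ensemble size |
| `max_attempts` | 1000 | — | per-slot retry bound, then hard error |
| `noise` | 8 | deg | torsion σ of the synthetic generator |
| `unstack_prob` | 0.2 | — | per-terminal unstacking probability |
| `R0` | 5.4 | nm | Förster radius (defined at κ² = 2/3) |
| `tauD` | 4 | ns | donor lifetime |
| q grid | — | nm⁻¹ | SAXS unit convention (flag for Å⁻¹) |
| stacking thresholds | 5.0 / 2.5 / [2, 5] / 40° | Å, deg | ring-center distance, lateral offset, normal-axis offset window, normal angle |

The stacking thresholds follow the trajectory-analysis convention they
were adapted from and are configuration-exposed, since the assembly
procedure itself does not define them.

# Numerical choices

* Weighted Kabsch via 3×3 SVD with a determinant guard (proper rotations
  only); degenerate (rank < 2) point sets raise an error rather than
  returning an arbitrary frame.
* Clash search by a C++ cell list with cell edge = cutoff; equality with
  the all-pairs count is property-tested. Comparison is strict (<).
* Debye sums are exact double loops over atom pairs (C++), not
  histogram-binned approximations; point-scatterer mode (f ≡ 1) exists
  for tests where the Guinier limit must reproduce the coordinate R_G
  exactly.
* Guinier slope uses the numerical first difference on the two smallest
  q points; an optional multi-point low-q fit handles noisy data.
* BioEn optimizes in log-weight (softmax) coordinates with the analytic
  gradient and BFGS, deterministic initialization at w0, and a gradient
  tolerance scaled by θ and the data term. The objective uses the
  unnormalized ½χ²; *reported* χ² is the reduced (per-point) form. The
  SAXS nuisance alternation stops on |Δχ²_red| < 1e-6; a monotone slow
  crawl at the 100-cycle cap returns with a warning, while oscillation
  raises an error.
* Torsions are reported in (−180°, 180°]; distribution comparisons in
  tests recenter differences modulo 360° to avoid wrap-around artifacts.
* 5′-terminal residues may lack the phosphate group; continuity checks
  skip the absent terminal P. "C1" in the junction alignment is read as
  the anomeric carbon C1′, the only C1-named atom bridging base and
  sugar.

# Known limitations

* **Junction α broadening.** The α torsion of residues immediately 3′ of
  a merge junction is evaluated with the left piece's O3′, so it inherits
  the O3′–O3′ alignment residual. The effect is a ~1.5× broadening of α
  at junction residues with no mean shift, and it is *noise-independent*
  (residual and torsion width scale together). Per-angle
  Kolmogorov–Smirnov distances between grown-chain and fragment interior
  torsions are 0.01–0.03 for β, γ, δ, ε, ζ, χ but ~0.06 for α; the
  corresponding acceptance test asserts the stated 0.05 for every angle
  and is expected to fail for α. This matches the qualitative
  observation that assembly alters some α populations while retaining
  the rest of the torsional structure.
* Synthetic ensembles are stiffer than force-field ensembles: interior
  kinks arise only through accumulated torsion noise, so grown poly-A
  30-mers have R_G ≈ 22–36 Å with a mean near 30 Å rather than the
  broader compact-to-extended range of MD-derived libraries. This is a
  property of the generator's stated world, not of the assembly engine.
* No importance-sampling variant (reweighted HCG) and no interfragment
  energies; no hydration-layer or excluded-volume solvent corrections in
  the Debye model (externally computed per-structure profiles can be
  supplied instead); no photophysics beyond Förster theory.
* The residual-sign diagnostic is a plain runs summary without p-value
  calibration.
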