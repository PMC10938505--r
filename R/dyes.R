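# Fluorophore (dye) mapping for FRET forward models. A dye library holds
# conformers of a mock fluorophore attached to a dideoxy-adenosine
# dinucleotide anchor. Labeling aligns the sugar+base heavy atoms of the
# chain's terminal nucleotide onto the corresponding anchor nucleotide
# (5' chain label onto the anchor's 3' end and vice versa), accepts on
# RMSD < 0.8 A and no heavy-atom clash within 2.0 A, then merges the
# fluorophore atoms while dropping the anchor nucleotides and the chain's
# replaced terminal hydroxyl oxygen.

#' Construct a dye conformer library
#'
#' @param dye_name label, also used as the merged residue name.
#' @param atoms shared atom metadata (anchor residues + fluorophore).
#' @param coords list of conformer coordinate matrices.
#' @param center_atom atom name whose position defines the interdye
#'   distance r.
#' @param dipole_atoms ordered pair of atom names defining the transition
#'   dipole direction.
#' @param anchor_residues residue indices of the anchor nucleotides.
#' @param align_residue anchor residue aligned onto the chain terminus.
#' @param attach_end chain end this dye labels ("5prime" or "3prime").
#' @param meta provenance list.
#' @return object of class `dye_library`.
#' @export
new_dye_library <- function(dye_name, atoms, coords, center_atom,
                            dipole_atoms, anchor_residues, align_residue,
                            attach_end, meta = list()) {
  stopifnot(length(coords) >= 1, length(dipole_atoms) == 2)
  dye_rows <- !(atoms$residue_index %in% anchor_residues)
  if (!center_atom %in% atoms$name[dye_rows])
    stop("center_atom not among fluorophore atoms")
  if (!all(dipole_atoms %in% atoms$name[dye_rows]))
    stop("dipole_atoms not among fluorophore atoms")
  structure(list(dye_name = dye_name, atoms = atoms, coords = coords,
                 center_atom = center_atom, dipole_atoms = dipole_atoms,
                 anchor_residues = anchor_residues,
                 align_residue = align_residue, attach_end = attach_end,
                 meta = meta),
            class = "dye_library")
}

#' @export
print.dye_library <- function(x, ...) {
  cat("<dye_library> ", x$dye_name, ": ", length(x$coords),
      " conformers, labels the ", x$attach_end, " end\n", sep = "")
  invisible(x)
}

#' Synthesize a mock dye library (synthetic stand-in)
#'
#' Builds a rigid mock fluorophore -- a six-membered carbon ring around a
#' central oxygen (the r-defining atom), linked by two carbons to a
#' dideoxy-adenosine dinucleotide anchor. Three linker torsions are drawn
#' uniformly per conformer, so dye positions cover a broad shell around
#' the terminus; anchor torsions get small Gaussian noise. This is a
#' synthetic geometry fixture, not a parameterization of a real
#' fluorophore.
#'
#' @param role "acceptor" (labels the 5' chain end, aligned via the
#'   anchor's 3' nucleotide) or "donor" (labels the 3' end, aligned via
#'   the anchor's 5' nucleotide).
#' @param n_conformers conformers to generate.
#' @param seed RNG seed.
#' @param noise anchor torsion noise, degrees.
#' @param dye_name residue name (defaults to MD59 for acceptor / MD48 for
#'   donor, mock labels).
#' @return a `dye_library`.
#' @export
synth_dye_library <- function(role = c("acceptor", "donor"),
                              n_conformers = 100, seed = 1, noise = 4,
                              dye_name = NULL) {
  role <- match.arg(role)
  if (is.null(dye_name)) dye_name <- if (role == "acceptor") "MD59" else "MD48"
  attach_res <- if (role == "acceptor") 1L else 2L  # dye hangs off this nt
  align_res <- if (role == "acceptor") 2L else 1L
  attach_end <- if (role == "acceptor") "5prime" else "3prime"
  with_seed(seed, {
    coords <- vector("list", n_conformers)
    atoms <- NULL
    for (k in seq_len(n_conformers)) {
      tt <- as.data.frame(as.list(.AFORM))[rep(1, 2), , drop = FALSE]
      for (cn in colnames(tt)) tt[[cn]] <- tt[[cn]] + rnorm(2, 0, noise)
      raw <- build_chain_internal("AA", tt)
      # dideoxy anchor: no 2'-hydroxyls
      keep <- raw$atoms$name != "O2'"
      am <- raw$atoms[keep, , drop = FALSE]
      X <- raw$coords[keep, , drop = FALSE]
      g <- function(res, nm) X[which(am$residue_index == res &
                                       am$name == nm)[1], ]
      if (attach_res == 1L) {
        a1 <- g(1, "C4'"); a2 <- g(1, "C5'"); a3 <- g(1, "O5'")
      } else {
        a1 <- g(2, "C4'"); a2 <- g(2, "C3'"); a3 <- g(2, "O3'")
      }
      t1 <- runif(1, -180, 180)
      t2 <- runif(1, -180, 180)
      t3 <- runif(1, -180, 180)
      cl1 <- place_atom(a1, a2, a3, 1.43, 113, t1)
      cl2 <- place_atom(a2, a3, cl1, 1.52, 112, t2)
      oc1 <- place_atom(a3, cl1, cl2, 1.43, 112, t3)
      u <- oc1 - cl2; u <- u / sqrt(sum(u^2))
      w <- cl2 - cl1
      nvec <- c(w[2] * u[3] - w[3] * u[2],
                w[3] * u[1] - w[1] * u[3],
                w[1] * u[2] - w[2] * u[1])
      nvec <- nvec / sqrt(sum(nvec^2))
      v <- c(nvec[2] * u[3] - nvec[3] * u[2],
             nvec[3] * u[1] - nvec[1] * u[3],
             nvec[1] * u[2] - nvec[2] * u[1])
      ring <- t(vapply(0:5, function(j) {
        th <- deg2rad(30 + 60 * j)
        oc1 + 1.39 * (cos(th) * u + sin(th) * v)
      }, numeric(3)))
      dye_names <- c("CL1", "CL2", "OC1", paste0("CD", 1:6))
      dye_coords <- rbind(cl1, cl2, oc1, ring)
      dam <- data.frame(name = dye_names,
                        element = c("C", "C", "O", rep("C", 6)),
                        residue_index = 3L, residue_name = dye_name,
                        stringsAsFactors = FALSE)
      if (is.null(atoms)) {
        atoms <- rbind(am, dam)
        rownames(atoms) <- NULL
      }
      coords[[k]] <- rbind(X, dye_coords)
      dimnames(coords[[k]]) <- NULL
    }
    new_dye_library(dye_name, atoms, coords, center_atom = "OC1",
                    dipole_atoms = c("CD1", "CD4"),
                    anchor_residues = 1:2, align_residue = align_res,
                    attach_end = attach_end,
                    meta = list(generator = "synth_dye_library",
                                role = role, seed = seed, noise = noise))
  })
}

# sugar + base heavy-atom names common to chain terminus and anchor
.SUGAR_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O2'", "O3'", "O4'",
                  "O5'")

#' Attach a dye conformer to one chain terminus
#'
#' Never moves any chain atom: the dye conformer is rigid-body transformed
#' onto the chain. On acceptance the fluorophore atoms are merged as an
#' extra residue (index 0 at the 5' end, n+1 at the 3' end), the anchor
#' nucleotides are dropped, and the chain's replaced terminal hydroxyl
#' oxygen is removed.
#'
#' @param conf an `rna_conformation`.
#' @param dye a `dye_library`.
#' @param conformer_index which dye conformer to use.
#' @param end "5prime" or "3prime" (defaults to the dye's declared end).
#' @param rmsd_cutoff alignment cutoff, Angstrom (default 0.8).
#' @param clash_cutoff heavy-atom clash distance, Angstrom (default 2.0).
#' @return labeled `rna_conformation` (with `provenance$dyes` recording
#'   the center-atom position and unit dipole), or an `hcg_rejection`
#'   with reason "rmsd" or "clash".
#' @export
attach_dye <- function(conf, dye, conformer_index = 1,
                       end = dye$attach_end, rmsd_cutoff = 0.8,
                       clash_cutoff = 2.0) {
  n <- n_residues(conf)
  term_res <- if (end == "5prime") 1L else n
  X_dye <- dye$coords[[conformer_index]]
  align_names <- intersect(
    conf$atoms$name[conf$atoms$residue_index == term_res],
    dye$atoms$name[dye$atoms$residue_index == dye$align_residue])
  align_names <- align_names[align_names %in%
                               c(.SUGAR_ATOMS,
                                 base_heavy_atoms(
                                   substr(conf$sequence, term_res,
                                          term_res)))]
  if (length(align_names) < 3)
    stop("fewer than 3 common sugar/base atoms for dye alignment")
  ic <- vapply(align_names, function(a) atom_row(conf, term_res, a),
               integer(1))
  id <- vapply(align_names, function(a)
    which(dye$atoms$residue_index == dye$align_residue &
            dye$atoms$name == a)[1], integer(1))
  fit <- weighted_superposition(X_dye[id, , drop = FALSE],
                                conf$coords[ic, , drop = FALSE])
  if (fit$wrmsd >= rmsd_cutoff)
    return(structure(list(reason = "rmsd", rmsd = fit$wrmsd),
                     class = "hcg_rejection"))
  X_dye_t <- apply_transform(X_dye, fit)
  dye_rows <- which(!(dye$atoms$residue_index %in% dye$anchor_residues))
  chain_rows <- which(conf$atoms$residue_index != term_res)
  nc <- .clash_count_cpp(conf$coords[chain_rows, , drop = FALSE],
                         X_dye_t[dye_rows, , drop = FALSE], clash_cutoff)
  if (nc > 0)
    return(structure(list(reason = "clash"), class = "hcg_rejection"))
  # merge: drop the chain's replaced terminal hydroxyl oxygen
  drop_name <- if (end == "5prime") "O5'" else "O3'"
  keep <- !(conf$atoms$residue_index == term_res &
              conf$atoms$name == drop_name)
  dam <- dye$atoms[dye_rows, , drop = FALSE]
  dam$residue_index <- if (end == "5prime") 0L else n + 1L
  atoms <- rbind(conf$atoms[keep, , drop = FALSE], dam)
  rownames(atoms) <- NULL
  coords <- rbind(conf$coords[keep, , drop = FALSE],
                  X_dye_t[dye_rows, , drop = FALSE])
  ctr <- X_dye_t[dye_rows, , drop = FALSE][
    which(dam$name == dye$center_atom)[1], ]
  d1 <- X_dye_t[dye_rows, , drop = FALSE][
    which(dam$name == dye$dipole_atoms[1])[1], ]
  d2 <- X_dye_t[dye_rows, , drop = FALSE][
    which(dam$name == dye$dipole_atoms[2])[1], ]
  mu <- (d2 - d1) / sqrt(sum((d2 - d1)^2))
  prov <- conf$provenance
  prov$dyes <- c(prov$dyes,
                 setNames(list(list(end = end, center = ctr, mu = mu,
                                    rmsd = fit$wrmsd)), dye$dye_name))
  new_conformation(atoms, coords, conf$sequence, prov)
}

#' Post-hoc dye-pair replacement with acceptance-rate weights
#'
#' Repeatedly attempts to place a randomly drawn donor and acceptor
#' conformer simultaneously on the two chain termini (acceptor at 5',
#' donor at 3' by the libraries' declared ends); an attempt succeeds only
#' if both labels pass their RMSD and clash tests and the two fluorophores
#' do not clash with each other. The normalized acceptance rate is the
#' chain's statistical weight for dye-averaged observables; the first
#' `max_placements` accepted placements are retained for model-2/3
#' averaging.
#'
#' @param chain an `rna_conformation` with both termini intact.
#' @param donor_lib,acceptor_lib `dye_library`s for the two ends.
#' @param n_attempts replacement attempts (default 1000).
#' @param seed RNG seed.
#' @param max_placements placements kept (default 20).
#' @param rmsd_cutoff,clash_cutoff acceptance thresholds (0.8 / 2.0 A).
#' @return list with `acceptance_weight` (successes / n_attempts),
#'   `n_success`, `n_attempts`, `distances` (interdye center distances of
#'   kept placements, nm) and `kappa2` (orientation factors of kept
#'   placements).
#' @export
remap_dye_pair <- function(chain, donor_lib, acceptor_lib,
                           n_attempts = 1000, seed = 1,
                           max_placements = 20, rmsd_cutoff = 0.8,
                           clash_cutoff = 2.0) {
  nd <- length(donor_lib$coords)
  na <- length(acceptor_lib$coords)
  distances <- numeric(0)
  k2s <- numeric(0)
  n_success <- 0L
  with_seed(seed, {
    for (att in seq_len(n_attempts)) {
      i <- sample.int(na, 1L)
      j <- sample.int(nd, 1L)
      lab1 <- attach_dye(chain, acceptor_lib, i, rmsd_cutoff = rmsd_cutoff,
                         clash_cutoff = clash_cutoff)
      if (inherits(lab1, "hcg_rejection")) next
      lab2 <- attach_dye(lab1, donor_lib, j, rmsd_cutoff = rmsd_cutoff,
                         clash_cutoff = clash_cutoff)
      if (inherits(lab2, "hcg_rejection")) next
      # fluorophore-fluorophore sterics
      accn <- acceptor_lib$dye_name
      donn <- donor_lib$dye_name
      ra <- which(lab2$atoms$residue_name == accn)
      rd <- which(lab2$atoms$residue_name == donn)
      if (.clash_count_cpp(lab2$coords[ra, , drop = FALSE],
                           lab2$coords[rd, , drop = FALSE],
                           clash_cutoff) > 0) next
      n_success <- n_success + 1L
      if (length(distances) < max_placements) {
        da <- lab2$provenance$dyes[[accn]]
        dd <- lab2$provenance$dyes[[donn]]
        rvec <- da$center - dd$center
        r <- sqrt(sum(rvec^2))
        distances <- c(distances, r / 10)  # Angstrom -> nm
        k2s <- c(k2s, kappa2(dd$mu, da$mu, rvec / r))
      }
    }
  })
  list(acceptance_weight = n_success / n_attempts, n_success = n_success,
       n_attempts = n_attempts, distances = distances, kappa2 = k2s)
}
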