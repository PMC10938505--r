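# Idealized per-residue geometry used by the synthetic fragment generator.
#
# Residues are built in internal coordinates: the six backbone torsions
# (alpha..zeta) and the glycosidic torsion chi are free parameters; bond
# lengths, bond angles, the C3'-endo sugar ring (pseudorotation P = 18 deg,
# amplitude 38 deg) and planar nucleobase geometries are fixed constants.
# Base in-plane coordinates and substituent torsion offsets were measured
# once from idealized ribonucleotide component geometries and are frozen
# here as plain numbers.

# bond lengths, Angstrom
.BL <- c(
  "O3'-P" = 1.607, "P-O5'" = 1.593, "P-OP" = 1.485,
  "O5'-C5'" = 1.440, "C5'-C4'" = 1.510, "C4'-C3'" = 1.524,
  "C3'-O3'" = 1.423, "C4'-O4'" = 1.451, "O4'-C1'" = 1.414,
  "C1'-C2'" = 1.528, "C2'-O2'" = 1.413, "C1'-N" = 1.468,
  "N9-C4" = 1.372, "N1-C2" = 1.344
)

# bond angles, degrees
.BA <- c(
  "C3'-O3'-P" = 119.7, "O3'-P-O5'" = 104.0, "P-O5'-C5'" = 120.9,
  "O5'-P-OP" = 108.0,
  "O5'-C5'-C4'" = 111.5, "C5'-C4'-C3'" = 115.5, "C4'-C3'-O3'" = 110.6,
  "C3'-C4'-O4'" = 104.8, "C5'-C4'-O4'" = 110.4, "C4'-O4'-C1'" = 109.7,
  "O4'-C1'-C2'" = 106.4,
  "C1'-C2'-O2'" = 110.7, "O4'-C1'-N" = 108.4,
  "C1'-N9-C4" = 126.3, "C1'-N1-C2" = 119.7
)

# C3'-endo sugar pseudorotation (P = 18 deg, tau_m = 38 deg):
# nu_j = tau_m * cos(P + 144 * (j - 2)) for j = 0..4
.NU <- 38 * cos(deg2rad(18 + 144 * ((0:4) - 2)))

# substituent torsion offsets about the parent-atom axis, measured from
# idealized ribonucleotide geometry; same-center offsets are rigid under
# pucker changes and encode the D-ribose chirality
.OFF <- c(N = -118.95,   # N vs C2' about O4'->C1'
          O2p = 118.80,  # O2' vs C3' about C1'->C2'
          O4p = -115.53) # O4' vs C3' about C5'->C4'

# A-form helical torsion means, degrees. Starting from canonical fibre
# values (alpha -68, beta 178, gamma 54, delta 82, epsilon -153, zeta -71,
# chi -158) each angle was calibrated by a few degrees so that the template
# chain reproduces A-form helical parameters (rise 2.81 A, twist ~33 deg)
# and clean base stacking under this bond-angle set.
.AFORM <- c(alpha = -67.3, beta = 172.6, gamma = 54.6, delta = 82.1,
            epsilon = -156.5, zeta = -69.6, chi = -155.2)

#' A-form mean torsions
#'
#' The per-residue torsion means (degrees) that the synthetic fragment
#' generator perturbs: backbone alpha..zeta plus glycosidic chi.
#' @return named numeric vector.
#' @export
aform_torsions <- function() .AFORM

# planar base heavy-atom coordinates (xi along N->first-chi-atom, eta
# in-plane) in the glycosidic frame; first atom is placed by chi itself
.BASE2D <- list(
  A = list(
    glyc = "N9", first = "C4",
    atoms = c("C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3"),
    xi  = c(-0.4080, 0.6255, 1.7594, 3.1332, 3.5744, 3.9985, 3.5856, 2.3105),
    eta = c(-1.3003, -2.0907, -1.3508, -1.6465, -2.9582, -0.6387, 0.6151,
            0.9402)
  ),
  G = list(
    glyc = "N9", first = "C4",
    atoms = c("C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3"),
    xi  = c(-0.4096, 0.6256, 1.7574, 3.1384, 3.5218, 4.0211, 3.5804, 4.5005,
            2.3007),
    eta = c(-1.3016, -2.0901, -1.3435, -1.6489, -2.8063, -0.6266, 0.6624,
            1.6807, 0.9594)
  ),
  U = list(
    glyc = "N1", first = "C2",
    atoms = c("O2", "N3", "C4", "O4", "C5", "C6"),
    xi  = c(1.9432, 2.0351, 1.3846, 2.0098, -0.0300, -0.6986),
    eta = c(1.0567, -1.1556, -2.3367, -3.3820, -2.3497, -1.1764)
  ),
  C = list(
    glyc = "N1", first = "C2",
    atoms = c("O2", "N3", "C4", "N4", "C5", "C6"),
    xi  = c(1.9448, 2.0323, 1.4047, 2.1246, -0.0048, -0.6891),
    eta = c(1.0618, -1.1409, -2.3094, -3.4811, -2.3433, -1.1753)
  )
)

#' Heavy-atom names of a nucleobase
#'
#' @param base one of "A", "U", "G", "C".
#' @return character vector of base ring/substituent heavy-atom names,
#'   starting with the glycosidic nitrogen.
#' @export
base_heavy_atoms <- function(base) {
  tpl <- .BASE2D[[base]]
  if (is.null(tpl)) stop("unknown base: ", base)
  c(tpl$glyc, tpl$first, tpl$atoms)
}

# full heavy-atom inventory of one residue (5' terminal residues lack the
# phosphate group, carrying a 5'-OH instead)
residue_atom_names <- function(base, five_prime_terminal = FALSE) {
  bb <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
          "C2'", "O2'", "C1'")
  if (five_prime_terminal) bb <- setdiff(bb, c("P", "OP1", "OP2"))
  c(bb, base_heavy_atoms(base))
}

.element_of <- function(name) substr(sub("^[0-9]", "", name), 1, 1)

# Build a chain from per-residue torsions. `torsions` is a data.frame with
# one row per residue and columns alpha..zeta, chi (degrees); alpha/beta of
# residue 1 and epsilon/zeta of the last residue are ignored.
# Returns list(atoms = meta data.frame, coords = matrix, sequence).
build_chain_internal <- function(sequence, torsions) {
  bases <- strsplit(sequence, "")[[1]]
  n <- length(bases)
  if (nrow(torsions) != n) stop("torsion table must have one row per residue")
  name_l <- list(); resi_l <- list(); resn_l <- list(); crd_l <- list()
  prev <- NULL  # list(C4, C3, O3) of previous residue
  for (i in seq_len(n)) {
    b <- bases[i]
    tt <- torsions[i, ]
    pos <- list()
    if (i == 1L) {
      pos[["O5'"]] <- c(0, 0, 0)
      pos[["C5'"]] <- c(.BL[["O5'-C5'"]], 0, 0)
      # torsion reference for the 5'-terminal residue is a virtual atom
      pos[["C4'"]] <- place_atom(c(0, 0, 1), pos[["O5'"]], pos[["C5'"]],
                                 .BL[["C5'-C4'"]], .BA[["O5'-C5'-C4'"]],
                                 tt$beta)
    } else {
      pos[["P"]] <- place_atom(prev$C4, prev$C3, prev$O3,
                               .BL[["O3'-P"]], .BA[["C3'-O3'-P"]],
                               prev$epsilon)
      pos[["O5'"]] <- place_atom(prev$C3, prev$O3, pos[["P"]],
                                 .BL[["P-O5'"]], .BA[["O3'-P-O5'"]],
                                 prev$zeta)
      pos[["C5'"]] <- place_atom(prev$O3, pos[["P"]], pos[["O5'"]],
                                 .BL[["O5'-C5'"]], .BA[["P-O5'-C5'"]],
                                 tt$alpha)
      pos[["C4'"]] <- place_atom(pos[["P"]], pos[["O5'"]], pos[["C5'"]],
                                 .BL[["C5'-C4'"]], .BA[["O5'-C5'-C4'"]],
                                 tt$beta)
      # pendant phosphate oxygens, +/-120 deg from the bridging O3'
      tb <- dihedral_angle(pos[["C5'"]], pos[["O5'"]], pos[["P"]], prev$O3)
      pos[["OP1"]] <- place_atom(pos[["C5'"]], pos[["O5'"]], pos[["P"]],
                                 .BL[["P-OP"]], .BA[["O5'-P-OP"]], tb + 120)
      pos[["OP2"]] <- place_atom(pos[["C5'"]], pos[["O5'"]], pos[["P"]],
                                 .BL[["P-OP"]], .BA[["O5'-P-OP"]], tb - 120)
    }
    pos[["C3'"]] <- place_atom(pos[["O5'"]], pos[["C5'"]], pos[["C4'"]],
                               .BL[["C4'-C3'"]], .BA[["C5'-C4'-C3'"]],
                               tt$gamma)
    pos[["O3'"]] <- place_atom(pos[["C5'"]], pos[["C4'"]], pos[["C3'"]],
                               .BL[["C3'-O3'"]], .BA[["C4'-C3'-O3'"]],
                               tt$delta)
    # sugar ring (C3'-endo) and exocyclic substituents
    pos[["O4'"]] <- place_atom(pos[["O5'"]], pos[["C5'"]], pos[["C4'"]],
                               .BL[["C4'-O4'"]], .BA[["C5'-C4'-O4'"]],
                               tt$gamma + .OFF[["O4p"]])
    pos[["C1'"]] <- place_atom(pos[["C3'"]], pos[["C4'"]], pos[["O4'"]],
                               .BL[["O4'-C1'"]], .BA[["C4'-O4'-C1'"]],
                               .NU[5])
    pos[["C2'"]] <- place_atom(pos[["C4'"]], pos[["O4'"]], pos[["C1'"]],
                               .BL[["C1'-C2'"]], .BA[["O4'-C1'-C2'"]],
                               .NU[1])
    pos[["O2'"]] <- place_atom(pos[["O4'"]], pos[["C1'"]], pos[["C2'"]],
                               .BL[["C2'-O2'"]], .BA[["C1'-C2'-O2'"]],
                               .NU[2] + .OFF[["O2p"]])
    # base, placed by chi about the glycosidic bond
    tpl <- .BASE2D[[b]]
    if (is.null(tpl)) stop("invalid base letter: ", b)
    pos[[tpl$glyc]] <- place_atom(pos[["C4'"]], pos[["O4'"]], pos[["C1'"]],
                                  .BL[["C1'-N"]], .BA[["O4'-C1'-N"]],
                                  .NU[1] + .OFF[["N"]])
    key_bond <- if (tpl$glyc == "N9") .BL[["N9-C4"]] else .BL[["N1-C2"]]
    key_ang <- if (tpl$glyc == "N9") .BA[["C1'-N9-C4"]] else .BA[["C1'-N1-C2"]]
    pos[[tpl$first]] <- place_atom(pos[["O4'"]], pos[["C1'"]],
                                   pos[[tpl$glyc]], key_bond, key_ang,
                                   tt$chi)
    Np <- pos[[tpl$glyc]]; Fp <- pos[[tpl$first]]; C1p <- pos[["C1'"]]
    xh <- Fp - Np; xh <- xh / sqrt(sum(xh^2))
    v <- C1p - Np
    zh <- c(xh[2] * v[3] - xh[3] * v[2],
            xh[3] * v[1] - xh[1] * v[3],
            xh[1] * v[2] - xh[2] * v[1])
    zh <- zh / sqrt(sum(zh^2))
    yh <- c(zh[2] * xh[3] - zh[3] * xh[2],
            zh[3] * xh[1] - zh[1] * xh[3],
            zh[1] * xh[2] - zh[2] * xh[1])
    for (k in seq_along(tpl$atoms))
      pos[[tpl$atoms[k]]] <- Np + tpl$xi[k] * xh + tpl$eta[k] * yh
    nm <- residue_atom_names(b, five_prime_terminal = (i == 1L))
    crd_l[[i]] <- do.call(rbind, pos[nm])
    name_l[[i]] <- nm
    resi_l[[i]] <- rep(i, length(nm))
    resn_l[[i]] <- rep(b, length(nm))
    prev <- list(C4 = pos[["C4'"]], C3 = pos[["C3'"]], O3 = pos[["O3'"]],
                 epsilon = tt$epsilon, zeta = tt$zeta)
  }
  name <- unlist(name_l)
  atoms <- data.frame(
    name = name,
    element = .element_of(name),
    residue_index = unlist(resi_l),
    residue_name = unlist(resn_l),
    stringsAsFactors = FALSE
  )
  coords <- do.call(rbind, crd_l)
  dimnames(coords) <- NULL
  list(atoms = atoms, coords = coords, sequence = sequence)
}

#' Build an ideal A-form single-stranded helix
#'
#' Constructs a single-stranded chain with every residue at the A-form
#' torsion means; consecutive bases are stacked under [detect_stacks()].
#'
#' @param sequence base string over A, U, G, C (5' to 3').
#' @return an `rna_conformation`.
#' @export
build_ideal_aform <- function(sequence) {
  check_sequence(sequence)
  n <- nchar(sequence)
  tt <- as.data.frame(as.list(.AFORM))[rep(1, n), , drop = FALSE]
  rownames(tt) <- NULL
  raw <- build_chain_internal(sequence, tt)
  new_conformation(raw$atoms, raw$coords, sequence,
                   provenance = list(source = "ideal_aform"))
}

#' Helical parameters of the ideal A-form template
#'
#' Screw decomposition of the rigid transform between consecutive residues
#' of the ideal template: per-residue rise (Angstrom) and twist (degrees).
#'
#' @return list with `rise`, `twist`, `axis` (unit 3-vector) and the
#'   residue-to-residue transform (`rotation`, `translation`).
#' @export
aform_helix_params <- function() {
  conf <- build_ideal_aform("AAAA")
  # transform mapping residue 2 atoms onto residue 3 atoms (both interior,
  # identical atom inventories)
  i2 <- which(conf$atoms$residue_index == 2)
  i3 <- which(conf$atoms$residue_index == 3)
  fit <- weighted_superposition(conf$coords[i2, ], conf$coords[i3, ])
  R <- fit$rotation
  tr <- fit$translation
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
  ev <- eigen(R)
  k <- which.min(abs(ev$values - 1))
  axis <- Re(ev$vectors[, k])
  axis <- axis / sqrt(sum(axis^2))
  rise <- sum(tr * axis)
  if (rise < 0) { axis <- -axis; rise <- -rise }
  list(rise = rise, twist = rad2deg(ang), axis = axis,
       rotation = R, translation = tr)
}
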