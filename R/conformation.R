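# The rna_conformation container: an ordered heavy-atom model of one chain.
# `atoms` is a data.frame (name, element, residue_index, residue_name),
# `coords` the matching n x 3 coordinate matrix in Angstrom.

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) < 1)
    stop("sequence must be a non-empty string")
  bad <- setdiff(strsplit(sequence, "")[[1]], c("A", "U", "G", "C"))
  if (length(bad))
    stop("invalid base letters in sequence: ", paste(bad, collapse = ", "))
  invisible(sequence)
}

#' Construct an RNA conformation
#'
#' @param atoms data.frame with columns `name`, `element`, `residue_index`,
#'   `residue_name`.
#' @param coords numeric n x 3 matrix, Angstrom.
#' @param sequence base string, one letter per residue (5' to 3').
#' @param provenance free-form list (source library, conformer index,
#'   merge history).
#' @return object of class `rna_conformation`.
#' @export
new_conformation <- function(atoms, coords, sequence, provenance = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(coords))
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  structure(list(sequence = sequence, atoms = atoms,
                 coords = as.matrix(coords), provenance = provenance),
            class = "rna_conformation")
}

#' @export
print.rna_conformation <- function(x, ...) {
  cat("<rna_conformation> ", x$sequence, "  (", n_residues(x), " nt, ",
      nrow(x$atoms), " heavy atoms)\n", sep = "")
  invisible(x)
}

#' Number of residues in a conformation
#' @param conf an `rna_conformation`.
#' @export
n_residues <- function(conf) nchar(conf$sequence)

# row index of one named atom in one residue (0 if absent)
atom_row <- function(conf, residue_index, name) {
  i <- which(conf$atoms$residue_index == residue_index &
               conf$atoms$name == name)
  if (length(i) == 0) 0L else i[1]
}

atom_xyz <- function(conf, residue_index, name) {
  i <- atom_row(conf, residue_index, name)
  if (i == 0L) stop("atom ", name, " missing in residue ", residue_index)
  conf$coords[i, ]
}

#' Validate a conformation
#'
#' Checks sequence/residue agreement, per-residue atom completeness
#' (backbone P -- absent only at a 5' terminus -- O5', C5', C4', C3', O3'
#' and the full heavy-atom base), unique atom names per residue, and
#' covalent continuity O3'(i)-P(i+1) < 2.5 Angstrom at internal junctions.
#'
#' @param conf an `rna_conformation`.
#' @param check_continuity verify the O3'-P junction distances.
#' @return invisibly TRUE; stops with a descriptive error otherwise.
#' @export
validate_conformation <- function(conf, check_continuity = TRUE) {
  n <- n_residues(conf)
  bases <- strsplit(conf$sequence, "")[[1]]
  resi <- sort(unique(conf$atoms$residue_index))
  if (!identical(resi, seq_len(n)))
    stop("residue indices not consecutive 1..", n)
  for (i in seq_len(n)) {
    sel <- conf$atoms$residue_index == i
    nm <- conf$atoms$name[sel]
    if (anyDuplicated(nm))
      stop("duplicate atom names in residue ", i)
    if (!all(conf$atoms$residue_name[sel] == bases[i]))
      stop("residue_name disagrees with sequence at residue ", i)
    need <- c("O5'", "C5'", "C4'", "C3'", "O3'", base_heavy_atoms(bases[i]))
    if (i > 1) need <- c("P", need)
    miss <- setdiff(need, nm)
    if (length(miss))
      stop("residue ", i, " missing atoms: ", paste(miss, collapse = ", "))
  }
  if (check_continuity && n > 1) {
    for (i in seq_len(n - 1)) {
      d <- sqrt(sum((atom_xyz(conf, i, "O3'") -
                       atom_xyz(conf, i + 1, "P"))^2))
      if (d >= 2.5)
        stop("covalent discontinuity at junction ", i, "-", i + 1,
             sprintf(": O3'-P = %.2f A", d))
    }
  }
  invisible(TRUE)
}

#' Radius of gyration from coordinates
#'
#' Root-mean-square distance of heavy atoms from their centroid.
#'
#' @param conf an `rna_conformation` (or bare n x 3 matrix).
#' @param mass_weighted weight atoms by approximate atomic mass.
#' @return R_G in Angstrom.
#' @export
radius_of_gyration <- function(conf, mass_weighted = FALSE) {
  x <- if (inherits(conf, "rna_conformation")) conf$coords else as.matrix(conf)
  if (nrow(x) < 1) stop("empty conformation")
  w <- rep(1, nrow(x))
  if (mass_weighted) {
    m <- c(C = 12.011, N = 14.007, O = 15.999, P = 30.974)
    w <- m[conf$atoms$element]
    w[is.na(w)] <- 12
  }
  w <- w / sum(w)
  ctr <- colSums(x * w)
  sqrt(sum(w * rowSums(sweep(x, 2, ctr)^2)))
}

#' End-to-end distance O5'(1) to O3'(n)
#'
#' @param conf an `rna_conformation`.
#' @return distance in Angstrom.
#' @export
end_to_end_distance <- function(conf) {
  n <- n_residues(conf)
  a <- atom_xyz(conf, 1, "O5'")
  b <- atom_xyz(conf, n, "O3'")
  sqrt(sum((a - b)^2))
}

#' Backbone and glycosidic torsion angles
#'
#' Standard nucleic-acid torsions alpha, beta, gamma, delta, epsilon, zeta
#' and chi per residue, degrees in (-180, 180]. Entries whose defining
#' atoms are missing (chain termini) are NA.
#'
#' @param conf an `rna_conformation`.
#' @return data.frame with one row per residue.
#' @export
backbone_torsions <- function(conf) {
  n <- n_residues(conf)
  g <- function(i, nm) {
    if (i < 1 || i > n) return(NULL)
    k <- atom_row(conf, i, nm)
    if (k == 0L) NULL else conf$coords[k, ]
  }
  tors <- function(p) {
    if (any(vapply(p, is.null, logical(1)))) return(NA_real_)
    dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
  }
  out <- data.frame(residue_index = seq_len(n), alpha = NA_real_,
                    beta = NA_real_, gamma = NA_real_, delta = NA_real_,
                    epsilon = NA_real_, zeta = NA_real_, chi = NA_real_)
  bases <- strsplit(conf$sequence, "")[[1]]
  for (i in seq_len(n)) {
    out$alpha[i] <- tors(list(g(i - 1, "O3'"), g(i, "P"), g(i, "O5'"),
                              g(i, "C5'")))
    out$beta[i] <- tors(list(g(i, "P"), g(i, "O5'"), g(i, "C5'"),
                             g(i, "C4'")))
    out$gamma[i] <- tors(list(g(i, "O5'"), g(i, "C5'"), g(i, "C4'"),
                              g(i, "C3'")))
    out$delta[i] <- tors(list(g(i, "C5'"), g(i, "C4'"), g(i, "C3'"),
                              g(i, "O3'")))
    out$epsilon[i] <- tors(list(g(i, "C4'"), g(i, "C3'"), g(i, "O3'"),
                                g(i + 1, "P")))
    out$zeta[i] <- tors(list(g(i, "C3'"), g(i, "O3'"), g(i + 1, "P"),
                             g(i + 1, "O5'")))
    if (bases[i] %in% c("A", "G"))
      out$chi[i] <- tors(list(g(i, "O4'"), g(i, "C1'"), g(i, "N9"),
                              g(i, "C4")))
    else
      out$chi[i] <- tors(list(g(i, "O4'"), g(i, "C1'"), g(i, "N1"),
                              g(i, "C2")))
  }
  out
}

#' Junction alignment specification for merging two pieces
#'
#' The overlap superposition pairs the backbone O3' of piece1's nucleotide
#' -2 with O3' of piece2's nucleotide 1, and P/O5' of piece1's nucleotide
#' -1 with P/O5' of piece2's nucleotide 2 (weight 2 each), plus all heavy
#' atoms of the nucleobase and C1' of piece1's nucleotide -1 paired with
#' piece2's nucleotide 2 (weight 1 each).
#'
#' @param piece1,piece2 `rna_conformation`s with >= 2 nucleotides; the base
#'   of piece1's last nucleotide must equal the base of piece2's second.
#' @param rmsd_cutoff acceptance threshold on the weighted RMSD (Angstrom).
#' @return list with `idx1`, `idx2` (atom row indices), `weights`,
#'   `atom_names` and `rmsd_cutoff`.
#' @export
junction_alignment_spec <- function(piece1, piece2, rmsd_cutoff = 0.64) {
  n1 <- n_residues(piece1)
  if (n1 < 2 || n_residues(piece2) < 2)
    stop("both pieces need at least 2 nucleotides")
  b1 <- substr(piece1$sequence, n1, n1)
  b2 <- substr(piece2$sequence, 2, 2)
  if (b1 != b2)
    stop("sequence incompatibility at overlap: piece1 ends ...",
         substr(piece1$sequence, max(1, n1 - 2), n1), " (overlap base ", b1,
         ") but piece2 starts ", substr(piece2$sequence, 1, 3),
         "... (overlap base ", b2, ")")
  names1 <- c("O3'", "P", "O5'")
  res1 <- c(n1 - 1L, n1, n1)
  res2 <- c(1L, 2L, 2L)
  base_atoms <- c(base_heavy_atoms(b1), "C1'")
  nm <- c(names1, base_atoms)
  r1 <- c(res1, rep(n1, length(base_atoms)))
  r2 <- c(res2, rep(2L, length(base_atoms)))
  idx1 <- mapply(function(r, a) atom_row(piece1, r, a), r1, nm)
  idx2 <- mapply(function(r, a) atom_row(piece2, r, a), r2, nm)
  if (any(idx1 == 0L) || any(idx2 == 0L))
    stop("missing junction atoms: ",
         paste(nm[idx1 == 0L | idx2 == 0L], collapse = ", "))
  list(idx1 = as.integer(idx1), idx2 = as.integer(idx2),
       weights = c(rep(2, 3), rep(1, length(base_atoms))),
       atom_names = nm, rmsd_cutoff = rmsd_cutoff)
}
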