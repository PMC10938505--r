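# Multi-model PDB reader/writer for conformational ensembles and fragment
# libraries. Atom names follow PDB v3 RNA conventions (primed, e.g. O5');
# legacy star names (O5*) and long residue names (ADE, URA, ...) are
# normalized on input. Hydrogens are dropped on read: the whole toolchain
# operates on heavy atoms.

normalize_atom_name <- function(name) gsub("*", "'", trimws(name), fixed = TRUE)

normalize_residue_name <- function(resn) {
  map <- c(A = "A", U = "U", G = "G", C = "C",
           ADE = "A", URA = "U", GUA = "G", CYT = "C",
           RA = "A", RU = "U", RG = "G", RC = "C",
           RA3 = "A", RA5 = "A", RU3 = "U", RU5 = "U",
           RG3 = "G", RG5 = "G", RC3 = "C", RC5 = "C")
  out <- unname(map[trimws(resn)])
  ifelse(is.na(out), trimws(resn), out)
}

#' Read a multi-model PDB file
#'
#' @param path PDB file with one or more MODEL/ENDMDL blocks (a file without
#'   MODEL records is treated as a single model).
#' @param drop_hydrogens discard hydrogen atoms (default TRUE).
#' @return list of models, each `list(atoms = data.frame, coords = matrix)`.
#' @export
read_pdb_models <- function(path, drop_hydrogens = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- rec == "MODEL "
  if (!any(is_atom)) stop("no ATOM records in ", path)
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  model_id[model_id == 0L] <- 1L
  al <- lines[is_atom]
  mid <- model_id[is_atom]
  name <- normalize_atom_name(substr(al, 13, 16))
  resn <- normalize_residue_name(substr(al, 18, 20))
  resi <- as.integer(substr(al, 23, 26))
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  element <- trimws(substr(al, 77, 78))
  element[element == ""] <- .element_of(name[element == ""])
  if (drop_hydrogens) {
    keep <- element != "H" & element != "D"
    al <- al[keep]; mid <- mid[keep]; name <- name[keep]
    resn <- resn[keep]; resi <- resi[keep]
    x <- x[keep]; y <- y[keep]; z <- z[keep]; element <- element[keep]
  }
  lapply(split(seq_along(al), mid), function(ix) {
    ri <- resi[ix]
    ri <- as.integer(factor(ri, levels = unique(ri)))  # renumber 1..n
    list(atoms = data.frame(name = name[ix], element = element[ix],
                            residue_index = ri,
                            residue_name = resn[ix],
                            stringsAsFactors = FALSE),
         coords = cbind(x[ix], y[ix], z[ix]))
  })
}

#' Read a multi-model PDB as a list of conformations
#'
#' @inheritParams read_pdb_models
#' @return list of `rna_conformation`s.
#' @export
read_pdb_conformations <- function(path) {
  models <- read_pdb_models(path)
  lapply(seq_along(models), function(i) {
    m <- models[[i]]
    seq <- paste(m$atoms$residue_name[!duplicated(m$atoms$residue_index)],
                 collapse = "")
    new_conformation(m$atoms, m$coords, seq,
                     provenance = list(source = path, model = i))
  })
}

format_atom_line <- function(serial, name, resn, resi, xyz, element) {
  nm <- ifelse(nchar(name) < 4, paste0(" ", name), name)
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resn, resi, xyz[1], xyz[2], xyz[3], 1, 0, element)
}

#' Write conformations as a multi-model PDB file
#'
#' @param confs a single `rna_conformation` or a list of them.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_pdb_models <- function(confs, path) {
  if (inherits(confs, "rna_conformation")) confs <- list(confs)
  if (length(confs) == 0) stop("no conformations to write")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(confs)) {
    cf <- confs[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- vapply(seq_len(nrow(cf$atoms)), function(i) {
      format_atom_line(i, cf$atoms$name[i], cf$atoms$residue_name[i],
                       cf$atoms$residue_index[i], cf$coords[i, ],
                       cf$atoms$element[i])
    }, character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
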