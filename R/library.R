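# Fragment libraries: pools of conformers sharing one short sequence, the
# synthetic library generator that stands in for MD-derived tetramer
# libraries, and the tiling planner that resolves a target sequence into
# fragment keys for hierarchical growth.

#' Construct a fragment library
#'
#' @param key fragment sequence (e.g. "AAAA", or "GUCA" for a G-capped
#'   heterotetramer).
#' @param atoms shared atom metadata data.frame (all conformers have the
#'   identical inventory).
#' @param coords list of n x 3 coordinate matrices, one per conformer.
#' @param meta provenance list (source path, or generator parameters + seed).
#' @return object of class `fragment_library`.
#' @export
new_fragment_library <- function(key, atoms, coords, meta = list()) {
  check_sequence(key)
  if (length(coords) < 1) stop("library needs at least one conformer")
  structure(list(key = key, atoms = atoms, coords = coords, meta = meta),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("<fragment_library> ", x$key, ": ", length(x$coords), " conformers, ",
      nrow(x$atoms), " heavy atoms each\n", sep = "")
  invisible(x)
}

#' Number of conformers in a library
#' @param lib a `fragment_library`.
#' @export
n_conformers <- function(lib) length(lib$coords)

#' Extract one conformer as a conformation
#'
#' @param lib a `fragment_library`.
#' @param i conformer index.
#' @return an `rna_conformation`.
#' @export
library_conformation <- function(lib, i) {
  if (i < 1 || i > n_conformers(lib)) stop("conformer index out of range")
  new_conformation(lib$atoms, lib$coords[[i]], lib$key,
                   provenance = list(library = lib$key, conformer = i))
}

#' Load a fragment library from a multi-model PDB file
#'
#' All models must share the same sequence and atom inventory; offending
#' model indices are reported otherwise. A JSON sidecar `<path>.json`, if
#' present, is attached as metadata.
#'
#' @param path multi-model PDB file.
#' @return a `fragment_library` keyed by the fragment sequence.
#' @export
load_library <- function(path) {
  models <- read_pdb_models(path)
  sig <- vapply(models, function(m)
    paste(m$atoms$name, m$atoms$residue_index, m$atoms$residue_name,
          collapse = "|"), character(1))
  bad <- which(sig != sig[1])
  if (length(bad))
    stop("inconsistent sequence/atom inventory across models in ", path,
         "; offending model indices: ", paste(bad, collapse = ", "))
  atoms <- models[[1]]$atoms
  key <- paste(atoms$residue_name[!duplicated(atoms$residue_index)],
               collapse = "")
  meta <- list(source = path, n_models = length(models))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- c(meta, jsonlite::read_json(sidecar))
  new_fragment_library(key, atoms, lapply(models, `[[`, "coords"), meta)
}

#' Write a fragment library to a multi-model PDB file (+ JSON sidecar)
#'
#' @param lib a `fragment_library`.
#' @param path output PDB path; metadata goes to `<path>.json`.
#' @return invisibly `path`.
#' @export
write_library <- function(lib, path) {
  confs <- lapply(seq_len(n_conformers(lib)), function(i)
    library_conformation(lib, i))
  write_pdb_models(confs, path)
  jsonlite::write_json(
    c(list(key = lib$key, n_conformers = n_conformers(lib)), lib$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# count intra-fragment heavy-atom clashes, exempting the covalent
# O3'(i)-P(i+1) linkage and adjacent phosphate-group contacts
self_clash_count <- function(atoms, coords, cutoff = 2.0) {
  .chain_clash_count_cpp(coords, as.integer(atoms$residue_index),
                         atoms$name == "O3'",
                         atoms$name %in% c("P", "OP1", "OP2", "O5'"),
                         cutoff)
}

#' Synthesize a fragment library from the idealized A-form template
#'
#' Emulates MD-derived tetramer libraries: conformers are built in internal
#' coordinates from per-residue templates, with Gaussian noise (sd `noise`
#' degrees) on the backbone torsions alpha..zeta and the glycosidic chi.
#' With probability `unstack_prob` per *terminal* residue, that residue is
#' additionally flipped to a syn-like, unstacked state (chi rotated by 180
#' degrees plus extra backbone noise). The default 0.2 per terminal makes
#' ~64% of tetramers fully A-form-like and ~32% carry one perturbed
#' terminal, emulating the cluster structure of MD tetramer libraries
#' (dominant stacked cluster plus a large terminal-base-inverted cluster
#' and sparse unstacked states). Conformers
#' with internal steric clashes are regenerated (MD libraries are
#' clash-free by construction).
#'
#' @param key fragment sequence (any length >= 1; tetramers in normal use).
#' @param n_conformers number of conformers to generate.
#' @param noise torsion standard deviation, degrees (default 8).
#' @param unstack_prob per-terminal-residue probability of an unstacked
#'   state (default 0.2).
#' @param seed RNG seed; the library is a deterministic function of it.
#' @return a `fragment_library`.
#' @export
synth_fragment_library <- function(key, n_conformers, noise = 8,
                                   unstack_prob = 0.2, seed = 1) {
  check_sequence(key)
  if (n_conformers < 1) stop("n_conformers must be >= 1")
  if (noise < 0) stop("noise must be >= 0")
  n <- nchar(key)
  base_t <- as.data.frame(as.list(.AFORM))[rep(1, n), , drop = FALSE]
  rownames(base_t) <- NULL
  with_seed(seed, {
    coords <- vector("list", n_conformers)
    atoms <- NULL
    for (k in seq_len(n_conformers)) {
      repeat {
        tt <- base_t
        for (cn in colnames(tt))
          tt[[cn]] <- tt[[cn]] + rnorm(n, 0, noise)
        for (i in unique(c(1L, n))) {
          if (runif(1) < unstack_prob) {
            tt$chi[i] <- tt$chi[i] + 180 + rnorm(1, 0, 20)
            tt$gamma[i] <- tt$gamma[i] + rnorm(1, 0, 25)
            if (i == 1L) tt$zeta[i] <- tt$zeta[i] + rnorm(1, 0, 25)
            else tt$alpha[i] <- tt$alpha[i] + rnorm(1, 0, 25)
          }
        }
        raw <- build_chain_internal(key, tt)
        if (self_clash_count(raw$atoms, raw$coords) == 0L) break
      }
      coords[[k]] <- raw$coords
      if (is.null(atoms)) atoms <- raw$atoms
    }
    new_fragment_library(key, atoms, coords,
                         meta = list(generator = "synth_fragment_library",
                                     noise = noise,
                                     unstack_prob = unstack_prob,
                                     seed = seed))
  })
}

#' Plan the fragment tiling for a target sequence
#'
#' Resolves a target sequence into an ordered list of fragment keys and the
#' positions each fragment contributes to the assembled chain. Each pairwise
#' merge removes the last nucleotide of the left piece and the first of the
#' right piece, so k tetramer fragments yield a chain of 2k + 2 nucleotides
#' before cap trimming.
#'
#' In `heteropolymer` mode, fragments are G-capped tetramers
#' G-s(2j-1)-s(2j)-s(2j+1); each interior fragment contributes its two
#' middle nucleotides (X, Y), the leading G cap and (for even-length
#' targets) the final fragment's 3' cap are trimmed. For odd-length targets
#' the final fragment's 3' position *is* the last target nucleotide and is
#' retained. In `homopolymer` mode a single repeated key (e.g. "AAAA") is
#' tiled; odd target lengths retain one terminal cap which is trimmed after
#' growth.
#'
#' @param sequence target chain sequence (length >= 4, alphabet A/U/G/C).
#' @param mode "homopolymer" or "heteropolymer".
#' @param final_cap base used for the very last fragment's 3' cap position
#'   in even-length heteropolymer tilings (trimmed from the chain; default
#'   "A").
#' @param keep_caps if TRUE, terminal caps are kept in the grown chain
#'   instead of trimmed (the chain then carries extra terminal
#'   nucleotides).
#' @return object of class `hcg_tiling_plan`.
#' @export
plan_tiling <- function(sequence, mode = c("heteropolymer", "homopolymer"),
                        final_cap = "A", keep_caps = FALSE) {
  mode <- match.arg(mode)
  check_sequence(sequence)
  L <- nchar(sequence)
  if (L < 4) stop("target sequence must have length >= 4")
  s <- strsplit(sequence, "")[[1]]
  if (mode == "homopolymer") {
    if (length(unique(s)) != 1)
      stop("homopolymer mode requires a single-letter sequence")
    k <- ceiling((L - 2) / 2)
    keys <- rep(strrep(s[1], 4), k)
    odd <- (2 * k + 2) > L
    trim3 <- !keep_caps && odd
    trim5 <- FALSE
    cap3 <- if (odd) s[1] else NA_character_
  } else {
    odd <- L %% 2 == 1
    k <- if (odd) (L - 1) / 2 else L / 2
    if (k < 2) stop("heteropolymer tiling needs length >= 4")
    keys <- character(k)
    for (j in seq_len(k - 1))
      keys[j] <- paste0("G", s[2 * j - 1], s[2 * j], s[2 * j + 1])
    if (odd) {
      keys[k] <- paste0("G", s[L - 2], s[L - 1], s[L])
      cap3 <- NA_character_  # final Z is a real target nucleotide
      trim3 <- FALSE
    } else {
      check_sequence(final_cap)
      keys[k] <- paste0("G", s[L - 1], s[L], final_cap)
      cap3 <- final_cap
      trim3 <- !keep_caps
    }
    trim5 <- !keep_caps
  }
  # retained within-fragment positions after all merges
  contributed <- lapply(seq_len(k), function(j) {
    lo <- if (j == 1) 1L else 2L
    hi <- if (j == k) 4L else 3L
    lo:hi
  })
  plan <- structure(list(sequence = sequence, mode = mode, n_fragments = k,
                         fragment_keys = keys, contributed = contributed,
                         trim_five_prime = trim5, trim_three_prime = trim3,
                         final_cap = cap3, keep_caps = keep_caps),
                    class = "hcg_tiling_plan")
  grown <- tiled_sequence(plan, trimmed = !keep_caps)
  if (!keep_caps && grown != sequence)
    stop("internal tiling error: retained positions give ", grown,
         " instead of ", sequence)
  plan
}

# sequence of the grown chain implied by a plan (before or after trimming)
tiled_sequence <- function(plan, trimmed = TRUE) {
  k <- plan$n_fragments
  pieces <- vapply(seq_len(k), function(j) {
    key <- strsplit(plan$fragment_keys[j], "")[[1]]
    lo <- if (j == 1) 1L else 2L
    hi <- if (j == k) 4L else 3L
    paste(key[lo:hi], collapse = "")
  }, character(1))
  out <- paste(pieces, collapse = "")
  if (trimmed) {
    if (plan$trim_five_prime) out <- substr(out, 2, nchar(out))
    if (plan$trim_three_prime) out <- substr(out, 1, nchar(out) - 1)
  }
  out
}

#' @export
print.hcg_tiling_plan <- function(x, ...) {
  cat("<hcg_tiling_plan> ", x$mode, " tiling of ", x$sequence, " (",
      nchar(x$sequence), " nt)\n", sep = "")
  cat("  fragments: ", paste(x$fragment_keys, collapse = " "), "\n", sep = "")
  cat("  trim 5' cap: ", x$trim_five_prime, ", trim 3' cap: ",
      x$trim_three_prime, "\n", sep = "")
  invisible(x)
}

#' Synthesize all fragment libraries needed by a tiling plan
#'
#' @param plan an `hcg_tiling_plan`.
#' @param n_conformers conformers per library.
#' @param seed top seed; per-key seeds derived deterministically.
#' @param ... passed to [synth_fragment_library()] (`noise`,
#'   `unstack_prob`).
#' @return named list of `fragment_library`, one per unique key.
#' @export
synth_plan_libraries <- function(plan, n_conformers = 200, seed = 1, ...) {
  keys <- unique(plan$fragment_keys)
  libs <- lapply(seq_along(keys), function(i)
    synth_fragment_library(keys[i], n_conformers,
                           seed = derive_seed(seed, 0, i), ...))
  names(libs) <- keys
  libs
}
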