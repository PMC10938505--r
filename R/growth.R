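# The hierarchical chain growth (HCG) engine. Fragment pools are combined
# pairwise: a random conformer is drawn from each pool, the right piece is
# rigidly superimposed onto the left at the two-nucleotide junction overlap
# (doubled backbone weights), and the pair is rejected if the weighted RMSD
# exceeds the cutoff or if any retained heavy-atom pair clashes. On a
# successful merge the overlap nucleotides (last of left, first of right)
# are removed; the bridging phosphate comes from the right piece, which
# preserves its sampled alpha torsion. Levels repeat until full length.

#' Growth configuration
#'
#' @param rmsd_cutoff junction alignment cutoff on the weighted RMSD,
#'   Angstrom (0.64 for fragment growth; 1.0 in structured/mixed assembly).
#' @param clash_cutoff heavy-atom steric clash distance, Angstrom.
#' @param n_chains target ensemble size.
#' @param max_attempts draw attempts per merged conformation before growth
#'   is declared failed (failing loudly rather than silently under-filling
#'   avoids biased ensembles).
#' @param seed top-level RNG seed; per-level, per-slot substreams are
#'   derived deterministically.
#' @return object of class `hcg_growth_config`.
#' @export
growth_config <- function(rmsd_cutoff = 0.64, clash_cutoff = 2.0,
                          n_chains = 10000, max_attempts = 1000, seed = 1) {
  if (rmsd_cutoff <= 0 || clash_cutoff <= 0) stop("cutoffs must be positive")
  if (n_chains < 1) stop("n_chains must be >= 1")
  if (max_attempts < 1) stop("max_attempts must be >= 1")
  structure(list(rmsd_cutoff = rmsd_cutoff, clash_cutoff = clash_cutoff,
                 n_chains = as.integer(n_chains),
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "hcg_growth_config")
}

# ---- pools ----------------------------------------------------------------

new_pool <- function(atoms, coords, sequence) {
  structure(list(atoms = atoms, coords = coords, sequence = sequence),
            class = "hcg_pool")
}

as_pool <- function(x) {
  if (inherits(x, "hcg_pool")) return(x)
  if (inherits(x, "fragment_library"))
    return(new_pool(x$atoms, x$coords, x$key))
  if (inherits(x, "rna_conformation"))
    return(new_pool(x$atoms, list(x$coords), x$sequence))
  if (is.list(x) && length(x) > 0 &&
        all(vapply(x, inherits, logical(1), "rna_conformation"))) {
    if (length(unique(vapply(x, `[[`, character(1), "sequence"))) != 1)
      stop("all conformations in a pool must share one sequence")
    return(new_pool(x[[1]]$atoms, lapply(x, `[[`, "coords"),
                    x[[1]]$sequence))
  }
  stop("cannot interpret object as a conformer pool")
}

pool_conformation <- function(pool, i, provenance = list()) {
  new_conformation(pool$atoms, pool$coords[[i]], pool$sequence, provenance)
}

meta_atom_row <- function(atoms, residue_index, name) {
  i <- which(atoms$residue_index == residue_index & atoms$name == name)
  if (length(i) == 0) 0L else i[1]
}

# ---- merge machinery ------------------------------------------------------

# Precompute everything reusable for merging conformers of pool1 x pool2:
# junction atom indices/weights, retained rows, clash-search rows and the
# merged atom metadata.
merge_cache <- function(atoms1, seq1, atoms2, seq2, cfg) {
  n1 <- nchar(seq1)
  n2 <- nchar(seq2)
  if (n1 < 2 || n2 < 2) stop("both pieces need at least 2 nucleotides")
  b1 <- substr(seq1, n1, n1)
  b2 <- substr(seq2, 2, 2)
  if (b1 != b2)
    stop("sequence incompatibility at overlap: piece1 overlap base ", b1,
         " vs piece2 overlap base ", b2, " (pieces ", seq1, " + ", seq2, ")")
  base_atoms <- c(base_heavy_atoms(b1), "C1'")
  nm <- c("O3'", "P", "O5'", base_atoms)
  r1 <- c(n1 - 1L, n1, n1, rep(n1, length(base_atoms)))
  r2 <- c(1L, 2L, 2L, rep(2L, length(base_atoms)))
  idx1 <- mapply(meta_atom_row, r1, nm, MoreArgs = list(atoms = atoms1))
  idx2 <- mapply(meta_atom_row, r2, nm, MoreArgs = list(atoms = atoms2))
  if (any(idx1 == 0L) || any(idx2 == 0L))
    stop("missing junction atoms for overlap alignment: ",
         paste(nm[idx1 == 0L | idx2 == 0L], collapse = ", "))
  keep1 <- which(atoms1$residue_index != n1)
  keep2 <- which(atoms2$residue_index != 1L)
  # clash search: all retained heavy atoms except the overlap-region
  # backbone atoms that were aligned (O3' of left nt -2; P/O5' of right
  # nt 2); atoms of the removed nucleotides are excluded implicitly
  clash1 <- which(atoms1$residue_index < n1 &
                    !(atoms1$residue_index == n1 - 1L & atoms1$name == "O3'"))
  clash2 <- which(atoms2$residue_index > 1L &
                    !(atoms2$residue_index == 2L &
                        atoms2$name %in% c("P", "O5'")))
  m2 <- atoms2[keep2, , drop = FALSE]
  m2$residue_index <- m2$residue_index + n1 - 2L
  merged_atoms <- rbind(atoms1[keep1, , drop = FALSE], m2)
  rownames(merged_atoms) <- NULL
  list(idx1 = as.integer(idx1), idx2 = as.integer(idx2),
       weights = c(rep(2, 3), rep(1, length(base_atoms))),
       keep1 = keep1, keep2 = keep2, clash1 = clash1, clash2 = clash2,
       merged_atoms = merged_atoms,
       merged_sequence = paste0(substr(seq1, 1, n1 - 1),
                                substr(seq2, 2, n2)))
}

merge_once <- function(X1, X2, cache, cfg) {
  fit <- tryCatch(
    weighted_superposition(X2[cache$idx2, , drop = FALSE],
                           X1[cache$idx1, , drop = FALSE], cache$weights),
    error = function(e) NULL)
  if (is.null(fit)) return(list(ok = FALSE, reason = "rmsd"))
  if (fit$wrmsd >= cfg$rmsd_cutoff) return(list(ok = FALSE, reason = "rmsd"))
  X2t <- apply_transform(X2, fit)
  nc <- .clash_count_cpp(X1[cache$clash1, , drop = FALSE],
                         X2t[cache$clash2, , drop = FALSE],
                         cfg$clash_cutoff)
  if (nc > 0) return(list(ok = FALSE, reason = "clash"))
  list(ok = TRUE,
       coords = rbind(X1[cache$keep1, , drop = FALSE],
                      X2t[cache$keep2, , drop = FALSE]),
       wrmsd = fit$wrmsd)
}

#' Attempt to merge two chain pieces
#'
#' Performs one junction alignment + clash test and, on success, returns
#' the merged covalently continuous conformation; otherwise a rejection
#' object carrying the reason ("rmsd" or "clash"). Precondition violations
#' (overlap base mismatch, missing atoms) raise errors instead.
#'
#' @param piece1,piece2 `rna_conformation`s; piece1's last two nucleotides
#'   overlap piece2's first two.
#' @param cfg an [growth_config()].
#' @return merged `rna_conformation`, or an object of class
#'   `hcg_rejection` with a `reason` field.
#' @export
attempt_merge <- function(piece1, piece2, cfg = growth_config()) {
  cache <- merge_cache(piece1$atoms, piece1$sequence,
                       piece2$atoms, piece2$sequence, cfg)
  res <- merge_once(piece1$coords, piece2$coords, cache, cfg)
  if (!res$ok)
    return(structure(list(reason = res$reason), class = "hcg_rejection"))
  new_conformation(cache$merged_atoms, res$coords, cache$merged_sequence,
                   provenance = list(
                     merge = list(left = piece1$provenance,
                                  right = piece2$provenance),
                     wrmsd = res$wrmsd))
}

#' @export
print.hcg_rejection <- function(x, ...) {
  cat("<hcg_rejection> reason:", x$reason, "\n")
  invisible(x)
}

# one merge slot: fill n_out conformations from pool1 x pool2
merge_pools <- function(pool1, pool2, n_out, cfg, seed, label = "") {
  cache <- merge_cache(pool1$atoms, pool1$sequence,
                       pool2$atoms, pool2$sequence, cfg)
  n1 <- length(pool1$coords)
  n2 <- length(pool2$coords)
  out <- vector("list", n_out)
  attempts_total <- 0L
  with_seed(seed, {
    for (m in seq_len(n_out)) {
      done <- FALSE
      for (a in seq_len(cfg$max_attempts)) {
        attempts_total <- attempts_total + 1L
        i <- sample.int(n1, 1L)
        j <- sample.int(n2, 1L)
        res <- merge_once(pool1$coords[[i]], pool2$coords[[j]], cache, cfg)
        if (res$ok) {
          out[[m]] <- res$coords
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("growth failure", label, ": no accepted merge in ",
             cfg$max_attempts, " attempts (acceptance so far ",
             sprintf("%.4f", (m - 1) / max(1, attempts_total)),
             "; rmsd_cutoff = ", cfg$rmsd_cutoff,
             ", clash_cutoff = ", cfg$clash_cutoff, ")")
    }
  })
  pool <- new_pool(cache$merged_atoms, out, cache$merged_sequence)
  attr(pool, "attempts") <- attempts_total
  attr(pool, "accepted") <- n_out
  pool
}

#' Merge two conformer pools at one hierarchical level
#'
#' Draws (member of pool1, member of pool2) uniformly with replacement,
#' retrying rejected pairs up to `cfg$max_attempts` per output slot.
#'
#' @param pool1,pool2 `fragment_library`s, lists of conformations, or
#'   internal pools.
#' @param n_out number of merged conformations to produce.
#' @param cfg an [growth_config()].
#' @param seed RNG seed for this level (defaults to `cfg$seed`).
#' @return list of merged `rna_conformation`s; the acceptance rate is in
#'   attribute "acceptance_rate".
#' @export
grow_level <- function(pool1, pool2, n_out, cfg = growth_config(),
                       seed = cfg$seed) {
  p <- merge_pools(as_pool(pool1), as_pool(pool2), n_out, cfg, seed)
  out <- lapply(seq_len(n_out), function(i) pool_conformation(p, i))
  attr(out, "acceptance_rate") <- attr(p, "accepted") / attr(p, "attempts")
  out
}

# hierarchical binary merge over an ordered list of pools; an odd piece at
# any level carries over unmerged (deterministic left-to-right tree)
grow_tree <- function(pools, cfg, n_out) {
  stats <- list()
  level <- 0L
  while (length(pools) > 1) {
    level <- level + 1L
    nxt <- list()
    slot <- 0L
    for (p in seq(1, length(pools) - 1, by = 2)) {
      slot <- slot + 1L
      merged <- tryCatch(
        merge_pools(pools[[p]], pools[[p + 1]], n_out, cfg,
                    derive_seed(cfg$seed, level, slot),
                    label = sprintf(" at level %d, slot %d", level, slot)),
        error = function(e) stop("HCG level ", level, ", slot ", slot,
                                 " (", pools[[p]]$sequence, " + ",
                                 pools[[p + 1]]$sequence, "): ",
                                 conditionMessage(e), call. = FALSE))
      stats[[length(stats) + 1]] <- data.frame(
        level = level, slot = slot,
        sequence = merged$sequence,
        attempts = attr(merged, "attempts"),
        accepted = attr(merged, "accepted"),
        acceptance_rate = attr(merged, "accepted") /
          attr(merged, "attempts"))
      nxt[[length(nxt) + 1]] <- merged
    }
    if (length(pools) %% 2 == 1)
      nxt[[length(nxt) + 1]] <- pools[[length(pools)]]
    pools <- nxt
  }
  list(pool = pools[[1]],
       stats = if (length(stats)) do.call(rbind, stats)
               else data.frame())
}

trim_pool <- function(pool, drop_first = FALSE, drop_last = FALSE) {
  if (!drop_first && !drop_last) return(pool)
  n <- nchar(pool$sequence)
  keep_res <- seq_len(n)
  if (drop_first) keep_res <- keep_res[-1]
  if (drop_last) keep_res <- keep_res[-length(keep_res)]
  rows <- which(pool$atoms$residue_index %in% keep_res)
  atoms <- pool$atoms[rows, , drop = FALSE]
  atoms$residue_index <- atoms$residue_index - (if (drop_first) 1L else 0L)
  rownames(atoms) <- NULL
  seq2 <- paste(strsplit(pool$sequence, "")[[1]][keep_res], collapse = "")
  new_pool(atoms, lapply(pool$coords, function(X) X[rows, , drop = FALSE]),
           seq2)
}

new_ensemble <- function(pool, weights, cfg, stats, provenance = list()) {
  w <- weights / sum(weights)
  structure(list(sequence = pool$sequence, atoms = pool$atoms,
                 coords = pool$coords, weights = w, config = cfg,
                 merge_statistics = stats, provenance = provenance),
            class = "hcg_ensemble")
}

#' @export
print.hcg_ensemble <- function(x, ...) {
  cat("<hcg_ensemble> ", length(x$coords), " members of ", x$sequence,
      " (", nchar(x$sequence), " nt)\n", sep = "")
  if (nrow(x$merge_statistics))
    cat("  overall merge acceptance: ",
        sprintf("%.3f", sum(x$merge_statistics$accepted) /
                  sum(x$merge_statistics$attempts)), "\n", sep = "")
  invisible(x)
}

#' Number of members in an ensemble
#' @param ens an `hcg_ensemble`.
#' @export
n_members <- function(ens) length(ens$coords)

#' Extract one ensemble member
#'
#' @param ens an `hcg_ensemble`.
#' @param i member index.
#' @return an `rna_conformation`.
#' @export
ensemble_member <- function(ens, i) {
  new_conformation(ens$atoms, ens$coords[[i]], ens$sequence,
                   provenance = list(ensemble_member = i))
}

#' Grow a full-length chain ensemble by hierarchical chain growth
#'
#' Builds the binary merge tree over the tiled fragment list (an odd piece
#' at any level carries over unmerged), producing `cfg$n_chains` members of
#' exactly the target sequence with uniform statistical weights. Terminal
#' caps are trimmed according to the plan.
#'
#' @param plan an [plan_tiling()] result.
#' @param libraries named list of `fragment_library`, keyed by fragment
#'   sequence; every plan key must be present.
#' @param cfg an [growth_config()].
#' @return an `hcg_ensemble`.
#' @export
grow_ensemble <- function(plan, libraries, cfg = growth_config()) {
  missing_keys <- setdiff(unique(plan$fragment_keys), names(libraries))
  if (length(missing_keys))
    stop("no library for fragment key(s): ",
         paste(missing_keys, collapse = ", "))
  pools <- lapply(plan$fragment_keys, function(k) as_pool(libraries[[k]]))
  if (length(pools) == 1) {
    # degenerate plan: sample conformers directly
    src <- pools[[1]]
    idx <- with_seed(cfg$seed, sample.int(length(src$coords),
                                          cfg$n_chains, replace = TRUE))
    res <- list(pool = new_pool(src$atoms, src$coords[idx], src$sequence),
                stats = data.frame())
  } else {
    res <- grow_tree(pools, cfg, cfg$n_chains)
  }
  pool <- trim_pool(res$pool, plan$trim_five_prime, plan$trim_three_prime)
  if (!plan$keep_caps && pool$sequence != plan$sequence)
    stop("grown sequence ", pool$sequence, " does not match target ",
         plan$sequence)
  new_ensemble(pool, rep(1, length(pool$coords)), cfg, res$stats,
               provenance = list(plan = plan))
}

#' Assemble a chain from structured and disordered segments
#'
#' Flexible segments are grown by HCG from their own tiling plans;
#' structured segments contribute conformers drawn at random from their
#' libraries (rigid-body transformed, internally unmodified). All segments
#' are then joined hierarchically with the same junction alignment and
#' clash machinery. Adjacent segments must overlap by two nucleotides
#' (the standard merge removes one nucleotide from each side of every
#' junction), so segment sequences include the shared overlap.
#'
#' @param segments ordered list; each element is either
#'   `list(type = "structured", library = <fragment_library>)` or
#'   `list(type = "flexible", plan = <hcg_tiling_plan>,
#'         libraries = <named list>)`.
#' @param cfg an [growth_config()]; in mixed assembly the RMSD cutoff is
#'   conventionally relaxed to 1.0 Angstrom.
#' @return an `hcg_ensemble` of full-length members.
#' @export
assemble_mixed <- function(segments,
                           cfg = growth_config(rmsd_cutoff = 1.0)) {
  if (length(segments) < 1) stop("no segments")
  pools <- lapply(seq_along(segments), function(i) {
    sg <- segments[[i]]
    if (identical(sg$type, "structured")) {
      as_pool(sg$library)
    } else if (identical(sg$type, "flexible")) {
      sub <- grow_ensemble(sg$plan, sg$libraries, cfg)
      new_pool(sub$atoms, sub$coords, sub$sequence)
    } else stop("segment ", i, ": unknown type ", sg$type)
  })
  if (length(pools) == 1) {
    src <- pools[[1]]
    idx <- with_seed(cfg$seed, sample.int(length(src$coords),
                                          cfg$n_chains, replace = TRUE))
    res <- list(pool = new_pool(src$atoms, src$coords[idx], src$sequence),
                stats = data.frame())
  } else {
    res <- grow_tree(pools, cfg, cfg$n_chains)
  }
  new_ensemble(res$pool, rep(1, length(res$pool$coords)), cfg, res$stats,
               provenance = list(segments = vapply(segments, `[[`,
                                                  character(1), "type")))
}

#' Post-hoc validation of a grown ensemble
#'
#' Checks every member for covalent continuity (O3'-P < 2.5 Angstrom along
#' the chain) and for residual steric clashes: heavy-atom pairs in
#' different residues closer than the clash cutoff, exempting the covalent
#' O3'(i)-P(i+1) linkage and its adjacent phosphate-group contacts (the
#' pairs excluded at junctions during growth).
#'
#' @param ens an `hcg_ensemble`.
#' @param clash_cutoff Angstrom (defaults to the growth configuration).
#' @return data.frame with per-member clash and discontinuity counts.
#' @export
validate_ensemble <- function(ens, clash_cutoff = ens$config$clash_cutoff) {
  at <- ens$atoms
  resi <- as.integer(at$residue_index)
  is_o3 <- at$name == "O3'"
  is_pg <- at$name %in% c("P", "OP1", "OP2", "O5'")
  o3_rows <- vapply(seq_len(max(resi) - 1), function(i)
    which(resi == i & at$name == "O3'")[1], integer(1))
  p_rows <- vapply(seq_len(max(resi) - 1) + 1L, function(i)
    which(resi == i & at$name == "P")[1], integer(1))
  out <- data.frame(member = seq_along(ens$coords), clashes = 0L,
                    discontinuities = 0L)
  for (m in seq_along(ens$coords)) {
    X <- ens$coords[[m]]
    out$clashes[m] <- .chain_clash_count_cpp(X, resi, is_o3, is_pg,
                                             clash_cutoff)
    d <- sqrt(rowSums((X[o3_rows, , drop = FALSE] -
                         X[p_rows, , drop = FALSE])^2))
    out$discontinuities[m] <- sum(d >= 2.5)
  }
  out
}
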