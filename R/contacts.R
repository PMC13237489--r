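#' Contact analysis specification
#'
#' Cutoffs and residue sets for hydrophobic contact-occupancy analysis:
#' hydrophobic residues are Ala, Val, Ile, Leu, Met, Phe, Tyr, Trp and
#' Pro; the helix of interest spans `helix_range` (124-134 preset);
#' partner selection uses a 0.60-nm heavy-atom cutoff in the first
#' analyzed frame, contacts a 0.45-nm closest heavy-atom cutoff.
#'
#' @param helix_range Integer residue ids of the helix.
#' @param partner_cutoff,contact_cutoff Distances in nm
#'   (`contact_cutoff <= partner_cutoff`).
#' @return A `contact_spec` object.
#' @export
contact_spec <- function(helix_range = 124:134, partner_cutoff = 0.60,
                         contact_cutoff = 0.45) {
  stopifnot(contact_cutoff <= partner_cutoff)
  structure(list(
    hydrophobic = c("ALA", "VAL", "ILE", "LEU", "MET", "PHE", "TYR",
                    "TRP", "PRO"),
    helix_range = as.integer(helix_range),
    partner_cutoff = partner_cutoff, contact_cutoff = contact_cutoff),
    class = "contact_spec")
}

# A trajectory is a list: system, replicate, resnames (named 3-letter
# codes keyed by residue id), frames (list; each frame a named list of
# n_atoms x 3 coordinate matrices in nm, heavy atoms only).
trajectory_frames <- function(system, replicate, resnames, frames) {
  ids <- names(resnames)
  for (f in frames) stopifnot(identical(sort(names(f)), sort(ids)))
  structure(list(system = system, replicate = replicate,
                 resnames = resnames, frames = frames),
            class = "trajectory_frames")
}

#' Read a multi-model PDB file as trajectory frames
#'
#' Each MODEL becomes one frame; hydrogens are dropped on ingest
#' ("heavy atoms" = all non-hydrogen atoms) and coordinates are
#' converted from Angstrom to nm.
#'
#' @param path PDB file path.
#' @param system,replicate Tags stored on the trajectory.
#' @return A `trajectory_frames` object.
#' @export
read_trajectory_pdb <- function(path, system = "WT", replicate = 1L) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  elem <- toupper(trimws(ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                                at$elesy, substr(trimws(at$elety), 1, 1))))
  heavy <- elem != "H"
  resno <- at$resno[heavy]
  ids <- as.character(sort(unique(resno)))
  resnames <- vapply(ids, function(r)
    at$resid[heavy][match(as.integer(r), resno)], "")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  heavy_cols <- as.vector(rbind(3 * (which(heavy) - 1) + 1,
                                3 * (which(heavy) - 1) + 2,
                                3 * (which(heavy) - 1) + 3))
  frames <- lapply(seq_len(nrow(xyz)), function(f) {
    co <- matrix(xyz[f, heavy_cols], ncol = 3L, byrow = TRUE) / 10  # A -> nm
    out <- lapply(ids, function(r) co[resno == as.integer(r), , drop = FALSE])
    names(out) <- ids
    out
  })
  trajectory_frames(system, replicate, resnames, frames)
}

#' Write trajectory frames as a multi-model PDB
#'
#' @param traj A `trajectory_frames` object (coordinates in nm; written
#'   in Angstrom).
#' @param path Output path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  ids <- names(traj$resnames)
  for (f in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    for (r in ids) {
      co <- traj$frames[[f]][[r]] * 10  # nm -> A
      for (a in seq_len(nrow(co))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d  C%-2d %3s A%4s    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, a, traj$resnames[[r]], r, co[a, 1], co[a, 2], co[a, 3]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' Multi-frame XYZ dialect in which each atom label is
#' `<RESNAME>_<resno>` (e.g. `VAL_129`) and coordinates are in nm.
#'
#' @param path XYZ file path.
#' @param system,replicate Tags stored on the trajectory.
#' @return A `trajectory_frames` object.
#' @export
read_trajectory_xyz <- function(path, system = "WT", replicate = 1L) {
  lines <- readLines(path)
  i <- 1L; frames <- list(); resnames <- NULL
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- as.integer(trimws(lines[i]))
    rows <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(rows), "[[:space:]]+")
    lab <- vapply(toks, `[`, "", 1L)
    parts <- strsplit(lab, "_", fixed = TRUE)
    rn <- vapply(parts, `[`, "", 1L)
    rid <- vapply(parts, `[`, "", 2L)
    co <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    ids <- unique(rid)
    if (is.null(resnames)) resnames <- setNames(rn[match(ids, rid)], ids)
    frames[[length(frames) + 1L]] <-
      setNames(lapply(ids, function(r) co[rid == r, , drop = FALSE]), ids)
    i <- i + 2L + n
  }
  trajectory_frames(system, replicate, resnames, frames)
}

min_residue_distance <- function(A, B) {
  # closest heavy-atom distance between two residues (atom coord matrices)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

#' Select hydrophobic partner residues from reference trajectories
#'
#' From the first analyzed frame of each reference (wild-type)
#' replicate, takes hydrophobic residues outside the helix whose closest
#' heavy-atom distance to any helix heavy atom is at or below the
#' partner cutoff; the union over replicates is returned and is meant to
#' be applied unchanged to both systems being compared.
#'
#' @param reference_trajs List of `trajectory_frames` (>= 1 frame each).
#' @param spec A [contact_spec()].
#' @return Sorted integer vector of partner residue ids.
#' @export
select_partner_set <- function(reference_trajs, spec = contact_spec()) {
  partners <- integer(0)
  for (traj in reference_trajs) {
    if (!length(traj$frames)) stop("replicate has no frames")
    fr <- traj$frames[[1]]
    helix_ids <- as.character(spec$helix_range)
    helix_ids <- helix_ids[helix_ids %in% names(fr)]
    if (!length(helix_ids)) stop("empty first frame: no helix residues present")
    helix_atoms <- do.call(rbind, fr[helix_ids])
    cand <- setdiff(names(fr), helix_ids)
    cand <- cand[traj$resnames[cand] %in% spec$hydrophobic]
    hit <- vapply(cand, function(r)
      min_residue_distance(fr[[r]], helix_atoms) <= spec$partner_cutoff,
      TRUE)
    partners <- union(partners, as.integer(cand[hit]))
  }
  sort(partners)
}

#' Helix residues eligible for contact pairs
#'
#' Hydrophobic residues inside the helix range, by residue identity.
#'
#' @param traj A `trajectory_frames`.
#' @param spec A [contact_spec()].
#' @return Sorted integer residue ids.
#' @export
helix_hydrophobic_residues <- function(traj, spec = contact_spec()) {
  ids <- as.character(spec$helix_range)
  ids <- ids[ids %in% names(traj$resnames)]
  sort(as.integer(ids[traj$resnames[ids] %in% spec$hydrophobic]))
}

#' Contact occupancies for helix-partner residue pairs
#'
#' For every (helix residue, partner residue) pair and every replicate,
#' the occupancy is the fraction of frames in which the closest
#' heavy-atom distance is at or below the contact cutoff.  Also returns
#' per-pair means across replicates, per-replicate means across pairs
#' (the unit of the trajectory-level permutation test), and the pooled
#' frame-wise total contact counts.
#'
#' @param trajs List of `trajectory_frames` (replicates of one system).
#' @param helix_residues Integer ids of helix residues to pair.
#' @param partner_set Integer ids of partner residues.
#' @param spec A [contact_spec()].
#' @return An `occupancy_table` list.
#' @export
contact_occupancy <- function(trajs, helix_residues, partner_set,
                              spec = contact_spec()) {
  if (!length(partner_set)) stop("partner set is empty")
  pairs <- expand.grid(helix = helix_residues, partner = partner_set)
  rows <- list()
  framewise <- numeric(0)
  for (traj in trajs) {
    nf <- length(traj$frames)
    if (nf == 0L) stop(sprintf("replicate %s has zero frames", traj$replicate))
    contact_mat <- matrix(FALSE, nf, nrow(pairs))
    for (f in seq_len(nf)) {
      fr <- traj$frames[[f]]
      for (p in seq_len(nrow(pairs))) {
        contact_mat[f, p] <-
          min_residue_distance(fr[[as.character(pairs$helix[p])]],
                               fr[[as.character(pairs$partner[p])]]) <=
          spec$contact_cutoff
      }
    }
    occ <- colMeans(contact_mat)
    rows[[length(rows) + 1L]] <-
      data.frame(helix = pairs$helix, partner = pairs$partner,
                 replicate = traj$replicate, occupancy = occ)
    framewise <- c(framewise, rowSums(contact_mat))
  }
  tab <- do.call(rbind, rows)
  pair_means <- stats::aggregate(occupancy ~ helix + partner, tab, mean)
  replicate_means <- stats::aggregate(occupancy ~ replicate, tab, mean)
  structure(list(table = tab, pair_means = pair_means,
                 replicate_means = setNames(replicate_means$occupancy,
                                            replicate_means$replicate),
                 framewise_counts = framewise,
                 n_pairs = nrow(pairs)),
            class = "occupancy_table")
}

#' Exact two-group permutation test on replicate means
#'
#' Enumerates every relabeling of the pooled replicate-level means into
#' groups of the original sizes (C(10, 5) = 252 for 5 + 5) and reports
#' `delta = mean(b) - mean(a)` with the two-sided exact p-value: the
#' fraction of relabelings whose |delta| is at least |delta observed|,
#' the observed relabeling included.  Attainable p-values are k/252.
#'
#' @param group_a,group_b Numeric replicate-level means (non-empty).
#' @return List with `delta`, `p`, `n_relabelings`.
#' @export
exact_permutation_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  pool <- c(group_a, group_b)
  obs <- mean(group_b) - mean(group_a)
  idx <- combn(na + nb, na)
  stopifnot(ncol(idx) == choose(na + nb, na))  # enumeration guard
  total <- sum(pool)
  deltas <- apply(idx, 2L, function(s) {
    ma <- mean(pool[s])
    (total - sum(pool[s])) / nb - ma
  })
  p <- mean(abs(deltas) >= abs(obs) - 1e-12)
  list(delta = obs, p = p, n_relabelings = ncol(idx))
}

#' Per-pair permutation tests with multiple-testing correction
#'
#' Runs the exact replicate-level permutation test for each
#' helix-partner pair and applies Benjamini-Hochberg correction across
#' pairs.
#'
#' @param occ_a,occ_b `occupancy_table`s of the two systems over the
#'   same pairs.
#' @return Data frame with per-pair `delta`, `p`, `p_adj`.
#' @export
pairwise_contact_tests <- function(occ_a, occ_b) {
  key <- function(df) paste(df$helix, df$partner)
  pairs <- unique(occ_a$table[c("helix", "partner")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sel_a <- occ_a$table$helix == pairs$helix[i] &
      occ_a$table$partner == pairs$partner[i]
    sel_b <- occ_b$table$helix == pairs$helix[i] &
      occ_b$table$partner == pairs$partner[i]
    tst <- exact_permutation_test(occ_a$table$occupancy[sel_a],
                                  occ_b$table$occupancy[sel_b])
    data.frame(helix = pairs$helix[i], partner = pairs$partner[i],
               delta = tst$delta, p = tst$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
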