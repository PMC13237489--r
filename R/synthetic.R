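#' Synthetic homolog family specification
#'
#' Conditions for the seeded family generator: homologs are point-mutated
#' copies of a random root sequence, species metadata is drawn from a
#' small genus/species pool (so taxonomy-holdout splits are exercisable),
#' and weak activity labels follow one of two planted rules.
#' `pooled_motif` labels a sequence `HIGH` when a single sequence motif
#' is present (detectable from pooled composition-like features);
#' `contextual_pair` labels `HIGH` only when two distinct motifs co-occur,
#' and plants double copies of single motifs in part of the `LOW` class so
#' that total motif content alone cannot separate the classes - the label
#' is then a function of residue co-occurrence, not of pooled content.
#' All natural sequences additionally carry an intact catalytic-site motif
#' whose knockout defines the `NONE` penalty class.
#'
#' @param root_length Root sequence length (residues).
#' @param n_sequences Number of natural homologs.
#' @param substitution_rate Per-site substitution probability from the
#'   root, in `[0, 1)`.
#' @param high_fraction Fraction of `HIGH` sequences (defaults to the
#'   imbalance of a weakly labeled enzyme family, about 8 percent
#'   high / 92 percent low).
#' @param label_rule `"contextual_pair"` or `"pooled_motif"`.
#' @param n_genera Number of genera in the species pool.
#' @param seed Integer seed; every generated artifact is a pure function
#'   of the spec.
#' @return A `family_spec` object.
#' @export
family_spec <- function(root_length = 100L, n_sequences = 505L,
                        substitution_rate = 0.02, high_fraction = 0.082,
                        label_rule = c("contextual_pair", "pooled_motif"),
                        n_genera = 12L, seed = 1L) {
  label_rule <- match.arg(label_rule)
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            high_fraction > 0, high_fraction < 1, root_length >= 30L)
  structure(list(root_length = as.integer(root_length),
                 n_sequences = as.integer(n_sequences),
                 substitution_rate = substitution_rate,
                 high_fraction = high_fraction, label_rule = label_rule,
                 n_genera = as.integer(n_genera), seed = as.integer(seed)),
            class = "family_spec")
}

MOTIF_A <- "CWCWC"  # first activity motif
MOTIF_B <- "HMHMH"  # second activity motif
MOTIF_C <- "WYWYW"  # conserved catalytic-site motif (knockout target)

scrub_stray <- function(chars, motif, keep_start) {
  s <- paste(chars, collapse = "")
  repeat {
    hits <- gregexpr(motif, s, fixed = TRUE)[[1]]
    hits <- hits[hits > 0 & !(hits %in% keep_start)]
    if (!length(hits)) break
    chars[hits[1] + 2L] <- "G"
    s <- paste(chars, collapse = "")
  }
  chars
}

#' Generate a labeled synthetic homolog family
#'
#' @param spec A [family_spec()].
#' @return List with `records` (a `seq_records` with species metadata),
#'   `labels` (factor `HIGH`/`LOW`), `catalytic_positions` (the residue
#'   indices of the intact catalytic motif) and `spec`.
#' @export
generate_family <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    L <- spec$root_length
    n <- spec$n_sequences
    pos_c <- L %/% 2L
    c_sites <- pos_c:(pos_c + 4L)
    root <- sample(AA_ALPHABET, L, replace = TRUE)
    root[c_sites] <- strsplit(MOTIF_C, "")[[1]]

    # deterministic category counts (HIGH = both motifs; decoy classes
    # carry doubled single motifs so motif mass does not separate labels)
    n_high <- max(1L, round(spec$high_fraction * n))
    if (spec$label_rule == "contextual_pair") {
      n_a <- round(0.12 * n); n_b <- round(0.12 * n)
      n_aa <- round(0.06 * n); n_bb <- round(0.06 * n)
      cats <- c(rep("both", n_high), rep("aonly", n_a), rep("bonly", n_b),
                rep("aa", n_aa), rep("bb", n_bb))
    } else {
      cats <- c(rep("both", n_high), rep("bonly", round(0.2 * n)))
    }
    cats <- c(cats, rep("none", n - length(cats)))
    cats <- cats[sample.int(n)]

    avoid <- (pos_c - 7L):(pos_c + 11L)
    slots <- setdiff(5:(L - 9L), avoid)
    a_chars <- strsplit(MOTIF_A, "")[[1]]
    b_chars <- strsplit(MOTIF_B, "")[[1]]

    genera <- sprintf("Genus%02d", seq_len(spec$n_genera))
    n_species <- pmax(1L, sample(1:4, spec$n_genera, replace = TRUE))
    species_pool <- unlist(lapply(seq_len(spec$n_genera), function(g)
      sprintf("%s species%02d", genera[g], seq_len(n_species[g]))))

    seqs <- character(n)
    for (i in seq_len(n)) {
      chars <- root
      mut <- runif(L) < spec$substitution_rate
      mut[c_sites] <- FALSE
      for (p in which(mut)) {
        chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
      }
      repeat {
        starts <- sort(sample(slots, 2L))
        if (diff(starts) >= 8L) break
      }
      plant <- switch(cats[i],
        both = list(list(starts[1], a_chars), list(starts[2], b_chars)),
        aonly = list(list(starts[1], a_chars)),
        bonly = list(list(starts[1], b_chars)),
        aa = list(list(starts[1], a_chars), list(starts[2], a_chars)),
        bb = list(list(starts[1], b_chars), list(starts[2], b_chars)),
        none = list())
      keep_a <- integer(0); keep_b <- integer(0)
      for (pl in plant) {
        chars[pl[[1]]:(pl[[1]] + 4L)] <- pl[[2]]
        if (identical(pl[[2]], a_chars)) keep_a <- c(keep_a, pl[[1]])
        else keep_b <- c(keep_b, pl[[1]])
      }
      chars <- scrub_stray(chars, MOTIF_A, keep_a)
      chars <- scrub_stray(chars, MOTIF_B, keep_b)
      chars <- scrub_stray(chars, MOTIF_C, pos_c)
      seqs[i] <- paste(chars, collapse = "")
    }
    species <- sample(species_pool, n, replace = TRUE)
    records <- make_seq_records(sprintf("syn%04d", seq_len(n)), seqs,
                               species = species)
    # the label is a property of the realized sequence
    has_a <- grepl(MOTIF_A, seqs, fixed = TRUE)
    has_b <- grepl(MOTIF_B, seqs, fixed = TRUE)
    labels <- if (spec$label_rule == "contextual_pair") {
      factor(ifelse(has_a & has_b, "HIGH", "LOW"), levels = ACTIVITY_LEVELS)
    } else {
      factor(ifelse(has_a, "HIGH", "LOW"), levels = ACTIVITY_LEVELS)
    }
    list(records = records, labels = labels,
         catalytic_positions = c_sites, spec = spec)
  })
}

#' Generate the full three-class training dataset
#'
#' Natural homologs from [generate_family()] plus an artificial `NONE`
#' penalty group obtained by knocking out every catalytic-site residue of
#' one or more parent sequences (19 substitutions per site).
#'
#' @param spec A [family_spec()].
#' @param n_penalty_parents Number of natural parents to knock out.
#' @return List with `records`, `labels` (HIGH/LOW/NONE), `family`,
#'   `penalty_variants`.
#' @export
generate_three_class_dataset <- function(spec = family_spec(),
                                         n_penalty_parents = 1L) {
  fam <- generate_family(spec)
  parents <- which(fam$labels == "LOW")[seq_len(n_penalty_parents)]
  pen_list <- lapply(parents, function(i)
    site_knockout_variants(fam$records[i, ], fam$catalytic_positions))
  pen <- do.call(rbind, pen_list)
  # knockout variants inherit their parent's species
  pen_species <- rep(fam$records$species[parents],
                     vapply(pen_list, nrow, 0L))
  pen_records <- variants_to_records(pen, species = pen_species)
  records <- rbind(fam$records, pen_records)
  class(records) <- c("seq_records", "data.frame")
  labels <- factor(c(as.character(fam$labels), rep("NONE", nrow(pen))),
                   levels = ACTIVITY_LEVELS)
  list(records = records, labels = labels, family = fam,
       penalty_variants = pen)
}

#' Generate a synthetic PSSM with a target library-wide mean delta
#'
#' Conserved positions receive strongly favorable wild-type scores (so
#' substitutions there are heavily penalized) and variable positions mild
#' ones; wild-type scores are calibrated per position so the mean
#' mutant-minus-wild-type score over the full single-mutant library lands
#' within about +/- 0.5 of `target_mean_delta`.
#'
#' @param parent Parent record (see [site_knockout_variants()]).
#' @param conservation Logical length-`L` vector flagging conserved
#'   positions, or a single fraction in `[0, 1]` (default 0.3).
#' @param seed RNG seed.
#' @param target_mean_delta Target library-wide mean delta score.
#' @return A `pssm` object.
#' @export
generate_pssm <- function(parent, conservation = 0.3, seed = 1L,
                          target_mean_delta = -6.7) {
  parent <- as_parent(parent)
  L <- nchar(parent$sequence)
  wt <- strsplit(parent$sequence, "")[[1]]
  if (length(conservation) == 1L && !is.logical(conservation)) {
    conservation <- with_seed(seed + 1L,
      sample(c(TRUE, FALSE), L, replace = TRUE,
             prob = c(conservation, 1 - conservation)))
  }
  if (length(conservation) != L) stop("conservation profile length mismatch")
  f <- mean(conservation)
  delta_cons <- -13
  delta_var <- if (f < 1) (target_mean_delta - f * delta_cons) / (1 - f)
    else target_mean_delta
  with_seed(seed, {
    scores <- matrix(0L, L, 20L, dimnames = list(NULL, PSSM_COLUMNS))
    for (i in seq_len(L)) {
      others <- round(rnorm(20L, mean = if (conservation[i]) -2 else 0, sd = 2))
      scores[i, ] <- as.integer(others)
      target_i <- if (conservation[i]) delta_cons else delta_var
      mean_others <- mean(scores[i, PSSM_COLUMNS != wt[i]])
      scores[i, wt[i]] <- as.integer(round(mean_others - target_i))
    }
    structure(list(parent_id = parent$record_id, scores = scores,
                   wt_residues = parent$sequence),
              class = "pssm")
  })
}

#' Generate planted-contact trajectory replicates
#'
#' Builds coordinate trajectories in which each planted helix-partner
#' residue pair is within the 0.45-nm contact cutoff with its specified
#' per-frame probability, independently across frames.  The synthetic
#' topology mirrors the analysis setup: five hydrophobic residues inside
#' the helix (ids 124, 126, 129, 131, 133), hydrophobic partner residues
#' at the planted ids, plus a near non-hydrophobic bystander (residue
#' 150) and a distant hydrophobic one (residue 200) that must never be
#' selected.  In the first frame every planted partner sits within the
#' 0.60-nm partner cutoff of the helix so partner selection is
#' reproducible.  The geometry is a synthetic scaffold for distance
#' computations, not a physical protein model.
#'
#' @param planted Data frame with columns `helix`, `partner`, `prob`.
#' @param n_replicates,n_frames Replicate and frame counts (5 x 100
#'   preset, one frame per snapshot).
#' @param seed RNG seed.
#' @param system System tag (e.g. `"WT"`).
#' @param occupancy_mode `"bernoulli"` draws each frame's contact state
#'   independently with the planted probability; `"deterministic"`
#'   realizes exactly `round(prob * n_frames)` contact frames (the first
#'   ones), so measured occupancies equal the planted values to within
#'   `1 / n_frames`.
#' @return List of `trajectory_frames`, one per replicate.
#' @export
generate_trajectories <- function(planted, n_replicates = 5L,
                                  n_frames = 100L, seed = 1L,
                                  system = "WT",
                                  occupancy_mode = c("bernoulli",
                                                     "deterministic")) {
  occupancy_mode <- match.arg(occupancy_mode)
  stopifnot(all(planted$prob >= 0), all(planted$prob <= 1))
  helix_ids <- 124:134
  helix_names <- c("ALA", "SER", "LEU", "GLY", "THR", "VAL", "ASN", "ILE",
                   "GLN", "PHE", "GLY")
  hydro_helix <- c(124L, 126L, 129L, 131L, 133L)
  station <- setNames(seq_along(hydro_helix) * 2.0, hydro_helix)
  partners <- sort(unique(planted$partner))
  pnames <- setNames(rep(c("VAL", "LEU", "ILE", "PHE", "MET", "TRP", "TYR",
                           "ALA", "PRO"), length.out = length(partners)),
                     partners)
  if ("160" %in% names(pnames)) pnames["160"] <- "ILE"
  resnames <- c(setNames(helix_names, helix_ids), pnames,
                "150" = "SER", "200" = "LEU")
  resnames <- resnames[!is.na(names(resnames))]

  helix_coords <- lapply(helix_ids, function(id) {
    # non-hydrophobic helix residues sit on a parallel line well away from
    # the partner contact stations so they never perturb pair distances
    base <- if (id %in% hydro_helix) c(station[as.character(id)], 0, 0)
      else c(min(station) + (id - 124) * 0.2, -1.5, 0)
    rbind(base, base + c(0.04, 0, 0), base + c(0, 0.04, 0))
  })
  names(helix_coords) <- helix_ids

  with_seed(seed, {
    lapply(seq_len(n_replicates), function(rep_i) {
      sched <- lapply(seq_len(nrow(planted)), function(p) {
        if (occupancy_mode == "bernoulli") runif(n_frames) < planted$prob[p]
        else seq_len(n_frames) <= round(planted$prob[p] * n_frames)
      })
      frames <- lapply(seq_len(n_frames), function(f) {
        fr <- helix_coords
        for (pk in seq_along(partners)) {
          pid <- partners[pk]
          rows <- which(planted$partner == pid)
          co <- matrix(0, length(hydro_helix), 3L)
          for (j in seq_along(hydro_helix)) {
            hid <- hydro_helix[j]
            row <- rows[planted$helix[rows] == hid]
            in_contact <- length(row) == 1L && sched[[row]][f]
            near_first <- f == 1L && length(rows) && hid == planted$helix[rows[1]]
            co[j, ] <- if (in_contact) {
              c(station[as.character(hid)] + 0.30, 0, 0)
            } else if (near_first) {
              c(station[as.character(hid)] + 0.55, 0, 0)
            } else {
              c(station[j], 6 + 2 * pk, 0)
            }
          }
          fr[[as.character(pid)]] <- co
        }
        fr[["150"]] <- if (f == 1L) matrix(c(station[1], 0.55, 0), 1L)
          else matrix(c(station[1], 8, 5), 1L)
        fr[["200"]] <- matrix(c(-10, -10, 0), 1L)
        fr[names(resnames)]
      })
      trajectory_frames(system, rep_i, resnames, frames)
    })
  })
}

#' Generate noisy enzyme-assay data
#'
#' Progress curves with product accumulating linearly at the
#' Michaelis-Menten rate for each substrate level, Gaussian signal
#' noise, and a matching fluorophore standard curve on the 0-50 uM
#' grid.
#'
#' @param vmax Maximal velocity, uM/min.
#' @param km Michaelis constant, mM.
#' @param substrate Substrate grid in mM (assay preset: 0.05, 0.1, 0.2,
#'   0.5, 1, 2, 5, 10, 15, 20).
#' @param noise_sd Gaussian RFU noise standard deviation.
#' @param seed RNG seed.
#' @param times Sampling times in seconds.
#' @param cal_slope,cal_intercept Standard-curve parameters (RFU/uM,
#'   RFU).
#' @return List with `curves` (per substrate level: data frame `time`,
#'   `signal`), `substrate`, `standard` (data frame `concentration`,
#'   `signal`), and the generating `truth`.
#' @export
generate_progress_curves <- function(vmax = 5.27, km = 3.04,
                                     substrate = c(0.05, 0.1, 0.2, 0.5, 1,
                                                   2, 5, 10, 15, 20),
                                     noise_sd = 0, seed = 1L,
                                     times = seq(0, 3600, by = 15),
                                     cal_slope = 120, cal_intercept = 35) {
  stopifnot(vmax > 0, km > 0, noise_sd >= 0)
  with_seed(seed, {
    curves <- lapply(substrate, function(S) {
      v <- vmax * S / (km + S)              # uM/min
      conc <- v * times / 60                # uM
      signal <- cal_slope * conc + cal_intercept +
        rnorm(length(times), sd = noise_sd)
      data.frame(time = times, signal = signal)
    })
    names(curves) <- paste0("S_", substrate)
    std_conc <- c(0, 2.5, 5, 10, 20, 30, 40, 50)
    standard <- data.frame(
      concentration = std_conc,
      signal = cal_slope * std_conc + cal_intercept +
        rnorm(length(std_conc), sd = noise_sd))
    list(curves = curves, substrate = substrate, standard = standard,
         truth = list(vmax = vmax, km = km, cal_slope = cal_slope,
                      cal_intercept = cal_intercept))
  })
}

#' Reconstruct a curation scenario at full scale
#'
#' Builds a synthetic input emulating a retrieval-and-curation run:
#' `n_unique` unique sequences, of which `n_nonmeso` carry genera the
#' annotator classes as non-mesophilic, plus `n_dup` appended exact
#' duplicates.  Returns the records together with a matching
#' [mock_annotator()].
#'
#' @param n_unique,n_dup,n_nonmeso Scenario counts.
#' @param seed RNG seed.
#' @param seq_length Sequence length for the synthetic records.
#' @return List with `records` and `annotator`.
#' @export
simulate_curation_inputs <- function(n_unique = 12231L, n_dup = 1408L,
                                     n_nonmeso = 1042L, seed = 1L,
                                     seq_length = 30L) {
  stopifnot(n_nonmeso <= n_unique)
  with_seed(seed, {
    mat <- matrix(sample(AA_ALPHABET, n_unique * seq_length, replace = TRUE),
                  n_unique)
    seqs <- apply(mat, 1L, paste, collapse = "")
    while (anyDuplicated(seqs)) {
      dup <- which(duplicated(seqs))
      seqs[dup] <- vapply(dup, function(i)
        paste(sample(AA_ALPHABET, seq_length, replace = TRUE), collapse = ""),
        "")
    }
    meso_genera <- sprintf("Mesogenus%02d", 1:20)
    hot_cold <- c("Thermogenus", "Psychrogenus")
    species <- character(n_unique)
    nonmeso_idx <- sample.int(n_unique, n_nonmeso)
    species[nonmeso_idx] <- sprintf("%s species%02d",
                                    sample(hot_cold, n_nonmeso, TRUE),
                                    sample(1:50, n_nonmeso, TRUE))
    meso_idx <- setdiff(seq_len(n_unique), nonmeso_idx)
    species[meso_idx] <- sprintf("%s species%02d",
                                 sample(meso_genera, length(meso_idx), TRUE),
                                 sample(1:50, length(meso_idx), TRUE))
    records <- make_seq_records(sprintf("u%05d", seq_len(n_unique)), seqs,
                                species = species)
    dup_src <- sample.int(n_unique, n_dup, replace = TRUE)
    dups <- make_seq_records(sprintf("d%05d", seq_len(n_dup)),
                             seqs[dup_src], species = species[dup_src])
    all_recs <- rbind(records, dups)
    class(all_recs) <- c("seq_records", "data.frame")
    annotator <- mock_annotator(
      high_genera = sample(meso_genera, 3L),
      thermophilic_genera = "Thermogenus",
      psychrophilic_genera = "Psychrogenus")
    list(records = all_recs, annotator = annotator)
  })
}
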