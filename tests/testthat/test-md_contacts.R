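planted_grid <- function(probs) {
  helix <- c(124L, 126L, 129L, 131L, 133L)
  partners <- c(93L, 117L, 160L)
  g <- expand.grid(helix = helix, partner = partners)
  g$prob <- probs
  g
}

test_that("saturated planted contacts give occupancy exactly 1", {
  planted <- planted_grid(1)
  trajs <- generate_trajectories(planted, n_replicates = 2L, n_frames = 10L,
                                 seed = 1L)
  spec <- contact_spec()
  occ <- contact_occupancy(trajs, c(124L, 126L, 129L, 131L, 133L),
                           c(93L, 117L, 160L), spec)
  expect_true(all(occ$table$occupancy == 1))
  expect_equal(occ$framewise_counts, rep(15, 20))
})

test_that("planted occupancy is recovered within binomial sampling error", {
  planted <- planted_grid(0.7)
  trajs <- generate_trajectories(planted, n_replicates = 5L, n_frames = 100L,
                                 seed = 2L)
  occ <- contact_occupancy(trajs, c(124L, 126L, 129L, 131L, 133L),
                           c(93L, 117L, 160L), contact_spec())
  overall <- mean(occ$table$occupancy)
  se <- sqrt(0.7 * 0.3 / (100 * 5 * 15))
  expect_lt(abs(overall - 0.7), 3 * se + 1e-9)
})

test_that("partner selection applies hydrophobicity, distance and union rules", {
  spec <- contact_spec()
  planted <- planted_grid(0.5)
  trajs <- generate_trajectories(planted, n_replicates = 3L, n_frames = 5L,
                                 seed = 3L)
  partners <- select_partner_set(trajs, spec)
  # all planted partners are selected from frame 1; the near
  # non-hydrophobic residue (150) and the distant hydrophobic one (200)
  # are excluded, as are helix residues themselves
  expect_equal(partners, c(93L, 117L, 160L))
  expect_false(any(partners %in% spec$helix_range))
  # no-contact case: partner cutoff made tiny
  tight <- contact_spec(partner_cutoff = 0.1, contact_cutoff = 0.05)
  expect_length(select_partner_set(trajs, tight), 0L)
})

test_that("helix hydrophobic residues are identified by residue name", {
  trajs <- generate_trajectories(planted_grid(0.5), n_replicates = 1L,
                                 n_frames = 2L, seed = 4L)
  expect_equal(helix_hydrophobic_residues(trajs[[1]]),
               c(124L, 126L, 129L, 131L, 133L))
})

test_that("occupancies equal a brute-force per-frame minimum-distance loop", {
  planted <- planted_grid(0.4)
  trajs <- generate_trajectories(planted, n_replicates = 2L, n_frames = 10L,
                                 seed = 5L)
  spec <- contact_spec()
  helix <- c(124L, 126L, 129L, 131L, 133L); partners <- c(93L, 117L, 160L)
  occ <- contact_occupancy(trajs, helix, partners, spec)
  for (t in seq_along(trajs)) {
    for (h in helix) for (p in partners) {
      hits <- 0L
      for (fr in trajs[[t]]$frames) {
        A <- fr[[as.character(h)]]; B <- fr[[as.character(p)]]
        dmin <- Inf
        for (a in seq_len(nrow(A))) for (b in seq_len(nrow(B))) {
          dmin <- min(dmin, sqrt(sum((A[a, ] - B[b, ])^2)))
        }
        hits <- hits + (dmin <= spec$contact_cutoff)
      }
      row <- occ$table$helix == h & occ$table$partner == p &
        occ$table$replicate == t
      expect_equal(occ$table$occupancy[row], hits / 10)
    }
  }
})

test_that("trajectories round-trip through the multi-model PDB writer/reader", {
  planted <- planted_grid(0.5)
  traj <- generate_trajectories(planted, n_replicates = 1L, n_frames = 3L,
                                seed = 6L)[[1]]
  tmp <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, tmp)
  back <- read_trajectory_pdb(tmp)
  expect_length(back$frames, 3L)
  expect_setequal(names(back$resnames), names(traj$resnames))
  for (id in names(traj$resnames)) {
    expect_equal(back$frames[[2]][[id]], unname(traj$frames[[2]][[id]]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(back$resnames[[id]], traj$resnames[[id]])
  }
})

test_that("the exact permutation test enumerates all 252 relabelings for 5+5", {
  set.seed(7)
  a <- rnorm(5L); b <- rnorm(5L) + 1
  tst <- exact_permutation_test(a, b)
  expect_equal(tst$n_relabelings, 252L)
  expect_equal(tst$delta, mean(b) - mean(a))
  # attainable p values are k/252; the printed-style 0.0159 is 4/252
  expect_equal(round(tst$p * 252), tst$p * 252, tolerance = 1e-9)
  expect_lt(abs(4 / 252 - 0.0159), 5e-5)
  # two-sided symmetry under label swap
  swap <- exact_permutation_test(b, a)
  expect_equal(swap$p, tst$p)
  expect_equal(swap$delta, -tst$delta)
  # identical groups: every relabeling ties the observed delta
  same <- exact_permutation_test(rep(1, 5L), rep(1, 5L))
  expect_equal(same$p, 1)
  expect_error(exact_permutation_test(numeric(0), b), "non-empty")
})

test_that("per-pair tests apply Benjamini-Hochberg across pairs", {
  planted_a <- planted_grid(0.8)
  planted_b <- planted_grid(0.4)
  ta <- generate_trajectories(planted_a, n_replicates = 3L, n_frames = 30L,
                              seed = 8L)
  tb <- generate_trajectories(planted_b, n_replicates = 3L, n_frames = 30L,
                              seed = 9L, system = "MUT")
  helix <- c(124L, 126L, 129L, 131L, 133L); partners <- c(93L, 117L, 160L)
  oa <- contact_occupancy(ta, helix, partners, contact_spec())
  ob <- contact_occupancy(tb, helix, partners, contact_spec())
  res <- pairwise_contact_tests(oa, ob)
  expect_equal(nrow(res), 15L)
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_equal(res$p_adj, stats::p.adjust(res$p, "BH"))
})

test_that("XYZ trajectories parse into the same structure", {
  traj <- generate_trajectories(planted_grid(1), n_replicates = 1L,
                                n_frames = 2L, seed = 10L)[[1]]
  tmp <- tempfile(fileext = ".xyz")
  lines <- character(0)
  for (f in seq_along(traj$frames)) {
    n_atoms <- sum(vapply(traj$frames[[f]], nrow, 0L))
    lines <- c(lines, as.character(n_atoms), sprintf("frame %d", f))
    for (id in names(traj$resnames)) {
      co <- traj$frames[[f]][[id]]
      for (a in seq_len(nrow(co))) {
        lines <- c(lines, sprintf("%s_%s %.6f %.6f %.6f",
                                  traj$resnames[[id]], id,
                                  co[a, 1], co[a, 2], co[a, 3]))
      }
    }
  }
  writeLines(lines, tmp)
  back <- read_trajectory_xyz(tmp)
  expect_length(back$frames, 2L)
  expect_equal(back$resnames[["129"]], "VAL")
  expect_equal(unname(back$frames[[1]][["160"]]),
               unname(traj$frames[[1]][["160"]]), tolerance = 1e-6)
})
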