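test_that("run-length event extraction matches the worked example", {
  cs <- cs_from_indicator(c(1, 1, 0, 1))
  ev0 <- extract_events(cs, gap_tolerance = 0)
  expect_equal(sort(ev0$duration_ns), c(0.1, 0.2))
  ev1 <- extract_events(cs, gap_tolerance = 1)
  expect_equal(ev1$duration_ns, 0.4)
  expect_equal(ev1$start_frame, 1L)
  expect_equal(ev1$end_frame, 4L)
  none <- extract_events(cs_from_indicator(c(0, 0, 0)))
  expect_equal(nrow(none), 0)
})

test_that("events equal the dense run-length oracle on random series", {
  set.seed(31)
  for (rep in 1:8) {
    mat <- matrix(rbinom(5 * 60, 1, 0.35), 5, 60)
    cs <- cs_from_indicator(mat)
    for (gap in c(0L, 1L)) {
      ev <- extract_events(cs, gap)
      for (mol in 1:5) {
        want <- rl_runs_oracle(mat[mol, ], gap)
        got <- ev[molecule_id == mol + 1L][order(start_frame)]
        expect_equal(got$start_frame, want$start)
        expect_equal(got$end_frame, want$end)
      }
    }
    # durations sum to dt x total contact frames at gap 0
    ev0 <- extract_events(cs, 0L)
    expect_equal(sum(ev0$duration_ns), 0.1 * sum(mat))
  }
})

test_that("kinetic profile extremes decompose duration and occupancy", {
  # one molecule bound the whole run
  cs <- cs_from_indicator(rep(1, 50))
  kp <- kinetic_profile(cs, "Chol")
  expect_equal(kp$contact_duration_ns, 5)
  expect_equal(kp$max_occupancy_ns, 5)
  expect_equal(kp$contact_duration_norm, 1)
  expect_equal(kp$max_occupancy_norm, 1)
  expect_equal(kp$n_distinct_partners, 1)

  # two molecules alternating every frame: full duration, minimal occupancy
  alt <- rbind(rep(c(1, 0), 25), rep(c(0, 1), 25))
  kp2 <- kinetic_profile(cs_from_indicator(alt), "Chol")
  expect_equal(kp2$contact_duration_ns, 5)
  expect_equal(kp2$max_occupancy_ns, 0.1)
  expect_equal(kp2$n_distinct_partners, 2)

  # molecule_sum duration counts both molecules
  kp3 <- kinetic_profile(cs_from_indicator(alt), "Chol",
                         duration_mode = "molecule_sum")
  expect_equal(kp3$contact_duration_ns, 5)
  one_overlap <- rbind(rep(1, 50), rep(1, 50))
  kp4 <- kinetic_profile(cs_from_indicator(one_overlap), "Chol",
                         duration_mode = "molecule_sum")
  expect_equal(kp4$contact_duration_ns, 10) # sum over molecules
  kp5 <- kinetic_profile(cs_from_indicator(one_overlap), "Chol")
  expect_equal(kp5$contact_duration_ns, 5)  # frame union

  empty <- cs_from_indicator(rep(0, 10))
  expect_warning(kp6 <- kinetic_profile(empty, "Chol"), "all-zero")
  expect_equal(kp6$contact_duration_ns, 0)
})

test_that("residue ranking breaks ties by ascending id and caps at n", {
  frames <- replicate(10, data.table(
    residue_id = c(322L, 323L, 324L), monomer_id = 0L,
    molecule_id = c(2L, 2L, 3L), molecule_class = "Chol"),
    simplify = FALSE)
  cs <- make_cs(frames)
  kp <- kinetic_profile(cs, "Chol")
  expect_equal(rank_residues(kp, "contact_duration", 2), c(322, 323))
  expect_equal(rank_residues(kp, "contact_duration", 99), c(322, 323, 324))
})

test_that("displacement maps: frozen lipids are zero, free diffusion matches
           the closed-form mean step length", {
  msp0 <- membrane_spec(n_per_leaflet = 40, diffusion = 0,
                        chol_flip_rate = 0)
  sys0 <- build_system(msp0, protein_spec(sites = list()), seed = 15)
  tr0 <- simulate_membrane(sys0, n_frames = 10, dt = 0.1, seed = 16)
  dg0 <- displacement_map(tr0, sys0$topology, "Chol", cutoff = NULL,
                          bins = 5)
  expect_true(all(dg0$mean_rate[dg0$n_samples > 0] == 0))
  expect_true(all(is.na(dg0$mean_rate[dg0$n_samples == 0])))

  # E|dr| = sqrt(pi D dt) for a 2D Gaussian step
  D <- 0.05; dt <- 0.1
  msp <- membrane_spec(n_per_leaflet = 150, diffusion = D,
                       chol_flip_rate = 0)
  sys <- build_system(msp, protein_spec(n_monomers = 0, radius = 1e-6,
                                        footprint_radius = 0,
                                        sites = list()), seed = 17)
  tr <- simulate_membrane(sys, n_frames = 800, dt = dt, seed = 18)
  dg <- displacement_map(tr, sys$topology, "Chol", cutoff = NULL, bins = 3)
  expect_true(all(dg$n_samples > 1e3))
  expected <- sqrt(pi * D * dt) / dt
  expect_true(all(abs(dg$mean_rate - expected) / expected < 0.05))
})

test_that("displacement over a planted slow site is below the bulk rate", {
  run <- validation_run()
  sys <- run$sys
  tr <- subset_frames(run$traj, 1:2500)
  dg <- displacement_map(tr, sys$topology, "Chol", cutoff = NULL, bins = 30)
  sl <- sys$sites[site_class == "non_annular"][1]
  ix <- findInterval(sl$cx, dg$x_edges, rightmost.closed = TRUE)
  iy <- findInterval(sl$cy, dg$y_edges, rightmost.closed = TRUE)
  expect_gt(dg$n_samples[ix, iy], 50)
  bulk <- stats::median(dg$mean_rate[dg$n_samples > 100], na.rm = TRUE)
  expect_lt(dg$mean_rate[ix, iy], 0.8 * bulk)
})

test_that("co-contacts are conditioned on anchor occupancy", {
  # molecule 5 touches the anchor and a neighbour simultaneously
  frames <- c(replicate(10, data.table(
    residue_id = c(339L, 340L), monomer_id = 0L, molecule_id = 5L,
    molecule_class = "Chol"), simplify = FALSE),
    replicate(4, data.table(   # neighbour alone: must not count
      residue_id = 340L, monomer_id = 0L, molecule_id = 5L,
      molecule_class = "Chol"), simplify = FALSE))
  cs <- make_cs(frames)
  cc <- co_contact_profile(cs, 339, "Chol")
  expect_equal(cc$residue_id, 340)
  expect_equal(cc$n_contacts, 10)

  expect_warning(
    none <- co_contact_profile(cs_from_indicator(rep(0, 5)), 322, "Chol"),
    "never in contact")
  expect_equal(nrow(none), 0)
})

test_that("co-contact counts match a frame-by-frame conditional recount", {
  run <- validation_run()
  cs <- run$cs_eq
  anchor <- 331
  cc <- co_contact_profile(cs, anchor, "Chol")
  m <- cs[molecule_class == "Chol"]
  manual <- integer(0)
  anc <- m[residue_id == anchor]
  for (f in unique(anc$frame)) {
    mols <- anc[frame == f, molecule_id]
    oth <- m[frame == f & molecule_id %in% mols & residue_id != anchor]
    if (nrow(oth)) manual <- c(manual, oth$residue_id)
  }
  want <- sort(table(manual), decreasing = TRUE)
  if (length(want)) {
    for (rid in names(want))
      expect_equal(cc[residue_id == as.integer(rid), n_contacts],
                   unname(want[[rid]]))
  } else {
    expect_equal(nrow(cc), 0)
  }
})

test_that("bead contact ratios resolve lipid orientation in the site", {
  # trivial: only ROH ever in contact -> fraction 1
  bead_frames <- replicate(6, data.table(
    residue_id = 331L, monomer_id = 0L, molecule_id = 7L,
    molecule_class = "Chol", protein_bead = "BB", lipid_bead = "ROH"),
    simplify = FALSE)
  cs <- make_cs(bead_frames, detail = "bead")
  # pretend the class has a multi-bead representation elsewhere
  cs2 <- make_cs(c(bead_frames, list(data.table(
    residue_id = 999L, monomer_id = 0L, molecule_id = 7L,
    molecule_class = "Chol", protein_bead = "BB", lipid_bead = "R1"))),
    detail = "bead")
  br <- bead_contact_ratio(cs2, 331, "Chol")
  expect_equal(br[lipid_bead == "ROH", fraction], 1)

  # uniform contacts over the 8 cholesterol beads -> 1/8 each
  beads <- c("ROH", "R1", "R2", "R3", "R4", "R5", "C1", "C2")
  uni <- replicate(4, data.table(
    residue_id = 331L, monomer_id = 0L, molecule_id = 7L,
    molecule_class = "Chol", protein_bead = "BB", lipid_bead = beads),
    simplify = FALSE)
  bru <- bead_contact_ratio(make_cs(uni, detail = "bead"), 331, "Chol")
  expect_equal(sort(unique(bru$fraction)), 0.125)
  expect_equal(sum(bru$fraction), 1)

  # molecule-detail series and single-bead lipids are refused
  expect_error(bead_contact_ratio(cs_from_indicator(rep(1, 3)), 322, "Chol"),
               "bead-detail")
  expect_error(bead_contact_ratio(cs, 331, "Chol"), "single-bead")
})

test_that("8-bead cholesterol pinned at a buried site contacts the anchor
           mainly through ROH and adjacent sterol beads", {
  ps <- protein_spec(sites = list(
    binding_site_spec(331, "all", "non_annular", k_on_prob = 0.2)))
  msp <- membrane_spec(n_per_leaflet = 60, chol_beads = 8)
  sys <- build_system(msp, ps, seed = 19)
  tr <- simulate_membrane(sys, n_frames = 1200, dt = 0.1, seed = 20)
  cs <- contact_series(tr, sys$topology, detail = "bead",
                       lipid_classes = "Chol")
  br <- bead_contact_ratio(cs, 331, "Chol")
  expect_equal(sum(br$fraction), 1)
  topbeads <- br[lipid_bead %in% c("ROH", "R1", "R2"), sum(fraction)]
  expect_gt(topbeads, 0.7)
  # the hydroxyl bead engages; the hydrocarbon tail stays out of the site
  expect_gt(br[lipid_bead == "ROH", fraction], 0.2)
  expect_lt(sum(br[lipid_bead %in% c("C1", "C2"), fraction]), 0.05)
})
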