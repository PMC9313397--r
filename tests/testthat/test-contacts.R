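two_bead_system <- function(d, box = c(10, 10, 10)) {
  top <- bead_topology(bead_name = c("BB", "ROH"),
                       residue_id = c(322L, 1000L),
                       residue_name = c("ALA", "CHOL"),
                       monomer_id = c(0L, NA),
                       molecule_id = c(1L, 2L),
                       molecule_class = c("protein", "Chol"))
  fr <- frame(0, rbind(c(1, 5, 5), c(1 + d, 5, 5)), box)
  list(topology = top, frame = fr)
}

test_that("the 0.6 nm contact boundary is strict", {
  s <- two_bead_system(0.59)
  expect_equal(nrow(find_contacts(s$frame, s$topology, 0.6)), 1)
  s <- two_bead_system(0.61)
  expect_equal(nrow(find_contacts(s$frame, s$topology, 0.6)), 0)
  s <- two_bead_system(0.60)
  expect_equal(nrow(find_contacts(s$frame, s$topology, 0.6)), 0)
})

test_that("contacts wrap across the periodic boundary", {
  s <- two_bead_system(0)
  s$frame$positions[1, ] <- c(0.3, 5, 5)
  s$frame$positions[2, ] <- c(9.8, 5, 5)
  cc <- find_contacts(s$frame, s$topology, 0.6)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$residue_id, 322)
  expect_equal(cc$molecule_id, 2)
})

test_that("an over-large cutoff is a geometry error", {
  s <- two_bead_system(0.5)
  expect_error(find_contacts(s$frame, s$topology, 5), "geometry error")
  expect_error(find_contacts(s$frame, s$topology, -1), "> 0")
})

test_that("cell-list contacts match the all-pairs oracle on random frames", {
  for (seed in 1:6) {
    np <- sample(3:40, 1)
    nl <- sample(3:60, 1)
    s <- random_toy_system(np, nl, box = c(4, 6, 9), seed = seed)
    got <- find_contacts(s$frame, s$topology, 0.6)
    setorder(got, residue_id, monomer_id, molecule_id)
    want <- brute_contacts(s$frame$positions, s$frame$box, s$topology, 0.6)
    expect_equal(got[, .(residue_id, monomer_id, molecule_id)], want)
  }
})

test_that("contact sets are invariant under rigid translation modulo the box", {
  s <- random_toy_system(20, 40, box = c(7, 8, 9), seed = 9)
  base <- find_contacts(s$frame, s$topology, 0.6)
  setorder(base, residue_id, molecule_id)
  for (shift in list(c(1.3, -2.7, 4.1), c(7, 8, 9) * 2 + 0.5)) {
    fr <- s$frame
    fr$positions <- sweep(fr$positions, 2, shift, `+`)
    got <- find_contacts(fr, s$topology, 0.6)
    setorder(got, residue_id, molecule_id)
    expect_equal(got, base)
  }
})

test_that("a residue-molecule pair counts once per frame at molecule detail", {
  # 3-bead cholesterol with two beads inside the cutoff of the same residue
  top <- bead_topology(bead_name = c("BB", "ROH", "R1", "R2"),
                       residue_id = c(322L, 1000L, 1000L, 1000L),
                       residue_name = c("ALA", rep("CHOL", 3)),
                       monomer_id = c(0L, NA, NA, NA),
                       molecule_id = c(1L, 2L, 2L, 2L),
                       molecule_class = c("protein", rep("Chol", 3)))
  pos <- rbind(c(5, 5, 5), c(5.3, 5, 5), c(5.3, 5, 5.22), c(5.3, 5, 6.5))
  fr <- frame(0, pos, c(10, 10, 10))
  expect_equal(nrow(find_contacts(fr, top, 0.6)), 1)
  tr <- cg_trajectory(array(rep(pos, 2), c(4, 3, 2)), c(0, 0.1),
                      c(10, 10, 10))
  cs_mol <- contact_series(tr, top, 0.6)
  cs_bead <- contact_series(tr, top, 0.6, detail = "bead")
  expect_equal(nrow(cs_mol), 2)   # one row per frame
  expect_equal(nrow(cs_bead), 4)  # two bead pairs per frame
  expect_setequal(unique(cs_bead$lipid_bead), c("ROH", "R1"))
})

test_that("shell counts: moving average arithmetic and the frozen limit", {
  expect_equal(moving_average(c(2, 4, 6), 3), c(3, 4, 5))
  expect_equal(moving_average(c(2, 4, 6), 1), c(2, 4, 6))

  msp <- membrane_spec(n_per_leaflet = 30, diffusion = 0,
                       chol_flip_rate = 0)
  sys <- build_system(msp, protein_spec(sites = list()), seed = 8)
  tr <- simulate_membrane(sys, n_frames = 10, dt = 0.1, seed = 9)
  cs <- contact_series(tr, sys$topology)
  sc <- shell_count_series(cs, "Chol", window_ns = 0.3)
  n0 <- length(unique(find_contacts(get_frame(tr, 1), sys$topology,
                                    0.6)[molecule_class == "Chol",
                                         molecule_id]))
  expect_equal(sc$count, rep(n0, 10))
  expect_equal(sc$smoothed, rep(n0, 10))
  # bounded by the number of molecules of the class
  expect_true(all(sc$count <= sum(sys$lipids$class == "Chol")))
  expect_warning(shell_count_series(cs, "PIP2"), "absent")
})

test_that("shell counts recomputed from the stored series match raw frames", {
  sys <- build_system(membrane_spec(n_per_leaflet = 60),
                      default_protein_spec(), seed = 10)
  tr <- simulate_membrane(sys, n_frames = 40, dt = 0.1, seed = 11)
  cs <- contact_series(tr, sys$topology)
  sc <- shell_count_series(cs, "Chol", window_ns = 0.1)
  raw <- vapply(seq_len(40), function(f) {
    cc <- find_contacts(get_frame(tr, f), sys$topology, 0.6)
    length(unique(cc[molecule_class == "Chol", molecule_id]))
  }, 0)
  expect_equal(sc$count, raw)
  # across-repeat mean and sd
  tr2 <- simulate_membrane(sys, n_frames = 40, dt = 0.1, seed = 12)
  cs2 <- contact_series(tr2, sys$topology)
  reps <- shell_count_series(list(cs, cs2), "Chol", window_ns = 0.5)
  expect_true(all(c("mean", "sd") %in% names(reps)))
  one <- shell_count_series(cs, "Chol", 0.5)$smoothed
  two <- shell_count_series(cs2, "Chol", 0.5)$smoothed
  expect_equal(reps$mean, (one + two) / 2)
  expect_equal(reps$sd, apply(cbind(one, two), 1, sd))
})

test_that("contact fractions are correct, normalised and oracle-checked", {
  frames <- c(replicate(7, data.table(residue_id = 322L, monomer_id = 0L,
                                      molecule_id = 5L,
                                      molecule_class = "PC"),
                        simplify = FALSE),
              replicate(3, data.table(residue_id = 322L, monomer_id = 0L,
                                      molecule_id = 9L,
                                      molecule_class = "Chol"),
                        simplify = FALSE))
  cs <- make_cs(frames)
  tab <- contact_fractions(cs)
  expect_equal(tab$frac_PC, 0.7)
  expect_equal(tab$frac_Chol, 0.3)
  expect_equal(tab$total, 10)

  # oracle recount on a simulated system with all classes
  sys <- build_system(membrane_spec(leaflets = composition_asymmetric(),
                                    n_per_leaflet = 80),
                      default_protein_spec(), seed = 13)
  tr <- simulate_membrane(sys, n_frames = 30, dt = 0.1, seed = 14)
  cs2 <- contact_series(tr, sys$topology)
  tab2 <- contact_fractions(cs2)
  fcols <- grep("^frac_", names(tab2), value = TRUE)
  sums <- rowSums(as.matrix(tab2[, ..fcols]))
  expect_true(all(abs(sums[tab2$total > 0] - 1) < 1e-9))
  recount <- data.table::rbindlist(lapply(seq_len(30), function(f)
    find_contacts(get_frame(tr, f), sys$topology, 0.6)))
  rid <- tab2$residue_id[which.max(tab2$total)]
  sub <- recount[residue_id == rid]
  expect_equal(tab2[residue_id == rid, total], nrow(sub))
  expect_equal(tab2[residue_id == rid, frac_Chol],
               mean(sub$molecule_class == "Chol"))
})

test_that("enrichment uses a strict threshold and is monotone", {
  frames <- c(replicate(31, data.table(residue_id = 322L, monomer_id = 0L,
                                       molecule_id = 2L,
                                       molecule_class = "Chol"),
                        simplify = FALSE),
              replicate(69, data.table(residue_id = 322L, monomer_id = 0L,
                                       molecule_id = 5L,
                                       molecule_class = "PC"),
                        simplify = FALSE),
              replicate(30, data.table(residue_id = 323L, monomer_id = 0L,
                                       molecule_id = 2L,
                                       molecule_class = "Chol"),
                        simplify = FALSE),
              replicate(70, data.table(residue_id = 323L, monomer_id = 0L,
                                       molecule_id = 5L,
                                       molecule_class = "PC"),
                        simplify = FALSE))
  cs <- make_cs(frames)
  tab <- contact_fractions(cs)
  expect_equal(enrichment_mask(tab, "Chol", 0.30), 322) # 0.31 in, 0.30 out
  expect_setequal(enrichment_mask(tab, "Chol", 0), c(322, 323))
  prev <- Inf
  for (th in c(0, 0.1, 0.3, 0.5, 0.9)) {
    n <- length(enrichment_mask(tab, "Chol", th))
    expect_lte(n, prev)
    prev <- n
  }
})
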