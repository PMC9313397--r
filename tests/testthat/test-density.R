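static_traj <- function(pos, box = c(10, 10, 10), nf = 1) {
  co <- array(NA_real_, c(nrow(pos), 3, nf))
  for (f in seq_len(nf)) co[, , f] <- pos
  cg_trajectory(co, (seq_len(nf) - 1) * 0.1, box)
}

chol_only_top <- function(n) {
  bead_topology(bead_name = rep("ROH", n),
                residue_id = seq_len(n) + 100L,
                residue_name = rep("CHOL", n),
                monomer_id = rep(NA_integer_, n),
                molecule_id = seq_len(n),
                molecule_class = rep("Chol", n))
}

test_that("a static bead gives a single occupied bin of density 1/area", {
  top <- chol_only_top(1)
  tr <- static_traj(matrix(c(3.21, 7.77, 5), 1), nf = 4)
  dm <- density_map(tr, top, "bead:ROH", bins = 10, sigma = 0)
  expect_equal(sum(dm$density > 0), 1)
  expect_equal(max(dm$density), 1 / dm$bin_area)
  # integral over the grid equals the mean selected-bead count per frame
  expect_equal(sum(dm$density) * dm$bin_area, 1, tolerance = 1e-6)
})

test_that("periodic Gaussian smoothing conserves mass and wraps edges", {
  m <- matrix(0, 12, 12)
  m[1, 1] <- 5
  s <- smooth_periodic(m, 2)
  expect_equal(sum(s), 5, tolerance = 1e-9)
  # wraps: the opposite corner neighbour sees the same weight as [2, 2]
  expect_equal(s[12, 12], s[2, 2], tolerance = 1e-12)
  expect_gt(s[12, 1], s[6, 1])

  top <- chol_only_top(30)
  set.seed(5)
  tr <- static_traj(cbind(runif(30, 0, 10), runif(30, 0, 10), 5), nf = 2)
  d0 <- density_map(tr, top, "bead:ROH", bins = 20, sigma = 0)
  d3 <- density_map(tr, top, "bead:ROH", bins = 20, sigma = 3)
  expect_equal(sum(d3$density), sum(d0$density), tolerance = 1e-9)
})

test_that("unsmoothed maps are translation-covariant modulo bins", {
  top <- chol_only_top(40)
  set.seed(6)
  pos <- cbind(runif(40, 0, 10), runif(40, 0, 10), 5)
  tr <- static_traj(pos)
  d0 <- density_map(tr, top, "bead:ROH", bins = 10, sigma = 0)
  shift <- c(2, 3) # whole bins (bin width 1)
  tr2 <- static_traj(sweep(pos, 2, c(shift, 0), `+`))
  d1 <- density_map(tr2, top, "bead:ROH", bins = 10, sigma = 0)
  expect_equal(d1$density[((seq_len(10) - 1 + shift[1]) %% 10) + 1,
                          ((seq_len(10) - 1 + shift[2]) %% 10) + 1],
               d0$density)
})

test_that("uniform ideal-gas lipids give a flat map within sampling error", {
  msp <- membrane_spec(n_per_leaflet = 100, chol_flip_rate = 0)
  sys <- build_system(msp, protein_spec(n_monomers = 0, radius = 1e-6,
                                        footprint_radius = 0,
                                        sites = list()), seed = 23)
  tr <- simulate_membrane(sys, n_frames = 150, dt = 0.1, seed = 24)
  dm <- density_map(tr, sys$topology, "lipid:Chol", bins = 6, sigma = 0)
  rho <- 60 / (15 * 15) # 30% of 2 x 100 lipids over the box area
  # Poisson 3 sigma band on per-bin counts, conservative for correlated frames
  n_per_bin <- dm$counts
  lam <- rho * dm$bin_area * dm$n_frames
  expect_true(all(abs(n_per_bin - lam) < 3 * sqrt(lam) * sqrt(150)))
  expect_equal(mean(dm$density), rho, tolerance = 0.05)
})

test_that("z-profiles are normalised, bimodal at the leaflet planes and
           symmetric for bulk cholesterol", {
  top <- chol_only_top(2)
  tr <- static_traj(rbind(c(1, 1, 5), c(2, 2, 5)), nf = 3)
  zp <- z_distribution(tr, top, "bead:ROH", bins = 20)
  expect_equal(sum(zp$freq), 1)
  expect_equal(sum(zp$freq > 0), 1)

  msp <- membrane_spec(n_per_leaflet = 120, chol_flip_rate = 0.02)
  sys <- build_system(msp, protein_spec(sites = list()), seed = 25)
  tr2 <- simulate_membrane(sys, n_frames = 400, dt = 0.1, seed = 26)
  zp2 <- z_distribution(tr2, sys$topology, "bead:ROH", bins = 50)
  expect_equal(attr(zp2, "mode_lower"), 3.5, tolerance = 0.15)
  expect_equal(attr(zp2, "mode_upper"), 6.5, tolerance = 0.15)
  expect_lt(attr(zp2, "between_min_freq"), 0.01)
  # mirror symmetry about the midplane (two-sample KS on bead z draws)
  roh <- select_beads(sys$topology, "bead:ROH")
  z <- as.vector(tr2$coords[roh, 3, seq(1, 400, by = 40)])
  ks <- suppressWarnings(stats::ks.test(z - 5, 5 - z))
  expect_gt(ks$p.value, 0.01)
})

test_that("cholesterol bound at a buried site fills the bilayer centre", {
  ps <- protein_spec(sites = list(
    binding_site_spec(331, "all", "non_annular", k_on_prob = 0.2)))
  sys <- build_system(membrane_spec(n_per_leaflet = 80), ps, seed = 27)
  tr <- simulate_membrane(sys, n_frames = 600, dt = 0.1, seed = 28)
  zp_bulk <- z_distribution(tr, sys$topology, "bead:ROH", bins = 40)
  zp_bound <- z_distribution(tr, sys$topology, "bead:ROH", bins = 40,
                             bound_filter = 0.6)
  mid <- abs(zp_bound$z - 5) < 0.5
  expect_gt(sum(zp_bound$freq[mid]), 0.2)
  expect_lt(sum(zp_bulk$freq[mid]), 0.05)
})

test_that("Boltzmann inversion: uniform density is zero, a density ratio of
           e is one thermal unit, the minimum is pinned at zero", {
  mk_grid <- function(dens, counts) {
    structure(list(x_edges = seq(0, 10, length.out = nrow(dens) + 1),
                   y_edges = seq(0, 10, length.out = ncol(dens) + 1),
                   density = dens, counts = counts, n_frames = 100,
                   bin_area = 1, sigma = 0, box = c(10, 10, 10),
                   label = "test"), class = "density_grid")
  }
  uni <- mk_grid(matrix(2, 5, 5), matrix(100, 5, 5))
  fe <- free_energy_from_density(uni, T = 310, ref = "global_mean")
  expect_true(all(fe$dG == 0))

  dens <- matrix(1, 5, 5)
  dens[2, 2] <- exp(1)
  fe2 <- free_energy_from_density(mk_grid(dens, matrix(100, 5, 5)),
                                  T = 310, ref = "explicit", rho_ref = 1)
  # the e-fold bin is kB T = 2.577 kJ/mol deeper than the reference bins
  expect_equal(fe2$dG[1, 1] - fe2$dG[2, 2], 0.0083144621 * 310,
               tolerance = 1e-9)
  expect_equal(fe2$dG[1, 1] - fe2$dG[2, 2], 2.577, tolerance = 1e-3)
  expect_equal(min(fe2$dG, na.rm = TRUE), 0)

  # undersampled bins are masked, never zero-filled
  cnt <- matrix(100, 5, 5); cnt[3, 3] <- 2
  fe3 <- free_energy_from_density(mk_grid(dens, cnt), ref = "global_mean")
  expect_true(is.na(fe3$dG[3, 3]))
  expect_true(fe3$mask[3, 3])
  expect_error(free_energy_from_density(mk_grid(dens, matrix(0, 5, 5))),
               "undersampled")

  # invariant to uniform rescaling of the lipid count under global_mean
  fe4 <- free_energy_from_density(mk_grid(dens * 7,
                                          matrix(100, 5, 5)),
                                  ref = "global_mean")
  fe5 <- free_energy_from_density(mk_grid(dens, matrix(100, 5, 5)),
                                  ref = "global_mean")
  expect_equal(fe4$dG, fe5$dG, tolerance = 1e-12)
})
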