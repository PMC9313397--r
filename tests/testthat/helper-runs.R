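# Shared synthetic runs, computed once per test session.
.run_cache <- new.env(parent = emptyenv())

# Full-scale validation run: 9000 frames at dt = 0.1 ns (0.9 us), default
# membrane (symmetric 70/30 PC/Chol) and demo protein with the planted
# annular (residue 339, k_off = 0.1/ns) and non-annular (residue 331,
# k_off = 0.001/ns) cholesterol sites.
validation_run <- function() {
  if (is.null(.run_cache$big)) {
    sys <- build_system(membrane_spec(), default_protein_spec(), seed = 101)
    traj <- simulate_membrane(sys, n_frames = 9000, dt = 0.1, seed = 102)
    cs_chol_full <- contact_series(traj, sys$topology,
                                   lipid_classes = "Chol")
    traj_eq <- slice_equilibrated(traj, 90)
    cs_eq <- contact_series(traj_eq, sys$topology)
    .run_cache$big <- list(sys = sys, traj = traj, traj_eq = traj_eq,
                           cs_chol_full = cs_chol_full, cs_eq = cs_eq,
                           true_events = attr(traj, "events"))
  }
  .run_cache$big
}
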