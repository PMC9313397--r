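# lipidprint

Lipid–protein interaction fingerprinting for coarse-grained membrane
simulations, in R.

Membrane proteins are wrapped in a shell of lipids whose composition and
exchange kinetics — the protein's *lipid fingerprint* — differ from the
bulk bilayer. Two regimes matter for interpretation: **annular** lipids
coat the protein surface and exchange rapidly with the bulk, while
**non-annular** lipids lodge at subunit or helix interfaces, exchange
slowly, and often stabilise or regulate the protein. Cholesterol in
particular binds ion channels at both kinds of site, and telling the two
apart from a trajectory is a kinetics problem, not a geometry problem.

`lipidprint` implements the full contact-based analysis used for this
classification on coarse-grained (Martini-style) trajectories:

* residue–lipid **contact detection** under periodic boundaries
  (cell-list neighbour search, strict `< 0.6` nm cut-off by default);
* **first-shell counts** over time (20 ns window average, multi-repeat
  mean ± SD) and per-residue **contact fractions** with enrichment masks
  ("over 30% of contacts" semantics);
* **binding events** and the kinetic metrics that separate the two
  regimes — **contact duration** (total contact time of a residue with a
  lipid type, frame-union) and **maximum occupancy** (longest continuous
  contact with one specific molecule), plus distinct-partner counts,
  displacement maps, anchor-conditioned co-contacts and per-bead contact
  ratios;
* spatial free energy by **Boltzmann inversion** of time-averaged
  lateral density, `dG = -kB*T*ln(rho/rho_ref)`, on a relative scale
  with the minimum pinned at 0 (kB = 0.0083144621 kJ/(mol K), T = 310 K
  by default);
* a **synthetic membrane simulator** — ideal-gas lipids diffusing in two
  leaflets around a static tetramer, cholesterol flip-flop, and planted
  Markovian binding sites with known `k_on`/`k_off` — providing ground
  truth against which every estimator in the package is validated.

A site classification falls out of the kinetics: high contact duration
with many exchanging partners marks an annular site; high maximum
occupancy with one to three partners marks a non-annular site.

## Worked example

Simulate the default system — a 15 × 15 × 10 nm box, 70/30 PC/cholesterol
in both leaflets, 300 lipids per leaflet, and a 4 × 20-residue tetramer
carrying a fast-exchange (annular) cholesterol site at residue 339
(`k_off = 0.1` /ns) and a slow-exchange (non-annular) site at residue 331
(`k_off = 0.001` /ns) — then run the fingerprint analysis:

```r
library(lipidprint)

sys  <- build_system(membrane_spec(), default_protein_spec(), seed = 7)
traj <- simulate_membrane(sys, n_frames = 9000, dt = 0.1, seed = 8)

traj_eq <- slice_equilibrated(traj, 90)     # drop the first tenth
cs <- contact_series(traj_eq, sys$topology, cutoff = 0.6)

shell_plateau(shell_count_series(cs, "Chol", window_ns = 20), 90)
#> [1] 9.1

kp <- kinetic_profile(cs, "Chol")
kp[kp$residue_id %in% c(331, 339),
   c("residue_id", "contact_duration_ns", "max_occupancy_ns",
     "n_distinct_partners")]
#>    residue_id contact_duration_ns max_occupancy_ns n_distinct_partners
#> 1:        331              206.55           206.55                0.50
#> 2:        339              638.65            52.80               34.75

classify_sites(kp)
#>    residue_id  site_class
#> 1:        322     annular
#> 2:        331 non_annular
#> 3:        338     annular
#> 4:        339     annular
#> 5:        340     annular
#> 6:        341     annular

ev <- extract_events(contact_series(traj, sys$topology,
                                    lipid_classes = "Chol"))
mean(ev$duration_ns[ev$residue_id == 339])   # 534 events
#> [1] 10.87
```

Reading the numbers: about 9 cholesterol molecules occupy the first
shell at the plateau. Residue 339 has the highest total contact time
(639 of 810 ns) spread over ~35 different cholesterol molecules — fast
exchange, the annular signature (neighbouring surface residues share
it). Residue 331 instead holds *one* cholesterol molecule for a
continuous 207 ns stretch (its contact duration and maximum occupancy
coincide) with 0.5 partners per monomer — slow exchange at a buried
site, the non-annular signature. The measured mean binding-event
duration at the fast site, 10.87 ns over 534 events, recovers the
planted mean dwell time `1/k_off = 10` ns. The same analysis runs
end-to-end from one configuration via `run_pipeline(run_config(...))`,
which also writes every table as TSV plus a JSON summary.

Real trajectories enter through `read_topology()` (GRO/PDB) and
`read_trajectory()` (a documented plain-text frame format; convert
binary XTC/TRR first).

## Package layout

* `R/`, `src/` — analysis modules and the Rcpp cell-list search
* `tests/testthat/` — unit, property and end-to-end validation tests
* `vignettes/lipid-fingerprinting.Rmd` — the methods vignette: model,
  parameters, generator design, numerical choices, limitations
* `inst/scripts/lipidprint` — thin command-line wrapper
  (`lipidprint simulate`, `lipidprint run`)
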