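---
title: "Fingerprinting lipid-protein interactions in coarse-grained membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting lipid-protein interactions in coarse-grained membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidprint)
library(data.table)
```

## The problem

Membrane proteins sit in a shell of lipids — their "lipid fingerprint" —
whose composition and exchange kinetics differ from the bulk bilayer.
Two regimes matter. *Annular* lipids coat the protein surface and swap
rapidly with the bulk; they provide the amphiphilic environment but no
specific, long-lived interaction. *Non-annular* lipids lodge at subunit
or helix interfaces, exchange slowly, and often stabilise or regulate the
protein. Cholesterol is a recurring non-annular guest of ion channels:
its small rigid sterol body and single hydroxyl let it slip into "greasy
hollows" at domain interfaces, and even flip between leaflets.

Coarse-grained (CG) molecular dynamics is the standard tool for mapping
these fingerprints: microsecond trajectories of a Martini-resolution
protein in a mixed bilayer, analysed through residue-lipid contact
statistics. `lipidprint` implements that analysis layer in R — contact
detection under periodic boundaries, shell counts, contact fractions and
enrichment, binding-event kinetics, displacement maps, co-contacts,
per-bead contact ratios, and spatial free energies by Boltzmann
inversion — together with a synthetic CG membrane simulator that plants
binding sites with known kinetics, so every estimator in the package can
be validated against ground truth.

## Contact model

Two CG beads are in contact when their minimum-image distance is
strictly below a cut-off, 0.6 nm by default. The strict inequality is a
deliberate convention: "within 0.6 nm" leaves the boundary case
unspecified, and a strict `<` keeps the definition consistent with the
strict ">" used for enrichment ("over 30%"); the cut-off is a plain
argument everywhere, so 0.63, 0.7 or 1.0 nm conventions are one keyword
away. A residue-lipid *molecule* pair counts once per frame no matter
how many bead pairs fall under the cut-off; this keeps contact counts
independent of bead multiplicity (an 8-bead cholesterol would otherwise
outvote a 1-bead one). Bead-resolved counting is retained as
`contact_series(..., detail = "bead")` for orientation analyses.
The whole lipid — headgroup and tails — is considered.

Detection uses a cell list with cells at least one cut-off wide, so each
bead is tested only against its 27 neighbouring cells; the test suite
holds the cell-list output equal to an all-pairs brute-force oracle over
randomised frames, sizes 10-500 beads. Boxes are rectangular only;
triclinic cells are rejected with a clear error.

## Kinetic metrics

From the per-frame contact table the package derives, per residue and
lipid class:

* **Contact duration** — total time the residue touches *any* molecule
  of the class (frame union). The alternative reading — summing over
  molecules — is available as `duration_mode = "molecule_sum"`; the
  union is the default because it keeps contact duration bounded by the
  trajectory length, which makes the invariant *maximum occupancy <=
  contact duration <= trajectory time* meaningful and testable.
* **Maximum occupancy** — the longest single run of continuous contact
  between the residue and one specific molecule.
* **Distinct partners** — how many different molecules ever bind the
  residue.

A *binding event* is a maximal run of consecutive contact frames for one
(residue, monomer, molecule) triple; `gap_tolerance` merges runs
separated by at most that many blank frames and defaults to 0 (no
smoothing — interruption tolerance is an analysis choice, not a given).
Event duration is the inclusive frame count times `dt`, so a single
contact frame has duration `dt`, and bridged gaps count into the merged
event.

The annular/non-annular contrast falls out of these metrics: a fast
site tops the contact-duration ranking with tens of distinct partners
(every one exchanging after ~tens of ns); a slow site tops maximum
occupancy while seeing only one to three molecules over the whole run.
`classify_sites()` encodes that heuristic with thresholds (<= 3
partners for non-annular, >= 20 for annular, within the top-10 of the
relevant metric) that are exposed in the configuration — they are a
distillation of a qualitative contrast, not measured constants.

Residue statistics are pooled across monomer copies at reporting time
(mean and SEM over the chain copies of a homotetramer), never at
detection time; normalised profiles divide by the maximum across
residues so the top residue of each metric sits at 1.

## The synthetic membrane

The simulator generates the study conditions, not a fit to any
particular trajectory:

* **Geometry.** A 15 x 15 x 10 nm box; a static protein of 4 monomers x
  20 residues on a 2.2 nm cylinder (static = the position-restraint
  limit), residue rows at z offsets -1.6..1.6 nm about the midplane;
  leaflet headgroup planes at +/-1.5 nm.
* **Lipids.** Ideal-gas single-bead lipids (no lipid-lipid excluded
  volume) at 300 per leaflet, i.e. ~0.75 nm^2 per lipid, the areal
  density a CG bilayer builder would produce for this box. Ideal-gas
  lipids are a feature, not a shortcut: they make the stationary density
  exactly uniform, so Boltzmann inversion has an analytic reference.
  Cholesterol is 1 bead (ROH) by default, or an 8-bead rigid rod (ROH,
  R1-R5, C1, C2 at 0.22 nm z spacing) where bead-level contact ratios
  are the point.
* **Dynamics.** 2D Gaussian random walk per axis with sd `sqrt(2 D dt)`,
  D = 0.05 nm^2/ns for every class (the CG-lipid scale), periodic
  wrapping, hard rejection of moves into the protein footprint (2.6 nm).
  Cholesterol flips leaflet as a Poisson process (0.001/ns, sub-us
  flip-flop). Default runs are 9000 frames at dt = 0.1 ns — the frame
  spacing of a production CG run, at one tenth of its length.
* **Sites.** A site is a lateral capture disc anchored at a residue: a
  free lipid of the selective class inside the capture radius binds with
  probability `k_on_prob` per frame; a bound lipid is pinned at the site
  centre (recorded with 0.03 nm Gaussian jitter) and unbinds with
  probability `1 - exp(-k_off dt)` per frame. Binding is Markovian by
  construction — no energetics — which is exactly what gives clean,
  checkable ground truth: dwell times are exponential with rate `k_off`.

Three geometric details of the site model deserve their rationale:

* **Escape displacement.** An unbinding lipid is re-placed just outside
  the capture radius (capture + 0.3 nm, random direction, outside the
  footprint). Left at the centre it would be recaptured almost surely
  within a frame or two, chaining dwells together and destroying the
  exponential ground truth. The escape also clears the anchor's contact
  range, so a contact event ends exactly when the binding event does.
* **Recessed annular anchor.** The fast site's anchor bead sits 0.2 nm
  behind the protein wall — an arch-like pocket whose anchor only the
  captured lipid can reach (free lipids outside the footprint stay
  > 0.6 nm away). Annular exchange at a surface residue would otherwise
  mix genuine binding events with grazing passes by bulk lipids and
  bias the measured mean dwell low.
* **Multi-occupancy.** Captures are independent per lipid (consistent
  with ideal-gas lipids), so a site can hold more than one molecule.
  This is also what makes the event statistics well-powered: a
  single-occupancy 10 ns site could host at most ~90 events in a 0.9 us
  run, far too few to resolve a mean dwell to a few percent.

Default site kinetics: annular `k_on_prob = 0.8`, `k_off = 0.1/ns`,
capture 0.8 nm (mean dwell 10 ns, hundreds of events per run);
non-annular `k_on_prob = 0.0008`, `k_off = 0.001/ns`, capture 0.5 nm
(mean dwell 1 us — effectively permanent at run scale, ~1-2 visits per
site per run). The annular parameters were chosen, by the entry-rate
arithmetic above, so that one default run yields >= 500 fast-site events
(the sample size at which a 10 ns mean dwell is resolved to ~3 standard
errors); the non-annular parameters straddle the opposite regime: fewer
than a handful of partners per run. They are generator conditions, fixed
once.

`ground_truth()` predicts each site's occupancy, event count and
distinct partners with an immigration-death chain whose arrival rate is
the ideal-gas rate (bulk density x accessible capture area x
`k_on_prob`), solved self-consistently for depletion by bound lipids.
That rate is exact in the reaction-limited regime (tiny `k_on_prob`,
the slow site) and an upper bound in the near-absorbing regime (the
fast site), where binding is limited by diffusive entry into the
capture zone; the returned bands are used accordingly in the tests.

### What the generator does and does not emulate

It emulates: two leaflets with the reference compositions, 2D lipid
diffusion, cholesterol flip-flop, fast- and slow-exchange binding with
controllable kinetics, a static tetramer, periodic boundaries. It does
not emulate: lipid-lipid interactions and packing, membrane
undulations and thickness deformations, protein flexibility, real
binding energetics or orientation-dependent binding. Passing tests
therefore show that the *estimators* are correct and well-calibrated on
a system whose truth is known — not that any particular real membrane
behaves this way.

### Membrane compositions

The symmetric reference membrane is 70% PC / 30% cholesterol in both
leaflets. The asymmetric (simplified plasma) membrane keeps cholesterol
at 30% of every leaflet and distributes the phospholipid share (70%)
over PC/PE/SM in the outer and PC/PE/PS/SM/PIP2 in the inner leaflet,
with PS and PIP2 inner-only. Per-class counts are exact by
largest-remainder rounding. Because cholesterol content is equal in
both membranes and lipids are ideal, the cholesterol shell count around
the protein is composition-independent by construction; the test suite
confirms the two plateaus agree to better than 10% using four-repeat
means — single runs scatter by ~10% because slow-site occupancy (a few
molecules persisting for hundreds of ns) dominates the variance, which
is why the comparison averages repeats, the same convention as
multi-repeat shell-count curves.

## Shell counts, fractions, enrichment

The first-shell count of a class is the number of distinct molecules
with any bead under the cut-off from any protein bead, per frame,
smoothed with a centred 20 ns moving average that shrinks at the series
ends (no padding — padded edges would bias the plateau estimate).
Contact fractions divide each residue's (frame, molecule) contact pairs
among lipid classes; a residue is *enriched* in a class when that class
accounts for strictly more than the threshold (default 0.30, the bulk
cholesterol fraction) of its contacts.

## Density maps and spatial free energy

Lateral density maps are per-frame 2D histograms (default bin width
0.1 nm), time-averaged, and smoothed with a *periodic* Gaussian kernel
(sigma = 3 bins by default) applied by FFT circular convolution — mass
is conserved to machine precision and the smoothing respects the
periodic cell. The free energy is the Boltzmann inversion

$$\Delta G(\mathbf{r}) = -k_B T \ln \frac{\rho(\mathbf{r})}{\rho_{\rm ref}},$$

with \(k_B = 0.0083144621\) kJ/(mol K) and T = 310 K by default,
shifted so the minimum over sampled bins is exactly 0 (a relative
scale). Three reference conventions are provided: the mean density in a
bulk annulus (>= 1.5 nm beyond the protein's lateral radius, the
default for protein systems), the global mean, or an explicit density.
Bins with fewer than 10 raw counts (or zero density) are masked `NA`,
never zero-filled — a zero-filled bin would masquerade as an infinitely
deep minimum. The implementation is 2D-lateral; site localisation in a
membrane is a lateral question, and a full 3D grid adds sampling cost
without changing the answer at this scale. The inversion is validated
by its inverse: positions rejection-sampled from a known 2.5 kJ/mol
square well recover the depth within 0.25 kJ/mol at 1e5 samples.

z-profiles histogram a bead selection along the membrane normal;
`bound_filter` restricts them to molecules in contact with the protein,
which is how a mid-membrane cholesterol population (hydroxyl buried at
an interfacial site) shows up between the two leaflet modes.

## Displacement maps

For each consecutive frame pair, tracked molecules contribute their
minimum-image step length divided by `dt` to the lateral bin of their
earlier position. The default uses the full 3D step; `lateral_only`
restricts to xy (the two differ only at flip events here). For free 2D
diffusion the bin means converge to \(\sqrt{\pi D\,dt}/dt\) (the mean of
a Rayleigh step), which the tests verify to 5%; bins over a planted
site run markedly slower — the pinned-lipid signature.

## Numerical and interface choices

* Units: nm, ns, kJ/mol throughout; bead indices are 1-based in R
  convention.
* Uniform frame spacing is enforced to 1e-6 ns; single-frame
  trajectories are valid containers but refused by kinetic analyses.
* Text trajectories (`t=<ns> box=<Lx> <Ly> <Lz>` header plus one
  `x y z` line per bead) are the interchange format; GRO/PDB topologies
  are parsed natively/via bio3d. Binary XTC/TRR are rejected with a
  conversion hint rather than half-supported.
* Lenient parsing logs warnings and classifies unknown residues as
  ions; `strict = TRUE` turns both into errors.
* Ranking ties break by ascending residue id (documented, deterministic).
* Every simulation, build and oracle takes an explicit integer seed;
  equal seeds give bit-identical trajectories and byte-identical
  pipeline outputs.

## Problem sizes

The bundled validation suite runs the full pipeline on 9000-frame
(0.9 us) trajectories of 4 x 20 residues and 600 lipids, four-repeat
pairs for the composition comparison, 1e5 samples for the free-energy
recovery, and randomised 10-500-bead frames for the contact oracle —
sizes chosen so the whole suite completes in a few minutes on one CPU
while every estimate keeps the statistical power its tolerance needs.

## Known limitations

* The simulator's sites are kinetic, not energetic; free-energy maps of
  planted sites are therefore validated against planted *densities*,
  not against the site kinetics.
* The fast-site arrival oracle is an upper bound (diffusion-limited
  entry is not modelled in closed form).
* No triclinic boxes, no velocities/forces, no atomistic backmapping,
  no Markov-state modelling or survival-curve k_off fitting beyond the
  event-mean estimator.
* Real CG trajectories must be converted to the text format first; at
  multi-gigabyte scale a dedicated reader would be preferable.
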