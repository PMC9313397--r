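#' Leaflet compositions of the two reference membranes
#'
#' `composition_symmetric()` is the two-component symmetric membrane
#' (70% PC / 30% cholesterol in both leaflets). `composition_asymmetric()`
#' is the six-component simplified plasma membrane with PS and PIP2
#' restricted to the inner leaflet. Cholesterol is 30% of every leaflet in
#' both membranes; the phospholipid percentages of the asymmetric recipe
#' are normalised within the 70% phospholipid share of their leaflet, so
#' that fractions sum to 1.
#'
#' @return named list with per-leaflet fraction vectors `outer` and `inner`.
#' @export
composition_symmetric <- function() {
  list(outer = c(PC = 70, Chol = 30) / 100,
       inner = c(PC = 70, Chol = 30) / 100)
}

#' @rdname composition_symmetric
#' @export
composition_asymmetric <- function() {
  norm70 <- function(phospho) c(phospho / sum(phospho) * 0.7, Chol = 0.3)
  list(outer = norm70(c(PC = 40, PE = 25, SM = 20)),
       inner = norm70(c(PC = 18, PE = 10, PS = 15, SM = 10, PIP2 = 2)))
}

#' Specify a synthetic membrane
#'
#' Defines the box, per-leaflet lipid compositions, lipid counts, lateral
#' diffusion coefficients, cholesterol flip-flop rate and leaflet planes of
#' the synthetic coarse-grained membrane. Lipids are ideal-gas particles
#' (no lipid-lipid excluded volume); cholesterol is a single ROH bead by
#' default or an 8-bead rigid rod (`chol_beads = 8`: ROH, R1-R5, C1, C2 at
#' fixed z offsets) for bead-resolved contact analyses.
#'
#' @param box `(Lx, Ly, Lz)` nm.
#' @param leaflets list with fraction vectors `outer` and `inner` (named by
#'   lipid class, each summing to 1, see [composition_symmetric()]).
#' @param n_per_leaflet lipids per leaflet.
#' @param diffusion named lateral diffusion coefficients (nm^2/ns) per lipid
#'   class; a single unnamed value is recycled to all classes.
#' @param chol_flip_rate cholesterol leaflet flip-flop rate (1/ns).
#' @param leaflet_offset distance (nm) of each leaflet headgroup plane from
#'   the membrane midplane (`Lz/2`).
#' @param chol_beads 1 or 8 beads per cholesterol.
#' @param chol_bead_spacing z spacing (nm) between consecutive cholesterol
#'   beads in 8-bead mode.
#' @return list of class `membrane_spec`.
#' @export
membrane_spec <- function(box = c(15, 15, 10),
                          leaflets = composition_symmetric(),
                          n_per_leaflet = 300,
                          diffusion = 0.05,
                          chol_flip_rate = 0.001,
                          leaflet_offset = 1.5,
                          chol_beads = 1,
                          chol_bead_spacing = 0.22) {
  stopifnot(length(box) == 3, all(box > 0), n_per_leaflet >= 0,
            chol_flip_rate >= 0, leaflet_offset > 0,
            leaflet_offset < box[3] / 2, chol_beads %in% c(1L, 8L))
  for (lf in c("outer", "inner")) {
    fr <- leaflets[[lf]]
    stopifnot(!is.null(fr), !is.null(names(fr)), all(fr >= 0))
    if (abs(sum(fr) - 1) > 1e-9)
      stop(lf, " leaflet fractions must sum to 1 (got ", sum(fr), ")")
    if (!all(names(fr) %in% .lipid_classes))
      stop("unknown lipid class in ", lf, " leaflet: ",
           paste(setdiff(names(fr), .lipid_classes), collapse = ", "))
  }
  classes <- union(names(leaflets$outer), names(leaflets$inner))
  if (length(diffusion) == 1 && is.null(names(diffusion)))
    diffusion <- stats::setNames(rep(diffusion, length(classes)), classes)
  stopifnot(all(classes %in% names(diffusion)), all(diffusion >= 0))
  structure(list(box = as.numeric(box), leaflets = leaflets,
                 n_per_leaflet = as.integer(n_per_leaflet),
                 diffusion = diffusion, chol_flip_rate = chol_flip_rate,
                 leaflet_offset = leaflet_offset,
                 chol_beads = as.integer(chol_beads),
                 chol_bead_spacing = chol_bead_spacing),
            class = "membrane_spec")
}

#' Specify a planted lipid binding site
#'
#' A site is a Markov two-state (bound/free) trap anchored at a protein
#' residue. A free lipid of the selective class whose reference bead lies
#' within `capture_radius` (lateral minimum-image distance) of the site
#' centre binds with probability `k_on_prob` per frame; a bound lipid is
#' pinned at the centre (small positional jitter) and unbinds with
#' probability `1 - exp(-k_off * dt)` per frame, after which it is released
#' just outside the capture zone. `site_class = "annular"` parameterises
#' fast exchange (large k_off, busy leaflet-plane pocket);
#' `"non_annular"` parameterises slow exchange at a buried, mid-membrane
#' position reachable from both leaflets.
#'
#' @param anchor_residue_id protein residue the site reports to.
#' @param monomer_id protein chain copy carrying the site (0-based), or the
#'   string `"all"` to replicate the site on every monomer.
#' @param site_class `"annular"` or `"non_annular"`.
#' @param k_on_prob per-frame binding probability for a lipid inside the
#'   capture radius (0..1).
#' @param k_off unbinding rate (1/ns), > 0.
#' @param capture_radius lateral capture radius (nm), > 0.
#' @param lipid_selectivity lipid class the site accepts.
#' @param center optional explicit site centre (nm); by default placed just
#'   outside the protein wall at the anchor's angular position during
#'   [build_system()].
#' @param anchor_inset radial recession (nm) of the anchor bead behind the
#'   protein wall; the annular default (0.25) models an arch-like pocket
#'   whose anchor only the captured lipid can touch.
#' @param jitter_sd positional jitter (nm) of the pinned lipid.
#' @return list of class `binding_site_spec`.
#' @export
binding_site_spec <- function(anchor_residue_id, monomer_id = "all",
                              site_class = c("annular", "non_annular"),
                              k_on_prob = NULL, k_off = NULL,
                              capture_radius = NULL,
                              lipid_selectivity = "Chol",
                              center = NULL,
                              anchor_inset = NULL,
                              jitter_sd = 0.03) {
  site_class <- match.arg(site_class)
  defs <- if (site_class == "annular") {
    list(k_on_prob = 0.8, k_off = 0.1, capture_radius = 0.8,
         anchor_inset = 0.2)
  } else {
    list(k_on_prob = 0.0008, k_off = 0.001, capture_radius = 0.5,
         anchor_inset = 0)
  }
  k_on_prob <- k_on_prob %||% defs$k_on_prob
  k_off <- k_off %||% defs$k_off
  capture_radius <- capture_radius %||% defs$capture_radius
  anchor_inset <- anchor_inset %||% defs$anchor_inset
  stopifnot(k_on_prob >= 0, k_on_prob <= 1, k_off > 0, capture_radius > 0,
            jitter_sd >= 0, lipid_selectivity %in% .lipid_classes)
  structure(list(anchor_residue_id = as.integer(anchor_residue_id),
                 monomer_id = monomer_id, site_class = site_class,
                 k_on_prob = k_on_prob, k_off = k_off,
                 capture_radius = capture_radius,
                 lipid_selectivity = lipid_selectivity, center = center,
                 anchor_inset = anchor_inset, jitter_sd = jitter_sd),
            class = "binding_site_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify the static tetrameric protein
#'
#' Protein beads are laid out on a cylinder: each monomer occupies a 90
#' degree sector (for `n_monomers = 4`), with `n_columns` angular columns of
#' residues stacked over `z_levels`. Residue ids run from
#' `first_residue_id` upward within each monomer (322.. by default,
#' matching a TRP-channel-like truncated construct). The protein is static
#' over the whole trajectory, emulating a position-restrained structure.
#'
#' @param n_monomers number of chain copies (default 4; 0 gives a
#'   protein-free system).
#' @param radius cylinder radius (nm) of the protein wall.
#' @param z_levels z positions (nm) of the residue rows, relative offsets
#'   added to `Lz/2` at build time if `relative_z = TRUE`.
#' @param relative_z interpret `z_levels` as offsets from the membrane
#'   midplane.
#' @param n_columns angular residue columns per monomer.
#' @param first_residue_id first residue id of each monomer.
#' @param footprint_radius lateral radius (nm) lipids cannot enter.
#' @param sites list of [binding_site_spec()].
#' @return list of class `protein_spec`. Residue `first_residue_id + r`
#'   sits in column `r %% n_columns`, row `r %/% n_columns`.
#' @export
protein_spec <- function(n_monomers = 4, radius = 2.2,
                         z_levels = c(-1.6, -0.8, 0, 0.8, 1.6),
                         relative_z = TRUE,
                         n_columns = 4, first_residue_id = 322,
                         footprint_radius = 2.6, sites = list()) {
  stopifnot(n_monomers >= 0, radius > 0, n_columns >= 1,
            footprint_radius >= 0)
  if (n_monomers > 0) stopifnot(footprint_radius >= radius)
  if (inherits(sites, "binding_site_spec")) sites <- list(sites)
  stopifnot(all(vapply(sites, inherits, TRUE, "binding_site_spec")))
  structure(list(n_monomers = as.integer(n_monomers), radius = radius,
                 z_levels = as.numeric(z_levels), relative_z = relative_z,
                 n_columns = as.integer(n_columns),
                 first_residue_id = as.integer(first_residue_id),
                 footprint_radius = footprint_radius, sites = sites),
            class = "protein_spec")
}

#' Demonstration protein with one annular and one non-annular site
#'
#' Four monomers of 20 residues (ids 322-341) on a 2.2 nm cylinder. An
#' annular (fast-exchange) cholesterol site is planted at residue 339
#' (upper-leaflet row, recessed arch pocket) and a non-annular
#' (slow-exchange) site at residue 331 (mid-membrane row, subunit-wall
#' position), both replicated on all four monomers.
#'
#' @param fast_anchor,slow_anchor anchor residue ids.
#' @return a [protein_spec()].
#' @export
default_protein_spec <- function(fast_anchor = 339, slow_anchor = 331) {
  protein_spec(sites = list(
    binding_site_spec(fast_anchor, "all", "annular"),
    binding_site_spec(slow_anchor, "all", "non_annular")
  ))
}

#' Expected site behaviour from the planted kinetics
#'
#' Closed-form mean dwell time (`1/k_off`) plus a 1000-replicate stochastic
#' oracle for the expected equilibrium occupancy, binding-event count and
#' distinct-partner count of every planted site. The oracle runs the
#' site's immigration-death chain: candidate lipids arrive in the capture
#' zone at the ideal-gas rate (bulk density of the selective class times
#' accessible capture area times `k_on_prob` per frame, solved
#' self-consistently for depletion by bound lipids) and each bound lipid
#' unbinds independently at `k_off`. Distinct partners per replicate are
#' counted by assigning arrivals uniformly over the accessible molecules
#' of the class.
#'
#' The arrival model is exact in the reaction-limited regime (small
#' `k_on_prob`, as at slow non-annular sites). For near-absorbing sites
#' (`k_on_prob` close to 1) binding is limited by diffusive entry into the
#' capture zone and the chain is an upper bound on event and partner
#' counts, not an estimate.
#'
#' @param system a [build_system()] result.
#' @param n_frames,dt run length to emulate.
#' @param n_rep oracle replicates.
#' @param seed RNG seed for the oracle.
#' @return `data.table` with one row per site: expected mean dwell (ns),
#'   occupancy, event count and distinct partners with 95% bands.
#' @export
ground_truth <- function(system, n_frames = 9000, dt = 0.1, n_rep = 1000,
                         seed = 1) {
  sites <- system$sites
  if (!nrow(sites)) return(data.table())
  set.seed(seed)
  msp <- system$mspec
  free_area <- prod(msp$box[1:2]) - pi * system$footprint_radius^2
  counts <- table(system$lipids$class)
  res <- vector("list", nrow(sites))
  for (s in seq_len(nrow(sites))) {
    st <- sites[s]
    cls <- st$lipid_selectivity
    n_cls <- if (cls %in% names(counts)) as.numeric(counts[[cls]]) else 0
    n_leaflets <- if (st$leaflet_mode == "both") 2 else 1
    n_access <- max(1, round(n_cls * n_leaflets / 2))
    # accessible part of the capture disc (outside the footprint), by grid
    acc <- .capture_area(st$cx, st$cy, st$capture_radius,
                         system$footprint_radius, msp$box)
    # self-consistent arrival rate: bound lipids at all sites deplete the pool
    n_sites_cls <- sum(sites$lipid_selectivity == cls)
    p_off <- 1 - exp(-st$k_off * dt)
    lambda <- 0
    bound_est <- 0
    for (it in 1:50) { # damped fixed point; bound pool clamped to supply
      dens <- (n_cls - bound_est * n_sites_cls) / 2 / free_area # per leaflet
      lambda <- max(dens, 0) * n_leaflets * acc * st$k_on_prob
      bound_est <- 0.5 * bound_est +
        0.5 * min(lambda / p_off, n_cls / max(n_sites_cls, 1))
    }
    # immigration-death chain, vectorised over replicates
    B <- integer(n_rep)
    arrivals <- integer(n_rep)
    occ_acc <- numeric(n_rep)
    half <- n_frames %/% 2
    for (f in seq_len(n_frames)) {
      B <- B - rbinom(n_rep, B, p_off)
      a <- rpois(n_rep, lambda)
      B <- B + a
      arrivals <- arrivals + a
      if (f > half) occ_acc <- occ_acc + B
    }
    partners <- vapply(arrivals, function(a)
      if (a == 0) 0L else uniqueN(sample.int(n_access, a, replace = TRUE)),
      0L)
    res[[s]] <- data.table(
      site = s, anchor_residue_id = st$anchor_residue_id,
      monomer_id = st$monomer_id, site_class = st$site_class,
      mean_dwell_ns = 1 / st$k_off,
      expected_occupancy = mean(occ_acc / (n_frames - half)),
      expected_events = mean(arrivals),
      events_lo = unname(quantile(arrivals, 0.025)),
      events_hi = unname(quantile(arrivals, 0.975)),
      expected_partners = mean(partners),
      partners_lo = unname(quantile(partners, 0.025)),
      partners_hi = unname(quantile(partners, 0.975)))
  }
  rbindlist(res)
}

# fraction-weighted accessible capture area (nm^2): part of the lateral
# capture disc lying outside the protein footprint, computed on a grid
.capture_area <- function(cx, cy, r, footprint, box) {
  g <- 101
  u <- seq(-r, r, length.out = g)
  xs <- rep(cx + u, g)
  ys <- rep(cy + u, each = g)
  inside <- (rep(u, g)^2 + rep(u, each = g)^2) <= r^2
  ax <- box[1] / 2; ay <- box[2] / 2 # protein axis at the box centre
  dx <- xs - ax; dy <- ys - ay
  ok <- inside & (dx^2 + dy^2 >= footprint^2)
  sum(ok) / sum(inside) * pi * r^2
}
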