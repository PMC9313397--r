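#' Extract binding events from a contact series
#'
#' A binding event is a maximal run of consecutive contact frames between
#' one residue (on one monomer) and one lipid molecule. Runs separated by
#' at most `gap_tolerance` non-contact frames are merged (default 0:
#' strict, no interruption smoothing). Event duration is the inclusive
#' frame run times `dt`, bridged gap frames included.
#'
#' @param cs a [contact_series] (a single-frame series is refused: event
#'   durations need a defined `dt`).
#' @param gap_tolerance frames (>= 0).
#' @return `data.table` of class `binding_events`: `residue_id`,
#'   `monomer_id`, `molecule_id`, `molecule_class`, `start_frame`,
#'   `end_frame`, `start_ns`, `end_ns`, `duration_ns`.
#' @export
extract_events <- function(cs, gap_tolerance = 0L) {
  stopifnot(gap_tolerance >= 0)
  dt <- attr(cs, "dt")
  if (is.na(dt))
    stop("kinetic analysis needs >= 2 frames (dt is undefined)")
  times <- attr(cs, "times")
  m <- .cs_molecule(cs)
  if (!nrow(m)) {
    ev <- data.table(residue_id = integer(), monomer_id = integer(),
                     molecule_id = integer(), molecule_class = character(),
                     start_frame = integer(), end_frame = integer(),
                     start_ns = numeric(), end_ns = numeric(),
                     duration_ns = numeric())
  } else {
    mm <- m[order(residue_id, monomer_id, molecule_id, frame)]
    ev <- mm[, {
      run <- cumsum(c(1L, (diff(frame) > gap_tolerance + 1L) * 1L))
      .(start_frame = tapply(frame, run, min),
        end_frame = tapply(frame, run, max),
        molecule_class = molecule_class[1])
    }, by = .(residue_id, monomer_id, molecule_id)]
    ev[, start_frame := as.integer(start_frame)]
    ev[, end_frame := as.integer(end_frame)]
    ev[, start_ns := times[start_frame]]
    ev[, end_ns := times[end_frame]]
    ev[, duration_ns := (end_frame - start_frame + 1L) * dt]
  }
  setattr(ev, "class", c("binding_events", class(data.table())))
  setattr(ev, "dt", dt)
  setattr(ev, "gap_tolerance", as.integer(gap_tolerance))
  ev
}

#' Per-residue kinetic profile for one lipid class
#'
#' Computes, per residue and monomer, then averaged across monomer copies:
#' \describe{
#'   \item{contact duration}{total contact time with the lipid type, i.e.
#'     `dt` times the number of frames in which at least one molecule of
#'     the class touches the residue (frame-union definition; the
#'     per-molecule sum is available as `duration_mode = "molecule_sum"`).}
#'   \item{maximum occupancy}{the longest continuous contact between the
#'     residue and one specific molecule of the class.}
#'   \item{distinct partners}{number of distinct molecules with at least
#'     one binding event at the residue.}
#' }
#' Normalised columns divide the across-monomer mean by its maximum over
#' residues, so the top residue of each metric sits at 1.
#'
#' @param cs a [contact_series].
#' @param lipid_class class of interest.
#' @param events optional precomputed [extract_events()] output for `cs`;
#'   computed on the fly when `NULL`.
#' @param gap_tolerance passed to [extract_events()].
#' @param duration_mode `"union"` (default) or `"molecule_sum"`.
#' @return `data.table` of class `kinetic_profile`, one row per residue id:
#'   `contact_duration_ns`, `max_occupancy_ns`, `n_distinct_partners`,
#'   their across-monomer SEMs, and `contact_duration_norm`,
#'   `max_occupancy_norm`. Attribute `per_monomer` holds the unpooled
#'   table; `traj_time_ns` the total trajectory time.
#' @export
kinetic_profile <- function(cs, lipid_class, events = NULL,
                            gap_tolerance = 0L,
                            duration_mode = c("union", "molecule_sum")) {
  duration_mode <- match.arg(duration_mode)
  dt <- attr(cs, "dt")
  if (is.na(dt))
    stop("kinetic analysis needs >= 2 frames (dt is undefined)")
  total_ns <- attr(cs, "n_frames") * dt
  m <- .cs_molecule(cs)[molecule_class == lipid_class]
  if (is.null(events)) events <- extract_events(cs, gap_tolerance)
  ev <- events[molecule_class == lipid_class]
  universe <- attr(cs, "residues")
  if (!nrow(m))
    warning("no contacts with class '", lipid_class, "': all-zero profile")
  cd <- if (duration_mode == "union") {
    m[, .(contact_duration_ns = uniqueN(frame) * dt),
      by = .(residue_id, monomer_id)]
  } else {
    m[, .(contact_duration_ns = .N * dt), by = .(residue_id, monomer_id)]
  }
  mo <- if (nrow(ev)) {
    ev[, .(max_occupancy_ns = max(duration_ns),
           n_distinct_partners = uniqueN(molecule_id)),
       by = .(residue_id, monomer_id)]
  } else {
    data.table(residue_id = integer(), monomer_id = integer(),
               max_occupancy_ns = numeric(),
               n_distinct_partners = integer())
  }
  pm <- merge(universe, cd, by = c("residue_id", "monomer_id"), all.x = TRUE)
  pm <- merge(pm, mo, by = c("residue_id", "monomer_id"), all.x = TRUE)
  for (col in c("contact_duration_ns", "max_occupancy_ns",
                "n_distinct_partners"))
    set(pm, which(is.na(pm[[col]])), col, 0)
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  prof <- pm[, .(contact_duration_ns = mean(contact_duration_ns),
                 contact_duration_sem = sem(contact_duration_ns),
                 max_occupancy_ns = mean(max_occupancy_ns),
                 max_occupancy_sem = sem(max_occupancy_ns),
                 n_distinct_partners = mean(n_distinct_partners),
                 n_distinct_partners_sem = sem(n_distinct_partners)),
             by = residue_id]
  setorder(prof, residue_id)
  mx_cd <- max(prof$contact_duration_ns)
  mx_mo <- max(prof$max_occupancy_ns)
  prof[, contact_duration_norm :=
         if (mx_cd > 0) contact_duration_ns / mx_cd else 0]
  prof[, max_occupancy_norm :=
         if (mx_mo > 0) max_occupancy_ns / mx_mo else 0]
  setattr(prof, "class", c("kinetic_profile", class(data.table())))
  setattr(prof, "lipid_class", lipid_class)
  setattr(prof, "traj_time_ns", total_ns)
  setattr(prof, "duration_mode", duration_mode)
  setattr(prof, "per_monomer", pm)
  prof
}

#' Rank residues by a kinetic metric
#'
#' Top-k residues by the across-monomer mean of the metric; ties broken by
#' ascending residue id. Asking for more residues than exist returns the
#' full ranking.
#'
#' @param profile a [kinetic_profile].
#' @param metric `"contact_duration"`, `"max_occupancy"` or
#'   `"n_distinct_partners"`.
#' @param k how many residues (default 10).
#' @return integer vector of residue ids, best first.
#' @export
rank_residues <- function(profile,
                          metric = c("contact_duration", "max_occupancy",
                                     "n_distinct_partners"),
                          k = 10) {
  metric <- match.arg(metric)
  stopifnot(k >= 1)
  col <- if (metric == "n_distinct_partners") metric else
    paste0(metric, "_ns")
  ord <- order(-profile[[col]], profile$residue_id)
  profile$residue_id[head(ord, k)]
}

#' Lateral map of lipid displacement rates near the protein
#'
#' For every consecutive frame pair, molecules of the class (optionally
#' restricted to those within `cutoff` of any protein bead at the earlier
#' frame) contribute their minimum-image displacement length divided by
#' `dt` to the bin of their lateral position at the earlier frame. Slow
#' bins flag sites where lipids are pinned; fast bins reflect free
#' diffusion (mean step length `sqrt(pi D dt)/dt` for a 2D Gaussian walk).
#'
#' @param traj a [cg_trajectory].
#' @param topology a [bead_topology].
#' @param lipid_class class to track (reference bead: first bead of each
#'   molecule, e.g. ROH for cholesterol).
#' @param cutoff contact cut-off (nm) for the near-protein filter, or
#'   `NULL` to track all molecules of the class.
#' @param bins number of lateral bins per axis.
#' @param lateral_only use the xy displacement only (default `FALSE`: 3D
#'   step length).
#' @return list of class `displacement_grid`: `x_edges`, `y_edges`,
#'   `mean_rate` (nm/ns; `NA` where unsampled), `n_samples`.
#' @export
displacement_map <- function(traj, topology, lipid_class, cutoff = 0.6,
                             bins = 30, lateral_only = FALSE) {
  nf <- n_frames(traj)
  if (nf < 2) stop(">= 2 frames required")
  box <- traj$box[1, ]
  mols <- topology[molecule_class == lipid_class,
                   .(ref = min(bead_id)), by = molecule_id]
  if (!nrow(mols)) stop("no molecules of class ", lipid_class)
  idx <- if (!is.null(cutoff)) .contact_groups(topology, lipid_class)
  xe <- seq(0, box[1], length.out = bins + 1)
  ye <- seq(0, box[2], length.out = bins + 1)
  ssum <- matrix(0, bins, bins)
  scnt <- matrix(0L, bins, bins)
  for (f in seq_len(nf - 1)) {
    p0 <- traj$coords[mols$ref, , f, drop = FALSE][, , 1, drop = TRUE]
    p1 <- traj$coords[mols$ref, , f + 1, drop = FALSE][, , 1, drop = TRUE]
    if (nrow(mols) == 1) { p0 <- matrix(p0, 1); p1 <- matrix(p1, 1) }
    keep <- seq_len(nrow(mols))
    if (!is.null(cutoff)) {
      cf <- .frame_contacts(traj$coords[, , f, drop = TRUE], traj$box[f, ],
                            idx, cutoff, bead_level = FALSE)
      keep <- which(mols$molecule_id %in% unique(cf$molecule_id))
    }
    if (!length(keep)) next
    d <- min_image_displacement(p1[keep, , drop = FALSE],
                                p0[keep, , drop = FALSE], box)
    if (lateral_only) d[, 3] <- 0
    rate <- sqrt(rowSums(d^2)) / traj$dt
    ix <- pmin(pmax(1L, findInterval(wrap_coords(p0[keep, 1], box[1]), xe,
                                     rightmost.closed = TRUE)), bins)
    iy <- pmin(pmax(1L, findInterval(wrap_coords(p0[keep, 2], box[2]), ye,
                                     rightmost.closed = TRUE)), bins)
    flat <- ix + (iy - 1L) * bins
    scnt <- scnt + matrix(tabulate(flat, bins * bins), bins, bins)
    gs <- rowsum(rate, flat)
    ssum[as.integer(rownames(gs))] <- ssum[as.integer(rownames(gs))] + gs[, 1]
  }
  mean_rate <- ifelse(scnt > 0, ssum / pmax(scnt, 1L), NA_real_)
  structure(list(x_edges = xe, y_edges = ye, mean_rate = mean_rate,
                 n_samples = scnt, lipid_class = lipid_class,
                 lateral_only = lateral_only),
            class = "displacement_grid")
}

#' Residues co-contacted by lipids bound to an anchor residue
#'
#' Over the frames in which the anchor residue touches at least one
#' molecule of the class, counts the contacts between those same molecules
#' and every other residue — the interaction neighbourhood of a binding
#' site, conditioned on occupancy of its anchor.
#'
#' @param cs a [contact_series].
#' @param anchor_residue_id anchor residue id.
#' @param lipid_class class of interest.
#' @param anchor_monomer restrict the anchor to one monomer copy (default:
#'   any copy; contacts are conditioned per monomer and pooled).
#' @return `data.table`: `residue_id`, `n_contacts` (frame-molecule
#'   pairs), `fraction` (normalised by the anchor's own contact count).
#' @export
co_contact_profile <- function(cs, anchor_residue_id, lipid_class,
                               anchor_monomer = NULL) {
  m <- .cs_molecule(cs)
  if (!anchor_residue_id %in% attr(cs, "residues")$residue_id)
    stop("anchor residue ", anchor_residue_id, " not in the topology")
  anc <- m[residue_id == anchor_residue_id & molecule_class == lipid_class]
  if (!is.null(anchor_monomer)) anc <- anc[monomer_id == anchor_monomer]
  if (!nrow(anc)) {
    warning("anchor residue ", anchor_residue_id,
            " is never in contact with ", lipid_class)
    return(data.table(residue_id = integer(), n_contacts = integer(),
                      fraction = numeric()))
  }
  key <- unique(anc[, .(frame, molecule_id)])
  hits <- m[molecule_class == lipid_class][key, on = .(frame, molecule_id),
                                           nomatch = NULL]
  hits <- hits[residue_id != anchor_residue_id]
  out <- hits[, .(n_contacts = .N), by = residue_id]
  out[, fraction := n_contacts / nrow(anc)]
  setorder(out, -n_contacts, residue_id)
  out[]
}

#' Per-bead contact ratio between a residue and a lipid class
#'
#' The fraction of bead-level contacts between the residue and molecules
#' of the class attributable to each lipid bead (e.g. the cholesterol
#' hydroxyl ROH versus sterol-body beads), resolving how the lipid is
#' oriented in the site. Requires a bead-detail contact series and a
#' multi-bead lipid representation.
#'
#' @param cs a [contact_series] built with `detail = "bead"`.
#' @param residue_id residue of interest.
#' @param lipid_class class of interest.
#' @param monomer restrict to one monomer copy (default: pooled).
#' @return `data.table`: `lipid_bead`, `n`, `fraction` (sums to 1).
#' @export
bead_contact_ratio <- function(cs, residue_id, lipid_class,
                               monomer = NULL) {
  if (attr(cs, "detail") != "bead")
    stop("a bead-detail contact series is required: rebuild with ",
         "contact_series(..., detail = \"bead\")")
  rid <- residue_id
  sub <- cs[residue_id == rid & molecule_class == lipid_class]
  if (!is.null(monomer)) sub <- sub[monomer_id == monomer]
  if (!nrow(sub))
    stop("residue ", rid, " has no bead-level contacts with ", lipid_class)
  if (uniqueN(sub$lipid_bead) == 1 && uniqueN(cs[molecule_class ==
      lipid_class]$lipid_bead) <= 1)
    stop("class ", lipid_class, " has a single-bead representation; ",
         "enable 8-bead cholesterol (membrane_spec(chol_beads = 8)) for ",
         "bead-resolved contact ratios")
  out <- sub[, .(n = .N), by = .(lipid_bead)]
  out[, fraction := n / sum(n)]
  setorder(out, -n, lipid_bead)
  out[]
}
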