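.lipid_resname <- c(PC = "POPC", Chol = "CHOL", PE = "POPE", PS = "POPS",
                    SM = "DPSM", PIP2 = "POP2")
.lipid_headbead <- c(PC = "PO4", Chol = "ROH", PE = "PO4", PS = "PO4",
                     SM = "PO4", PIP2 = "P1")
.chol8_beads <- c("ROH", "R1", "R2", "R3", "R4", "R5", "C1", "C2")

# largest-remainder apportionment of `total` among fractions
largest_remainder <- function(fractions, total) {
  raw <- fractions * total
  counts <- floor(raw)
  rem <- as.integer(round(total - sum(counts)))
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Build a synthetic membrane-protein system
#'
#' Places the static protein cylinder in the box centre and the lipids
#' uniformly at random in each leaflet outside the protein footprint, with
#' exact per-class counts obtained by largest-remainder rounding of the
#' leaflet fractions. Binding sites are resolved to explicit centres just
#' outside the protein wall at their anchor's angular position: annular
#' sites at the anchor's leaflet headgroup plane, non-annular sites at the
#' anchor's (typically mid-membrane) z, reachable from both leaflets.
#'
#' @param mspec a [membrane_spec()].
#' @param pspec a [protein_spec()].
#' @param seed RNG seed; the build is deterministic given the seed.
#' @return list of class `cg_system`: `topology`, `frame` (initial
#'   coordinates), resolved `sites` table, internal lipid state, and the
#'   input specs.
#' @export
build_system <- function(mspec, pspec = protein_spec(), seed = 1) {
  stopifnot(inherits(mspec, "membrane_spec"), inherits(pspec, "protein_spec"))
  set.seed(seed)
  box <- mspec$box
  zmid <- box[3] / 2
  z_levels <- if (pspec$relative_z) zmid + pspec$z_levels else pspec$z_levels
  leaflet_z <- c(lower = zmid - mspec$leaflet_offset,
                 upper = zmid + mspec$leaflet_offset)
  ax <- box[1] / 2; ay <- box[2] / 2
  if (pspec$n_monomers > 0 &&
      pspec$footprint_radius >= min(box[1:2]) / 2 - 0.5)
    stop("packing error: protein footprint leaves no room for lipids")

  # ---- resolve sites (expand monomer_id = "all") ----
  site_rows <- list()
  for (ss in pspec$sites) {
    mons <- if (identical(ss$monomer_id, "all"))
      seq_len(pspec$n_monomers) - 1L else as.integer(ss$monomer_id)
    for (m in mons)
      site_rows[[length(site_rows) + 1L]] <- data.table(
        anchor_residue_id = ss$anchor_residue_id, monomer_id = m,
        site_class = ss$site_class, k_on_prob = ss$k_on_prob,
        k_off = ss$k_off, capture_radius = ss$capture_radius,
        lipid_selectivity = ss$lipid_selectivity,
        anchor_inset = ss$anchor_inset, jitter_sd = ss$jitter_sd,
        cx = if (is.null(ss$center)) NA_real_ else ss$center[1],
        cy = if (is.null(ss$center)) NA_real_ else ss$center[2],
        cz = if (is.null(ss$center)) NA_real_ else ss$center[3])
  }
  sites <- if (length(site_rows)) rbindlist(site_rows) else
    data.table(anchor_residue_id = integer(), monomer_id = integer(),
               site_class = character(), k_on_prob = numeric(),
               k_off = numeric(), capture_radius = numeric(),
               lipid_selectivity = character(), anchor_inset = numeric(),
               jitter_sd = numeric(), cx = numeric(), cy = numeric(),
               cz = numeric())

  # ---- protein beads ----
  n_res <- pspec$n_columns * length(z_levels)
  prot <- NULL
  if (pspec$n_monomers > 0 && n_res > 0) {
    sector <- 360 / pspec$n_monomers
    rows <- list()
    for (m in seq_len(pspec$n_monomers) - 1L) {
      r <- seq_len(n_res) - 1L
      col <- r %% pspec$n_columns
      lev <- r %/% pspec$n_columns
      ang <- (m * sector + (col + 0.5) * sector / pspec$n_columns) * pi / 180
      resid <- pspec$first_residue_id + r
      radius <- rep(pspec$radius, n_res)
      resname <- rep("ALA", n_res)
      for (s in which(sites$monomer_id == m)) {
        hit <- which(resid == sites$anchor_residue_id[s])
        if (!length(hit))
          stop("site anchor residue ", sites$anchor_residue_id[s],
               " not in protein (monomer ", m, ")")
        radius[hit] <- pspec$radius - sites$anchor_inset[s]
        resname[hit] <- if (sites$site_class[s] == "annular") "VAL" else "THR"
        # resolve site centre just outside the protein wall
        if (is.na(sites$cx[s])) {
          set(sites, s, "cx", ax + (pspec$radius + 0.25) * cos(ang[hit]))
          set(sites, s, "cy", ay + (pspec$radius + 0.25) * sin(ang[hit]))
          zz <- z_levels[lev[hit] + 1]
          set(sites, s, "cz", if (sites$site_class[s] == "annular") {
            if (zz >= zmid) leaflet_z[["upper"]] else leaflet_z[["lower"]]
          } else zz)
        }
      }
      rows[[m + 1L]] <- data.table(
        bead_name = "BB", residue_id = resid, residue_name = resname,
        monomer_id = m, x = ax + radius * cos(ang),
        y = ay + radius * sin(ang), z = z_levels[lev + 1])
    }
    prot <- rbindlist(rows)
  }
  sites[, leaflet_mode := ifelse(site_class == "non_annular", "both",
                                 ifelse(cz >= zmid, "upper", "lower"))]

  # ---- lipids ----
  lip_rows <- list()
  lip_state <- list()
  next_resid <- if (is.null(prot)) 0L else max(prot$residue_id)
  nchb <- mspec$chol_beads
  for (lf in c("upper", "lower")) {
    fr <- mspec$leaflets[[if (lf == "upper") "outer" else "inner"]]
    counts <- largest_remainder(fr, mspec$n_per_leaflet)
    zplane <- leaflet_z[[lf]]
    lsign <- if (lf == "upper") 1L else -1L
    for (ci in seq_along(fr)) {
      cls <- names(fr)[ci]
      nn <- counts[ci]
      if (nn == 0) next
      # uniform placement outside the footprint
      xs <- numeric(nn); ys <- numeric(nn)
      todo <- seq_len(nn)
      tries <- 0L
      while (length(todo)) {
        xs[todo] <- runif(length(todo), 0, box[1])
        ys[todo] <- runif(length(todo), 0, box[2])
        dx <- xs[todo] - ax; dy <- ys[todo] - ay
        todo <- todo[dx^2 + dy^2 < pspec$footprint_radius^2]
        tries <- tries + 1L
        if (tries > 1000L)
          stop("packing error: could not place lipids outside the footprint")
      }
      nb <- if (cls == "Chol") nchb else 1L
      bnames <- if (nb == 8L) .chol8_beads else .lipid_headbead[[cls]]
      for (i in seq_len(nn)) {
        next_resid <- next_resid + 1L
        dz <- -lsign * mspec$chol_bead_spacing * (seq_len(nb) - 1)
        lip_rows[[length(lip_rows) + 1L]] <- data.table(
          bead_name = bnames, residue_id = next_resid,
          residue_name = .lipid_resname[[cls]], monomer_id = NA_integer_,
          x = xs[i], y = ys[i], z = zplane + dz)
        lip_state[[length(lip_state) + 1L]] <- data.table(
          class = cls, leaflet = lsign, x = xs[i], y = ys[i], n_beads = nb)
      }
    }
  }
  lip <- if (length(lip_rows)) rbindlist(lip_rows) else NULL
  lipids <- if (length(lip_state)) rbindlist(lip_state) else
    data.table(class = character(), leaflet = integer(), x = numeric(),
               y = numeric(), n_beads = integer())

  allb <- rbindlist(list(prot, lip), use.names = TRUE)
  if (is.null(allb) || !nrow(allb))
    stop("empty system: no protein and no lipids")
  # molecule ids: one per protein monomer, one per lipid residue
  is_prot <- !is.na(allb$monomer_id)
  mol <- integer(nrow(allb))
  mol[is_prot] <- allb$monomer_id[is_prot] + 1L
  nmon <- if (is.null(prot)) 0L else pspec$n_monomers
  if (any(!is_prot))
    mol[!is_prot] <- nmon + as.integer(factor(allb$residue_id[!is_prot],
                                              levels = unique(allb$residue_id[!is_prot])))
  cls_full <- ifelse(is_prot, "protein",
                     names(.lipid_resname)[match(allb$residue_name,
                                                 .lipid_resname)])
  top <- bead_topology(allb$bead_name, allb$residue_id, allb$residue_name,
                       allb$monomer_id, mol, cls_full)
  if (nrow(lipids)) {
    lipids[, molecule_id := nmon + .I]
    lipids[, ref_row := top[molecule_class != "protein",
                            .(r = min(bead_id)), by = molecule_id]$r]
  } else {
    lipids[, `:=`(molecule_id = integer(), ref_row = integer())]
  }
  fr0 <- frame(0, as.matrix(allb[, .(x, y, z)]), box)
  structure(list(topology = top, frame = fr0, sites = sites,
                 lipids = lipids, mspec = mspec, pspec = pspec,
                 protein_idx = which(is_prot),
                 footprint_radius = pspec$footprint_radius,
                 zmid = zmid, leaflet_z = leaflet_z),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("cg_system: %d beads (%d protein), %d lipids, %d sites\n",
              nrow(x$topology), length(x$protein_idx), nrow(x$lipids),
              nrow(x$sites)))
  invisible(x)
}

#' Simulate the synthetic membrane
#'
#' Free lipids perform a 2D Gaussian random walk (per-axis step standard
#' deviation `sqrt(2 D dt)`) with periodic wrapping and hard rejection of
#' moves into the protein footprint. Free cholesterol flips leaflet as a
#' Poisson process. A free lipid of a site's selective class inside its
#' capture radius binds with `k_on_prob` per frame; a bound lipid is pinned
#' at the site centre (recorded with Gaussian jitter) and unbinds with
#' probability `1 - exp(-k_off dt)` per frame, upon which it is released
#' just outside the capture zone. Fully reproducible given the seed.
#'
#' @param system a [build_system()] result.
#' @param n_frames number of frames including the initial one (>= 2).
#' @param dt frame spacing in ns (> 0).
#' @param seed RNG seed.
#' @return a [cg_trajectory] with attributes `events` (the ground-truth
#'   binding-event log: site, anchor, monomer, molecule, start/end frame,
#'   duration, censored flag) and `system`.
#' @export
simulate_membrane <- function(system, n_frames = 9000, dt = 0.1, seed = 1) {
  stopifnot(inherits(system, "cg_system"), n_frames >= 2, dt > 0)
  set.seed(seed)
  top <- system$topology
  box <- system$mspec$box
  nb <- nrow(top)
  nl <- nrow(system$lipids)
  coords <- array(NA_real_, c(nb, 3, n_frames))
  # static protein
  if (length(system$protein_idx)) {
    p0 <- system$frame$positions[system$protein_idx, , drop = FALSE]
    for (k in 1:3) coords[system$protein_idx, k, ] <- p0[, k]
  }
  sites <- system$sites
  ns <- nrow(sites)
  ev_site <- integer(0); ev_mol <- integer(0)
  ev_start <- integer(0); ev_end <- integer(0)

  if (nl > 0) {
    st <- system$lipids
    x <- st$x; y <- st$y
    lsign <- st$leaflet
    cls <- st$class
    nbead <- st$n_beads
    sdstep <- sqrt(2 * system$mspec$diffusion[cls] * dt)
    p_flip <- 1 - exp(-system$mspec$chol_flip_rate * dt)
    bound <- integer(nl)
    bstart <- integer(nl)
    zplane <- function(s) ifelse(s > 0, system$leaflet_z[["upper"]],
                                 system$leaflet_z[["lower"]])
    z <- zplane(lsign)
    ax <- box[1] / 2; ay <- box[2] / 2
    fp2 <- system$footprint_radius^2
    p_off <- if (ns) 1 - exp(-sites$k_off * dt) else numeric(0)
    esc_r <- if (ns) sites$capture_radius + 0.3 else numeric(0)
    spacing <- system$mspec$chol_bead_spacing

    record <- function(f) {
      rx <- x; ry <- y; rz <- z
      if (ns && any(bound > 0)) {
        bi <- which(bound > 0)
        s <- bound[bi]
        jit <- sites$jitter_sd[s]
        rx[bi] <- sites$cx[s] + rnorm(length(bi), 0, jit)
        ry[bi] <- sites$cy[s] + rnorm(length(bi), 0, jit)
        rz[bi] <- sites$cz[s] + rnorm(length(bi), 0, jit)
      }
      rx <- wrap_coords(rx, box[1]); ry <- wrap_coords(ry, box[2])
      rows <- st$ref_row
      coords[rows, 1, f] <<- rx
      coords[rows, 2, f] <<- ry
      coords[rows, 3, f] <<- rz
      mb <- which(nbead > 1L)
      for (i in mb) {
        kk <- seq_len(nbead[i] - 1L)
        coords[rows[i] + kk, 1, f] <<- rx[i]
        coords[rows[i] + kk, 2, f] <<- ry[i]
        coords[rows[i] + kk, 3, f] <<- rz[i] - lsign[i] * spacing * kk
      }
    }

    record(1L)
    for (f in 2:n_frames) {
      # unbinding + escape just outside the capture zone
      if (ns && any(bound > 0)) {
        bi <- which(bound > 0)
        off <- bi[runif(length(bi)) < p_off[bound[bi]]]
        for (i in off) {
          s <- bound[i]
          for (try in 1:200) {
            a <- runif(1, 0, 2 * pi)
            ex <- sites$cx[s] + esc_r[s] * cos(a)
            ey <- sites$cy[s] + esc_r[s] * sin(a)
            if ((ex - ax)^2 + (ey - ay)^2 >= fp2) break
          }
          x[i] <- wrap_coords(ex, box[1]); y[i] <- wrap_coords(ey, box[2])
          if (sites$leaflet_mode[s] == "both") {
            lsign[i] <- sample(c(-1L, 1L), 1)
          } else {
            lsign[i] <- if (sites$leaflet_mode[s] == "upper") 1L else -1L
          }
          z[i] <- zplane(lsign[i])
          ev_site <- c(ev_site, s); ev_mol <- c(ev_mol, i)
          ev_start <- c(ev_start, bstart[i]); ev_end <- c(ev_end, f - 1L)
          bound[i] <- 0L
        }
      }
      # 2D diffusion of free lipids with footprint rejection
      free <- which(bound == 0L)
      if (length(free)) {
        nx <- wrap_coords(x[free] + rnorm(length(free), 0, sdstep[free]),
                          box[1])
        ny <- wrap_coords(y[free] + rnorm(length(free), 0, sdstep[free]),
                          box[2])
        ok <- (nx - ax)^2 + (ny - ay)^2 >= fp2
        x[free[ok]] <- nx[ok]
        y[free[ok]] <- ny[ok]
        # cholesterol flip-flop
        if (p_flip > 0) {
          ch <- free[cls[free] == "Chol"]
          fl <- ch[runif(length(ch)) < p_flip]
          if (length(fl)) {
            lsign[fl] <- -lsign[fl]
            z[fl] <- zplane(lsign[fl])
          }
        }
      }
      # site capture
      for (s in seq_len(ns)) {
        cand <- which(bound == 0L & cls == sites$lipid_selectivity[s])
        if (!length(cand)) next
        if (sites$leaflet_mode[s] == "upper") cand <- cand[lsign[cand] > 0]
        else if (sites$leaflet_mode[s] == "lower")
          cand <- cand[lsign[cand] < 0]
        if (!length(cand)) next
        dx <- x[cand] - sites$cx[s]
        dx <- dx - box[1] * round(dx / box[1])
        dy <- y[cand] - sites$cy[s]
        dy <- dy - box[2] * round(dy / box[2])
        inside <- cand[dx^2 + dy^2 < sites$capture_radius[s]^2]
        if (!length(inside)) next
        newb <- inside[runif(length(inside)) < sites$k_on_prob[s]]
        if (length(newb)) {
          bound[newb] <- s
          bstart[newb] <- f
          x[newb] <- sites$cx[s]; y[newb] <- sites$cy[s]
          z[newb] <- sites$cz[s]
        }
      }
      record(f)
    }
    # close censored events
    open <- which(bound > 0)
    ev_site <- c(ev_site, bound[open]); ev_mol <- c(ev_mol, open)
    ev_start <- c(ev_start, bstart[open])
    ev_end <- c(ev_end, rep(n_frames, length(open)))
    censored <- c(rep(FALSE, length(ev_site) - length(open)),
                  rep(TRUE, length(open)))
    mol_ids <- st$molecule_id
  } else {
    censored <- logical(0)
    mol_ids <- integer(0)
  }

  traj <- cg_trajectory(coords, (seq_len(n_frames) - 1) * dt, box)
  events <- data.table(
    site = ev_site,
    anchor_residue_id = if (length(ev_site)) sites$anchor_residue_id[ev_site]
      else integer(0),
    monomer_id = if (length(ev_site)) sites$monomer_id[ev_site] else integer(0),
    site_class = if (length(ev_site)) sites$site_class[ev_site]
      else character(0),
    molecule_id = if (length(ev_mol)) mol_ids[ev_mol] else integer(0),
    start_frame = ev_start, end_frame = ev_end,
    duration_ns = (ev_end - ev_start + 1L) * dt,
    censored = censored)
  setattr(traj, "events", events)
  setattr(traj, "system", system)
  traj
}
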