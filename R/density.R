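#' Time-averaged lateral density map
#'
#' Per-frame 2D histogram of the selected beads (wrapped into the primary
#' cell), averaged over frames and optionally smoothed with a
#' periodic-boundary Gaussian kernel. Smoothing conserves total mass. With
#' a list of trajectories (repeats), per-repeat maps are averaged.
#'
#' @param traj a [cg_trajectory] or a list of them.
#' @param topology a [bead_topology].
#' @param selection bead indices or selection string(s) for
#'   [select_beads()].
#' @param bin_width lateral bin width in nm (default 0.1, so the default
#'   smoothing sigma of 3 is meaningful in bin units). Used when `bins` is
#'   `NULL`.
#' @param bins number of bins per axis (overrides `bin_width`).
#' @param sigma Gaussian smoothing sigma in bins (0 disables smoothing).
#' @return list of class `density_grid`: `x_edges`, `y_edges`, `density`
#'   (counts per frame per nm^2), `counts` (raw total counts per bin),
#'   `n_frames`, `bin_area`, `sigma`, `box`, `label`.
#' @export
density_map <- function(traj, topology, selection, bin_width = 0.1,
                        bins = NULL, sigma = 3) {
  if (is.list(traj) && !inherits(traj, "cg_trajectory")) {
    maps <- lapply(traj, density_map, topology = topology,
                   selection = selection, bin_width = bin_width,
                   bins = bins, sigma = sigma)
    out <- maps[[1]]
    out$density <- Reduce(`+`, lapply(maps, `[[`, "density")) / length(maps)
    out$counts <- Reduce(`+`, lapply(maps, `[[`, "counts"))
    out$n_frames <- sum(vapply(maps, `[[`, 1, "n_frames"))
    return(out)
  }
  sel <- if (is.character(selection)) {
    do.call(select_beads, c(list(topology), as.list(selection)))
  } else as.integer(selection)
  if (!length(sel)) stop("empty selection")
  box <- traj$box[1, ]
  nx <- if (!is.null(bins)) bins else max(2L, round(box[1] / bin_width))
  ny <- if (!is.null(bins)) bins else max(2L, round(box[2] / bin_width))
  stopifnot(nx >= 2, ny >= 2)
  nf <- n_frames(traj)
  counts <- matrix(0, nx, ny)
  for (f in seq_len(nf)) {
    x <- wrap_coords(traj$coords[sel, 1, f], box[1])
    y <- wrap_coords(traj$coords[sel, 2, f], box[2])
    ix <- pmin(floor(x / box[1] * nx) + 1L, nx)
    iy <- pmin(floor(y / box[2] * ny) + 1L, ny)
    counts <- counts + matrix(tabulate(ix + (iy - 1L) * nx, nx * ny), nx, ny)
  }
  bin_area <- (box[1] / nx) * (box[2] / ny)
  dens <- counts / nf / bin_area
  if (sigma > 0) dens <- smooth_periodic(dens, sigma)
  structure(list(x_edges = seq(0, box[1], length.out = nx + 1),
                 y_edges = seq(0, box[2], length.out = ny + 1),
                 density = dens, counts = counts, n_frames = nf,
                 bin_area = bin_area, sigma = sigma, box = box,
                 label = attr(selection, "label") %||%
                   paste(selection, collapse = ",")),
            class = "density_grid")
}

#' Periodic-boundary Gaussian smoothing of a matrix
#'
#' Circular convolution with a unit-mass Gaussian kernel via FFT: values
#' wrap across the edges, matching the periodic simulation cell, and the
#' matrix total is conserved to machine precision.
#'
#' @param mat numeric matrix.
#' @param sigma kernel sigma in grid units.
#' @return smoothed matrix of the same dimensions.
#' @export
smooth_periodic <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  nx <- nrow(mat); ny <- ncol(mat)
  gx <- stats::dnorm(pmin(0:(nx - 1), nx - 0:(nx - 1)), sd = sigma)
  gy <- stats::dnorm(pmin(0:(ny - 1), ny - 0:(ny - 1)), sd = sigma)
  ker <- outer(gx, gy)
  ker <- ker / sum(ker)
  out <- Re(stats::fft(stats::fft(mat) * stats::fft(ker), inverse = TRUE)) /
    (nx * ny)
  out
}

#' Distribution of selected beads along the membrane normal
#'
#' Normalised histogram of z coordinates of a bead selection over all
#' frames — e.g. the cholesterol ROH bead, whose bulk distribution is
#' bimodal at the two leaflet planes while protein-bound cholesterol can
#' populate the bilayer centre. With `bound_filter` set, only beads of
#' molecules having any bead within that cut-off of the protein
#' contribute. The two leaflet modes and the inter-leaflet minimum are
#' reported for bimodality assessment.
#'
#' @param traj a [cg_trajectory].
#' @param topology a [bead_topology].
#' @param selection bead indices or selection string(s) (e.g.
#'   `"bead:ROH"`).
#' @param bins z bins.
#' @param bound_filter contact cut-off in nm, or `NULL` (no filter).
#' @param cs optional molecule-level [contact_series] at `bound_filter`
#'   cut-off, to avoid recomputing contacts.
#' @return `data.table` of class `z_profile` (`z`, `freq`; frequencies sum
#'   to 1) with attributes `mode_lower`, `mode_upper`, `between_min`
#'   (z positions, nm) and `between_min_freq`.
#' @export
z_distribution <- function(traj, topology, selection, bins = 50,
                           bound_filter = NULL, cs = NULL) {
  sel <- if (is.character(selection)) {
    do.call(select_beads, c(list(topology), as.list(selection)))
  } else as.integer(selection)
  if (!length(sel)) stop("empty selection")
  box <- traj$box[1, ]
  nf <- n_frames(traj)
  if (!is.null(bound_filter) && is.null(cs)) {
    classes <- unique(topology$molecule_class[sel])
    classes <- intersect(classes, .lipid_classes)
    cs <- contact_series(traj, topology, cutoff = bound_filter,
                         lipid_classes = classes)
  }
  zs <- vector("list", nf)
  selmol <- topology$molecule_id[sel]
  for (f in seq_len(nf)) {
    keep <- sel
    if (!is.null(bound_filter)) {
      mols <- unique(cs[frame == f]$molecule_id)
      keep <- sel[selmol %in% mols]
      if (!length(keep)) next
    }
    zs[[f]] <- wrap_coords(traj$coords[keep, 3, f], box[3])
  }
  z <- unlist(zs)
  if (!length(z)) stop("no beads pass the bound filter")
  edges <- seq(0, box[3], length.out = bins + 1)
  h <- tabulate(pmin(floor(z / box[3] * bins) + 1L, bins), bins)
  freq <- h / sum(h)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  out <- data.table(z = mids, freq = freq)
  zmid <- box[3] / 2
  lo <- which(mids < zmid); hi <- which(mids >= zmid)
  ml <- lo[which.max(freq[lo])]; mu <- hi[which.max(freq[hi])]
  between <- seq(ml, mu)
  bm <- between[which.min(freq[between])]
  setattr(out, "class", c("z_profile", class(data.table())))
  setattr(out, "mode_lower", mids[ml])
  setattr(out, "mode_upper", mids[mu])
  setattr(out, "between_min", mids[bm])
  setattr(out, "between_min_freq", freq[bm])
  out
}

#' Spatial free energy by Boltzmann inversion of a density map
#'
#' `dG(bin) = -kB T ln(rho(bin) / rho_ref)` for sufficiently sampled bins,
#' shifted so that the minimum over sampled bins is exactly 0 (relative
#' scale). Bins with fewer than `min_count` raw counts, or zero density,
#' are masked (`NA`), never zero-filled.
#'
#' @param density a [density_map()] result.
#' @param T temperature in K (default 310).
#' @param ref reference density: `"bulk_annulus"` (mean density at lateral
#'   radius >= `annulus_from` nm from the box centre), `"global_mean"`, or
#'   `"explicit"` with `rho_ref`.
#' @param rho_ref explicit reference density (same units as the map).
#' @param annulus_from inner radius (nm) of the bulk annulus; typically
#'   the protein's maximal lateral radius plus 1.5 nm.
#' @param min_count minimum raw counts per bin before inversion.
#' @return list of class `free_energy_map`: grid edges, `dG` (kJ/mol,
#'   `NA` on masked bins), `mask`, `T`, `kB`, `rho_ref`.
#' @export
free_energy_from_density <- function(density, T = 310,
                                     ref = c("bulk_annulus", "global_mean",
                                             "explicit"),
                                     rho_ref = NULL, annulus_from = NULL,
                                     min_count = 10) {
  ref <- match.arg(ref)
  stopifnot(T > 0)
  d <- density$density
  sampled <- density$counts >= min_count & d > 0
  if (!any(sampled)) stop("all bins undersampled: nothing to invert")
  if (ref == "explicit") {
    if (is.null(rho_ref) || rho_ref <= 0)
      stop("explicit reference requires rho_ref > 0")
    rr <- rho_ref
  } else if (ref == "global_mean") {
    rr <- mean(d[sampled])
  } else {
    if (is.null(annulus_from))
      stop("bulk_annulus reference requires annulus_from (nm)")
    xm <- (density$x_edges[-1] + head(density$x_edges, -1)) / 2
    ym <- (density$y_edges[-1] + head(density$y_edges, -1)) / 2
    r <- sqrt(outer((xm - density$box[1] / 2)^2, (ym - density$box[2] / 2)^2,
                    `+`))
    annulus <- sampled & r >= annulus_from
    if (!any(annulus)) stop("no sampled bins in the bulk annulus")
    rr <- mean(d[annulus])
  }
  dG <- matrix(NA_real_, nrow(d), ncol(d))
  dG[sampled] <- -KB_KJMOL * T * log(d[sampled] / rr)
  dG <- dG - min(dG[sampled])
  structure(list(x_edges = density$x_edges, y_edges = density$y_edges,
                 dG = dG, mask = !sampled, T = T, kB = KB_KJMOL,
                 rho_ref = rr, ref = ref, box = density$box),
            class = "free_energy_map")
}
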