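#' Construct a single coordinate frame
#'
#' @param time time in ns.
#' @param positions numeric n x 3 matrix of bead positions (nm).
#' @param box rectangular box lengths `(Lx, Ly, Lz)` in nm; the membrane
#'   normal is z by convention.
#' @return list of class `cg_frame`.
#' @export
frame <- function(time, positions, box) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)),
            length(box) == 3, all(box > 0), is.finite(time))
  dimnames(positions) <- NULL
  structure(list(time = as.numeric(time), positions = positions,
                 box = as.numeric(box)), class = "cg_frame")
}

#' Construct a coarse-grained trajectory
#'
#' Frames are stored as an `n_beads x 3 x n_frames` array with strictly
#' increasing, uniformly spaced times. A single-frame trajectory is valid
#' but has `dt = NA`; kinetic analyses refuse it.
#'
#' @param coords `n_beads x 3 x n_frames` array (nm).
#' @param times frame times in ns.
#' @param box either a length-3 vector (constant box) or an
#'   `n_frames x 3` matrix.
#' @param dt_tol tolerance (ns) for non-uniform frame spacing.
#' @return list of class `cg_trajectory` with elements `coords`, `times`,
#'   `box` (matrix), `dt`.
#' @export
cg_trajectory <- function(coords, times, box, dt_tol = 1e-6) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  nf <- dim(coords)[3]
  stopifnot(length(times) == nf)
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  box <- as.matrix(box)
  stopifnot(nrow(box) == nf, ncol(box) == 3, all(box > 0))
  if (nf > 1) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("frame times must be strictly increasing")
    dt <- dts[1]
    if (any(abs(dts - dt) > dt_tol))
      stop("non-uniform frame spacing (beyond tolerance ", dt_tol, " ns)")
  } else {
    dt <- NA_real_
  }
  structure(list(coords = coords, times = as.numeric(times), box = box,
                 dt = dt), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "cg_trajectory: %d beads, %d frames, t = %.4g..%.4g ns (dt = %s ns)\n",
    dim(x$coords)[1], n_frames(x), x$times[1], x$times[n_frames(x)],
    format(x$dt)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [cg_trajectory].
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory
#' @param traj a [cg_trajectory].
#' @param i frame index (1-based).
#' @return a [frame()].
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  frame(traj$times[i], traj$coords[, , i, drop = TRUE], traj$box[i, ])
}

#' Subset trajectory frames by index
#' @param traj a [cg_trajectory].
#' @param idx increasing frame indices.
#' @return a [cg_trajectory].
#' @export
subset_frames <- function(traj, idx) {
  stopifnot(all(idx >= 1), all(idx <= n_frames(traj)), !is.unsorted(idx))
  cg_trajectory(traj$coords[, , idx, drop = FALSE], traj$times[idx],
                traj$box[idx, , drop = FALSE])
}

#' Discard the pre-equilibration part of a trajectory
#'
#' Keeps frames with time >= `t_start`, preserving `dt`. The convention
#' mirrors discarding the first tenth of a production run (e.g. 1 of
#' 10 microseconds) before computing interaction statistics.
#'
#' @param traj a [cg_trajectory].
#' @param t_start ns.
#' @return a [cg_trajectory].
#' @export
slice_equilibrated <- function(traj, t_start) {
  keep <- which(traj$times >= t_start - 1e-9)
  if (!length(keep))
    stop("t_start = ", t_start, " ns is beyond the trajectory (last frame ",
         traj$times[n_frames(traj)], " ns)")
  subset_frames(traj, keep)
}

#' Minimum-image distance under rectangular periodic boundaries
#'
#' @param p1,p2 length-3 vectors or n x 3 matrices of positions (nm).
#' @param box rectangular box lengths (nm).
#' @return numeric distance(s), each in `[0, ||box||/2]`.
#' @export
min_image_distance <- function(p1, p2, box) {
  stopifnot(all(box > 0))
  d <- min_image_displacement(p1, p2, box)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

#' Minimum-image displacement vector(s)
#' @inheritParams min_image_distance
#' @return displacement `p1 - p2` wrapped per axis into `[-L/2, L/2]`.
#' @export
min_image_displacement <- function(p1, p2, box) {
  d <- p1 - p2
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  } else {
    d <- d - box * round(d / box)
  }
  d
}

# wrap coordinates into [0, L)
wrap_coords <- function(x, L) {
  y <- x - L * floor(x / L)
  y[y >= L] <- 0
  y
}

#' Read a trajectory
#'
#' The plain-text trajectory format stores one frame per block:
#' a header line `t=<ns> box=<Lx> <Ly> <Lz>` followed by one `x y z` line
#' per bead (nm). XTC/TRR readers are not provided; convert binary
#' trajectories to this text format (e.g. with `gmx trjconv`/MDAnalysis
#' export) before loading.
#'
#' @param path file path.
#' @param topology optional [bead_topology]; if given, the bead count of
#'   every frame must match.
#' @param format `"text"` (the documented plain-text format), `"xtc"` or
#'   `"trr"` (rejected with a conversion hint).
#' @param strict logical; a corrupt trailing frame is an error when `TRUE`
#'   and truncates the trajectory with a warning when `FALSE` (default).
#' @return a [cg_trajectory].
#' @export
read_trajectory <- function(path, topology = NULL,
                            format = c("text", "xtc", "trr"),
                            strict = FALSE) {
  format <- match.arg(format)
  if (format %in% c("xtc", "trr"))
    stop("binary ", toupper(format), " trajectories are not supported; ",
         "convert to the plain-text frame format (see ?read_trajectory) ",
         "with gmx trjconv or an MDAnalysis export first")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^t=", lines)
  if (!length(hdr)) stop("trajectory format error: no frame headers found")
  nf <- length(hdr)
  ends <- c(hdr[-1] - 1L, length(lines))
  nb <- ends[1] - hdr[1]
  if (nb < 1) stop("trajectory format error: first frame has no beads")
  if (!is.null(topology) && nb != nrow(topology))
    stop("bead-count mismatch: trajectory has ", nb, " beads, topology has ",
         nrow(topology))
  times <- numeric(nf)
  box <- matrix(NA_real_, nf, 3)
  coords <- array(NA_real_, c(nb, 3, nf))
  keep <- nf
  for (f in seq_len(nf)) {
    h <- lines[hdr[f]]
    m <- regmatches(h, regexec(
      "^t=\\s*([-0-9.eE+]+)\\s+box=\\s*([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)", h))[[1]]
    ok <- length(m) == 5
    body_ok <- ok && (ends[f] - hdr[f] == nb)
    if (body_ok) {
      vals <- suppressWarnings(scan(text = lines[(hdr[f] + 1):ends[f]],
                                    quiet = TRUE))
      body_ok <- length(vals) == 3 * nb && !anyNA(vals)
      if (body_ok) coords[, , f] <- matrix(vals, nb, 3, byrow = TRUE)
    }
    if (!body_ok) {
      msg <- paste0("corrupt frame ", f, " in ", path)
      if (strict) stop(msg)
      warning(msg, "; trajectory truncated to ", f - 1L, " frames")
      keep <- f - 1L
      break
    }
    times[f] <- as.numeric(m[2])
    box[f, ] <- as.numeric(m[3:5])
  }
  if (keep < 1) stop("trajectory format error: no readable frames")
  cg_trajectory(coords[, , seq_len(keep), drop = FALSE], times[seq_len(keep)],
                box[seq_len(keep), , drop = FALSE])
}

#' Write a trajectory in the plain-text frame format
#'
#' @param traj a [cg_trajectory].
#' @param path output path.
#' @param digits coordinate digits after the decimal point.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, digits = 5) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%.%df %%.%df %%.%df", digits, digits, digits)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("t=%.6f box=%g %g %g", traj$times[f],
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
    p <- traj$coords[, , f, drop = TRUE]
    writeLines(sprintf(fmt, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}
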