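#' Detect residue-lipid contacts in one frame
#'
#' A protein residue and a lipid molecule are in contact when any bead of
#' the residue and any bead of the lipid are at minimum-image distance
#' strictly below the cut-off (0.6 nm by default; the boundary itself is
#' not a contact). Detection uses a cell list with cells at least one
#' cut-off wide.
#'
#' @param frame a [frame()].
#' @param topology a [bead_topology].
#' @param cutoff contact cut-off in nm; must be below half the smallest box
#'   length.
#' @param lipid_classes lipid classes to consider (default: all).
#' @return `data.table` with columns `residue_id`, `monomer_id`,
#'   `molecule_id`, `molecule_class`, one row per residue-molecule pair in
#'   contact.
#' @export
find_contacts <- function(frame, topology, cutoff = 0.6,
                          lipid_classes = NULL) {
  .check_cutoff(cutoff, frame$box)
  idx <- .contact_groups(topology, lipid_classes)
  pr <- .frame_contacts(frame$positions, frame$box, idx, cutoff,
                        bead_level = FALSE)
  pr[, .(residue_id, monomer_id, molecule_id, molecule_class)]
}

.check_cutoff <- function(cutoff, box) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (cutoff >= min(box) / 2)
    stop("geometry error: cutoff (", cutoff,
         " nm) must be below half the smallest box length (",
         min(box) / 2, " nm)")
}

.contact_groups <- function(topology, lipid_classes = NULL) {
  if (is.null(lipid_classes)) lipid_classes <- .lipid_classes
  list(pidx = which(topology$molecule_class == "protein"),
       lidx = which(topology$molecule_class %in% lipid_classes),
       topology = topology)
}

.frame_contacts <- function(positions, box, idx, cutoff, bead_level) {
  empty <- data.table(residue_id = integer(), monomer_id = integer(),
                      molecule_id = integer(), molecule_class = character(),
                      protein_bead = character(), lipid_bead = character())
  if (!length(idx$pidx) || !length(idx$lidx))
    return(if (bead_level) empty else
      empty[, .(residue_id, monomer_id, molecule_id, molecule_class)])
  pr <- contact_pairs_cellist(positions, box, idx$pidx, idx$lidx, cutoff)
  top <- idx$topology
  pb <- idx$pidx[pr[, 1]]
  lb <- idx$lidx[pr[, 2]]
  out <- data.table(residue_id = top$residue_id[pb],
                    monomer_id = top$monomer_id[pb],
                    molecule_id = top$molecule_id[lb],
                    molecule_class = top$molecule_class[lb])
  if (bead_level) {
    out[, protein_bead := top$bead_name[pb]]
    out[, lipid_bead := top$bead_name[lb]]
    out
  } else {
    unique(out)
  }
}

#' Contact series over a trajectory
#'
#' The central intermediate of the fingerprint analysis: a sparse per-frame
#' table of residue-lipid contacts, from which shell counts, contact
#' fractions, binding events and every kinetic metric are derived. With
#' `detail = "molecule"` (default) each residue-molecule pair counts once
#' per frame regardless of how many bead pairs are within the cut-off;
#' `detail = "bead"` keeps one row per bead pair for bead-resolved
#' analyses such as [bead_contact_ratio()].
#'
#' @param traj a [cg_trajectory].
#' @param topology a [bead_topology].
#' @inheritParams find_contacts
#' @param detail `"molecule"` or `"bead"`.
#' @return `data.table` of class `contact_series` with columns `frame`,
#'   `residue_id`, `monomer_id`, `molecule_id`, `molecule_class` (plus
#'   `protein_bead`, `lipid_bead` at bead detail). Attributes: `cutoff`,
#'   `dt`, `times`, `n_frames`, `detail`, `residues` (the protein
#'   residue x monomer universe), `class_counts` (molecules per class).
#' @export
contact_series <- function(traj, topology, cutoff = 0.6,
                           lipid_classes = NULL,
                           detail = c("molecule", "bead")) {
  detail <- match.arg(detail)
  .check_cutoff(cutoff, traj$box[1, ])
  stopifnot(dim(traj$coords)[1] == nrow(topology))
  idx <- .contact_groups(topology, lipid_classes)
  nf <- n_frames(traj)
  res <- vector("list", nf)
  for (f in seq_len(nf)) {
    cf <- .frame_contacts(traj$coords[, , f, drop = TRUE], traj$box[f, ],
                          idx, cutoff, bead_level = detail == "bead")
    if (nrow(cf)) {
      cf[, frame := f]
      res[[f]] <- cf
    }
  }
  cs <- rbindlist(res)
  if (!nrow(cs))
    cs <- data.table(residue_id = integer(), monomer_id = integer(),
                     molecule_id = integer(), molecule_class = character(),
                     frame = integer())
  setcolorder(cs, "frame")
  residues <- unique(topology[molecule_class == "protein",
                              .(residue_id, monomer_id)])
  class_counts <- topology[molecule_class %in% .lipid_classes,
                           .(n = uniqueN(molecule_id)), by = molecule_class]
  setattr(cs, "class", c("contact_series", class(data.table())))
  setattr(cs, "cutoff", cutoff)
  setattr(cs, "dt", traj$dt)
  setattr(cs, "times", traj$times)
  setattr(cs, "n_frames", nf)
  setattr(cs, "detail", detail)
  setattr(cs, "residues", residues)
  setattr(cs, "class_counts", class_counts)
  cs
}

# molecule-level view of a contact series (drops bead columns, dedupes)
.cs_molecule <- function(cs) {
  if (attr(cs, "detail") == "molecule") return(cs)
  out <- unique(cs[, .(frame, residue_id, monomer_id, molecule_id,
                       molecule_class)])
  for (a in c("cutoff", "dt", "times", "n_frames", "residues",
              "class_counts"))
    setattr(out, a, attr(cs, a))
  setattr(out, "detail", "molecule")
  setattr(out, "class", class(cs))
  out
}

#' First-shell lipid counts over time
#'
#' Counts, per frame, the distinct lipid molecules of a class with any bead
#' within the cut-off of any protein bead, then applies a centred moving
#' average (window shrinks at the series ends). Given several repeat
#' series, returns the per-frame mean and standard deviation across
#' repeats of the smoothed counts.
#'
#' @param cs a [contact_series], or a list of them (repeats).
#' @param lipid_class lipid class to count.
#' @param window_ns moving-average window in ns (default 20).
#' @return `data.table` of class `shell_count_series`: `time`, `count`,
#'   `smoothed` for a single series; `time`, `mean`, `sd` across repeats.
#' @export
shell_count_series <- function(cs, lipid_class, window_ns = 20) {
  if (inherits(cs, "contact_series")) {
    out <- .shell_one(cs, lipid_class, window_ns)
  } else {
    stopifnot(is.list(cs), length(cs) >= 1)
    sm <- lapply(cs, function(x) .shell_one(x, lipid_class, window_ns))
    nf <- unique(vapply(sm, nrow, 1L))
    if (length(nf) != 1) stop("repeat series differ in length")
    mat <- vapply(sm, function(x) x$smoothed, numeric(nf))
    out <- data.table(time = sm[[1]]$time, mean = rowMeans(mat),
                      sd = apply(mat, 1, sd))
  }
  setattr(out, "class", c("shell_count_series", class(data.table())))
  setattr(out, "lipid_class", lipid_class)
  setattr(out, "window_ns", window_ns)
  out
}

.shell_one <- function(cs, lipid_class, window_ns) {
  stopifnot(inherits(cs, "contact_series"))
  nf <- attr(cs, "n_frames")
  dt <- attr(cs, "dt")
  cc <- attr(cs, "class_counts")
  if (!lipid_class %in% cc$molecule_class)
    warning("lipid class '", lipid_class,
            "' absent from the topology; empty series")
  cnt <- numeric(nf)
  m <- .cs_molecule(cs)
  byf <- m[molecule_class == lipid_class, .(n = uniqueN(molecule_id)),
           by = frame]
  cnt[byf$frame] <- byf$n
  w <- if (is.na(dt)) 1L else max(1L, round(window_ns / dt))
  data.table(time = attr(cs, "times"), count = cnt,
             smoothed = moving_average(cnt, w))
}

#' Centred moving average with shrinking edges
#'
#' @param x numeric vector.
#' @param w window length in samples; the window is truncated (not padded)
#'   at the two ends of the series.
#' @return numeric vector of the same length.
#' @export
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n == 0) return(as.numeric(x))
  half <- (w - 1L) %/% 2L
  cums <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cums[hi + 1L] - cums[lo]) / (hi - lo + 1L)
}

#' Plateau value of a shell-count series
#'
#' Mean of the smoothed counts from `from_ns` onwards, i.e. the equilibrium
#' first-shell population.
#'
#' @param scs a [shell_count_series].
#' @param from_ns start of the plateau window (ns).
#' @return numeric scalar.
#' @export
shell_plateau <- function(scs, from_ns) {
  col <- if ("smoothed" %in% names(scs)) "smoothed" else "mean"
  v <- scs[[col]][scs$time >= from_ns]
  if (!length(v)) stop("no frames at or after ", from_ns, " ns")
  mean(v)
}

#' Per-residue lipid-class contact fractions
#'
#' For every protein residue, the fraction of its (frame, lipid molecule)
#' contact pairs attributable to each lipid class, identifying the lipid
#' most frequently in contact with each lipid-exposed residue. Fractions
#' sum to 1 for every contacted residue; residues with zero contacts keep
#' fraction `NA` and `total = 0`.
#'
#' @param cs a [contact_series].
#' @param pool_monomers average-free pooling: count over all monomer copies
#'   of a residue id (default `TRUE`).
#' @return `data.table` of class `contact_fraction_table`: `residue_id`
#'   (and `monomer_id` if not pooled), `total`, one `frac_<class>` column
#'   per lipid class present in the topology.
#' @export
contact_fractions <- function(cs, pool_monomers = TRUE) {
  m <- .cs_molecule(cs)
  keys <- if (pool_monomers) "residue_id" else c("residue_id", "monomer_id")
  classes <- attr(cs, "class_counts")$molecule_class
  universe <- unique(attr(cs, "residues")[, ..keys])
  if (!length(classes) || !nrow(m)) {
    out <- copy(universe)
    out[, total := 0L]
    for (cl in classes) out[, (paste0("frac_", cl)) := NA_real_]
    setorderv(out, keys)
    setattr(out, "class", c("contact_fraction_table", class(data.table())))
    setattr(out, "lipid_classes", classes)
    return(out)
  }
  counts <- m[, .N, by = c(keys, "molecule_class")]
  wide <- dcast(counts, stats::as.formula(
    paste(paste(keys, collapse = "+"), "~ molecule_class")),
    value.var = "N", fill = 0)
  for (cl in setdiff(classes, names(wide))) wide[, (cl) := 0]
  out <- merge(universe, wide, by = keys, all.x = TRUE)
  for (cl in classes) set(out, which(is.na(out[[cl]])), cl, 0)
  out[, total := rowSums(.SD), .SDcols = classes]
  for (cl in classes)
    out[, (paste0("frac_", cl)) := ifelse(total > 0, get(cl) / total,
                                          NA_real_)]
  out[, (classes) := NULL]
  setorderv(out, keys)
  setattr(out, "class", c("contact_fraction_table", class(data.table())))
  setattr(out, "lipid_classes", classes)
  out
}

#' Residues enriched in a lipid class
#'
#' Residues where the class accounts for strictly more than `threshold` of
#' all lipid contacts ("over 30%" semantics: a fraction exactly at the
#' threshold is not enriched). The natural threshold is the membrane bulk
#' fraction of the class, e.g. 0.30 for a 30% cholesterol membrane.
#'
#' @param tab a [contact_fractions()] table.
#' @param lipid_class class of interest.
#' @param threshold fraction in (0, 1), or 0 to flag every contacted
#'   residue with any contact of the class.
#' @return sorted integer vector of enriched residue ids.
#' @export
enrichment_mask <- function(tab, lipid_class, threshold = 0.30) {
  stopifnot(threshold >= 0, threshold < 1)
  col <- paste0("frac_", lipid_class)
  if (!col %in% names(tab)) {
    if (any(tab$total > 0)) stop("class not in table: ", lipid_class)
    warning("class '", lipid_class, "' absent and no contacts recorded")
    return(integer(0))
  }
  fr <- tab[[col]]
  sort(unique(tab$residue_id[!is.na(fr) & fr > threshold]))
}
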