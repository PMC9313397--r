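library(data.table)

# O(N^2) all-pairs contact oracle: residue-molecule pairs with any bead pair
# at minimum-image distance strictly below the cutoff.
brute_contacts <- function(positions, box, topology, cutoff) {
  pidx <- which(topology$molecule_class == "protein")
  lidx <- which(topology$molecule_class %in%
                  c("PC", "Chol", "PE", "PS", "SM", "PIP2"))
  pairs <- list()
  for (i in pidx) {
    d <- positions[lidx, , drop = FALSE]
    for (k in 1:3) {
      dk <- d[, k] - positions[i, k]
      d[, k] <- dk - box[k] * round(dk / box[k])
    }
    hit <- lidx[sqrt(rowSums(d^2)) < cutoff]
    if (length(hit))
      pairs[[length(pairs) + 1L]] <- data.table(
        residue_id = topology$residue_id[i],
        monomer_id = topology$monomer_id[i],
        molecule_id = topology$molecule_id[hit])
  }
  if (!length(pairs))
    return(data.table(residue_id = integer(), monomer_id = integer(),
                      molecule_id = integer()))
  out <- unique(rbindlist(pairs))
  setorder(out, residue_id, monomer_id, molecule_id)
  out
}

# Dense run-length oracle over a binary indicator vector: maximal runs of 1s,
# merging runs separated by <= gap zeros. Returns start/end indices.
rl_runs_oracle <- function(ind, gap = 0L) {
  if (gap > 0) {
    # close zero-gaps of length <= gap that are flanked by ones
    r <- rle(ind)
    n <- length(r$values)
    for (j in seq_len(n)) {
      if (r$values[j] == 0 && r$lengths[j] <= gap && j > 1 && j < n)
        r$values[j] <- 1
    }
    ind <- inverse.rle(r)
  }
  r <- rle(ind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1
  data.table(start = starts[keep], end = ends[keep])
}

# Random topology + frame with n protein beads and m single-bead lipids.
random_toy_system <- function(np, nl, box = c(10, 10, 8), seed = 1) {
  set.seed(seed)
  n <- np + nl
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  top <- bead_topology(
    bead_name = c(rep("BB", np), rep("ROH", nl)),
    residue_id = c(seq_len(np) + 321L, seq_len(nl) + 1000L),
    residue_name = c(rep("ALA", np), rep("CHOL", nl)),
    monomer_id = c(rep(0L, np), rep(NA_integer_, nl)),
    molecule_id = c(rep(1L, np), seq_len(nl) + 1L),
    molecule_class = c(rep("protein", np), rep("Chol", nl)))
  list(topology = top, frame = frame(0, pos, box))
}

# Hand-built contact series from a list of per-frame contact tables.
# rows: residue_id, monomer_id, molecule_id, molecule_class
make_cs <- function(frames, dt = 0.1, cutoff = 0.6,
                    residues = NULL, class_counts = NULL,
                    detail = "molecule") {
  rows <- list()
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (!is.null(fr) && nrow(fr)) {
      fr <- as.data.table(fr)
      fr[, frame := f]
      rows[[length(rows) + 1L]] <- fr
    }
  }
  cs <- if (length(rows)) rbindlist(rows, use.names = TRUE, fill = TRUE) else
    data.table(residue_id = integer(), monomer_id = integer(),
               molecule_id = integer(), molecule_class = character(),
               frame = integer())
  setcolorder(cs, "frame")
  if (is.null(residues))
    residues <- unique(cs[, .(residue_id, monomer_id)])
  if (is.null(class_counts))
    class_counts <- cs[, .(n = uniqueN(molecule_id)), by = molecule_class]
  setattr(cs, "class", c("contact_series", class(data.table())))
  setattr(cs, "cutoff", cutoff)
  setattr(cs, "dt", dt)
  setattr(cs, "times", (seq_along(frames) - 1) * dt)
  setattr(cs, "n_frames", length(frames))
  setattr(cs, "detail", detail)
  setattr(cs, "residues", as.data.table(residues))
  setattr(cs, "class_counts", class_counts)
  cs
}

# Indicator-vector contact series for one residue/molecule pair (and
# optionally more pairs via a matrix with one row per molecule).
cs_from_indicator <- function(mat, dt = 0.1) {
  if (is.vector(mat)) mat <- matrix(mat, nrow = 1)
  frames <- lapply(seq_len(ncol(mat)), function(f) {
    mols <- which(mat[, f] == 1)
    if (!length(mols)) return(NULL)
    data.table(residue_id = 322L, monomer_id = 0L,
               molecule_id = mols + 1L, molecule_class = "Chol")
  })
  make_cs(frames, dt = dt,
          residues = data.table(residue_id = 322L, monomer_id = 0L),
          class_counts = data.table(molecule_class = "Chol",
                                    n = nrow(mat)))
}
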