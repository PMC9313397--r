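#' Default residue-name to lipid-class mapping
#'
#' Maps Martini residue names to the lipid classes used throughout the
#' package. Standard three-letter amino acid names are classified as
#' `protein`; anything not covered is handled according to the parsing mode
#' of [read_topology()].
#'
#' @return Named character vector: residue name -> molecule class.
#' @export
default_class_map <- function() {
  c(POPC = "PC", DOPC = "PC", DPPC = "PC", POPC2 = "PC",
    CHOL = "Chol", CHOL8 = "Chol",
    POPE = "PE", DOPE = "PE",
    POPS = "PS", DOPS = "PS",
    DPSM = "SM", PSM = "SM",
    POP2 = "PIP2", PIP2 = "PIP2", PAP2 = "PIP2",
    W = "water", WF = "water", PW = "water",
    ION = "ion", NA0 = "ion", CL0 = "ion", NAC = "ion", CLA = "ion")
}

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.lipid_classes <- c("PC", "Chol", "PE", "PS", "SM", "PIP2")

#' Construct a bead topology
#'
#' A bead topology is the static per-bead metadata of a coarse-grained
#' system: bead and residue identity, protein monomer (chain copy),
#' molecule membership and molecule class. It is the reference frame for
#' every contact-based analysis in the package.
#'
#' @param bead_name character, bead names (e.g. `"BB"`, `"ROH"`, `"PO4"`).
#' @param residue_id integer residue numbers.
#' @param residue_name character residue names (e.g. `"VAL"`, `"CHOL"`).
#' @param monomer_id integer protein chain copy (0-based per tetramer
#'   convention); `NA` for non-protein beads.
#' @param molecule_id integer, one id per molecule (lipid molecule or
#'   protein chain).
#' @param molecule_class character, one of `protein`, `PC`, `Chol`, `PE`,
#'   `PS`, `SM`, `PIP2`, `water`, `ion`.
#' @return A `data.table` of class `bead_topology` with one row per bead and
#'   a `bead_id` column (1-based, contiguous).
#' @export
bead_topology <- function(bead_name, residue_id, residue_name, monomer_id,
                          molecule_id, molecule_class) {
  top <- data.table(
    bead_id = seq_along(bead_name),
    bead_name = as.character(bead_name),
    residue_id = as.integer(residue_id),
    residue_name = as.character(residue_name),
    monomer_id = as.integer(monomer_id),
    molecule_id = as.integer(molecule_id),
    molecule_class = as.character(molecule_class)
  )
  validate_topology(top)
  setattr(top, "class", c("bead_topology", class(data.table())))
  top[]
}

validate_topology <- function(top) {
  stopifnot(is.data.frame(top), nrow(top) >= 1)
  if (!identical(top$bead_id, seq_len(nrow(top))))
    stop("bead_ids must be contiguous 1..n and unique")
  if (anyNA(top$molecule_id))
    stop("every bead must map to a molecule_id")
  ncls <- top[, uniqueN(molecule_class), by = molecule_id]$V1
  if (any(ncls != 1L))
    stop("all beads of a molecule must share molecule_class")
  known <- c("protein", .lipid_classes, "water", "ion")
  bad <- setdiff(unique(top$molecule_class), known)
  if (length(bad))
    stop("unknown molecule_class: ", paste(bad, collapse = ", "))
  invisible(top)
}

#' @export
print.bead_topology <- function(x, ...) {
  cat(sprintf("bead_topology: %d beads, %d molecules\n", nrow(x),
              uniqueN(x$molecule_id)))
  tab <- x[, .(beads = .N, molecules = uniqueN(molecule_id)),
           by = molecule_class]
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

# classify residue names into molecule classes; unknown -> NA
.classify_resname <- function(resname, class_map) {
  cls <- unname(class_map[resname])
  cls[is.na(cls) & resname %in% .aa3] <- "protein"
  cls
}

#' Read a coarse-grained topology from a GRO or PDB file
#'
#' Parses the standard fixed-column GRO layout (or a PDB via bio3d) and
#' infers molecule grouping: consecutive beads sharing a residue number and
#' name form a molecule; runs of protein residues form one chain per run
#' (a decreasing residue number starts a new chain, i.e. a new monomer).
#' Lipid classes are inferred from residue names through `class_map`
#' (Martini defaults: POPC -> PC, CHOL -> Chol, POPE -> PE, POPS -> PS,
#' DPSM/PSM -> SM, POP2/PIP2 -> PIP2).
#'
#' @param path file path.
#' @param format `"GRO"` or `"PDB"` (case-insensitive; guessed from the file
#'   extension by default).
#' @param class_map named character vector residue name -> class, see
#'   [default_class_map()]; user entries override the defaults.
#' @param strict logical; if `TRUE` an unknown residue name is an error, if
#'   `FALSE` (default, lenient) it is classified as `ion` with a warning.
#' @return list with elements `topology` ([bead_topology]) and `frame`
#'   (a [frame()] holding the coordinates and box of the file).
#' @export
read_topology <- function(path, format = c("auto", "GRO", "PDB"),
                          class_map = default_class_map(), strict = FALSE) {
  format <- toupper(match.arg(format))
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "AUTO")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "PDB" else "GRO"
  cmap <- default_class_map()
  cmap[names(class_map)] <- class_map
  if (format == "GRO") .read_gro(path, cmap, strict) else
    .read_pdb(path, cmap, strict)
}

.finish_topology <- function(resid, resname, beadname, xyz, box, time,
                             class_map, strict, chain = NULL) {
  cls <- .classify_resname(resname, class_map)
  if (anyNA(cls)) {
    bad <- unique(resname[is.na(cls)])
    if (strict)
      stop("unknown residue name(s) in strict mode: ",
           paste(bad, collapse = ", "))
    warning("unknown residue name(s) classified as 'ion': ",
            paste(bad, collapse = ", "))
    cls[is.na(cls)] <- "ion"
  }
  n <- length(resid)
  # molecule breaks: new residue (id or name changes), except inside a
  # protein chain where consecutive residues share a molecule
  new_res <- c(TRUE, resid[-1] != resid[-n] | resname[-1] != resname[-n])
  is_prot <- cls == "protein"
  if (is.null(chain)) {
    # chain break when the previous bead is not protein or numbering restarts
    chain_brk <- new_res & is_prot &
      (c(TRUE, !is_prot[-n]) | c(TRUE, resid[-1] < resid[-n]))
  } else {
    chain_brk <- new_res & is_prot & c(TRUE, chain[-1] != chain[-n] | !is_prot[-n])
  }
  mol_brk <- (new_res & !is_prot) | chain_brk
  molecule_id <- cumsum(mol_brk | c(TRUE, rep(FALSE, n - 1)))
  # monomer id: 0-based index among protein chains
  chain_idx <- cumsum(chain_brk)
  monomer_id <- ifelse(is_prot, chain_idx - 1L, NA_integer_)
  top <- bead_topology(beadname, resid, resname, monomer_id, molecule_id, cls)
  list(topology = top, frame = frame(time = time, positions = xyz, box = box))
}

.read_gro <- function(path, class_map, strict) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("GRO format error: file too short (", path, ")")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1) stop("GRO format error at line 2: bad atom count")
  if (length(lines) < n + 3) stop("GRO format error: truncated file")
  al <- lines[3:(n + 2)]
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  beadname <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("GRO format error at line ", bad[1] + 2L, ": unparseable atom record")
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]]))
  if (length(box) < 3 || anyNA(box[1:3]) || any(box[1:3] <= 0))
    stop("GRO format error at line ", n + 3L, ": bad box record")
  .finish_topology(resid, resname, beadname, cbind(x, y, z), box[1:3], 0,
                   class_map, strict)
}

.read_pdb <- function(path, class_map, strict) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  # PDB is in Angstrom; package convention is nm
  xyz <- cbind(a$x, a$y, a$z) / 10
  box <- c(15, 15, 10)
  if (!is.null(pdb$cryst1) && !is.null(pdb$cryst1$abc) &&
      all(is.finite(pdb$cryst1$abc)) && all(pdb$cryst1$abc > 0))
    box <- pdb$cryst1$abc / 10
  chain <- a$chain
  chain[is.na(chain)] <- ""
  .finish_topology(as.integer(a$resno), a$resid, trimws(a$elety), xyz, box, 0,
                   class_map, strict, chain = chain)
}

#' Write a topology and coordinates as a GRO file
#'
#' @param topology a [bead_topology].
#' @param frame a [frame()] with matching bead count.
#' @param path output path.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(topology, frame, path, title = "lipidprint system") {
  stopifnot(nrow(topology) == nrow(frame$positions))
  p <- frame$positions
  recs <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  topology$residue_id %% 100000L,
                  substr(topology$residue_name, 1, 5),
                  substr(topology$bead_name, 1, 5),
                  topology$bead_id %% 100000L,
                  p[, 1], p[, 2], p[, 3])
  writeLines(c(title, sprintf("%5d", nrow(topology)), recs,
               sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                       frame$box[3])), path)
  invisible(path)
}

#' Select beads from a topology
#'
#' Selection expressions: `"protein"`, `"lipid"` (all lipid classes),
#' `"lipid:<class>"` (e.g. `"lipid:Chol"`), `"bead:<name>"`,
#' `"resid:<id>"`, `"class:<molecule class>"`. Several expressions form a
#' union.
#'
#' @param topology a [bead_topology].
#' @param ... one or more selection strings.
#' @return sorted integer vector of bead ids (no duplicates), with the
#'   selection label as the `"label"` attribute.
#' @export
select_beads <- function(topology, ...) {
  specs <- unlist(list(...), use.names = FALSE)
  stopifnot(length(specs) >= 1)
  idx <- integer(0)
  for (s in specs) {
    hit <- if (s == "protein") {
      topology$molecule_class == "protein"
    } else if (s == "lipid") {
      topology$molecule_class %in% .lipid_classes
    } else if (startsWith(s, "lipid:") || startsWith(s, "class:")) {
      topology$molecule_class == sub("^[a-z]+:", "", s)
    } else if (startsWith(s, "bead:")) {
      topology$bead_name == sub("^bead:", "", s)
    } else if (startsWith(s, "resid:")) {
      topology$residue_id == as.integer(sub("^resid:", "", s))
    } else stop("unknown selection expression: ", s)
    idx <- union(idx, which(hit))
  }
  idx <- sort(idx)
  attr(idx, "label") <- paste(specs, collapse = " | ")
  idx
}
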