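#' Assemble a run configuration
#'
#' Collects every tunable of the fingerprint pipeline with the package's
#' standard defaults: 0.6 nm contact cut-off, 20 ns shell-count window,
#' first tenth of the run discarded as equilibration, cholesterol as the
#' class of interest, gap tolerance 0. The configuration round-trips
#' losslessly through YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param seed integer seed controlling build and simulation.
#' @param n_frames,dt synthetic run length (frames) and spacing (ns).
#' @param composition `"symmetric"` or `"asymmetric"` (see
#'   [composition_symmetric()]).
#' @param n_per_leaflet lipids per leaflet.
#' @param chol_beads 1 or 8 beads per cholesterol.
#' @param cutoff contact cut-off (nm).
#' @param equilibration_ns discarded initial time; `NULL` means one tenth
#'   of the run.
#' @param window_ns shell-count moving-average window (ns).
#' @param lipid_class class of interest.
#' @param gap_tolerance event gap merging (frames).
#' @param duration_mode contact-duration definition, see
#'   [kinetic_profile()].
#' @param enrichment_threshold strict lower bound for [enrichment_mask()].
#' @param top_k residues per ranking.
#' @param partner_low,partner_high distinct-partner thresholds of the
#'   annular / non-annular classification heuristic.
#' @param outdir output directory, or `NULL` for no files.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_frames = 9000, dt = 0.1,
                       composition = c("symmetric", "asymmetric"),
                       n_per_leaflet = 300, chol_beads = 1,
                       cutoff = 0.6, equilibration_ns = NULL,
                       window_ns = 20, lipid_class = "Chol",
                       gap_tolerance = 0, duration_mode = "union",
                       enrichment_threshold = 0.30, top_k = 10,
                       partner_low = 3, partner_high = 20,
                       outdir = NULL) {
  composition <- match.arg(composition)
  cfg <- list(seed = as.integer(seed), n_frames = as.integer(n_frames),
              dt = dt, composition = composition,
              n_per_leaflet = as.integer(n_per_leaflet),
              chol_beads = as.integer(chol_beads), cutoff = cutoff,
              equilibration_ns = equilibration_ns %||%
                (n_frames * dt / 10),
              window_ns = window_ns, lipid_class = lipid_class,
              gap_tolerance = as.integer(gap_tolerance),
              duration_mode = duration_mode,
              enrichment_threshold = enrichment_threshold,
              top_k = as.integer(top_k),
              partner_low = partner_low, partner_high = partner_high,
              outdir = outdir)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, Filter(Negate(is.null), yaml::read_yaml(path)))
}

#' Classify binding-site anchors as annular or non-annular
#'
#' Heuristic distilled from the contrast between fast and slow cholesterol
#' exchange: residues in the top-k of maximum occupancy with at most
#' `partner_low` distinct partners are non-annular (slow exchange, few
#' molecules); residues in the top-k of contact duration with at least
#' `partner_high` partners are annular (fast exchange, many molecules);
#' everything else, including residues without contacts, stays
#' unclassified.
#'
#' @param profile a [kinetic_profile].
#' @param top_k ranking depth (default 10).
#' @param partner_low,partner_high partner-count thresholds.
#' @return `data.table`: `residue_id`, `site_class` for every residue
#'   classified either way.
#' @export
classify_sites <- function(profile, top_k = 10, partner_low = 3,
                           partner_high = 20) {
  top_mo <- rank_residues(profile, "max_occupancy", top_k)
  top_cd <- rank_residues(profile, "contact_duration", top_k)
  out <- data.table(residue_id = profile$residue_id,
                    site_class = "unclassified")
  prt <- profile$n_distinct_partners
  has <- profile$contact_duration_ns > 0
  out[residue_id %in% top_mo & prt <= partner_low & has,
      site_class := "non_annular"]
  out[residue_id %in% top_cd & prt >= partner_high & has,
      site_class := "annular"]
  out[site_class != "unclassified"]
}

#' Run the full fingerprint pipeline on a synthetic system
#'
#' simulate -> equilibration cut -> contacts -> shell counts -> contact
#' fractions & enrichment -> events -> kinetic profile & rankings -> site
#' classification -> lateral density & free energy. Intermediates are
#' written as TSV/JSON under `cfg$outdir` (when set) together with a
#' MANIFEST; the run is deterministic given the configuration.
#'
#' @param cfg a [run_config()].
#' @return list of class `fingerprint_report`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  comp <- if (cfg$composition == "symmetric") composition_symmetric()
    else composition_asymmetric()
  msp <- membrane_spec(leaflets = comp, n_per_leaflet = cfg$n_per_leaflet,
                       chol_beads = cfg$chol_beads)
  sys <- build_system(msp, default_protein_spec(), seed = cfg$seed)
  stage <- "simulate"
  report <- tryCatch({
    traj <- simulate_membrane(sys, n_frames = cfg$n_frames, dt = cfg$dt,
                              seed = cfg$seed + 1L)
    stage <- "equilibration"
    traj_eq <- slice_equilibrated(traj, cfg$equilibration_ns)
    stage <- "contacts"
    cs <- contact_series(traj_eq, sys$topology, cutoff = cfg$cutoff)
    stage <- "shell_counts"
    shell <- shell_count_series(cs, cfg$lipid_class, cfg$window_ns)
    plateau <- shell_plateau(shell, cfg$equilibration_ns)
    stage <- "fractions"
    fr <- contact_fractions(cs)
    enriched <- enrichment_mask(fr, cfg$lipid_class,
                                cfg$enrichment_threshold)
    stage <- "kinetics"
    empty_run <- nrow(cs) == 0
    if (empty_run) {
      warning("no contacts in the run: empty kinetic tables")
      prof <- NULL; ev <- NULL; cls <- data.table()
      top_cd <- integer(0); top_mo <- integer(0)
    } else {
      ev <- extract_events(cs, cfg$gap_tolerance)
      prof <- kinetic_profile(cs, cfg$lipid_class, events = ev,
                              duration_mode = cfg$duration_mode)
      top_cd <- rank_residues(prof, "contact_duration", cfg$top_k)
      top_mo <- rank_residues(prof, "max_occupancy", cfg$top_k)
      cls <- classify_sites(prof, cfg$top_k, cfg$partner_low,
                            cfg$partner_high)
    }
    stage <- "density"
    dm <- tryCatch(
      density_map(traj_eq, sys$topology, paste0("lipid:", cfg$lipid_class)),
      error = function(e) {
        warning("density map skipped: ", conditionMessage(e))
        NULL
      })
    fe <- if (is.null(dm)) NULL else tryCatch(
      free_energy_from_density(dm, ref = "bulk_annulus",
                               annulus_from = sys$footprint_radius + 1.5),
      error = function(e) NULL)
    list(config = cfg, system = sys, shell = shell, plateau = plateau,
         fractions = fr, enriched = enriched, events = ev, profile = prof,
         top_contact_duration = top_cd, top_max_occupancy = top_mo,
         site_classes = cls, density = dm, free_energy = fe,
         true_events = attr(traj, "events"))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  class(report) <- "fingerprint_report"
  if (!is.null(cfg$outdir)) .write_report(report, cfg$outdir)
  report
}

#' @export
print.fingerprint_report <- function(x, ...) {
  cat("fingerprint_report\n")
  cat(sprintf("  %s shell plateau: %.2f molecules\n",
              x$config$lipid_class, x$plateau))
  cat(sprintf("  enriched residues (> %.0f%%): %s\n",
              100 * x$config$enrichment_threshold,
              paste(x$enriched, collapse = ", ")))
  if (!is.null(x$profile)) {
    cat("  top contact duration:",
        paste(head(x$top_contact_duration, 5), collapse = ", "), "...\n")
    cat("  top max occupancy:",
        paste(head(x$top_max_occupancy, 5), collapse = ", "), "...\n")
  }
  if (nrow(x$site_classes)) {
    cat("  site classification:\n")
    print(as.data.frame(x$site_classes), row.names = FALSE)
  }
  invisible(x)
}

.write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  manifest <- character(0)
  put <- function(obj, name, writer) {
    path <- file.path(outdir, name)
    writer(obj, path)
    manifest <<- c(manifest, name)
  }
  tsv <- function(obj, path) fwrite(obj, path, sep = "\t")
  put(report$shell, "shell_counts.tsv", tsv)
  put(report$fractions, "contact_fractions.tsv", tsv)
  if (!is.null(report$events)) put(report$events, "events.tsv", tsv)
  if (!is.null(report$profile)) put(report$profile, "kinetic_profile.tsv",
                                    tsv)
  if (nrow(report$site_classes)) put(report$site_classes,
                                     "site_classes.tsv", tsv)
  if (!is.null(report$density))
    put(report$density$density, "density.tsv",
        function(o, p) utils::write.table(o, p, sep = "\t",
                                          row.names = FALSE,
                                          col.names = FALSE))
  if (!is.null(report$free_energy))
    put(report$free_energy$dG, "free_energy.tsv",
        function(o, p) utils::write.table(o, p, sep = "\t",
                                          row.names = FALSE,
                                          col.names = FALSE))
  summ <- list(
    config = unclass(cfg),
    plateau = report$plateau,
    enriched_residues = report$enriched,
    top_contact_duration = report$top_contact_duration,
    top_max_occupancy = report$top_max_occupancy,
    site_classes = if (nrow(report$site_classes))
      as.data.frame(report$site_classes) else NULL,
    provenance = list(package = "lipidprint",
                      version = as.character(utils::packageVersion(
                        "lipidprint")),
                      seed = cfg$seed))
  jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  manifest <- c(manifest, "summary.json")
  writeLines(c("status: complete", paste0("file: ", manifest)),
             file.path(outdir, "MANIFEST"))
  invisible(outdir)
}
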