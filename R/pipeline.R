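#' Pipeline run configuration
#'
#' Bundles every tunable of the simulation pipeline with defaults matching
#' the published study parameters: 43-electrode arrays at 1 mm pitch,
#' rotation within +/-45 degrees, coil distance under 20 mm, 3.6 mm array
#' separation, 50-neighbour inverse-distance electrode projection, Gaussian
#' phosphenes with sigma = radius/3, 40 px/deg rendering, and DBSCAN
#' relocation with eps = 200 px and 100 minimum points. Fully serialisable
#' to/from JSON.
#'
#' @param ... overrides of the default fields (see Details via
#'   `run_config()$...`): `seed`, `n_implants`, `implants_per_hemi`,
#'   `surface` (generator parameters), `placement` (constraint block plus
#'   `rotation_deg`, `min_center_spacing_mm`), `model` (size-model
#'   overrides), `rendering` (`px_per_deg`, `canvas`, `k`), `clustering`
#'   (`eps_px`, `min_pts`), `metrics` (`n_bins`, `mi_bins`), `stimulus`
#'   (`logmar`, `orientation`), `out_dir`.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_implants = 12L,
    surface = list(n_per_hemi = 2000L, ecc_range = c(0.5, 30),
                   fold_amplitude = 2, fold_wavelength = 20,
                   size_slope = 0.05, size_intercept = 0.5,
                   size_noise_sd = 0.1),
    placement = list(rotation_deg = 0, max_rotation_deg = 45,
                     max_coil_distance_mm = 20, min_separation_mm = 3.6,
                     min_center_spacing_mm = 13, allow_overlap = NULL),
    model = list(),
    rendering = list(px_per_deg = 40, canvas = c(1080L, 1080L), k = 50L),
    clustering = list(eps_px = 200, min_pts = 100),
    metrics = list(n_bins = 16L, mi_bins = 64L),
    stimulus = list(logmar = 2.0, orientation = "right"),
    out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) {
    o <- over[[nm]]
    if (is.null(o)) next                   # null override = keep the default
    if (is.list(cfg[[nm]]) && is.list(o)) {
      o <- Filter(Negate(is.null), o)
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], o)
    } else cfg[[nm]] <- o
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file.
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, js)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Suggest implant centre vertices on a surface
#'
#' Deterministic helper for scripted runs on synthetic surfaces, standing in
#' for the manual, surgeon-guided site selection used with real anatomy.
#' Candidates are gyral V1/V2 grayordinates; per hemisphere, candidates are
#' visited in order of distance from the hemisphere patch centroid and
#' greedily accepted when at least `min_center_spacing_mm` from every
#' previously accepted centre. No visual-outcome objective is optimised.
#'
#' @param surface a [retinotopic_surface()].
#' @param n_implants total implant count (split evenly across hemispheres).
#' @param min_center_spacing_mm minimum centre-to-centre distance (default
#'   13 mm, which keeps electrodes of 6 mm grids at least 3.6 mm apart for
#'   any relative orientation).
#' @param require_gyrus restrict candidates to gyral vertices (default
#'   TRUE; automatically relaxed on fold-free surfaces that have no gyri).
#' @return Integer vector of grayordinate ids, length `n_implants`.
#' @export
suggest_implant_sites <- function(surface, n_implants,
                                  min_center_spacing_mm = 13,
                                  require_gyrus = TRUE) {
  g <- surface$grayordinates
  per_hemi <- ceiling(n_implants / 2)
  chosen <- integer(0)
  chosen_pos <- matrix(numeric(0), 0, 3)
  for (hemi in c("left", "right")) {
    cand <- g$roi %in% c("V1", "V2") & g$hemisphere == hemi
    if (require_gyrus && any(cand & g$is_gyrus)) cand <- cand & g$is_gyrus
    idx <- which(cand)
    if (!length(idx)) next
    pos <- as.matrix(g[idx, c("x_mm", "y_mm", "z_mm")])
    ctr <- colMeans(pos)
    ord <- idx[order(cross_dist(pos, matrix(ctr, nrow = 1))[, 1])]
    taken <- 0L
    for (i in ord) {
      if (taken >= per_hemi || length(chosen) >= n_implants) break
      p <- as.numeric(g[i, c("x_mm", "y_mm", "z_mm")])
      if (nrow(chosen_pos) == 0 ||
          min(cross_dist(chosen_pos, matrix(p, nrow = 1))) >= min_center_spacing_mm) {
        chosen <- c(chosen, g$id[i])
        chosen_pos <- rbind(chosen_pos, p)
        taken <- taken + 1L
      }
    }
  }
  if (length(chosen) < n_implants)
    stopf("could only place %d of %d implants at %g mm spacing; use a larger surface",
          length(chosen), n_implants, min_center_spacing_mm)
  chosen[seq_len(n_implants)]
}

#' Run the full simulation pipeline
#'
#' Chains every stage: synthetic surface generation (or a supplied
#' surface), implant placement with constraint validation, phosphene-map
#' derivation, matched control-map generation, stimulus rendering through
#' the retinotopic, control and cluster-relocated conditions, and map
#' metrics. Deterministic for a fixed config seed. If `config$out_dir` is
#' set, artifacts (map CSV/JSON, rendered PNGs, metrics JSON, constraint
#' report, config echo) are written there.
#'
#' @param config a [run_config()].
#' @param surface optional pre-built [retinotopic_surface()]; by default a
#'   synthetic surface is generated from `config$surface` and
#'   `config$seed`.
#' @return Invisibly, a list bundle: `surface`, `implants`, `report`,
#'   `map`, `control_map`, `stimulus`, `frames` (named list of
#'   `rendered_frame`s), `metrics` (named list), `config`.
#' @export
run_pipeline <- function(config = run_config(), surface = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- as.integer(config$seed)
  if (is.null(surface)) {
    sp <- config$surface
    surface <- generate_synthetic_surface(
      n_per_hemi = sp$n_per_hemi, ecc_range = sp$ecc_range,
      fold_amplitude = sp$fold_amplitude, fold_wavelength = sp$fold_wavelength,
      size_slope = sp$size_slope, size_intercept = sp$size_intercept,
      size_noise_sd = sp$size_noise_sd, seed = seed)
  }
  pl <- config$placement
  centers <- suggest_implant_sites(surface, config$n_implants,
                                   min_center_spacing_mm = pl$min_center_spacing_mm)
  implants <- lapply(centers, function(cv)
    place_implant(surface, cv, rotation_deg = pl$rotation_deg))
  allow_overlap <- pl$allow_overlap %||% (config$n_implants >= 12)
  report <- validate_placement(implants, surface, c(
    pl[c("max_rotation_deg", "max_coil_distance_mm", "min_separation_mm")],
    list(allow_overlap = allow_overlap)))

  params <- do.call(size_model_params, config$model)
  rd <- config$rendering
  map <- derive_phosphene_map(surface, implants, params = params, k = rd$k,
                              px_per_deg = rd$px_per_deg, canvas = rd$canvas)
  fit <- fit_ecc_size(surface)
  field_radius <- stats::quantile(
    sqrt(map$phosphenes$x_deg^2 + map$phosphenes$y_deg^2), 0.95, names = FALSE)
  control <- generate_control_map(nrow(map$phosphenes), fit, field_radius,
                                  seed = seed, params = params,
                                  px_per_deg = rd$px_per_deg, canvas = rd$canvas)

  st <- config$stimulus
  stim <- make_tumbling_E(st$logmar, st$orientation,
                          px_per_deg = rd$px_per_deg, canvas = rd$canvas)
  cl <- config$clustering
  stim_reloc <- relocate_stimulus(map, stim, eps_px = cl$eps_px,
                                  min_pts = cl$min_pts)
  frames <- list(
    retinotopic = render_phosphenes(map, skeleton_sample(stim, map)),
    control = render_phosphenes(control, skeleton_sample(stim, control)),
    clustered = render_phosphenes(map, skeleton_sample(stim_reloc, map)))

  mb <- config$metrics
  metrics <- list()
  for (nm in c("retinotopic", "control")) {
    m <- if (nm == "retinotopic") map else control
    cx <- map_complexity(m, n_bins = mb$n_bins)
    ar <- map_area(m)
    metrics[[nm]] <- list(
      complexity = unclass(cx)[c("distance_entropy", "angle_entropy",
                                 "smoothness", "combined")],
      area_deg2 = ar$area,
      mi_bits = mutual_information(stim, frames[[nm]], n_bins = mb$mi_bins)$mi,
      n_phosphenes = nrow(m$phosphenes))
  }

  bundle <- list(surface = surface, implants = implants, report = report,
                 map = map, control_map = control, stimulus = stim,
                 stimulus_relocated = stim_reloc, frames = frames,
                 metrics = metrics, config = config)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

# Write pipeline artifacts to a run directory.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(out_dir, ...)
  write_run_config(bundle$config, f("config.json"))
  write_retinotopy_table(bundle$surface, f("surface.csv"))
  write_phosphene_map(bundle$map, f("map_retinotopic.csv"))
  write_phosphene_map(bundle$control_map, f("map_control.csv"))
  write_constraint_report(bundle$report, f("constraints.json"))
  write_stimulus_png(bundle$stimulus, f("stimulus.png"))
  for (nm in names(bundle$frames))
    write_stimulus_png(bundle$frames[[nm]]$image, f(paste0("frame_", nm, ".png")))
  jsonlite::write_json(bundle$metrics, f("metrics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
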