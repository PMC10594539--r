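#' Phosphene maps
#'
#' A `phosphene_map` holds simulated phosphenes in visual-field coordinates:
#' position (deg, x positive rightward, y positive upward), radius (deg) and
#' the source electrode, plus the pixel geometry used for rendering
#' (`px_per_deg`, canvas size). `kind` distinguishes brain-derived
#' retinotopic maps from spatially even control maps.
#'
#' @param phosphenes data.frame with columns `x_deg`, `y_deg`, `radius_deg`,
#'   `implant`, `electrode`.
#' @param kind "retinotopic" or "control".
#' @param px_per_deg pixels per degree of visual field (default 40).
#' @param canvas integer length 2, canvas (width, height) in pixels.
#' @param meta optional named list of provenance metadata.
#' @return An object of class `phosphene_map`.
#' @export
phosphene_map <- function(phosphenes, kind = c("retinotopic", "control"),
                          px_per_deg = 40, canvas = c(1080, 1080),
                          meta = list()) {
  kind <- match.arg(kind)
  req <- c("x_deg", "y_deg", "radius_deg", "implant", "electrode")
  missing <- setdiff(req, names(phosphenes))
  if (length(missing))
    stopf("phosphene table missing column(s): %s", paste(missing, collapse = ", "))
  if (any(phosphenes$radius_deg <= 0)) stopf("phosphene radii must be > 0")
  structure(list(phosphenes = as.data.frame(phosphenes)[req],
                 kind = kind,
                 px_per_deg = px_per_deg,
                 canvas = as.integer(canvas),
                 meta = meta),
            class = "phosphene_map")
}

#' @export
print.phosphene_map <- function(x, ...) {
  p <- x$phosphenes
  cat(sprintf("Phosphene map (%s): %d phosphenes, %d implant(s)\n",
              x$kind, nrow(p), length(unique(p$implant))))
  cat(sprintf("  radius %.3f-%.3f deg; canvas %dx%d px at %g px/deg\n",
              min(p$radius_deg), max(p$radius_deg),
              x$canvas[1], x$canvas[2], x$px_per_deg))
  invisible(x)
}

# Phosphene centres in pixel coordinates (col = x, row = y downwards).
map_to_px <- function(map) {
  cx <- (map$canvas[1] + 1) / 2
  cy <- (map$canvas[2] + 1) / 2
  cbind(col = cx + map$phosphenes$x_deg * map$px_per_deg,
        row = cy - map$phosphenes$y_deg * map$px_per_deg)
}

#' Project an electrode into the visual field
#'
#' Finds the `k` nearest grayordinates to the electrode (3D Euclidean
#' distance, an approximation to geodesic cortical distance) and returns the
#' inverse-distance-weighted (weights 1/d) average of their visual-field
#' positions and pRF sizes. Polar coordinates are converted to Cartesian
#' before averaging. If the electrode coincides with a grayordinate (within
#' 1e-9 mm) that grayordinate's values are returned exactly.
#'
#' @param surface a [retinotopic_surface()].
#' @param electrode_pos numeric length 3, electrode position in mm.
#' @param k number of neighbours (default 50).
#' @return Named numeric vector `c(x_deg, y_deg, prf_size_deg)`.
#' @export
electrode_to_visual_field <- function(surface, electrode_pos, k = 50) {
  g <- surface$grayordinates
  if (k > nrow(g))
    stopf("k = %d exceeds surface size %d", k, nrow(g))
  pos <- as.matrix(g[, c("x_mm", "y_mm", "z_mm")])
  d <- cross_dist(pos, matrix(electrode_pos, nrow = 1))[, 1]
  ord <- order(d)[seq_len(k)]
  xy <- polar_to_xy(g$polar_angle_deg[ord], g$eccentricity_deg[ord])
  if (d[ord[1]] < 1e-9) {
    return(c(x_deg = unname(xy[1, "x"]), y_deg = unname(xy[1, "y"]),
             prf_size_deg = g$prf_size_deg[ord[1]]))
  }
  w <- 1 / d[ord]
  w <- w / sum(w)
  c(x_deg = sum(w * xy[, "x"]),
    y_deg = sum(w * xy[, "y"]),
    prf_size_deg = sum(w * g$prf_size_deg[ord]))
}

#' Derive a retinotopic phosphene map from implants on a surface
#'
#' One phosphene per electrode: each electrode is projected into the visual
#' field by [electrode_to_visual_field()], and its phosphene radius is the
#' interpolated pRF size times the subject-specific pRF-to-phosphene scale
#' ([prf_to_phosphene_scale()] of the clamped eccentricity-size fit of the
#' surface).
#'
#' @param surface a [retinotopic_surface()].
#' @param implants list of [place_implant()] objects.
#' @param params a [size_model_params()].
#' @param k KNN neighbours for the electrode projection (default 50).
#' @param px_per_deg,canvas rendering geometry stored on the map.
#' @return A retinotopic [phosphene_map()] with `43 * n_implants` phosphenes
#'   for the default layout.
#' @export
derive_phosphene_map <- function(surface, implants,
                                 params = size_model_params(), k = 50,
                                 px_per_deg = 40, canvas = c(1080, 1080)) {
  if (inherits(implants, "implant")) implants <- list(implants)
  fit <- fit_ecc_size(surface)
  scale <- prf_to_phosphene_scale(fit, params)
  rows <- list()
  for (ii in seq_along(implants)) {
    ep <- implants[[ii]]$electrode_positions
    vf <- t(apply(ep, 1, function(p) electrode_to_visual_field(surface, p, k)))
    rows[[ii]] <- data.frame(x_deg = vf[, "x_deg"],
                             y_deg = vf[, "y_deg"],
                             radius_deg = vf[, "prf_size_deg"] * scale,
                             implant = ii,
                             electrode = seq_len(nrow(ep)))
  }
  phosphene_map(do.call(rbind, rows), kind = "retinotopic",
                px_per_deg = px_per_deg, canvas = canvas,
                meta = list(subject_id = surface$subject_id,
                            ecc_size_fit = unclass(fit),
                            prf_to_phosphene_scale = scale,
                            k = k,
                            params = unclass(params)))
}

#' Generate a spatially even control phosphene map
#'
#' Control maps emulate the regular maps used by earlier simulation studies:
#' `n` phosphene positions drawn uniformly over a disc of radius
#' `field_radius` centred on fixation, with sizes computed from an average
#' eccentricity-size fit so that cortical magnification is preserved
#' (`radius = (a*ecc + b) * scale(a)`).
#'
#' @param n number of phosphenes (match the paired retinotopic map).
#' @param avg_fit a [linear_fit()] of pRF size vs eccentricity (e.g. the
#'   dataset-average relation).
#' @param field_radius radius of the disc, deg.
#' @param seed RNG seed; fixed seed reproduces the map exactly.
#' @param params a [size_model_params()].
#' @param px_per_deg,canvas rendering geometry stored on the map.
#' @return A control [phosphene_map()].
#' @export
generate_control_map <- function(n, avg_fit, field_radius, seed = 1L,
                                 params = size_model_params(),
                                 px_per_deg = 40, canvas = c(1080, 1080)) {
  stopifnot(n >= 1, field_radius > 0)
  scale <- prf_to_phosphene_scale(avg_fit, params)
  with_seed(seed, {
    ecc <- field_radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    df <- data.frame(x_deg = ecc * cos(th),
                     y_deg = ecc * sin(th),
                     radius_deg = (avg_fit$a * ecc + avg_fit$b) * scale,
                     implant = 0L,
                     electrode = seq_len(n))
    phosphene_map(df, kind = "control", px_per_deg = px_per_deg,
                  canvas = canvas,
                  meta = list(seed = as.integer(seed),
                              field_radius = field_radius,
                              avg_fit = unclass(avg_fit)))
  })
}

#' Read and write phosphene maps
#'
#' CSV holds the per-phosphene table (`x_deg`, `y_deg`, `radius_deg`,
#' `implant`, `electrode`, `kind`); a JSON sidecar (same path with
#' `.json` appended) stores kind, pixel geometry and provenance metadata.
#'
#' @param map a [phosphene_map()].
#' @param path CSV path.
#' @return `read_phosphene_map` returns a [phosphene_map()];
#'   `write_phosphene_map` returns `path` invisibly.
#' @export
write_phosphene_map <- function(map, path) {
  df <- map$phosphenes
  df$kind <- map$kind
  num <- c("x_deg", "y_deg", "radius_deg")
  for (cn in num) df[[cn]] <- sprintf("%.17g", df[[cn]])
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(kind = map$kind, px_per_deg = map$px_per_deg,
                            canvas = map$canvas, meta = map$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phosphene_map
#' @export
read_phosphene_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    phosphene_map(df, kind = js$kind, px_per_deg = js$px_per_deg,
                  canvas = js$canvas, meta = as.list(js$meta))
  } else {
    kind <- if ("kind" %in% names(df)) df$kind[1] else "retinotopic"
    phosphene_map(df, kind = kind)
  }
}
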