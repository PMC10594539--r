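#' Retinotopically mapped cortical surfaces
#'
#' A `retinotopic_surface` bundles a cloud of grayordinates (cortical surface
#' vertices) with their population receptive-field (pRF) estimates: visual
#' field position (polar angle, eccentricity), pRF size (radius in degrees),
#' region-of-interest label (V1, V2 or other), hemisphere and a gyral/sulcal
#' flag. It is the world model every downstream stage (implant placement,
#' phosphene derivation) operates on.
#'
#' @param grayordinates data.frame with columns `id`, `x_mm`, `y_mm`, `z_mm`,
#'   `polar_angle_deg`, `eccentricity_deg`, `prf_size_deg`, `roi`,
#'   `hemisphere`, `is_gyrus`.
#' @param subject_id character label for the surface.
#' @param rng_seed integer seed the surface was generated with, or `NA` for
#'   measured data.
#' @return An object of class `retinotopic_surface`: a list with elements
#'   `grayordinates` (data.frame), `subject_id`, `mean_spacing` (mean
#'   nearest-neighbour 3D distance, mm) and `rng_seed`.
#' @export
retinotopic_surface <- function(grayordinates, subject_id = "synthetic",
                                rng_seed = NA_integer_) {
  required <- c("id", "x_mm", "y_mm", "z_mm", "polar_angle_deg",
                "eccentricity_deg", "prf_size_deg", "roi", "hemisphere",
                "is_gyrus")
  missing <- setdiff(required, names(grayordinates))
  if (length(missing))
    stopf("grayordinate table is missing column(s): %s",
          paste(missing, collapse = ", "))
  g <- grayordinates[, required]
  g$roi <- as.character(g$roi)
  g$hemisphere <- as.character(g$hemisphere)
  g$is_gyrus <- as.logical(g$is_gyrus)
  if (!all(g$roi %in% c("V1", "V2", "other")))
    stopf("roi labels must be one of V1, V2, other")
  if (!all(g$hemisphere %in% c("left", "right")))
    stopf("hemisphere must be left or right")
  num <- c("x_mm", "y_mm", "z_mm", "polar_angle_deg", "eccentricity_deg",
           "prf_size_deg")
  bad <- which(!stats::complete.cases(g[num]) |
                 !apply(is.finite(as.matrix(g[num])), 1, all))
  if (length(bad))
    stopf("non-finite pRF/position values at row id(s): %s",
          paste(g$id[bad], collapse = ", "))
  if (any(g$eccentricity_deg < 0)) stopf("eccentricity must be >= 0")
  if (any(g$prf_size_deg <= 0)) stopf("prf_size must be > 0")
  structure(list(grayordinates = g,
                 subject_id = subject_id,
                 mean_spacing = mean_nn_spacing(as.matrix(g[, c("x_mm", "y_mm", "z_mm")])),
                 rng_seed = rng_seed),
            class = "retinotopic_surface")
}

# Mean nearest-neighbour 3D distance; chunked to bound memory on large clouds.
mean_nn_spacing <- function(pos) {
  n <- nrow(pos)
  if (n < 2) return(NA_real_)
  nn <- numeric(n)
  chunk <- 2000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- cross_dist2(pos[s:e, , drop = FALSE], pos)
    d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
    nn[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  mean(nn)
}

#' @export
print.retinotopic_surface <- function(x, ...) {
  g <- x$grayordinates
  cat(sprintf("Retinotopic surface '%s': %d grayordinates (mean spacing %.2f mm)\n",
              x$subject_id, nrow(g), x$mean_spacing))
  cat("  ROI:", paste(sprintf("%s=%d", names(table(g$roi)), table(g$roi)),
                      collapse = ", "), "\n")
  cat(sprintf("  eccentricity %.2f-%.2f deg, pRF size %.2f-%.2f deg\n",
              min(g$eccentricity_deg), max(g$eccentricity_deg),
              min(g$prf_size_deg), max(g$prf_size_deg)))
  invisible(x)
}

#' Generate a synthetic retinotopically mapped cortical surface
#'
#' Emulates the structure of high-field pRF retinotopy data (grayordinates
#' roughly 2 mm apart carrying pRF position and size) without requiring any
#' download. Each hemisphere is a flat cortical sheet folded by a sinusoidal
#' gyral pattern. Retinotopy follows a complex-log (log-polar) template:
#' cortical distance along the eccentricity axis is `u = k*log(1 + ecc/a0)`
#' and distance along the angular axis is proportional to polar angle, which
#' reproduces cortical magnification (many mm of cortex per foveal degree,
#' few per peripheral degree). V1 occupies the central band of each sheet
#' (bounded by the vertical meridian); V2 is the mirror-reversed annulus
#' adjacent to it, meeting V1 at the vertical meridian and ending at the
#' horizontal meridian, as in real visuotopic maps. pRF size grows linearly
#' with eccentricity plus optional Gaussian noise.
#'
#' The sheet area is scaled so that uniformly sampled grayordinates have a
#' mean nearest-neighbour spacing of about 2 mm regardless of `n_per_hemi`.
#' The left hemisphere maps the right visual hemifield and vice versa.
#' Coordinate frame: x = left-right (the coronal plane is the x-z plane),
#' y = posterior-anterior, z = inferior-superior.
#'
#' @param n_per_hemi number of grayordinates per hemisphere (>= 100).
#' @param ecc_range length-2 numeric, eccentricity span in degrees, within
#'   (0, 90).
#' @param fold_amplitude amplitude of the sinusoidal folding, mm. Gyri are
#'   where the fold displacement is outward (positive); 0 gives a flat sheet
#'   (and no gyri).
#' @param fold_wavelength wavelength of the folding along the
#'   posterior-anterior axis, mm.
#' @param size_slope,size_intercept linear pRF size model:
#'   `prf_size = size_slope * ecc + size_intercept` (deg), both > 0.
#' @param size_noise_sd standard deviation of Gaussian noise added to pRF
#'   size, deg (sizes are floored at 1e-3 deg).
#' @param seed integer RNG seed; fixed seed gives a bit-identical surface.
#' @param subject_id label stored on the surface.
#' @return A [retinotopic_surface()].
#' @examples
#' surf <- generate_synthetic_surface(n_per_hemi = 300, seed = 1)
#' surf
#' @export
generate_synthetic_surface <- function(n_per_hemi = 500,
                                       ecc_range = c(0.5, 30),
                                       fold_amplitude = 2,
                                       fold_wavelength = 20,
                                       size_slope = 0.05,
                                       size_intercept = 0.5,
                                       size_noise_sd = 0.1,
                                       seed = 1L,
                                       subject_id = "synthetic") {
  if (n_per_hemi < 100) stopf("n_per_hemi must be >= 100")
  if (length(ecc_range) != 2 || ecc_range[1] < 0 || ecc_range[2] <= ecc_range[1] ||
      ecc_range[2] > 90 || ecc_range[2] <= 0)
    stopf("ecc_range must be increasing and within (0, 90]")
  if (size_slope <= 0 || size_intercept <= 0)
    stopf("size_slope and size_intercept must be > 0")
  if (fold_wavelength <= 0) stopf("fold_wavelength must be > 0")

  a0 <- 0.75                 # deg; foveal offset of the complex-log template
  target_spacing <- 2        # mm; emulated grayordinate spacing
  # Poisson point process: mean NN distance = 0.5/sqrt(density).
  area <- n_per_hemi * (2 * target_spacing)^2
  U <- sqrt(area / 2)        # eccentricity-axis extent, mm
  H <- 2 * U                 # angular-axis extent, mm (V1 inner half + V2)
  kmag <- U / (log(ecc_range[2] + a0) - log(ecc_range[1] + a0))
  sv <- H / (2 * pi)         # mm of cortex per radian of polar angle

  with_seed(seed, {
    out <- vector("list", 2)
    for (h in 1:2) {
      hemi <- c("left", "right")[h]
      hsign <- if (hemi == "left") -1 else 1      # cortical x side
      field_sign <- -hsign                        # contralateral hemifield
      u <- stats::runif(n_per_hemi, 0, U)
      v <- stats::runif(n_per_hemi, -H / 2, H / 2)
      in_v1 <- abs(v) <= sv * pi / 2
      beta <- ifelse(in_v1, v / sv, sign(v) * (pi - abs(v) / sv))
      ecc <- (ecc_range[1] + a0) * exp(u / kmag) - a0
      ecc <- pmin(pmax(ecc, ecc_range[1]), ecc_range[2])
      x_vf <- field_sign * ecc * cos(beta)
      y_vf <- ecc * sin(beta)
      pol <- xy_to_polar(x_vf, y_vf)
      disp <- fold_amplitude * sin(2 * pi * u / fold_wavelength)
      prf <- size_slope * ecc + size_intercept +
        if (size_noise_sd > 0) stats::rnorm(n_per_hemi, 0, size_noise_sd) else 0
      prf <- pmax(prf, 1e-3)
      out[[h]] <- data.frame(
        x_mm = hsign * (8 + disp),
        y_mm = -80 + u,
        z_mm = v,
        polar_angle_deg = pol[, 1],
        eccentricity_deg = ecc,
        prf_size_deg = prf,
        roi = ifelse(in_v1, "V1", "V2"),
        hemisphere = hemi,
        is_gyrus = disp > 0,
        stringsAsFactors = FALSE)
    }
    g <- rbind(out[[1]], out[[2]])
    g <- cbind(id = seq_len(nrow(g)), g)
    retinotopic_surface(g, subject_id = subject_id, rng_seed = as.integer(seed))
  })
}

#' Read and write retinotopy tables
#'
#' Plain delimited tables (CSV, or TSV for files ending in `.tsv`) with one
#' row per grayordinate and columns `id`, `x_mm`, `y_mm`, `z_mm`,
#' `polar_angle_deg`, `eccentricity_deg`, `prf_size_deg`, `roi`,
#' `hemisphere`, `is_gyrus`. Numeric columns are written with 17 significant
#' digits so write/read round-trips are bit-exact for finite values.
#'
#' @param path file path; `.tsv` selects tab separation, anything else comma.
#' @param surface a [retinotopic_surface()] (for writing).
#' @param subject_id optional label; defaults to the file name.
#' @return `read_retinotopy_table` returns a [retinotopic_surface()];
#'   `write_retinotopy_table` returns `path` invisibly.
#' @export
read_retinotopy_table <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  retinotopic_surface(tab, subject_id = subject_id %||% basename(path))
}

#' @rdname read_retinotopy_table
#' @export
write_retinotopy_table <- function(surface, path) {
  stopifnot(inherits(surface, "retinotopic_surface"))
  g <- surface$grayordinates
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  num <- c("x_mm", "y_mm", "z_mm", "polar_angle_deg", "eccentricity_deg",
           "prf_size_deg")
  out <- g
  for (cn in num) out[[cn]] <- sprintf("%.17g", g[[cn]])
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
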