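#' Stimulus images
#'
#' A `pv_stimulus` is a grayscale image in [0,1] at a physical scale
#' (`px_per_deg`), with optotype metadata where applicable. Images are
#' matrices indexed [row, col] with row 1 at the top.
#'
#' @param image numeric matrix in [0,1].
#' @param px_per_deg pixels per degree.
#' @param kind "tumbling_E", "grating" or "object".
#' @param logmar LogMAR level or `NA`.
#' @param orientation optotype orientation or `NA`.
#' @param centre_px numeric length 2 `(row, col)` stimulus centre.
#' @return An object of class `pv_stimulus`.
#' @export
pv_stimulus <- function(image, px_per_deg, kind = "object", logmar = NA_real_,
                        orientation = NA_character_, centre_px = NULL) {
  image <- as.matrix(image)
  if (any(image < -1e-12 | image > 1 + 1e-12)) stopf("image values must be in [0,1]")
  image[] <- pmin(pmax(image, 0), 1)
  if (px_per_deg <= 0) stopf("px_per_deg must be > 0")
  centre_px <- centre_px %||% c((nrow(image) + 1) / 2, (ncol(image) + 1) / 2)
  structure(list(image = image, px_per_deg = px_per_deg, kind = kind,
                 logmar = logmar, orientation = orientation,
                 centre_px = centre_px),
            class = "pv_stimulus")
}

#' @export
print.pv_stimulus <- function(x, ...) {
  cat(sprintf("Stimulus (%s): %dx%d px at %g px/deg", x$kind,
              nrow(x$image), ncol(x$image), x$px_per_deg))
  if (is.finite(x$logmar)) cat(sprintf(", %.1f LogMAR, %s", x$logmar, x$orientation))
  cat("\n")
  invisible(x)
}

# rotate a matrix 90 deg counter-clockwise n times
rot90 <- function(m, n = 1) {
  n <- n %% 4
  for (i in seq_len(n)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

# Place a small matrix at the centre of a canvas.
centre_on_canvas <- function(m, canvas) {
  out <- matrix(0, canvas[2], canvas[1])   # canvas = (width, height)
  r0 <- floor((nrow(out) - nrow(m)) / 2)
  c0 <- floor((ncol(out) - ncol(m)) / 2)
  out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  out
}

#' Generate a tumbling-E optotype
#'
#' Standard 5x5 construction: the letter is 5 MAR tall where
#' `MAR = 10^logmar` arc-minutes, with stroke width one fifth of the letter
#' height. The base orientation "right" has the vertical spine on the left
#' and three arms pointing right; "up"/"left"/"down" are 90-degree
#' rotations. The binary letter is centred on the canvas.
#'
#' @param logmar acuity level (single tumbling E ladder runs 0.8-2.6 in 0.2
#'   steps; other values are allowed for validation blocks).
#' @param orientation "up", "down", "left" or "right" (arm direction).
#' @param px_per_deg pixels per degree.
#' @param canvas integer length 2 `(width, height)` in px.
#' @return A binary [pv_stimulus()].
#' @export
make_tumbling_E <- function(logmar, orientation = c("right", "up", "left", "down"),
                            px_per_deg = 40, canvas = c(1080, 1080)) {
  orientation <- match.arg(orientation)
  mar_arcmin <- 10^logmar
  h <- round(5 * mar_arcmin / 60 * px_per_deg)
  if (h < 5)
    stopf("letter height %d px is below 5 px; increase px_per_deg", h)
  if (h > min(canvas)) stopf("letter (%d px) exceeds canvas", h)
  # 5 equal bands; band 1 = spine column, rows 1,3,5 = arms
  edges <- round(seq(0, h, length.out = 6))
  band <- function(i) (edges[i] + 1):edges[i + 1]
  m <- matrix(0, h, h)
  m[, band(1)] <- 1                       # spine (left column)
  m[c(band(1), band(3), band(5)), ] <- 1  # three arms
  m <- switch(orientation,
              right = m,
              up = rot90(m, 3),
              left = rot90(m, 2),
              down = rot90(m, 1))
  pv_stimulus(centre_on_canvas(m, canvas), px_per_deg, kind = "tumbling_E",
              logmar = logmar, orientation = orientation)
}

#' Generate a square-wave grating patch
#'
#' Bars of width `MAR = 10^logmar` arc-minutes at 50% duty cycle inside a
#' circular patch (binary image, background 0).
#'
#' @param logmar acuity level (grating ladder: 2.3, 2.5, 2.7, 2.9).
#' @param orientation "vertical" (vertical bars) or "horizontal".
#' @param px_per_deg pixels per degree.
#' @param patch_diameter_deg diameter of the circular patch, deg.
#' @param canvas integer length 2 `(width, height)` in px.
#' @return A binary [pv_stimulus()].
#' @export
make_grating <- function(logmar, orientation = c("vertical", "horizontal"),
                         px_per_deg = 40, patch_diameter_deg = 13.5,
                         canvas = c(1080, 1080)) {
  orientation <- match.arg(orientation)
  bar_px <- 10^logmar / 60 * px_per_deg
  if (bar_px < 1) stopf("bar width below 1 px; increase px_per_deg")
  w <- canvas[1]; h <- canvas[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  rows <- matrix(seq_len(h), h, w)
  coord <- if (orientation == "vertical") cols - cx else rows - cy
  img <- (floor(coord / bar_px) %% 2 == 0) * 1
  rad_px <- patch_diameter_deg / 2 * px_per_deg
  img[(cols - cx)^2 + (rows - cy)^2 > rad_px^2] <- 0
  pv_stimulus(img, px_per_deg, kind = "grating", logmar = logmar,
              orientation = orientation)
}

#' Generate a synthetic object silhouette
#'
#' Draws one of five parameterised clothing/accessory silhouettes (top,
#' trousers, dress, sneaker, bag) as a filled polygon on a square canvas,
#' emulating the object classes of common grayscale object-recognition sets.
#' These are synthetic stand-ins generated in code, not real photographs.
#'
#' @param class one of "top", "trousers", "dress", "sneaker", "bag".
#' @param size_px canvas side length in px (default 540).
#' @param px_per_deg pixels per degree.
#' @return A binary [pv_stimulus()] of kind "object".
#' @export
make_object_silhouette <- function(class = c("top", "trousers", "dress",
                                             "sneaker", "bag"),
                                   size_px = 540, px_per_deg = 40) {
  class <- match.arg(class)
  # polygons in unit coordinates, (x right, y up), origin bottom-left
  poly <- switch(class,
    top = cbind(x = c(.30, .42, .58, .70, .92, .80, .74, .74, .26, .26, .20, .08),
                y = c(.88, .82, .82, .88, .70, .56, .62, .12, .12, .62, .56, .70)),
    trousers = cbind(x = c(.30, .70, .72, .56, .50, .44, .28),
                     y = c(.92, .92, .08, .08, .62, .08, .08)),
    dress = cbind(x = c(.36, .46, .54, .64, .60, .82, .18, .40),
                  y = c(.92, .84, .84, .92, .62, .08, .08, .62)),
    sneaker = cbind(x = c(.10, .42, .58, .88, .92, .90, .10),
                    y = c(.62, .60, .44, .36, .26, .16, .16)),
    bag = cbind(x = c(.20, .80, .84, .16, .38, .38, .62, .62, .42, .42, .58, .58),
                y = c(.62, .62, .14, .14, .62, .80, .80, .62, .62, .74, .74, .62)))
  g <- seq(0.5 / size_px, 1 - 0.5 / size_px, length.out = size_px)
  img <- matrix(0, size_px, size_px)
  img[] <- point_in_polygon(
    rep(g, each = size_px),                # x varies over columns
    rep(rev(g), times = size_px),          # row 1 = top (y high)
    poly[, 1], poly[, 2]) * 1
  pv_stimulus(img, px_per_deg, kind = "object", orientation = class)
}

# Even-odd crossing test, vectorised over query points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Translate a stimulus image on its canvas
#'
#' Integer pixel shift with zero fill; the stored centre moves with the
#' image.
#'
#' @param stim a [pv_stimulus()].
#' @param shift_rc integer length 2 `(rows down, cols right)`.
#' @return The shifted [pv_stimulus()].
#' @export
translate_stimulus <- function(stim, shift_rc) {
  sr <- as.integer(round(shift_rc[1])); sc <- as.integer(round(shift_rc[2]))
  img <- stim$image
  out <- matrix(0, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - sr
  src_c <- seq_len(ncol(img)) - sc
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  stim$image <- out
  stim$centre_px <- stim$centre_px + c(sr, sc)
  stim
}

#' Write/read a grayscale stimulus or frame as PNG with a JSON sidecar
#'
#' @param x a [pv_stimulus()] or a plain matrix in [0,1].
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(x, path) {
  img <- if (inherits(x, "pv_stimulus")) x$image else as.matrix(x)
  png::writePNG(img, path)
  if (inherits(x, "pv_stimulus")) {
    jsonlite::write_json(list(px_per_deg = x$px_per_deg, kind = x$kind,
                              logmar = x$logmar, orientation = x$orientation,
                              centre_px = x$centre_px),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_stimulus_png
#' @export
read_stimulus_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    pv_stimulus(img, px_per_deg = js$px_per_deg, kind = js$kind,
                logmar = js$logmar %||% NA_real_,
                orientation = js$orientation %||% NA_character_,
                centre_px = js$centre_px)
  } else {
    pv_stimulus(img, px_per_deg = 40)
  }
}
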