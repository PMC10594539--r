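#' Skeletonize a binary image to 1-pixel-wide strokes
#'
#' Zhang-Suen iterative thinning: repeatedly peels boundary pixels that do
#' not break 8-connectivity until no change, leaving an 8-connected medial
#' axis one pixel wide. Used to reduce optotype strokes to sampling paths.
#'
#' @param img numeric or logical matrix; foreground is `> 0.5`.
#' @return Logical matrix of the same size, TRUE on the skeleton.
#' @export
skeletonize <- function(img) {
  m <- as.matrix(img) > 0.5
  if (!any(m)) return(m)
  # crop to bounding box (plus 1 px pad) for speed, restore at the end
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  sub <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  p <- matrix(FALSE, nrow(sub) + 2, ncol(sub) + 2)
  p[2:(nrow(sub) + 1), 2:(ncol(sub) + 1)] <- sub
  nr <- nrow(p); nc <- ncol(p)
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    r <- seq_len(nr) - dr; c <- seq_len(nc) - dc
    okr <- r >= 1 & r <= nr; okc <- c >= 1 & c <= nc
    out[which(okr), which(okc)] <- x[r[okr], c[okc]]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north
      p2 <- shift(p, 1, 0);  p3 <- shift(p, 1, -1); p4 <- shift(p, 0, -1)
      p5 <- shift(p, -1, -1); p6 <- shift(p, -1, 0); p7 <- shift(p, -1, 1)
      p8 <- shift(p, 0, 1);  p9 <- shift(p, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- p & b >= 2 & b <= 6 & a == 1
      if (step == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { p[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[rr[1]:rr[2], cc[1]:cc[2]] <- p[2:(nr - 1), 2:(nc - 1)]
  out
}

#' Select active phosphenes by skeleton sampling
#'
#' The presentation rule for thin optotypes: the stimulus stroke is thinned
#' to one pixel width and, for every skeleton pixel, the nearest phosphene
#' (Euclidean distance in pixel coordinates; ties broken by lowest phosphene
#' index) is switched on. A phosphene lights at its own visual-field
#' location, not at the stimulus pixel.
#'
#' @param stim a binary [pv_stimulus()] on the same canvas as `map`.
#' @param map a [phosphene_map()].
#' @return Sorted integer vector of active phosphene indices (empty for a
#'   blank stimulus).
#' @export
skeleton_sample <- function(stim, map) {
  if (nrow(map$phosphenes) == 0) stopf("empty phosphene map")
  skel <- skeletonize(stim$image)
  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) == 0) return(integer(0))
  centers <- map_to_px(map)                      # (col, row)
  pts <- cbind(idx[, "col"], idx[, "row"])
  d2 <- cross_dist2(pts, centers[, c("col", "row"), drop = FALSE])
  nearest <- apply(d2, 1, which.min)             # which.min takes lowest index on ties
  sort(unique(nearest))
}

#' Select active phosphenes by direct masking
#'
#' The presentation rule for area stimuli (gratings, objects): a phosphene
#' is active iff the stimulus intensity at its centre pixel exceeds
#' `threshold`. Phosphenes whose centres fall off the canvas are inactive
#' and counted in the `clipped` attribute.
#'
#' @param stim a [pv_stimulus()] on the same canvas as `map`.
#' @param map a [phosphene_map()].
#' @param threshold intensity threshold on [0,1] images (default 0.5).
#' @return Sorted integer vector of active phosphene indices, with attribute
#'   `clipped` giving the number of off-canvas phosphenes.
#' @export
direct_mask <- function(stim, map, threshold = 0.5) {
  if (nrow(map$phosphenes) == 0) stopf("empty phosphene map")
  centers <- map_to_px(map)
  r <- round(centers[, "row"]); c <- round(centers[, "col"])
  on_canvas <- r >= 1 & r <= nrow(stim$image) & c >= 1 & c <= ncol(stim$image)
  active <- logical(nrow(centers))
  active[on_canvas] <- stim$image[cbind(r[on_canvas], c[on_canvas])] > threshold
  structure(which(active), clipped = sum(!on_canvas))
}

#' Render phosphenes to an image
#'
#' Each active phosphene contributes a 2D isotropic Gaussian centred at its
#' visual-field position, with peak equal to its intensity (default 1) and
#' sigma equal to one third of the phosphene radius. Contributions are
#' summed pixel-wise and capped at 1.
#'
#' @param map a [phosphene_map()].
#' @param active integer indices of active phosphenes (default: all).
#' @param intensities optional per-active-phosphene peak values in [0,1].
#' @return An object of class `rendered_frame`: list with `image` (matrix in
#'   [0,1], canvas-sized) and `active_phosphenes`.
#' @export
render_phosphenes <- function(map, active = seq_len(nrow(map$phosphenes)),
                              intensities = NULL) {
  p <- map$phosphenes
  stopifnot(all(active %in% seq_len(nrow(p))))
  intensities <- intensities %||% rep(1, length(active))
  stopifnot(length(intensities) == length(active),
            all(intensities >= 0 & intensities <= 1))
  w <- map$canvas[1]; h <- map$canvas[2]
  img <- matrix(0, h, w)
  centers <- map_to_px(map)
  sig <- p$radius_deg * map$px_per_deg / 3
  for (j in seq_along(active)) {
    i <- active[j]
    s <- sig[i]
    half <- ceiling(4 * s)
    c0 <- centers[i, "col"]; r0 <- centers[i, "row"]
    cs <- max(1, floor(c0 - half)):min(w, ceiling(c0 + half))
    rs <- max(1, floor(r0 - half)):min(h, ceiling(r0 + half))
    if (!length(cs) || !length(rs) || cs[1] > w || rs[1] > h) next
    gx <- exp(-(cs - c0)^2 / (2 * s^2))
    gy <- exp(-(rs - r0)^2 / (2 * s^2))
    img[rs, cs] <- img[rs, cs] + intensities[j] * outer(gy, gx)
  }
  structure(list(image = pmin(img, 1), active_phosphenes = sort(active)),
            class = "rendered_frame")
}

#' @export
print.rendered_frame <- function(x, ...) {
  cat(sprintf("Rendered frame: %dx%d px, %d active phosphene(s), max %.3f\n",
              nrow(x$image), ncol(x$image), length(x$active_phosphenes),
              max(x$image)))
  invisible(x)
}
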