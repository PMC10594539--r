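#' Electrode array layouts
#'
#' Default layout modelled on an intracortical tile with 43 electrodes at
#' 1 mm pitch: a 7x7 grid with the four corner pads and the two
#' horizontal-mid-edge pads removed (49 - 6 = 43). The published hardware
#' does not print its pad geometry, so the layout is fully configurable:
#' supply any matrix of in-plane offsets.
#'
#' @param offsets n x 2 matrix of electrode offsets in the array plane, mm.
#'   Column 1 runs along the array's long axis, column 2 along its short
#'   axis.
#' @param pitch nominal minimum inter-electrode distance, mm.
#' @param footprint numeric length 2, physical (long-axis extent, short-axis
#'   extent) of the array body in mm; used for overlap quantification.
#' @return An object of class `array_layout`.
#' @export
array_layout <- function(offsets, pitch = 1, footprint = c(9, 9)) {
  offsets <- as.matrix(offsets)
  stopifnot(ncol(offsets) == 2, nrow(offsets) >= 1, all(is.finite(offsets)),
            pitch > 0, length(footprint) == 2, all(footprint > 0))
  structure(list(electrode_offsets = offsets,
                 n_electrodes = nrow(offsets),
                 pitch = pitch,
                 footprint = as.numeric(footprint)),
            class = "array_layout")
}

#' @rdname array_layout
#' @export
gennaris_layout <- function() {
  grid <- expand.grid(x = -3:3, y = -3:3)
  drop <- (abs(grid$x) == 3 & abs(grid$y) == 3) |     # 4 corners
    (abs(grid$x) == 3 & grid$y == 0)                  # 2 mid-edge pads
  array_layout(as.matrix(grid[!drop, c("x", "y")]), pitch = 1,
               footprint = c(9, 9))
}

# Least-squares tangent plane at a surface point: centroid + first two
# principal axes of the K nearest grayordinates. Returns orthonormal frame
# (e1 in the coronal x-z plane, e2 = n x e1, n outward normal).
tangent_frame <- function(surface, center_vertex, k = 20,
                          max_radius_mm = 20) {
  g <- surface$grayordinates
  row <- match(center_vertex, g$id)
  if (is.na(row)) stopf("center_vertex %s not found on surface", center_vertex)
  pos <- as.matrix(g[, c("x_mm", "y_mm", "z_mm")])
  d <- cross_dist(pos, pos[row, , drop = FALSE])[, 1]
  near <- which(d <= max_radius_mm)
  if (length(near) < k)
    stopf("degenerate surface: only %d grayordinates within %g mm of vertex %s (need %d)",
          length(near), max_radius_mm, center_vertex, k)
  nb <- pos[near[order(d[near])][seq_len(k)], , drop = FALSE]
  ctr <- colMeans(nb)
  sv <- svd(sweep(nb, 2, ctr))
  n <- sv$v[, 3]
  # orient outward: away from the interhemispheric plane (x = 0)
  hsign <- if (g$hemisphere[row] == "left") -1 else 1
  if (abs(n[1]) > 1e-9) {
    if (sign(n[1]) != hsign) n <- -n
  } else if (abs(n[3]) > 1e-9) {       # lateral component absent: prefer superior
    if (n[3] < 0) n <- -n
  } else if (n[2] < 0) n <- -n

  ey <- c(0, 1, 0)
  e1 <- cross3(n, ey)
  if (vnorm(e1) < 1e-8) e1 <- cross3(n, c(0, 0, 1))  # normal along y: fall back
  e1 <- unit(e1)
  e2 <- cross3(n, e1)
  list(center = pos[row, ], normal = n, e1 = e1, e2 = e2,
       hemisphere = g$hemisphere[row])
}

#' Pose an electrode array on the cortical surface
#'
#' Places the array centre at a chosen grayordinate and embeds the layout's
#' 2D offsets in the local tangent plane, estimated by least squares from
#' the `k_neighbours` nearest grayordinates. `rotation_deg` rotates the
#' array about the surface normal; by construction the long axis at
#' rotation 0 lies in the coronal (x-z) plane, so for a cortical sheet whose
#' normal is perpendicular to the posterior-anterior axis the parameter is
#' exactly the array's angle relative to the coronal plane.
#'
#' @param surface a [retinotopic_surface()].
#' @param center_vertex grayordinate id used as the implantation centre.
#' @param rotation_deg signed in-plane rotation of the long axis, degrees.
#' @param layout an [array_layout()]; default [gennaris_layout()].
#' @param k_neighbours neighbours used for the tangent-plane fit.
#' @return An object of class `implant`: layout, centre, rotation, the local
#'   orthonormal frame, and `electrode_positions` (n x 3 matrix, mm).
#' @export
place_implant <- function(surface, center_vertex, rotation_deg = 0,
                          layout = gennaris_layout(), k_neighbours = 20) {
  stopifnot(is.finite(rotation_deg))
  fr <- tangent_frame(surface, center_vertex, k = k_neighbours)
  th <- deg2rad(rotation_deg)
  off <- layout$electrode_offsets
  a <- off[, 1] * cos(th) - off[, 2] * sin(th)
  b <- off[, 1] * sin(th) + off[, 2] * cos(th)
  pos <- matrix(fr$center, nrow = nrow(off), ncol = 3, byrow = TRUE) +
    outer(a, fr$e1) + outer(b, fr$e2)
  axis_long <- cos(th) * fr$e1 + sin(th) * fr$e2
  axis_short <- -sin(th) * fr$e1 + cos(th) * fr$e2
  structure(list(layout = layout,
                 center_vertex = center_vertex,
                 rotation_deg = rotation_deg,
                 center = fr$center,
                 normal = fr$normal,
                 axis_long = axis_long,
                 axis_short = axis_short,
                 electrode_positions = pos,
                 hemisphere = fr$hemisphere),
            class = "implant")
}

#' @export
print.implant <- function(x, ...) {
  cat(sprintf("Implant at vertex %s (%s hemisphere), rotation %.1f deg, %d electrodes\n",
              x$center_vertex, x$hemisphere, x$rotation_deg,
              x$layout$n_electrodes))
  invisible(x)
}

#' Maximum overlap distance between two implant footprints
#'
#' Quantifies how far two neighbouring arrays' bodies overlap: both footprint
#' rectangles are projected into the plane midway between the implants
#' (normal = mean of the two surface normals), and the overlap is the mutual
#' extent by which the rectangles interpenetrate measured along the arrays'
#' short axes (the direction perpendicular to the long edges), provided
#' their long-axis extents also overlap. For identical poses this is the
#' footprint short-side length; for disjoint footprints it is 0. Symmetric.
#'
#' @param a,b posed [place_implant()] objects.
#' @return Overlap distance in mm (0 if disjoint).
#' @export
overlap_distance <- function(a, b) {
  n <- unit(a$normal + b$normal)
  origin <- (a$center + b$center) / 2
  # 2D basis of the mid-plane
  u <- cross3(n, c(0, 1, 0))
  if (vnorm(u) < 1e-8) u <- cross3(n, c(0, 0, 1))
  u <- unit(u); v <- cross3(n, u)
  proj <- function(p) c(sum((p - origin) * u), sum((p - origin) * v))
  corners <- function(im) {
    w <- im$layout$footprint[1] / 2; h <- im$layout$footprint[2] / 2
    sgn <- rbind(c(1, 1), c(1, -1), c(-1, -1), c(-1, 1))
    t(apply(sgn, 1, function(s)
      proj(im$center + s[1] * w * im$axis_long + s[2] * h * im$axis_short)))
  }
  ca <- corners(a); cb <- corners(b)
  pen <- function(cs, other) {
    # axes of this rectangle in the plane
    al <- unit(cs[1, ] - cs[4, ])            # long axis direction
    as_ <- unit(cs[1, ] - cs[2, ])           # short axis direction
    iv <- function(pts, ax) range(pts %*% ax)
    ol <- min(iv(cs, al)[2], iv(other, al)[2]) - max(iv(cs, al)[1], iv(other, al)[1])
    os <- min(iv(cs, as_)[2], iv(other, as_)[2]) - max(iv(cs, as_)[1], iv(other, as_)[1])
    if (ol <= 0 || os <= 0) 0 else os
  }
  max(0, min(pen(ca, cb), pen(cb, ca)))
}

# Minimum electrode-to-electrode distance between two implants.
implant_separation <- function(a, b) {
  min(cross_dist(a$electrode_positions, b$electrode_positions))
}

#' Validate anatomical and hardware constraints of an implant configuration
#'
#' Checks the constraints applied when planning cortical implant sites:
#' rotation limited to +/-45 degrees relative to the coronal plane, implant
#' centres within 20 mm of the inductive coil centroid, arrays separated by
#' at least 3.6 mm (electrode-to-electrode), most electrodes over V1/V2, and
#' centres on gyri. For dense configurations (`allow_overlap = TRUE`, the
#' 12-implant regime) separation violations are downgraded to warnings while
#' pairwise overlap distances are still quantified.
#'
#' @param implants list of [place_implant()] objects (>= 1).
#' @param surface the [retinotopic_surface()] the implants sit on.
#' @param constraints list; recognised fields `max_rotation_deg` (45),
#'   `max_coil_distance_mm` (20), `min_separation_mm` (3.6), `coil_centroid`
#'   (3D point; default the centroid of implant centres), `allow_overlap`
#'   (FALSE), `min_v1v2_fraction` (0.9).
#' @return An object of class `constraint_report` with boolean fields
#'   `rotation_ok`, `coil_ok`, `separation_ok`, `region_ok`, `gyrus_ok`, the
#'   pairwise `separation_mm` matrix, a list of positive pairwise
#'   `overlaps_mm`, the electrode `v1v2_fraction`, and any `warnings`.
#' @export
validate_placement <- function(implants, surface, constraints = list()) {
  if (inherits(implants, "implant")) implants <- list(implants)
  stopifnot(length(implants) >= 1)
  cfg <- utils::modifyList(list(max_rotation_deg = 45,
                                max_coil_distance_mm = 20,
                                min_separation_mm = 3.6,
                                coil_centroid = NULL,
                                allow_overlap = FALSE,
                                min_v1v2_fraction = 0.9), constraints)
  g <- surface$grayordinates
  pos <- as.matrix(g[, c("x_mm", "y_mm", "z_mm")])
  n <- length(implants)
  warnings <- character()

  tol <- 1e-9   # boundary-inclusive comparisons robust to roundoff
  rotation_ok <- all(vapply(implants, function(i)
    abs(i$rotation_deg) <= cfg$max_rotation_deg + tol, logical(1)))

  centers <- t(vapply(implants, function(i) i$center, numeric(3)))
  coil <- cfg$coil_centroid %||% colMeans(centers)
  coil_ok <- all(cross_dist(centers, matrix(coil, nrow = 1)) <=
                   cfg$max_coil_distance_mm + tol)

  sep <- matrix(0, n, n)
  overlaps <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      sep[i, j] <- sep[j, i] <- implant_separation(implants[[i]], implants[[j]])
      ov <- overlap_distance(implants[[i]], implants[[j]])
      if (ov > 0)
        overlaps[[length(overlaps) + 1]] <-
          list(pair = c(i, j), overlap_mm = ov)
    }
  }
  offdiag <- sep[upper.tri(sep)]
  sep_violation <- length(offdiag) > 0 &&
    any(offdiag < cfg$min_separation_mm - tol)
  if (sep_violation && cfg$allow_overlap) {
    warnings <- c(warnings, sprintf(
      "separation below %.1f mm for %d pair(s); allowed in dense configuration",
      cfg$min_separation_mm, sum(offdiag < cfg$min_separation_mm)))
    separation_ok <- TRUE
  } else {
    separation_ok <- !sep_violation
  }

  elec <- do.call(rbind, lapply(implants, function(i) i$electrode_positions))
  nearest <- apply(cross_dist2(elec, pos), 1, which.min)
  v1v2_fraction <- mean(g$roi[nearest] %in% c("V1", "V2"))
  region_ok <- v1v2_fraction >= cfg$min_v1v2_fraction

  gyrus_ok <- all(vapply(implants, function(i)
    isTRUE(g$is_gyrus[match(i$center_vertex, g$id)]), logical(1)))

  structure(list(rotation_ok = rotation_ok,
                 coil_ok = coil_ok,
                 separation_ok = separation_ok,
                 region_ok = region_ok,
                 gyrus_ok = gyrus_ok,
                 separation_mm = sep,
                 overlaps_mm = overlaps,
                 v1v2_fraction = v1v2_fraction,
                 warnings = warnings,
                 constraints = cfg[c("max_rotation_deg", "max_coil_distance_mm",
                                     "min_separation_mm", "allow_overlap",
                                     "min_v1v2_fraction")]),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  ok <- function(b) if (b) "ok" else "FAIL"
  cat("Placement constraint report\n")
  cat(sprintf("  rotation:   %s\n  coil:       %s\n  separation: %s\n  region:     %s (V1/V2 fraction %.2f)\n  gyrus:      %s\n",
              ok(x$rotation_ok), ok(x$coil_ok), ok(x$separation_ok),
              ok(x$region_ok), x$v1v2_fraction, ok(x$gyrus_ok)))
  if (length(x$overlaps_mm))
    cat(sprintf("  %d overlapping pair(s), max overlap %.2f mm\n",
                length(x$overlaps_mm),
                max(vapply(x$overlaps_mm, `[[`, numeric(1), "overlap_mm"))))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Serialise a constraint report to JSON
#' @param report a `constraint_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_constraint_report <- function(report, path) {
  out <- report
  out$separation_mm <- unclass(out$separation_mm)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
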