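# Fixtures and independent oracles used across the suite. Oracles are
# deliberately written with different algorithms than the package code.

# Hand-built surface from a position matrix and retinotopy vectors.
toy_surface <- function(pos, polar, ecc, prf = 0.05 * ecc + 0.5,
                        roi = "V1", hemisphere = "right", is_gyrus = TRUE,
                        subject_id = "toy") {
  n <- nrow(pos)
  retinotopic_surface(data.frame(
    id = seq_len(n), x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
    polar_angle_deg = rep_len(polar, n), eccentricity_deg = rep_len(ecc, n),
    prf_size_deg = rep_len(prf, n), roi = rep_len(roi, n),
    hemisphere = rep_len(hemisphere, n), is_gyrus = rep_len(is_gyrus, n)),
    subject_id = subject_id)
}

# Flat grid patch in the y-z plane at x = x0 (tangent plane analytically
# known: normal along x). Retinotopy: eccentricity grows with y, angle with
# z, left visual hemifield (right hemisphere).
flat_patch <- function(n_side = 15, spacing = 2, x0 = 8) {
  gr <- expand.grid(y = seq_len(n_side), z = seq_len(n_side))
  yy <- (gr$y - mean(gr$y)) * spacing
  zz <- (gr$z - mean(gr$z)) * spacing
  ecc <- 1 + 0.5 * (gr$y - 1)
  beta <- (gr$z - mean(gr$z)) / n_side * pi / 2
  x_vf <- -ecc * cos(beta)   # left hemifield
  y_vf <- ecc * sin(beta)
  toy_surface(cbind(x0, -60 + yy, zz),
              polar = atan2(x_vf, y_vf) * 180 / pi, ecc = ecc,
              hemisphere = "right")
}

# Minimal implant-shaped object for pure geometry tests (overlap distance
# only touches these fields).
fake_implant <- function(center, axis_long, axis_short, normal,
                         footprint = c(9, 9)) {
  lay <- array_layout(cbind(0, 0), footprint = footprint)
  structure(list(layout = lay, center = center, axis_long = axis_long,
                 axis_short = axis_short, normal = normal,
                 rotation_deg = 0, center_vertex = NA,
                 electrode_positions = matrix(center, 1, 3),
                 hemisphere = "right"),
            class = "implant")
}

# Brute-force DBSCAN oracle: core flags by direct counting, core clusters by
# iterated transitive closure of the core adjacency matrix, border points
# attached to the lowest-id cluster among their core neighbours.
dbscan_oracle <- function(points, eps, min_pts) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  nb <- d <= eps
  core <- colSums(nb) >= min_pts
  labels <- rep(-1L, n)
  if (any(core)) {
    adj <- nb[core, core, drop = FALSE]
    reach <- adj
    repeat {
      nxt <- (reach %*% reach) > 0
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    comp <- integer(sum(core))
    cid <- -1L
    for (i in seq_len(sum(core))) {
      if (comp[i] == 0) { cid <- cid + 1L; comp[reach[i, ]] <- cid + 1L }
    }
    comp <- comp - 1L
    labels[core] <- comp
    core_idx <- which(core)
    for (i in which(!core)) {
      nbc <- core_idx[nb[i, core]]
      if (length(nbc)) labels[i] <- min(labels[nbc])
    }
  }
  labels
}

# Phosphene map with phosphenes at given pixel (col, row) positions.
px_map <- function(cols, rows, canvas = c(200, 200), px_per_deg = 40,
                   radius_deg = 0.5, kind = "retinotopic") {
  cx <- (canvas[1] + 1) / 2; cy <- (canvas[2] + 1) / 2
  phosphene_map(data.frame(
    x_deg = (cols - cx) / px_per_deg,
    y_deg = (cy - rows) / px_per_deg,
    radius_deg = radius_deg,
    implant = 1L, electrode = seq_along(cols)),
    kind = kind, px_per_deg = px_per_deg, canvas = canvas)
}

rigid_rotate_implant <- function(im, R, shift = c(0, 0, 0)) {
  im$center <- as.numeric(R %*% im$center + shift)
  im$normal <- as.numeric(R %*% im$normal)
  im$axis_long <- as.numeric(R %*% im$axis_long)
  im$axis_short <- as.numeric(R %*% im$axis_short)
  im$electrode_positions <- t(R %*% t(im$electrode_positions) + shift)
  im
}

rotmat3 <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
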