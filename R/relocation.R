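#' Density-based clustering of 2D points (DBSCAN)
#'
#' Standard DBSCAN semantics with a closed neighbourhood: a point is a core
#' point iff at least `min_pts` points (itself included) lie within distance
#' `eps` of it; clusters are the connected components of core points plus
#' any border points within `eps` of a core point; remaining points are
#' noise. Border points reachable from several clusters join the cluster of
#' the lowest-indexed core neighbour, and cluster ids are numbered by first
#' core point, so the labelling is deterministic.
#'
#' @param points n x 2 numeric matrix (pixel coordinates for phosphene
#'   maps).
#' @param eps_px neighbourhood radius (default 200 px, about 5 degrees at
#'   40 px/deg).
#' @param min_pts minimum neighbourhood size for a core point (default
#'   100).
#' @return An object of class `cluster_labels`: list with `labels` (integer
#'   per point: -1 noise, cluster ids 0, 1, ...), `eps_px`, `min_pts`.
#' @export
dbscan_cluster <- function(points, eps_px = 200, min_pts = 100) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 1, ncol(points) == 2)
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  nb <- d <= eps_px                   # closed neighbourhood; diagonal TRUE
  core <- rowSums(nb) >= min_pts
  labels <- rep(-1L, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    # BFS over density-connected core points
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      reach <- which(nb[cur, ])
      for (r in reach) {
        if (labels[r] == -1L) {
          labels[r] <- cl
          if (core[r]) queue <- c(queue, r)
        }
      }
    }
  }
  structure(list(labels = labels, eps_px = eps_px, min_pts = min_pts,
                 core = core),
            class = "cluster_labels")
}

#' Relocate a stimulus to the densest phosphene cluster
#'
#' Runs [dbscan_cluster()] on the phosphene pixel positions and translates
#' the stimulus by the integer pixel shift that brings its centre closest
#' to the centroid (arithmetic mean of member positions) of the target
#' cluster:
#' the largest cluster, ties broken by the cluster whose centroid is closest
#' to the canvas centre. If no cluster forms the stimulus is returned
#' unchanged with attribute `relocated = FALSE`. The translation is clamped
#' so the stimulus foreground stays on canvas (attribute `clamped`).
#'
#' @param map a [phosphene_map()].
#' @param stim a [pv_stimulus()] on the same canvas.
#' @param eps_px,min_pts DBSCAN parameters (defaults 200 px / 100 points).
#' @return The (possibly translated) [pv_stimulus()] with attributes
#'   `relocated`, `clamped`, `target_centroid_px` (row, col) and `labels`.
#' @export
relocate_stimulus <- function(map, stim, eps_px = 200, min_pts = 100) {
  if (nrow(map$phosphenes) == 0) stopf("empty phosphene map")
  centers <- map_to_px(map)
  cl <- dbscan_cluster(centers[, c("col", "row"), drop = FALSE],
                       eps_px = eps_px, min_pts = min_pts)
  labs <- cl$labels
  if (all(labs == -1L)) {
    warning("no phosphene cluster found; stimulus not relocated")
    attr(stim, "relocated") <- FALSE
    attr(stim, "labels") <- labs
    return(stim)
  }
  ids <- sort(unique(labs[labs >= 0]))
  sizes <- vapply(ids, function(k) sum(labs == k), integer(1))
  best <- ids[sizes == max(sizes)]
  if (length(best) > 1) {
    ctr <- c((map$canvas[2] + 1) / 2, (map$canvas[1] + 1) / 2)  # (row, col)
    d2 <- vapply(best, function(k) {
      cen <- c(mean(centers[labs == k, "row"]), mean(centers[labs == k, "col"]))
      sum((cen - ctr)^2)
    }, numeric(1))
    best <- best[which.min(d2)]
  } else best <- best[1]
  centroid <- c(row = mean(centers[labs == best, "row"]),
                col = mean(centers[labs == best, "col"]))
  shift <- round(centroid - stim$centre_px)   # integer pixel translation
  # clamp so the foreground bounding box stays on canvas
  clamped <- FALSE
  fg <- which(stim$image > 0, arr.ind = TRUE)
  if (nrow(fg) > 0) {
    h <- nrow(stim$image); w <- ncol(stim$image)
    lo <- c(1 - min(fg[, 1]), 1 - min(fg[, 2]))
    hi <- c(h - max(fg[, 1]), w - max(fg[, 2]))
    sh <- pmin(pmax(shift, lo), hi)
    if (any(sh != shift)) clamped <- TRUE
    shift <- sh
  }
  out <- translate_stimulus(stim, shift)
  attr(out, "relocated") <- TRUE
  attr(out, "clamped") <- clamped
  attr(out, "target_centroid_px") <- centroid
  attr(out, "labels") <- labs
  out
}
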