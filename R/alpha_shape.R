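# Delaunay triangulation (Bowyer-Watson) and minimal-alpha single-component
# alpha shapes, used for the concave phosphene-map boundary. Point sets here
# are small (hundreds of phosphenes) so an O(n^2) incremental construction
# is ample.

# Circumcentre and circumradius of triangle (a, b, c); radius Inf when the
# points are (nearly) collinear.
circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12 * max(1, sum(abs(c(a, b, c)))))
    return(list(center = c(NA_real_, NA_real_), r = Inf))
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  list(center = c(ux, uy), r = sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
}

# Bowyer-Watson incremental Delaunay triangulation. `pts` must be free of
# duplicates and exact degeneracies (callers jitter). Returns an m x 3
# matrix of point indices (integer), or a 0-row matrix if fewer than 3
# points.
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(matrix(integer(0), 0, 3))
  span <- max(apply(pts, 2, function(x) diff(range(x))), 1e-9)
  mid <- colMeans(apply(pts, 2, range))
  big <- 50 * span
  sup <- rbind(mid + c(-big, -big), mid + c(big, -big), mid + c(0, big))
  all_pts <- rbind(pts, sup)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  tris <- list(c(s1, s2, s3))
  circ <- list(circumcircle(all_pts[s1, ], all_pts[s2, ], all_pts[s3, ]))

  for (p in seq_len(n)) {
    pt <- all_pts[p, ]
    bad <- vapply(seq_along(tris), function(t) {
      cc <- circ[[t]]
      if (!is.finite(cc$r)) return(TRUE)
      (pt[1] - cc$center[1])^2 + (pt[2] - cc$center[2])^2 <= cc$r^2 * (1 + 1e-12)
    }, logical(1))
    # polygonal hole boundary: edges of bad triangles not shared by two
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    keep_edge <- !(key %in% key[duplicated(key)])
    boundary <- edges[keep_edge, , drop = FALSE]
    tris <- tris[!bad]
    circ <- circ[!bad]
    for (e in seq_len(nrow(boundary))) {
      tr <- c(boundary[e, 1], boundary[e, 2], p)
      tris[[length(tris) + 1]] <- tr
      circ[[length(circ) + 1]] <-
        circumcircle(all_pts[tr[1], ], all_pts[tr[2], ], all_pts[tr[3], ])
    }
  }
  keep <- vapply(tris, function(tr) all(tr <= n), logical(1))
  if (!any(keep)) return(matrix(integer(0), 0, 3))
  matrix(as.integer(unlist(tris[keep])), ncol = 3, byrow = TRUE)
}

tri_area <- function(pts, tri) {
  a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
  abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
}

# Are the kept triangles edge-connected and do they cover every point?
alpha_ok <- function(tris, keep, n_points) {
  kept <- tris[keep, , drop = FALSE]
  if (nrow(kept) == 0) return(FALSE)
  if (length(unique(as.vector(kept))) < n_points) return(FALSE)
  if (nrow(kept) == 1) return(TRUE)
  edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  keys <- cbind(edge_key(kept[, 1], kept[, 2]),
                edge_key(kept[, 2], kept[, 3]),
                edge_key(kept[, 1], kept[, 3]))
  # union-find over triangles sharing an edge
  parent <- seq_len(nrow(kept))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_len(nrow(kept))) for (k in keys[t, ]) {
    prev <- get0(k, envir = seen)
    if (is.null(prev)) assign(k, t, envir = seen)
    else { ri <- find(prev); rj <- find(t); if (ri != rj) parent[ri] <- rj }
  }
  length(unique(vapply(seq_len(nrow(kept)), find, integer(1)))) == 1
}

#' Concave boundary area of a phosphene map
#'
#' Computes the area underneath a point set using a compact concave
#' boundary: the tightest single-component alpha shape that still contains
#' every point (the analogue of a boundary allowed to shrink maximally
#' towards the interior of the convex hull). Triangles of the Delaunay
#' triangulation are retained when their circumradius is at most alpha, and
#' alpha is the smallest value for which the retained triangles cover all
#' points in one edge-connected piece. The area is the summed area of the
#' retained triangles; for convex, well-sampled sets it equals the convex
#' hull area, while sets with concavities (or stragglers connected by thin
#' necks) get a smaller, tighter area than the hull.
#'
#' @param map a [phosphene_map()], or an n x 2 matrix of positions in
#'   degrees.
#' @return An object of class `area_result`: list with `area` (deg^2),
#'   `boundary` (ordered vertex matrix of the outer boundary loop),
#'   `alpha`, `shrink` (fixed at 1, maximal shrink), and `degenerate`
#'   (TRUE when the points are collinear and the area is 0).
#' @export
map_area <- function(map) {
  pts <- if (inherits(map, "phosphene_map"))
    as.matrix(map$phosphenes[, c("x_deg", "y_deg")]) else as.matrix(map)
  stopifnot(ncol(pts) == 2)
  pts <- pts[!duplicated(round(pts, 12)), , drop = FALSE]
  degen <- function() structure(list(area = 0, boundary = pts, alpha = NA_real_,
                                     shrink = 1, degenerate = TRUE),
                                class = "area_result")
  if (nrow(pts) < 3) return(degen())
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  span <- max(sv$d)
  if (sv$d[2] < 1e-9 * max(span, 1)) return(degen())   # collinear

  # deterministic sub-numerical jitter breaks cocircular/collinear ties in
  # the triangulation; areas and radii thresholds use original coordinates
  n <- nrow(pts)
  jit <- cbind(sin(1e4 * seq_len(n) + 1), cos(7e3 * seq_len(n) + 2)) *
    span * 1e-9
  tris <- delaunay_triangulate(pts + jit)
  if (nrow(tris) == 0) return(degen())
  radii <- vapply(seq_len(nrow(tris)), function(t)
    circumcircle(pts[tris[t, 1], ] + jit[tris[t, 1], ],
                 pts[tris[t, 2], ] + jit[tris[t, 2], ],
                 pts[tris[t, 3], ] + jit[tris[t, 3], ])$r, numeric(1))
  # quantise circumradii so cocircular ties (split only by the jitter) are
  # kept or dropped together
  tol_r <- span * 1e-6
  rq <- round(radii / tol_r)
  cand <- sort(unique(rq))
  lo <- 1L; hi <- length(cand)
  if (!alpha_ok(tris, rq <= cand[hi], n)) {
    # should not happen (full triangulation covers all points); be safe
    keep <- rep(TRUE, nrow(tris))
    alpha <- Inf
  } else {
    while (lo < hi) {
      midp <- (lo + hi) %/% 2L
      if (alpha_ok(tris, rq <= cand[midp], n)) hi <- midp else lo <- midp + 1L
    }
    keep <- rq <= cand[lo]
    alpha <- max(radii[keep])
  }
  kept <- tris[keep, , drop = FALSE]
  area <- sum(vapply(seq_len(nrow(kept)), function(t)
    tri_area(pts, kept[t, ]), numeric(1)))
  structure(list(area = area, boundary = boundary_loop(pts, kept),
                 alpha = alpha, shrink = 1, degenerate = FALSE),
            class = "area_result")
}

# Outer boundary loop of a triangle set: edges used by exactly one triangle,
# walked into loops; the loop enclosing the largest area is returned as an
# ordered coordinate matrix.
boundary_loop <- function(pts, tris) {
  if (nrow(tris) == 0) return(pts[integer(0), , drop = FALSE])
  edges <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(1, 3)])
  edges <- t(apply(edges, 1, sort))
  key <- paste(edges[, 1], edges[, 2])
  once <- edges[!(key %in% key[duplicated(key)]), , drop = FALSE]
  if (nrow(once) == 0) return(pts[integer(0), , drop = FALSE])
  adj <- split(c(once[, 2], once[, 1]), c(once[, 1], once[, 2]))
  used <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  loops <- list()
  for (s in unique(as.vector(once))) {
    repeat {
      nxt <- Filter(function(j) is.null(get0(ekey(s, j), envir = used)),
                    adj[[as.character(s)]])
      if (!length(nxt)) break
      loop <- s; cur <- s; prev <- NA
      repeat {
        cand <- Filter(function(j) is.null(get0(ekey(cur, j), envir = used)),
                       adj[[as.character(cur)]])
        if (!length(cand)) break
        nx <- cand[[1]]
        assign(ekey(cur, nx), TRUE, envir = used)
        if (nx == s) break
        loop <- c(loop, nx)
        prev <- cur; cur <- nx
      }
      if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
    }
  }
  if (!length(loops)) return(pts[integer(0), , drop = FALSE])
  areas <- vapply(loops, function(l) {
    x <- pts[l, 1]; y <- pts[l, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
  pts[loops[[which.max(areas)]], , drop = FALSE]
}

#' @export
print.area_result <- function(x, ...) {
  if (x$degenerate) cat("Map area: degenerate (collinear points), 0 deg^2\n")
  else cat(sprintf("Map area: %.3f deg^2 (alpha = %.3f, %d boundary vertices)\n",
                   x$area, x$alpha, nrow(x$boundary)))
  invisible(x)
}
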