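# Internal helpers shared across modules.

# Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Pairwise squared distances between rows of a and rows of b (dense, small n).
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
}

cross_dist <- function(a, b) sqrt(pmax(cross_dist2(a, b), 0))

# Indices of the k nearest rows of `pts` to the single point `q` (3D or 2D).
knn_indices <- function(pts, q, k) {
  d2 <- cross_dist2(pts, matrix(q, nrow = 1))[, 1]
  order(d2)[seq_len(k)]
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Visual-field conversion. Polar angle convention: 0 deg = upper vertical
# meridian, clockwise positive, so the right visual field has positive x.
polar_to_xy <- function(polar_angle_deg, ecc_deg) {
  th <- deg2rad(polar_angle_deg)
  cbind(x = ecc_deg * sin(th), y = ecc_deg * cos(th))
}

xy_to_polar <- function(x, y) {
  cbind(polar_angle_deg = rad2deg(atan2(x, y)), eccentricity_deg = sqrt(x^2 + y^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
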