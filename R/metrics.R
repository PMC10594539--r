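# Map-quality metrics: spatial complexity of a phosphene point set,
# image-to-image mutual information, and (in alpha_shape.R) concave
# boundary area. Entropies are in bits.

shannon_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

as_points <- function(x) {
  if (inherits(x, "phosphene_map"))
    as.matrix(x$phosphenes[, c("x_deg", "y_deg")])
  else as.matrix(x)
}

#' Global distance entropy of a point set
#'
#' Shannon entropy (bits) of the histogram of Euclidean distances from each
#' point to the set centroid, over `n_bins` equal-width bins spanning
#' [0, max distance]. Points on a common circle occupy one bin (0 bits);
#' distances spread evenly across bins approach `log2(n_bins)` bits.
#'
#' @param points n x 2 matrix or [phosphene_map()] (>= 2 points).
#' @param n_bins histogram bins (default 16).
#' @return Entropy in bits.
#' @export
global_distance_entropy <- function(points, n_bins = 16) {
  pts <- as_points(points)
  stopifnot(nrow(pts) >= 2)
  d <- sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2))
  if (max(d) < 1e-12) return(0)   # all points identical
  breaks <- seq(0, max(d), length.out = n_bins + 1)
  counts <- graphics::hist(d, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  shannon_entropy(counts)
}

# Angle at each point subtended by its two nearest neighbours, in [0, pi].
# Ties (including duplicated points) resolved toward the lowest index; a
# coincident neighbour contributes a zero vector and yields angle 0 (spike).
local_angles <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[1:2]
    v1 <- pts[nb[1], ] - pts[i, ]
    v2 <- pts[nb[2], ] - pts[i, ]
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-12 || n2 < 1e-12) return(0)
    acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1))
  }, numeric(1))
}

#' Local angle entropy of a point set
#'
#' For each point, the angle subtended at it by its two nearest neighbours
#' (in [0, pi]); the metric is the Shannon entropy (bits) of the histogram
#' of these angles over `n_bins` equal-width bins spanning [0, pi].
#' Regular arrangements (closed rings, polygon vertices, the interior of
#' collinear chains) concentrate in one bin and score near 0; the two
#' endpoints of an open chain see both neighbours on one side (angle 0,
#' the degenerate-spike case) and contribute a vanishing share 2/n.
#'
#' @inheritParams global_distance_entropy
#' @return Entropy in bits.
#' @export
local_angle_entropy <- function(points, n_bins = 16) {
  pts <- as_points(points)
  ang <- local_angles(pts)
  breaks <- seq(0, pi, length.out = n_bins + 1)
  counts <- graphics::hist(ang, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  shannon_entropy(counts)
}

#' Perceptual smoothness of a point set
#'
#' Mean over points of `1 - angle/pi`, where the angle is the local
#' two-nearest-neighbour angle: 0 for a point whose neighbours are
#' diametrically opposite (locally straight/smooth, angle pi) and 1 for a
#' degenerate spike whose neighbours lie in the same direction (angle 0).
#' Interior points of collinear chains score 0; the chain endpoints are
#' spikes by this definition, so an open chain of n points scores 2/n.
#'
#' @param points n x 2 matrix or [phosphene_map()] (>= 3 points).
#' @return Value in [0, 1].
#' @export
perceptual_smoothness <- function(points) {
  pts <- as_points(points)
  mean(1 - local_angles(pts) / pi)
}

#' Spatial complexity of a phosphene map
#'
#' Combines three normalised components — global distance entropy, local
#' angle entropy (each divided by their `log2(n_bins)` maximum) and
#' perceptual smoothness — into an unweighted mean in [0, 1]. Regular
#' arrangements such as a circle score near 0; uniformly random point sets
#' score high; a noisy polygon falls in between.
#'
#' @inheritParams global_distance_entropy
#' @return An object of class `complexity_score`: list with
#'   `distance_entropy`, `angle_entropy` (bits), `smoothness`, `combined`
#'   and `n_bins`.
#' @export
map_complexity <- function(points, n_bins = 16) {
  pts <- as_points(points)
  stopifnot(nrow(pts) >= 3)
  de <- global_distance_entropy(pts, n_bins)
  ae <- local_angle_entropy(pts, n_bins)
  sm <- perceptual_smoothness(pts)
  structure(list(distance_entropy = de,
                 angle_entropy = ae,
                 smoothness = sm,
                 combined = mean(c(de / log2(n_bins), ae / log2(n_bins), sm)),
                 n_bins = n_bins),
            class = "complexity_score")
}

#' @export
print.complexity_score <- function(x, ...) {
  cat(sprintf("Map complexity: %.3f (distance entropy %.2f bits, angle entropy %.2f bits, smoothness %.3f)\n",
              x$combined, x$distance_entropy, x$angle_entropy, x$smoothness))
  invisible(x)
}

#' Mutual information between two grayscale images
#'
#' Images are zero-padded (centred) to a common size, intensities are
#' binned into `n_bins` equal-width bins on [0, 1], and the joint
#' probability mass function is estimated from co-located pixel pairs.
#' Joint cells with probability below 1e-12 are excluded (their total mass
#' is reported); marginals are taken from the retained joint so the
#' identities MI(X, X) = H(X), MI symmetric and MI >= 0 hold exactly.
#'
#' @param img_a,img_b numeric matrices in [0, 1], [pv_stimulus()] or
#'   `rendered_frame` objects.
#' @param n_bins intensity bins (default 64).
#' @return An object of class `mi_result`: list with `mi` (bits), `n_bins`,
#'   `excluded_mass`.
#' @export
mutual_information <- function(img_a, img_b, n_bins = 64) {
  gi <- function(x) {
    if (inherits(x, "pv_stimulus")) x$image
    else if (inherits(x, "rendered_frame")) x$image
    else as.matrix(x)
  }
  a <- gi(img_a); b <- gi(img_b)
  if (length(a) == 0 || length(b) == 0) stopf("images must be non-empty")
  dims <- c(max(nrow(a), nrow(b)), max(ncol(a), ncol(b)))
  pad <- function(m) {
    out <- matrix(0, dims[1], dims[2])
    r0 <- floor((dims[1] - nrow(m)) / 2); c0 <- floor((dims[2] - ncol(m)) / 2)
    out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
    out
  }
  a <- pad(a); b <- pad(b)
  bin <- function(v) pmin(floor(v * n_bins) + 1L, n_bins)
  ia <- bin(as.vector(a)); ib <- bin(as.vector(b))
  joint <- matrix(tabulate((ia - 1L) * n_bins + ib, nbins = n_bins^2),
                  n_bins, n_bins)           # row = b bin, col = a bin
  pxy <- joint / sum(joint)
  excluded <- sum(pxy[pxy > 0 & pxy < 1e-12])
  pxy[pxy < 1e-12] <- 0
  px <- colSums(pxy); py <- rowSums(pxy)
  nz <- which(pxy > 0, arr.ind = TRUE)
  mi <- sum(pxy[nz] * log2(pxy[nz] / (px[nz[, 2]] * py[nz[, 1]])))
  structure(list(mi = max(mi, 0), n_bins = n_bins, excluded_mass = excluded),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("Mutual information: %.4f bits (%d bins, excluded mass %.2g)\n",
              x$mi, x$n_bins, x$excluded_mass))
  invisible(x)
}

#' Correlation between a map metric and task performance
#'
#' Convenience wrapper around [stats::cor.test()] (Pearson) for relating
#' map metrics to externally measured performance. Provided as a generic
#' utility; this package ships no human performance data.
#'
#' @param metric,performance numeric vectors of equal length.
#' @return The `htest` object from [stats::cor.test()].
#' @export
metric_correlation <- function(metric, performance) {
  stats::cor.test(metric, performance, method = "pearson")
}
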