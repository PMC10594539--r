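test_that("tumbling E geometry follows the 5x5 optotype construction", {
  # 2.0 LogMAR at 40 px/deg: MAR = 100 arcmin -> height 5*100/60*40 = 333 px
  e <- make_tumbling_E(2.0, "right", px_per_deg = 40)
  rows <- which(rowSums(e$image) > 0)
  cols <- which(colSums(e$image) > 0)
  expect_equal(length(rows), 333L)
  expect_equal(length(cols), 333L)
  # stroke-to-height ratio 1/5 (to rounding)
  first_col_height <- sum(e$image[, cols[1]] > 0)
  expect_equal(first_col_height, 333L)       # spine runs full height
  # band structure: 3 arms of ~1/5 height each separated by gaps
  prof <- rowSums(e$image[rows, cols])
  arm_rows <- sum(prof == 333)               # full-width rows = arms
  expect_equal(arm_rows / 333, 3 / 5, tolerance = 0.02)
})

test_that("opposite E orientations are exact 180-degree rotations", {
  # odd canvas so the odd-height letter centres symmetrically
  cv <- c(1081L, 1081L)
  up <- make_tumbling_E(1.6, "up", canvas = cv)$image
  down <- make_tumbling_E(1.6, "down", canvas = cv)$image
  expect_identical(up, down[nrow(down):1, ncol(down):1])
  left <- make_tumbling_E(1.6, "left", canvas = cv)$image
  right <- make_tumbling_E(1.6, "right", canvas = cv)$image
  expect_identical(left, right[nrow(right):1, ncol(right):1])
})

test_that("tiny letters are rejected with a resolution error", {
  expect_error(make_tumbling_E(0.8, "right", px_per_deg = 0.5), "px")
})

test_that("gratings have the prescribed bar width, duty cycle and symmetry", {
  # bar width at 2.3 LogMAR: 10^2.3 ~ 199.5 arcmin -> 133.0 px at 40 px/deg
  bar_px <- 10^2.3 / 60 * 40
  g2 <- make_grating(2.3, "vertical")
  # run lengths along the mid row, away from the circular patch edge
  rad <- 13.5 / 2 * 40
  mid <- g2$image[540, ceiling(540.5 - rad + 1):floor(540.5 + rad - 1)]
  runs <- rle(mid)$lengths
  inner <- runs[2:(length(runs) - 1)]      # drop the clipped edge runs
  expect_true(all(abs(inner - bar_px) <= 1.5))
  # transpose symmetry on a square canvas
  h <- make_grating(2.3, "horizontal")
  expect_equal(h$image, t(g2$image), tolerance = 0)
  # ~50% duty cycle inside the patch
  inside <- (col(g2$image) - 540.5)^2 + (row(g2$image) - 540.5)^2 <= rad^2
  expect_equal(mean(g2$image[inside]), 0.5, tolerance = bar_px / (2 * rad))
  # bar width at 2.9 LogMAR ~ 794 arcmin, direct arithmetic
  expect_equal(round(10^2.9), 794)
})

test_that("object silhouettes render all five classes as filled shapes", {
  for (cl in c("top", "trousers", "dress", "sneaker", "bag")) {
    s <- make_object_silhouette(cl)
    expect_equal(dim(s$image), c(540L, 540L))
    frac <- mean(s$image)
    expect_gt(frac, 0.05)
    expect_lt(frac, 0.8)
  }
})

test_that("skeletonization thins an E to a connected 1-px medial axis", {
  e <- make_tumbling_E(1.8, "right")
  sk <- skeletonize(e$image)
  expect_true(any(sk))
  expect_lt(sum(sk), sum(e$image > 0.5) / 5)
  # 1 px wide: no 2x2 block fully on
  two_by_two <- sk[-1, -1] & sk[-nrow(sk), -1] & sk[-1, -ncol(sk)] &
    sk[-nrow(sk), -ncol(sk)]
  expect_false(any(two_by_two))
  # single 8-connected component (flood fill oracle)
  lab <- matrix(0L, nrow(sk), ncol(sk))
  start <- which(sk, arr.ind = TRUE)[1, ]
  queue <- list(start); lab[start[1], start[2]] <- 1L
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= nrow(sk) && c >= 1 && c <= ncol(sk) &&
          sk[r, c] && lab[r, c] == 0L) {
        lab[r, c] <- 1L
        queue[[length(queue) + 1]] <- c(r, c)
      }
    }
  }
  expect_equal(sum(lab == 1L), sum(sk))
})

test_that("skeleton sampling activates the nearest phosphene per skeleton pixel", {
  # plus-sign strokes over an aligned 3x3 phosphene grid: only the 5
  # phosphenes on the stroke axes light up
  map <- px_map(cols = rep(c(60, 100, 140), 3),
                rows = rep(c(60, 100, 140), each = 3))
  img <- matrix(0, 200, 200)
  img[100, 30:170] <- 1
  img[30:170, 100] <- 1
  stim <- pv_stimulus(img, px_per_deg = 40)
  got <- skeleton_sample(stim, map)
  # brute-force oracle: nearest centre for every skeleton pixel
  sk <- skeletonize(img)
  pix <- which(sk, arr.ind = TRUE)
  centers <- cbind(rep(c(60, 100, 140), 3), rep(c(60, 100, 140), each = 3))
  oracle <- sort(unique(vapply(seq_len(nrow(pix)), function(i) {
    d2 <- (centers[, 1] - pix[i, "col"])^2 + (centers[, 2] - pix[i, "row"])^2
    which.min(d2)
  }, integer(1))))
  expect_equal(got, oracle)
  expect_setequal(got, c(2, 4, 5, 6, 8))   # the plus-shaped subset

  # blank stimulus -> empty set; single pixel -> single nearest phosphene
  expect_length(skeleton_sample(pv_stimulus(matrix(0, 200, 200), 40), map), 0)
  one <- matrix(0, 200, 200); one[58, 63] <- 1
  expect_equal(skeleton_sample(pv_stimulus(one, 40), map), 1L)
})

test_that("skeleton sampling is invariant to joint stimulus/map translation", {
  map <- px_map(cols = c(60, 90, 120, 150, 80), rows = c(50, 120, 70, 150, 160))
  img <- matrix(0, 200, 200)
  img[80:120, 90] <- 1; img[80, 70:110] <- 1
  a <- skeleton_sample(pv_stimulus(img, 40), map)
  sh <- c(15, -10)
  img2 <- matrix(0, 200, 200)
  img2[80:120 + sh[1], 90 + sh[2]] <- 1; img2[80 + sh[1], 70:110 + sh[2]] <- 1
  map2 <- px_map(cols = c(60, 90, 120, 150, 80) + sh[2],
                 rows = c(50, 120, 70, 150, 160) + sh[1])
  b <- skeleton_sample(pv_stimulus(img2, 40), map2)
  expect_equal(a, b)
})

test_that("direct masking activates phosphenes under bright regions only", {
  map <- px_map(cols = seq(20, 200, by = 20), rows = rep(100, 10),
                canvas = c(220, 220))
  white <- pv_stimulus(matrix(1, 220, 220), 40)
  expect_equal(direct_mask(white, map), 1:10, ignore_attr = TRUE)
  black <- pv_stimulus(matrix(0, 220, 220), 40)
  expect_length(direct_mask(black, map), 0)
  # left half white: phosphenes at cols 20..100 (vs centre 110.5) active
  half <- matrix(0, 220, 220); half[, 1:110] <- 1
  got <- direct_mask(pv_stimulus(half, 40), map)
  expect_equal(as.integer(got), 1:5)
  # threshold monotonicity: relaxing the threshold never drops phosphenes
  gray <- matrix(runif(220^2), 220, 220)
  sg <- pv_stimulus(gray, 40)
  a <- direct_mask(sg, map, threshold = 0.7)
  b <- direct_mask(sg, map, threshold = 0.3)
  expect_true(all(a %in% b))
})

test_that("off-canvas phosphenes are inactive and tallied", {
  map <- px_map(cols = c(50, 400), rows = c(50, 50), canvas = c(100, 100))
  white <- pv_stimulus(matrix(1, 100, 100), 40)
  got <- direct_mask(white, map)
  expect_equal(as.integer(got), 1L)
  expect_equal(attr(got, "clipped"), 1L)
})

test_that("rendered phosphenes are capped Gaussians with sigma = radius/3", {
  map <- px_map(cols = 100, rows = 100, canvas = c(200, 200), radius_deg = 0.75)
  fr <- render_phosphenes(map, 1)
  expect_s3_class(fr, "rendered_frame")
  expect_equal(max(fr$image), 1, tolerance = 1e-9)
  expect_equal(fr$image[100, 100], 1, tolerance = 1e-9)
  # radial monotone decay along a row
  prof <- fr$image[100, 100:140]
  expect_true(all(diff(prof) <= 1e-12))
  # value at 3 sigma = exp(-4.5) of peak; sigma = 0.75*40/3 = 10 px
  expect_equal(fr$image[100, 130], exp(-4.5), tolerance = 1e-3)
  # two coincident phosphenes cap to the same image as one
  map2 <- px_map(cols = c(100, 100), rows = c(100, 100), canvas = c(200, 200),
                 radius_deg = 0.75)
  fr2 <- render_phosphenes(map2, 1:2)
  expect_gte(min(fr2$image - fr$image), -1e-12)
  expect_equal(fr2$image[100, 100], 1)
  # permutation invariance in phosphene order
  map3 <- px_map(cols = c(60, 140), rows = c(70, 120), canvas = c(200, 200))
  f12 <- render_phosphenes(map3, c(1, 2))
  f21 <- render_phosphenes(map3, c(2, 1))
  expect_equal(f12$image, f21$image)
  expect_true(all(f12$image >= 0 & f12$image <= 1))
})

test_that("acuity ladder scoring applies the 4/8 and 7/8 pass rules", {
  r <- brvt_score(data.frame(level = c(2.0, 1.8), n_correct = c(5, 3),
                             n_total = 8))
  expect_equal(r$va_logmar, 2.0)
  # all E fail, grating 2.9 passes at 7/8
  tr <- data.frame(level = c(seq(0.8, 2.6, 0.2), 2.9),
                   n_correct = c(rep(3, 10), 7), n_total = 8)
  expect_equal(brvt_score(tr)$va_logmar, 2.9)
  # 7/8 rule is stricter: 6/8 at a grating level does not pass
  tr$n_correct[11] <- 6
  expect_equal(brvt_score(tr)$va_logmar, 3.0)
  # everything fails -> 3.0 LogMAR ceiling
  tr$n_correct <- 0
  expect_equal(brvt_score(tr)$va_logmar, 3.0)
  expect_error(brvt_score(data.frame(level = 2, n_correct = 9, n_total = 8)),
               "malformed")
})

test_that("ladder scoring matches brute force over all pass/fail patterns", {
  levels <- c(1.4, 1.6, 2.0, 2.4)
  for (mask in 0:15) {
    pass <- as.logical(bitwAnd(mask, 2^(0:3)))
    tr <- data.frame(level = levels,
                     n_correct = ifelse(pass, 8, 2), n_total = 8,
                     test = "E")
    want <- if (any(pass)) min(levels[pass]) else 3.0
    expect_equal(brvt_score(tr)$va_logmar, want)
  }
})

test_that("validation blocks bracket the measured acuity with 12 trials", {
  vb <- validation_block(2.0)
  expect_equal(vb$level, c(1.8, 2.0, 2.2))
  expect_equal(vb$n_trials, rep(12L, 3))
  expect_equal(sum(vb$n_trials), 36L)
  expect_false(any(attr(vb, "below_floor")))
  low <- validation_block(0.8)
  expect_true(attr(low, "below_floor")[1])   # 0.6 is under the ladder floor
})

test_that("stimuli round-trip through PNG with sidecar metadata", {
  e <- make_tumbling_E(2.0, "up", canvas = c(400, 400))
  path <- withr::local_tempfile(fileext = ".png")
  write_stimulus_png(e, path)
  r <- read_stimulus_png(path)
  expect_equal(r$image, e$image, tolerance = 1 / 255)
  expect_equal(r$logmar, 2.0)
  expect_equal(r$orientation, "up")
  expect_equal(r$px_per_deg, 40)
})
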