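test_that("activated cortex diameter follows the sigmoid model", {
  p <- size_model_params()
  # half-saturation: diameter MD/2 = 2.65 mm, radius 1.325 (~1.33) mm
  expect_equal(activated_cortex_diameter(0.89, p), 2.65, tolerance = 1e-12)
  expect_equal(activated_cortex_diameter(0.89, p) / 2, 1.33, tolerance = 0.01)
  # direct evaluation oracle at I = 0.5
  expect_equal(activated_cortex_diameter(0.5, p),
               5.3 / (1 + exp(5.85 * 0.39)), tolerance = 1e-12)
  # saturation from below, strict monotonicity, bounds (within the range
  # where the sigmoid is numerically distinguishable from its asymptote)
  I <- seq(0, 3, by = 0.02)
  ac <- activated_cortex_diameter(I, p)
  expect_true(all(diff(ac) > 0))
  expect_true(all(ac > 0 & ac < 5.3))
  expect_equal(activated_cortex_diameter(100, p), 5.3, tolerance = 1e-9)
})

test_that("inverse magnification is linear with slope 1/A", {
  p <- size_model_params()
  expect_equal(inverse_magnification(0, p), 3.67 / 29.8, tolerance = 1e-12)
  expect_equal(inverse_magnification(26.13, p), 1.0, tolerance = 1e-9)
  ecc <- c(0, 5, 10, 20)
  expect_equal(diff(inverse_magnification(ecc, p)) / diff(ecc),
               rep(1 / 29.8, 3), tolerance = 1e-12)
})

test_that("subdural size relation reproduces the printed coefficients", {
  rel <- subdural_size_relation()
  expect_equal(round(rel$a, 3), 0.044)
  expect_equal(round(rel$b, 3), 0.163)
  # evaluation at ecc = 10 against the closed form (MD/4)/A * ecc + (MD/4)*e2/A
  expect_equal(rel$a * 10 + rel$b,
               (5.3 / 4) / 29.8 * 10 + (5.3 / 4) * 3.67 / 29.8,
               tolerance = 1e-12)
  expect_equal(rel$a * 10 + rel$b, 0.044 * 10 + 0.163, tolerance = 1e-2)
  # doubling A halves both coefficients
  rel2 <- subdural_size_relation(size_model_params(A = 2 * 29.8))
  expect_equal(rel2$a, rel$a / 2, tolerance = 1e-12)
  expect_equal(rel2$b, rel$b / 2, tolerance = 1e-12)
})

test_that("pRF-to-phosphene scale combines both scaling factors", {
  p <- size_model_params()
  # unit subject slope: combined factor ~ 0.011
  expect_equal(prf_to_phosphene_scale(linear_fit(1, 0), p), 0.011,
               tolerance = 0.05)
  # subject slope equal to the subdural slope: pure intracortical/subdural ratio
  sub <- subdural_size_relation(p)
  expect_equal(prf_to_phosphene_scale(sub, p), 0.256, tolerance = 1e-2)
  expect_equal(prf_to_phosphene_scale(sub, p), 0.34 / 1.325, tolerance = 1e-12)
  # inverse proportionality in the subject slope
  expect_equal(prf_to_phosphene_scale(linear_fit(0.088, 0), p),
               prf_to_phosphene_scale(linear_fit(0.044, 0), p) / 2,
               tolerance = 1e-12)
  expect_error(prf_to_phosphene_scale(linear_fit(0, 1), p), "positive")
})

test_that("eccentricity-size fit recovers exact linear data and clamps outliers", {
  ecc <- seq(0.5, 30, length.out = 200)
  df <- data.frame(eccentricity_deg = ecc, prf_size_deg = 0.05 * ecc + 0.5)
  f <- fit_ecc_size(df)
  expect_equal(f$a, 0.05, tolerance = 1e-9)
  expect_equal(f$b, 0.5, tolerance = 1e-9)
  expect_equal(f$n_replaced, 0L)

  # one gross outlier: clamped to its prediction, coefficients recovered.
  # Reference bounds from the textbook prediction-interval formula.
  df2 <- df
  df2$prf_size_deg[100] <- df2$prf_size_deg[100] + 100
  m <- lm(prf_size_deg ~ eccentricity_deg, data = df2)
  s <- summary(m)$sigma
  xbar <- mean(ecc); sxx <- sum((ecc - xbar)^2)
  half <- qt(0.975, df = 198) * s * sqrt(1 + 1/200 + (ecc - xbar)^2 / sxx)
  outside <- abs(residuals(m)) > half + 1e-8
  expect_equal(sum(outside), 1L)
  expect_equal(which(outside), c(`100` = 100L), ignore_attr = TRUE)
  # one refit after clamping: the clamped point keeps the contaminated
  # prediction, so recovery is to O(outlier / n), ~0.5% here
  f2 <- fit_ecc_size(df2)
  expect_equal(f2$n_replaced, 1L)
  expect_equal(f2$a, 0.05, tolerance = 1e-2)
  expect_equal(f2$b, 0.5, tolerance = 1e-2)
})

test_that("degenerate eccentricity data cannot be fit", {
  df <- data.frame(eccentricity_deg = c(2, 2, 2),
                   prf_size_deg = c(0.5, 0.6, 0.7))
  expect_error(fit_ecc_size(df), "degenerate|collinear")
})

test_that("electrode projection is exact at zero distance and matches hand IDW", {
  # 3 grayordinates on the lower vertical meridian (angle 180): positions at
  # distances 1, 2, 2 mm from the probe with eccentricities 0, 3, 6
  s <- toy_surface(rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 2)),
                   polar = 180, ecc = c(0.5, 3, 6), prf = c(1, 2, 4))
  got <- electrode_to_visual_field(s, c(0, 0, 0), k = 3)
  w <- c(1, 0.5, 0.5) / 2
  expect_equal(unname(got["y_deg"]), -sum(w * c(0.5, 3, 6)), tolerance = 1e-12)
  expect_equal(unname(got["x_deg"]), 0, tolerance = 1e-12)
  expect_equal(unname(got["prf_size_deg"]), sum(w * c(1, 2, 4)),
               tolerance = 1e-12)

  # probe on a grayordinate: exact values of that grayordinate
  hit <- electrode_to_visual_field(s, c(1, 0, 0), k = 3)
  expect_equal(unname(hit["y_deg"]), -0.5, tolerance = 1e-12)
  expect_equal(unname(hit["prf_size_deg"]), 1, tolerance = 1e-12)

  expect_error(electrode_to_visual_field(s, c(0, 0, 0), k = 10), "exceeds")
})

test_that("IDW output stays within the convex hull of neighbour values", {
  set.seed(42)
  for (rep in 1:20) {
    pos <- matrix(rnorm(30), 10, 3)
    prf <- runif(10, 0.2, 3)
    ecc <- runif(10, 1, 20)
    s <- toy_surface(pos, polar = -90, ecc = ecc, prf = prf)
    got <- electrode_to_visual_field(s, rnorm(3), k = 10)
    expect_gte(got["prf_size_deg"], min(prf) - 1e-12)
    expect_lte(got["prf_size_deg"], max(prf) + 1e-12)
    expect_gte(got["x_deg"], min(-ecc) - 1e-12)  # all on left horizontal meridian
    expect_lte(got["x_deg"], max(-ecc) + 1e-12)
  }
})

test_that("derived maps have one phosphene per electrode (43 per implant)", {
  s <- generate_synthetic_surface(n_per_hemi = 400, seed = 21)
  sites <- suggest_implant_sites(s, 4)
  imps <- lapply(sites, function(v) place_implant(s, v))
  m <- derive_phosphene_map(s, imps)
  expect_equal(nrow(m$phosphenes), 172L)
  expect_equal(m$kind, "retinotopic")
  expect_equal(unname(table(m$phosphenes$implant)), rep(43L, 4),
               ignore_attr = TRUE)
  m1 <- derive_phosphene_map(s, imps[[1]])
  expect_equal(nrow(m1$phosphenes), 43L)
})

test_that("phosphene radii follow the closed-form chain on noise-free surfaces", {
  s <- generate_synthetic_surface(n_per_hemi = 800, size_noise_sd = 0,
                                  size_slope = 0.05, size_intercept = 0.5,
                                  seed = 13)
  sites <- suggest_implant_sites(s, 2)
  imps <- lapply(sites, function(v) place_implant(s, v))
  m <- derive_phosphene_map(s, imps)
  p <- size_model_params()
  scale <- prf_to_phosphene_scale(linear_fit(0.05, 0.5), p)
  # per-phosphene: radius = (0.05*ecc_e + 0.5) * scale with ecc_e the IDW
  # eccentricity of the electrode; prf_size is IDW-interpolated from an
  # exactly linear field, so verify against the interpolated prf directly
  for (i in seq_len(nrow(m$phosphenes))) {
    imp <- m$phosphenes$implant[i]; el <- m$phosphenes$electrode[i]
    vf <- electrode_to_visual_field(s, imps[[imp]]$electrode_positions[el, ])
    expect_equal(m$phosphenes$radius_deg[i], vf["prf_size_deg"] * scale,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # radii increase with electrode eccentricity (positive slope chain)
  ecc_e <- sqrt(m$phosphenes$x_deg^2 + m$phosphenes$y_deg^2)
  expect_gt(cor(ecc_e, m$phosphenes$radius_deg), 0.99)
})

test_that("mirrored implants on a mirror-symmetric brain mirror the map", {
  lh <- flat_patch(x0 = 8)$grayordinates            # right hemisphere patch
  rh <- lh
  rh$x_mm <- -rh$x_mm
  rh$polar_angle_deg <- -rh$polar_angle_deg          # mirror hemifield
  rh$hemisphere <- "left"
  rh$id <- rh$id + nrow(lh)
  s <- retinotopic_surface(rbind(lh, rh), "mirror")
  n <- nrow(lh)
  im_r <- place_implant(s, 112, 0)
  im_l <- place_implant(s, 112 + n, 0)
  m <- derive_phosphene_map(s, list(im_r, im_l), k = 20)
  a <- m$phosphenes[m$phosphenes$implant == 1, ]
  b <- m$phosphenes[m$phosphenes$implant == 2, ]
  # same electrodes up to mirror: x negated (possibly with electrode order
  # permuted by the mirrored frame), y and radii preserved as sets
  expect_equal(sort(a$x_deg), sort(-b$x_deg), tolerance = 1e-6)
  expect_equal(sort(a$y_deg), sort(b$y_deg), tolerance = 1e-6)
  expect_equal(sort(a$radius_deg), sort(b$radius_deg), tolerance = 1e-6)
})

test_that("control maps are deterministic, matched in count and uniform on the disc", {
  fit <- linear_fit(0.05, 0.5)
  m1 <- generate_control_map(172, fit, field_radius = 12, seed = 5)
  m2 <- generate_control_map(172, fit, field_radius = 12, seed = 5)
  expect_identical(m1$phosphenes, m2$phosphenes)
  expect_equal(nrow(m1$phosphenes), 172L)
  expect_equal(m1$kind, "control")
  ecc <- sqrt(m1$phosphenes$x_deg^2 + m1$phosphenes$y_deg^2)
  expect_true(all(ecc <= 12))
  # radii follow the scaled linear law
  scale <- prf_to_phosphene_scale(fit)
  expect_equal(m1$phosphenes$radius_deg, (0.05 * ecc + 0.5) * scale,
               tolerance = 1e-12)
  # uniform-disc expectation: mean eccentricity -> (2/3) R within 1%
  big <- generate_control_map(1e5, fit, field_radius = 12, seed = 8)
  eccb <- sqrt(big$phosphenes$x_deg^2 + big$phosphenes$y_deg^2)
  expect_equal(mean(eccb), 2 / 3 * 12, tolerance = 0.01)
})

test_that("phosphene maps round-trip through CSV + JSON sidecar", {
  s <- generate_synthetic_surface(n_per_hemi = 400, seed = 2)
  imps <- lapply(suggest_implant_sites(s, 2), function(v) place_implant(s, v))
  m <- derive_phosphene_map(s, imps)
  path <- withr::local_tempfile(fileext = ".csv")
  write_phosphene_map(m, path)
  r <- read_phosphene_map(path)
  expect_equal(r$phosphenes$x_deg, m$phosphenes$x_deg)
  expect_equal(r$phosphenes$radius_deg, m$phosphenes$radius_deg)
  expect_equal(r$kind, m$kind)
  expect_equal(r$px_per_deg, m$px_per_deg)
  expect_equal(r$canvas, m$canvas)
})
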