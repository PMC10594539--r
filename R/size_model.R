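#' Phosphene size model parameters
#'
#' Constants of the sigmoidal activated-cortex model and the cortical
#' magnification relation used to convert population receptive-field (pRF)
#' sizes into phosphene sizes. Defaults are the published model constants:
#' the activated cortical diameter saturates at `MD` mm with half-saturation
#' current `I50` mA and maximum slope `slope` mm/mA; the inverse cortical
#' magnification is `(ecc + e2)/A` deg/mm; intracortical stimulation at
#' `intracortical_current` mA is taken to activate a cortical radius of
#' `intracortical_radius` mm.
#'
#' @param MD predicted maximum activated-cortex diameter, mm.
#' @param I50 half of the saturation current, mA.
#' @param slope maximum slope of diameter increase with current, mm/mA.
#' @param e2 eccentricity at which cortical magnification halves, deg.
#' @param A cortical scaling factor, dimensionless.
#' @param intracortical_radius activated radius under intracortical
#'   stimulation, mm (taken as a given constant).
#' @param intracortical_current nominal intracortical current, mA.
#' @return A `size_model_params` list.
#' @export
size_model_params <- function(MD = 5.3, I50 = 0.89, slope = 5.85,
                              e2 = 3.67, A = 29.8,
                              intracortical_radius = 0.34,
                              intracortical_current = 0.08) {
  p <- list(MD = MD, I50 = I50, slope = slope, e2 = e2, A = A,
            intracortical_radius = intracortical_radius,
            intracortical_current = intracortical_current)
  if (any(unlist(p) <= 0)) stopf("all size-model parameters must be positive")
  structure(p, class = "size_model_params")
}

#' Activated cortical diameter as a function of current
#'
#' Sigmoid model `AC = MD / (1 + exp(-slope * (I - I50)))`: the diameter of
#' the cortical patch activated by subdural stimulation at current `I`,
#' bounded in (0, MD) and strictly increasing in `I`. At `I = I50` the
#' diameter is `MD/2`.
#'
#' @param I stimulation current, mA (vectorised, >= 0).
#' @param params a [size_model_params()].
#' @return Activated diameter(s), mm.
#' @export
activated_cortex_diameter <- function(I, params = size_model_params()) {
  stopifnot(all(I >= 0))
  params$MD / (1 + exp(-params$slope * (I - params$I50)))
}

#' Inverse cortical magnification
#'
#' `1/M = (ecc + e2) / A` in degrees of visual field per millimetre of
#' cortex; linear in eccentricity with slope `1/A`.
#'
#' @param ecc eccentricity, deg (vectorised, >= 0).
#' @param params a [size_model_params()].
#' @return deg/mm.
#' @export
inverse_magnification <- function(ecc, params = size_model_params()) {
  stopifnot(all(ecc >= 0))
  (ecc + params$e2) / params$A
}

#' Linear fit container
#'
#' Slope/intercept pair for linear eccentricity-size relations, with the
#' number of observations clamped during robust fitting.
#'
#' @param a slope (deg size per deg eccentricity).
#' @param b intercept (deg).
#' @param n_replaced observations replaced by their predicted value.
#' @param n number of observations behind the fit.
#' @return A `linear_fit` list.
#' @export
linear_fit <- function(a, b, n_replaced = 0L, n = NA_integer_) {
  stopifnot(is.finite(a), is.finite(b))
  structure(list(a = a, b = b, n_replaced = as.integer(n_replaced), n = n),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: size = %.4f * ecc + %.4f (n = %s, %d clamped)\n",
              x$a, x$b, x$n %||% NA, x$n_replaced))
  invisible(x)
}

#' Phosphene radius vs eccentricity for subdural stimulation
#'
#' At half-saturation current the activated cortical radius is `MD/4` mm;
#' multiplying by the inverse magnification gives the linear relation
#' `radius = (MD/4)/A * ecc + (MD/4)*e2/A` (deg). With the default
#' constants the coefficients evaluate to 0.044 and 0.163 (3 d.p.).
#'
#' @param params a [size_model_params()].
#' @return A [linear_fit()] with the subdural slope `a` and intercept `b`.
#' @export
subdural_size_relation <- function(params = size_model_params()) {
  r <- activated_cortex_diameter(params$I50, params) / 2   # = MD/4
  linear_fit(a = r / params$A, b = r * params$e2 / params$A)
}

#' Scaling factor from pRF size to phosphene size
#'
#' Combines the two scaling steps of the size model: (i) rescale a subject's
#' eccentricity-to-pRF-size slope `a` onto the subdural phosphene-size slope
#' (factor `a_subdural / a`), and (ii) shrink subdural to intracortical
#' stimulation by the ratio of activated radii (0.34 mm intracortical over
#' the `MD/4` = 1.325 mm subdural radius at half-saturation, approximately
#' 0.256). With default constants the combined factor is about `0.011 / a`.
#'
#' @param subject_fit a [linear_fit()] of pRF size vs eccentricity for the
#'   subject (slope must be positive).
#' @param params a [size_model_params()].
#' @return Dimensionless scale factor applied to pRF sizes.
#' @export
prf_to_phosphene_scale <- function(subject_fit, params = size_model_params()) {
  if (!is.finite(subject_fit$a) || subject_fit$a <= 0)
    stopf("subject eccentricity-size slope must be positive (got %s)",
          format(subject_fit$a))
  sub <- subdural_size_relation(params)
  subdural_radius <- activated_cortex_diameter(params$I50, params) / 2
  (sub$a / subject_fit$a) * (params$intracortical_radius / subdural_radius)
}

#' Robust linear fit of pRF size against eccentricity
#'
#' Ordinary least squares of pRF size (response) on eccentricity (predictor)
#' over the V1 and V2 grayordinates, with outlier clamping: observations
#' outside their 95% prediction bounds are replaced by the predicted value
#' and the model is refit once. The number of clamped observations is
#' reported so the clamping can be audited.
#'
#' @param surface a [retinotopic_surface()], or a data.frame with columns
#'   `eccentricity_deg` and `prf_size_deg`.
#' @param level prediction-interval coverage (default 0.95).
#' @return A [linear_fit()].
#' @export
fit_ecc_size <- function(surface, level = 0.95) {
  g <- if (inherits(surface, "retinotopic_surface")) {
    gg <- surface$grayordinates
    gg[gg$roi %in% c("V1", "V2"), ]
  } else as.data.frame(surface)
  if (nrow(g) < 3) stopf("need at least 3 V1/V2 grayordinates to fit")
  ecc <- g$eccentricity_deg
  size <- g$prf_size_deg
  if (diff(range(ecc)) < 1e-12)
    stopf("degenerate fit: eccentricities are collinear (no spread)")
  df <- data.frame(ecc = ecc, size = size)
  m <- stats::lm(size ~ ecc, data = df)
  pred <- suppressWarnings(
    stats::predict(m, interval = "prediction", level = level))
  tol <- 1e-8 * max(1, diff(range(size)))
  out <- size > pred[, "upr"] + tol | size < pred[, "lwr"] - tol
  n_rep <- sum(out)
  if (n_rep > 0) {
    df$size[out] <- pred[out, "fit"]
    m <- stats::lm(size ~ ecc, data = df)
  }
  co <- stats::coef(m)
  linear_fit(a = unname(co["ecc"]), b = unname(co["(Intercept)"]),
             n_replaced = n_rep, n = nrow(df))
}
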