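#' Divisive normalization parameters
#'
#' Bundle and validate the parameters of the divisive normalization model of
#' center-surround interaction. The normalized response of the center unit is
#' \deqn{R(\theta) = \frac{A_c C_c}{A_c C_c + C_s e^{-\theta/w} + \sigma}}
#' where `A_c` multiplicatively amplifies the center drive (focal attention or
#' good figure-ground segmentation, e.g. via high acuity), `C_c` and `C_s` are
#' the center and surround stimulus drives (contrast units, 0-1), `w` is the
#' orientation tuning width of surround suppression in degrees, and `sigma` is
#' the semi-saturation constant representing untuned (orientation-insensitive)
#' gain control.
#'
#' @param A_c center amplification, > 0.
#' @param C_c center drive (contrast, 0-1).
#' @param C_s surround drive (contrast, 0-1).
#' @param w_obs orientation tuning width of suppression, degrees, > 0.
#' @param sigma semi-saturation constant, > 0.
#' @return An object of class `norm_params`.
#' @seealso [norm_response()]
#' @export
#' @examples
#' norm_params(A_c = 2, C_c = 0.8, C_s = 0.8, w_obs = 30, sigma = 0.4)
norm_params <- function(A_c = 2, C_c = 0.8, C_s = 0.8, w_obs = 30, sigma = 0.4) {
  p <- list(A_c = A_c, C_c = C_c, C_s = C_s, w_obs = w_obs, sigma = sigma)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("norm_params: '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (A_c <= 0) stop("norm_params: A_c must be > 0", call. = FALSE)
  if (C_c < 0 || C_c > 1) stop("norm_params: C_c must be in [0, 1]", call. = FALSE)
  if (C_s < 0 || C_s > 1) stop("norm_params: C_s must be in [0, 1]", call. = FALSE)
  if (w_obs <= 0) stop("norm_params: w_obs must be > 0", call. = FALSE)
  if (sigma <= 0) stop("norm_params: sigma must be > 0", call. = FALSE)
  structure(p, class = "norm_params")
}

#' Normalized response of the center unit
#'
#' Evaluates the divisive normalization model at relative center-surround
#' orientation `theta` (degrees). Vectorized over `theta`.
#'
#' @param p a [norm_params()] object.
#' @param theta relative orientation(s), degrees, >= 0.
#' @return Normalized response(s) `R` in (0, 1).
#' @export
#' @examples
#' p <- norm_params(A_c = 2, sigma = 0.4)
#' norm_response(p, 0)   # ~0.5714
#' norm_response(p, 90)
norm_response <- function(p, theta) {
  if (!inherits(p, "norm_params")) p <- do.call(norm_params, as.list(p))
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta < 0))
    stop("norm_response: theta must be finite and >= 0", call. = FALSE)
  drive <- p$A_c * p$C_c
  drive / (drive + p$C_s * exp(-theta / p$w_obs) + p$sigma)
}

#' Simulated observer parameters
#'
#' An observer couples the normalization model to task behavior: a logistic
#' decision rule with slope `beta_true` and total lapse probability
#' `lapse_true`, a `far_gain` attenuation of the surround drive in far-surround
#' configurations, visual acuity in logMAR units, and a group label.
#'
#' @param norm a [norm_params()] object.
#' @param far_gain multiplier in `[0, 1]` applied to the surround drive for far
#'   surrounds (far surrounds produced little measurable suppression, so the
#'   default is small).
#' @param beta_true decision slope per percentage point of contrast decrement,
#'   > 0 (may be `Inf` for a deterministic observer).
#' @param lapse_true lapse probability in `[0, 0.5)`.
#' @param logmar visual acuity, logMAR units (0 is normal, larger is worse).
#' @param group group label, one of `PSZ, PBD, HC, PSZrel, PBDrel`.
#' @param observer_id identifier string.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(norm = norm_params(), far_gain = 0.15,
                            beta_true = 0.5, lapse_true = 0.04,
                            logmar = 0.08, group = "HC",
                            observer_id = "obs") {
  if (!inherits(norm, "norm_params")) norm <- do.call(norm_params, as.list(norm))
  if (!is.numeric(beta_true) || length(beta_true) != 1L || is.na(beta_true) ||
      beta_true <= 0)
    stop("observer_params: beta_true must be > 0", call. = FALSE)
  if (!is.numeric(lapse_true) || lapse_true < 0 || lapse_true >= 0.5)
    stop("observer_params: lapse_true must be in [0, 0.5)", call. = FALSE)
  if (!is.numeric(far_gain) || far_gain < 0 || far_gain > 1)
    stop("observer_params: far_gain must be in [0, 1]", call. = FALSE)
  group <- match.arg(group, c("PSZ", "PBD", "HC", "PSZrel", "PBDrel"))
  structure(list(norm = norm, far_gain = far_gain, beta_true = beta_true,
                 lapse_true = lapse_true, logmar = logmar, group = group,
                 observer_id = observer_id),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params> ", x$observer_id, " (", x$group, ")\n", sep = "")
  cat(sprintf("  A_c = %.3g, sigma = %.3g, w_obs = %.3g, C_c = %.3g, C_s = %.3g\n",
              x$norm$A_c, x$norm$sigma, x$norm$w_obs, x$norm$C_c, x$norm$C_s))
  cat(sprintf("  beta = %.3g, lapse = %.3g, far_gain = %.3g, logMAR = %.3g\n",
              x$beta_true, x$lapse_true, x$far_gain, x$logmar))
  invisible(x)
}

#' Model-true perceived-contrast decrement
#'
#' Maps the normalization model response to the quantity the matching task
#' measures: the contrast decrement (percentage points, relative to the 80%
#' target) at which the plain reference grating perceptually matches the
#' surrounded target. The read-out is the ratio to the observer's own
#' no-surround response, `delta = 80 * (R_cond / R_ns - 1)`, which anchors the
#' no-surround point of subjective equality at exactly 0. Far surrounds use a
#' surround drive attenuated by `far_gain`.
#'
#' @param obs an [observer_params()] object.
#' @param surround_class `"none"`, `"near"`, or `"far"`.
#' @param theta relative orientation(s), degrees.
#' @param target_contrast target contrast in percent (fixed at 80 in the task).
#' @return Decrement(s) in percentage points; 0 for `"none"`, <= 0 otherwise.
#' @export
#' @examples
#' obs <- observer_params()
#' perceived_decrement(obs, "near", c(0, 20, 45, 70, 90))
perceived_decrement <- function(obs, surround_class = c("none", "near", "far"),
                                theta = 0, target_contrast = 80) {
  surround_class <- match.arg(surround_class)
  if (surround_class == "none") return(rep(0, length(theta)))
  p <- obs$norm
  cs <- switch(surround_class, near = p$C_s, far = obs$far_gain * p$C_s)
  drive <- p$A_c * p$C_c
  r_cond <- drive / (drive + cs * exp(-theta / p$w_obs) + p$sigma)
  r_ns <- drive / (drive + p$sigma)
  target_contrast * (r_cond / r_ns - 1)
}

# P(respond "reference_higher") for reference decrement x, vectorized.
# F is the logistic 1 / (1 + exp(-beta (x - pse))); beta = Inf degenerates to a
# step function with F = 1/2 at x == pse.
p_reference_higher <- function(x, pse, beta, lapse) {
  if (any(is.infinite(beta))) {
    f <- ifelse(x > pse, 1, ifelse(x < pse, 0, 0.5))
    fin <- is.finite(beta)
    if (any(fin)) f[fin] <- plogis(beta[fin] * (x[fin] - pse[fin]))
  } else {
    f <- plogis(beta * (x - pse))
  }
  lapse / 2 + (1 - lapse) * f
}

#' Simulate one 2AFC matching response
#'
#' Draws the observer's response on a trial where the reference grating carries
#' contrast decrement `reference_decrement` and the observer's point of
#' subjective equality for the displayed target configuration is `true_pse`.
#' The response probability is
#' `P(reference_higher) = lapse/2 + (1 - lapse) * F(x; pse, beta)` with `F`
#' logistic; one Bernoulli draw is taken from the current RNG stream (or from
#' the supplied uniform deviate `u`).
#'
#' @param obs an [observer_params()] object.
#' @param reference_decrement reference contrast decrement, percentage points.
#' @param true_pse the observer's PSE for this condition, percentage points.
#' @param u optional uniform deviate in `[0, 1]` (defaults to one `runif()`
#'   draw), so callers can manage reproducible substreams.
#' @return `"reference_higher"` or `"target_higher"`.
#' @export
respond_trial <- function(obs, reference_decrement, true_pse, u = runif(1L)) {
  pr <- p_reference_higher(reference_decrement, true_pse,
                           obs$beta_true, obs$lapse_true)
  if (u < pr) "reference_higher" else "target_higher"
}
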