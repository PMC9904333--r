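# Exponential orientation-tuning model of surround suppression:
#   P(theta) = -M * exp(-theta / w) + o
# where P is the perceived-contrast decrement (percentage points, negative
# under suppression), M the orientation-tuned modulation magnitude, w the
# tuning width (degrees), and o the untuned (orientation-insensitive) offset.

#' Fit the exponential orientation-tuning model
#'
#' Least-squares fit of `P = -M exp(-theta/w) + o` to per-condition
#' perceived-contrast decrements. For fixed `w` the model is linear in
#' `(M, o)`, so the fit profiles the residual sum of squares over a log-spaced
#' `w` grid on `w_bounds` and refines the minimum with one-dimensional
#' optimization (tolerance 1e-8); `M` and `o` are then the exact linear
#' least-squares solution at the selected `w`. The procedure is deterministic
#' and cannot fail to converge; `M` and `o` are unbounded.
#'
#' With decrements stored as negative values, suppression at parallel implies
#' `M > 0` (group contrasts on the magnitude of `M` are invariant to this sign
#' convention).
#'
#' @param theta orientations, degrees (>= 4 distinct nonnegative values).
#' @param P perceived-contrast decrements, percentage points.
#' @param w_bounds search bounds for the tuning width, degrees.
#' @param n_grid number of profile grid points.
#' @return An object of class `tuning_fit` with components `coefficients`
#'   (`M`, `w`, `o`), `fitted.values`, `residuals`, `residual_variance` and
#'   `data_variance` (both population variances, divide-by-n), `adequate`
#'   (strict variance-reduction criterion, see [fit_adequacy()]), and
#'   `convergence`.
#' @seealso [fit_adequacy()], [fit_tuning_cohort()]
#' @export
#' @examples
#' th <- c(0, 20, 45, 70, 90)
#' P <- -20 * exp(-th / 30) - 5
#' fit <- fit_tuning(th, P)
#' coef(fit)            # M = 20, w = 30, o = -5
#' predict(fit, theta = 10)
fit_tuning <- function(theta, P, w_bounds = c(1, 180), n_grid = 120L) {
  if (length(theta) != length(P))
    stop("fit_tuning: theta and P lengths differ", call. = FALSE)
  keep <- is.finite(theta) & is.finite(P)
  theta <- theta[keep]; P <- P[keep]
  if (length(theta) < 4L || anyDuplicated(theta) || any(theta < 0))
    stop("fit_tuning: need >= 4 distinct nonnegative orientations",
         call. = FALSE)
  cl <- match.call()

  solve_w <- function(w) {
    b <- exp(-theta / w)
    fit <- lm.fit(cbind(o = 1, M = -b), P)
    list(sse = sum(fit$residuals^2), M = unname(fit$coefficients["M"]),
         o = unname(fit$coefficients["o"]))
  }
  wgrid <- exp(seq(log(w_bounds[1L]), log(w_bounds[2L]),
                   length.out = n_grid))
  sses <- vapply(wgrid, function(w) solve_w(w)$sse, numeric(1L))
  i <- which.min(sses)
  lo <- wgrid[max(1L, i - 1L)]
  hi <- wgrid[min(n_grid, i + 1L)]
  w_hat <- wgrid[i]; sse_hat <- sses[i]
  if (hi > lo) {
    opt <- optimize(function(w) solve_w(w)$sse, c(lo, hi), tol = 1e-8)
    if (opt$objective < sse_hat) {
      w_hat <- opt$minimum; sse_hat <- opt$objective
    }
  }
  best <- solve_w(w_hat)
  fitted <- -best$M * exp(-theta / w_hat) + best$o
  res <- P - fitted
  var_pop <- function(z) mean((z - mean(z))^2)
  rv <- var_pop(res); dv <- var_pop(P)
  structure(list(coefficients = c(M = best$M, w = w_hat, o = best$o),
                 theta = theta, P = P,
                 fitted.values = fitted, residuals = res,
                 sse = sse_hat, residual_variance = rv, data_variance = dv,
                 adequate = rv < dv, convergence = TRUE, call = cl),
            class = "tuning_fit")
}

#' Strict variance-reduction adequacy criterion
#'
#' A fit is adequate when the variance of the residuals (data minus fit) is
#' strictly lower than the variance of the raw data; both are population
#' variances (divide by n). A fit no better than a constant -- including any
#' fit to constant data -- is inadequate.
#'
#' @param P observed decrements.
#' @param fitted_values fitted decrements (same length).
#' @return Logical flag.
#' @export
fit_adequacy <- function(P, fitted_values) {
  if (length(P) != length(fitted_values))
    stop("fit_adequacy: length mismatch", call. = FALSE)
  var_pop <- function(z) mean((z - mean(z))^2)
  var_pop(P - fitted_values) < var_pop(P)
}

#' @export
print.tuning_fit <- function(x, digits = 4, ...) {
  cat("Exponential orientation-tuning fit: P = -M exp(-theta/w) + o\n")
  print(round(x$coefficients, digits))
  cat("residual variance", format(x$residual_variance, digits = digits),
      "vs data variance", format(x$data_variance, digits = digits),
      if (x$adequate) "(adequate)\n" else "(NOT adequate)\n")
  invisible(x)
}

#' @export
summary.tuning_fit <- function(object, ...) {
  structure(list(coefficients = object$coefficients,
                 residuals = object$residuals,
                 residual_variance = object$residual_variance,
                 data_variance = object$data_variance,
                 adequate = object$adequate,
                 n = length(object$P), call = object$call),
            class = "summary.tuning_fit")
}

#' @export
print.summary.tuning_fit <- function(x, digits = 4, ...) {
  cat("Call:\n"); print(x$call)
  cat("\nCoefficients:\n"); print(round(x$coefficients, digits))
  cat("\nResiduals (", x$n, " points):\n", sep = "")
  print(round(x$residuals, digits))
  cat("\nresidual variance:", format(x$residual_variance, digits = digits),
      "  data variance:", format(x$data_variance, digits = digits),
      "  adequate:", x$adequate, "\n")
  invisible(x)
}

#' @export
coef.tuning_fit <- function(object, ...) object$coefficients

#' @export
fitted.tuning_fit <- function(object, ...) object$fitted.values

#' @export
residuals.tuning_fit <- function(object, ...) object$residuals

#' Predict from a tuning fit
#'
#' @param object a [fit_tuning()] object.
#' @param theta orientations (degrees) at which to evaluate the fitted curve;
#'   defaults to the fitted orientations.
#' @param ... unused.
#' @return Predicted decrements.
#' @export
predict.tuning_fit <- function(object, theta = NULL, ...) {
  if (is.null(theta)) return(object$fitted.values)
  cf <- object$coefficients
  -cf[["M"]] * exp(-theta / cf[["w"]]) + cf[["o"]]
}

#' Simulate decrement data from a tuning fit
#'
#' Draws Gaussian noise with the fit's residual standard deviation around the
#' fitted curve.
#'
#' @param object a [fit_tuning()] object.
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A data frame with one column per simulation.
#' @export
simulate.tuning_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  s <- sqrt(object$residual_variance)
  out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), 0, s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.tuning_fit <- function(x, ...) {
  cf <- x$coefficients
  plot(x$theta, x$P, xlab = "relative orientation (deg)",
       ylab = "contrast decrement (pp)", pch = 19, ...)
  th <- seq(min(x$theta), max(x$theta), length.out = 200)
  lines(th, -cf[["M"]] * exp(-th / cf[["w"]]) + cf[["o"]])
  invisible(x)
}

#' Fit tuning curves for a cohort of session summaries
#'
#' Fits the exponential model to each observer's five near-surround estimates
#' (0, 20, 45, 70, 90 degrees).
#'
#' @param summaries data frame with one row per observer and columns
#'   `observer_id`, `group`, `logmar`, `near_0` ... `near_90`.
#' @return A data frame with one row per observer: fitted `M`, `w`, `o`,
#'   `residual_variance`, `data_variance`, `adequate`.
#' @export
fit_tuning_cohort <- function(summaries) {
  th <- c(0, 20, 45, 70, 90)
  cols <- paste0("near_", th)
  stopifnot(all(cols %in% names(summaries)))
  out <- summaries[, intersect(c("observer_id", "group", "logmar"),
                               names(summaries)), drop = FALSE]
  out$M <- out$w <- out$o <- out$residual_variance <-
    out$data_variance <- NA_real_
  out$adequate <- NA
  for (i in seq_len(nrow(summaries))) {
    P <- as.numeric(summaries[i, cols])
    if (any(!is.finite(P))) next
    f <- fit_tuning(th, P)
    out$M[i] <- f$coefficients[["M"]]
    out$w[i] <- f$coefficients[["w"]]
    out$o[i] <- f$coefficients[["o"]]
    out$residual_variance[i] <- f$residual_variance
    out$data_variance[i] <- f$data_variance
    out$adequate[i] <- f$adequate
  }
  out
}
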