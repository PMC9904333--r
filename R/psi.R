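# Psi adaptive staircase: grid posterior over psychometric threshold (alpha)
# and slope (beta), expected-entropy stimulus placement, Bayes updates.
#
# Grid cells are stored as a vector with alpha varying fastest. All heavy
# per-trial quantities reduce to products with matrices precomputed in
# psi_config(), so many staircases can be advanced together by stacking their
# posteriors as columns (used by the session engine).

xlogx <- function(p) {
  out <- p * log(p)
  out[p <= 0] <- 0
  out
}

#' Configuration (and precomputation) for a Psi staircase
#'
#' Defines the discretization of the psychometric model: a threshold grid
#' `alpha` (the contrast decrement, percentage points, at which the reference
#' is judged higher 50% of the time), a slope grid `beta`, a candidate
#' stimulus grid `intensity`, and a total lapse probability `delta` split
#' evenly between the two response tails. The psychometric family is logistic
#' by default (`F(x; a, b) = 1/(1 + exp(-b (x - a)))`), with a
#' cumulative-normal alternative. Defaults follow the task's staircase
#' settings: alpha in \[-40, 20\] step 1, beta in \[0.1, 5\] step 0.05,
#' intensity in \[-75, 15\] step 1, delta 0.08.
#'
#' The constructor precomputes the response-likelihood table over
#' `intensity x (alpha, beta)` together with its entropy transforms, which is
#' what makes trial placement a pair of matrix products.
#'
#' @param alpha threshold grid (strictly increasing, uniform spacing).
#' @param beta slope grid (strictly increasing, uniform spacing).
#' @param intensity candidate reference decrements (strictly increasing,
#'   uniform spacing).
#' @param delta total lapse probability in `[0, 0.5)`.
#' @param family psychometric family, `"logistic"` or `"gaussian"`.
#' @return An object of class `psi_config`.
#' @export
psi_config <- function(alpha = -40:20, beta = seq(0.1, 5, by = 0.05),
                       intensity = -75:15, delta = 0.08,
                       family = c("logistic", "gaussian")) {
  family <- match.arg(family)
  check_grid <- function(g, nm) {
    if (length(g) == 0L || any(!is.finite(g)))
      stop("psi_config: grid '", nm, "' must be nonempty and finite",
           call. = FALSE)
    if (length(g) > 1L) {
      d <- diff(g)
      if (any(d <= 0) || diff(range(d)) > 1e-8 * max(abs(d)))
        stop("psi_config: grid '", nm,
             "' must be strictly increasing with uniform spacing",
             call. = FALSE)
    }
  }
  check_grid(alpha, "alpha"); check_grid(beta, "beta")
  check_grid(intensity, "intensity")
  if (!is.numeric(delta) || delta < 0 || delta >= 0.5)
    stop("psi_config: delta must be in [0, 0.5)", call. = FALSE)

  n_a <- length(alpha); n_b <- length(beta); n_x <- length(intensity)
  alpha_cell <- rep(alpha, times = n_b)
  beta_cell <- rep(beta, each = n_a)
  z <- outer(intensity, alpha_cell, "-") *
    matrix(beta_cell, n_x, n_a * n_b, byrow = TRUE)
  F <- switch(family, logistic = plogis(z), gaussian = pnorm(z))
  L <- delta / 2 + (1 - delta) * F          # P(reference_higher | x, a, b)
  cfg <- list(alpha = alpha, beta = beta, intensity = intensity,
              delta = delta, family = family,
              n_a = n_a, n_b = n_b, n_x = n_x,
              alpha_cell = alpha_cell, beta_cell = beta_cell,
              K = rbind(L, xlogx(L), xlogx(1 - L)),  # (3 n_x) x cells
              Lt = t(L))                              # cells x n_x
  class(cfg) <- "psi_config"
  cfg
}

#' @export
print.psi_config <- function(x, ...) {
  cat("<psi_config> ", x$family, " family, delta = ", x$delta, "\n", sep = "")
  cat(sprintf("  alpha: [%g, %g] x %d; beta: [%g, %g] x %d; intensity: [%g, %g] x %d\n",
              min(x$alpha), max(x$alpha), x$n_a,
              min(x$beta), max(x$beta), x$n_b,
              min(x$intensity), max(x$intensity), x$n_x))
  invisible(x)
}

#' Initialize a Psi staircase
#'
#' Starts from a uniform joint posterior over the (alpha, beta) grid.
#'
#' @param config a [psi_config()].
#' @return An object of class `psi_state` with fields `posterior` (cell
#'   vector), `trial_count`, `estimate_history` (posterior-mean threshold
#'   after each completed trial), and trial traces `x_history`,
#'   `response_history`.
#' @export
psi_init <- function(config = psi_config()) {
  n <- config$n_a * config$n_b
  structure(list(posterior = rep(1 / n, n),
                 trial_count = 0L,
                 estimate_history = numeric(0),
                 x_history = numeric(0),
                 response_history = character(0),
                 alpha_cell = config$alpha_cell),
            class = "psi_state")
}

#' @export
print.psi_state <- function(x, ...) {
  cat("<psi_state> ", x$trial_count, " trial(s); threshold estimate ",
      format(psi_threshold(x), digits = 4), "\n", sep = "")
  invisible(x)
}

# Expected-entropy placement for a batch of posteriors (columns of Pmat).
# Returns the intensity-grid index minimizing
#   E[H] = p1 log p1 + p0 log p0 - A1 - A0
# per column, with ties broken toward the smallest intensity.
psi_entropy_select_idx <- function(Pmat, config) {
  cs <- colSums(Pmat)
  if (any(!is.finite(cs)) || any(cs <= 0))
    stop("psi_select: degenerate (all-zero) posterior", call. = FALSE)
  n_x <- config$n_x
  V2 <- xlogx(Pmat)
  G <- config$K %*% Pmat                     # 3 n_x stacked blocks
  Gb <- crossprod(config$Lt, V2)             # L %*% (post log post)
  P1 <- G[seq_len(n_x), , drop = FALSE]
  A1 <- G[n_x + seq_len(n_x), , drop = FALSE] + Gb
  A0 <- G[2L * n_x + seq_len(n_x), , drop = FALSE] +
    rep(colSums(V2), each = n_x) - Gb
  EH <- xlogx(P1) + xlogx(1 - P1) - A1 - A0
  # ties (within floating-point noise of the minimum) resolve to the
  # smallest candidate intensity
  mins <- EH[1L, ]
  for (i in seq_len(n_x)[-1L]) mins <- pmin(mins, EH[i, ])
  thr <- mins + 1e-9 * pmax(1, abs(mins))
  max.col(t(EH <= rep(thr, each = n_x)), ties.method = "first")
}

#' Select the next stimulus of a Psi staircase
#'
#' Returns the candidate reference decrement minimizing the expected posterior
#' entropy over the two possible responses, marginalized over the current
#' posterior; ties are broken toward the smallest intensity.
#'
#' @param state a [psi_init()] state.
#' @param config the matching [psi_config()].
#' @return A single intensity from `config$intensity`.
#' @export
psi_select <- function(state, config = psi_config()) {
  idx <- psi_entropy_select_idx(matrix(state$posterior, ncol = 1L), config)
  config$intensity[idx]
}

#' Bayes-update a Psi staircase with one response
#'
#' Multiplies the posterior by the response likelihood
#' `L = delta/2 + (1 - delta) F(x; alpha, beta)` (or `1 - L` for
#' `"target_higher"`), renormalizes, and appends the posterior-mean threshold
#' to the estimate history.
#'
#' @param state a `psi_state`.
#' @param x the presented intensity (must lie on `config$intensity`).
#' @param response `"reference_higher"` or `"target_higher"`.
#' @param config the matching [psi_config()].
#' @return The updated `psi_state`.
#' @export
psi_update <- function(state, x, response, config = psi_config()) {
  xi <- match(x, config$intensity)
  if (is.na(xi)) stop("psi_update: x is not on the intensity grid",
                      call. = FALSE)
  response <- match.arg(response, c("reference_higher", "target_higher"))
  lik <- config$Lt[, xi]
  if (response == "target_higher") lik <- 1 - lik
  q <- state$posterior * lik
  z <- sum(q)
  if (!is.finite(z) || z <= 0)
    stop("psi_update: zero normalizing constant (numerical degeneracy)",
         call. = FALSE)
  state$posterior <- q / z
  state$trial_count <- state$trial_count + 1L
  est <- sum(state$alpha_cell * state$posterior)
  state$estimate_history <- c(state$estimate_history, est)
  state$x_history <- c(state$x_history, x)
  state$response_history <- c(state$response_history, response)
  state
}

#' Posterior-mean threshold of a Psi staircase
#'
#' @param state a `psi_state`.
#' @return The posterior mean of alpha (marginal over beta), in
#'   percentage-point decrement units.
#' @export
psi_threshold <- function(state) {
  sum(state$alpha_cell * state$posterior)
}

#' Run a complete Psi staircase against a simulated observer
#'
#' Iterates select / respond / update for `n_trials` trials. Responses are
#' drawn with [respond_trial()] from the current RNG stream.
#'
#' @param obs an [observer_params()] object.
#' @param true_pse the observer's PSE for the tested condition (percentage
#'   points).
#' @param n_trials number of trials, >= 1.
#' @param config a [psi_config()].
#' @return The final `psi_state`, with full `estimate_history`.
#' @export
#' @examples
#' set.seed(7)
#' obs <- observer_params(beta_true = 5, lapse_true = 0)
#' st <- run_staircase(obs, true_pse = -20, n_trials = 48)
#' mean(tail(st$estimate_history, 3))
run_staircase <- function(obs, true_pse, n_trials = 48L,
                          config = psi_config()) {
  if (n_trials < 1L) stop("run_staircase: n_trials must be >= 1",
                          call. = FALSE)
  state <- psi_init(config)
  for (t in seq_len(n_trials)) {
    x <- psi_select(state, config)
    r <- respond_trial(obs, x, true_pse)
    state <- psi_update(state, x, r, config)
  }
  state
}

# Advance N independent staircases together. pse/beta/lapse are length-N;
# U is an n_trials x N matrix of uniform deviates (one per trial and column,
# consumed row by row). Column j evolves exactly as a lone staircase fed the
# same deviates.
psi_run_batch <- function(pse, beta, lapse, n_trials, config, U) {
  N <- length(pse)
  stopifnot(nrow(U) >= n_trials, ncol(U) == N)
  n_cell <- config$n_a * config$n_b
  P <- matrix(1 / n_cell, n_cell, N)
  est <- xs <- matrix(NA_real_, n_trials, N)
  ref_higher <- matrix(NA, n_trials, N)
  for (t in seq_len(n_trials)) {
    xi <- psi_entropy_select_idx(P, config)
    x <- config$intensity[xi]
    pr <- p_reference_higher(x, pse, beta, lapse)
    r <- U[t, ] < pr
    lik <- config$Lt[, xi, drop = FALSE]
    if (any(!r)) lik[, !r] <- 1 - lik[, !r, drop = FALSE]
    P <- P * lik
    z <- colSums(P)
    if (any(!is.finite(z)) || any(z <= 0))
      stop("psi_run_batch: zero normalizing constant", call. = FALSE)
    P <- P * rep(1 / z, each = n_cell)
    xs[t, ] <- x
    ref_higher[t, ] <- r
    est[t, ] <- as.numeric(crossprod(P, config$alpha_cell))
  }
  list(estimate_history = est, x = xs, reference_higher = ref_higher,
       posterior = P)
}
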