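# Independent oracles used across the suite. These deliberately share no code
# with the package internals: plain loops and textbook formulas.

# Brute-force expected-entropy stimulus selection for the Psi staircase.
# post: matrix length(alpha) x length(beta); returns the candidate x
# minimizing sum_r p(r|x) H(posterior | x, r), ties toward the smallest x.
oracle_psi_select <- function(post, alpha, beta, x_cands, delta = 0,
                              family = "logistic") {
  Ffun <- switch(family, logistic = plogis, gaussian = pnorm)
  best_x <- NA_real_
  best_eh <- Inf
  for (x in sort(x_cands)) {
    eh <- 0
    for (r in c(TRUE, FALSE)) {
      num <- matrix(0, length(alpha), length(beta))
      for (i in seq_along(alpha)) {
        for (j in seq_along(beta)) {
          L <- delta / 2 + (1 - delta) * Ffun(beta[j] * (x - alpha[i]))
          num[i, j] <- post[i, j] * (if (r) L else 1 - L)
        }
      }
      pr <- sum(num)
      if (pr > 0) {
        q <- num / pr
        H <- -sum(q[q > 0] * log(q[q > 0]))
        eh <- eh + pr * H
      }
    }
    if (eh < best_eh - 1e-12) {
      best_eh <- eh
      best_x <- x
    }
  }
  best_x
}

# Step-by-step Huynh-Feldt epsilon using a different orthonormal contrast
# basis (QR completion of the unit vector) than the package's Helmert basis.
oracle_hf_epsilon <- function(S, n, g) {
  k <- nrow(S)
  Q <- qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
  T <- t(Q) %*% S %*% Q
  gg <- sum(diag(T))^2 / ((k - 1) * sum(T * T))
  hf <- ((n - g + 1) * (k - 1) * gg - 2) / ((k - 1) * (n - g - (k - 1) * gg))
  min(1, max(1 / (k - 1), hf))
}

# Random symmetric positive-definite matrix.
random_spd <- function(k) {
  A <- matrix(rnorm(k * k), k)
  crossprod(A) + diag(k) * 0.1
}

# Population (divide-by-n) variance.
var_pop <- function(z) mean((z - mean(z))^2)

# Default near-surround orientations.
near_thetas <- c(0, 20, 45, 70, 90)

# Noise-free model decrements of one cohort row at the near orientations.
model_near_curve <- function(cohort, i) {
  perceived_decrement(cohort_observer(cohort, i), "near", near_thetas)
}
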