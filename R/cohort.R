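#' The 11 task conditions
#'
#' One no-surround condition plus near and far surrounds at relative
#' orientations 0, 20, 45, 70 and 90 degrees.
#'
#' @return A data frame with columns `condition`, `surround`, `theta`.
#' @export
condition_table <- function() {
  th <- c(0, 20, 45, 70, 90)
  data.frame(
    condition = c("no_surround", paste0("near_", th), paste0("far_", th)),
    surround = c("none", rep("near", 5L), rep("far", 5L)),
    theta = c(0, th, th),
    stringsAsFactors = FALSE
  )
}

#' Model-true PSEs of an observer for all task conditions
#'
#' @param obs an [observer_params()] object.
#' @return Named numeric vector of perceived-contrast decrements (percentage
#'   points), one per condition of [condition_table()].
#' @export
true_pses <- function(obs) {
  ct <- condition_table()
  out <- numeric(nrow(ct))
  for (i in seq_len(nrow(ct)))
    out[i] <- perceived_decrement(obs, ct$surround[i], ct$theta[i])
  names(out) <- ct$condition
  out
}

#' Specification of a simulated cohort
#'
#' Defines the generative conditions for a five-group cohort: group sizes,
#' per-group acuity (logMAR) distributions, the mapping from acuity to center
#' amplification `A_c`, and per-group semi-saturation (`sigma`) rules that may
#' depend on acuity. Defaults encode the study conditions this package
#' emulates: analyzed sample sizes 31/29/29/28/21 (PSZ/PBD/HC/PSZrel/PBDrel),
#' group acuity means and SDs from the study's demographics, `A_c = 2` for
#' acuity at logMAR 0.1 or better and `A_c = 1` otherwise, strong untuned gain
#' control (`sigma = 0.4`) in HC and PBDrel, reduced gain control
#' (`sigma = 0.1`) in PSZ with low acuity, and intermediate values (0.25) for
#' PBD and PSZrel.
#'
#' @param sizes named integer vector of group sizes.
#' @param logmar_mean,logmar_sd named numeric vectors of per-group acuity
#'   means/SDs (logMAR).
#' @param logmar_min lower truncation for sampled acuity.
#' @param acuity_threshold logMAR value separating high from low acuity.
#' @param A_c_high,A_c_low center amplification for acuity at or better than /
#'   worse than the threshold.
#' @param sigma_high,sigma_low named numeric vectors giving each group's
#'   semi-saturation constant for high- and low-acuity members.
#' @param w_obs,beta_true,lapse_true,far_gain,C_c,C_s shared observer
#'   parameters.
#' @param seed optional integer seed stored with the spec; [sample_cohort()]
#'   uses it when set.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(sizes = c(PSZ = 31L, PBD = 29L, HC = 29L,
                                  PSZrel = 28L, PBDrel = 21L),
                        logmar_mean = c(PSZ = 0.14, PBD = 0.12, HC = 0.08,
                                        PSZrel = 0.10, PBDrel = 0.04),
                        logmar_sd = c(PSZ = 0.15, PBD = 0.12, HC = 0.13,
                                      PSZrel = 0.12, PBDrel = 0.10),
                        logmar_min = -0.3,
                        acuity_threshold = 0.1,
                        A_c_high = 2.0, A_c_low = 1.0,
                        sigma_high = c(PSZ = 0.4, PBD = 0.25, HC = 0.4,
                                       PSZrel = 0.25, PBDrel = 0.4),
                        sigma_low = c(PSZ = 0.1, PBD = 0.25, HC = 0.4,
                                      PSZrel = 0.25, PBDrel = 0.4),
                        w_obs = 30, beta_true = 0.5, lapse_true = 0.04,
                        far_gain = 0.15, C_c = 0.8, C_s = 0.8,
                        seed = NULL) {
  groups <- names(sizes)
  if (is.null(groups) || any(!nzchar(groups)))
    stop("cohort_spec: 'sizes' must be a named vector", call. = FALSE)
  if (any(sizes < 0) || any(!is.finite(sizes)))
    stop("cohort_spec: group sizes must be finite and >= 0", call. = FALSE)
  if (any(logmar_sd[groups] < 0)) stop("cohort_spec: logmar_sd must be >= 0",
                                       call. = FALSE)
  num <- c(logmar_mean[groups], logmar_sd[groups], logmar_min,
           acuity_threshold, A_c_high, A_c_low, sigma_high[groups],
           sigma_low[groups], w_obs, beta_true, lapse_true, far_gain, C_c, C_s)
  if (any(!is.finite(num)))
    stop("cohort_spec: all numeric fields must be finite and cover every group",
         call. = FALSE)
  structure(list(sizes = sizes, logmar_mean = logmar_mean,
                 logmar_sd = logmar_sd, logmar_min = logmar_min,
                 acuity_threshold = acuity_threshold,
                 A_c_high = A_c_high, A_c_low = A_c_low,
                 sigma_high = sigma_high, sigma_low = sigma_low,
                 w_obs = w_obs, beta_true = beta_true,
                 lapse_true = lapse_true, far_gain = far_gain,
                 C_c = C_c, C_s = C_s, seed = seed),
            class = "cohort_spec")
}

# Truncated-normal draws via inverse-CDF so each observation consumes exactly
# one uniform deviate.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (any(sd == 0)) return(rep(mean, length.out = n))
  plo <- pnorm((lower - mean) / sd)
  u <- runif(n, min = plo, max = 1)
  mean + sd * qnorm(u)
}

#' Sample a cohort of simulated observers
#'
#' Draws one observer table from a [cohort_spec()]: per-group acuity from a
#' truncated normal, `A_c` from the acuity mapping, `sigma` from the group
#' rule, and shared decision parameters. Identical seeds produce identical
#' cohorts.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional integer seed; overrides `spec$seed`. When both are
#'   `NULL` the current RNG stream is used.
#' @return A data frame of class `cohort` with one row per observer and a
#'   per-observer `seed` column for downstream session simulation.
#' @export
#' @examples
#' coh <- sample_cohort(cohort_spec(), seed = 1)
#' table(coh$group)
sample_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!inherits(spec, "cohort_spec")) stop("sample_cohort: need a cohort_spec",
                                           call. = FALSE)
  seed <- if (!is.null(seed)) seed else spec$seed
  if (!is.null(seed)) set.seed(seed)
  groups <- names(spec$sizes)
  rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- as.integer(spec$sizes[[g]])
    if (n == 0L) next
    lm_g <- rtruncnorm_lower(n, spec$logmar_mean[[g]], spec$logmar_sd[[g]],
                             spec$logmar_min)
    high <- lm_g <= spec$acuity_threshold
    rows[[gi]] <- data.frame(
      observer_id = sprintf("%s_%02d", g, seq_len(n)),
      group = g,
      logmar = lm_g,
      A_c = ifelse(high, spec$A_c_high, spec$A_c_low),
      sigma = ifelse(high, spec$sigma_high[[g]], spec$sigma_low[[g]]),
      w_obs = spec$w_obs,
      far_gain = spec$far_gain,
      beta_true = spec$beta_true,
      lapse_true = spec$lapse_true,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # per-observer substream seeds, drawn from the same stream for determinism
  out$seed <- sample.int(.Machine$integer.max - 1L, nrow(out))
  attr(out, "spec") <- spec
  class(out) <- c("cohort", "data.frame")
  out
}

#' Turn one cohort row into an observer object
#'
#' @param cohort a `cohort` data frame from [sample_cohort()].
#' @param i row index or observer id.
#' @return An [observer_params()] object.
#' @export
cohort_observer <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$observer_id)
  r <- cohort[i, , drop = FALSE]
  sp <- attr(cohort, "spec")
  cc <- if (!is.null(sp)) sp$C_c else 0.8
  cs <- if (!is.null(sp)) sp$C_s else 0.8
  observer_params(
    norm = norm_params(A_c = r$A_c, C_c = cc, C_s = cs,
                       w_obs = r$w_obs, sigma = r$sigma),
    far_gain = r$far_gain, beta_true = r$beta_true,
    lapse_true = r$lapse_true, logmar = r$logmar,
    group = r$group, observer_id = r$observer_id
  )
}

#' Write / read a cohort as tab-separated text
#'
#' @param cohort a `cohort` data frame.
#' @param path file path.
#' @return `read_cohort` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  out
}
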