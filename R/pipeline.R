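# Orchestration: cohort -> sessions -> exclusions/outliers -> tuning fits ->
# group statistics, reproducible from one master seed.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec()].
#' @param psi a [psi_config()] (built on demand when `NULL`).
#' @param n_per_condition staircase trials per condition.
#' @param n_catch number of catch trials.
#' @param rm_conditions conditions entering the repeated-measures ANCOVA.
#' @param use_covariate include logMAR acuity as covariate in the group
#'   analyses (the no-covariate variants are always reported alongside).
#' @param keep_trials keep per-trial logs in the result (one row per trial per
#'   observer).
#' @param out_dir optional directory for tab-separated artifacts and a
#'   manifest.
#' @param seed default master seed for [run_pipeline()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), psi = NULL,
                            n_per_condition = 48L, n_catch = 48L,
                            rm_conditions = c("no_surround", "near_0",
                                              "near_90"),
                            use_covariate = TRUE, keep_trials = FALSE,
                            out_dir = NULL, seed = 1L) {
  structure(list(cohort = cohort, psi = psi,
                 n_per_condition = n_per_condition, n_catch = n_catch,
                 rm_conditions = rm_conditions,
                 use_covariate = use_covariate, keep_trials = keep_trials,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

# Run every observer's session with one batched staircase engine. Each
# observer's RNG substream is consumed in the same canonical order as in
# run_session(), so results are identical to looping run_session() over the
# cohort.
run_cohort_sessions <- function(cohort, config = psi_config(),
                                n_per_condition = 48L, n_catch = 48L,
                                keep_trials = FALSE) {
  ct <- condition_table()
  n_obs <- nrow(cohort)
  n_cond <- nrow(ct)
  plans <- vector("list", n_obs)
  U <- matrix(NA_real_, n_per_condition, n_obs * n_cond)
  u_catch <- matrix(NA_real_, n_catch, n_obs)
  pse <- matrix(NA_real_, n_cond, n_obs)
  observers <- vector("list", n_obs)
  for (i in seq_len(n_obs)) {
    obs <- cohort_observer(cohort, i)
    observers[[i]] <- obs
    set.seed(cohort$seed[i])
    plans[[i]] <- build_session(n_per_condition, n_catch)
    U[, (i - 1L) * n_cond + seq_len(n_cond)] <-
      matrix(runif(n_per_condition * n_cond), n_per_condition, n_cond)
    u_catch[, i] <- runif(n_catch)
    pse[, i] <- true_pses(obs)[ct$condition]
  }
  batch <- psi_run_batch(
    pse = as.numeric(pse),
    beta = rep(cohort$beta_true, each = n_cond),
    lapse = rep(cohort$lapse_true, each = n_cond),
    n_trials = n_per_condition, config = config, U = U)

  summaries <- vector("list", n_obs)
  trials <- if (keep_trials) vector("list", n_obs) else NULL
  estimates <- vector("list", n_obs)
  for (i in seq_len(n_obs)) {
    obs <- observers[[i]]
    cols <- (i - 1L) * n_cond + seq_len(n_cond)
    hist_i <- batch$estimate_history[, cols, drop = FALSE]
    colnames(hist_i) <- ct$condition
    est <- apply(hist_i, 2L, extract_condition_estimate)
    spread <- apply(hist_i, 2L, function(h) diff(range(tail(h, 3L))))
    plan <- plans[[i]]
    cidx <- which(plan$is_catch)
    catch_theta <- ifelse(plan$catch_orientation[cidx] == "parallel", 0, 90)
    catch_pse <- vapply(seq_along(cidx), function(k)
      perceived_decrement(obs, plan$catch_surround[cidx[k]], catch_theta[k]),
      numeric(1L))
    catch_dec <- attr(plan, "catch_decrement") %||% -50
    pr <- p_reference_higher(rep(catch_dec, length(cidx)), catch_pse,
                             obs$beta_true, obs$lapse_true)
    catch_rh <- u_catch[, i] < pr
    s <- data.frame(observer_id = obs$observer_id, group = obs$group,
                    logmar = obs$logmar, catch_accuracy = mean(!catch_rh),
                    stringsAsFactors = FALSE)
    for (cn in ct$condition) s[[cn]] <- unname(est[cn])
    for (cn in ct$condition) s[[paste0("spread_", cn)]] <- unname(spread[cn])
    summaries[[i]] <- s
    estimates[[i]] <- data.frame(observer_id = obs$observer_id,
                                 condition = ct$condition,
                                 estimate = unname(est[ct$condition]),
                                 stringsAsFactors = FALSE)
    if (keep_trials) {
      tr <- data.frame(
        observer_id = obs$observer_id, trial = plan$trial,
        condition = plan$condition, is_catch = plan$is_catch,
        decrement = NA_real_, response = NA_character_, correct = NA,
        stringsAsFactors = FALSE)
      sidx <- which(!plan$is_catch)
      flat <- cbind(plan$stair_trial[sidx],
                    match(plan$condition[sidx], ct$condition))
      tr$decrement[sidx] <- batch$x[, cols, drop = FALSE][flat]
      tr$response[sidx] <-
        ifelse(batch$reference_higher[, cols, drop = FALSE][flat],
               "reference_higher", "target_higher")
      tr$decrement[cidx] <- catch_dec
      tr$response[cidx] <- ifelse(catch_rh, "reference_higher",
                                  "target_higher")
      tr$correct[cidx] <- !catch_rh
      tr$condition[cidx] <- paste0("catch_", plan$catch_surround[cidx], "_",
                                   plan$catch_orientation[cidx])
      trials[[i]] <- tr
    }
  }
  summary <- apply_exclusions(do.call(rbind, summaries))
  rownames(summary) <- NULL
  list(summary = summary,
       estimates = do.call(rbind, estimates),
       trials = if (keep_trials) do.call(rbind, trials) else NULL)
}

#' Run the full simulation and analysis pipeline
#'
#' Executes, from one master seed: cohort sampling, all observer sessions
#' (batched staircases), compliance exclusions, the per-condition 5-SD
#' outlier rule (computed over included observers; flagged values are removed
#' only from analyses where that condition is a dependent variable),
#' exponential tuning fits (inadequate fits are dropped from the parameter
#' analyses), and the group statistics: the repeated-measures ANCOVA on
#' `rm_conditions`, one-way AN(C)OVAs on `M`, `w` and `o` (with and without
#' the acuity covariate), the acuity moderation test on `M`, and BH-FDR
#' pairwise comparisons on `o`. A manifest records the seed and the
#' observation counts at every filter step.
#'
#' @param config a [pipeline_config()].
#' @param seed master seed (defaults to `config$seed`).
#' @return An object of class `suppression_pipeline`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(cohort = cohort_spec(sizes = c(HC = 4, PSZ = 4)))
#' res <- run_pipeline(cfg, seed = 1)
#' res$manifest$counts
#' }
run_pipeline <- function(config = pipeline_config(), seed = config$seed) {
  psi_cfg <- config$psi %||% psi_config()
  set.seed(seed)
  cohort_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  cohort <- sample_cohort(config$cohort, seed = cohort_seed)

  sess <- run_cohort_sessions(cohort, psi_cfg, config$n_per_condition,
                              config$n_catch, config$keep_trials)
  summary <- sess$summary
  included <- summary[summary$included, , drop = FALSE]

  # per-condition outlier flags over included observers
  ct <- condition_table()
  flags <- sapply(ct$condition, function(cn) flag_outliers(included[[cn]]))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1L,
                                           dimnames = list(NULL, ct$condition))
  outliers <- data.frame(observer_id = included$observer_id, flags,
                         check.names = FALSE, stringsAsFactors = FALSE)

  # repeated-measures ANCOVA on the key conditions, outlier-flagged
  # observations removed where they would be dependent variables
  long <- sess$estimates
  long <- merge(long, included[, c("observer_id", "group", "logmar")],
                by = "observer_id")
  keep_rm <- rep(TRUE, nrow(long))
  for (cn in config$rm_conditions) {
    bad <- outliers$observer_id[outliers[[cn]]]
    keep_rm <- keep_rm & !(long$condition == cn & long$observer_id %in% bad)
  }
  long_rm <- long[keep_rm & long$condition %in% config$rm_conditions, ]
  rm_cov <- rm_ancova(long_rm, conditions = config$rm_conditions,
                      covariate = if (config$use_covariate) "logmar" else NULL)
  rm_nocov <- rm_ancova(long_rm, conditions = config$rm_conditions,
                        covariate = NULL)

  fits <- fit_tuning_cohort(included)
  fits_ok <- fits[fits$adequate, , drop = FALSE]

  one <- function(par, cov) ancova_oneway(fits_ok[[par]], fits_ok$group,
                                          if (cov) fits_ok$logmar else NULL)
  stats <- list(
    rm_ancova = rm_cov, rm_ancova_nocov = rm_nocov,
    M = one("M", config$use_covariate), M_nocov = one("M", FALSE),
    w = one("w", config$use_covariate), w_nocov = one("w", FALSE),
    o = one("o", config$use_covariate), o_nocov = one("o", FALSE),
    moderation_M = moderation_test(fits_ok$M, fits_ok$group, fits_ok$logmar),
    pairwise_o = pairwise_fdr(fits_ok$o, fits_ok$group,
                              if (config$use_covariate) fits_ok$logmar)
  )

  manifest <- list(
    seed = seed, cohort_seed = cohort_seed,
    counts = c(simulated = nrow(summary),
               excluded_catch = sum(summary$exclusion_reason == "catch_fail"),
               excluded_no_suppression =
                 sum(summary$exclusion_reason == "no_suppression"),
               included = nrow(included),
               outlier_flags = sum(as.matrix(outliers[, ct$condition])),
               inadequate_fit = sum(!fits$adequate, na.rm = TRUE),
               analyzed_parameters = nrow(fits_ok)),
    n_per_condition = config$n_per_condition, n_catch = config$n_catch
  )

  out <- structure(list(cohort = cohort, summary = summary,
                        estimates = sess$estimates, trials = sess$trials,
                        outliers = outliers, fits = fits, stats = stats,
                        manifest = manifest, config = config, seed = seed),
                   class = "suppression_pipeline")
  if (!is.null(config$out_dir)) out <- write_pipeline(out, config$out_dir)
  out
}

#' @export
print.suppression_pipeline <- function(x, ...) {
  cat("<suppression_pipeline> seed", x$seed, "\n")
  print(x$manifest$counts)
  cat("\nGroup means of fitted parameters (adequate fits):\n")
  ok <- x$fits[x$fits$adequate, ]
  print(aggregate(ok[, c("M", "w", "o")], list(group = ok$group), mean))
  cat("\nRepeated-measures ANCOVA (", paste(x$config$rm_conditions,
                                            collapse = ", "), "):\n", sep = "")
  print(x$stats$rm_ancova)
  cat("\nOne-way ANCOVA on o:\n")
  print(x$stats$o)
  invisible(x)
}

#' Write pipeline artifacts as delimited text with a manifest
#'
#' @param x a `suppression_pipeline` result.
#' @param dir output directory (created if needed).
#' @return The input, invisibly, with manifest extended by artifact hashes.
#' @export
write_pipeline <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(wt(x$cohort, "cohort.tsv"),
             wt(x$summary, "sessions.tsv"),
             wt(x$estimates, "estimates.tsv"),
             wt(x$outliers, "outliers.tsv"),
             wt(x$fits, "fits.tsv"))
  if (!is.null(x$trials)) paths <- c(paths, wt(x$trials, "trials.tsv"))
  stats_path <- file.path(dir, "stats.txt")
  con <- file(stats_path, "w")
  for (nm in names(x$stats)) {
    writeLines(paste0("== ", nm, " =="), con)
    utils::capture.output(print(x$stats[[nm]]), file = con, append = TRUE)
    writeLines("", con)
  }
  close(con)
  paths <- c(paths, stats_path)
  hashes <- tools::md5sum(paths)
  man_path <- file.path(dir, "manifest.txt")
  con <- file(man_path, "w")
  writeLines(c(paste("seed:", x$manifest$seed),
               paste("cohort_seed:", x$manifest$cohort_seed),
               paste("n_per_condition:", x$manifest$n_per_condition),
               paste("n_catch:", x$manifest$n_catch),
               paste0("count ", names(x$manifest$counts), ": ",
                      x$manifest$counts),
               paste0("md5 ", basename(names(hashes)), ": ", hashes)), con)
  close(con)
  x$manifest$artifacts <- hashes
  invisible(x)
}

#' Normalization-model tuning curves for the four canonical parameter sets
#'
#' Evaluates the normalized response `R(theta)` on a fine orientation grid for
#' the four illustrative parameter sets: baseline (`A_c = 2, sigma = 0.4`,
#' focal attention / good segmentation with strong untuned gain control),
#' distributed attention or low acuity (`A_c = 1`), reduced gain control
#' (`sigma = 0.1`), and the combination. Center and surround drives are held
#' at 0.8 (matched contrast) and the tuning width fixed at `w`. With
#' `check = TRUE` the qualitative orderings are asserted: the distributed
#' curve lies below baseline at every orientation, the reduced-gain curve
#' above it, and the combined set has the largest parallel-to-orthogonal
#' modulation `R(90) - R(0)`.
#'
#' @param params data frame with columns `set`, `A_c`, `sigma` (and
#'   optionally `C_c`, `C_s`); defaults to the four canonical sets.
#' @param w fixed tuning width, degrees.
#' @param theta orientation grid, degrees.
#' @param check assert the qualitative orderings.
#' @return Long data frame (`set`, `theta`, `R`) with attribute `"checks"`.
#' @export
#' @examples
#' tc <- reproduce_figure4()
#' attr(tc, "checks")
reproduce_figure4 <- function(params = NULL, w = 30, theta = 0:90,
                              check = TRUE) {
  if (is.null(params))
    params <- data.frame(
      set = c("baseline", "distributed", "reduced_sigma", "combined"),
      A_c = c(2, 1, 2, 1), sigma = c(0.4, 0.4, 0.1, 0.1),
      stringsAsFactors = FALSE)
  if (is.null(params$C_c)) params$C_c <- 0.8
  if (is.null(params$C_s)) params$C_s <- 0.8
  curves <- lapply(seq_len(nrow(params)), function(i) {
    p <- norm_params(A_c = params$A_c[i], C_c = params$C_c[i],
                     C_s = params$C_s[i], w_obs = w,
                     sigma = params$sigma[i])
    data.frame(set = params$set[i], theta = theta,
               R = norm_response(p, theta), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, curves)
  checks <- NULL
  if (all(c("baseline", "distributed", "reduced_sigma", "combined") %in%
          params$set)) {
    g <- function(s) out$R[out$set == s]
    mod <- vapply(unique(out$set), function(s) {
      r <- g(s); r[length(r)] - r[1L]
    }, numeric(1L))
    checks <- c(
      distributed_below_baseline = all(g("distributed") < g("baseline")),
      reduced_sigma_above_baseline = all(g("reduced_sigma") > g("baseline")),
      combined_largest_modulation =
        names(which.max(mod)) == "combined"
    )
    if (check && !all(checks))
      stop("reproduce_figure4: qualitative ordering check failed: ",
           paste(names(checks)[!checks], collapse = ", "), call. = FALSE)
  }
  attr(out, "checks") <- checks
  out
}
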