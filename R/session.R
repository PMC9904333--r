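# Session engine: builds the interleaved trial schedule (11 staircased
# conditions x 48 trials + 48 catch trials), runs it against a simulated
# observer, extracts per-condition estimates, and applies the compliance and
# outlier rules.

#' Build an interleaved session plan
#'
#' Creates the full trial schedule: `n_per_condition` staircase slots for each
#' of the 11 conditions plus `n_catch` catch trials (reference fixed at 30%
#' contrast, i.e. a -50 percentage-point decrement), evenly divided between
#' parallel (0 degree) and orthogonal (90 degree) surrounds and randomly
#' assigned to the near or far configuration. All slots are shuffled together
#' (conditions are mixed, not blocked); target orientation and reference side
#' are randomized per trial. Uses the current RNG stream.
#'
#' @param n_per_condition staircase trials per condition (default 48).
#' @param n_catch number of catch trials (default 48; must be even).
#' @param catch_decrement fixed reference decrement on catch trials
#'   (percentage points; default -50, i.e. 30% vs the 80% target).
#' @return A data frame of class `session_plan`; staircase rows carry
#'   `stair_trial`, the position of that slot within its condition's
#'   staircase.
#' @export
#' @examples
#' set.seed(1)
#' plan <- build_session()
#' nrow(plan)          # 576
#' sum(plan$is_catch)  # 48
build_session <- function(n_per_condition = 48L, n_catch = 48L,
                          catch_decrement = -50) {
  if (n_catch %% 2L != 0L)
    stop("build_session: n_catch must be even (parallel/orthogonal split)",
         call. = FALSE)
  ct <- condition_table()
  stair <- data.frame(
    condition = rep(ct$condition, each = n_per_condition),
    is_catch = FALSE,
    catch_surround = NA_character_,
    catch_orientation = NA_character_,
    stringsAsFactors = FALSE
  )
  catch <- data.frame(
    condition = NA_character_,
    is_catch = TRUE,
    catch_surround = sample(c("near", "far"), n_catch, replace = TRUE),
    catch_orientation = rep(c("parallel", "orthogonal"), each = n_catch / 2L),
    stringsAsFactors = FALSE
  )
  plan <- rbind(stair, catch)
  plan <- plan[sample.int(nrow(plan)), , drop = FALSE]
  plan$trial <- seq_len(nrow(plan))
  plan$target_orientation <- sample(c(0, 45, 90, 135), nrow(plan),
                                    replace = TRUE)
  plan$reference_side <- sample(c("left", "right"), nrow(plan),
                                replace = TRUE)
  plan$stair_trial <- NA_integer_
  idx <- !plan$is_catch
  plan$stair_trial[idx] <- stats::ave(rep(1L, sum(idx)), plan$condition[idx],
                                      FUN = seq_along)
  rownames(plan) <- NULL
  attr(plan, "catch_decrement") <- catch_decrement
  class(plan) <- c("session_plan", "data.frame")
  plan
}

#' Mean of the last three threshold estimates
#'
#' The per-condition perceived-contrast estimate is the arithmetic mean of the
#' final three per-trial threshold estimates of that condition's staircase.
#'
#' @param estimate_history numeric vector of per-trial threshold estimates
#'   (length >= 3).
#' @return A single decrement (percentage points).
#' @export
extract_condition_estimate <- function(estimate_history) {
  if (length(estimate_history) < 3L)
    stop("extract_condition_estimate: need at least 3 threshold estimates",
         call. = FALSE)
  mean(tail(estimate_history, 3L))
}

#' Run a full simulated session
#'
#' Runs the 11 interleaved staircases and the catch trials of a session plan
#' against one simulated observer. Each staircase slot consumes one
#' select/respond/update cycle of its condition's staircase; catch trials are
#' answered at the fixed catch decrement and touch no posterior. Because the
#' simulated observer is memoryless, the staircases are advanced
#' condition-by-condition on dedicated RNG substreams and the trial log is
#' then assembled in plan order -- trial-for-trial identical to a literal
#' interleaved loop.
#'
#' @param obs an [observer_params()] object.
#' @param plan a [build_session()] plan, or `NULL` to build one from the
#'   session's RNG stream.
#' @param config a [psi_config()].
#' @param seed optional integer seed for the session's substreams (plan
#'   randomization, staircase responses, catch responses); when `NULL` the
#'   current RNG stream is used.
#' @return An object of class `session_result`: a list with `summary` (one-row
#'   data frame: catch accuracy, inclusion flags, per-condition estimates and
#'   convergence spread), `estimates` (named vector), `trials` (576-row trial
#'   log), and `estimate_history` (trials x conditions matrix).
#' @export
#' @examples
#' res <- run_session(observer_params(), seed = 42)
#' res$summary[, c("catch_accuracy", "included")]
run_session <- function(obs, plan = NULL, config = psi_config(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(plan)) plan <- build_session()
  ct <- condition_table()
  n_per_condition <- sum(!plan$is_catch & plan$condition == ct$condition[1L])
  n_catch <- sum(plan$is_catch)
  catch_dec <- attr(plan, "catch_decrement")
  if (is.null(catch_dec)) catch_dec <- -50

  # canonical draw order: staircase deviates by condition, then catch deviates
  U <- matrix(runif(n_per_condition * nrow(ct)), n_per_condition, nrow(ct))
  u_catch <- runif(n_catch)

  pses <- true_pses(obs)
  batch <- psi_run_batch(pse = pses[ct$condition],
                         beta = rep(obs$beta_true, nrow(ct)),
                         lapse = rep(obs$lapse_true, nrow(ct)),
                         n_trials = n_per_condition, config = config, U = U)
  colnames(batch$estimate_history) <- ct$condition
  estimates <- apply(batch$estimate_history, 2L, extract_condition_estimate)
  spread <- apply(batch$estimate_history, 2L,
                  function(h) diff(range(tail(h, 3L))))

  # catch trials: PSE of the displayed configuration, response at the fixed
  # catch decrement; "target_higher" is the correct answer
  cidx <- which(plan$is_catch)
  catch_theta <- ifelse(plan$catch_orientation[cidx] == "parallel", 0, 90)
  catch_pse <- numeric(n_catch)
  for (k in seq_len(n_catch))
    catch_pse[k] <- perceived_decrement(obs, plan$catch_surround[cidx[k]],
                                        catch_theta[k])
  pr <- p_reference_higher(rep(catch_dec, n_catch), catch_pse,
                           obs$beta_true, obs$lapse_true)
  catch_ref_higher <- u_catch < pr
  catch_accuracy <- mean(!catch_ref_higher)

  # assemble the trial log in interleaved plan order
  trials <- data.frame(
    observer_id = obs$observer_id, trial = plan$trial,
    condition = plan$condition, is_catch = plan$is_catch,
    decrement = NA_real_, response = NA_character_, correct = NA,
    running_estimate = NA_real_, stringsAsFactors = FALSE
  )
  sidx <- which(!plan$is_catch)
  ci <- match(plan$condition[sidx], ct$condition)
  ti <- plan$stair_trial[sidx]
  flat <- cbind(ti, ci)
  trials$decrement[sidx] <- batch$x[flat]
  trials$response[sidx] <- ifelse(batch$reference_higher[flat],
                                  "reference_higher", "target_higher")
  trials$running_estimate[sidx] <- batch$estimate_history[flat]
  trials$decrement[cidx] <- catch_dec
  trials$response[cidx] <- ifelse(catch_ref_higher, "reference_higher",
                                  "target_higher")
  trials$correct[cidx] <- !catch_ref_higher
  trials$condition[cidx] <- paste0("catch_", plan$catch_surround[cidx], "_",
                                   plan$catch_orientation[cidx])

  summary <- data.frame(observer_id = obs$observer_id, group = obs$group,
                        logmar = obs$logmar, catch_accuracy = catch_accuracy,
                        stringsAsFactors = FALSE)
  for (cn in ct$condition) summary[[cn]] <- unname(estimates[cn])
  for (cn in ct$condition) summary[[paste0("spread_", cn)]] <-
    unname(spread[cn])
  summary <- apply_exclusions(summary)

  structure(list(summary = summary, estimates = estimates, trials = trials,
                 estimate_history = batch$estimate_history),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  s <- x$summary
  cat("<session_result> ", s$observer_id, ": catch accuracy ",
      format(s$catch_accuracy, digits = 3),
      if (s$included) ", included" else
        paste0(", EXCLUDED (", s$exclusion_reason, ")"), "\n", sep = "")
  print(round(x$estimates, 2))
  invisible(x)
}

#' Apply the participant-level inclusion rules
#'
#' A dataset is analyzed only if catch-trial accuracy is strictly better than
#' 75% and the near-surround estimates at 0 and 20 degrees are both negative
#' (perceived contrast reduced; participants who reported the combined
#' target-plus-surround pattern are removed). The first failed criterion is
#' recorded, catch accuracy checked first.
#'
#' @param x a `session_result` or a summary data frame with columns
#'   `catch_accuracy`, `near_0`, `near_20` (vectorized over rows).
#' @return The input with `included` (logical) and `exclusion_reason`
#'   (`"none"`, `"catch_fail"`, `"no_suppression"`) set.
#' @export
apply_exclusions <- function(x) {
  if (inherits(x, "session_result")) {
    x$summary <- apply_exclusions(x$summary)
    return(x)
  }
  stopifnot(all(c("catch_accuracy", "near_0", "near_20") %in% names(x)))
  catch_ok <- x$catch_accuracy > 0.75
  supp_ok <- x$near_0 < 0 & x$near_20 < 0
  x$included <- catch_ok & supp_ok
  x$exclusion_reason <- ifelse(!catch_ok, "catch_fail",
                               ifelse(!supp_ok, "no_suppression", "none"))
  x
}

#' Flag per-condition outliers by the 5-SD rule
#'
#' An observer is an outlier for a condition if their estimate lies more than
#' `n_sd` standard deviations from that condition's mean (computed across the
#' supplied values). Flagged values are meant to be dropped only from analyses
#' that use that condition as a dependent variable.
#'
#' @param values numeric vector of one condition's estimates across observers
#'   (`NA`s are never flagged and are ignored for the mean/SD).
#' @param n_sd flagging threshold in SD units (default 5).
#' @return Logical vector of flags, same length as `values`.
#' @export
flag_outliers <- function(values, n_sd = 5) {
  ok <- !is.na(values)
  if (sum(ok) < 3L)
    stop("flag_outliers: need at least 3 observers", call. = FALSE)
  m <- mean(values[ok])
  s <- sd(values[ok])
  flags <- rep(FALSE, length(values))
  if (is.na(s) || s == 0) return(flags)
  flags[ok] <- abs(values[ok] - m) > n_sd * s
  flags
}
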