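# Group-level inference: split-plot (mixed-design) repeated-measures ANCOVA
# with Huynh-Feldt correction, one-way ANCOVAs on fit parameters, an acuity
# moderation test, and BH-FDR pairwise contrasts.

new_anova_table <- function(df, epsilon = NA_real_, gg = NA_real_) {
  attr(df, "epsilon") <- epsilon
  attr(df, "gg_epsilon") <- gg
  class(df) <- c("anova_table", "data.frame")
  df
}

#' @export
print.anova_table <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(z) signif(z, digits))
  print(df, row.names = FALSE)
  eps <- attr(x, "epsilon")
  if (!is.na(eps))
    cat("Huynh-Feldt epsilon:", format(eps, digits = digits), "\n")
  invisible(x)
}

#' Huynh-Feldt sphericity correction factor
#'
#' Computes the Greenhouse-Geisser estimate from the covariance of the
#' orthonormalized within-subject contrasts, then applies the Huynh-Feldt
#' adjustment
#' `((n - g + 1) (k - 1) e_gg - 2) / ((k - 1) (n - g - (k - 1) e_gg))`,
#' clipped to `[1/(k - 1), 1]`. Under compound symmetry (sphericity) the
#' result is 1.
#'
#' @param S k x k covariance matrix of the within-subject measures
#'   (symmetric, positive semidefinite).
#' @param n number of subjects.
#' @param g rank of the between-subjects design (number of groups, plus one
#'   per between-subjects covariate, counting the intercept once); `g = 1`
#'   for a single-group design.
#' @return The clipped Huynh-Feldt epsilon, with the unclipped
#'   Greenhouse-Geisser estimate in attribute `"gg"`.
#' @export
#' @examples
#' S <- diag(3) * 0.5 + 0.5   # compound symmetric
#' hf_epsilon(S, n = 20, g = 1)   # 1
hf_epsilon <- function(S, n, g = 1) {
  S <- as.matrix(S)
  if (!isSymmetric(S, tol = 1e-8))
    stop("hf_epsilon: covariance matrix must be symmetric", call. = FALSE)
  k <- nrow(S)
  if (k < 2L) stop("hf_epsilon: need at least 2 within levels", call. = FALSE)
  H <- contr.helmert(k)
  C <- sweep(H, 2L, sqrt(colSums(H^2)), "/")    # orthonormal contrasts
  T <- t(C) %*% S %*% C
  gg <- sum(diag(T))^2 / ((k - 1) * sum(T^2))
  hf <- ((n - g + 1) * (k - 1) * gg - 2) /
    ((k - 1) * (n - g - (k - 1) * gg))
  out <- min(1, max(1 / (k - 1), hf))
  attr(out, "gg") <- gg
  out
}

#' Mixed-design repeated-measures ANCOVA with Huynh-Feldt correction
#'
#' Split-plot analysis of long-format condition estimates: a within-subject
#' condition factor, a between-subjects group factor, and (optionally) a
#' between-subjects covariate which also enters the within-subject tests
#' through its interaction with condition (the convention of standard
#' statistical packages). Within-subject degrees of freedom are multiplied by
#' the Huynh-Feldt epsilon; partial eta squared is reported per effect.
#' Observers without complete data on the selected conditions are dropped.
#'
#' Sums of squares are Type III with sum-to-zero contrasts (via
#' \code{car::Anova} on the multivariate linear model); epsilon comes from
#' [hf_epsilon()] applied to the pooled residual covariance.
#'
#' @param data long data frame.
#' @param dv,within,id,between,covariate column names; set `covariate = NULL`
#'   to omit it.
#' @param conditions which levels of `within` to analyze (default: all).
#' @return An `anova_table` with columns effect, F, df1, df2, p, peta2
#'   (within-subject rows carry HF-corrected dfs and p), and the epsilon as an
#'   attribute.
#' @export
rm_ancova <- function(data, dv = "estimate", within = "condition",
                      id = "observer_id", between = "group",
                      covariate = "logmar", conditions = NULL) {
  stopifnot(all(c(dv, within, id, between) %in% names(data)))
  if (!is.null(covariate)) stopifnot(covariate %in% names(data))
  if (!is.null(conditions))
    data <- data[data[[within]] %in% conditions, , drop = FALSE]
  levs <- unique(data[[within]])
  k <- length(levs)
  if (k < 2L) stop("rm_ancova: need >= 2 within-subject levels", call. = FALSE)

  wide <- stats::reshape(data[, c(id, within, dv, between, covariate)],
                  idvar = c(id, between, covariate),
                  timevar = within, direction = "wide")
  ycols <- paste(dv, levs, sep = ".")
  wide <- wide[complete.cases(wide[, ycols]), , drop = FALSE]
  n <- nrow(wide)
  grp <- factor(wide[[between]])
  if (nlevels(grp) < 2L || any(table(grp) < 2L))
    stop("rm_ancova: need >= 2 groups with >= 2 observers each",
         call. = FALSE)
  Y <- as.matrix(wide[, ycols])
  colnames(Y) <- levs

  btw <- data.frame(group = grp)
  form <- "Y ~ group"
  if (!is.null(covariate)) {
    btw$cov <- wide[[covariate]]
    form <- "Y ~ cov + group"
  }
  mod <- lm(as.formula(form), data = btw,
            contrasts = list(group = "contr.sum"))
  idata <- data.frame(condition = factor(levs, levels = levs))
  av <- car::Anova(mod, idata = idata, idesign = ~condition, type = "III")
  # car warns when its own (unclipped) HF estimate exceeds 1; we clip below
  s <- suppressWarnings(summary(av, multivariate = FALSE, univariate = TRUE))
  ut <- s$univariate.tests

  rk <- qr(stats::model.matrix(mod))$rank
  Spool <- crossprod(residuals(mod)) / (n - rk)
  eps <- hf_epsilon(Spool, n = n, g = rk)
  gg <- attr(eps, "gg")

  eff <- rownames(ut)
  is_within <- grepl("condition", eff)
  keep <- eff != "(Intercept)"
  rows <- lapply(which(keep), function(i) {
    F <- ut[i, "F value"]
    df1 <- ut[i, "num Df"]; df2 <- ut[i, "den Df"]
    p <- ut[i, "Pr(>F)"]
    peta2 <- ut[i, "Sum Sq"] / (ut[i, "Sum Sq"] + ut[i, "Error SS"])
    if (is_within[i]) {
      df1 <- df1 * eps; df2 <- df2 * eps
      p <- pf(F, df1, df2, lower.tail = FALSE)
    }
    nm <- eff[i]
    if (!is.null(covariate)) nm <- sub("^cov", covariate, nm)
    data.frame(effect = nm, F = F, df1 = df1, df2 = df2, p = p,
               peta2 = peta2, within = is_within[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  new_anova_table(out, epsilon = as.numeric(eps), gg = gg)
}

#' One-way ANCOVA on a per-observer parameter
#'
#' F test of the group effect, adjusting for an optional covariate
#' (`value ~ covariate + group` against `value ~ covariate`), with partial eta
#' squared.
#'
#' @param value numeric response, one per observer.
#' @param group group labels.
#' @param covariate optional numeric covariate (e.g. logMAR acuity);
#'   `NULL` gives a plain one-way ANOVA.
#' @return A one-row `anova_table`.
#' @export
ancova_oneway <- function(value, group, covariate = NULL) {
  group <- factor(group)
  ok <- is.finite(value) & !is.na(group) &
    (if (is.null(covariate)) TRUE else is.finite(covariate))
  value <- value[ok]; group <- droplevels(group[ok])
  if (!is.null(covariate)) covariate <- covariate[ok]
  if (nlevels(group) < 2L || any(table(group) < 2L))
    stop("ancova_oneway: need >= 2 groups with >= 2 observers each",
         call. = FALSE)
  if (is.null(covariate)) {
    m0 <- lm(value ~ 1)
    m1 <- lm(value ~ group)
  } else {
    m0 <- lm(value ~ covariate)
    m1 <- lm(value ~ covariate + group)
  }
  a <- anova(m0, m1)
  ss <- a$`Sum of Sq`[2L]
  rss <- a$RSS[2L]
  F <- a$F[2L]; df1 <- a$Df[2L]; df2 <- a$Res.Df[2L]
  if (!is.finite(F)) stop("ancova_oneway: degenerate design", call. = FALSE)
  new_anova_table(data.frame(
    effect = "group", F = F, df1 = df1, df2 = df2,
    p = a$`Pr(>F)`[2L], peta2 = ss / (ss + rss), within = FALSE,
    stringsAsFactors = FALSE))
}

#' Test whether acuity moderates the group effect
#'
#' Fits `value ~ group * covariate` (covariate mean-centered) and F-tests the
#' interaction block against the additive model; with `g` groups the
#' numerator has `g - 1` degrees of freedom. Also computes descriptive
#' sub-group means split at a covariate threshold (logMAR 0.1 by default),
#' attached as attribute `"split"`.
#'
#' @param value numeric response (e.g. fitted `M` per observer).
#' @param group group labels.
#' @param covariate numeric covariate (logMAR acuity).
#' @param threshold split point for the descriptive table.
#' @return A one-row `anova_table` for the interaction.
#' @export
moderation_test <- function(value, group, covariate, threshold = 0.1) {
  group <- factor(group)
  ok <- is.finite(value) & !is.na(group) & is.finite(covariate)
  value <- value[ok]; group <- droplevels(group[ok])
  covariate <- covariate[ok]
  v <- tapply(covariate, group, function(z) var(z))
  if (any(!is.finite(v)) || any(v == 0))
    stop("moderation_test: a group has no covariate variance; ",
         "interaction inestimable", call. = FALSE)
  cc <- covariate - mean(covariate)
  m0 <- lm(value ~ group + cc)
  m1 <- lm(value ~ group * cc)
  a <- anova(m0, m1)
  ss <- a$`Sum of Sq`[2L]
  out <- new_anova_table(data.frame(
    effect = "group:covariate", F = a$F[2L], df1 = a$Df[2L],
    df2 = a$Res.Df[2L], p = a$`Pr(>F)`[2L],
    peta2 = ss / (ss + a$RSS[2L]), within = FALSE,
    stringsAsFactors = FALSE))
  split <- aggregate(value,
                     list(group = group,
                          acuity = ifelse(covariate <= threshold,
                                          "high_acuity", "low_acuity")),
                     FUN = mean)
  names(split)[3L] <- "mean_value"
  attr(out, "split") <- split
  out
}

#' Covariate-adjusted pairwise group comparisons with BH-FDR correction
#'
#' For every pair of groups, fits `value ~ covariate + group` on that pair and
#' takes the two-sided t test of the group coefficient; p values are adjusted
#' across all pairs with the Benjamini-Hochberg step-up procedure.
#'
#' @param value numeric response.
#' @param group group labels.
#' @param covariate optional numeric covariate.
#' @return Data frame with one row per pair: adjusted mean difference
#'   (`group2 - group1`), t, df, raw and BH-adjusted p.
#' @export
pairwise_fdr <- function(value, group, covariate = NULL) {
  group <- factor(group)
  ok <- is.finite(value) & !is.na(group) &
    (if (is.null(covariate)) TRUE else is.finite(covariate))
  value <- value[ok]; group <- droplevels(group[ok])
  if (!is.null(covariate)) covariate <- covariate[ok]
  levs <- levels(group)
  if (length(levs) < 2L) stop("pairwise_fdr: need >= 2 groups", call. = FALSE)
  prs <- combn(levs, 2L)
  out <- data.frame(group1 = prs[1L, ], group2 = prs[2L, ],
                    estimate = NA_real_, t = NA_real_, df = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(prs))) {
    sel <- group %in% prs[, j]
    g2 <- droplevels(group[sel])
    if (is.null(covariate)) m <- lm(value[sel] ~ g2)
    else m <- lm(value[sel] ~ covariate[sel] + g2)
    co <- summary(m)$coefficients
    row <- grep("^g2", rownames(co))
    out$estimate[j] <- co[row, 1L]
    out$t[j] <- co[row, 3L]
    out$df[j] <- m$df.residual
    out$p[j] <- co[row, 4L]
  }
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' BIC-based Bayes factor approximation
#'
#' A rough Bayes factor in favor of the full model,
#' `exp((BIC(null) - BIC(full)) / 2)`. This unit-information approximation is
#' provided for orientation only and does not reproduce default-prior JZS
#' Bayes factors.
#'
#' @param full,null fitted model objects supporting [BIC()].
#' @return Approximate Bayes factor (full over null).
#' @export
bic_bayes_factor <- function(full, null) {
  exp((BIC(null) - BIC(full)) / 2)
}
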