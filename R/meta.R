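# Ratio-of-means meta-analysis engine: per-study effects, inverse-variance
# pooling with DerSimonian-Laird heterogeneity, weighted control statistics,
# implied absolute differences, meta-regression and leave-one-out.

STUDY_COLS <- c("study_id", "mean_t", "sd_t", "n_t", "mean_c", "sd_c", "n_c")

#' Validate a table of two-arm study summaries
#'
#' A study table is a data frame with one row per study and columns
#' `study_id`, `mean_t`, `sd_t`, `n_t`, `mean_c`, `sd_c`, `n_c` (treated and
#' control arm mean, SD and sample size), plus any moderator columns.
#'
#' @param studies A data frame.
#' @param require_positive_means If TRUE (the ratio-of-means case), reject
#'   non-positive arm means.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_studies <- function(studies, require_positive_means = TRUE) {
  if (!is.data.frame(studies)) stop("`studies` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(STUDY_COLS, names(studies))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num <- setdiff(STUDY_COLS, "study_id")
  for (cn in num) {
    if (!is.numeric(studies[[cn]])) {
      stop("column `", cn, "` must be numeric", call. = FALSE)
    }
  }
  bad_row <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      stop(sprintf("row %s: %s", paste(rows, collapse = ", "), what),
           call. = FALSE)
    }
  }
  bad_row(!is.finite(studies$sd_t) | studies$sd_t <= 0 |
          !is.finite(studies$sd_c) | studies$sd_c <= 0,
          "SDs must be positive")
  bad_row(!is.finite(studies$n_t) | studies$n_t < 2 |
          !is.finite(studies$n_c) | studies$n_c < 2,
          "per-arm n must be >= 2")
  if (require_positive_means) {
    bad_row(!is.finite(studies$mean_t) | studies$mean_t <= 0 |
            !is.finite(studies$mean_c) | studies$mean_c <= 0,
            "arm means must be positive for a ratio-of-means effect")
  }
  studies
}

#' Log ratio-of-means effect per study
#'
#' Computes for each study the natural-log ratio of means
#' `ln(mean_t / mean_c)` with its delta-method variance
#' `sd_t^2 / (n_t mean_t^2) + sd_c^2 / (n_c mean_c^2)`. The effect is
#' invariant to rescaling both arms, making it suitable for pooling
#' outcomes measured on different absolute scales.
#'
#' @param studies A study table (see [validate_studies()]).
#' @return A data frame of class `study_effects` with columns `study_id`,
#'   `yi` (log-ROM) and `vi` (variance); attribute `measure = "ROM"`.
#' @examples
#' s <- data.frame(study_id = "a", mean_t = 8, sd_t = 2, n_t = 10,
#'                 mean_c = 10, sd_c = 2, n_c = 10)
#' rom_effect(s)  # yi = log(0.8), vi = 0.01025
#' @export
rom_effect <- function(studies) {
  studies <- validate_studies(studies, require_positive_means = TRUE)
  out <- data.frame(
    study_id = studies$study_id,
    yi = log(studies$mean_t / studies$mean_c),
    vi = studies$sd_t^2 / (studies$n_t * studies$mean_t^2) +
         studies$sd_c^2 / (studies$n_c * studies$mean_c^2)
  )
  class(out) <- c("study_effects", "data.frame")
  attr(out, "measure") <- "ROM"
  out
}

#' Standardized mean difference (Hedges g) per study
#'
#' Bias-corrected standardized mean difference: `g = J * (mean_t - mean_c) /
#' s_pooled` with `J = 1 - 3 / (4 df - 1)`, `df = n_t + n_c - 2`, and the
#' usual large-sample variance `(n_t + n_c)/(n_t n_c) + g^2 / (2 (n_t +
#' n_c))`. Used as a scale-free cross-check of ratio-of-means results.
#'
#' @param studies A study table.
#' @return A `study_effects` data frame (`measure = "SMD"`), poolable by
#'   [pool()].
#' @export
smd_effect <- function(studies) {
  studies <- validate_studies(studies, require_positive_means = FALSE)
  df <- studies$n_t + studies$n_c - 2
  sp <- sqrt(((studies$n_t - 1) * studies$sd_t^2 +
              (studies$n_c - 1) * studies$sd_c^2) / df)
  if (any(sp <= 0)) {
    stop("row ", paste(which(sp <= 0), collapse = ", "),
         ": pooled SD is zero; SMD undefined", call. = FALSE)
  }
  j <- 1 - 3 / (4 * df - 1)
  g <- j * (studies$mean_t - studies$mean_c) / sp
  out <- data.frame(
    study_id = studies$study_id,
    yi = g,
    vi = (studies$n_t + studies$n_c) / (studies$n_t * studies$n_c) +
         g^2 / (2 * (studies$n_t + studies$n_c))
  )
  class(out) <- c("study_effects", "data.frame")
  attr(out, "measure") <- "SMD"
  out
}

#' Pool study effects by inverse-variance weighting
#'
#' Fixed-effect pooling uses weights `1/vi`; heterogeneity is quantified by
#' Cochran's `Q = sum(w (yi - yhat)^2)`, `I^2 = max(0, (Q - df)/Q) * 100`
#' and the DerSimonian-Laird between-study variance
#' `tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`. Random-effects
#' pooling uses weights `1/(vi + tau^2)`. With `method = "auto"` a
#' random-effects model is used iff `I^2 > 30` (the conventional threshold
#' for more-than-mild heterogeneity); otherwise fixed-effect.
#' Confidence intervals and p-values are two-sided normal-theory.
#'
#' @param effects A `study_effects` data frame (from [rom_effect()] or
#'   [smd_effect()]), or any data frame with `yi` and `vi` columns.
#' @param method `"auto"`, `"fixed"` or `"random"`.
#' @param i2_threshold I^2 cutoff (percent) for the auto rule.
#' @param conf_level Confidence level, default 0.95.
#'
#' @return An object of class `pooled_result`: list with `est` (pooled
#'   effect on the analysis scale), `se`, `ci` (length 2), `pval`, `Q`,
#'   `df`, `I2`, `tau2`, `k`, `method` (model actually used), `weights`
#'   (normalised, as used), `measure`, and — for ROM effects — `rom` and
#'   `rom_ci` (back-transformed).
#' @examples
#' eff <- data.frame(yi = c(0, 0.2, 0.4), vi = 0.01)
#' pool(eff)  # Q = 8, I2 = 75%, DL tau2 = 0.03, random-effects
#' @export
pool <- function(effects, method = c("auto", "fixed", "random"),
                 i2_threshold = 30, conf_level = 0.95) {
  method <- match.arg(method)
  if (!is.data.frame(effects) || !all(c("yi", "vi") %in% names(effects))) {
    stop("`effects` must be a data frame with `yi` and `vi` columns",
         call. = FALSE)
  }
  k <- nrow(effects)
  if (k < 1L) stop("at least one effect is required", call. = FALSE)
  yi <- effects$yi
  vi <- effects$vi
  if (any(!is.finite(vi) | vi <= 0)) stop("variances must be positive", call. = FALSE)

  w <- 1 / vi
  y_fixed <- sum(w * yi) / sum(w)
  df <- k - 1L
  Q <- sum(w * (yi - y_fixed)^2)
  I2 <- if (df > 0 && Q > 0) max(0, (Q - df) / Q) * 100 else 0
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (df > 0 && C > 0) max(0, (Q - df) / C) else 0

  used <- switch(method,
    auto = if (I2 > i2_threshold) "random" else "fixed",
    method
  )
  if (used == "random") {
    wr <- 1 / (vi + tau2)
    est <- sum(wr * yi) / sum(wr)
    se <- sqrt(1 / sum(wr))
    weights <- wr / sum(wr)
  } else {
    est <- y_fixed
    se <- sqrt(1 / sum(w))
    weights <- w / sum(w)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(est - z * se, est + z * se)
  pval <- 2 * stats::pnorm(-abs(est) / se)
  measure <- attr(effects, "measure") %||% "generic"

  out <- list(
    est = est, se = se, ci = ci, pval = pval,
    Q = Q, df = df, I2 = I2, tau2 = tau2, k = k,
    method = used, weights = weights,
    study_id = effects$study_id %||% seq_len(k),
    measure = measure, conf_level = conf_level
  )
  if (identical(measure, "ROM")) {
    out$rom <- exp(est)
    out$rom_ci <- exp(ci)
  }
  structure(out, class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, digits = 3, ...) {
  cat(sprintf("Pooled %s effect (%s-effect model, k = %d)\n",
              x$measure, x$method, x$k))
  cat(sprintf("  estimate %s  [%s, %s]  p = %s\n",
              format(x$est, digits = digits),
              format(x$ci[1], digits = digits),
              format(x$ci[2], digits = digits),
              format.pval(x$pval, digits = 2)))
  if (!is.null(x$rom)) {
    cat(sprintf("  ROM %s  [%s, %s]\n",
                format(x$rom, digits = digits),
                format(x$rom_ci[1], digits = digits),
                format(x$rom_ci[2], digits = digits)))
  }
  cat(sprintf("  Q = %s (df = %d), I2 = %s%%, tau2 = %s\n",
              format(x$Q, digits = digits), x$df,
              format(x$I2, digits = digits),
              format(x$tau2, digits = digits)))
  invisible(x)
}

#' Weighted control-arm statistics
#'
#' Control-condition mean and SD averaged with the same (normalised) weights
#' as the pooled model, giving the "typical control subject" scale on which
#' pooled ratios are re-expressed as absolute differences. The weighted SD
#' is the weighted average of study SDs (not a pooled variance).
#'
#' @param studies A study table.
#' @param weights Weights aligned with `studies` rows, e.g.
#'   `pool(...)$weights`; normalised internally.
#' @param sd_method `"average"` (weighted mean of study SDs, the default) or
#'   `"pooled"` (square root of the weighted mean of variances).
#' @return Named numeric vector `c(mean_wt, sd_wt)`.
#' @export
weighted_control_stats <- function(studies, weights,
                                   sd_method = c("average", "pooled")) {
  sd_method <- match.arg(sd_method)
  studies <- validate_studies(studies, require_positive_means = FALSE)
  if (length(weights) != nrow(studies)) {
    stop("`weights` must have one entry per study", call. = FALSE)
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("`weights` must be non-negative with positive sum", call. = FALSE)
  }
  w <- weights / sum(weights)
  sd_wt <- if (sd_method == "average") {
    sum(w * studies$sd_c)
  } else {
    sqrt(sum(w * studies$sd_c^2))
  }
  c(mean_wt = sum(w * studies$mean_c), sd_wt = sd_wt)
}

#' Implied absolute difference from a ratio of means
#'
#' Maps a pooled ratio (and its CI bounds) back to the control scale:
#' `ROM * mean_wt - mean_wt`. Applied bound-wise, so CI ordering is
#' preserved.
#'
#' @param rom A positive ratio (scalar or vector, e.g. `c(point, low,
#'   high)`) or a `pooled_result` from ROM effects.
#' @param mean_wt Weighted control mean (> 0).
#' @return Differences on the control scale, same shape as `rom`; for a
#'   `pooled_result`, a named vector `c(md, md_low, md_high)`.
#' @examples
#' absolute_difference(0.89, 38.2)  # about -4.2
#' @export
absolute_difference <- function(rom, mean_wt) {
  if (!is.numeric(mean_wt) || length(mean_wt) != 1L || mean_wt <= 0) {
    stop("`mean_wt` must be a single positive number", call. = FALSE)
  }
  if (inherits(rom, "pooled_result")) {
    if (is.null(rom$rom)) {
      stop("`rom` must come from ratio-of-means effects", call. = FALSE)
    }
    v <- c(rom$rom, rom$rom_ci)
    return(c(md = v[1] * mean_wt - mean_wt,
             md_low = v[2] * mean_wt - mean_wt,
             md_high = v[3] * mean_wt - mean_wt))
  }
  rom * mean_wt - mean_wt
}

#' Meta-regression of study effects on a moderator
#'
#' Weighted least squares of `yi` on a numeric moderator with weights
#' `1/(vi + tau2)`, where tau2 is the DerSimonian-Laird estimate from the
#' intercept-only model. Coefficient covariance is the fixed-weight
#' normal-theory `(X' W X)^{-1}`, as is conventional for meta-regression.
#'
#' @param effects A `study_effects` data frame (k >= 2).
#' @param moderator Numeric moderator, one value per study; must vary.
#' @param conf_level Confidence level for the slope CI.
#' @return A list of class `meta_regression`: `intercept`, `slope`,
#'   `slope_se`, `slope_ci`, `slope_pval`, `tau2`, `k`, `fitted`,
#'   `residuals`.
#' @export
meta_regress <- function(effects, moderator, conf_level = 0.95) {
  if (!is.data.frame(effects) || !all(c("yi", "vi") %in% names(effects))) {
    stop("`effects` must be a data frame with `yi` and `vi` columns",
         call. = FALSE)
  }
  k <- nrow(effects)
  if (k < 2L) stop("meta-regression needs at least 2 studies", call. = FALSE)
  if (length(moderator) != k || !is.numeric(moderator)) {
    stop("`moderator` must be numeric with one value per study", call. = FALSE)
  }
  if (length(unique(moderator)) < 2L) {
    stop("rank deficiency: `moderator` is constant across studies",
         call. = FALSE)
  }
  tau2 <- pool(effects, method = "random")$tau2
  w <- 1 / (effects$vi + tau2)
  X <- cbind(1, moderator)
  xtwx <- crossprod(X, w * X)
  beta <- solve(xtwx, crossprod(X, w * effects$yi))
  covb <- solve(xtwx)
  se <- sqrt(diag(covb))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  fitted <- drop(X %*% beta)
  structure(
    list(
      intercept = beta[1], slope = beta[2],
      slope_se = se[2],
      slope_ci = c(beta[2] - z * se[2], beta[2] + z * se[2]),
      slope_pval = 2 * stats::pnorm(-abs(beta[2]) / se[2]),
      tau2 = tau2, k = k,
      fitted = fitted, residuals = effects$yi - fitted
    ),
    class = "meta_regression"
  )
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the effect set with each study omitted in turn, exposing studies
#' that drive the pooled estimate or the heterogeneity.
#'
#' @param studies A study table with at least 2 rows.
#' @param effect `"rom"` or `"smd"`.
#' @param method Passed to [pool()].
#' @return A data frame with one row per omitted study: `omitted`, `k`,
#'   `est`, `ci_low`, `ci_high`, `I2`, `tau2`, `pval`, `method`, and for ROM
#'   also `rom`, `rom_low`, `rom_high`.
#' @export
leave_one_out <- function(studies, effect = c("rom", "smd"),
                          method = c("auto", "fixed", "random")) {
  effect <- match.arg(effect)
  method <- match.arg(method)
  studies <- validate_studies(studies, require_positive_means = effect == "rom")
  k <- nrow(studies)
  if (k < 2L) stop("leave-one-out needs at least 2 studies", call. = FALSE)
  eff_fun <- if (effect == "rom") rom_effect else smd_effect
  rows <- lapply(seq_len(k), function(i) {
    p <- pool(eff_fun(studies[-i, , drop = FALSE]), method = method)
    row <- data.frame(
      omitted = studies$study_id[i], k = p$k,
      est = p$est, ci_low = p$ci[1], ci_high = p$ci[2],
      I2 = p$I2, tau2 = p$tau2, pval = p$pval, method = p$method
    )
    if (!is.null(p$rom)) {
      row$rom <- p$rom
      row$rom_low <- p$rom_ci[1]
      row$rom_high <- p$rom_ci[2]
    }
    row
  })
  do.call(rbind, rows)
}
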