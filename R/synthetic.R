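# Seeded generator of two-arm study summary tables with known true ratio of
# means and between-study variance, plus a repeated generate-and-pool
# calibration experiment.

#' Configuration for the synthetic study generator
#'
#' Defines a population of studies with a known true ratio of means and
#' between-study heterogeneity on the log scale. Defaults emulate the
#' pooled eupneic-paCO2 analysis in acetazolamide studies: a true ROM of
#' 0.85 (a 15% reduction), homogeneous studies, 20 studies of 50 subjects
#' per arm, control means around 38.2 with SD 3.7 (mmHg), and within-arm
#' coefficients of variation of 5-15% (the pooled control CV of paCO2-like
#' outcomes is about 10%).
#'
#' @param true_rom True ratio of means (> 0).
#' @param tau2 Between-study variance of the log ratio (>= 0).
#' @param n_studies Number of studies (>= 1).
#' @param n_range Length-2 integer range for per-arm sample sizes (each arm
#'   drawn uniformly, min 2), or a single value used for all arms.
#' @param control_mean Location of the true control means.
#' @param control_sd Between-study SD of the true control means.
#' @param cv_range Length-2 range for the within-arm coefficient of
#'   variation, or a single value.
#' @param dist `"normal"` (default) or `"lognormal"` subject-level draws;
#'   the lognormal option guarantees strictly positive data for
#'   small-mean outcomes.
#' @param seed Integer seed; mandatory, so every table is reproducible.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(true_rom = 0.85, tau2 = 0, n_studies = 20,
                       n_range = c(50, 50), control_mean = 38.2,
                       control_sd = 3.7, cv_range = c(0.05, 0.15),
                       dist = c("normal", "lognormal"), seed) {
  dist <- match.arg(dist)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` is required and must be a single integer", call. = FALSE)
  }
  if (length(n_range) == 1L) n_range <- c(n_range, n_range)
  if (length(cv_range) == 1L) cv_range <- c(cv_range, cv_range)
  stopifnot(
    true_rom > 0, tau2 >= 0, n_studies >= 1,
    length(n_range) == 2L, n_range[1] >= 2, n_range[2] >= n_range[1],
    control_mean > 0, control_sd >= 0,
    length(cv_range) == 2L, cv_range[1] > 0, cv_range[2] >= cv_range[1]
  )
  structure(
    list(
      true_rom = true_rom, tau2 = tau2, n_studies = as.integer(n_studies),
      n_range = as.integer(round(n_range)), control_mean = control_mean,
      control_sd = control_sd, cv_range = cv_range, dist = dist,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

draw_arm <- function(n, mu, sigma, dist) {
  if (dist == "lognormal") {
    # match arm mean and SD on the natural scale
    s2 <- log(1 + (sigma / mu)^2)
    stats::rlnorm(n, meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
  } else {
    stats::rnorm(n, mu, sigma)
  }
}

generate_studies_impl <- function(cfg) {
  k <- cfg$n_studies
  theta <- stats::rnorm(k, log(cfg$true_rom), sqrt(cfg$tau2))
  mc_true <- stats::rnorm(k, cfg$control_mean, cfg$control_sd)
  if (any(mc_true <= 0)) {
    stop("configuration implies non-positive control means; ",
         "reduce `control_sd` or use `dist = \"lognormal\"` with a larger mean",
         call. = FALSE)
  }
  mt_true <- mc_true * exp(theta)
  cv <- stats::runif(k, cfg$cv_range[1], cfg$cv_range[2])
  sizes <- seq(cfg$n_range[1], cfg$n_range[2])
  n_t <- sizes[sample.int(length(sizes), k, replace = TRUE)]
  n_c <- sizes[sample.int(length(sizes), k, replace = TRUE)]

  rows <- lapply(seq_len(k), function(i) {
    xt <- draw_arm(n_t[i], mt_true[i], cv[i] * mt_true[i], cfg$dist)
    xc <- draw_arm(n_c[i], mc_true[i], cv[i] * mc_true[i], cfg$dist)
    data.frame(
      study_id = sprintf("study_%02d", i),
      mean_t = mean(xt), sd_t = stats::sd(xt), n_t = n_t[i],
      mean_c = mean(xc), sd_c = stats::sd(xc), n_c = n_c[i],
      true_log_rom = theta[i]
    )
  })
  out <- do.call(rbind, rows)
  if (any(out$mean_t <= 0 | out$mean_c <= 0)) {
    stop("simulated arm means include non-positive values; ",
         "the configuration is unsuitable for ratio-of-means analysis",
         call. = FALSE)
  }
  out
}

#' Generate a table of synthetic two-arm study summaries
#'
#' Per study, a true log ratio of means is drawn from
#' `Normal(log(true_rom), tau2)` and a true control mean from the configured
#' location; subject-level data are then drawn for both arms and summarised,
#' so the observed means and SDs are genuine sample statistics (the small-n
#' noise of the delta-method variance is exercised, not idealised away).
#' Deterministic given the config's seed.
#'
#' @param cfg A [sim_config()].
#' @return A study table (see [validate_studies()]) with an extra
#'   `true_log_rom` column recording each study's latent effect.
#' @examples
#' generate_studies(sim_config(n_studies = 3, seed = 1))
#' @export
generate_studies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  generate_studies_impl(cfg)
}

#' Repeated generate-and-pool calibration experiment
#'
#' Repeats [generate_studies()] plus [pool()] of the log-ROM effects and
#' aggregates calibration metrics of the pooled estimator: bias and RMSE of
#' the pooled log ratio, coverage of the nominal 95% CI for the true value,
#' mean I^2 and the distribution of DerSimonian-Laird tau^2 estimates.
#'
#' @param cfg A [sim_config()]; its seed also seeds the per-rep streams.
#' @param reps Number of replicate meta-analyses (>= 1).
#' @param method Pooling model passed to [pool()].
#' @return A list of class `recovery_summary`: `reps`, `bias`, `rmse`,
#'   `coverage_pct`, `mean_i2`, `median_tau2`, `mean_est`, plus the
#'   per-rep vectors `est`, `covered`, `i2`, `tau2`.
#' @examples
#' recovery_experiment(sim_config(n_studies = 5, seed = 1), reps = 20)
#' @export
recovery_experiment <- function(cfg, reps = 100,
                                method = c("auto", "fixed", "random")) {
  stopifnot(inherits(cfg, "sim_config"), reps >= 1)
  method <- match.arg(method)
  true_log <- log(cfg$true_rom)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  est <- i2 <- tau2 <- numeric(reps)
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    studies <- generate_studies_impl(cfg)
    p <- pool(rom_effect(studies), method = method)
    est[r] <- p$est
    i2[r] <- p$I2
    tau2[r] <- p$tau2
    covered[r] <- p$ci[1] <= true_log && true_log <= p$ci[2]
  }
  structure(
    list(
      reps = reps,
      true_log_rom = true_log,
      bias = mean(est) - true_log,
      rmse = sqrt(mean((est - true_log)^2)),
      coverage_pct = 100 * mean(covered),
      mean_i2 = mean(i2),
      median_tau2 = stats::median(tau2),
      mean_est = mean(est),
      est = est, covered = covered, i2 = i2, tau2 = tau2
    ),
    class = "recovery_summary"
  )
}

#' @export
print.recovery_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Calibration over %d replicate meta-analyses\n", x$reps))
  cat(sprintf("  bias of pooled log-ROM : %s\n", format(x$bias, digits = digits)))
  cat(sprintf("  RMSE                   : %s\n", format(x$rmse, digits = digits)))
  cat(sprintf("  95%% CI coverage        : %s%%\n", format(x$coverage_pct, digits = digits)))
  cat(sprintf("  mean I2                : %s%%\n", format(x$mean_i2, digits = digits)))
  cat(sprintf("  median DL tau2         : %s\n", format(x$median_tau2, digits = digits)))
  invisible(x)
}
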