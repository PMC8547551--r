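# Meta-analysis engine: effects, pooling, heterogeneity, weighted control
# statistics, implied differences, meta-regression and leave-one-out.
# metafor (when available) acts as the independent cross-check, never the
# implementation.

test_that("log ratio-of-means effect matches the delta-method formulas", {
  s <- data.frame(study_id = "a", mean_t = 8, sd_t = 2, n_t = 10,
                  mean_c = 10, sd_c = 2, n_c = 10)
  eff <- rom_effect(s)
  expect_equal(eff$yi, -0.22314, tolerance = 1e-4)
  expect_equal(eff$vi, 0.01025, tolerance = 1e-10)

  # equal means give a null effect whatever the SDs
  s2 <- data.frame(study_id = "b", mean_t = 5, sd_t = 3, n_t = 7,
                   mean_c = 5, sd_c = 1, n_c = 9)
  expect_equal(rom_effect(s2)$yi, 0)

  # scale equivariance: rescaling both arms changes nothing
  s3 <- s
  s3[c("mean_t", "sd_t", "mean_c", "sd_c")] <-
    s3[c("mean_t", "sd_t", "mean_c", "sd_c")] * 7.3
  expect_equal(rom_effect(s3)$yi, eff$yi)
  expect_equal(rom_effect(s3)$vi, eff$vi)

  s_bad <- s
  s_bad$mean_c <- 0
  expect_error(rom_effect(s_bad), "row 1")
})

test_that("study table validation names the offending rows", {
  s <- fixture_studies()
  s$sd_t[3] <- -1
  expect_error(validate_studies(s), "row 3")
  s2 <- fixture_studies()
  s2$n_c[2] <- 1
  expect_error(validate_studies(s2), "row 2")
  expect_error(validate_studies(fixture_studies()[, -2]), "mean_t")
})

test_that("pooling reproduces the hand-computed heterogeneity example", {
  eff <- data.frame(yi = c(0.0, 0.2, 0.4), vi = rep(0.01, 3))
  p <- pool(eff)
  expect_equal(p$Q, 8)
  expect_equal(p$I2, 75)
  expect_equal(p$tau2, 0.03)
  expect_equal(p$method, "random")   # I2 > 30 selects random effects
  expect_equal(p$est, 0.2)           # symmetric effects, equal weights
})

test_that("single-study and homogeneous pooling behave as identities", {
  one <- data.frame(yi = 0.3, vi = 0.02)
  p1 <- pool(one)
  expect_equal(p1$est, 0.3)
  expect_equal(p1$se, sqrt(0.02))
  expect_equal(p1$Q, 0)
  expect_equal(p1$I2, 0)

  k <- 5
  same <- data.frame(yi = rep(0.1, k), vi = rep(0.04, k))
  pk <- pool(same)
  expect_equal(pk$est, 0.1)
  expect_equal(pk$se, sqrt(0.04 / k))
  expect_equal(pk$Q, 0)
  expect_equal(pk$I2, 0)
  expect_equal(pk$method, "fixed")
  expect_error(pool(same[0, ]), "at least one")
})

test_that("fixed-effect estimate is the plain mean under equal variances", {
  eff <- data.frame(yi = c(-0.1, 0.05, 0.3, 0.15), vi = rep(0.02, 4))
  expect_equal(pool(eff, method = "fixed")$est, mean(eff$yi))
})

test_that("zero tau2 makes random and fixed pooling identical", {
  eff <- data.frame(yi = c(0.10, 0.11, 0.09, 0.10), vi = c(0.05, 0.04, 0.06, 0.05))
  pf <- pool(eff, method = "fixed")
  pr <- pool(eff, method = "random")
  expect_equal(pr$tau2, 0)
  expect_equal(pr$est, pf$est)
  expect_equal(pr$se, pf$se)
})

test_that("ROM back-transform preserves CI ordering and round-trips", {
  p <- pool(rom_effect(fixture_studies()))
  expect_lt(p$rom_ci[1], p$rom)
  expect_gt(p$rom_ci[2], p$rom)
  expect_equal(log(p$rom), p$est, tolerance = 1e-12)
  expect_equal(log(p$rom_ci), p$ci, tolerance = 1e-12)
  expect_true(p$I2 >= 0 && p$I2 <= 100)
  expect_gte(p$tau2, 0)
})

test_that("pooled log-ROM and DL heterogeneity agree with metafor", {
  skip_if_not_installed("metafor")
  studies <- fixture_studies()
  eff <- rom_effect(studies)
  ref <- metafor::rma(
    yi = eff$yi, vi = eff$vi, method = "DL", test = "z"
  )
  p <- pool(eff, method = "random")
  expect_equal(p$est, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(p$se, ref$se, tolerance = 1e-10)
  expect_equal(p$tau2, ref$tau2, tolerance = 1e-10)
  expect_equal(p$Q, ref$QE, tolerance = 1e-10)
  expect_equal(p$I2, ref$I2, tolerance = 1e-6)

  pf <- pool(eff, method = "fixed")
  ref_f <- metafor::rma(yi = eff$yi, vi = eff$vi, method = "FE")
  expect_equal(pf$est, as.numeric(ref_f$beta), tolerance = 1e-10)
  expect_equal(pf$se, ref_f$se, tolerance = 1e-10)
})

test_that("per-study ROM effects agree with metafor's escalc", {
  skip_if_not_installed("metafor")
  studies <- fixture_studies()
  eff <- rom_effect(studies)
  ref <- metafor::escalc(
    measure = "ROM",
    m1i = studies$mean_t, sd1i = studies$sd_t, n1i = studies$n_t,
    m2i = studies$mean_c, sd2i = studies$sd_c, n2i = studies$n_c
  )
  expect_equal(eff$yi, as.numeric(ref$yi), tolerance = 1e-10)
  expect_equal(eff$vi, as.numeric(ref$vi), tolerance = 1e-10)
})

test_that("weighted control statistics average with the pooling weights", {
  s <- data.frame(study_id = c("a", "b"),
                  mean_t = c(1, 1), sd_t = c(1, 1), n_t = c(5, 5),
                  mean_c = c(30, 40), sd_c = c(2, 6), n_c = c(5, 5))
  eq <- weighted_control_stats(s, c(0.5, 0.5))
  expect_equal(unname(eq["mean_wt"]), 35)
  expect_equal(unname(eq["sd_wt"]), 4)

  w <- weighted_control_stats(
    data.frame(study_id = c("a", "b"),
               mean_t = c(1, 1), sd_t = c(1, 1), n_t = c(5, 5),
               mean_c = c(40, 32), sd_c = c(3, 3), n_c = c(5, 5)),
    c(0.75, 0.25)
  )
  expect_equal(unname(w["mean_wt"]), 38.0)

  single <- fixture_studies()[1, ]
  ws <- weighted_control_stats(single, 1)
  expect_equal(unname(ws["mean_wt"]), single$mean_c)
  expect_equal(unname(ws["sd_wt"]), single$sd_c)
  expect_error(weighted_control_stats(s, c(1, 2, 3)), "one entry per study")
})

test_that("implied absolute difference maps ratios back to the control scale", {
  expect_equal(round(absolute_difference(0.89, 38.2), 1), -4.2)
  expect_equal(absolute_difference(1, 38.2), 0)
  expect_equal(absolute_difference(1.5, 10), 5)
  # bound-wise map preserves ordering
  md <- absolute_difference(c(0.89, 0.86, 0.92), 38.2)
  expect_true(md[2] < md[1] && md[1] < md[3])
  p <- pool(rom_effect(fixture_studies()))
  md_p <- absolute_difference(p, 38.2)
  expect_lt(md_p[["md_low"]], md_p[["md"]])
  expect_gt(md_p[["md_high"]], md_p[["md"]])
})

test_that("meta-regression fits, interpolates and is translation-invariant", {
  # two-point fit interpolates exactly
  eff2 <- data.frame(yi = c(0.1, 0.4), vi = c(0.02, 0.05))
  fit2 <- meta_regress(eff2, c(250, 1000))
  expect_equal(fit2$residuals, c(0, 0), tolerance = 1e-12)
  expect_equal(fit2$slope, 0.3 / 750, tolerance = 1e-12)

  eff <- rom_effect(fixture_studies())
  dose <- fixture_studies()$dose
  fit <- meta_regress(eff, dose)
  shifted <- meta_regress(eff, dose + 1234)
  expect_equal(fit$slope, shifted$slope, tolerance = 1e-10)
  expect_equal(fit$slope_se, shifted$slope_se, tolerance = 1e-10)
  expect_error(meta_regress(eff, rep(500, nrow(eff))), "constant")
})

test_that("null-moderator slope CIs cover zero at roughly the nominal rate", {
  set.seed(314)
  reps <- 400
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    k <- 25
    vi <- runif(k, 0.005, 0.02)
    tau2 <- 0.01
    yi <- rnorm(k, -0.15, sqrt(vi + tau2))  # heterogeneous, no moderator effect
    mod <- runif(k, 0, 1000)
    fit <- meta_regress(data.frame(yi = yi, vi = vi), mod)
    covered[r] <- fit$slope_ci[1] <= 0 && 0 <= fit$slope_ci[2]
  }
  # nominal 95%; small conservatism from DL tau2 estimation is expected
  expect_gt(mean(covered), 0.91)
  expect_lt(mean(covered), 0.99)
})

test_that("leave-one-out isolates influential studies", {
  s2 <- fixture_studies()[1:2, ]
  loo2 <- leave_one_out(s2)
  for (i in 1:2) {
    remaining <- pool(rom_effect(s2[-i, , drop = FALSE]))
    expect_equal(loo2$est[i], remaining$est)
    expect_equal(loo2$I2[i], 0)
  }

  # a homogeneous set: all omission rows agree
  homog <- data.frame(
    study_id = paste0("h", 1:4),
    mean_t = rep(34, 4), sd_t = rep(3, 4), n_t = rep(400, 4),
    mean_c = rep(40, 4), sd_c = rep(3, 4), n_c = rep(400, 4)
  )
  loo_h <- leave_one_out(homog)
  expect_equal(diff(range(loo_h$rom)), 0, tolerance = 1e-12)

  # an outlier inflating heterogeneity: its omission minimises I2
  out <- fixture_studies()
  out$mean_t[5] <- 20
  out$sd_t[5] <- 0.5
  out$sd_c[5] <- 0.5
  loo <- leave_one_out(out)
  expect_equal(which.min(loo$I2), 5)
  expect_error(leave_one_out(out[1, , drop = FALSE]), "at least 2")
})

test_that("standardized mean differences carry the small-sample correction", {
  s <- data.frame(study_id = "a", mean_t = 8, sd_t = 2, n_t = 10,
                  mean_c = 10, sd_c = 2, n_c = 10)
  g <- smd_effect(s)
  expect_equal(g$yi, -1 * (1 - 3 / 71), tolerance = 1e-12)
  expect_equal(round(g$yi, 2), -0.96)

  # equal means give zero whatever the spread
  s0 <- s
  s0$mean_t <- 10
  expect_equal(smd_effect(s0)$yi, 0)

  # unit-effect limit: mean difference of one pooled SD, large n
  big <- data.frame(study_id = "b", mean_t = 11, sd_t = 2, n_t = 5000,
                    mean_c = 9, sd_c = 2, n_c = 5000)
  expect_equal(smd_effect(big)$yi, 1, tolerance = 1e-3)

  degenerate <- s
  degenerate$sd_t <- degenerate$sd_c <- 1e-300
  expect_error(
    smd_effect(transform(degenerate, sd_t = 0, sd_c = 0)),
    "positive"
  )
  # SMD effects pool through the same engine
  p <- pool(smd_effect(fixture_studies()))
  expect_identical(p$measure, "SMD")
  expect_null(p$rom)
})

test_that("SMD effects agree with metafor's Hedges g", {
  skip_if_not_installed("metafor")
  studies <- fixture_studies()
  mine <- smd_effect(studies)
  ref <- metafor::escalc(
    measure = "SMD",
    m1i = studies$mean_t, sd1i = studies$sd_t, n1i = studies$n_t,
    m2i = studies$mean_c, sd2i = studies$sd_c, n2i = studies$n_c
  )
  # metafor applies the exact gamma-function bias correction; the classical
  # 1 - 3/(4 df - 1) approximation agrees to ~1e-4 at these sample sizes
  expect_equal(mine$yi, as.numeric(ref$yi), tolerance = 1e-3)
  expect_equal(mine$vi, as.numeric(ref$vi), tolerance = 1e-3)
})
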