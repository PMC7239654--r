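doses8 <- 10 / 3^(0:7)  # 8 three-fold dilutions from 10 nM

test_that("noiseless titrations recover all four parameters", {
  cases <- list(
    list(bottom = 100, top = 1000, ec50 = 0.05, hill = 1),
    list(bottom = 100, top = 1000, ec50 = 0.05, hill = 2),
    list(bottom = 50, top = 400, ec50 = 0.5, hill = 0.7))
  for (cs in cases) {
    d <- simulate_dose_response(cs$bottom, cs$top, cs$ec50, cs$hill,
                                doses8, noise_sd = 0, seed = 1)
    fit <- fit_4pl(d)
    expect_true(fit$converged)
    expect_equal(fit$bottom, cs$bottom, tolerance = 1e-6)
    expect_equal(fit$top, cs$top, tolerance = 1e-6)
    expect_equal(10^fit$log_ec50, cs$ec50, tolerance = 1e-6)
    expect_equal(fit$hill, cs$hill, tolerance = 1e-6)
    expect_lt(fit$rss, 1e-10)
  }
})

test_that("degenerate titrations are flagged not-converged or rejected", {
  flat <- data.frame(dose = doses8, response = 500)
  expect_false(fit_4pl(flat)$converged)
  expect_error(ec50(fit_4pl(flat)), "converge")
  expect_error(fit_4pl(data.frame(dose = c(1, 2, 3), response = c(1, 2, 3))),
               "4 distinct")
  expect_error(fit_4pl(data.frame(dose = c(-1, 1, 2, 3, 4),
                                  response = 1:5)), "non-negative")
  # EC50 far outside the dosed range is extrapolation, not an estimate
  d <- simulate_dose_response(100, 1000, 5000, 1, doses8, noise_sd = 0, seed = 1)
  expect_false(fit_4pl(d)$converged)
})

test_that("zero-dose wells are excluded, optionally anchoring the bottom", {
  d <- simulate_dose_response(100, 1000, 0.05, 1, doses8, noise_sd = 0, seed = 1)
  d0 <- rbind(data.frame(sample = "sim", dose_nM = 0, replicate = 1,
                         response = 100), as.data.frame(d))
  fit <- fit_4pl(d0)
  expect_equal(fit$n_points, 8)
  anchored <- fit_4pl(d0, anchor_bottom = TRUE)
  expect_equal(anchored$bottom, 100)
  expect_equal(anchored$se_bottom, 0)
  expect_equal(10^anchored$log_ec50, 0.05, tolerance = 1e-6)
})

test_that("EC50 back-transform uses the delta method", {
  d <- simulate_dose_response(100, 1000, 0.05, 1, doses8, noise_sd = 0, seed = 1)
  fit <- fit_4pl(d)
  expect_equal(ec50(fit)$value, 0.05, tolerance = 1e-6)
  fit$se_log_ec50 <- 0.1
  expect_equal(ec50(fit)$se, log(10) * ec50(fit)$value * 0.1)
  fit$se_log_ec50 <- 0
  expect_equal(ec50(fit)$se, 0)
})

test_that("fold-change and efficacy ratios behave as ratios", {
  f1 <- fit_4pl(simulate_dose_response(100, 1000, 0.048, 1, doses8, 0, seed = 1))
  f2 <- fit_4pl(simulate_dose_response(100, 280, 3.93, 1, doses8, 0, seed = 1))
  expect_equal(fold_change(f2, f1), 3.93 / 0.048, tolerance = 1e-5)
  expect_equal(fold_change(f1, f1), 1)
  expect_equal(fold_change(f1, f2) * fold_change(f2, f1), 1)
  expect_equal(efficacy_ratio(f2, f1), 0.2, tolerance = 1e-5)
  expect_equal(efficacy_ratio(f1, f1), 1)
  degenerate <- f1; degenerate$top <- degenerate$bottom
  expect_error(efficacy_ratio(f1, degenerate), "zero dynamic range")
})

test_that("EC50 comparison is a Welch t-test on the nM scale", {
  f <- fit_4pl(simulate_dose_response(100, 1000, 0.05, 1, doses8, 0, seed = 1))
  same <- compare_ec50(f, f)
  # identical estimates: t = 0, p = 1 (guarded because combined SE is tiny but > 0)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- f; a$log_ec50 <- log10(0.048); a$se_log_ec50 <- 0.005 / (log(10) * 0.048)
  b <- f; b$log_ec50 <- log10(0.63); b$se_log_ec50 <- 0.02 / (log(10) * 0.63)
  a$residual_df <- 12; b$residual_df <- 12
  out <- compare_ec50(a, b)
  expect_equal(abs(out$t), 28.23115, tolerance = 1e-4)
  expect_lt(out$p, 1e-4)
  # equal SEs and equal residual dfs: Welch df collapses to their sum
  c1 <- f; c1$log_ec50 <- log10(0.2); c1$se_log_ec50 <- 0.01; c1$residual_df <- 12
  c2 <- f; c2$log_ec50 <- log10(0.2); c2$se_log_ec50 <- 0.01; c2$residual_df <- 12
  expect_equal(compare_ec50(c1, c2)$df, 24)
  z <- f; z$se_log_ec50 <- 0
  expect_error(compare_ec50(z, z), "zero combined")
})

test_that("noisy-titration recovery: median EC50 error < 15%, >= 95% converge", {
  # standard titration design: 8 three-fold dilutions centered on the
  # expected EC50; per-well noise sd is 5% of the top asymptote
  doses_sym <- 0.05 * 3^seq(3.5, -3.5, by = -1)
  n_sim <- 100
  errs <- rep(NA_real_, n_sim)
  conv <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    d <- simulate_dose_response(100, 1000, 0.05, 1, doses_sym,
                                noise_sd = 50, n_replicates = 2, seed = 1000 + i)
    fit <- fit_4pl(d)
    conv[i] <- fit$converged
    if (fit$converged) errs[i] <- abs(10^fit$log_ec50 - 0.05) / 0.05
  }
  expect_gte(mean(conv), 0.95)
  expect_lt(median(errs, na.rm = TRUE), 0.15)
})

test_that("fit JSON serialization round-trips the parameters", {
  f <- fit_4pl(simulate_dose_response(100, 1000, 0.05, 1, doses8, 0, seed = 1))
  path <- tempfile(fileext = ".json")
  write_fit_json(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$log_ec50, f$log_ec50)
  expect_true(back$converged)
})

test_that("reference EC50 table loads with panels and standard errors", {
  ref <- rspo3_ec50_reference()
  expect_true(all(c("panel", "sample", "ec50_nM", "se_nM") %in% names(ref)))
  expect_true(all(ref$ec50_nM > 0))
  expect_true(all(ref$se_nM > 0))
  expect_gte(nrow(ref), 8)
})
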