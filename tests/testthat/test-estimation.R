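test_that("exponential-decay fitting recovers noise-free rates exactly", {
  tt <- c(0, 6, 12, 24, 48, 72)
  f <- fit_exponential_decay(tt, 10 * exp(-0.054 * tt))
  expect_equal(f$estimates$kdeg, 0.054, tolerance = 1e-8)
  expect_equal(f$estimates$c0, 10, tolerance = 1e-8)
  fc <- fit_exponential_decay(tt, rep(3, length(tt)))
  expect_equal(fc$estimates$kdeg, 0)
  expect_error(fit_exponential_decay(tt, c(1, -1, 1, 1, 1, 1)),
               "strictly positive")
  expect_error(fit_exponential_decay(c(0, 1), c(1, 0.9)), ">= 3")
})

test_that("decay fitting is unbiased under proportional noise", {
  tt <- c(0, 6, 12, 24, 48, 72)
  est <- vapply(1:100, function(s) {
    dd <- generate_degradation(1, 0.054, tt, noise_spec(cv = 0.05, seed = s))
    fit_exponential_decay(dd$time_h, dd$conc_um)$estimates$kdeg
  }, numeric(1))
  expect_lt(abs(median(est) / 0.054 - 1), 0.02)
})

test_that("the TD fit recovers generating parameters from noise-free data", {
  ds <- generate_viability(default_design(), ref_td, ref_deg,
                           noise_spec(cv = 0, seed = 1))
  f <- fit_td_simultaneous(ds, ref_deg)
  expect_equal(unclass(f$estimates), unclass(ref_td), tolerance = 1e-3)
  expect_lt(max(abs(unclass(f$estimates) / unclass(ref_td) - 1)), 1e-3)
  expect_identical(f$convergence$status, "converged")
  expect_length(f$inestimable, 0)
  expect_true(all(f$rse_percent >= 0, na.rm = TRUE))
})

test_that("missing condition classes are flagged inestimable, not fitted", {
  ds <- generate_viability(default_design(), ref_td, ref_deg,
                           noise_spec(cv = 0, seed = 1))
  no_combo <- ds[!(ds$c_dox0 > 0 & ds$c_dex0 > 0), ]
  expect_message(f <- fit_td_simultaneous(no_combo, ref_deg),
                 "imax_dexi, ic50_dexi")
  expect_setequal(f$inestimable, c("imax_dexi", "ic50_dexi"))
  expect_true(all(is.na(f$rse_percent[c("imax_dexi", "ic50_dexi")])))
  free <- setdiff(names(unclass(ref_td)), f$inestimable)
  expect_equal(unclass(f$estimates)[free], unclass(ref_td)[free],
               tolerance = 1e-3)
  ctrl_only <- ds[ds$c_dox0 == 0 & ds$c_dex0 == 0, ]
  expect_message(fit_td_simultaneous(ctrl_only, ref_deg), "s_dox")
  no_ctrl <- ds[ds$c_dox0 > 0 | ds$c_dex0 > 0, ]
  expect_error(fit_td_simultaneous(no_ctrl, ref_deg), "control")
})

test_that("fitted estimates are invariant to row order", {
  ds <- generate_viability(default_design(), ref_td, ref_deg,
                           noise_spec(cv = 0.075, seed = 11))
  f1 <- fit_td_simultaneous(ds, ref_deg)
  set.seed(99)
  f2 <- fit_td_simultaneous(ds[sample(nrow(ds)), ], ref_deg)
  expect_equal(unclass(f1$estimates), unclass(f2$estimates),
               tolerance = 1e-6)
})

test_that("asymptotic confidence intervals for kg have sane coverage", {
  hits <- vapply(1:50, function(s) {
    ds <- generate_viability(default_design(), ref_td, ref_deg,
                             noise_spec(cv = 0.075, seed = 4000 + s))
    f <- fit_td_simultaneous(ds, ref_deg)
    est <- f$estimates[["kg"]]
    se_log <- f$rse_percent[["kg"]] / 100
    lo <- est * exp(-1.96 * se_log)
    hi <- est * exp(1.96 * se_log)
    ref_td[["kg"]] >= lo && ref_td[["kg"]] <= hi
  }, logical(1))
  expect_gte(mean(hits), 0.85)
  expect_lte(mean(hits), 0.99)
})

test_that("the DEX PK fit recovers generating parameters", {
  truth <- pk_params_dex_default()
  dd <- generate_dex_pk(c(50, 500, 2500), truth, noise = noise_spec(cv = 0))
  f <- fit_pk_dex(dd)
  expect_equal(unlist(unclass(f$estimates)), unlist(unclass(truth)),
               tolerance = 1e-3)
  expect_identical(f$convergence$status, "converged")
  expect_error(fit_pk_dex(dd[dd$time_h == 2, ]), "timepoints")
})

test_that("fitting a 2-compartment model to 1-compartment data hits the bound", {
  p1c <- pk_params_dex(kel = 1, k12 = 1e-8, k21 = 1, v = 14.6)
  dd <- generate_dex_pk(c(50, 500, 2500), p1c, noise = noise_spec(cv = 0))
  f <- suppressMessages(
    fit_pk_dex(dd, init = c(kel = 0.8, k12 = 0.3, k21 = 0.8, v = 12),
               opts = fit_options(n_starts = 0, n_polish = 1)))
  expect_true("k12" %in% f$boundary ||
                f$estimates$k12 < 1e-4 ||
                f$convergence$status == "non-identifiable")
})

test_that("the DEX PK fit is unbiased under proportional noise", {
  truth <- pk_params_dex_default()
  vs <- vapply(1:30, function(s) {
    dd <- generate_dex_pk(c(50, 500, 2500), truth,
                          noise = noise_spec(cv = 0.10, seed = 700 + s))
    fit_pk_dex(dd, opts = fit_options(n_starts = 2, n_polish = 1))$estimates$v
  }, numeric(1))
  expect_lt(abs(median(vs) / 14.6 - 1), 0.05)
})
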