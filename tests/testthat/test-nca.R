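test_that("trapezoidal AUC matches hand and analytic values", {
  expect_equal(auc_last(c(0, 1, 2), c(0, 10, 5)), 12.5)
  expect_equal(auc_last(c(0, 1, 2), c(0, 0, 0)), 0)
  expect_error(auc_last(0, 5), "2 samples")
  # dense sampling of C = 100 exp(-0.2 t) on [0, 24]
  tt <- seq(0, 24, by = 0.05)
  expect_equal(auc_last(tt, 100 * exp(-0.2 * tt)),
               100 / 0.2 * (1 - exp(-4.8)), tolerance = 0.01)
  # exactness on linear segments: a collinear midpoint changes nothing
  t0 <- c(0, 1, 2, 4, 8)
  c0 <- c(0, 6, 9, 7, 1)
  t1 <- c(0, 1, 2, 3, 4, 8)
  c1 <- c(0, 6, 9, 8, 7, 1)  # (3, 8) is on the chord from (2,9) to (4,7)
  expect_equal(auc_last(t1, c1), auc_last(t0, c0), tolerance = 1e-12)
})

test_that("terminal slope estimation recovers known rates", {
  tt <- c(0, 1, 8, 12, 16, 24)
  cc <- c(0, 120, 100 * exp(-0.2 * c(8, 12, 16, 24)))
  fit <- lambda_z(tt, cc)
  expect_equal(fit$lambda_z, 0.2, tolerance = 1e-10)
  expect_equal(fit$n_points, 4L)
  # a zero inside the terminal window is excluded before regression
  cc0 <- cc
  cc0[4] <- 0
  expect_equal(lambda_z(tt, cc0)$lambda_z, 0.2, tolerance = 1e-10)
  # fewer than 3 usable points: flagged, not an error
  expect_true(is.na(lambda_z(c(0, 1, 2, 3), c(0, 10, 5, 2.5))$lambda_z))
  # rising terminal data: non-negative slope is flagged
  expect_true(is.na(lambda_z(c(0, 1, 4, 8, 12),
                             c(0, 10, 1, 2, 3))$lambda_z))
  # noisy biexponential: estimate within 10% of the slow macro-rate
  set.seed(42)
  tb <- c(0, 0.5, 1, 2, 4, 8, 12, 16, 24, 36, 48)
  cb <- (50 * exp(-1 * tb) + 50 * exp(-0.1 * tb)) * exp(rnorm(11, 0, 0.03))
  cb[1] <- 0
  expect_lt(abs(lambda_z(tb, cb)$lambda_z - 0.1), 0.01)
})

test_that("AUC extrapolation to infinity", {
  expect_equal(auc_inf(100, 5, 0.1)$auc_inf, 150)
  expect_equal(auc_inf(100, 5, 0.1)$extrap_frac, 50 / 150)
  expect_true(is.na(auc_inf(100, 5, NA_real_)$auc_inf))
  # mono-exponential: total area equals C0/lambda within 1%
  tt <- seq(0, 36, by = 0.25)
  cc <- 80 * exp(-0.15 * tt)
  fit <- lambda_z(tt, cc)
  ai <- auc_inf(auc_last(tt, cc), cc[length(cc)], fit$lambda_z)
  expect_equal(ai$auc_inf, 80 / 0.15, tolerance = 0.01)
})

test_that("Cmax/Tmax with earliest-time tie-break", {
  expect_equal(cmax_tmax(c(0, 1, 2), c(0, 10, 5)), list(cmax = 10, tmax = 1))
  expect_equal(cmax_tmax(c(0, 1, 2, 3), c(0, 10, 10, 5))$tmax, 1)
  # noiseless one-compartment profile: observed Tmax within one grid step
  m <- drug_profile("amlodipine")$model
  sched <- drug_profile("amlodipine")$schedule
  obs <- cmax_tmax(sched, predict_concentration(m, sched))$tmax
  expect_lt(abs(obs - tmax_analytic(m)), 1)  # 1 h grid spacing near peak
})

test_that("average slope of the ascent", {
  expect_equal(average_slope(c(0, 1, 2), c(0, 10, 5)), 10)
  expect_equal(average_slope(c(0, 1, 2, 3), c(0, 4, 10, 2)), 5)
  expect_error(average_slope(c(0, 1, 2), c(10, 5, 2)), "first sample")
  # faster absorption -> strictly larger AS (noiseless, fixed schedule)
  sched <- drug_profile("amlodipine")$schedule
  as_of_ka <- sapply(c(0.4, 0.6, 0.8, 1.2, 1.6), function(ka) {
    m <- pk_model("one_compartment", dose = 10, f_abs = 0.64, ka = ka,
                  cl = 25, v1 = 1800)
    average_slope(sched, predict_concentration(m, sched))
  })
  expect_true(all(diff(as_of_ka) > 0))
  # custom strategy plugs in
  expect_equal(average_slope(c(0, 1, 2), c(0, 10, 5),
                             strategy = function(t, c, m) c[m] / t[m]),
               10)
})

test_that("AS is inversely related to Tmax across a ka grid", {
  sched <- drug_profile("amlodipine")$schedule
  res <- t(sapply(seq(0.3, 1.5, by = 0.1), function(ka) {
    m <- pk_model("one_compartment", dose = 10, f_abs = 0.64, ka = ka,
                  cl = 25, v1 = 1800)
    cc <- predict_concentration(m, sched)
    c(as = average_slope(sched, cc), tmax = cmax_tmax(sched, cc)$tmax)
  }))
  # AS strictly increases with ka while Tmax (grid-valued) never increases
  expect_true(all(diff(res[, "as"]) > 0))
  expect_true(all(diff(res[, "tmax"]) <= 0))
})

test_that("endpoint table has one validated row per profile", {
  p <- drug_profile("irbesartan")
  d <- trial_design(24, p$schedule)
  tr <- simulate_trial(d, p$model, p$model, variability_spec(), seed = 3)
  ep <- build_endpoint_table(tr)
  expect_equal(nrow(ep), 48)
  expect_named(ep, c("subject", "sequence", "period", "treatment", "auc",
                     "auc_inf", "cmax", "tmax", "as_slope", "lambda_z",
                     "extrap_frac"))
  # type invariants on simulated data
  ok <- !is.na(ep$auc_inf)
  expect_true(all(ep$auc > 0 & ep$cmax > 0 & ep$as_slope > 0))
  expect_true(all(ep$auc_inf[ok] >= ep$auc[ok]))
  expect_true(all(ep$extrap_frac[ok] >= 0 & ep$extrap_frac[ok] < 1))
  expect_true(all(ep$tmax %in% p$schedule))
  # zero-variability identical arms: identical rows within a period
  tr0 <- simulate_trial(d, p$model, p$model, variability_spec(0, 0, 0),
                        seed = 3)
  ep0 <- build_endpoint_table(tr0)
  expect_equal(length(unique(round(ep0$auc, 10))), 1)
  # all-zero profile errors with the record named
  bad <- tr
  bad$conc[bad$subject == 2 & bad$period == 1] <- 0
  expect_error(build_endpoint_table(bad), "subject 2 period 1")
})

test_that("endpoint invariants hold across many random profiles", {
  set.seed(99)
  p <- drug_profile("hydrochlorothiazide")
  d <- trial_design(24, p$schedule)
  for (s in 1:5) {
    tr <- simulate_trial(d, p$model, p$model, variability_spec(), seed = s)
    ep <- build_endpoint_table(tr)
    ok <- !is.na(ep$auc_inf)
    expect_true(all(ep$auc > 0 & ep$cmax > 0))
    expect_true(all(ep$auc_inf[ok] >= ep$auc[ok]))
    expect_true(all(ep$lambda_z[ok] > 0))
  }
})
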