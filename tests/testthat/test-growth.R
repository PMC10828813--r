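test_that("log-linear fit recovers a pure exponential exactly", {
  t <- seq(0, 2.2, length.out = 6)
  cv <- growth_curve(t, 0.05 * exp(1.0 * t))
  fit <- fit_growth_rate(cv)
  expect_equal(fit$lambda, 1.0, tolerance = 1e-10)
  expect_equal(fit$ln_od_intercept, log(0.05), tolerance = 1e-9)
  expect_equal(fit$n_points, 6)
  expect_true(fit$r_squared > 1 - 1e-12)
})

test_that("OD window restricts the fitted points and reports insufficiency", {
  t <- seq(0, 6, by = 0.25)
  cv <- growth_curve(t, 0.02 * exp(0.8 * t))
  fit <- fit_growth_rate(cv, od_window = c(0.05, 0.5))
  expect_true(all(cv$od600[fit$window] >= 0.05 & cv$od600[fit$window] <= 0.5))
  expect_error(fit_growth_rate(cv, od_window = c(10, 20)),
               "insufficient data: 0 point")
})

test_that("curve validation rejects malformed series", {
  expect_error(growth_curve(c(0, 1), c(1, 2)), ">= 3")
  expect_error(growth_curve(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(growth_curve(c(0, 1, 2), c(1, -2, 3)), "positive")
})

test_that("post-shift window finds exactly the exponential range", {
  # pure post-shift exponential: all post-shift points selected
  sp <- curve_spec(lambda_pre = 0.9, lambda_post = 0.5, od0 = 0.1, lag_h = 0,
                   t_transition = 0, dt = 0.1, horizon = 5, cv = 0)
  cv <- gen_growth_curve(sp)
  expect_equal(select_postshift_window(cv), seq_along(cv$time_h))

  # lag-then-exponential: the flat phase is excluded, endpoints known
  sp2 <- curve_spec(lambda_pre = 0.9, lambda_post = 0.5, od0 = 0.1,
                    lag_h = 2, t_transition = 0, dt = 0.1, horizon = 8, cv = 0)
  cv2 <- gen_growth_curve(sp2)
  w <- select_postshift_window(cv2)
  expect_equal(cv2$time_h[w[1]], 2, tolerance = 1e-9)
  expect_equal(w[length(w)], length(cv2$time_h))

  flat <- growth_curve(seq(0, 2, by = 0.2), rep(0.1, 11), t_transition = 0)
  expect_error(select_postshift_window(flat), "window-search error")
})

test_that("lag time is the back-extrapolation of the post-shift exponential", {
  # exponential from od_ini at the transition: no lag
  sp <- curve_spec(lambda_pre = 0.9, lambda_post = 0.5, od0 = 0.1, lag_h = 0,
                   t_transition = 0, dt = 0.1, horizon = 5, cv = 0)
  lr <- lag_time(gen_growth_curve(sp), od_ini = 0.1)
  expect_equal(lr$t_lag, 0, tolerance = 1e-9)

  # flat at 0.1 for 2 h, then exponential at 0.5 /h: T_lag = 2
  t <- seq(0, 8, by = 0.1)
  od <- ifelse(t <= 2, 0.1, 0.1 * exp(0.5 * (t - 2)))
  lr2 <- lag_time(growth_curve(t, od, t_transition = 0), od_ini = 0.1)
  expect_equal(lr2$t_lag, 2, tolerance = 1e-6)
  expect_equal(lr2$t_resume, 2, tolerance = 1e-6)

  # negative computed lag clamps to 0 with a flag
  up <- growth_curve(t, 0.1 * exp(0.5 * t), t_transition = 0)
  lr3 <- lag_time(up, od_ini = 0.05)
  expect_true(lr3$clamped)
  expect_equal(lr3$t_lag, 0)

  # nonpositive post-shift slope is a no-growth error
  down <- growth_curve(seq(0, 2, 0.2), 0.5 * exp(-0.3 * seq(0, 2, 0.2)),
                       t_transition = 0)
  w <- seq_along(down$time_h)
  expect_error(lag_time(down, od_ini = 0.5, window = w), "no-growth")
})

test_that("lag is identifiable exactly on a noiseless piecewise grid", {
  for (L in c(0, 0.5, 1, 2, 4)) {
    for (lam in c(0.2, 0.5, 1.0)) {
      sp <- curve_spec(lambda_pre = 0.95, lambda_post = lam, od0 = 0.1,
                       lag_h = L, t_transition = 0, dt = 0.1, horizon = 10,
                       cv = 0)
      lr <- lag_time(gen_growth_curve(sp), od_ini = 0.1)
      expect_true(abs(lr$t_lag - L) <= 1e-6)
    }
  }
})

test_that("lag extraction is equivariant under time shifts", {
  t <- seq(0, 8, by = 0.1)
  od <- ifelse(t <= 1.5, 0.1, 0.1 * exp(0.4 * (t - 1.5)))
  base <- lag_time(growth_curve(t, od, t_transition = 0), od_ini = 0.1)
  shift <- lag_time(growth_curve(t + 3, od, t_transition = 3), od_ini = 0.1)
  expect_equal(shift$t_lag, base$t_lag, tolerance = 1e-9)
  expect_equal(shift$t_resume, base$t_resume + 3, tolerance = 1e-9)
})

test_that("lag survives 2% multiplicative OD noise (median error < 0.1 h)", {
  errs <- vapply(1:100, function(s) {
    sp <- curve_spec(lambda_pre = 0.95, lambda_post = 0.5, od0 = 0.1,
                     lag_h = 2, t_transition = 0, dt = 0.1, horizon = 8,
                     cv = 0.02, seed = s)
    lag_time(gen_growth_curve(sp), od_ini = 0.1)$t_lag - 2
  }, numeric(1))
  expect_lt(stats::median(abs(errs)), 0.1)
})

test_that("noisy growth-rate fits are unbiased (Monte Carlo)", {
  lams <- vapply(1:200, function(s) {
    sp <- curve_spec(lambda_pre = 0.95, od0 = 0.02, dt = 1 / 6, horizon = 4,
                     cv = 0.02, seed = s)
    fit_growth_rate(gen_growth_curve(sp))$lambda
  }, numeric(1))
  expect_lt(abs(mean(lams) - 0.95) / 0.95, 0.01)
})

test_that("growth-rate summaries aggregate per group and annotate failures", {
  sp <- preset("growth_wt_minimal")
  cv <- gen_growth_curve(sp)
  one <- growth_rate_summary(list(cv), groups = "wt")
  expect_equal(one$sd_lambda, 0)
  expect_equal(one$n_curves, 1)

  three <- growth_rate_summary(list(cv, cv, cv), groups = rep("wt", 3))
  expect_equal(three$mean_lambda, 0.95, tolerance = 1e-9)
  expect_equal(three$sd_lambda, 0)

  # a stalled culture fails its fit but does not poison the group
  dead <- growth_curve(c(0, 1, 2, 3), rep(0.02, 4))
  mix <- growth_rate_summary(list(cv, dead), groups = c("wt", "wt"))
  expect_equal(mix$n_failed, 1)
  expect_warning(growth_rate_summary(list(dead), groups = "wt"),
                 "all growth-rate fits failed")
})

test_that("growth curves round-trip through CSV with a YAML sidecar", {
  sp <- curve_spec(lambda_pre = 0.9, lambda_post = 0.5, od0 = 0.1, lag_h = 1,
                   t_transition = 0, dt = 0.2, horizon = 4, cv = 0)
  cv <- gen_growth_curve(sp)
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(time_h = cv$time_h, od600 = cv$od600), csv)
  yaml::write_yaml(list(t_transition = 0, od_ini = 0.1, strain = "wt"),
                   sub("\\.csv$", ".yaml", csv))
  back <- read_growth_curve(csv)
  expect_equal(back$od600, cv$od600)
  expect_equal(back$t_transition, 0)
  expect_equal(lag_time(back)$t_lag, 1, tolerance = 1e-6)
})
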