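test_that("selection statistics recover injected bias and amplitude distortion", {
  clim <- sin_clim()
  h <- gen_historic_sst(synth_sst_params(1900, 100, clim, rep(0.05, 12),
                                         seed = 1))
  st0 <- selection_stats(h, h, model_id = "self")
  expect_equal(st0$bias, 0)
  expect_equal(st0$seasonal_diff, 0)
  expect_true(st0$passes)

  m <- gen_model_sst(synth_sst_params(1900, 100, clim, rep(0.05, 12),
                                      bias = 2, seed = 2))
  st <- selection_stats(m, h)
  expect_equal(st$bias, 2, tolerance = 0.1)
  expect_true(st$passes)

  m25 <- gen_model_sst(synth_sst_params(1900, 100, clim, rep(0.05, 12),
                                        seasonal_amp_factor = 2.5, seed = 3))
  expect_false(selection_stats(m25, h)$passes)  # amplitude inflated 2.5x

  short <- gen_historic_sst(synth_sst_params(1995, 5, clim, rep(0.05, 12)))
  expect_error(selection_stats(short, h), class = "coralproj_data_error")
})

test_that("model screening applies strict limits and matches a brute-force count", {
  zero <- data.frame(model_id = letters[1:4], bias = 0, seasonal_diff = 0)
  expect_equal(nrow(select_models(zero)$passing), 4)

  edge <- data.frame(model_id = "edge", bias = 3.0, seasonal_diff = 0.5)
  expect_equal(nrow(select_models(edge)$passing), 0)  # strict < 3

  tab <- cmip3_selection_fixture()
  expect_equal(nrow(tab), 41)
  part <- select_models(tab)
  brute <- sum(!(abs(tab$bias) < 3 & tab$seasonal_diff < 1))
  expect_equal(nrow(part$failing), brute)
  expect_equal(nrow(part$passing) + nrow(part$failing), 41)
  expect_true(all(nzchar(part$failing$reason)))
  expect_error(select_models(tab[0, ]), class = "coralproj_param_error")
})

test_that("polynomial detrending reproduces constructed trends", {
  s <- sinusoid_series(2000, 20)
  tf <- 2000 + (seq_len(240) - 0.5) / 12
  poly_series <- monthly_series(s$year, s$month,
                                1e-4 * (tf - 2010)^4 + 0.01 * (tf - 2010)^2 + 25)
  fit <- fit_detrend(poly_series, 4)
  expect_true(all(abs(fit$residuals) < 1e-8))

  fit_sin <- fit_detrend(s, 4)
  # trend of a pure sinusoid is close to its mean (edge wiggle aside);
  # residuals keep essentially the full seasonal cycle
  expect_lt(sd(fit_sin$fitted), 0.15 * sd(s$sst_c))
  expect_equal(sd(fit_sin$residuals), sd(s$sst_c - mean(s$sst_c)),
               tolerance = 0.01)

  fit0 <- fit_detrend(s, 0)
  expect_equal(fit0$residuals, s$sst_c - mean(s$sst_c))
  expect_equal(mean(fit_sin$residuals), 0, tolerance = 1e-10)
})

test_that("seasonal rescaling maps residuals to the historic variability", {
  clim <- sin_clim()
  h <- gen_historic_sst(synth_sst_params(1950, 50, clim, rep(0.2, 12), seed = 4))
  m <- gen_model_sst(synth_sst_params(1950, 50, clim, rep(0.2, 12),
                                      seasonal_amp_factor = 2, seed = 5))
  tr <- downscale_transform(m, h)

  # identity when the two residual distributions coincide
  tr_id <- downscale_transform(h, h)
  r <- seq(-3, 3, by = 0.25)
  expect_equal(seasonal_scale(r, tr_id), r, tolerance = 1e-9)

  # N(0, 2) residuals land on the historic SD
  set.seed(6)
  draws <- rnorm(1e4, 0, tr$model_resid_sd)
  expect_equal(sd(seasonal_scale(draws, tr)), tr$hist_resid_sd,
               tolerance = 0.05 * tr$hist_resid_sd)

  # under normality the CDF path equals the linear map to machine precision
  lin <- (r - tr$model_resid_mean) * tr$hist_resid_sd / tr$model_resid_sd
  expect_equal(seasonal_scale(r, tr), lin, tolerance = 1e-9)
})

test_that("scenario downscaling restores historic mean and amplitude, keeps the trend", {
  clim <- sin_clim()
  h <- gen_historic_sst(synth_sst_params(1950, 50, clim, rep(0.15, 12), seed = 7))

  # identity case: model == historic, scenario is its continuation
  scen_id <- gen_historic_sst(synth_sst_params(2000, 100, clim, rep(0.15, 12),
                                               trend_per_century = 2, seed = 8))
  out_id <- downscale_scenario(h, scen_id, h)
  expect_lt(max(abs(out_id$sst_c - scen_id$sst_c)), 1e-6)

  for (bias in c(-2, 2)) for (amp in c(0.5, 1.5, 2.0)) {
    m20 <- gen_model_sst(synth_sst_params(1950, 50, clim, rep(0.15, 12),
                                          bias = bias, seasonal_amp_factor = amp,
                                          seed = 9))
    scen <- gen_model_sst(synth_sst_params(2000, 100, clim, rep(0.15, 12),
                                           trend_per_century = 3, bias = bias,
                                           seasonal_amp_factor = amp, seed = 10))
    ds <- downscale_scenario(m20, scen, h)
    # overlap-period mean restored (downscaling the 20C run onto itself)
    ds20 <- downscale_scenario(m20, m20, h)
    expect_lt(abs(mean(ds20$sst_c) - mean(h$sst_c)), 0.05)
    # seasonal amplitude restored to the historic ratio
    ratio <- sd(fit_detrend(ds)$residuals) / sd(fit_detrend(h)$residuals)
    expect_true(ratio > 0.9 && ratio < 1.1)
    # the scenario's net century trend survives within 5%
    net <- function(x) mean(x$sst_c[x$year >= 2090]) -
      mean(x$sst_c[x$year <= 2009])
    expect_equal(net(ds), net(scen), tolerance = 0.05)
  }
})

test_that("downscaling an already-downscaled series is the identity within tolerance", {
  clim <- sin_clim()
  h <- gen_historic_sst(synth_sst_params(1950, 50, clim, rep(0.15, 12), seed = 11))
  m20 <- gen_model_sst(synth_sst_params(1950, 50, clim, rep(0.15, 12), bias = 1.5,
                                        seasonal_amp_factor = 1.4, seed = 12))
  scen <- gen_model_sst(synth_sst_params(2000, 100, clim, rep(0.15, 12),
                                         trend_per_century = 2.5, bias = 1.5,
                                         seasonal_amp_factor = 1.4, seed = 13))
  once <- downscale_scenario(m20, scen, h)
  m20_once <- downscale_scenario(m20, m20, h)
  twice <- downscale_scenario(m20_once, once, h)
  expect_equal(twice$sst_c, once$sst_c, tolerance = 0.05)
})

test_that("multi-model trend removes the seasonal cycle and averages model trends", {
  s <- sinusoid_series(2000, 20, mean = 25, amp = 3)
  tr1 <- multi_model_trend(list(s))
  expect_equal(attr(tr1, "n_models_averaged"), 1)
  expect_equal(mean(tr1$trend_c), 25, tolerance = 1e-3)
  # residual 12-month cycle < 10% of the input's
  cyc <- function(x) diff(range(tapply(x, s$month, mean)))
  expect_lt(cyc(tr1$trend_c), 0.1 * cyc(s$sst_c))

  clim <- sin_clim()
  a <- gen_historic_sst(synth_sst_params(2000, 100, clim, rep(0, 12),
                                         trend_per_century = 2))
  b <- gen_historic_sst(synth_sst_params(2000, 100, clim, rep(0, 12),
                                         trend_per_century = 4))
  tr <- multi_model_trend(list(a, b))
  expect_equal(attr(tr, "n_models_averaged"), 2)
  fit <- lm(trend_c ~ I((year + (month - 0.5) / 12) / 100), data = tr)
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 0.1)

  expect_error(multi_model_trend(list(a, sinusoid_series(2001, 99))),
               class = "coralproj_data_error")
})

test_that("monthly anomaly distributions recover the generator's sigma pattern", {
  noisefree <- sinusoid_series(1950, 30)
  d0 <- monthly_anomaly_distributions(noisefree)
  expect_true(all(d0$anomaly_sd < 0.1))  # detrend edge leakage only
  expect_true(all(abs(d0$anomaly_mean) < 1e-10))

  sig <- seq(0.3, 0.8, length.out = 12)
  s <- gen_historic_sst(synth_sst_params(1900, 100, sin_clim(), sig, seed = 14))
  d <- monthly_anomaly_distributions(s)
  expect_true(all(abs(d$anomaly_sd - sig) / sig < 0.15))
  # generated ordering (August noisier than February) is preserved
  expect_gt(d$anomaly_sd[8], d$anomaly_sd[2])
  expect_error(monthly_anomaly_distributions(sinusoid_series(2000, 5)),
               class = "coralproj_data_error")
})

test_that("SST simulation reproduces trend plus climatology and is seed-stable", {
  sc <- test_scenario()
  d0 <- sc$dists
  d0$anomaly_sd[] <- 0
  sims0 <- simulate_sst(sc$trend, d0, n_sims = 3, seed = 1)
  base <- sc$trend$trend_c + d0$cycle_mean[sc$trend$month]
  for (s in sims0) expect_equal(s$sst_c, base)

  expect_equal(formals(simulate_sst)$n_sims, 500)

  sims <- simulate_sst(sc$trend, sc$dists, n_sims = 200, seed = 2)
  expect_identical(simulate_sst(sc$trend, sc$dists, n_sims = 200, seed = 2),
                   sims)
  # ensemble mean tracks the deterministic part within 2 SE per month
  mat <- sapply(sims, function(s) s$sst_c)
  base <- sc$trend$trend_c + sc$dists$cycle_mean[sc$trend$month]
  se <- sc$dists$anomaly_sd[sc$trend$month] / sqrt(200)
  frac_out <- mean(abs(rowMeans(mat) - base) > 2 * se)
  expect_lt(frac_out, 0.1)  # ~5% expected by chance
})
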