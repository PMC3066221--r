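# shared builders for the test suite; everything is generated in code

sin_clim <- function(mean = 25, amp = 3, peak_month = 8) {
  mean + amp * cospi((1:12 - peak_month) / 6)
}

# a pure seasonal series with no trend and no noise
sinusoid_series <- function(start_year = 2000, n_years = 10, mean = 25,
                            amp = 3, peak_month = 8) {
  gen_historic_sst(synth_sst_params(start_year, n_years,
                                    sin_clim(mean, amp, peak_month),
                                    rep(0, 12)))
}

# one warming study scenario shared across ensemble/sensitivity tests:
# an OAH-like synthetic site, 55-year historic record, two model scenarios
# warming +2 and +3 degC/century (multi-model mean +2.5), A1B-like CO2.
# Cached because the aragonite table involves ~400 carbonate solves.
.scenario_cache <- new.env(parent = emptyenv())
test_scenario <- function() {
  if (!is.null(.scenario_cache$s)) return(.scenario_cache$s)
  site <- site_preset("OAH")
  historic <- gen_historic_sst(synth_sst_params(
    1945, 55, site$monthly_clim, site$monthly_sigma,
    trend_per_century = 0.6, seed = 101))
  clim <- monthly_climatology(historic)
  mk <- function(tr, seed) gen_historic_sst(synth_sst_params(
    2000, 100, site$monthly_clim, site$monthly_sigma,
    trend_per_century = tr, seed = seed))
  s <- list(site = site, historic = historic, clim = clim,
            trend = multi_model_trend(list(mk(2.0, 1), mk(3.0, 2))),
            dists = monthly_anomaly_distributions(historic),
            co2 = co2_preset_a1b(),
            arag = build_aragonite_table(),
            mort = fit_mortality_curve(mortality_fixture("all_data")))
  .scenario_cache$s <- s
  s
}
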