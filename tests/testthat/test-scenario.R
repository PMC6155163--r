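test_that("the scenario catalogue crosses the stressors exactly as configured", {
  tab <- scenario_table()
  expect_equal(nrow(tab), 11)
  expected <- data.frame(
    id = 1:11,
    fishing = c("status_quo", "new_regulations", "new_regulations_stop_trawl",
                "new_regulations", "status_quo", "status_quo", "status_quo",
                "status_quo", "new_regulations", "new_regulations",
                "new_regulations"),
    temperature = c("constant", "constant", "constant", "constant",
                    "RCP2.6", "RCP4.5", "RCP8.5", "constant",
                    "RCP4.5", "RCP4.5", "RCP4.5"),
    alien = c("model_predicts", "model_predicts", "model_predicts",
              "force_constant", "model_predicts", "model_predicts",
              "model_predicts", "force_trend", "model_predicts",
              "force_trend", "force_constant"))
  expect_equal(tab[, c("id", "fishing", "temperature", "alien")], expected)
})

test_that("regulation scenario reaches the printed effort reductions", {
  f <- build_scenario(2, default_baseline())
  expect_equal(effort_at(f, "trawl", 2060), 0.50)
  expect_equal(effort_at(f, "artisanal", 2060), 0.85)
  expect_equal(effort_at(f, "recreational", 2060), 0.80)
  # phased in over the first two years, then held
  expect_equal(effort_at(f, "trawl", 2011), 0.75)
  expect_equal(effort_at(f, "trawl", 2030), 0.50)
})

test_that("business-as-usual holds every driver at its reference level", {
  b <- default_baseline()
  f <- build_scenario(1, b)
  for (fl in names(f$effort)) {
    expect_equal(effort_at(f, fl, c(2010, 2035, 2060)), rep(1, 3))
  }
  ref <- mean(tail(b$sst_history$value[order(b$sst_history$year)], 3))
  expect_equal(sst_at(f, c(2010, 2040, 2060)), rep(ref, 3))
  expect_length(f$biomass_forcing, 0)
})

test_that("the trawl ban eliminates trawling by simulation year three", {
  f <- build_scenario(3, default_baseline())
  expect_equal(effort_at(f, "trawl", 2013), 0)
  expect_equal(effort_at(f, "trawl", 2040), 0)
  expect_gt(effort_at(f, "trawl", 2012), 0)
  expect_equal(effort_at(f, "artisanal", 2060), 0.85)
})

test_that("SST projection adds the anomaly track to the 3-year reference mean", {
  hist <- data.frame(year = 2001:2010, value = c(rep(25, 7), 25.8, 26.0, 26.2))
  ref <- mean(c(25.8, 26.0, 26.2))
  zero <- data.frame(year = 2010:2060, value = 0)
  expect_equal(build_sst_projection(hist, zero)$value, rep(ref, 51))
  plus1 <- data.frame(year = 2010:2060, value = 1)
  expect_equal(build_sst_projection(hist, plus1)$value, rep(ref + 1, 51))
  lin <- data.frame(year = 2010:2060, value = seq(0, 2, length.out = 51))
  proj <- build_sst_projection(hist, lin)
  expect_equal(proj$value[proj$year == 2035], ref + 1)
  expect_error(build_sst_projection(data.frame(year = 2001:2010,
                                               value = c(25, NA, rep(25, 8))), zero),
               "gaps")
})

test_that("alien trend forcing extrapolates the 5-year slope and floors at zero", {
  flat <- data.frame(year = 2006:2010, value = 2)
  expect_equal(build_alien_trend_forcing(flat, 10)$value, rep(2, 11))
  rising <- data.frame(year = 2006:2010, value = 1 + 0.1 * (0:4))
  out <- build_alien_trend_forcing(rising, 10)
  expect_equal(out$value[out$year == 2020], tail(rising$value, 1) + 1.0)
  falling <- data.frame(year = 2006:2010, value = c(1, 0.8, 0.6, 0.4, 0.2))
  out2 <- build_alien_trend_forcing(falling, 10)
  expect_true(all(out2$value >= 0))
  expect_equal(tail(out2$value, 1), 0)
  expect_error(build_alien_trend_forcing(rising[1:4, ], 10), "at least 5")
})

test_that("the combined scenario is the exact merge of its ingredients", {
  b <- default_baseline()
  s2 <- build_scenario(2, b)
  s6 <- build_scenario(6, b)
  s9 <- build_scenario(9, b)
  expect_identical(s9$effort, s2$effort)
  expect_identical(s9$sst, s6$sst)
  expect_length(s9$biomass_forcing, 0)
  # and the fully combined variant adds the invader forcing of Scn8
  s8 <- build_scenario(8, b)
  s10 <- build_scenario(10, b)
  expect_identical(s10$biomass_forcing, s8$biomass_forcing)
  expect_identical(s10$effort, s2$effort)
  expect_identical(s10$sst, s6$sst)
})

test_that("alien forcing requires alien groups and pins or extrapolates biomass", {
  b <- default_baseline()
  f4 <- build_scenario(4, b)
  expect_gt(length(f4$biomass_forcing), 0)
  for (g in names(f4$biomass_forcing)) {
    expect_equal(length(unique(f4$biomass_forcing[[g]]$value)), 1)
  }
  b_empty <- b
  b_empty$alien_history <- list()
  expect_error(build_scenario(8, b_empty), "no alien histories")
  expect_error(build_scenario(12, b), "unknown scenario id")
})
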