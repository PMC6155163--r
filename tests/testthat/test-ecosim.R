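test_that("foraging-arena flow matches its closed form on the reference case", {
  expect_equal(consumption_rate(a = 1, v = 2, B = 1, P = 1), 0.4)
  expect_equal(consumption_rate(a = 1, v = 2, B = 0, P = 1), 0)
  expect_equal(consumption_rate(a = 1, v = 2, B = 1, P = 1, f = 0), 0)
  q3 <- consumption_rate(a = 1, v = 2, B = 1, P = 1, f = 0.3)
  q6 <- consumption_rate(a = 1, v = 2, B = 1, P = 1, f = 0.6)
  expect_equal(q6, 2 * q3)                       # linear in f
  expect_error(consumption_rate(a = -1, v = 2, B = 1, P = 1), "negative")
  expect_error(consumption_rate(1, 2, 1, 1, f = 1.2), "\\[0, 1\\]")
})

test_that("flow increases in prey biomass and predator abundance", {
  b <- seq(0.1, 5, length.out = 30)
  qb <- consumption_rate(a = 0.7, v = 1.3, B = b, P = 1)
  qp <- consumption_rate(a = 0.7, v = 1.3, B = 1, P = b)
  expect_true(all(diff(qb) > 0))
  expect_true(all(diff(qp) > 0))
})

test_that("calibration inverts the baseline identity on every link", {
  p <- default_params()
  n <- length(p$B0)
  Q <- matrix(consumption_rate(p$a, p$v, rep(p$B0, times = n), rep(p$B0, each = n)),
              n, n)
  Q[!p$link] <- 0
  expect_lt(max(abs(Q - p$Q0) / pmax(p$Q0, 1e-300)), 1e-10)
})

test_that("huge vulnerability multipliers recover mass action", {
  w <- default_web()
  p6 <- calibrate(w$model, k = 1e6, k_new_alien = NULL)
  i <- which(p6$link, arr.ind = TRUE)[1, ]
  B0p <- p6$B0[i[1]]; B0q <- p6$B0[i[2]]; Q0 <- p6$Q0[i[1], i[2]]
  for (scale in c(0.5, 1.3, 2)) {
    q <- consumption_rate(p6$a[i[1], i[2]], p6$v[i[1], i[2]],
                          scale * B0p, scale * B0q)
    expect_equal(unname(q), unname(Q0 * scale^2),
                 tolerance = 1e-4)                    # Q ~ (Q0/B0 P0) B P
  }
})

test_that("vulnerability multipliers at or below 1 are rejected", {
  w <- default_web()
  expect_error(calibrate(w$model, k = 1), "vulnerable pool smaller")
  expect_error(calibrate(w$model, k = 0.5), "vulnerable pool smaller")
})

test_that("recently established invaders carry the high-vulnerability override", {
  w <- default_web()
  p <- calibrate(w$model, responses = w$responses)     # default override 10
  new_alien <- has_tag(w$model, "new_alien")
  expect_true(any(new_alien))
  klinks <- p$k[, new_alien][p$link[, new_alien]]
  expect_true(all(klinks == 10))
  other <- p$k[, !new_alien][p$link[, !new_alien]]
  expect_true(all(other == 2))
})

test_that("calibrated webs start at an exact equilibrium and do not drift", {
  p <- default_params()
  expect_lt(max(abs(baseline_derivative(p))), 1e-9)
  s <- simulate_ecosim(p, baseline_forcing_set(p, years = 10))
  drift <- abs(s$biomass[, ncol(s$biomass)] / s$biomass[, 1] - 1)
  expect_lt(max(drift), 0.01)
  expect_equal(s$clamp_events, 0L)
})

test_that("production equals growth efficiency times total consumption at every mark", {
  s <- scenario_run(7)
  p <- s$params
  cons <- p$is_consumer
  for (i in c(1, 11, 31, 51)) {
    fl <- s$flows[[i]]
    Qtot <- colSums(fl$Q) + fl$Qimp
    resp <- (1 - p$GS[cons]) * Qtot[cons] - p$pq[cons] * Qtot[cons]
    expect_true(all(resp >= -1e-9))        # energetic feasibility maintained
  }
})

test_that("biomass forcing bypasses the dynamics exactly", {
  p <- default_params()
  f <- baseline_forcing_set(p, years = 5)
  g <- names(p$B0)[6]
  target <- 2 * p$B0[[g]]
  f$biomass_forcing <- list(data.frame(year = c(2010, 2015), value = target))
  names(f$biomass_forcing) <- g
  s <- simulate_ecosim(p, f)
  expect_equal(unname(s$biomass[g, -1]), rep(target, 5))
})

test_that("removing all fishing zeroes catches and releases exploited groups", {
  p <- default_params()
  f <- baseline_forcing_set(p, years = 3)
  for (fl in names(f$effort)) f$effort[[fl]]$value <- 0
  s <- simulate_ecosim(p, f)
  expect_true(all(s$catch == 0))
  # groups under substantial fishing mortality are released immediately;
  # lightly caught prey can still dip as their released predators grow
  fmort <- total_catch_by_group(p$model) / p$B0
  exploited <- fmort >= 0.1
  expect_gt(sum(exploited), 3)
  expect_true(all(s$biomass[exploited, 2] >= s$biomass[exploited, 1] - 1e-12))
})

test_that("halving the step changes a decade-long trajectory by less than 0.1%", {
  p <- default_params()
  f <- build_scenario(7, default_baseline(), horizon = 10)
  s1 <- simulate_ecosim(p, f, dt = 1 / 12)
  s2 <- simulate_ecosim(p, f, dt = 1 / 24)
  expect_lt(max(abs(s1$biomass / s2$biomass - 1)), 1e-3)
})

test_that("integrator agrees with an independent fixed-step solver", {
  skip_if_not_installed("deSolve")
  p <- default_params()
  f <- build_scenario(6, default_baseline(), horizon = 5)
  s <- simulate_ecosim(p, f)
  rhs <- function(t, y, parms) {
    d <- trophicdyn:::.ecosim_deriv(p, y, sapply(names(f$effort), function(fl) effort_at(f, fl, t)),
                                    sst_at(f, t), 1)
    list(d$dB)
  }
  out <- deSolve::rk4(p$B0, times = seq(2010, 2015, by = 1 / 12), func = rhs,
                      parms = NULL)
  final <- out[nrow(out), -1]
  expect_equal(unname(s$biomass[, 6]), unname(final), tolerance = 1e-6)
})

test_that("consumption never exceeds the vulnerable-pool exchange limit", {
  p <- default_params()
  links <- which(p$link, arr.ind = TRUE)
  set.seed(7)
  for (r in seq_len(nrow(links))) {
    i <- links[r, 1]; j <- links[r, 2]
    B <- runif(1, 0.1, 5) * p$B0[i]
    sup <- p$v[i, j] * B                     # supremum of the flow in P
    P <- 10^runif(1, -1, 3) * p$B0[j]
    expect_lte(consumption_rate(p$a[i, j], p$v[i, j], B, P), sup + 1e-12)
  }
})

test_that("effort interpolation is linear with right-continuous steps", {
  f <- forcing_set(
    years = 2010:2020,
    effort = list(trawl = data.frame(year = c(2010, 2010, 2013, 2020),
                                     value = c(1, 1, 0.5, 0.5)),
                  step = data.frame(year = c(2010, 2015, 2015, 2020),
                                    value = c(1, 1, 0.3, 0.3))),
    sst = data.frame(year = c(2010, 2020), value = c(20, 20)))
  expect_equal(effort_at(f, "trawl", 2011.5), 0.75)
  expect_equal(effort_at(f, "trawl", 2017), 0.5)
  expect_equal(effort_at(f, "step", 2015), 0.3)     # post-step value at the knot
  expect_equal(effort_at(f, "step", 2014.999), 1, tolerance = 1e-2)
  expect_error(effort_at(f, "trawl", 2025), "outside the forcing horizon")
  expect_error(effort_at(f, "nosuch", 2011), "unknown fleet")
})
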