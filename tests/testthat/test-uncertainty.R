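test_that("pedigree validation enforces range and parameter names", {
  expect_error(pedigree(data.frame(group = "a", parameter = "EE", ci = 0.1)),
               "B, PB, QB")
  expect_error(pedigree(data.frame(group = "a", parameter = "B", ci = 0.9)),
               "\\[0, 0.8\\]")
})

test_that("zero confidence intervals reproduce the base model exactly", {
  b <- default_web()$model
  ped <- pedigree(data.frame(group = group_names(b)[1], parameter = "B", ci = 0))
  set.seed(1)
  drawn <- draw_model(b, ped)
  expect_equal(drawn$groups, b$groups)
})

test_that("draws are uniform within the pedigree interval", {
  b <- solve_mass_balance(grazer_model())
  ped <- pedigree(data.frame(group = "producer", parameter = "B", ci = 0.1))
  set.seed(99)
  draws <- replicate(1e4, draw_model(b, ped)$groups$B[1])
  expect_true(all(draws >= 10 * 0.9 & draws <= 10 * 1.1))
  ks <- suppressWarnings(ks.test(draws, "punif", 9, 11))
  expect_gt(ks$p.value, 0.01)
})

test_that("a pedigree incompatible with balance exhausts its redraws", {
  # eight independent producer/consumer pairs, each producer at the EE = 1
  # boundary: a draw is only feasible when every producer biomass moves up,
  # so almost all draws are rejected and the cap is reached
  k <- 8
  nm <- c(paste0("prod", 1:k), paste0("cons", 1:k), "detritus")
  groups <- data.frame(
    name = nm,
    category = c(rep("producer", k), rep("consumer", k), "detritus"),
    B = c(rep(1, 2 * k), 1), PB = c(rep(10, k), rep(2, k), NA),
    QB = c(rep(0, k), rep(10, k), NA), EE = NA_real_,
    GS = c(rep(0, k), rep(0.2, k), 0), BA = 0, net_migration = 0,
    role_tags = "")
  diet <- matrix(0, 2 * k + 1, 2 * k + 1, dimnames = list(nm, nm))
  for (i in 1:k) diet[paste0("prod", i), paste0("cons", i)] <- 1
  b <- solve_mass_balance(ecopath_model(groups, diet))
  expect_equal(b$groups$EE[1:k], rep(1, k))
  ped <- pedigree(data.frame(group = paste0("prod", 1:k),
                             parameter = "B", ci = 0.5))
  set.seed(5)
  expect_error(draw_model(b, ped), "pedigree incompatible with balance")
})

test_that("monte carlo is seed-reproducible and degenerate at zero pedigree", {
  w <- default_web()
  b <- w$model
  f <- build_scenario(1, default_baseline(), horizon = 5)
  ped0 <- pedigree(data.frame(group = group_names(b)[3], parameter = "B", ci = 0))
  env <- run_monte_carlo(b, f, ped0, n = 3, seed = 7,
                         responses = w$responses, indicators = FALSE)
  expect_equal(env$outputs$biomass$lower, env$outputs$biomass$central)
  expect_equal(env$outputs$biomass$upper, env$outputs$biomass$central)

  ped <- w$pedigree
  e1 <- run_monte_carlo(b, f, ped, n = 4, seed = 11,
                        responses = w$responses, indicators = FALSE)
  e2 <- run_monte_carlo(b, f, ped, n = 4, seed = 11,
                        responses = w$responses, indicators = FALSE)
  expect_identical(e1$outputs, e2$outputs)
  e3 <- run_monte_carlo(b, f, ped, n = 4, seed = 12,
                        responses = w$responses, indicators = FALSE)
  expect_false(identical(e1$outputs$biomass$lower, e3$outputs$biomass$lower))
  expect_true(all(e1$outputs$biomass$lower <= e1$outputs$biomass$upper + 1e-12))
})

test_that("wider pedigrees give wider envelopes", {
  w <- default_web()
  b <- w$model
  f <- build_scenario(1, default_baseline(), horizon = 5)
  width_at <- function(ci) {
    ped <- pedigree(data.frame(group = rep(group_names(b)[c(3, 4, 7)], each = 2),
                               parameter = rep(c("B", "PB"), 3), ci = ci))
    env <- run_monte_carlo(b, f, ped, n = 25, seed = 21,
                           responses = w$responses, indicators = FALSE)
    mean(env$outputs$biomass$upper - env$outputs$biomass$lower)
  }
  expect_gt(width_at(0.4), width_at(0.1))
})

test_that("the seed does not leak into the caller's random stream", {
  w <- default_web()
  f <- build_scenario(1, default_baseline(), horizon = 3)
  set.seed(123)
  expected <- runif(5)
  set.seed(123)
  invisible(run_monte_carlo(w$model, f, w$pedigree, n = 2, seed = 5,
                            responses = w$responses, indicators = FALSE))
  expect_equal(runif(5), expected)
})
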