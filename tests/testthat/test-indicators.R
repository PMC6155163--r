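test_that("aggregate biomasses respect category and tag filters", {
  w <- default_web()
  m <- w$model
  TLs <- trophic_levels(m)
  state <- setNames(m$groups$B, m$groups$name)
  bi <- biomass_indicators(state, m, TLs)
  liv <- m$groups$category != "detritus"
  expect_equal(unname(bi[["TotalB"]]), sum(state[liv]))
  expect_equal(unname(bi[["ForF"]]), sum(state[has_tag(m, "forage")]))
  expect_equal(unname(bi[["InvB"]]), sum(state[has_tag(m, "benthic_invertebrate")]))
  expect_equal(unname(bi[["PredB"]]), sum(state[liv & TLs >= 4]))
  # no group at TL >= 4 -> predatory biomass is zero
  expect_equal(unname(biomass_indicators(state, m, pmin(TLs, 3.5))[["PredB"]]), 0)
})

test_that("Kempton's index matches its hand-evaluated formula", {
  state <- c(a = 1, b = 2, c = 4, d = 8)
  TLs <- c(a = 3.2, b = 3.5, c = 4, d = 4.5)
  # S = 4: quartile ranks 1 and 3 -> biomasses 1 and 4
  expect_equal(kemptons_q(state, TLs), 2 / log10(4))
  # ratio-based: scale invariance
  expect_equal(kemptons_q(state * 10, TLs), kemptons_q(state, TLs))
  # groups below TL 3 are invisible to the index
  expect_equal(kemptons_q(c(state, e = 100), c(TLs, e = 2)), kemptons_q(state, TLs))
  # degenerate cases return the missing marker
  expect_true(is.na(kemptons_q(state[1:3], TLs[1:3])))
  expect_true(is.na(kemptons_q(rep(2, 5), rep(3.5, 5))))
})

test_that("catch indicators weight trophic levels by removals", {
  expect_equal(unname(catch_indicators(c(x = 2), c(x = 3))[["mTLc"]]), 3)
  ci <- catch_indicators(c(a = 1, b = 1), c(a = 2, b = 4))
  expect_equal(unname(ci[["mTLc"]]), 3)
  ci2 <- catch_indicators(c(a = 1.0, b = 0.5), c(a = 2.5, b = 4.0))
  expect_equal(unname(ci2[["TotalC"]]), 1.5)
  expect_equal(unname(ci2[["mTLc"]]), 3.0)
  expect_true(is.na(catch_indicators(c(a = 0, b = 0), c(a = 2, b = 3))[["mTLc"]]))
})

test_that("community mean trophic level is the biomass-weighted mean", {
  m <- toy_chain_model()
  TLs <- c(producer = 1, herbivore = 2, carnivore = 3, detritus = 1)
  state <- c(producer = 10, herbivore = 2, carnivore = 0.5, detritus = 100)
  expect_equal(mean_tl_community(state, m, TLs), 15.5 / 12.5)   # 1.24
  single <- c(producer = 10, herbivore = 0, carnivore = 0, detritus = 0)
  expect_equal(mean_tl_community(single, m, TLs), 1)
  shifted <- c(producer = 8, herbivore = 2, carnivore = 2.5, detritus = 100)
  expect_gt(mean_tl_community(shifted, m, TLs), mean_tl_community(state, m, TLs))
})

test_that("acyclic webs have zero cycling and the loop web matches the series oracle", {
  nm <- c("producer", "consumer")
  Q <- matrix(c(0, 0, 10, 0), 2, 2, dimnames = list(nm, nm))
  fs <- flow_snapshot(Q, c(0, 4), c(2, 6), c(0, 0), c(12, 0))
  fi <- flow_indicators(fs)
  expect_equal(unname(fi[["FCI"]]), 0)
  expect_equal(unname(fi[["TST"]]), sum(Q) + 4 + 8)

  loop <- loop_snapshot()
  fci <- flow_indicators(loop)[["FCI"]]
  expect_gt(fci, 0)
  expect_equal(unname(fci), fci_series_oracle(loop), tolerance = 1e-10)
})

test_that("path length reduces to one when everything exits immediately", {
  nm <- c("a", "b")
  Q <- matrix(0, 2, 2, dimnames = list(nm, nm))
  fs <- flow_snapshot(Q, c(0, 0), c(0, 0), c(5, 3), c(5, 3))
  fi <- flow_indicators(fs)
  expect_equal(unname(fi[["PL"]]), 1)
})

test_that("cycling is scale-invariant but increases with the recycling flow", {
  loop <- loop_snapshot()
  scaled <- loop
  scaled$Q <- loop$Q * 3
  scaled$respiration <- loop$respiration * 3
  scaled$flows_to_detritus <- loop$flows_to_detritus * 3
  scaled$exports <- loop$exports * 3
  scaled$imports <- loop$imports * 3
  expect_equal(flow_indicators(scaled)[["FCI"]], flow_indicators(loop)[["FCI"]])
  more <- loop_snapshot(recycle = 4)
  expect_gt(flow_indicators(more)[["FCI"]], flow_indicators(loop)[["FCI"]])
})

test_that("negative respiration marks an energetically infeasible snapshot", {
  nm <- c("a", "b")
  Q <- matrix(c(0, 0, 5, 0), 2, 2, dimnames = list(nm, nm))
  expect_error(flow_snapshot(Q, c(0, -1), c(0, 0), c(0, 0), c(5, 0)),
               "energetically infeasible")
})

test_that("a 50-year run yields gap-free annual indicator series", {
  s <- scenario_run(7)
  ind <- indicator_series(s)
  expect_equal(nrow(ind), 50)
  expect_equal(ind$year, 2011:2060)
  core <- setdiff(names(ind), "year")
  expect_false(anyNA(ind[core]))
  expect_true(all(ind$FCI >= 0 & ind$FCI < 100))
  expect_true(all(ind$TST > 0))
  expect_true(all(ind$PL >= 1))
  tm <- trend_matrix(ind)
  expect_equal(nrow(tm), length(core))
})
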