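# Fixtures built in code, shared across test files.

# producer (B=10, PB=10) grazed by a single consumer (B=1, QB=5): the
# hand-checkable EE_producer = 5/100 = 0.05 case.
grazer_model <- function() {
  groups <- data.frame(
    name = c("producer", "grazer", "detritus"),
    category = c("producer", "consumer", "detritus"),
    B = c(10, 1, 5), PB = c(10, 1, NA), QB = c(0, 5, NA),
    EE = NA_real_, GS = c(0, 0.2, 0), BA = 0, net_migration = 0,
    role_tags = "")
  diet <- matrix(0, 3, 3, dimnames = list(groups$name, groups$name))
  diet["producer", "grazer"] <- 1
  landings <- matrix(c(0, 0.01, 0), ncol = 1,
                     dimnames = list(groups$name, "artisanal"))
  ecopath_model(groups, diet, landings = landings)
}

# two consumers feeding on each other (10%) plus a shared producer: TL is a
# genuine fixed point, not a cascade.
mutual_feeders_model <- function() {
  groups <- data.frame(
    name = c("producer", "omnivore_a", "omnivore_b", "detritus"),
    category = c("producer", "consumer", "consumer", "detritus"),
    B = c(20, 1, 1, 5), PB = c(10, 2, 2, NA), QB = c(0, 8, 8, NA),
    EE = NA_real_, GS = c(0, 0.2, 0.2, 0), BA = 0, net_migration = 0,
    role_tags = "")
  diet <- matrix(0, 4, 4, dimnames = list(groups$name, groups$name))
  diet["producer", "omnivore_a"] <- 0.9
  diet["omnivore_b", "omnivore_a"] <- 0.1
  diet["producer", "omnivore_b"] <- 0.9
  diet["omnivore_a", "omnivore_b"] <- 0.1
  landings <- matrix(c(0, 0.02, 0.02, 0), ncol = 1,
                     dimnames = list(groups$name, "fleet1"))
  ecopath_model(groups, diet, landings = landings)
}

# 3-compartment web with an explicit detritus recycling loop for the
# cycling-index oracle: producer -> consumer -> detritus -> consumer.
loop_snapshot <- function(recycle = 2) {
  nm <- c("producer", "consumer", "detritus")
  Q <- matrix(0, 3, 3, dimnames = list(nm, nm))
  Q["producer", "consumer"] <- 10
  Q["detritus", "consumer"] <- recycle          # detritivory closes a loop
  respiration <- c(producer = 0, consumer = 4, detritus = 0)
  to_det <- c(producer = 2, consumer = 5, detritus = 0)
  exports <- c(producer = 0, consumer = 3 + recycle, detritus = 7 - recycle)
  imports <- c(producer = 12, consumer = 0, detritus = 0)
  flow_snapshot(Q, respiration, to_det, exports, imports, detritus = "detritus")
}

# brute-force cycling oracle: diagonal of sum_k G^k by direct series summation
fci_series_oracle <- function(fs, tol = 1e-10) {
  Q <- fs$Q
  n <- nrow(Q)
  Fm <- Q
  det <- match(fs$detritus, rownames(Q))
  for (d in det) Fm[, d] <- Fm[, d] + fs$flows_to_detritus / length(det)
  Tin <- colSums(Fm) + fs$imports
  G <- Fm / rep(ifelse(Tin > 0, Tin, 1), each = n)
  G[, Tin <= 0] <- 0
  L <- diag(n)
  term <- diag(n)
  for (k in 1:10000) {
    term <- term %*% G
    L <- L + term
    if (max(abs(term)) < tol) break
  }
  lii <- diag(L)
  TST <- sum(Q) + sum(fs$exports) + sum(fs$respiration) + sum(fs$flows_to_detritus)
  100 * sum(Tin * (lii - 1) / lii) / TST
}

# cache the default synthetic web across test files
.web_cache <- new.env(parent = emptyenv())
default_web <- function(seed = 1) {
  key <- paste0("w", seed)
  if (is.null(.web_cache[[key]])) {
    .web_cache[[key]] <- generate_web(generator_config(seed = seed))
  }
  .web_cache[[key]]
}
default_baseline <- function(seed = 1) {
  key <- paste0("b", seed)
  if (is.null(.web_cache[[key]])) {
    .web_cache[[key]] <- generate_baseline_forcing(generator_config(seed = seed),
                                                   web = default_web(seed))
  }
  .web_cache[[key]]
}
default_params <- function(seed = 1) {
  key <- paste0("p", seed)
  if (is.null(.web_cache[[key]])) {
    w <- default_web(seed)
    .web_cache[[key]] <- calibrate(w$model, responses = w$responses)
  }
  .web_cache[[key]]
}
# cache full scenario runs used by several files
scenario_run <- function(id, seed = 1) {
  key <- paste0("s", seed, "_", id)
  if (is.null(.web_cache[[key]])) {
    f <- build_scenario(id, default_baseline(seed))
    .web_cache[[key]] <- simulate_ecosim(default_params(seed), f)
  }
  .web_cache[[key]]
}

# brute-force two-sided permutation p-value for the Spearman statistic
spearman_perm_p <- function(series, time = seq_along(series)) {
  rho_obs <- abs(cor(rank(series), rank(time)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  all_p <- perms(seq_along(series))
  hits <- vapply(all_p, function(p) {
    abs(cor(rank(series[p]), rank(time))) >= rho_obs - 1e-12
  }, logical(1))
  mean(hits)
}
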