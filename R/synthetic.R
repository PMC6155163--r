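#' Configuration of the synthetic food-web generator
#'
#' The generator emulates a balanced, exploited, invaded coastal shelf food
#' web: a phytoplankton producer and detritus pool, zooplankton, native and
#' alien benthic invertebrates, native forage fish, native and alien
#' demersal fish (including a recently established invader), an alien
#' herbivorous fish, a piscivorous top predator and a vulnerable megafauna
#' group taken only as bycatch; three fleets (trawl, artisanal,
#' recreational) by default. Alien groups carry warm-shifted thermal niches
#' relative to the cool-preferring natives.
#'
#' @param n_groups number of functional groups (>= 6, default 12).
#' @param n_fleets 3 (trawl, artisanal, recreational) or 4 (adds a purse
#'   seine).
#' @param alien_fraction target fraction of groups tagged alien (default 0.3).
#' @param seed integer seed (mandatory; the generator is deterministic per
#'   seed).
#' @param thermal_regime list with `native_pref` and `alien_pref` (each a
#'   `c(q10, q90)` preferable range, degrees C) and `baseline_sst` (reference
#'   level at the end of the historical period).
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_groups = 12, n_fleets = 3, alien_fraction = 0.3,
                             seed,
                             thermal_regime = list(native_pref = c(18, 26.8),
                                                   alien_pref = c(21, 33),
                                                   baseline_sst = 26)) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_groups < 6) stop("n_groups must be at least 6")
  if (!n_fleets %in% c(3, 4)) stop("n_fleets must be 3 or 4")
  if (alien_fraction < 0 || alien_fraction > 0.6) stop("alien_fraction must lie in [0, 0.6]")
  structure(list(n_groups = n_groups, n_fleets = n_fleets,
                 alien_fraction = alien_fraction, seed = as.integer(seed),
                 thermal_regime = thermal_regime),
            class = "generator_config")
}

# archetype table: base parameters, diet templates and catch templates.
# Inclusion order (top to bottom) respects the minimal web constraints.
.archetypes <- function() {
  d <- function(...) c(...)
  list(
    list(name = "phytoplankton", category = "producer", tags = "native",
         B = 15, PB = 25, QB = 0, GS = 0, diet = NULL),
    list(name = "detritus", category = "detritus", tags = "",
         B = 30, PB = NA, QB = NA, GS = 0, diet = NULL),
    list(name = "zooplankton", category = "consumer", tags = "native",
         B = 7, PB = 10, QB = 35, GS = 0.3,
         diet = d(phytoplankton = 0.8, detritus = 0.2)),
    list(name = "native_forage_fish", category = "consumer", tags = "native;forage",
         B = 4, PB = 1.8, QB = 7, GS = 0.25, thermal = "native",
         diet = d(zooplankton = 0.85, native_benthic_inverts = 0.1,
                  alien_benthic_inverts = 0.05)),
    list(name = "alien_demersal_fish", category = "consumer", tags = "alien",
         B = 1.0, PB = 1.15, QB = 4.8, GS = 0.25, thermal = "alien",
         diet = d(native_benthic_inverts = 0.4, alien_benthic_inverts = 0.25,
                  native_forage_fish = 0.25, alien_herbivorous_fish = 0.1)),
    list(name = "top_predator", category = "consumer", tags = "native",
         B = 0.4, PB = 0.5, QB = 2.4, GS = 0.2, thermal = "native",
         diet = d(native_forage_fish = 0.5, native_demersal_fish = 0.25,
                  alien_demersal_fish = 0.2, new_alien_demersal_fish = 0.05)),
    list(name = "native_benthic_inverts", category = "consumer",
         tags = "native;benthic_invertebrate",
         B = 8, PB = 2.6, QB = 9, GS = 0.4, thermal = "native",
         diet = d(detritus = 0.6, phytoplankton = 0.3, zooplankton = 0.1)),
    list(name = "native_demersal_fish", category = "consumer", tags = "native",
         B = 2.0, PB = 0.95, QB = 4.2, GS = 0.25, thermal = "native",
         diet = d(native_benthic_inverts = 0.45, alien_benthic_inverts = 0.15,
                  native_forage_fish = 0.3, alien_herbivorous_fish = 0.1)),
    list(name = "alien_benthic_inverts", category = "consumer",
         tags = "alien;benthic_invertebrate",
         B = 2.5, PB = 3.2, QB = 11, GS = 0.4, thermal = "alien",
         diet = d(detritus = 0.65, phytoplankton = 0.25, zooplankton = 0.1)),
    list(name = "new_alien_demersal_fish", category = "consumer",
         tags = "alien;new_alien",
         B = 0.35, PB = 1.3, QB = 5.5, GS = 0.25, thermal = "alien",
         diet = d(native_benthic_inverts = 0.35, alien_benthic_inverts = 0.3,
                  native_forage_fish = 0.3, alien_herbivorous_fish = 0.05)),
    list(name = "alien_herbivorous_fish", category = "consumer", tags = "alien",
         B = 1.8, PB = 1.3, QB = 9, GS = 0.45, thermal = "alien",
         diet = d(phytoplankton = 0.85, detritus = 0.15)),
    list(name = "vulnerable_megafauna", category = "consumer",
         tags = "native;vulnerable",
         B = 0.07, PB = 0.16, QB = 4.5, GS = 0.25, thermal = "native",
         diet = d(native_forage_fish = 0.6, native_demersal_fish = 0.15,
                  alien_demersal_fish = 0.15, native_benthic_inverts = 0.1))
  )
}

# landings/discards templates (t km^-2 yr^-1) by fleet and group
.catch_templates <- function() {
  list(
    trawl = list(
      landings = c(native_benthic_inverts = 1.0, alien_benthic_inverts = 0.5,
                   native_demersal_fish = 0.45, alien_demersal_fish = 0.25,
                   new_alien_demersal_fish = 0.05),
      discards = c(vulnerable_megafauna = 0.003, native_benthic_inverts = 0.1,
                   native_forage_fish = 0.05)),
    artisanal = list(
      landings = c(native_demersal_fish = 0.25, alien_demersal_fish = 0.1,
                   native_forage_fish = 0.15, alien_herbivorous_fish = 0.1,
                   top_predator = 0.03),
      discards = c(vulnerable_megafauna = 0.001)),
    recreational = list(
      landings = c(native_demersal_fish = 0.1, top_predator = 0.06),
      discards = c()),
    purse_seine = list(
      landings = c(native_forage_fish = 0.3),
      discards = c())
  )
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  force(expr)
}

#' Generate a balanced synthetic food web
#'
#' Draws group parameters and diets around fixed coastal-shelf archetypes,
#' solves the mass balance (estimating every ecotrophic efficiency), assigns
#' warm-shifted thermal response functions to alien groups and
#' cool-preferring ones to natives, and draws a pedigree with confidence
#' intervals in [0.1, 0.4]. Candidate webs failing balance (any EE outside
#' [0, 1]) or the local-stability screen (any eigenvalue of the baseline
#' Jacobian with real part above 1e-6) are rejected and redrawn, up to 100
#' attempts. Deterministic for a given seed.
#'
#' @param config a [generator_config()].
#' @return list with elements `model` (balanced `ecopath_model`),
#'   `responses` (named list of [env_response()]) and `pedigree`.
#' @export
generate_web <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    for (attempt in seq_len(100L)) {
      web <- tryCatch(.draw_web(config), error = function(e) e)
      if (!inherits(web, "error")) return(web)
    }
    stop("generator failed after 100 attempts; last error: ",
         conditionMessage(web))
  })
}

.selected_archetypes <- function(config) {
  arch <- .archetypes()
  n <- config$n_groups
  if (n <= length(arch)) {
    sel <- arch[seq_len(n)]
  } else {
    sel <- arch
    dupable <- c("native_demersal_fish", "native_forage_fish",
                 "native_benthic_inverts", "alien_demersal_fish")
    k <- 1L
    while (length(sel) < n) {
      base <- arch[[which(vapply(arch, `[[`, "", "name") ==
                            dupable[(k - 1L) %% length(dupable) + 1L])]]
      base$name <- paste0(base$name, "_", (k - 1L) %/% length(dupable) + 2L)
      base$B <- base$B * 0.5
      sel <- c(sel, list(base))
      k <- k + 1L
    }
  }
  # retag to hit the target alien count (surplus aliens become naturalized
  # native counterparts; tags only, topology unchanged)
  is_alien <- vapply(sel, function(a) grepl("alien", a$tags), logical(1))
  target <- round(config$alien_fraction * n)
  over <- sum(is_alien) - target
  if (over > 0) {
    for (i in rev(which(is_alien))[seq_len(over)]) {
      tags <- strsplit(sel[[i]]$tags, ";", fixed = TRUE)[[1]]
      tags <- setdiff(tags, c("alien", "new_alien"))
      sel[[i]]$tags <- paste(unique(c("native", tags)), collapse = ";")
      sel[[i]]$thermal <- "native"
    }
  }
  sel
}

.draw_web <- function(config) {
  sel <- .selected_archetypes(config)
  nm <- vapply(sel, `[[`, "", "name")
  n <- length(sel)
  jit <- function(x, w) x * (1 + stats::runif(length(x), -w, w))

  groups <- data.frame(
    name = nm,
    category = vapply(sel, `[[`, "", "category"),
    B = jit(vapply(sel, `[[`, 0, "B"), 0.15),
    PB = jit(vapply(sel, function(a) ifelse(is.na(a$PB), 0, a$PB), 0), 0.1),
    QB = jit(vapply(sel, function(a) ifelse(is.na(a$QB), 0, a$QB), 0), 0.1),
    EE = NA_real_,
    GS = vapply(sel, `[[`, 0, "GS"),
    BA = 0, net_migration = 0,
    role_tags = vapply(sel, `[[`, "", "tags"))
  groups$PB[groups$category == "detritus"] <- NA
  groups$QB[groups$category == "detritus"] <- NA
  groups$QB[groups$category == "producer"] <- 0

  diet <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    tmpl <- sel[[i]]$diet
    if (is.null(tmpl)) next
    tmpl <- tmpl[names(tmpl) %in% nm]
    if (!length(tmpl)) {      # prey archetypes absent in a small web
      tmpl <- c(detritus = 0.5, phytoplankton = 0.5)
      tmpl <- tmpl[names(tmpl) %in% nm]
    }
    w <- jit(as.numeric(tmpl), 0.2)
    diet[names(tmpl), i] <- w / sum(w)
  }

  fleets <- names(.catch_templates())[seq_len(config$n_fleets)]
  land <- disc <- matrix(0, n, length(fleets), dimnames = list(nm, fleets))
  for (f in fleets) {
    tm <- .catch_templates()[[f]]
    l <- tm$landings[names(tm$landings) %in% nm]
    if (length(l)) land[names(l), f] <- jit(as.numeric(l), 0.2)
    d <- tm$discards[names(tm$discards) %in% nm]
    if (length(d)) disc[names(d), f] <- jit(as.numeric(d), 0.2)
  }

  model <- ecopath_model(groups, diet, landings = land, discards = disc,
                         area_note = sprintf("synthetic shelf web (seed %d)", config$seed))
  model <- solve_mass_balance(model)

  th <- config$thermal_regime
  responses <- list()
  for (i in seq_len(n)) {
    kind <- sel[[i]]$thermal
    if (is.null(kind)) next
    pref <- if (kind == "alien") th$alien_pref else th$native_pref
    q10 <- pref[1] + stats::runif(1, -0.3, 0.3)
    q90 <- pref[2] + stats::runif(1, -0.2, 0.2)
    responses[[nm[i]]] <- env_response(q10 - 7, q10, q90, q90 + 4)
  }

  living <- nm[groups$category != "detritus"]
  cons_nm <- nm[groups$category == "consumer"]
  rows <- rbind(data.frame(group = living, parameter = "B"),
                data.frame(group = living, parameter = "PB"),
                data.frame(group = cons_nm, parameter = "QB"))
  ped <- pedigree(data.frame(rows, ci = stats::runif(nrow(rows), 0.1, 0.4)))

  params <- calibrate(model, responses = responses)
  resid <- baseline_derivative(params)
  if (max(abs(resid)) > 1e-9) stop("baseline derivative residual too large")
  if (!.locally_stable(params)) stop("candidate web fails the stability screen")
  list(model = model, responses = responses, pedigree = pedigree(ped),
       config = config)
}

# eigenvalue screen of the baseline Jacobian (finite differences)
.locally_stable <- function(params, tol = 1e-6) {
  B0 <- params$B0
  n <- length(B0)
  E <- rep(1, ncol(params$q_land))
  sst <- baseline_neutral_sst(params)
  f0 <- .ecosim_deriv(params, B0, E, sst, 1)$dB
  J <- matrix(0, n, n)
  h <- pmax(1e-7 * B0, 1e-10)
  for (j in seq_len(n)) {
    Bp <- B0
    Bp[j] <- Bp[j] + h[j]
    J[, j] <- (.ecosim_deriv(params, Bp, E, sst, 1)$dB - f0) / h[j]
  }
  max(Re(eigen(J, only.values = TRUE)$values)) <= tol
}

#' Generate the historical baseline forcings
#'
#' Emulates the drivers of the historical period leading up to the scenario
#' start: relative fleet effort above reference with a late-period decline
#' to 1.0, a mildly warming noisy SST series ending near the configured
#' reference temperature, rising alien-group biomass histories ending at
#' their balanced baseline value, and smooth RCP anomaly tracks whose
#' end-of-horizon warming is ordered RCP2.6 < RCP4.5 < RCP8.5.
#'
#' @param config a [generator_config()].
#' @param web optionally the [generate_web()] output for the same config
#'   (regenerated if omitted) — supplies alien group names and baselines.
#' @param years_history number of historical years (default 17).
#' @param start_year first scenario year / last historical year (default 2010).
#' @return a [baseline_forcings()] object.
#' @export
generate_baseline_forcing <- function(config, web = NULL, years_history = 17,
                                      start_year = 2010) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(web)) web <- generate_web(config)
  model <- web$model
  bs <- config$thermal_regime$baseline_sst
  .with_seed(config$seed + 1L, {
    yrs <- seq(start_year - years_history + 1, start_year)
    s <- (yrs - yrs[1]) / (length(yrs) - 1)

    fleets <- fleet_names(model)
    effort <- lapply(stats::setNames(nm = fleets), function(f) {
      peak <- stats::runif(1, 1.15, 1.35)
      v <- ifelse(yrs <= start_year - 4, peak,
                  1 + (peak - 1) * (start_year - yrs) / 4) +
        stats::rnorm(length(yrs), 0, 0.02)
      v[length(v)] <- 1
      data.frame(year = yrs, value = pmax(v, 0.05))
    })

    sst <- data.frame(year = yrs,
                      value = bs - 0.8 * (1 - s) + stats::rnorm(length(yrs), 0, 0.1))
    sst$value[length(yrs)] <- bs + stats::rnorm(1, 0, 0.05)

    alien <- group_names(model)[has_tag(model, "alien")]
    alien_history <- lapply(stats::setNames(nm = alien), function(g) {
      B0 <- model$groups$B[match(g, group_names(model))]
      v <- B0 * (0.35 + 0.65 * s) * (1 + stats::rnorm(length(yrs), 0, 0.02))
      v[length(v)] <- B0
      data.frame(year = yrs, value = pmax(v, 0))
    })

    py <- start_year + 0:50
    ps <- (py - start_year) / 50
    rcp <- data.frame(year = py,
                      rcp26 = 0.7 * (1 - exp(-ps / 0.45)) / (1 - exp(-1 / 0.45)),
                      rcp45 = 1.5 * ps^1.1,
                      rcp85 = 3.0 * ps^1.4)
    baseline_forcings(sst, alien_history, rcp, fleets)
  })
}

#' Baseline (equilibrium) forcing set for a calibrated web
#'
#' Unit effort for every fleet, SST held at the multiplier-neutral
#' temperature of the calibration, no biomass forcing: the model rests at
#' its balanced snapshot.
#'
#' @param params an `ecosim_params`.
#' @param years horizon in years (default 10).
#' @param start_year first year (default 2010).
#' @return a [forcing_set()].
#' @export
baseline_forcing_set <- function(params, years = 10, start_year = 2010) {
  yrs <- start_year + 0:years
  sst0 <- baseline_neutral_sst(params)
  effort <- lapply(stats::setNames(nm = colnames(params$q_land)), function(f) {
    data.frame(year = range(yrs), value = c(1, 1))
  })
  forcing_set(yrs, effort, data.frame(year = range(yrs), value = c(sst0, sst0)))
}
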