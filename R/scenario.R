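#' Baseline forcings: the historical drivers a scenario extends
#'
#' @param sst_history data.frame with columns `year`, `value`: annual
#'   sea-surface temperature over the historical period (degrees C).
#' @param alien_history named list (by alien-tagged group) of data.frames
#'   with columns `year`, `value`: observed biomass histories used to force
#'   invader trends.
#' @param rcp_anomalies data.frame with columns `year`, `rcp26`, `rcp45`,
#'   `rcp85`: SST anomaly tracks relative to the reference year, spanning
#'   the projection horizon.
#' @param fleets character vector of fleet names.
#' @return An object of class `baseline_forcings`.
#' @export
baseline_forcings <- function(sst_history, alien_history, rcp_anomalies, fleets) {
  stopifnot(all(c("year", "value") %in% names(sst_history)),
            all(c("year", "rcp26", "rcp45", "rcp85") %in% names(rcp_anomalies)))
  structure(list(sst_history = sst_history[order(sst_history$year), ],
                 alien_history = alien_history,
                 rcp_anomalies = rcp_anomalies[order(rcp_anomalies$year), ],
                 fleets = fleets),
            class = "baseline_forcings")
}

#' The scenario catalogue
#'
#' Eleven stressor combinations crossing fishing policy (status quo, new
#' national regulations, regulations plus a trawl ban phased in over three
#' years), temperature policy (held constant or following an RCP warming
#' track) and invasive-species policy (freely modelled, biomass forced to
#' continue its current trend, or forced constant at reference level).
#'
#' @return data.frame with columns `id`, `name`, `fishing`, `temperature`,
#'   `alien`.
#' @export
scenario_table <- function() {
  data.frame(
    id = 1:11,
    name = c("BAU", "Israeli regulation", "Stop trawl",
             "Israeli regulation (alien spp. constant)",
             "RCP2.6", "RCP4.5", "RCP8.5", "Increase alien species",
             "Combination (no forcing of alien spp.)",
             "Combination (forcing of alien spp.)",
             "Combination (forcing alien spp. constant)"),
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
              "force_trend", "force_constant"),
    stringsAsFactors = FALSE)
}

# effort multipliers of the new fishing regulations, by fleet role
.regulation_multipliers <- c(trawl = 0.50, artisanal = 0.85,
                             recreational = 0.80, purse_seine = 1.00)

.fleet_role <- function(fleet) {
  f <- tolower(fleet)
  if (grepl("trawl", f)) return("trawl")
  if (grepl("artisanal", f)) return("artisanal")
  if (grepl("recreation", f)) return("recreational")
  if (grepl("purse", f)) return("purse_seine")
  "other"
}

#' Project SST by applying an anomaly track to the observed series
#'
#' The projection is `reference + anomaly(t)`, with the reference level the
#' mean of the last three historical years (damping single-year noise in the
#' operational "reference-year level").
#'
#' @param baseline_sst data.frame with columns `year`, `value`: historical SST.
#' @param anomalies data.frame with columns `year`, `value`: anomaly track
#'   (degrees C relative to the reference level) spanning the horizon.
#' @return data.frame with columns `year`, `value`: projected SST.
#' @export
build_sst_projection <- function(baseline_sst, anomalies) {
  if (anyNA(baseline_sst$value) || anyNA(anomalies$value)) {
    stop("SST projection inputs contain gaps")
  }
  h <- baseline_sst[order(baseline_sst$year), ]
  ref <- mean(utils::tail(h$value, 3))
  data.frame(year = anomalies$year, value = ref + anomalies$value)
}

#' Extrapolate an invader biomass history along its current trend
#'
#' Fits a least-squares slope to the final five observed years and continues
#' it linearly over the horizon, floored at zero biomass.
#'
#' @param history data.frame with columns `year`, `value` (>= 5 rows).
#' @param horizon projection length in years beyond the last observation.
#' @return data.frame with columns `year`, `value` starting at the last
#'   observed year.
#' @export
build_alien_trend_forcing <- function(history, horizon) {
  history <- history[order(history$year), ]
  if (nrow(history) < 5L) stop("alien biomass history needs at least 5 points")
  tail5 <- utils::tail(history, 5L)
  slope <- stats::coef(stats::lm(value ~ year, data = tail5))[["year"]]
  y_last <- history$year[nrow(history)]
  v_last <- history$value[nrow(history)]
  yrs <- y_last + 0:horizon
  data.frame(year = yrs, value = pmax(v_last + slope * (yrs - y_last), 0))
}

#' Build the forcing set of a catalogued scenario
#'
#' Translates a scenario id into concrete forcing series over the horizon:
#' fishing-regulation effort reductions are phased in linearly over the
#' first two simulation years and then held (the trawl ban continues the
#' ramp to zero by year three); constant-temperature scenarios hold SST at
#' the reference level (mean of the last three historical years); warming
#' scenarios add the corresponding RCP anomaly track; invader forcing either
#' extrapolates the current biomass trend or pins biomass at its reference
#' value. The primary-production multiplier is 1 in every scenario.
#'
#' @param id scenario id, 1-11 (see [scenario_table()]).
#' @param baseline a [baseline_forcings()] object.
#' @param horizon projection length in years (default 50).
#' @param start_year first simulation year (default 2010).
#' @return a [forcing_set()].
#' @export
build_scenario <- function(id, baseline, horizon = 50, start_year = 2010) {
  tab <- scenario_table()
  if (!id %in% tab$id) stop("unknown scenario id: ", id)
  row <- tab[tab$id == id, ]
  years <- start_year + 0:horizon
  end <- start_year + horizon

  effort <- lapply(stats::setNames(nm = baseline$fleets), function(fl) {
    role <- .fleet_role(fl)
    mult <- if (role %in% names(.regulation_multipliers)) {
      .regulation_multipliers[[role]]
    } else 1
    if (row$fishing == "status_quo" || mult == 1) {
      knots <- data.frame(year = c(start_year, end), value = c(1, 1))
    } else {
      knots <- data.frame(year = c(start_year, start_year + 2, end),
                          value = c(1, mult, mult))
    }
    if (row$fishing == "new_regulations_stop_trawl" && role == "trawl") {
      knots <- data.frame(year = c(start_year, start_year + 2, start_year + 3, end),
                          value = c(1, mult, 0, 0))
    }
    knots
  })

  ref_sst <- mean(utils::tail(baseline$sst_history[order(baseline$sst_history$year), "value"], 3))
  sst <- if (row$temperature == "constant") {
    data.frame(year = c(start_year, end), value = c(ref_sst, ref_sst))
  } else {
    col <- c("RCP2.6" = "rcp26", "RCP4.5" = "rcp45", "RCP8.5" = "rcp85")[[row$temperature]]
    an <- baseline$rcp_anomalies
    if (min(an$year) > start_year || max(an$year) < end) {
      stop("RCP anomaly track does not span the horizon")
    }
    build_sst_projection(baseline$sst_history,
                         data.frame(year = an$year, value = an[[col]]))
  }

  bf <- list()
  if (row$alien != "model_predicts") {
    if (!length(baseline$alien_history)) {
      stop("scenario ", id, " forces alien biomass but the baseline has no alien histories")
    }
    bf <- lapply(baseline$alien_history, function(h) {
      h <- h[order(h$year), ]
      if (row$alien == "force_trend") {
        build_alien_trend_forcing(h, horizon)
      } else {
        data.frame(year = c(start_year, end),
                   value = rep(h$value[nrow(h)], 2))
      }
    })
  }

  forcing_set(years = years, effort = effort, sst = sst, biomass_forcing = bf)
}
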