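#' Assemble a forcing set for a simulation
#'
#' Bundles the time-indexed drivers of a run: relative fleet effort
#' (1.0 = reference year), sea-surface temperature, optional per-group
#' biomass forcing, and a primary-production multiplier.
#'
#' Effort series are piecewise-linear between knots; a duplicated knot year
#' encodes a right-continuous step (the later value applies from that year
#' on). SST, biomass forcing and the production multiplier are linearly
#' interpolated between annual values.
#'
#' @param years numeric vector of annual marks spanning the horizon, e.g.
#'   `2010:2060`.
#' @param effort named list (by fleet) of data.frames with columns `year`,
#'   `value` giving the effort knots.
#' @param sst data.frame with columns `year`, `value` (degrees C).
#' @param biomass_forcing named list (by group) of data.frames with columns
#'   `year`, `value` (t km^-2); forced groups bypass the dynamics.
#' @param pp data.frame with columns `year`, `value`: primary-production
#'   multiplier (default constant 1).
#' @return An object of class `forcing_set`.
#' @export
forcing_set <- function(years, effort, sst, biomass_forcing = list(), pp = NULL) {
  years <- as.numeric(years)
  stopifnot(length(years) >= 2, !is.unsorted(years, strictly = TRUE))
  if (is.null(pp)) pp <- data.frame(year = range(years), value = c(1, 1))
  chk <- function(d, what) {
    if (!all(c("year", "value") %in% names(d))) stop(what, " needs year/value columns")
    if (anyNA(d$value) || anyNA(d$year)) stop(what, " contains missing values")
    if (min(d$year) > years[1] || max(d$year) < years[length(years)]) {
      stop(what, " does not span the horizon ", years[1], "-", years[length(years)])
    }
    d[order(d$year), , drop = FALSE]
  }
  effort <- lapply(stats::setNames(nm = names(effort)), function(f) chk(effort[[f]], paste("effort", f)))
  sst <- chk(sst, "sst")
  pp <- chk(pp, "pp multiplier")
  biomass_forcing <- lapply(stats::setNames(nm = names(biomass_forcing)),
                            function(g) chk(biomass_forcing[[g]], paste("biomass forcing", g)))
  structure(list(years = years, effort = effort, sst = sst,
                 biomass_forcing = biomass_forcing, pp = pp),
            class = "forcing_set")
}

#' @export
print.forcing_set <- function(x, ...) {
  cat(sprintf("forcing_set: %s-%s | fleets: %s | SST %.2f-%.2f degC | %d forced group(s)\n",
              x$years[1], x$years[length(x$years)],
              paste(names(x$effort), collapse = ", "),
              min(x$sst$value), max(x$sst$value), length(x$biomass_forcing)))
  invisible(x)
}

# piecewise-linear interpolation over knots; duplicated x = right-continuous step
.interp_knots <- function(knots, t) {
  x <- knots$year
  y <- knots$value
  vapply(t, function(ti) {
    if (ti < x[1] - 1e-9 || ti > x[length(x)] + 1e-9) {
      stop("time ", ti, " outside the forcing horizon [", x[1], ", ", x[length(x)], "]")
    }
    ti <- min(max(ti, x[1]), x[length(x)])
    i <- max(which(x <= ti + 1e-12))
    if (i == length(x) || abs(x[i] - ti) < 1e-12) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (ti - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

#' Relative fishing effort of a fleet at a time point
#'
#' Piecewise-linear interpolation between the configured knots; steps
#' (duplicated knot years) are right-continuous.
#'
#' @param forcing a [forcing_set()].
#' @param fleet fleet name.
#' @param t time (calendar year, possibly fractional).
#' @return relative effort (dimensionless, >= 0).
#' @export
effort_at <- function(forcing, fleet, t) {
  if (!fleet %in% names(forcing$effort)) stop("unknown fleet: ", fleet)
  e <- .interp_knots(forcing$effort[[fleet]], t)
  if (any(e < 0)) stop("negative effort in series for fleet ", fleet)
  e
}

#' Sea-surface temperature at a time point
#' @param forcing a [forcing_set()].
#' @param t time (calendar year, possibly fractional).
#' @return temperature (degrees C).
#' @export
sst_at <- function(forcing, t) .interp_knots(forcing$sst, t)
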