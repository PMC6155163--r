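#' Snapshot of all energy flows through the food web at one instant
#'
#' The container consumed by the network-analysis indicators: within-system
#' consumption flows, respiration, flows to detritus, exports and imports.
#' Respiration of consumers is derived from the energy balance,
#' `R_j = (1 - GS_j) Q_j - P_j`; a negative value means the group is
#' energetically infeasible and is rejected.
#'
#' @param Q prey-by-predator consumption matrix (t km^-2 yr^-1), including
#'   detritivory rows.
#' @param respiration per-group respiration (t km^-2 yr^-1).
#' @param flows_to_detritus per-group flow into the detritus pool(s)
#'   (unassimilated food, non-predation deaths, discards).
#' @param exports per-group exports (landings plus net export).
#' @param imports per-group imports (imported diet, net immigration, and for
#'   producers their primary production, which enters from outside the
#'   trophic flow network).
#' @param detritus names of the detritus compartments (receive the
#'   `flows_to_detritus`, split equally if several).
#' @return An object of class `flow_snapshot`.
#' @export
flow_snapshot <- function(Q, respiration, flows_to_detritus, exports, imports,
                          detritus = character()) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  nm <- rownames(Q)
  if (is.null(nm)) stop("flow matrix needs group dimnames")
  if (any(respiration < -1e-9)) {
    stop("energetically infeasible group(s): negative respiration for ",
         paste(nm[respiration < -1e-9], collapse = ", "))
  }
  respiration <- pmax(respiration, 0)
  if (any(Q < 0) || any(flows_to_detritus < 0) || any(exports < 0) || any(imports < 0)) {
    stop("all flows must be non-negative")
  }
  if (!all(detritus %in% nm)) stop("unknown detritus compartment name")
  structure(list(Q = Q,
                 respiration = stats::setNames(respiration, nm),
                 flows_to_detritus = stats::setNames(flows_to_detritus, nm),
                 exports = stats::setNames(exports, nm),
                 imports = stats::setNames(imports, nm),
                 detritus = detritus),
            class = "flow_snapshot")
}

#' Build a flow snapshot from a simulation year mark
#'
#' @param result a `simulation_result`.
#' @param year calendar year of an annual mark in the result.
#' @return a [flow_snapshot()].
#' @export
build_flow_snapshot <- function(result, year) {
  i <- match(year, result$years)
  if (is.na(i)) stop("year ", year, " is not an annual mark of the result")
  p <- result$params
  fl <- result$flows[[i]]
  B <- fl$state
  Qtot <- colSums(fl$Q) + fl$Qimp
  production <- p$pq * Qtot
  resp <- ifelse(p$is_consumer, (1 - p$GS) * Qtot - production, 0)
  liv <- !p$is_detritus
  to_det <- ifelse(liv, p$GS * Qtot + p$M * B + fl$Fdisc * B, 0)
  exports <- fl$Fland * B + pmax(-p$N, 0) +
    ifelse(p$is_detritus, pmax(p$det_export, 0), 0)
  imports <- p$QB * p$import * B * result$f_multipliers[, i] + pmax(p$N, 0) +
    ifelse(p$is_detritus, pmax(-p$det_export, 0), 0)
  # producer production enters as an external input to the flow network
  dd <- p$producer_dd
  pp_in <- ifelse(p$is_producer, p$PB0 * (1 + dd) / (1 + dd * B / p$B0) * B, 0)
  imports <- imports + pp_in
  flow_snapshot(fl$Q, resp, to_det, exports, imports,
                detritus = names(p$B0)[p$is_detritus])
}

#' Aggregate biomass indicators
#'
#' Total living biomass (detritus pools excluded), forage-fish biomass,
#' benthic-invertebrate biomass, and predatory biomass (groups with
#' trophic level >= 4, using the baseline trophic levels).
#'
#' @param state named biomass vector (t km^-2) over groups.
#' @param model the `ecopath_model` (for categories and role tags).
#' @param TLs trophic levels (from [trophic_levels()] on the baseline model).
#' @return named numeric vector `c(TotalB, ForF, InvB, PredB)`.
#' @export
biomass_indicators <- function(state, model, TLs) {
  liv <- model$groups$category != "detritus"
  c(TotalB = sum(state[liv]),
    ForF = sum(state[has_tag(model, "forage")]),
    InvB = sum(state[has_tag(model, "benthic_invertebrate")]),
    PredB = sum(state[liv & TLs >= 4]))
}

#' Kempton's biomass-diversity index (upper-trophic groups)
#'
#' Restricted to groups with trophic level >= 3, the index is the scaled
#' inverse interquartile slope of the ranked-biomass curve:
#' `Q = 0.5 S / log10(B_0.75S / B_0.25S)`, with the quartile biomasses read
#' off at fractional ranks by linear interpolation.
#'
#' @param state named biomass vector over groups.
#' @param TLs trophic levels.
#' @return the index (dimensionless), or `NA` when fewer than 4 qualifying
#'   groups exist or all their biomasses are equal.
#' @export
kemptons_q <- function(state, TLs) {
  b <- sort(as.numeric(state[TLs >= 3]))
  S <- length(b)
  if (S < 4L) return(NA_real_)
  at_rank <- function(r) {
    r <- min(max(r, 1), S)
    lo <- floor(r); hi <- ceiling(r)
    if (lo == hi) b[lo] else b[lo] + (b[hi] - b[lo]) * (r - lo)
  }
  b25 <- at_rank(0.25 * S)
  b75 <- at_rank(0.75 * S)
  if (b25 <= 0 || b75 <= b25) return(NA_real_)
  0.5 * S / log10(b75 / b25)
}

#' Catch indicators: total catch and mean trophic level of the catch
#'
#' @param catch named per-group catch vector (t km^-2 yr^-1).
#' @param TLs trophic levels.
#' @return named numeric vector `c(TotalC, mTLc)`; `mTLc` is `NA` when the
#'   total catch is zero.
#' @export
catch_indicators <- function(catch, TLs) {
  if (any(catch < 0)) stop("catches must be non-negative")
  tot <- sum(catch)
  c(TotalC = tot,
    mTLc = if (tot > 0) sum(TLs * catch) / tot else NA_real_)
}

#' Biomass-weighted mean trophic level of the community
#'
#' Over living groups (detritus excluded, trophic-level-1 producers
#' included).
#'
#' @param state named biomass vector over groups.
#' @param model the `ecopath_model`.
#' @param TLs trophic levels.
#' @return mTLco (dimensionless).
#' @export
mean_tl_community <- function(state, model, TLs) {
  liv <- model$groups$category != "detritus"
  if (sum(state[liv]) <= 0) stop("no living biomass")
  sum(TLs[liv] * state[liv]) / sum(state[liv])
}

#' Whole-network flow indicators: TST, Finn's cycling index and path length
#'
#' Total System Throughput sums every flow in the snapshot (consumption,
#' exports, respiration, flows to detritus). Finn's Cycling Index is the
#' recycled share of TST computed from the diagonal of the Leontief inverse
#' `L = (I - G)^{-1}` of the input-proportion flow matrix `G`:
#' `FCI = 100 sum_i T_i (l_ii - 1) / l_ii / TST`, with `T_i` compartment
#' throughput (inflow). Path length is `TST / (exports + respiration)`, the
#' average number of compartments a unit of inflow traverses before leaving.
#'
#' @param flows a [flow_snapshot()].
#' @return named numeric vector `c(TST, FCI, PL)` (FCI in percent).
#' @export
flow_indicators <- function(flows) {
  Q <- flows$Q
  n <- nrow(Q)
  nm <- rownames(Q)
  TST <- sum(Q) + sum(flows$exports) + sum(flows$respiration) +
    sum(flows$flows_to_detritus)

  # full compartment-to-compartment flow matrix: consumption + detritus routing
  Fm <- Q
  det <- match(flows$detritus, nm)
  if (length(det)) {
    for (d in det) {
      Fm[, d] <- Fm[, d] + flows$flows_to_detritus / length(det)
    }
  }
  Tin <- colSums(Fm) + flows$imports          # compartment throughput (inflow)
  G <- Fm / rep(ifelse(Tin > 0, Tin, 1), each = n)
  G[, Tin <= 0] <- 0
  L <- tryCatch(solve(diag(n) - G), error = function(e) {
    stop("ill-conditioned flow network: ", conditionMessage(e))
  })
  lii <- diag(L)
  cycled <- sum(Tin * (lii - 1) / lii)
  FCI <- if (TST > 0) 100 * cycled / TST else 0

  outflow <- sum(flows$exports) + sum(flows$respiration)
  PL <- if (outflow > 0) TST / outflow else NA_real_
  c(TST = TST, FCI = FCI, PL = PL)
}

#' Annual series of all eleven ecological indicators
#'
#' One row per simulated year (annual marks after the start): the four
#' aggregate biomasses, Kempton's Q, total catch and mean trophic level of
#' the catch accrued over the preceding year, community mean trophic level,
#' TST, FCI and path length from the year's flow snapshot. Trophic levels
#' are the baseline (mass-balance) levels held fixed through time.
#'
#' @param result a `simulation_result`.
#' @return data.frame with columns `year`, `TotalB`, `ForF`, `InvB`,
#'   `PredB`, `Kempton`, `TotalC`, `mTLc`, `mTLco`, `TST`, `FCI`, `PL`.
#' @export
indicator_series <- function(result) {
  model <- result$params$model
  TLs <- trophic_levels(model)
  yrs <- result$years[-1]
  ac <- annual_catch(result)
  rows <- lapply(seq_along(yrs), function(k) {
    y <- yrs[k]
    state <- result$biomass[, k + 1]
    bi <- biomass_indicators(state, model, TLs)
    ci <- catch_indicators(ac[, k], TLs)
    fi <- flow_indicators(build_flow_snapshot(result, y))
    data.frame(year = y, t(bi), Kempton = kemptons_q(state, TLs), t(ci),
               mTLco = mean_tl_community(state, model, TLs), t(fi))
  })
  do.call(rbind, rows)
}
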