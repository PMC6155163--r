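#' Foraging-arena consumption rate for one predator-prey link
#'
#' Implements the foraging-arena flow
#' \deqn{Q = \frac{a v B P T_i T_j M / D}{v + v T_i M + a M P T_j / D} \, f}
#' where `a` is the effective search rate, `v` the vulnerability exchange
#' rate between the invulnerable and vulnerable prey pools, `B` the prey
#' biomass, `P` the predator abundance (biomass), `Ti`/`Tj` relative feeding
#' times, `M` a mediation multiplier, `D` a handling-time limit and `f` the
#' environmental multiplier in [0, 1].
#'
#' @param a effective search rate (> 0).
#' @param v vulnerability exchange rate (> 0).
#' @param B prey biomass (t km^-2).
#' @param P predator abundance (t km^-2).
#' @param Ti,Tj,M,D feeding-time, mediation and handling factors; default 1.
#' @param f environmental multiplier in [0, 1]; default 1.
#' @return consumption flow Q (t km^-2 yr^-1).
#' @examples
#' consumption_rate(a = 1, v = 2, B = 1, P = 1)   # 0.4
#' @export
consumption_rate <- function(a, v, B, P, Ti = 1, Tj = 1, M = 1, D = 1, f = 1) {
  if (any(c(a, v, B, P, Ti, Tj, M, D) < 0)) {
    stop("consumption_rate: negative inputs are not allowed")
  }
  if (any(f < 0 | f > 1)) stop("environmental multiplier f must lie in [0, 1]")
  num <- a * v * B * P * Ti * Tj * M / D
  den <- v + v * Ti * M + a * M * P * Tj / D
  q <- num / den
  q[num == 0] <- 0
  q * f
}

#' Calibrate foraging-arena parameters and closure rates to a balanced model
#'
#' For every predator-prey link with baseline flow
#' `Q0_ij = B0_j QB_j DC(i, j) > 0` the vulnerability exchange rate is
#' anchored at `v_ij = k Q0_ij / B0_i`, with `k > 1` the user-facing
#' vulnerability multiplier, and the search rate is solved in closed form
#' from the baseline identity `Q0 = a v B0 P0 / (2 v + a P0)`, i.e.
#' `a = 2 k Q0 / (B0 P0 (k - 1))`. Low `k` gives donor control (the flow
#' saturates near its baseline), large `k` approaches mass action.
#'
#' Non-predation mortality `M_i` is then set so the rate of biomass change is
#' exactly zero at the baseline state under baseline forcing, catchability is
#' `q_if = catch_if / B0_i` per fleet, and the detritus export closes the
#' detritus budget at baseline.
#'
#' @param model a balanced `ecopath_model`.
#' @param responses named list of [env_response()] objects; groups absent
#'   from the list are insensitive (multiplier 1). The multiplier scales the
#'   whole consumption column of an affected consumer and the production
#'   rate of an affected producer.
#' @param k default vulnerability multiplier for all links (default 2, the
#'   conventional mixed-control setting).
#' @param k_overrides named numeric vector (by predator name) or full
#'   prey-by-predator matrix of multipliers overriding the default.
#' @param k_new_alien multiplier applied to all links of consumers tagged
#'   `new_alien`, letting recently established invaders rise well above their
#'   baseline predation (default 10); set `NULL` to disable.
#' @param producer_dd saturation strength `m` of the producer production law
#'   `p(B) = PB0 (1 + m) / (1 + m B / B0)` (default 1: production rate at most
#'   twice its baseline).
#' @return An object of class `ecosim_params`.
#' @export
calibrate <- function(model, responses = list(), k = 2, k_overrides = NULL,
                      k_new_alien = 10, producer_dd = 1) {
  if (!isTRUE(model$balanced)) stop("calibrate() requires a balanced model")
  g <- model$groups
  n <- nrow(g)
  nm <- g$name
  cons <- g$category == "consumer"
  prod <- g$category == "producer"
  det <- g$category == "detritus"
  B0 <- g$B

  kmat <- matrix(k, n, n, dimnames = list(nm, nm))
  if (!is.null(k_new_alien)) {
    kmat[, has_tag(model, "new_alien") & cons] <- k_new_alien
  }
  if (!is.null(k_overrides)) {
    if (is.matrix(k_overrides)) {
      stopifnot(identical(dim(k_overrides), c(n, n)))
      kmat[!is.na(k_overrides)] <- k_overrides[!is.na(k_overrides)]
    } else {
      unknown <- setdiff(names(k_overrides), nm)
      if (length(unknown)) stop("k_overrides for unknown groups: ", paste(unknown, collapse = ", "))
      for (p in names(k_overrides)) kmat[, p] <- k_overrides[[p]]
    }
  }

  Q0 <- model$diet * rep(ifelse(cons, B0 * g$QB, 0), each = n)  # (i,j) prey i -> pred j
  dimnames(Q0) <- list(nm, nm)
  link <- Q0 > 0
  if (any(kmat[link] <= 1)) {
    stop("vulnerable pool smaller than baseline flow: k must exceed 1 on every link")
  }
  v <- matrix(0, n, n, dimnames = list(nm, nm))
  a <- matrix(0, n, n, dimnames = list(nm, nm))
  P0 <- B0
  v[link] <- (kmat * Q0 / rep(B0, times = n))[link]
  a[link] <- (2 * kmat * Q0 / (rep(B0, times = n) * rep(P0, each = n) * (kmat - 1)))[link]

  if (length(responses)) {
    unknown <- setdiff(names(responses), nm)
    if (length(unknown)) stop("responses for unknown groups: ", paste(unknown, collapse = ", "))
    ok <- vapply(responses, inherits, logical(1), what = "env_response")
    if (!all(ok)) stop("responses must be env_response objects")
  }

  catch_l <- model$landings
  catch_d <- model$discards
  q_land <- catch_l / B0
  q_disc <- catch_d / B0
  F0 <- rowSums(q_land) + rowSums(q_disc)

  pq <- ifelse(cons, g$PB / g$QB, 0)
  Qtot0 <- ifelse(cons, B0 * g$QB, 0)                 # includes imported diet
  pred0 <- rowSums(Q0)
  production0 <- ifelse(prod, B0 * g$PB, pq * Qtot0)
  N <- g$net_migration
  M <- numeric(n)
  liv <- !det
  M[liv] <- (production0[liv] - pred0[liv] + N[liv]) / B0[liv] - F0[liv]
  if (any(M[liv] < -1e-9)) {
    stop("negative other mortality at calibration for ",
         paste(nm[liv][M[liv] < -1e-9], collapse = ", "),
         "; model cannot rest at equilibrium")
  }
  M[M < 0] <- 0

  det_share <- stats::setNames(numeric(n), nm)
  det_share[det] <- if (sum(B0[det]) > 0) B0[det] / sum(B0[det]) else 1 / sum(det)
  inflow0 <- sum(g$GS[cons] * Qtot0[cons]) + sum(M[liv] * B0[liv]) + sum(catch_d)
  det_export <- det_share * inflow0 - ifelse(det, pred0, 0)

  resp_idx <- match(names(responses), nm)
  resp_anchors <- if (length(responses)) {
    t(vapply(responses, function(r) {
      if (r$shape == "step") c(r$min, r$min, r$max, r$max)
      else c(r$min, r$q10, r$q90, r$max)
    }, numeric(4)))
  }

  structure(list(
    model = model, a = a, v = v, k = kmat, Q0 = Q0, link = link,
    .two_v = 2 * v, .nolink = which(!link),
    .qb_import = ifelse(cons, g$QB, 0) * model$import,
    .iprod = which(prod), .idet = which(det), .iliv = which(!det),
    .M_liv = M[!det], .f_ones = stats::setNames(rep(1, n), nm),
    .resp_anchors = resp_anchors, .resp_idx = resp_idx,
    pq = stats::setNames(pq, nm), M = stats::setNames(M, nm),
    q_land = q_land, q_disc = q_disc,
    import = model$import, QB = stats::setNames(ifelse(cons, g$QB, 0), nm),
    GS = stats::setNames(g$GS, nm), PB0 = stats::setNames(g$PB, nm),
    B0 = stats::setNames(B0, nm), N = stats::setNames(N, nm),
    producer_dd = producer_dd, det_share = det_share, det_export = det_export,
    is_consumer = cons, is_producer = prod, is_detritus = det,
    responses = responses), class = "ecosim_params")
}

#' @export
print.ecosim_params <- function(x, ...) {
  cat(sprintf("ecosim_params: %d groups, %d trophic links, k range [%.1f, %.1f], %d response function(s)\n",
              length(x$B0), sum(x$link),
              min(x$k[x$link]), max(x$k[x$link]), length(x$responses)))
  invisible(x)
}

# Environmental multipliers per group at temperature sst (1 where no response)
.env_multipliers <- function(params, sst) {
  f <- rep(1, length(params$B0))
  names(f) <- names(params$B0)
  for (g in names(params$responses)) {
    f[g] <- response_multiplier(params$responses[[g]], sst)
  }
  f
}

# Vectorized trapezoid evaluation from the anchor matrix cached by calibrate()
.env_multipliers_fast <- function(params, sst) {
  f <- params$.f_ones
  ra <- params$.resp_anchors
  if (is.null(ra)) return(f)
  x <- rep(sst, nrow(ra))
  up <- ifelse(ra[, 2] > ra[, 1], (x - ra[, 1]) / (ra[, 2] - ra[, 1]),
               as.numeric(x >= ra[, 2]))
  dn <- ifelse(ra[, 4] > ra[, 3], (ra[, 4] - x) / (ra[, 4] - ra[, 3]),
               as.numeric(x <= ra[, 3]))
  f[params$.resp_idx] <- pmax(0, pmin(1, up, dn))
  f
}

# Rate of change of the state vector and instantaneous flows.
# B: state; E: fleet efforts; sst: temperature; ppm: primary production mult.
.ecosim_deriv <- function(params, B, E, sst, ppm) {
  n <- length(B)
  f <- .env_multipliers_fast(params, sst)
  P <- B
  num <- params$a * params$v * (B %o% P)
  den <- params$.two_v + params$a * rep(P, each = n)
  Q <- num / den
  Q[params$.nolink] <- 0
  Q <- Q * rep(f, each = n)                       # column scaling: predator multiplier
  Qimp <- params$.qb_import * B * f               # imported-diet consumption
  Qtot <- .colSums(Q, n, n) + Qimp
  pred <- .rowSums(Q, n, n)

  Fl <- if (length(E)) as.numeric(params$q_land %*% E) else numeric(n)
  Fd <- if (length(E)) as.numeric(params$q_disc %*% E) else numeric(n)
  Fmort <- Fl + Fd

  dd <- params$producer_dd
  prodrate <- params$pq * Qtot
  ip <- params$.iprod
  prodrate[ip] <- ppm * f[ip] * params$PB0[ip] * (1 + dd) /
    (1 + dd * B[ip] / params$B0[ip]) * B[ip]
  dB <- prodrate - pred - (params$M + Fmort) * B + params$N
  id <- params$.idet
  inflow <- sum(params$GS * Qtot) + sum(params$.M_liv * B[params$.iliv]) + sum(Fd * B)
  dB[id] <- params$det_share[id] * inflow - pred[id] - params$det_export[id]
  list(dB = dB, Q = Q, Qimp = Qimp, f = f, Fland = Fl, Fdisc = Fd)
}

#' Baseline derivative residual
#'
#' Evaluates the rate of biomass change at the baseline state with all
#' forcing at baseline (unit effort, multiplier-neutral temperature, unit
#' primary-production multiplier). A correct calibration returns zeros.
#'
#' @param params an `ecosim_params` object.
#' @return named numeric vector dB/dt (t km^-2 yr^-1) per group.
#' @export
baseline_derivative <- function(params) {
  E <- rep(1, ncol(params$q_land))
  sst <- baseline_neutral_sst(params)
  d <- .ecosim_deriv(params, params$B0, E, sst, 1)
  stats::setNames(d$dB, names(params$B0))
}

#' Temperature at which every response function is non-limiting
#'
#' Midpoint of the intersection of all preferable ranges `[q10, q90]`; with
#' no responses configured, 20 degrees C (any value works, all multipliers
#' are 1). Errors when the preferable ranges do not intersect.
#' @param params an `ecosim_params` object.
#' @return a temperature (degrees C).
#' @export
baseline_neutral_sst <- function(params) {
  if (!length(params$responses)) return(20)
  lo <- max(vapply(params$responses, function(r) r$q10, numeric(1)))
  hi <- min(vapply(params$responses, function(r) r$q90, numeric(1)))
  if (lo > hi) stop("response functions share no common preferable range")
  (lo + hi) / 2
}
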