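#' Solve the mass-balance equations of a food-web snapshot
#'
#' For every living group the balance condition
#' \deqn{B_i PB_i EE_i = \sum_j B_j QB_j DC_{ij} + Y_i + BA_i + E_i}
#' must hold, where the right-hand side collects predation by all consumers,
#' fishery removals `Y_i` (landings plus discards), biomass accumulation and
#' net export `E_i` (minus the net migration flow). Exactly one of `EE` or `B`
#' is unknown per group; the resulting linear system is solved directly.
#'
#' Detritus groups are closed afterwards: their `EE` is detritivory divided by
#' total inflow (unassimilated consumption, non-predation deaths and
#' discards), and any inflow surplus becomes a detritus export term.
#'
#' @param model an `ecopath_model`.
#' @param estimate character vector over groups, each `"EE"` (biomass known,
#'   estimate ecotrophic efficiency) or `"B"` (EE known, estimate biomass).
#'   Defaults to `"EE"` for every group. Detritus entries are ignored.
#' @return The model with all unknowns filled in, per-group balance residuals
#'   in `attr(, "residuals")` and `balanced = TRUE`.
#' @examples
#' m <- toy_chain_model()
#' b <- solve_mass_balance(m)
#' b$groups$EE
#' @export
solve_mass_balance <- function(model, estimate = NULL) {
  g <- model$groups
  n <- nrow(g)
  nm <- g$name
  if (is.null(estimate)) estimate <- rep("EE", n)
  if (length(estimate) != n || !all(estimate %in% c("EE", "B"))) {
    stop("estimate must give 'EE' or 'B' for every group")
  }
  living <- which(g$category != "detritus")
  for (i in living) {
    if (estimate[i] == "EE" && is.na(g$B[i])) {
      stop("group ", nm[i], ": B must be known to estimate EE")
    }
    if (estimate[i] == "B" && is.na(g$EE[i])) {
      stop("group ", nm[i], ": EE must be known to estimate B")
    }
  }

  catch <- total_catch_by_group(model)
  dc <- model$diet
  cons <- which(g$category == "consumer")

  nl <- length(living)
  A <- matrix(0, nl, nl, dimnames = list(nm[living], nm[living]))
  b <- numeric(nl)
  pos <- match(seq_len(n), living)           # group index -> unknown index
  for (r in seq_len(nl)) {
    i <- living[r]
    # production term B_i * PB_i * EE_i
    if (estimate[i] == "EE") {
      A[r, r] <- A[r, r] + g$B[i] * g$PB[i]
    } else {
      A[r, r] <- A[r, r] + g$PB[i] * g$EE[i]
    }
    # predation term  - sum_j B_j QB_j DC[i, j]
    for (j in cons) {
      if (dc[i, j] == 0) next
      if (estimate[j] == "B") {
        A[r, pos[j]] <- A[r, pos[j]] - g$QB[j] * dc[i, j]
      } else {
        b[r] <- b[r] + g$B[j] * g$QB[j] * dc[i, j]
      }
    }
    b[r] <- b[r] + catch[i] + g$BA[i] - g$net_migration[i]
  }

  x <- tryCatch(solve(A, b), error = function(e) {
    stop("structurally indeterminate mass-balance system: ", conditionMessage(e))
  })

  for (r in seq_len(nl)) {
    i <- living[r]
    if (estimate[i] == "EE") g$EE[i] <- x[r] else g$B[i] <- x[r]
  }
  bad_ee <- living[g$EE[living] < -1e-12 | g$EE[living] > 1 + 1e-12]
  if (length(bad_ee) > 0L) {
    stop("unbalanced model: EE outside [0, 1] for ",
         paste(sprintf("%s (EE = %.4f)", nm[bad_ee], g$EE[bad_ee]), collapse = ", "))
  }
  g$EE[living] <- pmin(pmax(g$EE[living], 0), 1)
  if (any(g$B[living] <= 0)) {
    stop("unbalanced model: estimated biomass non-positive for ",
         paste(nm[living][g$B[living] <= 0], collapse = ", "))
  }

  model$groups <- g
  # detritus closure: EE = detritivory / inflow, surplus exported
  det <- which(g$category == "detritus")
  inflow <- detritus_inflow(model)
  for (d in det) {
    detritivory <- sum(g$B[cons] * g$QB[cons] * dc[d, cons])
    g$EE[d] <- if (inflow[d] > 0) detritivory / inflow[d] else 0
  }
  model$groups <- g

  predation <- as.numeric(dc %*% ifelse(g$category == "consumer", g$B * g$QB, 0))
  resid <- g$B * g$PB * g$EE - predation - catch - g$BA + g$net_migration
  resid[det] <- 0
  tol <- 1e-9 * pmax(1, abs(g$B * g$PB))
  if (any(abs(resid[living]) > tol[living])) {
    stop("balance residual above tolerance for ",
         paste(nm[living][abs(resid[living]) > tol[living]], collapse = ", "))
  }
  model$balanced <- TRUE
  attr(model, "residuals") <- stats::setNames(resid, nm)
  validate_ecopath_model(model)
  model
}

#' Inflow to each detritus group
#'
#' Unassimilated consumption, non-predation mortality of living groups
#' (`(1 - EE) B PB`) and fleet discards, split across detritus groups in
#' proportion to detritus biomass (a single detritus pool receives it all).
#'
#' @param model an `ecopath_model` with EE known for living groups.
#' @return numeric vector over groups; zero for non-detritus groups.
#' @export
detritus_inflow <- function(model) {
  g <- model$groups
  det <- g$category == "detritus"
  cons <- g$category == "consumer"
  liv <- !det
  total_in <- sum(g$GS[cons] * g$B[cons] * g$QB[cons]) +
    sum((1 - g$EE[liv]) * g$B[liv] * g$PB[liv]) +
    sum(model$discards)
  share <- if (sum(g$B[det]) > 0) g$B[det] / sum(g$B[det]) else rep(1 / sum(det), sum(det))
  out <- numeric(nrow(g))
  out[det] <- total_in * share
  out
}

#' Fractional trophic levels
#'
#' Producers and detritus have TL 1; for each consumer
#' `TL_j = 1 + sum_i DC'(i, j) TL_i`, where `DC'` is the diet matrix
#' renormalized after removing the imported diet fraction. Solved as a
#' linear system over consumers.
#'
#' @param model an `ecopath_model` (balanced or not) with a valid diet matrix.
#' @return named numeric vector of trophic levels over groups.
#' @examples
#' trophic_levels(toy_chain_model())
#' @export
trophic_levels <- function(model) {
  g <- model$groups
  n <- nrow(g)
  nm <- g$name
  tl <- stats::setNames(rep(1, n), nm)
  cons <- which(g$category == "consumer")
  if (length(cons) == 0L) return(tl)

  dc <- model$diet
  dcp <- dc
  for (j in cons) {
    tot <- sum(dc[, j])
    if (tot <= 0) {
      stop("TL undefined under import convention for predator ", nm[j],
           " (diet is 100% import)")
    }
    dcp[, j] <- dc[, j] / tot
  }

  base <- g$category != "consumer"
  # TL_c - sum_{c' consumer} DC'(c', c) TL_c' = 1 + sum_{base i} DC'(i, c) * 1
  A <- diag(length(cons)) - t(dcp[cons, cons, drop = FALSE])
  rhs <- 1 + colSums(dcp[base, cons, drop = FALSE])
  tl[cons] <- solve(A, rhs)
  tl
}
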