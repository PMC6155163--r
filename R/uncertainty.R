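#' Pedigree table constructor/validator
#'
#' A pedigree records the data quality of each basic input as a confidence
#' interval half-width expressed as a fraction of the point value, per group
#' and parameter (`B`, `PB`, `QB`). Missing entries mean the parameter is
#' known exactly.
#'
#' @param df data.frame with columns `group`, `parameter`, `ci`.
#' @return the validated data.frame with class `pedigree`.
#' @export
pedigree <- function(df) {
  stopifnot(all(c("group", "parameter", "ci") %in% names(df)))
  if (!all(df$parameter %in% c("B", "PB", "QB"))) {
    stop("pedigree parameter must be one of B, PB, QB")
  }
  if (any(df$ci < 0 | df$ci > 0.8)) stop("pedigree ci must lie in [0, 0.8]")
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Draw a perturbed model from the pedigree and re-balance it
#'
#' Each `B`, `PB`, `QB` with a pedigree entry is drawn uniformly in
#' `[x (1 - ci), x (1 + ci)]`; ecotrophic efficiencies are then re-estimated
#' by the mass-balance solver. Draws whose re-balance fails (any EE outside
#' [0, 1], or an invalid parameter combination) are rejected and redrawn, up
#' to 50 attempts. Diet composition is never resampled.
#'
#' @param model a balanced `ecopath_model`.
#' @param ped a [pedigree()] table.
#' @return a balanced, perturbed `ecopath_model`.
#' @export
draw_model <- function(model, ped) {
  if (!isTRUE(model$balanced)) stop("draw_model() requires a balanced model")
  ped <- pedigree(as.data.frame(ped))
  unknown <- setdiff(ped$group, group_names(model))
  if (length(unknown)) stop("pedigree for unknown groups: ", paste(unknown, collapse = ", "))
  g0 <- model$groups
  idx <- match(ped$group, g0$name)
  for (attempt in seq_len(50L)) {
    g <- g0
    for (r in seq_len(nrow(ped))) {
      p <- ped$parameter[r]
      x <- g[[p]][idx[r]]
      g[[p]][idx[r]] <- stats::runif(1, x * (1 - ped$ci[r]), x * (1 + ped$ci[r]))
    }
    cand <- tryCatch({
      m <- model
      m$groups <- g
      m$groups$EE <- ifelse(m$groups$category == "detritus", m$groups$EE, NA_real_)
      m$balanced <- FALSE
      m <- validate_ecopath_model(m)
      solve_mass_balance(m)
    }, error = function(e) NULL)
    if (!is.null(cand)) return(cand)
  }
  stop("pedigree incompatible with balance: 50 consecutive draws rejected")
}

#' Monte Carlo uncertainty envelope over a scenario run
#'
#' Repeats draw -> re-calibrate -> simulate `n` times and summarizes each
#' output series by its 5th and 95th percentiles (linear interpolation
#' between order statistics) together with the deterministic central run.
#' Replicates whose simulation aborts are logged and excluded; more than 20%
#' exclusions is an error. Fully reproducible for a given seed.
#'
#' @param model a balanced `ecopath_model`.
#' @param forcing a [forcing_set()] (typically from [build_scenario()]).
#' @param ped a [pedigree()] table.
#' @param n number of replicates (default 500).
#' @param seed integer seed (required).
#' @param responses,k,k_new_alien passed to [calibrate()].
#' @param dt integration step (default 1/12 yr).
#' @param indicators also envelope the eleven ecological indicators
#'   (default TRUE).
#' @return An `uncertainty_envelope`: for each output (`biomass`, `catch`,
#'   and optionally each indicator) matrices/vectors `lower`, `upper`,
#'   `central`; plus `n`, `n_excluded` and `seed`.
#' @export
run_monte_carlo <- function(model, forcing, ped, n = 500, seed,
                            responses = list(), k = 2, k_new_alien = 10,
                            dt = 1 / 12, indicators = TRUE) {
  if (missing(seed)) stop("seed is required for reproducibility")
  if (n < 2) stop("need at least 2 replicates")
  central_params <- calibrate(model, responses = responses, k = k,
                              k_new_alien = k_new_alien)
  central <- simulate_ecosim(central_params, forcing, dt = dt)
  central_ind <- if (indicators) indicator_series(central)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  bio <- vector("list", n)
  cat_tot <- vector("list", n)
  ind <- vector("list", n)
  excluded <- 0L
  for (r in seq_len(n)) {
    rep_out <- tryCatch({
      m <- draw_model(model, ped)
      p <- calibrate(m, responses = responses, k = k, k_new_alien = k_new_alien)
      sim <- simulate_ecosim(p, forcing, dt = dt)
      list(b = sim$biomass, ct = colSums(annual_catch(sim)),
           ind = if (indicators) indicator_series(sim))
    }, error = function(e) NULL)
    if (is.null(rep_out)) {
      excluded <- excluded + 1L
      next
    }
    bio[[r]] <- rep_out$b
    cat_tot[[r]] <- rep_out$ct
    ind[[r]] <- rep_out$ind
  }
  if (excluded > 0.2 * n) {
    stop("more than 20% of Monte Carlo replicates aborted (", excluded, "/", n, ")")
  }
  keep <- !vapply(bio, is.null, logical(1))
  bio <- bio[keep]; cat_tot <- cat_tot[keep]; ind <- ind[keep]

  qband <- function(mats, dim_names) {
    arr <- simplify2array(mats)
    lower <- apply(arr, seq_along(dim(arr))[-length(dim(arr))], stats::quantile,
                   probs = 0.05, type = 7, names = FALSE)
    upper <- apply(arr, seq_along(dim(arr))[-length(dim(arr))], stats::quantile,
                   probs = 0.95, type = 7, names = FALSE)
    list(lower = lower, upper = upper)
  }
  out <- list()
  bb <- qband(bio)
  dimnames(bb$lower) <- dimnames(bb$upper) <- dimnames(central$biomass)
  out$biomass <- c(bb, list(central = central$biomass))
  cb <- qband(cat_tot)
  out$total_catch <- list(lower = cb$lower, upper = cb$upper,
                          central = colSums(annual_catch(central)))
  if (indicators) {
    ind_names <- setdiff(names(central_ind), "year")
    for (v in ind_names) {
      vals <- lapply(ind, function(d) d[[v]])
      vb <- qband(vals)
      out[[v]] <- list(lower = vb$lower, upper = vb$upper,
                       central = central_ind[[v]])
    }
  }
  structure(list(outputs = out, years = central$years, n = n,
                 n_excluded = excluded, seed = seed),
            class = "uncertainty_envelope")
}

#' @export
print.uncertainty_envelope <- function(x, ...) {
  cat(sprintf("uncertainty_envelope: %d replicates (%d excluded), seed %s, %d output series\n",
              x$n, x$n_excluded, format(x$seed), length(x$outputs)))
  invisible(x)
}
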