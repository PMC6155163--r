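#' Construct a mass-balance food-web model
#'
#' An `ecopath_model` is the static snapshot of a food web used to initialize
#' the temporal dynamics: functional groups with their basic parameters, a
#' diet composition matrix, and fishing fleets with landings and discards.
#'
#' @param groups data.frame with one row per functional group and columns
#'   `name`, `category` (one of `"consumer"`, `"producer"`, `"detritus"`),
#'   `B` (biomass, t km^-2), `PB` (production/biomass, yr^-1), `QB`
#'   (consumption/biomass, yr^-1), `EE` (ecotrophic efficiency, fraction; may
#'   be `NA` when it is to be estimated), `GS` (unassimilated fraction of
#'   consumption), `BA` (biomass accumulation, t km^-2 yr^-1),
#'   `net_migration` (immigration minus emigration, t km^-2 yr^-1) and
#'   `role_tags` (semicolon-separated subset of `"native"`, `"alien"`,
#'   `"forage"`, `"benthic_invertebrate"`, `"vulnerable"`, `"new_alien"`).
#'   Row order is the authoritative group index shared by all matrices.
#' @param diet square numeric matrix of diet fractions; entry `(i, j)` is the
#'   fraction of prey `i` in the diet of predator `j`. Dimnames must equal the
#'   group names.
#' @param import named numeric vector giving, per predator, the fraction of
#'   its diet imported from outside the system. Missing entries default to 0.
#' @param landings,discards numeric matrices (group x fleet, t km^-2 yr^-1)
#'   with fleet names as column names. `NULL` for an unfished web.
#' @param area_note free-text description of the modelled area.
#'
#' @return An object of class `ecopath_model`. The `balanced` flag is `FALSE`
#'   until [solve_mass_balance()] succeeds.
#' @seealso [solve_mass_balance()], [trophic_levels()], [generate_web()]
#' @export
ecopath_model <- function(groups, diet, import = NULL, landings = NULL,
                          discards = NULL, area_note = "") {
  stopifnot(is.data.frame(groups), is.matrix(diet))
  required <- c("name", "category", "B", "PB", "QB", "EE", "GS", "BA",
                "net_migration", "role_tags")
  missing_cols <- setdiff(required, names(groups))
  if (length(missing_cols) > 0L) {
    stop("groups table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  groups <- as.data.frame(groups)[, required]
  groups$name <- as.character(groups$name)
  groups$role_tags <- ifelse(is.na(groups$role_tags), "", as.character(groups$role_tags))
  n <- nrow(groups)
  nm <- groups$name
  if (anyDuplicated(nm)) stop("duplicated group names")
  if (!all(groups$category %in% c("consumer", "producer", "detritus"))) {
    stop("category must be one of consumer/producer/detritus")
  }
  if (!any(groups$category == "producer")) stop("at least one producer group required")
  if (!any(groups$category == "detritus")) stop("at least one detritus group required")

  if (!identical(dim(diet), c(n, n))) stop("diet matrix must be n_groups x n_groups")
  if (is.null(dimnames(diet))) dimnames(diet) <- list(nm, nm)
  if (!identical(rownames(diet), nm) || !identical(colnames(diet), nm)) {
    stop("diet matrix dimnames must match group names in group order")
  }
  imp <- stats::setNames(numeric(n), nm)
  if (!is.null(import)) {
    unknown <- setdiff(names(import), nm)
    if (length(unknown) > 0L) stop("import names not in groups: ", paste(unknown, collapse = ", "))
    imp[names(import)] <- as.numeric(import)
  }

  empty <- matrix(0, n, 0, dimnames = list(nm, NULL))
  landings <- if (is.null(landings)) empty else .as_catch_matrix(landings, nm, "landings")
  discards <- if (is.null(discards)) {
    matrix(0, n, ncol(landings), dimnames = dimnames(landings))
  } else {
    .as_catch_matrix(discards, nm, "discards")
  }
  if (ncol(discards) != ncol(landings) ||
      !identical(colnames(discards), colnames(landings))) {
    stop("landings and discards must share the same fleets")
  }

  model <- structure(
    list(groups = groups, diet = diet, import = imp,
         landings = landings, discards = discards,
         area_note = area_note, balanced = FALSE),
    class = "ecopath_model")
  validate_ecopath_model(model)
  model
}

.as_catch_matrix <- function(x, nm, what) {
  x <- as.matrix(x)
  if (nrow(x) != length(nm)) stop(what, " matrix must have one row per group")
  if (is.null(rownames(x))) rownames(x) <- nm
  if (!identical(rownames(x), nm)) stop(what, " row names must match group order")
  if (is.null(colnames(x)) && ncol(x) > 0L) stop(what, " needs fleet column names")
  storage.mode(x) <- "double"
  x
}

#' Validate an `ecopath_model` against its structural invariants
#'
#' Checks positivity of biomasses, parameter ranges, diet-column closure
#' (diet fractions plus import sum to one for every consumer) and fleet
#' catch non-negativity. Called by the constructor and after balancing.
#'
#' @param model an `ecopath_model`.
#' @return `model`, invisibly; errors describe the first violated invariant.
#' @export
validate_ecopath_model <- function(model) {
  g <- model$groups
  living <- g$category != "detritus"
  known_B <- !is.na(g$B)
  if (any(known_B & living & g$B <= 0)) {
    stop("living groups must have B > 0: ",
         paste(g$name[known_B & living & g$B <= 0], collapse = ", "))
  }
  if (any(known_B & !living & g$B < 0)) stop("detritus biomass must be >= 0")
  if (any(g$GS < 0 | g$GS >= 1)) stop("GS must lie in [0, 1)")
  cons <- g$category == "consumer"
  if (any(cons & (is.na(g$QB) | g$QB <= 0))) {
    stop("consumers must have QB > 0: ", paste(g$name[cons & (is.na(g$QB) | g$QB <= 0)], collapse = ", "))
  }
  if (any(cons & g$PB / g$QB >= 1)) {
    stop("consumers must have PB/QB < 1: ",
         paste(g$name[cons & g$PB / g$QB >= 1], collapse = ", "))
  }
  prod <- g$category == "producer"
  if (any(prod & g$QB != 0)) stop("producers must have QB = 0")

  dc <- model$diet
  if (any(dc < 0 | dc > 1)) stop("diet fractions must lie in [0, 1]")
  colsum <- colSums(dc) + model$import
  bad <- cons & abs(colsum - 1) > 1e-9
  if (any(bad)) {
    stop("diet column (plus import) does not sum to 1 for predator(s): ",
         paste(sprintf("%s (%.6f)", g$name[bad], colsum[bad]), collapse = ", "))
  }
  noncons <- !cons
  if (any(colSums(dc[, noncons, drop = FALSE]) > 0)) {
    stop("producers and detritus must have all-zero diet columns")
  }
  if (any(model$landings < 0) || any(model$discards < 0)) {
    stop("landings and discards must be non-negative")
  }
  tot <- colSums(model$landings) + colSums(model$discards)
  if (any(tot == 0)) {
    stop("fleet with zero total catch: ", paste(colnames(model$landings)[tot == 0], collapse = ", "))
  }
  invisible(model)
}

#' @export
print.ecopath_model <- function(x, ...) {
  g <- x$groups
  cat(sprintf("ecopath_model: %d groups (%d consumers, %d producers, %d detritus), %d fleet(s)%s\n",
              nrow(g), sum(g$category == "consumer"), sum(g$category == "producer"),
              sum(g$category == "detritus"), ncol(x$landings),
              if (isTRUE(x$balanced)) ", balanced" else ""))
  if (nzchar(x$area_note)) cat(" ", x$area_note, "\n")
  print(utils::head(g[, c("name", "category", "B", "PB", "QB", "EE")], 15L), row.names = FALSE)
  if (nrow(g) > 15L) cat("  ...\n")
  invisible(x)
}

#' Group names of a model
#' @param model an `ecopath_model`.
#' @return character vector in the authoritative group order.
#' @export
group_names <- function(model) model$groups$name

#' Fleet names of a model
#' @param model an `ecopath_model`.
#' @return character vector of fleet names (possibly empty).
#' @export
fleet_names <- function(model) colnames(model$landings)

#' Logical indicator for a role tag
#'
#' @param model an `ecopath_model`.
#' @param tag one of the role tags, e.g. `"alien"`, `"forage"`,
#'   `"benthic_invertebrate"`, `"vulnerable"`, `"new_alien"`.
#' @return logical vector over groups.
#' @export
has_tag <- function(model, tag) {
  vapply(strsplit(model$groups$role_tags, ";", fixed = TRUE),
         function(tags) tag %in% trimws(tags), logical(1))
}

#' Total fishery removals per group
#'
#' Sums landings and discards over all fleets: `Y_i = sum_f(L_if + D_if)`.
#'
#' @param model an `ecopath_model`.
#' @return named numeric vector (t km^-2 yr^-1) over groups.
#' @export
total_catch_by_group <- function(model) {
  stats::setNames(rowSums(model$landings) + rowSums(model$discards),
                  group_names(model))
}
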