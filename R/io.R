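#' Write a model directory (CSV file set)
#'
#' Emits `groups.csv`, `diet.csv` (square prey-by-predator matrix with a
#' final `import` row), `fleets.csv` (long format), and, when provided,
#' `responses.csv` and `pedigree.csv`. Files are name-keyed; row order
#' follows the authoritative group order. Writers are deterministic: stable
#' ordering and floats at 10 significant digits.
#'
#' @param model an `ecopath_model`.
#' @param dir output directory (created if needed).
#' @param responses optional named list of [env_response()] objects.
#' @param ped optional [pedigree()] table.
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir, responses = NULL, ped = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(d) {
    d[] <- lapply(d, function(x) if (is.numeric(x)) signif(x, 10) else x)
    d
  }
  utils::write.csv(fmt(model$groups), file.path(dir, "groups.csv"), row.names = FALSE)

  diet <- rbind(model$diet, import = model$import)
  dd <- data.frame(group = rownames(diet), signif(diet, 10), check.names = FALSE)
  utils::write.csv(dd, file.path(dir, "diet.csv"), row.names = FALSE)

  fl <- do.call(rbind, lapply(fleet_names(model), function(f) {
    data.frame(fleet = f, group = group_names(model),
               landings = signif(model$landings[, f], 10),
               discards = signif(model$discards[, f], 10))
  }))
  fl <- fl[fl$landings > 0 | fl$discards > 0, ]
  utils::write.csv(fl, file.path(dir, "fleets.csv"), row.names = FALSE)

  if (!is.null(responses)) {
    rr <- do.call(rbind, lapply(names(responses), function(g) {
      r <- responses[[g]]
      data.frame(group = g, min = r$min, q10 = r$q10, q90 = r$q90, max = r$max)
    }))
    utils::write.csv(fmt(rr), file.path(dir, "responses.csv"), row.names = FALSE)
  }
  if (!is.null(ped)) {
    utils::write.csv(fmt(as.data.frame(ped)), file.path(dir, "pedigree.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a model directory
#'
#' Counterpart of [write_model()]: reads `groups.csv` and `diet.csv`
#' (required), `fleets.csv`, `responses.csv` and `pedigree.csv` (optional;
#' a missing responses file means every group is temperature-insensitive).
#' All type invariants are re-validated with informative errors.
#'
#' @param dir model directory.
#' @return list with `model`, `responses` (possibly empty list) and
#'   `pedigree` (possibly `NULL`).
#' @export
read_model <- function(dir) {
  need <- file.path(dir, c("groups.csv", "diet.csv"))
  if (!all(file.exists(need))) {
    stop("model directory must contain groups.csv and diet.csv: ", dir)
  }
  groups <- utils::read.csv(file.path(dir, "groups.csv"), stringsAsFactors = FALSE)
  dd <- utils::read.csv(file.path(dir, "diet.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  mat <- as.matrix(dd[, -1, drop = FALSE])
  rownames(mat) <- dd$group
  if (!"import" %in% rownames(mat)) stop("diet.csv must end with an 'import' row")
  import <- mat["import", ]
  diet <- mat[setdiff(rownames(mat), "import"), , drop = FALSE]
  if (!identical(rownames(diet), groups$name) ||
      !identical(colnames(diet), groups$name)) {
    stop("diet.csv group names do not match groups.csv order")
  }

  landings <- discards <- NULL
  fp <- file.path(dir, "fleets.csv")
  if (file.exists(fp)) {
    fl <- utils::read.csv(fp, stringsAsFactors = FALSE)
    unknown <- setdiff(fl$group, groups$name)
    if (length(unknown)) stop("fleets.csv references unknown group(s): ",
                              paste(unknown, collapse = ", "))
    fleets <- unique(fl$fleet)
    landings <- discards <- matrix(0, nrow(groups), length(fleets),
                                   dimnames = list(groups$name, fleets))
    for (r in seq_len(nrow(fl))) {
      landings[fl$group[r], fl$fleet[r]] <- fl$landings[r]
      discards[fl$group[r], fl$fleet[r]] <- fl$discards[r]
    }
  }
  model <- ecopath_model(groups, diet, import = import,
                         landings = landings, discards = discards)
  if (all(!is.na(groups$EE))) model$balanced <- TRUE

  responses <- list()
  rp <- file.path(dir, "responses.csv")
  if (file.exists(rp)) {
    rr <- utils::read.csv(rp, stringsAsFactors = FALSE)
    unknown <- setdiff(rr$group, groups$name)
    if (length(unknown)) stop("responses.csv references unknown group(s): ",
                              paste(unknown, collapse = ", "))
    for (r in seq_len(nrow(rr))) {
      responses[[rr$group[r]]] <- env_response(rr$min[r], rr$q10[r],
                                               rr$q90[r], rr$max[r])
    }
  }
  ped <- NULL
  pp <- file.path(dir, "pedigree.csv")
  if (file.exists(pp)) {
    ped <- pedigree(utils::read.csv(pp, stringsAsFactors = FALSE))
  }
  list(model = model, responses = responses, pedigree = ped)
}

#' Write simulation results as tidy CSV plus a run manifest
#'
#' @param result a `simulation_result`.
#' @param dir output directory.
#' @param seed,scenario_id metadata recorded in `manifest.yaml`.
#' @param inputs named character vector of input files to digest (md5) into
#'   the manifest.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, seed = NA, scenario_id = NA,
                          inputs = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bio <- data.frame(year = rep(result$years, each = nrow(result$biomass)),
                    group = rownames(result$biomass),
                    biomass = signif(as.vector(result$biomass), 10))
  utils::write.csv(bio, file.path(dir, "biomass.csv"), row.names = FALSE)

  dn <- dimnames(result$catch)
  ct <- expand.grid(group = dn[[1]], fleet = dn[[2]], year = dn[[3]],
                    stringsAsFactors = FALSE)
  ct$value <- signif(as.vector(result$catch), 10)
  utils::write.csv(ct[, c("year", "group", "fleet", "value")],
                   file.path(dir, "catch.csv"), row.names = FALSE)

  ind <- indicator_series(result)
  tidy <- stats::reshape(ind, direction = "long",
                         varying = setdiff(names(ind), "year"),
                         v.names = "value", timevar = "indicator",
                         times = setdiff(names(ind), "year"))
  tidy <- tidy[order(tidy$year), c("year", "indicator", "value")]
  tidy$value <- signif(tidy$value, 10)
  utils::write.csv(tidy, file.path(dir, "indicators.csv"), row.names = FALSE)

  manifest <- list(
    tool = paste("trophicdyn", as.character(utils::packageVersion("trophicdyn"))),
    scenario_id = scenario_id, seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(vapply(inputs, function(f) unname(tools::md5sum(f)), "")))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
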