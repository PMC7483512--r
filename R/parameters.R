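#' Load and validate the functional-group model parameters
#'
#' Reads the resource table, growth-rate table, pH-corner table, stoichiometry
#' table and lactate-Ki table named by a YAML manifest, validates them (corner
#' ordering, non-negative stoichiometries, positive rates, unique ids, lactate
#' use restricted to M7/M8) and runs a carbon-balance check on every pathway
#' whose substrates and products all carry defined carbon counts. All
#' violations are collected and reported together.
#'
#' @param manifest path to a manifest YAML; defaults to the parameter set
#'   shipped with the package.
#' @return An object of class `mfg_model`: a list with `resources` (data
#'   frame), `mfgs` (named list of group specs, each with pathways, corners
#'   and Ki), `Ks_g_per_L`, `manifest` and per-file checksums.
#' @export
load_parameters <- function(manifest = default_manifest()) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest, call. = FALSE)
  man <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  paths <- vapply(man$tables, function(p) file.path(dir, p), character(1))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("parameter files missing: ", paste(missing, collapse = ", "), call. = FALSE)

  read_tsv <- function(p) utils::read.delim(p, stringsAsFactors = FALSE)
  resources <- read_tsv(paths[["resources"]])
  growth    <- read_tsv(paths[["growth"]])
  corners   <- read_tsv(paths[["ph_corners"]])
  stoich    <- read_tsv(paths[["stoichiometry"]])
  ki        <- read_tsv(paths[["lactate_ki"]])

  problems <- character(0)
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  ## --- resources ---
  if (anyDuplicated(resources$name))
    note("resources: duplicated name(s) %s",
         paste(unique(resources$name[duplicated(resources$name)]), collapse = ", "))
  if (any(resources$molar_mass <= 0, na.rm = TRUE))
    note("resources: molar_mass must be > 0")
  if (any(resources$in_feed < 0, na.rm = TRUE))
    note("resources: in_feed must be >= 0")
  if (!all(resources$unit %in% c("g_per_L", "mM")))
    note("resources: unit must be g_per_L or mM")

  ## --- corners ---
  for (i in seq_len(nrow(corners))) {
    cc <- as.numeric(corners[i, c("c1", "c2", "c3", "c4")])
    if (is.unsorted(cc))
      note("ph_corners row %d (%s): corner ordering violated (%s)",
           i, corners$mfg[i], paste(format(cc), collapse = ", "))
  }

  ## --- growth ---
  if (any(growth$mu_max < 0)) note("growth: mu_max must be >= 0")
  if (any(growth$yield <= 0)) note("growth: yield must be > 0")
  bad_primary <- setdiff(growth$primary_substrate, resources$name)
  if (length(bad_primary))
    note("growth: unknown primary substrate(s) %s", paste(bad_primary, collapse = ", "))

  ## --- stoichiometry ---
  if (any(stoich$moles < 0)) note("stoichiometry: coefficients must be >= 0")
  bad_res <- setdiff(stoich$resource, resources$name)
  if (length(bad_res))
    note("stoichiometry: unknown resource(s) %s", paste(bad_res, collapse = ", "))
  lac_users <- unique(stoich$mfg[stoich$resource == "lactate" &
                                 stoich$role == "substrate"])
  if (!all(lac_users %in% c("M7", "M8")))
    note("stoichiometry: only M7 and M8 may consume lactate (found %s)",
         paste(lac_users, collapse = ", "))

  mfg_ids <- paste0("M", 1:10)
  for (tab in list(corners = corners, ki = ki)) {
    if (!setequal(tab$mfg, mfg_ids) || anyDuplicated(tab$mfg))
      note("each of M1..M10 must appear exactly once per table")
  }
  if (!all(unique(growth$mfg) %in% mfg_ids)) note("growth: unknown MFG id")

  ## assemble specs (needed for the carbon check), then validate balance
  cmap <- stats::setNames(resources$carbon_atoms, resources$name)
  mfgs <- list()
  for (id in mfg_ids) {
    g <- growth[growth$mfg == id, , drop = FALSE]
    if (nrow(g) == 0L) { note("growth: no pathways for %s", id); next }
    cs <- corners[corners$mfg == id, ]
    ## a malformed corner row was already recorded above; use a placeholder so
    ## the remaining checks (e.g. carbon balance) still run and get reported
    corner_set <- tryCatch(ph_corners(cs$c1, cs$c2, cs$c3, cs$c4),
                           error = function(e) ph_corners(0, 0, 0, 0))
    pw <- lapply(seq_len(nrow(g)), function(j) {
      s <- stoich[stoich$mfg == id & stoich$pathway == g$pathway[j], , drop = FALSE]
      subs  <- s[s$role == "substrate", ]
      prods <- s[s$role == "product", ]
      if (nrow(subs) == 0L)
        note("stoichiometry: pathway %s/%s has no substrate", id, g$pathway[j])
      if (!g$primary_substrate[j] %in% subs$resource)
        note("growth: primary substrate of %s/%s absent from its stoichiometry",
             id, g$pathway[j])
      list(name = g$pathway[j],
           mu_max = g$mu_max[j], yield = g$yield[j],
           primary = g$primary_substrate[j],
           substrates = stats::setNames(subs$moles, subs$resource),
           products = stats::setNames(prods$moles, prods$resource))
    })
    names(pw) <- g$pathway
    mfgs[[id]] <- list(
      id = id,
      description = man$mfg_descriptions[[id]],
      pathways = pw,
      ph_corners = corner_set,
      Ki = ki$ki_mM[ki$mfg == id])
  }

  for (id in names(mfgs)) {
    for (pw in mfgs[[id]]$pathways) {
      bal <- pathway_carbon_balance(pw, cmap)
      if (!is.na(bal$diff) && abs(bal$diff) > 1e-9)
        note("carbon balance fails for %s/%s: substrates %s C vs products %s C",
             id, pw$name, format(bal$substrate_C), format(bal$product_C))
    }
  }

  if (length(problems))
    stop("parameter validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)

  structure(list(
    resources = resources,
    mfgs = mfgs,
    Ks_g_per_L = man$half_saturation_g_per_L,
    manifest = normalizePath(manifest),
    checksums = tools::md5sum(c(manifest, unname(paths)))
  ), class = "mfg_model")
}

#' Carbon balance of one pathway
#'
#' Sums carbon atoms over substrates and products using per-resource carbon
#' counts; resources with `NA` carbon (e.g. protein, whose amino-acid
#' composition is not resolved) make the balance unevaluable and the check is
#' skipped for that pathway.
#'
#' @param pathway a pathway spec (see [load_parameters()]).
#' @param carbon_map named vector of carbon atoms per mole, `NA` allowed.
#' @return List with `substrate_C`, `product_C` and their difference (`NA`
#'   when unevaluable).
#' @export
pathway_carbon_balance <- function(pathway, carbon_map) {
  count <- function(v) {
    if (length(v) == 0L) return(0)
    atoms <- carbon_map[names(v)]
    if (anyNA(atoms)) return(NA_real_)
    sum(atoms * v)
  }
  sC <- count(pathway$substrates)
  pC <- count(pathway$products)
  list(substrate_C = sC, product_C = pC, diff = sC - pC)
}

#' Path to the shipped parameter manifest
#' @return File path of the default `manifest.yaml`.
#' @export
default_manifest <- function() {
  system.file("extdata", "manifest.yaml", package = "mfgsim", mustWork = TRUE)
}

## Cached default model: loading + validation is cheap but called everywhere.
.model_cache <- new.env(parent = emptyenv())

#' Default model (cached)
#' @return The `mfg_model` from the shipped manifest.
#' @export
default_model <- function() {
  if (is.null(.model_cache$model)) .model_cache$model <- load_parameters()
  .model_cache$model
}

#' @export
print.mfg_model <- function(x, ...) {
  cat("<mfg_model> 10 microbial functional groups,",
      nrow(x$resources), "resources\n")
  for (m in x$mfgs) {
    cat(sprintf("  %-4s %-55s pathways: %s\n", m$id,
                if (is.null(m$description)) "" else m$description,
                paste(names(m$pathways), collapse = ", ")))
  }
  invisible(x)
}

#' Dilution rate from vessel turnover
#'
#' @param turnovers_per_day number of complete vessel volume exchanges per
#'   day (`> 0`); the experimental system runs at one per day.
#' @return List with `per_day` (the working unit of the model),
#'   `per_hour`, and `per_hour_display` (rounded to 3 decimals, the value a
#'   fermentor log would print: 1/d -> 0.042 h^-1).
#' @export
dilution_from_turnover <- function(turnovers_per_day) {
  if (!is.numeric(turnovers_per_day) || length(turnovers_per_day) != 1L ||
      !is.finite(turnovers_per_day) || turnovers_per_day <= 0)
    stop("turnovers_per_day must be a single positive number", call. = FALSE)
  list(per_day = turnovers_per_day,
       per_hour = turnovers_per_day / 24,
       per_hour_display = round(turnovers_per_day / 24, 3))
}
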