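#' Write a simulation result to disk
#'
#' Writes `trajectories.csv` (tidy long format: `time_days`, `kind`, `name`,
#' `run`, `value`, `unit`; values at full double precision) and
#' `metadata.json` (scenario configuration, seed, parameter-file checksums,
#' package version, timestamp). The pair round-trips losslessly through
#' [read_result()].
#'
#' @param result a `simulation_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "simulation_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tidy <- aggregate_result(result)
  tidy$value <- sprintf("%.17g", tidy$value)
  utils::write.csv(tidy, file.path(dir, "trajectories.csv"), row.names = FALSE)
  cfg <- result$config
  meta <- list(
    schema = "mfgsim-result/1",
    pH = cfg$pH, lactate_feed = cfg$lactate_feed,
    dilution_rate = cfg$dilution_rate, inoculum_total = cfg$inoculum_total,
    n_strains_per_mfg = cfg$n_strains_per_mfg, n_runs = cfg$n_runs,
    horizon = cfg$horizon, seed = cfg$seed, out_dt = cfg$out_dt,
    mu_ks_jitter = cfg$mu_ks_jitter,
    ph_shift_halfwidth = cfg$ph_shift_halfwidth,
    regime = cfg$regime$mode, ph_gate = cfg$regime$ph_gate,
    inoculum_label = cfg$inoculum$label,
    inoculum_fractions = as.list(cfg$inoculum$mfg_fractions),
    units = as.list(result$units),
    parameter_checksums = as.list(result$checksums),
    version = result$version,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulation result written by [write_result()]
#'
#' @param dir directory containing `trajectories.csv` and `metadata.json`.
#' @return A `simulation_result` whose numeric content equals the object
#'   that was written.
#' @export
read_result <- function(dir) {
  tidy <- utils::read.csv(file.path(dir, "trajectories.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(run = "character"))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  time <- sort(unique(tidy$time_days))
  wide <- function(sub) {
    nms <- unique(sub$name)
    m <- vapply(nms, function(nm) sub$value[sub$name == nm],
                numeric(length(time)))
    dimnames(m) <- list(NULL, nms)
    m
  }
  pick <- function(run, kind) wide(tidy[tidy$run == run & tidy$kind == kind, ])
  run_ids <- setdiff(unique(tidy$run), "mean")
  runs <- if (length(run_ids)) {
    lapply(run_ids[order(as.integer(run_ids))], function(r)
      list(mfg = pick(r, "mfg"), resources = pick(r, "resource")))
  }
  cfg <- scenario_config(
    pH = meta$pH,
    inoculum = donor_profile(unlist(meta$inoculum_fractions),
                             label = meta$inoculum_label),
    lactate_feed = meta$lactate_feed, dilution_rate = meta$dilution_rate,
    inoculum_total = meta$inoculum_total,
    n_strains_per_mfg = meta$n_strains_per_mfg, n_runs = meta$n_runs,
    horizon = meta$horizon, seed = meta$seed,
    regime = inhibition_regime(meta$regime, meta$ph_gate),
    mu_ks_jitter = meta$mu_ks_jitter,
    ph_shift_halfwidth = meta$ph_shift_halfwidth,
    out_dt = meta$out_dt, keep_runs = !is.null(runs))
  structure(list(
    time = time,
    mfg = pick("mean", "mfg"),
    resources = pick("mean", "resource"),
    units = unlist(meta$units),
    runs = runs,
    config = cfg,
    checksums = unlist(meta$parameter_checksums),
    version = meta$version
  ), class = "simulation_result")
}
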