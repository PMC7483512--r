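#' Scenario configuration
#'
#' Bundles the fermentor operating conditions and simulation settings: pH
#' set-point, dilution rate (vessel turnovers per day), feed composition
#' (from the model's resource table, with the scenario's lactate infusion
#' level substituted), inoculum, ensemble stochasticity and replication.
#'
#' @param pH pH set-point (externally controlled, constant).
#' @param inoculum a [donor_profile()].
#' @param lactate_feed lactate concentration in the feed, mM (0, 10 or 20 in
#'   the experiments; any value `>= 0` accepted).
#' @param dilution_rate day^-1 (default 1, i.e. one vessel turnover per day).
#' @param inoculum_total total inoculum biomass, g/L (default 2).
#' @param n_strains_per_mfg strains per group (default 10).
#' @param n_runs stochastic replicate runs to average (default 10).
#' @param horizon simulated time, days (default 4).
#' @param seed master seed; per-run substreams are derived by counter.
#' @param regime an [inhibition_regime()] (default `"full"`).
#' @param mu_ks_jitter,ph_shift_halfwidth ensemble stochasticity, see
#'   [ensemble_spec()].
#' @param out_dt output grid spacing, days (default 0.05).
#' @param rtol,atol relative and absolute integrator tolerances (defaults
#'   1e-6 and 1e-9).
#' @param keep_runs retain per-run trajectories in the result (default TRUE).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(pH, inoculum, lactate_feed = 0, dilution_rate = 1,
                            inoculum_total = 2, n_strains_per_mfg = 10,
                            n_runs = 10, horizon = 4, seed = 1L,
                            regime = inhibition_regime("full"),
                            mu_ks_jitter = 0.10, ph_shift_halfwidth = 0.2,
                            out_dt = 0.05, rtol = 1e-6, atol = 1e-9,
                            keep_runs = TRUE) {
  stopifnot(inherits(inoculum, "donor_profile"),
            inherits(regime, "inhibition_regime"),
            dilution_rate > 0, horizon > 0, lactate_feed >= 0,
            inoculum_total >= 0, n_runs >= 1, out_dt > 0)
  structure(list(pH = pH, inoculum = inoculum, lactate_feed = lactate_feed,
                 dilution_rate = dilution_rate, inoculum_total = inoculum_total,
                 n_strains_per_mfg = as.integer(n_strains_per_mfg),
                 n_runs = as.integer(n_runs), horizon = horizon,
                 seed = as.integer(seed), regime = regime,
                 mu_ks_jitter = mu_ks_jitter,
                 ph_shift_halfwidth = ph_shift_halfwidth,
                 out_dt = out_dt, rtol = rtol, atol = atol,
                 keep_runs = keep_runs),
            class = "scenario_config")
}

#' Initial vessel concentrations
#'
#' The vessel starts filled with fresh medium: every resource begins at its
#' feed concentration, including the scenario's lactate infusion level; no
#' growth lag is applied.
#'
#' @param config a [scenario_config()].
#' @param model an `mfg_model`.
#' @return Named numeric vector of concentrations in native units.
#' @export
substrate_t0 <- function(config, model = default_model()) {
  feed_concentrations(config, model)
}

feed_concentrations <- function(config, model) {
  feed <- stats::setNames(model$resources$in_feed, model$resources$name)
  feed[["lactate"]] <- config$lactate_feed
  feed
}

## Compile an ensemble into flat matrices for fast derivative evaluation.
## Per pathway row: effective mu (mu_max x pH factor, fixed because pH is a
## set-point), up to two substrate indices with native-unit Ks, the
## lactate-Ki applicable under the scenario's regime (NA = uninhibited), and
## the net resource flux per unit biomass growth.
compile_system <- function(ensemble, config, model) {
  res <- model$resources
  n_res <- nrow(res)
  res_idx <- stats::setNames(seq_len(n_res), res$name)
  inhibited <- inhibited_mfgs(config$regime, config$pH)

  rows <- list()
  for (k in seq_along(ensemble)) {
    st <- ensemble[[k]]
    phf <- ph_growth_factor(config$pH, st$ph_corners)
    for (pw in st$pathways) {
      subs <- names(pw$substrates)
      prim <- pw$primary
      mw_prim <- res$molar_mass[res_idx[[prim]]]
      ## mmol of primary per g biomass formed (yield is g biomass / g primary)
      q_prim <- 1000 / (pw$yield * mw_prim)
      flux <- numeric(n_res)
      for (r in subs) {
        q <- q_prim * pw$substrates[[r]] / pw$substrates[[prim]]
        i <- res_idx[[r]]
        flux[i] <- flux[i] - if (res$unit[i] == "g_per_L") q * res$molar_mass[i] / 1000 else q
      }
      for (r in names(pw$products)) {
        q <- q_prim * pw$products[[r]] / pw$substrates[[prim]]
        i <- res_idx[[r]]
        flux[i] <- flux[i] + if (res$unit[i] == "g_per_L") q * res$molar_mass[i] / 1000 else q
      }
      rows[[length(rows) + 1L]] <- list(
        strain = k,
        mu_eff = pw$mu_max * phf,
        Ki = if (st$mfg %in% inhibited) st$Ki else NA_real_,
        s1 = res_idx[[subs[1]]], Ks1 = pw$Ks[[1]],
        s2 = if (length(subs) > 1L) res_idx[[subs[2]]] else NA_integer_,
        Ks2 = if (length(subs) > 1L) pw$Ks[[2]] else NA_real_,
        flux = flux)
    }
  }
  npr <- length(rows)
  get <- function(f, what) vapply(rows, `[[`, f, what)
  list(
    n_strains = length(ensemble),
    n_res = n_res,
    res_names = res$name,
    res_units = ifelse(res$unit == "g_per_L", "g/L", "mM"),
    dil_mask = !res$is_gas_sink,
    lactate_idx = res_idx[["lactate"]],
    strain = get(integer(1), "strain"),
    mu_eff = get(numeric(1), "mu_eff"),
    Ki = get(numeric(1), "Ki"),
    s1 = get(integer(1), "s1"), Ks1 = get(numeric(1), "Ks1"),
    s2 = get(integer(1), "s2"), Ks2 = get(numeric(1), "Ks2"),
    has_s2 = !is.na(get(integer(1), "s2")),
    inhibited = !is.na(get(numeric(1), "Ki")),
    Fmat = do.call(rbind, lapply(rows, `[[`, "flux")),
    mfg_of_strain = vapply(ensemble, `[[`, character(1), "mfg"),
    b0 = vapply(ensemble, `[[`, numeric(1), "initial_biomass"))
}

## Time derivative of the full community state. Biomass: growth minus
## washout. Washout-coupled resources: dilution refill/outflow plus net
## metabolic flux; gas sinks omit the dilution term. Negative excursions are
## clipped in the kinetic terms only, never in the stored state.
community_derivs <- function(t, y, p) {
  B <- y[seq_len(p$n_strains)]
  S <- y[p$n_strains + seq_len(p$n_res)]
  Bc <- pmax(B, 0)
  Sc <- pmax(S, 0)

  mon <- Sc[p$s1] / (Sc[p$s1] + p$Ks1)
  if (any(p$has_s2)) {
    m2 <- Sc[p$s2[p$has_s2]] / (Sc[p$s2[p$has_s2]] + p$Ks2[p$has_s2])
    mon[p$has_s2] <- pmin(mon[p$has_s2], m2)
  }
  mu <- p$mu_eff * mon
  if (any(p$inhibited)) {
    L <- Sc[p$lactate_idx]
    mu[p$inhibited] <- mu[p$inhibited] * p$Ki[p$inhibited] / (p$Ki[p$inhibited] + L)
  }
  g <- mu * Bc[p$strain]                     # g/L/d biomass formed per pathway

  dB <- rowsum(g, p$strain, reorder = TRUE)[, 1] - p$D * B
  dS <- as.vector(crossprod(p$Fmat, g))
  dS[p$dil_mask] <- dS[p$dil_mask] + p$D * (p$feed[p$dil_mask] - S[p$dil_mask])

  dy <- c(dB, dS)
  if (!all(is.finite(dy))) {
    bad <- which(!is.finite(dy))[1]
    what <- if (bad <= p$n_strains) paste0("strain #", bad)
            else paste0("resource ", p$res_names[bad - p$n_strains])
    stop(sprintf("non-finite derivative at t = %.4f for %s", t, what),
         call. = FALSE)
  }
  list(dy)
}

integrate_run <- function(ensemble, config, model, rtol = config$rtol,
                          atol = config$atol) {
  p <- compile_system(ensemble, config, model)
  p$D <- config$dilution_rate
  p$feed <- unname(feed_concentrations(config, model))
  y0 <- c(p$b0, unname(substrate_t0(config, model)))
  names(y0) <- c(paste0("strain", seq_len(p$n_strains)), p$res_names)
  times <- seq(0, config$horizon, by = config$out_dt)

  solve_once <- function(rt, at) {
    out <- deSolve::ode(y = y0, times = times, func = community_derivs,
                        parms = p, method = "lsoda", rtol = rt, atol = at)
    if (nrow(out) < length(times))
      stop("integrator stopped early", call. = FALSE)
    out
  }
  out <- tryCatch(solve_once(rtol, atol), error = function(e) {
    ## one retry at tighter tolerance before giving up
    tryCatch(solve_once(rtol / 100, atol / 100), error = function(e2) {
      stop(sprintf("integration failed (pH %.2f, lactate feed %g mM): %s",
                   config$pH, config$lactate_feed, conditionMessage(e2)),
           call. = FALSE)
    })
  })
  list(out = out, sys = p)
}

#' Run a scenario
#'
#' Generates `n_runs` independent strain ensembles from counter-derived
#' sub-seeds of the master seed, integrates the community ODE system for
#' each over the horizon, and averages the trajectories on the common output
#' grid. Identical seed and configuration give bit-identical results.
#'
#' @param config a [scenario_config()].
#' @param model an `mfg_model` (default: shipped parameter set).
#' @return Object of class `simulation_result`: `time` (days), `mfg`
#'   (time x 10 matrix of run-averaged group biomass, g/L), `resources`
#'   (time x resource matrix, native units), `units`, per-run trajectories in
#'   `runs` (when `keep_runs`), and `config`/provenance metadata.
#' @export
run_scenario <- function(config, model = default_model()) {
  stopifnot(inherits(config, "scenario_config"), inherits(model, "mfg_model"))
  mfg_ids <- paste0("M", 1:10)
  runs <- vector("list", config$n_runs)
  mfg_acc <- NULL; res_acc <- NULL
  for (r in seq_len(config$n_runs)) {
    sub_seed <- as.integer((config$seed + 7919 * r) %% 2147483647L)
    espec <- ensemble_spec(n_strains_per_mfg = config$n_strains_per_mfg,
                           mu_ks_jitter = config$mu_ks_jitter,
                           ph_shift_halfwidth = config$ph_shift_halfwidth,
                           seed = sub_seed)
    ens <- generate_ensemble(model, espec)
    ens <- synth_donor(ens, config$inoculum, total = config$inoculum_total)
    sol <- integrate_run(ens, config, model)
    nt <- nrow(sol$out)
    Bmat <- sol$out[, 1 + seq_len(sol$sys$n_strains), drop = FALSE]
    Smat <- sol$out[, 1 + sol$sys$n_strains + seq_len(sol$sys$n_res),
                    drop = FALSE]
    ## aggregate strains to their functional group
    mfg_mat <- sapply(mfg_ids, function(id)
      rowSums(Bmat[, sol$sys$mfg_of_strain == id, drop = FALSE]))
    colnames(Smat) <- sol$sys$res_names
    if (is.null(mfg_acc)) {
      mfg_acc <- matrix(0, nt, length(mfg_ids), dimnames = list(NULL, mfg_ids))
      res_acc <- matrix(0, nt, sol$sys$n_res,
                        dimnames = list(NULL, sol$sys$res_names))
      time <- sol$out[, 1]
      units <- stats::setNames(sol$sys$res_units, sol$sys$res_names)
    }
    mfg_acc <- mfg_acc + mfg_mat
    res_acc <- res_acc + Smat
    if (config$keep_runs) runs[[r]] <- list(mfg = mfg_mat, resources = Smat)
  }
  structure(list(
    time = time,
    mfg = mfg_acc / config$n_runs,
    resources = res_acc / config$n_runs,
    units = units,
    runs = if (config$keep_runs) runs,
    config = config,
    checksums = model$checksums,
    version = as.character(utils::packageVersion("mfgsim"))
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  nt <- length(x$time)
  fin <- x$mfg[nt, ]
  shares <- fin / sum(fin)
  cat(sprintf("<simulation_result> pH %.1f, lactate feed %g mM, %d runs, %g d\n",
              x$config$pH, x$config$lactate_feed, x$config$n_runs,
              x$config$horizon))
  cat("  final biomass shares:",
      paste(sprintf("%s %.1f%%", names(shares), 100 * shares), collapse = ", "),
      "\n")
  cat(sprintf("  final lactate: %.2f mM, butyrate: %.2f mM, propionate: %.2f mM\n",
              x$resources[nt, "lactate"], x$resources[nt, "butyrate"],
              x$resources[nt, "propionate"]))
  invisible(x)
}

#' Final functional-group biomass shares
#'
#' @param result a `simulation_result`.
#' @return Named fractions of total community biomass at the horizon.
#' @export
final_shares <- function(result) {
  fin <- result$mfg[length(result$time), ]
  fin / sum(fin)
}

#' Tidy long-format view of a simulation result
#'
#' @param result a `simulation_result`.
#' @param include_runs include per-run rows in addition to the run mean
#'   (default TRUE when the result retained them).
#' @return Data frame with columns `time_days`, `kind` (`mfg`/`resource`),
#'   `name`, `run` (`"mean"` or the run number), `value`, `unit`.
#' @export
aggregate_result <- function(result, include_runs = !is.null(result$runs)) {
  stopifnot(inherits(result, "simulation_result"))
  block <- function(mfg, res, run) {
    rbind(
      data.frame(time_days = rep(result$time, ncol(mfg)),
                 kind = "mfg", name = rep(colnames(mfg), each = nrow(mfg)),
                 run = run, value = as.vector(mfg), unit = "g/L",
                 stringsAsFactors = FALSE),
      data.frame(time_days = rep(result$time, ncol(res)),
                 kind = "resource", name = rep(colnames(res), each = nrow(res)),
                 run = run,
                 value = as.vector(res),
                 unit = rep(unname(result$units[colnames(res)]),
                            each = nrow(res)),
                 stringsAsFactors = FALSE))
  }
  out <- block(result$mfg, result$resources, "mean")
  if (include_runs && !is.null(result$runs)) {
    for (r in seq_along(result$runs)) {
      out <- rbind(out, block(result$runs[[r]]$mfg, result$runs[[r]]$resources,
                              as.character(r)))
    }
  }
  out
}
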