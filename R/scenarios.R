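#' Paired lactate-infusion simulation at a fixed pH
#'
#' Runs the model for one donor community at a given pH set-point, once per
#' lactate infusion level (default 0 and 10 mM), sharing the master seed so
#' the stochastic ensembles are identical across the pair and the infusion
#' effect is isolated. This reproduces the layout of the lactate-infusion
#' simulation experiments at pH 6.5 and pH 5.5.
#'
#' @param donor a [donor_profile()].
#' @param pH set-point (6.5 or 5.5 in the experiments).
#' @param lactate_feeds infusion levels, mM.
#' @param model an `mfg_model`.
#' @param seed master seed.
#' @param n_runs replicate runs averaged per condition (default 10).
#' @param regime an [inhibition_regime()].
#' @param ... further arguments passed to [scenario_config()].
#' @return List of class `infusion_pair`: `results` (one `simulation_result`
#'   per infusion level, named by level), `diagnostics` (per level: the
#'   dominant group at the horizon, M1's final share, final lactate mM).
#' @export
run_infusion_pair <- function(donor, pH, lactate_feeds = c(0, 10),
                              model = default_model(), seed = 1L, n_runs = 10,
                              regime = inhibition_regime("full"), ...) {
  results <- lapply(lactate_feeds, function(lf) {
    run_scenario(scenario_config(pH = pH, inoculum = donor, lactate_feed = lf,
                                 n_runs = n_runs, seed = seed, regime = regime,
                                 ...), model)
  })
  names(results) <- paste0(lactate_feeds, "mM")
  diagnostics <- do.call(rbind, lapply(seq_along(results), function(i) {
    res <- results[[i]]
    sh <- final_shares(res)
    data.frame(lactate_feed = lactate_feeds[i],
               dominant_mfg = names(which.max(sh)),
               m1_share = unname(sh[["M1"]]),
               m4_share = unname(sh[["M4"]]),
               final_lactate_mM = res$resources[length(res$time), "lactate"],
               stringsAsFactors = FALSE)
  }))
  structure(list(results = results, diagnostics = diagnostics,
                 pH = pH, donor = donor$label),
            class = "infusion_pair")
}

#' @export
print.infusion_pair <- function(x, ...) {
  cat(sprintf("<infusion_pair> donor %s at pH %.1f\n", x$donor, x$pH))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Sweep the lactate-utilizer abundance at low pH
#'
#' Progressively rescales the joint M7+M8 (LUB) fraction of a donor
#' community and simulates each composition at pH 5.5 with no lactate
#' infusion, recording final lactate, the M4 (lactate-producer) share, and a
#' collapse flag: lactate above `collapse_lactate_mM` at the horizon
#' together with M4 being the dominant group. The ensemble seed is shared
#' across the sweep so only the inoculum varies.
#'
#' @param donor base [donor_profile()] (default the D2-like synthetic
#'   community).
#' @param lub_fractions joint M7+M8 fractions to test.
#' @param pH set-point (default 5.5).
#' @param collapse_lactate_mM lactate threshold for the collapse flag
#'   (default 10 mM, half the high-infusion level, with zero infusion).
#' @param model,seed,n_runs,regime,... as in [run_infusion_pair()].
#' @return Data frame with one row per fraction: `lub_fraction`,
#'   `final_lactate_mM`, `m4_share`, `m1_share`, `dominant_mfg`, `collapse`.
#' @export
run_lub_sweep <- function(donor = synthetic_donor("D2"),
                          lub_fractions = c(0, 2e-4, 5e-4, 1e-3, 2e-3, 5e-3,
                                            1e-2, 2e-2),
                          pH = 5.5, collapse_lactate_mM = 10,
                          model = default_model(), seed = 1L, n_runs = 10,
                          regime = inhibition_regime("full"), ...) {
  rows <- lapply(lub_fractions, function(f) {
    prof <- set_lub_fraction(donor, f)
    res <- run_scenario(scenario_config(pH = pH, inoculum = prof,
                                        lactate_feed = 0, n_runs = n_runs,
                                        seed = seed, regime = regime, ...),
                        model)
    sh <- final_shares(res)
    lac <- res$resources[length(res$time), "lactate"]
    data.frame(lub_fraction = f,
               final_lactate_mM = unname(lac),
               m4_share = unname(sh[["M4"]]),
               m1_share = unname(sh[["M1"]]),
               dominant_mfg = names(which.max(sh)),
               collapse = unname(lac > collapse_lactate_mM &&
                                 names(which.max(sh)) == "M4"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Contrast inhibition regimes
#'
#' Runs the same donor and conditions under several lactate-inhibition
#' regimes (by default all three) with a common seed, and reports the L1
#' distance between final community compositions relative to the `"full"`
#' regime.
#'
#' @param donor a [donor_profile()].
#' @param pH set-point (default 5.5, where regime choice matters most).
#' @param lactate_feed infusion level, mM (default 10).
#' @param modes regime modes to compare.
#' @param model,seed,n_runs,... as in [run_infusion_pair()].
#' @return List with `results` (named by mode) and `distances` (data frame
#'   of L1 composition distance from the `"full"` regime).
#' @export
run_regime_contrast <- function(donor, pH = 5.5, lactate_feed = 10,
                                modes = c("full", "lub_exempt", "none"),
                                model = default_model(), seed = 1L,
                                n_runs = 10, ...) {
  results <- lapply(modes, function(m) {
    run_scenario(scenario_config(pH = pH, inoculum = donor,
                                 lactate_feed = lactate_feed, n_runs = n_runs,
                                 seed = seed, regime = inhibition_regime(m),
                                 ...), model)
  })
  names(results) <- modes
  ref <- final_shares(results[["full"]])
  distances <- data.frame(
    mode = modes,
    l1_from_full = vapply(results, function(r)
      sum(abs(final_shares(r) - ref)), numeric(1)),
    stringsAsFactors = FALSE)
  list(results = results, distances = distances)
}

#' Methanogen presence/absence contrast
#'
#' Runs the same community with the methanogen (M10) fraction set to each of
#' two qPCR-style levels (default absent vs 0.6%), sharing the seed so the
#' bacterial ensembles are identical, and scores the divergence of every
#' washout-coupled metabolite trajectory between the pair. Methanogens are
#' expected to chiefly alter formate (their fermentation substrate), leaving
#' other metabolites nearly unchanged.
#'
#' @param donor base [donor_profile()].
#' @param m10_levels the two M10 fractions (default `c(0, 0.006)`).
#' @param pH set-point (default 6.5).
#' @param lactate_feed infusion, mM (default 0).
#' @param model,seed,n_runs,... as in [run_infusion_pair()].
#' @return List with `results` (named by M10 level), `divergence` (data
#'   frame per dissolved metabolite: RMS difference between the pair,
#'   normalised by the pooled maximum magnitude) and `ch4_produced` per run.
#' @export
run_methanogen_contrast <- function(donor, m10_levels = c(0, 0.006),
                                    pH = 6.5, lactate_feed = 0,
                                    model = default_model(), seed = 1L,
                                    n_runs = 10, ...) {
  stopifnot(length(m10_levels) == 2L)
  results <- lapply(m10_levels, function(m10) {
    f <- override_methanogens(donor$mfg_fractions, m10)
    prof <- donor_profile(f, label = sprintf("%s, M10 %.1f%%", donor$label,
                                             100 * m10))
    run_scenario(scenario_config(pH = pH, inoculum = prof,
                                 lactate_feed = lactate_feed, n_runs = n_runs,
                                 seed = seed, ...), model)
  })
  names(results) <- paste0("M10_", m10_levels)
  a <- results[[1]]; b <- results[[2]]
  dissolved <- names(a$units)[a$units == "mM"]
  dissolved <- setdiff(dissolved, c("H2", "CO2", "CH4", "H2O"))
  divergence <- do.call(rbind, lapply(dissolved, function(r) {
    xa <- a$resources[, r]; xb <- b$resources[, r]
    data.frame(resource = r,
               rel_rmsd = sqrt(mean((xa - xb)^2)) /
                 (max(abs(c(xa, xb))) + 1e-9),
               stringsAsFactors = FALSE)
  }))
  list(results = results, divergence = divergence,
       ch4_final = vapply(results, function(r)
         unname(r$resources[length(r$time), "CH4"]), numeric(1)))
}
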