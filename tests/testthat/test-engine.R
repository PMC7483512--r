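test_that("the vessel starts filled with fresh medium, including the infusion level", {
  cfg <- scenario_config(pH = 6.5, inoculum = even_profile(), lactate_feed = 10)
  s0 <- substrate_t0(cfg, tm())
  expect_equal(unname(s0[["starch"]]), 5.6)
  expect_equal(unname(s0[["protein"]]), 2.0)
  expect_equal(unname(s0[["NSP"]]), 1.8)
  expect_equal(unname(s0[["acetate"]]), 32)
  expect_equal(unname(s0[["lactate"]]), 10)
  cfg0 <- scenario_config(pH = 6.5, inoculum = even_profile(), lactate_feed = 0)
  expect_equal(unname(substrate_t0(cfg0, tm())[["lactate"]]), 0)
})

test_that("non-growing strains wash out as B0 exp(-D t)", {
  zm <- zero_growth_model()
  cfg <- scenario_config(pH = 6.5, inoculum = even_profile(), n_runs = 1,
                         horizon = 3, out_dt = 0.5, seed = 2,
                         mu_ks_jitter = 0, ph_shift_halfwidth = 0,
                         rtol = 1e-9, atol = 1e-12)
  res <- run_scenario(cfg, zm)
  for (id in paste0("M", 1:10)) {
    expect_equal(res$mfg[, id], 0.2 * exp(-res$time),
                 tolerance = 1e-6, info = id)
  }
})

test_that("with zero biomass, washout-coupled resources relax to feed by the closed form", {
  cfg <- scenario_config(pH = 6.5, inoculum = even_profile(), lactate_feed = 8,
                         n_runs = 1, seed = 2)
  ens <- generate_ensemble(tm(), ensemble_spec(seed = 2))  # biomass stays 0
  p <- mfgsim:::compile_system(ens, cfg, tm())
  p$D <- cfg$dilution_rate
  p$feed <- unname(mfgsim:::feed_concentrations(cfg, tm()))
  s0 <- 0.5 * p$feed + 1            # start away from the feed composition
  y0 <- c(rep(0, p$n_strains), s0)
  times <- seq(0, 4, 0.25)
  out <- deSolve::ode(y0, times, mfgsim:::community_derivs, p,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  S <- out[, 1 + p$n_strains + seq_len(p$n_res)]
  for (i in which(p$dil_mask)) {
    expected <- p$feed[i] + (s0[i] - p$feed[i]) * exp(-times)
    expect_equal(unname(S[, i]), expected, tolerance = 1e-6,
                 info = p$res_names[i])
  }
  # gas sinks have no dilution and, with no biomass, no dynamics at all
  for (i in which(!p$dil_mask)) {
    expect_equal(unname(S[, i]), rep(s0[i], length(times)),
                 tolerance = 1e-8, info = p$res_names[i])
  }
})

test_that("a single strain reaches the classical chemostat balance mu = D", {
  m <- tm()
  ens <- generate_ensemble(m, ensemble_spec(n_strains_per_mfg = 1,
                                            mu_ks_jitter = 0,
                                            ph_shift_halfwidth = 0, seed = 1))
  solo <- structure(ens[vapply(ens, `[[`, character(1), "mfg") == "M2"],
                    class = "strain_ensemble")
  solo[[1]]$initial_biomass <- 0.1
  cfg <- scenario_config(pH = 6.5, inoculum = even_profile(), lactate_feed = 0,
                         n_runs = 1, horizon = 30, out_dt = 1, seed = 1,
                         regime = inhibition_regime("none"))
  sol <- mfgsim:::integrate_run(solo, cfg, m, rtol = 1e-8, atol = 1e-11)
  yT <- sol$out[nrow(sol$out), -1]
  p <- sol$sys; p$D <- cfg$dilution_rate
  p$feed <- unname(mfgsim:::feed_concentrations(cfg, m))
  d <- mfgsim:::community_derivs(30, yT, p)[[1]]
  B <- yT[[1]]
  expect_gt(B, 0.5)                                  # persisted, not washed out
  mu <- d[[1]] / B + p$D
  expect_equal(mu, p$D, tolerance = 1e-4)            # growth balances dilution
  # steady-state mass balance: washout-coupled resources are stationary
  dS <- d[p$n_strains + seq_len(p$n_res)]
  expect_lt(max(abs(dS[p$dil_mask])), 1e-6)
  # residual substrate sits at the classical R* = Ks D / (mu_max - D)
  mu_max <- solo[[1]]$pathways$starch$mu_max
  expect_equal(yT[["starch"]], 0.001 * p$D / (mu_max - p$D), tolerance = 1e-3)
})

test_that("identical seed and configuration give bit-identical averaged results", {
  r1 <- run_scenario(quick_config(), tm())
  r2 <- run_scenario(quick_config(), tm())
  expect_identical(r1$mfg, r2$mfg)
  expect_identical(r1$resources, r2$resources)
  expect_identical(r1$runs, r2$runs)
  r3 <- run_scenario(quick_config(seed = 8L), tm())
  expect_false(identical(r1$mfg, r3$mfg))
})

test_that("no state variable dips below -1e-9 on a standard run", {
  res <- run_scenario(scenario_config(pH = 5.5, inoculum = synthetic_donor("D7"),
                                      lactate_feed = 10, n_runs = 2, seed = 4),
                      tm())
  expect_gt(min(res$mfg), -1e-9)
  expect_gt(min(res$resources), -1e-9)
})

test_that("aggregation sums strains to groups and averages runs", {
  cfg <- scenario_config(pH = 6.5, inoculum = even_profile(), n_runs = 3,
                         horizon = 1, out_dt = 0.5, seed = 6,
                         mu_ks_jitter = 0, ph_shift_halfwidth = 0)
  res <- run_scenario(cfg, tm())
  # at t0 each group holds total x fraction = 0.2 g/L; community total 2 g/L
  expect_equal(unname(res$mfg[1, ]), rep(0.2, 10))
  expect_equal(sum(res$mfg[1, ]), cfg$inoculum_total)
  # zero jitter -> all runs identical -> the mean equals any single run
  expect_equal(res$mfg, res$runs[[1]]$mfg)
  expect_equal(res$resources, res$runs[[3]]$resources)

  tidy <- aggregate_result(res)
  expect_named(tidy, c("time_days", "kind", "name", "run", "value", "unit"))
  expect_setequal(unique(tidy$run), c("mean", "1", "2", "3"))
  m1 <- tidy[tidy$kind == "mfg" & tidy$name == "M1" & tidy$run == "mean", ]
  expect_equal(m1$value, unname(res$mfg[, "M1"]))
  expect_true(all(tidy$unit[tidy$kind == "mfg"] == "g/L"))
  expect_true(all(tidy$unit[tidy$name == "starch"] == "g/L"))
  expect_true(all(tidy$unit[tidy$name == "lactate"] == "mM"))
})

test_that("a sterile vessel keeps every resource at the feed level", {
  cfg <- scenario_config(pH = 6.5, inoculum = even_profile(),
                         inoculum_total = 0, lactate_feed = 10, n_runs = 1,
                         horizon = 2, out_dt = 0.5, seed = 1)
  res <- run_scenario(cfg, tm())
  expect_true(all(res$mfg == 0))
  expect_equal(unname(res$resources[, "lactate"]),
               rep(10, length(res$time)), tolerance = 1e-8)
  expect_equal(unname(res$resources[, "starch"]),
               rep(5.6, length(res$time)), tolerance = 1e-8)
})
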