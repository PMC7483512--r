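# mfgsim

Mechanistic simulation of a human colonic microbial community in
pH-controlled continuous culture, for microbiologists and modellers who
want to explore why mildly acidic gut environments can tip a healthy,
butyrate-producing community into a lactate-accumulating, perturbed state —
and why lactate-utilizing bacteria (LUB) hold the line.

## The model

The community is coarse-grained into ten microbial functional groups
(M1–M10): *Bacteroidetes* propionate producers, starch-degrading and
generalist acetate producers, lactate producers (bifidobacteria and
relatives), two guilds of butyrate producers, two guilds of lactate
utilizers (propiogenic *Negativicutes*/*C. catus*, butyrogenic
*Anaerostipes*/*Anaerobutyricum*), acetogens and methanogens. Each group is
a small stochastic ensemble of "strains" (±10% kinetic jitter, ±0.2 pH-unit
curve shift) growing in a chemostat at one vessel turnover per day
(0.042 h⁻¹). The per-pathway specific growth rate is

```
mu = mu_max x S/(Ks + S) x f_pH(pH) x Ki/(Ki + L)
```

— Monod saturation (Ks = 0.001 g/L everywhere), a trapezoidal pH response
defined by four corner pH values, and noncompetitive lactate inhibition
(Ki = 5 mM for the *Bacteroidetes* group, 15 mM for all others except the
lactate producers, who are spared; below pH ~6 the inhibition applies
broadly, above it only to *Bacteroidetes*). Explicit fermentation
stoichiometries (e.g. 4 hexose + 2 acetate → 5 butyrate + 6 H₂ + 8 CO₂ +
2 H₂O for the M5 butyrate producers) couple growth to metabolite dynamics
under dilution. See the vignette `vignettes/community-model.Rmd` for the
full account, including how the parameter tables were authored.

## Worked example

```r
library(mfgsim)

model <- default_model()           # shipped, validated parameter set
d2 <- synthetic_donor("D2")        # LUB-replete synthetic donor community
d2
#> <donor_profile> D2-like (synthetic)  (LUB M7+M8: 1.50%, methanogens M10: 0.60%)
#>    M1    M2    M3    M4    M5    M6    M7    M8    M9   M10
#> 0.300 0.030 0.299 0.050 0.100 0.120 0.008 0.007 0.080 0.006

res <- run_scenario(scenario_config(pH = 6.5, inoculum = d2,
                                    lactate_feed = 0, n_runs = 3, seed = 1),
                    model)
res
#> <simulation_result> pH 6.5, lactate feed 0 mM, 3 runs, 4 d
#>   final biomass shares: M1 91.8%, M2 0.4%, M3 2.9%, M4 0.2%, M5 3.6%, M6 0.4%, M7 0.1%, M8 0.1%, M9 0.5%, M10 0.1%
#>   final lactate: 0.00 mM, butyrate: 2.77 mM, propionate: 62.21 mM
```

At pH 6.5 the *Bacteroidetes* group (M1) sweeps to ~92% of community
biomass within the 4-day horizon and propionate is the major acid — the
stable, near-neutral regime. Dropping the set-point to pH 5.5 and removing
the lactate utilizers flips the system:

```r
run_lub_sweep(d2, lub_fractions = c(0, 0.015), n_runs = 3, seed = 1)
#>  lub_fraction final_lactate_mM  m4_share   m1_share dominant_mfg collapse
#>         0.000      66.13830318 0.7377198 0.01676932           M4     TRUE
#>         0.015       0.00119455 0.1429091 0.21452898           M5    FALSE
```

With LUB absent, lactate produced by M4 accumulates to ~66 mM, suppresses
every other group, and the community collapses into an M4-dominated state
(`collapse` flags final lactate > 10 mM with M4 dominant). At the D2-like
1.5% LUB fraction the same community stays butyrate-rich and uncollapsed —
the lactate utilizers are the stabilising element.

Other entry points: `run_infusion_pair()` (0 vs 10 mM lactate infusion at a
given pH), `run_regime_contrast()` (what changes if lactate inhibition is
switched off or the utilizers are exempted), `run_methanogen_contrast()`
(methanogens chiefly move formate), `taxa_to_profile()` (map a 16S
taxon-abundance TSV to a functional-group inoculum), and
`write_result()`/`read_result()` for lossless tidy-CSV + JSON export.

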