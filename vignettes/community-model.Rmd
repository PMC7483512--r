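---
title: "A functional-group model of the colonic microbiota in pH-controlled continuous culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A functional-group model of the colonic microbiota in pH-controlled continuous culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mfgsim` simulates a human colonic microbial community growing in a
single-stage, pH-controlled chemostat. The community is coarse-grained into
ten microbial functional groups (MFGs), each defined by the substrates it
can ferment, the metabolites it produces, its maximum specific growth
rates, its pH tolerance and its sensitivity to lactate:

* M1 propionate producers (*Bacteroidetes*)
* M2 starch-degrading acetate producers (*Ruminococcus bromii*)
* M3 non-acetogenic acetate producers (*Lachnospiraceae*/*Ruminococcaceae*)
* M4 lactate producers (*Actinobacteria*, lactobacilli and relatives)
* M5 and M6 butyrate producers (*Roseburia*/*E. rectale*;
  *Faecalibacterium*/*Subdoligranulum*)
* M7 lactate utilizers producing propionate (*Negativicutes*, *C. catus*)
* M8 lactate utilizers producing butyrate (*Anaerostipes*, *Anaerobutyricum*)
* M9 acetogens (*Blautia*)
* M10 methanogens

Each group is realised as a small ensemble of "strains" (ten by default).
A strain's per-pathway growth rate is the product of four factors:

$$\mu = \mu_{\max}\;\cdot\;\min_k \frac{S_k}{K_s + S_k}\;\cdot\;f_{pH}(\mathrm{pH})\;\cdot\;\frac{K_i}{K_i + L}$$

* **Monod saturation** with a common half-saturation constant
  $K_s = 0.001$ g/L for every group and substrate (converted to mM for
  molar-tracked resources). Pathways with a co-substrate (the butyrate
  producers require acetate) are limited by the scarcest substrate.
* **pH response** $f_{pH}$ is a trapezoid defined by four corner pH values
  $c_1 \le c_2 \le c_3 \le c_4$: zero outside $(c_1, c_4)$, one on
  $[c_2, c_3]$, linear in between. pH is an externally held set-point (the
  fermentors are pH-controlled), so this factor is constant within a run.
* **Noncompetitive lactate inhibition** $K_i/(K_i+L)$, with
  $K_i = 5$ mM for M1 and $15$ mM for all other groups except M4, which is
  never inhibited (lactic acid bacteria tolerate their own product). Which
  groups the factor applies to depends on pH: above the gate (default pH
  6.0) only M1 is inhibited; below it, every group except M4. The
  `lub_exempt` regime additionally spares the lactate utilizers M7/M8, and
  `none` disables inhibition; these variants exist because the inhibition
  of lactate utilizers by lactate is poorly constrained experimentally.

Biomass and dissolved resources obey the chemostat balance

$$\dot B_i = B_i \Big(\sum_p \mu_{ip} - D\Big), \qquad
  \dot S_k = D\,(\mathrm{feed}_k - S_k) + \sum \mathrm{production} -
  \sum \mathrm{consumption},$$

with dilution rate $D = 1$/day (one vessel turnover per day, displayed as
0.042 h$^{-1}$). Per-pathway substrate flux is $\mu B / Y$ with yield $Y$ in
g biomass per g of the pathway's primary substrate; co-substrate and
product fluxes follow the stoichiometric ratios. Gases and water (H2, CO2,
CH4, H2O) are tracked as accumulating pools without a dilution term — they
leave the liquid phase — but H2, CO2 and formate remain available to the
acetogens and methanogens that consume them.

## Units and stoichiometry

Polymeric substrates (protein 2 g/L, starch 5.6 g/L, non-starch
polysaccharide 1.8 g/L in the feed) are tracked in g/L and converted
through a hexose-equivalent of 162 g/mol; fermentation acids and gases are
tracked in mM. The feed also carries 32 mM acetate and 0, 10 or 20 mM
lactate depending on the infusion scenario. The vessel starts filled with
fresh medium and seeded with 2 g/L of inoculum; no growth lag is applied.

Every pathway whose substrates and products all have defined carbon counts
is checked for carbon balance at load time. The flagship example is the M5
butyrate pathway, 4 hexose + 2 acetate → 5 butyrate + 6 H2 + 8 CO2 + 2 H2O,
which balances 28 carbon atoms on each side. Protein pathways skip the
check because an amino-acid-equivalent carbon count is not defined.

## Parameter provenance

The parameter tables shipped in `inst/extdata/` are package-authored. The
fixed constants of the framework ($K_s$, the two-tier $K_i$, the feed,
dilution, inoculum size, ensemble size and jitter, the M5 stoichiometry,
two pathways for M9, the 0.1%/0.6% methanogen levels) are taken as given;
the remaining per-group rates, pH corners, yields and stoichiometries were
chosen once to be microbiologically plausible and to reproduce the
qualitative regime structure the model is meant to study, and are not
tuned thereafter:

* M1 has the broadest substrate range and the highest summed rate, but the
  narrowest acid tolerance ($c_1 = 5.3, c_2 = 6.0$) and the strictest
  lactate sensitivity ($K_i = 5$ mM).
* M4 grows maximally between pH 4.5 and 5.8 and is already declining at pH
  6.5, reflecting bifidobacterial/lactobacillal acid adaptation.
* The butyrate producers and the lactate utilizers keep a full growth
  plateau at pH 5.5 ($c_2 \le 5.4$) — consistent with the higher butyrate
  observed in mildly acidic fermentors and with the acid tolerance of
  classic lactate utilizers such as *Megasphaera* and *Veillonella* — and
  M7/M8 carry modest carbohydrate pathways alongside their lactate
  pathways, as lactate-utilizing gut species also ferment sugars.
* Biomass yields default to 0.3 g/g on carbohydrates and protein, and are
  deliberately low on lactate (0.06 g/g), formate and H2; the engine
  accepts any positive yields.

All tables can be replaced: `load_parameters()` takes any manifest that
binds alternative TSVs and validates it (corner ordering, non-negative
stoichiometry, lactate use restricted to M7/M8, carbon balance), reporting
every violation at once.

## The stochastic ensemble and synthetic donors

Within each group, strains perturb $\mu_{\max}$ and $K_s$ per pathway by
independent uniform multiplicative draws within ±10%, and shift the whole
pH corner set rigidly by a uniform draw within ±0.2 pH units (the corner
set moves as one curve; yields are not varied). Initial biomass is split
equally among a group's strains. Ensembles are pure functions of the seed;
scenario replicates derive per-run sub-seeds from the master seed by
counter, so runs are order-independent and individually reproducible, and
averaged results are bit-reproducible.

Shipped donor profiles emulate the qualitative structure of three fecal
communities: `"D2"` with appreciable lactate utilizers (M7+M8 = 1.5%) and
0.6% methanogens, and `"D7"`/`"D19"` with ≤0.2% lactate utilizers and 0.1%
methanogens. They are synthetic stand-ins, constructed — not measured — and
labelled as such. `taxa_to_profile()` maps a real taxon-abundance table
onto the groups instead, using ordered exact-name rules (species before
family before phylum), redistributing unassigned taxa (e.g.
*Proteobacteria*) proportionally over the nine bacterial groups, and
overriding M10 with a qPCR-derived fraction.

What the generator does *not* emulate: OTU-level diversity, sequencing
noise, dead-cell carry-over in inocula, stereoisomer-specific lactate
chemistry (DL-lactate is one pool), dynamic pH feedback, or wall growth.
Passing tests therefore demonstrate the internal consistency and the
qualitative regime structure of the model, not quantitative agreement with
any particular fermentor run.

## Numerical choices

The stiff system (tiny $K_s$ against g/L-scale substrates) is integrated
with `deSolve::lsoda`, relative tolerance 1e-6 and absolute tolerance 1e-9
by default (configurable per scenario), sampled on a fixed 0.05-day output
grid over a 4-day horizon for run averaging. A failed integration is
retried once at 100-fold tighter tolerance before raising. Negative
excursions are clipped inside the kinetic terms only — uptake stops as a
pool empties — never in the stored state, and the dilution term pulls any
small negative excursion back; trajectories stay above −1e-9.

## Emergent behaviour and the collapse flag

Under the shipped parameters the model expresses the regime structure it
was built to study, verified end-to-end by the test suite: at pH 6.5 M1
dominates the community regardless of lactate infusion (infused lactate is
consumed by the utilizers); at pH 5.5 M1's share falls sharply and the
outcome splits on the lactate-utilizer fraction. With LUB absent, lactate
from M4 accumulates, suppresses every other group, and the community tips
into an M4-dominated state — the collapse flag in `run_lub_sweep()` marks
final lactate above 10 mM (half the high-infusion level, with zero
infusion; configurable) together with M4 dominance. With the D2-like 1.5%
LUB fraction the community stays butyrate-rich and uncollapsed. At the
4-day horizon the tip lies between 0.2% and 1.5% joint LUB fraction; the
positive feedback behind it is visible in the growth law: above a critical
lactate level the utilizers' suppressed growth rate falls below the
dilution rate, they wash out, and lactate rises unopposed.

Two further contrasts are part of the verified behaviour: removing lactate
inhibition (`regime = "none"`) materially changes the pH 5.5 outcome, and
the presence of 0.6% methanogens chiefly alters formate (which they
consume), leaving other dissolved metabolites nearly unchanged while
methane appears.

## Problem sizes

Default study conditions are 10 groups × 10 strains = 100 strains per run
and 10 replicate runs per scenario, 4 simulated days. The test suite runs
reduced replicates (1–3 runs) where a contrast is insensitive to the
run-to-run spread, and the analytic oracles (washout, relaxation,
steady-state balance) use single runs at tightened tolerances. The
acceptance script uses the full 10-run conditions.

## Known limitations

* Parameter values are plausible calibrations, not fitted estimates;
  quantitative metabolite levels should not be over-interpreted.
* The unassigned-taxon redistribution assumes unassigned organisms behave
  like the average assigned community.
* Gas pools are cumulative; no gas-phase partial pressures or
  inter-species hydrogen-transfer thermodynamics.
* The 4-day horizon matches the experiments the model emulates; longer
  horizons approach steady states the experiments never observed.
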