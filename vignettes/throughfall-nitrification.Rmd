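---
title: "Inferring nitrification in throughfall incubations from nitrate isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring nitrification in throughfall incubations from nitrate isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitritrace)
```

## The scientific problem

Rainwater that drips through a tree canopy (throughfall) carries microbes
washed off the leaf surface. If some of those microbes are nitrifiers, an
incubated throughfall sample will convert ammonium to nitrate. Concentration
changes alone are ambiguous — nitrate could be released from particles, or
analytical drift could mimic production — so the decisive evidence is
isotopic: atmospherically deposited nitrate carries a very high oxygen
isotope signature (delta-18O around +60 to +75 permil vs VSMOW), while
microbially produced nitrate assembles its oxygen mostly from ambient water
(delta-18O around -10 to -5 permil) and partly from dissolved O2. Mixing
newly nitrified nitrate into the standing pool therefore drags the pool's
delta-18O down in a quantitatively predictable way.

`nitritrace` implements that inference as a pipeline: nitrogen budgeting
across filter treatments, a two-end-member isotope mass balance, qPCR
normalization of the *amoA* marker gene for ammonia oxidizers, and a seeded
simulator that generates complete synthetic experiments with known truth.

## The mixing model

**Endmember.** During nitrification roughly two thirds of nitrate oxygen
derives from water and one third from dissolved O2. With water delta-18O in
$[w_\ell, w_h]$ and dissolved O2 at $\delta_{O_2}$,

$$\delta_{new} = \tfrac{2}{3}\,\delta_{w} + \tfrac{1}{3}\,\delta_{O_2},$$

evaluated at both water bounds. Defaults ($w \in [-10, -5]$ permil,
$\delta_{O_2} = +23.5$ permil, the atmospheric value) give an endmember
interval of $[+1.2, +4.5]$ permil. The water fraction is a parameter
(`water_fraction`, default 2/3) because communities deviating from the
canonical ratio are known.

**Mass balance.** If the pool's delta-18O moves from $\delta_i$ to
$\delta_f$ while new nitrate at $\delta_{new}$ is added (and nothing removes
nitrate), the fraction of the *final* pool that is new is

$$f = \frac{\delta_i - \delta_f}{\delta_i - \delta_{new}},$$

and the amount of new nitrate relative to the *original* pool is
$100\,f/(1-f)$ percent. Both denominators are exposed under explicit names
(`frac_new_of_final`, `new_to_original_pct`) because confusing them changes
the headline number by several percentage points. `attribute_nitrification()`
evaluates the balance at both endmember bounds and cross-checks the interval
against the observed relative increase of the nitrate concentration; the two
routes agreeing is what licenses the interpretation "the nitrate increase
*is* nitrification".

The worked example — unfiltered Cj1 throughfall, delta-18O falling from
+74.1 to +49.8 permil while nitrate rose from 219 to 332 uM:

```{r}
att <- attribute_nitrification(74.1, 49.8, nitrification_endmember(),
                               c_initial = 219, c_final = 332)
att
```

The implied delta-15N of the new nitrate is recovered by inverting the same
balance on the nitrogen isotopes; a strongly negative value is consistent
with an ammonium source (throughfall ammonium delta-15N is generally below
0 permil):

```{r}
implied_new_delta15n(6.1, -1.7, att$frac_new_of_final_low)
```

### Numerical choices and degenerate inputs

* The mass balance requires $\delta_f$ between $\delta_{new}$ and
  $\delta_i$. Analytical noise (0.59 permil SD for delta-18O) can push a
  measurement slightly past a bound; violations within 2 SD are clamped to
  the bound with a warning, larger ones are an error. This tolerates noise
  while refusing data that are not a two-source mixture.
* $\delta_{new} = \delta_i$ (no isotopic contrast) and $f = 1$ (ratio
  diverges) are errors, not NaNs.
* The consistency tolerance defaults to 2 percentage points: reporting
  values at one decimal already moves the comparison by a few tenths of a
  point, and analytical noise propagates to roughly 2 points on the
  percentage (see `mixing_pct_sd()`), so a tighter default would flag
  agreement as disagreement.
* All reported permil values and percentages are printed at one decimal;
  internal computation is unrounded.
* The delta-15N endmember is *not* predicted from first principles — there
  is no analogous atom-source rule — so the package only inverts the mass
  balance for it and checks the sign.

## Nitrogen budget and classification

`summarize_budget()` works on endpoint differences (week 0 to the latest
week with data), matching the before/after framing of incubation
experiments; rate fitting is deliberately out of scope. Ammonium measured
only at some weeks never blocks the nitrate and nitrite deltas — its delta
uses the latest determined week. Oxidized-N production is
$\Delta NO_3 + \Delta NO_2$, and production in excess of ammonium
consumption ($\Delta_{ox} - \max(0, -\Delta NH_4)$) quantifies the
contribution of mineralized organic nitrogen.

The three-way classification turns the qualitative incubation patterns into
a reproducible call. Defaults (config-exposed in `budget_thresholds()`):
*nitrifying* needs $\Delta NO_3 \ge 20$ uM **and** $\ge 10\%$ of the initial
nitrate pool (the two conditions make the call scale-aware without being
fooled by tiny absolute changes in dilute samples);
*nitrite-accumulating* needs $\Delta NO_2 \ge 5$ uM without a
nitrifying-scale nitrate gain — the fingerprint of ammonia oxidizers passing
a filter that retains nitrite oxidizers; everything else is *inactive*.
These cutoffs separate the four observed patterns (active unfiltered
throughfall; coarse-filtered fractions accumulating nitrite; weakly active
throughfall; inert rainfall) with comfortable margins on noise-free data.
Note the limitation: with 3% CV concentration noise, an endpoint difference
on a ~300 uM pool has an SD of ~11 uM, so a single noisy realization of a
scenario near a threshold can flip; classification of one experiment is a
point estimate, not a hypothesis test.

## qPCR normalization

Archaeal *amoA* copies quantify ammonia-oxidizing archaea. The chain is
copies/reaction -> copies/filter -> copies/mL (dividing by the filtered
volume). The per-reaction-to-per-filter factor defaults to the identity so
that reported per-filter totals pass through unchanged; set
`reaction_fraction` when per-reaction values need scaling by the extract
fraction loaded. Censoring against the limit of quantification (default 44
copies/reaction, boundary inclusive — the LOQ is the smallest quantifiable
value) is strict: a censored record never carries a numeric point abundance,
only the LOQ-equivalent upper bound. SDs are rescaled by the same factors;
no replicate-level error model is fitted because replicate-level data are
typically not available.

## The simulator

`simulate_incubation()` generates the statistical structure the analysis
assumes, so every stage is testable without downloads, and the ground truth
(the true new:original percentage per week) is emitted alongside the data.

**Dynamics.** Five pools — DON, NH4+, NO2-, NO3-, and immobilized N — with
first-order transfers: mineralization (`k_min`), immobilization (`k_immob`,
tracked rather than discarded so total N is conserved and assertable),
ammonia oxidation (`k_amo`), nitrite oxidation (`k_nob`), all per week. The
weekly snapshot structure mirrors a 0-4 week sampling design. Pool updates
use the exact matrix exponential of the linear rate system, computed once
per step size: nitrite oxidation must be much faster than ammonia oxidation
to reproduce the observed nitrite drawdown (`k_nob` of order 8/week vs
`k_amo` of 0.25/week), and an explicit Euler step at weekly-scale
resolution is inaccurate or unstable in that stiff regime, while the
exponential update is exact for any step size — step refinement provably
does not change the trajectory.

**Isotopes.** Newly produced nitrate carries a point endmember signature
(generation uses a point; the interval enters only at analysis time, which
keeps the truth well defined), and the pool value updates by exact
two-pool mixing each step. With a constant endmember this sequential mixing
is algebraically identical to a single injection, which is the closed form
the tests check against.

**Noise.** Concentration noise is multiplicative (CV 3% by default, how ion
chromatography precision is quoted), truncated at zero; isotope noise is
additive with the stated instrument SDs (0.59 and 0.19 permil). All
randomness flows from one integer seed in a fixed draw order, so identical
seeds give bit-identical experiments.

**Scenario presets** (`scenario_templates()`) encode the four study
conditions. Initial chemistry is the reported week-0 chemistry (174/11/219
uM NH4/NO2/NO3 for the active throughfall, 404/5/267 for the weak one, a
low-N profile summing to 59 uM for rainfall). Rates are chosen once to
reproduce the qualitative endpoint behaviour: the active unfiltered sample
(`k_amo` 0.25/week, DON 100 uM with `k_min` 0.07/week) gains ~115 uM
nitrate in 4 weeks with production exceeding ammonium consumption; the
weak sample's `k_amo` 0.004/week yields a ~11 uM gain, clearly below the
classification threshold even with measurement noise; sterile fractions
(0.2/0.4 um) have all microbial rates zero, with a small abiotic ammonium
loss (`k_immob`) reflecting the decline seen even in sterile samples.
The qPCR table is tied to activity only qualitatively — active scenarios
put quantifiable copies on the coarsest filter, inert ones stay below the
LOQ — because no quantitative copies-to-rate law is defensible from typical
data.

**What the simulator does not emulate**: Rayleigh fractionation of the
shrinking ammonium pool (the analysis is mixing-only, so simulating
fractionation would test a model the analysis deliberately does not use),
microbial growth (rates are constant, not Monod), within-treatment
replication of the water sample itself, and any coupling between noise in
different species. Passing recovery tests therefore shows the analysis is
correct *under its own assumptions*, not that real incubations satisfy
them.

## Validation harness

`recovery_study()` closes the loop: simulate n replicates, analyse each
with the interval endmember, compare the estimated interval to the truth.
Coverage is assessed against the interval widened by a tolerance whose
default is 2x the delta-method SD of the percentage under the stated
analytical precisions (`mixing_pct_sd()`) — the uncertainty actually
present in a single before/after isotope pair; the 2-point consistency
tolerance is a reporting allowance and would understate it. Under the
default noise model, 200 replicates of the active scenario give coverage
above 0.99 with bias well under one percentage point.

Problem sizes used throughout the test suite — 200-replicate recovery, 15
replicate simulations per scenario for modal classification, 10^4-draw
noise checks — were chosen as the smallest sizes at which the Monte-Carlo
error is negligible relative to the tested tolerances.

## Known limitations

* The mass balance assumes no nitrate consumption (no denitrification or
  assimilation); if nitrate were also consumed, f is biased.
* The endmember interval propagates the water range only; uncertainty in
  the O2 value and the 2/3 ratio is not modelled (set them explicitly to
  explore sensitivity).
* Endpoint-difference classification has the noise sensitivity discussed
  above.
* Censored qPCR values are bounds; no maximum-likelihood censored
  estimation is attempted.
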