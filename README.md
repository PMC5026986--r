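# nitritrace

Infers microbial nitrification in incubated throughfall (and rainfall)
samples from nitrate stable isotopes, inorganic-N budgets, and *amoA*
marker-gene abundances.

## The problem and who this is for

Tree canopies intercept atmospheric ammonium and host microbial communities;
when rain washes those microbes into throughfall and the water is incubated,
nitrate may appear. For biogeochemists the question is whether that nitrate
was *produced by nitrification* or merely redistributed. The decisive tracer
is the oxygen isotope ratio of nitrate: atmospheric nitrate is isotopically
very heavy (delta-18O ~ +60 to +75 permil), while nitrate built by microbes
takes ~2/3 of its oxygen from ambient water (delta-18O ~ -10 to -5 permil)
and ~1/3 from dissolved O2 (+23.5 permil), so freshly nitrified nitrate
falls near

    delta18O_new = (2/3) * delta18O_water + (1/3) * delta18O_O2  ~  [+1.2, +4.5] permil

Mixing new nitrate into the standing pool lowers the pool's delta-18O
predictably. With the pool moving from delta_i to delta_f, the fraction of
the final pool that is new is

    f = (delta_i - delta_f) / (delta_i - delta18O_new)

and the new nitrate amounts to `100 f / (1 - f)` percent of the original
pool — directly comparable with the observed concentration increase.

The package provides that mixing model plus everything around it: tidy-CSV
readers with validation, nitrogen budgeting and classification across filter
treatments (filtration switches specific organisms off), qPCR copy-number
normalization with limit-of-quantification censoring, a seeded simulator of
whole incubation experiments with ground truth, and a pipeline that writes a
reproducible report.

## Worked example

Unfiltered throughfall under tree Cj1, incubated four weeks: nitrate rose
from 219 to 332 uM while its delta-18O fell from +74.1 to +49.8 permil.

```r
library(nitritrace)

att <- attribute_nitrification(74.1, 49.8, nitrification_endmember(),
                               c_initial = 219, c_final = 332)
att
#> nitrate delta-18O: +74.1 -> +49.8 permil
#> endmember: [+1.2, +4.5] permil
#> new fraction of final pool: [0.333, 0.349]
#> new:original nitrate: [50.0, 53.6] %
#> concentration-based increase: 51.6 % -> consistent (tolerance 2.0 pp)
```

Reading: the isotope mass balance says 50.0-53.6 % of the original nitrate
amount was newly produced; the pool actually grew by 51.6 %, inside that
interval — the nitrate increase is quantitatively accounted for by
nitrification. The delta-15N the new nitrate must have carried,

```r
implied_new_delta15n(6.1, -1.7, 1/3)
#> [1] -17.3
```

is strongly negative, as expected for nitrate made from throughfall ammonium.

The same analysis runs end to end from CSV inputs:

```r
paths <- make_fixture("cj1_printed", "fixture_dir")   # writes the worked-example CSVs
res <- run_pipeline(list(profiles = paths[["profiles"]],
                         isotopes = paths[["isotopes"]],
                         qpcr = paths[["qpcr"]]),
                    out_dir = "run_out")
```

which writes `budget_summary.csv`, `mixing_attribution.csv`,
`qpcr_abundance.csv`, `report.txt` and a verbatim config echo. Synthetic
experiments come from `scenario_templates()` / `simulate_incubation()`, and
`recovery_study()` checks that the analysis recovers the simulator's ground
truth under the stated analytical noise. A thin command-line wrapper for
these entry points is installed at `inst/scripts/nitritrace.R`.

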