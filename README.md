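# pairtrace

Untargeted discovery of the metabolic fates of an isotope-labelled nutrient
from LC–MS feature tables.

When cells grow on a 1:1 mixture of unlabelled and fully labelled tracer —
the motivating case is cystine carrying U-¹³C,¹⁵N — every metabolite that
incorporates the tracer shows up in an untargeted feature table as a *pair*
of peaks: near-identical retention time, similar abundance, and masses
separated by the tracer shift

Δm = 3·(m₁₃C − m₁₂C) + (m₁₅N − m₁₄N) = **4.0071 Da**

per incorporated cysteine. `pairtrace` finds those pairs and strips away
everything that mimics them. The pipeline, in the order the stages run:

1. **Prefilter** — ion-count floors (>25,000 in any non-blank sample,
   >15,000 in a labelled-mix sample), fourfold-over-blank rule, 120 Da mass
   floor, and merging of duplicate features (≤50 ppm plus RT/correlation
   criteria).
2. **Pair search** — partner within 10 ppm of parent + 4.0071 and 0.25 min,
   with a labelling fraction `partner/(parent+partner)` inside 0.20–0.28
   (one cysteine, incorporation probability p ≈ 0.24) or 0.34–0.42 (two
   cysteines: 2p/(1+p) ≈ 0.39) in at least one labelled-mix sample.
3. **Artifact screen** — flag adduct satellites (≤200 ppm, ≤0.8 min against
   a configurable rule list) and natural-isotope satellites (≤200 ppm,
   ≤0.4 min, area correlation ≥0.7, area below parent); stringent filter
   (Δppm < 1.0, ΔRT < 0.06 min); cross-polarity deduplication by ion count.
4. **Annotation** — feature names like `C193_7.3`, bounded-CHNOPS formula
   enumeration for features and their implied added masses, and conjugate
   arithmetic (base + partner − leaving group) for thioether, condensation
   and hemithioacetal chemistry.

It also implements the surrounding quantitative procedures: NRF2 activation
scoring (sum of z-scored expression of nine target genes) and
dual-threshold classification, cell-volume-hour integration
N₀/(k·ln2)·(2^kT − 1), medium exchange-flux regression with overgrowth
(>300 µl·h) and 90%-depletion exclusions, proliferation rates,
response-ratio calibration (best of linear/power/quadratic), and the
M+0/M+3 detection rule for fractional labelling. A seeded synthetic
peak-list and growth-series generator provides ground truth for everything.

Functions take tibbles and return tibbles, so stages chain with the pipe;
fitted objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(pairtrace)

sim <- simulate_peaklist(sim_config(seed = 11))   # 430 features, known truth
run <- run_pipeline(sim$peaks, sim$samples)
run
#> Peak-pair tracing run
#>   input              430
#>   intensity_filter   342
#>   blank_filter       322
#>   mass_floor         322
#>   merge_duplicates   322
#>   candidates         105
#>   flagged            40
#>   stringent_pass     65
#>   final              65
#> final features: C150_13.8, C160_13.6, C160_10.9, C162_12.0, C193_4.8, ...

score_recovery(run$final, sim$truth)[c("precision", "recall")]
#> $precision
#> [1] 0.9230769
#> $recall
#> [1] 1
```

Reading the report: 430 simulated features shrink to 322 after the
intensity/blank/mass filters; the pair search finds 105 candidate pairs; 40
are flagged as adduct or isotope satellites and removed by the stringent
filter together with large mass/RT deviants, leaving 65 named features. All
60 planted fates are recovered (recall 1); a handful of noisy isotope
satellites whose area correlation fell below the 0.7 flagging gate slip
through (precision 0.92) — at zero noise both are exactly 1.

Annotating a recovered feature:

```r
annotate_features(
  tibble::tibble(feature = "C193_7.3", neutral_mass = 193.040879),
  partner_library = tibble::tibble(name = c("DHAP", "pyruvate"),
                                   formula = c("C3H7O6P", "C3H4O3")))
#>   feature  neutral_mass base added_mass feature_formula added_formula
#> 1 C193_7.3      193.041  CYS    72.0211       C6H11NO4S        C3H4O2
#>   conjugate_partner           conjugate_mode conjugate_ppm
#> 1              DHAP thioether_phosphate_loss   0.00085
```

The 72.0211 Da added mass is a sugar-like C3H4O2 addition, and the feature
mass matches cysteine + dihydroxyacetone phosphate with loss of phosphoric
acid to well under 1 ppm — the thioether conjugate chemistry.

A thin command-line wrapper over these functions ships at
`inst/cli/pairtrace.R` (subcommands `simulate` and `run`).

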