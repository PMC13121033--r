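---
title: "Isotopologue peak-pair tracing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopologue peak-pair tracing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairtrace)
```

## The problem

Targeted metabolomics can only confirm metabolite fates someone thought to
look for. When cells are fed a 1:1 mixture of unlabelled and fully labelled
tracer — here cystine carrying `U-13C,15N` — every downstream metabolite that
incorporates the tracer appears in an untargeted LC-MS feature table *twice*:
once light and once heavy, at nearly the same retention time, with similar
abundance, separated by a fixed mass shift. For one incorporated cysteine
(3 carbons, 1 nitrogen) that shift is

$$\Delta m = 3\,(m_{^{13}\mathrm{C}} - m_{^{12}\mathrm{C}}) +
            (m_{^{15}\mathrm{N}} - m_{^{14}\mathrm{N}}) = 4.0071\ \mathrm{Da}.$$

`pairtrace` searches a feature table for such pairs, screens out the ways an
LC-MS dataset fakes them (adducts, natural isotopes, duplicate features,
blank contaminants, cross-polarity duplicates), and annotates survivors with
plausible elemental compositions and conjugate chemistry. Everything runs on
plain delimited feature tables, so any upstream peak-picking tool can feed
it.

## The detection model

A candidate pair (parent P, partner Q, same ionisation polarity) must pass
three gates:

1. **Mass**: $|m_Q - (m_P + \Delta m)| \le 10$ ppm of the theoretical
   partner mass. The deviation is referenced to the theoretical mass because
   it is the difference between a theoretical and an observed mass.
2. **Retention time**: $|t_Q - t_P| \le 0.25$ min.
3. **Labelling fraction**: $f = A_Q / (A_P + A_Q)$, evaluated independently
   in each labelled-mix sample where either peak is detected, must fall in
   `[0.20, 0.28]` or `[0.34, 0.42]` in at least one sample.

The two windows encode incorporation statistics. If a single cysteine is
incorporated with heavy probability $p$, the pair fraction is $p$ itself;
empirically $p \approx 0.24$ rather than the naive 0.5, reflecting dilution
of the labelled pool by pre-existing and biosynthesised unlabelled cysteine.
A species carrying two independently drawn cysteines (such as glutathione
disulfide) splits into M+0/M+4/M+8 at $(1-p)^2 : 2p(1-p) : p^2$, so its
M+0/M+4 pair shows

$$f_{2} = \frac{2p(1-p)}{(1-p)^2 + 2p(1-p)} = \frac{2p}{1+p} \approx 0.39,$$

which is the upper window. Both windows are configurable
(`label_config()`), and the fraction definition
`partner / (parent + partner)` is what reproduces this two-window structure.

Where a parent is undetected in a sample but its partner is detected, the
fraction evaluates to 1 — outside every window — rather than erroring; the
sample simply cannot qualify the pair.

## Pre-pairing filters

Applied in order before the pair search (`filter_config()` defaults, all
from the published procedure):

| filter | rule | default |
|---|---|---|
| intensity | max area over non-blank samples, strict `>` | 25,000 counts |
| labelled intensity | max area over labelled-mix samples, strict `>` | 15,000 counts |
| blank | max non-blank area at least fold x max blank area | fold 4 |
| mass floor | neutral mass at least (one Dalton below cysteine) | 120 Da |

Boundary conventions: "over 25,000" is read literally as strict; a feature
at exactly 120 Da survives the floor ("less than 120" is removed); the
blank comparison is inclusive at exactly fourfold. Tables without blanks
skip the blank filter so that minimal fixtures and simulations work.

**Duplicate merging.** Peak pickers sometimes leave several features for one
molecule (small mass defects). Two same-polarity features are duplicates
when within 50 ppm (denominator: the smaller mass — a conservative,
symmetric choice) and either within 0.1 min, or within 0.2 min with a
Pearson correlation of per-sample areas $\ge 0.9$. Correlation uses
pairwise-complete samples and requires at least 3 of them, since $r$ is
meaningless below that. Duplicates are grouped by transitive closure (a
chain A-B-C collapses to one feature even if A and C alone would not
match); each group keeps the mass, RT and id of its largest-total-area
member and sums areas element-wise, so the per-sample total area of the
table is conserved.

## Artifact screening and stringent filtering

Candidate pairs are then cross-compared (`screen_config()`):

* **Adducts**: pair B is flagged `adduct_of:A` when B's parent mass matches
  A's parent mass plus a rule delta within 200 ppm and 0.8 min. Shipped
  deltas: Na-H, K-H, +NH3, -H2O, +HCOOH, +HCl and the dimer (expected mass
  = twice the parent). The original rule list is not printed anywhere, so
  the shipped set is a declared default, editable as a CSV.
* **Natural isotopologues**: as above with 200 ppm / 0.4 min and deltas
  +1.00336 (one ^13^C), +2.00671, +1.99580 (^34^S), +2.00425 (^18^O), plus
  two requirements that real satellites satisfy: area correlation with the
  putative parent $\ge 0.7$ and total area strictly below the parent.
* Flags accumulate and never delete rows (adduct pass first, then
  isotopologues), so a run's flag table is reproducible and auditable.

**Stringent filter.** Flagged pairs are removed; among the rest, a pair
survives only with $\Delta$ppm $< 1.0$ and $\Delta$RT $< 0.06$ min. These
cutoffs sit above the worst deviations observed for chemically verified
conjugates (0.66 ppm, 0.04 min), which is what makes them safe.

**Polarity deduplication.** A compound ionising in both modes yields two
pairs; parents matching across polarity within the pair-search tolerances
(10 ppm, 0.25 min — the procedure states none, so the pair gates are
reused) are grouped, and only the higher-total-ion-count parent survives.
Ties break toward negative mode, then lexicographic id, for determinism.

Final features are named `C<integer mass>_<RT to one decimal>`, e.g.
`C193_7.3`. The integer part is truncated, not rounded; every published
feature of this kind has fractional mass below 0.5, so the two conventions
agree there.

## Formula and conjugate annotation

`enumerate_formulas()` searches bounded CHNOPS compositions for a target
mass, solving the hydrogen count from the residual mass rather than looping
over it. Retained candidates need ring-plus-double-bond equivalents
$\mathrm{RDBE} = C - H/2 + N/2 + 1 \ge 0$ and element ratios within
plausibility screens ($0.1 \le H/C \le 6$, $N/C \le 4$, $O/C \le 3$,
$P/C \le 2$, $S/C \le 3$) — applied only when $C \ge 1$, so inorganic
leaving groups like phosphoric acid are representable. Defaults: 5 ppm for
feature masses, 10 ppm for added masses (a difference of two measured
masses carries both errors). These screens are declared defaults in the
spirit of published formula-plausibility heuristics, not a reconstruction
of any particular tool.

Conjugate arithmetic composes a base (cysteine 121.01975 Da, glutathione
307.08381 Da — both recomputed from one shared atomic-mass table, the
single source of truth for all masses in the package) with a partner mass
minus a leaving group: phosphate loss (97.97690, thioether formation from
sugar phosphates), water loss (18.01056, thiazolidine/condensation), or
nothing (hemithioacetal addition). Cysteine + pyruvate - H2O lands at
191.0252 (`C191`); cysteine + dihydroxyacetone phosphate - H3PO4 at
193.0409 (`C193`).

## Supporting quantitative procedures

* **NRF2 activation score**: per gene, expression is standardised across
  cell lines, $z = (x_i - \bar x)/\sigma_x$, and summed over nine NRF2
  target genes; classification is strict dual-threshold (Chronos dependency
  $< -0.3028$ and score $> 4.06$, the published top-quintile cutoffs, kept
  as fixed constants; `quintile_thresholds()` recomputes them for new
  cohorts).
* **Cell-volume-hours**: $\int N(t)\,dt = \frac{N_0}{k \ln 2}(2^{kT}-1)$
  per interval, with the $k \to 0$ limit $N_0 T$ taken analytically below
  $|k| < 10^{-12}$ (the expression is continuous there). Accumulation
  couples replicate wells exactly as described: each well adds its interval
  integral to the *average* accumulated value of the previous time point.
* **Exchange flux**: OLS slope of medium moles against accumulated
  cell-volume-hours, in mol per (ul h); positive = production. Points are
  excluded above 300 ul h of accumulated growth (overgrowth) or when the
  metabolite — or one linked to it, a user-supplied mapping since only one
  example (glutamate efflux upon cystine depletion) is published — is at or
  below 10% of its initial level. Replicates are pooled into a single
  regression (the per-well alternative is a trivial `group_by` away).
* **Calibration**: concentration is regressed on response ratio with
  linear, power and quadratic models; the smallest residual sum of squares
  wins, with exact ties resolved toward the simpler model (order: linear,
  power, quadratic). The published text names the three candidates but not
  the criterion; minimal RSS is the declared choice.
* **Fractional labelling** uses the detection rule: a sample contributes
  M+3/(M+0..M+3) only when both M+0 and M+3 are detected.

## What the simulator emulates — and what it does not

`simulate_peaklist()` generates a feature table with known ground truth:
one- and two-cysteine fates with exact binomial isotopologue shares, adduct
and isotope satellites emitted as full light/heavy pairs (so they reach the
candidate list and must be *caught*, not merely absent), blank-dominated
contaminants, and low-intensity noise. Defaults: 50 + 10 fates, 20 + 20
satellites, 200 noise peaks, 20 contaminants, 6 labelled-mix samples + 2
blanks, $p = 0.24$ (the midpoint of the single-cysteine window). Area noise
is multiplicative lognormal, matching ion-count behaviour.

Mass/RT jitter is modelled as *pair-differential*: each derived peak (heavy
partner, satellite) is perturbed about its theoretical position relative to
its species anchor. Co-eluting isotopologues 4 Da apart share the
instrument's calibration and elution state, so absolute (shared) offsets
cancel in every pairwise gate the pipeline applies; simulating them would
change nothing the method can see. Consequently `ppm_jitter_sd` is the
scatter of the observed pair deviation itself: at 0.5 ppm / 0.02 min the
expected survival of a true pair through the stringent gates is
$P(|N(0,0.5)| < 1) \cdot P(|N(0,0.02)| < 0.06) \approx 0.952$, and measured
recall at 60 planted fates scatters around that value.

What passing simulator tests does **not** show: robustness to correlated
(structured) RT drift, to ionisation suppression that breaks the
abundance-similarity assumption, to chimeric features from co-eluting
isobars, or to peak-picking errors upstream of the feature table. Real
datasets add all of these; the simulator validates the algorithmic
contract, not the chromatography.

Problem sizes used in the shipped tests — a few hundred features per
simulated table, twenty 100-500-feature tables for the brute-force
equivalence sweeps, 200 planted fates for labelling-fraction statistics —
are chosen so the full suite exercises every gate at meaningful multiplicity
while remaining quick to run routinely.

## Numerical choices and degenerate inputs

* All masses come from one internal atomic-mass table (AME/CODATA
  monoisotopic values); nothing is hard-coded downstream of it.
* ppm denominators: smaller mass for symmetric comparisons (duplicate
  merging, cross-polarity identity), theoretical mass where a theoretical
  value exists (pair search, satellite matching).
* Pearson branches require $\ge 3$ pairwise-complete samples and defined
  variances, otherwise the branch fails closed (no merge / no flag).
* Fractions with both areas zero are undefined and skipped, not 0/0.
* `find_pairs()` sorts by parent then partner mass; all tie-breaks
  (polarity dedup, calibration model ties) are deterministic, so a run is
  byte-reproducible for fixed inputs.
* If several partners satisfy all gates for one parent, all are emitted;
  downstream screening adjudicates rather than an arbitrary best-match
  pick.

## Known limitations

* Only the single tracer shift is searched; M+8 species are handled through
  the two-cysteine window, not as an independent gate.
* The adduct/isotope rule lists are defaults, not a reconstruction of any
  specific vendor list; unusual adducts must be supplied by the user.
* Formula enumeration is bounded CHNOPS; halogenated or metal-containing
  fates would need wider element support.
* Isobaric regioisomers (e.g. the two C193 sugar-conjugate isomers) are
  chromatographically, not computationally, distinguishable.
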