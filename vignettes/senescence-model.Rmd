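---
title: "Modeling telomere shortening and replicative senescence in budding yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling telomere shortening and replicative senescence in budding yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telosim)
```

## The model

`telosim` simulates telomerase-negative *Saccharomyces cerevisiae* cells as
agents. A haploid cell carries 16 chromosomes, hence 32 telomeres, stored
as a 2 x 16 matrix of lengths in bp. Its state is the tuple
(telomeres, type, cycle type, cycle duration, bookkeeping), where the type
is `A` or `B` and the cycle type is a normal cycle (`nor`), a non-terminal
arrest (`nta`) or a terminal senescent arrest (`sen`).

### Telomere replication

At each division the replication machinery leaves a single-stranded
overhang of `h = 7` bp on one telomere of each chromosome. Per chromosome,
a fair Bernoulli draw decides which of the two ends is shortened by `h`,
and the two daughters are coupled: the end shortened in one daughter is
inherited at the parental length by the other. Chromosomes are
independent. Lengths clamp at zero — a telomere cannot carry a negative
number of repeats (and the type-B threshold at 0 bp makes arrest certain
there anyway). A useful exact consequence: every division removes `16 h`
bp from a cell in total, so the mean telomere length of a non-arrested
clone decreases by exactly `h / 2` per generation, which the test suite
uses as an oracle.

### Arrest laws

Cell fate after division depends on the daughter's *shortest* telomere
`l` (computed after shortening) through laws of the common form
`p(l) = min(1, b exp(-a l))` for `l` above a hard threshold `l_min`, and
`p(l) = 1` at or below it. The fitted constants are:

| parameter | value | meaning |
|---|---|---|
| `a_nta`, `b_nta` | 0.02, 0.44 | non-terminal arrest law |
| `a_sen_A`, `b_sen_A`, `l_min_A` | 0.19, 0.73, 27 bp | type-A senescence (near all-or-nothing at 27 bp) |
| `a_sen_B`, `b_sen_B`, `l_min_B` | 0, 0.12, 0 bp | type-B senescence (flat: telomere-length independent) |
| `p_accident` | 0.43% | constant telomere-independent death per division |
| `p_repair` | 0.65 | per-cycle exit of an nta sequence (repair/adaptation) |
| `p_death` | 0.58 | per-cycle death exit of a senescent sequence |
| `h` | 7 bp | overhang |
| `D` | 180 min | long-cycle duration threshold |

All cells start as type A. A type-A cell divides normally until one
telomere reaches the almost deterministic 27-bp threshold and it enters
terminal senescence — or it experiences a first non-terminal arrest
(probability increasing as telomeres shorten) and becomes type B. Type-B
cells alternate between nta sequences and normal cycles, and enter
senescence with a flat per-division probability of 0.12, independent of
telomere length. Senescence is absorbing; consecutive senescent cycles
end in death with probability 0.58 per cycle (a geometric sequence
length), and nta sequences end by repair or adaptation with probability
0.65 per cycle.

### Order of competing events at one division

The transition kernel evaluates, in this fixed order: (1) accidental
death; (2) inherited senescence, with the death draw applied to each
daughter of a senescent mother independently; (3) for an nta mother,
repair/adaptation versus continuation; (4) senescence onset, then nta
onset. Two points deserve emphasis because the order is a genuine design
choice:

* a daughter that exits an nta sequence via repair is *immediately*
  subject to the type-B onset checks in the same division. This is what
  allows an nta sequence to run directly into terminal senescence with no
  intervening normal cycle. Such lineages are observationally
  indistinguishable from type A (no long cycle is ever followed by a
  normal one) and are flagged `is_M` in simulations, where the ground
  truth is known. Without this rule, hidden type-B lineages could arise
  only through accidental death during an arrest, contradicting how the
  misclassified class is defined.
* accidental death applies to every daughter, including arrested ones:
  it models telomere-independent background mortality.

The remaining order sensitivity is negligible because all per-division
probabilities are small except at the hard thresholds, where they are 1.

### Cycle durations

Durations enter only through time-resolved (population) simulations and
through the duration-based classification. They are resampled uniformly
from four empirical subdatasets keyed by (type, cycle type): normal
cycles of type-A cells, normal cycles of type-B cells, nta cycles and
senescent cycles (arrest categories pooled across types). The package
ships a generator of synthetic stand-in banks
(`synthetic_duration_bank()`): log-normal-shaped normal cycles with
median 90 min for type A (the wild-type doubling time in rich medium) and
100 min for type B, truncated below `D`; arrest cycles are `D` plus a
heavy-tailed log-normal (median excess 120 min), truncated at 1000 min.
These choices emulate the shapes of the microfluidics subdatasets; they
are configuration, not constants, and a measured bank can be supplied as
CSV.

### Observation modes

**Lineage mode** (`simulate_lineage()`, `simulate_lineages()`) mirrors a
microfluidics "mother machine": after each division one daughter is
tracked, chosen uniformly. Generation 0 is the cell present at telomerase
inactivation; it completes one cycle before the first division, and fates
are first evaluated on generation-1 daughters. A lineage is classified
from durations only, as an experimentalist would: a cycle is long if its
duration is at least `D = 180` min, and the lineage is observed type B iff
some long cycle is later followed by a normal cycle.
`arrest_generation_curves()` assembles the sorted per-lineage generations
of first nta and first senescence (overall and by observed type), the
summary used for calibration.

**Population mode** (`run_population_experiment()`) keeps both daughters.
Each cell divides at its birth time plus its sampled duration; the
simulation is event-driven (a binary heap over division times, implemented
in C++) and exact — no time discretization. The daily culture protocol:
`N_init` founders, growth frozen as soon as the living count reaches
`N_sat = r_sat * N_init`, dilution every 24 h to `N_dil = N_init` cells
sampled uniformly without replacement. Frozen cells retain their
remaining cycle time and resume at dilution; cells mid-cycle at an
ordinary dilution simply keep their schedule. Dead cells are removed
immediately. The end-of-day count is taken at the dilution instant,
pre-dilution. The half-saturation time (HSL) — the package's summary of
population senescence rate — is the time at which the end-of-day count
first falls to `N_sat / 2`, linearly interpolated between adjacent days.

### Initial telomere lengths

All 32 telomeres of every founder are i.i.d. from a distribution
`f_init`, constructed from a base distribution by two mode-preserving
dilations and a translation: the left support segment
`[l_inf, l_mode]` is mapped linearly onto `[l_inf + l_0, l_mode]`, the
right segment `[l_mode, l_sup]` onto `[l_mode, l_mode + l_1]`, then
`l_trans` is added. Fitted values: `l_0 = 40`, `l_1 = 58`,
`l_trans = 0`. The equilibrium length distribution of a
telomerase-positive population is not shipped with the package; the
default base is a synthetic stand-in — a scaled Beta density on
`[100, 500]` bp with mode 300 bp and concentration 4 (raw SD about 76
bp), values a yeast telomere biologist would call typical for wild-type
W303-background strains. Sampling is by inverse CDF, so runs with equal
seeds and different translations are exactly coupled, which the paired
perturbation scans exploit. A measured sample (one bp per line) can
replace the parametric base.

What the stand-in does *not* emulate: the true equilibrium distribution's
left tail, which is poorly characterized experimentally and to which
lineage dynamics are most sensitive. Population-level results that hinge
on the precise left tail — absolute HSL values, the high quantiles of
type-B onset lengths, the exact magnitude of translation effects — should
therefore be read as properties of the stated stand-in, not of any
particular strain. Structural results (threshold signature of type-A
onsets, type-A-to-type-B succession, hidden senescent fraction, direction
and rough magnitude of perturbation effects) are robust to it.

## Perturbation scans

`run_translation_scan()`, `run_left_tail_scan()` and
`run_mortality_scan()` re-run the population experiment while varying one
knob — the global translation `l_trans`, the left-tail dilation `l_0`, or
a multiplier on `p_accident` — with replicate seeds shared across
conditions, so per-replicate HSL differences isolate the parameter
effect; the control condition is always included. The mortality scan's
lineage mode mirrors the microfluidics setting instead (the rad51
deletion corresponds to 5.4% constant mortality, conventionally assessed
as 1000 virtual experiments of 11 lineages).

## Calibration

`fit_parameters()` infers the ten free parameters
(`a_nta`, `b_nta`, `a_sen_A`, `b_sen_A`, `a_sen_B`, `b_sen_B`,
`l_min_A`, `l_min_B`, `l_0`, `l_1`) by CMA-ES against target
arrest-generation curves, minimizing `curve_cost()`: the mean squared
difference of quantile-matched sorted curves per category plus a
squared-difference penalty on the observed type-B proportion. The exact
cost used in the original calibration of the laws is not public, so this
default is the package's own and the interface is pluggable.

Design choices that matter on this landscape, all validated on held-out
synthetic targets with known truth:

* **Coordinate warping.** The search runs in `[0, 1]^10`; rate
  coordinates (`a_*`) are cube-warped because any rate above ~0.1/bp acts
  as a hard threshold at realistic lengths — a linear box wastes most of
  its volume on that degenerate mimicry regime, which traps the search.
* **High-fidelity evaluations.** Each candidate simulates 600 lineages
  once, rather than averaging repeats of small batches: false local
  minima created by evaluation noise are the dominant failure mode.
* **Population size.** Lambda = 14 (above Hansen's default 10); larger
  populations escape the mimicry minima reliably.
* Thresholds are optimized continuously and rounded to integer bp at the
  end. The fit is bit-for-bit reproducible given its seed.

**Known identifiability limit.** Fitting to duration-derived curves alone
cannot anchor absolute lengths: raising `l_0` (which raises every
shortest-telomere trajectory) while rescaling the `b` scales by the
matching exponential factor and shifting `l_min_A` leaves all
arrest-generation distributions nearly unchanged. Absolute length
parameters such as `l_min_A` are therefore constrained only by
second-order shape effects of the initial-length order statistics, and a
recovered threshold should carry an uncertainty of roughly the overhang
scale or more; the degenerate type-B law (`a_sen_B` near 0) *is*
reliably recovered. In the
original experimental setting the degeneracy is broken by independent
telomere-length measurements that anchor the initial distribution.

## Numerical and implementation notes

* Randomness flows exclusively through R's generator, including inside
  the C++ engine, so any run is replayable from `set.seed()`; top-level
  protocols derive per-replicate seeds as `seed + i`, shared across scan
  conditions.
* The statistical mode of the pooled telomere-length distribution breaks
  ties toward the smaller length, so day-over-day mode comparisons are
  deterministic.
* Transformed initial lengths are rounded half-up to integer bp;
  shortening is integer; the mode statistic needs the discrete support.
* Lineage simulations carry a safety cap (default 200 generations);
  reaching it flags the record as truncated and signals immortal
  parameter settings rather than silently looping.
* An extinct population ends its run early with snapshots up to the
  extinction day; the HSL of a culture that never falls below half
  saturation is right-censored (`NA` with a `censored` attribute).
* Empty curve categories are skipped (target side, with a warning) or
  scored against a zero curve (candidate side), keeping the cost defined
  for degenerate regimes.

## Problem sizes

The shipped checks use 1000 lineages for lineage-level statistics, ten
replicate population experiments at `N_init = 300`, `r_sat = 1000` (3 x
10^5 cells at saturation, roughly 2-3 million division events per run)
for population-level statistics and paired scans, and a single
3000-evaluation fit against a 2000-lineage synthetic target for recovery
validation. These sizes put Monte-Carlo error comfortably below the
tolerances they are compared against while keeping a full reproduction on
one desktop core in the tens of minutes.

## Limitations

* Post-senescence survivors (telomerase-independent telomere
  re-lengthening) are outside the model's scope; simulated and real
  cultures are expected to diverge once survivors become demographically
  visible, typically after the first four to five days.
* Saturation is a hard count cap, not a nutrient model; mother-daughter
  asymmetry in cycle durations is not modeled.
* One threshold per law: chromosome-end-specific critical lengths are
  not represented.
* The synthetic stand-ins for the initial length distribution and the
  duration bank are calibrated to published summary features, not to any
  dataset shipped with the package (see above for which conclusions this
  does and does not affect).
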