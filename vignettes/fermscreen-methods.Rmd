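---
title: "Methods: kinetic screening analytics and the diauxic fermentation simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic screening analytics and the diauxic fermentation simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermscreen)
```

# The screening problem

Adaptive-evolution campaigns on pentose-fermenting yeasts such as
*Scheffersomyces stipitis* produce tens to hundreds of single-colony
isolates that must be ranked on messy, sparsely sampled fermentation
time courses across several lignocellulosic hydrolyzates. Two traits
drive industrial value: the **ethanol yield per initial sugar**
(g ethanol per g of total sugar supplied at inoculation) and the
**xylose uptake rate** (g/L/h over the xylose-consumption phase), the
latter because native strains suffer a *diauxic lag* — xylose
utilization is repressed until well after glucose is gone, and the
repression deepens as ethanol accumulates beyond roughly 15 g/L.

`fermscreen` implements the full analytics chain for such screens:
per-run kinetic feature extraction, a composite z-score ranking
(Relative Performance Index, RPI) across media, selection diagnostics,
factorial ANOVA with Student–Newman–Keuls (SNK) letter displays, and a
mechanistic simulator that generates screen-shaped data with known
ground truth so the chain is testable end to end.

# Kinetic feature extraction

A run is a `timecourse`: daily (or finer) samples of 620-nm absorbance
and concentration channels in g/L. Internally all absorbance is held in
reference-cuvette units (microplate readings are divided by 0.438 at
ingest) and biomass is 0.167 g/L dry cells per absorbance unit.

**Phase segmentation.** The glucose phase runs from inoculation to the
first sample with glucose below a depletion threshold (default 1 g/L,
configurable). The xylose phase starts at the first post-depletion
sample where xylose has fallen more than a noise threshold (default
2 g/L) below its running maximum — the running-maximum rule prevents
multiplicative measurement noise from triggering a phantom onset — and
ends at xylose depletion or the last sample. The diauxic lag is the gap
between the two; it is *undefined*, not zero, when xylose is never
consumed, and undefined values propagate as missing into the ranking
rather than being imputed.

**Estimators.** Rates are least-squares slopes of concentration versus
time over the detected phase, floored at zero. With daily sampling a
maximum two-point slope is noise-dominated; the regression slope is the
minimum-variance linear estimate and reproduces smooth orderings across
strains. Normalized rates divide by the arithmetic mean absorbance over
the phase. Overall ethanol productivity is peak ethanol over
time-to-peak (ethanol can decline after its maximum, so end-of-run
values would understate fast strains). Yields are peak product minus
initial product per total initial sugar, where "total initial sugar"
sums all six monosaccharide channels at the first sample. The maximum
specific growth rate is the steepest slope of log absorbance over any
window of at least three consecutive samples (exhaustive scan), which
recovers the generating rate exactly on a clean exponential. Lag time
is the linearly interpolated crossing of a fold-change (default 2x) of
the initial absorbance. Missing cells are skipped pairwise throughout;
nothing is interpolated or smoothed, and no parametric growth model
(Gompertz, Baranyi) is fitted — with 6–12 samples per run those models
add variance without adding information.

# RPI ranking

Within each (medium, trait) group across isolates, an observation
$X$ is scored as $F = (X - \bar X)/s$ with the sample ($n-1$) standard
deviation, then mapped to $\mathrm{RPI} = (2 + F) \times 100/4$, so a
group-average strain scores 50 and scores nominally span 0–100.
Replicates are averaged to one value per isolate before scoring (a
switch allows replicate-level scoring). Scores are deliberately **not
clamped** to [0, 100]: extreme strains land outside the nominal range,
and clamping would hide exactly the instability the dispersion
diagnostics exist to reveal.

Per-medium RPI is the (optionally weighted) mean of the yield and rate
components; the overall RPI is the mean of all $2n$ components across
the $n$ media. The dispersion $s$ is the sample standard deviation of
those same components and $\mathrm{Rel.}\,s = s/\mathrm{RPI_{overall}}
\times 100$; a strain ranked high with large Rel. s owes its rank to
one favourable environment. Ranks sort by descending overall RPI with
ties broken by ascending Rel. s, then lexically. Superior strains
require overall RPI > 60 with Rel. s < 40%; media where a strain's
per-medium RPI exceeds 55 are listed as its specialist media.

Two exact invariants are tested: the mean RPI across isolates in any
group is exactly 50, and all scores, ranks and reports are invariant
under positive affine rescaling of the trait values within a group —
so unit changes or calibration drifts common to a whole group cannot
reorder strains. Strains missing any (medium, trait) component are
excluded from the overall ranking and logged, rather than silently
renormalized over fewer media, because a missing medium usually means
the strain failed there.

# ANOVA and SNK letters

`screen_anova()` fits fixed-effects models of 1–3 factors through
`stats::lm`, reporting marginal (Type-II) sums of squares via
`car::Anova` for factorial designs — the conventional choice when the
isolate-by-medium interaction is itself of interest and the design may
be unbalanced. `snk_letters()` implements the Student–Newman–Keuls
step-down: level means are sorted, each range of span $p$ is tested
against the studentized-range quantile $q_{1-\alpha}(p, \nu)$ (computed
numerically with `stats::qtukey`, not from tables), unequal sizes use
the harmonic mean of the pair's sizes, and a non-significant range
protects all nested ranges, which keeps the letter display coherent.
Letters are maximal homogeneous intervals in the mean ordering; the
test suite verifies them against a brute-force maximal-clique oracle on
up to 8 levels. Zero residual variance degenerates to "all distinct
means differ", rather than an error.

# The simulator

The generator exists to produce data with the structure the analysis
assumes — with known ground truth — not to model cell physiology. One
run integrates six states (biomass, glucose, xylose, ethanol, xylitol,
and a xylose induction state $I \in [0,1]$) with a fixed-step
fourth-order Runge–Kutta scheme (step 0.1 h, compiled) and samples the
trajectory with multiplicative Gaussian noise (CV 3% by default,
truncated at zero) under a mandatory seed; identical seeds give
identical output, byte for byte.

The mechanisms, each anchored to screen phenomenology:

* Monod uptake of each sugar by biomass; xylose uptake and growth on
  xylose are gated by $I$.
* $I$ rises first-order (default 0.04/h) only once glucose is below
  1 g/L, at a rate linearly repressed by ethanol between a threshold
  (15 g/L for a parent-like strain) and a ceiling (50 g/L, full block).
  This produces the diauxic lag and its deepening with ethanol. The
  linear shape between threshold and ceiling is a modelling choice;
  only "progressive repression" over that range is empirically
  anchored.
* Ethanol is produced at a fixed yield (default 0.41 g/g, ceiling
  0.511) on *all* sugar consumed, so ethanol plus yield-weighted
  remaining sugar is conserved by every integrator stage and the mass
  balance is exact on noise-free runs; a small xylitol fraction
  (default 0.02 g/g of xylose) is diverted.
* Acetic acid multiplies the growth rate by $\max(0, 1 - k\,c)$ with
  slopes calibrated so growth at 15 g/L is 79% of uninhibited on
  glucose and 68% on xylose.
* Furfural imposes a dormancy (no growth, no uptake) of 37.6 h at
  25 mM for the parent, scaled linearly with concentration.
* Growth (not fermentation) stops as ethanol approaches 35 g/L and as
  biomass approaches a nitrogen-limited ceiling (default 5 g/L dry
  cells, about absorbance 30): hydrolyzates are nitrogen-poor, so real
  cultures stop growing long before sugars are exhausted while ethanol
  keeps accumulating. Without the ceiling, simulated cultures reach
  absorbances several-fold above anything a hydrolyzate supports.

Default uptake capacities (0.54 and 0.14 g sugar/g cells/h for glucose
and xylose) correspond to typical hydrolyzate-fermentation normalized
rates of 0.09 and 0.023 g/L/h per absorbance unit. On a defined
75 + 75 g/L glucose–xylose medium the parent defaults put ethanol near
30 g/L at the moment of glucose depletion — deep inside the repression
band, which is what makes the parent's diauxic lag long.

**Cohorts.** `make_cohort()` draws strain-to-strain parameter spreads
log-normally (CV 10%) around the parent defaults and plants superior
strains carrying (i) a 1.3x multiplier on xylose uptake capacity *and*
growth on xylose — in xylose-rich media fermentation is
growth/induction-limited, so a transport-only multiplier would not
express as a faster measured uptake rate — and (ii) an ethanol
repression threshold raised to 40 g/L (reduced diauxic lag). The
default screen ferments 30 isolates on three hydrolyzates in duplicate
and harvests at 144 h (six days of daily samples). The harvest time
matters: it is chosen so that baseline strains are still mid-xylose at
harvest, leaving residual xylose of roughly 0.1–0.3 g per g initial
sugar. That is what couples yield-at-harvest to the rate phenotype; a
screen run to completion would let every strain converge to the same
yield and the yield trait would carry no ranking information.

**What the simulator does not emulate.** No pH or temperature dynamics,
no CFU-level viability loss, no ethanol re-consumption after sugar
exhaustion (off by default), no nutrient chemistry beyond the biomass
ceiling, and no genetics of the adaptation process itself. Passing the
recovery tests therefore shows the *analytics* are sound on data with
this structure; it does not validate any claim about particular real
strains.

# Validation experiments the package runs on itself

* Kinetic estimators against closed-form and enumeration oracles
  (pairwise-slope identity for regression slopes; exhaustive window
  scan for growth rates), and against simulator ground truth
  (segmentation within one sampling interval of the true switch times;
  growth rate within 5% and phase rates within 10% on noise-free runs).
* SNK letters against the brute-force clique oracle; two-level SNK
  against the pooled t test, to which it is algebraically equivalent.
* One-way ANOVA type-I error near its nominal 5% over 1000 null
  simulations.
* End-to-end recovery: on 30-isolate cohorts with 5 planted superior
  strains, the ranking places at least 4 of the 5 in its top 6 in at
  least 80% of 20 seeds (typically ~90%). Recovery is not 100%, and
  should not be: with 10% parameter spread a planted strain
  occasionally draws a phenotype that genuinely is not superior, and a
  screen can only rank phenotypes.

Problem sizes in the tests (cohorts of 8–30 isolates, 2–3 media, 144 h
runs, 1000-rep null simulations) were chosen as the smallest sizes at
which these properties are statistically meaningful.

# Known limitations

* The exact windows and estimators behind historically reported kinetic
  tables for such screens are rarely published; numeric reproduction of
  any specific published table is out of scope, and the package instead
  guarantees internally consistent, oracle-checked estimators.
* The dispersion statistic `s` is defined here as the standard
  deviation of the 2n components entering the overall RPI; other
  published usages are ambiguous about replicate handling.
* Type-II sums of squares are one defensible convention for unbalanced
  factorial screens; commercial packages differ, so letter displays on
  unbalanced data need not match any particular program's output.
* RPI carries no multiple-testing control and no confidence intervals;
  it is a screening heuristic, and the ANOVA/SNK stage is the
  inferential complement.
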