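---
title: "Functional growth modeling and temporal QTL mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional growth modeling and temporal QTL mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the statistical machinery it
implements: the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generator does and does not
emulate. The numbered scripts under `analysis/` in the source repository
run the whole workflow; `run_pipeline()` does the same from one
configuration object.

## The problem

Drone (UAS) surveys of a field trial yield plot-level canopy height on a
handful of flight dates through the season. For mapping populations —
here recombinant inbred lines (RILs) from biparental maize crosses — this
turns plant height from a single end-of-season measurement into a
trajectory, and quantitative trait locus (QTL) mapping from a single scan
into a scan per day. The pipeline has five statistical stages:

1. **Canopy metrics**: reduce a 3D point cloud to per-plot percentile
   heights (P95 by default) above an interpolated ground surface.
2. **Per-flight mixed models**: separate genetic from design and spatial
   variance and extract entry BLUPs.
3. **Growth curves**: fit a three-parameter Weibull sigmoid per entry and
   impute daily heights on 1–85 days after sowing (DAS).
4. **Linkage map**: clean and bin the SNP genotypes, estimate the Kosambi
   genetic map.
5. **QTL scans**: inclusive composite interval mapping (ICIM-ADD) per
   functional parameter and per imputed day, clustered into temporal QTL.

## Per-flight mixed model

For one flight date, environment and population, with entries laid out in
a randomized complete block design (RCBD) with range/row spatial
structure,

$$Y_{ijkl} = \mu + G_i + Rep_j + Range_k + Row_l + \varepsilon_{ijkl},$$

with all terms random and independent. `fit_reml()` estimates the five
variance components by REML (via lme4), reports the percent-of-total
decomposition, the entry BLUPs, and the entry-mean heritability

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_\varepsilon / r},$$

with $r$ the number of replicates. Components estimated at the zero
boundary are reported as zero and flagged rather than the model being
refit without the term. One numerical special case: on exactly noise-free
data (which the simulator can produce) the profiled REML criterion is
flat as $\sigma^2_\varepsilon \to 0$ and the optimizer's split of variance
is arbitrary; entry-only models detect this and return the
method-of-moments limit ($\hat\sigma^2_G$ = variance of entry means,
unshrunk BLUPs). Group-mean comparisons use Fisher's LSD at
$\alpha = 0.05$ with deterministic greedy letter assignment on the
descending-sorted means.

## The Weibull growth curve

Height as a function of DAS $x$ is modeled as

$$f(x) = L\,\bigl(1 - e^{-(x/x_0)^b}\bigr),$$

with asymptote $L$ (m; terminal height), inflection-point parameter $x_0$
(DAS) and unitless shape $b$. Unlike the logistic, the inflection is not
pinned to $L/2$, which suits maize's asymmetric growth; at $x = x_0$ the
curve passes through $(1 - 1/e)\,L \approx 0.632\,L$.

Fitting is bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with starts $L_0 = \max(h)$, $x_{0,0}$ = first time
the trajectory exceeds $L_0/2$, $b_0 = 5$, and bounds
$L \in (0, 3\max(h)]$, $x_0 \in (0, 200]$, $b \in (0.5, 30]$. Constant
trajectories are flagged as non-fits rather than fit. Family comparison
(`select_growth_model()`) fits Weibull, Logistic, Gompertz and
Probit-type sigmoids and ranks them by AICc; exact ties break by that
fixed family order and are flagged.

The absolute growth rate (AGR) is the calculus derivative,

$$f'(x) = L\,\frac{b}{x_0}\Bigl(\frac{x}{x_0}\Bigr)^{b-1}
e^{-(x/x_0)^b},$$

reported in mm/day and verified against central finite differences in
the tests. Its argmax is $x_0\,((b-1)/b)^{1/b}$, about 2% below $x_0$ at
$b = 7$; because field studies conventionally quote the maximum AGR at
$x = x_0$, `agr_max()` reports the convention value as the headline and
the exact argmax alongside.

**Goodness-of-fit filter.** Poor fits are removed before imputation. With
noise variance $\sigma^2$ (taken from the REML residual of the BLUP
stage, scaled by replicates), $RSS/\sigma^2$ has expectation $n - p$
under an adequate model; the standardized excess
$z = (RSS/\sigma^2 - (n-p))/\sqrt{2(n-p)}$ is squared and referred to
$\chi^2_1$ at $\alpha = 0.05$. The test is one-sided (only excess misfit
drops an entry) and a statistic exactly at the critical value keeps the
fit. This statistic is a documented, swappable choice — the filter's
contract is only that gross misfits do not feed the daily scans.

Daily heights are the fitted curve evaluated on integer DAS 1–85,
exactly 85 values per entry.

## Linkage map construction

Genotypes are coded 0/2 for the parental homozygotes, 1 het, −1 missing.
QC drops lines then markers with more than 10% missing (strict
inequality). Residual het calls — about 3% at F6, the generator's
default, $\approx (1/2)^5$ — are set missing, and all analysis uses the
two homozygous classes.

**Double-recombinant cleaning.** Single-locus genotyping errors appear as
short genotype "islands" implying two crossovers within a few markers,
which interference makes vanishingly rare at sub-cM marker spacing. Along
each line, homozygous runs shorter than a minimum region (0.1% of the
chromosome's cM length, and fewer than `min_run_markers` markers) are
absorbed into their flanking runs — true islands (equal-valued
neighbors) first, since flipping them is unambiguous — until all runs
meet the minimum. Breakpoints between surviving runs are reported at the
midpoint of the bounding marker interval. At the package's default map
density (~0.7 cM spacing) a 3-marker minimum run is appropriate: a true
sub-3-marker run would require a double crossover within ~1.5 cM. The
tests compare the heuristic against an independent dynamic-programming
segmentation oracle (minimize mismatches plus a per-breakpoint penalty).

**Binning and map estimation.** Markers whose non-missing calls agree on
every shared line are binned; the representative has the fewest missing
calls (ties to the smallest physical position). Marker order is fixed by
physical position. Adjacent-pair recombination is estimated as the
recombinant fraction $R$ among homozygous-informative lines (capped at
0.4999 and flagged), converted to the meiotic fraction by inverting the
selfed-RIL expectation $R = 2r/(1+2r)$, and to map distance by the
Kosambi function $d = 25\,\ln\{(1+2r)/(1-2r)\}$. The same RIL-scale
Markov model is used end to end — simulator, map construction and
genotype probabilities — a deliberate internal-consistency choice.

## ICIM-ADD genome scans

Scan positions are every 1 cM plus every marker. Conditional
probabilities of the two homozygous classes given the nearest informative
flanking markers come from the two-state Markov chain with transition
probability $R$ over each interval; lines with no informative flank get
the (0.5, 0.5) prior. The scan core is Haley–Knott regression of the
phenotype on the expected additive score $P(BB) - P(AA) \in [-1, 1]$:

$$LOD = \frac{n}{2}\log_{10}\frac{RSS_0}{RSS_1},$$

with the additive effect the regression slope (half the difference
between homozygous class means; positive = parent-B allele increases the
trait) and PVE $= 1 - RSS_1/RSS_0$. For RIL populations with two
homozygous classes this is near-identical to the EM normal-mixture scan
and exactly equals single-marker regression at fully informative markers
(asserted in the tests to 1e-8).

ICIM's background control first runs forward–backward stepwise regression
of the phenotype on all (mean-imputed) marker scores with entry
probability PIN = 0.001 and removal probability POUT = 2·PIN, then scans
each interval with the phenotype adjusted by the selected markers
*excluding that interval's flanks*. When nothing enters, the scan reduces
exactly to plain interval mapping. POUT and the mean-imputation rule are
defaults of this package (the published ICIM constants beyond PIN are
tool-specific).

**Calling.** QTL are peaks with LOD > 2.0 and PVE ≥ 3% — deliberately
liberal, matching a temporal-trends analysis rather than
marker-assisted-selection confidence. Two same-chromosome peaks are
distinct calls when separated by a dip below the LOD threshold, or by
≥ 20 cM with an intervening valley at least 1 LOD below the smaller peak.
The prominence clause is this package's refinement: without it, sampling
wiggles on the shoulder of one strong peak (whose LOD can sit above
threshold across half a chromosome) are called repeatedly. Support
intervals are the contiguous region within 1 LOD of the peak; names
follow `q{chrom}_{rounded peak cM}`.

A practical note visible in the tests: with two strong linked QTL, plain
interval mapping shows a "ghost" ridge between them; the ICIM adjustment
removes it. This is the textbook motivation for composite methods and the
reason the daily scans default to ICIM.

## Temporal QTL

Scans run once per imputed day (1–85 DAS). Daily calls are clustered per
chromosome by single linkage on peak position with a 10 cM window, then
split in time where more than 2 consecutive non-significant days
intervene. Onset/offset are the first/last significant day (same
LOD/PVE rule as calling); the consensus peak is the LOD-weighted mean of
member peaks; full-season LOD/effect/PVE trajectories are read off at
the scan position nearest the consensus peak, including sub-threshold
days. A QTL "switches sign" only when its additive effect changes sign
between two days on both of which it is significant. Cross-trait
co-localization pairs QTL within 10 cM on the same chromosome;
candidate-gene proximity is the bp distance from the physical center of
the support interval to the nearest gene span on the same chromosome
(zero inside the span), with counts within 1 and 5 Mbp. The clustering
window, gap bridge and thresholds are exposed in `pipeline_config()`.

## Canopy metrics

Ground classification is a transparent two-step: seed the ground set with
the lowest point per grid cell, then iteratively fit a plane by least
squares and re-classify points within a vertical tolerance of the
surface as ground. The DEM is a grid of node elevations from the fitted
plane, bilinearly interpolated per point; the canopy height model is
point elevation minus DEM. Per-plot heights are percentiles (default the
95th) of normalized heights inside the plot rectangle
(min-edge-inclusive), using linear interpolation between order
statistics — stated explicitly because percentile conventions differ.
This stage intentionally replaces a photogrammetry-specific hierarchical
interpolation with the simplest classifier that honors the same
downstream contract (correct normalized heights over gently varying
terrain); steep or strongly curved terrain would need a cellwise or TIN
surface instead of a plane.

## The synthetic-data generator

The generator emulates the study conditions: three RIL populations of
102, 237 and 178 lines; 10 chromosomes with total map lengths ~1,315,
1,207 and 1,474 cM at ~0.7 cM marker spacing (binned-SNP density); two
environments (irrigated / non-irrigated) × two replicates in an RCBD
with range/row effects; eight flights at 35, 43, 57, 62, 65, 69, 100,
117 DAS.

Genotypes follow a per-chromosome two-state Markov chain with the
selfed-RIL transition probability $R = 2r/(1+2r)$, $r$ from inverting
Kosambi on the marker spacing — matching the F6+ expectation directly
rather than simulating generations (an explicit-meiosis oracle backs
this in the tests). Residual het is injected at 3%. Crossover
interference beyond Kosambi's implicit level is not modeled, so very
tight true double recombinants occur at low Markov rates — one reason
the cleaning stage quotes its guarantees at realistic marker density.

Phenotypes: each entry's $(L, x_0, b)$ = population means (1.10 m, 58
DAS, 7 — mid-range for irrigated maize inbreds) + environment shift
(non-irrigated: −5 cm on $L$, +2 DAS on $x_0$, −0.8 on $b$, the
direction of water stress) + additive QTL effects at linked markers +
polygenic deviations (sd 0.05 m, 2 DAS, 0.5). QTL effects default to the
magnitudes seen in maize RIL trials: 2–5 cm on the asymptote, 0.2–0.5
DAS on the inflection, 0.2–0.3 on the shape; an optional
`param = "height"` locus acts directly on height inside a DAS window —
an "opportunistic" locus a temporal scan should localize in time. Plot
heights add replicate/range/row effects (sd 0.01/0.015/0.01 m) and
per-flight noise (sd 0.03 m), and a recorded `SyntheticTruth` carries
every draw for recovery tests. Under these defaults the genetic share of
per-flight variance runs high (around 80% mid-to-late season in the
analysis scripts' output) — cleaner than a real field study, where
photogrammetric error, weather and flight-quality variation dilute the
genetic signal; the generator's noise terms model only the design-level
sources.

What the generator does **not** emulate — and hence what green tests do
not show about real data: photogrammetric height bias (real UAS
asymptotes sit ~0.5 m under manual terminal heights; the correlation
stage models this as a constant offset plus noise), weather-driven
growth fluctuation within a season, genotype-by-environment interaction
beyond a mean shift, spatial autocorrelation beyond range/row main
effects, segregation distortion, and non-random missingness in
genotyping.

## Problem sizes and determinism

The analysis scripts run all three populations, both environments and
all 85 days at the defaults above (a few minutes end to end on one
core); the tests exercise the same code on one- or two-chromosome
designs with 40–237 lines, and the heavier recovery suites use 100–200
replicate simulations. Every stochastic entry point takes a seed; a
fixed seed reproduces every output byte-for-byte, and each output table
carries its seed in `#` metadata header lines.

## Known limitations

- The ground model is a single plane per cloud; fields with real relief
  need a finer DEM.
- Stepwise background selection uses F-test p-values with no multiplicity
  control beyond the stringent PIN; it is a background-control device,
  not an inference on the selected markers.
- The LOD > 2.0 threshold is not a genome-wide error rate; permutation
  thresholds are out of scope by design.
- Onset/offset of temporal QTL inherit the liberal calling rule: at low
  power the detected window underestimates the true activity window.
- Map estimation assumes the physical marker order is correct; no de
  novo ordering is attempted.
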