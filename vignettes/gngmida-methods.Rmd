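---
title: "Measuring fractional gluconeogenesis by heavy-water MIDA: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fractional gluconeogenesis by heavy-water MIDA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gngmida)
```

## The measurement problem

Endogenous glucose production draws on two sources: breakdown of liver
glycogen (glycogenolysis, GGL) and synthesis from non-sugar precursors
(gluconeogenesis, GNG), the latter with two arms — the PEPCK route from
pyruvate/oxaloacetate and the glycerol route entering at the
triose-phosphates. After heavy-water (^2^H~2~O) labeling, each route leaves a
distinct deuterium signature on blood glucose because each passes a different
number of enzymatic steps that exchange C–H hydrogens with solvent water:

* PEPCK-GNG labels all seven non-acidic positions (n = 7),
* glycerol-GNG labels C-5 (triose-phosphate isomerase) and C-2
  (phosphoglucose isomerase), n = 2,
* glycogenolysis labels only C-2, n = 1.

GC-MS of the glucose methoxyamine-pentaacetate derivative (positive chemical
ionization, fragment C~15~H~22~N~1~O~9~ monitored at m/z 360/361/362 as
M+0/M+1/M+2) measures the *mass*-isotopomer pattern — how many labels a
molecule carries, not where they sit. Mass isotopomer distribution analysis
(MIDA) turns that pattern into pathway fractions.

## The generative model

For a population produced through a pathway with `n` exchangeable sites at
body-water enrichment `p`, the number of deuterium labels is binomial:
the probability of `k` labels is `choose(n, k) p^k (1-p)^(n-k)`. The observed
spectrum is this label distribution convolved with the fragment's
natural-abundance isotopologue pattern, itself the convolution of every
atom's isotope distribution (`natural_isotope_pattern()`).

Fractional abundances over the monitored window give the *excess*
enrichments
`EM_x = A_x(labeled) − A_x(baseline)`, and the core observable is their
ratio `R = EM2/EM1`. Two properties carry the whole method:

* **Linearity.** Excess enrichments of a molecule-level mixture are the
  weight-weighted sums of the component enrichments, so for a GNG/GGL
  mixture `R` is a ratio of linear forms in f(GNG), strictly increasing, and
  invertible in closed form (`mixture_ratio()`, `invert_fgng()`).
* **Dilution immunity.** Mixing in unlabeled glucose (diet-derived) scales
  EM1 and EM2 by the same factor and cancels from `R` exactly — the package
  demonstrates this to 1e-9 under 80% dilution.

Total GNG is modeled as two-thirds PEPCK (n = 7) plus one-third glycerol
(n = 2); for table generation this mixture is approximated by a homogeneous
n = 6 population. A measured `R` at measured `p` then yields f(GNG) either
by exact root finding or by the bench lookup-table route
(`tabular_fgng()`: locate `R` in the two bracketing 0.5% rows of the table
and average — adequate between rows, and noticeably coarser than exact
recomputation, which programmatic use should prefer).

```{r table}
model <- mida_model(calibrate = TRUE)
head(mida_table(model = model)[, 1:6], 3)
```

## Numerical conventions

**Isotope constants.** Defaults are IUPAC representative abundances
(^13^C 0.0107, ^2^H 0.000115, ^15^N 0.00364, ^17^O 0.00038, ^18^O 0.00205).
The reference lookup table pins the unlabeled baseline through its f = 0
column (0.173155, the p-independent excess ratio of a one-site species);
`calibrate_c13()` solves for the ^13^C abundance reproducing it, giving
0.010949 — inside the published range of natural variation. With that single
calibration the generated table agrees with the reference grid to about 0.6%
everywhere; with raw IUPAC constants, to about 2.7%.

**Window normalization.** A three-ion measurement only admits fractional
abundances normalized over M+0..M+2, and the reference table agrees with
that convention to a few parts in 10^5 at its corners, so `three_ion` is the
package default; a `full` mode (normalization over the whole truncated
distribution) is available and differs by under 0.5% relative in `R` at
p ≤ 8%. Patterns are truncated at K = 6 mass shifts; the truncated tail is
of order 1e-8 and far below measurement noise.

**Degenerate inputs.** `R` is undefined when EM1 ≤ 0 (unlabeled or
near-unlabeled samples) and is flagged rather than computed. Measured ratios
slightly outside the model range — replicate noise near f = 0 or f = 1 —
are clamped to [0, 1] and flagged when within a slack of twice the
replicate SE of `R`; beyond that they are flagged `out_of_model`. The
sensitivity simulations invert unclamped so that errors are measured, not
hidden.

**Replicates.** `R` is computed per technical replicate and averaged (the
ratio of averaged enrichments is also reported via the summary table);
the SE of f(GNG) comes from per-replicate inversions.

## The equivalent site count and the choice p = 0.08

Every homogeneous `n` has a unique `R` at a given `p`, and `R(n)` is very
nearly linear in `n`. Reading a mixture's `R` back onto the `n` scale
(ordinary least squares of `n` on `R` over integer n = 1..7 — the fit
convention; an exact continuous-`n` solve is also provided and agrees to
well under 0.01) defines the *equivalent n* of the mixture. Because the
higher-`n` population contributes disproportionately to the enrichments, the
mixing curve is curvilinear and the equivalent count of the 2/3 : 1/3
subpathway mixture sits above the count-weighted 5.33:

```{r neq}
sapply(c(0.045, 0.08), function(p)
  n_equivalence_curve(p = p, f_pepck_grid = 2/3, model = model)$n_equiv)
```

The equivalent count falls slowly with `p`. The package's simulation default
is p = 0.08 — the drinking-water enrichment of the labeling protocol and the
top row of the lookup table — because at that enrichment the mixing-curve
equivalent count evaluates to 6.11–6.12, matching the published mixing-curve
analysis essentially exactly; at the 4.5% body-water regime it evaluates to
about 6.24. All simulation functions take `p` as an argument.

## Sensitivity simulations

**Glycerol-contribution variation.** The one-third glycerol assumption is a
fixed point of the analysis; `glycerol_variation_error()` quantifies what
happens when the truth deviates. The truth at each grid point is a
molecule-level n = 7/n = 2 mixture with glycerol share `g`, mixed with GGL
at the true f(GNG); the measured `R` is inverted under the fixed one-third
assumption. Two inversion conventions exist. Against the assumed mixture
pattern itself (the default), the error is *exactly* zero at g = 1/3 and
reflects only the deviation; sweeping `g` 10% above and below one-third
(0.300–0.3667) over f(GNG) = 0.20–0.80 puts the worst case at the
f(GNG) = 0.80, low-glycerol corner (about 5.6 points at p = 0.08) and keeps
the error under 4 points for f(GNG) ≤ 0.60. Against the integer n = 6 table
(`assumed = "integer_n6"`), an additional residual from the 6.12-vs-6
approximation appears, growing with f(GNG) and present even at g = 1/3; with
a wider absolute ±0.10 sweep this convention produces errors an order of
magnitude larger. The package defaults to the convention whose null is exact
because an error attributed to "glycerol variation" should vanish when there
is none.

**Transaldolase / pentose-phosphate exchange.** Non-productive PPP cycling
can label glucose C-5 without net gluconeogenesis. The affected position has
two exchange opportunities, so the extra site is occupied with probability
`2p(1-p)`. Molecules that traversed GNG already exchange C-5, so the extra
site is applied to the glycogen-derived subpopulation (default
`mode = "ggl"`); applying it to the whole population (`mode = "all"`) is
available but produces an error that *grows* with f(GNG), contrary to the
mechanism's physiology. With 6% of glycogen-derived glucose exchanged, the
error in f(GNG) is largest when true GNG is zero (about 1 point) and stays
near or below one point for f(GNG) > 10% (1.06 points at p = 0.08).

## The synthetic-data generator

`simulate_spectra()` emulates the three-ion measurement: exact mixture
pattern, arbitrary total area, independent multiplicative log-normal noise
per ion, optional fully-correlated intensity drift (which cancels in the
fractions), optional dilution with unlabeled glucose, and a
carbon-13-glycerol mode (two subunits labeled at enrichment `q`, for the
triose-phosphate precursor analysis).

The noise default deserves a note. Replicate injections are summarized in
practice by the CV of EM1, reported at 0.63% for low-enrichment samples.
A *per-ion* CV of 0.63% would inflate the EM1 CV to about 4% — ion areas
within an injection are far more correlated than that. The generator's
per-ion default (0.0009) is therefore calibrated by the delta method
(`calibrate_ion_cv()`) so that simulated technical replicates reproduce the
observed EM1 CV of 0.63% at p = 1.25%, f(GNG) = 0.5. Under those conditions
10 replicate injections give SE(f̂) around 0.015–0.02, consistent with the
2% standard error reported for the replicate experiment.

What the generator does *not* emulate: chromatographic peak shape and
integration, detector saturation and the concentration effect (addressed
instead by the empirical-baseline mode), drift and carryover, and
between-animal biological variance. Passing tests therefore validate the
estimators against the model's own assumptions, not against instrument
physics.

## Body water and the carbon-13 glycerol arm

`body_water_enrichment()` fits the acetone standard curve (fractional M+1
abundance against known water enrichment) by ordinary least squares and
inverts it at the sample response, rejecting curves with 1 − R² above 0.003
unless overridden and flagging extrapolation. `triose_precursor_13c()`
treats glucose as a two-subunit condensation polymer: the subunit
enrichment `q` is solved from the measured `R`, the ratio q / (plasma
glycerol enrichment) gives the glycerol share of the triose-phosphate pool,
and multiplying by f(GNG) gives the glycerol contribution to endogenous
glucose production. The fasted-state subpathway split
(`estimate_subpathways_fasted()`) assumes f(GNG) ≈ 1 and ignores any
residual glycogen contribution below about 5%; the assumption is recorded as
a flag in every result.

## Problem sizes and determinism

All analytic computations (tables, inversions, sensitivity grids) are exact
and run in well under a second; the sensitivity simulations use no random
numbers and are bit-reproducible. Monte-Carlo checks in the test suite use
10 replicates × 30 simulated samples at fixed seeds, enough to estimate
SE(f̂) to within a few percent while keeping the suite fast.

## Known limitations

* The inversion presumes the two-population mixture; a third independent
  pathway fraction is not identifiable from a single `R` (the one-third
  glycerol assumption closes the system, and its cost is quantified by the
  variation simulation).
* Equivalent-`n` values depend mildly on `p` and on the line-fit convention;
  second-decimal differences between conventions are expected.
* The tabular inversion inherits the 0.5% row spacing of the reference
  layout; between rows it can deviate from the exact inversion by more than
  0.01 at high f(GNG), so the exact route is the default everywhere.
* At low enrichments (p near 1%) the f(GNG) scale compresses; estimates near
  f = 1 become noise-sensitive and should be replicated.
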