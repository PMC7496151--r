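---
title: "Methods: relative potency factors and the change in cumulative exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative potency factors and the change in cumulative exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccemix)
```

## The problem

Two aerosol-producing products — in the packaged case study a heated
tobacco product (HTP) and a combustible cigarette — emit overlapping sets
of carcinogens at very different levels. Applying compound-by-compound
risk assessment to each constituent does not answer the practical
question a regulator faces: *how much does the overall carcinogenic
burden change if a user switches products?* `ccemix` answers it through
the **change in cumulative exposure (CCE)**,

$$\mathrm{CCE} \;=\; \frac{\sum_i E^{cig}_i \,\mathrm{RPF}_i}
                         {\sum_i E^{alt}_i \,\mathrm{RPF}_i},$$

where \(E_i\) is the per-stick emission of compound \(i\) and
\(\mathrm{RPF}_i\) its relative potency factor with respect to a
reference carcinogen. Under dose addition the potency-weighted sum is an
equipotent dose of the reference compound, so the CCE is the fold-change
in reference-equivalent exposure: CCE > 1 means the alternative product
delivers less cumulative carcinogen. The ratio form has two useful
consequences: the choice of reference compound cancels out, and
systematic errors that affect both products (e.g. mild synergism among
constituents, or a biased smoking-machine regime) at least partly cancel.

## Dose-response model and assumptions

Relative potencies come from quantal (tumor-incidence) bioassay data.
Incidence is modelled with the quantal exponential (Weibull-type) model

$$p(d) \;=\; c + (1-c)\,\bigl[1 - e^{-(d/\beta)^g}\bigr],$$

with background incidence \(c \in [0,1)\), dose scale \(\beta > 0\) and
steepness \(g > 0\). Background correction uses **extra risk**
\(\mathrm{ER}(d) = (p(d)-c)/(1-c) = 1 - e^{-(d/\beta)^g}\), the scale on
which the benchmark response (BMR) is defined by international
convention. The benchmark dose solves \(\mathrm{ER}(\mathrm{BMD}) =
\mathrm{BMR}\), giving the closed form
\(\mathrm{BMD} = \beta\,(-\ln(1-\mathrm{BMR}))^{1/g}\).

Key properties exploited downstream:

* curves sharing \(g\) are **parallel on log-dose**, the assumption
  underpinning dose addition;
* under shared \(g\), the RPF is the horizontal shift
  \(\mathrm{RPF}_i = \beta_{ref}/\beta_i = \mathrm{BMD}_{ref}/\mathrm{BMD}_i\),
  a pure ratio of dose scales that is **exactly independent of the BMR**
  (the package parameterises the likelihood in \(\beta\), so the BMR
  never enters the fit at all — BMR invariance holds to the bit, not just
  to optimizer tolerance);
* the ratio \(\mathrm{BMD10}/\mathrm{BMD05} = \ln 0.9/\ln 0.95 \approx
  2.054\) for \(g = 1\), consistent with the general observation that a
  halving of effect size corresponds to roughly a 2-fold dose change.

The parallelism assumption is checked in retrospect by
`check_parallelism()`: a likelihood-ratio comparison of the shared-\(g\)
model against per-compound steepness, on \(K - 1\) degrees of freedom.
The check is advisory — RPFs are only interpretable under approximate
parallelism, but a rejection does not halt the pipeline.

## The six steps

1. **Severity classification.** Each endpoint's pathology term maps to an
   ordinal category: (1) preneoplastic lesion, (2) benign tumor(s), (3)
   malignant tumor(s) in a single organ, (4) malignant (metastasizing)
   tumors in different organs, (5) tumor-bearing animals. Only categories
   2–5 enter potency estimation, and only datasets with exposure duration
   strictly above 96 weeks (the conventional near-lifetime threshold for
   rodent inhalation studies) are eligible. The packaged lookup table is a
   documented reconstruction of the category definitions over common
   rodent lesion terminology, not a validated pathology reference; the
   authoritative assignments in any given analysis should come from a
   pathologist-supplied table (`read_severity_lookup()`). Unknown terms
   are a hard error — a silent default severity would corrupt the
   analysis invisibly.
2. **Per-dataset BMD fits.** Every dataset (one compound × tissue × sex ×
   tumor type × exposure duration × study duration) is fitted by maximum
   binomial likelihood; within each severity category the dataset with
   the lowest BMD is the compound's *critical* dataset — the most
   sensitive signal.
3. **Covariate joint fit.** The critical datasets are fitted jointly with
   one shared steepness, per-dataset background and per-compound dose
   scale. Sharing the steepness lets data-poor compounds borrow strength:
   even a dataset with no significant trend yields an informative
   one-sided RPF interval. Two-sided 90% profile-likelihood intervals are
   computed on each log RPF (log-likelihood drop
   \(\chi^2_{0.90,1}/2 = 1.3528\)). Severity-specific intervals are
   pooled into one interval per compound by treating each as the 5th/95th
   percentile pair of a lognormal and taking the 5th/95th percentiles of
   the equal-weight mixture.
4. **Emission intervals.** Per-stick emissions from replicate
   smoking-machine measurements are summarised as geometric-mean 90%
   confidence intervals: a Student-t interval on the log values,
   exponentiated — the standard construction for positive,
   multiplicatively varying measurements. Known consumption differences
   between products enter as a scalar multiplier on one product's bounds.
5. **Probabilistic CCE.** Every interval (emissions for both products,
   RPFs) is calibrated to the lognormal whose 5th/95th percentiles equal
   its bounds: \(\mu = (\ln lb + \ln ub)/2\),
   \(\sigma = (\ln ub - \ln lb)/(2 \times 1.6449)\). A Monte-Carlo sample
   (default \(n = 10^6\), fixed seed recorded in the output) draws every
   quantity independently and evaluates the CCE ratio per draw; the
   empirical 5th/50th/95th percentiles (linear-interpolation order
   statistics, R's default type 7) summarise the uncertainty.
6. **Health translation.** Continuous toxicological dose-response curves
   are empirically quite uniform in steepness: halving an effect size
   typically corresponds to about a 2-fold (2–2.6 in rat time-to-tumor
   data) dose reduction. `health_translation()` therefore reports
   \(h = \ln(\mathrm{CCE})/\ln(\text{halving factor})\), the implied
   number of effect-size halvings, along with a qualitative rubric: CCE
   of 1, no change; a lower bound of 10 or more, substantial reduction in
   harm; CCE below 1, an increase in harm.

## Design choices in detail

**Correlation structure in step 5.** Within one Monte-Carlo draw each
compound's RPF value multiplies both the numerator and the denominator —
it describes the same compound in both products. All other quantities are
sampled independently; no correlation data exist to support anything
richer. This sharing is what makes reference invariance hold draw-by-draw
rather than only in distribution, and the package asserts it in tests
(`reference_rescale()` followed by `sample_cce()` at the same seed).

**The reference compound's RPF.** A compound's potency relative to itself
is 1 by definition, so the reference enters step 5 as an exact point mass.
The packaged potency table also records the reference compound's own BMD
interval, which is useful for calibration checks but is not an RPF.

**Severity pooling.** The equal-weight lognormal mixture is computed
analytically (root-finding on the mixture CDF) rather than by resampling:
the estimand is identical, but the computation is deterministic and free
of Monte-Carlo error; the test suite cross-checks it against a brute-force
mixture simulation.

**Optimisation.** All fits optimise over \((\operatorname{logit} c,
\log \beta, \log g)\) — every parameter unconstrained on its transformed
scale. Single-dataset fits use a deterministic 8-point multi-start grid
(steepness 0.5–4, dose scale half to twice the top dose) of Nelder-Mead
runs polished by BFGS; joint fits use BFGS with an analytic gradient from
five deterministic starts seeded by the single fits, with a simplex
polish as a guard. Everything is seedless and deterministic; convergence
tolerance is 1e-10 … 1e-12 relative on the log-likelihood. Profile bounds
step outward from the MLE (geometrically accelerating steps) and finish
with root-finding to 1e-6.

**Degenerate data.** A dataset with no dose-response signal (e.g. zero
tumors throughout) has an unbounded dose scale: the BMD point estimate
and upper bound are coded `Inf`, while the profile lower bound remains
finite and informative. Similarly, a weak dataset inside a joint fit
yields an RPF interval with a finite upper bound and a lower bound
approaching 0 (coded 0 when the profile never crosses within the search
span). Probabilities are clamped to \([10^{-12}, 1-10^{-12}]\) inside the
likelihood; doses of zero contribute only through the background.

**Units.** Doses must share one inhalation unit (e.g. mg/m³) across all
datasets entering a joint fit; the fit refuses mixtures because no
defensible automatic conversion exists. Emissions are µg per stick
(cigarette); exposure durations are weeks.

## What the synthetic generator emulates — and what it does not

`simulation_config()` describes a complete synthetic study:
tumor-incidence tables drawn binomially from exactly parallel log-dose
curves with known RPFs, and lognormal emission replicates with known
geometric means. The defaults mirror a realistic product comparison:
eight compounds with potencies spanning four orders of magnitude around
one reference, steepness 1.2, 5% background incidence, four dose groups
of 50 animals (the standard chronic-bioassay group size), five emission
replicates per compound and product at a geometric SD of 1.3, and a
baseline product emitting 10-fold more than the alternative across the
board (so the true CCE is 10). Each compound is dosed on its own
potency-adjusted grid, as a well-designed bioassay would be.

Because the generator draws from the same model family the estimator
fits, passing recovery tests demonstrates *statistical correctness of the
machinery* — near-nominal profile-interval coverage, unbiased potency
recovery, calibrated CCE intervals — not robustness to the ways real
bioassay data violate the model: non-parallel curves, litter effects,
differing study durations treated as equivalent, intercurrent mortality,
or dose placement far from the response range. The parallelism check
catches the first; the others are limitations shared with any analysis of
this design.

Validation problem sizes used by the test suite (chosen to exercise the
statistics at bioassay-realistic scale): 200 simulated four-compound
studies (true RPFs 1, 0.5, 10, 50; groups of 50) for profile-interval
coverage, which lands at 87–91% for a nominal 90%; and 100 full
simulate–fit–propagate replicates, in which the 90% CCE interval covers
the configured truth about 95% of the time (the interval also carries
emission-sampling uncertainty, so above-nominal coverage of the exact
truth is expected).

## Known limitations

* RPFs estimated from rodent data are assumed to transfer to humans — the
  standard, and untestable-within-the-data, dose-addition premise.
* Study durations beyond the 96-week eligibility threshold are treated as
  equivalent; no time-to-tumor adjustment is attempted.
* Emissions are the exposure surrogate; no uptake, topography or
  population-level (prevalence, dual-use, gateway) modelling is included.
* The case-study potency and emission tables enter as packaged interval
  fixtures; the raw animal datasets behind them are not redistributable,
  so the fitting machinery is validated by simulation instead.
* Below-detection-limit emission values are substituted at the limit
  divided by √2 with a prominent warning — a convention, not a censoring
  model; supply a different `lod_factor` or pre-treated values if the
  analysis is sensitive to it.
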