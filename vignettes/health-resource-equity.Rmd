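---
title: "Measuring equity of regional health-resource allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring equity of regional health-resource allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrequity)
```

## The problem

Whether medical resources — institutions, beds, health workers, public
health spending — are distributed fairly across the subregions of a large
territory can be asked in three distinct ways: fairly with respect to
*land area* (geographic accessibility), fairly with respect to
*population* (per-capita sufficiency), and fairly with respect to
*economic level* (whether richer regions capture more than their
population share). hrequity implements one estimator for each question and
a composite score that summarises all indicators at once, for yearbook-style
panel data: one row per region and year carrying population, land area,
per-capita GDP and a configurable set of resource indicators. The motivating
setting is the eleven provinces of the Yangtze River Economic Belt grouped
into downstream, midstream and upstream reaches, but nothing in the code is
specific to it.

## Agglomeration degrees

For region $i$ inside a parent territory $n$, the health-resource
agglomeration degree of a resource $HR$ and the population agglomeration
degree are share ratios

$$HRAD_i = \frac{HR_i/HR_n}{A_i/A_n}, \qquad
  PAD_i = \frac{P_i/P_n}{A_i/A_n},$$

where $A$ is land area and $P$ population. Both equal 1 exactly when the
region's density matches the parent's; the percentage factors often written
into these formulas cancel, so we compute pure share ratios. Their ratio

$$\frac{HRAD_i}{PAD_i} = \frac{HR_i/P_i}{HR_n/P_n}$$

is the region's per-capita holding relative to the parent's: above 1 the
resource is in surplus relative to population size, near 1 allocation by
population is fair. Two algebraic identities make good invariant tests and
are asserted in the suite: the area-weighted mean of HRAD (and of PAD) over
any partition of the parent is exactly 1, and the ratio equals the
independent per-capita computation.

Ranks are descending with ties broken by panel row order ("ordinal"
ranking). Competition-style ranking would be equally defensible; the stable
ordinal rule was chosen because it keeps output deterministic under any tie
and published tables show no ties to disambiguate. Regions with zero area
or population are rejected at ingest rather than propagating infinities;
a resource with a zero parent total raises an undefined-statistic error
rather than silently returning 0.

## Entropy-weight TOPSIS

The composite score treats regions as alternatives and indicators as
criteria. By default the scored matrix holds the HRAD values (the analysis
scores the *level of agglomeration*, not raw stocks); raw values are
available via `source = "raw"`. Entropy weighting is the standard
column-proportion construction: with $p_{ij} = x_{ij}/\sum_i x_{ij}$,

$$e_j = -\frac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}, \qquad
  d_j = 1 - e_j, \qquad w_j = \frac{d_j}{\sum_j d_j},$$

with $0\ln 0 = 0$. More dispersed columns are more informative and weigh
more; a constant column gets weight 0, and an all-constant matrix raises a
degenerate-weights error (the utility $d_j$ is floored at $10^{-12}$ so
that columns constant only up to floating point are treated as constant).
$n$ is always the number of alternatives actually scored, so provinces
(n = 11) and reaches (n = 3) get separate entropy scales — which is why
published reach-level entropies can sit far below provincial ones for the
same indicator. Since the underlying normalization is not stated in most
published applications, column proportions were chosen as the textbook
construction, with min-max pre-scaling available behind a flag.

TOPSIS uses the classical vector normalization
$r_{ij} = x_{ij}/\sqrt{\sum_i x_{ij}^2}$ (which removes column scale — the
suite verifies closeness is invariant to rescaling any raw column),
weighted cells $v_{ij} = w_j r_{ij}$, per-column ideals (max for benefit
criteria, min for cost; all agglomeration indicators are benefit-type by
default), Euclidean distances $D_i^+, D_i^-$ and relative closeness

$$C_i = \frac{D_i^-}{D_i^+ + D_i^-} \in [0,1],$$

ranked descending. The whole chain is tested against a deliberately naive
loop-based reimplementation at $10^{-12}$, and the stage from published
distances to published composite scores reproduces all 14 published values
to 5 decimals.

## Concentration curve and index

For economic-gradient fairness, regions are ordered by ascending per-capita
GDP (ties by panel order) and the curve of cumulative resource share $Y$
against cumulative population share $X$ is traced from the origin. With the
trapezoid rule over the $n$ steps,

$$S = \frac12\sum_{i=0}^{n-1}(Y_i + Y_{i+1})(X_{i+1} - X_i), \qquad
  CI = 2(0.5 - S) \in [-1, 1].$$

$CI > 0$ means the curve lies below the fairness diagonal: the resource is
concentrated in richer regions (pro-rich); $CI < 0$ pro-poor; 0 exact
per-capita proportionality. The X axis is cumulative *population* share,
not region count — with heavily unequal region sizes the two differ
materially. The trapezoid form is verified at $10^{-9}$ against the
independent grouped covariance form
$CI = \tfrac{2}{\mu}\sum_i s_i \mu_i (R_i - \bar R)$
($s_i$ population share, $\mu_i$ per-capita resource, $R_i$
population-weighted fractional rank), which is an exact algebraic identity
for grouped data, and satisfies reversal antisymmetry and refinement
stability (splitting a region into identical halves changes nothing). No
standard errors, dominance tests or bounded-variable corrections
(Erreygers/Wagstaff) are computed: the resources here are unbounded counts.

## The synthetic generator

Published concentration-index and entropy tables cannot be regenerated
without the original yearbook panels, so the package ships a generator
whose panels have controllable inequality structure. Areas are lognormal
(meanlog $\ln 2\times10^5$ km², sdlog 0.9), populations are area times a
lognormal density (meanlog $\ln 250$ persons/km², sdlog 0.7), per-capita
GDP is lognormal (meanlog $\ln 6\times10^4$ yuan, sdlog 0.35) — all chosen
once as order-of-magnitude provincial values; heavy right tails are the
point, since real provincial areas and populations span an order of
magnitude. Indicator $k$ in region $i$, year $t$ is

$$x_{ikt} = \text{base}_k \cdot P_i \cdot (g_i/\bar g)^{\gamma_k}
            \cdot \varepsilon_{ikt} \cdot \text{trend}_k^{\,t-t_0},$$

with $\bar g$ the geometric mean GDP (so the gradient term is centred in
log space) and $\varepsilon$ mean-one lognormal noise with a configurable
coefficient of variation. $\gamma_k = 0$ makes the indicator exactly
proportional to population, forcing $CI = 0$ and ratio $= 1$ through the
whole pipeline — the no-noise limit is asserted at $10^{-12}$. Positive
$\gamma$ produces pro-rich allocation; the mean CI is monotone in
$\gamma$, which is the generator-recovery test. Demographics and GDP are
held fixed across years so that all time variation is attributable to the
indicator process.

The `yeb_preset()` fixes 11 regions in contiguous reaches of 4/3/4 and
per-indicator $\gamma$ calibrated so the 2019 CI *sign pattern* matches the
published qualitative finding — pro-poor for health institutions, TCM
institutions and grassroots beds, pro-rich for the rest, general
practitioners most extreme ($\gamma = 1.5$). Magnitudes $|\gamma| \ge 0.3$
keep the signs stable against the 5% noise across seeds. It is a
sign-pattern fixture only: absolute CI values would require the real
yearbook panel and are deliberately not calibrated.

What the generator does not emulate: spatial autocorrelation between
neighbouring provinces, within-province heterogeneity, administrative
shocks (hospital reclassifications), or correlated noise across indicators.
Passing tests therefore demonstrate correctness of the estimators and the
pipeline on data with realistic marginal structure, not that any
substantive conclusion transfers to real yearbook data.

## Numerical and design choices

* All internal computation is at full double precision; rounding
  half-away-from-zero (the yearbook convention, not R's banker's rounding)
  is applied only when writing tables, 3 decimals by default.
* Published reference tables ship as plain CSV and are used only for their
  internally recomputable relationships (ratio from HRAD/PAD, weights from
  entropies, closeness from distances, ranks, CI signs); the test suite at
  those stages tolerates one unit in the last printed place where the
  published inputs are themselves rounded.
* Reach membership is configuration, not hard-coded: the standard
  downstream (Shanghai, Jiangsu, Zhejiang, Anhui), midstream (Jiangxi,
  Hubei, Hunan), upstream (Chongqing, Sichuan, Guizhou, Yunnan) division is
  the documented default grouping for real data, and the generator labels
  its contiguous groups the same way.
* GDP ties in the concentration ordering and value ties in ranking are both
  broken by panel row order, making every output deterministic for a fixed
  input file.
* Test and acceptance problem sizes — panels of 3–15 regions, 1,000 random
  panels for the oracle identity, 500 replicate seeds per gradient value —
  were chosen to give Monte-Carlo standard errors well below the effect
  sizes being detected while keeping the default suite quick to run.

## Limitations

Concentration-index standard errors and dominance testing are out of scope,
as are spatial-accessibility models (travel-time, two-step floating
catchment) that would qualify the purely geographic HRAD. The entropy-TOPSIS
result depends on the undocumented normalization choices discussed above;
when comparing against published scores, only the stages downstream of the
published intermediate quantities are reproducible, and the package makes
that boundary explicit rather than pretending to regenerate the whole table.
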