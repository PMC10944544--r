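---
title: "Methods: from soil microbiome profiles to forest carbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from soil microbiome profiles to forest carbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mycocarbon` implements the statistical chain that links soil microbial
community composition and diversity to forest carbon storage on
permanent inventory plots: stand-level carbon accounting from tree
censuses, soil stocks, community ecology of amplicon OTU tables,
constrained and unconstrained ordination with permutation inference,
negative-binomial indicator analysis against continuous carbon
covariates, and additive regression models with collinearity
diagnostics. This vignette explains the models, their assumptions, the
tunable parameters, and the design decisions taken where the design was
genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Stand carbon from tree censuses

Each plot contributes a list of periodically measured trees with DBH at
a first and a last census. Records are filtered before any estimation:
dead trees, trees below 5 cm DBH at the first census, and trees whose
DBH decreased are removed (`filter_trees()`). Shrinkage uses the strict
inequality — a tree with identical DBH at both censuses is legitimate
zero growth. Tree mass follows the allometric power law
$m = a\,\mathrm{DBH}^b$ with species-specific $(a, b)$ from a pluggable
registry (`allometry_registry()`); published equations for specific
species can be supplied as a data frame, and unknown species fall back
to a documented generic default ($a = 0.25$ kg cm$^{-b}$, $b = 2.4$,
mid-range for temperate trees) with a warning. Carbon is a constant
fraction of mass, 50% by default, applied uniformly across species.

Because not every stem on a plot is measured, measured trees cannot
simply be summed. `bootstrap_stand_estimate()` resamples measured trees
with replacement until the in situ stem density is reached
(`round(stems_per_ha)` draws, interpreted per hectare so no plot-area
scaling is needed), sums tree growth rates and final-census carbon,
and repeats 1000 times; the replicate mean is the stand estimate and
the replicate SD its spread. Growth is reported in t C ha$^{-1}$
yr$^{-1}$ and biomass in t C ha$^{-1}$. The resample count rounding and
the use of the final census for biomass are config-exposed choices, not
field conventions: "live biomass" is naturally the state at the end of
the growth interval. Internally the resampling is drawn as multinomial
tree multiplicities, which is distributionally identical to drawing
individual stems and much faster at realistic stem densities.

Soil stocks are arithmetic: stock (t ha$^{-1}$) $= \%/100 \times$ bulk
density (g cm$^{-3}$) $\times$ depth (cm) $\times 100$, per horizon
(organic, mineral).

## Community workflows

OTU tables hold integer counts with samples in rows. Quality control
(`qc_filter()`) first drops samples under the per-marker depth
threshold — 5000 reads for 16S, 500 for ITS, reflecting the much
shallower long-read fungal libraries — and then removes global
singletons (total count 1 across retained samples). Singleton removal
after, not before, the depth filter is a deliberate ordering (an OTU
whose second read lives in a discarded sample is a singleton of the
analysed data); it is configurable.

`rarefy()` subsamples each sample without replacement (multivariate
hypergeometric) to a common depth, by default the smallest retained
sample total, with the seed recorded in the output. Rarefaction runs
independently per marker-by-horizon table. Richness is the count of
detected OTUs and Shannon diversity $H = -\sum p_i \ln p_i$ uses
natural logarithms (a `base` argument gives bits). Bray-Curtis
dissimilarity is computed on relative abundances:
$BC(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$.

Fungal OTUs are split into functional guilds at the genus level.
Genera with several trophic annotations keep the hyphen-joined
compound label (e.g. `ectomycorrhizal-saprotroph`); additional
`pure_ectomycorrhizal` and `pure_saprotroph` views hold only
single-annotation taxa, because mixed-mode genera blur the
interpretation of those two guilds specifically. Unannotated genera go
to `unassigned`, and the non-`pure` subsets always partition the OTU
set.

## Ordination and permutation inference

`pcoa()` is classical metric scaling: Gower double-centering
$G = -\tfrac12 J D^2 J$, symmetric eigendecomposition, coordinates
scaled by $\sqrt{\lambda}$. Bray-Curtis matrices are semimetric, so
negative eigenvalues occur; they are reported and flagged but not
corrected (no Lingoes/Cailliez), and axis proportions are taken over
positive inertia only — this pins the semantics of "variation
explained" and matches the uncorrected default of the standard
implementations. Eigenvector signs are fixed by making the
largest-magnitude loading positive; tests never depend on axis sign.

`envfit_vector()` regresses an environmental variable on ordination
axes 1–2 (count configurable), reporting the squared multiple
correlation and an arrow of length $\sqrt{r^2}$;
`envfit_factor()` reports the between-centroid share of coordinate
variance. Significance comes from permuting the variable across
samples with the $+1$ correction, $p = (1 + \#\{r^2_{perm} \ge
r^2_{obs}\})/(1 + n_{perm})$, so $p$ is never 0 and the floor with 999
permutations is 1/1000.

`dbrda()` projects the PCoA site scores on all positive axes onto the
column space of the predictor matrix; numeric predictors are
standardized so effect sizes are comparable, categorical predictors
dummy-coded, aliased columns dropped with a warning. The proportion
explained is constrained inertia over total positive inertia; whether
negative eigenvalues should enter the denominator is genuinely
ambiguous, and the package's explicit choice (exclude, report their
sum) is switch-visible in the result.

## Indicator species against continuous carbon variables

The per-OTU analysis runs on the *non-rarefied* table; depth is
handled by "poscounts" median-of-positive-ratios size factors, which
tolerate the zero-rich tables typical of amplicon data. Dispersions
are estimated per OTU by method of moments on normalised counts, a
parametric trend $\alpha(\mu) = a_0 + a_1/\mu$ is fitted across OTUs,
and the final value interpolates OTU-wise estimate and trend on the
log scale (weight $\delta = 0.5$, floor $10^{-8}$). Two details
matter: the trend fit iteratively trims OTUs whose moment dispersion
exceeds twice the trend, because genuinely differential OTUs have
covariate-inflated marginal variance and would otherwise drag the
trend up and make null tests conservative; and constant-count OTUs
(moment estimate 0) take the trend value directly. This estimator is a
deliberately simpler, documented alternative to full empirical-Bayes
shrinkage; its validity is established by parameter-recovery tests,
not by numeric identity with any external tool.

Each OTU is then fitted with a log-link negative-binomial regression,
$\log \mu_j = \log s_j + \beta_0 + \beta_1 x_j$, by IRLS with the
dispersion held fixed, and tested with a Wald $z$ on $\beta_1$. Slopes
are reported as log2 fold change per unit covariate, with the
covariate deliberately unstandardised so "per unit change in tree
growth" keeps t C ha$^{-1}$ yr$^{-1}$ units. An OTU is called an
indicator when its BH-adjusted $p \le 0.05$ **and** $|$log2FC$| > 0.6$
strictly; `adjust = "none"` reproduces the literal unadjusted reading,
and results carry the mode used. Non-converged fits are flagged and
never called.

## Carbon models and collinearity

`fit_additive_model()` regresses a carbon outcome on the covariate set
(nitrogen deposition, MAT, MAP, soil pH, clay, stem density, forest
age, forest type, plus soil N stocks for tree growth only) and exactly
one microbiome predictor per model — PCoA axis 1 or 2, richness, or
Shannon diversity of one marker-by-horizon table — so model
comparisons across microbiome predictors stay independent. Selected
covariates (default MAT, MAP, N deposition, age) enter as penalized
cubic B-spline smooths (basis dimension 10, second-derivative
penalty); the engine is `mgcv::gam` with GCV smoothing-parameter
selection. GCV rather than REML is a documented divergence kept
because the package's correctness argument rests on the forced-linear
OLS limit and on parameter recovery, not on coefficient identity with
any particular fit of the original kind; with all smooths forced
linear the fit reproduces ordinary least squares to numerical
precision. The microbiome slope always enters linearly and is reported
raw and standardized ($\beta \cdot sd(x)/sd(y)$).

VIFs are computed by auxiliary regressions on the linearised design
(each smooth represented by its covariate). Infinite VIF (perfect
collinearity) refuses the model; max VIF above 5 sets a flag, with an
optional hard failure. Models use complete cases and report `n`.

## The synthetic-study generator

The generator exists so the whole chain can run and be tested without
restricted inventory data. Its defaults are the study conditions the
package targets: 238 plots, MAT uniform on $[-2.5, 15.5]$ °C, MAP on
$[443, 2082]$ mm yr$^{-1}$, mean stand age 90 years (SD 25, truncated
at 20), lognormal stem densities around 700 ha$^{-1}$, and per-tree
growth calibrated so stand productivity spans roughly 0.1–50 t C
ha$^{-1}$ yr$^{-1}$ and the pipeline-computed growth-biomass Pearson
correlation lands near the configured 0.7.

Latent structure per plot: a growth latent $g$ and a size latent $h$
drawn bivariate normal — the latent correlation is mapped as $0.93
\times$ the configured target because shared stem density and
lognormal upscaling push the realised product-moment correlation above
the latent one (the map was set by simulation at the default
calibration and is only claimed near it) — plus an independent
evenness latent that scales the spread of OTU baselines. Tree censuses
draw lognormal initial DBH (location shifted by $h$) and a lognormal
per-tree carbon growth target driven by $g$ (the within-plot increment
distribution is a modelling convenience, not a field claim); the final
DBH is obtained by inverting the allometry, so the census run back
through the carbon module returns exactly the simulated growth.
Configurable fractions of dead, sub-5-cm and shrinking records
exercise the filters.

OTU tables follow a log-normal-composition → multinomial model: per
OTU log abundance = baseline + loading × gradient + environmental
loadings + noise, softmaxed into compositions and sampled at lognormal
per-sample depths chosen so a few percent of samples fall below the QC
thresholds. Fungal tables load on the growth latent; bacterial tables
load on a pH / organic-carbon surrogate instead. Environmental
loadings are spread over all plot covariates with the realised
per-axis norm pinned, and — importantly — the community responds to a
*microhabitat* version of each covariate, the measured value plus
plot-level mismatch noise (SD 0.65). That mismatch is what lets the
generator satisfy two constraints that would otherwise conflict:
environmental predictors explain a realistic ~23–25% of Bray-Curtis
inertia in dbRDA, while no compositional axis is collinear enough with
the measured covariates to push any model VIF above 5. Soils couple
organic-horizon carbon stocks positively to the evenness latent (hence
negatively to observed richness) and mineral-horizon stocks to the
growth latent. True latents and per-OTU loadings are recorded in a
`truth` slot for parameter-recovery scoring.

One master seed expands into independent substreams (covariates,
latents, per-plot trees, soils, each OTU table), so identical
configurations reproduce byte-identical studies and adding plots does
not perturb earlier draws.

What the generator does *not* emulate: spatial autocorrelation between
plots, raw-read artifacts (chimeras, clustering error), real species
allometries, multi-census trajectories beyond first/last, or
phylogenetic structure among OTUs. Passing tests therefore demonstrate
the statistical machinery is correct and calibrated on data with the
assumed structure — not that real forests behave this way.

## Numerical choices and problem sizes

Permutation tests use the $+1$ correction everywhere; 999 permutations
by default, 199 in the heaviest calibration tests (the correction
keeps the test exact at any count). The NB-IRLS converges at
$10^{-8}$ on coefficients with a 50-iteration cap; non-convergence is
flagged, excluded from calls, and counted. Eigenvalues below
$10^{-10}$ of the leading one are treated as zero in PCoA. The test
suite runs the full default study (238 plots, 1000 bootstrap
replicates), 500-replicate permutation-size checks at $n = 30$, and a
2400-OTU, 200-sample Wald recovery simulation; these sizes were chosen
to make Monte-Carlo error small relative to the tolerances asserted
while keeping the default `R CMD check` workflow quick on one core.

## Known limitations

Dispersion shrinkage is a fixed-weight geometric interpolation, not
empirical Bayes; very low-count OTUs inherit mostly the trend. The
additive models assume Gaussian outcomes (carbon stocks and rates are
treated on their natural scale). dbRDA significance testing
(permutation of rows under the reduced model) is not implemented —
the package reports effect sizes, mirroring its role here. The CLI
(`inst/scripts/mycocarbon.R`) is a thin convenience wrapper; the
functions are the interface.
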