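---
title: "Methods: non-equilibrium free energy estimation and selectivity validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-equilibrium free energy estimation and selectivity validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neqsel)
```

## The problem

Alchemical relative binding free energy calculations estimate how much a
chemical modification changes a ligand's affinity for a protein target. In
the non-equilibrium (NEQ) variant, one ligand is switched into the other
during many short, fast transitions, in both directions, and the work values
recorded along those switches encode the free energy difference through
fluctuation theorems. Running the transformation once in the protein--ligand
complex and once in solvent closes a thermodynamic cycle whose difference is
the relative binding free energy,

$$\Delta\Delta G = \Delta G_{\mathrm{complex}} - \Delta G_{\mathrm{solvent}}.$$

Applied across a panel of homologous kinases, the same machinery predicts
*selectivity*: for a pair of compounds $(i, j)$ and a kinase $k$ compared
with a reference kinase,

$$\Delta S_{ij} = \Delta\Delta G_{ij}^{(k)} - \Delta\Delta G_{ij}^{(\mathrm{ref})}.$$

This package implements the statistical core of that workflow — everything
downstream of the molecular dynamics engine — plus the experimental side
(IC50 conversion) and the regression validation that links the two.

## Free energy estimators

All three standard NEQ estimators are implemented over a `work_set` holding
forward works $W_F$ (0→1 switches) and reverse works $W_R$ stored in the
reverse direction's own sign convention (the work done during the 1→0
switch). With $\beta = 1/RT$, $R = 8.314462618\times10^{-3}$ kJ/(mol K):

* **Jarzynski (JAR)**: the one-sided exponential average
  $\Delta G = -\beta^{-1}\ln \langle e^{-\beta W_F}\rangle$ (forward), and
  its negation for the reverse direction. All exponential averages go
  through a log-sum-exp formulation, so $\beta W$ products of any magnitude
  cannot overflow. The headline "JAR" value is the arithmetic mean of the
  two one-sided estimates when both directions exist, else the available
  side (the method tag records which). One-sided JAR is biased — high from
  the forward side, low from the reverse — and the bias shrinks with sample
  size; the tests resolve this signature explicitly.
* **Crooks Gaussian intersection (CGI)**: normal densities are fitted to
  the forward and negated-reverse works by sample moments (mean and
  unbiased $n-1$ variance — a deliberate choice over hidden
  maximum-likelihood conventions, for closed-form testability), and the
  estimate is the intersection point of the two densities. Equal variances
  (relative tolerance $10^{-9}$) give the midpoint of the means; otherwise
  the quadratic from equating log-densities is solved and the root between
  the two means is taken. If neither root lies between the means (possible
  under sampling noise) the root closer to the midpoint is returned and the
  estimate is flagged.
* **Bennett acceptance ratio (BAR)**: the unique root of the Bennett
  self-consistency equation, located by bracketed root finding
  (`uniroot`, default tolerance $10^{-8}$ kJ/mol) on the work range padded
  by 50 kJ/mol, doubling the padding up to three times before declaring a
  convergence error. The residual is strictly monotone in $\Delta G$
  (each forward term increases with $\Delta G$, each reverse term
  decreases), which guarantees uniqueness; the logistic form
  `plogis` keeps every term in $(0,1)$ without overflow.

Standard errors are bootstrap SDs over resamples drawn independently within
each direction, preserving per-direction sample sizes (default 1000
replicates; a seed is required, and per-method streams are derived from it
deterministically). If more than 20% of replicates fail the bootstrap
aborts loudly.

A practical note on CGI: when the forward/reverse distributions nearly
coincide (narrow work distributions), the intersection point is
ill-conditioned — its sampling error is dominated by variance-estimation
noise of order $(RT/2)\sqrt{2/n}$ and does not shrink with the work SD.
The test suite's Monte-Carlo bands for CGI are therefore wider than for
BAR/JAR; this mirrors the estimator's real statistics, not an
implementation artifact.

## Cycle assembly and conformer selection

`assemble_ddg()` pairs complex and solvent legs per (pair, target, method,
conformer), forms $\Delta\Delta G$ with quadrature errors, and resolves
alternative starting conformers (e.g. the *sin*/*anti* intramolecular
hydrogen-bond orientations of a ligand) by keeping the candidate with the
lowest $\Delta\Delta G$. Exact ties break lexicographically on the conformer
label. Two open points were decided as follows:

* selection is applied **per estimator method independently**, because
  results are reported method-wise and a consensus selection would obscure
  which method chose which pose;
* the selected conformer's own SE is carried unchanged — no
  selection-uncertainty inflation, matching the plain lowest-value rule.

Missing legs surface as diagnostics and are never imputed. Derived pairs
(between two non-reference compounds) come from `rebase_pair()`:
$\Delta\Delta G(a{\to}b) = \Delta\Delta G(\mathrm{ref}{\to}b) -
\Delta\Delta G(\mathrm{ref}{\to}a)$, exactly cycle-consistent by
construction.

## Experimental side

IC50 values with 95% confidence intervals are converted to relative binding
free energies via $\Delta\Delta G_{ij} = RT\ln(K_i/K_j)$. For an
ATP-competitive inhibitor the Cheng–Prusoff relation
$K_i = \mathrm{IC}_{50}/(1 + [\mathrm{ATP}]/K_m)$ links IC50 to the
inhibition constant; within one target at fixed [ATP] the correction factor
cancels in the ratio, so the pipeline defaults to the Km-free IC50 ratio and
requires an explicit Km only to report absolute $K_i$ values. (Published
Km values for the panel kinases vary by source; hard-coding one would be a
false precision.)

The assay temperature is taken as 303.15 K (a 30 °C incubation), the one
defensible reading; it is configurable. Confidence intervals of potency
assays are treated as symmetric in log-IC50 — their multiplicative error
structure — giving the per-measurement log-SE
$s = \ln(\mathrm{CI_{high}}/\mathrm{CI_{low}})/(2z)$ with $z = 1.959964$,
and $\mathrm{se}(\Delta\Delta G) = RT\sqrt{s_i^2 + s_j^2}$.

The packaged panel (`inst/extdata/cdk_ic50.csv`) is a published in vitro
CDK/cyclin inhibition table for four imidazole-4-N-acetamide compounds
across CDK1/2/5/9; with compound 1 as reference it yields 12 experimental
$\Delta\Delta G$ values and, re-referenced to compound 2 (the least
selective compound), 9 experimental $\Delta S$ values.

## Selectivity

`selectivity_table()` re-references the assembled pairs to a chosen
compound via `rebase_pair()` before differencing across targets, and
propagates the full error of both $\Delta\Delta G$ terms in quadrature.
Selectivity against the reference target is identically zero by
construction and is excluded. Km never enters: across-target Km differences
cancel within each $\Delta\Delta G$ term.

## Validation: errors-in-variables regression

Calculated values are validated against experimental ones with a
generalized Deming regression — each point weighted by its own variances on
both axes. The objective

$$\sum_i \frac{(x_i - \xi_i)^2}{s_{x,i}^2} +
        \frac{(y_i - a - b\,\xi_i)^2}{s_{y,i}^2}$$

is exactly the York errors-in-variables formulation once the latent
$\xi_i$ are profiled out, and is minimized by the standard York iteration
(relative slope change below $10^{-10}$, at most 100 iterations,
OLS-initialized). Points with a zero SE — e.g. a zero-noise synthetic study
— are assigned the smallest positive SE present on that axis, or 1 when all
are zero, which reduces the fit to the unweighted orthogonal case.

The 95% slope CI is a leave-one-out jackknife with the normal quantile;
a relationship is declared significant when the CI excludes zero. The
orientation is x = experimental, y = calculated. $R^2$ is the squared
Pearson correlation, and RMSE/MAE are computed **against the identity
line**, not the fitted line — the question being "how far are predictions
from measurements", not "how well does a refitted line do". RMSE ≥ MAE
always (power-mean inequality), and both are exposed in kcal/mol via
`kj_to_kcal()`; note that both the thermochemical (4.184) and IT (4.1868)
calorie conventions are provided, since printed one- and two-decimal kcal
equivalents in the literature are reproducible only under a specific
truncation/convention choice (3.5 kJ/mol → 0.8365 kcal/mol, printed 0.83
under truncation, 0.84 under rounding).

## The synthetic study generator

`make_synthetic_study()` exists so the entire pipeline is testable without
molecular dynamics. It emulates the *statistical* output of a switching
engine, not the physics: for each transformation leg, forward works are
drawn from $N(\Delta G + \beta\sigma^2/2,\ \sigma^2)$ and reverse works
from $N(-\Delta G + \beta\sigma^2/2,\ \sigma^2)$, the unique Gaussian pair
satisfying the Crooks fluctuation theorem
$P_F(W)/P_R(-W) = e^{\beta(W - \Delta G)}$ around the configured truth.
The complex leg is centred on
$\Delta G_{\mathrm{solv}} + \Delta\Delta G_{\mathrm{true}}$ and the solvent
leg on $\Delta G_{\mathrm{solv}}$ (target-independent, as the cycle
demands), so cycle closure recovers the truth exactly in expectation.
IC50 records derive from the same truth: $K_i = e^{\Delta G/RT}$ (molar
standard state, reported in µM), $\mathrm{IC}_{50} = K_i(1 + [\mathrm{ATP}]/K_m)$,
multiplied by $e^{N(0, \mathrm{sd}^2)}$ noise with a log-symmetric 95% CI
of matching width.

Defaults define the study conditions and were chosen once:

| parameter | default | rationale |
|---|---|---|
| panel | 4 compounds × CDK1/2/5/9, reference compound 1, reference target CDK2 | the geometry of the motivating study |
| `true_dG` | from the packaged IC50 panel at 303.15 K | realistic micromolar-range affinities |
| `work_sigma` | 2 kJ/mol | typical 50-ps switching work spread |
| `n_forward`, `n_reverse` | 100 | typical per-direction transition counts |
| `ic50_noise_sd` | 0.15 (ln units) | matches the CI widths of the packaged panel |
| `atp_conc` | 1 µM | the assay's ATP concentration |
| `km` | 10 µM per target | synthetic stand-in; within-target analyses never use it |
| `temperature` | 298.15 K | simulation-side convention |

Randomness uses a single root seed with per-work-set streams derived
deterministically from (seed, pair, target, leg), so identical specs are
bit-identical and adding a work set never perturbs the others.

What the generator does **not** emulate: anharmonic (non-Gaussian) work
distributions, forward/reverse asymmetry from poor switching overlap,
conformer-dependent work landscapes, correlated errors between targets, or
assay-to-assay systematic shifts. Passing recovery tests therefore shows
the statistical machinery is correct, not that real MD work distributions
are Gaussian.

## Numerical choices, briefly

* exponential averages: log-sum-exp, always;
* BAR: bracketed `uniroot`, tolerance $10^{-8}$ kJ/mol, 50 kJ/mol padding
  doubled ≤ 3 times;
* CGI: equal-variance branch at relative tolerance $10^{-9}$; degenerate
  (zero-variance, unequal-mean) input is an error, not a guess;
* Deming: York iteration, tolerance $10^{-10}$, max 100 iterations;
  jackknife CI; zero-SE repair as above;
* trapezoidal integration for dH/dλ traces (quadrature choice; standard
  for switching traces, and exact for the linear test fixtures);
* kJ/mol is the single internal unit; kcal only at presentation
  boundaries.

## Problem sizes in the shipped tests

The suite runs the full pipeline at reduced but statistically meaningful
sizes chosen as the package's own test design: estimator accuracy at
$n = 200$/direction over 50 seeds; recovery studies at $\sigma = 0.2$–1
kJ/mol with 150–1000 transitions/direction; bootstrap at 30–100
replicates; Deming coverage over 50 seeded replicates of 12 points. The
acceptance script re-runs the experimental pipeline on the packaged panel
and a zero-assay-noise synthetic study at 1000 transitions/direction.

## Known limitations

* The JAR combination rule (mean of the one-sided estimates) is a
  documented convention; other combinations (e.g. variance-weighted) exist.
* CGI's flagged fallback (no root between the means) returns a usable
  number but should be treated as a warning sign of poor overlap.
* The jackknife slope CI is approximate at very small n (it is the cited
  convention of the validation literature, and its coverage is tested).
* No equilibrium multi-window FEP/MBAR: only two-state non-equilibrium
  work inputs are in scope.
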