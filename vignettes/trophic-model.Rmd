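---
title: "A multi-level trophic model of the gut microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-level trophic model of the gut microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutcascade)
```

## The model

`gutcascade` treats the lower gut as a staged flow-through reactor. A
nutrient intake vector $\vec c_{nut}$ (amounts of candidate intake
metabolites, typically polysaccharide breakdown products) enters the first
trophic level, where it is consumed by the resident microbial community.
Every species converts a fraction $1-f$ of what it consumes into biomass and
secretes the remaining fraction $f$ as metabolic byproducts, which form the
metabolite pool of the next level. After $N_\ell$ such consumption steps the
process stops; everything never consumed — plus the final level's byproducts
— exits as the fecal metabolome.

Two matrices encode who-eats-what. The **uptake matrix** $A_{in}$ splits
each metabolite $i$ across its consumers $\alpha$ in proportion to abundance
times uptake rate,

$$(A_{in})_{\alpha i} = \kappa_i\,\lambda_{\alpha i}\,B^{exp}_\alpha,
\qquad \kappa_i = \Big(\sum_\alpha \lambda_{\alpha i} B^{exp}_\alpha\Big)^{-1},$$

so each column with at least one present consumer sums to exactly 1; by
default all $\lambda_{\alpha i} = 1$ on consumption edges. The **secretion
matrix** $A_{out}$ splits each species' byproduct mass equally over the
$N_{out}(\alpha)$ metabolites it can secrete,
$(A_{out})_{i\alpha} = 1/N_{out}(\alpha)$ on production edges.

One consumption step maps the entering pool $\vec d_{\ell-1}$ (with
$\vec d_0 = \vec c_{nut}$) to

$$\vec b^{(\ell)} = (1-f)\,A_{in}\,\vec d_{\ell-1}, \qquad
  \vec d_\ell = f\,A_{out} A_{in}\,\vec d_{\ell-1},$$

after first setting aside the unconsumable part $\vec u_\ell$ of
$\vec d_{\ell-1}$ (metabolites no present species can eat, identified per
sample), which is banked directly into the predicted metabolome. Total
biomass is $B_\alpha = \sum_\ell b^{(\ell)}_\alpha$ and the predicted
metabolome is $\vec M = \vec d_{N_\ell} + \sum_{\ell=1}^{N_\ell}\vec u_\ell$.
Equivalently, on networks where every consumer also secretes something,

$$B_\alpha = \sum_{\ell=1}^{N_\ell} (1-f)\,f^{\ell-1}
  \big[A_{in} (A_{out}A_{in})^{\ell-1}\,\vec c_{nut}\big]_\alpha .$$

We use this power form with exponents $f^{\ell-1}$ and
$(A_{out}A_{in})^{\ell-1}$ (and $f^\ell (A_{out}A_{in})^\ell$ for the
byproduct pools) because it is the unique closed form consistent with the
single-step recursion at $\ell = 1$; the recursion itself is what the engine
executes, and the tests verify the two agree to $10^{-10}$.

Three accounting conventions keep the mass balance exact, testable as
$\sum_\alpha B_\alpha + \sum_i M_i + \text{sink} = \sum_i c_{nut,i}$ to
within $10^{-9}$ relative:

* a species with no recorded byproducts still converts $1-f$ of its intake
  to biomass; the $f$-fraction it "secretes" has nowhere to go and is
  tracked in an explicit **sink** rather than silently lost or forced into
  the metabolome;
* intake metabolites that do not occur in the capability network at all pass
  straight through to the metabolome as level-1 unconsumables;
* consumability is evaluated per sample: a metabolite with consumers in the
  database but none present (at positive abundance) in this individual is
  unconsumable here.

Measured relative abundances are used inside $A_{in}$ at every level — the
model never updates abundances between levels — and metabolite amounts are
never normalized by molecular weight. Both profiles returned by
`predict_profiles()` are normalized to sum to 1 and are invariant under
rescaling of the intake, which is why fitted intakes can be reported on the
simplex.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `f` | byproduct fraction (dimensionless, 0–1) | 0.9 | grid value at which predicted fecal metabolomes agree best with measurements |
| `n_levels` | number of consumption steps | 4 | companion calibrated value; biomass saturates geometrically beyond it |
| `uptake_rates` | $\lambda_{\alpha i}$ per consumption edge | 1 | kinetic rates are unknown at this scale; robustness is probed with `randomize_uptake_rates()` and `enzyme_budget_rates()` |
| `secretion_mode` | byproduct splitting | equal split | `dirichlet_secretion()` provides the randomized-weights control |
| `floor` | log-scale floor on relative profiles | $10^{-6}$ | species unreachable from any intake predict exactly zero biomass; the floor keeps $\log_{10}$ residuals finite |

## Intake inference and calibration

The intake is the one fitted quantity. For a sample with observed relative
abundances $m_\alpha$ over $S$ species, `fit_intake()` minimizes the
residual vector $\log_{10} p_\alpha(\vec c) - \log_{10} m_\alpha$ by bounded
(non-negative) Levenberg–Marquardt least squares, reporting the mean
absolute residual $\frac1S\sum_\alpha |\log_{10}p_\alpha - \log_{10}m_\alpha|$
as the objective. Starting points draw each component uniformly on $(0,1)$
and normalize to sum 1; because the objective is non-convex in log space the
fitter defaults to 10 random restarts and keeps the best. Two numerical
choices are worth knowing:

* for fixed $(f, N_\ell)$ and fixed abundances the cascade is **linear** in
  the intake, so `intake_response()` collapses it once into an
  species-by-intake response matrix; each optimizer evaluation is then a
  matrix product and the Jacobian is analytic. This is an exact
  reformulation (unit-tested against `run_cascade()`), not an
  approximation;
* optimization runs over free non-negative amounts and the result is
  renormalized to the simplex afterwards, valid because of the scale
  invariance above.

`calibrate_grid()` scores every $(f, N_\ell)$ cell by refitting each
sample's intake and comparing the *predicted* metabolome (an out-of-fit
prediction — nothing in the fit sees the measured metabolome) with the
measured one, on $\log_{10}$ scale: mean Pearson correlation, mean
logarithmic accuracy (mean absolute $\log_{10}$ difference, i.e. the
order-of-magnitude error, in dex), and the median adjusted P-value. The
P-value adjustment divides the usual $t$ statistic by
$\sqrt{(n-2)/(n-2-p)}$ and uses $n-2-p$ degrees of freedom with $p = 2$
fitted model parameters, making the one-tailed test conservative. Because
the predicted metabolome is relative while measured units are
instrument-specific, both vectors are renormalized over the matched
metabolite subset before scoring by default (`renormalize = FALSE` scores
raw logs instead). Both best-cell criteria (max mean correlation, min mean
log accuracy) are reported; log accuracy is the sharper of the two at
separating neighboring $f$ values, correlation being insensitive to the
overall tilt that $f$ imposes.

The default grid spans $f \in \{0.1, \dots, 0.9, 0.95, 0.99\}$ and
$N_\ell \in \{2, \dots, 10\}$; both axes are configurable, and the package's
own validation uses a 4×4 sub-grid around the region of interest to keep the
simulation-budget modest.

## Null models

Five controls probe which ingredients carry the signal: degree-preserving
double-edge swaps of the consumption and production edge sets separately
(`shuffle_capabilities()`, $3\times|E|$ attempted swaps per set, attempts
that would create duplicate edges are skipped — enough to push edge-set
Jaccard similarity below 0.5), species-label permutation that moves whole
capability sets between names (`shuffle_species_labels()`), i.i.d.
uniform$(0,1)$ uptake rates, Dirichlet-distributed secretion weights
(concentration 1 by default — flat on each species' byproduct simplex, the
natural uninformative choice), and cohort bootstrap for the uncertainty of
the calibrated $(f, N_\ell)$. The consumption and production shuffles use
independent RNG streams derived from the seed, and every generator is
seed-deterministic.

## Level-resolved diversity

For a cohort of flows, `level_contributions()` normalizes each entity's
contribution within every (level, sample) slice; `diversity_summary()` then
computes inverse-Simpson diversities per level: within samples
$D_\alpha(\ell) = 1/\langle \sum_i p_i(\ell,j)^2\rangle_j$, of the
cohort-mean profile $D_\gamma(\ell) = 1/\sum_i \bar p_i(\ell)^2$, and their
ratio $D_\beta = D_\gamma / D_\alpha \ge 1$ (Jensen's inequality), with no
finite-sample correction. Species contributions come from the per-level
biomass increments; genus contributions sum congeners before normalizing —
comparing the two exposes lottery-like assembly, where functionally
equivalent congeners exclude each other across individuals and
$D_\beta$(genus) drops well below $D_\beta$(species). For metabolites the
per-level profile is ambiguous, so three definitions are offered: the pool
*entering* a level (default, making level-1 metabolite diversity the intake
diversity), the byproducts *produced* at it, or its *unconsumed* part.
Microbial levels are stored as consumption-step indices 1..$N_\ell$;
reporting offers a shifted "figure level" labeling (step + 1) in which the
intake occupies level 1 and microbes first appear at level 2.

## What the synthetic data emulate — and what they do not

`generate_network()` draws random bipartite capability networks (Poisson
degrees floored at 1, every species with at least one consumable and one
byproduct, genus labels by partition). Designated intake metabolites receive
at least `intake_min_consumers` (default 10) consumers: intake nutrients are
breakdown products that many gut species can use, and a generous consumer
base keeps the 19-dimensional intake identifiable from a few dozen observed
abundances. `generate_cohort()` draws per-sample true intakes from a
symmetric Dirichlet, a presence mask over species, and then obtains
"measured" abundances as the **fixed point** of the forward map (run the
cascade, feed the resulting relative biomass back in as the measured
abundances, repeat to convergence at $10^{-13}$, dropping species below a
$10^{-5}$ detection limit as a sequencing survey would). The fixed point
matters: the real pipeline uses measured abundances inside $A_{in}$, so only
a self-consistent profile can be *exactly* reproduced by the model at the
true intake — and exact noiseless inversion is what the recovery tests
check. A single bootstrap pass leaves a residual floor that masquerades as
fitting error. Observation noise is multiplicative log-normal, specified in
dex ($10^{\mathcal N(0,\sigma)}$), matching the order-of-magnitude scale on
which all comparisons operate; the default validation cohorts use
$\sigma = 0.1$ dex.

Default scale mirrors a realistic calibration study: networks of 80 species
and 150 metabolites, 19 intake metabolites, 41 individuals per cohort,
samples retaining roughly 20–45 species after competitive exclusion and the
detection limit. The validation suite scales some of this down (20-sample
cohorts, a 4×4 calibration grid, 10 calibration seeds) to keep the full run
in the minutes range.

What passing these tests does *not* show about real data: synthetic
communities are exact fixed points of the very model being fitted, so
recovery results certify the inference machinery (identifiability,
optimizer, scoring), not the model's biological adequacy; real capability
databases are incomplete and biased toward well-studied taxa; real
metabolomes include host-derived and diet-derived compounds the cascade
never produces; and real abundance noise is not log-normal i.i.d. Headline
agreement statistics on real cohorts therefore cannot be reproduced here and
are out of scope.

## Known limitations

* No dynamics: abundances are inputs, not outcomes; there is no chemostat,
  pH, spatial structure, or host interaction.
* The byproduct fraction is global — all species share one $f$.
* Fixed-point cohort generation converges to low-diversity communities when
  few species hold a private resource; the generator's intake-consumer
  floor mitigates but does not eliminate this.
* With fewer observed species than intake candidates the inverse problem is
  under-determined; the fitter pads the residual vector and returns one
  valid solution, flagged only by the sample's species count.
* `adjusted_pvalue()` returns the continuous limit (0 or 1) at $|r| = 1$,
  which arises routinely on noiseless synthetic data.
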