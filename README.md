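# gutcascade

Multi-level trophic modeling of the human gut microbiome.

The gut hosts hundreds of microbial species exchanging hundreds of
metabolites through cross-feeding: one species' metabolic byproducts are
another's nutrients. `gutcascade` implements a coarse-grained
consumer-resource model of this ecosystem as a trophic cascade with two
global parameters. Nutrients entering the lower gut are consumed level by
level; at each level every consuming species converts a fraction *1 − f* of
its intake to biomass and secretes the fraction *f* as byproducts that feed
the next level. After *N<sub>ℓ</sub>* levels, everything left unconsumed
exits as the fecal metabolome. Formally, with a column-stochastic uptake
matrix *A<sub>in</sub>* (each metabolite split across its consumers in
proportion to abundance × uptake rate) and a column-stochastic secretion
matrix *A<sub>out</sub>* (equal splitting across each species' byproducts):

    b(ℓ) = (1 − f) · A_in · d(ℓ−1),      d(ℓ) = f · A_out · A_in · d(ℓ−1)
    B_α  = Σ_ℓ b(ℓ)_α                    M = d(N) + Σ_ℓ u(ℓ)

where *d(0)* is the intake vector and *u(ℓ)* collects metabolites no
present species can consume. The package is for microbiome researchers who
want to connect metagenome composition to metabolome composition
mechanistically: it predicts a fecal metabolome from species abundances,
infers the unobserved nutrient intake per individual by nonlinear least
squares, calibrates *(f, N<sub>ℓ</sub>)* against measured metabolomes by
grid search, generates degree-preserving and rate-randomizing null models,
and quantifies inverse-Simpson α/β/γ diversity per trophic level.

## A worked example

Two species, one intake nutrient, a two-step chain: a *Bacteroides*
consumes arabinose and secretes acetate; a *Eubacterium* consumes the
acetate and secretes butyrate, which nothing downstream eats.

```r
library(gutcascade)

ia <- data.frame(
  species    = c("Bacteroides sp", "Bacteroides sp",
                 "Eubacterium sp", "Eubacterium sp"),
  metabolite = c("arabinose", "acetate", "acetate", "butyrate"),
  direction  = c("consumption", "production", "consumption", "production"))
net <- cross_feeding_network(ia)

s  <- community_sample("donor1", c("Bacteroides sp" = 0.5,
                                   "Eubacterium sp" = 0.5))
fl <- run_cascade(net, s, c(arabinose = 1),
                  flow_parameters(f = 0.9, n_levels = 2))
fl
#> Trophic flow for sample donor1 : f = 0.9 , levels = 2
#>   biomass 0.19 (19.0%), metabolome 0.81 (81.0%), sink 0

flow_summary(fl)[, c("level", "consumed_fraction",
                     "biomass_fraction", "passed_on_fraction")]
#>   level consumed_fraction biomass_fraction passed_on_fraction
#> 1     1               1.0             0.10               0.90
#> 2     2               0.9             0.09               0.81
```

Of one unit of arabinose, the *Bacteroides* fixes 0.10 as biomass and passes
0.90 on as acetate; the *Eubacterium* fixes 0.09 of that and the remaining
0.81 leaves the gut as butyrate — the predicted metabolome. Normalizing:

```r
predict_profiles(fl)$abundance
#> Bacteroides sp Eubacterium sp
#>         0.5263         0.4737
predict_profiles(fl)$metabolome["butyrate"]
#> butyrate
#>        1
```

Mass is conserved exactly: biomass (0.19) + metabolome (0.81) = intake (1).

Given only the observed abundances, `fit_intake()` inverts this pipeline to
infer the intake; `calibrate_grid()` scans *(f, N<sub>ℓ</sub>)* cells,
refitting intakes and scoring predicted against measured metabolomes;
`generate_network()` / `generate_cohort()` build synthetic studies with
known ground truth; and `run_command()` (with the wrapper script in
`inst/cli/gutcascade.R`) exposes all of it as `synth`, `simulate`,
`fit-intake`, `calibrate`, `diversity` and `null` commands. See the
`trophic-model` vignette for the model's assumptions, numerical choices and
limitations.

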