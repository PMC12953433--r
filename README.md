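# BayesMCA

Bayesian Metabolic Control Analysis (BMCA) with lin-log kinetics, for
metabolic engineers who want to rank genetic intervention targets —
which enzymes to overexpress, which to delete — from multi-strain,
multi-omics fermentation data instead of intuition.

## The method

Near a reference steady state, each reaction rate is approximated by the
**lin-log** rate law

```
v = diag(v*) (e/e*) ∘ (1 + εx log(x/x*) + εy log(y/y*))
```

where `v*`, `e*`, `x*`, `y*` are reference fluxes, enzyme levels and
internal/external metabolite levels, and `εx`, `εy` are the elasticity
matrices (∂ln v/∂ln x), the local kinetic parameters. Imposing the
steady-state condition `N v = 0` makes the steady state of a perturbed
strain one linear solve. Given a strain panel with relative proteomics
(log e/e*), relative metabolomics (log x/x*) and flux estimates, the
package infers the posterior over `εx`, `εy` by mean-field automatic
differentiation variational inference (ADVI; Adagrad, run to convergence
of the negative evidence lower bound), with extreme log-ratios clipped
and entered as censored observations so that the fit stays in the
lin-log validity region.

The posterior over elasticities is then propagated to **flux control
coefficients** on the product-export flux via

```
CX = −(N diag(v*) εx)⁻¹ N diag(v*),   CJ = I + εx CX
```

(`CJ[j,k] = ∂ln J_j/∂ln e_k`; rows of CJ sum to 1, and `CJ εx = 0`). A
reaction is called a target when the 95% highest-posterior-density
interval of its FCC excludes zero: positive FCC ⇒ overexpress, negative
FCC ⇒ delete.

Around this core the package provides the standard supporting stages:
model import (SBML Level 3 with fbc gene associations, plus a JSON
dialect), reduction to reactions with nonzero reference flux, removal of
conserved moieties, exchange-rate estimation from batch fermentation
time series under an exponential growth model, expression-constrained
flux estimation (E-Flux2: GPR-scaled bounds, objective maximization,
minimum-norm solution), posterior predictive checks, and a synthetic
multi-strain data generator with known ground truth.

## Worked example

A 17-reaction central-carbon network with a heterologous β-alanine
route to 3-hydroxypropionic acid (3-HP), a competing
malonic-semialdehyde drain (ALD6 analog) and a TCA-like branch; 17
strains in triplicate with 80% observed features and noise sd 0.1:

```r
library(BayesMCA)
truth     <- makeToyNetwork("branched_3hp", seed = 1)
sim       <- simulateDataset(truth, NoiseSpec(seed = 1))
problem   <- buildBmcaModel(truth@model, truth@ref, sim$data)
posterior <- fitVariational(problem, seed = 1, draws = 500)
fcc       <- fccPosterior(posterior, truth@model, truth@ref)
targets   <- callTargets(fcc, truth@model)
head(as.data.frame(targets)[, c("reaction_id", "fcc_median",
                                "hpd_low", "hpd_high", "direction")], 5)
```

```
  reaction_id fcc_median hpd_low hpd_high   direction
1      r_hpdh     0.4723  0.4545   0.4891 overexpress
2      r_ald6    -0.1162 -0.1252  -0.1086      delete
3       r_pyc     0.1159  0.1065   0.1263 overexpress
4     r_bapat     0.0970  0.0885   0.1037 overexpress
5       r_aat     0.0886  0.0815   0.0957 overexpress
```

The ranked table reads directly as an engineering plan: the terminal
pathway dehydrogenase (`r_hpdh`) carries the most control and is the
top overexpression candidate; the competing drain on malonic
semialdehyde (`r_ald6`) is the top deletion candidate; the
anaplerotic carboxylase (`r_pyc`) feeding the pathway should be
overexpressed. Both calls match the sign of the analytic ground-truth
FCCs stored in `truth@fcc`. `fitVariational` reports convergence of the
ELBO (here after 5000 iterations); `posteriorPredictive()` /
`ppdCoverage()` check the fitted model against the observations.

The same analysis runs end to end from a YAML config (or the bundled
defaults) with

```r
run <- runPipeline(defaultConfig(outputDir = "bmca_run", seed = 1))
```

which writes the rate, flux, target and PPD tables, a run manifest with
the config hash and seed, and the forest/PPD figures; a thin CLI lives
in `inst/scripts/bmca.R`.

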