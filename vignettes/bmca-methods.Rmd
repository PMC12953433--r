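---
title: "Bayesian metabolic control analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian metabolic control analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the kinetic model and its assumptions, the statistical
model, the parameters a user may want to move, what the synthetic data
generator does and does not emulate, and the numerical and design
choices that were genuinely open.

## The lin-log kinetic model

Every reaction rate is linearized around a reference steady state
$(v^*, e^*, x^*, y^*)$:

$$ v = \mathrm{diag}(v^*)\,\frac{e}{e^*} \circ
  \Big(1 + \varepsilon_x \log\frac{x}{x^*}
         + \varepsilon_y \log\frac{y}{y^*}\Big). $$

The elasticities $\varepsilon_x, \varepsilon_y$ (dimensionless,
$\partial\ln v/\partial\ln x$ at the reference) are the only kinetic
parameters. The approximation assumes proportionality of rate to enzyme
level and log-linearity in metabolites, both of which hold only near
the reference state — the reason observed log-ratios are clipped before
fitting (below). Imposing $N v = 0$ gives the steady state of a
perturbed strain as a single linear solve

$$ \big[N\,\mathrm{diag}(v^* e)\,\varepsilon_x\big] x_{\log}
   = -N\,\mathrm{diag}(v^* e)\,(1 + \varepsilon_y y_{\log}), $$

which requires $N$ to have full row rank: conserved moieties (dependent
rows) are removed first, with a link matrix retained to reconstruct the
dropped rows. Reactions with zero reference flux are removed before
analysis because the lin-log form divides by $v^*$; the default
zero-flux threshold is `1e-9` mmol/gDCW/h (the scale of solver noise,
far below any biologically meaningful flux). Enzyme reference levels
$e^*$ are fixed at 1 because proteomics enter only as ratios to a
reference strain.

Control coefficients follow from the implicit function theorem at the
reference state:
$C^X = -(N\,\mathrm{diag}(v^*)\,\varepsilon_x)^{-1} N\,\mathrm{diag}(v^*)$,
$C^J = I + \varepsilon_x C^X$. Under these formulas the summation
($\sum_k C^J_{jk} = 1$) and connectivity ($C^J \varepsilon_x = 0$)
theorems hold identically; the test suite also verifies $C^J$ against a
finite-difference Jacobian computed through the steady-state solver
(central differences, $h = 10^{-6}$ log units), which is the ground
truth the analytic formula must reproduce.

## The observation model

Per strain $s$ the latent variables are $\log e_s$ (one per reaction,
prior $\mathcal N(0,1)$); the steady state $x_s, v_s$ is a
deterministic function of $(\varepsilon, e_s, y_s)$. Likelihoods:

* protein log-ratios $\sim \mathcal N(\log e_s, \sigma_p)$,
* metabolite log-ratios $\sim \mathcal N(x_{\log,s}, \sigma_m)$,
* fluxes $\sim \mathcal N(v_s, \sigma_f \cdot |v^*|)$ per reaction.

Flux noise is scaled by $|v^*|$ because fluxes are signed,
span two orders of magnitude in a typical network and cross zero, so a
single absolute (or log) sd is ill-defined; the relative
parameterization makes $\sigma_f$ a dimensionless fractional error.

Elasticities exist only for structurally allowed reaction–metabolite
pairs (an optional allow-list can free regulatory cross-talk entries):
substrates get a $\mathcal N(+0.5, 1)$ prior, products
$\mathcal N(-0.5, 1)$, encoding the thermodynamic sign expectation
weakly. Observation sds get half-normal(0.5) hyperpriors unless pinned
in the configuration.

**Clipping.** Log-ratios beyond $\pm 2$ natural-log units (default) are
truncated to the bound and enter the likelihood as *censored* terms
($P(Y > b)$ rather than a density at $b$). Exact values far from the
reference would both violate the lin-log region and be given
unwarranted weight; censoring keeps the information that the value is
extreme without pretending to know it. Clipping applies to protein and
metabolite log-ratios; fluxes are absolute-scale and are not clipped.

**Deletions.** The lin-log law is undefined at $e = 0$, so knockouts
are encoded as a relative level of 0.05 (configurable floor): flux
through the reaction is strongly reduced while the model stays in its
log-linear regime.

## Inference

The posterior is approximated by mean-field ADVI: a diagonal Gaussian
in the unconstrained parameters (free elasticities, latent
$\log e_s$, log noise sds), optimized with reparameterization
gradients and Adagrad (learning rate 0.2, one Monte Carlo sample per
step by default). No automatic-differentiation framework is involved:
the gradient of the log joint through the steady-state solve is derived
analytically with the adjoint method — one extra $m \times m$ linear
solve per strain per step — and is checked against central finite
differences in the unit tests. Convergence is declared when the mean of
the negative ELBO over a 500-iteration window changes by less than
$10^{-4}$ relative to the previous window; the iteration cap (default
20000) is flagged in the result if reached. All randomness derives from
a single integer seed, and fits are bitwise reproducible.

Posterior draws of $\varepsilon_x$ are pushed through the analytic
control-coefficient formula draw by draw; draws with a singular or
ill-conditioned system (condition number above $10^{10}$) are masked
rather than regularized, and the masked fraction is reported (more than
50% masked aborts). Targets are called from the 95% HPD interval
(narrowest window containing 95% of sorted draws) with a qualitative
magnitude floor of 0.05 on the median |FCC|, exposed in the
configuration and reported with the calls; ranking is by |median FCC|,
with the posterior probability of a positive FCC reported alongside.

## Supporting stages

*Exchange rates.* Batch growth is modeled as
$X(t) = X_0 e^{\mu t}$ (fitted log-linearly); a constant specific rate
$q$ then gives $S(t) = S(0) + (q X_0/\mu)(e^{\mu t}-1)$, linear in $q$.
Rates are estimated per strain on replicate-averaged series (the
replicate structure of fermentation sampling rarely supports
per-replicate growth fits; the choice is recorded here as the
package's default).

*E-Flux2.* Per-sample expression is aggregated to reactions through the
GPR rules (isozymes sum, complex subunits take the minimum), normalized
by the sample maximum, and scaled by a flux ceiling $M = 100$
mmol/gDCW/h to give bounds; reactions without expression information
get the ceiling itself. Measured exchange fluxes are held in a ±5%
band (configurable) rather than pinned exactly, absorbing measurement
noise. Phase 1 maximizes the objective flux (LP); phase 2 returns the
minimum-norm flux among phase-1 optima (QP), the E-Flux2 uniqueness
criterion. Reversible reactions are handled inside the solver; the
reported flux is net.

## The synthetic data generator

The generator stands in for a real multi-omics strain panel. The
`branched_3hp` preset is a 17-reaction lumped network — glucose uptake
and glycolysis, pyruvate carboxylase into oxaloacetate, the
heterologous aspartate → β-alanine → malonic semialdehyde → 3-HP
export route, a competing malonic-semialdehyde drain to acetyl-CoA
(the ALD6 analog), a TCA-like succinyl-CoA branch with a two-subunit
ligase complex, an ethanol drain and a biomass sink. Reference fluxes
are fixed positive values satisfying $N v^* = 0$, scaled so the
implied fermentation (inoculum 0.05 gDCW/L, reference growth rate
0.025 h⁻¹, 555 mM initial glucose, sampling at days 3/5/7) stays in
physically sensible concentration ranges. True elasticities are drawn
sign-consistently — substrates Uniform(0.3, 1.2), products
Uniform(−1.2, −0.3), redrawn if the steady-state system is
ill-conditioned — which keeps the ground truth well-posed. The strain
panel mirrors a realistic engineering campaign: one reference strain
at the linearization point, one wild-type without the pathway
(enzymes at the knockout floor), pathway dosage variants (×2), single
overexpressions (×5) and single deletions, 17 strains in triplicate
(51 samples), 80% of features observed per sample, log-scale noise sd
0.1, clipping at 2.

One deliberate deviation from the obvious emulation: the log-ratio
*reference strain* is the base pathway strain whose design is the
identity — i.e. the model's linearization point — not the wild-type. A
wild-type reference is internally inconsistent here: the reduced model
keeps the pathway (nonzero $v^*$), while a strain without the pathway
sits at the knockout floor, so its own log-ratios could not be zero.
The reference strain remains configurable for data sets where the two
roles genuinely coincide.

The canonical ground truth is the preset's default seed; the
simulation study used by the tests and the acceptance script holds
that truth fixed (as a real study has one biology) and varies the
observation noise and inference seeds across replicates.

What the generator does **not** emulate: protein-level measurement
structure below the reaction level (observations are generated at
reaction resolution), correlated noise between omics layers, batch
effects between replicates, growth-phase dependence of rates, or any
quantitative resemblance to a real organism's parameter values.
Passing the recovery tests therefore shows the inference machinery is
correct and well-calibrated under its own assumptions — not that those
assumptions hold for any particular real dataset.

## Numerical choices

* Steady-state and control systems are solved with dense LU
  (`solve`); condition numbers above $10^{10}$ flag the solution as
  singular, which errors in strict mode or falls back to the
  Moore–Penrose pseudoinverse when requested.
* Rank decisions in moiety removal use pivoted QR with relative
  tolerance $10^{-9}$.
* Matrices are ordered lexicographically by metabolite/reaction id,
  making every derived matrix reproducible across dialects and runs.
* ADVI initializes latent enzyme means at the observed per-strain mean
  protein log-ratio (zero where unmeasured), elasticity means at their
  prior means, variational sds at 0.1.
* Simulation sizes in the tests (two-step fits, 17-strain study with
  500 posterior draws, 300–400 PPD draws) were chosen as the smallest
  problems that exercise every code path at study scale.

## Known limitations

* **Mean-field underdispersion.** The factorized Gaussian family
  underestimates marginal posterior variance when the true posterior
  is strongly correlated — which elasticities are, through the
  steady-state constraint. Posterior *means*, FCC signs, rankings and
  target calls are robust to this (they are what the recovery tests
  assert), and posterior-predictive intervals remain calibrated
  because observation noise dominates them; but marginal credible
  intervals for individual elasticities are too narrow and should not
  be read as frequentist-calibrated. A full-rank family would address
  this at quadratic parameter cost and is not currently implemented.
* The lin-log approximation degrades for perturbations far from the
  reference state; strong knockouts are handled by flooring and
  censoring, not by a globally valid rate law.
* Exchange-rate estimation assumes balanced exponential growth over
  the sampled interval.
* The E-Flux2 stage inherits the usual FBA caveats: bounds from
  relative expression are heuristic, and the minimum-norm criterion is
  a uniqueness device, not a biological principle.
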