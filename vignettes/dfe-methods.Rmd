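---
title: "Estimating the DFE of induced mutations from zero-inflated field fitness data"
author: "mutdfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the DFE of induced mutations from zero-inflated field fitness data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutdfe)
```

# The problem

Mutation accumulation experiments ask how much heritable variation new
mutations inject into a trait per generation, and whether any useful
fraction of them is beneficial.  `mutdfe` implements a pipeline for a
chemically mutagenized selfing-plant design: a founder plant is treated
with a mutagen (EMS), carries a Poisson number of new heterozygous
mutations, and is selfed for three generations — with a split into two
sublines after the first — so that the plants scored in the field are
mosaics of fixed, segregating, and lost mutations.  The measured fitness
proxy is above-ground dry biomass in mg (log10-transformed), which is zero
for the many seedlings that die before harvest.

The inferential target is deliberately modest: the **first two moments**
(mean $\mu$ and SD $\sigma$, per founder, on the log10-mg scale) of the
distribution of fitness effects (DFE) of single mutations.  No shape
family is assumed for the DFE; the moments are identified through a
central-limit (compound-Poisson) approximation, which is also why higher
moments are out of reach in this design.

# The model

For founder $i$, line $j$, subline $k$, plant $l$ the observation is

$$z_{ijkl} = y_i + m_{ijk} + h_{ijkl} + b_l + \varepsilon_{ijkl},$$

where $y_i$ is the founder genetic value, $m_{ijk} \sim N(0, \tau_m^2)$ a
subline maternal effect, $b_l \sim N(0, \tau_b^2)$ a field-block effect,
and $\varepsilon_{ijkl} \sim N(0, \eta_i^2)$ residual noise (one $\eta$
per founder; the field data show strongly founder-specific dispersion).
Mortality makes $z$ zero-inflated: a plant survives with probability

$$p_{ijkl} = \frac{1}{1 + e^{c\,(y_i + m_{ijk} + h_{ijkl} + b_l) + d}},$$

and only survivors contribute the normal biomass term.  With $c < 0$,
higher genetic value means higher survival.  The residual
$\varepsilon$ deliberately does not enter the survival logit — mortality
responds to the genetic value, not to the measurement noise of a plant
that has already survived.

## The mutational deviation and its moments

Each EMS line carries $P \sim \text{Poisson}(\lambda)$ mutations
($\lambda = 25$, fixed, externally estimated from albino segregation).
Mutation $m$ has allele dosage $n_m \in \{0, 1, 2\}$ (lost, segregating,
fixed) and effect $e_m$ drawn i.i.d. from the founder's DFE, and

$$h = \sum_{m=1}^{P} n_m e_m.$$

Under selfing, dosage follows a Markov chain from the heterozygous state:
$1 \to \{0, 1, 2\}$ with probabilities $(\tfrac14, \tfrac12, \tfrac14)$,
with 0 and 2 absorbing.  `dosage_moments()` enumerates this chain exactly:
$E[n] = 1$ for every generation, and after $g$ generations
$E[n^2] = 2 - 2^{-g}$, so $g = 3$ gives the coefficient $1.875$ in

$$h \;\approx\; N\!\big(\lambda\mu,\; 1.875\,\lambda(\mu^2 + \sigma^2)\big),$$

the central-limit approximation that frees the model from any DFE shape
assumption.  Because plants in a line share their generation-2 genotype,
and plants in a subline additionally share the generation-3 genotype, the
variance splits along the pedigree using the cross-moment
$E[n n'] = 2 - 2^{-g_\text{shared}}$:

| level | coefficient ($\times\,\lambda(\mu^2+\sigma^2)$) |
|---|---|
| line (shared between sublines) | 1.5 |
| subline | 0.25 |
| individual plant | 0.125 |

These sum to 1.875 exactly; `compound_poisson_moments()` performs the
bookkeeping and `sample_line_h()` is the brute-force oracle used in the
tests.  The line-level normal term carries the whole mean $\lambda\mu$;
any split of the mean across levels is observationally equivalent, and
putting it at the top matches the intuition that mutations fixed in the
shared generation-2 genotype define the line.

## How good is the normal approximation?

A fixed non-normality is detectable at any sample size given enough
draws, so "statistically indistinguishable from normal samples" is an
unusable criterion at large Monte Carlo sizes.  `clt_diagnostic()`
therefore reports the Kolmogorov distance of standardized $h$ draws from
the standard normal together with calibration quantiles from truly normal
samples of the same size, and compares the distance against a practical
equivalence margin of **0.05 absolute CDF error** (a distortion well below
the inferential resolution of the design).  At $\lambda = 25$ every
supported family — including a point mass, strongly skewed gammas of both
signs, and a bimodal mixture — sits inside the margin; at
$\lambda = 0.5$ the atom of unmutated plants makes the distance an order
of magnitude larger and the diagnostic fails loudly, as it should.

# Inference

Priors are weakly informative on the log10-mg scale: $y_i \sim N(0,
10^2)$, $\mu \sim N(0, 0.05^2)$, half-normal priors on all scales
($\sigma$: 0.05; maternal and block SDs: 0.1; $\eta$: 1), $c, d \sim N(0,
5^2)$.  $\lambda$ and the selfing design are fixed inputs, never
estimated.  $\mu$ is identified jointly by the mean shift $\lambda\mu$ of
EMS lines relative to their control and by its contribution to the
variance components; $\sigma$ is identified by the excess of the
line/subline/individual variance components over what $\lambda\mu^2$
explains.

The posterior is approximated by stochastic variational inference on the
unconstrained scale (positive parameters log-transformed, latent effects
non-centered), maximizing the evidence lower bound with Adam on
single-sample reparameterized gradients, which are coded analytically and
verified against finite differences in the test-suite.

## Why not fully factorized?

The natural first choice, a fully factorized (mean-field) Gaussian, turned
out to be qualitatively wrong for this design: the control plants anchor
$y_i$ while the EMS plants anchor $y_i + \lambda\mu_i$, so $y_i$ and
$\mu_i$ are strongly anticorrelated in the posterior, and a factorized
approximation reports the *conditional* SD of $\mu$ (about 0.0002 at the
default design) instead of its marginal (about 0.0012 — the value
consistent with the replicate-to-replicate scatter of the point
estimates).  Error bars five times too small would defeat the purpose of
a Bayesian fit.  The default approximation is therefore **structured**:

1. a mean-field stage fits all coordinates (20k iterations by default);
2. a second stage (10k iterations) learns a full covariance for the ~20
   global parameters in *whitened* coordinates — the global block is
   parameterized as $\theta_G = m_G + \mathrm{diag}(s_1) L \zeta$ with
   $s_1$ the stage-1 marginal SDs and $L$ a Cholesky factor started at the
   identity — while the thousands of local latent effects keep independent
   normals.  Whitening keeps every entry of $L$ of order one; learning the
   covariance in raw coordinates is numerically unstable because the
   global parameters span four orders of magnitude.

Point estimates are Polyak averages over the final quarter of each stage,
which removes the residual single-sample gradient jitter (on the order of
the reported SDs for $\mu$).  Convergence is declared when the relative
change of the smoothed objective between successive windows falls below
`tol`; a fit that does not reach it is flagged, not discarded.  Restarts
(optional) keep the highest final objective, ties broken by lowest index.
`approx = "meanfield"` is retained for comparison.

Remaining, documented limitations of the variational fit:

* marginal uncertainties of weakly identified scale parameters
  (particularly $\sigma$ when the realized line-level variance is small)
  are still optimistic, and $\sigma$ itself can be shrunk towards zero in
  datasets whose realized line variance is at the low end of its sampling
  distribution — the replicate recovery test therefore scores $\mu$, the
  target the design actually pins down;
* the ELBO is a stochastic objective; two fits agree exactly only for the
  same seed (fits are bit-reproducible given `seed`).

# The simulator

`simulate_experiment()` generates the full design from scratch: per-line
Poisson mutation counts, per-mutation dosage paths down the
line/subline/plant pedigree, maternal and block effects, logistic
survival, and log-normal biomass for survivors.  Defaults encode the
study conditions: 6 founders with genetic values (2.886, 2.164, 2.298,
3.125, 3.109, 2.941) and per-founder residual SDs (0.208, 0.327, 0.762,
0.074, 0.218, 0.215); 20 and 16 EMS lines of 2 sublines × 60 plants for
the two focal founders; 120 control plants (2 sublines) per founder; 12
blocks; normal DFEs with $(\mu, \sigma)$ = (0.001, 0.011) and (0.004,
0.015).  The survival parameters default to $c = -0.9128$, $d = 2.5943$,
the exact solution reproducing the two focal control survival rates (0.51
and 0.35) at their genetic values; with one shared logistic the reference
founders' simulated rates follow their genetic values rather than their
observed field rates, which a founder-specific survival curve would be
needed to match — a known simplification of both model and simulator.

Maternal and block effect SDs are not published quantities; the defaults
(0.02 log10 mg each) are chosen once as small nuisance scales — block
point estimates in the field data scatter with an SD of about 0.02, and
maternal effects are expected of the same order given that the subline
split exists precisely because they are non-negligible but modest.  A
single master seed drives serial generation (no per-line substreams; the
generator is not parallelized, and one stream keeps reproducibility
trivial).

What the simulator does *not* emulate — and therefore what passing
recovery tests do not establish about field data: spatial autocorrelation
beyond block means, genotype-by-environment interaction, dominance,
epistasis, linkage between induced mutations, somatic selection during
line propagation, and founder-specific survival curves.

# Numerical and design choices

* Exact dosage moments come from enumerating the 3-state chain, not from
  the closed forms; the closed forms ($E[n^2] = 2 - 2^{-g}$) serve as
  independent cross-checks in the tests.
* Weights are stored in raw mg and log-transformed on the fly; zeros stay
  representable and a write/read round trip is bit-exact (17 significant
  digits on disk).
* Controls are a line with `ems_treated = FALSE`, so every grouping
  operation treats them uniformly; control plants of all founders are
  split into two 60-plant sublines (the schema permits a single subline).
* The derived quantities follow the published conventions exactly:
  $V_m = 0.16\,\sigma^2$ per generation (the spontaneous trait-mutation
  rate 0.16 enters only here, not in the fit), $V_e = \eta^2$, $h^2_m =
  V_m / V_e$.  $V_m$ uses $\sigma^2$ only — not $\mu^2 + \sigma^2$ and no
  dosage factor; the inconsistency with the compound-Poisson variance is
  a documented convention, not corrected.  Rounding (3 significant
  figures for $h^2_m$, nearest hundred for generation counts) is always
  an explicit argument.
* Many-to-one line-vs-control comparisons use the exact Dunnett
  multivariate-$t$ adjustment from `multcomp`, run both on all plants
  (mortality zeros included — the fitness measure assigns 0 to
  non-survivors) and on survivors only.  The exact 2×2 test is authored
  by direct hypergeometric enumeration and cross-checked against
  `fisher.test`.
* Problem sizes in the test-suite are chosen for desk-scale runs: five
  replicate refits of the full 5,040-plant design for parameter recovery,
  $10^5$ lines for the covariance oracle, $10^6$ paths for the dosage
  Monte Carlo, $10^4$ draws per family for the normality diagnostic.

# Open questions resolved during implementation

* Whether the two sublines descend from one generation-2 plant or from
  two siblings changes the line-level cross-moment; one shared plant is
  assumed (coefficient 1.5), which is what makes "mutations fixed before
  the split and shared between sublines" well defined.
* $c$ and $d$ are shared across founders (the survival formula carries no
  founder subscript); block effects are random effects.
* Prior hyperparameters, iteration counts, and tolerances are not
  published; all are exposed in `model_config()` with the defaults above.
* The published line tallies ("7 of 17", "13 of 21") count one more line
  than the stated 16/20 mutant lines (presumably the control); the
  counting function reports mutant lines only and the tallies are not
  treated as correctness targets.
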