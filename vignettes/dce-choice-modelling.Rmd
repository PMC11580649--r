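---
title: "Choice modelling methods in dcekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choice modelling methods in dcekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcekit)
```

## The setting

`dcekit` implements the analysis workflow of a stated-preference discrete
choice experiment (DCE) for a digital health product. The packaged
vocabulary is a sexual-health risk-assessment tool described by six
attributes — cost (Free/\$5/\$10), speed of results, accuracy band,
anonymity (login requirement), application type and additional services —
with 3/3/4/3/2/4 levels. Respondents repeatedly choose between two
designed tool configurations or an opt-out ("neither"), and the pattern of
trade-offs identifies the utility each attribute level carries.

The original survey behind this vocabulary (415 respondents, each
answering one block of six choice sets, opting out in about 6.4% of 2490
tasks) is not publicly available, so the package ships a synthetic
respondent generator that emulates its structure. Every model is exercised
end-to-end against that generator, and parameter-recovery experiments are
the package's evidence of correctness.

## Effects coding

Categorical levels are effects coded: an attribute with $L$ levels
contributes $L-1$ design columns; a non-reference level sets its own
column to $+1$, and the reference level (the last listed, by default) is
$-1$ in every column of the block. Level utilities then sum to zero within
each attribute, so the omitted level's coefficient is recoverable as minus
the sum of the estimated ones (`complete_coefficients()`), and which level
is omitted is immaterial for reporting. The study space has
$\sum_k (L_k - 1) = 13$ coded columns. Cost is treated as categorical, not
continuous, because per-level cost utilities are the quantity of interest.

## Choice models

All models share the conditional-logit kernel: alternative $j$ in task $t$
has utility $V_{tj} = x_{tj}'\beta$ and is chosen with probability
$\exp(V_{tj}) / \sum_m \exp(V_{tm})$. The opt-out carries an all-zero
attribute profile plus an alternative-specific constant (ASC); designed
alternatives are unlabelled and carry none. An ASC near $-1.8$ reproduces
an opt-out share near 6% alongside a high status-quo uptake, which is why
it is on by default.

**Conditional logit (`fit_mnl`)** is fitted by BFGS from the zero vector —
the likelihood is globally concave, so the start only provides the
$-T\log J$ baseline check — followed by Newton polishing to a gradient
infinity-norm below $10^{-6}$. Standard errors come from the inverse
observed information; respondent-clustered sandwich errors are available.

**Panel mixed logit (`fit_rpl`)** gives each respondent a normal random
coefficient vector $\beta_n = \mu + \sigma \odot z_n$ (independent
spreads, no correlation structure) on all 13 coded columns, with the ASC
fixed. The panel product over a respondent's tasks sits *inside* the draw
average:
$$\log L = \sum_n \log \frac{1}{R} \sum_r \prod_t P_{nt}(\mu + \sigma z_r),$$
computed in log space with log-sum-exp guards and an analytic gradient.
Draws are Halton sequences, one prime base per coefficient assigned in
column order from 2, first 10 points discarded, $R = 1000$ by default; the
same draw matrix is shared by all respondents, so a fit is a deterministic
function of the data. Spreads are estimated unconstrained and reported as
absolute values (the likelihood is symmetric in their sign). The
degenerate point $\sigma = 0$ reproduces the conditional logit exactly and
is retained as a fallback candidate, so the fitted mixed logit never
reports a likelihood below the conditional logit's.

A draw-quality note: at 13 dimensions the residual discrepancy of
unscrambled Halton points is visible — the simulated log-likelihood at the
study scale moves by a few tenths of a unit (about 0.1% of its magnitude)
between 500 and 2000 draws. We measured deterministic digit scrambling and
respondent-specific sequence slicing as alternatives; neither reduced the
noise (consecutive high-base Halton segments are poorly equidistributed on
their own), so the package keeps the simple shared-draw scheme and treats
~0.1–0.2% relative draw noise as the attainable accuracy at this
dimension. In 3 dimensions the same difference is below 0.05 units.

**Latent-class conditional logit (`fit_lca`)** is a finite mixture:
class $c$ has its own coefficient vector (including its own ASC), and
respondent $n$ belongs to class $c$ with multinomial-logit probability
built from an intercept plus binary covariates (recent arrival,
bachelor-plus education, clinic attendance); the last class is the
reference. The intercept is included even though covariate coefficients
are the reported quantity — without it the class shares would be chained
to the covariate mix. Estimation is expectation-maximization (posterior
E-step; weighted conditional-logit and weighted membership-logit M-steps)
from `n_starts` perturbed starts (short EM per start, best start continued
to a relative tolerance of $10^{-8}$, at most 500 iterations), then a
bounded quasi-Newton polish of the full mixture likelihood with its
analytic gradient. Membership coefficients are capped at $\pm 10$ — beyond
that scale the logit is saturated and unbounded drift is quasi-separation,
not information. Classes are relabelled by descending average posterior
share so output order is deterministic; reported shares are mean posterior
probabilities.

AIC is $2K - 2\,\mathrm{LL}$ throughout. AIC per $N$ is reported with a
labelled convention flag: the default divides by the number of choice
tasks (2490 at study scale), which is the scale on which a per-observation
AIC near 1.4 arises; dividing by respondents is available as the
alternative convention.

## D-efficient design

`search_design()` builds the choice sets: random start, then coordinate
exchange — visit each (set, alternative, attribute), try each alternative
level, accept the first strict improvement in D-error, keep the incumbent
on ties, stop after a sweep budget or a sweep without improvement. The
criterion is $\det(I(\beta_0)^{-1})^{1/K}$ with the multinomial-logit
Fisher information averaged over choice sets (so replicating sets changes
nothing) and zero priors by default. Rank matters: with 12 sets of 2
designed alternatives, the designed-only information has rank at most 12
and can never identify 13 parameters, so the packaged design is optimized
for the *administered* choice situation — each set evaluated with its
opt-out alternative appended (`include_optout = TRUE`), which restores
identifiability (rank 2 per set). The designed-only criterion remains the
default of `d_error()` for spaces where it is well posed. Blocking into
two blocks of six uses greedy pairwise swaps minimizing between-block
level-count imbalance. The packaged `study_design()` is built once with a
fixed internal seed and cached, so all presets refer to one deterministic
design.

Whether the original survey showed two or three designed alternatives per
set is ambiguous in its description; the package defaults to two designed
alternatives plus opt-out (matching "neither option A nor B") and leaves
the count configurable.

## The synthetic generator

`default_truth()` freezes the simulation conditions:

* **LCA world (default).** The two published preference classes are the
  ground truth: an accuracy-driven majority class and a cost-driven
  minority class, with membership covariate coefficients
  $(0.93, -0.62, -0.88)$ for recent arrival, bachelor-plus education and
  clinic attendance. Covariate prevalences are 30%/68%/86%, mirroring the
  study population's margins (the joint distribution is unreported;
  independence is assumed). The membership intercept is calibrated by
  root-finding so the expected majority-class share is 66% at those
  prevalences, and the opt-out ASC is calibrated the same way so the
  expected opt-out share is 6.4% on the packaged design. Both
  calibrations are closed-form expectations (over the 8 covariate cells,
  and over choice sets and classes), so the preset is deterministic.
* **RPL world.** Means are the share-weighted pooled class utilities,
  all spreads 0.5 — a moderate heterogeneity a mixed logit should both
  detect and recover — with the ASC calibrated against a fixed Halton
  panel.

Simulation draws covariates, class labels or coefficient vectors, and
choices per task from the logit kernel, reproducibly from one seed. What
the generator does *not* emulate: survey dropout, attribute
non-attendance, straight-lining, scale heterogeneity, or any correlation
between covariates. Passing recovery tests therefore demonstrates that
the estimators invert the package's own data-generating process at
realistic sizes — not that the original survey's estimates are
reproduced, which is impossible without its data.

## Post-estimation

Relative importance of attribute $k$ is its utility range share,
$(\max_l \beta_{kl} - \min_l \beta_{kl}) / \sum_{k'} \mathrm{range}_{k'}$,
on completed zero-sum level sets — applied to mixed-logit means for the
pooled figure and per class for class profiles. Predicted uptake of a
scenario is the probability of choosing it over opting out in a
{scenario, opt-out} pair: the logistic of $V - \mathrm{ASC}$ for the
conditional logit, averaged over the fit's own Halton draws for the mixed
logit, share-weighted across classes for the latent-class model. Offering
competitor profiles alongside (uptake = 1 − opt-out probability) is
available as the alternative renormalization; pairwise is the default.
The packaged scenarios are the status-quo, best and worst configurations
of the tool.

## Numerical choices and sizes

* Gradient tolerance $10^{-6}$ (infinity norm) for the conditional logit;
  simulated and mixture likelihoods are maximized by (L-)BFGS with
  analytic gradients and tight relative tolerances.
* EM convergence: relative log-likelihood change below $10^{-8}$ or 500
  iterations; degenerate classes (share < 1%) trigger a warning.
* Test and demonstration sizes are chosen to make recovery informative at
  desk scale: mixed-logit recovery uses 600 respondents × 6 tasks at 300
  draws; latent-class recovery uses 1000 respondents with 20 starts; the
  end-to-end pipeline runs the study's own 415 × 6 with 1000 draws.
* Ties in coordinate exchange keep the incumbent; all searches, blocks,
  fits and simulations are deterministic given their seeds.

## Known limitations

Mixing distributions other than the normal, correlated random
coefficients, Bayesian estimation, willingness-to-pay transforms,
scale-adjusted latent classes and nested logit are out of scope. The
membership logit caps coefficients at ±10, so covariate cells that
perfectly predict class membership are reported at the cap rather than
diverging. Standard errors are curvature-based (observed information);
for spread parameters near zero they are unreliable, and significance
statements about near-zero spreads should lean on likelihood comparison
(AIC) instead.
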