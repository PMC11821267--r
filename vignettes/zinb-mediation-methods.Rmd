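---
title: "Zero-inflated mediation analysis: models, tests and design choices"
author: "zinbMediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-inflated mediation analysis: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
mediation model, the two tests and how they are combined, the effect
decomposition, the simulators, and every place where the design was
genuinely open and a choice had to be made.

## The mediation model

For $n$ samples we observe a binary treatment $T$, a continuous outcome
$Y$, a count matrix $M$ of $m$ taxa, and optionally $q$ baseline
covariates $X$. Each taxon $j$ follows a zero-inflated negative binomial
(ZINB): with probability $\pi_{ij}$ the count is a structural zero,
otherwise it is $\mathrm{NB}(\lambda_{ij}, \phi_j)$ (mean $\lambda$,
variance $\lambda + \lambda^2/\phi$), with

$$\operatorname{logit}(\pi_{ij}) = \gamma_{0j} + \gamma_{1j} T_i + \gamma_{xj}^\top X_i,
\qquad
\log(\lambda_{ij}) = o_i + \alpha_{0j} + \alpha_{1j} T_i + \alpha_{xj}^\top X_i,$$

where $o_i$ is a fixed per-sample offset. The outcome is Gaussian:
$Y \sim N(\beta_0 + \beta_1 T + \beta_x^\top X + \beta_m^\top M,\ \sigma^2)$.
Identification of natural direct/indirect effects needs the usual
sequential-ignorability assumptions (no unmeasured confounding of the
treatment–outcome, mediator–outcome and treatment–mediator relationships,
and no treatment-induced mediator–outcome confounders), plus mediators
that are not causally related to each other. None of these are testable
from data; the confounded simulator exists precisely to probe what
happens when the first one fails.

**The offset.** The structural model conditions on a per-sample
sequencing depth through $o_i$. When fitting real data the default offset
is the log library size; simulated data carry their true log depth
(`logDepth`) and the pipeline uses it. Setting `offset = "none"` drops
depth adjustment. A consequence worth knowing: effect decompositions are
evaluated at offset zero, i.e. on the expected-count scale per unit
depth.

## Testing mediation: joint significance

The per-taxon null is composite:
$H_{0j}: \beta_{mj} = 0 \ \text{or}\ \alpha_{1j} = \gamma_{1j} = 0$ —
taxon $j$ is a mediator only if the treatment moves it *and* it moves the
outcome. Each branch gets its own p-value and the joint-significance
(max-P) rule combines them: $p_{\max,j} = \max(p_{1j}, p_{2j})$. Under
either branch of the null, $p_{\max}$ stochastically dominates the
uniform distribution, so the combination is conservative by construction.

### p1: the zero-inflated distilled conditional randomization test

The conditional randomization test asks: if $M_j$ were irrelevant to $Y$
given everything else, how surprising is the observed association between
the *residualized* outcome and the *residualized* mediator?

1. Fit the ZINB regression of $M_j$ on $(T, X)$; the fitted value is the
   conditional mean $\hat M_{ij} = (1 - \hat\pi_{ij})\hat\lambda_{ij}$.
   (A mixture model has no single canonical "fitted value"; the mean is
   the natural choice and the one used throughout.)
2. Distill the outcome: cross-validated LASSO of $Y$ on $(T, X, M_{-j})$,
   with $T$ and $X$ unpenalized so the exposure and confounders always
   stay in the model. Keep in-sample fitted values $\hat Y_j$.
3. For $b = 1, \dots, B$: draw $M_j^{(b)}$ from the fitted ZINB and
   *refit* the ZINB regression to the draw to get $\hat M_j^{(b)}$.
   Refitting (rather than reusing the original fitted means) is required
   for the exchangeability that makes the test exact.
4. With $s(M) = |(Y - \hat Y_j)^\top (M - \hat M)| / \lVert M - \hat M \rVert_2$,
   report
   $p_{1j} = \bigl(1 + \#\{b : s(M_j^{(b)}) \ge s(M_j)\}\bigr)/(B + 1)$.

Ties count as exceedances, exactly as the indicator is written, with no
randomized tie-breaking. The p-value therefore lives on the grid
$\{k/(B+1)\}$ with floor $1/(B+1)$ — with the default $B = 100$, nothing
can fall below $0.0099$. Resample refits are warm-started from the
observed fit; a failed refit falls back to the observed fitted means and
is counted, and a taxon with more than 20% failed refits is flagged. A
mediator whose residual has zero norm has an undefined statistic; the
taxon gets $p_1 = 1$ and a flag rather than killing the run.

**The floor matters downstream.** BH adjustment across a screened set of
size $|D|$ multiplies the best attainable $p_{\max}$ by roughly
$|D|/(\text{number of taxa at the floor})$, so with $B = 100$ and
$|D| \approx 20$ a taxon needs companions at the floor to clear a 5% FDR.
This produces visibly all-or-nothing selections on small samples; raising
$B$ is the remedy when single-taxon resolution matters.

### p2: the treatment Wald test

$W^2 = \hat\theta_j^\top \widehat{\operatorname{cov}}(\hat\theta_j)^{-1}\hat\theta_j$
with $\hat\theta_j = (\hat\alpha_{1j}, \hat\gamma_{1j})$, referred to
$\chi^2_2$. The covariance is the $(\alpha_1, \gamma_1)$ block of the
inverse *observed* information, obtained by finite differences of the
analytic gradient at the optimum (the asymptotic covariance could equally
be defined through expected information or a sandwich; observed
information is the standard choice when the model is taken at face value,
and the block extraction is invariant to the internal log-$\phi$
parameterization). Known caveat: under quasi-separation of the zero model
(e.g. a treated arm with no structural zeros) $\hat\gamma_1$ diverges,
its standard error diverges faster, and the Wald statistic collapses —
the classic Hauck–Donner effect. The fit is still reported honestly; the
taxon simply loses power. A taxon with numerically singular covariance is
flagged untestable instead of contributing a fake p-value.

### Screening, BH, and selection

A cross-validated LASSO of $Y$ on $(T, M)$ (and $X$; the screening model
keeps the covariates for consistency with distillation) defines
$D = \{j: \hat\beta_{mj} \neq 0\}$ at the CV-minimum penalty, and the
mediation tests run conditional on $D$. BH is applied to
$\{p_{\max,j}: j \in D\}$ only — p-values outside $D$ are never computed,
so adjusting "across all $m$" would be fiction. An empty $D$ is a valid
outcome with zero discoveries. Selection reports $p^{adj} < $ `fdr`
(default 0.05).

### The Gaussian baseline

`runNaiveMediation` is the same pipeline with the mediator model replaced
by a linear regression of $\log(M_j + 1)$ on $(T, X)$ — the log-plus-one
transform being the conventional way normality-based methods consume
count tables — Gaussian resampling with the plug-in residual variance,
and a 1-df Wald test on the slope. It exists as the controlled
comparison: everything identical except the mediator distribution. No
depth offset enters the Gaussian model; the log transform already
absorbs scale differences, and adding one would change the baseline away
from how such methods are actually run. Its effect decomposition is
undefined (there is no presence–absence component in a Gaussian model),
so it reports tests only.

## Fitting the ZINB regression

The observed-data log-likelihood is maximized directly by bounded
quasi-Newton (L-BFGS-B) with analytic gradients implemented in C++, the
dispersion on the log scale to keep $\phi > 0$ (box $|{\log\phi}| \le 15$,
coefficients bounded at $\pm 50$ to stop separation-driven divergence).
Direct maximization rather than EM is deliberate: it is what established
zero-inflation fitters default to, and the randomization test refits the
model $B$ times per taxon, so per-fit cost dominates the pipeline (a
warm-started refit takes a few milliseconds). Initialization: logistic
regression on the zero indicator for $\gamma$, Poisson regression on the
positive counts for $\alpha$, and a moment estimate for $\phi$ (clamped
to $[0.05, 100]$). On non-convergence the optimizer restarts once from a
deterministically perturbed start, then falls back to a plain NB fit,
then flags the taxon untestable — in that order, with every fallback
recorded in `flags` and `converged` set honestly.

Two boundary cases have defined behavior. A taxon with *no* zeros makes
$\pi$ non-identifiable: the fitter returns a plain NB fit with
$\hat\pi \equiv 0$, `gamma = NA`, and a 1-df Wald test of $\alpha_1$
alone. A taxon that is *all* zeros carries no information and raises a
classed error that the pipeline converts to an untestable flag.

## Effect decomposition

Conditional on $X = x$, the natural direct effect is $\beta_1$ and the
per-taxon natural indirect effect is

$$NIE_j = \beta_{mj}\left\{\frac{e^{a_1}}{1 + e^{g_1}} - \frac{e^{a_0}}{1 + e^{g_0}}\right\},
\qquad a_t = \alpha_{0j} + t\,\alpha_{1j} + \alpha_{xj}^\top x,\quad
g_t = \gamma_{0j} + t\,\gamma_{1j} + \gamma_{xj}^\top x.$$

Introducing the latent presence indicator splits this exactly:
$NIEP_j$ replaces the abundance contrast by its $t=1$ value (the part
carried by presence–absence), $NIEA_j$ the presence contrast by its $t=0$
value (the part carried by abundance when present), and
$NIE_j = NIEP_j + NIEA_j$ as an algebraic identity — the test suite
verifies it to $10^{-10}$ over $10^4$ random coefficient draws. All
evaluation is log-space to survive extreme linear predictors. The total
indirect effect is the sum over taxa.

Three open points were settled as follows:

* **Covariate profile.** Effects are reported at the reference profile
  $x = 0$ (and offset 0). Any other profile can be passed via
  `xProfile`.
* **Post-selection coefficients.** $\hat\beta_{mj}$ for reporting comes
  from an *unpenalized* least-squares fit of $Y$ on the selected taxa
  (plus $T$, $X$) — the standard de-biasing practice after LASSO
  selection. A rank-deficient post-selection design is an error that
  names the collinear columns.
* **Confidence intervals.** Uncertainty for a point estimate needs the
  estimator's sampling distribution, so intervals are nonparametric
  bootstrap percentiles: resample rows with replacement, re-estimate,
  take the $(\alpha/2, 1-\alpha/2)$ quantiles of 1000 re-estimates
  (permuting treatment labels would produce a null distribution, not a
  CI, which is why "shuffling"-style intervals are implemented as a
  bootstrap here). Resamples that fail to fit are dropped; more than 20%
  failures is an error, and an interval that fails to cover its own point
  estimate — possible only under degenerate resampling — raises rather
  than being reported.

## The simulators

`simulateZinbData` reproduces the validation conditions exactly:
$T \sim \mathrm{Bernoulli}(0.5)$; $\log S_i \sim U(7.1, 10.5)$ as the
offset; per-taxon coefficients drawn by class — taxa 1–3 with both
treatment paths and an outcome path ($\gamma_1, \alpha_1 \sim N(-2,1)$,
$\beta_m \sim N(2,1)$), taxon 4 zero-model-silent, taxon 5
count-model-silent, taxa 6–10 outcome-path only, taxa 11–25 treatment
paths only in the three possible patterns, and taxa 26..$m$ fully null —
with $\gamma_0 \sim U(-2,2)$, $\phi \sim U(0.1,10)$, $\alpha_0 = -7$,
$\beta_0 = 1$, $\beta_1 = -2$, $\sigma^2 = 1$. Exactly taxa 1–5 satisfy
the causal-mediator rule ($\beta_m \neq 0$ and a nonzero treatment path),
and the generated matrices carry roughly 50–60% zeros. The hurdle
variants keep everything but draw counts from a two-part model (zero with
probability $\pi$, else zero-truncated NB or Poisson) to probe count-model
misspecification.

The confounded generator violates treatment–outcome ignorability: $d = 3$
latent $N(0,1)$ confounders $X_u$ drive the treatment through
$\operatorname{logit}(\eta_i) = \Delta_u^\top X_{iu}$ and the outcome
through an added $\beta_u^\top X_{iu}$, with
$\Delta_u, \beta_u \sim N(0.2h, 0.5)$ (mean/variance convention, matching
the $N(-2,1)$-style notation elsewhere; $\Delta_u$ is read as a single
$d$-vector since the treatment is one draw per sample). Treatment-path
and outcome-path coefficients are redrawn at the stronger $N(\mp 5, 1)$
scale, class structure unchanged. The confounders are stored in `colData`
for inspection but deliberately *not* exposed as observed covariates.

**What the simulators do not emulate** — and hence what passing tests do
not certify about real data: compositional coupling between taxa (taxa
are conditionally independent here), taxon–taxon ecological correlation,
batch structure, covariate-dependent dispersion, and empirically shaped
depth distributions. Results on real microbiome tables inherit all the
usual caveats about unmeasured confounding.

## Defaults, numerics and scale

| Parameter | Default | Why |
|---|---|---|
| `B` | 100 | the study's operating value; sets the p-value floor $1/(B+1)$ |
| `fdr` | 0.05 | conventional FDR threshold |
| `nFolds` | 10 | CV folds for screening and distillation |
| `prevalence` | 0.10 | drop taxa nonzero in <10% of samples on input |
| `ciReps` / `level` | 1000 / 0.95 | bootstrap repetitions / coverage |
| optimizer | L-BFGS-B, `factr 1e7`, 500 iters | relative tolerance ~1e-9 |

All randomness flows from a single integer seed; per-taxon and
per-replicate work derive their own RNG streams from (seed, index), so
results are independent of execution order and bit-reproducible.

The statistical test suite runs at desk scale, chosen to give each check
real resolution while keeping the suite runnable as a routine gate: CRT
calibration at $n = 200$, $B = 50$, 300 replicates; Wald size at
$n = 500$, 500 replicates; parameter recovery at
$n \in \{200, 500, 2000\}$, 50 replicates each; FDR, baseline-comparison
and confounding benchmarks at $(n, m) = (100, 100)$ with 20 replicates
($B = 100$ where selection power is at stake, $B = 50$ under the null;
the confounding trend is checked at its endpoints $h = 1$ and $h = 9$).

## Known limitations

* Joint significance is conservative under the complete null; combined
  with the CRT floor and BH this makes small-$B$ runs blunt instruments.
* Wald power degrades under zero-model separation (see above);
  a likelihood-ratio alternative would dodge this but is not what the
  method specifies.
* Continuous or multi-level treatments, binary/survival outcomes,
  interaction between treatment and mediator, and causally ordered
  mediators are out of scope.
* Empirical p-values make the pipeline's cost linear in $B \times |D|$;
  that is the price of exactness under zero inflation.
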