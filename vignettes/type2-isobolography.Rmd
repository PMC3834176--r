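---
title: "Type II isobolographic analysis: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Type II isobolographic analysis: models, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobolr)
```

## The quantal dose–response model

Every analysis in *isobolr* starts from quantal data: at each dose $d_i$
(mg/kg), $n_i$ animals are tested and $r_i$ respond. The response
probability is modelled as a probit in log dose,

$$p(d) = \Phi\!\big(\beta\,(\log_{10} d - \log_{10}\mathrm{ED}_{50})\big),$$

with $\Phi$ the standard-normal CDF and $\beta$ the slope in probits per
log10-dose unit. `fit_log_probit()` maximizes the Bernoulli
log-likelihood $\sum_i r_i \log p_i + (n_i - r_i)\log(1 - p_i)$ by
iteratively reweighted least squares (a probit-link binomial GLM with
convergence tolerance $10^{-10}$ and at most 200 iterations). This is
the maximum-likelihood formulation of classical log-probit analysis:
historically the computation was nomographic/graphical, but the ML fit
is fully specified, reproducible, and testable against a brute-force
likelihood grid — the test suite verifies that the returned optimum
dominates a dense grid over $(\log_{10}\mathrm{ED}_{50}, \beta)$ and
matches the arg-max of a 2000×2000 grid to better than $10^{-3}$
relative. Groups with 0% or 100% response enter the likelihood as-is;
any continuity correction would be an arbitrary extra choice, and the
likelihood handles such groups naturally.

The fitted curve passes through 50% at the ED50 by construction. The
standard error of $\log_{10}\mathrm{ED}_{50} = -\alpha/\beta$ (with
$\alpha$ the intercept) comes from the delta method on the ML
covariance; the 95% confidence limits are
$10^{\log_{10}\mathrm{ED}_{50} \pm 1.96\,SE}$, symmetric on the log
scale as log-probit intervals are. Data that cannot bracket the ED50 —
all responses zero or all full — raise an explicit "not estimable"
error, as do dose–response patterns with no increasing trend;
non-convergence of the IRLS iteration is flagged and warned about, never
silently returned.

### Confidence limits to SEM

Published studies report ED50s with 95% confidence limits, while the
Welch comparison needs SEMs. `ci_to_sem()` recovers the standard error
where the interval is symmetric — the log scale — and carries it back to
the dose scale by the delta method:

$$\mathrm{SEM}_{\log} = \frac{\log_{10} U - \log_{10} L}{2 \times 1.96},
\qquad \mathrm{SEM} = \mathrm{ED}_{50}\,\ln(10)\,\mathrm{SEM}_{\log}.$$

The naive arithmetic alternative $(U - L)/3.92$ looks similar but does
not propagate correctly: for an alone-drug ED50 of 48.61 mg/kg with
limits 39.18–60.31, the log-scale formula gives 5.349 mg/kg and, divided
by the mass proportions $P_1$ of the 200:1…25:1 ratios, reproduces the
published additive-SEM column (5.37, 5.40, 5.45, 5.55) to ±0.02, whereas
the arithmetic version (5.39) does not. The log-scale form is therefore
the one implemented; `summary_fit()` applies it when packing published
summaries into the fit container.

### The probit-window n

The animal count reported with a log-probit ED50 is conventionally not
the total tested but the number in groups whose *expected* response lies
between 4 and 6 probits on the classical 5-centred scale, i.e. fitted
response in $[\Phi(-1), \Phi(1)] \approx [0.159, 0.841]$ — the
informative part of the curve. `probit_window_n()` implements exactly
this sum; it is the default $n$ attached to fits and carried into the
Welch degrees of freedom.

## Additivity for type II mixtures

A fixed-ratio mixture $a\!:\!b$ (effective : ineffective, by mass) has
proportions $P_1 = a/(a+b)$ and $P_2 = 1 - P_1$ (computed as the
complement so the two sum to one exactly). Because the second drug
contributes no effect of its own, dose additivity predicts the mixture
to act exactly through its effective-drug content:

$$\mathrm{ED}_{50,\mathrm{add}} = \frac{\mathrm{ED}_{50,\mathrm{drug 1}}}{P_1},
\qquad \mathrm{SEM}_{\mathrm{add}} = \frac{\mathrm{SEM}_{\mathrm{drug 1}}}{P_1}.$$

Both scale by $1/P_1$, so the coefficient of variation is preserved —
an invariant the tests check to $10^{-12}$ — and the effective-drug
component of the additive dose, $\mathrm{ED}_{50,\mathrm{add}} \cdot P_1$,
equals the alone ED50 for every ratio (stored exactly by construction,
not recomputed through the division). On the isobologram this is a
horizontal additivity line. The theoretical animal count
$n_\mathrm{add}$ has no closed form in the source conventions
(published tables print a constant, e.g. 22); it is therefore a caller
input, defaulting to the probit-window n of the alone experiment when
one exists.

`decompose_mixture_dose()` splits any total mixture dose by the mass
proportions, computing the second component as total minus first so the
sum reconstitutes the total exactly in floating point.

## Welch classification

`welch_t()` implements the summary-statistic Welch test: SEMs are
treated as standard errors of the means (variance of each estimate
$= \mathrm{SEM}^2$), giving

$$t = \frac{m_2 - m_1}{\sqrt{s_1^2 + s_2^2}}, \qquad
\nu = \frac{(s_1^2 + s_2^2)^2}{s_1^4/(n_1-1) + s_2^4/(n_2-1)},$$

with fractional (unrounded) Welch–Satterthwaite degrees of freedom and a
two-sided p-value — two-sided because star conventions
(0.05/0.01/0.001) never pre-specify a direction. The test suite verifies
the implementation against `stats::t.test()` on raw samples constructed
to have exactly the given means and SEMs. Replaying all 24 published
mixture rows through this test reproduces every published significance
star — including the distinction between the 0.05, 0.01 and 0.001 levels
— which confirms both the fractional-df convention and the log-scale
CI→SEM transform. No multiple-testing correction is applied across the
ratios of a study, matching field practice for these designs.

`classify_interaction()` labels a comparison supra-additive when
$p < 0.05$ and the experimental ED50 lies below the additive one,
sub-additive when significantly above, and additive otherwise; the
reported significance level is the most stringent threshold passed.

## The synthetic-data generator

`simulate_single_drug()` draws $r_i \sim
\mathrm{Binomial}\big(n, \Phi(\beta(\log_{10} d_i - \log_{10}\mathrm{ED}_{50}))\big)$
per dose. The defaults mirror the emulated assay design: 8 animals per
group, five dose levels at 30–70 mg/kg around a true ED50 of
48.61 mg/kg. The slope default of 5 probits per log10-dose unit is not
printed in the source summaries; it was chosen once as a realistic
steepness for this assay — it places the default doses at roughly
15–79% expected response, the informative window a titrated design aims
for.

Seeding derives one substream per dose group from the experiment seed
and the dose value (a small deterministic string hash), so adding a dose
level never perturbs the other groups' draws, and the caller's RNG state
is left untouched.

`simulate_mixture()` gives the mixture a true total-dose ED50 of
$\lambda \cdot \mathrm{ED}_{50}/P_1$ — the additive prediction scaled by
an interaction index $\lambda$ (1 additive, <1 synergy, >1 antagonism) —
and keeps the effective drug's slope, since the emulated studies provide
no mixture-slope information. The dose grid is the alone grid scaled by
$\lambda/P_1$: centred on the mixture's own potency, emulating the
adaptive titration ("doses chosen to obtain a variable percentage of
protection") that quantal assays use in practice. With $P_1 = 1$ and
$\lambda = 1$ the generator reproduces the single-drug experiment
byte-for-byte.

What the generator does *not* emulate: litter/batch effects,
between-day drift, observer error in the all-or-none endpoint, and any
pharmacokinetic interaction between the drugs (brain concentrations are
outside this package's scope). Passing tests therefore validate the
statistical pipeline under clean binomial sampling, not the biology of
any particular assay.

## Operating characteristics and problem sizes

The acceptance checks exercise three Monte-Carlo properties, with
problem sizes chosen for tight Monte-Carlo error at modest runtime:

* **ED50 recovery** — over 500 simulated experiments at the default
  design, the median recovered ED50 falls within 10% of truth
  (typically within 1%).
* **False-synergy rate** — over 4000 replicates with $\lambda = 1$
  (alone and mixture experiments simulated and fitted independently,
  then classified), the supra-additive call rate is checked against
  2.5% ± 1.5 points, the one-direction share of two-sided
  $\alpha = 0.05$. The observed rate is about 1.2–1.5%: at 8 animals per
  group the Wald standard error of $\log_{10}\mathrm{ED}_{50}$ is
  somewhat conservative (empirical coverage of the 95% CI is about 97%),
  and replicates with near-flat likelihoods report inflated SEMs that
  can never reject. The rate sits inside the tolerance band, on its
  conservative side — the pipeline under-calls synergy rather than
  over-calling it, the safer direction for a screening method.
* **Power** — with $\lambda = 0.5$ at the 1:10 ratio the supra-additive
  call rate exceeds 50% (observed ≈ 93–94% over 500 replicates).

Replicates that fail to converge (possible at n = 8 with steep curves,
e.g. complete separation) return no label and are excluded from the
rates; the Welch step floors the probit-window n at 2 so that degrees of
freedom remain defined when a window is empty.

## Numerical and degenerate-input choices

* Proportions: $P_2 = 1 - P_1$ exactly; component doses computed as
  total-minus-first so decompositions reconstitute totals exactly.
* `ci_to_sem()` accepts a zero-width interval (SEM 0) but rejects
  non-ordered limits; `welch_t()` rejects two zero SEMs (undefined t)
  and n < 2.
* Fits are order-invariant in the dose groups and equivariant under
  rescaling all doses by $c > 0$ (ED50, CI and SEM scale by $c$; slope
  unchanged) — both tested.
* Report tables print 2 decimals (field display convention); the JSON
  sidecar keeps full precision. The isobologram error bars project the
  mixture SEM onto the axes by the mass proportions
  ($\mathrm{SEM}\cdot P_1$ vertically, $\mathrm{SEM}\cdot P_2$
  horizontally) — the natural reading of "vertical and horizontal
  components of the error", isolated in one place
  (`render_isobologram()`) since other conventions exist.

## Known limitations

Type I analysis (both drugs active alone, oblique additivity line),
three-drug mixtures, response-surface models (Loewe/Bliss), interaction
indices with propagated confidence intervals, and toxicity (TD50)
fitting are out of scope. Summary-mode analyses inherit whatever
heterogeneity corrections the original study did or did not apply to its
printed confidence limits; no such correction is applied here.
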