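---
title: "Modelling multiphasic dose-response curves with phasefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multiphasic dose-response curves with phasefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(phasefit)
```

## The model

Classical pharmacology describes a dose-response curve with a single Hill
equation. Written on the scale where the untreated response is 1, a single
phase is

$$E_i(C) \;=\; E_{\infty,i} + \frac{1 - E_{\infty,i}}{1 + (C/EC_{50,i})^{H_i}},$$

with midpoint $EC_{50,i}$, steepness $H_i$ and asymptote $E_{\infty,i}$. A
phase is *inhibitory* when $E_{\infty,i} < 1$, *stimulatory* (hormetic) when
$E_{\infty,i} > 1$, and an *identity* phase ($E_{\infty,i} = 1$) contributes
a constant factor of 1. Many real curves are not monophasic: they show a
low-dose stimulatory hump, or two distinct inhibitory transitions, or both.
phasefit models such curves as the product of independent phases,

$$E(C) \;=\; E_0 \prod_{i=1}^{n} E_i(C),$$

the Bliss-independence composition rule on the fractional-response scale:
each phase is read as the drug engaging a separate underlying process, and
independent surviving fractions multiply. The product formulation is only
valid when the baseline response is unity, which is why every input scale
(1→0, 100→0, 0→1, 0→100) is converted to the canonical descending-from-1
scale on ingestion. The optional global factor $E_0$ (`baseline_scale`,
default 1, bounded to $[0.5, 2]$ when freed) absorbs modest
control-normalization error — it corrects a misplaced baseline, it is not an
arbitrary rescaling.

Evaluation supports any number of phases (the five-phase curve in
`reference_shapes()` is an example), but the automated selection searches
exactly four configurations, the cases that cover most of cancer
pharmacology:

| label | phases | free parameters |
|---|---|---|
| `HILL_1I` | 1 inhibitory | 3 |
| `BIPHASIC_2I` | 2 inhibitory | 6 |
| `BIPHASIC_1S1I` | 1 stimulatory + 1 inhibitory | 6 |
| `TRIPHASIC_1S2I` | 1 stimulatory + 2 inhibitory | 9 |

Each phase costs 3 parameters; reduced models are conceptually embedded in
the richest one by fixing surplus phases to the identity, and only free
parameters are counted in the information criteria (+1 when the baseline
scale is freed).

## The objective and its weights

Fitting minimizes the replicate-weighted least-squares objective

$$F \;=\; \sum_{j=1}^{p} \sum_{i=1}^{n_j}
\frac{\left[E^{exp}_{i}(c_j) - E(c_j)\right]^2}{w_j^2},$$

with $w_j = \sigma_j$ (the per-concentration dispersion) under `"sd"`
weighting or $w_j = 1$ under `"unit"` weighting; missing cells are skipped,
never imputed. Under Gaussian noise with known $\sigma_j$, minimizing $F$ is
maximum likelihood and $F$ at the optimum is a $\chi^2$ statistic, which is
what makes the goodness-of-fit test and the information criteria below
meaningful.

$\sigma_j$ must be estimated from the replicates, and with typical replicate
counts (2–4) the raw per-concentration sample sd is a terrible estimator:
its sampling distribution puts heavy mass near zero, and a near-zero
$\hat\sigma_j$ gives one concentration an effectively infinite weight,
letting richer models "win" by interpolating a single lucky triple.
`compute_sigma()` therefore moderates the per-concentration variances toward
the classical pooled variance with prior weight equivalent to 4 degrees of
freedom,

$$\hat\sigma_{j,mod}^2 = \frac{d_0\, s^2_{pool} + d_j\, s_j^2}{d_0 + d_j},
\qquad d_0 = 4,$$

preserving genuine heteroscedasticity while removing degenerate weights.
Concentrations without replicates receive the pooled value (the $d_j = 0$
case), and when no usable dispersion exists at all — single replicates
throughout, or exactly replicated noiseless data — the fit falls back to
unit weighting and flags the fact. This moderation was decisive in
validation: with raw 2-df sds, monophasic curves in simulated screens were
regularly misclassified as multiphasic because a single under-estimated
$\hat\sigma_j$ manufactured spurious lack of fit.

## Ranking: BIC, AIC and the unit-weighting caveat

The four fitted candidates are ranked by BIC (lowest wins; AIC is available
via `criterion = "aic"`), with ties broken toward fewer free parameters —
the conservative choice that favours simpler models. Under `"sd"` weighting
the criteria use $F$ directly as the $-2\log L$ core with constants dropped:

$$\mathrm{AIC} = F + 2k, \qquad \mathrm{BIC} = F + k \ln N,$$

where $N$ counts non-missing observations. Under `"unit"` weighting $F$ is a
raw sum of squares carrying no noise scale, and $F + k\ln N$ would compare a
fit term and a penalty in incommensurate units (concretely: for data in
which the residual scale is small, the penalty always dominates and the Hill
model wins regardless of shape). The package therefore uses the
profiled-variance Gaussian forms there,

$$\mathrm{AIC} = N\ln(F/N) + 2k, \qquad \mathrm{BIC} = N\ln(F/N) + k\ln N,$$

flooring $F$ at an RMS residual of $10^{-7}$ so that numerically perfect
fits of nested candidates tie (and the penalty decides) instead of racing to
$-\infty$.

When more than one replicate is available and sd weighting is in effect, the
goodness of fit is the upper-tail $\chi^2$ probability of $F$ at $N - k$
degrees of freedom. Because $\sigma_j$ is estimated and moderated rather
than known, this p-value is approximately calibrated: on correctly specified
simulations it is spread over $(0,1)$ without collapsing toward either end,
but it is not exactly uniform, and it is absent under unit weighting.

## Estimation

All three optimizers minimize the same $F$ on a smooth reparameterization
that enforces the interpretable regime without hard box constraints:
$\log_{10} EC_{50}$ (clamped to $\pm 15$ for numerical safety),
$\log H$ (clamped to $H \in [10^{-3}, 10^{3}]$), a logistic map keeping
inhibitory $E_\infty$ in $(0,1)$ and stimulatory $E_\infty$ in
$(1, E_{\infty}^{max}]$ with $E_{\infty}^{max} = 5$ by default, and a
logistic map into $[0.5, 2]$ for a free baseline.

* `trust_region` (default): least squares on the $\sqrt{w}$-scaled residual
  vector via Levenberg–Marquardt (`minpack.lm::nls.lm`), whose implicit
  objective equals $F$ exactly. It converges in tens of evaluations and is
  the fastest of the three.
* `simplex`: derivative-free Nelder–Mead on $F$.
* `simplex_constrained`: Nelder–Mead on $F$ plus a smooth quadratic penalty
  that activates when consecutive phases (sorted by $EC_{50}$) come within
  `separation_delta` decades of each other (default 0.5), realizing the
  requirement that the underlying processes be well separated in
  concentration space. The penalty scale ($10^4$ per squared decade of
  violation) dominates $F$ near violation.

The $F$ surface of a multiphasic model is multimodal, so each fit runs from
`n_starts` deterministic starts (default 10): $EC_{50}$ seeds rotate through
quantile patterns of the tested log-concentration range (including
edge-heavy patterns, where secondary transitions hide), $H$ starts at 1,
inhibitory asymptotes start from the mean effect at the top concentration,
stimulatory ones at $\max(\text{peak mean effect}, 1.2)$, and starts after
the first receive seeded Gaussian jitter. Identical settings and seed give
bit-identical fits.

`select_model()` adds two deterministic refinements around the prescribed
fitting order (Hill, then two-inhibitory, then stimulatory+inhibitory, then
triphasic):

* *warm starts*: each richer candidate also starts from the best simpler
  fit with the surplus phase parked near the identity at either edge of the
  tested range — this is what guarantees, in practice, that a richer model
  never fits worse than a nested simpler one;
* *a backward pruning pass*: after all four forward fits, each reduced
  candidate is re-fit from every richer fit with its surplus phases
  dropped, keeping any improvement in $F$. This matters because a reduced
  model can sit in a local optimum that the richer fit escaped; without it,
  two-inhibitory curves were regularly over-classified as triphasic.

Candidates whose fitted phases are degenerate (asymptote within $10^{-3}$
of baseline, or $EC_{50}$ more than 3 decades outside the tested range) are
kept in the ranking but flagged `"effectively_simpler"`.

Convergence tolerances default to $10^{-8}$ on both $F$ and the parameters,
with at most 2000 iterations per start.

## Derived metrics

`effective_concentration()` computes ECx values. On a multiphasic curve the
textbook definition is ambiguous (absolute level vs span-relative, and a
non-monotone curve can cross a level several times). The package solves

$$E(c) = E_0 - \mathrm{level} \times (E_0 - E_{floor}),$$

where $E_{floor}$ is the model value at the upper edge of the search window
(default: the tested range widened by 3 decades each side). All crossings
found by a 1000-point log-grid sign scan refined by bisection are returned
in ascending order, with the smallest flagged primary. This definition
degrades gracefully to the standard Hill ECx — exactly so as the window
widens, since $E_{floor} \to E_\infty$ — and never hides multiplicity.

`model_auc()` integrates the fitted curve over $\log_{10} C$ with a
2001-point composite trapezoid (optionally normalized by the interval width
to a mean-effect scale), and `effect_at()` interpolates or extrapolates
effects, flagging predictions outside the tested range.

## The synthetic generator

`simulate_curve()` adds i.i.d. Gaussian noise (sd $\sigma$, truncated at 0
from below, since a viability readout cannot be negative) to a known model —
the truncation slightly biases noise near full inhibition, and recovery
tolerances account for that. `simulate_screen()` draws each curve's class
from given proportions and its parameters log-uniformly within
`default_screen_ranges()`: $EC_{50}$s in the interior of the tested range
(half a decade in from each edge) with at least 1.5 decades of separation
between consecutive phases, $H \in [0.5, 4]$, terminal inhibitory
$E_\infty \in [0, 0.4]$, intermediate inhibitory $E_\infty \in [0.35,
0.65]$, stimulatory $E_\infty \in [1.25, 1.6]$ with curves redrawn until
the realized peak exceeds 1.2. The intermediate-vs-terminal split exists
because an early phase with $E_\infty \approx 0$ flattens the curve and
leaves later phases with no signal — the generator's job is to produce
phases that are actually present in the data, like the canonical reference
shapes. The default grid is 9 concentrations, one per decade over
$10^{-4}$–$10^{4}$, with 3 replicates and $\sigma = 0.05$, a deliberately
modest HTS-like design.

What the generator does *not* emulate: plate spatial effects, batch
drifts, heavy-tailed or proportional noise, or correlated replicates. A
passing recovery suite therefore shows that the estimation machinery is
correct and well-calibrated under its own assumptions, not that every real
screen will classify as cleanly.

## Validation problem sizes

The test suite validates parameter recovery on 50 simulated monophasic
curves (9 concentrations, 3 replicates, $\sigma = 0.05$; median relative
$EC_{50}$ error under 10%) and 50 well-separated biphasic curves (EC50 gaps
of at least 2 decades, half-decade sampling over 8 decades — two
transitions cannot be localized from one or two points each; the median
over all 100 recovered $EC_{50}$s stays under 15%, while individual curves
can do worse since a per-transition error of 15–20% is the intrinsic
statistical uncertainty at this noise level). Class recovery runs a
200-curve screen (50 per class) and requires at least 80% per-class
accuracy and at least 90% on the mono- vs multi-phasic dichotomy. The
acceptance script (`scripts/acceptance.R`) recomputes all of these from
scratch for any seed.

## Known limitations

* The selection search is restricted to the four configurations; curves
  with more phases (or two stimulatory phases) are evaluable and simulable
  but not selectable.
* ECx on multiphasic curves is definition-dependent; the span-relative
  choice here is one defensible convention, reported with all crossings so
  nothing is hidden.
* The GOF p-value is approximate when $\sigma$ is estimated from few
  replicates (see above).
* Asymmetric (5-parameter) Hill variants, robust losses, and parameter
  uncertainty (bootstrap or profile intervals) are out of scope.

## A worked example

```{r example}
shapes <- reference_shapes()
ds <- simulate_curve(shapes$stimulatory_inhibitory,
                     concentrations = 10^seq(-4, 2, by = 0.5),
                     n_replicates = 3, sigma = 0.04, seed = 5,
                     unit = "uM", title = "hormetic example")
sel <- select_model(ds, fit_settings(seed = 5))
tidy(sel)[, c("configuration", "f_value", "bic", "rank", "best")]
classify(sel)
effective_concentration(sel$candidates[[sel$best]], level = 0.5)
```

```{r plot}
autoplot(sel)
```
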