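---
title: "Growth kinetics and minimal defined media: models, assumptions, choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth kinetics and minimal defined media: models, assumptions, choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthmedia)
```

## The problem

Lactic acid bacteria grown in microtiter plates produce optical-density
(OD600) time series: a lag phase while cells adapt, roughly exponential
growth, then saturation as nutrients run out. Two questions drive this
package. First, *kinetics*: what are a strain's lag duration, maximum
specific growth rate, minimum doubling time and maximum density, estimated
from the whole curve rather than from an eyeballed exponential window?
Second, *nutrition*: which components of a chemically defined medium (CDM)
does a strain actually need, and what minimal defined medium (MDM) follows
from that?

## The model family

All fitted models are members of one nested family. The general form is the
Baranyi–Roberts model

$$N(t) = \frac{K}{\left[1 + \left((K/N_0)^v - 1\right)
  e^{-r v A(t)}\right]^{1/v}},$$

with the physiological adjustment function
$\alpha(t) = q_0 / (q_0 + e^{-mt})$ and its integral
$A(t) = t + \frac{1}{m}\log\frac{e^{-mt} + q_0}{1 + q_0}$. The
differential form is $dN/dt = r\,\alpha(t)\,N\,(1 - (N/K)^v)$. Here $N_0$
is the initial density (OD), $r$ the intrinsic rate constant (h⁻¹), $K$
the carrying capacity (OD), $v$ a dimensionless shape parameter, $q_0$ the
initial physiological state (small $q_0$ means a long lag) and $m$ the
adjustment rate (h⁻¹).

Fixing parameters gives the nested members: `Logistic` ($v = 1$, no lag;
3 free parameters), `Richards` (free $v$, no lag; 4), `LogisticLag2`
($v = 1$ with the lag machinery; 5) and `BaranyiRoberts` (all 6). Two
representation choices matter:

* The no-lag limit $q_0, m \to \infty$ is represented structurally
  ($\alpha \equiv 1$), never by numeric infinities.
* `LogisticLag2` is defined as Baranyi–Roberts with $v$ fixed at 1 — the
  unique nesting step between the logistic and the full model that carries
  a lag term.

Printed versions of these equations sometimes mix $t$ and $A(t)$, or $m$
and $v$, inside the adjustment integral; the package uses the
self-consistent form above, which agrees with the differential form — the
two are cross-checked numerically in the test suite with an independent
Runge–Kutta integration (`integrate_ode()`, sup-error below 1e-6 across
seeded parameter sweeps).

### Numerical evaluation

Exponentials are evaluated in log space
($\log((K/N_0)^v - 1)$ via `log1p`, the denominator via a softplus), so
valid parameter sets never overflow to `NaN`; output is clipped to
$(0, K]$ only to absorb last-bit rounding. The ODE solver is an adaptive
Dormand–Prince 5(4) scheme written for this package (no initial-value
solver is available in the declared dependency set), with per-component
error control and a step budget; it serves as the oracle for the closed
forms and as the integrator for the competition system.

## Fitting and model selection

Replicate wells are pooled into one residual vector — no averaging — so
the point count `n` entering the information criterion is the true number
of observations and replicate variance is preserved. Residuals are on the
raw OD scale. Least squares uses `stats::optim` (L-BFGS-B) on a
transformed scale: $N_0 = K \cdot \mathrm{logistic}(\theta_1)$ enforces
$N_0 < K$ by construction, all other parameters are optimised on the log
scale inside generous physical bounds ($r \in [10^{-3}, 10]$ h⁻¹,
$K \in [10^{-3}, 10]$ OD, $v \in [0.05, 20]$, $q_0 \in [10^{-4}, 10^4]$,
$m \in [10^{-3}, 20]$ h⁻¹). Five multi-starts per model (the first from
data-driven heuristics or the best nested simpler fit, the rest jittered
±20% log-uniformly under a fixed seed) guard against local minima; the
lowest-RSS converged start wins. A start that stops with a line-search
warning is accepted only when it is at least as good as a start that
converged cleanly — the "started at the optimum" pathology, not a failure
to fit.

Model choice uses the least-squares Bayesian information criterion
$\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + k \ln n$ (natural logarithm; the
base is a documented choice — "log" alone is ambiguous, and the natural
log is the standard definition). Lower is better. Fits whose BIC differ by
at most 2 units are treated as tied and ordered by parameter count — the
conventional "not worth more than a bare mention" margin; this is what
lets the 3-parameter logistic win over a 6-parameter fit that merely
matches it. A perfect fit (RSS = 0, possible only on noise-free synthetic
data) has an undefined criterion; perfect fits rank by parameter count
alone.

## Derived kinetics

All summaries come from the fitted curve on a dense grid (default step
0.01 h over the observation window, each extremum refined by a local 1-D
optimisation):

* $\mu_{max} = \max_t (1/N)\,dN/dt$ — maximum specific growth rate;
* minimum doubling time $= \ln 2 / \mu_{max}$, an exact identity by
  construction (note: a published summary pair 0.26 h⁻¹ / 2.74 h is
  internally inconsistent with this identity — $\ln 2 / 0.26 = 2.67$; the
  package never reproduces that inconsistency);
* lag $\lambda$: the tangent to $N(t)$ at the point of maximum derivative
  intersects the level $N_0$ at $t^* - (N(t^*) - N_0)/N'(t^*)$, clipped
  at 0;
* maximum density: the model asymptote $K$;
* AUC: trapezoidal area under the fitted curve, an integrated growth
  summary correlated with both rate and yield.

`params_from_summary()` inverts this map: given a published
$(N_0, K, \mu_{max}, \lambda)$ summary it finds lagged parameters (with
$v = 1$) whose derived summaries reproduce it. Two targets with three
unknowns $(r, q_0, m)$ are closed with the common Baranyi convention
$m = r$ (one adjustment timescale). This is how the simulation studies
regenerate plate data "like" a published strain without its raw curves.

## Competition simulation

Mixed-culture dynamics are predicted — not fitted — from monoculture
parameters with the two-strain Lotka–Volterra system

$$\frac{dN_1}{dt} = r_1 \alpha_1(t) N_1
  \left(1 - \frac{N_1^{v_1}}{K_1^{v_1}}
          - c_2 \frac{N_2^{v_2}}{K_1^{v_1}}\right),$$

and symmetrically for strain 2 (the multiplying density in the second
equation is $N_2$; a transcription that multiplies by $N_1$ breaks the
symmetric limit and is not the named model). With no mixed-culture OD to
fit, the competition coefficients default to $c_i = 1$. The cross term's
denominator follows the resident strain's capacity by default
(`cross_k = "resident"`, the printed convention); a competitor-capacity
normalisation is exposed as an option since the choice is not identifiable
from monoculture data. Integration uses the package Runge–Kutta solver at
relative tolerance 1e-8 with densities clipped at 0. Structural checks:
an absent or uncoupled competitor reproduces the monoculture closed form
to 1e-6; identical strains with $v = 1$, $c = 1$ split the monoculture
solution exactly; increasing the pressure on a strain never raises its
final density.

## Single-omission analysis and media composition

Relative growth is the plain 24-h OD ratio,
$100 \times \mathrm{OD}_{omit} / \mathrm{OD}_{control}$. The threshold
rule calls a component **essential** below 40%, **stimulatory** from 40 to
80% (both endpoints inclusive — the source phrasing "between 40 and 80%"
leaves the boundaries open; strictly-below-40 for essential forces 40 into
the middle class, and 80 is kept there by symmetry) and **non-essential**
above 80%. The bundled 37-row omission table ships with its printed
relative-growth values; classifying those reproduces all 74 printed calls.
The complete-medium control OD behind the printed percentages is not
published, so `analyze_soe_table()` accepts either per-strain controls or
precomputed percentages rather than inventing a control value.

Minimal media follow mechanically from the calls: essential and
stimulatory components are retained, non-essential ones dropped,
un-called components kept. Two documented exception sets make the
published compositions reproducible without silent special cases:
cysteine is kept despite non-essential calls in both strains
(`keep_overrides`), and six trace minerals are dropped although they have
no omission rows (`drop_overrides`). Group omissions (all amino acids,
all vitamins, all nucleotides at once) are pseudo-components: they are
classified like any row but never drive composition. The co-culture
medium is the set union of the two per-strain media, with equal
concentrations required for shared components. One fixture annotation: the
omission row printed as "Thiamine (T)" sits among the nucleotide bases
between uracil and xanthine and is mapped to thymidine (the medium table
has thymidine and a separate thiamine-HCl row); this is flagged in the
fixture header.

## The synthetic-data generator

`generate_plate()` emulates the plate design the analysis assumes: 36 h at
15-min intervals giving exactly 144 readings per well (t = 0 to 35.75 h —
the printed reading count is matched by sampling up to duration minus one
interval), 40 replicate wells per strain by default, 8 uninoculated blank
wells, a 0.05-OD background added to every well, and additive Gaussian
noise with sd 0.02 OD (typical plate-reader repeatability; proportional
noise available, default 0). Identical seeds give byte-identical
datasets, and the RNG state of the calling session is left untouched.

What a green test establishes: the estimator recovers the generating
kinetics through the full generate → blank-correct → fit → select →
summarise pipeline under this noise model. What it does not establish:
robustness to evaporation and edge effects, OD nonlinearity at high
density (published endpoint ODs up to ~5.9 are taken at face value), or
path-length differences — none of these are simulated, deliberately.

`generate_soe_dataset()` draws omission endpoints from class bands placed
away from the 40/80 boundaries (essential 0–35%, stimulatory 45–75%,
non-essential 85–115% of control), so truth labels are recoverable and a
classifier failure indicates a real defect rather than boundary noise.

## Scope decisions

* Gompertz and three-phase linear models are out of scope; the family is
  exactly the four nested members above. A five-parameter variant with
  only `m` fixed is conceivable but is not part of the published family
  and is not implemented.
* No confidence intervals or bootstrap on fitted parameters; point
  summaries only.
* No CFU/OD calibration anywhere; OD is the density unit throughout, and
  time is hours (readers convert declared minutes columns on request).
* Residuals default to the raw OD scale; a log-scale residual option was
  considered and deferred — the published account describes log plots for
  display, not for fitting.
* Fitting the competition model to mixed-culture data is out of scope
  (none exists in the motivating setting); simulation only.
* Scaled-down designs in the routine test suite (fewer wells per run, the
  seeded-selection sweep at one well per run) keep runtimes in minutes;
  the published 30-well design is exercised in the acceptance checks.
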