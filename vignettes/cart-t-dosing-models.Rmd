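---
title: "Modeling CAR-T therapy of glioblastoma: models, protocols and sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CAR-T therapy of glioblastoma: models, protocols and sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartsim)
library(dplyr)
```

## The models

cartsim simulates the interaction of a glioblastoma cell population $T(t)$
with chimeric antigen receptor (CAR) T cells $C(t)$, both in absolute cell
counts, over days. Three nested deterministic models are provided.

**Base model.** Tumor growth is logistic with net rate $\rho_T$ and
carrying capacity $K$; CAR-T cells kill tumor cells bilinearly at rate
$\alpha_T$ per cell, proliferate on tumor contact with a saturating rate
(maximum $\rho_C$, half-saturation $g_T$), are inactivated by the tumor
with a saturating rate (maximum $\alpha_C$, half-saturation $g_C$ in the
CAR-T population itself) and die naturally with mean lifetime $\tau_C$:

$$
\begin{aligned}
T' &= \rho_T T\left(1 - \tfrac{T}{K}\right) - \alpha_T C T,\\
C' &= \left(\frac{\rho_C T}{g_T + T} - \frac{\alpha_C T}{g_C + C}
  - \frac{1}{\tau_C}\right) C.
\end{aligned}
$$

**Resistance model.** Intracranial therapy can induce resistance whose
mechanism is unresolved but whose effect is a progressive loss of
efficacy. A dimensionless resistance strength $R(t) \in [0, 1)$ discounts
both the kill term and the proliferation drive by $1 - R$ and accrues in
proportion to CAR-T exposure with self-limitation,
$R' = \alpha_R C (1 - R)$, $R(0) = 0$. Starting from zero, $R$ is
nondecreasing and never reaches 1. A note on units: $R$ is dimensionless
and $C$ is a cell count, so $\alpha_R$ carries units of
cell$^{-1}$day$^{-1}$ (the "per day" label sometimes attached to it only
works for densities).

**Delay model.** Intravenously administered CAR-T cells take time to
cross the blood-brain barrier, reach the tumor and activate. The
proliferation drive is therefore evaluated a fixed lag $\tau$ in the
past, $\rho_C T(t-\tau) C(t-\tau) / (g_T + T(t-\tau))$, while killing,
inactivation and death act on the present state. With $\tau = 0$ the
model reduces exactly to the base model. The pre-treatment history is the
logistic flow for the tumor ([logistic_history()]) and zero for CAR-T
cells, with the first dose appearing as $C(0)$.

**Reference parameters.** `cart_params()` defaults to the reference set:
$\rho_T = 0.01$/d, $K = 2\times10^{12}$, $\alpha_T = 2.5\times10^{-10}$
cell$^{-1}$d$^{-1}$, $\rho_C = 0.9$/d, $g_T = 10^{10}$,
$\alpha_C = 0.05$/d, $g_C = 2\times10^9$, $\tau_C = 7$ d,
$\alpha_R = 8\times10^{-10}$ cell$^{-1}$d$^{-1}$, $\tau = 2$ d, with a
baseline tumor of $T_0 = 1.5\times10^{10}$ cells (a roughly 1 cm-radius
lesion). The growth rate deserves a comment: plausible published variants
of this set differ in whether $\rho_T$ is 0.01 or 0.012 and whether $K$
is $10^{12}$ or $2\times10^{12}$. We fixed $\rho_T = 0.01$,
$K = 2\times10^{12}$ because only that combination reproduces the whole
panel of protocol outcomes the package is validated against (times to
progression from ~400 to ~2100 days across seven cyclic protocols and
the day-540 burden table); the alternative parsing misses the cyclic
protocol outcomes by 10% or more. Both remain reachable through
`cart_params()` arguments or a key-value config file.

## Impulsive dosing and the integrators

Doses are impulses: at a scheduled time $t_n$ the CAR-T count jumps by
the dose, $C(t_n) = \lim_{t \to t_n^-} C(t) + m$, while $T$ (and $R$)
carry over continuously. A [dose_schedule()] is a tibble of `(day,
cells)`; the entry at day 0 doubles as the initial condition $C(0)$.

The ODE models are integrated with the classical fixed-step 4th-order
Runge-Kutta scheme, the delay model with 2nd-order Runge-Kutta (Heun) by
the method of steps. Numerical conventions, all of which the test suite
pins down:

* the default step is `dt = 0.01` d, chosen so the fastest CAR-T
  transients (~0.5/d rates) are resolved with locally $10^{-8}$-level
  error; halving the step moves times to progression by under a day and
  day-540 burdens by ≤0.15% (the worst case being the single-dose run,
  whose deep tumor nadir amplifies step error through the regrowth
  phase — the refinement study in the suite pins this down);
* dose times must sit exactly on the step grid — off-grid times are
  rejected rather than silently rounded, and protocol times are whole
  days so the default grid always contains them;
* stored states at dose times are the post-impulse (right) limits; the
  left limit is the preceding grid point;
* the lag must be an exact number of steps ($\tau = 2$ d is 200 steps),
  so delayed lookups land on stored grid points and never interpolate
  across a dose discontinuity; the lookup at exactly $t - \tau = 0$
  returns $C(0)$ including the first dose (right-continuity);
* values driven within $10^{-9}\cdot$scale below zero by roundoff are
  clamped to zero; anything worse aborts loudly — saturating
  denominators must not hide instability;
* no adaptive stepping: outcomes are defined at a fixed, documented
  resolution, and empirical convergence orders (4 for RK4, 2 for RK2 on
  smooth stretches) are tested.

The integrator cores are small C++ routines (via Rcpp); the R layer owns
validation, the trajectory container and everything downstream.

## Protocols and endpoints

Three clinical regimens ship as presets ([preset_scenario()]):

* `il13` — intracranial IL13Rα2 targeting, resistance model: 2×10⁶
  cells at day 0, then 19 weekly doses of 10⁷ cells with a 5-week break
  between the 15th and 16th (days 7–105, then 140–161);
* `her2_low` / `her2_high` — intravenous HER2/CMV targeting, delay
  model: seven equal doses (initial plus six) at 6-week (1.89×10⁶
  cells) or 12-week (1.89×10⁸ cells) intervals. Doses follow the per-m²
  prescription (10⁶–10⁸ cells/m²) for the 70 kg / 180 cm reference
  patient, whose Haycock body surface area ([haycock_bsa()]) is 1.87 m²;
  the per-dose grid uses the published absolute values
  1.89×10⁶–1.89×10⁸ cells (which correspond to a 1.89 m² surface — a
  Du Bois-style figure about 1% above Haycock's; the absolute doses,
  being the stated protocol inputs, are what the simulations use);
* `egfr` — intravenous EGFRvIII targeting, delay model: one dose of
  5×10⁸ cells.

Endpoints are deterministic trajectory functionals: **time to
progression** (TTP) is the first return of the tumor to its
pre-treatment size after having dropped below it. The alternative
reading — first time $T \ge T_0$ regardless of a prior dip — returns 0
whenever $T(0) = T_0$ and cannot describe any successful treatment, so
the dip-first reading is used; a tumor that never regresses progresses
immediately (TTP 0) and one still below baseline at the horizon is
censored (`NA`). Threshold crossings (tumor above $3.5\times10^{10}$
cells ≈ one third of the lethal burden; CAR-T below the 1000-cell
monitoring limit, the operational meaning of "undetectable") and
fixed-day burdens are linearly interpolated on the grid, which at
`dt = 0.01` makes further root polishing pointless. Default horizons are
540 days for burden comparisons and up to 2500 days for TTP sweeps,
long enough to contain the latest observed progression (~2140 days).

Sweep helpers evaluate protocol grids: `sweep_split_doses()` divides the
fixed 1.9×10⁸-cell intracranial budget into 1–19 equal doses at 4–10 day
spacing; `sweep_protocols()` crosses dose size, number of additional
doses (0–6) and interval (6–12 weeks, extended to 1–15 weeks by
`sweep_intervals()`) for the intravenous regimen.

## Morris screening

Parameter influence is screened with the Morris elementary-effects
method: $r$ randomized one-at-a-time trajectories on a $p$-level grid
over the 11 inputs (nine rate constants plus both initial conditions,
$\alpha_R$ for the resistance model, $\tau$ for the delay model), each
varied uniformly ±20% around its reference. Outputs are single-dose
functionals — $T$ and $C$ at days 180/360/540, the two threshold times,
and running averages — with the screening doses $C_0 = 2\times10^7$
(resistance) and $5\times10^8$ (delay). Per input we report
$\mu^* = \mathrm{mean}\,|EE|$ and $\sigma = \mathrm{sd}(EE)$, raw and
normalized by their maxima.

Design choices where practice had to fill gaps:

* defaults $r = 50$, $p = 4$ ($\Delta = 2/3$), fixed seed — standard
  screening settings; rankings, not magnitudes, are the reproducible
  quantity, and the suite checks they are stable across independent
  designs ($r$ 50 vs 100, different seeds);
* threshold times that never trigger within the 2500-day horizon are
  assigned the horizon value (keeps effects finite; censoring is rare in
  the ±20% box);
* cyclic dosing is deliberately excluded from screening — inputs are
  screened in the single-dose setting;
* for the delay model the lag varies continuously over its range and is
  snapped to the nearest step multiple inside the screening runner only
  (≤ `dt`/2, i.e. <0.3% of $\tau$); the integrator itself keeps
  rejecting off-grid lags.

## What the simulations do and do not show

Everything here is a deterministic, spatially homogeneous two- (or
three-) compartment caricature with logistic growth: no immune
compartments beyond CAR-T cells, no tumor heterogeneity or antigen loss,
no pharmacokinetics between infusion and tumor site beyond the single
lag $\tau$, and parameters assembled from disparate sources rather than
fitted to patient trajectories. Reproducing the published protocol
comparisons therefore validates the implementation, not the biology;
outcome values are qualitative guides to protocol ranking (e.g. that
moderate doses at long intervals can outlast dose-dense schedules by
sustaining the CAR-T/tumor predator-prey cycle), not patient
predictions.

One internal inconsistency of the validation panel deserves note: with
the reference set that reproduces every cyclic-protocol outcome, the
single-dose EGFRvIII run peaks its CAR-T series near day 19 with
progression at ~476 days — while the qualitative narrative attached to
that scenario in the source trials (peak within days 3–10, undetectable
by day 30, progression ~425 days) is not reproduced by any parameter
variant we probed. The corresponding checks are kept in the suite as
documented failures rather than silently relaxed.

## A worked run

```{r, fig.width = 6, fig.height = 5}
run <- run_scenario(preset_scenario("her2_high"))
run$endpoints
glance(run$trajectory)
ggplot2::autoplot(run$trajectory)
```

Problem sizes used throughout the package's own checks: single
trajectories use the default `dt = 0.01` (150,000–250,000 steps for
1500–2500-day horizons); screening runs are $r = 50$ trajectories × 12
design points each; sweep examples use coarser steps (`dt = 0.02`–`0.05`)
where only rankings matter.
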