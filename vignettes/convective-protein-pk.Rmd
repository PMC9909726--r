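---
title: "A lumped convective model for plasma-protein pharmacokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped convective model for plasma-protein pharmacokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protpk)
```

## The model

Plasma proteins — albumin, therapeutic antibodies, and the diagnostic
enzymes (transaminases, amylase, lipase, creatine kinase, lactate
dehydrogenase, alkaline phosphatases) — distribute essentially in the
extracellular space. `protpk` models their disposition with three
compartments: the plasma volume $V_p$ and two lumped tissue interstitia,
a large slow-turnover lump $V_1$ (skin, subcutis, skeletal muscle) and a
smaller fast-turnover lump $V_2$ (the splanchnic bed). Transcapillary
transport is purely convective: water filters from plasma into tissue $i$
at the lymph flow rate $L_i$, carrying protein sieved by a factor
$f_i \in (0, 1]$, and returns unsieved with the lymph. Catabolism removes
protein from the plasma at clearance $Cl_p$. The concentrations obey

$$
\begin{aligned}
V_p \frac{dC_p}{dt} &= -(Cl_p + f_1 L_1 + f_2 L_2)\,C_p
  + L_1 C_1 + L_2 C_2 + u(t),\\
V_i \frac{dC_i}{dt} &= f_i L_i C_p - L_i C_i, \qquad i = 1, 2 .
\end{aligned}
$$

The liver is deliberately *not* a tissue compartment: its sinusoids are so
permeable that hepatic interstitium equilibrates with plasma within
minutes and is folded into $V_p$.

An equivalent parameterisation uses five steady-state time constants:
the metabolic constant $T_M = V_p / Cl_p$, the filtration constants
$T_{Pi} = V_p T_{Ti} / (f_i V_i)$ and the tissue washout constants
$T_{Ti} = V_i / L_i$. The two parameter sets interconvert exactly
(`compartmental_to_physiological()`, `physiological_to_compartmental()`);
the round trip is the identity to machine precision. Plasma kinetics
depend only on the five time constants; the physiological reading is what
additionally predicts tissue and lymph concentrations, which is the
model's real constraint on reality.

Three steady-state summaries anchor the tissue volumes to measurable
quantities (`steady_state_summary()`): total lymph flow $L_1 + L_2$; the
pooled (thoracic-duct-like) lymph/plasma concentration ratio
$(f_1 L_1 + f_2 L_2)/(L_1 + L_2)$; and the extravascular distribution
volume $V_\mathrm{ECF} = f_1 V_1 + f_2 V_2$.

## What makes the model restrictive

Within a species, $L_1$, $L_2$, $V_1$ and $V_2$ are fixed once — human
and baboon use $V_1/V_p = 1.3$, $V_2/V_p = 0.4$; dog and lamb use 1.0
and 0.3, with $V_p = 2800$ ml throughout (everything scaled to a 70 kg
human). The capillary pore should look the same to both tissue lumps, so
$f_1 \approx f_2$, and $f$ must decrease with molecular weight. A protein
is then characterised by just two adjustable numbers, $Cl_p$ and $f$ — or
one, when a similarly sized protein has already pinned $f$. The packaged
catalog (`load_catalog()`) holds both parameterisations for 13 proteins
in four species; `check_catalog()` verifies their mutual consistency
(entries agree within 1 % or to their printed precision — one clearance
is printed to only two significant digits).

## Dosing, simulation, derived quantities

`simulate_pk()` integrates the system under bolus or constant-rate
infusion schedules into plasma, tissue 1 (a subcutaneous-like route) or
tissue 2 (a gastrointestinal-like route), with optional periodic
repetition. The system is linear with piecewise-constant inputs, so the
solver (`deSolve::lsoda`, relative tolerance $10^{-10}$, absolute
tolerance $10^{-12}$ scaled by the dose-equivalent plasma concentration)
is restarted at every known input discontinuity; no event detection is
involved. Boluses are instantaneous mixing: $C_p(0) = D/V_p$. The tests
hold every simulation to the piecewise matrix-exponential closed form
within $10^{-8}$ and to a global mass balance within $10^{-6}$.

Two derived quantities deserve comment:

* `half_time()` — the first time $C_p$ falls to half its post-bolus
  value, refined below 0.1 min by root-finding on the eigen-mode
  propagation of the input-free system. For albumin this is about 2 days,
  an order of magnitude shorter than the terminal decay: the early fall
  is distribution, not catabolism.
* `terminal_time_constant()` — the equilibrated-pool approximation
  $T_M (1 + T_{T1}/T_{P1} + T_{T2}/T_{P2})$, about 26 days for albumin.
  The exact slowest eigen-mode (`method = "eigen"`) is 39,521 min,
  5.2 % above the approximation; both are exposed because the
  approximation is the quantity usually quoted.

A limiting regime worth knowing: when $T_M$ is far shorter than the
exchange constants (amylase, lipase, mitochondrial AST), the bolus decay
is effectively a single exponential. Its fitted rate over the first
$2 T_M$ is within about 1–2 % of $(Cl_p + f_1 L_1 + f_2 L_2)/V_p$ — the
sieved filtration outflux also drains the plasma early on — and hence
some 5 % faster than $Cl_p/V_p$ alone for amylase. The package reports
$V_p/Cl_p$ as the metabolic constant and the tests assert both facts at
those honest tolerances.

## The liver-recycling extension

Intestinal alkaline phosphatase (and its recombinant chimera recAP) is a
glycoprotein handled by the hepatic asialoglycoprotein receptor: rapid
binding, uptake and mostly intact recycling, with slow hepatic
catabolism. `simulate_liver_model()` adds a liver compartment of
equivalent volume $V_L$ (a binding capacity, 26 plasma volumes for
recAP), exchanging with plasma by a symmetric bidirectional clearance $k$
(50 times the plasma-to-tissue convective transport, ≈ 52 ml/min) and
eliminating at $Cl_L C_L$ (66.2 ml/min; liver metabolic time constant
$V_L / Cl_L \approx 1100$ min). The symmetric form $k (C_p - C_L)$ is the
minimal flux consistent with intact recycling and a capacity-like $V_L$;
receptor saturation is deliberately not modelled, so the system stays
linear — a known limitation at very high doses.

`scenario_recap()` reproduces the 60-min, 70,000 U infusion and its two
counterfactuals: disconnecting the liver ($k = 0$) abolishes elimination
entirely and parks $C_p$ at the three-compartment distribution plateau,
while removing only the hepatic clearance ($Cl_L = 0$) leaves the early
biphasic distribution essentially unchanged — the early phase is receptor
capture, not metabolism. `simulate_meal_train()` emulates the
post-prandial story: 360 IU released into the gastrointestinal lump over
120 min every 24 h, iterated until consecutive daily plasma profiles
agree in sup-norm (default $10^{-6}$ relative). At the limit cycle the
amount eliminated per period equals the per-meal dose, and the fasting
baseline is strictly positive — the fasting level is simply yesterday's
meals still being cleared.

## Fitting

`fit_protein()` estimates $Cl_p$ (and optionally one shared $f$) on the
fixed species scaffold by bounded Levenberg–Marquardt on
log-concentration residuals — a proportional-error loss matching the
multi-decade semilog character of protein PK data, and invariant to joint
rescaling of dose and concentrations. Lymph observations enter through
the pooled-lymph prediction with equal weight after the log transform.
Enzyme-activity data may carry an additive background, either fixed and
subtracted or co-estimated. A first-valid-sample-time option excludes
early pre-mixing samples (the classical convention is 5–10 min
post-bolus; the default is 0, the pure model).

`fit_compartmental()` is the unconstrained five-parameter comparison fit,
run from 16 starts (one moment-based heuristic from the initial and
terminal log-slopes, the rest Latin-hypercube over the log-parameter
bounds, fixed seed). Because the constrained model is nested in it, its
loss can never be lower; `compare_nested_fits()` supplies the F-ratio.
`profile_identifiability()` displaces each time constant fourfold,
refits the rest and reports whether the data notice — with six samples,
none of the five constants is identified, which is exactly why the
physiological constraints earn their keep.

`calibrate_species()` inverts the steady-state anchors for the tissue
volumes. A subtlety the implementation had to respect: with the time
constants fixed, $f_i V_i = V_p T_{Ti}/T_{Pi}$, so $V_\mathrm{ECF}$ and
the lymph/plasma ratio do not constrain $(V_1, V_2)$ at all and the
target system is rank-deficient. The solver therefore treats the shared
sieving factor as an unknown alongside the volumes
($f = $ ratio, $V_1 + V_2 = V_\mathrm{ECF}/f$, plus the lymph-flow
equation), which is well posed and exact when all three targets are
given; with a target missing, the volume split falls back to the
equal-sieving rule $V_2/V_1 = T_{T2} T_{P1} / (T_{T1} T_{P2})$ with an
explicit warning. Applied to the albumin constants with ratio 0.725 and
$V_\mathrm{ECF} = 3479$ ml, this returns the packaged human ratios
(1.3, 0.4) within 2 %.

## Synthetic data

No public deposited datasets exist for these classical studies, so
`generate_dataset()` stands in for them: it evaluates the exact model at
the design's sample times and applies multiplicative log-normal noise
(log-scale SD $\sqrt{\log(1 + cv^2)}$, so the sampled CV is exactly the
nominal one), an optional additive background, and a lower limit of
quantification below which points are flagged, never dropped. The default
CV of 10 % is a convention — the true assay error of the underlying
decades of literature data is unknowable; what the generator reproduces
is the visually constant relative scatter of semilog protein PK plots,
not any figure's literal point coordinates. One integer seed derives
per-replicate sub-streams, so extending the number of replicates never
perturbs existing ones. `make_design()` supplies the canonical designs:
log-spaced sampling from 10 min (twice the post-bolus mixing convention)
to five terminal time constants for bolus studies, the 60-min/70,000 U
infusion, and the daily meal train.

Passing the recovery loop on such data shows that the estimation
machinery is unbiased and well identified *under the model's own error
structure*; it cannot show that real capillaries are purely convective,
that two tissue lumps suffice, or that assay errors are log-normal.

## Numerical choices and problem sizes

* Solver: `lsoda` (stiff-capable), rtol $10^{-10}$, atol $10^{-12}$
  scaled; segment restarts at exact event times. Sub-tolerance negative
  round-off is zeroed; larger negativity is an error, never clamped
  silently.
* Fits run in log-parameter space with bounds ($Cl$ free over 8 decades,
  $f \le 1$); convergence at a bound is warned about, not hidden.
* Model predictions inside fitting loops use rtol $10^{-11}$ so that
  finite-difference Jacobians stay clean; with looser solver tolerances
  the Levenberg–Marquardt line search stalls visibly above the
  $10^{-6}$ self-consistency level.
* The test and acceptance runs use deliberately modest problem sizes —
  12–24 samples per curve, 20 noisy replicates, 16 multi-starts, daily
  meal cycles to a $10^{-6}$ limit cycle (about 26 periods) — chosen as
  representative of the sparse designs of the source studies.

## Limitations

The model is linear throughout: no receptor saturation, no
concentration-dependent clearance, no diffusional (bidirectional)
capillary term, and no intra-organ resolution beyond the two lumps. The
baboon tissue-volume ratios are assumed equal to the human ones. The
lamb lymph flows rest on plasma data alone. Pore-radius estimation from
the sieving factors is deliberately out of scope — the sieving data are
far too sparse to support it.
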