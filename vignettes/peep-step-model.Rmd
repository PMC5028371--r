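---
title: "A lung / expanding-chest-wall bench model and the PEEP-step estimate of transpulmonary pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lung / expanding-chest-wall bench model and the PEEP-step estimate of transpulmonary pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peepstep)
```

## The physical system

Transpulmonary pressure — airway minus pleural pressure, the pressure that
actually distends the lung — is the quantity that matters for
ventilator-induced lung injury, but measuring it requires an esophageal
balloon, which is rarely used at the bedside. `peepstep` simulates a
physical bench model built to show why a much simpler route works: below the
resting volume of the chest wall, the rib cage *springs outward*, so at
end-expiration the chest wall does not lean on the lung at all. If that is
true, raising PEEP leaves end-expiratory pleural pressure essentially
unchanged, end-expiratory transpulmonary pressure rises by the full PEEP
change, and lung elastance is simply

$$E_L = \frac{\Delta PEEP}{\Delta EELV},$$

the PEEP step divided by the change in end-expiratory lung volume, which a
ventilator can measure on its own from inspired/expired tidal volumes.

The bench apparatus the model reproduces:

* **Lung** — one to three parallel elastic test lungs, nominal compliance
  19 ml/cmH2O each (totals 19/38/57), inside an airtight box.
* **Pleural space** — the sealed gas above the water surface of a semi-stiff
  plastic container, plus the lung box and tubing, evacuated to −5 cmH2O.
  That suction inflates the lung to FRC (transpulmonary pressure
  0 − (−5) = 5 cmH2O) and raises the container's water level above that of
  the abdomen.
* **Abdomen** — the container (surface 1500 cm²) drains through a resistive
  valve into a 10 l plastic sack (surface 1800 cm²) whose walls bear no
  elastic tension, so pressure at the sack surface is atmospheric. Moving
  water out lowers the hydraulic head by
  $(1/1500 + 1/1800) \approx 1.22$ cmH2O per litre — this *is* the rib-cage
  spring-out analogue: an end-expiratory chest-wall "elastance" of order 1
  cmH2O/L, two orders below a patient's tidal chest-wall elastance.
* **Stiff chest wall** — strapping the container (smaller wall-bulge
  compliance) raises tidal chest-wall elastance from 18 to 24 cmH2O/L.

## Governing equations

The bench description is hardware, not mathematics, so the dynamics are the
simplest laws consistent with it:

* quasi-static linear lung behind a small airway resistance:
  $V_L = C_L \, P_{TP}$ (a measured, piecewise-linear P/V table can replace
  the linear curve via `lung_params(pv_table=)`);
* isothermal ideal-gas pleural space: $(P_{atm} + P_{pl}) V_{gas}$ is
  conserved, with $V_{gas}$ changed by lung expansion, water displacement
  and linear wall bulging $C_w \, dP_{pl}$. Pleural pressure is therefore
  *algebraic* — solved from the gas law at every integrator stage, which
  makes gas conservation exact by construction;
* linear resistive hydraulic valve driven by
  $P_{pl} - P_{ev} - \kappa W$, where $W$ is the displaced water volume and
  $\kappa$ the total static stiffness (geometric head term plus a small
  residual recoil term, below);
* volume-controlled ventilator: square inspiratory flow, end-inspiratory
  pause, passive expiration through a one-way valve referenced to PEEP.

The state is just (lung volume, displaced water); a fixed-step classical
RK4 integrator at `dt` = 1 ms advances it, and channels are recorded at
100 Hz. Phase durations are aligned to the 10 ms record grid (4 s cycle =
0.93 s flow + 0.40 s pause + 2.67 s expiration, I:E within 0.25% of 1:2), so
the integrator never straddles a flow discontinuity and sampled tidal
volumes are exact. The recorded flow channel is the 10 ms interval average
(identically $\Delta V/\Delta t$); pressures and volume are instantaneous
samples.

## Parameters, defaults, and what was calibrated

| parameter | default | why |
|---|---|---|
| compliance per test lung | 19 ml/cmH2O | nominal bench value |
| capacity per test lung | 600 ml | chosen so a single lung accommodates the 8.4 step but not the 12.2 step, reproducing the bench's step-omission rule |
| airway / expiratory resistance | 0.003 / 0.007 cmH2O·s/ml | wide-bore (22 mm) tubing; passive expiration complete well inside the 2.67 s window at every arm |
| pleural gas volume | 15 l | order of the box + container head space; its gas compliance ($V_g/P_{abs} \approx 14.6$ ml/cmH2O) is part of tidal chest-wall stiffness |
| wall (bulge) compliance | 35.7 normal / 21.6 stiff ml/cmH2O | calibrated by `calibrate_chest_wall()` (bisection on simulated breaths at ZEEP) to tidal chest-wall elastance 18 / 24 cmH2O/L |
| valve resistance | 0.1 cmH2O·s/ml | sets the slow pleural relaxation time constant to ~9 s, i.e. equilibration within 10–15 breaths after a PEEP step |
| residual static recoil | ~0.4 cmH2O/L | see below |
| ventilator | VT 300 ml, 15/min, I:E 1:2, pause 10% | bench settings |

Two calibrations deserve comment. First, tidal chest-wall elastance: during
one breath the valve barely moves water, so the pleural swing is set by gas
compression plus wall bulging, $\Delta P_{pl} \approx VT/(G + C_w)$; `Cw` is
the free knob and is tuned once against simulated breaths. Second, the
static (end-expiratory) chest-wall elastance: geometry alone gives 1.22
cmH2O/L, but part of any sustained volume change is absorbed by the gas and
wall storage compliance, so the *effective* static elastance is
$\kappa/(1 + \kappa (G + C_w))$. The bench measured ~1.5 cmH2O/L
(end-expiratory chest-wall compliance ~640 ml/cmH2O);
`calibrate_static_recoil()` solves the relation analytically for the small
residual recoil term (~0.4 cmH2O/L) that makes the effective value 1.5. A
purely geometric model remains available
(`calibrate_static_recoil(cfg, NULL)`).

Commanded PEEP levels in the shipped protocols are the bench's *measured*
levels (4.4, 8.4, 12.2 from ZEEP; 4.1 per incremental step), since the
simulator's expiratory valve regulates exactly while the bench valve
overshot its nominal setting slightly.

## The measurement pipeline

`segment_breaths()` delimits breaths at inspiration onsets (phase channel,
or a +25 ml/s flow threshold held 100 ms when only noisy flow is
available), sums flow samples into inspired/expired tidal volumes, and
reads end-expiratory / plateau pressures as means over the final 100 ms of
expiration / pause — the window length is a read-out decision, not bench
doctrine. `detect_peep_changes()` flags breaths whose measured PEEP moved
by more than 1 cmH2O. `delta_eelv()` implements the estimator:

$$\Delta EELV = \sum_{k=1}^{15} (VT_{i,k} - VT_{e,k}) \;-\; 15 \cdot
  \overline{(VT_i - VT_e)}_{k=16..20},$$

the cumulative inspired-minus-expired volume over the first 15 breaths at
the new level, offset-compensated by the mean imbalance of the five
following breaths. The offset rule is what makes the estimator robust to a
constant flow-sensor bias: a ±2 ml/s bias moves the corrected estimate by
<5 ml while the uncorrected sum drifts by 60 ml per ml/s (15 breaths × 4 s).
We read the 15-breath window as starting with the first breath whose
expiration occurs at the new level.

`tidal_elastances()`, `peepstep_result()`, `pv_points()` and
`eelv_regression()` implement the elastance partitioning
($E_{TOT} = E_{CW} + E_L$, exact by construction), the PEEP-step summaries,
the P/V-point extraction with the fitted lung line, and the study-level
regression.

## Numerical and design choices

* **Statics oracle.** `equilibrium_solver()` solves the coupled lung /
  valve / gas-law statics in closed form (one scalar root). An apneic CPAP
  hold (`hold_at_pressure()`) converges to it within 1 ml and 0.05 cmH2O —
  the independent check on the integrator.
* **Ventilation rectification.** Under ventilation the time-averaged
  pleural pressure is elevated above its end-expiratory value, so water is
  rectified out through the valve until mean drive vanishes; the ventilated
  end-expiratory operating point therefore sits ~1–2 cmH2O below the apneic
  equilibrium. This is genuine physics of the apparatus, not integrator
  error. Because the model is linear, the offset is identical at every PEEP
  level and cancels exactly in all PEEP-level *differences* — which is what
  every reported quantity is. Ventilated runs are validated against the
  statics on differences (1% / 0.1 cmH2O).
* **Capacity guard.** Exceeding `n_units * capacity_per_unit` raises a
  typed capacity error; `run_protocol()` converts it to step omission and
  truncation, as at the bench (a single lung omits the 12.2 step, and the
  isolated single lung omits 5-17-5).
* **Regression direction.** The study regression is reported as the
  zero-intercept slope of the *predicted* $\Delta PEEP/E_L$ on the
  *measured* $\Delta EELV$. With an end-expiratory chest-wall elastance of
  1.5 cmH2O/L the measured change is $E_L/(E_L + 1.5)$ of the prediction in
  every arm, so this direction has slope slightly above one (~1.07 pooled)
  while the reverse is ~0.93; only the first is numerically consistent with
  a near-unit reported slope alongside a nonzero end-expiratory chest-wall
  elastance. Both directions and a free-intercept fit are returned.
* **Determinism.** Noise-free runs are bit-identical; sensor noise
  (`noise_settings()`) is Gaussian per sample plus a constant flow offset,
  seeded, with repetition *r* of a protocol using `seed + r`.

## What the simulations can and cannot show

The generator emulates the bench: linear test lungs, a single hydraulic
abdomen, no airway nonlinearity, no recruitment/derecruitment, no
viscoelastic tissue, no cardiogenic noise, no temperature or humidity
effects. Protocol sizes are 25 breaths per PEEP level (the estimator needs
20 after a change; the pleural relaxation completes within ~12), triplicate
runs only when noise is enabled, and the six arms are 1/2/3 lungs ×
normal/stiff chest wall. Passing tests therefore show that the *pipeline
and the mechanism* — spring-out force, near-zero end-expiratory chest-wall
elastance, $\Delta EELV = \Delta PEEP/E_L$ — are reproduced quantitatively
for a linear bench; they do not show that a nonlinear, recruiting patient
lung obeys the same arithmetic at every PEEP, nor validate absolute
esophageal-pressure calibration, which the method is designed to avoid.

Known limitations worth keeping in mind: the printed isolated-lung FRC
values of real test lungs (92/167/242 ml at 5 cmH2O) are a few percent
below the nominal linear prediction (95/190/285), i.e. real test lungs are
slightly sub-nominal at low pressure; the default model keeps nominal
linear lungs and exposes a measured P/V table as a configuration option.

## A short session

```{r, eval = FALSE}
cfg <- make_default_config(n_lungs = 2, chest_wall_mode = "normal")
run <- run_protocol(cfg, protocol_spec(c(0, 8.4, 0), repetitions = 1))
measure_peep_steps(run)

study <- run_peep_step_study()     # all six arms, all steps, ~2 s
summarize_study(study)
eelv_regression(study)
```
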