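---
title: "Competing calcium oscillation mechanisms in T cells: model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing calcium oscillation mechanisms in T cells: model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(tcellosc)
```

## The biological problem

Antigen stimulation of T-cell receptors raises IP$_3$ and triggers
cytosolic Ca$^{2+}$ oscillations.  Two qualitatively different waveforms
are observed, depending on whether the cell can exchange Ca$^{2+}$ with
the extracellular medium.  With extracellular Ca$^{2+}$ present, slow
("sinusoidal") oscillations are sustained by store-operated Ca$^{2+}$
entry (SOCE) through the CRAC channel, the STIM-Orai complex that
assembles when the ER store depletes.  Without extracellular Ca$^{2+}$,
the cell instead fires fast spikes driven by Ca$^{2+}$-induced
Ca$^{2+}$ release (CICR) through the IP$_3$ receptor: narrow spikes,
wide spikes, or wide spikes carrying an oscillatory plateau, depending
on stimulation strength and store load.  This package implements a
five-variable ODE model in which both mechanisms coexist, and the
numerical bifurcation machinery needed to map out where in parameter
space each one operates.

## The model

The open-cell state is $(c, c_e, h, p, s)$: cytosolic and ER Ca$^{2+}$
(µM), the IP$_3$R inactivation gate $h \in [0,1]$, IP$_3$ ($p$, µM) and
the CRAC influx rate variable $s$ (µM/s).  The equations are

$$\frac{dc}{dt} = J_{\mathrm{IP_3R}} - J_{\mathrm{SERCA}}
  + \delta\,(s - J_{\mathrm{PM}}), \qquad
\frac{dc_e}{dt} = \gamma\,(J_{\mathrm{SERCA}} - J_{\mathrm{IP_3R}}),$$

$$\tau_h \frac{dh}{dt} = h_\infty - h, \qquad
\tau_p \frac{dp}{dt} = V_{\mathrm{PLC}} - J_{\mathrm{deg}}, \qquad
\tau_s \frac{ds}{dt} = J_{\mathrm{SOCE}} - s.$$

$\gamma$ is the cytosol:ER volume ratio and $\delta$ measures the rate
of plasma-membrane transport relative to the ER fluxes.  With
$\delta = 0$ the total free Ca$^{2+}$ $C_t = c + c_e/\gamma$ is
conserved and $s$ decouples, giving the three-variable closed-cell
model in $(c, h, p)$ with $c_e = \gamma (C_t - c)$; `rhs_closed()`
implements it independently and the test suite verifies the two forms
agree to $10^{-12}$ under substitution.

The fluxes are the standard forms of this model family, with the
package defaults taken from the published reference set
(`ca_params()`):

* **SOCE** (phenomenological CRAC activation):
  $J_{\mathrm{SOCE}} = V_{\mathrm{SOCE}} / (1 + e^{s_1 (c_e - K_e)})$,
  a decreasing sigmoid in the ER load with midpoint $K_e$ (800 µM) and
  steepness $s_1$ (0.2 /µM).  $s$ relaxes to it on the CRAC formation
  timescale $\tau_s$ (15 s), which encodes the delay of STIM-Orai
  assembly.
* **IP$_3$R** (modal gating):
  $J_{\mathrm{IP_3R}} = k_f P_0 (c_e - c)$ with open probability
  $P_0 = \beta / (\beta + k_\beta(\beta + \alpha))$, where
  $\beta = \phi_p \phi_c h$, $\alpha = \phi_p^-(1 - \phi_c h_\infty)$,
  $\phi_c = c^4/(c^4 + K_c^4)$, $\phi_p = p^2/(p^2 + K_p^2)$,
  $\phi_p^- = 1 - \phi_p$.  The gate relaxes to
  $h_\infty = K_h^4/(c^4 + K_h^4)$ on the Ca$^{2+}$-modulated timescale
  $\tau_h = \tau_{\max} K_\tau^4 / (K_\tau^4 + c^4)$: at resting $c$
  inactivation is slow ($\tau_{\max}$ = 7.5 s), at spike peaks it
  collapses to milliseconds, terminating CICR.
* **SERCA** (bidirectional pump):
  $J_{\mathrm{SERCA}} = V_{\mathrm{SERCA}} (c^2 - \bar K c_e^2)/(c^2 +
  K_{\mathrm{SERCA}}^2)$; the small reverse term
  $\bar K = 10^{-8}$ sets the resting balance $c = \sqrt{\bar K}\,c_e$
  once IP$_3$ has decayed.
* **PMCA**: $J_{\mathrm{PM}} = V_{\mathrm{PM}} c^2/(c^2 +
  K_{\mathrm{PM}}^2)$, and **IP$_3$ degradation**
  $J_{\mathrm{deg}} = V_{\mathrm{deg}}\,c^2/(c^2 + K_{\mathrm{deg}}^2)\,p$
  by the Ca$^{2+}$/calmodulin-stimulated 3-kinase.

Units are µM and seconds throughout; no non-dimensionalisation is
performed.  The right-hand sides exist twice: a readable R
implementation (`rhs_open()`, `rhs_closed()`) and a compiled C
implementation used by the integrators and the shooting code, including
the variational equations $\dot M = J(x) M$ for monodromy matrices.
The test suite pins the two against each other.

### How the two mechanisms compete

At the reference parameters a stimulated open cell ($\delta = 2$,
$V_{\mathrm{PLC}} = 0.1$) settles on a slow cycle: the IP$_3$R leaks
Ca$^{2+}$ gradually (open probability low and nearly constant — no fast
CICR), the store drains by roughly 20 µM, SOCE switches on with delay,
refills the store, and the cycle repeats with a period in the tens of
seconds.  The closed cell instead spikes: CICR fires, the gate $h$
inactivates within a fraction of a second, and the store barely moves
(≲ 1 µM per narrow spike).  CRAC activity suppresses the spikes;
removing it (or slowing membrane transport, $\delta \to 0$) releases
them.

## Simulation and feature extraction

`ca_integrate()` wraps `deSolve::ode` (lsoda, stiff-capable) at
`rtol = 1e-8`, `atol = 1e-10`; runs are deterministic.
`oscillation_features()` discards the first half of a record as
transient (the slow CRAC cycle needs long horizons; runs of 20+
estimated periods are used throughout), then measures the period from
upward crossings of $c$ through its midrange level with linear
interpolation (robust for sinusoidal and spiking waveforms and
insensitive to the output step), the peak amplitude (the post-transient
maximum of $c$; the peak-to-trough swing is reported alongside, since
for these waveforms the two readings differ and both are useful), the
ER swing per cycle and the CRAC utilisation $\max s / V_{\mathrm{SOCE}}$.
For bursting waveforms whose midline is crossed several times per burst,
the period between principal spikes (peaks above 75% of the swing) is
reported separately.

`classify_regime()` applies deterministic waveform rules (thresholds
exposed as arguments): *steady* when the swing is below $10^{-3}$ µM;
*narrow_spike* when the duty cycle (fraction of the period above the
midline) is below 0.25; *crac_sinusoidal* when the duty cycle is in
$[0.4, 0.6]$ with appreciable influx; *wide_spike_plateau* when at
least two secondary maxima ride the elevated phase;
*hybrid* when fast spikes (duty $<$ 0.25) coexist with a large slow
swing of $s$ (more than 20% of $V_{\mathrm{SOCE}}$ peak-to-trough —
distinguishing true store cycling from the nearly constant $s$ of a
plain spiker); *wide_spike* otherwise.

`unstimulated_equilibrium()` constructs the $V_{\mathrm{PLC}} = 0$ rest
state semi-analytically: IP$_3$ decays to zero, so the IP$_3$R flux
vanishes and the SERCA balance pins $c = \sqrt{\bar K} c_e$; for the
open cell the remaining condition
$s = J_{\mathrm{PM}}(c) = J_{\mathrm{SOCE}}(c_e)$ is a 1-D root
problem.  With the defaults this gives
$(c, c_e, s) = (0.0809, 809.05, 0.4219)$.
`unstimulated_partial_equilibrium()` solves the same balances at a
prescribed ER load, which is how the ER-load stimulation scenarios
(`run_er_load_scenario()`) build their initial conditions: a replete
store ($c_e = 850$, CRAC fully off) fires transient narrow spikes for
about the CRAC formation time before the slow cycle takes over, while a
partially depleted store ($c_e = 809$, CRAC partially formed) starts
close to the cycle and shows none.

## Numerical bifurcation analysis

**Equilibria** (`continue_equilibria()`): pseudo-arclength continuation
with a damped-Newton corrector and adaptive step, in scaled coordinates
(states divided by typical magnitudes, so the ER concentration — three
orders larger than $c$ — does not dominate the metric).  Eigenvalues
are computed at every accepted point; a Hopf point is flagged when the
leading complex pair crosses the imaginary axis and localised by
bisection to $10^{-6}$ in the parameter, a fold via a determinant sign
change.  Jacobians are central finite differences with step
$10^{-7}(1 + |x_j|)$.

**Periodic orbits** (`continue_periodic_orbits()`): multiple shooting
with $m$ equispaced segments (24–40 here).  The defining system is the
cyclic matching of the segment flows plus an anchor phase condition
$\langle x_1 - x_{\mathrm{ref}}, f(x_{\mathrm{ref}})\rangle = 0$;
segment transition matrices come from the compiled variational
equations and multiply up to the monodromy matrix, whose eigenvalues
are the Floquet multipliers.  Shooting was chosen over orthogonal
collocation because one method then serves every branch in the package
— including the stiff closed-cell spikes for which collocation needs
aggressive mesh adaptation — and the variational route gives the
monodromy matrix as a by-product; the orbit tolerance ($10^{-9}$ on the
matching residual) and the trivial-multiplier error (below $10^{-3}$,
typically $10^{-8}$, on well-conditioned orbits) are comparable to what
collocation delivers.

Near a Hopf point the fixed-parameter shooting system is nearly
singular, so `po_from_hopf()` uses the standard well-conditioned
variant: the orbit amplitude (projection on the linearised eigenplane)
is pinned and the parameter is freed.  The emergent period reproduces
$2\pi/\mathrm{Im}\,\lambda$ to better than 2%.  Branches not connected
to an equilibrium Hopf point (the isolated plateau branch) are started
from a converged attractor with `po_from_simulation()` and continued
from there; no attempt is made to connect the isolated branch to the
primary one.

Along a branch, folds of cycles (SNPO) are detected as parameter-fold
points (sign reversal of the tangent's parameter component, localised
by a quadratic fit), period doublings by a real multiplier crossing
$-1$ and torus points by a complex pair crossing the unit circle, both
refined by bisection at fixed parameter to $10^{-4}$.  Three
safeguards matter in practice:

* a parameter fold at near-zero orbit amplitude (or at moderate
  amplitude right at a known equilibrium Hopf) is the branch reflecting
  through its Hopf endpoint, not an SNPO, and is recorded as `"HB"`;
* on violently unstable orbit sheets (nontrivial multipliers beyond
  $10^6$) the small multipliers of the monodromy matrix are numerical
  noise, so torus tests are suppressed there, and period-doubling /
  fold points flanking the *upper* subcritical Hopf of the closed-cell
  diagrams are obtained by tracing a second branch from that Hopf
  point rather than across the unstable sheet (whose multipliers reach
  $10^{14}$);
* a branch that folds back over itself detects the same point twice;
  detections of one kind closer than a small parameter tolerance are
  merged, and torus detections coinciding with a PD or SNPO (an
  eigenvalue-pairing artifact) are dropped.

**Two-parameter Hopf curves** (`continue_hopf_2par()`): the extended
defining system — equilibrium plus a purely imaginary eigenpair,
written in real form with the eigenvector normalised and its rotation
phase fixed by $v_a \!\cdot\! v_b = 0$ — is continued by
pseudo-arclength in both directions until the curve leaves a
user-supplied box or closes on itself.  Sampled points re-verify
against one-parameter Hopf localisation to $10^{-4}$.
`region_overlap_delta()` uses two such curves (one seeded from the
high-$\delta$ CRAC family, one from the low-$\delta$ spike family) to
measure, slice by slice in $V_{\mathrm{PLC}}$, the $\delta$ intervals
occupied by each oscillatory region, and reports the smallest $\delta$
at which they overlap.  `region_map()` provides the simulation-based
ground truth for regime occupancy on a grid.

## Reference scenarios

`reproduce_figure()` scripts the model's reference computations as
deterministic pipelines writing CSV data and a JSON summary: the four
oscillation regimes ("3A"–"3D"), the open-cell diagram in
$V_{\mathrm{PLC}}$ ("4"), the steepness/delay analyses ("5A"–"5F"), the
open-probability comparison ("6" — the qualitative contrast "fast CICR
gating during spikes, none during CRAC cycling" is encoded as the
within-cycle modulation of $P_0$, max/min ≈ 9 for the narrow spike
against ≈ 2.6 for the CRAC cycle, rather than as a ratio of maxima:
the two maxima are within a factor 1.5 of each other because the fast
collapse of $\tau_h$ caps the spike's open probability), the ER-load
scenarios ("7"), the
closed-cell diagrams at $C_t = 140/95/75$ ("8A"/"8C"/"8E"), the
closed-cell two-parameter set ("9", Hopf curve by continuation, with
PD/SNPO/TR loci collected from one-parameter cuts at a few $C_t$
values), the $\delta$ comparison ("10") and the region analyses at
$K_e = 800$ and $400$ ("11"/"12").

Problem sizes are desk scale by design: simulations of 200–1000 s at
output steps of 0.01–0.05 s, branches of one to a few hundred points,
shooting meshes of 24–40 segments.  Each pipeline runs in seconds to a
couple of minutes on one core.

## What the scenarios do and do not show

The model reproduces the full qualitative repertoire at the reference
parameter set: both oscillation families and their bifurcation
skeleton.  Quantitative agreement with the reference descriptions is
close but not uniform — e.g. the CRAC cycle's period comes out near
35 s against a reference value of approximately 40 s, and the
narrow-spike period near 2.9 s against approximately 4 s — differences
consistent with the approximate nature of those reference values.  Two
further caveats:

* Resting-state values of $c = 0.809$ at $c_e = 809$ sometimes
  associated with the ER-load scenarios are inconsistent with the SERCA
  balance implied by the same parameter set, which forces
  $c = \sqrt{\bar K}\,c_e = 10^{-4} c_e$; the influx value that goes
  with them ($s = 0.421$) equals $J_{\mathrm{PM}}(0.0809)$, confirming
  $c = 0.0809$ as the consistent reading.  The package returns the
  self-consistent state.
* At $(K_e, \delta, V_{\mathrm{PLC}}) = (400, 0.62, 0.1)$ with the
  default kinetics, every initial condition tried converges to a plain
  narrow-spike attractor; the hybrid waveform (narrow spikes riding a
  large slow store cycle) appears at $\delta \approx 1$ instead.  The
  hybrid regime and its classification are demonstrated there.

These are model-internal statements; nothing here is fitted to
experimental traces, and agreement with the reference computations does
not by itself validate the model against real T-cell data.

## A worked example

```{r example, eval = FALSE}
p <- ca_params(V_PLC = 0.1, delta = 2)   # stimulated open cell
tr <- ca_integrate(p, t_end = 800, dt_out = 0.05)
oscillation_features(tr)

br <- continue_equilibria(ca_params(V_PLC = 0.01, delta = 2),
                          "V_PLC", c(0.01, 0.3), model = "open")
branch_points(br, "HB")
```
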