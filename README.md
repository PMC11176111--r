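# tcellosc

Simulation and numerical bifurcation analysis of competing Ca²⁺
oscillation mechanisms in T lymphocytes.

## The problem

Stimulated T cells show two distinct kinds of cytosolic Ca²⁺
oscillation. With extracellular Ca²⁺ available, slow sinusoidal cycles
are sustained by store-operated Ca²⁺ entry (SOCE) through the CRAC
(STIM–Orai) channel; in a Ca²⁺-free medium the same cells instead fire
fast IP₃-receptor-mediated spikes — narrow, wide, or wide with an
oscillatory plateau. `tcellosc` implements a five-variable ODE model in
which both mechanisms coexist, and the continuation machinery needed to
map out which mechanism operates where in parameter space. It is aimed
at modellers of intracellular Ca²⁺ signalling who want a scriptable,
tested alternative to interactive XPPAUT/AUTO sessions for this class
of model.

## The model

State `(c, c_e, h, p, s)`: cytosolic and ER Ca²⁺ (µM), IP₃R
inactivation gate, IP₃ (µM), and the CRAC influx rate `s` (µM/s):

    dc/dt   = J_IP3R − J_SERCA + δ (s − J_PM)
    dc_e/dt = γ (J_SERCA − J_IP3R)
    τ_h dh/dt = h∞ − h
    τ_p dp/dt = V_PLC − J_deg
    τ_s ds/dt = J_SOCE − s,    J_SOCE = V_SOCE / (1 + exp(s1 (c_e − K_e)))

With δ = 0 the total Ca²⁺ `C_t = c + c_e/γ` is conserved and the model
reduces to a three-variable closed cell. The IP₃R uses the modal gating
form (open probability `P0` built from Hill functions of `c` and `p`
and the slow gate `h`), SERCA is a bidirectional pump, PMCA a Hill-2
pump; `V_PLC` (stimulation strength) is the usual bifurcation
parameter. See the vignette `vignettes/model-and-methods.Rmd` for the
full flux forms, parameter meanings and numerical methods.

Key capabilities:

* stiff-capable deterministic integration (compiled right-hand sides,
  `deSolve`), oscillation feature extraction and rule-based regime
  classification (`steady`, `crac_sinusoidal`, `narrow_spike`,
  `wide_spike`, `wide_spike_plateau`, `hybrid`);
* pseudo-arclength equilibrium continuation with Hopf/fold detection
  (`continue_equilibria`);
* periodic-orbit continuation by multiple shooting with Floquet
  multipliers and SNPO/PD/TR detection (`continue_periodic_orbits`);
* two-parameter Hopf curves (`continue_hopf_2par`) and oscillatory
  region analysis (`region_map`, `region_overlap_delta`);
* scripted reference scenarios (`reproduce_figure`) and a CLI wrapper
  (`inst/scripts/tcellosc-cli.R`).

## Worked example

```r
library(tcellosc)

p  <- ca_params(V_PLC = 0.1, delta = 2)       # stimulated open cell
tr <- ca_integrate(p, t_end = 800, dt_out = 0.05)
oscillation_features(tr)
#> crac_sinusoidal oscillation: T = 35.1 s (principal 35.1 s)
#>   c in [0.119, 0.173] uM (peak amplitude 0.173)
#>   c_e in [793, 813.7] uM; ER swing/cycle 20.4 uM
#>   max s = 48.7% of V_SOCE
```

The stimulated open cell settles on the CRAC-mediated cycle: a slow
(~35 s) sinusoidal oscillation during which the ER drains and refills
by ~20 µM and the CRAC influx variable cycles up to about half its
maximal rate. The closed cell spikes instead:

```r
pn <- ca_params(V_PLC = 0.1, C_t = 140)       # closed cell, full store
oscillation_features(ca_integrate(pn, t_end = 200, dt_out = 0.01,
                                  model = "closed"))
#> narrow_spike oscillation: T = 2.91 s (principal 2.91 s)
#>   c in [0.095, 0.218] uM (peak amplitude 0.218)
#>   c_e in [768.9, 769.6] uM; ER swing/cycle 0.675 uM
```

Narrow spikes barely touch the store (< 1 µM per cycle) — the
signature distinguishing the IP₃R-mediated family from the
CRAC-mediated one. The bifurcation diagram behind the open-cell
oscillation:

```r
br <- continue_equilibria(ca_params(V_PLC = 0.01, delta = 2),
                          "V_PLC", c(0.01, 0.3), model = "open")
br
#> equilibrium branch in V_PLC over [0.01, 0.3]: 304 points
#>   HB at V_PLC = 0.0507584
#>   HB at V_PLC = 0.112672
```

Two Hopf bifurcations bound the stimulation window in which the CRAC
cycle exists; `po_from_hopf()` + `continue_periodic_orbits()` continue
the stable orbit branch between them, and
`plot(br, po = <orbit branch>)` draws the diagram.

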