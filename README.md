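# ifngate

Kinetic modelling of interferon-stimulated gene induction under coupled
fast positive and delayed negative feedback, with the delay set by a
cell-cycle gate.

## The problem

Cells pre-exposed to type-I interferon respond to a second dose in two
opposite ways: short pretreatments *prime* (a stronger second response),
prolonged pretreatments *desensitize* (a weaker one).  The switch is
explained by timing: the ISGF3 component IRF9 (positive feedback) is
induced quickly, while the receptor-level suppressor USP18 (negative
feedback) is induced only after a substantial delay — and that delay is
heterogeneous across cells because USP18 induction can only *start* during
an early-cell-cycle window; cells treated outside the window wait for the
next cycle.

`ifngate` is for systems biologists who want to simulate, fit and analyze
this circuit: it implements the two-species production-only model

    dIRF9/dt  = I(t) · (k4 + pf·nf)          pf = k1·IRF9/(k2+IRF9)
    dUSP18/dt = I(t) · Su(t) · (k5 + pf·nf)  nf = k3/(k3+USP18)

with a binary input program `I(t)`, a stepwise delay gate `Su` (fixed delay
τ, or a cell-cycle gate with cycle length T = 21.82 h and open window
w = 7.3 h), forward-Euler integration (dt = 0.001 h), a stochastic
single-cell cohort simulator with additive expression noise, least-squares
parameter estimation with a delay scan (τ = 1…20 h) and AIC comparison of
loop-ablated variants (AIC = 2k − 2 ln L), the analytic gate delay
distribution with window fitting, a synthetic dual-reporter trace
generator, and single-cell trace quantification (activation times, delay
times, % cell-cycle progression, induction amounts).

## Worked example

Deterministic pretreatment protocol — pretreat for 0/2/10/24 h, 8-h break,
then a 10-h second input — reporting IRF9 induction by the second input
normalized to the no-pretreatment control:

```r
library(ifngate)
p <- ifn_params()      # reference kinetic constants, tau = 8 h
normalized_induction(p, c(2, 10, 24))
#>    pre_2h   pre_10h   pre_24h
#> 1.4054507 1.7266827 0.9204832
```

Values above 1 mean priming (the 2-h and 10-h pretreatments raise IRF9 and
arm the positive feedback before USP18 appears), below 1 desensitization
(24 h of input leaves enough USP18 to attenuate the second response).

A stochastic cohort of 400 single cells per condition, each with a uniform
cell-cycle phase at treatment onset gating its USP18 delay:

```r
coh <- simulate_cohort(p, pre_durations = c(2, 10, 24), n_cells = 400,
                       seed = 1, dt = 0.002)
summary(coh)
#> Cohort summary (per condition):
#>  condition   n mean_usp18 cv_usp18 mean_irf9_induction cv_irf9_induction
#>     pre_2h 400      152.1   0.7834               27794           0.15492
#>    pre_10h 400     4307.0   0.5783               27605           0.20226
#>    pre_24h 400    16453.1   0.1107               19595           0.05809
#> Pooled Pearson correlation (USP18 end-of-break vs IRF9 induction): -0.712
```

The cell-to-cell variability of USP18 shrinks as pretreatment lengthens
(short inputs induce USP18 only in the fraction of cells whose gate was
open — a bimodal cohort; 24 h covers every cell's window), and cells with
more USP18 at the end of the break induce less IRF9 on re-stimulation —
the negative correlation that defines desensitization at the single-cell
level.

Other entry points: `simulate_pathway()` (deterministic trajectories under
arbitrary input programs, e.g. `pulse_program(5, 8, 8)` vs
`pulse_program(1, 40, 0)`), `scan_tau()` / `compare_models_aic()` (delay
estimation and feedback-loop model selection), `fit_window()` (open-window
length from a delay distribution), `generate_cohort()` /
`analyze_traces()` (synthetic dual-reporter cohorts and their
quantification).  A thin command-line wrapper lives at
`inst/exec/ifngate.R`.

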