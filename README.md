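# evacdyn

Simulation and analysis of collective evacuation decision dynamics.

`evacdyn` is for researchers studying how people decide *when* to evacuate
under an evolving threat: it reimplements, as a tested R pipeline, the
analysis of a laboratory paradigm in which 50 networked participants watch a
disaster's strike likelihood update every second and compete for limited
shelter space under time pressure. The package simulates the whole
experiment (threat trajectories, per-second Bernoulli decisions, shelter
filling, scoring), estimates per-likelihood evacuation rates, fits
hazard-rate decision models, and validates them by bootstrap and
cross-validation.

## The model

Each second an at-home individual evacuates with a probability ("rate")
that depends on the displayed strike likelihood *q* through a Hill
function:

    r(q) = r_max * q^h / (q^h + theta^h)

where `theta` is the half-maximum decision threshold and `h` the steepness
(large `h` approaches a strict threshold policy). The full six-parameter
population law lets the threshold shift linearly with shelter capacity *B*
and the maximum rate depend on time urgency:

    r(q; B, T) = r_T * q^h / (q^h + theta(B)^h),   theta(B) = theta0 + c * B

with separate maximum rates for the three urgency windows: `r_T1`
(VariableTime runs before 30 s, when the disaster cannot yet strike),
`r_T2` (VariableTime at/after 30 s, when it can strike any moment), and
`r_T3` (CertainTime runs, which resolve at exactly 60 s).

Rates are *measured* from run logs by pooling, over a partition cell *k*
(a likelihood level, optionally crossed with capacity and urgency window),
the at-home seconds `n_k` and evacuation events `m_k`; the cell rate is the
Beta-posterior mean `R_k = (m_k + 1) / (n_k + 2)` with standard deviation
`sqrt((m_k+1)(n_k-m_k+1) / ((n_k+2)^2 (n_k+3)))`. Models are fit by
maximizing the count-level log-likelihood
`sum_k [ m_k log r_k + (n_k - m_k) log(1 - r_k) ]`
— a fit to the raw counts, never to the measured rates. Expected collective
behavior follows the recursion `H[t+1] = H[t] (1 - r(q_t; B, T(t)))` from
`H[0] = 50`.

## Worked example

```r
library(evacdyn)

pool   <- trajectory_pool(23, seed = 7)              # curated scenario pool
design <- make_design(47, trajectories = pool, seed = 2)
logs   <- generate_experiment(design, evac_model(), seed = 11)

fit <- evac_fit(logs, model = "sixparam")
fit
#> Evacuation decision model (sixparam family), 130 cells
#>       h    r_T1    r_T2    r_T3  theta0       c
#> 9.26013 0.06707 0.34482 0.11664 0.57735 0.00238
#> log-likelihood: -3004.03
```

(The example above was generated with 188 runs; a 47-run experiment gives
noisier estimates.) The fitted numbers say: the population behaves like a
fairly sharp threshold rule (`h ≈ 9`) around a likelihood of
`theta(B) ≈ 0.58 + 0.0024 B` — scarcer shelter lowers the threshold, i.e.
people bolt earlier — and the maximum rate jumps five-fold (0.07 → 0.34
evacuations/second) once a VariableTime run passes the 30-second mark and
the disaster can strike at any moment.

Forward prediction and model criticism:

```r
pred <- expected_at_home(fit, design[[1]])   # expected at-home curve
cmp  <- compare_runs(pred, logs[[1]])        # RMSE, max deviation
cv   <- loocv(logs)                          # held-out vs full-model curves
sds  <- bootstrap_params(logs, n_boot = 200) # run-level bootstrap SDs
pay  <- strict_threshold_payoff(seq(0, 1, 0.1), design)
```

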