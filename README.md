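# infusim

Transient dosing errors in multi-pump intravenous infusion therapy,
predicted before they happen.

When several syringe pumps share one vascular access point — routine in
neonatal and adult intensive care — the drug flow that actually enters the
patient is not the flow set on each pump. Three physical mechanisms cause
transient deviations after any set-flow change:

1. **Push-out.** The shared ("dead") volume between the mixing point and the
   catheter tip still holds the *old* mixing ratio, but after a flow change
   it is expelled at the *new* total rate. Until the dead volume V_d is
   flushed, every other drug on the line is over- or under-dosed; the excess
   volume of a bystander drug is `V_d (f_old − f_new)`, where `f` is its
   volume fraction of the total flow.
2. **Poiseuille flow profile.** Infusion flow is laminar, with a parabolic
   velocity profile: the centerline moves at twice the cross-sectional mean,
   so a new fluid first arrives after *half* the mean transit time `V/Q`,
   and the washout fraction follows `F(t) = 1 − (τ/2t)²` for `t ≥ τ/2`
   (τ = V/Q, no radial mixing).
3. **Mechanical compliance.** Compressible parts (chiefly the air-filled
   rubber syringe plunger) store volume `C·ΔP` when the line pressure
   changes. Hydraulic resistance scales as `R = 128 μL/(π d⁴)` — the inverse
   *fourth* power of the lumen diameter — so with a thin (1 Fr) catheter a
   set-flow increase on one pump raises the junction pressure enough to push
   mixed fluid *backwards* into the other lines: an overdose followed by an
   underdose of the bystander drug, which clinicians reliably find
   counter-intuitive.

`infusim` simulates all three mechanisms together: a lumped
compliance–resistance network (implicit-Euler, unconditionally stable for
stiff thin-catheter setups) drives a volume-slice shift register tracking
the drug composition of the shared volume, with laminar residence-time
dispersion and last-in-first-out backflow buffering in the branch lines.
The deviation of each drug's delivered dose rate is decomposed exactly into
its push-out, Poiseuille and compliance contributions by nested ablation.

## Worked example

How long does a newly loaded medicine take to reach the patient through a
3 mL line running at 6 mL/h?

```r
library(infusim)
first_arrival_time(3, 6) * 60
#> [1] 15
```

The mean transit time is 3 mL / 6 mL/h = 0.5 h = 30 min, but the laminar
centerline travels twice as fast: the first drug arrives after 15 min.

The counter-intuitive thin-catheter case — pump A stepped 10 → 20 mL/h at
t = 0.1 h while pump B runs critical medication at 1 mL/h, both through a
1 Fr catheter:

```r
sim <- simulate_scenario(builtin_case(4))
sim
#> <dose_sim> poiseuille kernel, 2 drug(s), 2 pump(s), 0.6 h @ dt = 6.20483e-05 h
#> # A tibble: 2 × 5
#>   drug   signed_ml overdose_ml underdose_ml peak_deviation_ml_h
#>   <chr>      <dbl>       <dbl>        <dbl>               <dbl>
#> 1 drug_A   -0.108      0.0440        0.152                9.97
#> 2 drug_B   -0.0615     0.00720       0.0687               0.962
```

Drug B (set at 1 mL/h) transiently swings by almost its entire set rate.
Which mechanism is responsible?

```r
dec <- decompose(builtin_case(4)$network, simulation_grid(0.6))
glance(dec)
#> # A tibble: 8 × 5
#>   drug   component       signed_ml overdose_ml underdose_ml
#>   <chr>  <chr>               <dbl>       <dbl>        <dbl>
#> 1 drug_A compliance      -0.0862      0.0470       1.33e- 1
#> 2 drug_A poiseuille       0.000313    0.00567      5.35e- 3
#> 3 drug_A push_out        -0.0226      0            2.26e- 2
#> 4 drug_A total_deviation -0.108       0.0440       1.52e- 1
#> 5 drug_B compliance      -0.0837      0.000189     8.39e- 2
#> 6 drug_B poiseuille      -0.000313    0.00535      5.67e- 3
#> 7 drug_B push_out         0.0226      0.0226       6.46e-18
#> 8 drug_B total_deviation -0.0615      0.00720      6.87e- 2
```

The compliance mechanism (0.084 mL of drug-B underdose, the syringe
plungers charging against the 1 Fr resistance) dominates the push-out
excess (0.023 mL) — with a 7 Fr catheter (`builtin_case(2)`) the same flow
change leaves a compliance contribution three orders of magnitude smaller.
`autoplot(sim)`, `autoplot(dec)` and `plot_flows(sim)` draw the
corresponding set-vs-delivered, mechanism and branch-flow panels; `tidy()`
returns the underlying tibbles.

A small CLI wraps the same functions:

```sh
exec/infusim run-case 4 --out out/       # flows.csv, dose.csv, decomposition.csv, summary.json
exec/infusim run my_scenario.yaml --out out/
exec/infusim list-components
exec/infusim fixtures --seed 7 --n 3 --out out/
```

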