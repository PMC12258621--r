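# rloopkin

Single-molecule and kinetic analysis of CRISPR–Cas9 two-step target
capture from rotor-bead tracking (RBT) twist traces.

When a Cas9 ribonucleoprotein engages DNA, guide-RNA strand invasion
unwinds the duplex and the twist stored in a torsionally constrained
tether changes by a measurable angle (helicity 10.5 bp/turn). Equilibrium
traces resolve three states — closed DNA **C** (0 bp unwound), an R-loop
intermediate **I** (~10 bp) and the complete R-loop **O** (~20 bp) — and
the concentration dependence of the C→I rate separates target capture into
initial binding and initial unwinding:

- linear law (weak initial binding, far from saturation):
  *k*<sub>C→I</sub> = *k*<sub>on,eff</sub>·[RNP]
- hyperbolic law (saturable initial binding, the two-step model
  C<sub>free</sub> ⇌ C<sub>bound</sub> ⇌ I):
  *k*<sub>C→I</sub> = *k*<sub>open</sub>·[RNP]/(*K*<sub>d,init</sub> + [RNP])

The package is aimed at single-molecule biophysicists who need the full
chain from raw bead trajectories to a free-energy landscape:

- **simulate** — generative twin of the assay: Gillespie three-state paths
  observed through exact AR(1) Ornstein–Uhlenbeck angular noise, plus
  synthetic bulk datasets (cleavage/2AP time courses, binding isotherms,
  droplet counts, footprinting lanes);
- **trace preparation** — per-window ellipse drift correction, angle
  unwrapping, boxcar filtering to the 500 Hz analysis rate, re-zeroing to
  the closed state;
- **change-point analysis** — piecewise-constant-mean AR(1) exact
  likelihood, recursive binary splitting with Monte-Carlo–calibrated
  thresholds, brute-force oracle for verification;
- **states** — C/I/O clustering and merging with lifetime-weighted levels,
  population histograms, 100-ms left-censored exponential-mixture dwell
  MLE;
- **kinetics** — transition rates *k*<sub>ij</sub> = *N*<sub>ij</sub>/*T*<sub>i</sub>
  with Poisson errors, weighted linear/hyperbolic capture-model fits,
  Langmuir fits of non-specific baseline shifts;
- **landscape** — *K*<sub>ij</sub> = *k*<sub>ij</sub>/*k*<sub>ji</sub>,
  ΔG<sub>ij</sub> = −k<sub>B</sub>T·ln *K*<sub>ij</sub>, barrier heights
  −ln *k*<sub>ij</sub> + C (C = 7 k<sub>B</sub>T) over
  C<sub>free</sub> → C<sub>bound</sub> → I → O;
- **bulk fits** — mono/double-exponential cleavage fits with a principled
  fallback rule, 2-aminopurine fits with a fixed control intercept,
  active-fraction endpoints, ddPCR %DSB, permanganate footprint
  probabilities.

## Worked example

Recover the two-step capture parameters of a kinetically trapped enzyme
from a fully synthetic concentration series (seven concentrations spanning
1–100 nM, one hour of 500 Hz trace each), through segmentation, state
clustering and rate counting:

```r
library(rloopkin)

series <- run_capture_series(reference_config("dSpRY"),
                             concentrations = c(1, 2, 5, 10, 20, 50, 100),
                             duration = 3600, seed = 1,
                             model = "hyperbolic")
series$fit
#> Capture-model fit (hyperbolic law):
#>   k_CI = kopen [RNP] / (Kd_init + [RNP]);  kopen = 0.06103 +/- 0.0075 /s, Kd_init = 11.2 +/- 3.1 nM
#>   low-concentration slope kopen/Kd_init = 0.005451 /nM/s
#>   weighted RSS 12.21 on 5 residual df
```

The generative truth is *k*<sub>open</sub> = 0.06 s⁻¹ and
*K*<sub>d,init</sub> = 10 nM: the saturating unwinding rate comes back
within a few percent and the initial-binding constant within its standard
error. The per-concentration table (`series$rates_table`) also records the
re-zeroing offsets, which recover the injected Langmuir baseline shift of
non-specific binding (3.7 bp saturating amplitude, 14 nM):

```r
lfit <- langmuir_fit(data.frame(conc_nM = series$rates_table$conc_nM,
                                shift_bp = series$rates_table$baseline_offset_bp))
lfit
#> Langmuir isotherm fit: delta_theta_sat = 3.699 +/- 0.0013 bp, KD = 13.99 +/- 0.015 nM
```

Composing rate fold-differences into the free-energy penalty of the
bound-closed → intermediate step (unwinding ~833× slower, collapse 5×
faster) gives the ~8 k<sub>B</sub>T gap between a trapped and a fast
enzyme:

```r
delta_delta_g(fold_kopen = 50 / 0.06, fold_kic = 5)
#> [1] 8.334872
```

A full free-energy landscape at 100 nM RNP:

```r
build_landscape(kd_init = 10, kopen = 0.06, k_ic = 0.2,
                k_io = 0.1, k_oi = 0.1, conc_nM = 100)
#> Free-energy landscape at [RNP] = 100 nM (C = 7 kBT):
#>     kind         name coordinate_bp energy_kBT
#>     well        Cfree          -5.0   0.000000
#>     well       Cbound           0.0  -2.302585
#>     well            I          10.0  -1.098612
#>     well            O          20.0  -1.098612
#>  barrier Cfree-Cbound          -2.5   4.697415
#>  barrier     Cbound-I           5.0   7.510826
#>  barrier          I-O          15.0   8.203973
```

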