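# ecgidipole

Noninvasive localization of ectopic ventricular activity — typically a
premature ventricular contraction (PVC) — as a **single equivalent
current dipole**, from multi-electrode body surface potential maps
(BSPM) and a patient-like torso volume-conductor model.  The package is
aimed at researchers in the inverse problem of electrocardiography
(ECGI) who want a self-contained, testable implementation of the
dipole-scanning inverse solution, of SVD-based electrode-significance
ranking, and of the forward boundary element method (BEM) that connects
them — together with a synthetic phantom generator so that everything
runs without clinical data.

## The method

**Forward model.** The torso is a piecewise-homogeneous volume
conductor bounded by closed triangulated surfaces (torso; optionally
lungs at 0.25× and intracavitary blood at 3× the torso conductivity).
For a dipole at position *j*, the transfer matrix
*T<sub>j</sub>* ∈ ℝ<sup>M×3</sup> maps the three orthogonal moment
components (X, Y, Z; mA·mm) to potentials at the M torso electrodes.
*T<sub>j</sub>* is computed by a vertex-collocation BEM with analytic
solid-angle weights, row-sum auto terms, and deflation of the
constant-potential null space; all potentials use a zero-mean common
reference.

**First inverse solution.** Given a map Φ<sub>B</sub> ∈ ℝ<sup>M×T</sup>
(an averaged ectopic beat's first 30 ms at 1 kHz), the moments at each
candidate position (the vertices of an endo-epicardial ventricular
surface) are the least-squares fit
S<sub>c</sub> = T<sup>+</sup> Φ<sub>B</sub>, and each fit is scored by
the relative residual error

> RRE(t, j) = ‖Φ<sub>B</sub>(·,t) − Φ<sub>C</sub>(·,t)‖₂ / ‖Φ<sub>B</sub>(·,t)‖₂,  Φ<sub>C</sub> = T<sub>j</sub> S<sub>c</sub>,

minimized over all positions *j* and samples *t*.

**Electrode significance.** At the winning position, the singular
values σ₁ ≥ σ₂ ≥ σ₃ of row subsets of *T* rank the electrodes by three
criteria: **A** = σ₁/σ₃ (condition number, minimized), **B** = σ₁σ₂σ₃
(volume, maximized), **C** = σ₁+σ₂+σ₃ (nuclear norm, maximized).  The
ranking is greedy: the best 4-electrode subset is found by exhaustive
enumeration (all 10,668,000 combinations at M = 128, evaluated via a
3×3 Gram-matrix fast path in C++), then electrodes are added one at a
time, each step locally optimal.

**Second inverse solution.** The dipole scan is re-run using only the
k most significant electrodes (k = 4…M), and localization errors
(Euclidean distance to ground truth, mm) are compared against the
full-montage solution.

## Worked example

```r
library(ecgidipole)

spec  <- phantom_spec(snr_db = 20, true_vertex = 42, seed = 3)
ph    <- make_phantom(spec)                       # torso + heart + 16x8 montage
stack <- transfer_stack(ph$conductor, ph$heart)   # BEM transfer matrices
sim   <- simulate_pvc_map(ph$conductor, ph$heart, spec, stack = stack)

fit <- fit_dipole(stack, sim$map, truth = sim$truth)
print(fit)
#> Single-dipole inverse solution
#>   position index : 42
#>   position (mm)  :    35,    40,    30
#>   min RRE        : 0.05469 (sample 30 of 30)
#>   electrodes     : 128
#>   localization error : 0.00 mm

print(stack)
#> transfer_stack: 162 positions, 128 electrodes; conditioning 1.25 +/- 0.18

res <- two_step(stack, sim$map, criteria = c("B", "C"), truth = sim$truth,
                k_values = c(32, 64, 128))
print(res)
#> Two-step inverse solution (M = 128 electrodes)
#>   first solution: position 42, min RRE 0.05469
#>   LE (all electrodes): 0.00 mm
#>   second solutions (delta = LE(k) - LE(all), mm):
#>     criterion B, k =  32: LE   0.00  delta +0.00
#>     criterion B, k =  64: LE   0.00  delta +0.00
#>     criterion B, k = 128: LE   0.00  delta +0.00
#>     criterion C, k =  32: LE   0.00  delta +0.00
#>     criterion C, k =  64: LE   0.00  delta +0.00
#>     criterion C, k = 128: LE   0.00  delta +0.00
```

Reading the output: at 20 dB SNR the scan recovers the true candidate
vertex (index 42) exactly, so the localization error is 0 mm both with
all 128 electrodes and with the 32 or 64 most significant ones; the
minimum RRE of ≈ 0.055 reflects the injected noise floor rather than
model mismatch.  The mean transfer-matrix condition number of ≈ 1.25
shows the single-dipole operator is well conditioned, which is what
makes the pseudoinverse solution stable.  `coef()`, `fitted()`,
`residuals()`, `predict()`, `plot()` and `simulate()` methods are
available on the fit, and `summary()` reports an RRE-surface flatness
diagnostic that flags unreliable small-k solutions.

A command-line front end with `simulate`, `forward`, `solve`,
`rank-electrodes` and `pipeline` subcommands is installed at
`inst/scripts/ecgi-dipole`.

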