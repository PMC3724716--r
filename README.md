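# synergait

Muscle-synergy analysis of treadmill and robotic-guided (exoskeleton)
walking, for movement scientists and rehabilitation engineers who want a
tested, scriptable version of the standard modular-control analysis chain:
from raw multi-channel surface EMG to motor modules, activation-timing
statistics and joint-level kinematic/kinetic summaries.

## The analysis

Surface EMG from seven leg muscles (RF, VL, ST, BF, GM, GL, TA) is band-pass
filtered (3rd-order Butterworth, 20–400 Hz, zero phase), rectified, smoothed
with a 50-point moving RMS, segmented at heel strikes, time-normalized to a
101-point gait cycle (0–100 %GC), averaged over the ten central strides, and
amplitude-normalized per muscle by its maximum over all walking conditions.
The resulting envelope matrix **EMG₀** (m muscles × t = 101 samples) is
factorized by non-negative matrix factorization,

    EMG₀ ≈ W · A ,   W ∈ ℝ₊^{m×n},  A ∈ ℝ₊^{n×t},

where the columns of **W** are *motor modules* (fixed muscle weightings,
unit-maximum) and the rows of **A** the *activation signals* driving them
across the gait cycle. The factors minimize the squared Frobenius error
Σᵢⱼ (EMG₀ᵢⱼ − (WA)ᵢⱼ)² via Lee–Seung multiplicative updates, best of 20
seeded restarts. Reconstruction quality is measured by the variance
accounted for,

    VAF = 1 − Σ (EMG₀ − WA)² / Σ EMG₀² ,

overall, per muscle, and within the seven gait subphases (initial double
support 0–10 %GC, mid stance 10–30, terminal stance 30–50, pre-swing 50–60,
initial swing 60–73, mid swing 73–87, terminal swing 87–100). The module
count is the smallest n with per-phase and per-muscle VAF ≥ 0.80 and overall
VAF ≥ 0.90. Downstream reductions include fixed-module activation re-fitting
(exact per-sample NNLS under a frozen **W**), subphase integrals and
percentage contributions of each activation signal, triple-SD on/off timing
detection, and joint range-of-motion (ROM) / range-of-forces (ROF)
summaries.

Because gait EMG of this kind is rarely shared, the package includes a
seeded synthetic-data generator with known modular ground truth (Gaussian
activation bursts at phase-appropriate times, dominant-muscle weightings,
condition-dependent gains, stride-to-stride jitter, band-limited carrier
noise) so the whole chain can be validated end to end.

## Worked example

```r
library(synergait)

gt   <- make_ground_truth(n_modules = 4, seed = 1)      # known ground truth
cond <- condition_spec("robotic", speed = 2.0, guidance_force = 70)
emg0 <- synthesize_envelopes(gt, cond, noise_sd = 0.05, seed = 2)

sel <- select_module_count(emg0, candidates = 2:5, restarts = 10, seed = 1)
print(sel)
#> Selected 4 modules (meets the VAF rule)
#> VAF report (2 modules): overall 0.887, min muscle 0.709, min phase 0.599
#> VAF report (3 modules): overall 0.948, min muscle 0.790, min phase 0.615
#> VAF report (4 modules): overall 0.989, min muscle 0.968, min phase 0.963
#> VAF report (5 modules): overall 0.994, min muscle 0.968, min phase 0.979
```

Two or three modules leave whole subphases poorly reconstructed (minimum
per-phase VAF 0.60–0.62), while four modules pass every mask — so n = 4 is
selected. The recovered modules separate the four functional muscle groups,
and matching them against the generating ground truth gives weight-vector
correlations ≥ 0.99:

```r
fac <- sel$factorizations[["4"]]
round(fac$W, 2)
#>    module_1 module_2 module_3 module_4
#> RF     0.97     0.10     0.10     0.06
#> VL     1.00     0.00     0.01     0.18
#> ST     0.02     0.01     0.11     0.92
#> BF     0.02     0.05     0.00     1.00
#> GM     0.01     0.94     0.05     0.00
#> GL     0.02     1.00     0.00     0.03
#> TA     0.03     0.07     1.00     0.00
round(match_modules(list(W = gt$W_true), fac)$similarities, 3)
#> [1] 0.997 0.994 0.999 0.995

subphase_integrals(fac$A["module_2", ])$percents  # plantarflexor module
#> terminal stance carries 54% of its activity (late-stance propulsion)
```

The full pipeline (simulate → preprocess → extract → timing → biomech, with
CSV artifacts and provenance headers) runs from one configuration:

```r
report <- run_pipeline(run_config(out_dir = "out", seed = 1, n = 4))
```

A command-line front end with the same stages is installed at
`inst/cli/synergait.R` (subcommands `simulate`, `preprocess`, `extract`,
`timing`, `biomech`, `run`).

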