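# difcr — two-probe diffuse in vivo flow cytometry signal analysis

Circulating tumor cells (CTCs) are so rare — often a handful per
milliliter of blood — that a standard blood draw samples too little
volume to count them reliably. Diffuse in vivo flow cytometry (DiFC)
addresses this by counting fluorescently labeled cells *in the
bloodstream*: two fiber-optic probes, P1 and P2, placed 3 mm apart on the
skin over a large blood vessel, each record a fluorescence time series,
and every labeled cell transit produces a pulse on one probe followed by
the other with a delay equal to the probe separation divided by the flow
speed. `difcr` implements the complete enumeration pipeline for such
recordings, plus a ground-truthed synthetic recording generator and a
two-color flow-cytometry gating module, so every stage is testable
without animal data.

The pipeline, per probe channel, is:

1. background = moving **median**, 5 s window; subtracted;
2. local noise σ(t) = moving **standard deviation** of the subtracted
   signal, 1-minute window;
3. peak candidates = local maxima with amplitude `A > 4 σ(t)`, i.e.
   SNR = 20 log₁₀(A/σ) > 20 log₁₀(4) = 12.04 dB;
4. cross-probe **matching**: candidate pairs with delay
   `Δt ∈ [0.005, 0.5] s` are assigned to maximize the number of matched
   cells, then minimize total |Δt|; P1→P2 order means forward (arterial)
   flow, P2→P1 reverse (venous); speed `v = 3 mm / Δt`. Unmatched peaks
   are discarded, which is what keeps the false-alarm rate near zero.

Downstream statistics: count rate (cells/min), false-alarm rate from
control recordings, blood sampling rate (count rate ÷ cell concentration,
µL/min), detectable fraction of a brightness distribution above the
threshold, noise ratios between conditions, and the clinical projection
`concentration × flow × scan time × sensitivity`.

## Worked example

Simulate a 2-minute mouse-scale scan (3.6 transits/min, bright cells,
drifting baseline, 100 Hz band-limited noise) and process it:

```r
library(difcr)
sim  <- simulate_recording(difc_sim_config(duration_s = 120, seed = 7))
scan <- difc_process(sim$recording)
summary(scan)
#> DiFC scan summary (2.0 min)
#>   matched detections : 9 (4.5 / min)
#>   direction          : 6 forward (arterial), 3 reverse (venous)
#>   unmatched discarded: 2 (P1), 2 (P2)
#>   mean local noise   : 0.02633 (P1), 0.02769 (P2)
#>   mean peak amplitude: 0.6687
#>   mean speed         : 82.29 mm/s
#>   median SNR         : 26.7 dB
```

Nine cell transits were matched across the two probes (4.5/min — a
2-minute draw from a 3.6/min Poisson process), six moving in the arterial
direction; four single-probe peaks (artifacts and noise) were discarded
as unmatched. Each matched detection carries its delay and speed:

```r
head(scan$matched[, c("t_p1", "t_p2", "direction", "delay_s", "speed_mm_s")], 4)
#>     t_p1   t_p2 direction delay_s speed_mm_s
#> 1  0.350  0.372   forward   0.022   136.3636
#> 2 27.132 27.172   forward   0.040    75.0000
#> 3 60.640 60.666   forward   0.026   115.3846
#> 4 78.240 78.270   forward   0.030   100.0000
```

Because the recording is synthetic, the result can be scored against the
generator's ground truth:

```r
evaluate_against_truth(scan, sim$truth)[c("recall", "precision")]
#> $recall
#> [1] 1
#> $precision
#> [1] 1
```

With an independently measured cell concentration the count rate converts
to an effective blood sampling rate:

```r
blood_sampling_rate(3.6, 60)   # 3.6 cells/min at 60 cells/mL
#> [1] 60                       # microliters of blood interrogated per minute
```

`vignettes/difc-methods.Rmd` documents the models, parameters and design
decisions; `inst/cli/difc.R` is a command-line front end
(`simulate` / `process` / `gate` / `report`) over the same functions.

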