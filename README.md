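# glenocard

Quantifying anterior glenoid bone loss on 2-D en-face views, for orthopaedic
surgeons, radiologists and imaging researchers working on shoulder
instability. After an anterior dislocation with a bony Bankart lesion, the
fraction of the inferior glenoid that is missing drives the choice between
soft-tissue repair and bony reconstruction, so the defect percentage has to
be measured reliably and without heavyweight software.

`glenocard` implements two measurement routes on the same scene and the
statistics to compare them:

* **Comparison card.** The inferior glenoid approximates a circle en face.
  A transparent overlay divides that circle into `8n` grid cells of exactly
  equal area (the standard card: diameter 50 mm, `n = 5` strips per
  quadrant, 40 cells of 2.5% each, ≈ 49 mm² per cell). The cut abscissae
  solve the equal-area condition on the quarter disc,

  ```
  F(k_i) = i · πr²/(4n),   F(x) = x√(r² − x²)/2 + (r²/2)·arcsin(x/r),
  ```

  and each vertical strip is halved by a split ordinate `y_i` satisfying the
  arc-aware area condition `area_below(y_i) = πr²/(8n)`. The defect
  percentage is read by counting cells, `p = n_full · u`, with partially
  filled cells read by the half-grid tolerance rule `λ = u/2 ± α`
  (`u = 2.5%`, `α = 0.5%`), whose worst-case quantization error is
  `max(u/2 − α, α)` per partial cell — 0.75% for one cell, 3% for four.

* **Sugaya best-fit circle.** A circle is fitted to the inferior rim
  (algebraic Taubin fit refined by geometric least squares), the defect
  outline is clipped to the fitted disc by exact arc-aware intersection, and
  the defect ratio is `D = A/S` with severity classes small (< 5%),
  medium (5–20%), large (> 20%).

* **Validation machinery.** Synthetic glenoid phantoms with known true
  defect fraction, seeded observer noise, and agreement statistics:
  ICC(2,1) (two-way random, absolute agreement, single measures) with
  good/fair/poor grading, Bland–Altman bias ± 1.96 SD limits with a t-based
  CI of the bias, and one-way ANOVA across observers.

## Worked example

```r
library(glenocard)

card <- build_card(card_spec(diameter_mm = 50, strips_per_quadrant = 5))
card
#> <card_geometry> diameter 50 mm, 40 cells of 2.5% (49.09 mm^2) each
#>   cuts (mm):            3.94, 7.99, 12.30, 17.18
#>   split ordinates (mm): 12.45, 12.12, 11.40, 10.06, 6.51

# a phantom with a known 19.55% anterior chord defect, observed with
# 0.2 mm tracing noise
ph    <- make_phantom(radius_mm = 25, target_fraction = 0.1955,
                      shape = "chord", seed = 7)
scene <- observe_phantom(ph, observer_model(0.2, 0.2, seed = 1))

measure_sugaya(scene$rim, scene$defect)
#>   method defect_fraction defect_percent defect_area_mm2 circle_area_mm2 severity
#> 1 sugaya          0.1971          19.71           388.6            1972   medium

measure_card(card, scene$rim, scene$defect)
#>   method defect_percent defect_fraction full_count n_partial error_bound_pct severity
#> 1   card             17            0.17          4         4               3   medium
```

The Sugaya route recovers 19.71% against the true 19.55% (the 0.16
percentage points come from the rim/edge tracing noise). The card reads 4
full cells (10%) plus 4 partial cells read under the tolerance rule, giving
17% with a worst-case quantization bound of ±3 percentage points — the two
methods agree within the bound, and both classify the defect as medium.

A full synthetic validation study (33 phantoms, 3 card observers plus a
Sugaya reader, 2 occasions):

```r
st <- run_validation_study(n_patients = 33, noise_sd_mm = 0.2, seed = 1)
glance(st)
#>   n_patients icc_inter_mean icc_intra_min anova_p_min ba_bias ba_sd ba_loa_lower ba_loa_upper
#> 1         33          0.988         0.987       0.995   0.126  1.31        -2.44         2.69
```

All inter- and intra-observer ICCs grade "good" (> 0.75), observers are
statistically indistinguishable (ANOVA p ≈ 1), and the mean card reading is
unbiased against Sugaya to within 0.13 percentage points.

A command-line wrapper with `design`, `measure`, `simulate` and `validate`
subcommands lives in `inst/cli/glenocard.R`:

```sh
Rscript inst/cli/glenocard.R design --diameter 50 --strips 5 --out-svg card.svg
```

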