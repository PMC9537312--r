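---
title: "Equal-area comparison cards and best-fit-circle quantification of glenoid bone loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equal-area comparison cards and best-fit-circle quantification of glenoid bone loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glenocard)
```

## The measurement problem

Recurrent anterior shoulder dislocation erodes the anteroinferior glenoid
rim. The fraction of the inferior glenoid that is missing is the main input
to the surgical decision: small defects (< 5%) are usually managed with
soft-tissue repair, large ones (> 20%) push toward bony reconstruction. The
standard quantification works on an en-face view of the glenoid, where the
inferior portion approximates a circle: fit that circle, and express the
missing area as a fraction of the circle area.

`glenocard` implements two routes to that fraction. The *best-fit-circle
ratio* (the Sugaya approach) computes `D = A/S` exactly, where `S` is the
area of the circle fitted to the rim and `A` the area of the defect region
clipped to the fitted disc. The *comparison card* replaces the area
computation with counting: a transparent overlay divides the circle into
equal-area cells, so the defect percentage is the number of covered cells
times the per-cell percentage. The card trades a bounded quantization error
for the ability to read a defect without any software at all; this package
provides the geometry solver that makes the card, the exact-area simulation
of how it reads, and the statistics used to establish that the two routes
agree.

## Card geometry: equal-area partition of a disc

For a card of radius $r$ with $n$ vertical strips per quadrant, the cut
abscissae $k_1 < \dots < k_{n-1}$ solve

$$\int_0^{k_i}\sqrt{r^2 - x^2}\,dx \;=\; i\,\frac{\pi r^2}{4n},$$

using the closed-form antiderivative
$F(x) = \tfrac{x\sqrt{r^2-x^2}}{2} + \tfrac{r^2}{2}\arcsin(x/r)$, which is a
strictly increasing bijection of $[0, r]$ onto $[0, \pi r^2/4]$. Each strip
$[a_i, b_i]$ is then halved by a split ordinate $y_i$ with

$$\mathrm{area}\{(x,t): a_i \le x \le b_i,\; 0 \le t \le \min(y_i,
\sqrt{r^2-x^2})\} \;=\; \frac{\pi r^2}{8n},$$

and the quarter partition is mirrored across both axes, giving $8n$ cells of
exactly $\pi r^2/(8n)$ each. For the default card (diameter 50 mm, $n = 5$)
that is 40 cells of 2.5% — about 49 mm² — with cuts at 3.9434, 7.9923,
12.2965 and 17.1762 mm and split ordinates 12.4480, 12.1237, 11.4044,
10.0596 and 6.5119 mm.

Two numerical points matter here:

* **Root-finding.** Both solves are bracketed root-finds (`stats::uniroot`)
  on monotone functions, so convergence is guaranteed; the absolute area
  tolerance is $10^{-10} r^2$. Cuts are solved once on the unit radius and
  scaled, which makes the partition exactly scale-equivariant.
* **The rectangle shortcut is not valid in the outermost strip.** Where the
  arc clears the split line across the whole strip, the area condition
  reduces to a rectangle rule, $y_i = (\pi r^2/8n)/(b_i - a_i)$, and the
  solver returns that closed form. In the outermost strip the arc dips below
  any candidate line, the cell is arc-bounded, and only the exact rule is
  correct: it gives 6.51 mm where the rectangle shortcut would give 6.27 mm.
  The exact, arc-aware rule is normative throughout this package. Reported
  geometry is rounded to two decimals only at presentation; full precision
  is kept internally.

The coordinate convention is: card centre at the origin, $x$ rightward, $y$
upward, quadrant 1 the positive quadrant, strips indexed 0-based outward
from the vertical axis, and each cell tagged `lower`/`upper` relative to its
strip's split ordinate. `export_card_svg()` writes the card as stroke-only
SVG 1.1 with user units of millimetres, suitable for printing on transparent
film; output is byte-deterministic.

## Reading the card, and its error model

The card is registered onto the fitted circle by a similarity transform:
translation to the fitted centre and scaling by the radius ratio. Rotation
is fixed to the identity — angular alignment is not part of the overlay
protocol, and rotating the card only changes *which* cells are partial, not
the error bound — but `rotation_rad` is exposed for sensitivity checks.

After clipping the defect region to the registered disc, each cell's filled
fraction is computed exactly (half-plane clipping of the defect polygon to
the cell's slab, then arc-aware polygon–disc intersection). Cells with
fraction $\ge 1 - \varepsilon$ count as full, $\le \varepsilon$ as empty
($\varepsilon = 10^{-6}$); a partial cell is read by the half-grid tolerance
rule with per-cell unit $u$ (percent) and tolerance $\alpha$:

$$\lambda(t) = \begin{cases} u/2 + \alpha & t > u/2 \\ u/2 & t = u/2 \\
u/2 - \alpha & t < u/2,\end{cases}$$

defaulting to $u = 2.5$, $\alpha = 0.5$. The defect percentage is
$p = n_\mathrm{full}\,u + \sum \lambda$. The rule's worst-case error per
partial cell is $\max(u/2-\alpha, \alpha)$ — 0.75 percentage points at the
defaults, hence 3 points when four cells are partial — and the package
verifies this both in closed form and by brute-force maximization over true
fills. $\alpha$ must lie in $[0, u/2]$; outside that range a reading could
leave $[0, u]$, and the constructor rejects it.

A human reader judges "more than half" visually; the simulation uses exact
areas. This is deliberate: it isolates the quantization error of the rule
itself from perceptual error, so the end-to-end property
$|p - p_\mathrm{true}| \le n_\mathrm{partial}\cdot\max(u/2-\alpha,\alpha)$
can be tested sharply (the tests allow 0.05 percentage points of geometric
slack for floating point).

## Best-fit-circle ratio

The rim trace is fitted with the algebraic Taubin circle fit (SVD form),
refined by Gauss–Newton on the radial distances. The Taubin fit is exact on
noise-free circular data and nearly unbiased at small noise, which is what
rim traces look like; collinear input is rejected explicitly. The defect
area `A` is the exact area of the defect polygon intersected with the
fitted disc, computed by a per-edge Green's-theorem decomposition (inside
pieces contribute triangle areas, outside pieces circular sectors); no
polygonization of the circle is involved, so closed-form cases (chords,
containment, disjointness) are reproduced to near machine precision.
Severity uses the small/medium/large thresholds at 5% and 20%; both
boundaries are assigned to `medium`, matching the strict inequalities on
either side.

Defects are clipped to the fitted disc before ratio-ing: `D = A/S` only
makes sense with $A \subseteq S$, so any superior extension of a traced
defect outline contributes nothing. Free bone fragments (the fragment-area
variant of the ratio) are out of scope.

## Synthetic phantoms: what they emulate and what they do not

`make_phantom()` builds an en-face scene with a known true fraction:

* `chord` — a straight anterior cut at the offset solving the
  circular-segment equation $f(d) = (r^2\arccos(d/r) - d\sqrt{r^2-d^2})/
  (\pi r^2)$ for the target fraction; the analytic ground truth used in
  closed-form tests.
* `bite` — the chord edge perturbed by three seeded low-order sine modes
  (default amplitude 4% of the radius), with the offset re-solved so the
  realized fraction stays within $2\times10^{-3}$ of target; an irregular
  erosion while remaining a simple polygon.

`observe_phantom()` emulates a reader: at least 24 rim samples on the intact
part of the true circle and the defect vertices, each jittered with
isotropic Gaussian noise (default SD 0.2 mm — sub-pixel for typical CT
en-face reconstructions). Streams are keyed by (seed, phantom, observer,
occasion), so any single measurement is reproducible in isolation.
`make_cohort()` draws true fractions from a truncated normal (mean 0.10,
SD 0.08, bounds $[0, 0.45]$), a case mix that exercises all three severity
classes with mostly small-to-medium defects, as seen in instability
cohorts. An optional superior pear-shaped lobe (height $0.6r$ over the
60–120° arc) can be added to the outline; both methods operate on the
inferior circle only, and tests verify the lobe changes nothing.

The phantoms are deliberately idealized. They do not model CT texture,
partial-volume edge blur, the 3-D-to-en-face projection step (and the
angular bias a mis-aligned viewing axis introduces), reader-specific
systematic bias, or irregular multi-fragment defects. Passing the
validation study therefore shows that the card's geometry, reading rule and
statistics behave as designed under honest tracing noise — not that a human
reader on clinical CT will reach the same ICCs.

## The validation study design

`run_validation_study()` mirrors a reliability study: a cohort (default 33
phantoms) is measured by one Sugaya reader and three card observers on two
occasions, each with independent seeded noise. It reports per occasion the
one-way ANOVA across the four measurement columns, the inter-observer
ICC of the card readers, and the Bland–Altman comparison of the Sugaya
reading against the mean of the card observers (the mean is the
standard choice of final value per glenoid); plus each card observer's
intra-observer ICC across occasions.

Statistical choices:

* **ICC form.** Two-way random effects, absolute agreement, single measures
  — ICC(2,1) from the mean squares — because observers are a sample of
  possible readers and absolute agreement (not mere consistency) is what a
  clinical measurement needs. A one-way form, ICC(1,1), is exposed as an
  option. Grading: good > 0.75, fair 0.4–0.75, poor < 0.4, boundaries to
  `fair`. A table with zero total variance raises an explicit
  undefined-ICC error rather than returning a conventional value.
* **Inter-observer ICC across occasions.** "The average of the two
  measurements" is ambiguous (mean of the per-occasion ICCs vs ICC of
  averaged occasions); the report gives the per-occasion ICCs *and* their
  mean, labelled as such.
* **Bland–Altman.** Bias, sample SD of differences, limits
  $\mathrm{bias} \pm 1.96\,\mathrm{SD}$, and a t-based 95% CI of the bias
  ($\mathrm{bias} \pm t_{0.975,n-1}\,\mathrm{SD}/\sqrt{n}$), the convention
  of the common agreement-analysis tools.
* **Observer comparison.** One-way fixed-effects ANOVA across columns;
  Kruskal–Wallis is available as an option but not the default, since the
  defect percentages are approximately normal within this design.

## Problem sizes and runtime choices

The shipped tests run the full pipeline at sizes chosen to exercise the
statistics without waste: the default 33-phantom cohort for the study-level
properties, 200 independent phantoms for the card-vs-exact quantization
bound, 100 re-simulated observer replicates for the ANOVA null behaviour,
and $10^4$ synthetic differences for Bland–Altman coverage. Geometry
oracles (quadrature, bisection, rasterization at 0.05 mm pixels) are
independent of the implementation paths they check.

## Known limitations

* Strictly 2-D: the package starts from an en-face point set and takes no
  position on how that view is reconstructed from CT, which is itself a
  known source of bias.
* The defect must be supplied as one closed simple polygon; how a drawn
  free curve is closed against the rim is the user's responsibility, and
  multi-fragment defects are not represented.
* The card reading simulation is exact-area; perceptual misjudgement of
  "more than half" is outside the error model (though any misjudgement
  changes a reading by at most $2\alpha$ per cell).
* The contralateral-circle (Pico) and depth/radius (Barchilon) methods are
  not implemented.
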