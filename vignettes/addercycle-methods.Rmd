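---
title: "Models and methods behind addercycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind addercycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addercycle)
```

addercycle analyses the cell cycle of *Escherichia coli* in steady-state
exponential populations. This vignette explains the models it implements,
the assumptions they rest on, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design decisions taken where the published record leaves
choices open.

## The population model

All population-level relations assume **steady-state exponential growth**:
every cell doubles its length with the population doubling time
$T_d$, division produces two daughters, and the cell-age density is

$$\phi(a) = \frac{2\ln 2}{T_d}\, 2^{-a/T_d}, \qquad 0 \le a \le T_d,$$

with twice as many newborns as dividers. Three consequences are used
throughout:

* **Mean DNA per cell.** With replication period $C$ (origin-to-terminus
  fork transit) and post-termination period $D$,
  $G_c = \frac{T_d}{C\ln 2}\left(2^{(C+D)/T_d} - 2^{D/T_d}\right)$
  chromosome equivalents. `mean_genome_equivalents()` evaluates this;
  `solve_d_period()` inverts it for $D$ by bisection on $[0, 3T_d]$ to a
  tolerance of $10^{-6}$ min ($G_c$ is strictly increasing in $D$, so the
  root is unique, and an infeasible target below the $D = 0$ floor raises
  an error rather than clamping).
* **Terminal periods.** A morphological class occupying the last $T$
  minutes of the cycle (visible constriction; two separated nucleoids)
  contains the fraction $F = 2^{T/T_d} - 1$ of the population, hence
  $T = T_d \log_2(1+F)$. This formula is not printed in the experimental
  record we reimplement; it is the unique inversion consistent with
  $\phi(a)$ and it reproduces the published period values (15 and 10 min
  for constriction, 23 min for fast-growth segregation). One published
  number disagrees: the slow-growth segregation period is printed as
  24 min, while 17% two-nucleoid cells at $T_d = 122$ min give 27.6 min.
  The package reports the formula value; we could not reconstruct the
  printed one.
* **Newborn length.** Under exponential elongation the mean newborn length
  is $L_b = \langle L\rangle / (2\ln 2)$.

## The single-cell replication state machine

A `replication_state` is a count of complete chromosome backbones plus an
ordered vector of active replication-round progress fractions. The
chromosome is collapsed to one normalized coordinate $x \in [0,1]$ from
origin to terminus, merging the two bidirectional forks — the standard
Cooper–Helmstetter reduction, which preserves every DNA amount the
analysis uses. Genome content is the exact piecewise integral
$G = n_{\text{chrom}} \int_0^1 2^{k(x)}\,dx$, where $k(x)$ counts rounds
past position $x$.

Assumptions: initiation is synchronous on all origins present; forks move
at the constant rate $1/C$; every division is fed by a round initiated
exactly $C+D$ minutes earlier. `steady_state_cell()` applies that schedule
at divisions $T_d, 2T_d, \dots$; when $C + D > T_d$ the newborn inherits
running rounds from its ancestors (multifork replication), and when a
division arrives sooner than $D$ after birth the corresponding termination
fired in an ancestor — the newborn then carries the doubled backbone,
which keeps genome content continuous in the schedule.

`population_mean_genome()` averages the single-cell model over $\phi(a)$
(quadrature split at the initiation/termination event ages, where per-age
DNA has kinks, or Monte-Carlo over sampled ages) and serves as the
independent oracle for the closed form: the two agree to $10^{-3}$ across
slow, fast and $C+D = T_d$ conditions in the test suite.

**Run-off simulation.** `runoff_curve()` blocks initiation at $t = 0$ in a
steady-state population and lets active forks finish. Fork dynamics are
exact (event-driven); the `timestep` argument only selects the reported
time points. Division is frozen and DNA is reported per original cell — the
published record does not state its per-cell vs per-culture normalization,
so this choice is ours; it makes the curve plateau exactly at $t = C$ at
one chromosome per origin present at drug time (population mean
$2^{(C+D)/T_d}$), which reproduces the published plateau times of 70 and
53 min.

## Adder sibling lineages

`construct_sibling_lineages()` builds the two branches born from one
asymmetric division of an average cell: newborn lengths
$L_b^\star(1 \pm s)$, exponential elongation at the population rate,
division after adding the fixed increment $\Delta L$, and each branch
followed through one daughter of every subsequent symmetric division. The
generation time is $\tau = T_d \log_2((L_b + \Delta L)/L_b)$, so the large
sibling divides earlier — the homeostasis direction — and newborn-length
deviations halve each generation ($s = 0.15$, one SD of observed newborn
lengths, falls below 1% in `convergence_cycles(0.15, 0.01)` = 4 cycles).
The construction anchors $L_b^\star = \Delta L$ (the steady state); other
values are accepted but not what the published construction shows.

`schedule_initiations()` places one initiation $C+D$ before each division
and assigns it to the ancestor alive at that instant; times before the
founding division fall in the pre-asymmetry ancestor line, which is
assumed to have been at steady state (a stated, testable assumption —
`genome_trajectory()` seeds each branch with the steady-state newborn
state for the same reason). Initiations feeding divisions beyond the
constructed window can still fall inside it when $C+D$ spans several
generations; the schedule is therefore extended along the adder map far
enough to cover the window. Genome content is evolved event-wise — no time
grid — and the state splits symmetrically at each division, conserving
DNA exactly.

At fast growth this construction predicts a transient DNA excess at
division in the large branch, decaying to zero as the lineages converge;
the package's tests verify both the direction and the decay.

## The cytometry pipeline

The pipeline starts from per-cell measurement tables (lengths, diameters,
constriction diameter, integrated fluorescence) and optional 1-D axial
profiles; no 2-D image processing is performed.

* **Background.** The modal value of an image (or profile) is taken as
  background and subtracted, negative residuals clamped to zero.
  `modal_value()` uses the majority value for discrete-looking data and a
  Silverman-bandwidth KDE mode otherwise.
* **Calibration.** The reference population carries one or two fully
  replicated chromosomes; its left fluorescence peak defines one
  chromosome equivalent. `calibrate_fluorescence()` takes the leftmost
  local maximum (height at least 10% of the global maximum) of a
  Silverman-bandwidth KDE. We chose the full-sample KDE over a
  lower-half-only fit because truncating at the median biases the mode of
  a unimodal reference; the leftmost-substantial-peak rule handles the
  bimodal and unimodal cases uniformly. Round-trip accuracy on synthetic
  references is within 3% for a resolved 1C/2C pair.
* **Classification.** Constricting cells are those with a measured waist;
  deeply-constricted cells have a waist strictly below the mean waist of
  all constricting cells. Deeply-constricted cells are split at their mean
  length into small and large prospective daughters; a length exactly at
  the mean goes to the large group (tie rule, documented).
* **Contrasts.** `compare_groups()` defaults to Welch's unequal-variance
  two-tail $t$ test (group SDs in the published tables differ up to
  1.5-fold); the pooled Student variant is available.
  `compare_groups_summary()` computes the same tests from published
  means/SDs/counts, and the tests verify it against `t.test()` on
  moment-matched samples.
* **Nucleoids.** Nucleoids are maximal runs of profile samples above 20%
  of the profile maximum (the manual rule — "fluorescence still visible
  between nucleoids" — is qualitative; the threshold is a parameter). Both
  distance conventions are reported: edge-to-edge gap (matching manual
  measurements, which are far smaller) and centre-of-mass distance
  (matching profile-plot calculations).
* **Asymmetry.** $K(L)$ is the prospective-daughter/whole-cell length
  ratio at the division plane (given directly or located at the
  diameter-profile minimum). Each cell contributes $K$ and $1-K$ to one
  pooled symmetric sample whose CV is reported; whether the published CVs
  were computed per-daughter or per-pair is not stated, so the symmetric
  convention is our documented choice.
* **Profiles.** Collective profiles resample each cell to 100 points on
  normalized length and average pointwise; no pole-orientation flipping is
  applied before averaging. Profile maps sort cells by ascending length
  with stable id order on ties, bottom-aligned at the pole.

## The synthetic-population generator

`generate_population()` emulates a fixed-and-stained snapshot of one
steady-state culture: ages from $\phi(a)$, lognormal newborn lengths
(CV 15%, as observed), exponential elongation, a linear waist-closure
trajectory over the constriction window, two nucleoids whose
centre-of-mass separation grows linearly to $L/2$ through the segregation
window, Gaussian division-plane asymmetry at the configured $K$ CV, and
multiplicative lognormal fluorescence noise around a configurable
AU-per-equivalent factor. Defaults are the slow-growth condition
($T_d = 122$, $C = 70$, $D = 40$ min, $T$ from the 9% constricting
fraction, $S$ from the 17% two-nucleoid fraction); `synth_config_fast()`
is the fast-growth preset ($T_d = 29$, $C = 53$, $D = 25$, 26% and 74%).

Each cell's DNA is conditioned on its **own adder-consistent division
schedule**: its division age follows from its perturbed birth length via
the adder rule, descendant generation times follow the adder map, and
every initiation sits $C+D$ before the division it feeds. This is the
mechanism by which the large/small DNA contrast emerges at fast growth —
anchoring descendants to fixed $T_d$ instead would tie every fork to the
division it feeds and erase the contrast. The waist-closure and
nucleoid-separation trajectories are linear for lack of published
within-window dynamics; both are flagged as modelling conveniences.

Profiles are sums of trapezoid-shaped nucleoid pulses (ramps one sample
wide, a 5% axial tilt so that no plateau of identical values can be
mistaken for the modal background) rescaled so the trapezoid integral
equals the cell's integrated fluorescence exactly, plus a smooth cosine
constriction notch in the diameter channel and an optional constant
background.

What the generator does **not** emulate: segmentation errors, focus and
photobleaching gradients, nucleoid shape irregularity (lobular multifork
nucleoids), cell curvature, and any correlation between measurement noise
and cell size. Pipeline tests passing on synthetic data therefore
demonstrate correctness of the computations and the internal consistency
of the model chain, not robustness to real-microscopy artefacts.

## Numerical choices and problem sizes

* Quadrature: `stats::integrate` per event-delimited segment, relative
  tolerance $10^{-9}$; run-off adds the event ages shifted by the elapsed
  time as extra breakpoints.
* Bisection tolerance for $D$: $10^{-6}$ min. Round-trip identities hold
  to $10^{-5}$ on the test grid.
* Age sampling uses the inverse CDF $a = -T_d\log_2(1 - u/2)$; generators
  take explicit seeds and restore the caller's RNG state.
* Test problem sizes: synthetic populations of 2000 cells (matching the
  order of the published counts of 1022 and 772 cells per condition),
  $10^5$ Monte-Carlo ages for the closed-form cross-check, 1500-cell
  calibration references. Binomial-fraction checks use 4-sigma bands;
  recovery tolerances are 10% for periods, 5% for mean DNA, 3% for the
  calibration factor, half a percentage point for the $K$ CV.

## Known limitations

* The slow-growth segregation period and the $D$ value implied by the
  rounded $G_c = 3.7$ disagree slightly with the printed values (27.6 vs
  24 min; 25.5 vs 25 min); the package reports its computed values and
  does not special-case the printed ones.
* Initiation asynchrony, per-fork speed variability, stochastic adder
  noise and growth-rate variability between cells are all out of scope;
  the constructions treat the adder increment and $C+D$ as exact.
* The run-off normalization (freeze division, report per original cell)
  is an interpretation; a per-culture normalization would change the curve
  between 0 and $C$ but not the plateau time.
* Published raw per-cell measurements are not available, so group means,
  SDs and $p$ values from the real populations can only be recomputed
  from their printed summaries, not from scratch.
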