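---
title: "Coincidence-corrected competition assays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coincidence-corrected competition assays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocompete)
library(dplyr)
```

`cytocompete` implements the quantitative chain from gated flow-cytometry
event counts to ecological verdicts for serial-transfer competition
experiments between microbial strains. This vignette explains each model in
the chain, the assumptions it rests on, the tunable parameters and why their
defaults are what they are, and the numerical and design choices that a
maintainer would otherwise have to reverse-engineer.

## The coincidence model

A flow cytometer records an *event* whenever fluorescence crosses a
threshold while sample fluid passes the laser. If cells arrive as a Poisson
process — constant rate, no temporal correlation — then the number of cells
inside a recorded event follows a Poisson distribution conditioned on being
at least one, i.e. a zero-truncated Poisson:

$$p(n) = \frac{\lambda^n}{n!\,(e^\lambda - 1)}, \qquad n \ge 1,$$

where $\lambda$ (dimensionless, mean cells per event window) grows with cell
concentration and shrinks with sample dilution and flow rate. Two tagged
strains with true frequencies $f_1, f_2$ produce an event gated as "pure
color $i$" only when all fluorescent cells in the event are color $i$:

$$f_i^{obs} = \sum_{n\ge1} p(n)\, f_i^{\,n}
            = \frac{e^{\lambda f_i}-1}{e^{\lambda}-1},$$

and two-color events land in a double-positive cloud. With a third,
nonfluorescent strain read through a DNA dye, "pure color $i$" means at
least one color-$i$ cell, no other-color cell, any number of dye-only cells:
$\sum_n p(n)\,[(f_i+f_0)^n - f_0^n]$, and the dye-only fraction is
$\sum_n p(n) f_0^{\,n}$.

**Assumptions.** (i) Poisson arrivals — violated by clumping or aggregation,
which inflates apparent $\lambda$; (ii) gating cleanly separates the noise
cloud from fluorescent particles; (iii) fluorescence classification is
error-free given the cells in the event. Noise events are excluded from all
class fractions: they carry no cells of interest, so they belong in neither
numerator nor denominator.

### Inversion

The observed pure-class fractions give as many equations as unknowns
($\lambda, f_1$ for two colors; $\lambda, f_1, f_2$ for three classes).
Rather than a general multivariate root search, `invert_frequencies()`
exploits the structure: given $\lambda$, each true frequency has a closed
form in its observed fraction, e.g.
$f_i = \log\!\big(1 + f_i^{obs}(e^\lambda - 1)\big)/\lambda$, and the sum of
the implied frequencies is strictly increasing in $\lambda$. So $\lambda$ is
the bracketed root of "frequencies sum to one", found with `stats::uniroot`
to a $10^{-14}$ bracket tolerance. This converges whenever a solution
exists; observed fractions with no solution (pure classes summing above 1,
or mixed events with only one color present) raise informative errors
rather than returning a silent best effort.

Numerical choices worth recording:

* **Series truncation.** The forward model has an exact closed form; the
  truncated series (`n_max = 100` by default) is also implemented, and the
  two agree below $10^{-12}$ for $\lambda \le 5$ — the equivalence is
  asserted in the test suite over a 50 × 50 grid. The closed form is used
  internally; `n_max` only controls the residual report.
* **The no-mixed-event shortcut.** A sample with zero double-positive
  events maps to $\lambda = 0$ and frequencies equal to observed fractions
  exactly, with no solver call, so the no-coincidence limit is continuous
  and exact.
* **Total-count correction.** $N_{corr} = N_{obs}\,\lambda e^{\lambda} /
  (e^{\lambda}-1)$, the zero-truncated Poisson mean, defined as $N_{obs}$ at
  $\lambda = 0$ by continuity.
* **Uncertainty.** The frequency-error model of a gated measurement is not
  standardised; `correct_samples(n_boot = ...)` offers a multinomial
  parametric bootstrap over the event-class counts (off by default, 1000
  draws typical) rather than a closed-form delta approximation.

## Fitness and growth statistics

Relative fitness is the change in logit frequency per unit time,
$s = \Delta\,\mathrm{logit} f / \Delta t$, in **logit units per transfer
cycle** by default. Per-generation values divide by $\log_2(\text{dilution})$
($\log_2 100 = 6.6439$ generations per daily 1:100 cycle); the unit is
always carried in the result object because axes in this literature are
ambiguous. Replicates are aggregated as an unweighted mean with its standard
error; the default window is first-to-last measurement, with per-interval
increments available via `per_cycle_fitness()` (they sum exactly to the
whole-window change).

Frequencies of exactly 0 or 1 are **censored, not pseudocounted**: the logit
is undefined there, and any imputation choice would bias $s$ in a direction
that depends on the imputation, not the data. Estimators raise an error
naming the offending replicate so the analyst decides.

Within-cycle growth rates are log-slopes between adjacent timepoints,
reported at the second timepoint of each pair; the stationary-phase net rate
is the log-slope across a fixed late window, 8–24 h by default (the part of
a daily cycle after glucose exhaustion where survival and residual growth
differentiate strains). The window endpoints resolve to the *nearest
measured* timepoints, and a late measurement up to 10% of the window span
before the nominal end still counts — end-of-cycle measurements are taken
"at about 24 h", not on a grid — but a series ending earlier than that is an
error, not an extrapolation.

## Coexistence inference

Stable coexistence is operationalised as mutual invasibility: the focal
strain's fitness is significantly positive when started rare (~1%) and
significantly negative when started common (~99%). Significance uses
replicate-level two-sided t intervals at $\alpha = 0.05$. Both-negative is
exclusion of the focal strain, both-positive fixation, and anything else —
including the biologically real case of clones whose low-frequency fitness
sits near zero — is reported as `inconclusive` rather than forced into a
call.

`frequency_dependence_fit()` fits $s(f_0) = s_0 + b f_0$ by least squares.
The linear-in-$f_0$ form is a deliberate choice: with only two starting
frequencies it is the most complex identifiable model, and its zero crossing
$f^* = -s_0/b$ is the predicted equilibrium. Intervals come two ways:
replicate-level stratified bootstrap percentiles (1000 resamples, seeded)
for everything including $f^*$, and classical t intervals for the two line
coefficients, which are exact under normal replicate noise and better
calibrated than small-sample percentile intervals. Classification mirrors
the reciprocal-invasion logic using the fitted fitness at $f \to 0$ and
$f \to 1$; with noise-free input the bootstrap degenerates to zero-width
intervals and the point-estimate signs decide, so exact fixtures classify
exactly.

For triple competitions, `resident_pair_invasion()` measures the invader
against the whole population (the residents' internal ratio is reported
separately), warns — but still computes — when the invader starts above the
5% minority threshold, and calls `cannot_invade` only when the interval lies
below zero.

## The synthetic-data generator

The generator exists so that every stage has a ground truth. It emulates:

* **the cytometer**: events drawn with zero-truncated Poisson cell counts
  and multinomial strain composition, plus an optional sub-threshold noise
  fraction — this is the Monte-Carlo oracle the coincidence inversion is
  tested against;
* **reciprocal invasion designs**: deterministic logit-linear frequency
  dynamics ($\mathrm{logit} f \mathrel{+}= s_0 + b f$ per cycle) from ~1%
  and ~99% starts over 3 daily cycles, observed through simulated event
  tables;
* **within-cycle dynamics**: piecewise lag / exponential / stationary growth
  with a joint 100-fold expansion cap (the 1:100 dilution into identical
  medium), sampled hourly for 8 h plus a 24 h endpoint, with per-sample
  dilution factors chosen the way an operator would (diluting to a roughly
  constant target concentration at the instrument);
* **triple competitions**: residents pinned at their pairwise equilibrium
  with a minority invader whose $s(f)$ is negative everywhere.

Defaults the experimental literature does not pin down were fixed once:
50,000 events per measurement (a typical one-minute autosampler run),
8 biological replicates per condition, $\lambda = 0.3$ at the instrument
(doublet fractions of a few percent, the regime where correction matters but
gating still works). Sampling noise in trajectories is binomial at the
measurement, not demographic: census sizes in these experiments (~$10^8$
cells/mL) make drift negligible next to counting noise at these event
counts. One top-level seed drives everything; the same seed yields
byte-identical fixture files.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: mechanistic resource dynamics
(glucose/acetate cross-feeding), fluorescence spillover and gating errors,
aggregation (non-Poisson coincidence), day-to-day environmental variation,
and evolutionary change during the assay. The generator shares its forward
model with the correction stage *for the cytometer step only*; the
trajectory and growth layers are independent of the estimators tested
against them.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use: $10^6$-event Monte-Carlo
checks (3-SE agreement); a 50 × 50 $(\lambda, f)$ grid for closed-form
equivalence; a 5 × 5 grid for inversion round trips at $10^{-8}$; 100 seeded
neutral competitions (8 replicates each) for estimator calibration; 20
seeded full-pipeline runs for recovery of $s(f) = 0.3 - 0.6 f$, its
equilibrium at 0.5, and the coexistence/exclusion verdicts; and
$\Delta t = 0.01$ h sampling for the $10^{-6}$ growth-rate recovery checks.
These sizes give comfortable statistical resolution while keeping a full run
in the low minutes on one core.

## Known limitations

* The three-class inversion extends the two-color model to dye-read triple
  competitions; the equation system is the natural generalisation, but no
  published protocol pins down how such data "should" be corrected.
* The coincidence model has no spillover/compensation layer; apply it after
  gating has been validated.
* $f^*$ from a two-point design leans on the linear form of $s(f_0)$;
  curvature between 1% and 99% is invisible to it.
* The fitness estimator assumes measurement noise dominates; at very small
  event counts or near-fixation frequencies, censoring (not modelling) is
  the only handling offered.

```{r example}
ev <- simulate_events(c(0.2, 0.8), lambda = 0.3, n_events = 1e5, seed = 1)
correct_samples(ev) |> select(f_ch1, f_ch2, lambda_hat, n_corrected)
```
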