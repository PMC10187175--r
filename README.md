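# cytocompete

Analysis of microbial competition experiments read out by flow cytometry:
coincidence-corrected frequency estimation, logit-frequency selection
coefficients, within-cycle growth decomposition, and
frequency-dependent-selection / coexistence inference — with a synthetic-data
generator so the whole pipeline can be exercised and validated without an
instrument.

## The problem

In serial-transfer competition experiments (daily 1:100 dilutions into fresh
medium, as in the *E. coli* long-term evolution experiment), two fluorescently
tagged strains — or two tagged strains plus a nonfluorescent third read
through a DNA dye — are mixed and their relative frequencies tracked by flow
cytometry. Cytometers undercount: when several cells pass the laser together
they are recorded as **one** event, and a two-color pair shows up as a
spurious "double-positive" event. Left uncorrected, coincidence biases both
the measured frequencies and the total cell counts, and everything downstream
(selection coefficients, growth rates, coexistence calls) inherits the bias.

## The model

Cell arrivals at the laser are a Poisson process, so the number of cells in a
*recorded* event (which by definition contains at least one cell) follows a
zero-truncated Poisson with mean-cells-per-event λ:

```
p(n) = λ^n / ( n! (e^λ − 1) ),   n ≥ 1
```

An event reads as "pure color *i*" only when every fluorescent cell in it is
color *i*, so the observed pure-class fraction is a power sum over the
cell-count distribution,

```
f_i^obs = Σ_{n≥1} p(n) f_i^n  =  (e^{λ f_i} − 1) / (e^λ − 1),
```

with the double-positive fraction as the remainder. Two observed pure-class
fractions give two equations in two unknowns (λ, f₁); `cytocompete` reduces
the system to one monotone scalar equation in λ and solves it with a
bracketed root finder (three equations / three unknowns for the dye-only
three-strain design). Total counts are corrected by the zero-truncated
Poisson mean, `N_corr = N_obs · λ e^λ / (e^λ − 1)`, and scaled by the
dilution factor to culture-scale abundances.

Downstream, relative fitness is the change in logit frequency per transfer
cycle, `s = Δ logit f / Δt`; within-cycle growth rates are log-slopes between
adjacent timepoints; and stable coexistence is called by mutual invasibility:
`s > 0` when rare and `s < 0` when common, with an explicit `inconclusive`
category. A linear fit `s(f₀) = s₀ + b·f₀` across starting frequencies gives
the equilibrium frequency `f* = −s₀/b`.

## Worked example

```r
library(cytocompete)

# one million simulated events at lambda = 0.3 with true f1 = 0.2
ev <- simulate_events(c(0.2, 0.8), lambda = 0.3, n_events = 1e6, seed = 1)
invert_frequencies(ev)
#> <coincidence inversion>
#>   lambda_hat: 0.300568
#>   f_hat:      ch1=0.19949  ch2=0.80051
#>   N_corrected: 1157801.2  (from 1000000 events; residual 2.64e-16, converged)

# reciprocal invasion: focal strain started at ~1% and ~99%
low  <- simulate_competition(s0 = 0.3, b = -0.6, f_init = 0.01, seed = 1)
high <- simulate_competition(s0 = 0.3, b = -0.6, f_init = 0.99, seed = 2)
reciprocal_invasion(relative_fitness(low), relative_fitness(high))
#> <reciprocal invasion>
#>   rare   (f0 = 0.01): s = +0.2944  CI [+0.2790, +0.3099]
#>   common (f0 = 0.99): s = -0.2900  CI [-0.3000, -0.2801]
#>   verdict: stable_coexistence
```

The inversion recovers the generating frequency (0.1995 vs 0.2) and
coincidence intensity (0.3006 vs 0.3) to Monte-Carlo precision; the corrected
count restores the ~16% of cells hidden inside multi-cell events. The
invasion verdict reads the sign pattern of fitness when rare vs common:
positive-then-negative is negative frequency-dependent selection strong
enough for stable coexistence.

```r
generations_elapsed(9, 100)   # 9 daily 1:100 cycles
#> 59.7947
```

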