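---
title: "Methods: EMU-based 13C flux analysis, rate regression, and gene-set statistics"
author: "emuflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMU-based 13C flux analysis, rate regression, and gene-set statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emuflux)
```

emuflux implements a steady-state ^13^C metabolic flux analysis (MFA)
pipeline for small carbon-atom-mapped networks, together with the two
companion analyses such a study needs: specific-rate estimation from
culture time courses, and gene-set level transcriptome statistics. A
synthetic-data generator produces every input with known ground truth, so
the whole chain — atom-map parsing, EMU simulation, measurement
correction, flux fitting, confidence intervals, rate regression,
expression tests — is exercised end to end by the test suite.

## The flux model

A network is a set of reactions with per-carbon atom maps, e.g.
`emp: G (abc) -> P (ab) + CO2 (c)`. Metabolites are `balanced`
(steady-state mass balance applies), `substrate` (labeled feed), or
`sink` (drains; balanced by construction but without a constraint row).
At metabolic steady state the net flux vector $v$ satisfies $S v = 0$
over the balanced metabolites. Measured exchange rates (glucose uptake,
acetate secretion) and biomass effluxes fix individual fluxes; biomass
effluxes are precursor demand coefficients (mmol gDCW^-1^) multiplied by
the growth rate $\mu$. The remaining freedom is parameterized by an
orthonormal null-space basis, plus one exchange flux
$v_{exch} \in [0, \infty)$ per reversible reaction (forward/backward
fluxes are $v^+ = \max(v,0)+v_{exch}$ and $v^- = \max(-v,0)+v_{exch}$).

An important structural point, visible already on the toy network: branch
splits downstream of the last labeling-sensitive node (here, the split of
pyruvate-like carbon between overflow and the TCA-like cycle) do not
change any mass isotopomer distribution (MID) and are therefore not
identifiable from labeling data. This is why the method fixes secretion
fluxes from the measured specific rates rather than fitting them.

## EMU simulation and its oracle

Label propagation uses the elementary-metabolite-unit decomposition: each
target EMU (a subset of a metabolite's carbons) is traced backwards
through the atom maps; condensation reactions whose product EMU spans two
substrate molecules become convolutions of strictly smaller EMUs. The
resulting balance systems are linear within each EMU size and are solved
layer by layer; cycles inside a layer are handled exactly by the single
linear solve, not by iteration. EMUs are ordered deterministically
(lexicographic within size) so the linear systems are reproducible.

Correctness is verified against an independent brute-force oracle that
tracks the full $2^n$ positional-isotopomer distribution of every
non-substrate metabolite and solves the steady state by
production-normalized fixed-point iteration (convergence tolerance
1e-13 on successive changes). The oracle is exponential in carbon count
and is capped at 12 balanced carbons; both built-in networks are below
the cap, and the suite checks EMU/oracle agreement to 1e-9 over 100
random flux/labeling draws.

Natural ^13^C abundance inside the network is off by default: tracer
patterns state it explicitly per position (`N`), and natural-isotope
effects of derivatization atoms live in the measurement model. This keeps
simulation and correction concerns separate.

## Measurement model

GC-MS fragments of derivatized amino acids carry non-backbone C/H/N/O/Si/S
atoms. The correction matrix $M$ maps the backbone MID to the observed
one; its columns are shifted copies of the natural-isotope kernel of the
derivatization formula, truncated to the observed mass window (columns
are substochastic). Correction solves $Mx = y$ under $x \ge 0$
(non-negative least squares) and renormalizes; a condition number above
1e8 triggers a warning. Measured MIDs may deviate from sum 1 by up to
0.02 before renormalization, reflecting truncated intensity windows; when
no SDs are supplied a default per-channel SD of 0.003 mass fractions is
used — this default matters because it scales the RSS, so it is explicit
and configurable.

## Fitting, goodness of fit, confidence intervals

The objective is the residual sum of squares over fragments and mass
channels, SD-weighted by default,
$RSS = \sum_i ((s_i - m_i)/\sigma_i)^2$; an unweighted mode exists and is
recorded in the result. The printed acceptance threshold logic
(chi-square quantile at $n_{data} - n_{free}$ degrees of freedom
compared directly with the RSS) presumes SD-scaled residuals, which is
why weighting is the default. Optimization is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) over the free coordinates from 20 random starts by
default, seed-controlled and bit-reproducible; net-flux bounds enter as
penalty residuals and feasibility is re-checked at the optimum. `n_data`
counts all measured mass channels.

Per-flux 95% confidence intervals use the grid-search (profile
likelihood) construction: the flux of interest is fixed at a grid value,
all other free fluxes are re-optimized (warm-started from the neighboring
grid point), and the CI is the set where the profiled RSS stays within
$\Delta = \chi^2_{0.95,1} = 3.84$ of the minimum. The initial step comes
from a finite-difference curvature estimate of the profile; endpoints are
refined by bisection to a tolerance of 1e-3 relative to the estimate's
magnitude, and endpoints that reach a flux bound are reported
bound-censored. On a quadratic RSS surface this reproduces the analytic
Wald interval $v^* \pm 1.96\,s$, which the suite asserts. Two strains
differ significantly in a flux when their CIs are disjoint; intervals
sharing an endpoint count as overlapping.

## Specific rates

With $dX/dt = \mu X$, $d[\mathrm{glc}]/dt = -\nu X$ and
$d[\mathrm{ace}]/dt = \rho X$, concentrations are linear in the
integrated biomass $\int_0^t X\,d\tau$, so $\nu$ and $\rho$ are ordinary
least-squares slopes of concentration against the cumulative trapezoidal
integral of biomass (consumption slopes are negated so uptake rates are
positive), and $\mu$ is the slope of $\ln X$ against time. The
exponential-phase window is explicit user input (default: all points);
no automatic phase detection is attempted. When biomass is given as
OD600, an explicit OD-to-DCW factor is required — none is assumed.

## Gene-set expression statistics

Signals are normalized per sample to a mean of exactly 500. Set-level
shifts between conditions are tested with a one-sided Mann–Whitney U
test: exact by enumeration of all $\binom{m+n}{n}$ reassignments for
$m+n \le 16$ (ties counted 1/2), normal approximation with tie and
continuity correction otherwise. The exact p-value is
$P(U \ge U_{obs})$; a documented `continuity = "midp"` option returns
the mid-p value instead, which is exactly 0.5 for identical groups but
halves the p-value of a fully separated configuration — the default
reproduces the classical exact test (p = 0.05 for `[1,2,3]` vs
`[4,5,6]`). Volcano classification calls a gene up at log2 fold change
$\ge 1$ and p < 0.05, down at $\le -1$ and p < 0.05 (the down threshold
is the sign-corrected reading of the rule); a plain fold-change
classification at 1.5-fold (down below 1/1.5) is also provided. Genes
belonging to both the CMP and AbrB sets are excluded from both sets'
statistics. Per-gene p-values come from a pooled-variance two-sample
t-test on log2 signals; the tiling-array pipeline this emulates used
limma, and the deliberate omission of empirical-Bayes moderation is
flagged in the output's `method` attribute. Box summaries use type-7
(linearly interpolated) quantiles; no convention was mandated, so the R
default is used and stated.

## The synthetic generator

`make_scenario()` bundles the study conditions. Defaults mirror the
measured culture parameters of the study design this pipeline targets:
growth rate 0.46 h^-1^ (0.51 for the derivative state), glucose uptake
5.9 (6.7), acetate production 2.7 (4.4), succinate 0.2 mmol gDCW^-1^
h^-1^, cultures starting at 10 g l^-1^ glucose (55.5 mmol l^-1^) sampled
every 15 min over 6 h, per-channel MID SD 0.003, and 2% multiplicative
time-course noise. The biomass demand coefficient (2.2 mmol gDCW^-1^)
and the tracer design (80% position-1-labeled + 20% uniformly labeled
substrate) are the package's own choices: the first is of the order of a
bacterial precursor drain for a 3-carbon unit, the second is a common
mixed-tracer design that separates the two decarboxylating branches
while keeping higher mass channels informative. The published tracer
composition is not printed in the source study, so the preset is
explicitly not presented as it.

The `TOY_CMP` preset mimics the branch structure of central carbon
metabolism at toy scale — glycolysis-like and PPP-like routes that
decarboxylate different positions, a reversible isomerase, acetate
overflow, a biomass drain and a TCA-like cycle entered through a
condensation — with 11 balanced carbons so the exhaustive oracle applies.
Its two ground-truth flux states move glycolysis and overflow up and the
PPP-like branch down between strains, so the strain comparison logic
(disjoint CIs, set-level expression shifts) can be exercised
qualitatively.

MID noise is additive Gaussian per channel, clipped at zero and
renormalized, matching the weighted-RSS assumption. Expression signals
are log-normal with configurable per-set log2 shifts, three replicates
per condition, and a planted block of dual AbrB/CMP members to exercise
the exclusion rule. All generators are pure functions of the scenario
and its seed and leave the caller's RNG state untouched.

What the generator does *not* emulate: GC-MS spectral artifacts and
instrument drift, tiling-array probe effects, non-exponential growth
phases, and real biological replicate structure in MIDs. Passing tests
therefore demonstrate the correctness of the algorithms under the stated
statistical assumptions, not robustness to real-instrument systematics.

## Numerical choices and limitations

* Problem sizes used by the suite and the acceptance script: 100 random
  draws for the EMU/oracle comparison, 50 simulated replicates (20
  optimizer starts each) for the CI-coverage study, 6-h cultures at
  15-min sampling, 2000-gene expression tables.
* The clip-and-renormalize MID noise model slightly biases channels near
  zero and correlates channels within a fragment; empirically the mean
  fitted RSS sits below the channel count minus the free-parameter
  count, and profile-CI coverage of the true flux runs a few points
  below the nominal 95% (the suite requires at least 90% over 50
  replicates).
* Degenerate inputs are errors, not silent results: zero-production
  EMUs name the dead branch, infeasible constraint sets name the
  conflict, sinks/substrates cannot be balanced, and exact ties in the
  Mann–Whitney test follow the documented convention.
* Symmetric metabolites can be encoded as two alternative atom maps on
  duplicated half-flux reactions (the `TOY1` preset's `v1`/`v3` pair is
  exactly this pattern); no dedicated symmetry syntax exists.
* Isotopically nonstationary MFA, ^15^N/^2^H tracers, genome-scale
  models, FBA, bootstrap CIs and global-optimality certificates are out
  of scope.
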