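---
title: "Methods: occupancy kinetics, transition paths, free energies and gating statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy kinetics, transition paths, free energies and gating statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kgate)
```

`kgate` analyses how cation binding couples to gate motion in elevator-type
membrane transporters. This vignette documents the statistical models behind
each stage, the parameters that matter, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Occupancy discretization and dwell-time kinetics

An ion–site distance trajectory is reduced to a binary bound/unbound flag
per site and frame by a distance threshold. Working thresholds for
mean-squared distances to coordinating atoms fall in the 3.3–3.65 Å range;
the package default is the midpoint, 3.5 Å, overridable per site. Frames at
exactly the threshold count as bound — an arbitrary but deterministic tie
rule. Per-site flags are packed into an occupancy-state index (site *s* on
bit *s*−1), giving 2^N states for N sites: 16 states for a four-site
transporter, 8 for a three-site one.

Rates come from the maximum-likelihood estimator for discretized jump
processes,

$$\hat k_{ij} = N_{ij} / t_i,$$

with `N_ij` the pooled transition count and `t_i` the pooled dwell time of
the origin state over all monomer trajectories. The estimator is invariant
to how monomer traces are ordered or concatenated; states never visited are
flagged undefined rather than given zero rates (a zero rate is a statement
about observed events, an undefined one about missing data). Site-level on
and off rates pool every compound state sharing the site's bit, because a
single `K_D` per site — off rate over second-order on rate, the latter the
pseudo-first-order on rate divided by the bulk concentration — is the
quantity of interest. Errors are bootstrap SDs over complete monomer
trajectories (default 1,000 resamples), never over frames, since frames
within a trajectory are strongly autocorrelated.

Two choices deserve a note. First, the flicker filter `min_dwell` defaults
to 0 (no filter): the discretization threshold sits in a region of near-zero
emission density for both bound and unbound distributions, so flickers are
rare, and any filter value is a statement about timescales the user should
make explicitly. Runs shorter than the filter are merged into the longer
flanking run, with the earlier run winning ties. Second, when several site
flags flip within one frame interval we count the single observed compound
transition rather than inventing an ordering; the frequency of such
compound transitions is reported (`compound_fraction`) so the user can
judge whether the frame interval is fine enough.

For a site that is never seen to unbind, `kd_upper_bound()` posits exactly
one escape event (a relocation to a reference site) in the accumulated
site-bound dwell time, `k_out^max = 1/t_bound`, and combines it with the
observed reverse relocation rate and the reference site's `K_D` through
detailed balance on the relocation step:
`K_D(target) ≤ K_D(ref) · k_out^max / k_in^obs`. The combining formula is a
modeling assumption (logged in the returned object) — the construction
yields an upper bound precisely because fewer than one escape was actually
observed in `t_bound`.

## Transition-path analysis

The estimated rate matrix defines a continuous-time Markov chain whose
generator Q has the rates off-diagonal and rows summing to zero. The
stationary distribution solves πQ = 0; on reducible chains each recurrent
class is solved separately (with a warning), transient states get zero
mass, and class weights — undefined without extra information — are split
equally. The forward committor q⁺ (probability of reaching the sink set
before the source set) solves the linear system `Σ_j Q_ij q⁺_j = 0` on
intermediate states with boundary values 0 and 1; with at most 16 states a
dense solve is exact and cheap.

Reactive flux uses `f_ij = π_i (1 − q⁺_i) k_ij q⁺_j`, which identifies the
backward committor with `1 − q⁺`. That identification is exact for
reversible chains; physical occupancy networks at equilibrium satisfy
detailed balance, and the package's demonstration and test networks are
built from state free energies with symmetric kinetic prefactors so that
reversibility holds by construction. Both gross and net
(`f⁺ = max(f − fᵀ, 0)`) fluxes are reported, since either convention
appears in the literature. Pathways are extracted from the net-flux graph
by the canonical bottleneck decomposition: repeatedly find the widest
(maximum-bottleneck) source→sink path, assign it its bottleneck capacity,
subtract, and continue. Ties between equal-bottleneck paths are broken by
lexicographic state order, making the decomposition deterministic. On
conserved (reversible) networks the extracted path fluxes sum exactly to
the total reactive flux once the network is exhausted.

## Crooks Gaussian-intersection free energies

Non-equilibrium work distributions from forward and reverse switching obey
the Crooks relation `P_f(W) = P_r(−W) e^{β(W−ΔG)}`; the free-energy change
is the work value at which the two distributions intersect. The estimator
fits a Normal to each direction (sample mean, unbiased sample SD; reverse
works are stored as −W so both live on the same axis) and solves the
intersection quadratic, taking the root between the two means. When the
fitted variances agree to within a relative tolerance of 10⁻⁶ the quadratic
is numerically degenerate and the equal-variance midpoint `(μ_f + μ_r)/2`
is used; when no root lies between the means (pathological overlap, e.g.
at tiny sample sizes) the midpoint is used and flagged. Errors are
bootstrap SDs resampling works within each direction.

Convergence follows the two-block criterion: each direction is split
chronologically (never randomly — the point is to detect drift) into
halves, and the estimate is converged when the block values differ by less
than 10% of their mean magnitude, switching to an absolute 1 kJ/mol
criterion when the mean is below 1 kJ/mol so that near-zero ΔG does not
make the relative criterion explode. A head-drop fraction is available for
equilibration trimming and defaults to 0 for synthetic data.

Double differences ΔΔG = ΔG_a − ΔG_b serve both ion selectivities and
mutation effects (transformation in the ligand-bound vs the apo protein).
The default error adds the two bootstrap SDs in quadrature — the two legs
are independent simulations — with a paired-bootstrap mode available; both
are provided because the pairing convention is a genuine free choice.

The Gaussian work generator draws from the exact Crooks-consistent pair:
forward works from `N(ΔG + σ²/2kT, σ²)` and reverse (−W) works from
`N(ΔG − σ²/2kT, σ²)`. For a common σ these are the only Gaussians
satisfying the relation, which makes the generator a strict oracle: the
sampler's log density ratio has slope β and intercept −βΔG, and tests
verify this by binned regression.

## Umbrella sampling, WHAM and gating statistics

Biased windows (harmonic restraint, center c, force constant k) are
combined by the standard self-consistent WHAM iteration on a histogram
grid: window free energies f and unbiased density p are alternated until
the largest change in f per sweep falls below 10⁻⁶ kT, on a 200-bin grid by
default — choices matching the precision of standard WHAM tools at this
problem scale. Adjacent windows must share histogram support, otherwise the
iteration is ill-posed and the offending gap is named in the error.
Per-bin errors come from resampling each window's samples (multinomially on
its histogram) and re-running WHAM warm-started from the converged window
free energies, 60–100 resamples by default. Convergence over simulated time
is assessed by splitting windows chronologically into blocks and requiring
the last three block densities to overlap pairwise by at least 80%, with
overlap measured as histogram intersection `Σ min(p, q) dx` — the simplest
normalized choice, adopted because the criterion's original statement does
not pin down a metric.

The open/closed gate boundary is defined as the first interior local
minimum of the ligand-bound gate-distance histogram, scanning from small
distances. A Gaussian smoothing kernel of 2 bins is applied first (width 0
disables it); raw histograms at fine binning have spurious single-bin
minima, and 2 bins is the smallest width that reliably removes them without
moving the minimum. The closed-state probability integrates the density
below the boundary (profile mode) or counts frames (trace mode, with
monomer bootstrap). The K-type allosteric efficacy is the odds ratio

$$\alpha = \frac{p_b/(1-p_b)}{p_a/(1-p_a)},$$

the factor by which ligand binding multiplies the gate-closure equilibrium
constant. Its bootstrap SD pairs independent resamples of the apo and
bound probabilities, because the two come from separate simulations.
Efficacies computed from published rounded probabilities will not match
published α values computed from unrounded data; the package therefore
validates the formula and generator-calibrated recovery, not any specific
printed α.

RMSF block statistics split a pre-aligned coordinate series into 10
contiguous blocks and report per-residue mean ± SD of the within-block
root-mean-square deviation from the block mean; no superposition fitting
is attempted — inputs are assumed aligned upstream. The 2-D gate/
salt-bridge histogram reports quadrant occupancies under two thresholds
with the same at-or-below tie rule as discretization.

## Capacitor fits and thermophoresis curves

The double-bilayer capacitor model is linear, `V = (q_sol + q_p0)/C₀`, and
is fitted by unweighted OLS (the model statement implies homoscedastic
voltage noise); `C₀` is the inverse slope and `q_p0` the intercept/slope
ratio, so the fitted voltage vanishes at `q_sol = −q_p0` identically.
Bootstrap resamples whole replicate trajectories at fixed charge imbalance.
Charge displacements between states difference the `q_p0` values with
quadrature SDs.

Thermophoresis traces are normalized twice: the steady-state fluorescence
is divided by the value 0.4 s after the temperature jump (the initial
rapid decay is a dye artifact), and each replicate curve is anchored to 1
at its lowest concentration. Binding curves are fitted by Nadaraya–Watson
local-constant regression with a Gaussian kernel on the log₁₀-concentration
axis — serial dilutions are geometric, so that is the natural design
scale — with the bandwidth from Silverman's rule of thumb on the design
points (the standard automatic default; the bandwidth used is reported).
Confidence bands are percentile intervals over bootstrap resamples of
whole curves (default 10,000 resamples, 99% level). Two conditions differ
significantly where their bands fail to overlap; the overall verdict
requires a contiguous non-overlapping run covering at least 10% of the
grid, a guard against isolated-point multiplicity artifacts. Parametric
Hill fitting is deliberately not offered as a headline: curves that do not
saturate leave Hill parameters unidentifiable, which is what motivates the
non-parametric route.

## The synthetic-data generators

The generators define the study conditions for every recovery test.

**Binding traces.** A continuous-time Markov chain over occupancy states is
simulated exactly (event-driven Gillespie sampling), then emitted on the
frame grid. Bound frames draw distances from `N(3.0, 0.15²)` Å truncated
above at the threshold; unbound frames follow an Ornstein–Uhlenbeck process
(mean 15 Å, SD 5 Å, relaxation time 1 ns) reflected at threshold + 0.5 Å.
The truncation/floor pair guarantees the discretizer recovers the hidden
state path exactly, which is intentional: it lets tests separate
discretization errors (zero by construction here) from kinetic estimation
errors (the quantity under study). Real distance traces violate this
separation near the threshold; the generators deliberately do not emulate
threshold-straddling noise, multi-ion exchange at one site, or
emission autocorrelation while bound, so passing recovery tests speak to
the estimator chain, not to threshold robustness on real data. Rates are
pseudo-first-order at the stated bulk concentration; `two_state_spec()`
derives the on rate from a target `K_D` as `k_on = k_off·C/K_D`.

**Langevin traces and umbrella windows.** Analytic profiles (harmonic, or
a double well with wells at ±0.5 nm and adjustable barrier and tilt) are
sampled either by overdamped Euler–Maruyama integration
(`dx = −βD G′ dt + √(2D dt) ξ`, reflecting walls, with a documented
stability bound `dt < 0.1·kT/(a_max·D)` evaluated over the thermally
accessible region) or exactly, per umbrella window, by inverse-CDF sampling
of the biased Boltzmann density on a dense grid. The exact window sampler
means WHAM recovery tests are free of integrator bias;
`calibrate_double_well()` tilts the profile until the closed-basin
Boltzmann weight hits a target probability, providing gating ground truth.

**Work sets, capacitor series, binding curves.** As described above; each
generator attaches its ground truth as an attribute and is bit-reproducible
given a seed.

## Problem sizes and defaults

The recovery suites run at desk scale, chosen to finish in seconds to a
couple of minutes per stage while leaving comfortable statistical margins:
dissociation-constant recovery uses 20 monomer traces and roughly 500
binding events per regime (frame intervals 0.2–20 ns depending on the
fastest rate, so that `dt·k_max ≤ 0.03` and frame aliasing of short dwells
stays at the percent level); CGI recovery uses 250 works per direction at
σ = 4 kJ/mol; gating recovery uses 44 windows of 9,000 exact samples at
k = 1,000 kJ/mol/nm². Bootstrap defaults are 1,000 resamples for scalar
statistics (10,000 for thermophoresis bands, 60–100 for per-bin WHAM
errors, where each resample re-runs the full iteration).

## Known limitations

- The committor-based flux formula assumes detailed balance; on a
  non-reversible rate matrix the reported fluxes are the spec'd estimator
  applied outside its exactness regime, and conservation diagnostics will
  reveal the discrepancy rather than mask it.
- The upper-bound `K_D` construction is an assumption-laden inequality,
  not an estimator; it is reported with its assumption string attached.
- WHAM errors resample within windows, so they capture sampling noise but
  not window-placement bias; profile-convergence blocks are the tool for
  the latter.
- Bootstrap percentile bands undercover slightly at small replicate
  counts (e.g. 5 curves); the band level is nominal.
- The pipeline consumes precomputed 1-D reaction-coordinate projections
  and plain coordinate tables; it does not construct reaction coordinates
  or align structures.
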