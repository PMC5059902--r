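---
title: "Models and methods: magnetosome chain segregation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: magnetosome chain segregation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetochain)
library(dplyr)
```

Magnetotactic bacteria such as *Magnetospirillum gryphiswaldense* build a
linear chain of membrane-enclosed magnetite crystals — magnetosomes — that
acts as a cellular compass needle. At division the chain must be positioned
at midcell, cleaved, and the two daughter chains moved from the new cell
poles back to the centres of the daughter cells. The machinery behind this
is the bacterial actin MamK, whose treadmilling filaments, coupled to
magnetosomes through the adaptor MamJ, provide directed transport. This
package implements the quantitative layer of that biology: a stochastic
simulator of chain assembly and repositioning, partition-accuracy
statistics, single-particle track statistics, FRAP and photoconversion
kinetics, and treadmilling-speed estimation, together with seeded
generators of synthetic data for all of them.

## The chain simulator

The simulator evolves `n` magnetosomes on the cell axis `[0, L]` by
overdamped (inertia-free) Langevin dynamics with the Euler–Maruyama scheme:

$$\Delta x_i = \frac{F_{\text{active}} + F_{\text{dipole}} + F_{\text{steric}}}{\gamma}\,\Delta t + \sqrt{2 D \Delta t}\;\xi_i,$$

with `ξ` standard normal. Three modelling points matter:

* **Active transport with a linear force–velocity relation.** The transport
  term is a constant force of magnitude `F_s` (the stall force) directed
  toward midcell. Because the friction coefficient `γ` is an independent
  parameter — deliberately *not* tied to `D` through a
  fluctuation–dissipation relation — the force-free speed is `v0 = F_s/γ`
  and an opposing load `F` yields `v = v0(1 − F/F_s)`: the classic linear
  force–velocity law of a cytomotive filament pushing cargo. A dead-band of
  one force-free step (`v0·Δt`) around `L/2` switches the force off so the
  integrator does not chatter across midcell.
* **Magnetostatic attraction.** Neighbouring crystals attract with the
  collinear point-dipole law `F = 3μ₀ m₁ m₂ /(2π r⁴)` (attractive sign
  convention in `dipole_force()`), applied only while the
  surface-to-surface gap is at most 50 nm — the distance scale beyond which
  magnetite crystals of this size are effectively magnetically independent.
  Only nearest neighbours interact; with an `r⁻⁴` law the next-nearest
  contribution at contact spacing is below 7 %, and the restriction keeps
  stepping `O(n)`. The force is capped at its contact value so that a
  diffusive step into overlap cannot produce a numerical blow-up;
  overlapping neighbours are then projected back to contact symmetrically,
  preserving their centre of mass (a hard-sphere treatment adequate at
  these time scales). Boundaries reflect.
* **Units.** The API speaks nm, s and pN; the dipole prefactor folds the
  SI-to-package conversion into a single constant (`6×10⁴¹` when `m` is in
  A·m² and `r` in nm), with `μ₀ = 4π×10⁻⁷` exact.

Default parameters describe a newborn daughter cell: `L = 4000` nm, fifteen
50-nm magnetosomes each carrying `1.6×10⁻¹⁷` A·m² (a 40-nm magnetite core at
saturation magnetization ≈ 480 kA/m), `F_s = 1` pN (the order of force an
actin-like polymerization machine can exert, and the order required to move
a chain against cytoplasmic friction), `v0 = 1` nm/s, `D = 10` nm²/s as the
"low diffusive mobility" condition, `Δt = 0.01` s and 2500 s of simulated
time — enough for a pole chain to reach midcell at `v0` with margin. These
are model choices, stated once and used throughout; none of them is a
measured constant.

The `pole_chain` initial layout places the fifteen particles regularly
spaced against one cell boundary with 60-nm surface gaps — just beyond the
50-nm magnetostatic cutoff. That reading of "regularly spaced at the
boundary" makes chain *formation* an outcome of the dynamics rather than an
initial condition: particles begin magnetically independent, the leading
particle arrests at midcell, followers pile onto it, and the dipole
attraction locks the chain. With defaults this reproducibly yields a single
chain centred at midcell. Reducing `F_s` tenfold while raising `D` tenfold
reproduces the fragmentation phenotype: diffusion brings subsets of the
slow-moving particles into contact en route, and at the end of the run two
or more short chains remain scattered instead of one centred chain.

```{r sim-example}
cfg <- sim_config(seed = 7)
traj <- simulate_chain(cfg)
m <- repositioning_metrics(traj)
c(final_chains = m$final_chain_count,
  final_offset_nm = round(m$final_offset_nm, 1),
  half_time_s = m$half_repositioning_time)
```

Reproducibility is strict: all noise is drawn up front from R's RNG seeded
with the config seed, so equal seeds give bit-identical trajectories, and
the noise matrix can be supplied explicitly, which is how the test suite
verifies exact mirror symmetry of the dynamics under `x → L − x`.

## Partition statistics

A division event is summarised by the folded fraction
`x = max(a, b)/(a + b) ∈ [0.5, 1]` of the mother chain (length or
magnetosome count) inherited by the larger daughter. Accurate
centre-finding machinery makes large `x` exponentially rare, which the
cumulative model

$$F(x) = 1 - \exp\!\left(-\frac{x - 0.5}{\lambda}\right)$$

captures with a single accuracy parameter `λ` (a fraction of chain
length). Its median is `0.5 + λ ln 2` exactly — `partition_median()` — so
`λ = 0.061` corresponds to a median split of 0.542, a 4.2 % typical
deviation from perfect halving, about two magnetosomes on a 40-magnetosome
chain: essentially the best precision physically available when cleavage
must pass between two crystals.

`fit_partition_cdf()` estimates `λ` by nonlinear least squares of the model
against the empirical CDF evaluated at midpoint plotting heights
`(i − 0.5)/n` (reducing small-`n` bias at the extremes of the step
function), and reports the closed-form maximum-likelihood estimate
`mean(x) − 0.5` alongside as an internal cross-check; the two must agree
within sampling error on well-behaved data. Because published goodness-of-fit
"R" values are ambiguous, both the Pearson correlation of model versus
empirical heights (`fit_R`) and the regression `r_squared` are returned.

The null model of *random* splitting — cleaving a line at a uniform random
position — folds to `x ~ U(0.5, 1)`, a linear cumulative distribution.
`ks_test_uniform()` tests against it with a one-sample Kolmogorov–Smirnov
test; the null is fully specified (no estimated parameter), so no
Lilliefors-type correction is needed, and `stats::ks.test()` supplies the
exact small-sample p-value (n < 100) or the asymptotic Kolmogorov series.

Bucket classification uses inclusive boundaries: `equal` for `x ≤ 0.60`
(within 10 % fluctuation), `unequal` for `x ≥ 0.70` (70/30 to 100/0), both
configurable since the inclusivity convention of published counts is not
recoverable. Events with the whole chain in one daughter (`x = 1`) are kept
by default; `exclude_whole_chain = TRUE` reproduces the usual sensitivity
check. Position scoring (`classify_chain_position()`) applies the
400/800-nm pole/adjacent zones with the chain anchored at its pole-nearest
magnetosome and the 51 % length-fraction rule for the adjacent class;
length fraction, not particle count, is used, and the pole-proximal class
wins at zone borders.

```{r partition-example}
ev <- gen_partition_events(500, lambda = 0.061, seed = 42)
rep1 <- partition_report(ev)
glance(rep1$fit)
c(ks_D = round(rep1$ks$D, 3), ks_p = signif(rep1$ks$p_value, 3))
```

## Track statistics

Chain-centroid tracks (nm versus min) are summarised per cell and as
ensembles. All ensemble quantities are computed **from each track's own
origin**, not as time-lag averages, because post-division chain motion is
non-stationary — directed transport followed by abrupt arrest at midcell —
and origin-referenced curves are what make the biphasic signature visible;
time-lag averaging would smear it. Concretely:

* `cumulative_displacement()`: running sum of step lengths (mean ± SEM);
* `track_msd()`: `⟨|r(t) − r(0)|²⟩`, ballistic `(vt)²` under drift, `2·dim·D·t`
  under diffusion;
* `apparent_diffusion()`: `D*(t) = MSD/(2·dim·t)` with `dim` read from the
  columns present (1 for axial, 2 for xy), constant for diffusion and
  linearly increasing for directed motion, so a rise-then-decay identifies
  transport that arrests;
* `windowed_velocity()`: net displacement per non-overlapping, left-aligned
  10-min window (partial trailing windows dropped);
* `mean_speed()`: path length over elapsed time, optionally truncated at
  the first window below a configurable arrest floor.

No localization-noise floor is subtracted by default; the noise
contribution to speed at the scales involved (σ ≈ 20 nm against ≈ 92 nm
true displacement per 5-min frame) biases the mean by well under the 10 %
recovery tolerance the tests enforce.

## Photokinetics

FRAP traces are normalized by **double normalization**: per frame,
background-subtracted ROI over background-subtracted whole-cell intensity
(cancelling acquisition photobleaching, which scales both), then division
by the pre-event mean of that ratio so the pre-bleach level is exactly 1.
Recovery is fitted as `F(t) = A(1 − e^{−kt}) + F(0)` with bounded
Levenberg–Marquardt (initialised at `F0` = first post-event value,
`A` = last − first, `k` = ln2 over the time to half range, with restarts),
giving `t½ = ln 2/k` with a first-order propagated standard error. The
mobile fraction is defined as `A/(1 − F0)` — plateau recovery relative to
the pre-bleach level above the post-bleach floor — so complete recovery to
1 yields exactly 1. A fit whose amplitude's 95 % CI includes zero is
flagged `no_recovery`; fixed-cell (dark-state) control traces must trip
this flag, which the tests enforce as a guard against reporting spurious
kinetics.

Photoconversion experiments are normalized the same way but anchored at
the photoconverted zone's corrected intensity immediately after the pulse
(the maximum obtainable signal = 1). Zone kinetics are fitted as single
exponentials, rise or decay, with an infinite half-time flag for flat
series and a direction-mismatch warning when the fitted amplitude
contradicts the requested direction. The matching generator uses a
three-compartment first-order chain (converted pole → opposite pole →
non-polar area) with conserved total signal — a test harness chosen to
reproduce the observed ordering of half-times (pole decay ≈ opposite-pole
rise, non-polar rise lagging), not a mechanistic claim about monomer
diffusion.

Treadmilling speed is the OLS slope of the kymograph growth-front position
versus time, in nm/min with the slope's standard error, requiring at least
four consecutive frames (a 90-s interval at 30-s imaging) and starting only
once the front is distinguishable (≈ 60 s post-bleach). The cross-strain
relationship between treadmilling speed and recovery half-time is
summarised by `speed_t12_correlation()` — Pearson r with the two-sided
t-test on `r` (df = n − 2), applied to strain means.

## Synthetic data

Every estimator has a matched generator (`gen_partition_events()`,
`gen_tracks()`, `gen_frap_traces()`, `gen_photoconversion()`,
`gen_fronts()`), seeded and bit-reproducible, emitting the exact tidy
schema the estimator consumes. Generator defaults sit at the measured
scales of the biology (λ ≈ 0.061, chain speed ≈ 18.4 nm/min with arrest
near 1.1 µm, t½ ≈ 68 s, treadmilling ≈ 313 nm/min, 30-s kymograph frames)
so that recovery tests run at realistic signal-to-noise. Two generator
choices are assumptions, not measurements: localization noise defaults to
σ = 20 nm (a typical centroid precision), and partition draws above
`x = 1` are resampled, which preserves the exponential shape (the
truncated mass is ~10⁻⁴ for λ ≈ 0.06).

What the generators deliberately do *not* emulate: image-level artefacts
(drift, focus loss, segmentation error), heterogeneity between cells in
the kinetic parameters, correlated localization noise, and chain length
changes from de-novo magnetosome synthesis. Passing recovery tests
therefore demonstrate estimator correctness under the stated statistical
structure, not robustness to every failure mode of real imaging data.

## Numerical choices and problem sizes

Tolerances and sizes used by the test suite are chosen to keep the full
run in a few minutes on one CPU while leaving comfortable statistical
margins: 50 replicate simulations per arm for the repositioning and
fragmentation phenotypes (binomial SE ≈ 4 % at the 90 % threshold), 500
single-particle replicas for the free-diffusion MSD check, 1000 + 200
replicates for KS size and power, 87/30/36-unit ensembles (matching
published sample sizes) for parameter-recovery checks at 5–10 %
tolerances, and `≤ 10⁻⁶` relative error for all noiseless round-trips.
The two-particle coalescence check is validated against an independent
adaptive ODE integration (deSolve) of the same force law to 1 %.

## Known limitations

The simulator is strictly one-dimensional: no torque or rotation, no 3-D
magnetostatics, no explicit MamK polymer — treadmilling enters only as the
constant active force. Growth of crystals during simulation is out of
scope (particles are born at full size and magnetization). The FRAP model
is a single exponential; reaction–diffusion FRAP models are deliberately
not implemented. Front-line extraction from kymograph images is upstream
of this package: fronts enter as tables.
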