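# magnetochain

Quantitative analysis of magnetosome chain positioning, splitting and
segregation in magnetotactic bacteria.

Magnetotactic bacteria like *Magnetospirillum gryphiswaldense* align with
the geomagnetic field using a linear chain of magnetite organelles
(magnetosomes). At cell division the chain must be placed at midcell,
cleaved with near-single-organelle precision, and each daughter chain moved
from the new cell pole back to the centre of its daughter cell — work done
by treadmilling filaments of the bacterial actin MamK coupled to the chain
through the adaptor MamJ. This package provides the quantitative machinery
for studying that process, for microscopists and modellers working from
extracted tracks, traces and measurements (not raw images):

* **Chain simulator** — 1-D overdamped Langevin dynamics of `n`
  magnetosomes: midcell-directed active transport with a linear
  force–velocity relation (stall force `F_s`, zero-force velocity
  `v0 = F_s/γ`), diffusion, collinear point-dipole attraction
  `F = 3μ₀m₁m₂/(2πr⁴)` with a 50-nm interaction cutoff, hard-sphere
  exclusion and reflecting boundaries (`sim_config()`, `simulate_chain()`,
  `repositioning_metrics()`; stepping kernel in C++).
* **Partition statistics** — folded daughter fractions
  `x = max(a,b)/(a+b)`, fit of the exponential-suppression cumulative model
  `F(x) = 1 − exp(−(x − 0.5)/λ)` (model median `0.5 + λ ln 2`),
  Kolmogorov–Smirnov test against the uniform random-splitting null,
  bucket and 400/800-nm position scoring (`fit_partition_cdf()`,
  `ks_test_uniform()`, `partition_report()`).
* **Track statistics** — cumulative displacement, origin-referenced MSD,
  apparent diffusion `D* = MSD/(2·dim·t)`, windowed velocity and mean speed
  (`track_msd()`, `apparent_diffusion()`, `mean_speed()`).
* **Photokinetics** — whole-cell-corrected double normalization of
  FRAP/photoconversion traces, single-exponential fits
  `F(t) = A(1 − e^{−kt}) + F(0)` with `t½ = ln2/k` and mobile fraction,
  kymograph front-line treadmilling speed, speed-vs-t½ correlation
  (`normalize_frap()`, `fit_recovery()`, `treadmilling_speed()`).
* **Synthetic data** — seeded generators matched to every estimator, so
  the full pipeline runs and is tested without any imaging data
  (`gen_partition_events()`, `gen_tracks()`, `gen_frap_traces()`,
  `gen_photoconversion()`, `gen_fronts()`).

All user-facing functions take tidy data frames and return tibbles; fitted
objects have `tidy()`/`glance()` and `autoplot()` methods.

## Worked example

Partition accuracy on a synthetic cohort of 500 dividing cells generated
at accuracy λ = 0.061, then analysed blind:

```r
library(magnetochain)

ev <- gen_partition_events(500, lambda = 0.061, seed = 42)
partition_report(ev)
#> <partition_fit> n = 500
#>   lambda = 0.0585 (SE 0.0001; MLE 0.0592)
#>   median = 0.5406 (4.1% deviation from equal split)
#>   fit R = 0.9995, R^2 = 0.9985
#>   KS vs random splitting: D = 0.6190, p = 0
#>   buckets: equal=400, intermediate=81, unequal=19
```

The fitted accuracy (λ̂ = 0.0585) recovers the generating value; the
median 0.541 says the typical split deviates ~4 % from perfect halving;
and the KS test rejects random splitting outright (D = 0.62). A chain
simulated at default parameters relocates from the pole to midcell:

```r
m <- repositioning_metrics(simulate_chain(sim_config(seed = 7)))
#> final_chain_count 1, final_offset_nm 37.5, half_repositioning_time 650 s
```

i.e. the fifteen magnetosomes end as a single chain 37 nm from midcell,
having halved the initial offset after 650 s. FRAP kinetics round-trip the
same way:

```r
trc <- gen_frap_traces(k = log(2)/68.3, A = 0.8, F0 = 0.2, noise_sd = 0.03, seed = 9)
nr  <- normalize_frap(trc)
glance(fit_recovery(nr$t_post_s[nr$post], nr$norm[nr$post]))
#>   t_half t_half_se mobile_fraction no_recovery converged     n
#>     66.2      2.94            1.01 FALSE       TRUE         61
```

recovering the generating half-time (68.3 s) within its standard error,
with full mobility.

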