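# sptkin

Kinetic modelling of live-cell single-particle tracking (sptPALM) data,
and Luria–Delbrück fluctuation analysis of mutation rates.

`sptkin` is for quantifying how strongly a nuclear protein complex —
an SMC complex such as Smc5/6 or cohesin, a repair factor, a
transcription regulator — associates with chromatin in living cells.
Individual photoconverted fluorophore-tagged molecules are localised
frame by frame; the distribution of their frame-to-frame jump lengths
is a mixture of diffusive states, and the occupancy of the slowest
state is the chromatin-bound fraction, **F_bound**.  The companion
module estimates marker-loss (mutation) rates from parallel-culture
fluctuation assays with plating-efficiency correction.

## The model

Jump lengths of a single Brownian state with diffusion coefficient *D*
at lag Δt, observed with localisation error σ per axis, are Rayleigh:

    P(r ≤ R) = 1 − exp( −R² / (4(DΔt + σ²)) )

The observed displacement distribution is a 2- or 3-state mixture
whose state weights are corrected for **defocalisation** — fast
molecules leave the axial detection slab of depth dZ, with in-slab
survival given by the absorbing-slab eigenseries

    Z(D, t) = Σ_{odd j} 8/(j²π²) · exp(−j²π² D t / dZ²)

— and additionally averaged over the jump-collection protocol (only
the first 4 jumps of each trajectory enter the histograms).  The model
CDF is least-squares fitted to the empirical CDFs jointly across lags;
2- vs 3-state is decided by AIC = n·ln(RSS/n) + 2k.  F_bound is the
fraction of the lowest-D state.

Mutation rates use the Luria–Delbrück distribution (Ma–Sandri–Sarkar
recursion; compound Poisson over clone sizes 1/(j(j+1))), with
binomial thinning of clones for partial plating, maximum-likelihood
estimation of the expected mutations per culture *m*, a
profile-likelihood 95% CI, and rate = m / (final cells per culture).

## Worked example

Simulate an acquisition resembling a kleisin-subunit experiment
(40% bound / 20% slow / 40% free, D = 0.01 / 0.15 / 1.0 μm²/s,
σ = 35 nm, 20 ms frames, dZ = 0.9 μm, 2000 molecules over 50 nuclei),
then run the full analysis chain:

```r
library(sptkin)

cfg    <- make_fixture("nse4-like", n_molecules = 2000L, seed = 42L)
sim    <- simulate_spt(cfg)
kept   <- filter_localizations(sim$localizations)   # ≥20 photons, ≤40 nm
tracks <- link_trajectories(kept)                   # 0.8 µm gate
ds     <- compute_jump_dataset(tracks)              # lags 1–4 × 20 ms
f2     <- fit_model(ds, 2, seed = 42L)
f3     <- fit_model(ds, 3, seed = 42L)
sel    <- select_by_aic(f2, f3)
print(sel)
```

```
<spt_fit> 3-state, RSS = 0.0043283, AIC = -15081.33, F_bound = 0.420
<diffusion_model> 3 state(s), sigma = 0.0363 um, dZ = 0.9 um
  state 1: F = 0.420, D = 0.008748 um^2/s (no defocalisation)
  state 2: F = 0.236, D = 0.1735 um^2/s
  state 3: F = 0.344, D = 0.9165 um^2/s
```

AIC picks the 3-state model (ΔAIC ≈ −2195 against 2-state) and
recovers the simulated truth: F_bound 0.42 vs 0.40, state diffusion
coefficients 0.009/0.17/0.92 vs 0.01/0.15/1.0 μm²/s, σ 36 vs 35 nm.
The bound fraction is read with `f_bound(sel)`; `run_spt()` wraps the
same chain behind a config object and writes a JSON report, per-lag
CDF curves and a log.

Fluctuation analysis of mutant-colony counts from ten parallel
cultures per condition (~10⁷ cells plated per culture):

```r
on  <- estimate_rate(fluctuation_experiment(
         c(31, 2, 8, 61, 4, 11, 3, 19, 7, 5), n_final = 1e7,
         condition = "induced"))
off <- estimate_rate(fluctuation_experiment(
         c(0, 1, 0, 0, 2, 0, 1, 0, 0, 0), n_final = 1e7,
         condition = "uninduced"))
print(on); print(off)
fc <- fold_change(on, off)
```

```
<rate_estimate> [induced] m = 3.577 (95% CI 2.098-5.449); rate = 3.58e-07 per cell per generation
<rate_estimate> [uninduced] m = 0.3193 (95% CI 0.07982-0.8213); rate = 3.19e-08 per cell per generation
fold change: 11.2 (95% CI 3.2-39.5)
```

## Command line

`inst/cli/sptkin.R` exposes subcommands `simulate`, `spt`,
`fluctuation` and `fixtures`, with flags mirroring every analysis
parameter (defaults: `--min-photons 20 --max-precision 40
--max-jump 0.8 --frame-interval 0.02 --timepoints 5 --jumps 4
--bin-width 0.01 --max-jump-hist 3 --dZ 0.9 --d-slow-min 0.08`):

```sh
Rscript inst/cli/sptkin.R simulate --preset nse4-like --out sim --seed 7
Rscript inst/cli/sptkin.R spt --input sim/localizations.csv --out run --seed 7
```

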