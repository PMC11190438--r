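# ultradian

Delayed stochastic models and single-cell analysis of ultradian gene
expression oscillations.

## What this is for

Hes/Her family transcriptional repressors (zebrafish Her6, mammalian HES1)
oscillate with 1-3 h periods in neural progenitors, driven by delayed
negative autoregulation and coupled between cells by Notch-Delta lateral
inhibition. A counterintuitive experimental observation motivates this
package: destabilising the protein by only ~10 percent makes the
*population* more heterogeneous - high- and low-expressing cells become
interspersed in a salt-and-pepper pattern - and this emerges from cell
coupling rather than from single-cell dynamics alone.

The package is for quantitative biologists who want to

1. **simulate** Her6-like mRNA/protein dynamics in single cells and in
   hexagonal lattices coupled by lateral inhibition (stochastic delay
   differential equations, chemical Langevin noise, Euler-Maruyama);
2. **search** parameter space (generalised pattern search) for regimes in
   which increasing the protein degradation rate increases population
   heterogeneity, and contrast coupled against uncoupled models;
3. **analyse** single-cell fluorescence tracks: coefficients of variation,
   relative trend, control normalisation, detrending, Hilbert
   peak-to-trough fold-change, periodogram coherence, wavelet period with
   a permutation null, and Gaussian-process classification of oscillatory
   versus aperiodic tracks (OU vs OUosc, log-likelihood ratio, FDR
   control);
4. **quantify** spatial heterogeneity in 3D snapshots: nearest-neighbour
   intensity correlations and ratios, Venus-positive fractions, persistent
   close pairs;
5. **generate** synthetic tracks, snapshots and decay chases with known
   ground truth, so every estimator can be validated end to end.

## The model

Each cell (i, j) on a hexagonal grid carries mRNA m and protein p:

    dm/dt = alpha_m * H_auto(p(t - tau_auto)) * H_LI(<p>(t - tau_LI)) - mu_m * m + eta_m
    dp/dt = alpha_p * m - mu_p * p + eta_p

with repressive Hill functions `H(x) = 1 / (1 + (x/P0)^n)`, `<p>` the mean
protein of the adjacent neighbours (lateral inhibition; absent in the
uncoupled Model 1), and chemical Langevin noise terms whose variance is
(production + degradation) x dt. Protein destabilisation is a multiplier
on `mu_p` (1.1x for the destabilised protein). The heterogeneity search
minimises

    E(theta) = CV(mu_p x 1.0) - CV(mu_p x 1.1)

over a documented parameter box, accepting sets with `E < -0.25` and mean
protein above 2000; the headline result is that only the *coupled* model
yields accepted sets.

## A worked example

```r
library(ultradian)

# synthetic population: 40 cells, 30% oscillators at 1.9 h, 6-min sampling
gen <- generate_tracks(track_spec(n_cells = 40, seed = 1))

# classify oscillatory vs aperiodic at 3% FDR
calls <- classify_tracks(gen$tracks, gen$background,
                         target_fdr = 0.03, n_synth = 500, seed = 1)
calls
#> <oscillation_calls: 40 tracks, 30.0% oscillatory (LLR threshold 10.140)>

median(calls$calls$period_h[calls$calls$is_oscillatory], na.rm = TRUE)
#> [1] 1.834006
```

30 percent of tracks are called oscillatory (12 true oscillators were
generated, so the call rate combines high power among true oscillators
with the 3 percent false-discovery calibration), and the median
recovered period, 1.83 h, is close to the generated 1.9 h period.

A minimal simulation of the coupled lattice:

```r
p <- model_params(coupled = TRUE, rows = 10, cols = 6, t_end = 100, seed = 1)
sim <- simulate_her6(p)
x <- sim$p[, sim$times >= 50]            # discard burn-in
population_cv(as.vector(x))              # tissue heterogeneity
timeseries_cv(as_track_table(sim, every = 6, from_time = 50))
```

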