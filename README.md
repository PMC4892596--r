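# chemorace

Run-and-tumble chemotaxis in *Escherichia coli*: linear-response theory,
agent-based simulation of bacterial "speed races" in microfluidic channel
gradients, a drift–diffusion continuum model, and the trajectory and
front-progression statistics used to analyse such experiments — plus a
synthetic-data generator so the whole pipeline runs and is tested without
any external data.

The package is for quantitative microbiologists and biophysicists who want
to ask how *adaptation precision* shapes gradient climbing. *E. coli*
lengthens its runs after an attractant upshift and then adapts back; the
linear impulse response is the bilobed kernel

    K(t) = K0 * lambda * exp(-lambda*t) * [lambda*t - (1-A)/2 * (lambda*t)^2]

whose time integral K0·A measures the loss of precise adaptation (A = 0:
precise, as for aspartate; A ≈ 0.03: imprecise, as for serine). In a
shallow gradient the chemotactic drift is v = chi · dc/dx with

    chi = (K0 u^2 alpha / (3 sigma^2)) * lambda^2 (sigma + A lambda) / (sigma + lambda)^3,

alpha = (1 - <cos phi>)/tau_r, sigma = 2 D_rot + alpha. Maximizing over the
memory rate lambda gives lambda* = 2 sigma/(1 - 3A), and the maximized
coefficient at A = 0.03 exceeds the precisely adapted optimum by about 6–7% —
imprecise adaptation can be an advantage, not a defect. The simulator,
continuum model and race statistics let you take this from formulas to
channel-scale front dynamics (progression functions, rank-k fronts, slope
fits, saturation) under the four experimental conditions: aspartate,
serine, aspartate with a 30 uM serine background (which breaks adaptation
to aspartate), and a no-gradient control.

## Worked example

```r
library(chemorace)

# Theory: how much does breaking adaptation help at the optimal memory rate?
100 * (adaptation_velocity_gain(0.03) - 1)
#> [1] 6.28122

# chi for wild-type-like parameters and a precisely adapted kernel
mp <- motility_params(u = 15, tau_r = 1.15, D_rot = 0.1, mean_cos_phi = 0.3)
chemotactic_coefficient_closed(mp, response_kernel(K0 = 1, lam = 1, A = 0))
#> [1] 9.540692        # um^2/(s uM): drift = 9.54 * gradient

# Simulator vs theory in a shallow gradient
v <- validate_against_theory(mp, response_kernel(1, 1, 0), gradient = 0.01,
                             c0 = 5, n_agents = 1500, T = 150, seed = 11)
c(v$v_mc, v$v_theory, v$z)
#> [1] 0.10194581 0.09540692 0.22944600   # um/s, um/s, discrepancy in SEs

# A synthetic tracking assay at 3 mM serine: run times lengthen 2.1-fold
pre <- condition_preset("serine")
cfg <- generator_config(seed = 11, n_tracks = 300, duration = 120)
base <- generate_homogeneous_assay(pre, 0, cfg)
high <- generate_homogeneous_assay(pre, 3000, cfg)
fl <- 0.2  # detection resolution floor (2 frames at 10 Hz)
m0 <- mean_run_time(segment_runs(base), resolution_floor = fl)$mean
normalized_run_time(segment_runs(high), baseline_s = m0, resolution_floor = fl)
#> [1] 1.977   # measured fold change, cf. the 2.1 +- 0.2 anchor

# A race: rank-10 front in the aspartate channel
race <- simulate_race(sim_config(dt = 0.02, T = 2100, seed = 5),
                      channel_geometry(), pre$env, pre$sensing, pre$modulation)
fit_front_slope(front_trajectory(race, k = 10), window = c(0, 1800))$slope
```

The first number is the percent gain in chemotactic velocity from the
serine-like adaptation defect; the chi value converts a 0.25 uM/um gradient
into a ~2.4 um/s local drift at full response amplitude; the validation
shows Monte-Carlo drift and closed form agreeing within one standard error;
the assay example reproduces the ~2.1-fold run-time increase measured at
3 mM serine from raw synthetic trajectories.

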