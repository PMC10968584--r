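# problgmd

Bio-inspired visual collision detection with stochastic synapses.

The lobula giant movement detector (LGMD) is a looming-sensitive neuron in
the locust visual brain. Its four-layered computational abstraction —
photoreceptor (P), excitatory (E), inhibitory (I) and summation (S) layers
feeding one output cell — is a standard low-power collision detector for
robots, vehicles and UAVs, but the deterministic network is notoriously
fragile under sensor noise. `problgmd` implements a probabilistic variant
in which every inter-layer synaptic connection is gated by an independent
Bernoulli random variable with a shared transmission probability `prob`,
mirroring the stochasticity of biological synaptic transmission. Random
gate closures break the chance local coincidences that let spatially
incoherent noise through, while the spatially coherent looming edge
survives — so at an intermediate `prob` the network separates the collision
moment from background activity far better than its deterministic limit
(`prob = 1`, recovered exactly).

The per-frame pipeline, for a gray-scale sequence `L(x, y, t)` with gates
`X ~ Bernoulli(prob)` resampled independently per pixel and frame:

    P_t = Σ_i p_i P_{t-i} + L_t − L_{t−1},   p_i = (1 + e^{u i})^{-1}
    E_t = P_t · X_PE
    I_t(x,y) = Σ_{i,j} P_{t−1}(x+i, y+j) ω_I(i,j) X_PI(x,y,i,j)
    S_t = E_t X_ES − W_I I_t X_IS
    Ce_t = 3×3 mean of S_t;   ω = max|Ce_t| / C_ω + 0.01
    S̃_t = S_t Ce_t / ω, zeroed below the threshold T_s
    K_t = Σ_{x,y} S̃_t X_SL;   κ_t = (1 + e^{−K_t / n_cell})^{-1}

The output is the membrane-potential trace `κ_t ∈ [0.5, 1)`; there is no
spiking mechanism. Performance is summarised by the **distinct ratio**
`DR = κ_max − (Σ_i κ(i) − κ_max) / (T − 1)`: peak response minus the mean
background response. The package also provides a synthetic
looming-stimulus generator (an expanding disc under a perspective growth
law), salt-and-pepper and Gaussian noise on inputs or intermediate layers,
median/Gaussian pre-filter engineering baselines, replicate-trial
ensembles, probability sweeps, and reproducible run manifests.

## Worked example

A 100×100, 60-frame synthetic approach (dark disc, collision at frame 55),
clean and with 1% impulse noise:

```r
library(problgmd)
clean <- looming_sequence()      # 100x100 px, 60 frames, collision at frame 55
deterministic_lgmd(clean)
#> Deterministic LGMD response trace
#>   input: 100 x 100 pixels, 60 frames
#>   peak output kappa = 1.0000 at frame 52; distinct ratio = 0.3295

noisy <- add_salt_pepper(clean, pnr = 0.01, seed = 42)
deterministic_lgmd(noisy)
#> Deterministic LGMD response trace
#>   input: 100 x 100 pixels, 60 frames
#>   peak output kappa = 1.0000 at frame 52; distinct ratio = 0.0281

prob_sweep(noisy, probs = seq(0.1, 1, 0.1), n = 20, seed = 11)
#> Distinct ratio vs transmission probability
#>  prob dr_mean    dr_sd  n
#>   0.1 0.03755 0.010342 20
#>   0.2 0.15579 0.028599 20
#>   0.3 0.34568 0.023781 20
#>   0.4 0.37455 0.005919 20
#>   0.5 0.31008 0.005540 20
#>   0.6 0.23599 0.004570 20
#>   0.7 0.16775 0.005773 20
#>   0.8 0.10385 0.003987 20
#>   0.9 0.05574 0.001761 20
#>   1.0 0.02810 0.000000 20
#>   best prob on grid: 0.4 (DR = 0.3746)
```

Reading the numbers: on the clean sequence the deterministic model peaks
within 3 frames of the true collision and separates peak from background by
DR ≈ 0.33. One percent impulse noise destroys that separation for the
deterministic model (DR ≈ 0.03: the network responds to noise on every
frame), while the gated network recovers it, with a unimodal DR-versus-prob
curve peaking at an interior probability (DR ≈ 0.37 at `prob = 0.4`,
mean ± sd over 20 replicate trials). `comparative_method()` shows the
engineering alternative — median pre-filtering before the deterministic
model — recovering less separation (DR ≈ 0.32) than the best gated setting
on the same input.

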