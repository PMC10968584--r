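---
title: "Probabilistic synaptic gating in an LGMD collision detector: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic synaptic gating in an LGMD collision detector: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(problgmd)
```

## The model

The lobula giant movement detector (LGMD) is a wide-field visual neuron in
the locust that responds selectively to looming — the rapid retinal
expansion of an object on a collision course. Its standard computational
abstraction is a four-layered retinotopic network. `problgmd` implements a
probabilistic variant of that network in which every inter-layer synaptic
connection is gated by an independent Bernoulli random variable with one
shared transmission probability `prob`, modelling the intrinsically
stochastic nature of synaptic transmission. The deterministic classic model
is recovered exactly at `prob = 1`.

Per frame $t$ of a gray-scale sequence $L(x, y, t)$, with all gate variables
$X \sim \mathrm{Bernoulli}(prob)$ drawn independently per pixel and frame:

* **Photoreceptor (P) layer** — luminance change with a short persistence
  memory:
  $P_t = \sum_{i=1}^{n_p} p_i P_{t-i} + L_t - L_{t-1}$, with
  $p_i = (1 + e^{u i})^{-1}$. The first frame has no predecessor; its P
  field is defined as zero.
* **Excitatory (E) layer** — a gated copy: $E_t = P_t \cdot X_{P,E}$.
* **Inhibitory (I) layer** — the previous frame's P field spread onto the
  eight neighbours through the fixed kernel $\omega_I$ (0.25 to edge
  neighbours, 0.125 to diagonals, 0 centre), each kernel tap gated
  independently: $I_t(x,y) = \sum_{i,j} P_{t-1}(x+i, y+j)\,
  \omega_I(i,j)\, X_{P,I}(x,y,i,j)$. Out-of-frame neighbours contribute
  zero.
* **Summation (S) layer** — gated competition,
  $S_t = E_t X_{E,S} - W_I\, I_t X_{I,S}$ (may be negative).
* **Passing coefficient and threshold** — $Ce_t$ is the 3×3 neighbourhood
  mean of $S_t$ (uniform mask $1/9$, zero padding); the per-frame scale is
  $\omega = \max|Ce_t| / C_\omega + 0.01$; the modulated signal
  $\tilde S_t = S_t\, Ce_t / \omega$ is zeroed wherever it falls below the
  threshold $T_s$ (the comparison is inclusive). This step suppresses
  isolated excitations: a lone noise impulse has a small neighbourhood mean
  and dies at the threshold, while the spatially coherent looming edge
  survives.
* **Output cell** — gated integration
  $K_t = \sum_{x,y} \tilde S_t\, X_{S,LGMD}$ and sigmoid readout
  $\kappa_t = (1 + e^{-K_t / n_{cell}})^{-1}$ with $n_{cell}$ the pixel
  count. Since $\tilde S \ge 0$, $\kappa_t \in [0.5, 1)$; 0.5 is the
  quiescent level. There is no spiking mechanism: $\kappa_t$ itself is the
  model output.

Why gating helps on noisy input: sensor noise (impulse or additive) is
spatially incoherent, so the excitation it contributes relies on chance
local coincidences to pass the neighbourhood-mean threshold. Random gate
closures break those coincidences multiplicatively (a pixel's signal must
survive three independent gates on its way to the output), while the
looming edge — a thick coherent annulus — loses only a fraction of its mass.
Lowering `prob` therefore trades a mild attenuation of the collision peak
for a strong suppression of background response; the peak-to-background
separation is maximised at an interior transmission probability.

## Parameters

| name | meaning | default | notes |
|------|---------|---------|-------|
| `np` | persistence depth (frames) | 1 | 0–2 allowed |
| `u`  | persistence decay shape | 1.0 | $p_1 \approx 0.269$ at the default |
| `WI` | inhibition weight | 0.3 | strength of E–I competition |
| `Ts` | S-layer threshold | 30 | on the 0–255 luminance scale |
| `Cw` | scale constant | 4 | normalises the passing coefficient |
| `prob` | transmission probability | 0.5 | the single stochastic parameter |

Defaults other than `u` and `np` follow the standard parameterisation of
this network family. `u` is genuinely open in that family; we default to
`u = 1`, which gives a mild one-frame memory ($p_1 \approx 0.27$), and make
it configurable. Luminance is processed on the 0–255 scale — `Ts = 30` is
only meaningful there — while the Gaussian input-noise variance `gnv` is
specified on the normalised [0, 1] scale, the convention of image-processing
toolboxes, and rescaled internally.

## Design choices at points the model family leaves open

* **Gate resampling.** Gate fields carry no time index in the model's
  defining equations; we resample every gate family independently at every
  frame (and the P→I gates per kernel tap per pixel). Per-frame resampling
  models per-event synaptic stochasticity and produces the trial-to-trial
  output variance that replicate ensembles report; a static random wiring
  would make replicates differ only through their single frozen draw.
* **Scale positivity.** $\omega$ uses $\max|Ce|$ rather than the signed
  maximum, so it is strictly positive even on frames whose passing
  coefficient is everywhere negative and the modulation never flips sign.
* **Thresholding of negative values.** $S$ and $\tilde S$ may be negative
  before thresholding; the positive threshold then zeroes them. We follow
  that literal reading rather than taking magnitudes.
* **Borders.** Both 3×3 convolutions use zero padding: cells outside the
  field of view contribute no signal.
* **First frame.** $P \equiv 0$ at $t = 1$ (so $\kappa_1 = 0.5$ and no gate
  randomness is consumed there); the inhibition at $t = 2$ uses that zero
  history.
* **RNG contract.** One seed per run; gate families are consumed in a fixed
  documented order per frame, and replicate ensembles derive one substream
  seed per trial from a master seed. Identical (input, parameters, seed)
  gives bitwise-identical traces; `simulate()` and `run_trials()` expose
  this.

## The synthetic looming generator

The recordings this model family is normally evaluated on (approaching
dark/light balls indoors, vehicle and UAV scenes) are not distributable, so
the package generates synthetic analogues: a centred disc of one luminance
level on a uniform (optionally textured) background, expanding until it
fills the frame at the collision frame `tc`. The default growth law is
perspective: the retinal radius of an object approaching at constant speed
is $r(t) = a / (t^* - t)$. The two constants are solved so the disc starts
at the requested initial radius and reaches full coverage exactly at `tc`
(the collision epoch $t^*$ falls just after `tc`). A linear law is
available for comparison. Default scene: 100×100 pixels, 60 frames,
collision at frame 55, dark disc (level 30) on a light background (level
200) — a high-contrast indoor-like scene.

Input corruption follows the two standard noise models: salt-and-pepper
noise replaces a fraction `pnr` of pixels per frame (independently per
frame) with 0 or full scale, equiprobably; Gaussian noise adds zero-mean
draws of variance `gnv` (normalised scale) and clips to range. Noise can
also be injected at an intermediate layer (P, E, I or S) to emulate noise
arising inside neural transmission. Intermediate fields are signed with no
fixed range, so impulse amplitudes are taken relative to the field's
maximum magnitude (replaced entries become 0 half the time, otherwise
$\pm\max|field|$ with random sign), Gaussian draws get standard deviation
$\sqrt{variance} \cdot \max|field|$, and no clipping is applied. Noise
injected at P becomes the canonical P field: it feeds the persistence
history, the E layer and the delayed inhibition alike. Layer-noise draws
are pre-generated from the run's seed before any gate sampling, so a
deterministic and a gated run sharing one seed receive identical injected
noise — the comparison the layer-noise experiments need.

What the generator does *not* emulate: camera ego-motion, optic flow of a
real background, motion blur, exposure changes, low figure–ground contrast.
Results on synthetic stimuli demonstrate the mechanism — they do not
certify performance on real footage, where the model family is known to be
weaker at low contrast.

## Evaluation

The distinct ratio of an output trace,
$DR = \kappa_{max} - \frac{\sum_i \kappa(i) - \kappa_{max}}{T - 1}$,
measures how sharply the collision moment stands out from background
activity. Ties at the maximum are resolved to the first occurrence and one
copy of the maximum is excluded from the background mean, reading the
defining formula literally. Replicate ensembles (default 20 trials) report
per-frame mean and sample variance and the DR mean ± sample standard
deviation; `prob_sweep()` tabulates DR over a probability grid (default
$\{0.1, \dots, 1.0\}$).

```{r sweep-demo, eval = FALSE}
clean <- looming_sequence()                       # 100x100, collision at 55
noisy <- add_salt_pepper(clean, pnr = 0.01, seed = 42)
sw <- prob_sweep(noisy, probs = seq(0.1, 1, 0.1), n = 20, seed = 11)
plot(sw)
```

On this noisy input the DR-versus-prob curve is unimodal with an interior
maximum near 0.4–0.5, and the deterministic limit (`prob = 1`) collapses to
a DR two orders of magnitude below it; the median-prefiltered deterministic
baseline recovers much of the separation but stays below the best gated
setting. One behaviour worth flagging: on *clean* high-contrast input the
deterministic model is **not** the DR optimum either. The collision peak
saturates the sigmoid ($\kappa \to 1$) with or without gating, while gating
still attenuates the smaller pre-collision responses, so DR keeps improving
as `prob` decreases until signal loss sets in. Noise rejection is therefore
not the only mechanism behind the interior optimum; background attenuation
contributes even without noise.

## Numerical notes and limitations

* The sigmoid saturates in double precision once $K_t / n_{cell} \gtrsim
  37$; near collision, high-contrast stimuli produce exact ties at
  $\kappa = 1$, and the reported peak frame is the first tied frame. Peak
  timing on clean saturating stimuli is therefore accurate only to the
  width of the saturated plateau (about 3 frames under the default scene).
* The threshold comparison `>= Ts` is exact; tests pin the boundary case.
* Problem sizes used by the test-suite and the acceptance script — 100×100
  × 60-frame sequences, 20-trial ensembles, a 10-point probability grid —
  are the package's chosen desk-scale study conditions; they reproduce the
  qualitative phenomena (interior DR optimum, pre-filter comparison,
  layer-noise robustness) rather than any specific recorded-video figure.
* No spiking mechanism, no collision-alarm threshold, no ON/OFF-channel
  (LGMD2-style) pathway and no feed-forward inhibition are implemented;
  comparisons are between membrane-potential outputs only.
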