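---
title: "Cortical-inspired sound reconstruction: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical-inspired sound reconstruction: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundlift)
```

## The model

The human auditory system repairs degraded sounds remarkably well.
`soundlift` implements a neuro-geometric model of this ability, built on
an analogy with the primary visual cortex: where vision lifts an image
to a space of positions *and* orientations and diffuses along the lifted
geometry, audition is modelled as lifting a time–frequency
representation to a space of frequencies *and* chirpinesses and evolving
it with a neural-field equation.

The pipeline has three stages.

**Analysis.** A mono signal $s$ is mapped to its short-time Fourier
transform $S(\tau,\omega)$ using a periodic Hann window (64 ms by
default) and unitary-per-frame DFTs. Only non-negative frequency bins
are stored; the other half follows from the Hermitian symmetry of real
signals.

**Lift and evolution.** Each time–frequency point is assigned the
chirpiness $\nu^\ast = -\partial_\tau|S| \,/\, \partial_\omega|S|$ of
the level line of $|S|$ through it, and the complex coefficient
$S(\tau,\omega)$ is carried, in full, by the nearest bin of a bounded
chirpiness grid $[-\nu_{\max}, \nu_{\max}]$ — a discrete Dirac layer
over the lift surface $\Sigma = \{\nu\,\partial_\omega|S| +
\partial_\tau|S| = 0\}$. The lifted field $I(t,\omega,\nu)$ drives a
delayed Wilson–Cowan equation for the cortical activation
$a(t,\omega,\nu)$:

$$
\partial_t a = -\alpha\, a + \beta\, I
 + \gamma \int k_\delta(\omega,\nu \,\|\, \omega',\nu')\,
   \sigma\!\big(a(t-\delta,\omega',\nu')\big)\, d\omega'\, d\nu' ,
$$

with zero initial history, a decay rate $\alpha$, an input gain $\beta$,
an interaction gain $\gamma$ and a delay $\delta$. The sigmoid
$\sigma(\rho e^{i\theta}) = \min\{1, \kappa\rho\}\, e^{i\theta}$
saturates the modulus and never touches the phase.

The interaction kernel is the point of the model: neurons are coupled
along the natural dynamics of a chirp, $\dot\omega = \nu$, perturbed by
noise in the chirpiness, $d\nu = \sqrt{2b}\, dW$. The kernel
$k_\delta(\cdot\|\omega',\nu')$ is the closed-form transition density of
this degenerate (hypoelliptic) diffusion after one delay:

$$
k_\delta(\omega,\nu\|\omega',\nu') = \frac{\sqrt3}{2\pi b\delta^2}
 \exp\!\Big(-\frac{g_\delta(\omega,\nu\|\omega',\nu')}{b\delta^3}\Big),
\qquad
g_\delta = 3\Delta\omega^2 - 3\delta\,\Delta\omega(\nu+\nu')
 + \delta^2(\nu^2+\nu\nu'+\nu'^2),
$$

a Gaussian with mean $(\omega'+\nu'\delta,\ \nu')$ and covariance
$\mathrm{var}\,\nu = 2b\delta$, $\mathrm{var}\,\omega = 2b\delta^3/3$,
$\mathrm{cov} = b\delta^2$. It *transports* activation along the lifted
slope (a chirp continues itself) and *diffuses* it across nearby slopes.
It is not a convolution kernel, so it is tabulated row by row; the set
where $k_\delta \ge \varepsilon$ is an explicit parabolic region
(`support_bounds()`), which keeps the tables sparse. `simulate_sde()`
provides an independent Monte-Carlo check that the closed form really is
the transition density of the stated dynamics.

**Synthesis.** The activation is summed over chirpiness and passed
through the inverse STFT. Because the input lift is Hermitian, the
kernel satisfies $k_\delta(-\omega,-\nu\|\omega',\nu') =
k_\delta(\omega,\nu\|-\omega',-\nu')$ and the sigmoid is phase-only, the
evolution preserves Hermitian symmetry and the output signal is real up
to floating round-off; the residual imaginary part is measured and
reported before being discarded.

## Parameters that matter

| parameter | meaning | unit | default |
|---|---|---|---|
| `window_len`, `hop` | STFT geometry | s | 0.064, 0.016 |
| `alpha` | activation decay | 1/s | 55 |
| `beta` | input gain | – | 1 |
| `gamma` | interaction gain | 1/s | 55 |
| `kappa` | sigmoid slope | – | 1 |
| `delta` | interaction delay | s | 0.0625 |
| `b` | chirpiness diffusion (normalised axes) | – | 0.05 |
| `eps_rel` | kernel truncation / max | – | 1e-4 |
| `nu_max`, `nu_count` | chirpiness grid | Hz/s, – | auto, 33 |

With $\gamma = 0$ the equation is a causal exponential smoother with
time constant $1/\alpha \approx 18$ ms; $\gamma \approx \alpha$ with a
near-unit-mass kernel makes the delayed interaction roughly compensate
the decay, so a ridge sustains and propagates itself — this is what
bridges gaps. $\kappa$ sets where self-amplification saturates.

**Axis scaling.** The kernel is evaluated on normalised axes: both
$\omega$ and $\nu$ are divided by the Nyquist frequency. Dividing both
by the *same* scale is deliberate: it keeps normalised chirpiness
exactly the time derivative of normalised frequency, so the kernel
drift continues a ridge along its own slope. An independent
normalisation of the $\nu$ axis (say to $[-1,1]$) would be equally
legal dimensionally but would rotate the transport direction away from
the ridges. On these axes, diffusion strengths $b$ of order 0.01–0.2
move mass by a few bins per delay, which is the regime the experiments
use.

**Time stepping.** The forward-Euler step equals the STFT hop, so each
step consumes one spectrogram frame — the sound image reaches the model
sequentially, as it reaches the cortex. The delay is snapped to a whole
number of frames (0.0625 s becomes 4 × 16 ms = 0.064 s, with a
message). Stability of the explicit linear part requires
$\alpha\,dt < 1$ ($0.88$ at the defaults), and the $\gamma = 0$ limit
is verified to converge to the exact exponential filter at first order
in $dt$. The evolution makes a single causal pass over the signal; it
is not iterated to a steady state — the delayed interaction is
precisely what lets a single pass carry information forward in time.

## Numerical choices

* **Lift assignment.** The discrete lift condition
  $\nu\,\partial_\omega|S| = -\partial_\tau|S|$ almost never holds
  exactly on a float grid, so each point's full coefficient goes to the
  *nearest* chirpiness bin. Summing over $\nu$ then reproduces the
  input exactly on all kept points (asserted as an identity, not a
  tolerance).
* **Vertical contours.** Where $|\partial_\omega|S||$ falls below
  `tol_grad` ($10^{-3}$ of its own maximum — the two gradient
  components carry different units, so the test is made against the
  frequency component alone) the chirpiness diverges and the point is
  masked and dropped, not clamped: clamping would pile spurious mass at
  $\pm\nu_{\max}$ and bias the transport direction.
* **Automatic chirpiness bound.** By default $\nu_{\max}$ is the 99th
  percentile of $|\nu^\ast|$ over the strongest bins (top 1% of
  magnitudes), times a 1.25 headroom factor. This serves signals of
  unknown content. The canned experiments instead size the grid from
  the known chirp geometry (1.5 × the largest nominal slope): on a pair
  of crossing chirps, the interference fringes between the ridges have
  extreme level-line slopes that inflate any purely data-driven bound
  by an order of magnitude.
* **Half-spectrum evolution and the Nyquist row.** The evolution runs on
  non-negative frequencies only; kernel mass reaching below zero
  frequency is routed through the Hermitian mirror (the operator acts on
  the conjugated field there). A dedicated test shows the half-lattice
  evolution equals the full-lattice one to ~1e-15. The top (Nyquist) row
  is left inert: its coefficient is shared between the two spectral
  halves and must remain real, and evolving it as an interior row of the
  continuous half-space model measurably breaks the reality of the
  output.
* **Kernel truncation.** Tables store values above
  $\varepsilon = 10^{-4} \times \max k_\delta$; row masses stay within
  2% of unity wherever the lattice amply covers the support, and the
  truncated operator agrees with a dense quadrature to the predicted
  $\varepsilon \times$ area bound. $C_\varepsilon$ is computed as
  $-4b\delta\log(\varepsilon/\max k)$, which is exact (zero) at
  $\varepsilon = \max k$ where the naive form cancels catastrophically.
* **Degenerate inputs.** Empty or non-finite signals, aliasing chirp
  specs, non-invertible STFT geometries, over-threshold truncations and
  NaNs entering the evolution are all rejected with explicit errors;
  an all-zero input provably stays at the zero fixed point.

## What the synthetic signals do and do not show

The generators produce the four study conditions: a linear chirp
(500 Hz + 1000 Hz/s over 2 s at 8 kHz), the same chirp with a hard
0.125 s mid-signal gap (twice the delay), two crossing chirps
(500 Hz + 1000 Hz/s and 2500 Hz − 1000 Hz/s), and a sinusoidal-FM chirp
(1500 ± 800 Hz at 1 Hz). Amplitudes are exactly zero inside the gap, so
gap energies are unambiguous. These signals have isolated,
well-separated ridges and no noise floor; passing tests on them shows
the geometry of the method (transport along slopes, stratum decoupling,
gap bridging) but says nothing about dense spectra, reverberation or
speech, where level lines are far more tangled and the automatic
chirpiness bound is less reliable.

```{r experiment, eval = FALSE}
ex <- run_experiment("interrupted")
ex$metrics
#>  gap_fraction_in gap_fraction_out gap_energy_ratio
#>      0.004216429      0.004836949      1.147161
```

The reported metrics are deliberate formalisations of qualitative
claims: the gap-energy ratio compares energy *fractions* in the gap box
(full gap interval × ridge band ± 150 Hz) so the evolution's overall
gain cancels — the central half of the gap contains literally zero input
energy, which would make a raw ratio infinite; the cross-talk index
re-runs each branch on the identical lattice; ridge duration is measured
at −20 dB of peak; the FM spread is an energy-weighted RMS time width.
Each box and threshold is stated in `?run_experiment`.

## Known limitations

* The chirpiness grid is global and uniform; strongly multi-component
  sounds may need per-component bounds (chosen case by case, as the
  experiments do).
* The lift is single-valued: one chirpiness per time–frequency point,
  so two ridges crossing *within one bin* share a single slope there.
* The model amplifies: with $\gamma \approx \alpha$ the output scale is
  not calibrated to the input, and all shipped metrics are
  scale-invariant for exactly that reason.
* Reconstruction is offline and single-pass over a whole recording; a
  streaming variant would be possible (the state only needs a
  $[t-\delta, t]$ window) but is not implemented.
* Only mono audio; multichannel files are collapsed to channel 1.
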