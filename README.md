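# soundlift

Cortical-inspired reconstruction of degraded sounds.

Human listeners restore interrupted or noisy sounds with striking ease.
`soundlift` implements a mathematical model of that ability, inspired by
the functional architecture of the primary auditory cortex: a sound is
not repaired in the time–frequency plane itself, but in an *augmented*
three-dimensional space of time, frequency ω and chirpiness ν = dω/dτ —
the same kind of geometric lift that underlies cortical models of visual
inpainting, here carrying a Heisenberg group structure.

The package is aimed at researchers in computational neuroscience and
audio signal processing who want a complete, testable reference
implementation of the lift–evolve–project pipeline on synthetic chirps.

## The model

For a signal $s$ with STFT $S(\tau,\omega)$ (periodic Hann window,
overlap-add invertible):

1. **Lift.** Every time–frequency point is assigned the slope of the
   level line of $|S|$ through it,
   $\nu^\ast = -\partial_\tau|S|/\partial_\omega|S|$, and $S(\tau,\omega)$
   is placed on the nearest bin of a bounded chirpiness grid, giving a
   field $I(t,\omega,\nu)$ concentrated on the lift surface
   $\Sigma=\{\nu\,\partial_\omega|S|+\partial_\tau|S|=0\}$.
2. **Evolve.** The activation $a(t,\omega,\nu)$ obeys a Wilson–Cowan
   equation with delay δ,

   $$\partial_t a = -\alpha a + \beta I + \gamma\!\int\!
   k_\delta(\omega,\nu\|\omega',\nu')\,
   \sigma\big(a(t-\delta,\omega',\nu')\big)\,d\omega' d\nu',$$

   where $\sigma$ saturates the modulus and preserves the phase, and
   the interaction kernel is the closed-form transition density of the
   chirp diffusion $\dot\omega=\nu$, $d\nu=\sqrt{2b}\,dW$ after one
   delay:

   $$k_\delta = \frac{\sqrt3}{2\pi b\delta^2}
   \exp\!\Big(\!-\tfrac{3\Delta\omega^2-3\delta\Delta\omega(\nu+\nu')+
   \delta^2(\nu^2+\nu\nu'+\nu'^2)}{b\delta^3}\Big).$$

   The kernel transports activation along lifted slopes and diffuses it
   across neighbouring slopes; its ε-super-level sets have closed-form
   parabolic bounds, which keeps the interaction operator sparse.
3. **Project.** Sum over ν and invert the STFT. The evolution preserves
   Hermitian symmetry, so the output is a real waveform up to floating
   round-off (the residual is measured and reported).

## Worked example

Reconstruct a linear chirp whose middle 0.125 s — twice the interaction
delay — has been silenced:

```r
library(soundlift)

s <- make_chirp(chirp_spec("interrupted"))
s
#> <sound_signal> 16000 samples @ 8000 Hz (2 s), peak 1

res <- reconstruct(s)
#> delay 0.0625 s snapped to 4 frames = 0.064 s
res$S_in
#> <tf_image> 122 frames x 257 bins, t in [0.032, 1.97] s, f in [0, 4000] Hz
res$diagnostics$imag_ratio
#> [1] 1.17e-15
```

The reconstructed waveform is `res$signal`; `res$S_out` holds the
processed spectrogram. The imaginary residual near 1e-15 confirms the
symmetry-preservation property that guarantees a real output. The
canned experiment quantifies the gap bridging:

```r
ex <- run_experiment("interrupted")
signif(ex$metrics, 4)
#>  gap_fraction_in gap_fraction_out gap_energy_ratio
#>         0.004216         0.004836         1.147
```

After processing, the share of spectrogram energy inside the silent
gap's time–frequency box has grown by a factor 1.15: the delayed
transport along the lifted slope has carried the ridge across the
interruption. The other experiments — `"linear"` (diffusion tail),
`"crossing"` (decoupled evolution of crossing chirps, cross-talk index
≈ 1.06), `"sine_fm"` (slope-dependent diffusion of a non-linear chirp)
— run the same way and can write spectrogram PNGs and a metrics CSV
with `run_experiment(name, dir = "out")`.

A command-line front end is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "soundlift", package = "soundlift"))')
Rscript "$CLI" synth --kind linear --out chirp.wav
Rscript "$CLI" reconstruct chirp.wav --out restored.wav --gamma 55 --b 0.05
Rscript "$CLI" experiment interrupted --dir results/
Rscript "$CLI" kernel-check
```

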