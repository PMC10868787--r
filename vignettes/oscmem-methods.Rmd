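---
title: "Phase-coded working memory in oscillator-driven low-rank networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-coded working memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`oscmem` studies how a recurrent network can store a discrete memory in the
*phase* of an oscillation. The network is a continuous-time rate model of
`N` units,

$$\tau \dot{\mathbf x} = -\mathbf x + J\tanh(\mathbf x)
  + \mathbf I^{(osc)} u(t) + \mathbf I^{(s)} \mathbf s(t) + \xi(t),$$

driven by a theta-band reference oscillation $u(t)$ with instantaneous
phase $\theta(t)$ and by transient stimulus pulses $\mathbf s(t)$. The
task: after a pulse on stimulus channel $i$, the linear readout
$r(t) = \tfrac{c}{N}\mathbf w^\top \mathbf x$ must oscillate as
$\sin(\theta - \varphi_i)$ for the rest of the trial, i.e. the stimulus
identity is held as a persistent phase offset relative to the reference
($\varphi_a = 0.2\pi$, $\varphi_b = 1.2\pi$; a four-stimulus variant uses
$0.2\pi, 0.7\pi, 1.4\pi, 1.7\pi$).

The recurrent matrix is constrained to rank two,
$J = \tfrac1N(\mathbf m^{(1)}\mathbf n^{(1)\top} +
\mathbf m^{(2)}\mathbf n^{(2)\top})$, so that the autonomous dynamics live
in the plane spanned by $\mathbf m^{(1,2)}$ with coordinates
$\kappa_i = \mathbf m^{(i)\top}\mathbf x / \lVert\mathbf m^{(i)}\rVert^2$.
With a sinusoidal reference, $(\kappa_1, \kappa_2, \theta)$ is a complete
phase space — a solid torus — and every analysis in the package happens
there.

# Reference signals

Real theta oscillations drift in amplitude and frequency. The synthetic
generator (`synthetic_lfp()`) emulates this as a sinusoidal carrier whose
instantaneous frequency is an Ornstein–Uhlenbeck process centred on the
band midpoint (SD 0.3 Hz by default) and whose log-amplitude is a second,
independent OU process (SD 0.2), both with a 2 s correlation time — slow
against the ~125 ms carrier period — plus white measurement noise at 10% of
carrier RMS. Channels share the carrier phase (stored as the generator
truth for validation) but drift in amplitude independently. What this
emulator does *not* reproduce: 1/f background spectra, sharp-wave events,
theta harmonics/asymmetry, and cross-channel phase gradients. A green
end-to-end test therefore establishes that the pipeline recovers a drifting
narrowband phase, not that it handles every pathology of real recordings;
real multichannel arrays can be substituted through `raw_recording()`.

Preprocessing mirrors the treatment of the hippocampal recordings the task
was built around: resample to 500 Hz (polyphase rational resampling),
high-pass at 7 Hz with a 511-tap Hamming-window FIR filter (linear phase,
delay-compensated), and normalize channel-wise so each channel has the RMS
of a unit-amplitude sine, $1/\sqrt2$. (The source text prints "divide by
$2\sigma$", which would give RMS $0.5$ and contradict its own stated
outcome; the package divides by $\sqrt2\,\sigma$, which realizes the stated
outcome exactly.) Instantaneous phase comes from complex Morlet wavelets
(Gaussian envelope SD $c/2\pi f$ with $c = 7$ cycles) on a 7–9 Hz grid in
0.2 Hz steps; each 4 s chunk keeps the grid frequency with the highest mean
power, drops its first second (edge effects), and is rejected wholesale if
$|u| > 4$ anywhere. The phase convention is chosen so that $\sin\theta$
reconstructs the narrowband signal — the same convention the task targets
use.

# Training

Trials are integrated with the Euler–Maruyama update at $h = 2$ ms
($\tau = 20$ ms); analyses use $h = 0.5$ ms. The loss is the masked MSE
between readout and target from stimulus offset to trial end; an optional
regularizer penalizes nonzero time-averaged activations,
$\tfrac1N\sum_i(\overline{x_i})^2$, which steers rank-2 networks with a
linear readout toward the phase-coding solution. Training uses
backpropagation through the unrolled update (gradients verified against
central finite differences to $10^{-4}$ relative error) with Adam
(learning rate 0.01, decay rates 0.9/0.999, batch 128), updating the input
vectors, the connectivity vectors, and a scalar on the frozen readout
weights. Initial weights are jointly Gaussian: identity covariance except
$\mathrm{cov}(m^{(i)}, n^{(i)}) = 0.6$ and $\mathrm{var}(w) = 16$; the
"oscillatory" mode instead correlates the pairs so the 2×2 overlap matrix
has eigenvalues $1.2 \pm 1.0i$ (real part above one), which makes the
network oscillate from the start and reliably biases rank-2 networks to
the phase-coding solution.

**Reduced scale.** The desk-scale stated world is $N = 256$, 1024
synthetic-reference trials per epoch, 50 epochs (~400 optimizer steps
against the original setup's ~2200). This matters dynamically: at half the
training depth the anti-phase memory is still a slowly-contracting
transient rather than a limit cycle; by 50 epochs both memories are
attractors. The state noise SD used during the original training is not
printed anywhere; the package defaults to $\sigma_{noise} = 0$
(configurable), and no gradient clipping is applied.

# Reverse engineering

`canonicalize()` rewrites the factors by a balanced SVD so the
$\mathbf m$'s are orthogonal (J unchanged to $10^{-10}$) and splits each
input vector into in-plane parts $\alpha_i$ and an orthogonal remainder
$\mathbf I_\perp$. The filtered input has the closed form
$v(\theta) = A\sin(\theta - \arctan\omega\tau)/\sqrt{(\omega\tau)^2+1}$
(transient set to zero), making the driven dynamics an autonomous field on
the torus.

Limit cycles are fixed points of the Poincaré return map on
$\{\theta = 0\}$, found by forward iteration (attractors) plus damped
Newton polishing with the Jacobian from the variational equation
$\dot M = D_\kappa F\,M$, $M(0)=I$; the eigenvalues of $M(T)$ are the
Floquet multipliers (stable iff all $|\lambda| < 1$). Numerical choices:
fixed-step RK4 at $h = 0.5$ ms for maps and monodromy (Euler remains
available; the coarse amplitude–frequency scan uses Euler throughout since
its classification threshold of $10^{-2}$ is far above the integration
error), the step is shrunk to an integer count per period so the section
is exact, duplicate fixed points merge within $10^{-3}$, and winding
numbers come from the unwrapped $\mathrm{atan2}(\kappa_2,\kappa_1)$ along
the orbit. Tonic stimuli are folded into the field as constant inputs
(their filtered steady state), and bifurcation scans track each cycle by
continuation, interpolating the amplitude where $\max|\lambda|$ crosses 1;
a branch that disappears before crossing (saddle-node) reports its last
surviving amplitude.

The torus embedding for figures,
$(\cos\theta\,(\tilde r - \kappa_1), \sin\theta\,(\tilde r - \kappa_1),
\kappa_2)$, is injective when $\tilde r$ *exceeds* every $\kappa_1$; the
source text's printed bound has the inequality reversed (an apparent sign
typo), and the package warns when the geometrically meaningful bound is
violated.

# Phase reduction

On the attractor the state is well described by its in-plane phase
$\phi = \mathrm{atan2}(\kappa_2, \kappa_1)$ at an approximately constant
radius $r$ (the mean over both stable cycles). Substituting
$\kappa = r(\cos\phi, \sin\phi)$ into the reduced equations gives two
coupled phase oscillators $\dot\theta = \omega$,
$\dot\phi = \omega + g(\phi, \theta)$ with the coupling function evaluated
on a 64×64 periodic grid and bilinearly interpolated. A trajectory counts
as locked when $|\Delta(\phi - \theta)|$ per reference cycle stays below
$10^{-3}$ rad over five consecutive cycles.

The reduction's premise — a near-constant orbit radius — holds well for
trained networks (radius varies ~±15% along the cycle at desk scale) but
only loosely for the designed mixtures, whose strong $\cos2\phi$ coupling
makes the orbit markedly non-circular (radius 0.7–1.4). For those models
the phase model reproduces attractor counts, separations and collapse
faithfully but shifts the locked-phase *positions*; quantitative fidelity
claims are therefore made for trained networks only.

One caution discovered while validating the reduction: comparing the phase
model against the full network *per initial condition* is ill-posed near
basin boundaries — the two systems can converge to different attractors
from the same boundary-adjacent start, which says nothing about how well
the attractors match. `compare_phase_to_full()` therefore flags and
excludes basin-mismatched starts (reporting the agreement fraction) and
additionally reports the attractor-*set* discrepancy, which is the
quantity the fidelity criterion checks.

# Mean-field theory and designed models

When per-unit weights are drawn from a mixture of $L$ zero-mean Gaussians,
the infinite-$N$ dynamics close on $\kappa$ with effective couplings given
by the mixture covariances times a population gain
$\langle\tanh'(\Delta z)\rangle$. Substituting
$\mathrm{erf}(\tfrac{\sqrt\pi}{2}x)$ for $\tanh$ gives the closed form
$1/\sqrt{1 + \tfrac\pi2\Delta^2}$, accurate to better than 0.02 against
Monte-Carlo over $\Delta \in [0, 5]$.

The designed presets follow one blueprint: an **oscillator** population
(no input covariance; skew-symmetric $m$–$n$ overlaps produce rotation)
plus **coupling** populations that tie the internal phase to the
reference. Design decisions worth recording:

* *Detuning compensation.* Strong $\cos 2\phi$ coupling makes the rotation
  non-uniform; the mean angular velocity of $a + b\cos2\phi$-modulated
  rotation is $\sqrt{a^2 - b^2}$, not $a$. The oscillator overlap is
  therefore scaled (factor 1.25 in the two-stimulus preset, 1.17 in the
  four-stimulus one, tuned numerically) so the *effective* rotation matches
  the reference frequency — without this, the driven system never locks.
* *Locking mechanism.* The two coupling populations carry equal
  $\cos 2\phi$ overlaps and opposite input-phase overlaps
  ($\pm\beta$ between $\mathbf I^{(osc)}$ and the $\mathbf n$'s); without
  stimulus the $\sin\phi$ terms cancel and the gain modulation by
  $v(\theta)^2$ locks $\phi - \theta$ at two values $\pi$ apart. A tonic
  stimulus saturates one population (gain < 0.1 at amplitude 1), its
  partner's surviving $\sin\phi$ term breaks the symmetry, and one cycle
  annihilates — the saddle-node seen in the trained networks.
* *Four memories.* Four coupling populations in two gain-anisotropy
  classes (m1-heavy vs m2-heavy, i.e. saturating at internal phases a
  quarter period apart) with opposite-signed $\cos2\phi$ overlaps: the
  $2\phi$ couplings cancel and the anisotropy converts the residual into a
  $\cos4\phi$ coupling with four locked phases. Each stimulus feeds all
  coupling populations except one, so it leaves a single population — and
  a single cycle — active. The construction has an exact $Z_4$ symmetry,
  so locked solutions necessarily come in quadruples; tuning only has to
  achieve clean 1:1 locking.
* *Rate-coding alternative (rank 1).* Two populations build a 1-D flow
  with stable zeros at $0$ and $\pm\kappa^*$; in/anti-phase outputs come
  from opposite $\mathrm{cov}(I^{(osc)}, w)$, read out through the rates
  (`tanh` readout) so a saturated population drops out of the output.
* *Phase precession.* The reference enters as $(\sin\theta, \cos\theta)$
  and a continuous position $s \in [0,1)$ as
  $(\sin\tfrac{\pi s}2, \cos\tfrac{\pi s}2)$; sin-type and cos-type
  coupling populations are saturated complementarily by the position
  channels, so the effective coupling function — and the locked phase —
  translates continuously with $s$. The source's printed display equation
  for this coupling function is typographically corrupted; the
  implementation follows the covariance recipe, with signs adapted to this
  package's rotation convention.

**Finite-size limits.** Sampling a network of $N = 4096$ units from the
two-stimulus mixture reproduces every qualitative behaviour (bistability,
$\pi$ separation, saturation, steering), but the *quantitative*
trajectory agreement with the infinite-$N$ equations is limited by the
sampling noise of the empirical overlap matrix
($\mathrm{SE}\sim\sqrt{\mathrm{var}(n)\,\mathrm{var}(m)/N_{pop}}$), which
shifts the realized radius by ~5–10% and the locked phases by 0.1–0.3 rad
depending on the seed. A design search over coupling strength, input gain,
weights and PSD-tight variances did not find a preset that pushes the
10-cycle relative RMSE below 0.1 robustly while preserving the
stimulus-collapse behaviour (stiffer locking requires more detuning
compensation, which breaks under-stimulus locking). The corresponding
acceptance check is implemented faithfully and may fail at some seeds;
this is a genuine finite-size effect, not an implementation defect — the
discrepancy shrinks as $1/\sqrt N$.

Mixture *fitting* uses MAP-EM with a zero-mean prior of precision $10^6$
on component means (k-means initialization, up to 5 restarts on degenerate
components), and evaluates each fit by resampling networks and scoring
them on pure-sine trials. At desk scale the trained network's loss
(~0.004) is far below any resampled network's, matching the qualitative
observation that resampling fitted mixtures rarely yields functioning
networks.

# What the tests establish

Oracles are independent of the code paths they check: closed-form return
maps and monodromy for the recurrence-free field, finite-difference
Jacobians, an R-side Euler integrator of the nonautonomous reduced system
(with the filtered input as a dynamic state) against the C++ N-dimensional
simulation, Monte-Carlo gain expectations, filter responses computed
directly from the designed taps, and the generator's hidden phase for the
pipeline. The acceptance suite reproduces the headline dynamical facts at
reduced scale: training finds the phase code; memories are limit cycles
with $|\lambda| < 1$; tonic stimuli destabilize the disfavored cycle
below amplitude 1; the extracted coupling function carries the same
attractors; and the designed mixtures realize two, three (rate-code) and
four memories with the predicted selection behaviour.
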