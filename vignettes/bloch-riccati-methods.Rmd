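---
title: "Exact Bloch-equation propagation for sech/tanh, chirp, and square pulses"
author: "BlochRiccati authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact Bloch-equation propagation for sech/tanh, chirp, and square pulses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BlochRiccati)
```

## The model

In the rotating frame at the RF carrier frequency, and neglecting
relaxation, the bulk magnetization of a spin-1/2 isochromat with resonance
offset $\Omega = \omega_0 - \omega_c$ obeys

$$
\frac{d\mathbf{M}}{dt} =
\begin{pmatrix}
0 & \Omega & -\omega_{1y} \\
-\Omega & 0 & \omega_{1x} \\
\omega_{1y} & -\omega_{1x} & 0
\end{pmatrix}
\mathbf{M},
$$

where $\omega_{1x} + i\,\omega_{1y} = \omega_{AM}(t)\,e^{i\phi_1(t)}$ is
the complex RF field of a shaped pulse with amplitude modulation
$\omega_{AM}$ and phase $\phi_1$. The matrix is skew-symmetric, so $|M|$ is
conserved; any norm $|M| \in (0, M_0]$ is supported.

Stereographic projection onto the extended complex plane (the Riemann
sphere),

$$
f = \frac{M_x + i M_y}{|M| + M_z},
$$

maps $+z$ to $0$, the equator to the unit circle, and $-z$ to the point at
infinity, and turns the Bloch equation into the first-order complex
Riccati equation

$$
\frac{df}{dt} = \frac{i}{2}\,\omega_1 - i\,\Omega f
  - \frac{i}{2}\,\omega_1^{*} f^2 .
$$

The standard Riccati-to-linear substitution
$f = -2i\,(\dot q/q)/\omega_1^{*}$ converts this to a second-order
*linear* ODE for $q$. For three driving functions that ODE is classical:

* **sech/tanh (HS1) pulse.** With
  $\omega_{AM} = \omega_{1m}\,\mathrm{sech}\,x$,
  $\omega_{FM} = A \tanh x$, $x = (2\beta/T_p)(t - t_c)$, and the logistic
  time variable $p = (1 + \tanh x)/2 \in (0,1)$, the equation becomes the
  Gauss hypergeometric ODE. The fundamental pair about $p = 0$ is
  $F_A = {}_2F_1(a, b; c; p)$ and
  $F_B = p^{\,1-c}\,{}_2F_1(a-c+1,\, b-c+1;\, 2-c;\, p)$, with
  $a = \frac{T_p}{4\beta}\!\left(-iA + \sqrt{\omega_{1m}^2 - A^2}\right)$,
  $b = \frac{T_p}{4\beta}\!\left(-iA - \sqrt{\omega_{1m}^2 - A^2}\right)$,
  $c = \tfrac12 + i\frac{T_p}{4\beta}(\Omega - A)$
  (principal square root). Since $\mathrm{Re}\,c = \tfrac12$ always, $c$
  is never a nonpositive integer and the pair is always fundamental.
* **Chirp pulse.** With constant amplitude and a linear sweep
  $\omega_{FM} = 2A(t-t_c)/T_p$, the complex time variable
  $p = \sqrt{iA/T_p}\,(t - t_c + T_p\Omega/2A)$ reduces the equation to
  the Hermite-type form $q'' + 2pq' + 2(a{+}1)q = 0$ with
  $a = -1 - i\,T_p\omega_{1m}^2/(8A)$. The fundamental pair is
  $F_A = M\!\big(\tfrac{a+1}{2}, \tfrac12, -p^2\big)$ (Kummer confluent
  hypergeometric) and $F_B\,e^{-p^2}$ with $F_B = H_a(p)$, the Hermite
  function of complex order.
* **Square pulse.** Constant amplitude and phase give an elementary
  solution,
  $f(t) = \frac{e^{i\phi_c}}{\omega_{1m}}
  \left(-\Omega + \omega_{\text{eff}} \tanh\!\big(C +
  \tfrac{i}{2} t\,\omega_{\text{eff}}\big)\right)$ with
  $\omega_{\text{eff}} = \sqrt{\Omega^2 + \omega_{1m}^2}$.

In every case the trajectory through a known state is selected by a
*single* integration constant: although the linear ODE has two constants
$(C_A, C_B)$, only their ratio $C = C_B/C_A$ enters $f$. The package
stores the pair projectively (class `ParticularConstant`), so anchors at
the point at infinity (magnetization at $-z$) and at zeros of $q$ are
handled without special cases. Because one known magnetization at one time
fixes the whole trajectory, solutions chain naturally across composite
pulses: each segment is anchored at its start with the coordinate
inherited from the previous segment's end, at full precision and without
re-projection.

### Sign conventions

The package defines the waveform phase as the accumulated frequency
modulation, $\dot\phi_1 = +\omega_{FM}$, for all pulse families; this is
the phase that `evalWaveform()` reports, that the shape export writes, and
that the RK4 oracle integrates. The hypergeometric parameters above are
stated in the same convention (this is why $-iA$ and $\Omega - A$ appear
where a sweep of the opposite sign convention would show $+iA$ and
$\Omega + A$). Internal consistency of the waveform surface, the analytic
propagators, and the numerical oracle was verified term by term: tests
substitute the evaluated fundamental pairs back into their defining ODEs
and compare whole trajectories against the independent integrator.

### The BIR-4 composite

`makeBir4(theta, component)` assembles the B1-insensitive rotation pulse
from four asymmetrically truncated half pulses of the sech/tanh template
(duration $T_p/2$ each): amplitude descends from its peak to the
truncation level, rises back to a peak at the composite midpoint, and
repeats, so the amplitude is continuous at the outer junctions and peaks
at the start, middle, and end. The frequency sweep follows the template's
tanh branch within each half and reverses sign at the outer junctions.
Literature descriptions of this composite give the phase scheme only
in prose, so the package adopts the original composite-pulse convention: phase offsets
$\Delta\phi = \pi + \theta/2$ applied to segments 2 and 3 and removed for
segment 4 set the net flip angle $\theta$. An alternative reading — a
single phase discontinuity at the composite midpoint only — was
considered and rejected because it does not reproduce a $\theta$-flip
under the numerical oracle. Offsets are folded into each segment's
$\phi_c$ before solving, so each segment is solved in its own phase
convention and the state remains continuous at junctions.

## Numerical evaluation of the fundamental systems

The special functions are evaluated in C++ extended precision
(`long double`, about 18-19 significant digits), and results are returned
in double precision. Two complementary strategies are used:

* **Maclaurin series** where they are well conditioned. For the Gauss
  series with complex parameters of magnitude $\mu$ the largest term
  exceeds the sum by roughly $e^{2\mu\sqrt{p}}$, so the series is used
  only below $p_0 = \min(0.02,\ 0.25/\mu^2)$, where at most a few digits
  are lost.
* **Taylor-series analytic continuation** of the defining ODE elsewhere:
  from $p_0$ the fundamental system (value and derivative of both
  branches) is advanced by adaptive-order Taylor steps whose radius is
  held at 45% of the distance to the nearest singular point ($p = 0, 1$)
  for the hypergeometric equation, and at $3/(1+|p|)$ for the entire
  Hermite-type equation. Along the physical evaluation paths — the real
  interval $(0,1)$, where the local exponents $p^{\pm i\sigma}$ and
  $(1-p)^{1/2 + i\sigma}$ have unit or decaying modulus, and the rotated
  real line $e^{i\pi/4}\mathbb{R}$, where $|e^{-p^2}| = 1$ — the
  fundamental matrix has no exponential dichotomy (the underlying
  dynamics is a rotation), so the continuation does not lose relative
  accuracy to growth. This matters: the chirp argument $-p^2$ reaches
  magnitudes of order $10^2$ at large time-bandwidth products, where a
  direct series would lose all digits.

Verification is layered: the evaluated pairs are compared against frozen
30-digit reference values from an independent arbitrary-precision
implementation, against the direct series on its domain of validity
(a dual code path), against closed-form Wronskians (the Abel identity
fixes the Wronskian up to one constant, which is matched exactly), and by
residual substitution into their defining ODEs at random points.

Near the end of a low-truncation pulse, $1 - p$ is as small as
$\tfrac12\mathrm{sech}^2\beta$ ($2.5\times10^{-7}$ at 0.1% truncation);
$p$ and $1-p$ are computed from the logistic closed form separately so
the small complement retains full relative precision, and continuation
targets above $p = 1/2$ are reconstructed from the complement in extended
precision.

Further numerical policies:

* Stereographic projection switches to the declared point at infinity
  when $|M| + M_z < 10^{-12}\,|M|$; in the southern hemisphere the
  denominator is computed as $(M_x^2 + M_y^2)/(|M| - M_z)$ to avoid
  cancellation, and inverse projection of $|f| > 1$ uses the inverted
  chart $g = 1/f$. Round trips are exact to $10^{-12}$ per component
  everywhere outside the declared-infinity ball, whose radius (about
  $10^{-12}$ in angle) is far below every error bound used.
* The angular error between magnetization vectors is computed as
  `atan2(|M1 x M2|, M1 . M2)`: identical to the arccosine of the clamped
  normalized dot product, but fully accurate for the sub-microradian
  differences the convergence studies resolve.
* Principal branches are used for the complex square root and
  $\mathrm{artanh}$; square-pulse anchors whose artanh argument falls
  within $10^{-10}$ of a branch point are rejected with an error rather
  than silently perturbed. Anchor times default to the pulse start but
  any time is accepted.
* `beta` may take either sign (the sign sets the sweep direction); the
  evaluation grid is sorted in $p$ internally.

## The RK4 verification oracle

`propagateRK4()` is a deliberately classic fixed-step fourth-order
Runge-Kutta integrator of the same Bloch equation, with the RF field
sampled at the sub-stage times $t$, $t + h/2$, $t + h$ (required for
fourth-order accuracy under time-dependent driving). It is kept fixed-step
because the convergence studies are parameterized by step count.
Requested evaluation times snap to the nearest grid point, and the
returned trajectory carries the snapped times. For composite pulses all
sub-stages of a step are evaluated on the segment containing the step
midpoint, so grid-aligned junctions do not degrade the order within
segments. RK4 does not conserve the norm exactly; the drift at $10^4$
steps on the inversion-pulse workload is below $10^{-10}$ and is itself
asserted in the tests.

Because the analytic evaluation is accurate to $\sim 10^{-12}$ rad, the
analytic-vs-RK4 angular error is dominated by the integrator: it falls as
$n^{-4}$ (log-log slope $-4 \pm 0.3$ over $10^2$–$10^5$ steps) before
flattening at the evaluation floor, and the trajectory-averaged error at
$10^4$ steps is orders of magnitude below the $10^{-5}$ rad acceptance
level for the reference inversion-pulse settings.

## Self-induced transparency

For a non-frequency-modulated sech pulse on resonance the dynamics is an
exactly integrable planar rotation by the accumulated pulse area, with
polar angle
$\theta(t) = (\omega_{1m} T_p/\beta)\,\arctan e^{(2\beta/T_p)(t - t_c)}$
(the infinite-period pendulum). `sitClosedForm()` reports $\theta$
relative to the pulse start — in that convention it matches the full
propagator at the precision floor for any truncation — while
`sitAmplitude(beta, Tp)` $= 2\pi\beta/(T_p \arctan e^{\beta})$ inverts the
absolute final angle for an exact $2\pi$ rotation. Two distinct
comparisons follow, and the tests keep them separate: the particular
solution with $C = 0$ (the idealized transparency trajectory) returns to
$+z$ at the precision floor, whereas a trajectory anchored at equilibrium
at the truncated start misses the ideal pendulum by an angle of the order
of the truncation fraction (the ideal trajectory is tilted by
$\approx \arctan e^{-\beta}$ when the pulse switches on), a deviation
that shrinks proportionally as the truncation decreases.

## What the fixtures emulate — and what they do not

There is no external data: isochromat ensembles are generated by
`randomIsochromats()` (orientations uniform on the sphere via normalized
Gaussian triples, offsets uniform over a chosen band, seeded and
reproducible), and pulse settings cover the standard validation
conditions for these pulse families: inversion pulses at $\omega_{1m}/2\pi = 2$ kHz, $T_p = 5$ ms,
$R = 10$, truncations $\{0.01, 0.1, 0.25\}$; chirps at 1.5 kHz with
$R \in \{10, 50, 100\}$; a 200 Hz square pulse; BIR-4 with $R = 32$,
component $T_p = 5$ ms, and a 100 Hz offset. Problem sizes in the tests
(1000 comparison intervals per trajectory, $10^2$–$10^6$ RK4 steps, 100
randomized square-pulse draws, $10^4$ projection round trips) were chosen
so the whole suite completes in well under a minute while still resolving
every claimed error floor.

Passing these tests demonstrates mathematical correctness of the
propagators for ideal, relaxation-free, spatially homogeneous isochromat
dynamics. It says nothing about effects the model excludes: relaxation
($T_1$, $T_2$), radiation damping, diffusion, B1/B0 spatial distributions
within a voxel, amplifier distortion of the waveform, or
gradient-modulated and multidimensional pulse variants. The chirp and HS1
families plus composites of them are the only waveforms covered;
arbitrary user-supplied AM/FM pairs are out of scope.

## Tunable parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `omega1m` | rad/s | — | peak Rabi frequency; config files accept Hz and convert by $2\pi$ |
| `A` | rad/s | — | sweep magnitude; `hs1FromSpec()`/`chirpPulse()` accept `R` instead |
| `beta` | — | — | signed truncation factor; $\mathrm{sech}\,\beta$ is the boundary amplitude fraction |
| `Tp` | s | — | characteristic duration (twice the time from peak to the $\mathrm{sech}\,\beta$ level for HS1; sweep-width reference for chirp) |
| `tc`, `phic` | s, rad | `Tp/2`, 0 | peak/center time and the phase there |
| `tStart`, `tEnd` | s | symmetric | support; set independently of `tc` for asymmetric truncation |
| `nSteps` | — | — | RK4 step count; $10^4$ is the reference comparison setting |
| pole threshold | — | $10^{-12}$ | declared-infinity radius of the projection |

The time-bandwidth convention for the chirp is $R = A T_p/\pi$, the
low-truncation limit of the corrected sech/tanh relation
$R = A T_p \tanh(\beta)/\pi$, so quoted chirp time-bandwidth products map
directly onto `A`.

## A worked example

```{r example}
pulse <- hs1FromSpec(omega1m = 2 * pi * 2000, Tp = 5e-3, R = 10,
                     truncation = 0.1)
iso <- isochromat(offset = 0)          # equilibrium, on resonance
tt <- seq(0, 5e-3, length.out = 1001)
analytic <- propagate(pulse, iso, tt)
oracle <- propagateRK4(pulse, iso, nSteps = 1e4, evalTimes = tt)
cmp <- compareTrajectories(analytic, oracle)
c(mean = cmp$mean, max = cmp$max)      # radians
tail(trajM(analytic), 1)               # adiabatic inversion: Mz near -1
```

## Known limitations

* No relaxation; the norm is a strict invariant.
* Working precision is fixed at extended precision (~18-19 digits); the
  double-precision output floor is around $10^{-12}$ rad. Pathological
  parameter magnitudes (e.g. $|a|, |c| \gtrsim 10^3$) would need more
  headroom than the continuation currently carries.
* Constant determination from a *numerically perturbed* anchor state
  inherits the chart's conditioning: near the south pole the map from
  magnetization to $f$ amplifies perturbations quadratically in $|f|$.
  Anchoring from exact states is everywhere exact (this is tested); when
  anchoring from simulated states, prefer anchors away from the poles.
* The square-pulse constant is defined modulo $i\pi$ (the artanh branch
  period); comparisons across anchors reduce by that period first.
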