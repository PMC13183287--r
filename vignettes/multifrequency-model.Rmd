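---
title: "A multi-frequency Jansen-Rit network model with homeostatic feedback inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-frequency Jansen-Rit network model with homeostatic feedback inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jansenrit)
```

## The model

Each brain region is a cortical column built from two Jansen-Rit
subpopulations, one tuned to the EEG alpha band and one to the gamma band.
A subpopulation consists of pyramidal cells, excitatory interneurons and
inhibitory interneurons. Mean membrane potentials are converted to firing
rates by the sigmoid

$$S(v) = \frac{\zeta_{max}}{1 + e^{-r\,(v - v_{th})}},$$

and rates are converted back to post-synaptic potentials by critically
damped second-order kernels with gain $A$ (excitatory) or $B$ (inhibitory)
and inverse time constants $a$, $b$. Writing $x_0$ for the PSP produced by
the pyramidal population (the input to both interneuron pools), $x_1$ for
the excitatory and $x_2$ for the inhibitory PSP on the pyramidal cells, each
subpopulation $s \in \{\alpha, \gamma\}$ of node $i$ obeys

$$
\begin{aligned}
\ddot x_{0,i}^s &= A^s a^s\, S(x_{1,i} - x_{2,i}) - 2 a^s \dot x_{0,i}^s -
 (a^s)^2 x_{0,i}^s\\
\ddot x_{1,i}^s &= A^s a^s\, \big(p_i(t) + C_2 S(C_1 x_{0,i}) +
 K C \textstyle\sum_{j \ne i} M_{ij}\, S(x_{1,j} - x_{2,j})\big)
 - 2 a^s \dot x_{1,i}^s - (a^s)^2 x_{1,i}^s\\
\ddot x_{2,i}^s &= B^s b^s\, C_4 S(C_3 x_{0,i}) - 2 b^s \dot x_{2,i}^s -
 (b^s)^2 x_{2,i}^s,
\end{aligned}
$$

where the unsuperscripted arguments of $S$ are the node-level mixture
variables

$$x_{k,i} = r^\alpha x_{k,i}^\alpha + (1 - r^\alpha)\, x_{k,i}^\gamma,
\qquad k = 0, 1, 2,$$

and the EEG-like observable is $x_{1,i} - x_{2,i}$. The proportion
$r^\alpha \in [0, 1]$ controls how much each subpopulation contributes; the
gamma column's gains are tied to its rate constants
($A^\gamma = 32.5\,a^\gamma/1000$, $B^\gamma = 440\,b^\gamma/1000$), which
makes the gamma subsystem an exact time-rescaled copy of the alpha one with
identical DC gains.

Homeostatic inhibitory synaptic plasticity (ISP) turns the
inhibitory-to-pyramidal gain $C_4$ of every node into a state:

$$\tau \frac{dC_4}{dt} = \zeta_{inh}\,(\zeta_{pyr} - \rho)
 \left(\frac{C_4 - C_{4,min}}{C}\right)^\beta,$$

with $\zeta_{pyr} = S(x_1 - x_2)$ and $\zeta_{inh} = S(C_3 x_0)$ evaluated
on the mixture variables, one shared $C_4$ per node. When pyramidal activity
exceeds the target $\rho$, inhibition grows; below target it decays. The
multiplicative soft-bound factor keeps $C_4 \ge C_{4,min}$ (default 0); a
hard clip after each step guards against finite-step overshoot.

## Conventions the equations leave open

Three structural choices are not pinned down unambiguously by the usual
presentations of this model family, and all three change the dynamics
qualitatively. The package fixes defaults by requiring the single-node and
network phenomenology of the model family to hold, and exposes each choice
as a switch.

**Mixture sign** (`mixture_sign`). Some write-ups print the mixture as
$r^\alpha x^\alpha_k - (1-r^\alpha) x^\gamma_k$. With the subtractive form a
pure gamma node ($r^\alpha = 0$) feeds $S(-(x_1^\gamma - x_2^\gamma))$ back
into its own loops and settles into a fixed point: no gamma rhythm exists at
all, and ISP cannot clamp mixed nodes (the blended pyramidal potential
cancels). The additive (convex) mixture restores both the slow (~17.5 Hz)
and fast (~40 Hz) gamma-only regimes and the exact rate clamping at
$r^\alpha = 0.5$. The default is therefore `+1`; the subtractive reading
remains available via `mixture_sign = -1`.

**Sigmoid arguments** (`sigmoid_args`). The equations above use the
node-level mixtures inside every sigmoid, so both subpopulations share one
effective drive ("combined", the default). The alternative — each
subpopulation reading its own states — also produces gamma-only rhythms,
but then the node never reaches the interior homeostatic fixed point at
intermediate $r^\alpha$: it stays on a limit cycle where the *weighted*
average $\langle \zeta_{inh}\zeta_{pyr}\rangle / \langle\zeta_{inh}\rangle$
is clamped rather than the plain mean rate, which comes out ~25% below
$\rho$. Only the combined convention reproduces exact clamping.

**Coupling scale** (`coupling_scaled_by_Aa`). Placed outside the synaptic
gain, the inter-regional input $K C \sum_j M_{ij} S(\cdot)$ is smaller than
the external drive $A a\, p$ by a factor $A a \approx 468$, and the global
coupling $K \in [0, 1]$ has no observable effect. With the coupling
premultiplied by $A a$ (i.e. in the same units as $p$, the default), the
model shows the expected behaviour: pure gamma at $K = 0$, theta/alpha
rhythms at $K \approx 0.5$ with ISP, and saturation-driven loss of
oscillations at large $K$ without ISP.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| $A^\alpha$, $B^\alpha$ | 3.9, 26.4 | mV | alpha EPSP/IPSP gains |
| $a^\alpha$, $b^\alpha$ | 120, 60 | 1/s | alpha inverse time constants |
| $a^\gamma$, $b^\gamma$ | 660, 330 | 1/s | gamma inverse time constants |
| $\zeta_{max}$, $r$, $v_{th}$ | 5, 0.56, 6 | 1/s, 1/mV, mV | sigmoid |
| $C$; $C_1..C_4$ | 135; $C$, $0.8C$, $0.25C$, $0.25C$ | — | local connectivity |
| $r^\alpha$ | 0.5 | — | alpha/gamma mixture |
| $\langle p \rangle$, $\sigma_p$ | 220, 31 | 1/s | external input |
| $\rho$, $\tau$, $\beta$ | 2.5, 2, 1 | 1/s, s, — | ISP target, timescale, bound |
| $K$ | 0 | — | global coupling |
| $\Delta t$ | 1 | ms | Euler step |

The alpha column is exactly the classical Jansen-Rit parameter set
(3.25, 22, 100, 50) rescaled in time by a factor 1.2 with the input axis
preserved. Every bifurcation of the classical model therefore appears at
the same $p$ here, while every frequency is multiplied by 1.2: the
equilibrium continuation reproduces the classical Hopf points at
$p = 89.83$ and $315.70$ and the fold at $p = 113.59$ to three decimals,
and the alpha-regime cycle at $p = 220$ runs at 13.0 Hz (RK4) rather than
the classical 10.9 Hz. Under the 1 ms Euler protocol the same cycle
measures 11.5 Hz (see below). Descriptions of this regime as "~10 Hz
alpha" are band labels rather than measured peaks; the package reports
what the stated protocol computes.

## Integration and noise

The network integrator is an explicit Euler scheme at $\Delta t = 1$ ms
(compiled), with the external input redrawn every step from
$\mathcal N(\langle p\rangle, \sigma_p)$ and held constant across the step.
This sampled-input convention treats $\sigma_p$ as the standard deviation of
the held input; the `sde_scaling` flag instead scales the fluctuation by
$1/\sqrt{\Delta t}$ (diffusion convention). Initial conditions are all-zero
PSP states with $C_4(0) = 0.25\,C$. Analyses discard a 60 s transient by
default and store traces at 200 Hz after zero-phase anti-alias filtering.

Explicit Euler at 1 ms is part of the protocol definition, not a converged
integrator: on the alpha-only node at $p = 220$ it biases the spectral peak
from the converged 13.0 Hz down to 11.5 Hz. The suite pins this bias down
explicitly, and checks convergence proper on the RK4 path used by the
bifurcation toolkit (halving the step moves the peak by less than one
0.5 Hz bin).

ISP convergence is slow at the defaults: the soft-bound factor $C_4/C$ and
the small inhibitory rate put the homeostatic fixed point minutes away at
the single-node level. The clamping checks therefore integrate 1000 s and
average the final 100 s, after verifying that the 63.2% convergence time of
the $C_4$ trace falls well before the averaging window. Shorter windows
(e.g. stopping at 300 s) overestimate the mean rate by several percent
because the approach to the fixed point is from above.

## Observables

Spectra use Welch's method with 2 s Hann windows and 50% overlap (0.5 Hz
resolution), mean-detrended per segment. Relative band power integrates
half-open bands delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30 Hz and
normalizes by the 0.5-30 Hz total. Peak frequencies break ties toward the
lower bin, a convention that matters because the 0.5 Hz grid makes narrow
ridges step-like.

Band-pass filtering uses a 3rd-order Bessel design (phase-normalized
analog prototype, band transform, bilinear mapping — coefficients agree
with the reference scientific-Python implementation to machine precision),
applied forward and backward so all filters are zero-phase. Envelopes are
the magnitude of the FFT-based analytic signal, high-passed at 0.5 Hz with
a 3rd-order Butterworth. EEG functional connectivity is the Pearson
correlation of band-limited envelopes; BOLD connectivity band-passes
0.01-0.08 Hz first. FC diagonals are zeroed before any comparison so the
trivial self-correlation cannot inflate similarity scores.

The haemodynamic stage is the Balloon-Windkessel model (signal decay
0.65 s, inflow 0.41 s, volume and deoxyhemoglobin 0.98 s, stiffness 0.32,
resting extraction 0.4), integrated with Euler at 10 ms and sampled at
TR = 2.08 s. The deoxyhemoglobin outflow term uses the volume-normalized
form $q\,v^{1/\kappa}/v$; the printed flat form is typographically
ambiguous and this reading matches the standard formulation and has the
resting state $(0,1,1,1)$ as a stable fixed point with zero BOLD. The
default drive is the node-level pyramidal rate; a mode driving with
$r^\alpha$-weighted per-subpopulation rates is provided.

## Bifurcation toolkit

The deterministic single-subpopulation node (6 states, 7 with ISP — the
extended system is continued with $C_4$ as a state) is analyzed
numerically: Newton location of equilibria (residual below $10^{-10}$),
analytic Jacobians (cross-checked against finite differences and
complex-step derivatives), pseudo-arclength continuation with step
rejection on predictor distance and tangent angle, and event
classification. Folds are refined by Newton on the extended system
$(f = 0,\ Jv = 0,\ \|v\| = 1)$ and Hopf points by bisection to
$10^{-3}$ in $p$. Limit cycles are found by single shooting with an
anchor-plane phase condition; monodromy matrices and parameter
sensitivities come from RK4 integration of the variational equations, so
Newton steps are exact and Floquet multipliers fall out of the monodromy
spectrum (the trivial multiplier, recovered to $10^{-4}$, is a built-in
accuracy check). Cycle branches are continued in $(x_0, T, p)$; torus
points are bisected on the modulus of the leading complex multiplier pair
and folds of cycles located from the tangent reversal.

Two practical notes. First, with ISP the monodromy has a second multiplier
near 1 (the slow $C_4$ direction, $\approx 0.999$ at $\tau = 2$); the
shooting Newton needs the residual-norm line search it implements to stay
in its basin. Second, below the torus point the ISP model has no simply
attracting cycle to settle onto, so the cycle branch is seeded in the
robust oscillatory regime (p = 150, after a 200 s settle) and continued
downward through the torus.

On this model the toolkit locates the ISP saddle-node at $p = 6.624$, the
torus at $p = 111.35$, and the no-ISP fold of cycles at $p = 137.39$ (the
slow spike-like cycle family meets its unstable partner; the printed
round figure for this event is 140, 1.9% away).

## Synthetic connectomes and fixtures

Unit tests and the network property checks run on synthetic connectomes:
symmetric, zero-diagonal, max-normalized weight matrices with log-normal
weights, block-modular structure, mirror-symmetric hemispheres (homotopic
pairs on the anti-diagonal, matching the AAL-style ordering that
`reinforce_homotopic()` assumes), single-component hemispheres and a
homotopic bridge. Defaults: 20 regions, edge density 0.3, 2 modules per
hemisphere, within/between weight ratio 4 — values in the range of
group-averaged tractography matrices. What they do not emulate: realistic
degree distributions, distance-dependent weight decay, or inter-subject
variability; passing network tests therefore demonstrates the mechanics of
the coupling, plasticity and fitting pipeline, not fidelity to any
empirical connectome. Signal fixtures (Gaussian series with prescribed
correlation, amplitude-modulated carrier pairs with a controlled shared
envelope fraction) back the connectivity tests with analytically known
ground truth.

One caveat the K = 0 tests exposed: nodes started from identical initial
conditions share the deterministic skeleton of their dynamics, and at
intermediate $r^\alpha$ the slow rhythm's timing is so robust to input
noise that band-limited envelopes of *uncoupled* nodes stay correlated for
hundreds of seconds within a single run, even though the raw signals
decorrelate. The null behaviour of the envelope-FC estimator is therefore
tested on independent realizations (it is clean: |r| < 0.01 on independent
Gaussian series), and within-run FC at K = 0 should not be read as a
coupling estimate near deterministic regimes.

## Whole-brain property checks

At the desk scale used by the tests (10-20 regions, 120-360 s):
ISP keeps the network mean rate near $\rho$ while the no-ISP network pins
against the sigmoid ceiling at $K = 1$ (the saturation that motivates ISP);
the equilibrated mean $C_4$ increases linearly with nodal strength with a
slope that grows with $K$ (200 s runs — the 20 s transient protocol
saturates at this connectome scale and flattens the slope at $K = 0.75$);
and the 63.2% convergence time of the region-averaged $C_4$ increases
monotonically with $\tau$ across four decade values (0.01-10 s) in 120 s
noise-free runs at $K = 0.5$.

## Limitations

No conduction delays, no per-subpopulation plasticity, no codimension-2
continuation, and no claim about the non-convergent switching regime
between the saddle-node and the torus other than what simulations show.
Grid sweeps are orchestrated serially; large sweeps should be parallelized
externally over cells. Empirical fitting (SSIM against measured FC,
Clarkson similarity against measured band power, the 0.85-masked dual fit)
is implemented and oracle-tested, but no empirical data ship with the
package, so its scientific calibration is exercised only on synthetic
targets.
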