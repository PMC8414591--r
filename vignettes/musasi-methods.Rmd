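---
title: "Stochastic cross-bridge mechanics with implicit active stiffness: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic cross-bridge mechanics with implicit active stiffness: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
molecular model, the multiple-time-step coupling scheme, the choices made
where the design was genuinely open, and the limits of what the simulations
shown here can establish.

## The problem

Cardiac muscle contracts because myosin heads cycle stochastically through
attachment, power strokes, and detachment on actin thin filaments, on a
microsecond-to-millisecond time scale.  Tissue-level mechanics — a strip of
myocardium, a myofibril, ultimately a ventricle — is continuum mechanics on
a millisecond-to-second time scale, and is almost always integrated
implicitly because passive tissue is stiff and nearly incompressible.
Coupling the two creates two specific problems:

1. **Time-scale separation.**  A Monte Carlo (MC) cross-bridge model needs
   steps of ~5 µs; an implicit finite-element-scale integrator wants steps
   of ~1 ms.  Running the macro solver at the micro step is prohibitively
   expensive.
2. **Active stiffness.**  Bound myosin rods make the tissue *much* stiffer
   along the fiber than its passive elasticity — of order
   $K_A = (R_S/SA_0)\,R_B\,2N_M k_{rod}\,(SL_0/2) \approx 104\,R_B$ MPa at
   binding ratio $R_B$, against passive stiffness of order kPa.  If the
   active tension computed by the MC model is applied *explicitly* (frozen
   during the macro step), this stiffness is absent from the Newton matrix
   and the macro integration is only conditionally stable, with the bound
   $\Delta T \le \mu_S/K_A \approx 0.35/R_B$ µs for tissue viscosity
   $\mu_S = 36.66$ Pa·s — a bound *smaller than the MC step itself* once a
   few percent of heads are bound.

The scheme implemented here (multiple-step active stiffness integration)
resolves both: $n$ MC micro-steps run once per macro interval with
stretches extrapolated from the macro state, and during the macro Newton
iterations the *frozen* MC event record is re-read with rod strains
re-interpolated from the trial end-of-step stretch.  The active tension
then depends on the trial stretch, and its derivative — a consistent,
provably non-negative active stiffness — enters the Newton matrix.

## The molecular model

Each of $N_F$ thin filaments carries $N_M = 38$ myosin molecules, each in
one of six states: three detached (`N_XB`, weakly bound `P_XB`, and the
post-rigor `N_ATP` recovery state) and three strongly bound
(`XB_PreR`, `XB_PostR1`, `XB_PostR2`).  Strong binding transmits force
through an elastic rod with piecewise-quadratic strain energy
$W(x) = \tfrac12 k_\pm x^2$ ($k_+ = 2$ pN/nm for stretch; $k_- \le k_+$,
default 1 pN/nm, for compression — convexity is what makes the active
stiffness non-negative).  Heads whose rod strain leaves $[-10, 10]$ nm are
forcibly detached to `N_ATP`.

**Power and reverse strokes.**  The two lever-arm strokes advance the
stroke offset by $s_1 = 6$ nm and $s_2 = 4$ nm and release chemical free
energy $E_{i-1} - E_i > 0$.  Rates are strain dependent and obey detailed
balance,
$$\frac{h_{f,i}(x)}{h_{b,i}(x+s_i)} =
  \exp\!\Big(-\frac{E_i + W(x+s_i) - E_{i-1} - W(x)}{k_BT}\Big),$$
under both implemented laws: the *destination strain energy* (DSE) law,
where the forward rate is penalised by the strain energy at the
destination and the reverse rate by the strain energy at the origin, and
the *barrier strain energy* (BSE) law of Kramers type, where both rates
reference the strain energy at the mid-stroke barrier $W(x + s_i/2)$.
The two laws differ sharply in how reverse strokes respond to load: under
BSE the reverse rate *grows* with rod strain (enabling avalanches of
reverse strokes during rapid lengthening), under DSE it shrinks.  Rates
are capped at $r_{max} = 10^5$/s; when one member of a forward/backward
pair exceeds the cap, both are rescaled so the detailed-balance ratio is
preserved exactly.

**Calcium regulation and cooperativity.**  One troponin/tropomyosin unit
per molecule gates attachment through a three-state scheme (no calcium /
calcium-bound / permissive); only permissive units allow the
`N_XB -> P_XB` transition.  Nearest-neighbour cooperativity multiplies
that rate by $\gamma^{n_g}$ and divides the reverse by $\gamma^{n_g}$,
with $\gamma = 40$ and $n_g \in \{0,1,2\}$ the number of attached
neighbours in the same filament.  This steep, almost switch-like
cooperative activation is what removes the bound population at diastolic
calcium (~10% of the systolic peak) and steepens the force–pCa relation;
reducing $\gamma$ to 20 or 10 visibly flattens it.

**Sampling scheme.**  Within a micro-step of $\Delta t = 5$ µs each
molecule and each T/T unit resolves at most one transition, drawn with
probability $(r_e/r_{tot})(1 - e^{-r_{tot}\Delta t})$.  The engine checks
$r_{tot}\Delta t \le 0.6$ and raises an error beyond it: with the rate cap,
a single capped edge gives exactly $0.5$, so the bound allows one capped
edge plus slow edges but rejects pathological configurations.  Fresh
attachments draw their initial strain from the rod Boltzmann distribution
$\propto e^{-W(x)/k_BT}$ (an asymmetric truncated Gaussian, sampled by
side-selection plus rejection against the domain edge) and record the
stretch and micro-step index of attachment — the bookkeeping the implicit
re-evaluation needs.

**Filament overlap.**  The attachment rate is scaled by a tent-shaped
function of stretch (zero below 0.75 and above 1.35, plateau 1 between
0.95 and 1.05).  This emulates double overlap at short sarcomere lengths
and loss of single overlap at long lengths.  It is a standard piece of
sarcomere physiology, and it matters here: without any force–length
dependence, a serial chain of half-sarcomeres settles into static
heterogeneity and spontaneous oscillations cannot arise, because a
shortened half-sarcomere never loses its force advantage.

## The coupling scheme

With macro step $\Delta T$ and baseline micro-step $\Delta t_0$, the
number of micro-steps is $n = \lfloor(\Delta T - 0.5\Delta t_0)/\Delta
t_0\rfloor + 1$ (250 at $\Delta T = 1.25$ ms, 63 at 0.3125 ms).  During
the MC pass the stretch is extrapolated,
$\tilde\lambda_k = \lambda_T + k\Delta t\,\dot\lambda_T$, and a bound
molecule's rod strain is
$\tilde x = x_A + s + (SL_0/2)(\tilde\lambda_k - \tilde\lambda_A)$.

The active tension over the interval matches impulses between the scales:
$$T_{act} = \frac{2R_S}{SA_0\,N_F\,n} \sum_{j,i,k}
  \delta_{A}\, \frac{dW}{dx}(x_{ij,k}),$$
with the factor 2 because the half-sarcomere model carries only one of the
two tropomyosin spirals of a real thin filament.  In the *implicit*
evaluation the strains $x_{ij,k}$ are recomputed at every Newton trial:
the stretch at micro-step $k$ is interpolated,
$\lambda_k = \lambda_T + (k/n)(\lambda_{T+\Delta T} - \lambda_T)$, and the
attachment stretch of within-interval attachments is the interpolated
stretch at the attachment step.  Differentiating gives the active
stiffness
$$\frac{\partial T_{act}}{\partial\lambda_{T+\Delta T}}
  = \frac{2R_S}{SA_0 N_F n}\sum \delta_A\,
    \frac{d^2W}{dx^2}\,\frac{SL_0}{2}\Big(\frac{k}{n} -
    \frac{\partial\lambda_A}{\partial\lambda}\Big), \qquad
  \frac{\partial\lambda_A}{\partial\lambda} =
  \begin{cases} k_A/n & \text{attached in-interval}\\
                0 & \text{carried} \end{cases}$$
Every factor $k/n - k_A/n$ is non-negative, so convex $W$ makes the
stiffness non-negative — the stability property.  At full binding with a
linear rod it equals the closed form $K_A$ above, which also settles an
ambiguity in the printed prefactor: the stiffness must carry the same
$R_S$ factor as the tension to be its derivative (a flag restores the
literal form).  The *explicit* comparator evaluates the same sum with the
frozen MC strains; it is independent of the trial stretch and contributes
zero stiffness.

Two small choices the formulas do not fix:

* **Newton trials beyond the rod domain.**  The frozen event set cannot
  detach heads, so an aggressive trial stretch can push a recorded strain
  past ±10 nm.  Strains are clamped at the domain edge with
  $d^2W/dx^2 = 0$ beyond it, keeping the residual continuous.
* **Committing a step.**  After the Newton loop accepts
  $\lambda_{T+\Delta T}$, attachment stretches of in-interval attachments
  are re-mapped to their accepted interpolated values so the next interval
  starts from consistent strains (the explicit scheme keeps the
  extrapolated values, as it never re-interpolates).

## Continuum side and testbeds

The tensor utilities implement fiber stretch $\lambda = \lVert Ff\rVert$,
its rate and second variation
($\delta^2\lambda \ge 0$ by Cauchy–Schwarz), and the rank-1 active
second Piola–Kirchhoff stress $S_{act} = (T_{act}/\lambda) f\otimes f$
satisfying the work identity $S_{act}{:}\,\delta E = T_{act}\delta\lambda$.
Together with the reduced testbeds these exercise every term of the
element force and stiffness integrals without a 3D mesh, which is out of
scope.

The integrator is Newmark-beta ($\beta = 1/4$, $\gamma = 1/2$) with Newton
iterations on acceleration increments, the first iteration using the
corrected right-hand side required because initial guesses do not satisfy
the interpolation rules.  A backtracking line search (halving, up to six
times) guards against overshoot across the piecewise rod stiffness; the
uniaxial twitch converges in ≤ 4 iterations per step, the 40-element chain
in ≤ ~6.

**Uniaxial strip.**  One stretch DOF with active tension, exponential
passive tension $c(e^{b(\lambda-1)}-1)$ ($c = 2$ kPa, $b = 10$: kPa-scale
below 20% strain), viscosity $\mu_S = 36.66$ Pa·s = 0.03666 MPa·ms, and
mass 0.01 MPa·ms² — the consistent inertia of a cm-scale strip at tissue
density, not a tuning knob; it matters for reproducing the explicit
scheme's failure mode (below).  Driven by a calcium transient (period 1 s,
peak 1 µM by convention, diastolic floor 10% of peak, product-of-
exponentials pulse).

**Stability dichotomy.**  With the implicit scheme the twitch at
$\Delta T = 1.25$ ms is unconditionally well behaved.  With the explicit
scheme at the same step, tension onset triggers a growing grid-frequency
oscillation; forced detachment saturates its amplitude (molecular states
cannot follow the oscillation), so the stretch does not run off to
infinity — the run is *wrong* rather than exploded, exactly the
"incorrect results without Newton breakdown" failure mode.  The
divergence classifier therefore flags, besides $|\lambda - 1| > 0.5$ and
non-finite states, sign-alternating consecutive stretch increments both
exceeding 0.01: implicit trajectories show alternating jitter below
~0.004 (Monte Carlo noise), the unstable explicit runs show 0.02–0.08,
and physical velocity reversals happen on the calcium time scale, never
within one macro step.  At $\Delta T \approx 10$ µs the explicit scheme
tracks the implicit solution, consistent with the $\mu_S/K_A$ estimate
at twitch-peak binding ratios of a few percent.

**Myofibril chain.**  40 half-sarcomeres in series (20 sarcomeres), fixed
ends, node positions as DOFs, tridiagonal tangent, per-half-sarcomere
viscosity $\mu_S$ and a nodal drag of 1 MPa·ms.  At constant 0.3 µM
calcium the chain sits on the steep shoulder of the force–pCa relation;
the combination of cooperative on/off switching, the yield instability of
stretched half-sarcomeres (forced detachment at +10 nm rod strain — one
percent of stretch moves rod strains by 9.5 nm), and the overlap-mediated
loss of force at short lengths produces sustained sawtooth length
oscillations (slow shortening, fast lengthening; stretch amplitudes of
≈ 0.1).  The drag and passive scale (1.5 kPa) are calibration, documented
as such: the drag is deliberately far above the half-sarcomere viscosity
because it sets the mechanical response to Monte Carlo tension noise —
with light damping, stretch jitter of one percent repeatedly sweeps rod
strains across the detachment bound and strips the chain of bound heads.
Under the destination-strain-energy law the oscillation period is below a
second; the barrier-strain-energy law binds more strongly and cycles
roughly three times slower, so its protocols observe a longer window
(6 s against 3.5 s).

## Parameters

Quantities printed in the reference parameter set: $\gamma = 40$,
$N_M = 38$, $SA_0 = 693$ nm², $R_S = 0.5$, $k_{rod} = 2$ pN/nm,
$SL_0/2 = 0.95$ µm, $r_{max} = 10^5$/s, $\Delta t_0 = 5$ µs,
$\Delta T_0 = 1.25$ ms, $\mu_S = 36.66$ Pa·s, BSE prefactors
$g_1 = 20$/s and $g_2 = 0.1$/s, and the BSE calibration factor 1.1 on
$k_{np}$.  $N_F = 16$ filaments suffice for ensemble outputs; protocols
accept 4–64.

Everything else lives in supplementary material unavailable here and is
therefore configuration with calibrated fallback defaults (all flagged
non-reference): $k_BT = 4.28$ pN·nm (310 K); ladder drops
$E_0{-}E_1 = 28$, $E_1{-}E_2 = 22$ pN·nm; DSE prefactors 3000/s; cycle
rates $k_{np} = 100$, $k_{pn} = 3000$, $f_{attach} = 30$,
$d_{detach} = 1500$, $d_{PostR2} = 75$, $k_{ATP} = 2000$ (1/s); T/T
kinetics $k_{on} = 60$/µM/s, $k_{off} = 150$/s, $k_{open} = 120$/s,
$k_{close} = 60$/s.  The calibration targets were the prescribed ones:
half-activation of the $\gamma = 40$ force–pCa curve near pCa 6 (landed
at ≈ 6.2 — 0.3 µM must sit on the activated shoulder for spontaneous
oscillations to exist at that concentration), duty ratio of order 0.1 on
the activated branch (≈ 0.06 at 0.3 µM, ≈ 0.3 at 1 µM), detectable
reverse-stroke activity under both rate
laws, and relaxation to < 1% bound at diastolic calcium.  Physiological
realism is emergent, not per-constant: the T/T calcium affinity, for
example, is weaker than isolated troponin's because cooperative feedback
supplies the remaining sensitivity.

## Reproducibility and problem sizes

All randomness flows through R's session RNG: one `set.seed()` before a
run reproduces it bitwise (interval records, event logs, CSV outputs).
Counter-based per-molecule streams would allow reproducibility that is
additionally independent of molecule iteration order; since the iteration
order is fixed, the single stream delivers the same tested guarantee with
the idiomatic R mechanism.

The simulations in the test suite and the acceptance script are sized for
a single desktop core: force–pCa grids of 6–7 points at 0.8–1.5 s per
point with $N_F = 8$–16; twitches of 0.7–1 s; the chain at $N_F = 4$ for
3–5 s of simulated time.  These are the package's own choices of problem
size; the statistical checks (3-standard-error bounds, one-sided ordering
tests) are sized to be decisive at these ensembles.

## What the synthetic protocols do and do not show

The testbeds exercise the *numerics* (detailed balance, impulse matching,
stiffness consistency, the stability dichotomy, SPOC emergence) under the
calibrated molecular model.  They do not validate the molecular constants
against real myocardium: absolute tensions, ATP turnover rates and SPOC
periods depend on supplementary-material values this package replaces
with fallbacks.  Orderings and mechanisms (cooperativity steepening,
DSE/BSE contrasts, force–velocity monotonicity, the stability boundary
scaling) are the reproducible content.  The 3D ventricle, circulation
coupling, and electrophysiology are explicitly out of scope.

## Known limitations

* One-dimensional filament pair per half-sarcomere; no explicit 3D
  lattice, no lateral forces, no Langevin head dynamics.
* The T/T unit maps one-to-one to molecules; real stoichiometry (~1:7)
  and tropomyosin span are absorbed into the calibrated $\gamma$.
* The overlap tent and passive law are phenomenological stand-ins.
* The discretization resolves at most one transition per entity per
  micro-step; with the rate cap this biases branching probabilities by
  $O(r\Delta t)^2 \lesssim 10^{-3}$ per step, which the master-equation
  comparison bounds in practice.
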