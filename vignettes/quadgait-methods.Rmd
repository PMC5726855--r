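---
title: "Model and methods behind quadgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind quadgait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`quadgait` simulates the spinal circuitry coordinating the four limbs of a
quadruped. Each limb is governed by a rhythm generator (RG): a half-center
oscillator made of a flexor center (RG-F) and an extensor center (RG-E)
that inhibit each other through local inhibitory interneurons. Both centers
carry a slowly inactivating persistent sodium current (INaP), so each can
burst intrinsically; under the standard drive configuration the extensor
centers are driven into tonic activity and burst only because the flexor
centers rhythmically inhibit them — the flexor side dictates the tempo
(flexion-dominated asymmetry). Locomotor frequency therefore follows the
excitatory drive to the flexor centers.

Populations are non-spiking, activity-based units. Each population `i` has
an average membrane potential obeying

    C dV/dt = -INaP - IL - ISynE - ISynI - INoise    (RG centers)
    C dV/dt =       - IL - ISynE - ISynI - INoise    (all other populations)

with leak `IL = gL (V - EL)`, synaptic currents

    ISynE = gSynE { sum_j S(w_ji) f(V_j) + DE } (V - ESynE)
    ISynI = gSynI { sum_j S(-w_ji) f(V_j) + DI } (V - ESynI)

(`S` the half-rectifier, so each signed weight feeds exactly one
conductance), a piecewise-linear output `f(V)` rising from 0 at -50 mV to 1
at 0 mV, and INaP with instantaneous activation and slow inactivation
`tau_h(V) dh/dt = h_inf(V) - h` (time constant 80–160 ms). Every constant
is listed in `?cell_constants` and can be overridden.

Brainstem input is two drives. One is constant and excites the extensor
centers (`DE = 0.1`). The other scales with the free parameter `alpha` and
(i) excites the flexor centers (`DE = 0.1 alpha`), setting speed, and (ii)
inhibits the left-right-alternation-promoting commissural pathways: the
local V0D and V0V CINs and the descending diagonal V0D LPNs (`DI = 0.75
alpha` for V0D-class populations, `0.15 alpha` for local V0V). Increasing
`alpha` therefore simultaneously speeds the rhythm and tilts the balance of
commissural interactions from alternation (V0D, V0V) toward
synchronization (V3, CINi), which is what produces the walk → trot →
gallop → bound sequence. The V0V-diag LPNs receive no direct drive in the
default configuration — their speed dependence is inherited from their
V2a-diag input; because drive coefficients are per-population columns of
the network table, the alternative wiring is a one-line configuration
change rather than a code change.

The connectome (`build_intact_network()`) comprises four sections (fore /
hind × left / right): 15 populations per fore section, 13 per hind
section — the inhibitory long propriospinal neurons (Ini-Hom, V0D-diag)
project only cervical-to-lumbar and exist only in fore sections — and 84
directed weighted connections. This fore–hind asymmetry (no ascending
inhibitory LPNs, stronger lumbar-to-cervical excitation) is what selects
the lateral-sequence walk and the transverse gallop; the exact left-right
symmetry of the wiring is what makes 0.5 phase differences and mirrored
gallop pairs exact properties rather than approximations, and the test
suite asserts both.

## Numerical integration

The ODEs are integrated by a compiled adaptive Dormand–Prince 5(4) stepper
(relative and absolute tolerances 1e-8 by default). The analysis
observables — limit-cycle phases and periods — are insensitive to the
particular high-order adaptive method at these tolerances, and the test
suite cross-checks trajectories against an independent solver (`deSolve`)
and verifies that halving the tolerance moves phase differences by less
than 1e-3 of a cycle.

The noisy current is an Ornstein–Uhlenbeck process (time constant 10 ms)
discretized *exactly* on a fixed 1 ms grid: decay factor `exp(-dt/tau)`,
innovation sd `sigma sqrt(1 - exp(-2 dt/tau))`. Its stationary standard
deviation is exactly `sigma` and its autocorrelation `exp(-lag/tau)` —
the two properties the analyses rely on. The value is held constant within
each grid cell and the adaptive solver is stepped cell by cell, so it only
ever sees a smooth right-hand side and never straddles a noise
discontinuity. Draws come from R's RNG, so a seed fixes the entire
trajectory bit-for-bit. Baseline runs use `sigma = 0.005` pA — orders of
magnitude below every other current; it only nudges the system off
unstable invariant sets (e.g. the exactly symmetric manifold). The
variability experiments raise it to 1.75 pA.

Deleting a population clamps its output to zero inside the synaptic sums
while its state keeps being integrated; this reproduces "output set to
zero" semantics at no bookkeeping cost, and the deletion is exactly
reversible.

## Gait analysis

An RG is *in flexion* while its flexor-center output is at least 0.1
(crossings located by linear interpolation between the 1 ms samples, which
matters at 12 Hz where a cycle is ~80 samples). The locomotor period is
the interval between consecutive left-hind flexion onsets. Normalized
phase differences are delays between *extension* onsets of an RG pair
divided by the period, wrapped to [0, 1): hind left-right (RH−LH), fore
left-right (RF−LF), homolateral (LF−LH), diagonal (RF−LH). They are
circular quantities; all aggregation uses circular means and circular
standard deviations in cycle units.

Gaits are classified from per-cycle (or cycle-averaged) phase differences
by interval rules, closures exactly as printed in `?classify_gait`; walk
additionally requires extension longer than flexion. The regions are
pairwise disjoint away from their boundary points (verified against an
independent grid oracle in the tests); boundary ties are broken in the
order walk, trot, gallop, bound.

One subtlety is gait *chirality*. The interval rules reference one
specific diagonal pair (right fore − left hind). The model's gallop comes
in mirror-image pairs (left- and right-leading, both stable, selected by
initial conditions), and only one of them satisfies the printed diagonal
interval — the mirror branch has a diagonal value reflected outside
[0.25, 0.75]. `classify_gait_sym()` therefore classifies the observed
tuple first and, if unclassified, the left-right mirrored tuple built from
the mirrored RG pairs (RF−RH, LF−RH). This restores the invariance of
labels under left-right relabeling that the interval rules intend, without
altering any interval.

## Experiment protocols

**Bifurcation sweeps.** `alpha` is stepped across an equally spaced grid,
10 s (canonical, 1000 steps) per value, each step starting from the
previous final state; up, then down. A step is *accepted* as a stable
solution when the circular sd of each phase difference over the last five
cycles is below 0.001. Disagreement between up and down branches marks
bistability; discrete jumps (> 0.05 in any phase difference between
adjacent steps) trigger auxiliary opposite-direction runs from the
pre-jump state to uncover missed branches, which stop after merging with
the like-directed main branch. Independent repetitions from randomized
initial states (`n_seeds`, protocol default 3) are merged, because branch
selection at symmetry-breaking bifurcations is initial-condition
dependent.

*Coarse grids need longer steps.* With ~0.01-wide alpha steps a 10 s step
occasionally leaves a transitional state that still passes the
last-five-cycle sd check (we observed a spurious extra gait label this
way); at the canonical 0.00105 step the artifact is absent. The package
convention is therefore 20 s per step whenever a coarse (≲ 200-step) grid
is used — verified to agree with canonical fine-grid results — while the
canonical protocol keeps 10 s.

**Initial states.** Randomized initial conditions draw V uniformly from
[-65, -55] mV (spanning sub- and suprathreshold values around the leak
reversal) and h from [0.2, 0.8]; these ranges are a package choice,
configurable. At high drive (`alpha` ≳ 0.8) a non-oscillatory tonic state
coexists with the locomotor rhythm, and a cold random start can fall into
it; protocol code reaches high-drive attractors through an intermediate
trot state (settle at `alpha` = 0.5, then step), which mirrors how a real
preparation reaches high speeds by accelerating.

**Deletions, noise, transitions, robustness.** Deletion phenotyping sweeps
a lesioned network and reports the set of gaits expressed at accepted
steps. The variability experiment runs long fixed-drive simulations at
`sigma` = 1.75 pA and bins each cycle's fore and hind left-right phase
difference into three equal circular arcs — centered on 0.5
(trot-appropriate), 0.25/0.75 (quarter-off) and 0 (synchronized); the arcs
are equal thirds because only "three equally sized bins" is specified,
with no printed edges. Transition protocols settle 10 s, change the drive
(or switch on extra per-population drives) abruptly, and count the
post-change cycles until the gait label and instantaneous frequency (±5%)
are stationary. The robustness screen multiplies every weight by
independent N(1, sigma_p) draws (untruncated: at the sigma_p used a sign
flip has negligible probability) and reports the fraction of models whose
sweep no longer expresses some intact-network gait.

## Problem sizes used by the tests and the acceptance script

The shipped tests and `scripts/acceptance.R` run desk-scale versions of
the protocols: 100-step (band edges) and 50–60-step (deletions, robustness)
grids at 20 s per step, 100 s noise runs, two merged sweep repetitions,
and 6–8 perturbed models per robustness level; the canonical sizes
(1000-step grids, 10 s steps, three repetitions, 1000 s noise runs, 100
models) are available through the same functions' arguments. Coarse grids quantize band edges (about one grid step, i.e.
~0.01 in `alpha`, or 0.1–0.3 Hz at the band boundaries) and small model
counts give binomial noise on loss fractions; both are reported as the
sizes used, not hidden.

## What the model does and does not capture

The network is a central-interactions model: no limb or body mechanics,
no afferent feedback, no motoneuron or pattern-formation layers, no
synaptic kinetics or plasticity, and non-spiking population units. Passing
its battery therefore says that the *central* coupling structure suffices
for speed-dependent gait selection, hysteretic transitions, the deletion
phenotypes and the noise-driven coordination variability — not that these
phenomena are independent of biomechanics in vivo. Quantities tied to the
top of the drive range (bound band edges, the maximal frequency) are the
most sensitive to small parameter differences: the gallop→bound
bifurcation sits close to the upper end of the oscillatory range, so
small weight changes can push bound beyond it — visible in the robustness
screen, where the lost gait is typically bound.
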