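---
title: "Chaotic versus non-chaotic nodes in small-world neuronal networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaotic versus non-chaotic nodes in small-world neuronal networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hbihsync` asks how the dynamics of single neurons — chaotic or not —
shape what an electrically coupled network of them does: how it
synchronizes as the gap-junction conductance grows, how strongly its
global coherence fluctuates (metastability), and whether it visits a
repertoire of transiently stable synchronization patterns
(multi-stability, read off functional connectivity dynamics). This
vignette explains the model, every analysis stage, the choices made where
the design was genuinely open, and what the desk-scale test conditions do
and do not show.

## The single-neuron model

The node is a Huber–Braun cold-thermoreceptor neuron extended with a
hyperpolarization-activated cation current (`I_h`) — "HB + Ih". Five
state variables: membrane voltage $V$ and gating variables $a_r$ (fast
repolarizing K), $a_{sd}$ (slow persistent depolarizing Na/Ca), $a_{sr}$
(a calcium-like variable gating the slow repolarizing K(Ca) current) and
$a_h$. The voltage obeys

$$C_m \dot V = -(I_{sd} + I_{sr} + I_h + I_d + I_r + I_l) + I_{syn},$$

with ohmic currents $I_i = \rho(T)\, g_i a_i (V - E_i)$; the fast
depolarizing gate is instantaneous ($a_d = a_d^\infty(V)$), the leak gate
is 1, and the K(Ca) current gates through the Hill factor
$a_{sr}^2 / (a_{sr}^2 + 0.4^2)$. Gates relax as
$\dot a_i = \phi(T)(a_i^\infty(V) - a_i)/\tau_i$ with Boltzmann
steady-states; calcium follows
$\dot a_{sr} = \phi(T)(-\eta I_{sd} - \kappa a_{sr})/\tau_{sr}$, so
inward (negative) $I_{sd}$ raises $a_{sr}$. Temperature enters through
$\rho = 1.3^{(T-25)/10}$ (conductances) and $\phi = 3^{(T-25)/10}$
(kinetics); all runs use 36 °C. `hbih_params()` carries the full
reference constant set; `g_sd`, `g_sr` and `g_h` are the knobs that move
the neuron between subthreshold oscillation, tonic spiking, parabolic
bursting, spike skipping and chaos. Setting `g_h = 0` gives the NoIh
model — the dynamics reduce to four variables (the decoupled `a_h`
equation is contracting and does not feed back), and this plane contains
no chaos at all, which is what makes NoIh the clean non-chaotic control.

Units are mutually consistent: ms, mV, mS/cm², µA/cm², µF/cm², so
$\dot V$ is mV/ms. The model is fully deterministic; randomness enters
only through connectivity, parameter draws and initial conditions, all
seeded. Initial conditions are not critical (the transient is discarded):
the default is $V_0 = -60$ mV with gates at steady state and
$a_{sr} = 0.1$; networks jitter $V_0$ per node, uniformly in
(−70, −50) mV, to start desynchronized.

## Networks

Connectivity is Newman–Watts small-world: a ring of $N$ nodes each linked
to its $K$ nearest neighbours per side, plus — for each node, with
probability $p$ — one shortcut to a uniformly drawn non-neighbour (no
duplicates, no self-loops, no edges removed), then symmetrized. The
reference geometry is $N = 250$, $K = 5$, $p = 0.1$; the desk-scale
profile uses $N = 50$. Coupling is a uniform gap junction: the current
into node $k$ is $g \sum_l C_{kl} (V_l - V_k)$. The diffusive sign
matters — it pulls coupled voltages together, and over a symmetric
adjacency the coupling currents sum to zero at machine precision (tested
invariant). Topology seeds are controlled so all populations and all $g$
values see the same set of connectivity matrices.

## Integration

Fixed-step forward Euler with $dt = 0.025$ ms, the same scheme for single
neurons and networks (compiled). A 3–5 s transient is discarded; voltage
is stored at 1 ms resolution (1000 Hz), comfortably above the 50 Hz
analysis band. Euler at this step is adequate for this model: an
adaptive-step reference integration (deSolve's LSODA) reproduces the
firing rate within 2% on 30 s runs, and halving $dt$ moves spike times at
first order only — both are tests. Integration aborts with an explicit
diverged-simulation error if $|V|$ exceeds 500 mV.

## Quantifying chaos

The maximal Lyapunov exponent (MLE) is estimated on the full state space
(5 variables per neuron; $5N$ for networks) with the two-trajectory
renormalization scheme: a reference and a perturbed copy (separation
$d_0 = 10^{-6}$ in the unweighted Euclidean state norm) are integrated
together; every 1 ms the log expansion of their separation is recorded
and the perturbation is rescaled back to $d_0$; the MLE is the
time-normalized mean after discarding the first 10% of intervals. The
estimator is validated on closed-form and canonical systems: a linear
contraction returns −1.0 ± 0.01, and the Lorenz system (10, 28, 8/3)
matches a frozen long-run Benettin oracle (0.9049, computed with an
independent implementation at smaller step and 2000 time units) within
±0.02. Chaos is declared for MLE > 0 (strict); because the estimator at
20 s averaging scatters by a few 10⁻⁴ /ms around zero on periodic
orbits, scans additionally flag $|\mathrm{MLE}| \le 5\times10^{-4}$ /ms
as *uncertain*, and population sampling requires chaotic points to clear
that noise band while non-chaotic points must sit at MLE ≤ 0. The
convergence flag demands the running mean move < 5% over the last
quarter of the averaging window; near-zero exponents rarely satisfy a
relative criterion, so the flag is informative, not a gate.

## Firing patterns and bursts

Spikes are upward crossings of −20 mV (interpolated between samples,
2 ms refractory) — action potentials here overshoot 0 mV while
subthreshold oscillations stay below −40 mV. Spikes are grouped into
*events* riding the slow rhythm: consecutive spikes separated by less
than half the slow-oscillation period (spectral peak below 20 Hz of the
trace) join one event; the burst fraction $b_k$ is the fraction of a
neuron's events with ≥ 2 spikes, and MB is its network mean. The pattern
code (0 no oscillation, 1 subthreshold only, 2 skipping, 3 tonic, 4
bursting, 5 tonic 20–50 /s, 6 > 50 /s) is total and deterministic;
where the caption-style definitions leave residual cases (irregular,
non-skipping, non-bursting firing below 20 /s) they land on code 3. The
event-gap fraction (0.5), the skipping excess (cycles ≥ 1.2 × events)
and the burst-majority threshold (0.5) are explicit configuration, since
no published criteria exist for them.

## Phase, synchrony, metastability

Each voltage trace is zero-phase low-pass filtered (4th-order
Butterworth, 50 Hz, forward–backward) and transformed with a complex
Morlet continuous wavelet ($\omega_0 = 6$; 32 logarithmically spaced
scales covering 0.5–50 Hz). The *predominant frequency* of a node is the
scale with the largest time-averaged wavelet power (computed spectrally,
via Parseval, so only one inverse transform per node is needed), and the
instantaneous phase is the complex angle at that single scale — one
frequency per neuron, not a time-varying ridge. Half a wavelet support
(the e-folding time $\sqrt{2}s$ of the widest selected wavelet) is
trimmed from each end before any metric is computed.

Global synchrony is the Kuramoto order parameter
$R_t = |\langle e^{i\phi_k(t)}\rangle_N|$, summarized by its time mean
$R$; metastability is $\chi = \mathrm{var}(R_t)$ (population variance —
dividing by the sample count makes $\chi$ independent of the sampling
rate). $\chi \le 1/4$ always; for $N$ independent uniform phases
$E[R_t] = \sqrt{\pi}/(2\sqrt{N})$, the finite-size incoherence baseline
used in tests.

## Functional connectivity dynamics

FC windows are 2 s wide with 90% overlap (200 ms stride; a 30 s series
gives exactly 141 windows). Within a window,
$FC_{kl} = \langle |(e^{i\phi_k} + e^{i\phi_l})/2| \rangle_t$ — the
two-oscillator order parameter, equal to the time average of
$|\cos((\phi_k-\phi_l)/2)|$: 1 for locked pairs, 0 for antiphase,
$|\cos(\delta/2)|$ for a constant lag $\delta$. Each FC is vectorized
from its lower triangle excluding the diagonal and the first
sub-diagonal; the FCD matrix is the Pearson correlation between all
window pairs. Fully synchronized windows have constant FC vectors and no
defined correlation: two constant equal vectors are assigned 1 (matching
the frozen-synchrony regime, which is reported as an all-1 FCD), a
constant against a varying vector 0, and such windows carry a
degeneracy flag. The multi-stability measure is the variance of FCD
entries with $|i-j|$ beyond an exclusion band; the default band (9
off-diagonals at 2 s / 90%) is exactly the set of window pairs that
overlap in time and are therefore trivially correlated. Both the
sub-diagonal exclusion and the band are configurable.

## Surrogate fixtures

Every analysis stage is testable without ODE runs through seeded
surrogates with closed-form truth: `locked` ($R=1$, $\chi=0$, FCD all
1), `independent` (i.i.d. uniform phases per sample — every time point a
fresh incoherent draw; $E[R_t]=\sqrt{\pi}/(2\sqrt{N})$, off-diagonal FCD
≈ 0), `constant_lag` ($FC_{kl}=|\cos(\mathrm{lag}(k-l)/2)|$ exactly),
`block_switching` (two phase-offset patterns alternating per block; with
windows aligned to blocks the FCD takes values 1 and $c$ and its
off-band variance is $q(1-q)(1-c)^2$), plus voltage-level `spike_train`
and `subthreshold` fixtures amplitude-matched to the neuron (−90 to +40
mV) so detector thresholds transfer. Surrogates do not emulate chaotic
dynamics — chaos validation uses real ODE systems (Lorenz, the neuron
itself).

## Populations with matched firing-rate distributions

To compare chaotic against non-chaotic nodes at equal functional
heterogeneity, parameter pairs are drawn from the scanned
$(g_{sd}, g_{sr})$ plane so that the three populations — chaotic
(MLE above the noise band, $g_h=0.4$), non-chaotic (MLE ≤ 0, $g_h=0.4$)
and NoIh ($g_h=0$) — share the firing-rate *distribution* in the
3.0–4.5 spikes/s band: the band is cut into 0.1 Hz bins and the same
number of parameter pairs is drawn from each region per bin, verified by
pairwise Kolmogorov–Smirnov tests.

The shipped scan rectangle is $g_{sd} \in [0.15, 0.36]$,
$g_{sr} \in [0.24, 0.40]$ (our own MLE map; the desk profile steps it at
0.005). One genuine feature of this plane deserves note: the non-chaotic
firing rate moves in mode-locked plateaus, and certain rates
(≈ 3.45–3.75 and 4.0–4.25 spikes/s) occur *only* inside chaotic
transition zones. Strictly requiring every 0.1 Hz bin to be populated in
all three regions therefore fails structurally, independent of grid
density. The sampler keeps that strict behaviour as its default error,
and offers `drop_empty_bins = TRUE` — used by the shipped pipeline — in
which a bin that cannot be filled in every region contributes zero draws
to *all* populations: per-bin counts remain exactly equal (the matching
invariant) and all three populations simply skip those rates.

## The sweep

For each population, coupling value and realization seed, the pipeline
builds the network (topology seed shared across populations and $g$),
simulates, extracts phases and reports $R$, $\chi$, the network MLE, the
FCD variance and MB; aggregation is across seeds only (mean, SD, SEM),
never across time. Per-run rows are written as small CSVs, so
interrupted sweeps resume without recomputation. The desk profile —
what the tests and the acceptance script run — uses $N = 50$, 3 seeds,
20 s recordings, 20 s Lyapunov averaging and a 7-point $g$ ladder from
$10^{-4}$ to 1; the `paper` profile ($N = 250$, 10–20 seeds, 30 s
recordings, the full 26-point grid) is the overnight configuration of
`analysis/01`–`04`.

## What the desk-scale conditions show — and what they do not

The desk profile reproduces the qualitative physics: the rise of $R$
from the finite-size incoherence baseline to > 0.95 across the $g$
sweep, the metastability peak at intermediate coupling, the FCD-variance
(multi-stability) maximum at intermediate coupling, chaos confined to
the $g_h > 0$ plane, and matched-rate populations with KS $p > 0.05$.
It does not resolve fine distinctions that need $N = 250$ and 10–20
seeds — e.g. the precise ordering of chaotic vs non-chaotic transition
steepness, the burst-fraction rebound near $g \approx 0.043$, or
SEM-scale differences between FCD-variance curves; those belong to the
`paper` profile. Surrogate-based tests validate the analysis chain
exactly but say nothing about the ODE dynamics; the ODE-based tests
cover that side.

## Numerical choices, in one place

dt = 0.025 ms; trace sampling 1000 Hz; spike threshold −20 mV,
refractory 2 ms; transient 3000–5000 ms; MLE: $d_0=10^{-6}$, renorm 1 ms,
10% discard, noise band 5×10⁻⁴ /ms; wavelet: $\omega_0=6$, 32 scales,
0.5–50 Hz, e-folding edge trim; FC: 2 s / 90%; FCD: exclude first
sub-diagonal in vectorization, 9-off-diagonal band in the variance;
degenerate-window correlation 1 (equal constants) / 0 (otherwise);
event gap 0.5 × slow period; burst majority 0.5; skipping excess 20%;
tonic bands 20–50 and > 50 spikes/s. All are function arguments; none is
hard-wired.
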