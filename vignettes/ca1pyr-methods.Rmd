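---
title: "ca1pyr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ca1pyr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ca1pyr` is a desk-scale workflow for comparative conductance-based
modelling of mouse and rat hippocampal CA1 pyramidal neurons. It covers the
full chain from ion-channel kinetics to population-level analysis: a
branched-cable simulator with a declarative channel library, species presets
whose main difference is a slower mouse h-current and a thinner mouse
morphology, electrophysiological feature extraction, a two-stage fitting
pipeline (h-current + passive prefit, then feature-driven evolutionary
optimization with the sd &lt; 3 acceptance rule), parameter-degeneracy
analysis (normalized heatmaps, PCA species clustering), and theta/gamma
synaptic-drive experiments scored through inverse-ISI distributions and the
sharp-wave-ripple (SWR, 150–250 Hz) band. A synthetic-data module generates
every input the pipeline needs, so nothing is downloaded and every result in
the test suite is recomputed from code.

This vignette records the scientific and numerical decisions a maintainer
would want to know. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Channel kinetics

Gates follow one of four declarative forms; a channel is a product of gates
with integer powers times an ohmic driving force.

The **Borg–Graham form** is the thermodynamic gating model in which voltage
sensitivity enters through effective gating charges:

$$x_\infty(v) = \frac{1}{1 + e^{k\,\zeta_l\,(v - V_{l,1/2})}},\qquad
\tau(v) = \frac{e^{k\,\zeta_t\,\gamma\,(v - V_{t,1/2})}}
               {q\,a_0\,\bigl(1 + e^{k\,\zeta_t\,(v - V_{t,1/2})}\bigr)},$$

with $k = F/RT$ fixed at 0.0378/mV (33 °C, the recording temperature),
$\gamma$ the asymmetry factor (`gmt`), $a_0$ the rate scale (`a0t`, 1/ms)
and $q$ a lumped temperature factor (default 1; no q10 machinery beyond this
scalar). A positive $\zeta_l$ gives activation by hyperpolarization — the
h-current convention.

The h-current is the only channel with species-specific kinetics; both
parameter sets ship with the package (`ih_params()`, `make_ih_preset()`) and
are pinned bit-exactly by tests. The auxiliary parameter `clk` (0.24 mouse,
1 rat) is stored and reported but **inert by default**: its kinetic role is
not documented in the source model. The package offers
`clk_mode = "multiply_a0t"`, under which the effective rate scale is
$a_0\,\mathrm{clk}$; this is the only reading consistent with the reported
~4-fold mouse slowdown ($1/0.24 \approx 4.2$), and under it the mouse curve
is slower than the rat curve at every voltage. With `clk` inert the species
ordering holds overall but not pointwise (the rat curve peaks at its own
midpoint, −64.1 mV). The tests assert the pointwise ordering only under the
multiplicative reading.

The remaining twelve channels (Nax/Na3, KDR, KA proximal/distal, KM, KD,
three Ca²⁺ channels, two Ca²⁺-dependent K⁺ channels) are **not printed in
the source study** (they are cited to the prior rat CA1 literature), so the
package ships a plausible CA1 family in JSON
(`inst/extdata/channels/default_*.json`), editable without code changes.
Calibration choices made once during development, and their reasons:

* Na activation midpoints −35 mV (soma/dendrite) and −38 mV (axon); with
  midpoints at −30 mV the full cell found a stable subthreshold fixed point
  near −49 mV after its first spike and never fired again.
* Slow K⁺ currents (KM, KD) use a small asymmetry factor (`gmt` ≈ 0.1) so
  their activation time constant stays tens of milliseconds at depolarized
  voltages. With a symmetric choice they activated fully during each ~2 ms
  action potential and silenced the cell for hundreds of milliseconds — an
  accommodation artifact, not adaptation.
* KDR rate scale and Na inactivation-recovery speed are set so the somatic
  action potential is ≈ 2.4 ms wide at the −20 mV measurement level and
  doublets can reach the 150–250 Hz band; the first calibration pass left
  the minimum inter-spike interval at ≈ 6.8 ms, capping instantaneous rates
  just *below* the SWR band.
* The calcium pool (single-exponential extrusion, 100 ms) uses a
  current-to-concentration gain of 0.01 mM/(mA cm⁻² ms), keeping per-spike
  transients in the low-micromolar range; a 10× larger gain made the
  SK-type current (Hill function of calcium, n = 2, K½ = 1 µM) latch for
  ~100 ms after each spike.
* Somatic BK density is high (4e-3 S/cm2): its fast, voltage-shifted
  calcium-dependent AHP suppresses doublets under somatic current steps, so
  DC trains are regular and their ISI features are well-posed fitting
  targets, while large synchronous synaptic volleys still force doublets in
  the 150-250 Hz band. Without it the recalibrated cell fired burst-pause
  patterns under DC whose ISI-sequence features were effectively chaotic in
  the conductances.
* Calcium channels are ohmic with a fixed +120 mV reversal (no GHK); KCa is
  voltage-independent; the BK-type gate's calcium affinity shifts e-fold per
  30 mV.

## 2. Morphology and species presets

Reduced morphologies are section trees (soma, axon, tapering apical trunk,
obliques at stated path offsets, basal sections) discretized into an odd
number of compartments per section with a 20 µm default bound. Path
distances run from the soma centre to the compartment midpoint; the soma
contributes zero length. The species presets encode the documented trends:
the rat trunk is thicker at every distance (3.5→1.0 µm over 450 µm vs
2.2→0.6 over 350), the rat has more total dendrite, and the synapse-bearing
obliques are 0.75 µm (mouse) vs 1.1 µm (rat). The oblique contrast is wider
than the trunk contrast alone would suggest; it was widened deliberately
because with near-equal oblique diameters the rat preset burst at mouse
levels under synchronous drive, contrary to the modelled species difference.
Passive densities (5e-5 vs 1.1e-4 S/cm²) were chosen so the somatic input
resistance contrast is ~3-fold (≈ 200 vs ≈ 65 MΩ), matching the reported
species gap.

SWC files are supported with the standard type mapping; apical trunk vs
oblique, which SWC does not distinguish, is labelled by the
maximal-diameter path from the apical root — consistent with synapses
targeting the *thinner* apical dendrites. Graded channels follow
distance-dependent rules: Ih and distal KA increase linearly ~6-fold over
350 µm, KD rises sigmoidally; all bases and slopes are plain data.

## 3. Simulator numerics

The integrator (C++) advances gates by the exponential update
$x \leftarrow x_\infty + (x - x_\infty)e^{-\Delta t/\tau}$ at the current
voltage, then solves the voltage system implicitly with a
$\theta$-scheme ($\theta = 1/2$, Crank–Nicolson, default;
$\theta = 1$, implicit Euler, available) using tree-ordered Gaussian
elimination (one child-to-parent sweep, one parent-to-child sweep;
compartments are ordered parent-before-child by the assembler). Voltage
dependence of every gate is pre-tabulated on a 0.05 mV grid from −150 to
60 mV, storing $x_\infty$ and the per-step decay factor directly;
calcium-dependent gates are evaluated directly each step. Synapses are
peak-normalized double-exponential conductances advanced by exact decay
with event insertion at spike times, so a lone spike of weight $w$ reaches
peak conductance exactly $w$ at
$t_p = \frac{\tau_1\tau_2}{\tau_2-\tau_1}\ln\frac{\tau_2}{\tau_1}$.

Verified properties (all in the test suite): the passive RC closed form to
within 0.5% at dt = 0.025 ms; observed temporal convergence order ≥ 1.8 on
that benchmark; steady-state attenuation along a uniform passive cable
within 2% of $e^{-x/\lambda}$ for $x \le 2\lambda$; spatial refinement
(20 → 10 µm) changes the somatic subthreshold trace by < 1% RMS; a cell
initialized at its resting fixed point drifts < 0.01 mV over a second.
Default dt is 0.025 ms and v_init −70 mV; simulations settle unrecorded
before t = 0 (500 ms default; 4 s when a true fixed point is needed).
Instability (non-finite or |v| > 1000 mV) aborts with a diagnostic rather
than returning garbage.

## 4. Feature extraction

Conventions follow the measurement tool used for the recordings this
package emulates: spike threshold −20 mV (one spike per contiguous
suprathreshold window, timed at the window's peak); AP width measured
between interpolated threshold crossings around the peak; sag = steady
state minus stimulus minimum (clamped ≥ 0); steady state averaged over the
final 10% of the stimulus (the averaging window is not stated at source;
10% is this package's pin); membrane time constant fitted from onset to the
voltage minimum, capped at 100 ms, to avoid sag contamination; input
resistance from the smallest-magnitude negative injection; adaptation index
as the mean of $(\mathrm{ISI}_{i+1}-\mathrm{ISI}_i)/(\mathrm{ISI}_{i+1}+\mathrm{ISI}_i)$
(the symmetric variant, pinned). Spike-dependent features are *absent*
(`NA`), never zero, when no spike qualifies. Because the reference
feature-extraction library is not available offline, the cross-check oracle
is an independent naive-loop implementation in the test helpers; the
package and oracle agree to 1e-6 relative on a 20-trace synthetic panel.

Group statistics mirror the source conventions: per-species OLS slope of
the mean feature versus injected current; per-amplitude two-sample test
(Student t when both groups pass Shapiro at α = 0.05, Mann–Whitney
otherwise); no multiple-testing correction.

## 5. Two-stage fitting

**Stage 1** (`prefit_ih`) fits the six Borg–Graham Ih parameters plus the
Ih peak conductance and passive properties (C, g_leak, E_leak) of an
isopotential cell to all hyperpolarizing traces simultaneously, by
box-constrained quasi-Newton least squares (multi-start: the literature
kinetics plus two perturbed starts). It reports the RMS pointwise voltage
error; the workflow's quality bar is 0.3 mV. On synthetic traces with
0.1 mV noise the fit reaches the noise floor and recovers the half-activation
voltage to well under 1 mV (acceptance criterion 2).

**Stage 2** (`run_evolution`) is an elitist non-dominated-sorting GA with
crowding over log10-scaled conductances: log-uniform initialization, binary
tournaments, SBX crossover, polynomial mutation. Objectives are per-feature
z-scores $|f_\mathrm{model} - f_\mathrm{target}|/\sigma_f$; a missing
feature where the target expects one scores the documented penalty 250; an
individual with all z < 3 is acceptable, and `select_and_accept` returns
the 10 lowest-aggregate individuals (aggregate = max z, ties by sum of z,
then seed-stable archive order). Two pragmatic deviations from textbook
NSGA-II, both forced by the desk budget (population 16, 10 generations,
~26 objectives): within equal Pareto ranks — and with this many objectives
almost everything is rank 1 — tournaments and environmental selection break
ties on the aggregate score before crowding; and the optional
`init_jitter_sd` initializes the population around the log-space bounds
centre at the synthetic study's cell-to-cell variability scale (0.15
log10), mirroring how the original workflow constrains ranges with
preliminary simulations. With log-uniform initialization the desk budget
stalls around max z ≈ 5; with the informative start it reaches max z < 3
(the acceptance criterion asserts only the < 3 rule, not a specific value).
The self-consistency study that exercises this pipeline jitters exactly the
eight conductances the GA searches (the rest of the cell template stays at
preset values), so the target-generating cell lies inside the searched
subspace — the standard construction for a well-posed recovery experiment.
When instead every regional conductance is jittered while only eight are
searched, the jittered cell's irregular burst-pause ISI sequences can be
unreachable from the 8-parameter subspace at the desk budget.
Recovered *parameters* are deliberately not compared with the generator's:
distinct conductance combinations reproducing the same features is the
degeneracy phenomenon under study.

Target σ values are not recoverable from the source at desk scale, so the
synthetic studies fix realistic ones: 1 mV for voltage features (2 mV for
the base), 1 spike for counts, 10% with a 5 ms floor for spike times, 10%
with a 2 Hz floor for inverse ISIs.

## 6. Degeneracy and PCA

The heatmap matrix normalizes each parameter row to its maximum over all
individuals (columns grouped by cell, provenance kept in the column names)
and orders rows by descending mean — the same presentation as the source's
ensemble figure. PCA runs on pooled individuals after per-parameter
standardization (the package's pin; max-normalization is offered as an
alternative since the source does not state its scaling), on log10
parameters in the shipped analyses. Species separation on a component is
reported as range overlap plus a standardized mean difference, with
`separated = TRUE` only at zero overlap — a deliberately strict reading of
"clearly separates".

The ensemble generator draws log-normal parameters around the preset means
(σ = 0.15 log10) for 100 mouse and 130 rat individuals (10 and 13 cells ×
10 best individuals). Four parameters — dendritic Na, axonal KDR, somatic
KA, and the calcium-dependent K current, the channels highlighted by the
source's loadings — differ in mean by 4σ. The shift was calibrated once to
the prescribed Monte-Carlo property (zero PC1 overlap in ≥ 95% of seeds
with the shift, ≤ 5% without): a 3σ shift, plausible in a ~20-parameter
space, leaves visible overlap in this package's ~30-parameter space.

## 7. Synaptic regimes and the SWR band

In vivo-like drive uses 80 AMPA synapses (0.25 nS, double-exponential
0.5/3 ms, reversal 0 mV) placed randomly on dendrites thinner than 1.0 µm
(mouse) or 1.2 µm (rat) within 330/360 µm of the soma, activated as
homogeneous Poisson trains at 8–80 Hz, synchronously (one train replicated)
or asynchronously (independent trains), or as theta-paced bursts of gamma
spikes. Output spikes use the −20 mV convention; the analysis is the
inverse-ISI distribution (10 Hz bins over 0–300 Hz; the overflow lands in
the final bin so counts always total the ISI count) and the fraction of
instantaneous frequencies inside 150–250 Hz. Bursts (consecutive ISIs <
10 ms) are reported descriptively; no formal bimodality test is attempted,
since the comparison at source is made on histograms. The directional
claims — mouse band fraction positive and above the rat's under synchronous
gamma drive, and a 3× synaptic weight restoring the high-frequency
component in the rat — are asserted at fixed seed in the acceptance suite.

## 8. What the synthetic world does and does not establish

The generators emulate the *structure* of the experimental data — 20 mouse
and 53 rat cells, 6 positive (0.15–0.65 nA) and 4 negative (−0.05…−0.2 nA)
injections per cell, log-normal cell-to-cell conductance variability
(σ = 0.1 log10), 0.2 mV additive Gaussian recording noise — not its
empirical content. A green test therefore establishes that the machinery
(simulation, feature extraction, fitting, PCA, regime analysis) behaves as
specified on data with realistic structure; it does not reproduce the
experimental population statistics (feature-trend slopes, Fig-level spike
counts), which require the deposited recordings. The trend/statistics
machinery is exercised on synthetic data only.

## 9. Known limitations

* Non-Ih kinetics are a calibrated stand-in family, not the unpublished
  originals; all are swappable via the JSON library.
* No GHK calcium formalism, no NMDA/GABA synapses, no stochastic gating,
  no variable-step integration, no network context.
* The clk parameter's kinetic role remains unverifiable from the source;
  both conventions are implemented and only the multiplicative one
  reproduces the reported slowdown factor.
* Axial resistivity (150 Ω cm) and capacitance (1 µF/cm²) are fixed
  defaults exposed as parameters, not fitted per cell.
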