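---
title: "Noise-assisted pacemaking in sinoatrial-node cells: models and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-assisted pacemaking in sinoatrial-node cells: models and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sansr)
```

# The scientific problem

Sinoatrial-node (SAN) pacemaker cells are heterogeneous: alongside robustly
firing "classical" pacemakers, SAN tissue contains slowly or irregularly
firing cells and a large population of *dormant* cells that fire no action
potentials (APs) at all but show subthreshold oscillations of membrane
potential (V~m~) and intracellular Ca. Because the tissue is also pervaded by
local, noisy Ca signaling and other biological noise sources, a natural
hypothesis is that pacemaker cells exploit **stochastic resonance**: an
injected (or naturally occurring) zero-mean noise current can lift
subthreshold oscillations over the AP threshold, converting silent or
dysrhythmic cells into rhythmically firing ones, with the benefit peaking at
an intermediate noise intensity and collapsing when the noise is extreme.

`sansr` provides the computational toolkit for studying this hypothesis:

1. a **common-pool coupled-clock cell model** (membrane "M clock" of voltage
   gated currents coupled to an SR-based Ca "C clock") with carbachol
   modulation and arbitrary current injection;
2. **stimulus protocols**: sine waves parameterized by one-direction
   amplitude *a* and frequency *F*, and band-limited zero-mean white noise;
3. **AP metrics**: detection, rate, CV = SD/mean, population classes,
   one-to-one capture (resonance spectra) and burst flags;
4. a **two-parameter firing diagram** over the L-type Ca conductance g~CaL~
   and the SR Ca pumping rate P~up~;
5. a **2-D coupled tissue model** showing noise rescue of sinus arrest;
6. **Ca-imaging analysis**: PCA subtraction of the global AP-induced Ca
   transient (APCT), local Ca release (LCR) detection with path-area sizing,
   L-moment tail statistics, mean-excess curves, and subthreshold
   V~m~--Ca cross-correlation;
7. seeded **synthetic-data generators** for every stage, so the full
   pipeline is testable without any experimental download.

# The cell model

## Structure

The model is a deterministic ODE system of the classical "common-pool"
coupled-clock type for rabbit SAN cells, in the Kurata/Maltsev--Lakatta
lineage. The membrane clock comprises I~CaL~, I~CaT~, I~Kr~, I~Ks~, I~to~,
I~sus~, I~f~, I~st~, I~bNa~, I~NaK~, I~NCX~ and (under cholinergic
stimulation) I~KACh~. The Ca clock comprises SERCA uptake into the network
SR (maximal rate P~up~, Michaelis constant K~up~), diffusional transfer to
the junctional SR, load-dependent RyR release (a four-state
resting/open/inactivated scheme whose opening rate increases with junctional
SR load) into a submembrane shell, diffusion into the bulk cytosol, and
Ca buffering by calmodulin, troponin (Ca and Ca--Mg sites) and
calsequestrin. The two clocks couple through submembrane Ca: release
activates inward I~NCX~ (accelerating diastolic depolarization) and
Ca-dependent inactivation of I~CaL~.

The rate equations and constants are a reconstruction of that published
lineage, assembled and then *calibrated as one versioned parameter set*
(`inst/extdata/basal_params.json`) so that the model reproduces the
qualitative surface this package is about:

* basal parameters (g~CaL~ = 0.464 nS/pF, P~up~ = 12 mM/s) fire rhythmically
  at ~2.5 Hz with CV < 0.05;
* at g~CaL~ = 0.37 nS/pF the firing boundary sits near P~up~ ≈ 7.5 mM/s, so
  most of the tissue-model range P~up~ ∈ (0, 9.5) mM/s is dormant;
* with the SR pump off (P~up~ = 0) the cell is dormant over almost the whole
  g~CaL~ axis of the firing diagram -- firing requires the Ca clock;
* dormant models show subthreshold V~m~ oscillations of a few mV around
  −40 to −25 mV, the substrate that noise can amplify.

Exact reproduction of any particular published trace is *not* a goal and not
claimed; the acceptance surface is qualitative and regression-style. Two
calibration choices deserve an explicit note. The apparent I~CaL~ reversal
potential is set to +40 mV, which compresses AP overshoot just enough that
full APs (overshoot > 0 mV) separate cleanly from subthreshold oscillations
(peaks below 0 mV); and the NCX scale factor k~NCX~ uses the classical
single-exponential NCX formulation with the scale chosen to give diastolic
I~NCX~ of order −1 pA/pF. The model's SR concentrations run higher than in
some published variants (tens of mM free Ca in the SR compartments at full
pump rate); this is a known idiosyncrasy of the calibration, it does not
affect the dimensionless behavior the package studies, and total Ca is
exactly conserved in closed-cell tests.

## Numerics

The canonical integrator is fixed-step and explicit, so stochastic forcing
is well defined and runs are bit-reproducible: forward Euler for V~m~,
concentrations, RyR states and buffers, and Rush--Larsen exponential
relaxation for all gating variables (which keeps gates in [0, 1]
unconditionally). Default dt = 0.01 ms; halving it changes the basal firing
rate by well under 0.5 %. Voltage-dependent gating functions are tabulated
on a 0.05 mV grid and interpolated linearly inside the integrator;
`derivatives()` always evaluates the exact expressions and is the reference
in tests (an independent stiff solver cross-check is included). On the rare
steps where Euler would drive a Ca concentration negative -- this happens
only under extreme injected currents, far outside the physiological
protocols -- the Ca subsystem falls back to a positivity-preserving
semi-implicit (Patankar-type) update. Non-finite or out-of-range V~m~
aborts with the offending time rather than silently clipping.

The shipped initial state is a settled late-diastolic state of the basal
model (frozen after 38 s of integration). Because it is a *firing-cell*
state, the first simulated cycle can produce one AP even in dormant-zone
parameter sets; all metrics therefore discard a 5 s transient by default, a
convention used consistently in tests.

# Protocols and AP metrics

Sine stimuli are `a * sin(2*pi*F*t)` with *a* the one-direction (peak)
amplitude -- peak-to-peak 2*a*. The convention is isolated in
`sine_segment()` so the alternative reading is a one-line change. Noise is
uniform sample-and-hold: every `hold` ms (default 1 ms) a new value is drawn
uniformly from [−a, a]. This gives bounded amplitude matching the pA
amplitude language of experimental protocols, zero mean, SD a/√3, and a
flat spectrum far beyond the < 6 Hz resonance band of these cells. Gaussian
noise would differ mainly in its unbounded tails; the uniform choice makes
"amplitude" exact. Standard protocols: a noise run (quiet 10 s, noise
10 s, quiet tail), a sine sweep over 0.5--6 Hz (0.25 Hz steps optional),
and the amplitude series 10/20/25/50 pA (sine) and 25/31.25/62.5/125 pA
(noise).

AP detection is an upward crossing of −20 mV with an 80 ms refractory
period, plus two morphology gates chosen from the model's own AP waveform:
the excursion must reach a peak above 0 mV (true SAN APs overshoot; the
model's subthreshold oscillations peak below −5 mV) and must stay above
threshold for at least 40 ms (the model's AP duration at −20 mV is 70--95 ms,
while noise-driven crossings at extreme amplitudes last only 2--10 ms). All
four settings are configuration keys. Mean frequency is the mean of
per-beat instantaneous frequencies and CV = SD/mean of those frequencies
(interval-based CV is available); classes follow the standard bands
(fast > 2.5 Hz, moderate 1--2.5 Hz, slow < 1 Hz, dormant = none).
One-to-one capture requires the mean frequency within ±0.1 Hz of the
stimulus frequency with at least two APs, evaluated after a 2 s settle
(capture occurs within one or two cycles in practice). The capture window
regularity beyond the mean-frequency criterion is deliberately not
constrained.

# The firing diagram and its noise expansion

`build_grid()` constructs exact inclusive grids: the full-resolution axes
are g~CaL~ from 0.28 to 0.52 nS/pF in 0.0025 steps (97 values) and P~up~
from 0 to 12 mM/s in 0.2 steps (61 values) -- 5,917 models per condition and
23,668 over the four conditions (basal/carbachol, with/without 25 pA
noise). The desk-scale default used by tests and the acceptance script is a
13 × 9 reduced grid spanning the same ranges with 15--20 s per model; the
full sweep is a function argument away but takes hours of CPU, which is why
the reduced grid is the shipped default. Every grid point gets an
independent, reproducible sub-seed from a deterministic hash of (master
seed, indices, condition), so single points can be re-run in isolation.
Adding 25 pA noise strictly shrinks the non-firing (dormant) region in both
basal and carbachol conditions; `diagram_delta()` quantifies the awakened
count.

# Carbachol

Carbachol effects are modeled as three Hill-type dose--response curves with
a shared EC50 (250 nM) and Hill coefficient 1.5: I~KACh~ conductance up (to
0.0084 nS/pF at saturation), g~CaL~ down (to −40 %), P~up~ down (to −30 %),
plus a −7.8 mV shift of I~f~ activation. The published record does not print
the dose--response formulas used in its modeling supplement, so these
defaults are configurable stand-ins calibrated to a simple specification:
monotone slowing with dose, with 100 nM a mild slowing, ~0.2 Hz residual
firing at 300 nM, and dormancy at 1000 nM of the basal model. All constants
are arguments of `apply_carbachol()`.

# The tissue model

`tissue_config()` describes a rectangular lattice (default 15 × 15) of
coupled-clock cells sharing g~CaL~ = 0.37 nS/pF, with per-cell P~up~ drawn
i.i.d. uniformly from (0, 9.5) mM/s -- at the calibrated single-cell
boundary (~7.5 mM/s) this leaves roughly 80 % of cells intrinsically
dormant. Cells couple by nearest-neighbour gap junctions (no-flux
boundaries); the conductance default g~gap~ = 2 nS is a calibrated value
(the literature value for this preparation is not printed) chosen so that
the electrotonic load of the dormant majority suppresses the firing
minority. Per-cell noise streams are independent, since biological noise
sources are local.

Without noise the lattice fires one or two synchronized beats (driven by
the Ca-loaded initial state) and then collapses into tissue-wide
quiescence -- sinus arrest -- within about a second; the arrest is robust
across P~up~ draws and coupling strengths 0.5--4 nS. With independent
100 pA per-cell noise the same lattice keeps firing for the whole run in
every seed tested. The calibrated rescue amplitude of 100 pA sits inside
the experimentally motivated 25--125 pA series; weaker noise (50 pA)
rescues only marginally at g~gap~ = 2 nS. `detect_arrest()` diagnoses
arrest as the last AP anywhere in the lattice followed by ≥ 2 s of
tissue-wide silence. The tissue integrator uses dt = 0.02 ms by default --
the arrest/rescue contrast is insensitive to halving it, and per-cell rates
shift by only a few percent.

# Ca-imaging analysis

`normalize_movie()` computes per-pixel ΔF/F0 against a 10th-percentile
baseline. `subtract_global_component()` computes the leading principal
component of the pixel × time matrix -- for SAN movies this is the global
APCT flash, one spatial gain map times one periodic time course -- and
returns the rank-1 reconstruction and the residual. One component is
subtracted by default; the count is an argument. The published denoising
step (a penalized matrix-decomposition pipeline) is *not* reimplemented:
the separation result depends on the PCA subtraction, and the residual-based
detector below tolerates the extra pixel noise.

`detect_lcrs()` centers each pixel's residual time course at its median,
thresholds at `k_mad` (default 3) times the per-pixel median absolute
deviation, labels 26-connected components in (x, y, t), filters by minimum
footprint (4 px²) and duration (2 frames), and sizes each event by its
**path area** -- the area of the component's 2-D spatial projection, i.e.
the full territory swept as the release propagates, so a travelling wave
scores its whole path rather than its instantaneous width. Coordinates are
0-based pixels, areas are reported in px² and µm². The threshold,
connectivity and size defaults are configuration keys; the published
pipeline's exact settings are not printed in the main text.

Tail statistics use unbiased sample L-moments: `l_kurtosis()` returns
τ₄ = λ₄/λ₂ (0 for uniform, 1/6 for exponential samples -- both used as
closed-form test oracles), and `mean_excess_curve()` returns
e(u) = E[X − u | X > u], flat for exponential tails and increasing with
slope ξ/(1 − ξ) for generalized-Pareto tails (shape ξ > 0). Points with
fewer than 10 exceedances are reported as undefined. Reproducing the
experimental τ₄ values requires the deposited recordings and is explicitly
out of scope.

`vm_ca_crosscorr()` linearly detrends both traces over a window and
computes the normalized cross-correlation (positive lag = Ca follows V~m~).
With `subthreshold = TRUE` it refuses windows extending past the first AP:
once APs occur, each AP is strictly paired with its Ca transient and the
correlation is high regardless of subthreshold coupling -- the synthetic
generator includes an inserted-AP mode that demonstrates exactly this
failure mode.

# Synthetic data: what it does and does not emulate

`synth_movie()` builds baseline + rank-1 global APCT + three local event
patterns + i.i.d. Gaussian noise, with a truth table of every insertion.
The patterns follow the qualitative descriptions of SAN background signals:
cell-width waves propagating at 50--150 µm/s along a cell axis, compact
LCRs lasting 2--6 frames with lognormal (or generalized-Pareto) footprint
areas, and cell-sized AP-like flashes with APCT kinetics but incoherent
timing. Event amplitudes default to the APCT amplitude (background signals
are comparable in magnitude to the global transient). The defaults
(200 frames of 64 × 64 px at 10 ms/frame, 25 LCRs + 4 waves + 3 flashes,
peak SNR 20) represent a sparsely active field; detector validation holds
precision and recall ≥ 0.9 down to SNR 5. What the generator does *not*
emulate: photon-counting noise statistics, motion, bleaching, overlapping
cell geometry, and the spatial correlation structure of real optical noise.
Passing detector tests on these movies therefore demonstrates algorithmic
correctness, not performance parity on experimental recordings.

`synth_vm_ca()` produces a shared band-limited latent with independent
noise on each channel, a configurable coupling in [0, 1] and a Ca lag;
`synth_ap_train()` draws gamma-distributed intervals with requested rate
and CV (the per-beat frequency of a gamma-interval train has mean
rate·k/(k−1) and CV 1/√(k−2) for shape k = 1/CV², the oracle used in its
test).

# Problem sizes used by tests and the acceptance script

Unit and acceptance tests run the reduced 13 × 9 sweep at 15 s per model,
tissue runs of 6 s, single-cell runs of 12--20 s, and 5 seeds for every
stochastic claim; the acceptance script mirrors these sizes. These are the
package's desk-scale defaults; the full-resolution 97 × 61 sweep and longer
tissue runs use the same code paths through explicit arguments.

# Known limitations

* The cell model is a calibrated reconstruction of its lineage, not a
  constant-for-constant reproduction; absolute rates and the exact firing
  boundary are specific to the shipped parameter file.
* Dormant models here entrain 1:1 up to ~5 Hz under sine drive, a broader
  spectrum than real dormant cells, which struggle above ~2 Hz; resonance
  spectra should be read qualitatively.
* At extreme noise (≥ 500 pA) a depolarized fluctuation regime replaces
  organized firing, but occasional AP-like excursions still pass the
  detector; the bell-shaped benefit is assessed as a large rate collapse,
  not a literal zero.
* The tissue model is a small homogeneous-coupling lattice with no
  geometry, fibrosis or exit pathways; only the arrest/rescue contrast is
  calibrated.
* Stochastic LCR forcing is a Poisson point-flux stand-in for subcellular
  release dynamics, sufficient for coupled subthreshold Vm--Ca fluctuations
  but not for spatial Ca wave phenomena inside the cell.

# A worked example

```{r example, eval = FALSE}
library(sansr)

# dormant cell, 62.5 pA noise from 10 to 20 s
pd <- cell_params(g_CaL = 0.37, P_up = 5)
sim <- simulate_cell(pd, protocol_noise_run(62.5), duration = 25, seed = 1)
train <- detect_aps(sim$V_m, sim$time)
firing_metrics(train, c(10, 20))   # awakened: ~2-3 Hz during noise
firing_metrics(train, c(5, 10))    # dormant before noise

# firing-diagram expansion by 25 pA noise
d0 <- run_sweep(reduced_grid(), duration = 15, seed = 1)
d1 <- run_sweep(reduced_grid(noise_amp = 25), duration = 15, seed = 1)
diagram_delta(d0, d1)

# tissue arrest vs rescue
cfg <- tissue_config(duration = 6)
simulate_tissue(cfg, seed = 1, noise_amp = 0)$arrest_time    # ~0.8 s
simulate_tissue(cfg, seed = 1, noise_amp = 100)$arrest_time  # NA (no arrest)
```
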