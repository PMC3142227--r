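---
title: "Characterizing volume-dependent molecular noise with exact stochastic simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing volume-dependent molecular noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brnnoise)
```

## The problem

Chemical reactions in a cell fire as discrete, random events. When copy
numbers are small — as they are for many signalling proteins in a dendritic
spine or a small organelle — this discreteness makes concentrations
fluctuate, and the strength and colour of those fluctuations depend on the
reaction volume. `brnnoise` characterizes this intrinsic noise numerically:
it simulates a mass-action reaction network exactly with the Gillespie
stochastic simulation algorithm (SSA), starting from the deterministic
steady state, and summarizes each species' fluctuations in the time domain
(coefficient of variation, frequency of change) and the frequency domain
(periodogram power spectral densities and their log-log slopes) across a
grid of volumes.

## Model and algorithms

**Stochastic model.** A network of n species and m elementary one-way
reactions is a continuous-time discrete-state Markov jump process on the
molecule-count vector X(t). Reaction j has a propensity a_j(X): c_j x for a
unimolecular channel, c_j x_A x_B for a heterodimeric one, and
c_j x_A (x_A − 1)/2 for a homodimeric one. Firing updates X by the
stoichiometric column v_j. The *direct method* draws the waiting time from
Exp(a_0), a_0 = Σ a_j, and picks channel j with probability a_j/a_0 — an
exact sample of the jump process, with no time-step approximation. The
compiled inner loop (`src/ssa.cpp`) keeps per-reaction propensities current
through a species-to-reaction dependency list; with m = 110 a linear
cumulative-sum selection is entirely adequate.

**Units.** Model files declare concentrations in molar and deterministic
rate constants k (s⁻¹ or M⁻¹s⁻¹). At volume V, counts are
x = round(c · N_A · V) (rounding half away from zero) and second-order
constants convert as c_j = k/(N_A V) (doubled for homodimers). N_A is fixed
at the 2019 SI exact value 6.02214076 × 10²³ mol⁻¹. The half-away rounding
rule matters: the number of species that start with *zero* molecules —
and therefore the set of visibly "quantized" trajectories — changes with
the rounding convention when steady-state concentrations sit near
0.5/(N_A V).

**Constant inputs.** Species can be declared `constant`: they enter
propensities at their fixed abundance but their rows of the stoichiometric
matrix are forced to zero, so they are never produced or consumed. This is
also how the immigration–death oracle encodes a constant source.

**Deterministic steady state.** Stochastic runs are initialized at the
fixed point of dC/dt = S u(C), u_j = k_j Π[reactants]. No ODE solver
package is available in the target environment, so the package integrates
with an adaptive implicit Euler scheme (L-stable, analytic mass-action
Jacobian, step doubling up to t = 10⁶ s) and then polishes with a damped
Gauss–Newton iteration on S u = 0 restricted to the variable species
(Levenberg damping handles the rank deficiency that conservation laws
induce). Convergence demands max|f_i|/max(c_i, 10⁻¹⁸ M) ≤ 10⁻⁹; the
packaged network converges to ~10⁻¹⁴. Networks with conserved moieties
have initial-condition-dependent fixed points; the integration always
starts from the declared initial concentrations and no other fixed points
are sought.

## Sampling and spectra

**Zero-order-hold sampling.** An SSA trace is piecewise constant with
half-open plateaus [t_i, t_{i+1}). `sampleTrace()` evaluates it at
T + nΔt; changes between sample instants are deliberately neglected.
Whether that is acceptable is decided by the *captured-power criterion*:
`capturedPowerFraction()` compares the sample variance of the sampled
signal with the exact time-weighted variance of the trace over the same
window, and `selectSamplingFrequency()` takes the smallest candidate
frequency (defaults 10³, 10⁴, 10⁵ Hz) capturing at least 95 % of it.
"Power" is operationalized as variance about the mean because the analysis
concerns fluctuations around a steady state, not the DC level. The
criterion is applied per species: event rates differ by orders of
magnitude across a network.

**Decimation.** Before down-sampling by an integer factor the signal is
low-pass filtered, otherwise fluctuations above the new Nyquist frequency
alias into the analysis band. The filter is a linear-phase windowed-sinc
FIR (Blackman window) applied centred with reflection padding, passband
edge at 0.4 of the new Nyquist (amplitude error < 1 %) and ≥ 60 dB
stopband attenuation at the new Nyquist; the realization is free as long
as this contract holds, and the tests assert the contract, not the kernel.

**Periodogram.** `periodogramPSD()` removes the sample mean, applies a
weighting window (rectangular by default — the study convention; Hamming
and Blackman are available), and reports the one-sided estimate
P(f_k) = 2|C(k)|²/(F N W) on f_k = F k/N, k = 1…N/2, with W the window's
mean-square normalization. DC is excluded. The factor 2 is applied to the
Nyquist bin as well; this costs one bin's half-power in Parseval sums
(asserted exactly in the tests) and nothing in smoothed log-log slopes.
Raw periodogram bins have chi-squared scatter, so `smoothBins()` averages
non-overlapping groups of m = 8 adjacent bins (the group *mean*, not the
sum, so units stay (counts)²/Hz — the two differ by the constant m and fit
identical slopes), and `ensembleAverage()` averages replicate
realizations.

**Power-law classification.** `loglogSlope()` fits log₁₀ P on log₁₀ f by
OLS over a band whose default is [10 f₁, f_max/10], where f₁ is the raw
(pre-smoothing) fundamental F/N — one decade of margin against window
leakage at the bottom and sampling roll-off at the top. A 1/f^α process
yields slope −α: 0 for white noise, −1 for pure 1/f noise, −2 for a random
walk or the tail of a Lorentzian.

## Time-domain statistics

`timeWeightedMoments()` computes the mean and SD of a window *exactly*
from plateau durations; CV = σ/μ, with μ = 0 flagged NA (the gray cells of
a heat map). The statistic is a single-realization time average
(stationarity assumed); ensemble averages over replicates are available as
a cross-check through the replicate machinery. `frequencyOfChange()`
counts the events that actually alter a species' count. Heat maps order
species rows by ascending steady-state concentration and normalize each
matrix by its own global maximum (CV and FC independently).

## The packaged network

`packagedNetworkPath()` ships a 66-species, 110-reaction mass-action
network combining PKC activation, the Raf/Ras/MEK/MAPK cascade with its
phosphatases (PP2A, MKP-1), PLA2-mediated arachidonic-acid production, and
PLCβ/Gq PIP2 hydrolysis, after Bhalla & Iyengar (1999). Five species (APC,
tempPIP2, Inositol, PC, PIP2) are constant inputs at 30, 2.5, 0, 0 and
2.5 µM; the other 61 are variables. **Provenance:** the file is a
*synthetic reconstruction* — topology, species names and constant-input
concentrations follow the published scheme, but a number of the 110 rate
constants could not be recovered verbatim and are set to published
magnitudes or plausible values of the correct order (frozen before any
acceptance quantity was measured). Structural consequences are exact: with
no receptor-level stimulus the Gq activation branch (G*GTP, GqPLC,
GqCaPLC, GqCaPLCbcomplex) and the doubly-phosphorylated Raf arm (cRaf1**,
craf**deph) carry zero flux, so those six species stay at zero in every
volume and G*GDP keeps a constant level. Quantities that depend on the
exact constants — the count of zero-molecule species at a given volume, or
the precise PSD slope of PLC — do *not* reproduce the published values
(the reconstruction gives 37 rather than 39 zero-count species at
5 × 10⁻¹⁶ l, 25 rather than 18 at 10⁻¹³ l, and a PLC slope of ≈ −1.99
rather than −1.7…−1.8, because PLC here exchanges on a single fast time
scale and the fitted band sits on a pure Lorentzian tail). The
corresponding acceptance tests assert the published values unchanged and
fail visibly rather than being weakened.

## What the synthetic generators establish

`randomWalkSignal()` and `oneOverFSignal()` (spectral synthesis:
amplitudes ∝ f^(−α/2), uniform phases, conjugate symmetry, zero DC, unit
variance) calibrate the slope estimator; `immigrationDeathNetwork()` has a
Poisson stationary law (mean = variance, CV = 1/√mean) and a closed-form
Lorentzian PSD S(f) = 4σ²τ/(1+(2πfτ)²), τ = 1/k_out, which the
SSA → sample → periodogram → average pipeline must match bin-wise — the
end-to-end oracle binding the simulator, the sampler and the spectral
estimator together; `isomerizationNetwork()` supplies the
Binomial(N, k_b/(k_f+k_b)) stationary law used as an exactness
goodness-of-fit oracle. Green tests on these processes establish that the
pipeline measures stationary, exponentially-correlated and power-law noise
correctly; they cannot establish that the packaged network's constants
equal the published ones, nor how the pipeline behaves on strongly
non-stationary species (intermittent activity like MAPK* is summarized
but its PSDs should be read with care — stationarity within the window is
the standing assumption of the periodogram method).

## Reproducible parallelism

A volume scan is a pure function of (network file, configuration,
master seed). Each (volume, replicate) task derives its own RNG substream
seed by an integer hash `deriveSeed(master, volumeIndex, replicateIndex)`
(< 2³¹) and reseeds R's generator at task start; aggregation is a
deterministic reduce in index order. Results are therefore bit-identical
whether the scan runs on 1 worker or 8 (asserted in the tests). The
full-scale preset (`scanConfig(preset = "full")`: 300 equidistant volumes
from 5 × 10⁻¹⁶ to 10⁻¹³ l, 100 s time-domain windows, 10 s spectral
windows) reproduces the published study design and needs a multi-core
machine or cluster; the desk preset (4 volumes, 5–10 s windows) runs in
well under a minute.

## Numerical choices and limitations

* Rounding of counts: half away from zero (sensitivity documented above).
* Event-time ties have probability zero; IEEE ordering is used as-is.
* An all-zero-propensity state is absorbing, not an error.
* CV/FC default to the first replicate (time averages of one realization,
  matching the study design); PSDs ensemble-average all replicates.
* Default smoothing m = 8 and slope band [10 f₁, f_max/10]; the reference
  study states neither, so both are configuration with these defaults.
* Replicate counts per volume are likewise unstated; the configuration
  default is 10 for spectral estimates and replicate 1 for CV/FC.
* Out of scope: approximate accelerations (tau-leaping), direct CME
  solutions, non-stationary time-frequency analysis, spatial/compartment
  models, non-mass-action kinetics, bifurcation analysis.
* Trace export is plain-text CSV (no HDF5 library in the supported
  environment); scan configurations serialize to JSON.

## A worked example

```{r example, eval = FALSE}
net <- loadNetwork(packagedNetworkPath())
ss  <- findSteadyState(net)
ctx <- VolumeContext(5e-16)
tr  <- simulateSSA(net, concentrationsToCounts(ss, ctx), ctx,
                   tEnd = 10, seed = 1L)
f   <- selectSamplingFrequency(tr, "PLC")
sig <- sampleTrace(tr, "PLC", 0, 10 * f, 1 / f)
psd <- smoothBins(periodogramPSD(sig), 8)
loglogSlope(psd, 10 * f / length(signalValues(sig)), max(psd@freqs) / 10)
```
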