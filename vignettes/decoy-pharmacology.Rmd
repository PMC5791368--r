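---
title: "Modeling the pharmacology of NF-kB synthetic decoy ODNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the pharmacology of NF-kB synthetic decoy ODNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Synthetic decoy oligodeoxynucleotides (ODNs) are double-stranded DNA
fragments carrying an NF-kB binding motif. Delivered into the nucleus, they
sequester free NF-kB and thereby blunt transcription of NF-kB target genes —
a proposed anti-inflammatory and anti-cancer strategy. `nfkbdecoy` implements
a minimal quantitative model of how such a dose interacts with the core
IkBa/NF-kB negative-feedback circuit, to ask the pharmacological questions:
how much does a dose of given affinity suppress nuclear NF-kB activity, for
how long in the face of nuclease degradation, and what does it do to the
stochastic coherence of NF-kB oscillations in single cells?

The reaction network couples four site classes competing for free nuclear
NF-kB (`N_n`):

* the single IkBa promoter (`ON`/`OFF`, binding `k_on`, unbinding `k_off`);
  while `ON`, IkBa mRNA is transcribed (`k_tr`), translated (`k_tl`) and
  decays (`k_d`);
* ~2x10^4 genomic decoy sites — NF-kB binding sites with no (known)
  regulatory output, whose unbinding rates follow a log-normal spectrum
  `ln k_doff ~ Normal(delta_G_hat, sigma^2)` reflecting the spread of
  binding free energies measured on protein-binding microarrays;
* the synthetic ODN dose (`AD_U`/`AD_B`, binding `k_son`, unbinding
  `k_soff`), degraded by nucleases at `lambda_s`;
* IkBa itself, which shuttles between compartments (`k_in`, `k_out`),
  binds NF-kB in either compartment (`k_f`, `k_fn`) and, crucially, can
  actively *strip* NF-kB off any bound site at rate `k_s` (molecular
  stripping), producing the nuclear NF-kB–IkBa complex directly.

IkBa degradation within the cytoplasmic complex (`alpha`) releases NF-kB and
closes the delayed negative-feedback loop that drives limit-cycle
oscillations of nuclear NF-kB.

### Unit convention

All simulation is in copy numbers. The volume factor `omega` (default
1e5 copies per uM) fixes the cell volume so that the total NF-kB pool
(1e5 copies) is 1 uM. Bimolecular rate constants printed in uM^-1 min^-1 are
divided by `omega`; the transcription rate, printed in uM min^-1 per active
promoter, is multiplied by it. This bookkeeping is the only reading
consistent with a single promoter copy and an exactly conserved NF-kB pool:
treating the dimensionless promoter occupancy as a concentration would let
one promoter sequester 1 uM of NF-kB. Two sign/bookkeeping corrections are
applied relative to naive mass-action transcription of the published rate
list: promoter binding *consumes* free nuclear NF-kB, and degradation of an
NF-kB-bound ODN returns its cargo to the free nuclear pool (see
`bound_degradation` below).

### The decoy affinity spectrum

`build_decoy_bins()` discretizes the log-normal unbinding-rate spectrum by a
histogram: `n_bins` equal-width bins in ln-space across
`delta_G_hat ± span_in_sigmas * sigma`, counts proportional to the Gaussian
mass of each bin renormalized over the span, rounded to integers by largest
remainder so they sum to `D_total` exactly. The default is 15 bins over
±3 sigma; deterministic observables change by well under 2% between 9, 15 and
31 bins (tested), so the histogram resolution is not a sensitive choice.
With the defaults `delta_G_hat = 0`, `sigma = 1`, the spectrum's median
unbinding rate is 1 min^-1 — the promoter's own `k_off`.

### What degradation does to a bound ODN

The published rate list degrades both the unbound and the bound ODN pool at
`lambda_s`, but a literal reading destroys the NF-kB riding on a degraded
bound ODN, which contradicts the model's stated NF-kB conservation (and, at
slow unbinding, permanently silences the circuit). `decoy_params()` exposes
the choice:

* `"release"` (default): the bound ODN degrades and its NF-kB returns to
  the free nuclear pool. NF-kB is conserved and the *total* ODN pool decays
  exactly as `AD_dose * exp(-lambda_s t)` — a property the test suite
  checks against the integrator.
* `"none"`: bound ODNs are protected from nuclease attack; only the
  unbound pool degrades. Also conserving, but clearance of a high-affinity
  dose becomes unbinding-limited.
* `"destroy"`: the literal bookkeeping, kept for comparison.

## Simulators

`simulate_ode()` integrates the mass-action equations with VODE (stiff,
variable-order, variable-step; full internally generated Jacobian) at
`rtol = 1e-8`, `atol = 1e-10` in copy units — the solver tolerances are our
choice. The exactly conserved coordinates (the OFF gene state and the
unbound pool of each decoy bin) are eliminated before integration and
reconstructed on output, so those invariants hold identically and NF-kB
conservation drifts only at integrator precision (observed ~1e-14 relative
over 3000 min). The output grid is 0.5 min, resolving the ~260-min
oscillation with >500 points per cycle. Negative round-off values are
clipped to zero with a warning; anything beyond `10 * atol` aborts.

`simulate_ssa()` is an exact Gillespie direct-method sampler of the chemical
master equation over the identical reaction set (no tau-leaping — exactness
is the contract). The mean-field identity — stoichiometry times propensities
equals the deterministic derivative — is asserted numerically in the tests,
and the ensemble mean over 200 replicates is checked to track the ODE
within three standard errors. States are recorded by zero-order hold
(default 1 min), not per event. Published-scale runs (`omega = 1e5`) are
supported but slow; stochastic experiments here use `scale_volume()` to run
at `omega = 1e3` with all copy-number totals scaled by 1/100 and every
concentration preserved. Replicate `r` of a scan always uses seed
`base_seed + r`, and a given seed reproduces a trajectory bit for bit.

## Observables

**Peak amplitude** (`peak_amplitude()`): the maximum free nuclear NF-kB
concentration over `(burn_in, horizon]`, defaults 500 and 3000 min — the
steady-state oscillation amplitude.

**Duration of action** (`duration_of_action()`): the time from dosing until
free nuclear NF-kB first rises above 0.1 uM, located by linear interpolation
on the 0.5-min grid (refinement-stable to <0.5 min); capped at the horizon if
never crossed. Duration scans dose the *running* oscillator by default: the
undosed circuit is settled on its limit cycle for 3000 min
(`equilibrium_state()`) and the dose is added to that state. This choice
matters: from the cold start the duration is almost exactly
`ln(dose / AD_crit) / lambda_s`, whereas dosing the running oscillator lets
the recovery lock to the next qualifying oscillation peak, which is what
produces the degradation-rate plateau discussed below. The cold-start
protocol remains available (`equilibrate = FALSE`).

**Dephasing time** (`dephasing_time()`, `trajectory_dephasing()`): the
coherence of stochastic oscillations, defined through the normalized
autocorrelation (ACF) of nuclear free NF-kB, which for a noisy oscillator
decays as `exp(-t / tau_phi) * cos(2 pi t / T)`. The estimator:

* ACF with the biased (1/n) normalization (variance-stable at large lags);
  the deterministic `(1 - lag/n)` taper of that estimator is removed before
  deciding whether any decay is resolvable, so a perfectly coherent signal
  is reported as *capped* rather than assigned the taper as a decay;
* period from the dominant spectral peak (parabolically interpolated), with
  an overtone check (spiky waveforms put most power in harmonics) and
  refinement by the ACF's up-crossing spacing;
* envelope by walking the ACF peak to peak — one local maximum per cycle —
  which tolerates the period wander of stochastic trajectories; the lag-0
  point is excluded (it carries the white-noise variance spike);
* `tau_phi` by least squares of `A exp(-t/tau)` on the consecutive run of
  envelope peaks above a noise floor estimated from the ACF's lag-to-lag
  jitter. When fewer than two (clean ACF) or three (jittery ACF) peaks are
  usable the envelope slope is unidentifiable and the estimator falls back
  to a direct damped-cosine fit of the full ACF, which is also available
  explicitly as a cross-check (`method = "direct"`).

On noise-free damped cosines with tau in 50–800 min and T in 60–160 min the
estimator recovers tau within 5% and T within 2%; under white noise of sd
0.05 it recovers tau = 50 as 50.8 ± 1.9 (mean ± sd over 20 seeds). Fits
whose envelope decays by less than 10% across the lag window are flagged
`capped` and reported as at least the window length; a signal whose first
ACF peak sits below the noise floor (no resolvable oscillation — e.g. a
saturating dose of slow decoys) raises an error, and scan drivers count such
replicates separately. Reported dephasing times for stationary signals
retain a finite-window attenuation common to all conditions of equal window
length, so cross-condition comparisons — the quantity of interest — are
unaffected.

## Scan drivers

`scan_peak_amplitude()`, `scan_duration()`, `dose_response()` and
`scan_dephasing()` return tidy tibbles, one row per parameter tuple and
observable, with the standard errors and capped/failed counts where
stochastic. Default deterministic grids: 21 doses in 0–2 uM, 13
log-spaced unbinding rates in 0.02–20 min^-1, 11 degradation rates in
0–0.02 min^-1. Default stochastic scans run at `omega = 1e3` with 20
replicates per condition — a deliberate scaled-down design; the dose-0
condition is simulated once per replicate and shared across `k_soff`, since
without ODNs the unbinding rate cannot influence the dynamics (the identity
is exact, realization by realization).

Two headline quantities are distilled from the scans:

* `duration_plateau()`: on a doubling grid of `lambda_s` at `k_soff = 0.02`,
  dose 1 uM, `k_s = 0`, `alpha = 0.55`, the duration of action stops
  decreasing (<5% change per doubling) at `lambda_s = 8e-3` min^-1: beyond
  that, the duration is set by the time to the next qualifying oscillation
  peak of the re-igniting limit cycle rather than by dose clearance.
* `resonant_ksoff()`: from the stochastic dephasing scan, the unbinding rate
  with the largest relative drop of mean tau_phi from dose 0 to the largest
  dose. The theoretically expected resonance is at `k_soff ~ k_off = 1`
  min^-1, where the decoys' binding noise couples most strongly to the
  oscillator phase. At the desk-scale volume used here (omega = 1e3) that
  coupling is *not* the leading noise source: the undosed oscillator keeps
  4-15 periods of coherence (tau_phi at or beyond the resolvable lag window
  of a 3000-min run, so many fits are capped), dosing mostly leaves
  coherence unchanged or slightly increased, and slow decoys
  (0.02 min^-1) at 1 uM abolish the oscillation outright — an amplitude
  effect that the scan reports as unmeasurable dephasing. The largest
  measured relative drop therefore lands on the slow, quenching decoys
  rather than on the resonant ones; resolving the resonance proper requires
  volumes near the published scale, which is outside the desk-scale scope
  of this package's default experiments.

## Choices made where the design was open

* **alpha**: only the range 0.10–0.55 min^-1 is established; the default is
  0.55. Below ~0.3 the free nuclear NF-kB amplitude falls under the 0.1 uM
  duration threshold and durations diverge, so the upper end is the regime
  where all three observables are well defined.
* **Dosing protocol**: pre-equilibration before dosing (see above). The
  burn-in length (3000 min) and its 0.5-min grid fix the dosing phase
  deterministically; the burn-in end happens to fall in the quiescent
  segment of the spiky oscillation, so durations are non-degenerate. Because
  recovery locks to oscillation peaks, equilibrated-dosing response curves
  carry one-cycle phase-slippage quanta (dips of up to ~0.3 period on
  multi-thousand-minute durations); the cold-start protocol gives strictly
  monotone dose and degradation response surfaces and is used when the
  monotone structure itself is under test.
* **Duration horizon**: 6000 min, so that slowly cleared doses
  (`lambda_s` down to 5e-4) are measured rather than capped.
* **Oscillation period**: the default circuit (alpha 0.55, `k_s` 10,
  dose 0) has a 260-min period and ~0.57 uM peak amplitude; the period is
  frozen in a regression test at 1% relative tolerance.
* **Stochastic problem sizes**: test-suite ensembles use omega = 1e3
  (mean-field comparison: 200 replicates to 200 min; dephasing scans: 20
  replicates to 3000 min), chosen so the whole suite runs on a laptop in
  minutes while leaving the law-of-large-numbers and resonance conclusions
  statistically resolvable.

## What the simulations do and do not show

Everything here is synthetic: the generator *is* the model, so passing tests
demonstrate internal consistency (conservation, mean-field agreement,
estimator recovery, reproduction of the published response-surface
structure), not agreement with cellular measurements. Known limitations
carried over from the model itself: a single well-stirred nuclear/cytoplasmic
compartment pair; one promoter copy and a purely sequestering role for
genomic decoys; no chromatin or cofactor modulation of binding kinetics; no
delivery, export or compartmental pharmacokinetics of the ODN dose beyond a
single first-order nuclease sink; and a decoy affinity spectrum taken as
log-normal with fixed mean and variance rather than fit to array data.
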