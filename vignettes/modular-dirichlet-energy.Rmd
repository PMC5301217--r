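---
title: "Modular Dirichlet Energy: model, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular Dirichlet Energy: model, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdenergy)
```

## The problem

Functional-connectivity analysis of multichannel EEG estimates a weighted
graph from correlations between channel time courses. Reliable correlation
estimates need long windows (hundreds of milliseconds), which makes the
resulting networks blind to the fast, transient dynamics that actually
carry event-related cognition. `mdenergy` implements a graph-signal-processing
answer: estimate one graph per long task epoch, then treat the short-window
multichannel signal as a *graph signal* on that fixed topology, and ask, window
by window, where the signal amplitudes agree or disagree with the long-epoch
connectivity. The connectivity acts as a spatial filter; the graph signal
restores the temporal resolution.

## Energies on a weighted graph

For a graph with channels as nodes, edge weights $w_{ij}$ (correlations over
the epoch) and node amplitudes $f_i$ (the EEG at one time sample, zero-averaged
over the channel space), the Dirichlet energy is

$$E(f) \;=\; \sum_{\{i,j\}} w_{ij}\,(f_i - f_j)^2 ,$$

the sum running over unordered node pairs, each edge once, with no 1/2
factor. It is an inverse smoothness measure with a sign semantics under
signed correlation weights: a strongly positive term means correlated
channels carry dissimilar amplitudes at this instant (signal at odds with
the long-epoch structure); a strongly negative term means anticorrelated
channels are far apart (signal agreeing with the structure). Sums of such
terms locate moments where short-time activity drives, or departs from,
the long-window connectivity.

Per node, the *node gradient* $\sum_{j \ne i} w_{ij}(f_i - f_j)^2$ is a
local version of the same quantity; summed over nodes it counts every edge
twice, so it equals $2E(f)$ — an identity the test suite checks on every
random instance.

Given a partition of (some) nodes into named modules — pre-defined
electrode groups over scalp regions, never the output of a community
detection algorithm — the energy decomposes edge-wise:

* **MDE** (modular Dirichlet energy): the terms with both endpoints in one
  module;
* **BMDE** (between-module energy): the terms with one endpoint in each of
  two disjoint modules;
* a **residual**: terms touching unassigned nodes.

These three classes partition the edge set, so MDE + BMDE + residual
reconstructs the total exactly; `decompose_energy()` asserts this to a
relative tolerance of 1e-9, appropriate for double-precision accumulation
over the ≤ ~10³ edges of EEG-sized graphs.

Two deliberately different edge conventions coexist. `mde()` is
within-module only, so that the decomposition above is disjoint and
cross-module energy lives exclusively in `bmde()`. The level-1 statistic
`total_modular_weight()` instead uses the *adjacent-edge* convention —
absolute weights of all edges with at least one endpoint in the module —
because a module is defined together with all its adjacent edges and the
level-1 question is how strongly the module couples to the whole network.
The moduli are used there because only correlation strength matters at
level 1; the signed weights are reserved for the energies, where the sign
carries the agreement semantics.

Time extends everything linearly: the energy of a window is the sum of the
per-sample energies, and `windowed_energy()` tiles a period with
non-overlapping windows (default 20 ms = 5 samples at 250 Hz; a 0–200 ms
encoding period yields exactly 10 windows). Trailing samples that do not
fill a window are dropped rather than padded, so the default periods tile
exactly. A window length that is not a whole number of samples is an
error, not a rounding.

## The two-level inference pipeline

`run_full_analysis()` reproduces a strict discovery protocol:

1. **Preprocessing** (`preprocess_dataset()`): per trial, average
   re-reference (subtract the scalp mean per sample); artifact rejection
   with the defaults 200 µV peak-to-peak fluctuation, 100 µV
   sample-to-sample transient, 70 µV EOG peak-to-peak on designated
   channels, and removal of incorrect-response trials; noisy-channel
   rejection at 30 µV mean absolute amplitude (an SD-based leave-one-out
   variant is available); trial averaging into one ERP per subject ×
   condition. "Transient" is operationalised as the largest absolute first
   difference between consecutive samples, the natural single-sample
   reading. Cells where no trial survives are dropped with a log entry and
   the analysis proceeds complete-case.
2. **Connectivity** (`build_period_graphs()`): per period (encoding
   0–200 ms, maintenance 200–1000 ms; half-open intervals, stimulus onset
   at t = 0, 0-based samples, so the periods share no sample), Pearson
   correlation of the channel-space-centred period signals. One
   correlation computation yields both sign regimes — the absolute graph
   is the elementwise modulus of the signed one — so levels 1 and 2 see
   consistent connectivity by construction. Pearson (not rank, not phase)
   is the estimator because the method targets amplitude effects.
   Zero-variance channels get zero weights and a warning rather than
   aborting a subject. Graphs stay fully weighted; no thresholding.
3. **Level 1**: per (contrast, period, module), the per-subject difference
   of total modular weights (first-listed minus second-listed condition,
   e.g. Shape − Bind) is paired-t-tested across subjects
   (`paired_t_test()`, the closed form mean/(sd/√n) with n−1 df,
   two-sided). With two modules, two periods and two hemifield contrasts
   this is an 8-hypothesis family. A one-sample Kolmogorov–Smirnov screen
   of the standardised differences is attached to every test; it is
   advisory only and never blocks a test, and its p-value is approximate
   because mean and SD are estimated from the same data.
4. **Hierarchical FDR** (`hierarchical_fdr()`): Benjamini–Hochberg step-up
   at q = 0.05 on the level-1 family; for each discovered parent, its
   children (the per-window level-2 tests) form one BH family at the same
   q; children of undiscovered parents are never tested. This is the
   strict fixed-q reading of hierarchical FDR; a conservative variant that
   halves q per family is available (`method = "yekutieli"`) but off by
   default.
5. **Level 2** (`run_level2()`): for each discovered (module, period,
   contrast), per-subject windowed MDE on the *signed* graph of each
   condition with that condition's own signals, paired-tested per window.
   When both members of a module pair are discovered for the same period
   and contrast, their BMDE is tested per window as well — the
   interaction is probed exactly when both regions matter. Each BMDE node
   needs a single parent in the hypothesis tree; it is attached to the
   member with the smaller level-1 p-value, and since BMDE nodes are only
   created when both members are discovered, parent gating is unaffected
   by the choice.

The analysis path contains no randomness: re-running on the same inputs
produces byte-identical report tables. Degenerate cells (zero-variance
differences, e.g. identical conditions) surface as per-hypothesis notes
with `not_tested` decisions instead of aborting the run.

By default no band-pass is applied inside the pipeline (`band = "none"`):
epoched inputs are assumed band-limited upstream by the acquisition
filter, and a 0.01 Hz zero-phase high-pass is ill-posed on a 1.2 s epoch.
`band_filter()` provides broadband (0.01–40 Hz, realised as a second-order
high-pass cascaded with an order-4 low-pass, numerically better behaved
than a direct band-pass with a near-zero lower edge) plus theta (4–8 Hz),
alpha (8–13 Hz) and beta (13–30 Hz) Butterworth zero-phase filters; the
narrow-band cutoffs are conventional values and configurable, since band
analysis is a capability here, not a calibrated result.

## The synthetic generator

`generate_dataset()` emulates the study conditions the pipeline was built
for: 19 subjects × four task cells (Shape/Bind × left/right hemifield) ×
trials of 30-channel, 250 Hz epochs spanning −200..1000 ms. Channels in a
module follow a latent-factor law,
$x = \sqrt{\rho}\,\ell(t) + \sqrt{1-\rho}\,\varepsilon(t)$ at noise scale
10 µV, which gives pairwise within-module correlation exactly ρ in
expectation and a closed form to test against. Coupling overrides may be
restricted to a condition and/or a millisecond interval, so connectivity
differences can be planted in a single task period. Subjects carry a
log-normal gain (sdlog 0.1) emulating population heterogeneity;
correlations are scale-free, so the gain stresses only the amplitude
pathway. Everything is reproducible from a mandatory seed.

Planted transients are raised-cosine bumps (smooth, effectively
band-limited, no filter-ringing confounds) entering with fixed *zero-mean*
per-channel gains: a linear −1..1 ramp across the module, i.e. a graded,
dipole-like deflection. This choice matters twice over. A common-mode bump
cancels in every pairwise difference and is invisible to MDE by
construction; and a non-zero-mean bump leaks into the long-epoch
correlation weights, smearing a nominally window-local effect over every
window of the period. The zero-mean ramp maximises within-module amplitude
differences while cancelling from the scalp average and, to first order,
from the pairwise covariances, so planted effects stay local to their
window — which the test suite verifies directly.

The reference validation scenario (`planted_config()`) plants, in the
right-hemifield encoding period only: an *energy-neutral* connectivity
deficit — within-module coupling 0.65 (Shape.R) vs 0.35 (Bind.R), a
complementary pair chosen because expected within-module energy scales as
$2\rho(1-\rho)$, so the modular weights separate strongly while expected
window energies stay matched, leaving level-2 localisation attributable to
the transient — plus a 40 ms bump (occipital 100–140 ms; frontal
140–180 ms when planted). The default 6 µV amplitude was calibrated once
by simulation so that a single planted window's paired t-test has power
≈ 0.9 at 19 subjects under these conditions.

What the generator does *not* emulate: volume conduction and realistic
forward models, 1/f spectral shape, oscillatory rhythms, latency jitter
across trials, or correlated artifacts. Passing the validation suite
therefore demonstrates that the estimator and the inference chain behave
as designed under a controlled generative law — not that any particular
neurophysiological effect exists in real recordings.

## Validation and problem sizes

The package's guarantees are checked at these scales, chosen to keep the
full validation runnable on one CPU in minutes while leaving the study
design (19 subjects, 8-hypothesis level-1 family, 10 encoding windows)
intact:

* decomposition identity on 200 random (graph, signal, partition)
  instances at 1e-9 relative tolerance, and agreement of every energy
  primitive with an exhaustive pair-enumeration oracle on 100 random
  graphs with up to 8 nodes at 1e-12;
* false-discovery control of the full two-level procedure over 500
  global-null synthetic datasets (6 trials per cell — the trial count
  shapes only ERP noise, not the null), realised FDR compared with
  q = 0.05 within three Monte-Carlo standard errors;
* planted-effect recovery over 100 seeded datasets of the reference
  scenario (8 trials per cell): the planted module/period must carry the
  smallest level-1 p and be discovered, and the minimal level-2 p must
  fall within one window of the planted interval;
* a qualitative-structure check on the two-module scenario: the planted
  hypotheses are the strongest level-1 discoveries, level-2 output is
  gated to them, and the strongest per-module windows are adjacent at the
  planted intervals. Because BH lets an isolated borderline window or a
  tag-along level-1 false discovery through in a minority of datasets —
  that is what FDR control means — the whole-set cleanliness and
  contiguity statements are judged by majority over seeds rather than
  per run.

The generator default of 60 trials per cell reflects the trial counts the
design targets in practice; the simulation-based checks use 6–8 trials per
cell, which changes ERP noise levels but none of the tested properties.

## Known limitations

* Windowed MDE inherits a plug-in coupling: the weights are estimated from
  the same epoch the windows tile, so window energies and weights are not
  independent, and strong transients that are not common-mode can still
  bleed into the weights. The energy-neutral/zero-mean planting choices
  quantify and control this in validation; on real data it is a property
  of the method itself.
* The KS normality screen is approximate (estimated parameters) and
  advisory.
* Channels rejected per subject × condition shrink that subject's graph;
  modules referencing a rejected channel will error for that subject
  rather than silently re-weight.
* The hypothesis tree is strictly two levels; deeper hierarchies are out
  of scope.
* The module symbols and naming follow common network-science usage
  (modules as node subsets with their adjacent edges); where upstream
  descriptions of the decomposition are ambiguous about whether per-module
  energy includes cross edges, this package fixes the within-only
  convention for `mde()` because it is the unique convention under which
  the disjoint decomposition identity holds without double counting.

## A worked example

```{r example, eval = FALSE}
library(mdenergy)

cfg <- planted_config(seed = 1)        # occipital plant, right hemifield
ds  <- generate_dataset(cfg)           # 19 subjects x 4 cells x 8 trials
rep <- run_full_analysis(ds)           # preprocess -> graphs -> 2 levels
rep
rep$level1[rep$level1$decision == "rejected", ]
subset(rep$level2, decision == "rejected",
       c(id, window, window_start_ms, window_end_ms, p))
recovery_score(rep, cfg)
write_report(rep, "mde_report")
```

The same pipeline is scriptable from a shell through `exec/mde`
(`mde simulate`, `preprocess`, `graph`, `analyze`, `report`), with a YAML
study config covering montage, modules, contrasts, periods, window length,
band and q.
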