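---
title: "Quantifying correlogram shape: uniformity, peaks, and firing order"
author: "correloscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying correlogram shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(correloscope)
```

## The problem

Multi-unit extracellular recordings (for example from cultured cortical
networks on microelectrode arrays) produce one spike raster per sorted
unit. How pairs of units fire relative to one another -- independently,
in patterned sequences, or in a consistent leader/follower order -- is
visible in the **cross-correlogram**: the histogram of relative timings
$t = t_c - t_r$ between every comparison event $t_c$ and every reference
event $t_r$ within a lag window $[-R, +R]$. Normalized by its total count
$S$, the correlogram $C(x)$ estimates the conditional probability of a
comparison spike at lag $x$ given a reference spike at 0.

correloscope builds these correlograms for all unit pairs within
**analysis regions** (consecutive windows of the recording) and reduces
each to three shape metrics:

1. **Uniformity.** A chi-squared test of the binned counts against a flat
   histogram. A uniform correlogram means the two spike trains carry no
   information about each other's timing; a nonuniform one means they are
   dependent (by synapse, common input, or population synchrony -- the
   metric makes no causal claim).
2. **Peak count and peak times.** The number and lags of prominent local
   maxima, after local-regression smoothing. More peaks indicate more
   diverse relative-timing patterns; regularly spaced peaks indicate
   rhythmic co-activation.
3. **Area left of zero** $A = \sum_{x<0} C(x)$. The fraction of mass at
   negative lags, i.e. how consistently the comparison unit fires
   *before* the reference: $A = 1$ always leads, $A = 0$ always follows,
   $A = 0.5$ no consistent order.

Each metric is then classified into a small set of labels, and the labels
are tracked across regions: per-region class fractions, region-to-region
transition probabilities, and the combined
uniformity x leader/follower x peak-count table.

## Binning geometry and bin assignment

Bin centers sit at integer multiples of the bin width $w$, so the center
bin always contains lag 0; with $K = \mathrm{round}(R/w)$ the bin count
is $L = 2K + 1$, odd by construction. A $\pm 1$ s window at $w = 1$ ms
gives $L = 2001$. A lag is assigned to the nearest bin center; a lag
landing exactly on a bin edge (halfway between centers) resolves toward
zero, so $+2.5$ ms falls in bin 2 and $-6.5$ ms in bin $-6$ at $w = 1$
ms. This nearest-center/tie-toward-zero rule is the unique uniform-width
rule consistent with both worked assignments and a center bin at 0. Only
pairs with $|t| \le R$ contribute; a consequence worth knowing is that
the two extreme bins collect only half a bin width of admissible lags,
so under a flat null their expected count is $E/2$ rather than $E$ --
negligible at $L = 2001$, but visible if one runs the uniformity test on
very coarse geometries (see *Numerical notes*).

Two further construction rules:

* **Regions are self-contained.** Events are clipped to
  $[\mathrm{start}, \mathrm{end})$ before pairing; pairs spanning a
  region boundary are not counted.
* **Autocorrelogram self-pairs are excluded.** Pairing an event with
  itself contributes a structural count at lag 0 that carries no timing
  information and would drag every autocorrelogram's $A$ toward a
  spurious value; removing exactly one lag-0 count per event keeps
  autocorrelograms symmetric (so $A = 0.5$) while retaining genuine
  duplicate-timestamp coincidences between different units.

## The uniformity test

With observed counts $O_x$, total $S$ and expected count $E = S/L$, the
package's default statistic is Pearson's
$\chi^2 = \sum_x (O_x - E)^2 / E$ with $L - 1$ degrees of freedom and an
upper-tail p-value. A variant that omits the $1/E$ scaling
(`chi2Variant = "as_printed"`) is provided for comparison with the
original MATLAB formulation of this pipeline, which wrote the statistic
as $\sum_x (S[C(x) - 1/L])^2$ while computing its p-value from the
chi-squared law; that law only holds for the Pearson-scaled form, which
is why Pearson is the default. The two variants differ by the constant
factor $E$, so they order correlograms identically within a correlogram
but can classify differently; when that matters, run both.

A correlogram is **uniform** iff $p > \alpha$ (default
$\alpha = 0.05$); $p$ exactly at the cutoff is nonuniform. The
chi-squared approximation needs $E \gtrsim 5$; the implementation flags
(`expected_count_warning`) rather than refuses low-$E$ correlograms,
since in practice the test is applied to whatever the recording yields.
$S$ is defined as the sum of the bin counts (events that landed in the
window), the only reading under which $O_x = S\,C(x)$ are integers.

## Peak detection

Correlograms are smoothed by loess-style **local quadratic regression**:
at each bin a degree-2 polynomial is fit by weighted least squares over a
centered window of $W$ bins with tricube weights, and evaluated at the
bin. $W$ is in bins, must be odd, and $W = 1$ disables smoothing (the
default; smoothing is an explicit analysis choice). Edge windows are
truncated to the available bins, with the degree reduced when fewer than
three bins remain. Exactly quadratic inputs are reproduced to numerical
precision, so the smoother is unbiased on locally parabolic peaks.

A **peak** is a strict local maximum of the smoothed correlogram;
plateaus collapse to their center bin, and the first/last bins are never
peaks. Its **prominence** is its height minus the higher of its two
reference minima, each being the lowest value between the peak and its
nearest strictly higher value on that side (or the signal end). Peaks
must have prominence strictly greater than $1/L$ -- the height of a
uniform correlogram -- so uniform-level wiggles never count.

## Firing order

$A$ includes half the center-bin mass:
$A = \sum_{x<0} C(x) + \tfrac12 C(0)$. This amendment makes the mirror
identity $A_{j,i} = 1 - A_{i,j}$ hold *exactly* (swapping reference and
comparison reverses the bin order, and the center bin maps to itself)
even when mass sits at lag 0. The literal center-exclusion form is
available via `centerBin = "exclude"`. Leader/follower strength is
classified into five intervals symmetric about 0.5 (weak
$0.4 < A < 0.6$ through strong $A \ge 0.9$ or $A \le 0.1$), so mirrored
correlograms always share a class.

## Classification schemes

* **Peak count** classes are $0, 1, \dots, M-1, M{+}$ for a user ceiling
  $M$; $M = 10$ gives 11 classes and hence
  $2 \times 5 \times 11 = 110$ combined cells.
* **Peak times** classify either by timescale -- log-decade classes
  anchored at $R$ (for $R = 1$ s and the default floor $R/1000$: $\le 1$
  ms, $(1,10]$ ms, $(10,100]$ ms, $(100\,\mathrm{ms}, 1\,\mathrm{s}]$) --
  or by frequency $f = 1/|t|$ into EEG-style bands. The conventional band
  quotations leave 7--8 Hz and 30--32 Hz unassigned; the package uses
  contiguous half-open bands delta $[0,4)$, theta $[4,8)$, alpha
  $[8,13)$, beta $[13,32)$, gamma $[32,\infty)$ Hz so every $f$ maps to
  exactly one band, taking 32 Hz as the gamma floor. A lag of exactly 0
  belongs to the smallest timescale class and is excluded from frequency
  classing ($f$ undefined).
* **Transitions.** For each consecutive region pair and each correlogram
  identity, class$(r-1) \to$ class$(r)$ is tallied and rows are
  normalized to conditional probabilities. Steps with a sparse endpoint
  are skipped (and counted), never imputed. Period mode pools steps by
  the period of the *destination* region, so the step crossing a
  treatment belongs to "after" -- consistent with grouping the
  treatment-containing region itself as "after", since it already
  contains the start of the response.

## Analysis regions and sparsity

Automatic segmentation tiles $[0, D)$ with fixed-length regions and
drops the trailing partial region, giving
$\lfloor D/L_\mathrm{region} \rfloor$ regions (a 20.5 h recording at 7
min regions gives 175; 1.7 h gives 14). Region length trades off event
count per correlogram (sparsity) against time resolution.

A correlogram is **sparse** when its raster-event product
$n_\mathrm{ref} \cdot n_\mathrm{cmp}$ is at or below the user threshold,
or when it contains no events at all. The default threshold 0 excludes
only empty correlograms. Sparse correlograms keep their place in all
outputs (blank heatmap cells, flagged rows) but carry no metrics or
classes.

## The synthetic generators

Four scenarios provide ground truth for every pipeline stage:

* `genPoissonPopulation()` -- independent homogeneous Poisson units; the
  null for the uniformity test's calibration.
* `genLaggedPair()` -- a Poisson leader plus a follower delayed by a
  fixed lag with Gaussian jitter; ground truth for $A$, strength
  classes, and peak-time recovery. Followers pushed outside the
  recording are dropped; jitter-induced reordering is re-sorted.
* `genPeriodicBursts()` -- population bursts every `burstPeriod`
  seconds, each unit joining with probability `participation`, over a
  sparse baseline; ground truth for rhythmic peak structure (peaks at
  integer multiples of the period).
* `genRegimeSwitch()` -- one parameter set before `switchTime`, another
  after (including unit death via `deadFraction`); with identical
  parameters on both sides it is a negative control: a correct pipeline
  must show no class-fraction change beyond sampling noise.

Each generator seeds its own RNG stream (restoring the caller's), so a
fixed seed gives byte-identical rasters. The generators emulate timing
structure only: they do not model refractoriness, bursty within-unit ISI
structure, rate drift, electrode cross-talk, or waveform-sorting errors.
Passing the recovery checks therefore demonstrates that the *metrics*
recover known timing structure, not that real recordings are this clean.

## Numerical notes and validation design

* **Tie handling** in bin assignment uses a relative tolerance of
  $10^{-9}$ bins to detect exact half-edge lags under floating point.
* **Calibration check.** The uniformity test's false-positive rate is
  checked on 500 pairs of independent 1 Hz Poisson trains over 5500 s at
  $R = 0.1$ s, $w = 1$ ms ($E \approx 5.5$), where the rejection
  fraction at $\alpha = 0.05$ must fall in $[0.03, 0.08]$. Two
  conditions of the test drive this design: the expected bin count must
  reach $\approx 5$, and successive reference windows should rarely
  overlap (overlapping $\pm R$ windows re-use comparison events across
  reference events, mildly overdispersing the counts and inflating the
  rejection rate above nominal -- at 1 Hz and $R = 0.1$ s the overlap
  factor $2R \cdot \mathrm{rate}$ is 0.2). Practitioners testing
  high-rate recordings with wide windows should expect conservative
  calibration to fail in the same way; this is a property of applying a
  multinomial test to overlapping-window histograms, not of the
  implementation.
* **Recovery checks.** The lagged pair (10 ms lag, 2 ms jitter, 2 Hz,
  600 s) is analyzed at $R = 20$ ms, matched to the tens-of-milliseconds
  delay under study: at $R = 1$ s the $\approx 4800$ unrelated-pair
  background lags would dilute $A$ toward 0.5 by construction, which is
  the correct behaviour of the metric but not a test of delay recovery.
  The periodic-burst scenario (period 0.25 s) is analyzed at
  $R = 0.85$ s so that every burst harmonic ($0, \pm0.25, \pm0.5,
  \pm0.75$ s) lies interior to the window; at $R = 1$ s the harmonic at
  exactly $\pm R$ sits on the window edge and produces the expected
  truncated edge bumps (7--9 detected peaks rather than exactly 7),
  which the synthetic-module tests cover separately.
* **Problem sizes** throughout the suite (hundreds of trains of
  $10^2$--$10^4$ events, $L \le 2001$) were chosen as the smallest sizes
  at which the statistical assertions have comfortable power.

## Caching and reproducibility

Correlogram construction is the expensive stage; `runPipeline()` caches
it keyed by a hash of the input trains, region definitions, and
correlogram settings. Changing only classification parameters (e.g.
$\alpha$, $M$, smoothing window) replays correlograms from cache;
changing bin width or range forces a rebuild. Identical configuration
and input produce byte-identical tables, and every run writes a manifest
with per-file content hashes and elapsed time.

## Limitations

* Nonuniformity indicates statistical dependence, not connectivity or
  causality; no shift-predictor or jitter correction is applied.
* Rhythm fundamental frequencies are not extracted from harmonic peak
  spacing; peak-time classes treat each peak independently.
* Refractory-period estimation from autocorrelograms is out of scope.
* The chi-squared p-values are approximate for low expected counts and
  anticonservative for strongly overlapping windows (see above).
* Vendor file formats are supported only through the `readRecording()`
  adapter hook; the native format is long CSV.
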