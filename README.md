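# correloscope

Correlogram shape metrics for multi-unit spike recordings.

## What it does, and for whom

Electrophysiologists recording many spiking units at once (e.g. cultured
cortical networks on microelectrode arrays) often want to know how the
*relative timing* of unit pairs changes through a recording — when a drug
is washed in, when pH rises, when the culture is injured. correloscope
answers this with cross-correlograms: for each ordered pair of units and
each **analysis region** (a time window of the recording), it histograms
every lag t = t_c − t_r between comparison and reference spikes with
|t| ≤ R, normalizes to a probability C(x), and reduces each correlogram
to three shape metrics:

- **Uniformity** — Pearson's chi-squared test of the bin counts against a
  flat histogram, χ² = Σ(O_x − E)²/E with E = S/L and L − 1 degrees of
  freedom. Uniform ⇒ the two trains fire independently.
- **Peak count and times** — local maxima of the (optionally
  loess-smoothed) correlogram whose prominence strictly exceeds 1/L, the
  height of a uniform correlogram.
- **Area left of zero** — A = Σ_{x<0} C(x) + ½·C(0), the probability
  mass at negative lags: how consistently the comparison unit fires
  *before* the reference (A = 0.5 ⇒ no consistent order; the mirrored
  pair satisfies A_ji = 1 − A_ij exactly).

The metrics are classified (uniform/nonuniform; 0…M−1, "M+" peaks; five
leader/follower strength grades; peak-time timescale or frequency-band
labels) and tracked across regions: per-region class fractions,
region-to-region transition probabilities, and the combined
2 × 5 × (M+1)-cell classification table. Synthetic raster generators
(Poisson populations, fixed-lag follower pairs, periodic population
bursts, mid-recording regime switches) provide ground truth for every
stage.

## Worked example

A leader/follower pair with a 10 ms delay and 2 ms jitter, analyzed at a
±20 ms lag window:

```r
library(correloscope)

rec <- genLaggedPair(rate = 2, duration = 600, lag = 0.01,
                     jitterSd = 0.002, seed = 42)
spec <- correlogramSpec(range = 0.02, binWidth = 0.001)
cg <- buildCorrelogram("leader", "follower", spec, rec = rec)
cg
#> Correlogram follower (cmp) vs leader (ref), region 1
#>   41 bins of 0.001 s over +/- 0.02 s; S = 1332 events (1247 x 1247 raster events)

r <- chiSquaredUniformity(cg)
sprintf("chi2 = %.1f, p = %.3g, uniform = %s", r$chi2, r$pValue, r$uniform)
#> "chi2 = 5368.4, p = 0, uniform = FALSE"

pk <- countAndTimePeaks(cg, metricParams(smoothWindow = 5))
pk$peakTimes
#> [1] 0.01

A <- areaLeftOfZero(cg)
sprintf("A = %.3f -> %s", A, classifyLeaderFollower(A))
#> "A = 0.034 -> strong"
```

Reading the output: the correlogram is decisively nonuniform (the trains
are dependent), has a single prominent peak at +10 ms (the planted
delay), and nearly all its mass right of zero (A ≈ 0.03), i.e. the
follower fires after the leader — a "strong" leader/follower pair. The
full pipeline over a recording is one call:

```r
runPipeline(list(input = "raster.csv", regionLength = 420,
                 range = 1, binWidth = 0.001,
                 treatments = data.frame(time = 3600, label = "drug"),
                 outputDir = "out"))
```

which writes `metrics.csv`, `classes.csv`, `fractions.csv`,
`transitions_period.csv`, `combos.csv`, raster statistics, and a
`manifest.json` with content hashes and timing. A thin CLI wrapper lives
in `inst/scripts/correloscope-cli.R` (`analyze` / `simulate`
subcommands).

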