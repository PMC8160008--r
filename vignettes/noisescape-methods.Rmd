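---
title: "Methods: community noise metrics, source prevalence, and the synthetic monitoring campaign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community noise metrics, source prevalence, and the synthetic monitoring campaign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisescape)
```

# Scope

`noisescape` characterizes urban community noise from two coupled data
streams typical of large monitoring campaigns: minute-resolution A-weighted
sound-level logs (LAeq_1min, dBA) from integrating sound-level meters, and
multi-label audio-classifier output from short clips recorded on a 10-minute
grid. The package computes window sound levels and the Intermittency Ratio,
turns classifier labels into source-category presence and prevalence,
produces stratified descriptive summaries, and quantifies how well a few
randomly sampled measurement days represent a year-long average. A synthetic
generator emulates the measurement design (week-long "rotating" sites plus
year-long "fixed" sites) so every stage is testable without field data.

# Sound-level metrics

All level averaging is *energetic*: levels are converted to relative energy
$10^{L/10}$, averaged, and converted back,

$$\mathrm{LAeq} = 10\log_{10}\Bigl(\tfrac{1}{n}\sum_i 10^{L_i/10}\Bigr),$$

so the result is the steady level carrying the same total energy as the
fluctuating signal. It always lies within the range of the inputs and is
never below their arithmetic mean.

Window metrics are computed per site and calendar date: `laeq_24hr` over the
whole day, `l_day` over 06:00–21:59, and `l_night` over 22:00–05:59. The two
windows always partition the 24-h clock (the day window is configurable; the
night window is its complement). By default the *night of date D* consists
of minutes 00:00–05:59 and 22:00–23:59 of D, so every metric is a pure
function of one calendar date; the spanning alternative (22:00 of D to 05:59
of D+1) is available via `analysis_config(night_convention = "spanning")`
for settings where the sleep night is the unit of interest.

## Intermittency Ratio

The Intermittency Ratio (IR) separates "peaky" from steady sound
environments. A minute is a sound *event* when its LAeq_1min strictly
surpasses the window's own LAeq plus a fixed cutoff $K$ (default 3 dBA,
with 4 and 5 dBA computed alongside):

$$\mathrm{IR} = 100 \cdot
  \frac{\sum_{i:\,L_i > \mathrm{LAeq}+K} 10^{L_i/10}}
       {\sum_i 10^{L_i/10}} \,\%.$$

Properties that the test suite verifies directly: IR lies in $[0, 100)$ for
$K > 0$ (all minutes can never exceed the energetic mean plus a positive
cutoff), it is non-increasing in $K$, it is 0 for a steady series, and it is
invariant under adding a constant to every level (while every LAeq shifts by
exactly that constant). For a two-level series with fraction $p$ of minutes
at $L + \Delta$ and the high level above threshold,
$\mathrm{IR} = 100\,p\,10^{\Delta/10} / (p\,10^{\Delta/10} + 1 - p)$, which
the implementation matches to $10^{-9}$.

Numerical and definitional choices:

* **Strict inequality.** A minute exactly at the threshold is *not* an
  event ("surpass"); covered by a boundary test.
* **Minute granularity.** The logger integrates per minute, so an event is
  an event-minute; no sub-minute onset/offset reconstruction is attempted.
  If events were instead defined as contiguous supra-threshold runs, the
  minute-level form is the natural specialization at 1-min logging.
* **Coverage rule.** A window's metric is emitted only when at least 80% of
  its clock-expected minutes (1440/960/480) were observed
  (`min_coverage = 0.8`, configurable); otherwise the metric is missing and
  the coverage is still reported. Monitoring practice has no universal
  completeness rule; 0.8 keeps a metric honest while tolerating realistic
  logger gaps.
* **No implicit clipping.** Levels below the 30 dBA instrument noise floor
  are flagged on input but never altered by readers or the metrics engine.
* **Duplicate minutes are a hard error**, not averaged: silently merging
  minutes would corrupt event detection.

# Source categories and prevalence

Classifiers over AudioSet-style ontologies emit hundreds of fine labels;
for interpretation these are grouped into seven categories adapted from ISO
acoustic-environment taxonomies: road-transport, animals-and-insects,
outdoor-music, human-speech, aircraft, nature, and "other". The shipped map
(`default_category_map()`) covers the common urban labels and is an editable
table; any unmapped label resolves to "other", so the map is total and every
clip has at least one category present.

A category is *present* in a clip iff at least one of the clip's three
retained top-ranked labels maps to it (presence is multi-label, and derived
from the top-3 set only — no additional score floor, since retention is
already the classifier's ranking decision). *Prevalence* is the percentage
of clips in a stratum with the category present; pooled over sites and
times it is a measure of site-time. Pooling is clip-weighted, so the
prevalence of a union of strata is exactly the clip-count-weighted mean of
the stratum prevalences.

Level–source linkage joins each clip to the LAeq_1min of its enclosing
minute (the 10-s clip standing for its minute) and bins levels into
half-open `(lo, hi]` 5-dB intervals with open-ended extremes (edges
configurable; a minute at exactly an edge falls in the lower bin).
Score ties in top-k retention break lexicographically for determinism.
Flight-path proximity uses the great-circle distance from each site to the
nearest point of a configurable polyline (default buffer 1 km); aircraft
prevalence is then reported separately within/outside the buffer.
Classifier accuracy is summarized as positive predictive value,
$100\,\mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$, per category against blinded
manual labels.

# Descriptive summaries and representativeness

Stratified summaries report medians and interquartile ranges with quartiles
by linear interpolation between closest order statistics (`quantile`
type 7), so ports can match bit-for-bit. Group contrasts use the two-sided
Wilcoxon rank-sum test: exact when both groups have at most 20 observations
without ties, otherwise the normal approximation with mid-ranks, tie and
continuity corrections. Weekday/weekend, monthly, and intervention-period
contrasts are expressed through stratum keys, not bespoke stages. Empirical
CDFs of minute levels are evaluated on a common dBA grid per group.

The representativeness analysis asks whether a few random measurement days
characterize a site's long-term level: for each fixed site it samples
`n_days = 5` daily LAeq_24hr values *without replacement* (the natural
reading of "random days of measurement"), and compares each to the site's
yearly average — by default the **energetic** mean of the daily values,
which is the physically consistent long-term LAeq; an arithmetic-mean
alternative is a flag. Differences are reported in dBA and as percent of
the yearly average (computed on the dB scale), with per-site and pooled
medians of signed and absolute quantities. Pooled medians are medians over
the concatenated per-site samples. Note one small but real consequence of
energetic averaging: for a stationary year with day-to-day dB fluctuation
of standard deviation $\sigma$, the yearly energetic mean sits about
$0.115\sigma^2$ dB above the median day, so the median sampled-day
difference is slightly negative even under perfect stationarity (about
−0.26 dBA at $\sigma = 1.5$ dB, the day-to-day variability used in the
package's stationary-year checks).

# The synthetic generator

The generator is the package's stand-in for field data and defines the
conditions under which the pipeline is exercised. Minute levels follow

$$L(t) = \mathrm{base} + \mathrm{diurnal}(h(t)) + \varepsilon(t), \qquad
  \varepsilon \sim \mathrm{AR}(1),$$

with Poisson-arriving sound events superimposed energetically. Events are
*absolute-level sources*: each draws a lognormal excess relative to the
archetype's daytime baseline, so the same passing vehicle is more salient
against the quieter night background — which reproduces the night-time rise
in intermittency seen in urban measurements. An event of effective excess
$\Delta$ on a background minute at $L$ yields
$10\log_{10}(10^{L/10} + 10^{(L+\Delta)/10})$; overlapping events add their
energy. Levels are clipped below at the 30 dBA noise floor (simulator
only).

Defaults per land-use archetype (night base dBA / day contrast dBA /
day rate per h / night rate per h / median excess dB):

| archetype | base | contrast | rate day | rate night | excess |
|---|---|---|---|---|---|
| peri-urban background | 47 | 7 | 1.3 | 0.3 | 10 |
| medium/low-density residential | 52 | 7 | 2.0 | 0.8 | 7.5 |
| high-density residential | 58 | 7 | 3.5 | 1.3 | 6 |
| commercial-business-industrial | 61 | 7 | 12 | 1.8 | 3 |

AR(1) noise has coefficient 0.6 and stationary sd 2.2 dB; event durations
are geometric with mean 2 min; excess sd is 0.5 log-units. These values
were chosen once, qualitatively, so that the archetypes reproduce the
canonical urban pattern: daily level medians ordered CBI > high-density >
medium/low-density > peri-urban (about 70/67/61/57 dBA), day above night by
roughly 7 dBA, and intermittency ordered the *other* way (peri-urban most
intermittent, CBI least) because busy areas have a dense event stream that
merges into a steady background from which few events still emerge. A
single global excess distribution cannot produce that inversion — IR grows
with both rate and excess until threshold saturation — so the excess median
declines across archetypes as the event rate rises; this is the package's
own design choice.

Clip streams draw per-category presence Bernoulli with
`logit = qlogis(base_p[land_use]) + hour_logit[hour] + coupling * event`,
the positive coupling (default 1.5) applying to road-transport on event
minutes. Present categories, ranked by a drawn salience, fill up to three
label slots from their label pools; spare slots take distinct unmapped
filler labels (which resolve to "other"). Because presence is read back
from the top-3 set, more than three concurrently present categories truncate
— exactly as in the real post-processing. Validation sets draw manual truth
Bernoulli at a target PPV so the bookkeeping identity
`ppv(counts) == realized PPV` can be checked exactly.

What the generator deliberately does **not** emulate: spectral content and
frequency weighting, sub-minute event structure, weather and seasonal
trends, instrument drift, spatial correlation between nearby sites, and
classifier confusion structure (label scores are exchangeable given
presence). Passing tests therefore demonstrate the correctness and
statistical calibration of the *analysis* under a plausible data-generating
process, not the field accuracy of any classifier or meter.

# Problem sizes and reproducibility

The test suite exercises: 1,000 random series (length ≤ 1440) against a
brute-force IR oracle at three cutoffs; a (p, Δ) grid of two-level series
against the closed form; 100 seeds of a 1,008-clip Bernoulli(0.6) stream
for prevalence recovery; a 10,000-clip validation set against a 76% PPV
target; 200 seeds of a 10-site stationary year for the representativeness
null; 10,000 null replicates of the rank-sum test at n = 8 per group (a
group size at which the exact test's attainable size, 0.0499, is essentially
nominal — the discrete null makes the attainable size depend on n); 50
mixed-archetype sites for the prevalence–intermittency anticorrelation; and
one full campaign of 136 rotating × 7-day plus 10 fixed × 365-day sites run
end-to-end. `scripts/acceptance.R` recomputes the headline quantities from
scratch at comparable sizes. Every stochastic step takes an explicit seed;
identical (profile, seed) pairs give byte-identical simulator output.

# Known limitations

* Timestamps are timezone-naive local wall clock; the intended settings
  observe no daylight-saving shifts. Campaigns crossing DST changes would
  need explicit handling upstream.
* The minute-level event definition understates intermittency relative to
  fast-response (e.g. 125 ms) analysis when events are much shorter than a
  minute.
* Sub-minute logger artifacts (clock drift, partial first/last minutes) are
  surfaced as counts by the readers but not corrected.
* The shipped category map covers common urban labels only; a production
  deployment should supply its classifier's full grouping table.
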