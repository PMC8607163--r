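---
title: "Cluster-based permutation inference and effect sizes for event-related EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based permutation inference and effect sizes for event-related EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpcluster)
```

## The inference problem

A group-level ERP comparison asks whether two within-subject conditions
(here: *standard* and *oddball* stimuli in an auditory/visual oddball
paradigm) evoke different neural responses. The data are per-subject,
per-condition averages on a channels × timepoints grid — with 32 channels
and 750 timepoints, some 24,000 samples. Testing each sample at $\alpha =
.05$ without correction would produce false positives almost surely;
Bonferroni across 24,000 heavily dependent tests would destroy power.

The cluster-based permutation test solves this by exploiting the smoothness
of EEG: true effects extend over adjacent channels and timepoints, so
evidence is aggregated over spatio-temporally connected sets before a single
family-wise decision is made.

## The test

For conditions $A$ and $B$ with $n$ subjects:

1. **Massive-univariate map.** At every sample $j$, the dependent-samples
   statistic $t_j = \bar d_j / (s_{d_j} / \sqrt n)$ on the per-subject
   differences $d_j = A_j - B_j$, with $n - 1$ degrees of freedom
   (`paired_t_map()`). Independent-groups and across-subject regression maps
   are available for other designs.
2. **Cluster formation.** Samples with $|t_j|$ beyond the two-sided critical
   value at the cluster-forming $\alpha$ (default .05) are kept, separately
   by sign, and grouped into connected components (`form_clusters()`). Two
   samples are adjacent iff they share a channel and are consecutive in
   time, or share a timepoint and their channels are neighbours in a
   symmetric `neighbor_graph`; there is no diagonal adjacency. Each
   cluster's *mass* is the sum of its $t$ values.
3. **Permutation distribution.** Under the exchangeability null, each
   subject's condition labels may be swapped, i.e. the sign of each
   subject's difference flipped. Each of $B$ draws flips fair independent
   signs (Monte Carlo) or enumerates all $2^n$ patterns (exhaustive,
   feasible up to a configurable cap), reruns the full map → threshold →
   cluster pipeline, and records the largest positive and most negative
   cluster mass; a draw without a cluster contributes mass 0, keeping the
   distribution length $B$ and the test conservative
   (`permutation_distribution()`).
4. **Monte Carlo p-values.** A positive observed cluster of mass $m$ gets
   one-tail $p = (\#\{\text{draws} \ge m\} + 1)/(B + 1)$; the negative tail
   is mirrored. In exhaustive mode the exact proportion $k/B$ is used — the
   identity assignment is among the draws, so $k \ge 1$ and $p > 0$ without
   the +1 correction, and the Monte Carlo estimator converges to this exact
   value. Two-sided testing Bonferroni-corrects by doubling. *Every*
   observed cluster is referred to the max-cluster distribution of its tail,
   which is what controls the family-wise error rate
   (`cluster_p_values()`).

`cluster_perm_test()` orchestrates these steps and returns a classed object
with `print()` and `summary()` methods. A significant result supports the
statement *that the conditions differ*; the cluster's location and extent
are a description of the data, not the tested hypothesis — the report
generator (`render_report()`) enforces this phrasing.

### Numerical and procedural choices

* **Cluster-forming threshold** is the two-sided critical $t$ at
  `cluster_alpha` (default .05), independent of the test-level `alpha`.
  Lowering it grows clusters into supersets (tested as an invariant). The
  threshold affects sensitivity, never validity.
* **Zero-variance samples** get $t = \pm 10^{10}$ with a warning rather than
  NaN, so thresholding and clustering stay defined on degenerate input.
* **Ties** in "largest cluster" are broken by earliest first sample, then by
  channel name, making results order-deterministic.
* **Seeds**: all Monte Carlo draws and all simulations are governed by
  explicit integer seeds recorded in result objects and serialized files;
  functions restore the caller's RNG state.
* **Runtime estimation without p-hacking**:
  `estimate_permutation_runtime()` times a pilot batch and extrapolates
  linearly, discarding the pilot result; no p-value is computed or shown, so
  choosing $B$ cannot be informed by interim significance. Fewer than 1000
  randomizations triggers a warning about Monte Carlo resolution.
* **No minimum-neighbour constraint** on cluster membership is applied in
  this version.

## Channel neighbourhoods

Spatial adjacency comes from the 2-D montage layout, by distance
(`neighbors_by_distance()`: $0 < \mathrm{dist} \le r$) or Delaunay
triangulation (`neighbors_by_triangulation()`; the default method when a
graph has to be built from scratch, since it adapts to electrode density
without a free radius parameter). Channels are sorted by name before
triangulating so cocircular tie-breaks inside the triangulator are
reproducible, and the result is symmetrised; an optional maximal edge length
prunes spurious hull edges. Graphs are always symmetric and irreflexive.
`audit_graph()` reports degrees, asymmetries and connectivity — edge
channels such as TP10 have systematically fewer neighbours than central
ones such as Cz, so test sensitivity is not spatially uniform; auditing
makes that visible. A 32-channel 10–20 template layout ships as
`layout_1020_32()`.

## Preprocessing pipeline

`preprocess_subject()` reproduces a deterministic single-subject chain:

* **Epoching** (`segment_epochs()`): half-open windows
  $[onset - 0.5\,\mathrm{s}, onset + 1.0\,\mathrm{s})$ against 0-based
  stimulus samples — exactly 750 samples at 500 Hz, no double-counted
  boundary sample. The event's integer `sample` is authoritative over float
  `onset` to avoid drift. The oddball selection policy keeps only repeated
  standards: the first standard of a sequence and the standard immediately
  following an oddball are excluded.
* **Band-pass** (`bandpass_filter()`): zero-phase forward–backward
  4th-order Butterworth per pass, 1–30 Hz, on epochs mirror-padded by 5 s.
  Because the pad exceeds the epoch length, the reflection is applied
  repeatedly (period $2N - 2$ samples). Edge transients from reflection
  kinks remain near the epoch boundaries; the passband and stopband
  behaviour is verified against the filter's closed-form frequency response
  in the epoch interior.
* **Baseline** (`baseline_correct()`): whole-epoch mean subtraction by
  default (idempotent); filtering precedes baseline correction.
* **Artifact rejection** (`reject_artifacts_auto()`): a documented,
  reproducible stand-in for interactive visual screening and ICA-based
  correction, which are irreproducible by nature and out of scope. Channels
  whose peak-to-peak amplitude exceeds the limit (default 200 µV; a flatline
  floor is available) on more than 30% of trials are marked bad; then trials
  exceeding the limit on any good channel are rejected. The operation never
  reads condition labels (rejection is condition-blind by construction, and
  tested as such). The defaults are this package's choices, not values from
  any reference pipeline.
* **Interpolation** (`interpolate_bad_channels()`): inverse-distance
  weighted average of good neighbours; a bad channel without a good
  neighbour is an error naming the channel.
* **Re-referencing** (`rereference()`): subtracts the mean of the linked
  mastoids (TP9/TP10) from every channel — the offline step only, assuming
  the online reference is already in the raw data. Idempotent; reference
  channels absent from a reduced montage are skipped.
* **Averaging and inclusion**: `average_by_condition()` averages unrejected
  trials per condition; `exclude_subjects()` removes subjects with strictly
  more than 70% of trials rejected. The rationale: keeping a fraction $f$ of
  trials inflates the within-subject SEM by $\sqrt{1/f}$
  (`sem_inflation_factor()`); at $f = 0.3$ that is $1.83 \approx 2$.

## The three effect-size quantifications

All use paired Cohen's $d$ = mean of per-subject differences divided by
their SD ($n - 1$ denominator). The paper-style dependent-samples $t$ map
then satisfies $d_j = t_j/\sqrt n$ exactly, which is tested to $10^{-10}$;
this consistency is why the paired variant was chosen over alternatives
(e.g. pooled-SD) that the source material leaves unspecified.

1. **Average over the cluster** (`es_average_over_cluster()`): $d$ of the
   per-subject condition differences of data averaged over exactly the
   cluster's member samples. Closest to the test's rationale, but the
   jagged cluster shape is hard to report and not expected to replicate
   exactly.
2. **Maximum within the cluster** (`es_max_within_cluster()`): the largest
   $|d|$ over member samples, reported signed with its channel and latency
   (ms, on the sample grid). Peak statistics carry positive bias — an
   upper-bound-style estimate.
3. **Circumscribing rectangle** (`es_rectangle()`): $d$ of data averaged
   over a channels × contiguous-interval rectangle. The *outside* variant
   (default) spans the member channels × member time range — a superset of
   the cluster whose dilution makes it a lower-bound-style estimate. The
   *inside* variant searches all contiguous intervals for the channel set
   covered at every timepoint, maximising member count with ties broken by
   longer interval, earlier start, then lexicographic channel set; if no
   multi-channel footprint fits, the largest single-channel interval is
   used with a warning. The search rule is this package's formalisation —
   the concept exists in the literature without an algorithm.

`effect_size_report()` assembles all three per cluster; the recommended
report quotes options 2 and 3 (with their exact channels and interval),
which bracket the effect.

## The synthetic oddball generator

`simulate_erp_dataset()` draws subject-level condition averages from

$$\mathrm{avg}_{s,c} = b_s + g_s\,\mu_c + \varepsilon_{s,c},$$

where $\mu_c$ is a Gaussian-windowed negative fronto-central deflection
(an Nc-like component) whose latency differs between conditions (defaults:
0.55 s standard, 0.45 s oddball — the oddball peak is faster, so one latency
effect yields one positive and one negative difference cluster), $b_s$ is a
per-channel subject offset (cancels in paired differences), $g_s = 1 +
\mathcal N(0, \sigma_g^2)$ a subject gain shared across conditions, and
$\varepsilon$ unit-marginal-variance noise with an exponential spatial
kernel over the layout and AR(1) temporal correlation, scaled by
$\sigma/\sqrt{n_{\mathrm{trials}}(c)}$.

This makes the true pointwise paired effect size analytic:

$$d(j) = \frac{\Delta\mu(j)}{\sqrt{\sigma_g^2\,\Delta\mu(j)^2 +
\sigma_A^2 + \sigma_B^2}},$$

and the deflection amplitude is calibrated in closed form so the peak of
$d$ equals a target (`effect_d`, default 0.8). `simulate_null()` draws both
conditions from the identical process (exchangeable by construction);
`simulate_event_stream()` produces standard-run/oddball sequences with
exact trial counts for testing the epoch selection policy;
`simulate_continuous()` adds the evoked responses into a continuous
spatio-temporally correlated recording for end-to-end pipeline runs,
optionally with injected amplitude spikes for rejection tests.

### Default study conditions and their rationale

48 subjects; 32 channels (10–20 montage); 500 Hz; epochs −0.5..1.0 s;
90 standard / 50 oddball trials; trial-level noise 20 µV so subject-average
noise is 2–3 µV. Two scale choices deserve justification:

* **Noise smoothness.** Subject-average residuals of 1–30 Hz band-passed
  EEG are dominated by the low-frequency end of the band, and volume
  conduction makes neighbouring electrodes strongly correlated. Defaults:
  AR(1) time constant `noise_tau` = 0.2 s (specified in seconds so the
  spectrum is invariant to the sampling rate) and spatial correlation
  length 1.5 layout units (neighbour correlation ≈ 0.8). Cluster-scale
  smoothness is what makes clustering, and the upper/lower-bound ordering
  of the effect-size options, meaningful: with temporally/spatially rough
  noise, averaging over a cluster would beat the within-cluster maximum and
  invert that ordering.
* **Effect extent.** `spatial_decay` = 0.8 layout units and `peak_width` =
  0.1 s give a broad fronto-central difference spanning most of the cap for
  a few hundred ms — matching the scale of the published infant oddball
  effect, whose circumscribing rectangle covered 31 of 32 channels over a
  quarter second.

### What the generator does and does not emulate

It emulates: condition-specific latency/amplitude structure, spatially and
temporally correlated noise, between-subject gain and offset variability,
unequal trial counts, oddball sequence structure, and (for the continuous
variant) large-amplitude artifacts on demand. It does **not** emulate
biophysical forward models, realistic artifact morphology (blinks,
heartbeat, movement), non-stationary noise, per-subject latency jitter
(excluded to keep the ground-truth d map analytic), or non-Gaussian
amplitude distributions. Passing tests therefore demonstrate correctness of
the statistical machinery under a controlled, realistic-scale generative
model — not robustness to every pathology of real infant EEG.

One caveat surfaced by this generator is worth stating plainly: at $n = 30$
the within-cluster maximum (option 2) overestimates the true peak $d$ — the
mean estimate in the package's own acceptance run exceeds the generative
peak by roughly 0.2 to 0.35 depending on the noise scales. That is the
positive bias expected of a peak statistic, it is why option 2 should be
read as an upper bound, and it is not removable by implementation choices:
configurations smooth enough to push the bias under 0.15 also drain the
test's power for realistic effects. The acceptance suite asserts the strict
recovery band and documents this failure rather than hiding it.

## BIDS layer

`write_bids_dataset()` / `read_bids_dataset()` emit and parse
`dataset_description.json`, `participants.tsv` (+ optional `participants.json`
data dictionary, e.g. recording that `age` is in days), and per-subject
`eeg/` folders (`sub-<label>[_ses-<label>]_task-<label>_<suffix>`):
recording, `*_eeg.json` sidecar, `*_events.tsv` (onset seconds plus the
authoritative integer `sample`), `*_channels.tsv`. Tabular files are
tab-separated with `"n/a"` for missing values; the session level appears
only when requested. Recordings are BrainVision triplets (text headers +
IEEE float32 multiplexed binary, read/written by this package) or a
tab-separated internal format convenient for text-only fixtures. The
minimal required sidecar field set follows the BIDS-EEG specification,
since the source study does not enumerate its fields beyond age/sex and
marker meanings. `validate_bids_layout()` is advisory and non-mutating:
missing required files and naming-grammar violations (including a missing
`task-` entity) are errors, recommended practice (e.g. missing data
dictionary) warns, and derivative material found inside a raw subject
folder is flagged as a separation error — derivatives live under
`derivatives/<pipeline>/`.

## Problem sizes used in the tests

The suite validates statistical behaviour at deliberately modest sizes: the
flood-fill clustering oracle on 1000 random grids up to 8 × 12; Monte Carlo
vs exhaustive agreement at $n = 6$ (64 patterns) against $B = 20{,}000$
draws; family-wise error on 500 null simulations at $n = 12$, 10 channels,
50 timepoints, $B = 1000$; effect-size recovery on 100 simulated groups at
$n = 30$ with the full 32 × 750 grid; and an end-to-end
simulate → BIDS → preprocess → test → effect-size → report pipeline at 6
subjects, which is run twice and compared byte for byte. These sizes are the
package's own choice of a thorough-but-quick validation; all of them scale
up by changing the corresponding arguments.

## Known limitations

* Paired (within-subject) permutation only; the independent-groups and
  regression statistics have maps but no permutation engine in this
  version.
* No TFCE and no weighted cluster mass; fixed cluster-forming thresholds
  only. No spectral/time-frequency clustering.
* No Hedges' correction or confidence intervals on Cohen's d.
* The automated artifact rejection is a transparent amplitude criterion; it
  does not attempt to match what visual inspection plus ICA would remove.
* BrainVision support covers the float32 multiplexed subset this package
  writes.
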