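---
title: "Optical map simulation, alignment and QC with omapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical map simulation, alignment and QC with omapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement being modeled

Optical mapping images single DNA molecules of 150 kb to 2 Mb that have been
stretched on a surface and digested with a restriction enzyme. Each molecule
is observed as an ordered list of restriction fragment sizes — an *Rmap*.
Compared with the in-silico digest of a reference genome (the *reference
map*), an observed molecule differs in four ways:

* **partial digestion** — each true site is cut with probability
  `p_digest` < 1 (published estimates for human KpnI data are 0.66–0.69);
* **false (extra) cuts** — random breakage and imaging artefacts add cuts at
  a rate of roughly 0.75 per 100 kb;
* **small-fragment loss** — fragments of ≲ 2 kb desorb from the surface or
  fall below the imaging resolution and disappear;
* **sizing error** — fluorescence-intensity sizing has a roughly
  proportional error, modeled here as multiplicative Gaussian noise.

`omapr` implements the full desk-scale workflow around this model:
in-silico digestion (`digest_contigs()`), enzyme choice
(`fragment_stats()`, `rank_enzymes()`), a simulator (`sample_molecules()`),
a glocal aligner (`align_all()`), and QC estimators (`qc_summarize()`).

## In-silico digestion

Reference sequences are read from FASTA and split at every maximal run of at
least `min_gap` N bases (default 1). Assembly gaps must split the map:
a multi-megabase run of N would otherwise masquerade as one enormous
fragment, distorting every fragment-size statistic. Coordinates are 0-based
half-open throughout; fragment *i* covers `[cut[i-1], cut[i])`, so per-contig
fragment lengths always sum to the contig length. All thirteen built-in
enzymes have palindromic recognition sites, so one strand is scanned;
user-defined non-palindromic sites are scanned on both strands and the cut
sets merged. Soft-masking is ignored (restriction chemistry does not care),
and an N in the *sequence* never matches, even against a degenerate code in
the pattern.

The enzyme-selection report counts the fraction of fragments inside "usable"
size windows (5–20, 6–15, 6–12 kb by convention: smaller fragments size
poorly, larger ones make maps with too few fragments). Window bounds are
inclusive; the percentage is a plain per-fragment count fraction, pooled
over contigs with terminal fragments included. Published enzyme tables do
not state their operational definition of "usable %", so no attempt is made
to reverse-engineer one; the transparent per-fragment definition is used
and documented.

## The simulator

`sample_molecules()` draws a contig proportional to length, a uniform start,
a molecule length from a truncated exponential (minimum 150 kb, mean 285 kb
— the published average molecule size for GM12878-type data — capped at
2 Mb), clips at the contig end, and picks a uniform orientation. Error
channels are applied in a fixed order — digestion, false cuts, small-fragment
loss, sizing — so the recorded truth block is well defined. Defaults are the
published error-rate estimates (`p_digest = 0.66`,
`lambda_false = 0.751`/100 kb). Choices the data do not pin down:

* **sizing CV 0.10** — no sizing-error figure is published for this
  platform; 10% is a conventional magnitude and is configurable.
* **p_small_loss 0.5, threshold 2 kb** — the literature reports the
  *outcome* (a small-missing-fragment ratio of 0.15–0.19) but not the
  underlying loss probability; 0.5 is a plausible default, configurable.
* **false cuts keep ≥ 100 bp from existing cuts** — two gaps closer than
  ~100 bp cannot be resolved optically, and this avoids degenerate
  zero-length fragments.
* **lost fragments are deleted, not merged** — desorption physically removes
  the fragment's mass; merging is already modeled by missed cuts.
* The 100 bp floor on observed sizes applies only when sizing noise is on,
  so that with all channels off a molecule's fragments tile its source
  interval exactly (the identity the test suite asserts).

What the simulator does *not* emulate: chimeric molecules, non-uniform
stretch along channels, surface-density effects, or the imaging quality
score (carried as pass-through metadata only). Tests that pass on simulated
data therefore validate the algorithms under the declared error model, not
the full messiness of real images.

## The glocal aligner

A molecule must be explained end to end, but may land anywhere on the
reference: a *glocal* alignment. The aligner runs dynamic programming over
(molecule cut, reference cut) states; between consecutive matched cut pairs,
up to `delta` fragments may be merged on either side. A block of molecule
size $m$ against reference size $r$ scores

$$ -\frac{(m - r)^2}{2\,(\mathrm{cv}\cdot r)^2} \;-\;
   \mu\,(\text{merged ref} - 1) \;-\; \phi\,(\text{merged mol} - 1) $$

Terminal molecule fragments are partial (molecules start and end
mid-fragment), so they are scored one-sided: free if they fit inside the
flanking reference fragment, quadratic on the excess. Both orientations and
every contig are evaluated; ties are broken deterministically (score, then
contig order, start position, forward orientation).

The penalty constants are calibrated to the error model rather than
invented: a missed site occurs with probability $1-p$, so
$\mu = -\ln(1 - 0.66) \approx 1.1$; a false cut lands in a given ~10 kb
fragment with probability $0.751 \times 0.1 \approx 0.075$, so
$\phi = -\ln(0.075) \approx 2.5$. The lookback bound must cover runs of
consecutive missed sites: at $p = 0.66$ a run of ≥ 4 occurs in ~29% of
285-kb molecules (breaking any `delta = 4` chain), while runs of ≥ 6 are
negligible (~0.15% per gap), hence `delta = 6`. With weaker penalties
(e.g. 1.2/1.2) the aligner happily trades a matched pair for a
miss-plus-false, which inflates the extra-cut estimate by ~50% — the
parameter-recovery tests exist precisely to catch that failure mode.

Acceptance of a placement requires `min_matched_cuts = 6` matched pairs and
a score `margin = 5` over the best placement overlapping it by less than
50% (overlap measured in reference fragments, relative to the shorter
span). The margin replaces a p-value — no statistical alignment-confidence
model is published for this assay — and is calibrated against two
simulation controls: noise-free molecules must all align uniquely to their
origin, and molecules simulated from one genome must align to an unrelated
equal-size genome at a rate below 5% (margin 3 lets ~13% of such junk
through; margin 5 brings it to ~2% while keeping the true alignment rate
near 0.65 at realistic noise).

The DP is exact (no pruning or seeding heuristics), and a property test
checks it against exhaustive enumeration of all monotone block matchings on
small instances. Exhaustive per-contig DP is O(molecule cuts × reference
cuts × delta²), comfortable at desk scale (a 50-Mb reference, ~3,000
molecules, ~90 s on one core); a seed index would be needed for full
mammalian genomes and is out of scope.

## QC estimators

Rates are pooled across uniquely aligned molecules (sums of counts, not
means of per-molecule ratios), which keeps short molecules from dominating;
per-molecule averaging is a one-line change a user can make from the
alignment table. Two estimator subtleties matter:

* **Digestion rate.** An aligned span is delimited by its first and last
  matched cuts, which are therefore matched *by construction* and carry no
  information about `p_digest`. Counting them biases the pooled ratio up by
  about $2(1-p)/n_\text{sites}$ per molecule — measured as ~+0.025 at study
  conditions, enough to matter for a parameter of 0.66. The default
  estimator excludes the two delimiting pairs per alignment
  (`exclude_delimiters = TRUE`); the raw ratio remains available.
* **Extra-cut rate** divides unmatched molecule cuts by the summed *full*
  molecule length of uniquely aligned molecules (whole-molecule accounting,
  consistent with how yield is reported: published yield/theoretical ratios
  exceed count-based alignment rates because longer molecules align more
  often).

Theoretical coverage is `n_maps × mean length / genome size` with a 3.0 Gb
human default — the value that reproduces published coverage parentheticals
from their printed map counts and mean sizes exactly. The
small-missing-fragment ratio looks at reference fragments ≤ 2 kb strictly
inside aligned spans and reports the fraction whose two flanking cuts are
not both matched; with no qualifying fragment it is reported as absent, not
zero.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything from scratch on
synthetic references — 5–20 Mb for unit and property tests, 50 Mb with
~3,000 molecules for parameter recovery — sizes chosen so the whole suite
completes in a few minutes on one core while leaving estimator standard
errors an order of magnitude below the tolerances being checked. Every
random draw flows from a single user-supplied seed; equal seeds give
byte-identical output files end to end.

## Known limitations

* Scoring constants target the human-KpnI error regime; other enzymes or
  platforms with very different digestion or false-cut rates warrant
  recalibration via the same likelihood recipe (all constants are exposed).
* No split/chimeric alignments, molecule-vs-molecule overlap, or consensus
  assembly.
* The uniqueness margin is a calibrated heuristic, not a significance test;
  reported alignment rates are not comparable across references of very
  different size or repetitiveness.
* Circular chromosomes, methylation sensitivity and star activity are not
  modeled.
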