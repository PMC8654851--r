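---
title: "Mapping Cas9 cleavage sites from read-end pileups: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping Cas9 cleavage sites from read-end pileups: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgenseq)
```

## The measurement this package models

RGEN-seq-style libraries map double-strand breaks produced by an RNA-guided
endonuclease (RGEN; Cas9 complexed with a single guide RNA) directly from
genomic DNA, without PCR. Digested DNA is ligated to a truncated sequencing
adapter (p7L) that can only attach to free ends present at ligation time —
overwhelmingly the RGEN cut ends. After random fragmentation, the
complementary truncated adapter (p5L) is ligated to the newly created ends.
Only molecules carrying one adapter of each kind form clusters on the
flowcell, so essentially every sequenced read starts at a cut end. In the
alignment, a cleavage site therefore appears as two opposing pileups of read
5' ends: forward-strand reads starting at the breakpoint and running right,
reverse-strand reads starting one base left of it and running left. SpCas9
cuts bluntly 3 bp upstream of its NGG PAM, which ties every genuine pileup
junction to a nearby protospacer placement.

`rgenseq` implements both halves of this picture: a generative model of the
chemistry (so every downstream statistic can be tested against planted
ground truth), and the detection/scoring/diagnostic machinery a user would
run on real alignments.

## Coordinate conventions

All coordinates are 0-based, half-open (BED convention). For a plus-strand
protospacer occupying `[s, s+20)` with PAM at `[s+20, s+23)`, the blunt-cut
breakpoint coordinate is `s + 17` — the first base 3' of the break on the
forward strand, leaving exactly 3 protospacer bases between break and PAM.
The minus strand is the mirror image: for a forward-strand `CCN` image at
`[t, t+3)` with the reverse-complemented protospacer at `[t+3, t+23)`, the
breakpoint is `t + 6`. A productive read from the PAM-proximal flank is a
read whose 5' end sits at the breakpoint; the distal-flank read's 5' end
sits at breakpoint − 1 on the opposite strand. `pam_distance()` reports the
break-to-PAM gap in protospacer orientation and equals 3 on end-repaired
data for both strands.

## The cleavage model

Cas9 is a single-turnover enzyme: once it cleaves, it stays bound, so site
recovery as a function of concentration reflects occupancy rather than
catalytic cycling. We model per-copy cleavage as a Bernoulli event with Hill
saturation

$$p(C) = \frac{C^h}{C^h + K^h},$$

where `C` is the RGEN concentration (nM), `K` the site's affinity (the
concentration of half-maximal cleavage, `affinity_K` in `plant_sites()`),
and `h` the Hill coefficient (default 1). Each genome copy is cleaved at
each site independently at most once. No kinetic equation is prescribed by
the chemistry itself; this is the simplest saturating occupancy model
consistent with single-turnover behaviour, and it reproduces the sigmoid
growth of recovered sites across a 16–1024 nM concentration sweep.

In `concentration_response()` the concentration grid shares randomness: each
(site, copy) pair draws one uniform and is cleaved at every concentration
whose `p(C)` exceeds it. Realized cleavage counts are therefore exactly
non-decreasing in `C`, separating the model's monotonicity from sampling
noise. The optional `read_budget` emulates a fixed sequencing run: when the
library yields more productive molecules than the budget, reads are
down-sampled, so at high concentration many newly cleaved low-affinity sites
share the same total depth — this, together with the influx of low-score
sites, is what makes the median site score fall after its initial rise.

## The library-chemistry model

Each cleaved molecule yields up to two productive reads, one per flank,
each accepted independently with probability `p7L_ligation_efficiency`
(default 0.9). With `end_repair = TRUE` both 5' ends sit exactly at the
breakpoint.

With `end_repair = FALSE` the PAM-distal end is degraded ("temporal
bidirectional degradation" of the cleavage product, observed as skewed flank
coverage in un-repaired libraries). We model degradation depth as a
geometric offset `k` with mean `resection_mean` (bp), shifting the distal 5'
end away from the cut, and let ligation of a degraded end succeed with
probability `theta^k`, where `theta = resection_mean / (1 + resection_mean)`
is the same geometric continuation probability. One parameter thus controls
both observable consequences of degradation: shifted distal ends among the
reads that survive, and a depleted distal flank. At `resection_mean = 5`
the distal flank retains roughly 55% of the proximal count, giving median
per-site skewness near 30% versus under 2% with end repair on — the
direction and rough magnitude seen when comparing repaired and un-repaired
libraries.

Background breaks (pre-existing nicks, handling damage, residual adapter)
are uniform: `background_break_rate` is the expected number of background
cut ends per kb per genome copy, each yielding at most one read at the
ligation efficiency on a random strand. The rate is a free parameter of the
simulator, not an estimate from any particular dataset; the default is 0 and
the benchmark fixture uses 2×10⁻⁵ (a few hundred background reads per
190k-read library).

The simulator emits coordinate-sorted SAM directly (with `@SQ` lines
matching the generated FASTA), so tests need no external aligner, and
sequencing-error models, quality-score variation and adapter artifacts are
deliberately out of scope. Reads that would extend past a contig end are
truncated, or dropped (with a message) below 20 bp.

### What the simulator does not emulate

Passing recovery tests on these simulations shows that the caller correctly
inverts this generative model; it does not bound performance on real data,
where mapping ambiguity in repeats, chromatin-accessibility artifacts,
non-blunt cut heterogeneity beyond the geometric model, GC-dependent
coverage and structural variation all add failure modes that the uniform
i.i.d. genome and ideal alignments lack.

## Planted truth sets

`plant_sites()` writes protospacer+PAM placements (strand-aware, exact
mismatch counts at random positions, concrete PAM drawn from the pattern) at
positions at least 200 bp apart and 100 bp from contig ends. Because a
random megabase is expected to contain a few chance placements within 5–6
mismatches of any 20-mer, planting alone cannot guarantee a clean truth set:
after planting, the genome is scanned (`enumerate_genome_matches()`) and any
unintended placement at up to the maximum planted mismatch count has one PAM
base mutated, iterating until the scan returns exactly the planted sites.
Positions are re-drawn instead whenever a chance hit overlaps a planted
placement and cannot be disrupted without touching it.

## Detection and scoring

A site's score is the sum of read 5'-end counts on both strands in a 10-bp
window centered on the cut. "Centered" is ambiguous for an even width; we
fix the window as the half-open `[c − w/2, c + w/2)`, i.e. positions
`c−5 … c+4` for the default `w = 10`.

Candidate generation is signature-first (genome-wide from the track, with
`enumerate_genome_matches()` available as an optional restriction), with
three filters:

* **Score threshold** — window score ≥ `min_score` (default 5).
* **Bidirectionality** — at least one forward- and one reverse-strand end in
  the window (default on). Genuine cuts produce both flanks; one-sided
  spikes are usually background. The filter is toggleable because heavy
  distal degradation can empty one flank.
* **Junction consistency** — a candidate center `c` must have a forward end
  at `c` or a reverse end at `c − 1`. The window score is constant over a
  9-position plateau around a clean cut, so score alone cannot localize the
  breakpoint; requiring the center to sit at an observed end junction pins
  the candidate to the breakpoint, which is where the pileups terminate by
  construction of the chemistry. The intact proximal flank anchors the
  junction even when the distal flank is degraded.

Overlapping candidates within one window width are reduced by non-maximum
suppression (highest score kept, ties broken leftmost). Each surviving
candidate is then matched against the guide: every protospacer+PAM placement
on either strand whose implied breakpoint lies within `position_tolerance`
(default 2 bp) of the candidate is enumerated, and among placements with a
matching PAM and at most `max_mismatches` (default 7, reflecting how
permissive biochemical screens are at 6–7 mismatches) the winner minimizes
(mismatches, |implied breakpoint − candidate|, plus strand, leftmost) — a
fully specified tie-break so outputs are reproducible. The reported position
is the placement's implied breakpoint, and the stored score is recomputed
there, so `window_score(track, chrom, start) == score` holds for every
emitted call.

## Diagnostics

* `skewness(L, R) = 100·|L−R|/(L+R)`, undefined (NA) when both flanks are
  empty. `site_skewness()` counts ends in `[cut − flank, cut)` and
  `[cut, cut + flank)` with `flank = 200` bp — large enough to capture
  trimmed ends at `resection_mean ≤ 20`, small enough to stay inside the
  200-bp planting separation — and labels sides proximal/distal by the
  matched strand (PAM side proximal); the value itself is symmetric.
* `productive_read_fraction()` is the percentage of mapped read ends within
  ±5 bp of a known cut; the tolerance is this package's choice.
* `saturation_curve()` subsamples the track at each fraction. Subsampling
  assigns each read one uniform draw under the seed and keeps it wherever
  the draw is below the fraction, so smaller samples are subsets of larger
  ones and recovered-site counts are monotone by construction rather than up
  to sampling noise (independent subsets would show the same trend, noisier).
* `score_stats_by_mismatch()` pools 0–3 mismatches into one group (the
  convention used when comparing detection methods) and reports per-group
  count, median and variance, optionally on log10 scores.

## Comparing site sets

`merge_site_sets()` clusters sites across inputs by single linkage at a
5-bp default tolerance (caller jitter of ±2 bp plus end heterogeneity);
single linkage merges borderline pairs symmetrically and is the one place
our set counts can differ from tools using fixed binning. Strand is ignored
when merging: a cleavage site is a genomic breakpoint. `combination_counts()`
reports UpSet-style distinct mode (exact combination; counts partition the
merged rows) and intersect mode (at least the combination).
`score_correlation()` computes Pearson r and R² over shared sites and
refuses fewer than three.

## Benchmark fixtures and problem sizes

The packaged benchmark (`standard_fixture()`) is a 1-Mb genome with 12
planted sites at 0–6 mismatches on alternating strands, affinities
log-spaced over 16–64 nM, 10,000 template molecules at 256 nM, end repair
on, ligation efficiency 0.9 and low background — about 190k productive
reads, i.e. heavily oversequenced so that subsampling probes the
low-depth regime. The test suite uses this fixture for recovery, offset-law,
saturation and round-trip checks; replicate-correlation tests use 36 sites
on 400 kb at ~1,000 copies (over 1,100 expected reads per site), and
concentration sweeps use 20 sites with affinities spanning 8–800 nM on
300 kb with a 2,000-read budget. These sizes keep the whole suite within a
couple of minutes on a single core while leaving every tested contrast far
from its decision boundary.

## Known limitations

* The caller assumes blunt, fixed-offset cuts; nucleases with staggered or
  variable cut geometry would need a different junction model.
* Guide matching is Hamming-only: DNA/RNA bulges are not considered, and
  only a single user-supplied 3-mer IUPAC PAM is searched.
* The simulator plants sites on one contig and models neither sequencing
  error nor mapping ambiguity; `load_read_starts()` however accepts any
  coordinate-sorted, indexed multi-contig BAM.
* Concordance with any specific external calling pipeline's internal
  thresholds is not promised — only the scoring and conventions documented
  here.

## A worked example

```{r example, eval = FALSE}
library(rgenseq)

guide <- random_guide(7)
spec <- data.frame(mismatches = c(0, 1, 2, 3), strand = c("+", "-", "+", "-"),
                   affinity_K = c(16, 24, 32, 48))
cfg <- sim_config(genome_length = 1e5, genome_copies = 500, seed = 7)
lib <- simulate_library(guide, spec, cfg)

calls <- call_cut_sites(lib$track, lib$genome, lib$guide)
recovery_table(calls, lib$truth)
site_skewness(lib$track, calls)
saturation_curve(lib$track, lib$genome, lib$guide,
                 fractions = c(0.1, 0.5, 1), seed = 7)
```
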