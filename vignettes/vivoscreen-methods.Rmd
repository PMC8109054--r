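---
title: "Scoring in vivo pooled CRISPR screens with vivoscreen"
author: "vivoscreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring in vivo pooled CRISPR screens with vivoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vivoscreen)
```

## The problem

A pooled CRISPR knockout screen run in transplanted animals asks a simple
question per gene: when this gene is disrupted, do leukemia (or other
engrafting) cells expand or disappear between the transduced input pool
(T0) and the tissue harvested at the end of the assay (T12)? The readout
is sequencing of the integrated sgRNA cassettes: each guide's share of
reads is a proxy for the abundance of the cells that carry it.

What makes the *in vivo* setting statistically distinctive is the
engraftment bottleneck. Only a random fraction of the transplanted cells
seeds disease in each recipient, so each mouse observes a multinomially
thinned version of the input pool before any selection acts. For a
486-guide library and a bottleneck of 2×10^5 cells, each guide enters each
mouse with only ~400 cells; guide-level trajectories are therefore noisy
and irreproducible mouse to mouse even for neutral guides. The screen
design this package is built around answers that with replication — five
recipient mice from one shared T0 pool — and a deliberately robust
statistic: the **median across-replicate fold change** per guide, and
gene-level calls based on **how many of a gene's guides** pass a
fold-change threshold, rather than on means or variance-weighted
statistics that a single engraftment-skewed mouse could dominate.

## The scoring model

For raw count $c_{gs}$ of guide $g$ in sample $s$ with pseudocount $k$:

$$\mathrm{rep}_{gs} = 10^6\,\frac{c_{gs}+k}{\sum_{g'}(c_{g's}+k)},\qquad
\mathrm{FC}_{gr} = \frac{\mathrm{rep}_{g,T12_r}}{\mathrm{rep}_{g,T0}},\qquad
M_g = \mathrm{median}_r\,\mathrm{FC}_{gr}.$$

Guides are ranked by $\log_2 M_g$ (the waterfall), and a gene is called a
**positive regulator** (its loss depletes the cells) when at least
`minGuides` (default 2) of its guides have $M_g \le 1/T$ and depleted
guides outnumber enriched ones; **negative regulator** symmetrically. The
threshold $T$ defaults to 2.0, i.e. $|\log_2 M_g| \ge 1$.

Choices worth making explicit:

* **Normalization.** Total-count scaling to reads per million is the
  de facto standard for pooled screens. The pseudocount (default 1 read)
  exists because strong dropouts — 30-fold and deeper depletion is
  expected for essential genes at this depth — can reach zero T12 counts,
  and the fold change must stay finite and strictly positive. With
  pseudocount 0 the representation is exactly scale invariant; columns
  always sum to 10^6.
* **Threshold semantics.** "Beyond a 2-fold median change" is applied
  symmetrically: enrichment at $M_g \ge 2$, depletion at $M_g \le 0.5$.
  The threshold is applied to the *median* of per-replicate fold changes,
  not to per-replicate values before the median.
* **Median convention.** Even replicate counts use the classical sample
  median (midpoint of the central pair). The log2 column is computed
  after the median, so it is exactly `log2(median_fc)`.
* **T0 structure.** One shared T0 sample (the pre-transplant pool,
  sequenced once) pairs against every mouse's T12 by default;
  per-replicate T0 samples pair by replicate label, and an explicit
  pairing table overrides both.
* **Ranking.** The published statistic defines only the guide counts, so
  the total order is completed deterministically: direction count
  (descending), then |median of the gene's guide-level log2 medians|
  (descending), then gene name. Two lists are emitted, one per direction.
* **Controls.** Nontargeting (NTC) guides are excluded from gene scoring
  and reported separately; the essential positive-control gene is scored
  like any other gene, which is precisely how it demonstrates that the
  screen works (all five of its guides should pass the depletion
  threshold).

No p-value or FDR machinery is attached: the screen's published analysis
is threshold counting with replicate medians, and this package implements
exactly that. Users who want significance statements should export the
count table to a dedicated rank-aggregation tool.

## Read counting

Screen reads have fixed structure: vector constant region, 20-nt spacer,
scaffold. `countReads()` therefore does anchored extraction — find the
anchor (default `GAAACACCG`, the 3' end of the hU6 constant region in
pLKO5-style vectors), take the next 20 bases, and look the result up in
the library — instead of full read alignment. At this read structure the
two approaches carry identical information, but anchored matching is
deterministic and fully specified. One mismatch can be allowed
(`maxMismatches = 1`): a spacer with no exact match is assigned to a
library guide at Hamming distance 1 only if that neighbor is unique;
otherwise the read counts as unassigned and is tallied as ambiguous. `N`
bases never match and are only absorbed by the mismatch budget. Reads are
searched in fixed orientation by default (amplicon primers fix strand);
`bothStrands = TRUE` enables reverse-complement search. Qualities are
parsed but not used for filtering. Per sample, assigned + unassigned
always equals reads processed. All coordinates in the package are
0-based, half-open.

## Editing quantification

`quantifyEditing()` measures the fraction of amplicon reads carrying a
CRISPR-induced indel at a guide's target site:

1. The cut site is placed 3 bp 5' of the PAM (between protospacer
   positions 17 and 18), strand-aware: spacer start $s$ gives cut $s+17$
   on the forward strand, $s+3$ in forward coordinates for a
   reverse-strand protospacer.
2. Each read is globally aligned to the amplicon (Needleman–Wunsch, unit
   costs) with deterministic tie-breaking — mismatch preferred over gap,
   deletion over insertion — and indels canonicalized to their leftmost
   equivalent placement, so a deletion in a homopolymer is always reported
   at the run's left edge. The alignment is implemented in C++ because it
   is the inner loop over thousands of reads.
3. Reads with edit distance above `maxEditDistanceFraction` (default 0.3)
   of their length are discarded as unalignable chimeras.
4. An aligned read is *edited* iff at least one indel's reference span
   intersects the window of ±`cutWindow` bases (default 3) around the cut
   site. The statistic is read-level: multiple indels, or one deletion
   spanning the whole window, count the read once. Substitution-only
   errors can never produce an edited call.

This indel-at-cut-window rule is the field-standard definition of
"% editing" for amplicon sequencing. The window of ±3 covers the
positional wobble of NHEJ repair products without picking up PCR or
sequencing noise away from the cut.

## What the simulator emulates

`simulateScreen()` generates screens with the study-design structure the
scoring method was built for, with stochasticity at each sampling stage
and deterministic expectation in between:

| stage | model | default |
|---|---|---|
| plasmid pool skew | lognormal(0, sd) per guide | sd = 0.5 |
| transduction | multinomial over plasmid proportions | 10^6 cells |
| engraftment per mouse | multinomial over T0 proportions | 2×10^5 cells |
| selection | deterministic growth of expected abundances | 12 days |
| sequencing | Dirichlet-multinomial per sample | 5×10^6 reads |

Fitness effects are planted per gene as **log2 growth multipliers over the
whole assay** applied to knocked-out cells; each targeting guide adds a
normal deviation (default sd 0.3) modeling variable guide efficacy, and
only a fraction `editingEfficiency` (default 0.9, matching measured
editing rates above 90%) of a guide's cells is actually knocked out — the
rest grow neutrally, which caps the observable depletion of even a lethal
gene at $\mathrm{eff}\cdot 2^{e} + (1-\mathrm{eff})$. The assay length
and doubling time only set the common baseline expansion, which cancels
in proportions; effects are "over the assay" by construction. The NTC is
pinned at effect 0.

The sequencing stage uses a Dirichlet-multinomial with per-guide
concentration `proportion × n_guides × seqDispersion` (default 1000), i.e.
a mild ~3% extra coefficient of variation on top of multinomial sampling
at screen scale. This parameterization was chosen over a total-
concentration reading of the same parameter because the latter would make
sequencing noise, not the engraftment bottleneck, the dominant variance
source — contradicting both the biology the simulator emulates and the
observed stability of nontargeting controls in such screens. With the
defaults, the bottleneck stage (~400 cells/guide/mouse, close to the
~500 cells per sgRNA the assayed gDNA corresponds to) dominates, null
guides stay within 2-fold in well over 95% of cases, and the
false-positive gene rate of the default classifier is below 5%.

What the simulator deliberately does **not** model: clonal birth–death
dynamics within a mouse (selection acts on expected abundances; the
spread of replicates comes from the bottleneck and sequencing stages),
cross-guide recombination, PCR jackpotting beyond the
Dirichlet-multinomial, immune-microenvironment interactions, and
multi-locus cutting by promiscuous guides. Passing recovery tests on
simulated screens therefore demonstrates that the analysis correctly
inverts this generative process, not that it is robust to every artifact
of real screens.

`simulateAmpliconReads()` plants indels (size uniform in 1–10 bp,
deletion/insertion coin-flip, deletions covering the cut coordinate,
insertions at the cut) in a fixed `round(n × fraction)` share of reads
and adds independent per-base substitution noise to all reads, emitting
truth labels for closed-loop testing of the editing quantifier.

## Numerical and degenerate-input choices

* All randomness flows from a single integer seed per entry point;
  identical configuration and seed give byte-identical outputs.
* `normalizeCounts()` refuses an all-zero sample when the pseudocount is
  0, naming the sample; `quantifyEditing()` refuses a read set with zero
  aligned reads (the fraction would be undefined).
* Truncated FASTQ input errors with the record index rather than
  silently dropping the tail.
* An empty library writes an empty FASTA without error; an empty read
  stream yields an all-zero count column with unassigned = 0.
* Spacer uniqueness violations are construction errors, not warnings; an
  optional Hamming-distance-1 cross-match check (`validateLibrary(...,
  crossMatch = TRUE)`) flags near-duplicate spacers, off by default
  because legitimate libraries can contain related family members.
* Waterfall ties keep stable input order; gene ranking is a
  deterministic total order (counts, then effect size, then name).

## Problem sizes used in the tests

The unit suite runs on miniature libraries (tens of guides, read depths
of 10^3–10^5) chosen so that each property is exercised in seconds; the
screen-scale checks (486 guides, five mice, 5×10^6 reads/sample, 20
replicate null screens; 10^4 amplicon reads) reproduce the study-scale
behavior — 5/5 depleted guides for a planted essential gene, ≥4/5
enriched for a planted negative regulator, ~95% measured editing — at
the simulator's default conditions. These sizes are the package's own
fixture choices and match the published screen's dimensions.

## Known limitations

* Anchored counting assumes the vector context is known; exotic vector
  designs need their own anchor (or an external aligner upstream,
  importing counts via `readCountsTsv()`).
* The editing quantifier's unit-cost alignment does not model long-range
  rearrangements or large structural variants; reads beyond the edit
  distance filter are simply discarded.
* Threshold counting has no error model: two guides scraping past a
  2.0-fold threshold is a hit by definition. That is faithful to the
  method it implements, and it is why the simulator's false-positive-rate
  property is part of the test suite.
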