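---
title: "Calling topological domain boundaries from banded Hi-C maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling topological domain boundaries from banded Hi-C maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(hictad)
library(dplyr)
```

## The problem

In *Drosophila*, high-resolution Hi-C (a 4-cutter enzyme, MboI, and 500 bp
bins) resolves topologically associating domains (TADs) down to a few
kilobases.  The boundaries between them are short elements (~500–2000 bp)
that coincide with insulator-protein binding sites, DNase-hypersensitive
regions, and polytene interbands.  `hictad` implements the complete
computational path from aligned Hi-C read pairs to called boundaries and
their sequence/feature characterization:

1. **pairs** — duplicate removal, read-orientation classification, and
   removal of short un-ligated "genomic" fragments;
2. **contact maps** — banded 500 bp binning, vanilla-coverage
   normalization, histogram-equalized display;
3. **boundaries** — coverage-weighted directionality scores and a
   heuristic boundary caller with restriction-site masking;
4. **enrichment** — metaplots, fold-enrichment fractions, interval
   concordance, and the four-way domain-termination sort;
5. **kmers** — exact-word counting in 41 × 500 bp windows and the
   3-vs-38-bin enrichment score;
6. **synthetic data** — a generator with planted truth that makes every
   stage testable without any external download.

## The directionality model

For bin $i$, let $U_i$ and $D_i$ be the summed contact counts linking the
bin to the windows 1–15 kb up- and downstream: the two proximal 500 bp
bins are skipped and the next 28 are summed on each side.  The raw
directionality is the log-ratio

$$ d_i = \log_{10}\frac{D_i + c}{U_i + c}, $$

with pseudocount $c = 1$ so the ratio is defined at zero coverage (the
smallest neutral regularizer; at usable coverage it is swamped by the
counts).  Low-coverage bins produce wildly noisy ratios, so scores are
weighted by the information they carry:

$$ d^w_i = (U_i + D_i)^{a}\, d_i, \qquad a = 0.5 . $$

Inside a domain $d^w$ hovers near zero or drifts smoothly; at a boundary
it flips sign sharply, from strongly negative (bins just upstream look
back into their domain) to strongly positive.  The caller exploits
exactly this signature:

* **candidates** — bins whose 5 upstream neighbours average below $-2$
  and whose 5 downstream neighbours average above $+2$ (all ten flank
  bins must be defined, i.e. not truncated by a chromosome end);
* **score** — $B_i = \sum_{k=1}^{5} d^w_{i+k} - \sum_{k=1}^{5} d^w_{i-k}$,
  the boundary strength used for ranking and sorting;
* **masking** — bins without a single GATC are invisible to an MboI assay
  and inflate neighbouring directionality; any bin with more than one
  such bin within a 5-bin radius has its score zeroed;
* **merging** — consecutive candidate bins describe the same transition
  (the window just slides by one bin), so runs are merged and only the
  maximal-$B$ bin (leftmost on ties, for determinism) is emitted.

Key parameter choices that were genuinely open, and how they were fixed:

* *Where the weight enters.*  The weight is applied multiplicatively,
  $d^w = w\,d$, and the $\pm 2$ candidate threshold is applied to these
  weighted scores — the minimal reading of weighting "these scores", and
  the selection step operates on "these directional scores".
* *Mask radius.*  The flank length (5 bins) is the only radius in play in
  the scoring step, so the mask radius defaults to it; it is exposed as
  `mask_radius` so the 30-bin directionality window can be tried instead.
* *Merging gap.*  Strictly consecutive candidates only (gap 0), the
  literal reading of merging "adjacent bins".
* *Raw vs normalized counts.*  Directionality operates on raw counts
  (counts are "assigned to bins", then scored); since
  `directionality()` consumes whatever counts its map carries, passing a
  `vc_normalize()`d map gives the sensitivity check.

## The contact-map container

Maps are stored per chromosome as upper-triangle sparse triplets limited
to ±500 kb of the diagonal — the band is the entire data model, matching
how the maps are used (directionality needs 15 kb; display rarely needs
more than a few hundred kb).  Consequences of that choice:

* row sums for vanilla coverage are computed within the band;
* "vanilla coverage" is a single balancing pass
  $M'_{ij} = M_{ij}/(s_i s_j)$, not iterative correction; zero-coverage
  rows yield zeros, never NaN, and the result is rescaled so the mean of
  nonzero cells is preserved (a pure display convention);
* the display transform takes $\log_{10}$ of positive cells and
  histogram-equalizes them over `n_gray_levels`; it is a monotone rank
  transform, hence invariant to global rescaling, and leaves zeros at
  background intensity 0;
* bin coordinates are 0-based half-open, BED-compatible, with
  `bin = floor(pos5 / 500)`.

## Read-pair filtering

Only the four-orientation convention needed fixing: with the leftmost end
first, `(+,-)` is **in-out** — the convergent configuration a plain
genomic fragment produces — `(-,+)` is out-in, `(+,+)` in-in, `(-,-)`
out-out.  Un-ligated fragments contaminate real libraries as a hump of
in-out pairs spanning roughly 150–500 bp, so `filter_genomic_contamination()`
removes intra-chromosomal in-out pairs spanning `< 500` bp and touches
nothing else — trans pairs and the other three classes pass through at
any span.  Duplicates are collapsed on 5′ coordinates alone (strand
ignored), keeping the first occurrence.

## The k-mer score

For every word of length 4–7, occurrences (word + reverse complement,
pooled under the lexicographically smaller key) are counted per 500 bp
bin across 41 bins centered on each boundary bin (±10 kb), summed over
boundaries.  The enrichment is

$$ E = \frac{\text{mean count over the 3 central bins}}
           {\text{mean count over the remaining 38 bins}} . $$

Two conventions the score definition leaves open:

* *Overlaps and palindromes.*  An occurrence is counted at every position
  whose leftmost base lies in the bin — overlapping occurrences all
  count, and words may extend past the bin edge.  Self-complementary
  words (GATC, …) are counted once per position; naive pooling of both
  strand scans would exactly double them.
* *Zero-background words.*  Words never seen in the 38 flank bins get an
  infinite $E$ rather than a pseudocounted one (the headline words are
  high-frequency, and any pseudocount choice would silently reorder the
  rare-word tail); they rank among themselves by central count.

One caveat follows from the leftmost-base rule: strand symmetry of $E$ is
exact only for occurrences that do not straddle a bin edge (a straddling
occurrence is assigned to the adjacent bin after reverse-complementing).
The strand-invariance test therefore plants words at bin-interior
positions.

## Enrichment statistics

`fraction_enriched()` reports the percentage of boundaries whose signal
within ±1.5 kb exceeds twice a background level.  The background and the
window summary are both unstated degrees of freedom; the defaults are the
chromosome-wide (length-weighted) track mean and the **maximum** 500 bp
bin in the window — boundaries are sub-bin elements and ChIP peaks are
sharp, so a window mean would dilute a genuine peak — with `"flank"`
background and `"mean"` summary exposed as alternatives.
`match_within()` matches midpoint-to-midpoint, each query element counted
once; the reverse direction is the same call with the lists swapped.
`fourway_sort()` compares each anchor's 50 kb up- and downstream signal
totals to the median of all side-totals, with strict comparisons: when
every side-total equals the median (constant track), every anchor falls
in the final "both below" category.

## What the generator emulates — and what it does not

`simulate_contact_map()` draws independent Poisson counts around

$$ \lambda_{ij} = \beta_{ij}\, b\, s^{-\alpha}, \qquad s = |i - j| \ge 1, $$

where $b$ is the expected count at 1-bin separation, $\alpha$ the decay
exponent, and $\beta_{ij}$ the domain term: $\beta$ for intra-domain
pairs, 1 across a boundary, and the mixture $q\beta + (1-q)$,
$q = \prod(1-\text{penetrance})$ over intervening breakpoints, for
partially penetrant boundaries — modelling boundaries formed in only a
fraction of nuclei, as the variable-boundary pattern in real maps
suggests.  Poisson noise is the standard count model for Hi-C and
matches the motivation for coverage-weighting the directionality.
Defaults ($\alpha = 1$, $\beta = 8$, $b = 50$, penetrance 1) produce
maps on which domain structure is unmistakable but noisy at the bin
level, comparable to a deeply sequenced 500 bp map.

`simulate_read_pairs()` emits ligation pairs proportional to matrix
counts with uniform strands (so the four orientations are ~25% each) and
a `contamination` fraction of convergent genomic fragments with spans
uniform on [150, 500] bp — only the range of the real hump is known, so
the flat span law is the least-informative choice.
`simulate_sequence_and_tracks()` plants motif words (4 copies per bin by
default) in the central 3 bins of each boundary, guarantees a GATC in
every non-cut bin while scrubbing all GATCs from declared cut-deficient
bins (so the annotated mask equals the planted truth exactly), and lays
Gaussian-smoothed peaks (height 5 over background 1, σ = 300 bp) at a
`peak_fraction = 0.6` subset of boundaries — emulating marks present at
a majority, but not all, boundaries so that recovered colocalization
percentages are informative rather than saturated.

Not emulated: realistic nucleotide composition, chromatin states,
sequencing error, inter-arm/Rabl geometry, loops, or nested domain
hierarchies.  Passing tests on this generator demonstrate that the
*operations* are correct and that the caller recovers block-structured
insulation under Poisson noise; they do not certify performance on real
libraries, where coverage biases, repeats, and unmodelled structures
matter.

## Numerical choices and degenerate inputs

* Penetrance is capped at $1 - 10^{-12}$ inside the log-space cumulative
  product, so fully penetrant boundaries are handled on the same path
  (cross-boundary multiplier $1 + 7\times10^{-12}(\beta-1)$, numerically 1).
* The diagonal carries no ligation signal: the generator leaves it
  empty, and the directionality window starts at 3 bins out by default.
* Ties for maximal $B$ inside a merged block go to the leftmost bin.
* Empty inputs: empty pair lists dedup/filter to empty; a map with no
  candidate bins yields an empty call table; an all-zero map normalizes
  to itself.
* `aggregate_signal()` excludes uncovered cells from means and drops
  anchors with more than half their columns missing (with a warning).

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on generated
data at desk scale, chosen so the whole suite completes in well under a
minute while every statistical check retains power: oracle-equivalence
sweeps use 50 random maps of ≤ 400 bins; boundary recovery uses 20
replicates of a 400-bin chromosome with five planted boundaries
($\beta = 8$, background 50); the decay-slope regression uses a 3000-bin
chromosome; read-pair statistics use $10^5$ pairs; k-mer rankings use
~11 boundaries on a 250 kb chromosome.  At these sizes recovery is
expected to be essentially perfect (recall/precision ≥ 0.9 with margin);
the interesting regressions are the exact ones — oracle agreement
bin-for-bin, window arithmetic, mask suppression, and the closed-form
filtering mixture.

## Known limitations

* The caller emits point boundaries, not domain intervals; segmentation,
  loop calling, and compartment eigenvectors are out of scope.
* Vanilla coverage is one balancing pass; maps with strong systematic
  coverage gradients would need iterative correction, deliberately not
  provided here.
* The k-mer score has no significance model; it is a descriptive ranking.
* Whether the ±2 candidate threshold should apply to weighted or raw
  scores is not decidable from the method description alone; weighted is
  implemented (see above), and `directionality_params()` exposes every
  constant so the alternative reading costs one argument.

## A worked run

```{r pipeline}
model <- domain_model(2e5, breakpoints = c(80, 160, 240, 320),
                      beta = 8, background = 50)
sim <- simulate_contact_map(model, seed = 1, max_separation = 3e4,
                            cut_deficient_bins = c(30, 31))

pairs <- simulate_read_pairs(sim$map, 5e4, contamination = 0.15, seed = 2) |>
  classify_orientation()
glance(orientation_summary(pairs))

filtered <- pairs |> dedup_pairs() |> filter_genomic_contamination()
map <- bin_contacts(filtered, "chrS", chrom_length = 2e5,
                    max_separation = 3e4)

st <- simulate_sequence_and_tracks(sim$truth, seed = 3)
map <- annotate_cut_deficient_bins(map, st$genome)

calls <- call_boundaries(directionality(map))
as_tibble(calls)
```

The planted boundaries sit at bins `r paste(c(80, 160, 240, 320), collapse = ", ")`;
the calls land within one bin of each.  Boundary-feature colocalization
and sequence analysis then run off the same objects:

```{r enrich}
anchors <- as_tibble(calls)[, c("chrom", "start", "end", "score")]
fraction_enriched(st$track, anchors)
kmer_enrichment(count_words(st$genome, anchors, k = 7)) |> head(3)
```
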