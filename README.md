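# hictad

Post-alignment Hi-C analysis for high-resolution (500 bp) *Drosophila*-style
contact maps: read-pair filtering, banded contact matrices, vanilla-coverage
normalization with histogram-equalized display, coverage-weighted
directionality scores, a heuristic caller for topologically associating
domain (TAD) boundaries, boundary–feature colocalization statistics, and
exact-word (k-mer) enrichment analysis of boundary sequences.  A
synthetic-data generator with planted truth makes the entire pipeline
testable offline.

## Who this is for

Chromatin-topology analysts who start from aligned Hi-C read pairs (two
uniquely mapped ends, each a chromosome / 5′ position / strand) and want
high-resolution boundary calls plus the standard downstream
characterization — metaplots of ChIP/DNase signal around boundaries,
fold-enrichment percentages, concordance between boundary lists, and
boundary sequence composition.

## The method in brief

For each 500 bp bin *i*, sum the contacts linking it to the regions 1–15 kb
upstream (*U*) and downstream (*D*) (skip 2 bins, sum the next 28 on each
side), and form the coverage-weighted directionality

> d\_i = log10((D + 1) / (U + 1)),  d\_i^w = (U + D)^0.5 · d\_i .

A boundary is a sharp sign flip in d^w: candidate bins have mean weighted
directionality < −2 over the 5 upstream bins and > +2 over the 5 downstream
bins; the boundary score is

> B = Σ d^w(downstream 5) − Σ d^w(upstream 5) .

Bins near MboI-invisible (GATC-free) bins are zeroed, runs of consecutive
candidates are merged to their maximal-B bin, and calls are ranked by B.
K-mer analysis counts every 4–7-mer (word + reverse complement, pooled) in
41 × 500 bp bins around each boundary and scores enrichment as the mean of
the 3 central bins over the mean of the remaining 38.

See `vignettes/boundary-calling.Rmd` for the full model, parameter
rationale, and the generator's scope.

## Worked example

```r
library(hictad)
library(dplyr)

model <- domain_model(2e5, breakpoints = c(80, 160, 240, 320),
                      beta = 8, background = 50)
sim <- simulate_contact_map(model, seed = 1, max_separation = 3e4,
                            cut_deficient_bins = c(30, 31))

pairs <- simulate_read_pairs(sim$map, 5e4, contamination = 0.15, seed = 2) |>
  classify_orientation()
glance(orientation_summary(pairs))
#> # A tibble: 1 × 6
#>   `in-in` `in-out` `out-in` `out-out` n_cis n_trans
#>     <dbl>    <dbl>    <dbl>     <dbl> <int>   <int>
#> 1   0.211    0.363    0.215     0.211 50000       0

filtered <- pairs |> dedup_pairs() |> filter_genomic_contamination()
map <- bin_contacts(filtered, "chrS", chrom_length = 2e5,
                    max_separation = 3e4)
st <- simulate_sequence_and_tracks(sim$truth, seed = 3)
map <- annotate_cut_deficient_bins(map, st$genome)

calls <- call_boundaries(directionality(map))
as_tibble(calls)
#> # A tibble: 4 × 8
#>   chrom   bin  start    end score block_start block_end  rank
#>   <chr> <int>  <int>  <int> <dbl>       <int>     <int> <int>
#> 1 chrS     79  39500  40000  66.4          77        81     1
#> 2 chrS    320 160000 160500  64.5         318       322     2
#> 3 chrS    159  79500  80000  63.1         157       161     3
#> 4 chrS    239 119500 120000  56.7         238       242     4
```

The excess of in-out pairs over the other three orientation classes (36%
vs ~21%) is the injected genomic contamination, which the span filter then
removes.  The four calls land within one 500 bp bin of the four planted
boundaries (80, 160, 240, 320), ranked by boundary strength B.  Downstream
characterization runs off the same objects:

```r
anchors <- as_tibble(calls)[, c("chrom", "start", "end", "score")]
fraction_enriched(st$track, anchors)
#> # A tibble: 1 × 3
#>   n_anchors n_enriched percent
#>       <int>      <int>   <dbl>
#> 1         4          2      50

kmer_enrichment(count_words(st$genome, anchors, k = 7)) |> head(3)
#> # A tibble: 3 × 5
#>   word        k central_mean flank_mean enrichment
#>   <chr>   <dbl>        <dbl>      <dbl>      <dbl>
#> 1 CACACAC     7        13.7       0.553       24.7
#> 2 ACACACA     7         8.67      0.447       19.4
#> 3 ACGATAC     7        10         0.579       17.3
```

Half the called boundaries carry a >2-fold ChIP-like peak within ±1.5 kb
(the generator plants peaks at 60% of boundaries by default), and the two
planted motif families (a CACA repeat and a CGATA-context word) top the
7-mer enrichment ranking.  `autoplot()` methods render contact maps,
directionality tracks, metaplot matrices, and pair-QC histograms.

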