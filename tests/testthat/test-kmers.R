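# Exact-word counting around boundaries and the 3-vs-38 enrichment score,
# checked against brute-force string scans.

make_genome <- function(seq_str, chrom = "chrT") setNames(seq_str, chrom)

test_that("homopolymer counting follows the leftmost-base rule", {
  # 41 full bins plus trailing context: every interior bin yields 500
  # leftmost AAAA starts (occurrences may extend into the next bin);
  # pooled canonical partner TTTT contributes 0
  L <- 41 * 500 + 10
  g <- make_genome(strrep("A", L))
  anch <- tibble::tibble(chrom = "chrT", start = 20 * 500,
                         end = 21 * 500)           # center bin 20
  kc <- count_words(g, anch, k = 4)
  aaaa <- dplyr::filter(kc, word == "AAAA")
  expect_equal(nrow(aaaa), 41L)
  expect_equal(sort(unique(aaaa$offset)), -20:20)
  expect_true(all(aaaa$count == 500))
  # brute-force oracle on one interior bin agrees
  expect_equal(oracle_count_word(strrep("A", L), "AAAA", 10 * 500, 11 * 500),
               500L)
  # at a window edge with no trailing context the brute force gives 497:
  # an isolated 500-mer has starts 0..496 only
  expect_equal(oracle_count_word(strrep("A", 500), "AAAA", 0, 500), 497L)
  # a word absent from the genome counts zero everywhere
  expect_true(all(dplyr::filter(kc, word == "ACGT")$count == 0))
})

test_that("word and reverse complement pool under the canonical key", {
  # plant ACGGTCA (revcomp TGACCGT) on both strands of an A-background
  L <- 41 * 500 + 10
  chars <- rep("A", L)
  w <- "ACGGTCA"; rc <- oracle_revcomp(w)
  set.seed(3)
  starts <- sample(0:(L - 520), 30)
  for (s in starts[1:15]) chars[(s + 1):(s + 7)] <- strsplit(w, "")[[1]]
  for (s in starts[16:30]) chars[(s + 1):(s + 7)] <- strsplit(rc, "")[[1]]
  g <- make_genome(paste(chars, collapse = ""))
  anch <- tibble::tibble(chrom = "chrT", start = 20 * 500, end = 21 * 500)
  kc <- count_words(g, anch, k = 7)
  canon <- min(w, rc)
  total <- sum(dplyr::filter(kc, word == canon)$count)
  seq_str <- paste(chars, collapse = "")
  expect_equal(total,
               oracle_count_word(seq_str, w, 0, 41 * 500) +
                 oracle_count_word(seq_str, rc, 0, 41 * 500))
  expect_gt(total, 0)
  # the non-canonical orientation does not appear as a separate row
  expect_equal(nrow(dplyr::filter(kc, word == max(w, rc))), 0L)
})

test_that("palindromic words are counted once per position, never doubled", {
  # GATC is self-complementary: a constructed sequence with exactly 5
  # occurrences in the center bin must report 5, not 10
  L <- 41 * 500 + 10
  chars <- rep("A", L)
  for (s in 20 * 500 + c(10, 100, 200, 300, 400)) {
    chars[(s + 1):(s + 4)] <- c("G", "A", "T", "C")
  }
  seq_str <- paste(chars, collapse = "")
  g <- make_genome(seq_str)
  anch <- tibble::tibble(chrom = "chrT", start = 20 * 500, end = 21 * 500)
  kc <- count_words(g, anch, k = 4)
  center <- dplyr::filter(kc, word == "GATC", offset == 0)
  expect_equal(center$count, 5)
  expect_equal(oracle_count_word(seq_str, "GATC", 20 * 500, 21 * 500), 5L)
})

test_that("anchors without full window context are skipped and tallied", {
  g <- make_genome(strrep("A", 30 * 500))
  anch <- tibble::tibble(chrom = "chrT",
                         start = c(2 * 500, 14 * 500, 28 * 500),
                         end = c(3 * 500, 15 * 500, 29 * 500))
  expect_error(count_words(g, anch, k = 4), "context")   # none fits 41 bins
  g2 <- make_genome(strrep("A", 60 * 500))
  anch2 <- tibble::tibble(chrom = "chrT", start = c(2, 25, 58) * 500,
                          end = c(3, 26, 59) * 500)
  kc <- count_words(g2, anch2, k = 4)
  expect_equal(attr(kc, "n_anchors_used"), 1L)
  expect_equal(attr(kc, "n_skipped"), 2L)
})

test_that("enrichment scores implement the 3-vs-38 split", {
  # constructed toy: 4 in each central bin, 1 in each of the other 38 -> 4
  counts <- tibble::tibble(word = "AACCGGT", k = 7, offset = -20:20,
                           count = ifelse(abs(-20:20) <= 1, 4, 1))
  expect_equal(kmer_enrichment(counts)$enrichment, 4)
  # uniform counts -> E = 1
  counts$count <- 3
  expect_equal(kmer_enrichment(counts)$enrichment, 1)
  # the window is 41 bins: 3 central + 38 background
  expect_equal(length(-20:20), 41L)
  expect_equal(sum(abs(-20:20) <= 1), 3L)
  expect_equal(sum(abs(-20:20) > 1), 38L)
  # zero flank, positive center -> infinite E ranked by central count
  two <- dplyr::bind_rows(
    tibble::tibble(word = "AAAACCC", k = 7, offset = -20:20,
                   count = ifelse(abs(-20:20) <= 1, 2, 0)),
    tibble::tibble(word = "AAAAGGG", k = 7, offset = -20:20,
                   count = ifelse(abs(-20:20) <= 1, 9, 0)),
    tibble::tibble(word = "AAAATTT", k = 7, offset = -20:20,
                   count = ifelse(abs(-20:20) <= 1, 5, 1)))
  ke <- kmer_enrichment(two)
  expect_true(all(is.infinite(ke$enrichment[1:2])))
  expect_equal(ke$word[1:2], c("AAAAGGG", "AAAACCC"))
})

test_that("a word planted at boundaries tops the 7-mer ranking", {
  # enough anchors that background 7-mer frequencies concentrate and the
  # planted word's central excess dominates every chance fluctuation
  model <- domain_model(2.5e5, breakpoints = seq(40, 440, by = 40),
                        background = 50)
  sim <- simulate_contact_map(model, seed = 81, max_separation = 2e4)
  st <- simulate_sequence_and_tracks(sim$truth, motif_words = "AGTCGAT",
                                     seed = 82, motif_rate = 4)
  anch <- tibble::tibble(chrom = "chrS",
                         start = sim$truth$planted_boundaries * 500,
                         end = (sim$truth$planted_boundaries + 1) * 500)
  ke <- kmer_enrichment(count_words(st$genome, anch, k = 7))
  canon <- min("AGTCGAT", oracle_revcomp("AGTCGAT"))
  expect_equal(ke$word[1], canon)
  # central offsets dominate the planted word's profile
  kc <- count_words(st$genome, anch, k = 7)
  prof <- dplyr::filter(kc, word == canon)
  expect_gt(min(prof$count[abs(prof$offset) <= 1]),
            max(prof$count[abs(prof$offset) > 1]))
})

test_that("strand invariance: revcomp genome + mirrored anchors give equal E", {
  # A-background with a word planted at bin-interior positions (offset 100
  # within each chosen bin), so no informative occurrence straddles a bin
  # edge; leftmost-base assignment then mirrors bin-exactly
  L <- 41 * 500 + 10
  chars <- rep("A", L)
  w <- "ACGATAC"
  for (b in c(5, 19, 20, 21, 33)) {
    s <- b * 500 + 100
    chars[(s + 1):(s + 7)] <- strsplit(w, "")[[1]]
  }
  g <- make_genome(paste(chars, collapse = ""))
  anch <- tibble::tibble(chrom = "chrT", start = 20 * 500, end = 21 * 500)
  fwd <- kmer_enrichment(count_words(g, anch, k = 7))
  g_rc <- Biostrings::reverseComplement(load_genome(g))
  names(g_rc) <- "chrT"
  anch_rc <- tibble::tibble(chrom = "chrT", start = L - anch$end,
                            end = L - anch$start)
  rev <- kmer_enrichment(count_words(g_rc, anch_rc, k = 7))
  cmp <- dplyr::left_join(fwd, rev, by = c("word", "k"))
  expect_equal(nrow(cmp), nrow(fwd))
  expect_equal(cmp$central_mean.x, cmp$central_mean.y)
  expect_equal(cmp$flank_mean.x, cmp$flank_mean.y)
  expect_equal(cmp$enrichment.x, cmp$enrichment.y)
})

test_that("occurrence maps aggregate to the per-bin word counts", {
  model <- domain_model(6e4, breakpoints = c(40, 80), background = 50)
  sim <- simulate_contact_map(model, seed = 85, max_separation = 2e4)
  st <- simulate_sequence_and_tracks(sim$truth, motif_words = "CACACAC",
                                     seed = 86)
  anch <- tibble::tibble(chrom = "chrS",
                         start = sim$truth$planted_boundaries * 500,
                         end = (sim$truth$planted_boundaries + 1) * 500)
  om <- motif_occurrence_map(st$genome, anch, "CACACAC")
  expect_true(all(om$offset >= -10000 & om$offset < 10500))
  canon <- min("CACACAC", oracle_revcomp("CACACAC"))
  agg <- om |>
    dplyr::mutate(bin_offset = floor(offset / 500)) |>
    dplyr::count(bin_offset, name = "count")
  kc <- dplyr::filter(count_words(st$genome, anch, k = 7), word == canon,
                      count > 0)
  expect_equal(agg$count, kc$count[match(agg$bin_offset, kc$offset)])
  expect_equal(sum(agg$count), sum(kc$count))
  # planted word appears as a stripe at the central offsets for each anchor
  expect_true(all(sim$truth$planted_boundaries * 0 + 1 > 0))
  expect_gt(nrow(dplyr::filter(om, abs(offset) <= 750)), 0)
  # empty result for a word absent from a constructed genome
  gA <- make_genome(strrep("A", 41 * 500 + 10))
  anchA <- tibble::tibble(chrom = "chrT", start = 20 * 500, end = 21 * 500)
  expect_equal(nrow(motif_occurrence_map(gA, anchA, "GGGGGGG")), 0L)
})
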