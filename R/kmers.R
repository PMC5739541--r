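# Exact-word (k-mer) analysis of boundary sequences: counts of every word
# of length 4-7 in the 41 x 500 bp window centered on each boundary bin,
# and the 3-central-vs-38-flank enrichment score.

kmer_window_geometry <- function(anchors, seq_len_chr, bin_size, flank_bins, kmax) {
  mid <- floor(interval_mid(anchors$start, anchors$end))
  center_bin <- mid %/% bin_size
  win_start <- (center_bin - flank_bins) * bin_size
  win_end <- (center_bin + flank_bins + 1L) * bin_size
  ok <- win_start >= 0 & (win_end + kmax - 1L) <= seq_len_chr
  tibble(center_bin = center_bin, win_start = win_start,
         win_end = win_end, ok = ok)
}

#' Count DNA words around boundary anchors
#'
#' For every word of each length in `k`, counts occurrences in each of the
#' `2 * flank_bins + 1` bins (default 41 x 500 bp, spanning 10 kb on
#' either side of the anchor's bin), summed over anchors.  An occurrence
#' is counted at every position whose leftmost base lies in the bin, so
#' overlapping occurrences all count and words may extend past the bin
#' edge.  A word and its reverse complement are pooled under the
#' lexicographically smaller canonical key; self-complementary
#' (palindromic) words are counted once per position, never doubled.
#' Anchors lacking the full window context are skipped and tallied in the
#' `n_skipped` attribute.
#'
#' @param genome Genome (see [load_genome()]).
#' @param anchors BED-style tibble of boundary intervals.
#' @param k Word lengths (default `4:7`).
#' @param bin_size Window bin width in bp (default 500).
#' @param flank_bins Bins on either side of the anchor bin (default 20).
#' @return A long tibble of class `kmer_counts`: `word` (canonical), `k`,
#'   `offset` (bin offset, `-flank_bins..flank_bins`), `count`.
#' @export
count_words <- function(genome, anchors, k = 4:7, bin_size = 500,
                        flank_bins = 20) {
  dss <- load_genome(genome)
  kmax <- max(k)
  offsets <- seq.int(-flank_bins, flank_bins)
  acc <- lapply(k, function(kk) NULL)  # per-k word x offset matrices
  names(acc) <- as.character(k)
  n_used <- 0L; n_skipped <- 0L
  for (chr in unique(anchors$chrom)) {
    if (!chr %in% names(dss)) {
      abort(sprintf("Chromosome '%s' absent from the genome.", chr))
    }
    seq_chr <- dss[[chr]]
    geo <- kmer_window_geometry(anchors[anchors$chrom == chr, , drop = FALSE],
                                length(seq_chr), bin_size, flank_bins, kmax)
    n_skipped <- n_skipped + sum(!geo$ok)
    geo <- geo[geo$ok, , drop = FALSE]
    n_used <- n_used + nrow(geo)
    for (r in seq_len(nrow(geo))) {
      for (ki in seq_along(k)) {
        kk <- k[ki]
        starts <- geo$win_start[r] + (seq_along(offsets) - 1L) * bin_size
        views <- Biostrings::Views(seq_chr, start = starts + 1L,
                                   width = bin_size + kk - 1L)
        of <- Biostrings::oligonucleotideFrequency(views, width = kk)
        m <- t(of)   # words x offsets
        acc[[ki]] <- if (is.null(acc[[ki]])) m else acc[[ki]] + m
      }
    }
  }
  if (n_used == 0L) abort("No anchor has the full k-mer window context.")
  rows <- lapply(seq_along(k), function(ki) {
    m <- acc[[ki]]
    canon <- canonical_word(rownames(m))
    mc <- rowsum(m, canon)   # pools word + revcomp; palindromes appear once
    tibble(word = rep(rownames(mc), times = ncol(mc)),
           k = k[ki],
           offset = rep(offsets, each = nrow(mc)),
           count = as.vector(mc))
  })
  out <- bind_rows(rows)
  structure(out, class = c("kmer_counts", class(out)),
            bin_size = bin_size, flank_bins = flank_bins,
            n_anchors_used = n_used, n_skipped = n_skipped)
}

#' K-mer enrichment scores
#'
#' For each canonical word, `E` is the mean count over the three central
#' bins (the boundary bin and its immediate neighbours) divided by the
#' mean count over the remaining flanking bins (38 with the default
#' 41-bin window).  Words with a zero flank mean get an infinite `E` and
#' rank among themselves by central count; the table is sorted by `E`
#' descending.
#'
#' @param counts A [count_words()] table (or any tibble with `word`, `k`,
#'   `offset`, `count`).
#' @return A tibble: `word`, `k`, `central_mean`, `flank_mean`,
#'   `enrichment`, sorted by enrichment.
#' @export
kmer_enrichment <- function(counts) {
  out <- counts %>%
    group_by(.data$word, .data$k) %>%
    summarise(central_mean = mean(.data$count[abs(.data$offset) <= 1]),
              flank_mean = mean(.data$count[abs(.data$offset) > 1]),
              .groups = "drop") %>%
    mutate(enrichment = ifelse(.data$flank_mean > 0,
                               .data$central_mean / .data$flank_mean,
                               ifelse(.data$central_mean > 0, Inf, NA_real_))) %>%
    arrange(desc(.data$enrichment), desc(.data$central_mean))
  out
}

#' Per-anchor occurrence map for chosen words
#'
#' Base-pair offsets (relative to the anchor bin start) of every
#' occurrence of each word or its reverse complement within the k-mer
#' window, suitable for scatter rendering of motif positioning around
#' boundaries.  Aggregating the offsets per 500 bp bin reproduces the
#' [count_words()] row for the same canonical word.
#'
#' @inheritParams count_words
#' @param words DNA words to map.
#' @return A tibble: `anchor` (row index into `anchors`), `word`
#'   (canonical form), `offset` (bp, leftmost base relative to the anchor
#'   bin start).
#' @export
motif_occurrence_map <- function(genome, anchors, words, bin_size = 500,
                                 flank_bins = 20) {
  if (any(!grepl("^[ACGT]+$", words))) abort("Words must be over {A,C,G,T}.")
  dss <- load_genome(genome)
  kmax <- max(nchar(words))
  hits <- list()
  for (chr in unique(anchors$chrom)) {
    if (!chr %in% names(dss)) {
      abort(sprintf("Chromosome '%s' absent from the genome.", chr))
    }
    seq_chr <- dss[[chr]]
    rows <- which(anchors$chrom == chr)
    geo <- kmer_window_geometry(anchors[rows, , drop = FALSE],
                                length(seq_chr), bin_size, flank_bins, kmax)
    for (r in seq_len(nrow(geo))) {
      if (!geo$ok[r]) next
      for (w in words) {
        kk <- nchar(w)
        win <- Biostrings::subseq(seq_chr, start = geo$win_start[r] + 1L,
                                  end = min(geo$win_end[r] + kk - 1L,
                                            length(seq_chr)))
        scan_words <- if (is_palindrome_word(w)) w else {
          c(w, as.character(Biostrings::reverseComplement(Biostrings::DNAString(w))))
        }
        pos <- unlist(lapply(scan_words, function(sw) {
          Biostrings::start(Biostrings::matchPattern(sw, win))
        }))
        pos <- pos[pos <= geo$win_end[r] - geo$win_start[r]]  # leftmost base in window
        if (length(pos)) {
          hits[[length(hits) + 1L]] <- tibble(
            anchor = rows[r], word = canonical_word(w),
            offset = geo$win_start[r] + pos - 1L - geo$center_bin[r] * bin_size)
        }
      }
    }
  }
  if (!length(hits)) {
    return(tibble(anchor = integer(), word = character(), offset = integer()))
  }
  arrange(bind_rows(hits), .data$anchor, .data$word, .data$offset)
}
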