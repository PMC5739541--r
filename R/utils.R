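# Shared internal helpers.  Coordinates are 0-based, half-open (BED-style)
# throughout; bins are 0-based indices of width `bin_size`.

# positive scalar check used by most constructors
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number, not %s.",
                  name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

# interval midpoints (numeric; callers floor where a bp coordinate is needed)
interval_mid <- function(start, end) (start + end) / 2

# Sum of x over the trailing window [i - w, i - 1] (NA if any element NA or
# the window runs off the end).  stats::filter propagates NA, which is what
# the flank-window semantics need: a candidate requires all flank bins
# defined.
trailing_window_sum <- function(x, w) {
  y <- as.numeric(stats::filter(x, rep(1, w), sides = 1))  # sum over i-w+1 .. i
  out <- rep(NA_real_, length(x))
  if (length(x) > w) out[(w + 1L):length(x)] <- y[w:(length(x) - 1L)]
  out
}

# Sum of x over the leading window [i + 1, i + w]
leading_window_sum <- function(x, w) {
  y <- as.numeric(stats::filter(x, rep(1, w), sides = 1))
  out <- rep(NA_real_, length(x))
  if (length(x) > w) out[1:(length(x) - w)] <- y[(w + 1L):length(x)]
  out
}

# Count of TRUE in mask within [i - r, i + r], truncated at the ends.
centered_window_count <- function(mask, r) {
  cs <- c(0, cumsum(as.numeric(mask)))
  nb <- length(mask)
  i <- seq_len(nb)
  lo <- pmax(i - r, 1L)
  hi <- pmin(i + r, nb)
  cs[hi + 1L] - cs[lo]
}

#' Load a genome as a DNAStringSet
#'
#' Accepts a `Biostrings::DNAStringSet`, a named character vector of
#' sequences, or the path to a FASTA file.  Sequences are uppercased so that
#' soft-masked (lowercase) bases are counted like any other.
#'
#' @param genome A `DNAStringSet`, named character vector, or FASTA path.
#' @return A `Biostrings::DNAStringSet`, uppercased.
#' @export
load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    dss <- genome
  } else if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    dss <- Biostrings::readDNAStringSet(genome)
    names(dss) <- sub("\\s.*$", "", names(dss))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) {
      abort("A character-vector genome must be named by chromosome.")
    }
    dss <- Biostrings::DNAStringSet(toupper(genome))
  } else {
    abort("`genome` must be a DNAStringSet, a named character vector, or a FASTA path.")
  }
  Biostrings::DNAStringSet(toupper(dss))
}

# canonical (lexicographically smaller of word / reverse complement) key
canonical_word <- function(words) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  ifelse(words <= rc, words, rc)
}

is_palindrome_word <- function(words) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  words == rc
}

# derive a fresh sub-seed deterministically; keeps values well under 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}
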