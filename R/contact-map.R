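#' Banded contact map
#'
#' A per-chromosome symmetric Hi-C contact matrix in fixed-width bins,
#' stored as an upper-triangle sparse triplet tibble and restricted to bin
#' pairs within `max_separation` of the diagonal (the "band").  Bins are
#' 0-based; `counts` holds one row per stored cell with `bin1 <= bin2`.
#'
#' @param counts Tibble with integer/numeric columns `bin1`, `bin2`,
#'   `count` (0-based bins, `bin1 <= bin2`, non-negative counts).
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp (default 500).
#' @param n_bins Number of bins on the chromosome.
#' @param max_separation Band half-width in bp (default 500 kb).
#' @param bin_mask Optional logical vector of length `n_bins`; `TRUE` marks
#'   restriction-site-deficient (assay-invisible) bins.
#' @param discarded Tally of read pairs that fell outside the band or were
#'   inter-chromosomal when the map was binned.
#' @return An object of class `contact_map`.
#' @seealso [bin_contacts()], [vc_normalize()], [display_transform()]
#' @export
contact_map <- function(counts, chrom, bin_size = 500, n_bins,
                        max_separation = 5e5, bin_mask = NULL,
                        discarded = 0L) {
  check_positive_scalar(bin_size, "bin_size")
  check_positive_scalar(n_bins, "n_bins")
  check_positive_scalar(max_separation, "max_separation")
  counts <- as_tibble(counts)
  stopifnot(all(c("bin1", "bin2", "count") %in% names(counts)))
  band <- max_sep_bins(max_separation, bin_size)
  if (nrow(counts) > 0) {
    if (any(counts$bin1 > counts$bin2)) {
      abort("`counts` must be upper-triangular: bin1 <= bin2.")
    }
    if (any(counts$count < 0)) abort("Counts must be non-negative.")
    if (any(counts$bin2 - counts$bin1 > band)) {
      abort("`counts` holds a cell beyond `max_separation`.")
    }
    if (any(counts$bin1 < 0) || any(counts$bin2 >= n_bins)) {
      abort("Bin indices must lie in [0, n_bins).")
    }
  }
  if (!is.null(bin_mask) && length(bin_mask) != n_bins) {
    abort("`bin_mask` must have length `n_bins`.")
  }
  structure(
    list(chrom = chrom, bin_size = as.integer(bin_size),
         n_bins = as.integer(n_bins),
         max_separation = max_separation,
         counts = counts, bin_mask = bin_mask,
         discarded = as.integer(discarded)),
    class = "contact_map")
}

max_sep_bins <- function(max_separation, bin_size) {
  as.integer(max_separation %/% bin_size)
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s: %d bins x %d bp, band %s bp, %d stored cells (%s counts)\n",
              x$chrom, x$n_bins, x$bin_size,
              format(x$max_separation, big.mark = ","),
              nrow(x$counts), format(sum(x$counts$count), big.mark = ",")))
  if (!is.null(x$bin_mask)) {
    cat(sprintf("  %d cut-deficient bins masked\n", sum(x$bin_mask)))
  }
  invisible(x)
}

#' @export
tidy.contact_map <- function(x, ...) {
  mutate(x$counts, chrom = x$chrom, separation = .data$bin2 - .data$bin1,
         .before = 1)
}

#' @export
glance.contact_map <- function(x, ...) {
  tibble(chrom = x$chrom, bin_size = x$bin_size, n_bins = x$n_bins,
         max_separation = x$max_separation, n_cells = nrow(x$counts),
         total_count = sum(x$counts$count), discarded = x$discarded,
         n_masked_bins = if (is.null(x$bin_mask)) NA_integer_ else sum(x$bin_mask))
}

#' Densify a banded contact map
#'
#' @param map A [contact_map()].
#' @return A symmetric `n_bins x n_bins` numeric matrix (cells outside the
#'   band are zero).
#' @export
as_matrix <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  m <- matrix(0, map$n_bins, map$n_bins)
  m[cbind(map$counts$bin1 + 1L, map$counts$bin2 + 1L)] <- map$counts$count
  m[cbind(map$counts$bin2 + 1L, map$counts$bin1 + 1L)] <- map$counts$count
  m
}

#' Bin filtered read pairs into a banded contact map
#'
#' Each intra-chromosomal pair whose ends fall within `max_separation` of
#' each other increments exactly one unordered bin-pair cell
#' (`bin = floor(pos5 / bin_size)`).  Inter-chromosomal pairs and pairs
#' beyond the band are counted in the `discarded` tally so that
#' `stored + discarded = input`.
#'
#' @param pairs Read-pair tibble (see [read_pairs_file()]); should already
#'   be deduplicated and contamination-filtered.
#' @param chrom Chromosome to bin.
#' @param chrom_length Chromosome length in bp; defaults to the largest
#'   observed coordinate rounded up to a full bin.
#' @inheritParams contact_map
#' @return A [contact_map()].
#' @export
bin_contacts <- function(pairs, chrom, chrom_length = NULL, bin_size = 500,
                         max_separation = 5e5) {
  check_positive_scalar(bin_size, "bin_size")
  onchrom <- pairs$chrom1 == chrom | pairs$chrom2 == chrom
  pp <- pairs[onchrom, , drop = FALSE]
  cis <- pp$chrom1 == chrom & pp$chrom2 == chrom
  cp <- pp[cis, , drop = FALSE]
  if (is.null(chrom_length)) {
    hi <- if (nrow(cp)) max(cp$pos1, cp$pos2) + 1 else bin_size
    chrom_length <- ceiling(hi / bin_size) * bin_size
  }
  n_bins <- as.integer(ceiling(chrom_length / bin_size))
  band <- max_sep_bins(max_separation, bin_size)
  b1 <- pmin(cp$pos1 %/% bin_size, cp$pos2 %/% bin_size)
  b2 <- pmax(cp$pos1 %/% bin_size, cp$pos2 %/% bin_size)
  inband <- (b2 - b1) <= band
  cells <- tibble(bin1 = as.integer(b1[inband]), bin2 = as.integer(b2[inband])) %>%
    count(.data$bin1, .data$bin2, name = "count") %>%
    arrange(.data$bin1, .data$bin2)
  contact_map(cells, chrom = chrom, bin_size = bin_size, n_bins = n_bins,
              max_separation = max_separation,
              discarded = nrow(pp) - sum(inband))
}

#' Flag bins that lack MboI (GATC) restriction sites
#'
#' Bins without a single GATC site are invisible to an MboI Hi-C assay and
#' inflate directionality scores in their neighbourhood; the boundary
#' caller zeroes scores near them.  A site is assigned to the bin
#' containing its leftmost base.
#'
#' @param map A [contact_map()].
#' @param genome Genome (see [load_genome()]); must contain `map$chrom`.
#' @param site Recognition sequence (default `"GATC"`).
#' @return The map with `bin_mask` set (`TRUE` = no site in bin).
#' @export
annotate_cut_deficient_bins <- function(map, genome, site = "GATC") {
  stopifnot(inherits(map, "contact_map"))
  dss <- load_genome(genome)
  if (!map$chrom %in% names(dss)) {
    abort(sprintf("Chromosome '%s' absent from the genome.", map$chrom))
  }
  hits <- Biostrings::matchPattern(site, dss[[map$chrom]])
  site_bins <- unique((Biostrings::start(hits) - 1L) %/% map$bin_size)
  site_bins <- site_bins[site_bins < map$n_bins]
  mask <- rep(TRUE, map$n_bins)
  mask[site_bins + 1L] <- FALSE
  map$bin_mask <- mask
  map
}

#' Vanilla-coverage normalization
#'
#' Divides each cell by the product of its row and column coverage sums
#' computed within the stored band (a single balancing pass, not iterative
#' correction), then rescales so the mean of the nonzero cells is
#' preserved -- a pure display convention.  Rows with zero coverage yield
#' zeros, never NaN.
#'
#' @param map A [contact_map()].
#' @return A [contact_map()] whose counts are normalized values.
#' @export
vc_normalize <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  cc <- map$counts
  if (nrow(cc) == 0) return(map)
  s <- numeric(map$n_bins)
  add1 <- rowsum(cc$count, cc$bin1)
  s[as.integer(rownames(add1)) + 1L] <- s[as.integer(rownames(add1)) + 1L] + add1[, 1]
  off <- cc$bin1 != cc$bin2   # diagonal contributes once
  add2 <- rowsum(cc$count[off], cc$bin2[off])
  if (nrow(add2)) {
    s[as.integer(rownames(add2)) + 1L] <- s[as.integer(rownames(add2)) + 1L] + add2[, 1]
  }
  denom <- s[cc$bin1 + 1L] * s[cc$bin2 + 1L]
  v <- ifelse(denom > 0, cc$count / denom, 0)
  nz_before <- cc$count[cc$count > 0]
  nz_after <- v[v > 0]
  if (length(nz_after) > 0) v <- v * mean(nz_before) / mean(nz_after)
  map$counts$count <- v
  map
}

#' Log / histogram-equalized display transform
#'
#' Takes log10 of the positive cells and histogram-equalizes them over
#' `n_gray_levels` levels; zero cells render as background intensity 0.
#' The transform is a monotone rank transform, so it is invariant to a
#' global rescaling of the matrix, and the equalized histogram over nonzero
#' cells is uniform to within one count per level (for distinct values).
#'
#' @param map A [contact_map()] (normally after [vc_normalize()]).
#' @param n_gray_levels Number of display levels (>= 2; default 256).
#' @return A tibble `bin1, bin2, intensity` (class `contact_intensity`)
#'   with intensities in `[0, 1]`.
#' @export
display_transform <- function(map, n_gray_levels = 256) {
  stopifnot(inherits(map, "contact_map"))
  if (!is.numeric(n_gray_levels) || n_gray_levels < 2) {
    abort("`n_gray_levels` must be at least 2.")
  }
  v <- map$counts$count
  intensity <- numeric(length(v))
  pos <- which(v > 0)
  if (length(pos)) {
    lv <- log10(v[pos])
    # ties.method = "max" gives equal values equal intensity; ceiling to a
    # level grid yields a uniform per-level histogram for distinct values
    fr <- rank(lv, ties.method = "max") / length(lv)
    intensity[pos] <- ceiling(fr * n_gray_levels) / n_gray_levels
  }
  out <- tibble(bin1 = map$counts$bin1, bin2 = map$counts$bin2,
                intensity = intensity)
  structure(out, class = c("contact_intensity", class(out)),
            chrom = map$chrom, bin_size = map$bin_size,
            n_bins = map$n_bins)
}

#' Write / read a contact map as sparse triplet text
#'
#' Plain-text persistence: `#` header lines carrying chrom, bin_size,
#' n_bins and max_separation, followed by tab-separated
#' `bin_i  bin_j  count` triplets.
#'
#' @param map A [contact_map()].
#' @param path Output file.
#' @return `write_contact_map()` returns `path` invisibly;
#'   `read_contact_map()` returns a [contact_map()].
#' @export
write_contact_map <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  header <- c(sprintf("#chrom=%s", map$chrom),
              sprintf("#bin_size=%d", map$bin_size),
              sprintf("#n_bins=%d", map$n_bins),
              sprintf("#max_separation=%g", map$max_separation))
  writeLines(header, path)
  readr::write_tsv(map$counts, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- lines[startsWith(lines, "#")]
  field <- function(key) sub(sprintf("^#%s=", key), "", hdr[startsWith(hdr, sprintf("#%s=", key))])
  counts <- readr::read_tsv(path, comment = "#",
                            col_names = c("bin1", "bin2", "count"),
                            col_types = "iid", progress = FALSE)
  contact_map(counts, chrom = field("chrom"),
              bin_size = as.integer(field("bin_size")),
              n_bins = as.integer(field("n_bins")),
              max_separation = as.numeric(field("max_separation")))
}

#' Write a bin mask as BED3
#'
#' @param map A [contact_map()] with `bin_mask` set.
#' @param path Output BED file.
#' @export
write_bin_mask <- function(map, path) {
  stopifnot(inherits(map, "contact_map"), !is.null(map$bin_mask))
  bins <- which(map$bin_mask) - 1L
  write_bed(tibble(chrom = map$chrom,
                   start = bins * map$bin_size,
                   end = (bins + 1L) * map$bin_size), path)
}
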