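#' Read-pair tables
#'
#' Hi-C ligation products are represented as a tibble with one row per
#' pair: `read_id`, then (`chrom`, `pos`, `strand`) for each end, with 5'
#' mapping positions in 0-based bp.  Pairs are kept in canonical order
#' (end1 <= end2 by chromosome then position); [canonicalize_pairs()]
#' enforces this, swapping ends (and their strands) where needed.
#'
#' The plain-text pairs format is 7 tab-separated columns
#' (`readID chrom1 pos1 strand1 chrom2 pos2 strand2`) with `#` header
#' lines.
#'
#' @param pairs A read-pair tibble.
#' @param path File path.
#' @name pairs_format
NULL

pair_cols <- c("read_id", "chrom1", "pos1", "strand1",
               "chrom2", "pos2", "strand2")

#' @rdname pairs_format
#' @export
read_pairs_file <- function(path) {
  readr::read_tsv(path, comment = "#", col_names = pair_cols,
                  col_types = "cciccic", progress = FALSE) %>%
    mutate(pos1 = as.integer(.data$pos1), pos2 = as.integer(.data$pos2))
}

#' @rdname pairs_format
#' @export
write_pairs_file <- function(pairs, path) {
  writeLines(paste0("#columns: ", paste(pair_cols, collapse = "\t")), path)
  readr::write_tsv(pairs[, pair_cols], path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' @rdname pairs_format
#' @export
canonicalize_pairs <- function(pairs) {
  swap <- pairs$chrom2 < pairs$chrom1 |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos2 < pairs$pos1)
  if (any(swap)) {
    for (cols in list(c("chrom1", "chrom2"), c("pos1", "pos2"),
                      c("strand1", "strand2"))) {
      tmp <- pairs[[cols[1]]][swap]
      pairs[[cols[1]]][swap] <- pairs[[cols[2]]][swap]
      pairs[[cols[2]]][swap] <- tmp
    }
  }
  pairs
}

#' Remove duplicate read pairs
#'
#' Duplicates share identical 5' mapping positions on both ends
#' (`chrom1, pos1, chrom2, pos2`); strand and read identity are ignored.
#' The first occurrence is kept and input order is preserved, so the
#' operation is idempotent and stable.
#'
#' @param pairs Canonically ordered read-pair tibble.
#' @return The deduplicated tibble.
#' @export
dedup_pairs <- function(pairs) {
  distinct(pairs, .data$chrom1, .data$pos1, .data$chrom2, .data$pos2,
           .keep_all = TRUE)
}

#' Classify read-pair orientation
#'
#' With the leftmost end first, strand combination (+,-) is "in-out" (the
#' convergent configuration produced by un-ligated genomic fragments),
#' (-,+) is "out-in", (+,+) "in-in" and (-,-) "out-out".
#' Inter-chromosomal pairs are labelled "trans" with undefined span.
#' Adds `orientation` and `span` (pos2 - pos1, bp) columns.
#'
#' @param pairs Canonically ordered read-pair tibble.
#' @return The tibble with `orientation` and `span` columns.
#' @export
classify_orientation <- function(pairs) {
  cis <- pairs$chrom1 == pairs$chrom2
  key <- paste0(pairs$strand1, pairs$strand2)
  lab <- c("+-" = "in-out", "-+" = "out-in",
           "++" = "in-in", "--" = "out-out")[key]
  lab[!cis] <- "trans"
  mutate(pairs, orientation = unname(lab),
         span = ifelse(cis, .data$pos2 - .data$pos1, NA_integer_))
}

#' Filter short-span genomic contamination
#'
#' Removes exactly the intra-chromosomal in-out pairs spanning less than
#' `min_span` bp -- the signature of un-ligated genomic fragments.  All
#' other orientation classes (and trans pairs) pass through untouched at
#' any span.
#'
#' @param pairs Classified read-pair tibble (see [classify_orientation()];
#'   classification is applied on the fly if absent).
#' @param min_span Minimum retained in-out span in bp (default 500).
#' @return The filtered tibble.
#' @export
filter_genomic_contamination <- function(pairs, min_span = 500) {
  if (!is.numeric(min_span) || length(min_span) != 1L || min_span < 0) {
    abort("`min_span` must be a single non-negative number.")
  }
  if (!"orientation" %in% names(pairs)) pairs <- classify_orientation(pairs)
  drop <- pairs$orientation == "in-out" & !is.na(pairs$span) &
    pairs$span < min_span
  pairs[!drop, , drop = FALSE]
}

#' Orientation and distance QC summary
#'
#' The primary library-quality indicators: the span distribution of mapped
#' pairs per orientation class (log-spaced bins) and the relative
#' frequencies of the four classes among intra-chromosomal pairs (which
#' should be ~25% each for a genuine ligation library).
#'
#' @param pairs Classified read-pair tibble.
#' @param n_breaks Number of log-spaced span histogram bins.
#' @return A list of class `pairs_qc`: `fractions` (class, n, fraction
#'   over cis pairs) and `histogram` (class, span_lo, span_hi, n).
#' @export
orientation_summary <- function(pairs, n_breaks = 40) {
  if (!"orientation" %in% names(pairs)) pairs <- classify_orientation(pairs)
  cis <- filter(pairs, .data$orientation != "trans")
  fractions <- cis %>%
    count(.data$orientation, name = "n") %>%
    tidyr::complete(orientation = c("in-in", "in-out", "out-in", "out-out"),
                    fill = list(n = 0L)) %>%
    mutate(fraction = .data$n / sum(.data$n))
  spans <- pmax(cis$span, 1)
  hi <- max(spans, 10)
  breaks <- unique(round(10^seq(0, log10(hi + 1), length.out = n_breaks + 1)))
  bin <- cut(spans, breaks = breaks, right = FALSE, include.lowest = TRUE)
  histogram <- tibble(orientation = cis$orientation,
                      span_lo = breaks[as.integer(bin)],
                      span_hi = breaks[as.integer(bin) + 1L]) %>%
    count(.data$orientation, .data$span_lo, .data$span_hi, name = "n")
  structure(list(fractions = fractions, histogram = histogram,
                 n_cis = nrow(cis), n_trans = sum(pairs$orientation == "trans")),
            class = "pairs_qc")
}

#' @export
print.pairs_qc <- function(x, ...) {
  cat(sprintf("<pairs_qc> %d cis pairs, %d trans\n", x$n_cis, x$n_trans))
  print(x$fractions)
  invisible(x)
}

#' @export
tidy.pairs_qc <- function(x, ...) x$histogram

#' @export
glance.pairs_qc <- function(x, ...) {
  tidyr::pivot_wider(select(x$fractions, "orientation", "fraction"),
                     names_from = "orientation", values_from = "fraction") %>%
    mutate(n_cis = x$n_cis, n_trans = x$n_trans)
}
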