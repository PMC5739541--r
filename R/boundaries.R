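#' Directionality and boundary-calling parameters
#'
#' Defaults reproduce the published heuristic for 500 bp fly Hi-C maps:
#' each bin's up/downstream sums skip the 2 proximal bins and sum the next
#' 28 (covering 1-15 kb), log10 ratios are weighted by
#' `(total reads)^0.5`, candidate bins need mean weighted directionality
#' < -2 over the 5 upstream and > +2 over the 5 downstream flank bins, and
#' bins with more than one restriction-site-deficient bin within
#' `mask_radius` are zeroed.
#'
#' @param skip_bins Proximal bins skipped on each side (default 2).
#' @param window_bins Bins summed on each side after the skip (default 28).
#' @param weight_exponent Exponent `a` in the weight `(U + D)^a`
#'   (default 0.5).
#' @param flank_bins Flank length used for candidate selection and the
#'   boundary score (default 5).
#' @param threshold Candidate threshold on mean weighted directionality
#'   (default 2).
#' @param mask_radius Bins on either side scanned for cut-deficient bins
#'   (default: the flank length, 5).
#' @param pseudocount Added to both sums before the log ratio (default 1),
#'   so the ratio is defined at zero coverage.
#' @return A list of class `directionality_params`.
#' @export
directionality_params <- function(skip_bins = 2, window_bins = 28,
                                  weight_exponent = 0.5, flank_bins = 5,
                                  threshold = 2, mask_radius = 5,
                                  pseudocount = 1) {
  stopifnot(skip_bins >= 0, window_bins >= 1, weight_exponent >= 0,
            flank_bins >= 1, threshold > 0, mask_radius >= 0,
            pseudocount >= 0)
  structure(list(skip_bins = as.integer(skip_bins),
                 window_bins = as.integer(window_bins),
                 weight_exponent = weight_exponent,
                 flank_bins = as.integer(flank_bins),
                 threshold = threshold,
                 mask_radius = as.integer(mask_radius),
                 pseudocount = pseudocount),
            class = "directionality_params")
}

#' Per-bin directionality track
#'
#' For each bin `i`, sums the counts linking it to the window of bins
#' `[i - skip - window, i - skip - 1]` upstream (`U`) and the mirror
#' window downstream (`D`), takes `d = log10((D + pc) / (U + pc))`, and
#' weights it by `w = (U + D)^a` to suppress noise from low-coverage
#' regions: `dw = w * d`.  Bins within `skip + window` of a chromosome end
#' are flagged undefined.
#'
#' @param map A [contact_map()] binned at 500 bp (or any width) whose band
#'   is at least `(skip_bins + window_bins) * bin_size` wide.
#' @param params A [directionality_params()].
#' @return A tibble of class `directionality_track` with columns `bin`,
#'   `up_sum`, `down_sum`, `score` (raw log10 ratio), `weight`,
#'   `weighted_score`, `defined`; map geometry, mask and params are
#'   carried as attributes.
#' @export
directionality <- function(map, params = directionality_params()) {
  stopifnot(inherits(map, "contact_map"))
  reach <- params$skip_bins + params$window_bins
  if (max_sep_bins(map$max_separation, map$bin_size) < reach) {
    abort("Map band is narrower than the directionality window.")
  }
  n <- map$n_bins
  cc <- map$counts
  sep <- cc$bin2 - cc$bin1
  keep <- sep >= params$skip_bins + 1L & sep <= reach
  U <- numeric(n)
  D <- numeric(n)
  if (any(keep)) {
    dn <- rowsum(cc$count[keep], cc$bin1[keep])   # bin1 sees bin2 downstream
    D[as.integer(rownames(dn)) + 1L] <- dn[, 1]
    up <- rowsum(cc$count[keep], cc$bin2[keep])
    U[as.integer(rownames(up)) + 1L] <- up[, 1]
  }
  pc <- params$pseudocount
  d <- log10((D + pc) / (U + pc))
  w <- (U + D)^params$weight_exponent
  bin <- seq.int(0L, n - 1L)
  defined <- bin >= reach & bin <= n - 1L - reach
  out <- tibble(bin = bin, up_sum = U, down_sum = D, score = d,
                weight = w, weighted_score = ifelse(defined, w * d, NA_real_),
                defined = defined)
  structure(out, class = c("directionality_track", class(out)),
            chrom = map$chrom, bin_size = map$bin_size, n_bins = n,
            bin_mask = map$bin_mask, params = params)
}

# flank sums/means of the weighted score around every bin; NA unless all
# flank bins are defined
flank_statistics <- function(dw, flank) {
  list(up_sum = trailing_window_sum(dw, flank),
       down_sum = leading_window_sum(dw, flank))
}

#' Call TAD boundaries from a directionality track
#'
#' The published heuristic: (1) candidate bins are those where the mean
#' weighted directionality of the 5 adjacent upstream bins is below
#' `-threshold` and the mean of the 5 adjacent downstream bins is above
#' `+threshold` (all flank bins must be defined); (2) each candidate's
#' boundary score `B` is the downstream flank sum minus the upstream flank
#' sum; (3) `B` is zeroed for any bin with more than one cut-deficient bin
#' within `mask_radius`; (4) runs of strictly consecutive candidate bins
#' are merged and the bin with maximal `B` in each run (leftmost on ties)
#' is emitted.  Output is sorted by `B` descending; only calls with
#' `B > 0` are emitted.
#'
#' @param track A [directionality()] track.
#' @param params A [directionality_params()]; defaults to the parameters
#'   the track was computed with.
#' @param bin_mask Logical cut-deficient mask; defaults to the mask carried
#'   by the track's source map.
#' @return A tibble of class `boundary_calls`: `chrom`, `bin`, `start`,
#'   `end` (the winning bin as a BED interval), `score` (B),
#'   `block_start`, `block_end` (merged candidate run), `rank`.
#' @export
call_boundaries <- function(track, params = attr(track, "params"),
                            bin_mask = attr(track, "bin_mask")) {
  stopifnot(inherits(track, "directionality_track"))
  params <- params %||% directionality_params()
  fl <- params$flank_bins
  dw <- track$weighted_score
  fs <- flank_statistics(dw, fl)
  up_mean <- fs$up_sum / fl
  down_mean <- fs$down_sum / fl
  cand <- !is.na(up_mean) & !is.na(down_mean) &
    up_mean < -params$threshold & down_mean > params$threshold
  B <- fs$down_sum - fs$up_sum
  if (!is.null(bin_mask)) {
    n_masked <- centered_window_count(bin_mask, params$mask_radius)
    B[n_masked > 1] <- 0
  }
  idx <- which(cand)
  empty <- tibble(chrom = character(), bin = integer(), start = numeric(),
                  end = numeric(), score = numeric(), block_start = integer(),
                  block_end = integer(), rank = integer())
  if (!length(idx)) {
    return(structure(empty, class = c("boundary_calls", class(empty)),
                     bin_size = attr(track, "bin_size")))
  }
  run <- cumsum(c(1L, diff(idx) > 1L))
  calls <- tibble(i = idx, run = run, B = B[idx]) %>%
    group_by(.data$run) %>%
    summarise(block_start = min(.data$i), block_end = max(.data$i),
              winner = .data$i[which.max(.data$B)], score = max(.data$B),
              .groups = "drop") %>%
    filter(.data$score > 0)
  bs <- attr(track, "bin_size")
  out <- calls %>%
    mutate(chrom = attr(track, "chrom"), bin = .data$winner - 1L,
           start = .data$bin * bs, end = (.data$bin + 1L) * bs,
           block_start = .data$block_start - 1L,
           block_end = .data$block_end - 1L) %>%
    arrange(desc(.data$score), .data$bin) %>%
    mutate(rank = dplyr::row_number()) %>%
    select("chrom", "bin", "start", "end", "score",
           "block_start", "block_end", "rank")
  structure(out, class = c("boundary_calls", class(out)), bin_size = bs)
}

#' Boundary strength at given bins
#'
#' The boundary score `B`: sum of the weighted directionality over the
#' `flank_bins` bins downstream minus the sum over the `flank_bins` bins
#' upstream of the bin.  Shares its implementation with
#' [call_boundaries()].  `NA` where a flank runs past a chromosome end.
#'
#' @param track A [directionality()] track.
#' @param bins 0-based bin indices.
#' @param params A [directionality_params()].
#' @return Numeric vector of scores, one per requested bin.
#' @export
boundary_strength <- function(track, bins, params = attr(track, "params")) {
  stopifnot(inherits(track, "directionality_track"))
  params <- params %||% directionality_params()
  fs <- flank_statistics(track$weighted_score, params$flank_bins)
  B <- fs$down_sum - fs$up_sum
  B[bins + 1L]
}

#' @export
glance.boundary_calls <- function(x, ...) {
  tibble(n_calls = nrow(x),
         max_score = if (nrow(x)) max(x$score) else NA_real_,
         median_score = if (nrow(x)) median(x$score) else NA_real_)
}

#' Export boundary calls as BED6
#'
#' `name` is the strength rank and `score` is B rescaled to 0-1000.
#'
#' @param calls A `boundary_calls` tibble.
#' @param path Output BED file.
#' @export
write_boundaries_bed <- function(calls, path) {
  stopifnot(inherits(calls, "boundary_calls"))
  sc <- if (nrow(calls) && max(calls$score) > 0) {
    as.integer(round(1000 * calls$score / max(calls$score)))
  } else integer(0)
  write_bed(tibble(chrom = calls$chrom, start = calls$start, end = calls$end,
                   name = as.character(calls$rank), score = sc,
                   strand = "."), path)
}

#' Export a directionality track as bedGraph
#'
#' @param track A [directionality()] track.
#' @param path Output bedGraph file.
#' @param column Which score to write (`"weighted_score"` or `"score"`).
#' @export
write_directionality_bedgraph <- function(track, path,
                                          column = "weighted_score") {
  stopifnot(inherits(track, "directionality_track"))
  bs <- attr(track, "bin_size")
  keep <- track$defined
  write_bedgraph(tibble(chrom = attr(track, "chrom"),
                        start = track$bin[keep] * bs,
                        end = (track$bin[keep] + 1L) * bs,
                        value = track[[column]][keep]), path)
}
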