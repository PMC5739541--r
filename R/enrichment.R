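# Colocalization of boundaries with signal tracks and peak lists:
# metaplot matrices, fold-enrichment fractions, interval matching, and the
# four-way domain-termination sort.

# Step-function view of one chromosome's track: cumulative integral and
# cumulative covered length at interval breakpoints.  Intervals must be
# sorted and non-overlapping (the package's writers and simulators emit
# such tracks).
track_stepfun <- function(track_chr) {
  o <- order(track_chr$start)
  S <- track_chr$start[o]; E <- track_chr$end[o]; V <- track_chr$value[o]
  list(S = S, E = E, V = V,
       cum_int = c(0, cumsum(V * (E - S))),
       cum_len = c(0, cumsum(as.numeric(E - S))))
}

# integral of the track (and covered length) over (-Inf, x]
stepfun_eval <- function(sf, x) {
  idx <- findInterval(x, sf$S)
  i <- pmax(idx, 1L)
  width <- sf$E[i] - sf$S[i]
  partial <- pmin(pmax(x - sf$S[i], 0), width)
  int <- sf$cum_int[idx + 1L] - sf$V[i] * width + sf$V[i] * partial
  len <- sf$cum_len[idx + 1L] - width + partial
  int[idx == 0L] <- 0
  len[idx == 0L] <- 0
  list(int = int, len = len)
}

# mean track value over [a, b); NA where the window has no coverage
track_window_mean <- function(sf, a, b) {
  fa <- stepfun_eval(sf, a); fb <- stepfun_eval(sf, b)
  len <- fb$len - fa$len
  ifelse(len > 0, (fb$int - fa$int) / len, NA_real_)
}

track_window_total <- function(sf, a, b) {
  fa <- stepfun_eval(sf, a); fb <- stepfun_eval(sf, b)
  fb$int - fa$int
}

# length-weighted mean over the whole track
track_global_mean <- function(track) {
  sum(track$value * (track$end - track$start)) / sum(track$end - track$start)
}

#' Aggregate track signal around anchors (metaplot matrix)
#'
#' Builds the anchors x offsets matrix behind boundary metaplots: row `r`,
#' column `c` holds the mean track value in the `bin`-wide window centered
#' at offset `(c - 1 - window_half/bin) * bin` from anchor `r`'s midpoint.
#' With the defaults (50 kb half-window, 500 bp bins) that is 201 columns
#' spanning a 100 kb window.  Rows are ordered by `sort_key` (descending
#' `score` when the anchors carry one, e.g. boundary strength).  Windows
#' truncated by chromosome ends yield missing values; anchors with more
#' than half their columns missing are dropped with a warning.
#'
#' @param track bedGraph-style tibble (`chrom`, `start`, `end`, `value`).
#' @param anchors BED-style tibble of anchor intervals (boundaries, peaks);
#'   an optional `score` column is used as the default sort key.
#' @param window_half Half-window in bp (default 50 kb).
#' @param bin Column width in bp (default 500).
#' @return A list of class `anchor_matrix`: `values` (matrix), `anchors`
#'   (row metadata, sorted), `offsets` (column centers, bp), `sort_key`.
#' @export
aggregate_signal <- function(track, anchors, window_half = 5e4, bin = 500) {
  missing_chr <- setdiff(unique(anchors$chrom), unique(track$chrom))
  if (length(missing_chr)) {
    abort(sprintf("Track lacks chromosome(s) %s required by anchors.",
                  paste(missing_chr, collapse = ", ")))
  }
  k <- as.integer(window_half %/% bin)
  offsets <- seq.int(-k, k) * bin
  anchors <- as_tibble(anchors)
  anchors$.mid <- floor(interval_mid(anchors$start, anchors$end))
  if ("score" %in% names(anchors)) {
    anchors <- arrange(anchors, desc(.data$score))
    sort_key <- "score"
  } else sort_key <- NULL
  values <- matrix(NA_real_, nrow(anchors), length(offsets))
  for (chr in unique(anchors$chrom)) {
    sf <- track_stepfun(track[track$chrom == chr, , drop = FALSE])
    rows <- which(anchors$chrom == chr)
    for (ci in seq_along(offsets)) {
      a <- anchors$.mid[rows] + offsets[ci] - bin / 2
      values[rows, ci] <- track_window_mean(sf, a, a + bin)
    }
  }
  frac_missing <- rowMeans(is.na(values))
  if (any(frac_missing > 0.5)) {
    warn(sprintf("Dropping %d anchor(s) with >50%% missing signal columns.",
                 sum(frac_missing > 0.5)))
    keep <- frac_missing <= 0.5
    values <- values[keep, , drop = FALSE]
    anchors <- anchors[keep, , drop = FALSE]
  }
  structure(list(values = values, anchors = select(anchors, -".mid"),
                 offsets = offsets, window_half = window_half, bin = bin,
                 sort_key = sort_key),
            class = "anchor_matrix")
}

#' @export
print.anchor_matrix <- function(x, ...) {
  cat(sprintf("<anchor_matrix> %d anchors x %d bins of %d bp (+/- %g kb)%s\n",
              nrow(x$values), ncol(x$values), x$bin, x$window_half / 1e3,
              if (is.null(x$sort_key)) "" else paste0(", sorted by ", x$sort_key)))
  invisible(x)
}

#' @export
tidy.anchor_matrix <- function(x, ...) {
  tibble(anchor = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
         offset = rep(x$offsets, each = nrow(x$values)),
         value = as.vector(x$values))
}

#' Fraction of anchors enriched above a fold cutoff
#'
#' The metaplot summary statistic: the percentage of anchors whose signal
#' within `+/- half_window` of the midpoint exceeds `fold` times a
#' background level.  By default the summary inside the window is the
#' maximum `bin`-wide value (boundaries are sub-bin elements and ChIP
#' peaks sharp) and the background is the length-weighted chromosome-wide
#' track mean; both are exposed as arguments.
#'
#' @inheritParams aggregate_signal
#' @param fold Fold-enrichment cutoff (default 2).
#' @param half_window Half-width of the scored window in bp (default
#'   1.5 kb, i.e. a 3 kb window).
#' @param background `"global"` (track-wide mean), `"flank"` (per-anchor
#'   mean over `+/- 50 kb` excluding the scored window), or an explicit
#'   positive number.
#' @param stat `"max"` or `"mean"` summary within the window.
#' @return A one-row tibble: `n_anchors`, `n_enriched`, `percent`.
#' @export
fraction_enriched <- function(track, anchors, fold = 2, half_window = 1500,
                              background = c("global", "flank"),
                              stat = c("max", "mean"), bin = 500) {
  stat <- match.arg(stat)
  am <- aggregate_signal(track, anchors, window_half = half_window, bin = bin)
  summary_fun <- if (stat == "max") {
    function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  } else {
    function(r) mean(r, na.rm = TRUE)
  }
  signal <- apply(am$values, 1, summary_fun)
  if (is.numeric(background)) {
    bg <- rep(background, length(signal))
  } else {
    background <- match.arg(background)
    if (background == "global") {
      bg <- rep(track_global_mean(track), length(signal))
    } else {
      wide <- aggregate_signal(track, am$anchors, window_half = 5e4, bin = bin)
      inner <- abs(wide$offsets) <= half_window
      bg <- apply(wide$values[, !inner, drop = FALSE], 1,
                  function(r) mean(r, na.rm = TRUE))
    }
  }
  if (any(!is.finite(bg)) || any(bg <= 0)) {
    abort("Background level is zero or undefined; supply an explicit positive `background`.")
  }
  enriched <- !is.na(signal) & signal > fold * bg
  tibble(n_anchors = length(signal), n_enriched = sum(enriched),
         percent = 100 * sum(enriched) / length(signal))
}

#' Match two interval lists within a distance
#'
#' An element of `a` is matched if some element of `b` has its midpoint
#' within `max_dist` bp of `a`'s midpoint (each `a` counted once).  Used
#' for computational-vs-manual boundary concordance and peak-to-boundary
#' matching; call with the lists swapped for the reverse direction.
#'
#' @param a,b BED-style tibbles (`chrom`, `start`, `end`).
#' @param max_dist Maximum midpoint-to-midpoint distance in bp.
#' @return A tibble of class `boundary_match`, one row per `a` element
#'   (`chrom`, `mid`, `nearest_dist`, `matched`); [glance()] returns
#'   `n`, `n_matched`, `fraction`.
#' @export
match_within <- function(a, b, max_dist) {
  amid <- floor(interval_mid(a$start, a$end))
  bmid <- floor(interval_mid(b$start, b$end))
  nearest <- rep(Inf, length(amid))
  for (chr in unique(a$chrom)) {
    ai <- which(a$chrom == chr)
    bm <- sort(bmid[b$chrom == chr])
    if (!length(bm)) next
    idx <- findInterval(amid[ai], bm)
    d1 <- ifelse(idx >= 1L, amid[ai] - bm[pmax(idx, 1L)], Inf)
    d2 <- ifelse(idx < length(bm), bm[pmin(idx + 1L, length(bm))] - amid[ai], Inf)
    nearest[ai] <- pmin(abs(d1), abs(d2))
  }
  out <- tibble(chrom = a$chrom, mid = amid, nearest_dist = nearest,
                matched = nearest <= max_dist)
  structure(out, class = c("boundary_match", class(out)), max_dist = max_dist)
}

#' @export
glance.boundary_match <- function(x, ...) {
  tibble(n = nrow(x), n_matched = sum(x$matched),
         fraction = if (nrow(x)) sum(x$matched) / nrow(x) else NA_real_,
         max_dist = attr(x, "max_dist"))
}

#' Four-way sort of a metaplot matrix by flanking signal
#'
#' The domain-termination sort used for H3K27me3-style marks: each
#' anchor's total signal in the `flank`-bp windows immediately upstream
#' and downstream is compared to the median of all such side-totals, and
#' anchors are ordered top to bottom as (1) upstream above the median and
#' downstream not above, (2) upstream not above and downstream above,
#' (3) both above, (4) both not above, stably within category.
#'
#' @param mat An [aggregate_signal()] matrix.
#' @param track The track used for the side totals.
#' @param flank Flanking window in bp (default 50 kb).
#' @return The reordered `anchor_matrix`; its `anchors` carry
#'   `upstream_total`, `downstream_total` and `category`.
#' @export
fourway_sort <- function(mat, track, flank = 5e4) {
  stopifnot(inherits(mat, "anchor_matrix"))
  anchors <- mat$anchors
  mid <- floor(interval_mid(anchors$start, anchors$end))
  up <- down <- numeric(nrow(anchors))
  for (chr in unique(anchors$chrom)) {
    sf <- track_stepfun(track[track$chrom == chr, , drop = FALSE])
    rows <- which(anchors$chrom == chr)
    up[rows] <- track_window_total(sf, mid[rows] - flank, mid[rows])
    down[rows] <- track_window_total(sf, mid[rows], mid[rows] + flank)
  }
  med <- median(c(up, down))
  upA <- up > med; dnA <- down > med
  category <- ifelse(upA & !dnA, 1L,
              ifelse(!upA & dnA, 2L,
              ifelse(upA & dnA, 3L, 4L)))
  ord <- order(category)   # stable in R
  mat$values <- mat$values[ord, , drop = FALSE]
  mat$anchors <- mutate(anchors[ord, , drop = FALSE],
                        upstream_total = up[ord],
                        downstream_total = down[ord],
                        category = category[ord])
  mat$sort_key <- "category"
  mat
}
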