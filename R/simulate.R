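#' Domain model for synthetic Hi-C data
#'
#' Parameterizes a single synthetic chromosome: contact frequency decays as
#' a power law of genomic separation (`background * s^-alpha` expected
#' counts at separation `s` bins), multiplied by `beta >= 1` for bin pairs
#' lying in the same domain.  Domains are delimited by `breakpoints` (bin
#' indices; a breakpoint at bin `t` separates bins `< t` from bins `>= t`).
#' Per-breakpoint `penetrance` is the fraction of simulated cells in which
#' that boundary is active: a pair spanning breakpoints is intra-domain in
#' the fraction of cells where all intervening boundaries are inactive, so
#' its expected multiplier is the mixture `q * beta + (1 - q)` with
#' `q = prod(1 - penetrance)`.
#'
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp (default 500).
#' @param breakpoints Strictly increasing bin indices in `[1, n_bins - 1)`.
#' @param alpha Distance-decay exponent (> 0).
#' @param beta Within-domain contact multiplier (>= 1).
#' @param penetrance Per-boundary activity fraction in `[0, 1]`, recycled
#'   to `length(breakpoints)`.
#' @param background Expected count at separation = 1 bin.
#' @param chrom Chromosome name used in all emitted objects.
#' @return An object of class `domain_model`.
#' @export
domain_model <- function(chrom_length, bin_size = 500, breakpoints = integer(),
                         alpha = 1, beta = 8, penetrance = 1,
                         background = 50, chrom = "chrS") {
  check_positive_scalar(chrom_length, "chrom_length")
  check_positive_scalar(bin_size, "bin_size")
  check_positive_scalar(alpha, "alpha")
  check_positive_scalar(background, "background")
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1) {
    abort("`beta` must be a single number >= 1.")
  }
  n_bins <- as.integer(chrom_length %/% bin_size)
  if (n_bins < 2) abort("`chrom_length` must cover at least two bins.")
  breakpoints <- as.integer(breakpoints)
  if (length(breakpoints)) {
    if (is.unsorted(breakpoints, strictly = TRUE)) {
      abort("`breakpoints` must be strictly increasing.")
    }
    if (any(breakpoints < 1L) || any(breakpoints >= n_bins - 1L)) {
      abort("`breakpoints` must lie in [1, n_bins - 1).")
    }
  }
  penetrance <- rep_len(penetrance, length(breakpoints))
  if (length(penetrance) && (any(penetrance < 0) || any(penetrance > 1))) {
    abort("`penetrance` must lie in [0, 1].")
  }
  structure(
    list(chrom = chrom, chrom_length = chrom_length,
         bin_size = as.integer(bin_size), n_bins = n_bins,
         breakpoints = breakpoints, alpha = alpha, beta = beta,
         penetrance = penetrance, background = background),
    class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  cat(sprintf("<domain_model> %s: %s bp, %d x %d bp bins, %d breakpoints, alpha=%g beta=%g bg=%g\n",
              x$chrom, format(x$chrom_length, big.mark = ","), x$n_bins,
              x$bin_size, length(x$breakpoints), x$alpha, x$beta, x$background))
  invisible(x)
}

# expected (Poisson mean) counts for all band cells of a model; returns a
# tibble bin1/bin2/lambda.  Cut-deficient rows are zeroed.
expected_contact_lambda <- function(model, band, cut_deficient_bins = integer()) {
  n <- model$n_bins
  band <- min(band, n - 1L)
  s_all <- rep.int(seq_len(band), n - seq_len(band))
  i_all <- unlist(lapply(seq_len(band), function(s) seq.int(0L, n - 1L - s)),
                  use.names = FALSE)
  j_all <- i_all + s_all
  # cumulative log(1 - penetrance) at each bin; pen capped below 1 so the
  # difference never hits -Inf - -Inf
  A <- numeric(n + 1L)
  if (length(model$breakpoints)) {
    pen <- pmin(model$penetrance, 1 - 1e-12)
    A[model$breakpoints + 1L] <- A[model$breakpoints + 1L] + log1p(-pen)
  }
  C <- cumsum(A)
  q <- exp(C[j_all + 1L] - C[i_all + 1L])   # P(no active boundary in (i, j])
  mult <- q * model$beta + (1 - q)
  lambda <- model$background * s_all^(-model$alpha) * mult
  if (length(cut_deficient_bins)) {
    dead <- i_all %in% cut_deficient_bins | j_all %in% cut_deficient_bins
    lambda[dead] <- 0
  }
  tibble(bin1 = i_all, bin2 = j_all, lambda = lambda)
}

#' Simulate a banded contact map with planted domains
#'
#' Draws independent Poisson counts around the [domain_model()] expectation
#' for every bin pair with separation `1 <= s <= max_separation / bin_size`
#' (the diagonal carries no ligation information and is left empty).  Rows
#' belonging to `cut_deficient_bins` are zeroed, mimicking bins without
#' MboI sites.
#'
#' @param model A [domain_model()].
#' @param seed Integer seed; fixed seed gives identical maps.
#' @param max_separation Band half-width in bp (default 500 kb).
#' @param cut_deficient_bins Bin indices to zero out and record as truth.
#' @return A list with elements `map` (a [contact_map()]) and `truth`
#'   (class `synthetic_truth`: planted boundary bins and bp positions,
#'   penetrance, cut-deficient bins, and the model geometry).
#' @export
simulate_contact_map <- function(model, seed = NULL, max_separation = 5e5,
                                 cut_deficient_bins = integer()) {
  stopifnot(inherits(model, "domain_model"))
  if (!is.null(seed)) set.seed(seed)
  band <- max_sep_bins(max_separation, model$bin_size)
  lam <- expected_contact_lambda(model, band, cut_deficient_bins)
  cnt <- rpois(nrow(lam), lam$lambda)
  keep <- cnt > 0
  cells <- tibble(bin1 = lam$bin1[keep], bin2 = lam$bin2[keep],
                  count = as.numeric(cnt[keep])) %>%
    arrange(.data$bin1, .data$bin2)
  mask <- rep(FALSE, model$n_bins)
  mask[as.integer(cut_deficient_bins) + 1L] <- TRUE
  map <- contact_map(cells, chrom = model$chrom, bin_size = model$bin_size,
                     n_bins = model$n_bins, max_separation = max_separation,
                     bin_mask = mask)
  truth <- structure(
    list(chrom = model$chrom, chrom_length = model$chrom_length,
         bin_size = model$bin_size,
         planted_boundaries = model$breakpoints,
         boundary_positions = model$breakpoints * model$bin_size,
         penetrance = model$penetrance,
         cut_deficient_bins = as.integer(cut_deficient_bins),
         planted_motif_positions = NULL, planted_peak_positions = NULL),
    class = "synthetic_truth")
  list(map = map, truth = truth)
}

#' Simulate Hi-C read pairs from a contact map
#'
#' A fraction `1 - contamination` of pairs are ligation products: cells are
#' sampled proportionally to matrix counts, 5' positions uniformly within
#' each sampled bin, and strands independently uniform, so the four read
#' orientations are equally frequent.  The remaining `contamination`
#' fraction are un-ligated "genomic" fragments: convergent (in-out) pairs
#' whose span is uniform on `contamination_span` (default 150-500 bp), the
#' short-fragment hump that contaminates real libraries.
#'
#' @param map A [contact_map()] with at least one nonzero cell.
#' @param n_pairs Number of pairs to emit.
#' @param contamination Fraction in `[0, 1]` of genomic pairs.
#' @param seed Integer seed.
#' @param contamination_span Length-2 numeric, inclusive bp span range of
#'   contaminating fragments.
#' @return A read-pair tibble (`read_id`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`), canonically ordered.
#' @export
simulate_read_pairs <- function(map, n_pairs, contamination = 0, seed = NULL,
                                contamination_span = c(150, 500)) {
  stopifnot(inherits(map, "contact_map"))
  if (contamination < 0 || contamination > 1) {
    abort("`contamination` must lie in [0, 1].")
  }
  if (nrow(map$counts) == 0 || sum(map$counts$count) == 0) {
    abort("Cannot sample read pairs from an empty contact map.")
  }
  if (!is.null(seed)) set.seed(seed)
  n_gen <- rbinom(1L, n_pairs, contamination)
  n_lig <- n_pairs - n_gen
  bs <- map$bin_size
  L <- map$n_bins * bs

  idx <- sample.int(nrow(map$counts), n_lig, replace = TRUE,
                    prob = map$counts$count)
  p1 <- map$counts$bin1[idx] * bs + sample.int(bs, n_lig, replace = TRUE) - 1L
  p2 <- map$counts$bin2[idx] * bs + sample.int(bs, n_lig, replace = TRUE) - 1L
  s1 <- sample(c("+", "-"), n_lig, replace = TRUE)
  s2 <- sample(c("+", "-"), n_lig, replace = TRUE)
  swap <- p1 > p2
  tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
  tms <- s1[swap]; s1[swap] <- s2[swap]; s2[swap] <- tms
  lig <- tibble(chrom1 = map$chrom, pos1 = p1, strand1 = s1,
                chrom2 = map$chrom, pos2 = p2, strand2 = s2)

  span <- floor(runif(n_gen, contamination_span[1], contamination_span[2] + 1))
  g1 <- floor(runif(n_gen, 0, L - span))
  gen <- tibble(chrom1 = map$chrom, pos1 = g1, strand1 = "+",
                chrom2 = map$chrom, pos2 = g1 + span, strand2 = "-")

  out <- bind_rows(lig, gen)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  out$read_id <- sprintf("rp%07d", seq_len(nrow(out)))
  select(out, "read_id", "chrom1", "pos1", "strand1",
         "chrom2", "pos2", "strand2")
}

bin_has_site <- function(chars, bin_start, bin_end, site = "GATC") {
  k <- nchar(site)
  seg <- paste(chars[bin_start:min(length(chars), bin_end + k - 1L)],
               collapse = "")
  hits <- gregexpr(site, seg, fixed = TRUE)[[1]]
  any(hits != -1 & hits <= bin_end - bin_start + 1L)  # leftmost base in bin
}

# mutate one base of a GATC occurrence until a bin is site-free; bounded
scrub_sites_from_bin <- function(chars, bin_start, bin_end, site = "GATC") {
  k <- nchar(site)
  for (iter in 1:25) {
    seg <- paste(chars[max(1, bin_start - k + 1):min(length(chars), bin_end + k - 1)],
                 collapse = "")
    hits <- gregexpr(site, seg, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(chars)
    starts <- hits + max(1, bin_start - k + 1) - 1L
    starts <- starts[starts >= bin_start & starts <= bin_end]  # leftmost base in bin
    if (!length(starts)) return(chars)
    for (s in starts) {
      pos <- s + sample.int(k, 1) - 1L
      chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1)
    }
  }
  chars
}

#' Simulate genome sequence, a ChIP-like track, and a peak list
#'
#' Builds an i.i.d. uniform ACGT chromosome matching a simulated map's
#' truth, plants extra copies of each motif word in the central 3 x
#' `bin_size` window of every planted boundary, scrubs GATC from the
#' declared cut-deficient bins (and guarantees at least one GATC in every
#' other bin, so the restriction-site mask equals the planted truth
#' exactly), lays a smoothed (Gaussian-kernel) peak of
#' height `peak_height` over background 1.0 at a `peak_fraction` subset of
#' boundaries, and writes the chosen peaks as BED intervals.
#'
#' @param truth A `synthetic_truth` from [simulate_contact_map()].
#' @param motif_words DNA words of length 4-7 to plant (defaults: a
#'   BEAF-32-like CGATA-context 7-mer and a CACA-repeat 7-mer).
#' @param seed Integer seed.
#' @param motif_rate Planted copies of each word per central bin.
#' @param peak_height Track value at a peak summit (background is 1.0).
#' @param peak_fraction Fraction of planted boundaries that receive a peak.
#' @param peak_sd Gaussian kernel width of the smoothed peak, bp.
#' @param track_step Track interval width in bp (bedGraph resolution).
#' @return A list: `genome` (`DNAStringSet`), `track` (bedGraph tibble),
#'   `peaks` (BED tibble), and the updated `truth` carrying
#'   `planted_motif_positions` and `planted_peak_positions`.
#' @export
simulate_sequence_and_tracks <- function(truth, motif_words = c("ACGATAC", "CACACAC"),
                                         seed = NULL, motif_rate = 4,
                                         peak_height = 5, peak_fraction = 0.6,
                                         peak_sd = 300, track_step = 100) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(motif_words)) {
    if (any(!grepl("^[ACGT]+$", motif_words))) abort("Motif words must be over {A,C,G,T}.")
    if (any(nchar(motif_words) < 4 | nchar(motif_words) > 7)) {
      abort("Motif words must have length 4-7.")
    }
    if (any(nchar(motif_words) > truth$bin_size)) {
      abort("Motif words must be shorter than one bin.")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(truth$chrom_length)
  bs <- truth$bin_size
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  motif_pos <- list()
  for (t in truth$planted_boundaries) {
    for (b in (t - 1L):(t + 1L)) {
      if (b < 0 || (b + 1L) * bs > L) next
      for (w in motif_words) {
        k <- nchar(w)
        starts <- b * bs + sample.int(bs - k + 1L, motif_rate, replace = TRUE) - 1L
        for (s in starts) chars[(s + 1L):(s + k)] <- strsplit(w, "")[[1]]
        motif_pos[[length(motif_pos) + 1L]] <-
          tibble(word = w, boundary_bin = t, pos = starts)
      }
    }
  }
  # guarantee assay visibility outside the declared deserts: every non-cut
  # bin gets at least one GATC (random 500 bp bins lack one ~14% of the
  # time), placed off any planted motif footprint where possible
  occupied <- if (length(motif_pos)) bind_rows(motif_pos) else NULL
  n_full_bins <- L %/% bs
  for (b in setdiff(seq_len(n_full_bins) - 1L, truth$cut_deficient_bins)) {
    if (bin_has_site(chars, b * bs + 1L, (b + 1L) * bs)) next
    occ <- if (is.null(occupied)) integer() else {
      occupied$pos[occupied$pos >= (b - 1L) * bs & occupied$pos < (b + 1L) * bs]
    }
    for (try in 1:50) {
      g <- b * bs + sample.int(bs - 3L, 1L) - 1L     # 0-based leftmost
      clash <- length(occ) && any(g + 3L >= occ & g <= occ + 7L)
      if (!clash || try == 50L) {
        chars[(g + 1L):(g + 4L)] <- c("G", "A", "T", "C")
        break
      }
    }
  }
  for (b in truth$cut_deficient_bins) {
    chars <- scrub_sites_from_bin(chars, b * bs + 1L, (b + 1L) * bs)
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""),
                                              truth$chrom))

  bpos <- truth$planted_boundaries * bs + bs %/% 2   # boundary-bin centers
  n_pk <- round(peak_fraction * length(bpos))
  pk <- sort(sample(bpos, n_pk))
  starts <- seq(0L, L - 1L, by = track_step)
  ends <- pmin(starts + track_step, L)
  mids <- (starts + ends) / 2
  value <- rep(1, length(starts))
  for (p in pk) {
    value <- value + (peak_height - 1) * exp(-0.5 * ((mids - p) / peak_sd)^2)
  }
  track <- tibble(chrom = truth$chrom, start = starts, end = ends, value = value)
  peaks <- tibble(chrom = truth$chrom, start = pk - bs %/% 2, end = pk + bs %/% 2,
                  name = sprintf("peak%03d", seq_along(pk)))
  truth$planted_motif_positions <- if (length(motif_pos)) bind_rows(motif_pos) else NULL
  truth$planted_peak_positions <- pk
  list(genome = genome, track = track, peaks = peaks, truth = truth)
}
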