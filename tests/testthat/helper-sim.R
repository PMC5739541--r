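# Shared fixture builders (all in-code; nothing read from disk).

# small randomized simulated map for oracle-equivalence sweeps
random_test_map <- function(seed, max_bins = 400) {
  set.seed(seed)
  n_bins <- sample(120:max_bins, 1)
  n_bk <- sample(1:5, 1)
  bk <- sort(sample(35:(n_bins - 36), n_bk))
  bk <- bk[c(TRUE, diff(bk) > 34)]          # keep domains wider than the window
  model <- domain_model(n_bins * 500, breakpoints = bk,
                        alpha = runif(1, 0.8, 1.4),
                        beta = sample(c(1, 2, 6, 8, 12), 1),
                        penetrance = sample(c(1, 1, 0.5), length(bk), replace = TRUE),
                        background = sample(c(10, 30, 60), 1))
  cut <- if (runif(1) < 0.5) sort(sample(0:(n_bins - 1), sample(1:6, 1))) else integer()
  simulate_contact_map(model, seed = seed + 7, max_separation = 4e4,
                       cut_deficient_bins = cut)
}

# hand-built directionality track (bypasses any map) for caller unit tests
make_track <- function(dw, bin_size = 500, chrom = "chrT", bin_mask = NULL) {
  n <- length(dw)
  out <- tibble::tibble(bin = seq.int(0L, n - 1L), up_sum = NA_real_,
                        down_sum = NA_real_, score = NA_real_,
                        weight = NA_real_, weighted_score = dw,
                        defined = !is.na(dw))
  structure(out, class = c("directionality_track", class(out)),
            chrom = chrom, bin_size = bin_size, n_bins = n,
            bin_mask = bin_mask, params = directionality_params())
}

# minimal read-pair tibble builder
make_pairs <- function(pos1, pos2, strand1 = "+", strand2 = "-",
                       chrom1 = "chrT", chrom2 = chrom1) {
  n <- max(length(pos1), length(pos2))
  tibble::tibble(read_id = sprintf("r%03d", seq_len(n)),
                 chrom1 = rep_len(chrom1, n), pos1 = as.integer(pos1),
                 strand1 = rep_len(strand1, n),
                 chrom2 = rep_len(chrom2, n), pos2 = as.integer(pos2),
                 strand2 = rep_len(strand2, n))
}

# dense matrix -> contact_map (full band unless given)
map_from_matrix <- function(M, bin_size = 500, chrom = "chrT",
                            max_separation = NULL, bin_mask = NULL) {
  n <- nrow(M)
  idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  cc <- tibble::tibble(bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                       count = M[idx])
  contact_map(cc, chrom = chrom, bin_size = bin_size, n_bins = n,
              max_separation = max_separation %||% (n * bin_size),
              bin_mask = bin_mask)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
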