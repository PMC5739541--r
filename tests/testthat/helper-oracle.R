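# Independent brute-force oracles: naive loops over dense matrices and
# character-by-character string scans.  Deliberately unvectorized and kept
# separate from the package implementation they check.

oracle_directionality <- function(M, skip = 2, window = 28, a = 0.5, pc = 1) {
  n <- nrow(M)
  U <- D <- d <- w <- dw <- rep(NA_real_, n)
  defined <- rep(FALSE, n)
  reach <- skip + window
  for (i in 1:n) {                 # 1-based matrix row = bin i - 1
    usum <- 0; dsum <- 0
    for (kk in (skip + 1):reach) {
      if (i - kk >= 1) usum <- usum + M[i, i - kk]
      if (i + kk <= n) dsum <- dsum + M[i, i + kk]
    }
    U[i] <- usum; D[i] <- dsum
    d[i] <- log10((dsum + pc) / (usum + pc))
    w[i] <- (usum + dsum)^a
    defined[i] <- (i - 1) >= reach && (i - 1) <= (n - 1) - reach
    dw[i] <- if (defined[i]) w[i] * d[i] else NA_real_
  }
  list(U = U, D = D, d = d, w = w, dw = dw, defined = defined)
}

oracle_call_boundaries <- function(M, mask = NULL, skip = 2, window = 28,
                                   a = 0.5, pc = 1, flank = 5, thr = 2,
                                   mask_radius = 5) {
  n <- nrow(M)
  dw <- oracle_directionality(M, skip, window, a, pc)$dw
  cand <- rep(FALSE, n)
  B <- rep(NA_real_, n)
  for (i in 1:n) {
    if (i - flank < 1 || i + flank > n) next
    up <- dw[(i - flank):(i - 1)]
    dn <- dw[(i + 1):(i + flank)]
    if (any(is.na(up)) || any(is.na(dn))) next
    usum <- 0; for (v in up) usum <- usum + v
    dsum <- 0; for (v in dn) dsum <- dsum + v
    cand[i] <- (usum / flank) < -thr && (dsum / flank) > thr
    B[i] <- dsum - usum
  }
  if (!is.null(mask)) {
    for (i in 1:n) {
      cnt <- 0
      for (j in max(1, i - mask_radius):min(n, i + mask_radius)) {
        if (mask[j]) cnt <- cnt + 1
      }
      if (cnt > 1) B[i] <- 0
    }
  }
  calls <- list()
  i <- 1
  while (i <= n) {
    if (isTRUE(cand[i])) {
      j <- i
      while (j + 1 <= n && isTRUE(cand[j + 1])) j <- j + 1
      best <- i; for (x in i:j) if (B[x] > B[best]) best <- x  # leftmost tie
      if (B[best] > 0) {
        calls[[length(calls) + 1]] <- data.frame(
          bin = best - 1L, score = B[best],
          block_start = i - 1L, block_end = j - 1L)
      }
      i <- j + 1
    } else i <- i + 1
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(bin = integer(), score = numeric(),
               block_start = integer(), block_end = integer())
  list(cand = cand, B = B, calls = calls)
}

# brute-force count of a word (leftmost base) in seq[(from+1)..to], 0-based
# half-open window [from, to); the word may extend beyond `to`
oracle_count_word <- function(seq_string, word, from, to) {
  k <- nchar(word)
  cnt <- 0L
  for (s in (from + 1):to) {               # 1-based leftmost positions
    if (s + k - 1 <= nchar(seq_string) &&
        substr(seq_string, s, s + k - 1) == word) cnt <- cnt + 1L
  }
  cnt
}

oracle_revcomp <- function(word) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(word, "")[[1]]]), collapse = "")
}
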