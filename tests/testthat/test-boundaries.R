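# Directionality scores and the heuristic boundary caller, checked against
# the naive brute-force oracle and on simulated maps with planted truth.

test_that("directionality arithmetic matches direct evaluation", {
  # bin i with U = 10, D = 1000, pseudocount 0:
  # d = log10(1000/10) = 2; w = 1010^0.5; dw = w * d
  n <- 80
  M <- matrix(0, n, n)
  i <- 40
  M[i, i - 5] <- 10; M[i - 5, i] <- 10
  M[i, i + 5] <- 1000; M[i + 5, i] <- 1000
  map <- map_from_matrix(M)
  p0 <- directionality_params(pseudocount = 0)
  tr <- directionality(map, p0)
  row <- tr[tr$bin == i - 1, ]
  expect_equal(row$up_sum, 10)
  expect_equal(row$down_sum, 1000)
  expect_equal(row$score, 2)
  expect_equal(row$weight, 1010^0.5)
  expect_equal(row$weighted_score, 2 * 1010^0.5)
  expect_equal(round(row$weight, 2), 31.78)
  expect_equal(round(row$weighted_score, 2), 63.56)

  # U = D -> d = 0, dw = 0
  j <- 40
  M2 <- matrix(0, n, n)
  M2[j, j - 4] <- 100; M2[j - 4, j] <- 100
  M2[j, j + 4] <- 100; M2[j + 4, j] <- 100
  tr2 <- directionality(map_from_matrix(M2), p0)
  expect_equal(tr2$score[tr2$bin == j - 1], 0)
  expect_equal(tr2$weighted_score[tr2$bin == j - 1], 0)
})

test_that("directionality windows cover exactly skip+1 .. skip+window bins", {
  n <- 80
  i <- 40
  for (s in c(2, 3, 30, 31)) {
    M <- matrix(0, n, n)
    M[i, i + s] <- 50; M[i + s, i] <- 50
    tr <- directionality(map_from_matrix(M))
    inside <- s >= 3 && s <= 30     # 1-15 kb at 500 bp bins
    expect_equal(tr$down_sum[tr$bin == i - 1] > 0, inside, info = paste("s =", s))
    expect_equal(tr$up_sum[tr$bin == i + s - 1] > 0, inside, info = paste("s =", s))
  }
})

test_that("band narrower than the window is rejected; ends are undefined", {
  sim <- simulate_contact_map(domain_model(5e4), seed = 1,
                              max_separation = 1e4)
  expect_error(directionality(sim$map), "narrower")
  sim2 <- simulate_contact_map(domain_model(5e4), seed = 1,
                               max_separation = 2e4)
  tr <- directionality(sim2$map)
  expect_false(any(tr$defined[c(1:30, 71:100)]))
  expect_true(all(tr$defined[31:70]))
})

test_that("mirror-symmetric maps give antisymmetric directionality", {
  set.seed(3)
  n <- 101; m <- 51                       # center bin (1-based)
  A <- matrix(rpois(n * n, 5), n, n)
  A <- A + t(A)                           # contact symmetry
  B <- A[n:1, n:1]                        # reflect about the center
  M <- A + B                              # mirror-symmetric about bin m
  tr <- directionality(map_from_matrix(M), directionality_params(pseudocount = 1))
  d <- tr$score
  for (k in 1:15) {
    expect_equal(d[m - k], -d[m + k], tolerance = 1e-12)
  }
})

test_that("the caller scores the canonical hand example", {
  # dw = five -3s, candidate bin, five +3s: B = 15 - (-15) = 30
  dw <- c(rep(0, 10), rep(-3, 5), 0, rep(3, 5), rep(0, 10))
  tr <- make_track(dw)
  calls <- call_boundaries(tr)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$bin, 15L)
  expect_equal(calls$score, 30)
  expect_equal(boundary_strength(tr, 15L), 30)

  # flat track -> no calls
  expect_equal(nrow(call_boundaries(make_track(rep(0, 40)))), 0L)
})

test_that("boundary strength algebra and end behavior", {
  dw <- c(rep(0, 6), rep(-2, 5), 0, rep(4, 5), rep(0, 6))
  tr <- make_track(dw)
  # B = sum(down) - sum(up) even where flanks are asymmetric
  expect_equal(boundary_strength(tr, 11L), 20 - (-10))
  # antisymmetric flanks: B = 2 * sum(|downstream flank|)
  dw2 <- c(rep(0, 6), rep(-4, 5), 0, rep(4, 5), rep(0, 6))
  expect_equal(boundary_strength(make_track(dw2), 11L), 2 * 20)
  # all-zero flanks -> 0; too close to the end -> NA
  expect_equal(boundary_strength(tr, 17L), sum(dw[19:23]) - sum(dw[13:17]))
  expect_true(is.na(boundary_strength(tr, 2L)))
  expect_true(is.na(boundary_strength(tr, length(dw) - 2L)))
})

test_that("candidates with more than one masked bin in radius are zeroed", {
  dw <- c(rep(0, 10), rep(-3, 5), 0, rep(3, 5), rep(0, 10))
  mask <- rep(FALSE, length(dw))
  mask[c(17, 19)] <- TRUE                 # two masked bins within radius 5
  tr <- make_track(dw, bin_mask = mask)
  expect_equal(nrow(call_boundaries(tr)), 0L)
  # a single masked bin does not suppress
  mask1 <- rep(FALSE, length(dw))
  mask1[17] <- TRUE
  expect_equal(nrow(call_boundaries(make_track(dw, bin_mask = mask1))), 1L)
})

test_that("merging keeps the leftmost maximal bin of each candidate run", {
  base <- c(rep(-5, 6), rep(5, 6))
  dw <- c(rep(0, 8), base, rep(0, 8))
  tr <- make_track(dw)
  calls <- call_boundaries(tr)
  expect_equal(nrow(calls), 1L)
  # candidate run spans several bins; block extent reported
  expect_lte(calls$block_start, calls$bin)
  expect_gte(calls$block_end, calls$bin)
})

test_that("caller agrees bin-for-bin with the brute-force oracle", {
  for (seed in 101:106) {
    sim <- random_test_map(seed)
    M <- as_matrix(sim$map)
    mask <- sim$map$bin_mask
    tr <- directionality(sim$map)
    calls <- call_boundaries(tr)
    orc <- oracle_call_boundaries(M, mask)
    fs <- hictad:::flank_statistics(tr$weighted_score,
                                    5L)
    up_mean <- fs$up_sum / 5; down_mean <- fs$down_sum / 5
    cand <- !is.na(up_mean) & !is.na(down_mean) & up_mean < -2 & down_mean > 2
    expect_equal(which(cand), which(orc$cand), info = seed)
    got <- dplyr::arrange(tibble::as_tibble(calls), bin)
    expect_equal(got$bin, orc$calls$bin, info = seed)
    expect_equal(got$score, orc$calls$score, tolerance = 1e-9, info = seed)
    expect_equal(got$block_start, orc$calls$block_start, info = seed)
    expect_equal(got$block_end, orc$calls$block_end, info = seed)
  }
})

test_that("planted boundaries are recovered at high precision and recall", {
  hits <- 0; n_truth <- 0; n_calls <- 0; good_calls <- 0
  for (seed in 201:205) {
    model <- domain_model(2e5, breakpoints = c(80, 160, 240, 320),
                          beta = 8, background = 50)
    sim <- simulate_contact_map(model, seed = seed, max_separation = 3e4)
    calls <- call_boundaries(directionality(sim$map))
    truth <- sim$truth$planted_boundaries
    n_truth <- n_truth + length(truth)
    n_calls <- n_calls + nrow(calls)
    hits <- hits + sum(sapply(truth, function(t) any(abs(calls$bin - t) <= 1)))
    good_calls <- good_calls + sum(sapply(calls$bin, function(b) any(abs(truth - b) <= 1)))
  }
  expect_gte(hits / n_truth, 0.9)          # recall
  expect_gte(good_calls / n_calls, 0.9)    # precision
})

test_that("boundary score is monotone in the insulation strength beta", {
  med_B <- sapply(c(2, 6, 12), function(beta) {
    scores <- c()
    for (seed in 301:303) {
      model <- domain_model(1.2e5, breakpoints = c(80, 160),
                            beta = beta, background = 50)
      sim <- simulate_contact_map(model, seed = seed, max_separation = 3e4)
      tr <- directionality(sim$map)
      scores <- c(scores, boundary_strength(tr, c(80L, 160L)))
    }
    median(scores)
  })
  expect_true(all(diff(med_B) >= 0))
})

test_that("cut-site deserts beside a true boundary suppress its call", {
  model <- domain_model(1.2e5, breakpoints = 120, beta = 8, background = 50)
  clean <- simulate_contact_map(model, seed = 401, max_separation = 3e4)
  masked <- simulate_contact_map(model, seed = 401, max_separation = 3e4,
                                 cut_deficient_bins = c(120, 121))
  calls_clean <- call_boundaries(directionality(clean$map))
  calls_masked <- call_boundaries(directionality(masked$map))
  expect_true(any(abs(calls_clean$bin - 120) <= 1))
  expect_false(any(abs(calls_masked$bin - 120) <= 2))
})

test_that("directionality track exports to bedGraph and BED", {
  sim <- simulate_contact_map(domain_model(6e4, breakpoints = 60,
                                           background = 50),
                              seed = 71, max_separation = 2e4)
  tr <- directionality(sim$map)
  calls <- call_boundaries(tr)
  bg_path <- withr::local_tempfile(fileext = ".bedgraph")
  write_directionality_bedgraph(tr, bg_path)
  bg <- read_bedgraph(bg_path)
  expect_equal(nrow(bg), sum(tr$defined))
  expect_equal(bg$value, tr$weighted_score[tr$defined])
  bed_path <- withr::local_tempfile(fileext = ".bed")
  write_boundaries_bed(calls, bed_path)
  bed <- read_bed(bed_path)
  expect_equal(nrow(bed), nrow(calls))
  expect_true(all(bed$score >= 0 & bed$score <= 1000))
})
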