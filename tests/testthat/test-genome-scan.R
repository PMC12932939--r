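test_that("window parameters are validated before any scan work", {
  r <- tibble::tibble(chrom = "c1", pos = 1, delta = 0)
  cl <- tibble::tibble(chrom = "c1", length_bp = 1e6)
  expect_error(window_scan(r, cl, step_bp = 0), "step_bp")
  expect_error(window_scan(r, cl, window_bp = 5e4, step_bp = 1e5), "window_bp")
  expect_error(call_regions(tibble::tibble(), -0.1), "threshold")
})

test_that("a single marker fills every window containing it", {
  r <- tibble::tibble(chrom = "c1", pos = 5e5, delta = 0.8)
  cl <- tibble::tibble(chrom = "c1", length_bp = 3e6)
  w <- window_scan(r, cl, window_bp = 1e6, step_bp = 1e5, min_markers = 1)
  containing <- w$start <= 5e5 & w$end >= 5e5
  expect_true(all(w$mean_delta[containing] == 0.8))
  expect_true(all(is.na(w$mean_delta[!containing])))
  expect_true(all(w$n_markers[containing] == 1))
  # a chromosome with no markers reports every window missing
  cl2 <- tibble::tibble(chrom = c("c1", "c2"), length_bp = c(3e6, 2e6))
  w2 <- window_scan(r, cl2, min_markers = 1)
  expect_true(all(is.na(w2$mean_delta[w2$chrom == "c2"])))
  expect_true(all(w2$n_markers[w2$chrom == "c2"] == 0))
})

test_that("window means equal the brute-force interval oracle on random instances", {
  set.seed(42)
  for (i in 1:25) {
    cl <- tibble::tibble(
      chrom = c("cA", "cB"),
      length_bp = c(sample(2e6:8e6, 1), sample(1e6:4e6, 1))
    )
    n <- sample(10:150, 1)
    r <- tibble::tibble(
      chrom = sample(cl$chrom, n, replace = TRUE),
      pos = NA_real_,
      delta = round(runif(n, -1, 1), 3)
    )
    r$pos <- floor(runif(n, 1, cl$length_bp[match(r$chrom, cl$chrom)]))
    r <- dplyr::arrange(r, chrom, pos)
    mm <- sample(1:4, 1)
    got <- window_scan(r, cl, window_bp = 1e6, step_bp = 25e4, min_markers = mm)
    want <- oracle_window_means(r, cl, 1e6, 25e4, mm)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_markers, want$n_markers)
    expect_equal(got$mean_delta, want$mean_delta, tolerance = 1e-12)
    # order invariance
    got2 <- window_scan(r[sample(nrow(r)), ], cl,
      window_bp = 1e6, step_bp = 25e4, min_markers = mm
    )
    expect_equal(got2$mean_delta, got$mean_delta, tolerance = 1e-12)
  }
})

test_that("threshold uses linear-interpolation percentiles of the maxima", {
  expect_equal(threshold_from_null(rep(0.37, 50), 95), 0.37)
  expect_equal(threshold_from_null(seq(0.01, 1, by = 0.01), 95), 0.9505)
  expect_equal(threshold_from_null(c(0.2, 0.9, 0.4), 100), 0.9)
  expect_error(threshold_from_null(numeric(0)), "empty")
  expect_error(threshold_from_null(1:5, 0), "percentile")
  expect_error(threshold_from_null(1:5, 101), "percentile")
  # monotone non-decreasing in the percentile
  set.seed(9)
  mx <- runif(200)
  th <- vapply(c(50, 80, 90, 95, 99, 100), function(p) {
    threshold_from_null(mx, p)
  }, numeric(1))
  expect_true(all(diff(th) >= 0))
})

test_that("null maxima are bit-reproducible and degenerate cases collapse", {
  gm <- toy_map(60)
  pop <- simulate_ril_genotypes(gm, 40, 8, seed = 91)
  ad <- sample_pool_depths(
    pop, pop$line_ids[1:10], pop$line_ids[11:20],
    pool_seq_spec(10, 30, 0, seed = 92)
  )
  ad$b_allele <- ad$true_b_allele
  si <- compute_delta(apply_marker_filters(compute_snp_index(ad)))
  for (sch in c("ril_null", "label_swap", "binomial_null")) {
    n1 <- permutation_null(si, gm$chromosomes,
      n_iterations = 20, scheme = sch, seed = 5, step_bp = 2.5e5
    )
    n2 <- permutation_null(si, gm$chromosomes,
      n_iterations = 20, scheme = sch, seed = 5, step_bp = 2.5e5
    )
    expect_identical(n1$maxima, n2$maxima)
    expect_length(n1$maxima, 20)
    expect_equal(n1$threshold, threshold_from_null(n1$maxima, 95))
  }
  # all-zero deltas under label swap give a zero threshold
  si0 <- dplyr::mutate(si, delta = 0)
  n0 <- permutation_null(si0, gm$chromosomes,
    n_iterations = 10, scheme = "label_swap", seed = 1, step_bp = 2.5e5
  )
  expect_true(all(n0$maxima == 0) && n0$threshold == 0)
  expect_error(
    permutation_null(si[0, ], gm$chromosomes, n_iterations = 5),
    "no informative loci"
  )
  expect_error(
    permutation_null(si[1:2, ], gm$chromosomes,
      n_iterations = 5, min_markers = 50
    ),
    "zero informative windows"
  )
})

test_that("significant windows merge into regions by overlap or book-ending", {
  w <- tibble::tibble(
    chrom = c("c1", "c1", "c1", "c2", "c2"),
    start = c(1, 100001, 3000001, 1, 1500001),
    end = c(1e6, 1.1e6, 4e6, 1e6, 2.5e6),
    mean_delta = c(0.9, 0.8, -0.85, 0.2, 0.95),
    n_markers = 5L
  )
  reg <- call_regions(w, 0.7)
  expect_equal(nrow(reg), 3)
  r1 <- reg[reg$chrom == "c1" & reg$start == 1, ]
  expect_equal(r1$end, 1.1e6)
  expect_equal(r1$peak_delta, 0.9)
  expect_equal(r1$n_windows, 2L)
  expect_equal(reg$peak_delta[reg$start == 3000001], -0.85)
  expect_equal(nrow(reg[reg$chrom == "c2", ]), 1)
  # book-ended windows (adjacent, no gap) merge too
  wb <- tibble::tibble(
    chrom = "c1", start = c(1, 1000001), end = c(1e6, 2e6),
    mean_delta = c(0.9, 0.9), n_markers = 3L
  )
  expect_equal(nrow(call_regions(wb, 0.5)), 1)
  # nothing significant -> empty frame with the right shape
  empty <- call_regions(w, 0.99)
  expect_equal(nrow(empty), 0)
  expect_named(
    empty,
    c("chrom", "start", "end", "peak_delta", "n_windows", "n_loci")
  )
  # locus counting inside regions
  rec <- tibble::tibble(chrom = "c1", pos = c(10, 5e5, 2e6, 3.5e6))
  reg2 <- call_regions(w, 0.7, rec)
  expect_equal(reg2$n_loci[reg2$start == 1], 2L)
  expect_equal(reg2$n_loci[reg2$start == 3000001], 1L)
})
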