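#' Sliding-window means of the delta SNP index
#'
#' Windows are anchored at position 1 of each chromosome and advanced by
#' `step_bp`; the last windows are truncated at the chromosome end.  The
#' window statistic is the unweighted mean delta over member markers
#' (`start <= pos <= end`); windows with fewer than `min_markers` markers
#' report a missing mean (they are retained in the output but never enter
#' threshold computation or region calls).
#'
#' @param records Coordinate-sorted tibble with `chrom`, `pos`, `delta`.
#' @param chrom_lengths Tibble `chrom`, `length_bp` (e.g. a map's
#'   `$chromosomes`); every chromosome listed is scanned, including ones
#'   with no markers.
#' @param window_bp Window size in bp (default 1 Mb).
#' @param step_bp Step in bp (default 100 kb); must satisfy
#'   `0 < step_bp <= window_bp`.
#' @param min_markers Minimum markers per informative window (default 3).
#' @return Tibble `chrom`, `start`, `end`, `mean_delta`, `n_markers`.
#' @export
window_scan <- function(records, chrom_lengths, window_bp = 1e6, step_bp = 1e5,
                        min_markers = 3) {
  check_window_params(window_bp, step_bp)
  records <- as_tibble(records)
  chrom_lengths <- as_tibble(chrom_lengths)
  stopifnot(all(c("chrom", "length_bp") %in% names(chrom_lengths)))
  windows <- make_windows(chrom_lengths, window_bp, step_bp)
  hits <- window_membership(records, chrom_lengths, window_bp, step_bp)
  if (nrow(hits)) {
    agg <- hits %>%
      group_by(.data$window_id) %>%
      summarise(sum_delta = sum(.data$delta), n_markers = n(), .groups = "drop")
    windows$n_markers <- 0L
    windows$n_markers[agg$window_id] <- agg$n_markers
    windows$sum_delta <- 0
    windows$sum_delta[agg$window_id] <- agg$sum_delta
  } else {
    windows$n_markers <- 0L
    windows$sum_delta <- 0
  }
  windows %>%
    mutate(
      mean_delta = if_else(
        .data$n_markers >= min_markers,
        .data$sum_delta / pmax(.data$n_markers, 1L),
        NA_real_
      )
    ) %>%
    select("chrom", "start", "end", "mean_delta", "n_markers")
}

check_window_params <- function(window_bp, step_bp) {
  if (!is.numeric(step_bp) || step_bp <= 0) abort("`step_bp` must be > 0")
  if (!is.numeric(window_bp) || window_bp < step_bp) {
    abort("`window_bp` must be >= `step_bp`")
  }
  invisible(TRUE)
}

# Window frame: one row per window genome-wide, with a global window_id.
make_windows <- function(chrom_lengths, window_bp, step_bp) {
  out <- purrr::pmap_dfr(
    chrom_lengths[, c("chrom", "length_bp")],
    function(chrom, length_bp) {
      starts <- seq(1, length_bp, by = step_bp)
      tibble(
        chrom = chrom,
        start = starts,
        end = pmin(starts + window_bp - 1, length_bp)
      )
    }
  )
  out$window_id <- seq_len(nrow(out))
  out
}

# Long marker-to-window membership table (one row per marker x window).
window_membership <- function(records, chrom_lengths, window_bp, step_bp) {
  windows_per_chrom <- ceiling(chrom_lengths$length_bp / step_bp)
  offset <- cumsum(c(0, head(windows_per_chrom, -1)))
  names(offset) <- chrom_lengths$chrom
  records <- records[records$chrom %in% chrom_lengths$chrom, , drop = FALSE]
  if (!nrow(records)) {
    return(tibble(marker_id = integer(0), window_id = integer(0), delta = numeric(0)))
  }
  pos <- records$pos
  k_max <- windows_per_chrom[match(records$chrom, chrom_lengths$chrom)]
  k_hi <- pmin(k_max, floor((pos - 1) / step_bp) + 1)
  k_lo <- pmax(1, ceiling((pos - window_bp) / step_bp) + 1)
  n_k <- pmax(0L, as.integer(k_hi - k_lo + 1))
  marker_id <- rep(seq_len(nrow(records)), times = n_k)
  win_local <- sequence(n_k, from = as.integer(k_lo))
  tibble(
    marker_id = marker_id,
    window_id = as.integer(offset[records$chrom[marker_id]] + win_local),
    delta = records$delta[marker_id]
  )
}

#' Null distribution of the genome-wide maximum windowed delta
#'
#' Re-generates null per-locus indices `n_iterations` times, re-runs the
#' sliding-window scan with identical parameters, and records the
#' genome-wide maximum |windowed delta| each time.  Three null schemes:
#'
#' * `ril_null` (default): a model-based null that regenerates both noise
#'   sources of a pooled RIL contrast.  Per iteration, each pool's line
#'   composition is simulated as independent no-QTL inbred-line genotype
#'   chains along the observed marker positions (two-state Markov chain
#'   with switch probability equal to the Haldane-Waddington RIL
#'   recombination fraction \eqn{R = 2r/(1+2r)}), the true pooled B
#'   frequency is their mean, and reads are drawn
#'   Binomial(observed depth, frequency).  This preserves the long-range
#'   autocorrelation that pool-composition noise induces across linked
#'   markers, which per-locus resampling destroys.
#' * `label_swap`: per locus, swap the high/low bulk values with
#'   probability 1/2.  Preserves the empirical depth and index marginals
#'   but breaks linkage autocorrelation, so its genome-wide threshold is
#'   anti-conservative for pool-sequenced populations.
#' * `binomial_null`: redraw each pool's B-allele reads as
#'   Binomial(observed depth, 0.5).  Models read sampling only; strongly
#'   anti-conservative (no composition noise at all).
#'
#' @param records Filtered tibble with `chrom`, `pos`, `delta`,
#'   `depth_high`, `depth_low` (deltas present).
#' @param chrom_lengths Tibble `chrom`, `length_bp`.
#' @param n_iterations Number of iterations (default 1000).
#' @param scheme Null scheme (see above).
#' @param seed Integer seed; maxima are reproducible bit-exactly.
#' @param window_bp,step_bp,min_markers Passed to [window_scan()].
#' @param percentile Percentile of the maxima used as the genome-wide
#'   threshold (default 95).
#' @param pool_size Lines per pool for `ril_null` (default 15; use a
#'   length-2 vector for unequal pools).
#' @param cm_per_mb Genetic map expansion used by `ril_null` to convert
#'   marker spacing to recombination fractions (default 3).
#' @return A `perm_null` object: list with `maxima`, `n_iterations`,
#'   `scheme`, `percentile`, `threshold` and the window parameters.
#' @export
permutation_null <- function(records, chrom_lengths, n_iterations = 1000,
                             scheme = c("ril_null", "label_swap", "binomial_null"),
                             seed = 1, window_bp = 1e6, step_bp = 1e5,
                             min_markers = 3, percentile = 95,
                             pool_size = 15, cm_per_mb = 3) {
  scheme <- match.arg(scheme)
  check_window_params(window_bp, step_bp)
  records <- as_tibble(records)
  if (!nrow(records) || all(is.na(records$delta))) {
    abort("no informative loci for the permutation null")
  }
  records <- records[!is.na(records$delta), , drop = FALSE]
  chrom_lengths <- as_tibble(chrom_lengths)

  hits <- window_membership(records, chrom_lengths, window_bp, step_bp)
  cnt <- table(hits$window_id)
  eligible_ids <- as.integer(names(cnt))[cnt >= min_markers]
  if (!length(eligible_ids)) {
    abort("zero informative windows (all below `min_markers`)")
  }
  keep <- hits$window_id %in% eligible_ids
  em <- hits$marker_id[keep]
  ew <- factor(hits$window_id[keep])
  wn <- as.vector(table(ew))

  n <- nrow(records)
  delta <- records$delta
  dh <- records$depth_high
  dl <- records$depth_low
  pool_size <- rep(as.integer(pool_size), length.out = 2L)
  # per-chromosome marker index blocks and RIL switch probabilities,
  # precomputed once for ril_null
  if (scheme == "ril_null") {
    ord <- order(match(records$chrom, chrom_lengths$chrom), records$pos)
    if (any(ord != seq_len(n))) abort("records must be coordinate-sorted")
    blocks <- lapply(split(seq_len(n), factor(records$chrom, unique(records$chrom))), function(idx) {
      r <- haldane_r(records$pos[idx], cm_per_mb)
      list(idx = idx, switch_p = 2 * r / (1 + 2 * r))
    })
  }
  set.seed(seed)
  maxima <- vapply(seq_len(n_iterations), function(i) {
    d_null <- switch(scheme,
      label_swap = delta * (1 - 2 * (runif(n) < 0.5)),
      binomial_null = {
        ih <- rbinom(n, dh, 0.5) / pmax(dh, 1L)
        il <- rbinom(n, dl, 0.5) / pmax(dl, 1L)
        ih - il
      },
      ril_null = {
        f_high <- numeric(n)
        f_low <- numeric(n)
        n_lines <- sum(pool_size)
        for (b in blocks) {
          g <- ril_chain(n_lines, b$switch_p)
          f_high[b$idx] <- colMeans(g[seq_len(pool_size[1]), , drop = FALSE])
          f_low[b$idx] <- colMeans(g[pool_size[1] + seq_len(pool_size[2]), , drop = FALSE])
        }
        rbinom(n, dh, f_high) / pmax(dh, 1L) - rbinom(n, dl, f_low) / pmax(dl, 1L)
      }
    )
    sums <- rowsum(d_null[em], ew)
    max(abs(sums / wn))
  }, numeric(1))

  out <- structure(
    list(
      maxima = maxima, n_iterations = as.integer(n_iterations),
      scheme = scheme, percentile = percentile,
      window_bp = window_bp, step_bp = step_bp, min_markers = min_markers,
      seed = seed
    ),
    class = "perm_null"
  )
  out$threshold <- threshold_from_null(out, percentile)
  out
}

# n_lines independent two-state (A/B) genotype chains over the markers of
# one chromosome; switch_p[j] = P(state change between markers j and j+1).
ril_chain <- function(n_lines, switch_p) {
  parity_chain(n_lines, switch_p)
}

#' @export
print.perm_null <- function(x, ...) {
  cat(
    "<perm_null> ", x$n_iterations, " iterations (", x$scheme, "), ",
    x$percentile, "th percentile threshold = ", signif(x$threshold, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy perm_null
#' @export
tidy.perm_null <- function(x, ...) {
  tibble(iteration = seq_along(x$maxima), max_abs_delta = x$maxima)
}

#' @method glance perm_null
#' @export
glance.perm_null <- function(x, ...) {
  tibble(
    n_iterations = x$n_iterations, scheme = x$scheme,
    percentile = x$percentile, threshold = x$threshold
  )
}

#' Genome-wide threshold from a permutation null
#'
#' The stated percentile of the per-iteration maxima, using the
#' linear-interpolation percentile convention (R's quantile type 7) for a
#' bit-exact, documented definition.
#'
#' @param null A `perm_null` object or a numeric vector of maxima.
#' @param percentile Percentile in (0, 100\]; 100 returns the maximum.
#' @return The threshold (single numeric).
#' @export
threshold_from_null <- function(null, percentile = 95) {
  maxima <- if (inherits(null, "perm_null")) null$maxima else null
  if (!length(maxima)) abort("empty null distribution")
  if (!is.numeric(percentile) || percentile <= 0 || percentile > 100) {
    abort("`percentile` must be in (0, 100]")
  }
  unname(quantile(maxima, percentile / 100, type = 7, names = FALSE))
}

#' Call candidate regions from significant windows
#'
#' Windows whose |mean delta| meets the threshold are merged when they
#' overlap or are book-ended (adjacent with no gap); region bounds are the
#' union extent, `peak_delta` is the member window mean with the largest
#' magnitude (sign retained), and `n_loci` counts filtered markers inside
#' the region when `records` are supplied.
#'
#' @param windows Output of [window_scan()].
#' @param threshold Non-negative threshold on |mean delta|.
#' @param records Optional marker tibble (`chrom`, `pos`) for `n_loci`.
#' @return Tibble `chrom`, `start`, `end`, `peak_delta`, `n_windows`,
#'   `n_loci` (0 rows when nothing is significant).
#' @export
call_regions <- function(windows, threshold, records = NULL) {
  if (threshold < 0) abort("`threshold` must be >= 0")
  sig <- windows %>%
    filter(!is.na(.data$mean_delta), abs(.data$mean_delta) >= threshold) %>%
    arrange(.data$chrom, .data$start)
  if (!nrow(sig)) {
    return(tibble(
      chrom = character(0), start = numeric(0), end = numeric(0),
      peak_delta = numeric(0), n_windows = integer(0), n_loci = integer(0)
    ))
  }
  regions <- sig %>%
    group_by(.data$chrom) %>%
    mutate(
      new_region = .data$start > cummax_lag_end(.data$end) + 1,
      region_id = cumsum(.data$new_region)
    ) %>%
    group_by(.data$chrom, .data$region_id) %>%
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      peak_delta = .data$mean_delta[which.max(abs(.data$mean_delta))],
      n_windows = n(),
      .groups = "drop"
    ) %>%
    select(-"region_id")
  regions$n_loci <- if (is.null(records)) {
    NA_integer_
  } else {
    purrr::pmap_int(
      regions[, c("chrom", "start", "end")],
      function(chrom, start, end) {
        sum(records$chrom == chrom & records$pos >= start & records$pos <= end)
      }
    )
  }
  arrange(regions, .data$chrom, .data$start)
}

# Running max of previous ends within a group (Inf-free; first element
# returns -Inf so the first window always opens a region).
cummax_lag_end <- function(end) {
  if (!length(end)) return(numeric(0))
  c(-Inf, cummax(end)[-length(end)])
}
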