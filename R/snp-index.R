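#' Compute per-bulk SNP indices
#'
#' The SNP index of a pool at a locus is the fraction of that pool's reads
#' carrying the parent-B allele (orientation set by the `b_allele`
#' annotation from [select_homozygous_polymorphic()]; flip with
#' `orientation = "parent_a"`).  A pool with zero depth gets a missing
#' index.
#'
#' @param records Allele-depth tibble annotated with `b_allele`.
#' @param orientation Which parent's allele the index counts
#'   (default `"parent_b"`).
#' @return Tibble `chrom`, `pos`, `index_high`, `index_low`, `depth_high`,
#'   `depth_low` (plus the input's allele columns).
#' @export
compute_snp_index <- function(records, orientation = c("parent_b", "parent_a")) {
  orientation <- match.arg(orientation)
  records <- as_tibble(records)
  if (!"b_allele" %in% names(records)) {
    abort("records lack the `b_allele` annotation; run select_homozygous_polymorphic() first")
  }
  b_is_alt <- records$b_allele == "alt"
  if (orientation == "parent_a") b_is_alt <- !b_is_alt
  depth_high <- records$bulk_high_ref + records$bulk_high_alt
  depth_low <- records$bulk_low_ref + records$bulk_low_alt
  b_high <- if_else(b_is_alt, records$bulk_high_alt, records$bulk_high_ref)
  b_low <- if_else(b_is_alt, records$bulk_low_alt, records$bulk_low_ref)
  records %>%
    mutate(
      index_high = if_else(depth_high > 0L, b_high / depth_high, NA_real_),
      index_low = if_else(depth_low > 0L, b_low / depth_low, NA_real_),
      depth_high = depth_high,
      depth_low = depth_low
    )
}

#' Apply per-locus marker filters
#'
#' A locus is dropped when (a) its SNP index is below `min_index` in
#' *both* pools, or (b) its depth is below `min_depth` in *either* pool,
#' or (c) its index is missing in *any* pool.  Counts removed per rule
#' (non-exclusive) are attached as the `filter_report` attribute.
#'
#' @param records Tibble from [compute_snp_index()].
#' @param min_index Minimum SNP index (default 0.3).
#' @param min_depth Minimum per-pool depth (default 7).
#' @return Filtered tibble (a subset of the input rows, original order).
#' @seealso [marker_filter_report()]
#' @export
apply_marker_filters <- function(records, min_index = 0.3, min_depth = 7) {
  records <- as_tibble(records)
  stopifnot(all(c("index_high", "index_low", "depth_high", "depth_low") %in% names(records)))
  missing_any <- is.na(records$index_high) | is.na(records$index_low)
  low_index_both <- !missing_any &
    records$index_high < min_index & records$index_low < min_index
  low_depth <- records$depth_high < min_depth | records$depth_low < min_depth
  drop <- missing_any | low_index_both | low_depth
  out <- records[!drop, , drop = FALSE]
  attr(out, "filter_report") <- list(
    n_input = nrow(records),
    n_removed = sum(drop),
    removed_low_index_both = sum(low_index_both),
    removed_low_depth = sum(low_depth),
    removed_missing_index = sum(missing_any),
    min_index = min_index,
    min_depth = min_depth
  )
  out
}

#' Filter report from [apply_marker_filters()]
#' @param records The filtered tibble.
#' @return Named list of per-rule removal counts and thresholds.
#' @export
marker_filter_report <- function(records) {
  attr(records, "filter_report")
}

#' Compute the delta SNP index
#'
#' delta = index_high - index_low, in \[-1, 1\]; missing when either index
#' is missing.
#'
#' @param records Tibble with `index_high`, `index_low`.
#' @return Input with a `delta` column.
#' @export
compute_delta <- function(records) {
  records <- as_tibble(records)
  mutate(records, delta = .data$index_high - .data$index_low)
}
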