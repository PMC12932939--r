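#' Nitrogen use efficiency (NUtE)
#'
#' NUtE is total plant dry weight divided by whole-plant nitrogen content,
#' in grams of biomass per gram of nitrogen.
#'
#' @param dry_weight Dry weight in g (> 0), vectorised.
#' @param n_content Whole-plant N content in g (> 0), vectorised.
#' @return NUtE in g/g.
#' @examples
#' compute_nue(50, 2.5) # 20
#' @export
compute_nue <- function(dry_weight, n_content) {
  if (any(!is.finite(dry_weight)) || any(!is.finite(n_content)) ||
    any(dry_weight <= 0) || any(n_content <= 0)) {
    abort("`dry_weight` and `n_content` must be positive and finite")
  }
  dry_weight / n_content
}

#' Select extreme phenotype bulks
#'
#' Lines qualify for the low bulk when their NUtE lies inside `low_range`
#' and for the high bulk when it exceeds `high_min`.  When more than
#' `pool_size` lines qualify, the pools take the most extreme qualifying
#' lines (lowest NUtE for the low pool, highest for the high pool), with
#' ties broken by line id, so selection is deterministic and invariant to
#' input row order.
#'
#' @param records Tibble with `line_id` and either `nue` or both
#'   `dry_weight` and `n_content` (NUtE is then computed).
#' @param low_range Length-2 numeric, inclusive NUtE window for the low
#'   class (default c(25, 35) g/g).
#' @param high_min Exclusive lower bound for the high class (default 75 g/g).
#' @param pool_size Lines per bulk (default 15).
#' @return A `bulk_selection` object: list with `low_lines`, `high_lines`,
#'   and `summary` (per-pool mean NUtE and the high/low mean ratio).
#' @export
select_extreme_bulks <- function(records, low_range = c(25, 35), high_min = 75,
                                 pool_size = 15) {
  records <- as_tibble(records)
  if (!"nue" %in% names(records)) {
    records$nue <- compute_nue(records$dry_weight, records$n_content)
  }
  records <- arrange(records, .data$line_id)
  low_q <- records[records$nue >= low_range[1] & records$nue <= low_range[2], ]
  high_q <- records[records$nue > high_min, ]
  shortfall <- c(
    if (nrow(low_q) < pool_size) paste0("low (", nrow(low_q), " qualify)"),
    if (nrow(high_q) < pool_size) paste0("high (", nrow(high_q), " qualify)")
  )
  if (length(shortfall)) {
    abort(paste0(
      "fewer than ", pool_size, " qualifying lines for bulk class: ",
      paste(shortfall, collapse = "; ")
    ))
  }
  low <- low_q %>% arrange(.data$nue, .data$line_id) %>% head(pool_size)
  high <- high_q %>% arrange(desc(.data$nue), .data$line_id) %>% head(pool_size)
  structure(
    list(
      low_lines = low$line_id,
      high_lines = high$line_id,
      summary = tibble(
        mean_low = mean(low$nue),
        mean_high = mean(high$nue),
        ratio_high_low = mean(high$nue) / mean(low$nue)
      )
    ),
    class = "bulk_selection"
  )
}

#' @export
print.bulk_selection <- function(x, ...) {
  cat(
    "<bulk_selection> ", length(x$high_lines), " high + ", length(x$low_lines),
    " low lines; high/low mean NUtE ratio ",
    signif(x$summary$ratio_high_low, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy bulk_selection
#' @export
tidy.bulk_selection <- function(x, ...) {
  tibble(
    line_id = c(x$low_lines, x$high_lines),
    bulk = rep(c("low", "high"), c(length(x$low_lines), length(x$high_lines)))
  )
}

#' @method glance bulk_selection
#' @export
glance.bulk_selection <- function(x, ...) {
  x$summary
}

#' Distribution moments with small-sample bias correction
#'
#' Mean, sample SD, adjusted Fisher-Pearson skewness and bias-corrected
#' excess kurtosis — the conventions printed by mainstream statistics
#' suites (SPSS/SAS; e1071 "type 2").  With moment estimators
#' \eqn{g_1 = m_3 / m_2^{3/2}} and \eqn{g_2 = m_4 / m_2^2 - 3} (central
#' moments \eqn{m_k} with divisor \eqn{n}):
#' \deqn{G_1 = g_1 \sqrt{n(n-1)} / (n-2)}
#' \deqn{G_2 = \left((n+1)\, g_2 + 6\right) \frac{n-1}{(n-2)(n-3)}}
#'
#' @param values Numeric vector, `n >= 4`, non-constant.
#' @return One-row tibble `n`, `mean`, `sd`, `skewness`, `kurtosis`
#'   (excess).
#' @export
distribution_moments <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) abort("need at least 4 finite values for bias-corrected kurtosis")
  if (sd(values) == 0) abort("zero variance: moments undefined")
  tibble(
    n = n,
    mean = mean(values),
    sd = sd(values),
    skewness = e1071::skewness(values, type = 2),
    kurtosis = e1071::kurtosis(values, type = 2)
  )
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((ct_target_treat - ct_ref_treat) - (ct_target_ctrl - ct_ref_ctrl))`.
#'
#' @param ct_target_treat,ct_ref_treat Target and reference-gene Ct in the
#'   treatment condition.
#' @param ct_target_ctrl,ct_ref_ctrl Target and reference-gene Ct in the
#'   control condition.
#' @return Fold change relative to control (vectorised).
#' @examples
#' relative_expression_ddct(20, 18, 24, 19) # 8
#' @export
relative_expression_ddct <- function(ct_target_treat, ct_ref_treat,
                                     ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_treat, ct_ref_treat, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts))) abort("Ct values must be finite")
  ddct <- (ct_target_treat - ct_ref_treat) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
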