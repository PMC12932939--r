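#' Genes in candidate regions with qualifying variant effects
#'
#' A gene is included when its span overlaps a candidate region *and* it
#' carries at least one variant of a qualifying category (by default
#' nonsynonymous, stop_gain or stop_loss) located inside the region.
#'
#' @param regions Region tibble from [call_regions()].
#' @param models A [gene_models()].
#' @param effects Effect-annotated variant tibble from
#'   [classify_variant_effects()].
#' @param categories Qualifying effect categories.
#' @return Tibble `gene_id`, `chrom`, `region_start`, `region_end`,
#'   `nonsynonymous`, `stop_gain`, `stop_loss` (per-category counts inside
#'   the region).
#' @export
genes_in_regions <- function(regions, models, effects,
                             categories = c("nonsynonymous", "stop_gain", "stop_loss")) {
  spans <- gene_spans(models)
  effects <- as_tibble(effects)
  regions <- as_tibble(regions)
  if (!nrow(regions)) {
    return(tibble(
      gene_id = character(0), chrom = character(0),
      region_start = numeric(0), region_end = numeric(0),
      nonsynonymous = integer(0), stop_gain = integer(0), stop_loss = integer(0)
    ))
  }
  out <- purrr::pmap_dfr(
    regions[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      g <- spans[spans$chrom == chrom & spans$start <= end & spans$end >= start, ]
      if (!nrow(g)) return(NULL)
      ev <- effects[
        !is.na(effects$gene_id) &
          effects$gene_id %in% g$gene_id &
          effects$chrom == chrom &
          effects$pos >= start & effects$pos <= end &
          effects$category %in% categories, ,
        drop = FALSE
      ]
      if (!nrow(ev)) return(NULL)
      ev %>%
        count(.data$gene_id, .data$category) %>%
        tidyr::pivot_wider(
          names_from = "category", values_from = "n", values_fill = 0L
        ) %>%
        mutate(chrom = chrom, region_start = start, region_end = end)
    }
  )
  if (is.null(out) || !nrow(out)) {
    return(tibble(
      gene_id = character(0), chrom = character(0),
      region_start = numeric(0), region_end = numeric(0),
      nonsynonymous = integer(0), stop_gain = integer(0), stop_loss = integer(0)
    ))
  }
  for (cat in c("nonsynonymous", "stop_gain", "stop_loss")) {
    if (!cat %in% names(out)) out[[cat]] <- 0L
  }
  out %>%
    select(
      "gene_id", "chrom", "region_start", "region_end",
      "nonsynonymous", "stop_gain", "stop_loss"
    ) %>%
    arrange(.data$chrom, .data$region_start, .data$gene_id)
}

#' Intersect region genes with a differential-expression table
#'
#' Keeps genes present in both inputs that pass |log2FC| > `fc_threshold`
#' and FDR < `fdr_threshold`.  Genes absent from the DEG table are not
#' silently dropped: they are reported in the `missing_from_deg` attribute
#' (see [missing_from_deg()]).  The linear fold change is signed:
#' `sign(log2fc) * 2^|log2fc|`, negative meaning higher expression in the
#' low/sensitive genotype.
#'
#' @param gene_map Output of [genes_in_regions()].
#' @param deg_table Tibble `gene_id`, `log2fc`, `fdr` (one row per gene).
#' @param fc_threshold Minimum |log2FC| (default 1).
#' @param fdr_threshold Maximum FDR, exclusive (default 0.05).
#' @return Candidate tibble: gene map columns plus `log2fc`, `fdr`,
#'   `fold_change`.
#' @export
join_deg <- function(gene_map, deg_table, fc_threshold = 1, fdr_threshold = 0.05) {
  gene_map <- as_tibble(gene_map)
  deg_table <- as_tibble(deg_table)
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(deg_table)))
  dup <- deg_table$gene_id[duplicated(deg_table$gene_id)]
  if (length(dup)) {
    abort(paste0(
      "duplicate gene_id rows in DEG table (ambiguous join): ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  missing <- setdiff(gene_map$gene_id, deg_table$gene_id)
  out <- gene_map %>%
    inner_join(deg_table[, c("gene_id", "log2fc", "fdr")], by = "gene_id") %>%
    filter(abs(.data$log2fc) > fc_threshold, .data$fdr < fdr_threshold) %>%
    mutate(fold_change = sign(.data$log2fc) * 2^abs(.data$log2fc))
  attr(out, "missing_from_deg") <- missing
  out
}

#' Region genes absent from the DEG table
#' @param candidates Output of [join_deg()].
#' @return Character vector of gene ids.
#' @export
missing_from_deg <- function(candidates) {
  attr(candidates, "missing_from_deg") %||% character(0)
}

#' Rank candidates and flag strong expression contrasts
#'
#' Ranks by |fold change| descending (ties broken by gene id) and flags
#' candidates whose |fold change| exceeds `min_abs_fold_change`.
#'
#' @param candidates Output of [join_deg()] (needs `fold_change`).
#' @param min_abs_fold_change Priority threshold on the linear |fold
#'   change| (default 4).
#' @return The input rows, reordered, with `rank` and `priority_flag`
#'   columns.
#' @export
prioritize <- function(candidates, min_abs_fold_change = 4) {
  candidates <- as_tibble(candidates)
  stopifnot("fold_change" %in% names(candidates))
  candidates %>%
    arrange(desc(abs(.data$fold_change)), .data$gene_id) %>%
    mutate(
      rank = row_number(),
      priority_flag = abs(.data$fold_change) > min_abs_fold_change
    )
}
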