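#' Read per-sample allele depths from a VCF
#'
#' Keeps biallelic SNP rows only; indel and multiallelic rows are skipped
#' and counted.  Each sample's AD field is split into (ref, alt) read
#' counts.
#'
#' @param vcf_path Path to a VCF 4.x file with a FORMAT AD field.
#' @param sample_map Named character vector mapping the four canonical
#'   roles `parent_a`, `parent_b`, `bulk_high`, `bulk_low` to VCF sample
#'   names.
#' @param on_unsorted `"error"` (default) to reject a VCF that is not
#'   coordinate-sorted, `"sort"` to re-sort.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt` and
#'   `<role>_ref`/`<role>_alt` integer depths per role.  Skip counts are
#'   attached as the `skipped` attribute (see [read_skip_report()]).
#' @export
read_allele_depths <- function(vcf_path,
                               sample_map = c(
                                 parent_a = "ParentA", parent_b = "ParentB",
                                 bulk_high = "BulkH", bulk_low = "BulkL"
                               ),
                               on_unsorted = c("error", "sort")) {
  on_unsorted <- match.arg(on_unsorted)
  roles <- c("parent_a", "parent_b", "bulk_high", "bulk_low")
  if (!all(roles %in% names(sample_map))) {
    abort(paste0(
      "sample_map must name all of: ", paste(roles, collapse = ", ")
    ))
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  missing_samples <- setdiff(unname(sample_map[roles]), colnames(v@gt))
  if (length(missing_samples)) {
    abort(paste0("VCF missing sample(s): ", paste(missing_samples, collapse = ", ")))
  }

  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  multiallelic <- grepl(",", fix$ALT %||% "", fixed = TRUE)
  skipped <- list(
    multiallelic = sum(multiallelic, na.rm = TRUE),
    indel_or_other = sum(!is_snp & !multiallelic)
  )

  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || !all(unname(sample_map[roles]) %in% colnames(ad))) {
    abort("VCF FORMAT lacks an AD field for the mapped samples")
  }
  out <- tibble(
    chrom = fix$CHROM[is_snp],
    pos = as.integer(fix$POS[is_snp]),
    ref = fix$REF[is_snp],
    alt = fix$ALT[is_snp]
  )
  for (role in roles) {
    col <- ad[is_snp, sample_map[[role]]]
    parts <- stringr::str_split_fixed(col, ",", 2L)
    out[[paste0(role, "_ref")]] <- suppressWarnings(as.integer(parts[, 1L]))
    out[[paste0(role, "_alt")]] <- suppressWarnings(as.integer(parts[, 2L]))
  }
  unsorted <- out %>%
    group_by(.data$chrom) %>%
    summarise(ok = !is.unsorted(.data$pos), .groups = "drop")
  if (any(!unsorted$ok)) {
    if (on_unsorted == "error") {
      abort(paste0(
        "VCF not coordinate-sorted on: ",
        paste(unsorted$chrom[!unsorted$ok], collapse = ", "),
        " (use on_unsorted = \"sort\" to re-sort)"
      ))
    }
    out <- arrange(out, .data$chrom, .data$pos)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Skip-count report from [read_allele_depths()]
#' @param records The tibble returned by [read_allele_depths()].
#' @return Named list of skip counts (also serialisable to a JSON log line).
#' @export
read_skip_report <- function(records) {
  attr(records, "skipped") %||% list(multiallelic = 0L, indel_or_other = 0L)
}

#' Select parental homozygous-polymorphic markers
#'
#' Keeps loci where both parents are confidently homozygous for opposite
#' alleles: per-parent depth at least `min_parent_depth`, per-parent
#' minor-allele read fraction at most `max_minor_fraction`, and the two
#' parental major alleles differ.  Each retained record is annotated with
#' `b_allele` ("ref"/"alt"): the allele carried by parent B, the reference
#' orientation for downstream SNP indices.
#'
#' @param records Allele-depth tibble (see [read_allele_depths()]).
#' @param min_parent_depth Minimum reads per parent (default 7).
#' @param max_minor_fraction Maximum minor-allele read fraction per parent
#'   (default 0.1).
#' @return Filtered tibble with a `b_allele` column; a subset of its input
#'   (the operation is idempotent).
#' @export
select_homozygous_polymorphic <- function(records, min_parent_depth = 7,
                                          max_minor_fraction = 0.1) {
  records <- as_tibble(records)
  pa_tot <- records$parent_a_ref + records$parent_a_alt
  pb_tot <- records$parent_b_ref + records$parent_b_alt
  pa_minor <- pmin(records$parent_a_ref, records$parent_a_alt) / pmax(pa_tot, 1L)
  pb_minor <- pmin(records$parent_b_ref, records$parent_b_alt) / pmax(pb_tot, 1L)
  pa_allele <- if_else(records$parent_a_alt > records$parent_a_ref, "alt", "ref")
  pb_allele <- if_else(records$parent_b_alt > records$parent_b_ref, "alt", "ref")
  keep <- pa_tot >= min_parent_depth & pb_tot >= min_parent_depth &
    pa_minor <= max_minor_fraction & pb_minor <= max_minor_fraction &
    pa_allele != pb_allele
  out <- records[keep, , drop = FALSE]
  out$b_allele <- pb_allele[keep]
  out
}
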