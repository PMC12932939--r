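#' Assemble and validate a pipeline run configuration
#'
#' Defaults follow the published analysis conventions for this kind of
#' scan: 1-Mb windows on a 100-kb step, SNP-index floor 0.3 and per-pool
#' depth floor 7, 1,000 permutation iterations with a 95th-percentile
#' genome-wide threshold, DEG cut-offs |log2FC| > 1 and FDR < 0.05, and a
#' priority flag at linear |fold change| > 4.  A stricter DEG preset is
#' available via `deg_preset = "strict"` (|log2FC| > 3, FDR < 0.01).
#'
#' @param vcf,gff3,cds_fasta,deg,phenotypes Input paths (VCF with AD for
#'   ParentA/ParentB/BulkH/BulkL; GFF3 gene models; spliced-CDS FASTA;
#'   DEG TSV `gene_id`, `log2fc`, `fdr`; phenotype TSV).
#' @param out_dir Artifact directory.
#' @param window_bp,step_bp,min_markers Scan parameters.
#' @param min_index,min_depth Marker filter parameters.
#' @param min_parent_depth,max_minor_fraction Parental marker selection.
#' @param n_iterations,percentile,scheme,pool_size,cm_per_mb Null-threshold
#'   parameters (see [permutation_null()]).
#' @param fc_threshold,fdr_threshold,min_abs_fold_change Candidate
#'   intersection and prioritization parameters.
#' @param deg_preset `"default"` or `"strict"`; the preset overrides
#'   `fc_threshold`/`fdr_threshold` when set to `"strict"`.
#' @param seed Global seed (stage substreams are derived from it).
#' @return A validated `bsa_config` list.
#' @export
run_config <- function(vcf = NULL, gff3 = NULL, cds_fasta = NULL, deg = NULL,
                       phenotypes = NULL, out_dir = "bsa_results",
                       window_bp = 1e6, step_bp = 1e5, min_markers = 3,
                       min_index = 0.3, min_depth = 7,
                       min_parent_depth = 7, max_minor_fraction = 0.1,
                       n_iterations = 1000, percentile = 95,
                       scheme = "ril_null", pool_size = 15, cm_per_mb = 3,
                       fc_threshold = 1, fdr_threshold = 0.05,
                       min_abs_fold_change = 4,
                       deg_preset = c("default", "strict"),
                       seed = 1) {
  deg_preset <- match.arg(deg_preset)
  if (deg_preset == "strict") {
    fc_threshold <- 3
    fdr_threshold <- 0.01
  }
  check_window_params(window_bp, step_bp)
  if (min_index < 0 || min_index > 1) abort("`min_index` must be in [0, 1]")
  if (min_depth < 0) abort("`min_depth` must be >= 0")
  if (n_iterations < 1) abort("`n_iterations` must be >= 1")
  if (percentile <= 0 || percentile > 100) abort("`percentile` must be in (0, 100]")
  if (!scheme %in% c("ril_null", "label_swap", "binomial_null")) {
    abort("`scheme` must be 'ril_null', 'label_swap' or 'binomial_null'")
  }
  structure(
    list(
      vcf = vcf, gff3 = gff3, cds_fasta = cds_fasta, deg = deg,
      phenotypes = phenotypes, out_dir = out_dir,
      window_bp = window_bp, step_bp = step_bp, min_markers = min_markers,
      min_index = min_index, min_depth = min_depth,
      min_parent_depth = min_parent_depth,
      max_minor_fraction = max_minor_fraction,
      n_iterations = n_iterations, percentile = percentile, scheme = scheme,
      pool_size = pool_size, cm_per_mb = cm_per_mb,
      fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
      min_abs_fold_change = min_abs_fold_change,
      deg_preset = deg_preset, seed = seed
    ),
    class = "bsa_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' `load(serialize(config))` returns an identical configuration.
#'
#' @param config A `bsa_config`.
#' @param path YAML path.
#' @return `read_run_config()` returns a validated `bsa_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "bsa_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full bulked-segregant pipeline
#'
#' Stage order: read allele depths, select parental homozygous-polymorphic
#' markers, compute SNP indices and delta, apply marker filters, sliding
#' window scan, permutation threshold, region calls, variant-effect
#' annotation, DEG intersection and prioritization.  All artifacts (TSV,
#' BED, JSON manifest) are written under `config$out_dir`; a rerun with an
#' identical configuration is byte-identical.
#'
#' @param config A [run_config()] (or path to its YAML).
#' @return A `bsa_run` object: list with the stage tibbles (`records`,
#'   `markers`, `snp_index`, `windows`, `null`, `threshold`, `regions`,
#'   `effects`, `gene_map`, `candidates`), the `config`, and `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "bsa_config"))
  for (f in c("vcf", "gff3", "cds_fasta", "deg")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      abort(paste0("stage input missing [", f, "]: ", config[[f]] %||% "<unset>"))
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage [", name, "] failed: ", conditionMessage(e)))
    })
  }

  records <- stage("variants", read_allele_depths(config$vcf))
  chrom_lengths <- vcf_contigs(config$vcf)
  models <- stage("variants", read_gene_models(config$gff3, config$cds_fasta))

  markers <- stage("variants", select_homozygous_polymorphic(
    records,
    min_parent_depth = config$min_parent_depth,
    max_minor_fraction = config$max_minor_fraction
  ))
  snp_index <- stage("snp_index", {
    compute_snp_index(markers) %>%
      apply_marker_filters(min_index = config$min_index, min_depth = config$min_depth) %>%
      compute_delta()
  })
  filter_report <- marker_filter_report(snp_index)

  windows <- stage("genome_scan", window_scan(
    snp_index, chrom_lengths,
    window_bp = config$window_bp, step_bp = config$step_bp,
    min_markers = config$min_markers
  ))
  null <- stage("genome_scan", permutation_null(
    snp_index, chrom_lengths,
    n_iterations = config$n_iterations, scheme = config$scheme,
    pool_size = config$pool_size, cm_per_mb = config$cm_per_mb,
    seed = sub_seed(config$seed, 11),
    window_bp = config$window_bp, step_bp = config$step_bp,
    min_markers = config$min_markers, percentile = config$percentile
  ))
  regions <- stage("genome_scan", call_regions(windows, null$threshold, snp_index))

  effects <- stage("variants", classify_variant_effects(markers, models))
  gene_map <- stage("candidates", genes_in_regions(regions, models, effects))
  deg_table <- stage("candidates", readr::read_tsv(
    config$deg,
    show_col_types = FALSE, progress = FALSE
  ))
  candidates <- stage("candidates", {
    join_deg(
      gene_map, deg_table,
      fc_threshold = config$fc_threshold, fdr_threshold = config$fdr_threshold
    ) %>%
      prioritize(min_abs_fold_change = config$min_abs_fold_change)
  })

  paths <- write_run_artifacts(
    config, snp_index, windows, null, regions, candidates,
    skip_report = read_skip_report(records), filter_report = filter_report
  )
  structure(
    list(
      config = config, records = records, markers = markers,
      snp_index = snp_index, windows = windows, null = null,
      threshold = null$threshold, regions = regions, effects = effects,
      gene_map = gene_map, candidates = candidates, paths = paths
    ),
    class = "bsa_run"
  )
}

# Contig names/lengths from VCF header lines.
vcf_contigs <- function(vcf_path) {
  hdr <- readr::read_lines(vcf_path, n_max = 500)
  hdr <- hdr[startsWith(hdr, "##contig")]
  if (!length(hdr)) abort("VCF header has no ##contig lines")
  tibble(
    chrom = stringr::str_match(hdr, "ID=([^,>]+)")[, 2],
    length_bp = as.numeric(stringr::str_match(hdr, "length=(\\d+)")[, 2])
  )
}

write_run_artifacts <- function(config, snp_index, windows, null, regions,
                                candidates, skip_report, filter_report) {
  out <- config$out_dir
  paths <- list(
    snp_index = file.path(out, "snp_index.tsv"),
    windows = file.path(out, "windows.tsv"),
    null_maxima = file.path(out, "null_maxima.tsv"),
    regions_tsv = file.path(out, "regions.tsv"),
    regions_bed = file.path(out, "regions.bed"),
    candidates = file.path(out, "candidates.tsv"),
    manifest = file.path(out, "manifest.json")
  )
  readr::write_tsv(
    select(
      snp_index, "chrom", "pos", "index_high", "index_low",
      "depth_high", "depth_low", "delta"
    ),
    paths$snp_index
  )
  readr::write_tsv(windows, paths$windows)
  readr::write_tsv(tidy(null), paths$null_maxima)
  readr::write_tsv(regions, paths$regions_tsv)
  # BED is 0-based half-open
  readr::write_tsv(
    tibble(
      chrom = regions$chrom,
      start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
      end = format(regions$end, scientific = FALSE, trim = TRUE),
      name = sprintf("region_%d", seq_len(nrow(regions)))
    ),
    paths$regions_bed,
    col_names = FALSE
  )
  readr::write_tsv(candidates, paths$candidates)
  manifest <- list(
    parameters = unclass(config),
    threshold = null$threshold,
    n_regions = nrow(regions),
    n_candidates = nrow(candidates),
    skip_report = skip_report,
    filter_report = filter_report,
    input_checksums = as.list(tools::md5sum(unlist(
      config[c("vcf", "gff3", "cds_fasta", "deg")]
    )))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  paths
}

#' @export
print.bsa_run <- function(x, ...) {
  cat(
    "<bsa_run> ", nrow(x$snp_index), " filtered markers, threshold ",
    signif(x$threshold, 4), ", ", nrow(x$regions), " region(s), ",
    nrow(x$candidates), " candidate gene(s)\n",
    sep = ""
  )
  invisible(x)
}

#' @method glance bsa_run
#' @export
glance.bsa_run <- function(x, ...) {
  tibble(
    n_markers = nrow(x$snp_index),
    threshold = x$threshold,
    n_regions = nrow(x$regions),
    n_candidate_genes = nrow(x$candidates),
    n_priority_genes = sum(x$candidates$priority_flag),
    top_gene = if (nrow(x$candidates)) x$candidates$gene_id[1] else NA_character_,
    top_fold_change = if (nrow(x$candidates)) x$candidates$fold_change[1] else NA_real_
  )
}

#' @method tidy bsa_run
#' @export
tidy.bsa_run <- function(x, ...) {
  as_tibble(x$candidates)
}
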