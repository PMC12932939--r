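SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))

# Random single-segment CDS of n_codons: ATG start, TAA stop, sense body.
random_cds <- function(n_codons) {
  body <- sample(setdiff(SENSE_CODONS, "ATG"), n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Build the synthetic gene complement for a fixture genome
#'
#' Plants a configurable set of candidate genes around a focal position
#' (each with one engineered nonsynonymous site), plus in-region decoys (a
#' gene with only a synonymous site, a gene whose nonsynonymous site has no
#' expression support) and an out-of-region decoy on another chromosome
#' with both a nonsynonymous site and strong differential expression —
#' exactly the cases the candidate intersection must separate.  Background
#' genes without engineered sites fill out the gene universe.
#'
#' @param map A [genetic_map()] (chromosome names/lengths are taken from it).
#' @param qtl_chrom,qtl_pos Focal chromosome and position the planted
#'   candidate genes flank.
#' @param n_planted Number of planted candidate genes (default 6).
#' @param n_background Background genes scattered genome-wide.
#' @param seed Integer seed for the random coding sequences.
#' @return List: `models` ([gene_models()]), `variant_sites` (tibble
#'   `chrom`, `pos`, `ref`, `alt`, `b_allele`, `gene_id`,
#'   `expected_category`), `planted_genes`, `decoys` (named list),
#'   `gene_ids` (full universe).
#' @export
make_synthetic_genes <- function(map, qtl_chrom = "chr3", qtl_pos = 20e6,
                                 n_planted = 6, n_background = 30, seed = 1) {
  set.seed(seed)
  n_codons <- 100L
  cds_len <- n_codons * 3L
  planted_ids <- sprintf("cand_%02d", seq_len(n_planted))
  # flank the focal position within ~1.6 Mb either side
  offsets <- round(seq(-1.6e6, 1.6e6, length.out = n_planted))
  planted <- tibble(
    gene_id = planted_ids,
    chrom = qtl_chrom,
    start = as.numeric(qtl_pos + offsets),
    strand = rep(c("+", "-"), length.out = n_planted),
    site = "nonsynonymous"
  )
  decoys <- tibble(
    gene_id = c("decoy_synonymous", "decoy_no_de", "decoy_off_region"),
    chrom = c(qtl_chrom, qtl_chrom, "chr5"),
    start = c(qtl_pos + 0.45e6, qtl_pos - 0.45e6, 20e6),
    strand = c("+", "-", "+"),
    site = c("synonymous", "nonsynonymous", "nonsynonymous")
  )
  chroms <- map$chromosomes
  bg <- tibble(
    gene_id = sprintf("bg_%03d", seq_len(n_background)),
    chrom = sample(chroms$chrom, n_background, replace = TRUE),
    strand = sample(c("+", "-"), n_background, replace = TRUE),
    site = NA_character_
  )
  bg$start <- floor(runif(
    n_background, 1e6,
    chroms$length_bp[match(bg$chrom, chroms$chrom)] - 1e6
  ))
  genes <- bind_rows(planted, decoys, bg) %>%
    mutate(end = .data$start + cds_len - 1)

  cds <- vapply(genes$gene_id, function(g) random_cds(n_codons), character(1))
  # engineered site at codon 50: AAA with first-base A>G (Glu,
  # nonsynonymous) or third-base A>G (Lys, synonymous)
  codon_i <- 50L
  cds_site1 <- (codon_i - 1L) * 3L + 1L
  sites <- purrr::pmap_dfr(
    genes[!is.na(genes$site), c("gene_id", "chrom", "start", "end", "strand", "site")],
    function(gene_id, chrom, start, end, strand, site) {
      s <- cds[[gene_id]]
      substr(s, cds_site1, cds_site1 + 2L) <- "AAA"
      cds[[gene_id]] <<- s
      cds_pos <- if (site == "synonymous") cds_site1 + 2L else cds_site1
      genomic_pos <- if (strand == "+") start + cds_pos - 1 else end - cds_pos + 1
      ref_t <- "A"
      alt_t <- "G"
      tibble(
        chrom = chrom,
        pos = genomic_pos,
        ref = if (strand == "+") ref_t else COMPLEMENT[[ref_t]],
        alt = if (strand == "+") alt_t else COMPLEMENT[[alt_t]],
        b_allele = "alt",
        gene_id = gene_id,
        expected_category = site
      )
    }
  )
  segments <- genes %>%
    select("gene_id", "chrom", "strand", "start", "end")
  list(
    models = gene_models(segments, cds),
    variant_sites = sites,
    planted_genes = planted_ids,
    decoys = list(
      synonymous = "decoy_synonymous",
      no_de = "decoy_no_de",
      off_region = "decoy_off_region"
    ),
    gene_ids = genes$gene_id
  )
}

#' Write allele-depth records as a VCF 4.2 file
#'
#' Emits one biallelic SNP row per record with a FORMAT `AD` field for the
#' four samples ParentA, ParentB, BulkH, BulkL.
#'
#' @param records Allele-depth tibble (see [sample_pool_depths()]).
#' @param path Output path.
#' @param chrom_lengths Tibble `chrom`, `length_bp` for contig headers.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(records, path, chrom_lengths) {
  records <- arrange(as_tibble(records), .data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bulkscan",
    sprintf(
      "##contig=<ID=%s,length=%d>",
      chrom_lengths$chrom, as.integer(chrom_lengths$length_bp)
    ),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      "ParentA", "ParentB", "BulkH", "BulkL",
      sep = "\t"
    )
  )
  ad <- function(role) {
    paste0(records[[paste0(role, "_ref")]], ",", records[[paste0(role, "_alt")]])
  }
  body <- paste(
    records$chrom, records$pos, ".", records$ref, records$alt, ".", "PASS", ".",
    "AD", ad("parent_a"), ad("parent_b"), ad("bulk_high"), ad("bulk_low"),
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write gene models as GFF3 plus a spliced-CDS FASTA
#'
#' @param models A [gene_models()].
#' @param gff3_path,fasta_path Output paths.
#' @return `gff3_path`, invisibly.
#' @export
write_gene_models <- function(models, gff3_path, fasta_path) {
  spans <- gene_spans(models)
  segs <- models$segments
  feat <- bind_rows(
    spans %>% mutate(
      type = "gene", ID = .data$gene_id, Parent = NA_character_
    ),
    spans %>% mutate(
      type = "mRNA", ID = paste0(.data$gene_id, ".1"), Parent = .data$gene_id
    ),
    segs %>% mutate(
      type = "CDS", ID = NA_character_, Parent = paste0(.data$gene_id, ".1"),
      phase = .data$cds_offset %% 3L
    )
  )
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(start = feat$start, end = feat$end),
    strand = feat$strand
  )
  gr$type <- feat$type
  gr$ID <- feat$ID
  gr$Parent <- as_parent_list(feat$Parent)
  gr$phase <- feat$phase
  rtracklayer::export(gr, gff3_path, format = "gff3")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(models$cds), fasta_path
  )
  invisible(gff3_path)
}

as_parent_list <- function(x) {
  IRanges::CharacterList(lapply(x, function(v) if (is.na(v)) character(0) else v))
}

#' Write a complete synthetic input bundle
#'
#' Generates every input the pipeline consumes — pooled allele-depth VCF,
#' gene models (GFF3 + CDS FASTA), phenotype and differential-expression
#' TSVs, and a YAML run config — from a single global seed, with the
#' statistical structure the analysis assumes: an F8 RIL population by
#' single-seed descent, a Normal quantitative trait with one major
#' additive QTL, extreme-bulk selection, and depth-limited pooled allele
#' counts with sequencing error.  A `truth.json` manifest records every
#' stage seed and the planted truth for end-to-end checks.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed; per-stage substreams are derived from
#'   it.
#' @param n_lines Lines in the RIL population (default 120).
#' @param generation Filial generation (default 8).
#' @param map A [genetic_map()]; default [default_map()].
#' @param qtl A [qtl_spec()]; default: chr3 at 20 Mb, additive effect 54
#'   phenotype units over baseline 30, residual sd 6 (a major QTL that
#'   reproduces the 25-35 / >75 g/g extreme-class structure).
#' @param baseline Trait baseline (default 30 g/g).
#' @param pool_spec A [pool_seq_spec()]; default 15-line pools at mean
#'   depth 23 with error rate 0.001.
#' @param low_range,high_min,pool_size Extreme-bulk selection rules (see
#'   [select_extreme_bulks()]).
#' @param config Optional [run_config()] overrides (list).
#' @return Invisibly, a list with component objects (`map`, `genes`,
#'   `pop`, `phenotypes`, `bulks`, `records`, `deg`, `config`) and `paths`.
#' @export
write_fixture_set <- function(out_dir, seed = 1, n_lines = 120, generation = 8,
                              map = default_map(),
                              qtl = qtl_spec("chr3", 20e6, 54, 6),
                              baseline = 30,
                              pool_spec = NULL,
                              low_range = c(25, 35), high_min = 75,
                              pool_size = 15,
                              config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create output directory: ", out_dir))
  genes <- make_synthetic_genes(
    map,
    qtl_chrom = qtl$chrom, qtl_pos = qtl$position_bp,
    seed = sub_seed(seed, 1)
  )
  # keep gene bodies free of grid markers so the only in-CDS segregating
  # sites are the engineered ones, then add those sites as map markers
  spans <- gene_spans(genes$models)
  grid <- map$markers
  in_gene <- purrr::map_lgl(seq_len(nrow(grid)), function(i) {
    any(spans$chrom == grid$chrom[i] &
      spans$start <= grid$pos[i] & spans$end >= grid$pos[i])
  })
  map <- genetic_map(map$chromosomes, cm_per_mb = map$cm_per_mb,
                     markers = grid[!in_gene, ])
  map <- add_markers(map, genes$variant_sites)
  pop <- simulate_ril_genotypes(map, n_lines, generation, seed = sub_seed(seed, 2))
  phen <- assign_phenotypes(pop, qtl, baseline = baseline, seed = sub_seed(seed, 3))

  set.seed(sub_seed(seed, 4))
  n_content <- pmax(0.2, rnorm(n_lines, 0.5, 0.05))
  nue <- pmax(1, phen$phenotype)
  phenotypes <- tibble(
    line_id = phen$line_id,
    dry_weight_g = nue * n_content,
    n_content_g = n_content
  )
  bulks <- select_extreme_bulks(
    phenotypes %>% rename(dry_weight = "dry_weight_g", n_content = "n_content_g"),
    low_range = low_range, high_min = high_min, pool_size = pool_size
  )

  # allele table: engineered in-gene sites keep their fixed bases, grid
  # markers get random biallelic assignments
  set.seed(sub_seed(seed, 5))
  mk <- map$markers
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(mk), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  b_allele <- if_else(runif(nrow(mk)) < 0.5, "alt", "ref")
  alleles <- tibble(chrom = mk$chrom, pos = mk$pos, ref = ref, alt = alt, b_allele = b_allele)
  site_key <- paste(genes$variant_sites$chrom, genes$variant_sites$pos)
  idx <- match(site_key, paste(alleles$chrom, alleles$pos))
  alleles$ref[idx] <- genes$variant_sites$ref
  alleles$alt[idx] <- genes$variant_sites$alt
  alleles$b_allele[idx] <- genes$variant_sites$b_allele

  pool_spec <- pool_spec %||% pool_seq_spec(
    bulk_size = pool_size, mean_depth = 23, error_rate = 0.001,
    seed = sub_seed(seed, 6)
  )
  records <- sample_pool_depths(
    pop, bulks$high_lines, bulks$low_lines, pool_spec,
    alleles = alleles
  )

  # expression: planted candidates get the engineered fold-change pattern
  # (two strong positive, two at roughly the priority boundary on either
  # side, two moderate negative); the off-region decoy is strongly DE, the
  # in-region no-DE decoy stays flat
  planted_fc <- c(15.01, 30.36, -4.30, 4.10, -3.22, -3.80)
  planted <- tibble(
    gene_id = c(genes$planted_genes, genes$decoys$off_region),
    log2fc = c(sign(planted_fc) * log2(abs(planted_fc)), 3.2)
  )
  deg <- generate_deg_table(
    genes$gene_ids,
    de_genes = c(genes$planted_genes, genes$decoys$off_region),
    seed = sub_seed(seed, 7),
    planted = planted
  )

  paths <- list(
    vcf = file.path(out_dir, "pool_ad.vcf"),
    gff3 = file.path(out_dir, "genes.gff3"),
    cds_fasta = file.path(out_dir, "cds.fasta"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    deg = file.path(out_dir, "deg.tsv"),
    config = file.path(out_dir, "config.yaml"),
    truth = file.path(out_dir, "truth.json")
  )
  write_pool_vcf(records, paths$vcf, map$chromosomes)
  write_gene_models(genes$models, paths$gff3, paths$cds_fasta)
  readr::write_tsv(phenotypes, paths$phenotypes)
  readr::write_tsv(deg, paths$deg)

  cfg <- do.call(run_config, modifyList(
    list(
      vcf = paths$vcf, gff3 = paths$gff3, cds_fasta = paths$cds_fasta,
      deg = paths$deg, phenotypes = paths$phenotypes,
      out_dir = file.path(out_dir, "results"), seed = seed
    ),
    config
  ))
  write_run_config(cfg, paths$config)

  truth <- list(
    seed = seed,
    stage_seeds = list(
      genes = sub_seed(seed, 1), genotypes = sub_seed(seed, 2),
      phenotypes = sub_seed(seed, 3), n_content = sub_seed(seed, 4),
      alleles = sub_seed(seed, 5), depths = pool_spec$seed,
      deg = sub_seed(seed, 7)
    ),
    qtl = list(
      chrom = qtl$chrom, position_bp = qtl$position_bp,
      additive_effect = qtl$additive_effect, residual_sd = qtl$residual_sd
    ),
    planted_genes = genes$planted_genes,
    planted_fold_change = planted_fc,
    decoys = genes$decoys,
    bulks = list(high = bulks$high_lines, low = bulks$low_lines)
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    map = map, genes = genes, pop = pop, phenotypes = phenotypes,
    bulks = bulks, records = records, deg = deg, config = cfg, paths = paths
  ))
}
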