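#' Build a validated set of gene models
#'
#' A gene model is a strand, an ordered set of CDS segments (1-based
#' inclusive genomic intervals) and the spliced coding sequence they imply,
#' given in transcript orientation (5' to 3').  Models whose total CDS
#' length is not divisible by 3, or whose supplied sequence length does not
#' match the segments, are flagged incomplete and excluded from effect
#' calls (variants inside them are reported noncoding, with a warning
#' count).
#'
#' @param segments Data frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end`.  Segments of one gene must share chromosome
#'   and strand and must not overlap.
#' @param cds_seqs Named character vector (or `Biostrings::DNAStringSet`)
#'   of spliced CDS, one per gene id, transcript orientation.
#' @return A `gene_models` object: list with `segments` (tibble with
#'   per-segment transcript offsets), `cds` (named character), `incomplete`
#'   (character vector of flagged gene ids).
#' @export
gene_models <- function(segments, cds_seqs) {
  segments <- as_tibble(segments)
  need <- c("gene_id", "chrom", "strand", "start", "end")
  stopifnot(all(need %in% names(segments)))
  if (!all(segments$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(segments$end < segments$start)) abort("segment end < start")
  if (inherits(cds_seqs, "DNAStringSet")) {
    cds_seqs <- setNames(as.character(cds_seqs), names(cds_seqs))
  }
  cds_seqs <- toupper(cds_seqs)

  # order segments 5'->3' in transcript orientation, compute offsets
  segs <- segments %>%
    group_by(.data$gene_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(
      minus = first(.data$strand) == "-",
      ord = if (first(.data$strand) == "-") rev(row_number()) else row_number()
    ) %>%
    arrange(.data$ord, .by_group = TRUE) %>%
    mutate(
      seg_len = .data$end - .data$start + 1L,
      cds_offset = cumsum(.data$seg_len) - .data$seg_len
    ) %>%
    ungroup() %>%
    select(-"minus", -"ord")

  incomplete <- character(0)
  for (g in unique(segs$gene_id)) {
    s <- segs[segs$gene_id == g, ]
    total <- sum(s$seg_len)
    if (length(unique(s$chrom)) > 1L || length(unique(s$strand)) > 1L) {
      abort(paste0("gene ", g, ": segments on mixed chromosome/strand"))
    }
    o <- s[order(s$start), ]
    if (nrow(o) > 1L && any(o$start[-1] <= o$end[-nrow(o)])) {
      abort(paste0("gene ", g, ": overlapping CDS segments"))
    }
    seq_ok <- g %in% names(cds_seqs) && nchar(cds_seqs[[g]]) == total
    if (total %% 3L != 0L || !seq_ok) incomplete <- c(incomplete, g)
  }
  structure(
    list(segments = segs, cds = cds_seqs, incomplete = incomplete),
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat(
    "<gene_models> ", length(unique(x$segments$gene_id)), " gene(s), ",
    nrow(x$segments), " CDS segment(s), ", length(x$incomplete),
    " incomplete\n",
    sep = ""
  )
  invisible(x)
}

#' Gene spans (union extent of CDS segments)
#' @param models A [gene_models()].
#' @return Tibble `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
gene_spans <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  models$segments %>%
    group_by(.data$gene_id) %>%
    summarise(
      chrom = first(.data$chrom), strand = first(.data$strand),
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    )
}

#' Read gene models from GFF3 + spliced CDS FASTA
#'
#' Expects a three-level GFF3 (gene / mRNA / CDS) where each gene has one
#' mRNA named `<gene_id>.1`, and a FASTA of spliced CDS keyed by gene id.
#'
#' @param gff3_path Path to GFF3.
#' @param cds_fasta_path Path to CDS FASTA.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(gff3_path, cds_fasta_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  parent <- unlist(cds$Parent)
  segments <- tibble(
    gene_id = sub("\\.\\d+$", "", parent),
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds)
  )
  seqs <- Biostrings::readDNAStringSet(cds_fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gene_models(segments, seqs)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify coding consequences of SNPs
#'
#' For each biallelic substitution, locates the CDS segment containing the
#' position, maps it to a transcript coordinate (reverse-complementing on
#' the minus strand), substitutes the alternate base into the affected
#' codon, and translates codon-before vs codon-after with the standard
#' genetic code.  Categories: `synonymous`, `nonsynonymous` (amino-acid
#' change, including start-codon loss), `stop_gain` (sense to stop),
#' `stop_loss` (stop to sense), `noncoding` (outside all CDS, or inside a
#' model flagged incomplete — the latter also increments a warning count
#' stored in the `n_incomplete_hits` attribute).
#'
#' @param records Data frame with `chrom`, `pos`, `ref`, `alt`
#'   (single bases).
#' @param models A [gene_models()].
#' @return The input with columns `gene_id`, `category`, `codon_before`,
#'   `codon_after` appended (`NA` codons for noncoding).
#' @export
classify_variant_effects <- function(records, models) {
  stopifnot(inherits(models, "gene_models"))
  records <- as_tibble(records)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(records)))
  segs <- models$segments
  n <- nrow(records)
  gene_id <- rep(NA_character_, n)
  category <- rep("noncoding", n)
  codon_before <- rep(NA_character_, n)
  codon_after <- rep(NA_character_, n)
  n_incomplete <- 0L

  gc_tab <- Biostrings::GENETIC_CODE
  for (i in seq_len(n)) {
    hit <- which(
      segs$chrom == records$chrom[i] &
        segs$start <= records$pos[i] & segs$end >= records$pos[i]
    )
    if (!length(hit)) next
    hit <- hit[1L]
    g <- segs$gene_id[hit]
    if (g %in% models$incomplete) {
      n_incomplete <- n_incomplete + 1L
      next
    }
    gene_id[i] <- g
    minus <- segs$strand[hit] == "-"
    cds_pos <- if (minus) {
      segs$cds_offset[hit] + (segs$end[hit] - records$pos[i] + 1L)
    } else {
      segs$cds_offset[hit] + (records$pos[i] - segs$start[hit] + 1L)
    }
    cds <- models$cds[[g]]
    ref_t <- if (minus) COMPLEMENT[[records$ref[i]]] else records$ref[i]
    alt_t <- if (minus) COMPLEMENT[[records$alt[i]]] else records$alt[i]
    codon_idx <- (cds_pos - 1L) %/% 3L
    within <- (cds_pos - 1L) %% 3L + 1L
    cb <- substr(cds, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
    ca <- cb
    substr(ca, within, within) <- alt_t
    codon_before[i] <- cb
    codon_after[i] <- ca
    aa_b <- gc_tab[[cb]]
    aa_a <- gc_tab[[ca]]
    category[i] <- if (aa_b == aa_a) {
      "synonymous"
    } else if (aa_a == "*") {
      "stop_gain"
    } else if (aa_b == "*") {
      "stop_loss"
    } else {
      "nonsynonymous"
    }
  }
  out <- records %>%
    mutate(
      gene_id = gene_id, category = category,
      codon_before = codon_before, codon_after = codon_after
    )
  attr(out, "n_incomplete_hits") <- n_incomplete
  out
}
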