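# Independent brute-force oracles and tiny fixture builders used across
# the suite.  The oracles deliberately share no code with the package
# implementations they check.

# Direct interval-scan window means: for every window, average the deltas
# with start <= pos <= end by filtering the full marker table.
oracle_window_means <- function(records, chrom_lengths, window_bp, step_bp,
                                min_markers) {
  out <- list()
  for (ci in seq_len(nrow(chrom_lengths))) {
    cn <- chrom_lengths$chrom[ci]
    len <- chrom_lengths$length_bp[ci]
    starts <- seq(1, len, by = step_bp)
    for (s in starts) {
      e <- min(s + window_bp - 1, len)
      d <- records$delta[records$chrom == cn & records$pos >= s & records$pos <= e]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = s, end = e,
        mean_delta = if (length(d) >= min_markers) mean(d) else NA_real_,
        n_markers = length(d)
      )
    }
  }
  tibble::as_tibble(do.call(rbind, out))
}

# Full-transcript translation diff: rebuild the entire spliced CDS with
# the variant substituted at its transcript coordinate, translate both
# versions, and classify from the changed amino acid.
oracle_effect <- function(chrom, pos, ref, alt, models) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  segs <- models$segments
  hit <- which(segs$chrom == chrom & segs$start <= pos & segs$end >= pos)
  if (!length(hit)) return("noncoding")
  hit <- hit[1L]
  g <- segs$gene_id[hit]
  if (g %in% models$incomplete) return("noncoding")
  minus <- segs$strand[hit] == "-"
  cds_pos <- if (minus) {
    segs$cds_offset[hit] + (segs$end[hit] - pos + 1L)
  } else {
    segs$cds_offset[hit] + (pos - segs$start[hit] + 1L)
  }
  cds_before <- models$cds[[g]]
  alt_t <- if (minus) comp[[alt]] else alt
  cds_after <- cds_before
  substr(cds_after, cds_pos, cds_pos) <- alt_t
  tr <- function(s) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(s),
      if.fuzzy.codon = "X", no.init.codon = TRUE
    ))
  }
  p_before <- tr(cds_before)
  p_after <- tr(cds_after)
  aa_i <- (cds_pos - 1L) %/% 3L + 1L
  b <- substr(p_before, aa_i, aa_i)
  a <- substr(p_after, aa_i, aa_i)
  if (b == a) "synonymous" else if (a == "*") "stop_gain" else if (b == "*") "stop_loss" else "nonsynonymous"
}

# Random multi-exon gene models with consistent genomic context: returns
# models plus a lookup to draw valid in-CDS variants (genomic ref base
# derived from the CDS, random different alt).
random_gene_set <- function(n_genes, chrom = "chrZ", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  segs <- list()
  cds <- character(0)
  cursor <- 1000L
  for (i in seq_len(n_genes)) {
    n_codons <- sample(20:60, 1)
    n_exons <- sample(1:3, 1)
    total <- n_codons * 3L
    cuts <- sort(sample(seq_len(total - 1L), n_exons - 1L))
    lens <- diff(c(0L, cuts, total))
    strand <- sample(c("+", "-"), 1)
    seq_tx <- paste0(
      "ATG", paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""), "TAA"
    )
    gid <- sprintf("rg_%03d", i)
    starts <- integer(n_exons)
    ends <- integer(n_exons)
    p <- cursor
    for (k in seq_len(n_exons)) {
      starts[k] <- p
      ends[k] <- p + lens[k] - 1L
      p <- ends[k] + sample(50:200, 1) # intron
    }
    cursor <- p + sample(500:1500, 1)
    segs[[i]] <- data.frame(
      gene_id = gid, chrom = chrom, strand = strand,
      start = starts, end = ends
    )
    cds[gid] <- seq_tx
  }
  models <- bulkscan::gene_models(do.call(rbind, segs), cds)
  models
}

# Draw one random in-CDS variant for a gene set: returns chrom/pos/ref/alt
# with the genomic ref consistent with the model's CDS.
random_cds_variant <- function(models) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  segs <- models$segments
  row <- segs[sample.int(nrow(segs), 1), ]
  pos <- row$start + sample.int(row$end - row$start + 1L, 1L) - 1L
  minus <- row$strand == "-"
  cds_pos <- if (minus) {
    row$cds_offset + (row$end - pos + 1L)
  } else {
    row$cds_offset + (pos - row$start + 1L)
  }
  base_t <- substr(models$cds[[row$gene_id]], cds_pos, cds_pos)
  ref_g <- if (minus) comp[[base_t]] else base_t
  alt_g <- sample(setdiff(c("A", "C", "G", "T"), ref_g), 1)
  list(chrom = row$chrom, pos = pos, ref = ref_g, alt = alt_g)
}

# Per-meiosis gamete-by-gamete SSD simulator for a two-marker chromosome:
# an explicit, scalar re-implementation of single-seed descent used as the
# recombination oracle.
oracle_ssd_two_markers <- function(n_lines, r, generation) {
  res <- matrix(0, n_lines, 2)
  for (i in seq_len(n_lines)) {
    h1 <- c(0L, 0L)
    h2 <- c(1L, 1L)
    for (g in seq_len(generation - 1L)) {
      gam <- function() {
        first <- if (stats::runif(1) < 0.5) 1L else 2L
        second <- if (stats::runif(1) < r) 3L - first else first
        c(
          if (first == 1L) h1[1] else h2[1],
          if (second == 1L) h1[2] else h2[2]
        )
      }
      n1 <- gam()
      n2 <- gam()
      h1 <- n1
      h2 <- n2
    }
    res[i, ] <- (h1 + h2) / 2
  }
  res
}

# Small two-chromosome map for scan tests.
toy_map <- function(n_markers = 40) {
  genetic_map(
    data.frame(
      chrom = c("c1", "c2"),
      length_bp = c(5e6, 3e6),
      n_markers = c(n_markers, max(1, n_markers %/% 2))
    ),
    cm_per_mb = 3
  )
}

# A single-gene model with a fully specified CDS, for exact codon tests.
# codon_str is placed at codon index `at` (1-based).
one_gene_model <- function(cds_codons, strand = "+", chrom = "cX", start = 101L) {
  cds <- paste(cds_codons, collapse = "")
  gene_models(
    data.frame(
      gene_id = "g1", chrom = chrom, strand = strand,
      start = start, end = start + nchar(cds) - 1L
    ),
    c(g1 = cds)
  )
}
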