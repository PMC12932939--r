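#' Simulate a recombinant inbred line population by single-seed descent
#'
#' Each line descends independently from a fully heterozygous F1 between
#' two inbred parents (A and B).  Every generation one selfed offspring is
#' kept per line: two gametes are drawn from the line's current pair of
#' haplotypes, with crossovers between adjacent markers occurring at the
#' Haldane recombination fraction implied by the map (no interference).
#' Advancing to generation \eqn{n} therefore applies \eqn{n - 1} rounds of
#' meiosis, and the expected per-marker heterozygosity is
#' \eqn{(1/2)^{n-1}}.
#'
#' @param map A [genetic_map()].
#' @param n_lines Number of lines (>= 2).
#' @param generation Filial generation to advance to (>= 2; 8 for an F8 RIL).
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @return A `ril_pop` object: list with `line_ids`, `map`, `generation`,
#'   and `dose` — an `n_lines x n_markers` matrix of B-allele dose per line
#'   in \{0, 0.5, 1\} (fraction of B haplotypes), marker columns named
#'   `chrom:pos` in map order.  Use [tidy()] for a long tibble with
#'   genotype codes AA/AB/BB.
#' @examples
#' gm <- genetic_map(data.frame(chrom = "chr1", length_bp = 1e6, n_markers = 3))
#' pop <- simulate_ril_genotypes(gm, n_lines = 20, generation = 8, seed = 1)
#' tidy(pop)
#' @export
simulate_ril_genotypes <- function(map, n_lines, generation = 8, seed = 1) {
  stopifnot(inherits(map, "genetic_map"))
  if (n_lines < 2) abort("`n_lines` must be >= 2")
  if (generation < 2) abort("`generation` must be >= 2 (F2 or later)")
  set.seed(seed)

  chroms <- split(map$markers$pos, map$markers$chrom)
  chroms <- chroms[unique(map$markers$chrom)] # map order
  dose_blocks <- lapply(names(chroms), function(cn) {
    pos <- chroms[[cn]]
    m <- length(pos)
    r <- haldane_r(pos, map$cm_per_mb)
    # haplotypes as logical matrices, TRUE = B allele
    h1 <- matrix(FALSE, n_lines, m)
    h2 <- matrix(TRUE, n_lines, m)
    for (g in seq_len(generation - 1L)) {
      g1 <- draw_gametes(h1, h2, r)
      g2 <- draw_gametes(h1, h2, r)
      h1 <- g1
      h2 <- g2
    }
    d <- (h1 + h2) / 2
    colnames(d) <- paste0(cn, ":", pos)
    d
  })
  dose <- do.call(cbind, dose_blocks)
  line_ids <- sprintf("L%03d", seq_len(n_lines))
  rownames(dose) <- line_ids
  structure(
    list(line_ids = line_ids, map = map, generation = as.integer(generation), dose = dose),
    class = "ril_pop"
  )
}

# One gamete per line from haplotype pair (h1, h2); r = recombination
# fractions between adjacent markers.  Crossover indicators are cumulated
# as parity so each meiosis is an alternating mosaic of the two inputs.
draw_gametes <- function(h1, h2, r) {
  sel <- parity_chain(nrow(h1), r)
  out <- h1
  out[sel] <- h2[sel]
  out
}

# n independent alternating-state indicator chains over m = length(p) + 1
# positions: start uniform, state flips between positions j and j+1 with
# probability p[j].  Chooses the faster of two equivalent evaluation
# orders (column loop vs per-row cumulative parity) by shape.
parity_chain <- function(n, p) {
  m <- length(p) + 1L
  start <- runif(n) < 0.5
  if (m == 1L) {
    return(matrix(start, n, 1L))
  }
  if (m > n) {
    sw <- matrix(runif(n * (m - 1L)) < rep(p, each = n), n, m - 1L)
    t(apply(cbind(start, sw), 1L, cumsum)) %% 2L == 1L
  } else {
    out <- matrix(FALSE, n, m)
    cur <- start
    out[, 1L] <- cur
    for (j in 2:m) {
      cur <- xor(cur, runif(n) < p[j - 1L])
      out[, j] <- cur
    }
    out
  }
}

#' @export
print.ril_pop <- function(x, ...) {
  cat(
    "<ril_pop> ", length(x$line_ids), " lines, F", x$generation, ", ",
    ncol(x$dose), " markers\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy ril_pop
#' @export
tidy.ril_pop <- function(x, ...) {
  mk <- x$map$markers
  tibble(
    line_id = rep(x$line_ids, times = nrow(mk)),
    chrom = rep(mk$chrom, each = length(x$line_ids)),
    pos = rep(mk$pos, each = length(x$line_ids)),
    b_dose = as.vector(x$dose),
    genotype = c("AA", "AB", "BB")[as.vector(x$dose) * 2 + 1]
  )
}

#' Specify a single additive QTL
#'
#' @param chrom Chromosome name.
#' @param position_bp Physical position (resolved to the nearest simulated
#'   marker when phenotypes are assigned).
#' @param additive_effect Phenotype units per unit of B-haplotype dose
#'   (dose in 0/0.5/1, so a homozygous B line shifts by the full effect).
#' @param residual_sd Standard deviation of Normal residual noise (>= 0).
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(chrom, position_bp, additive_effect, residual_sd) {
  if (residual_sd < 0) abort("`residual_sd` must be >= 0")
  structure(
    list(
      chrom = chrom, position_bp = position_bp,
      additive_effect = additive_effect, residual_sd = residual_sd
    ),
    class = "qtl_spec"
  )
}

#' Assign phenotypes from an additive QTL model
#'
#' Trait value = `baseline` + `additive_effect` x B-dose at the QTL marker
#' + Normal(0, `residual_sd`) noise.
#'
#' @param pop A `ril_pop`.
#' @param qtl A [qtl_spec()]; its position must fall on the population's map
#'   (nearest marker on that chromosome is used, and the position must lie
#'   within the chromosome).
#' @param baseline Trait baseline (phenotype of an AA line, expectation).
#' @param seed Integer seed for the residual draws.
#' @return Tibble `line_id`, `b_dose` (at the QTL marker), `phenotype`.
#' @export
assign_phenotypes <- function(pop, qtl, baseline = 0, seed = 1) {
  stopifnot(inherits(pop, "ril_pop"), inherits(qtl, "qtl_spec"))
  map <- pop$map
  chrom_len <- map$chromosomes$length_bp[match(qtl$chrom, map$chromosomes$chrom)]
  if (is.na(chrom_len) || qtl$position_bp < 1 || qtl$position_bp > chrom_len) {
    abort(paste0("QTL position off-map: ", qtl$chrom, ":", qtl$position_bp))
  }
  on_chrom <- which(map$markers$chrom == qtl$chrom)
  if (!length(on_chrom)) abort(paste0("no markers on QTL chromosome ", qtl$chrom))
  nearest <- on_chrom[which.min(abs(map$markers$pos[on_chrom] - qtl$position_bp))]
  set.seed(seed)
  dose <- pop$dose[, nearest]
  tibble(
    line_id = pop$line_ids,
    b_dose = unname(dose),
    phenotype = baseline + qtl$additive_effect * unname(dose) +
      rnorm(length(dose), 0, qtl$residual_sd)
  )
}

#' Specify the pooled sequencing model
#'
#' @param bulk_size Lines per pool (>= 1).
#' @param mean_depth Mean reads per locus per pool (Poisson mean, > 0).
#' @param error_rate Per-read allele flip probability in \[0, 0.5).
#' @param seed Integer seed.
#' @return A `pool_seq_spec` list.
#' @export
pool_seq_spec <- function(bulk_size = 15, mean_depth = 23, error_rate = 0.001, seed = 1) {
  if (bulk_size < 1) abort("`bulk_size` must be >= 1")
  if (mean_depth <= 0) abort("`mean_depth` must be > 0")
  if (error_rate < 0 || error_rate >= 0.5) abort("`error_rate` must be in [0, 0.5)")
  structure(
    list(
      bulk_size = as.integer(bulk_size), mean_depth = mean_depth,
      error_rate = error_rate, seed = as.integer(seed)
    ),
    class = "pool_seq_spec"
  )
}

#' Sample pooled allele depths for two bulks and the parents
#'
#' At each marker the pool's true B-allele frequency is the mean B dose over
#' its member lines.  Each sample's total depth is Poisson(`mean_depth`);
#' B-supporting reads are Binomial(depth, f') with
#' f' = f(1 - e) + (1 - f)e for sequencing error rate e.  Parents are
#' emitted as pure A (f = 0) and pure B (f = 1) under the same depth model.
#'
#' @param pop A `ril_pop`.
#' @param high_lines,low_lines Disjoint, non-empty character vectors of line
#'   ids drawn from `pop`.
#' @param spec A [pool_seq_spec()].
#' @param alleles Optional tibble `chrom`, `pos`, `ref`, `alt`, `b_allele`
#'   ("ref" or "alt": which VCF allele the B parent carries).  When absent,
#'   bases and orientation are drawn from the spec's seed.
#' @return Tibble of allele-depth records: `chrom`, `pos`, `ref`, `alt`, and
#'   `<sample>_ref` / `<sample>_alt` read counts for samples `parent_a`,
#'   `parent_b`, `bulk_high`, `bulk_low`.
#' @export
sample_pool_depths <- function(pop, high_lines, low_lines, spec, alleles = NULL) {
  stopifnot(inherits(pop, "ril_pop"), inherits(spec, "pool_seq_spec"))
  if (!length(high_lines) || !length(low_lines)) {
    abort("both pools must be non-empty")
  }
  if (length(intersect(high_lines, low_lines))) {
    abort("high and low pools must be disjoint")
  }
  missing_lines <- setdiff(c(high_lines, low_lines), pop$line_ids)
  if (length(missing_lines)) {
    abort(paste0("pool lines not in population: ", paste(missing_lines, collapse = ", ")))
  }
  set.seed(spec$seed)
  mk <- pop$map$markers
  n <- nrow(mk)
  if (is.null(alleles)) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    b_allele <- if_else(runif(n) < 0.5, "alt", "ref")
  } else {
    alleles <- as_tibble(alleles)
    idx <- match(paste(mk$chrom, mk$pos), paste(alleles$chrom, alleles$pos))
    if (anyNA(idx)) abort("`alleles` must cover every map marker")
    ref <- alleles$ref[idx]
    alt <- alleles$alt[idx]
    b_allele <- alleles$b_allele[idx]
  }

  f_high <- colMeans(pop$dose[high_lines, , drop = FALSE])
  f_low <- colMeans(pop$dose[low_lines, , drop = FALSE])
  e <- spec$error_rate
  draw <- function(f) {
    depth <- rpois(n, spec$mean_depth)
    b <- rbinom(n, depth, f * (1 - e) + (1 - f) * e)
    list(depth = depth, b = b)
  }
  samples <- list(
    parent_a = draw(rep(0, n)),
    parent_b = draw(rep(1, n)),
    bulk_high = draw(f_high),
    bulk_low = draw(f_low)
  )
  out <- tibble(chrom = mk$chrom, pos = mk$pos, ref = ref, alt = alt)
  b_is_alt <- b_allele == "alt"
  for (nm in names(samples)) {
    s <- samples[[nm]]
    alt_n <- if_else(b_is_alt, s$b, s$depth - s$b)
    out[[paste0(nm, "_ref")]] <- as.integer(s$depth - alt_n)
    out[[paste0(nm, "_alt")]] <- as.integer(alt_n)
  }
  out$true_b_allele <- b_allele
  out
}

#' Generate a synthetic differential-expression table
#'
#' Emulates the shape of a DESeq2 result table: designated DE genes receive
#' |log2FC| inside `log2fc_range` with random sign and FDR below
#' `fdr_alpha`; all other genes receive |log2FC| < 1 and FDR >= `fdr_alpha`.
#'
#' @param gene_ids Character vector of gene ids (non-empty).
#' @param n_de Number of DE genes (<= length(gene_ids)); the first `n_de`
#'   ids are designated unless `de_genes` is given.
#' @param log2fc_range Length-2 numeric, |log2FC| range for DE genes.
#' @param fdr_alpha FDR significance level separating DE from non-DE.
#' @param seed Integer seed.
#' @param de_genes Optional explicit character vector of DE gene ids.
#' @param planted Optional tibble `gene_id`, `log2fc` of exact values to
#'   plant (these genes get FDR < `fdr_alpha` and the stated log2FC).
#' @param comparison Label for the contrast column.
#' @return Tibble `gene_id`, `log2fc`, `fdr`, `comparison`.
#' @export
generate_deg_table <- function(gene_ids, n_de = 0, log2fc_range = c(1.5, 5),
                               fdr_alpha = 0.05, seed = 1, de_genes = NULL,
                               planted = NULL, comparison = "high_vs_low") {
  if (!length(gene_ids)) abort("`gene_ids` must be non-empty")
  if (is.null(de_genes)) de_genes <- head(gene_ids, n_de)
  if (length(de_genes) > length(gene_ids)) abort("more DE genes than genes")
  if (!all(de_genes %in% gene_ids)) abort("`de_genes` must be a subset of `gene_ids`")
  set.seed(seed)
  n <- length(gene_ids)
  is_de <- gene_ids %in% de_genes
  log2fc <- runif(n, -0.9, 0.9)
  fdr <- runif(n, fdr_alpha, 1)
  mag <- runif(sum(is_de), log2fc_range[1], log2fc_range[2])
  log2fc[is_de] <- mag * sample(c(-1, 1), sum(is_de), replace = TRUE)
  fdr[is_de] <- runif(sum(is_de), 0, fdr_alpha / 5)
  out <- tibble(gene_id = gene_ids, log2fc = log2fc, fdr = fdr, comparison = comparison)
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    idx <- match(planted$gene_id, out$gene_id)
    if (anyNA(idx)) abort("planted gene ids must be in `gene_ids`")
    out$log2fc[idx] <- planted$log2fc
    out$fdr[idx] <- fdr_alpha / 10
  }
  out
}
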