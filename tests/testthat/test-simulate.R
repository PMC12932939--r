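test_that("map validation rejects bad marker tables and names the chromosome", {
  chroms <- data.frame(chrom = c("c1", "c2"), length_bp = c(1e6, 1e6))
  expect_error(
    genetic_map(chroms, markers = data.frame(chrom = "c1", pos = c(10, 10))),
    NA
  ) # duplicates collapse silently via distinct()
  expect_error(
    genetic_map(chroms, markers = data.frame(chrom = "c9", pos = 10)),
    "unknown chromosome"
  )
  expect_error(
    genetic_map(chroms, markers = data.frame(chrom = "c2", pos = c(5, 2e6))),
    "outside chromosome.*c2"
  )
  expect_error(genetic_map(chroms, cm_per_mb = 0), "positive")
})

test_that("F2 selfing reproduces 1:2:1 Mendelian segregation at one marker", {
  gm <- genetic_map(data.frame(chrom = "c1", length_bp = 1e6, n_markers = 1))
  pop <- simulate_ril_genotypes(gm, n_lines = 4000, generation = 2, seed = 11)
  freq <- table(factor(pop$dose, levels = c(0, 0.5, 1))) / 4000
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / 4000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("single-seed descent halves heterozygosity each generation", {
  gm <- genetic_map(data.frame(chrom = "c1", length_bp = 1e6, n_markers = 1))
  for (gen in c(3, 5, 8)) {
    n <- 5000
    pop <- simulate_ril_genotypes(gm, n_lines = n, generation = gen, seed = 20 + gen)
    p <- 0.5^(gen - 1)
    ab <- mean(pop$dose == 0.5)
    expect_lt(abs(ab - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("two-marker recombination matches an explicit per-meiosis SSD oracle", {
  # 1 Mb at 3 cM/Mb
  r <- 0.5 * (1 - exp(-2 * 0.03))
  gm <- genetic_map(
    data.frame(chrom = "c1", length_bp = 2e6),
    cm_per_mb = 3,
    markers = data.frame(chrom = "c1", pos = c(5e5, 15e5))
  )
  set.seed(31)
  n <- 4000
  pop <- simulate_ril_genotypes(gm, n_lines = n, generation = 8, seed = 31)
  # recombinant class: homozygous opposite at the two markers
  rec <- mean((pop$dose[, 1] == 0 & pop$dose[, 2] == 1) |
    (pop$dose[, 1] == 1 & pop$dose[, 2] == 0))
  set.seed(32)
  orc <- oracle_ssd_two_markers(n, r, 8)
  rec_oracle <- mean((orc[, 1] == 0 & orc[, 2] == 1) |
    (orc[, 1] == 1 & orc[, 2] == 0))
  se <- sqrt(rec_oracle * (1 - rec_oracle) / n) * sqrt(2)
  expect_lt(abs(rec - rec_oracle), 3 * se)
  # and close to the Haldane-Waddington RIL expectation 2r/(1+2r)
  expect_lt(abs(rec - 2 * r / (1 + 2 * r)), 0.025)
})

test_that("simulation is deterministic for a fixed seed", {
  gm <- toy_map(10)
  p1 <- simulate_ril_genotypes(gm, 30, 8, seed = 7)
  p2 <- simulate_ril_genotypes(gm, 30, 8, seed = 7)
  p3 <- simulate_ril_genotypes(gm, 30, 8, seed = 8)
  expect_identical(p1$dose, p2$dose)
  expect_false(identical(p1$dose, p3$dose))
})

test_that("phenotypes follow the additive model exactly when noise is zero", {
  gm <- genetic_map(data.frame(chrom = "c1", length_bp = 1e6, n_markers = 3))
  pop <- simulate_ril_genotypes(gm, 200, 8, seed = 5)
  ph <- assign_phenotypes(pop, qtl_spec("c1", 5e5, 10, 0), baseline = 50, seed = 1)
  expect_equal(ph$phenotype, 50 + 10 * ph$b_dose)
  expect_setequal(unique(ph$phenotype[ph$b_dose == 0]), 50)
  expect_setequal(unique(ph$phenotype[ph$b_dose == 1]), 60)
  expect_error(
    assign_phenotypes(pop, qtl_spec("c1", 5e6, 10, 0), seed = 1),
    "off-map"
  )
  expect_error(
    assign_phenotypes(pop, qtl_spec("c9", 5e5, 10, 0), seed = 1),
    "off-map"
  )
})

test_that("null-effect phenotypes are symmetric and QTL variance fraction is honoured", {
  gm <- genetic_map(data.frame(chrom = "c1", length_bp = 1e6, n_markers = 1))
  pop <- simulate_ril_genotypes(gm, 1000, 8, seed = 41)
  ph0 <- assign_phenotypes(pop, qtl_spec("c1", 5e5, 0, 3), baseline = 50, seed = 42)
  expect_lt(abs(distribution_moments(ph0$phenotype)$skewness), 3 * sqrt(6 / 1000))
  expect_lt(abs(cor(ph0$phenotype, ph0$b_dose)), 0.1)
  # variance decomposition: effect a, residual sd chosen for ~50% PVE
  a <- 10
  ph <- assign_phenotypes(pop, qtl_spec("c1", 5e5, a, a / 2), baseline = 0, seed = 43)
  pve <- var(a * ph$b_dose) / var(ph$phenotype)
  expect_lt(abs(pve - 0.5), 0.1)
})

test_that("pooled depths reflect pool composition, depth model and error rate", {
  gm <- genetic_map(data.frame(chrom = "c1", length_bp = 2e7, n_markers = 1500))
  pop <- simulate_ril_genotypes(gm, 40, 8, seed = 51)
  spec <- pool_seq_spec(bulk_size = 10, mean_depth = 30, error_rate = 0, seed = 52)
  high <- pop$line_ids[1:10]
  low <- pop$line_ids[11:20]
  ad <- sample_pool_depths(pop, high, low, spec)
  # pool frequency unbiasedness over many loci, 3 SE
  b_high <- ifelse(ad$true_b_allele == "alt", ad$bulk_high_alt, ad$bulk_high_ref)
  f_true <- colMeans(pop$dose[high, ])
  f_hat <- b_high / (ad$bulk_high_ref + ad$bulk_high_alt)
  resid <- f_hat - f_true
  expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(length(resid)))
  # parents are pure
  expect_true(all(ifelse(ad$true_b_allele == "alt", ad$parent_a_alt, ad$parent_a_ref) == 0))
  expect_true(all(ifelse(ad$true_b_allele == "alt", ad$parent_b_ref, ad$parent_b_alt) == 0))
  # depth is Poisson(mean_depth)
  dp <- ad$bulk_low_ref + ad$bulk_low_alt
  expect_lt(abs(mean(dp) - 30), 3 * sqrt(30 / length(dp)))
  expect_error(sample_pool_depths(pop, high, high, spec), "disjoint")
  expect_error(sample_pool_depths(pop, character(0), low, spec), "non-empty")
  expect_error(sample_pool_depths(pop, c(high, "nope"), low, spec), "nope")
})

test_that("pure-parent pools drive the SNP index to its extremes", {
  gm <- genetic_map(data.frame(chrom = "c1", length_bp = 1e6, n_markers = 50))
  pop <- simulate_ril_genotypes(gm, 30, 8, seed = 61)
  # force all pooled lines to pure A or pure B
  pop$dose[1:10, ] <- 0
  pop$dose[11:20, ] <- 1
  spec <- pool_seq_spec(10, 40, error_rate = 0, seed = 62)
  ad <- sample_pool_depths(pop, pop$line_ids[11:20], pop$line_ids[1:10], spec)
  ad$b_allele <- ad$true_b_allele
  si <- compute_snp_index(ad)
  expect_true(all(si$index_high == 1))
  expect_true(all(si$index_low == 0))
  expect_true(all(compute_delta(si)$delta == 1))
})

test_that("synthetic DEG tables separate DE and non-DE genes by construction", {
  ids <- sprintf("g%02d", 1:20)
  expect_error(generate_deg_table(character(0)), "non-empty")
  d0 <- generate_deg_table(ids, n_de = 0, seed = 1)
  expect_true(all(abs(d0$log2fc) < 1) && all(d0$fdr >= 0.05))
  d6 <- generate_deg_table(ids, n_de = 6, log2fc_range = c(2, log2(31)), seed = 2)
  de <- d6[d6$gene_id %in% ids[1:6], ]
  expect_true(all(abs(de$log2fc) > 1) && all(de$fdr < 0.05))
  expect_true(all(2^abs(de$log2fc) > 4)) # survives the fold-change>4 filter
  dp <- generate_deg_table(ids,
    n_de = 1, seed = 3,
    planted = data.frame(gene_id = "g07", log2fc = log2(30.36))
  )
  expect_equal(2^dp$log2fc[dp$gene_id == "g07"], 30.36, tolerance = 1e-12)
})
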