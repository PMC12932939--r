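make_vcf <- function(lines,
                     path = withr::local_tempfile(
                       fileext = ".vcf", .local_envir = parent.frame()
                     )) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=1000000>",
    "##contig=<ID=c2,length=1000000>",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "ParentA", "ParentB", "BulkH", "BulkL"
    ), collapse = "\t")
  )
  writeLines(c(header, lines), path)
  path
}

row_tsv <- function(...) paste(..., sep = "\t")

test_that("allele-depth parsing is an identity on clean biallelic SNP rows", {
  p <- make_vcf(c(
    row_tsv("c1", 100, ".", "A", "G", ".", "PASS", ".", "AD", "10,0", "0,12", "5,6", "8,3"),
    row_tsv("c1", 200, ".", "C", "T", ".", "PASS", ".", "AD", "7,1", "1,9", "3,3", "2,10")
  ))
  rec <- read_allele_depths(p)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$pos, c(100L, 200L))
  expect_equal(rec$parent_a_ref[1], 10L)
  expect_equal(rec$parent_a_alt[1], 0L)
  expect_equal(rec$parent_b_alt[1], 12L)
  expect_equal(rec$bulk_high_ref[1], 5L)
  expect_equal(rec$bulk_high_alt[1], 6L)
  expect_equal(rec$bulk_low_ref[1], 8L)
  expect_equal(rec$bulk_low_alt[1], 3L)
  expect_equal(read_skip_report(rec)$indel_or_other, 0)
})

test_that("indel and multiallelic rows are skipped and counted", {
  p <- make_vcf(c(
    row_tsv("c1", 100, ".", "A", "G", ".", "PASS", ".", "AD", "10,0", "0,12", "5,6", "8,3"),
    row_tsv("c1", 150, ".", "AT", "A", ".", "PASS", ".", "AD", "10,0", "0,12", "5,6", "8,3"),
    row_tsv("c1", 180, ".", "A", "G,T", ".", "PASS", ".", "AD", "9,1,0", "0,8,1", "4,4,0", "5,3,1"),
    row_tsv("c2", 90, ".", "G", "GAA", ".", "PASS", ".", "AD", "10,0", "0,12", "5,6", "8,3")
  ))
  rec <- read_allele_depths(p)
  expect_equal(nrow(rec), 1)
  rep <- read_skip_report(rec)
  expect_equal(rep$multiallelic, 1)
  expect_equal(rep$indel_or_other, 2)
})

test_that("unsorted VCFs are rejected by default and re-sorted on request", {
  p <- make_vcf(c(
    row_tsv("c1", 300, ".", "A", "G", ".", "PASS", ".", "AD", "10,0", "0,12", "5,6", "8,3"),
    row_tsv("c1", 100, ".", "C", "T", ".", "PASS", ".", "AD", "9,0", "0,9", "4,4", "6,2")
  ))
  expect_error(read_allele_depths(p), "not coordinate-sorted")
  rec <- read_allele_depths(p, on_unsorted = "sort")
  expect_equal(rec$pos, c(100L, 300L))
})

test_that("a missing sample is a hard error naming the sample", {
  p <- make_vcf(row_tsv(
    "c1", 100, ".", "A", "G", ".", "PASS", ".", "AD", "10,0", "0,12", "5,6", "8,3"
  ))
  expect_error(
    read_allele_depths(p, sample_map = c(
      parent_a = "ParentA", parent_b = "ParentX",
      bulk_high = "BulkH", bulk_low = "BulkL"
    )),
    "ParentX"
  )
})

test_that("homozygous-polymorphic selection follows its truth table and is idempotent", {
  rec <- tibble::tribble(
    ~chrom, ~pos, ~parent_a_ref, ~parent_a_alt, ~parent_b_ref, ~parent_b_alt,
    "c1", 1, 12L, 0L, 0L, 15L, # kept, B allele = alt
    "c1", 2, 0L, 11L, 14L, 0L, # kept, B allele = ref
    "c1", 3, 6L, 6L, 0L, 15L, # dropped: parent A heterozygous
    "c1", 4, 12L, 0L, 14L, 0L, # dropped: monomorphic
    "c1", 5, 3L, 0L, 0L, 15L, # dropped: parent A depth < 7
    "c1", 6, 18L, 2L, 0L, 15L, # kept: minor fraction 0.1 allowed
    "c1", 7, 17L, 3L, 0L, 15L # dropped: minor fraction 0.15 > 0.1
  )
  rec$bulk_high_ref <- 5L
  rec$bulk_high_alt <- 5L
  rec$bulk_low_ref <- 5L
  rec$bulk_low_alt <- 5L
  out <- select_homozygous_polymorphic(rec)
  expect_equal(out$pos, c(1, 2, 6))
  expect_equal(out$b_allele, c("alt", "ref", "alt"))
  # subset of input, idempotent
  expect_true(all(out$pos %in% rec$pos))
  again <- select_homozygous_polymorphic(out)
  expect_equal(again$pos, out$pos)
  expect_equal(again$b_allele, out$b_allele)
})

test_that("fixture VCFs round-trip through the reader", {
  dir <- withr::local_tempdir()
  gm <- genetic_map(
    data.frame(chrom = c("c1", "c2"), length_bp = c(2e6, 1e6), n_markers = c(25, 10))
  )
  pop <- simulate_ril_genotypes(gm, 20, 8, seed = 71)
  ad <- sample_pool_depths(
    pop, pop$line_ids[1:5], pop$line_ids[6:10],
    pool_seq_spec(5, 25, 0.001, seed = 72)
  )
  vcf <- file.path(dir, "x.vcf")
  write_pool_vcf(ad, vcf, gm$chromosomes)
  back <- read_allele_depths(vcf)
  cols <- c(
    "chrom", "pos", "ref", "alt",
    "parent_a_ref", "parent_a_alt", "parent_b_ref", "parent_b_alt",
    "bulk_high_ref", "bulk_high_alt", "bulk_low_ref", "bulk_low_alt"
  )
  expect_equal(
    as.data.frame(back[, cols]),
    as.data.frame(ad[order(ad$chrom, ad$pos), cols]),
    ignore_attr = TRUE
  )
})
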