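# Variant filtering, monomorphic exclusion, pi, normalisation, K-S check.

toy_records <- function() {
  tibble::tibble(
    chrom = c("2", "2", "2", "3", "X", "4"),
    pos = c(10, 20, 30, 40, 50, 60),
    coverage = c(50L, 9L, 700L, 50L, 50L, 50L),
    variant_count = c(25L, 4L, 350L, 2L, 25L, 6L)
  ) # frequencies .5, .44, .5, .04, .5, .12
}

test_that("filters apply all five retention rules", {
  kept <- filter_variants(toy_records())
  expect_equal(nrow(kept), 2)
  expect_equal(kept$pos, c(10, 60))
  # each rule in isolation
  expect_equal(nrow(filter_variants(toy_records(), min_cov = 0,
                                    max_cov = Inf, min_count = 0,
                                    min_freq = 0)), 5) # autosomes only
  one <- function(...) nrow(filter_variants(toy_records(), ...))
  expect_equal(one(min_freq = 0), 3)     # frequency rule dropped
  expect_equal(one(max_cov = Inf), 3)    # coverage ceiling dropped
  expect_error(filter_variants(toy_records(), min_cov = 20, max_cov = 10),
               "min_cov")
})

test_that("filtering preserves order, is idempotent, validates counts", {
  set.seed(2)
  recs <- tibble::tibble(
    chrom = sample(c("2", "3", "4", "X"), 500, TRUE),
    pos = 1:500,
    coverage = sample(0:700, 500, TRUE)
  )
  recs$variant_count <- as.integer(floor(recs$coverage * runif(500)))
  once <- filter_variants(recs)
  expect_identical(filter_variants(once), once)
  expect_true(all(diff(once$pos) > 0)) # input order preserved
  bad <- tibble::tibble(chrom = "2", pos = 1, coverage = 10L,
                        variant_count = 11L)
  expect_error(filter_variants(bad), "row")
})

test_that("cross-sample monomorphic exclusion follows the fixed-everywhere rule", {
  recs <- tibble::tibble(
    line_id = rep(c("A", "B", "C"), each = 3),
    chrom = "2",
    pos = rep(c(1, 2, 3), 3),
    coverage = 50L,
    variant_count = 25L,
    frequency = c(1, 1, 0.5,   1, 1, 0.5,   1, 0.5, 0.5)
  )
  out <- remove_cross_sample_monomorphic(recs)
  # locus 1 fixed in all three lines -> dropped everywhere;
  # locus 2 fixed in A and B but polymorphic in C -> kept everywhere
  expect_false(any(out$pos == 1))
  expect_equal(sum(out$pos == 2), 3)
  expect_equal(sum(out$pos == 3), 3)
  # single line, no fixed loci: unchanged
  single <- dplyr::filter(recs, line_id == "C", pos != 1)
  expect_equal(nrow(remove_cross_sample_monomorphic(single)), nrow(single))
})

test_that("pi sums p(1-p) over variant loci", {
  recs <- tibble::tibble(chrom = "2", pos = 1:3, coverage = 10L,
                         variant_count = c(1L, 2L, 5L),
                         frequency = c(0.1, 0.2, 0.5))
  est <- nucleotide_diversity(recs)
  expect_equal(est$pi_sum, 0.09 + 0.16 + 0.25)
  expect_equal(est$n_snps, 3L)
  # boundary values
  expect_equal(nucleotide_diversity(
    dplyr::mutate(recs[1, ], frequency = 0.5))$pi_sum, 0.25)
  expect_equal(nucleotide_diversity(
    dplyr::mutate(recs[1, ], frequency = 1))$pi_sum, 0)
  empty <- nucleotide_diversity(recs[0, ])
  expect_equal(empty$pi_sum, 0)
  expect_equal(empty$n_snps, 0L)
  # invariant: 0 <= pi_sum <= 0.25 * n_snps, and adding a record never
  # decreases the sum
  set.seed(5)
  r <- tibble::tibble(chrom = "2", pos = 1:50, coverage = 100L,
                      variant_count = sample(10:100, 50, TRUE))
  r$frequency <- r$variant_count / r$coverage
  s <- nucleotide_diversity(r)
  expect_lte(s$pi_sum, 0.25 * s$n_snps)
  expect_gte(nucleotide_diversity(dplyr::bind_rows(r, r[1, ]))$pi_sum,
             s$pi_sum)
})

test_that("relative pi normalises to the outbred mean", {
  est <- tibble::tibble(line_id = c("OB1", "OB2", "I1"),
                        pi_sum = c(100, 140, 60))
  out <- relative_pi(est, c("OB1", "OB2"))
  expect_equal(out$pi_relative, c(100 / 120, 140 / 120, 0.5))
  expect_equal(mean(out$pi_relative[1:2]), 1)
  single <- relative_pi(est[c(1, 3), ], "OB1")
  expect_equal(single$pi_relative[1], 1)
  expect_error(relative_pi(est, "nope"), "outbred")
  expect_error(relative_pi(tibble::tibble(line_id = "OB1", pi_sum = 0),
                           "OB1"), "zero")
})

test_that("K-S diagnostic: identical, disjoint and hand-counted cases", {
  same <- coverage_ks_diagnostic(list(a = 1:20, b = 1:20))
  expect_equal(same$d, 0)
  apart <- coverage_ks_diagnostic(list(a = 1:10, b = 101:110))
  expect_equal(apart$d, 1)
  expect_true(apart$flagged)
  hand <- coverage_ks_diagnostic(list(a = c(1, 2, 3), b = c(1, 2, 4)))
  expect_equal(hand$d, 1 / 3, tolerance = 1e-12)
  three <- coverage_ks_diagnostic(list(a = 1:9, b = 2:10, c = 3:11))
  expect_equal(nrow(three), 3)
  expect_error(coverage_ks_diagnostic(list(a = 1:5, b = 3)), ">= 2")
})

test_that("estimate_diversity integrates the pipeline on a small cohort", {
  coh <- generate_cohort(
    cohort_config(n_loci = 400,
                  group_sizes = c(Low = 3, Medium = 0, High = 3, OB = 3)),
    seed = 99)
  div <- estimate_diversity(coh$reads, coh$lines)
  expect_setequal(div$line_id, coh$lines$line_id)
  ob <- div$pi_relative[div$line_id %in%
                          coh$lines$line_id[coh$lines$group == "OB"]]
  expect_equal(mean(ob), 1, tolerance = 1e-12)
  # X-linked loci never contribute
  filtered <- filter_variants(coh$reads)
  expect_false(any(filtered$chrom == "X"))
})

test_that("variant tables round-trip as TSV and minimal VCF", {
  coh <- generate_cohort(
    cohort_config(n_loci = 50,
                  group_sizes = c(Low = 1, Medium = 0, High = 0, OB = 1)),
    seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(coh$reads, path)
  back <- read_variant_table(path)
  expect_equal(back$variant_count, coh$reads$variant_count)

  skip_if_not_installed("vcfR")
  # minimal two-sample VCF with DP/AD genotype fields
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "2\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP:AD\t0/1:50:25,25\t0/1:40:36,4",
    "3\t200\t.\tC\tG\t.\tPASS\t.\tGT:DP:AD\t1/1:30:0,30\t0/1:20:10,10"
  ), vcf)
  tbl <- read_variant_vcf(vcf)
  expect_equal(nrow(tbl), 4)
  s1 <- dplyr::filter(tbl, line_id == "S1")
  expect_equal(s1$coverage, c(50L, 30L))
  expect_equal(s1$variant_count, c(25L, 30L))
  expect_equal(s1$frequency, c(0.5, 1))
})
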