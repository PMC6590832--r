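# Founder pool, Wright-Fisher drift, pooled reads, phenotypes, cohort.

small_config <- function(...) {
  cohort_config(n_loci = 300,
                group_sizes = c(Low = 3, Medium = 3, High = 3, OB = 2), ...)
}

test_that("founder pool: determinism, constraints, point-mass law", {
  p1 <- founder_pool(500, seed = 9)
  p2 <- founder_pool(500, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$p0 > 0 & p1$p0 < 1))
  expect_true(all(p1$p0 >= 0.05 & p1$p0 <= 0.95))
  for (ch in unique(p1$chrom)) {
    expect_true(all(diff(p1$pos[p1$chrom == ch]) > 0))
  }
  expect_setequal(unique(p1$chrom), c("2", "3", "4", "X"))
  expect_error(founder_pool(0), ">= 1")
  expect_error(founder_pool(10, shape1 = -1), "frequency law")
  # frequency law collapsed to a point mass at 0.5
  p <- founder_pool(200, shape1 = 1, shape2 = 1,
                    freq_range = c(0.4999999, 0.5000001), seed = 1)
  expect_equal(sum(p$p0 * (1 - p$p0)), 200 * 0.25, tolerance = 1e-6)
})

test_that("drift: determinism, absorbing states, no-drift limit", {
  pool <- founder_pool(200, seed = 3)
  d1 <- simulate_drift(pool, bottleneck_design(3), seed = 5)
  d2 <- simulate_drift(pool, bottleneck_design(3), seed = 5)
  expect_identical(d1, d2)
  expect_true(all(d1$freq >= 0 & d1$freq <= 1))
  # fixed loci stay fixed through further drift
  fixed <- dplyr::mutate(pool, p0 = rep(c(0, 1), length.out = 200))
  dd <- simulate_drift(fixed, bottleneck_design(5), seed = 1)
  expect_equal(dd$freq, fixed$p0)
  # an enormous census leaves frequencies essentially unchanged
  big <- bottleneck_design(2, bottleneck_size = 5e5, flush_size = 5e5)
  db <- simulate_drift(pool, big, seed = 2)
  expect_equal(db$freq, pool$p0, tolerance = 0.02)
})

test_that("mean retained heterozygosity matches the drift expectation", {
  pool <- founder_pool(400, seed = 21)
  founder_het <- sum(pool$p0 * (1 - pool$p0))
  design <- bottleneck_design(1) # a single bottleneck generation
  withr::with_seed(77, {
    ret <- vapply(1:300, function(i) {
      d <- simulate_drift(pool, design, n_flush_gens = 0)
      sum(d$freq * (1 - d$freq)) / founder_het
    }, numeric(1))
  })
  se <- sd(ret) / sqrt(length(ret))
  expect_lt(abs(mean(ret) - 0.875), 3 * se + 1e-12)
})

test_that("pooled reads: counts bounded by coverage, fixed-zero lines", {
  pool <- founder_pool(300, seed = 4)
  drifted <- dplyr::mutate(pool, freq = p0)
  reads <- simulate_pool_reads(drifted, seed = 8)
  expect_true(all(reads$variant_count <= reads$coverage))
  expect_true(all(reads$coverage >= 0 & reads$coverage <= 600))
  # all-reference line: variant counts are all zero but rows remain
  zero <- simulate_pool_reads(dplyr::mutate(pool, freq = 0), seed = 8)
  expect_true(all(zero$variant_count == 0))
  expect_equal(nrow(zero), nrow(pool))
  # zero coverage yields an empty effective table
  nocov <- simulate_pool_reads(drifted, coverage = 0, seed = 8)
  expect_true(all(nocov$variant_count == 0))
  expect_true(all(is.na(nocov$frequency)))
})

test_that("read-sampled heterozygosity has the binomial finite-depth bias", {
  # at known pool frequency q and fixed coverage c,
  # E[p(1-p)] = q(1-q)(1-1/c)
  q <- 0.3
  c <- 20
  drifted <- tibble::tibble(chrom = "2", pos = 1:20000, freq = q)
  reads <- simulate_pool_reads(drifted, coverage = c, pool_sampling = FALSE,
                               seed = 12)
  ph <- reads$frequency * (1 - reads$frequency)
  se <- sd(ph) / sqrt(length(ph))
  expect_lt(abs(mean(ph) - q * (1 - q) * (1 - 1 / c)), 3 * se)
})

test_that("phenotypes: exact response without noise, trade-off wiring", {
  quiet <- cohort_config(
    productivity = list(baseline = 2, beta = 0.3, sd = 0),
    body_mass = list(sd = 0))
  ph <- simulate_phenotypes("Low", retention = 1, config = quiet, seed = 2)
  prod <- dplyr::filter(ph$traits, trait == "productivity")
  if (is.na(ph$extinction_gen)) {
    fit <- response_slopes(dplyr::mutate(prod, line_id = "x"))
    expect_equal(fit$slope, 0.3, tolerance = 1e-12)
  }
  # zero response coefficient: slope exactly zero
  flat <- cohort_config(productivity = list(beta = 0, sd = 0))
  ph0 <- simulate_phenotypes("Low", retention = 0.6, config = flat, seed = 2)
  prod0 <- dplyr::filter(ph0$traits, trait == "productivity")
  if (nrow(prod0) >= 3) {
    fit0 <- response_slopes(dplyr::mutate(prod0, line_id = "x"))
    expect_equal(fit0$slope, 0, tolerance = 1e-12)
  }
  expect_error(cohort_config(productivity = list(sd = -1)), ">= 0")
})

test_that("lines with low diversity go extinct more often", {
  cfg <- cohort_config()
  withr::with_seed(31, {
    retention <- runif(600, 0.4, 1)
    ext <- vapply(retention, function(r) {
      !is.na(simulate_phenotypes("Low", r, cfg)$extinction_gen)
    }, logical(1))
  })
  expect_gt(mean(ext), 0.02)
  expect_lt(mean(retention[ext]), mean(retention[!ext]))
})

test_that("cohort generation: sizes, determinism, minimal cohort", {
  cfg <- small_config()
  c1 <- generate_cohort(cfg, seed = 6)
  c2 <- generate_cohort(cfg, seed = 6)
  expect_identical(c1$lines, c2$lines)
  expect_identical(c1$reads, c2$reads)
  expect_identical(c1$traits, c2$traits)
  expect_equal(nrow(c1$lines), 11)
  expect_equal(as.vector(table(c1$lines$group)[c("Low", "Medium", "High", "OB")]),
               c(3L, 3L, 3L, 2L))
  expect_true(all(c1$lines$realized_het <= c1$lines$founder_het))
  expect_true(all(c1$lines$acid_level %in% c(1.0, 2.5)))
  expect_true(all(c1$lines$acid_level[c1$lines$group == "OB"] == 2.5))
  expect_true(all(is.na(c1$lines$extinction_gen) |
                    c1$lines$extinction_gen %in% 1:9))
  # expected F keyed to group designs
  ef <- unique(c1$lines[, c("group", "expected_f")])
  expect_equal(ef$expected_f[match(c("OB", "Low", "Medium", "High"),
                                   ef$group)],
               c(0, 0.125, 0.21875, 0.380859375))
  # smoke: one line per group still runs end to end
  mini <- generate_cohort(
    cohort_config(n_loci = 100,
                  group_sizes = c(Low = 1, Medium = 1, High = 1, OB = 1)),
    seed = 1)
  expect_equal(nrow(mini$lines), 4)
})

test_that("the default cohort has 132 lines in the study proportions", {
  gs <- cohort_config()$group_sizes
  expect_equal(sum(gs), 132)
  expect_equal(unname(gs[c("Low", "Medium", "High", "OB")]),
               c(42, 40, 40, 10))
})

test_that("group ordering of retained diversity: OB > Low > Medium > High", {
  cfg <- cohort_config(n_loci = 300,
                       group_sizes = c(Low = 8, Medium = 8, High = 8,
                                       OB = 4))
  means <- sapply(1:5, function(i) {
    coh <- generate_cohort(cfg, seed = 400 + i)
    tapply(coh$lines$het_retention, coh$lines$group, mean)
  })
  m <- rowMeans(means)
  expect_true(m["OB"] > m["Low"])
  expect_true(m["Low"] > m["Medium"])
  expect_true(m["Medium"] > m["High"])
})

test_that("cohort round-trips through plain-text files", {
  coh <- generate_cohort(small_config(), seed = 13)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$lines), as.data.frame(coh$lines))
  expect_equal(as.data.frame(back$reads), as.data.frame(coh$reads))
  expect_equal(as.data.frame(back$traits), as.data.frame(coh$traits),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$viability),
               as.data.frame(coh$viability))
})
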