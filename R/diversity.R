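# Per-line nucleotide diversity from pooled variant tables: filters,
# autosome restriction, cross-sample monomorphic exclusion, pi = sum p(1-p),
# normalisation to the outbred mean, and the coverage K-S diagnostic.

#' Filter pooled variant records
#'
#' Applies the variant-call retention rules for pooled sequencing data:
#' autosomal chromosome, coverage within `[min_cov, max_cov]`, variant read
#' count at least `min_count`, and variant-allele frequency at least
#' `min_freq`. The frequency threshold applies to the called variant-allele
#' frequency (the caller's convention), not the folded minor-allele
#' frequency. Input row order is preserved and the operation is idempotent.
#'
#' @param records A data frame with columns `chrom`, `pos`, `coverage`,
#'   `variant_count` and optionally `frequency` (recomputed from counts when
#'   absent); extra columns (e.g. `line_id`) pass through.
#' @param min_cov,max_cov Coverage bounds (defaults 10 and 600).
#' @param min_count Minimum variant read count (default 1).
#' @param min_freq Minimum variant-allele frequency (default 0.10).
#' @param autosomes Chromosome labels retained (default `c("2", "3", "4")`).
#' @return The retained records as a tibble.
#' @examples
#' recs <- tibble::tibble(chrom = c("2", "X"), pos = c(100, 200),
#'                        coverage = c(50L, 50L), variant_count = c(25L, 25L))
#' filter_variants(recs)
#' @export
filter_variants <- function(records, min_cov = 10, max_cov = 600,
                            min_count = 1, min_freq = 0.10,
                            autosomes = c("2", "3", "4")) {
  stopifnot(is.data.frame(records),
            all(c("chrom", "pos", "coverage", "variant_count") %in%
                  names(records)))
  if (min_cov < 0 || max_cov < min_cov || min_count < 0 || min_freq < 0) {
    stop("Filter thresholds must be non-negative with min_cov <= max_cov.",
         call. = FALSE)
  }
  bad <- which(records$variant_count > records$coverage |
                 records$variant_count < 0 | records$coverage < 0)
  if (length(bad) > 0) {
    stop("Malformed variant record(s): variant_count outside [0, coverage] ",
         "at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  if (!"frequency" %in% names(records)) {
    records$frequency <- ifelse(records$coverage > 0,
                                records$variant_count / records$coverage,
                                NA_real_)
  }
  dplyr::filter(
    records,
    as.character(.data$chrom) %in% as.character(autosomes),
    .data$coverage >= min_cov, .data$coverage <= max_cov,
    .data$variant_count >= min_count,
    !is.na(.data$frequency), .data$frequency >= min_freq
  )
}

#' Drop loci monomorphic for the non-reference allele across all lines
#'
#' A site that differs from the reference but is fixed (frequency exactly 1)
#' in every line where it passes the filters carries no diversity signal in
#' any line and is removed everywhere. Loci polymorphic in at least one line
#' are kept in every line where they appear; loci absent from some lines are
#' judged on the lines where they are present.
#'
#' @param records Filtered variant records for one or more lines, with a
#'   `line_id` column (a single line without `line_id` is also accepted).
#' @return The records minus cross-sample monomorphic loci.
#' @export
remove_cross_sample_monomorphic <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 0)
  if (!"frequency" %in% names(records)) {
    stop("`records` must carry a `frequency` column.", call. = FALSE)
  }
  if (nrow(records) == 0) return(tibble::as_tibble(records))
  mono <- tibble::as_tibble(records) |>
    dplyr::summarise(all_fixed = all(.data$frequency == 1),
                     .by = c("chrom", "pos"))
  dplyr::anti_join(tibble::as_tibble(records),
                   dplyr::filter(mono, .data$all_fixed),
                   by = c("chrom", "pos"))
}

#' Nucleotide diversity of filtered variant records
#'
#' Per line, sums per-locus expected heterozygosity `p (1 - p)` over all
#' variant loci, where `p` is the variant-allele frequency. Also reports the
#' locus count and the per-SNP mean (a diagnostic; downstream analyses use
#' the sum).
#'
#' @param records Filtered variant records; if a `line_id` column is present
#'   one row per line is returned, otherwise a single row with
#'   `line_id = NA`.
#' @return A tibble with `line_id`, `n_snps`, `pi_sum`, `pi_mean`.
#' @examples
#' nucleotide_diversity(tibble::tibble(
#'   chrom = "2", pos = 1:3, coverage = 10L,
#'   variant_count = c(1L, 2L, 5L), frequency = c(0.1, 0.2, 0.5)))
#' @export
nucleotide_diversity <- function(records) {
  stopifnot(is.data.frame(records))
  records <- tibble::as_tibble(records)
  if (!"line_id" %in% names(records)) records$line_id <- NA_character_
  out <- records |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      pi_sum = sum(.data$frequency * (1 - .data$frequency)),
      .by = "line_id"
    ) |>
    dplyr::mutate(pi_mean = ifelse(.data$n_snps > 0,
                                   .data$pi_sum / .data$n_snps, NA_real_))
  if (nrow(out) == 0) {
    out <- tibble::tibble(line_id = NA_character_, n_snps = 0L,
                          pi_sum = 0, pi_mean = NA_real_)
  }
  out
}

#' Express diversity relative to the outbred mean
#'
#' Adds `pi_relative = pi_sum / mean(pi_sum of outbred lines)`, so the
#' outbred group has mean 1 by construction.
#'
#' @param estimates A tibble from [nucleotide_diversity()] (needs `line_id`
#'   and `pi_sum`).
#' @param outbred_ids Character vector of outbred line ids present in
#'   `estimates`.
#' @return `estimates` with a `pi_relative` column.
#' @export
relative_pi <- function(estimates, outbred_ids) {
  stopifnot(is.data.frame(estimates),
            all(c("line_id", "pi_sum") %in% names(estimates)))
  ob <- estimates$pi_sum[estimates$line_id %in% outbred_ids]
  if (length(ob) == 0) {
    stop("No outbred lines found among `estimates`.", call. = FALSE)
  }
  m <- mean(ob)
  if (!is.finite(m) || m <= 0) {
    stop("Outbred mean diversity is zero or undefined; cannot normalise.",
         call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(estimates),
                pi_relative = .data$pi_sum / m)
}

#' Pairwise Kolmogorov-Smirnov diagnostic of coverage distributions
#'
#' Sampling bias of pooled frequency estimates at low coverage cancels in
#' between-group comparisons only when the read-coverage distributions are
#' alike; this diagnostic runs a two-sample K-S test (asymptotic two-sided
#' p-value) for every pair of groups and flags pairs differing at `alpha`.
#'
#' @param coverages Named list of numeric coverage vectors, one per group
#'   (each of length >= 2).
#' @param alpha Flagging level (default 0.05).
#' @return A tibble with `group_a`, `group_b`, `d` (sup-distance of the
#'   ECDFs), `p_value`, `flagged`.
#' @export
coverage_ks_diagnostic <- function(coverages, alpha = 0.05) {
  stopifnot(is.list(coverages), length(coverages) >= 2)
  if (is.null(names(coverages)) ||
      any(lengths(coverages) < 2)) {
    stop("`coverages` must be a named list with >= 2 values per group.",
         call. = FALSE)
  }
  pairs <- utils::combn(names(coverages), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ks <- suppressWarnings(
      stats::ks.test(coverages[[a]], coverages[[b]], exact = FALSE)
    )
    tibble::tibble(group_a = a, group_b = b,
                   d = unname(ks$statistic), p_value = ks$p.value,
                   flagged = ks$p.value < alpha)
  })
}

#' Estimate per-line diversity from a cohort's read tables
#'
#' Convenience pipeline: [filter_variants()], then (optionally)
#' [remove_cross_sample_monomorphic()], then [nucleotide_diversity()] and
#' [relative_pi()] against the outbred lines of the manifest.
#'
#' @param reads Long variant table with `line_id` (e.g. `cohort$reads`).
#' @param lines Manifest with `line_id` and `group` (`"OB"` marks outbred).
#' @param drop_monomorphic Apply the cross-sample monomorphic exclusion
#'   after the per-line filters (default `TRUE`).
#' @param ... Passed to [filter_variants()].
#' @return A tibble `line_id`, `n_snps`, `pi_sum`, `pi_mean`, `pi_relative`.
#' @examples
#' coh <- generate_cohort(cohort_config(
#'   n_loci = 300, group_sizes = c(Low = 2, Medium = 0, High = 0, OB = 2)),
#'   seed = 1)
#' estimate_diversity(coh$reads, coh$lines)
#' @export
estimate_diversity <- function(reads, lines, drop_monomorphic = TRUE, ...) {
  stopifnot(all(c("line_id", "group") %in% names(lines)))
  filtered <- filter_variants(reads, ...)
  if (isTRUE(drop_monomorphic)) {
    filtered <- remove_cross_sample_monomorphic(filtered)
  }
  est <- nucleotide_diversity(filtered)
  # lines whose table is empty after filtering get an explicit zero row
  missing <- setdiff(unique(reads$line_id), est$line_id)
  if (length(missing) > 0) {
    est <- dplyr::bind_rows(
      est, tibble::tibble(line_id = missing, n_snps = 0L, pi_sum = 0,
                          pi_mean = NA_real_))
  }
  relative_pi(est, lines$line_id[lines$group == "OB"])
}

#' Read a per-line variant table
#'
#' `read_variant_table()` reads the TSV schema written by [write_cohort()]
#' (columns `chrom`, `pos`, `coverage`, `variant_count`, optionally
#' `frequency` and `line_id`). `read_variant_vcf()` ingests a minimal VCF,
#' taking per-sample `DP` as coverage and the first alternate allele's `AD`
#' entry as the variant count (requires the vcfR package).
#'
#' @param path File path.
#' @return A tibble of variant records.
#' @export
read_variant_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(chrom = "c"))
  stopifnot(all(c("chrom", "pos", "coverage", "variant_count") %in%
                  names(tbl)))
  if (!"frequency" %in% names(tbl)) {
    tbl$frequency <- ifelse(tbl$coverage > 0,
                            tbl$variant_count / tbl$coverage, NA_real_)
  }
  tbl
}

#' @rdname read_variant_table
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("Package `vcfR` is required for VCF ingestion.", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  alt_count <- apply(ad, 2, function(col) {
    as.numeric(vapply(strsplit(col, ","), function(x) {
      if (length(x) >= 2) x[2] else NA_character_
    }, character(1)))
  })
  fix <- vcfR::getFIX(v)
  samples <- colnames(dp)
  purrr::map_dfr(seq_along(samples), function(j) {
    tibble::tibble(
      line_id = samples[j],
      chrom = as.character(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      coverage = as.integer(dp[, j]),
      variant_count = as.integer(alt_count[, j])
    )
  }) |>
    dplyr::mutate(frequency = ifelse(.data$coverage > 0,
                                     .data$variant_count / .data$coverage,
                                     NA_real_))
}
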