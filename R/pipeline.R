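# End-to-end orchestration: simulate -> diversity -> respond -> compare,
# theory validation of the simulator, assay-design arithmetic, config IO.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a cohort, estimates per-line diversity from its read tables,
#' computes response slopes and viability changes, and runs the
#' pi-vs-expected-F predictor comparison. With `outdir` set, every stage's
#' table is written as CSV/TSV, stamped (in `run_info.csv`) with the master
#' seed and a hash of the configuration; re-running with the same config and
#' seed reproduces identical outputs.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed.
#' @param outdir Optional output directory.
#' @param alpha,family_size Passed to [compare_predictors()].
#' @return An object of class `pipeline_result`: `cohort`, `diversity`,
#'   `slopes`, `viability_changes`, `comparison`
#'   ([compare_predictors()] result), `cv`, `ks`, `ob_paired_t` (paired
#'   t-test of outbred benign viability before vs after), `theory`
#'   (the [theory_table()]), `seed` and `config_hash`.
#' @examples
#' \donttest{
#' res <- run_pipeline(cohort_config(
#'   n_loci = 500,
#'   group_sizes = c(Low = 8, Medium = 8, High = 8, OB = 4)), seed = 1)
#' res$comparison
#' }
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, outdir = NULL,
                         alpha = 0.05, family_size = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("Pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- stage("simulate", generate_cohort(config, seed = seed))
  if (!any(cohort$lines$group == "OB")) {
    stop("Pipeline stage `diversity` failed: no outbred lines to ",
         "normalise against.", call. = FALSE)
  }
  diversity <- stage("diversity",
                     estimate_diversity(cohort$reads, cohort$lines))
  slopes <- stage("respond", {
    # slopes are only meaningful for lines that completed the experiment
    surv <- cohort$lines$line_id[is.na(cohort$lines$extinction_gen)]
    response_slopes(dplyr::filter(cohort$traits,
                                  .data$line_id %in% surv))
  })
  deltas <- stage("respond", viability_change(cohort$viability))
  comparison <- stage("compare",
                      compare_predictors(slopes, deltas, diversity,
                                         cohort$lines, alpha = alpha,
                                         family_size = family_size))
  cv <- stage("respond", cv_by_group(cohort$traits, cohort$lines))
  ks <- stage("diversity", {
    cov_by_group <- dplyr::inner_join(
      cohort$reads, dplyr::select(cohort$lines, "line_id", "group"),
      by = "line_id")
    coverage_ks_diagnostic(split(cov_by_group$coverage, cov_by_group$group))
  })
  ob_ids <- cohort$lines$line_id[cohort$lines$group == "OB" &
                                   is.na(cohort$lines$extinction_gen)]
  ob_ben <- dplyr::filter(deltas, .data$line_id %in% ob_ids,
                          .data$medium == "benign")
  ob_paired <- if (nrow(ob_ben) >= 2) {
    paired_t(ob_ben$v0, ob_ben$v10)
  } else {
    NULL
  }
  config_hash <- config_digest(config)
  result <- structure(
    list(cohort = cohort, diversity = diversity, slopes = slopes,
         viability_changes = deltas, comparison = comparison, cv = cv,
         ks = ks, ob_paired_t = ob_paired, theory = theory_table(),
         seed = seed, config_hash = config_hash),
    class = "pipeline_result"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, outdir)
    num <- function(x) dplyr::mutate(x, dplyr::across(
      dplyr::where(is.numeric), ~ signif(.x, 10)))
    readr::write_csv(num(diversity), file.path(outdir, "diversity.csv"))
    readr::write_csv(num(slopes), file.path(outdir, "slopes.csv"))
    readr::write_csv(num(deltas), file.path(outdir, "viability_change.csv"))
    readr::write_csv(num(comparison$models),
                     file.path(outdir, "comparison_report.csv"))
    readr::write_csv(num(comparison$contrasts),
                     file.path(outdir, "group_contrasts.csv"))
    readr::write_csv(num(cv), file.path(outdir, "cv_by_group.csv"))
    readr::write_csv(num(ks), file.path(outdir, "coverage_ks.csv"))
    readr::write_csv(
      tibble::tibble(seed = seed, config_hash = config_hash,
                     n_lines = nrow(cohort$lines),
                     n_extinct = sum(!is.na(cohort$lines$extinction_gen)),
                     n_eligible = comparison$n_eligible),
      file.path(outdir, "run_info.csv"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_result> seed %s, config %s\n",
                     "  %d lines, %d extinct, %d eligible for comparison\n"),
              format(x$seed), x$config_hash, nrow(x$cohort$lines),
              sum(!is.na(x$cohort$lines$extinction_gen)),
              x$comparison$n_eligible))
  print(x$comparison)
  invisible(x)
}

# small deterministic digest of the config (no external dependency)
config_digest <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
             collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 1000))) {
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Validate the drift simulator against closed-form theory
#'
#' For each bottleneck design, simulates `n_replicates` independent lines
#' (at a reduced locus count, which does not affect the expectation) and
#' compares the mean realised gene-diversity retention against the
#' closed-form drift expectation (one factor `1 - 1/(2N)` per generation;
#' see [expected_line_retention()]), within `se_mult` Monte-Carlo standard
#' errors. The table also reports the breeding-pair expected F of each
#' design ([design_expected_f()]) next to the drift-based expectation
#' `1 - retention`: the two describe different processes (pedigree identity
#' by descent vs allele-frequency gene diversity) and agree only at a
#' single bottleneck step, so only the drift expectation is used as the
#' pass/fail calibration oracle.
#'
#' @param n_replicates Replicate lines per design (default 1000).
#' @param n_loci Loci per replicate line (default 400).
#' @param designs Designs to check (default [default_designs()]).
#' @param bottleneck_only If `TRUE`, skip the flush phase so the check
#'   isolates the per-bottleneck-generation factor `1 - 1/(2N)`.
#' @param se_mult Tolerance in Monte-Carlo standard errors (default 3).
#' @param seed Seed.
#' @return A tibble per design: `design`, `drift_steps`, `expected_retention`,
#'   `mean_retention`, `mc_se`, `z`, `ok`, `expected_f_wf`,
#'   `mean_realized_f`, `expected_f_pairs`. Attribute `"ok"` is `TRUE` when
#'   every design passes.
#' @export
validate_against_theory <- function(n_replicates = 1000, n_loci = 400,
                                    designs = default_designs(),
                                    bottleneck_only = FALSE, se_mult = 3,
                                    seed = 1) {
  stopifnot(n_replicates >= 2)
  n_flush <- if (bottleneck_only) 0 else 2
  out <- withr::with_seed(seed, {
    pool <- founder_pool(n_loci, n_blocks = 8)
    founder_het <- sum(pool$p0 * (1 - pool$p0))
    purrr::imap_dfr(designs, function(d, lab) {
      ret <- vapply(seq_len(n_replicates), function(i) {
        drifted <- simulate_drift(pool, d, n_flush_gens = n_flush)
        sum(drifted$freq * (1 - drifted$freq)) / founder_het
      }, numeric(1))
      expd <- expected_line_retention(d, n_flush_gens = n_flush)
      se <- stats::sd(ret) / sqrt(n_replicates)
      tibble::tibble(
        design = lab,
        drift_steps = d$n_bottleneck_gens + n_flush,
        expected_retention = expd,
        mean_retention = mean(ret),
        mc_se = se,
        z = (mean(ret) - expd) / se,
        ok = abs(mean(ret) - expd) <= se_mult * se,
        expected_f_wf = 1 - expd,
        mean_realized_f = 1 - mean(ret),
        expected_f_pairs = design_expected_f(d)
      )
    })
  })
  attr(out, "ok") <- all(out$ok)
  out
}

#' Egg and vial counts of a viability assay layout
#'
#' Design arithmetic of an egg-to-adult viability assay: `lines x media x
#' vials` vials, each seeded with `eggs_per_vial` eggs. The study layouts
#' are the baseline characterisation (132 lines x 5 media x 5 vials x 15
#' eggs = 49,500 eggs in 3,300 vials) and the generation-10 assay (96
#' surviving lines x 2 media x 10 vials x 15 eggs = 28,800 eggs in 1,920
#' vials).
#'
#' @param n_lines,n_media,n_vials Number of lines, media, and replicate
#'   vials per line and medium.
#' @param eggs_per_vial Eggs seeded per vial (default 15).
#' @return A tibble with `vials` and `eggs`.
#' @examples
#' assay_layout(132, 5, 5) # 3300 vials, 49500 eggs
#' @export
assay_layout <- function(n_lines, n_media, n_vials, eggs_per_vial = 15) {
  stopifnot(n_lines >= 1, n_media >= 1, n_vials >= 1, eggs_per_vial >= 1)
  vials <- n_lines * n_media * n_vials
  tibble::tibble(vials = vials, eggs = vials * eggs_per_vial)
}

#' Write / read a run configuration as YAML
#'
#' Serialises a [cohort_config()] (bottleneck designs included) so that
#' `read_run_config(write_run_config(cfg, path))` reproduces the identical
#' configuration.
#'
#' @param config A [cohort_config()].
#' @param path File path (`.yaml`).
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` the restored `cohort_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$designs <- purrr::map(x$designs, function(d) {
    list(n_bottleneck_gens = d$n_bottleneck_gens,
         founder_size = d$founder_size,
         bottleneck_size = d$bottleneck_size,
         flush_size = d$flush_size, label = d$label)
  })
  # keep names of named numeric vectors through YAML as mappings
  for (nm in c("group_sizes", "chrom_weights")) {
    x[[nm]] <- as.list(x[[nm]])
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$designs <- purrr::map(x$designs, function(d) {
    bottleneck_design(d$n_bottleneck_gens, d$founder_size,
                      d$bottleneck_size, d$flush_size, d$label)
  })
  for (nm in c("group_sizes", "chrom_weights")) {
    x[[nm]] <- unlist(x[[nm]])
  }
  for (nm in c("freq_shape", "freq_range")) x[[nm]] <- as.numeric(x[[nm]])
  do.call(cohort_config, x)
}
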