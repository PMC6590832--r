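# Synthetic study generator: founder allele frequencies, Wright-Fisher drift
# through bottleneck designs, pooled-GBS read tables, trait trajectories with
# diversity-coupled response, extinction, and before/after viability.

#' Draw a founder pool of polymorphic loci
#'
#' Emulates the variable sites segregating in a large mass-bred base
#' population. Founder variant-allele frequencies are drawn i.i.d. from a
#' Beta distribution truncated away from the boundaries (default
#' Beta(0.5, 0.5) on `[0.05, 0.95]`, a U-shaped spectrum). Loci are placed on
#' chromosomes 2, 3, 4 and X with the given weights and grouped into
#' contiguous linkage blocks: all loci in a block share one genealogy during
#' the bottleneck phase of [simulate_drift()], which is what gives replicate
#' lines realistic line-level variation in retained diversity.
#'
#' @param n_loci Number of loci (>= 1).
#' @param shape1,shape2 Beta shape parameters of the founder frequency law.
#' @param freq_range Truncation interval for founder frequencies.
#' @param chrom_weights Named proportions for chromosomes; the default keeps
#'   a nonzero X fraction so the downstream autosome filter is exercised.
#' @param n_blocks Total number of linkage blocks across the genome.
#' @param seed Optional integer seed (local to this call).
#' @return A tibble with columns `chrom`, `pos` (1-based, strictly increasing
#'   within chromosome), `block`, and `p0` (founder variant-allele
#'   frequency in (0, 1)).
#' @examples
#' founder_pool(100, seed = 1)
#' @export
founder_pool <- function(n_loci, shape1 = 0.5, shape2 = 0.5,
                         freq_range = c(0.05, 0.95),
                         chrom_weights = c(`2` = 0.38, `3` = 0.40,
                                           `4` = 0.02, X = 0.20),
                         n_blocks = 8, seed = NULL) {
  if (length(n_loci) != 1L || is.na(n_loci) || n_loci < 1) {
    stop("`n_loci` must be a single integer >= 1.", call. = FALSE)
  }
  if (shape1 <= 0 || shape2 <= 0 || freq_range[1] <= 0 ||
      freq_range[2] >= 1 || freq_range[1] >= freq_range[2]) {
    stop("Invalid founder frequency law.", call. = FALSE)
  }
  if (is.null(names(chrom_weights)) || any(chrom_weights < 0) ||
      sum(chrom_weights) <= 0) {
    stop("`chrom_weights` must be named non-negative proportions.",
         call. = FALSE)
  }
  draw <- function() {
    chrom <- sample(names(chrom_weights), n_loci, replace = TRUE,
                    prob = chrom_weights)
    u <- stats::runif(n_loci,
                      stats::pbeta(freq_range[1], shape1, shape2),
                      stats::pbeta(freq_range[2], shape1, shape2))
    p0 <- stats::qbeta(u, shape1, shape2)
    pool <- tibble::tibble(chrom = chrom, p0 = p0) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(pos = sort(sample.int(25e6, dplyr::n()))) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$chrom, .data$pos)
    # contiguous blocks per chromosome, count proportional to its weight
    w <- chrom_weights / sum(chrom_weights)
    pool |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(
        block = paste0(.data$chrom[1], "_",
                       dplyr::ntile(.data$pos,
                                    max(1L, round(n_blocks * w[[.data$chrom[1]]]))))
      ) |>
      dplyr::ungroup() |>
      dplyr::select("chrom", "pos", "block", "p0")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate neutral Wright-Fisher drift through a bottleneck design
#'
#' Propagates the founder pool through the census trajectory of a design.
#' Each generation at census size `N` resamples the line's gene pool as a
#' draw of `2N` gene copies. During the bottleneck phase this is done at the
#' level of founder gene copies within each linkage block: the line is
#' founded by `2 * bottleneck_size` copies drawn from the base (this founding
#' sample is the first bottleneck generation), each subsequent bottleneck
#' generation multinomially resamples copy counts, and loci within a block
#' share the resulting genealogy. The flush and maintenance generations
#' resample at `2 * flush_size`. With `design = NULL` (outbred control
#' lines) the bottleneck phase is skipped and loci drift independently at
#' the maintenance size for `ob_gens` generations.
#'
#' The expected retained gene diversity is exactly
#' `prod(1 - 1/(2 N_i))` over the per-generation sizes after the founder
#' (see [expected_line_retention()]); loci may fix at 0 or 1.
#'
#' When `breeder_counts` is supplied (one count per bottleneck generation),
#' generation `t` of the bottleneck phase resamples `2 * breeder_counts[t]`
#' gene copies instead of `2 * bottleneck_size`: the gene pool of the
#' adults that actually contributed offspring. This emulates the
#' line-to-line variance in realised breeder numbers of real breeding-pair
#' lines (deaths and unequal reproductive success during the pairing
#' windows), which makes realised drift line specific. With
#' `breeder_counts = NULL` every generation uses the idealised
#' equal-contribution census size, and the closed-form retention oracle is
#' exact.
#'
#' @param pool A founder pool from [founder_pool()].
#' @param design A [bottleneck_design()], or `NULL` for an outbred line.
#' @param n_flush_gens Generations spent at `flush_size` before sequencing
#'   (default 2: the flush itself plus one maintenance generation).
#' @param ob_gens Generations of drift at the maintenance size for outbred
#'   lines (default 5, spanning the asynchronous set-up window).
#' @param ob_size Census size of outbred lines (default 200).
#' @param breeder_counts Optional integer vector, one realised breeder
#'   count per bottleneck generation (each in
#'   `[1, bottleneck_size]`); `NULL` for equal contribution at the census
#'   size.
#' @param seed Optional integer seed (local to this call).
#' @return The pool tibble with an added column `freq`, the realised
#'   variant-allele frequency of the line (in `[0, 1]`).
#' @export
simulate_drift <- function(pool, design = NULL, n_flush_gens = 2,
                           ob_gens = 5, ob_size = 200,
                           breeder_counts = NULL, seed = NULL) {
  stopifnot(is.data.frame(pool), all(c("block", "p0") %in% names(pool)))
  run <- function() {
    if (is.null(design)) {
      freq <- pool$p0
      for (g in seq_len(ob_gens)) {
        freq <- stats::rbinom(length(freq), 2L * ob_size, freq) / (2 * ob_size)
      }
      return(dplyr::mutate(pool, freq = freq))
    }
    stopifnot(inherits(design, "bottleneck_design"))
    if (is.null(breeder_counts)) {
      breeder_counts <- rep(design$bottleneck_size,
                            design$n_bottleneck_gens)
    }
    stopifnot(length(breeder_counts) == design$n_bottleneck_gens,
              all(breeder_counts >= 1),
              all(breeder_counts <= design$bottleneck_size))
    copies <- 2L * as.integer(breeder_counts)
    n_flush_copies <- 2L * design$flush_size
    freq <- numeric(nrow(pool))
    for (idx in split(seq_len(nrow(pool)), pool$block)) {
      p0 <- pool$p0[idx]
      # founding sample: alleles of the first generation's contributing
      # copies, drawn from the base
      alleles <- matrix(stats::runif(copies[1] * length(idx)) <
                          rep(p0, each = copies[1]), nrow = copies[1])
      counts <- rep(1L, copies[1])
      for (g in seq_len(design$n_bottleneck_gens - 1L)) {
        counts <- as.vector(stats::rmultinom(1L, copies[g + 1L], counts))
      }
      pool_size <- copies[length(copies)]
      for (g in seq_len(n_flush_gens)) {
        counts <- as.vector(stats::rmultinom(1L, n_flush_copies, counts))
        pool_size <- n_flush_copies
      }
      freq[idx] <- as.vector((counts / pool_size) %*% alleles)
    }
    # guard against floating-point spill just outside [0, 1]
    dplyr::mutate(pool, freq = pmin(1, pmax(0, freq)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Expected gene-diversity retention of a simulated line
#'
#' Closed-form expectation of `sum(freq * (1 - freq)) / sum(p0 * (1 - p0))`
#' for [simulate_drift()]: one factor `1 - 1/(2N)` per generation lived at
#' census size `N` after the founder generation.
#'
#' @inheritParams simulate_drift
#' @return Scalar retention factor in `[0, 1]`.
#' @export
expected_line_retention <- function(design = NULL, n_flush_gens = 2,
                                    ob_gens = 5, ob_size = 200,
                                    breeder_counts = NULL) {
  if (is.null(design)) {
    return(expected_het_retention(ob_size, ob_gens))
  }
  stopifnot(inherits(design, "bottleneck_design"))
  if (is.null(breeder_counts)) {
    breeder_counts <- rep(design$bottleneck_size, design$n_bottleneck_gens)
  }
  prod(1 - 1 / (2 * breeder_counts)) *
    expected_het_retention(design$flush_size, n_flush_gens)
}

#' Simulate a pooled-sequencing read table
#'
#' Emulates pooled GBS of `n_males` individuals: the sequenced pool carries
#' `2 * n_males` gene copies sampled binomially from the line's allele
#' frequency, per-site read depth follows a negative-binomial law clipped to
#' `[0, max_coverage]`, and the variant read count at a site is binomial in
#' the pool frequency. Sites fixed for the reference in the pool still
#' appear, with `variant_count = 0`. Male hemizygosity on the X is not
#' modelled (X-linked sites are removed by the downstream autosome filter).
#'
#' @param drifted A tibble from [simulate_drift()] (needs `chrom`, `pos`,
#'   `freq`).
#' @param n_males Number of pooled individuals (default 15).
#' @param depth_mu,depth_size Negative-binomial mean and dispersion of read
#'   depth. The defaults (mu 60, size 2) give a mode near 30 with a long
#'   right tail reaching the mid-hundreds across tens of thousands of sites.
#' @param max_coverage Depth clip (default 600).
#' @param coverage Optional fixed per-site coverage vector (recycled),
#'   overriding the depth law; used for calibration.
#' @param pool_sampling If `FALSE`, skip the finite-pool sampling step and
#'   treat `freq` itself as the pool frequency (calibration use).
#' @param seed Optional integer seed (local to this call).
#' @return A tibble with `chrom`, `pos`, `coverage`, `variant_count` and
#'   `frequency` (`variant_count / coverage`, `NA` at zero coverage).
#' @export
simulate_pool_reads <- function(drifted, n_males = 15, depth_mu = 60,
                                depth_size = 2, max_coverage = 600,
                                coverage = NULL, pool_sampling = TRUE,
                                seed = NULL) {
  stopifnot(is.data.frame(drifted), all(c("chrom", "pos", "freq") %in%
                                          names(drifted)))
  if (n_males < 1) stop("`n_males` must be >= 1.", call. = FALSE)
  run <- function() {
    n <- nrow(drifted)
    q <- if (isTRUE(pool_sampling)) {
      stats::rbinom(n, 2L * n_males, drifted$freq) / (2 * n_males)
    } else {
      drifted$freq
    }
    cov <- if (is.null(coverage)) {
      pmin(stats::rnbinom(n, mu = depth_mu, size = depth_size), max_coverage)
    } else {
      rep_len(as.integer(coverage), n)
    }
    vc <- stats::rbinom(n, cov, q)
    tibble::tibble(
      chrom = drifted$chrom, pos = drifted$pos,
      coverage = as.integer(cov), variant_count = as.integer(vc),
      frequency = ifelse(cov > 0, vc / cov, NA_real_)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Default configuration of the synthetic cohort
#'
#' Returns (and validates) the full parameter set of [generate_cohort()].
#' The defaults encode the study design being emulated: 42/40/40 inbred
#' lines at 2/3/5 bottleneck generations of census size 4 plus 10 outbred
#' controls (132 lines), 15-male pools, ten generations of rearing on a
#' line-specific acid-stress medium chosen to give roughly 50% baseline
#' egg-to-adult viability, an extinction rule at 200 collected adults, and
#' a per-generation trait response proportional to the line's retained
#' diversity. Any element can be overridden through `...`.
#'
#' @param ... Named overrides of the default elements.
#' @return An object of class `cohort_config` (a named list).
#' @examples
#' cohort_config(n_loci = 500, group_sizes = c(Low = 2, Medium = 2,
#'                                             High = 2, OB = 2))
#' @export
cohort_config <- function(...) {
  config <- list(
    group_sizes = c(Low = 42, Medium = 40, High = 40, OB = 10),
    designs = default_designs(),
    n_loci = 25000,
    n_blocks = 8,
    freq_shape = c(0.5, 0.5),
    freq_range = c(0.05, 0.95),
    chrom_weights = c(`2` = 0.38, `3` = 0.40, `4` = 0.02, X = 0.20),
    n_flush_gens = 2,
    ob_gens = 5,
    ob_size = 200,
    n_males = 15,
    depth_mu = 60,
    depth_size = 2,
    max_coverage = 600,
    n_generations = 10,
    # trait response: mean(g) = baseline + beta * retention * g + noise
    productivity = list(baseline = 1.5, beta = 0.08, sd = 0.16),
    body_mass = list(baseline = 0.30, beta = 0.003, sd = 0.006, n = 15),
    # realised breeders per bottleneck generation: each of the census
    # adults fails to contribute with prob fail_prob (death, sterility,
    # unequal success during the pairing windows), floored at one pair
    breeders = list(fail_prob = 0.10, min_breeders = 2),
    # extinction: adults collected per generation ~ N(base + het * retention,
    # sd), plus a line-level shift; extinct at the first generation < threshold
    extinction = list(adults_base = 199, adults_het = 34, adults_sd = 12,
                      line_sd = 5, threshold = 200),
    viability = list(benign_mean = 0.85, benign_sd = 0.04,
                     benign_range = c(0.60, 0.97),
                     acid_sens_mean = 0.28, acid_sens_sd = 0.08,
                     acid_sens_min = 0.08,
                     acid_levels = c(1.0, 2.5, 5.0, 10.0),
                     allowed_acid = c(1.0, 2.5),
                     eggs_per_vial = 15, vials_gen0 = 5, vials_gen10 = 10,
                     stress_gain_base = -0.05, stress_gain_het = 0.20,
                     benign_shift = -0.03, line_sd = 0.04)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    stop("Unknown cohort_config element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(overrides)) {
    if (is.list(config[[nm]]) && is.list(overrides[[nm]]) &&
        !inherits(config[[nm]], "bottleneck_design") && nm != "designs") {
      config[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      config[[nm]] <- overrides[[nm]]
    }
  }
  validate_cohort_config(structure(config, class = "cohort_config"))
}

validate_cohort_config <- function(config) {
  gs <- config$group_sizes
  if (is.null(names(gs)) ||
      !all(names(gs) %in% c("Low", "Medium", "High", "OB")) ||
      any(gs < 0)) {
    stop("`group_sizes` must be named among Low/Medium/High/OB and >= 0.",
         call. = FALSE)
  }
  inbred <- setdiff(names(gs)[gs > 0], "OB")
  if (!all(inbred %in% names(config$designs))) {
    stop("Every inbred group needs a design of the same name.", call. = FALSE)
  }
  for (p in c("productivity", "body_mass")) {
    if (config[[p]]$beta < 0 || config[[p]]$sd < 0) {
      stop("Trait response coefficients and noise SDs must be >= 0.",
           call. = FALSE)
    }
  }
  if (config$viability$line_sd < 0 || config$extinction$adults_sd < 0) {
    stop("Noise SDs must be >= 0.", call. = FALSE)
  }
  if (config$n_loci < 1) stop("`n_loci` must be >= 1.", call. = FALSE)
  config
}

#' Simulate trait trajectories, viability and extinction for one line
#'
#' Draws everything phenotypic for one line, given its retained-diversity
#' fraction `retention` (realised heterozygosity relative to the founder
#' pool). Per-generation trait means follow
#' `baseline + beta * retention * g + noise`; adult output per generation is
#' normal around a mean increasing in `retention`, and the line is extinct
#' at the first of generations 1..9 where fewer than 200 adults are
#' collected (traits are recorded up to and including that generation).
#' Baseline viability is assayed on a benign medium and at four acetic-acid
#' doses; the dose bringing egg-to-adult viability closest to 50% (among
#' the levels used in the main experiment) becomes the line's stress
#' medium. After ten generations, surviving lines are re-assayed on both
#' media: the true stress viability gains `stress_gain_base +
#' stress_gain_het * retention`, while the benign viability shifts by a
#' retention-independent `benign_shift` (the correlated response carries
#' the same cost regardless of diversity).
#'
#' @param group One of `"Low"`, `"Medium"`, `"High"`, `"OB"`.
#' @param retention Realised heterozygosity of the line relative to the
#'   founder pool, in `[0, 1]`.
#' @param config A [cohort_config()].
#' @param seed Optional integer seed (local to this call).
#' @return A list with elements `traits` (tibble: `generation`, `trait`,
#'   `value`, `n`), `viability` (tibble: `medium`, `generation`, `vial`,
#'   `eggs`, `survivors`), `acid_level`, and `extinction_gen` (integer or
#'   `NA`).
#' @export
simulate_phenotypes <- function(group, retention, config = cohort_config(),
                                seed = NULL) {
  # retention can exceed 1 slightly by chance (drift toward intermediate
  # frequencies at loci founded near the boundary), so only a lower bound
  # is enforced
  stopifnot(group %in% c("Low", "Medium", "High", "OB"),
            is.finite(retention), retention >= 0)
  run <- function() {
    vb <- config$viability
    ex <- config$extinction
    clamp <- function(x, lo = 0.02, hi = 0.98) pmin(hi, pmax(lo, x))

    # line-specific benign viability and acid sensitivity
    v_benign <- clamp(stats::rnorm(1, vb$benign_mean, vb$benign_sd),
                      vb$benign_range[1], vb$benign_range[2])
    sens <- max(vb$acid_sens_min,
                stats::rnorm(1, vb$acid_sens_mean, vb$acid_sens_sd))
    v_at <- function(acid) clamp(v_benign * exp(-sens * acid))

    # baseline assay: benign control plus the acid dose range
    assay <- function(v_true, n_vials, medium, generation) {
      tibble::tibble(
        medium = medium, generation = generation,
        vial = seq_len(n_vials), eggs = vb$eggs_per_vial,
        survivors = stats::rbinom(n_vials, vb$eggs_per_vial, v_true)
      )
    }
    base_stress <- lapply(vb$acid_levels, function(a) {
      assay(v_at(a), vb$vials_gen0, paste0("acid_", a), 0L)
    })
    names(base_stress) <- as.character(vb$acid_levels)
    base_benign <- assay(v_benign, vb$vials_gen0, "benign", 0L)

    # stress-level selection: survival closest to 50%, restricted to the
    # levels run in the main experiment; outbred lines all get 2.5
    observed <- vapply(base_stress,
                       function(x) sum(x$survivors) / sum(x$eggs), numeric(1))
    allowed <- as.character(vb$allowed_acid)
    acid_level <- if (group == "OB") {
      max(vb$allowed_acid)
    } else {
      select_stress_level(stats::setNames(observed[allowed],
                                          allowed))
    }
    v0_stress <- v_at(acid_level)

    # extinction: adult output per generation, line extinct when < threshold
    mu_adults <- ex$adults_base + ex$adults_het * retention +
      stats::rnorm(1, 0, ex$line_sd)
    adults <- round(stats::rnorm(9, mu_adults, ex$adults_sd))
    extinction_gen <- classify_extinction(adults, threshold = ex$threshold)
    last_gen <- if (is.na(extinction_gen)) config$n_generations else
      extinction_gen

    # per-generation trait means
    gens <- seq_len(last_gen)
    traits <- dplyr::bind_rows(
      tibble::tibble(
        generation = gens, trait = "productivity",
        value = pmax(0, config$productivity$baseline +
                       config$productivity$beta * retention * gens +
                       stats::rnorm(length(gens), 0, config$productivity$sd)),
        n = 1L
      ),
      tibble::tibble(
        generation = gens, trait = "body_mass",
        value = pmax(0.01, config$body_mass$baseline +
                       config$body_mass$beta * retention * gens +
                       stats::rnorm(length(gens), 0, config$body_mass$sd)),
        n = as.integer(config$body_mass$n)
      )
    )

    # generation-0 viability records: benign + the selected stress medium
    viability <- dplyr::bind_rows(
      dplyr::mutate(base_benign, medium = "benign"),
      dplyr::mutate(base_stress[[as.character(acid_level)]],
                    medium = "stress")
    )
    if (is.na(extinction_gen)) {
      v10_stress <- clamp(v0_stress + vb$stress_gain_base +
                            vb$stress_gain_het * retention +
                            stats::rnorm(1, 0, vb$line_sd))
      v10_benign <- clamp(v_benign + vb$benign_shift +
                            stats::rnorm(1, 0, vb$line_sd))
      viability <- dplyr::bind_rows(
        viability,
        assay(v10_stress, vb$vials_gen10, "stress", 10L),
        assay(v10_benign, vb$vials_gen10, "benign", 10L)
      )
    }
    list(traits = traits, viability = viability,
         acid_level = acid_level, extinction_gen = extinction_gen)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a full synthetic cohort
#'
#' Runs the whole generator: one founder pool shared by all lines, then per
#' line Wright-Fisher drift through its group's design, a pooled-GBS read
#' table, and trait/viability/extinction phenotypes coupled to the line's
#' realised diversity. Outbred (OB) lines skip the bottleneck phase. Each
#' inbred line draws its realised breeder count per bottleneck generation
#' (census minus failures at `breeders$fail_prob`, floored at
#' `breeders$min_breeders`), so realised drift varies among replicate
#' lines of the same design, as it does among real breeding-pair lines.
#' Every line's randomness derives from a per-line seed drawn once under
#' the master seed, so results are reproducible and independent of global
#' RNG state.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed (integer).
#' @return An object of class `cohort`: a list with tibbles `lines`
#'   (manifest: `line_id`, `group`, `n_bottleneck_gens`, `expected_f`,
#'   `acid_level`, `extinction_gen`, `founder_het`, `realized_het`,
#'   `het_retention`), `reads` (per-line variant tables, long),
#'   `traits`, `viability`, plus `founder` (the pool), `config` and `seed`.
#' @examples
#' coh <- generate_cohort(cohort_config(
#'   n_loci = 200,
#'   group_sizes = c(Low = 2, Medium = 2, High = 2, OB = 2)), seed = 1)
#' coh$lines
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  gs <- config$group_sizes[config$group_sizes > 0]
  prefix <- c(Low = "L", Medium = "M", High = "H", OB = "OB")
  lines <- purrr::map2_dfr(names(gs), gs, function(g, n) {
    tibble::tibble(line_id = sprintf("%s%02d", prefix[[g]], seq_len(n)),
                   group = g)
  })
  withr::with_seed(seed, {
    pool <- founder_pool(config$n_loci, config$freq_shape[1],
                         config$freq_shape[2], config$freq_range,
                         config$chrom_weights, config$n_blocks)
    line_seeds <- sample.int(.Machine$integer.max - 1L, nrow(lines))
  })
  founder_het <- sum(pool$p0 * (1 - pool$p0))

  per_line <- purrr::pmap(
    list(lines$line_id, lines$group, line_seeds),
    function(id, group, line_seed) {
      design <- if (group == "OB") NULL else config$designs[[group]]
      withr::with_seed(line_seed, {
        breeders <- if (is.null(design)) NULL else {
          pmax(config$breeders$min_breeders,
               design$bottleneck_size -
                 stats::rbinom(design$n_bottleneck_gens,
                               design$bottleneck_size,
                               config$breeders$fail_prob))
        }
        drifted <- simulate_drift(pool, design,
                                  n_flush_gens = config$n_flush_gens,
                                  ob_gens = config$ob_gens,
                                  ob_size = config$ob_size,
                                  breeder_counts = breeders)
        reads <- simulate_pool_reads(drifted, n_males = config$n_males,
                                     depth_mu = config$depth_mu,
                                     depth_size = config$depth_size,
                                     max_coverage = config$max_coverage)
        realized_het <- sum(drifted$freq * (1 - drifted$freq))
        phen <- simulate_phenotypes(group, realized_het / founder_het,
                                    config)
      })
      list(
        manifest = tibble::tibble(
          line_id = id, group = group,
          n_bottleneck_gens = if (is.null(design)) NA_integer_ else
            design$n_bottleneck_gens,
          expected_f = if (is.null(design)) 0 else design_expected_f(design),
          acid_level = phen$acid_level,
          extinction_gen = phen$extinction_gen,
          mean_breeders = if (is.null(breeders)) NA_real_ else
            mean(breeders),
          founder_het = founder_het,
          realized_het = realized_het,
          het_retention = realized_het / founder_het
        ),
        reads = dplyr::mutate(reads, line_id = id, .before = 1),
        traits = dplyr::mutate(phen$traits, line_id = id, .before = 1),
        viability = dplyr::mutate(phen$viability, line_id = id, .before = 1)
      )
    }
  )
  structure(
    list(
      lines = purrr::map_dfr(per_line, "manifest"),
      reads = purrr::map_dfr(per_line, "reads"),
      traits = purrr::map_dfr(per_line, "traits"),
      viability = purrr::map_dfr(per_line, "viability"),
      founder = pool, config = config, seed = seed
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  ext <- sum(!is.na(x$lines$extinction_gen))
  cat(sprintf(paste0("<cohort> %d lines (%s), %d loci, seed %s\n",
                     "  %d extinct; %d variant rows\n"),
              nrow(x$lines),
              paste(sprintf("%s=%d", names(table(x$lines$group)),
                            table(x$lines$group)), collapse = ", "),
              nrow(x$founder), format(x$seed), ext, nrow(x$reads)))
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` writes the manifest, traits and viability tables as CSV
#' and the per-line variant tables as one TSV (`variants.tsv`:
#' `line_id`, `chrom`, `pos`, `coverage`, `variant_count`, `frequency`).
#' `read_cohort()` reads them back into the same tibbles.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a list
#'   of tibbles `lines`, `reads`, `traits`, `viability`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$lines, file.path(dir, "lines.csv"))
  readr::write_csv(cohort$traits, file.path(dir, "traits.csv"))
  readr::write_csv(cohort$viability, file.path(dir, "viability.csv"))
  readr::write_tsv(cohort$reads, file.path(dir, "variants.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(
    lines = readr::read_csv(
      file.path(dir, "lines.csv"), show_col_types = FALSE,
      col_types = readr::cols(extinction_gen = "i",
                              n_bottleneck_gens = "i")),
    reads = readr::read_tsv(file.path(dir, "variants.tsv"),
                            show_col_types = FALSE,
                            col_types = readr::cols(chrom = "c")),
    traits = readr::read_csv(file.path(dir, "traits.csv"),
                             show_col_types = FALSE),
    viability = readr::read_csv(file.path(dir, "viability.csv"),
                                show_col_types = FALSE)
  )
}
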