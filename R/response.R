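# Per-line evolutionary response: productivity rate, OLS response slopes,
# viability change with variance-sum-law SE, between-line CV, extinction
# classification, and baseline stress-level selection.

#' Productivity rate
#'
#' Adult flies produced per female per day, assuming a 1:1 sex ratio among
#' the parents: `total_flies / ((n_parents / 2) * laying_days)`.
#'
#' @param total_flies Total adults produced (>= 0).
#' @param n_parents Number of parental flies (> 0).
#' @param laying_days Egg-laying duration in days (> 0; default 4, i.e. two
#'   48-hour laying bottles).
#' @return Rate in flies per female per day; vectorised.
#' @examples
#' productivity_rate(400, 200) # 1.0
#' @export
productivity_rate <- function(total_flies, n_parents, laying_days = 4) {
  if (any(n_parents <= 0) || any(laying_days <= 0)) {
    stop("`n_parents` and `laying_days` must be positive.", call. = FALSE)
  }
  if (any(total_flies < 0)) stop("`total_flies` must be >= 0.", call. = FALSE)
  total_flies / ((n_parents / 2) * laying_days)
}

# closed-form simple OLS on (x, y); returns slope, intercept, r_squared
ols_line <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("Zero variance in generation index.", call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  tss <- sum((y - mean(y))^2)
  rss <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_)
}

#' Per-line response slopes across generations
#'
#' The evolutionary response of a line in a trait is the ordinary
#' least-squares slope of its per-generation means on the generation index.
#' Lines with fewer than `min_generations` observed generations for a trait
#' are ineligible: they are returned with `slope = NA` and the reason in
#' `exclusion_reason`, not dropped silently. Missing generations are
#' allowed; the regression uses the available points.
#'
#' @param traits Long trait table with columns `line_id`, `trait`,
#'   `generation`, `value` (e.g. `cohort$traits`).
#' @param min_generations Minimum number of generation means needed for a
#'   slope (default 3).
#' @return A tibble `line_id`, `trait`, `slope`, `intercept`, `n_points`,
#'   `r_squared`, `exclusion_reason` (`NA` for eligible lines).
#' @examples
#' tr <- tibble::tibble(line_id = "L01", trait = "productivity",
#'                      generation = 1:10, value = 2 + 0.3 * (1:10))
#' response_slopes(tr)
#' @export
response_slopes <- function(traits, min_generations = 3) {
  stopifnot(is.data.frame(traits),
            all(c("line_id", "trait", "generation", "value") %in%
                  names(traits)))
  tibble::as_tibble(traits) |>
    dplyr::reframe({
      x <- .data$generation
      y <- .data$value
      if (length(unique(x)) != length(x)) {
        stop("Duplicate generation index within a line/trait series.",
             call. = FALSE)
      }
      if (length(x) < min_generations) {
        tibble::tibble(slope = NA_real_, intercept = NA_real_,
                       n_points = length(x), r_squared = NA_real_,
                       exclusion_reason = sprintf(
                         "only %d generation(s); need >= %d",
                         length(x), min_generations))
      } else {
        fit <- ols_line(x, y)
        tibble::tibble(slope = fit$slope, intercept = fit$intercept,
                       n_points = length(x), r_squared = fit$r_squared,
                       exclusion_reason = NA_character_)
      }
    }, .by = c("line_id", "trait"))
}

#' Viability change with its variance-sum-law standard error
#'
#' For two independent mean viabilities (before and after), the change is
#' `delta = v10 - v0` and its standard error follows the variance sum law,
#' `se = sqrt(var10 / n10 + var0 / n0)`.
#'
#' @param v0,v10 Mean viability (proportion) at generation 0 and 10.
#' @param var0,var10 Between-replicate variances of the two means' inputs.
#' @param n0,n10 Replicate counts (>= 1).
#' @return A tibble with `delta` and `se`; vectorised over its arguments.
#' @examples
#' viability_delta(0.5, 0.62, var0 = 0.09, n0 = 5, var10 = 0.04, n10 = 10)
#' @export
viability_delta <- function(v0, v10, var0, n0, var10, n10) {
  if (any(var0 < 0) || any(var10 < 0)) {
    stop("Variances must be >= 0.", call. = FALSE)
  }
  if (any(n0 < 1) || any(n10 < 1)) {
    stop("Sample sizes must be >= 1.", call. = FALSE)
  }
  tibble::tibble(delta = v10 - v0, se = sqrt(var10 / n10 + var0 / n0))
}

#' Per-line viability change from vial-level records
#'
#' Aggregates vial-level egg/survivor counts to per-line, per-medium mean
#' viabilities at generations 0 and 10 and applies [viability_delta()].
#' Lines lacking either time point on a medium (e.g. extinct lines) are
#' omitted.
#'
#' @param viability Vial-level table with `line_id`, `medium`, `generation`
#'   (0 or 10), `vial`, `eggs`, `survivors` (e.g. `cohort$viability`).
#' @return A tibble `line_id`, `medium`, `v0`, `v10`, `delta`, `se`,
#'   `n0`, `n10`.
#' @export
viability_change <- function(viability) {
  stopifnot(all(c("line_id", "medium", "generation", "eggs", "survivors")
                %in% names(viability)))
  per <- tibble::as_tibble(viability) |>
    dplyr::filter(.data$generation %in% c(0, 10),
                  !startsWith(as.character(.data$medium), "acid_")) |>
    dplyr::summarise(
      v = mean(.data$survivors / .data$eggs),
      var = stats::var(.data$survivors / .data$eggs),
      n = dplyr::n(),
      .by = c("line_id", "medium", "generation")
    ) |>
    tidyr::pivot_wider(names_from = "generation",
                       values_from = c("v", "var", "n"))
  if (!all(c("v_0", "v_10") %in% names(per))) {
    return(tibble::tibble(line_id = character(), medium = character(),
                          v0 = numeric(), v10 = numeric(), delta = numeric(),
                          se = numeric(), n0 = integer(), n10 = integer()))
  }
  per |>
    dplyr::filter(!is.na(.data$v_0), !is.na(.data$v_10)) |>
    dplyr::mutate(viability_delta(.data$v_0, .data$v_10, .data$var_0,
                                  .data$n_0, .data$var_10, .data$n_10)) |>
    dplyr::select(line_id = "line_id", medium = "medium", v0 = "v_0",
                  v10 = "v_10", "delta", "se", n0 = "n_0", n10 = "n_10")
}

#' Between-line coefficient of variation
#'
#' CV = sample SD / mean across the lines of a group, reported in percent;
#' a measure of divergence among replicate lines within an inbreeding
#' level at a given generation.
#'
#' @param values Numeric vector of per-line values (length >= 2).
#' @return CV in percent; an error if the mean is zero.
#' @examples
#' between_line_cv(c(8, 12)) # ~28.3
#' @export
between_line_cv <- function(values) {
  if (length(values) < 2) {
    stop("CV needs at least 2 lines.", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) stop("CV undefined: group mean is zero.", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Between-line CV per group and generation
#'
#' @param traits Long trait table (`line_id`, `trait`, `generation`,
#'   `value`).
#' @param lines Manifest with `line_id` and `group`.
#' @return A tibble `group`, `trait`, `generation`, `n_lines`, `cv`
#'   (percent; `NA` where fewer than 2 lines remain).
#' @export
cv_by_group <- function(traits, lines) {
  dplyr::inner_join(tibble::as_tibble(traits),
                    dplyr::select(tibble::as_tibble(lines),
                                  "line_id", "group"),
                    by = "line_id") |>
    dplyr::summarise(
      n_lines = dplyr::n(),
      cv = if (dplyr::n() >= 2 && mean(.data$value) != 0)
        between_line_cv(.data$value) else NA_real_,
      .by = c("group", "trait", "generation")
    )
}

#' Classify extinction from per-generation collected counts
#'
#' A line is extinct at the first generation where fewer than `threshold`
#' adults could be collected.
#'
#' @param counts Collected adult counts for consecutive generations starting
#'   at 1.
#' @param threshold Collection target (default 200).
#' @return The first failing generation (integer) or `NA` if none fails.
#' @examples
#' classify_extinction(c(250, 180, 300)) # 2
#' @export
classify_extinction <- function(counts, threshold = 200) {
  fail <- which(counts < threshold)
  if (length(fail) == 0) NA_integer_ else as.integer(fail[1])
}

#' Select the stress level closest to 50% viability
#'
#' Picks the acid concentration whose baseline egg-to-adult viability is
#' closest to 0.5; ties break toward the lower concentration.
#'
#' @param viabilities Named numeric vector: names are acid levels (mL/L),
#'   values baseline viabilities in `[0, 1]`. `NA` entries are ignored.
#' @return The chosen acid level as a number.
#' @examples
#' select_stress_level(c(`1` = 0.60, `2.5` = 0.48, `5` = 0.30, `10` = 0.10))
#' @export
select_stress_level <- function(viabilities) {
  viabilities <- viabilities[!is.na(viabilities)]
  if (length(viabilities) == 0 || is.null(names(viabilities))) {
    stop("Need at least one named viability estimate.", call. = FALSE)
  }
  levels <- as.numeric(names(viabilities))
  # round the distance so exact ties survive floating point, then order by
  # distance and concentration so ties break toward the lower dose
  dist <- round(abs(viabilities - 0.5), 9)
  ord <- order(dist, levels)
  levels[ord[1]]
}
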