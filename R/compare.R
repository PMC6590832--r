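# Predictor comparison: single-predictor OLS fits with R^2 and F-tests, the
# encompassing (combined-model) comparison of pi vs expected F with
# partial-F/Wald tests, Welch and paired t contrasts, Holm correction.

#' Ordinary least-squares fit with overall F-test
#'
#' Fits `response ~ predictors` by OLS and reports the coefficient table,
#' R-squared, and the overall F-test against the intercept-only model.
#'
#' @param data A data frame.
#' @param response Name of the response column (string).
#' @param predictors Character vector of one or more predictor columns.
#' @return An object of class `ols_fit` with elements `coefficients`
#'   (tibble: `term`, `estimate`, `std_error`, `t_statistic`, `p_value`),
#'   `r_squared`, `residual_ss`, `total_ss`, `df_residual`, `f_statistic`,
#'   `df1`, `df2`, `p_value`, `n`, and the underlying `lm` object as `fit`.
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 + 3 * (1:10) + rnorm(10))
#' ols_fit(d, "y", "x")
#' @export
ols_fit <- function(data, response, predictors) {
  stopifnot(is.data.frame(data), length(response) == 1,
            length(predictors) >= 1,
            all(c(response, predictors) %in% names(data)))
  data <- stats::na.omit(data[, c(response, predictors)])
  n <- nrow(data)
  k <- length(predictors)
  if (n <= k + 1) stop("Need more observations than coefficients.",
                       call. = FALSE)
  x <- as.matrix(data[, predictors, drop = FALSE])
  if (k > 1 || any(apply(x, 2, stats::sd) == 0)) {
    if (qr(cbind(1, x))$rank < k + 1) {
      stop("Singular design: predictors are collinear.", call. = FALSE)
    }
  }
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = data)
  sm <- summary(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((data[[response]] - mean(data[[response]]))^2)
  fstat <- ((tss - rss) / k) / (rss / fit$df.residual)
  structure(
    list(
      coefficients = tibble::tibble(
        term = rownames(sm$coefficients),
        estimate = unname(sm$coefficients[, 1]),
        std_error = unname(sm$coefficients[, 2]),
        t_statistic = unname(sm$coefficients[, 3]),
        p_value = unname(sm$coefficients[, 4])
      ),
      r_squared = sm$r.squared,
      residual_ss = rss, total_ss = tss,
      df_residual = fit$df.residual,
      f_statistic = fstat, df1 = k, df2 = fit$df.residual,
      p_value = stats::pf(fstat, k, fit$df.residual, lower.tail = FALSE),
      n = n, response = response, predictors = predictors, fit = fit
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %s ~ %s  (n = %d)\n", x$response,
              paste(x$predictors, collapse = " + "), x$n))
  cat(sprintf("R^2 = %.4f, F(%d, %d) = %.3f, p = %.4g\n",
              x$r_squared, x$df1, x$df2, x$f_statistic, x$p_value))
  print(x$coefficients)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ols_fit <- function(x, ...) x$coefficients

#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, f_statistic = x$f_statistic,
                 df1 = x$df1, df2 = x$df2, p_value = x$p_value, n = x$n,
                 residual_ss = x$residual_ss, df_residual = x$df_residual)
}

#' Encompassing-model comparison of two non-nested predictors
#'
#' The two competing single-predictor models (here: diversity pi, or
#' expected inbreeding F) are nested inside the combined model
#' `response ~ a + b`. For each predictor, the Wald test of dropping it from
#' the combined model is computed as the partial F,
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (n - 3))` on df `(1, n - 3)`
#' (identical, for a single linear restriction in OLS, to the squared t of
#' that predictor's coefficient). A large partial F for a predictor means it
#' adds explanatory value beyond the other.
#'
#' @param data A data frame.
#' @param response Response column name (string).
#' @param a,b Names of the two competing predictor columns.
#' @return An object of class `encompassing`: the combined [ols_fit()] as
#'   `combined`, the single-predictor fits `fit_a`/`fit_b`, and `tests`
#'   (tibble: `dropped`, `partial_f`, `df1`, `df2`, `p_value`).
#' @examples
#' d <- tibble::tibble(pi = runif(30), f = runif(30),
#'                     y = 2 * pi + rnorm(30, 0, 0.1))
#' encompassing_test(d, "y", "pi", "f")
#' @export
encompassing_test <- function(data, response, a, b) {
  stopifnot(all(c(response, a, b) %in% names(data)))
  data <- stats::na.omit(tibble::as_tibble(data)[, c(response, a, b)])
  if (nrow(data) < 4) stop("Need at least 4 complete observations.",
                           call. = FALSE)
  if (abs(stats::cor(data[[a]], data[[b]])) > 1 - 1e-10) {
    stop("Singular design: the two predictors are collinear, the ",
         "comparison is unidentifiable.", call. = FALSE)
  }
  combined <- ols_fit(data, response, c(a, b))
  fit_a <- ols_fit(data, response, a)
  fit_b <- ols_fit(data, response, b)
  partial <- function(reduced) {
    f <- (reduced$residual_ss - combined$residual_ss) /
      (combined$residual_ss / combined$df_residual)
    tibble::tibble(partial_f = f, df1 = 1L, df2 = combined$df_residual,
                   p_value = stats::pf(f, 1, combined$df_residual,
                                       lower.tail = FALSE))
  }
  tests <- dplyr::bind_rows(
    dplyr::mutate(partial(fit_b), dropped = a, .before = 1), # drop a: keep b
    dplyr::mutate(partial(fit_a), dropped = b, .before = 1)
  )
  structure(list(combined = combined, fit_a = fit_a, fit_b = fit_b,
                 tests = tests, response = response, a = a, b = b),
            class = "encompassing")
}

#' @export
print.encompassing <- function(x, ...) {
  cat(sprintf("Encompassing model: %s ~ %s + %s  (n = %d)\n", x$response,
              x$a, x$b, x$combined$n))
  cat(sprintf("  R^2: combined %.3f | %s alone %.3f | %s alone %.3f\n",
              x$combined$r_squared, x$a, x$fit_a$r_squared, x$b,
              x$fit_b$r_squared))
  print(x$tests)
  invisible(x)
}

#' @export
tidy.encompassing <- function(x, ...) x$tests

#' @export
glance.encompassing <- function(x, ...) {
  tibble::tibble(r_squared_combined = x$combined$r_squared,
                 r_squared_a = x$fit_a$r_squared,
                 r_squared_b = x$fit_b$r_squared, n = x$combined$n)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t contrast with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value.
#'
#' @param sample_a,sample_b Numeric vectors (each >= 2 values with positive
#'   variance).
#' @return A tibble `t_statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @examples
#' welch_t(rnorm(10), rnorm(10, 1))
#' @export
welch_t <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 2 || length(sample_b) < 2 ||
      stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    stop("Both samples need >= 2 values and positive variance.",
         call. = FALSE)
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  tibble::tibble(t_statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 mean_a = mean(sample_a), mean_b = mean(sample_b))
}

#' Paired two-sample t-test
#'
#' One-sample t-test on paired differences, df = n - 1. Zero-variance
#' differences are flagged as undefined rather than raising an error.
#'
#' @param before,after Equal-length paired numeric vectors (n >= 2).
#' @return A tibble `t_statistic`, `df`, `p_value`, `mean_difference`,
#'   `undefined` (TRUE when the differences have zero variance, in which
#'   case the statistics are `NA`).
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after) || length(before) < 2) {
    stop("`before` and `after` must be equal-length vectors, n >= 2.",
         call. = FALSE)
  }
  d <- after - before
  if (stats::sd(d) == 0) {
    return(tibble::tibble(t_statistic = NA_real_,
                          df = length(d) - 1L, p_value = NA_real_,
                          mean_difference = mean(d), undefined = TRUE))
  }
  ht <- stats::t.test(after, before, paired = TRUE)
  tibble::tibble(t_statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 mean_difference = mean(d), undefined = FALSE)
}

#' Holm step-down (sequential Bonferroni) adjustment
#'
#' Sequentially rejective Bonferroni correction for a family of `m` tests;
#' `m` may exceed the number of p-values supplied (e.g. when only part of a
#' planned family is being adjusted).
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param m Family size (default `length(p_values)`).
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_correction(c(0.01, 0.04, 0.03)) # 0.03 0.06 0.06
#' @export
holm_correction <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  if (m < length(p_values)) {
    stop("Family size `m` must be >= the number of p-values.", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm", n = m)
}

#' Compare diversity against expected inbreeding as response predictors
#'
#' The headline analysis: for each evolutionary-response measure (trait
#' slopes and per-medium viability changes), fit the two single-predictor
#' models (`response ~ pi` and `response ~ expected F`), report their
#' R-squared and overall F-tests, and run the encompassing-model Wald
#' (partial-F) tests of each predictor's added value in the combined model.
#' Group contrasts of diversity (outbred vs each inbreeding level, and
#' extinct vs surviving lines) are tested with Welch's t and Holm-adjusted.
#'
#' Only eligible lines enter the regressions: not extinct, with a diversity
#' estimate, and (for slopes) with a reported slope.
#'
#' @param slopes Tibble from [response_slopes()].
#' @param deltas Tibble from [viability_change()] (may be empty).
#' @param diversity Tibble from [estimate_diversity()] (needs `line_id`,
#'   `pi_relative`).
#' @param lines Manifest with `line_id`, `group`, `expected_f`,
#'   `extinction_gen`.
#' @param alpha Significance level used for flags (default 0.05).
#' @param family_size Family size for the Holm adjustment of the group
#'   contrasts (default: the number of contrasts performed).
#' @param min_lines Refuse to fit with fewer eligible lines than this
#'   (default 10).
#' @return An object of class `predictor_comparison`: `models` (one row per
#'   response measure and predictor: `response`, `predictor`, `r_squared`,
#'   `f_statistic`, `df1`, `df2`, `p_value`, `partial_f`, `partial_df2`,
#'   `partial_p`, `coefficient`), `contrasts` (Welch tests with `p_holm`),
#'   `n_eligible`, `alpha`, and `data` (the merged analysis table).
#' @export
compare_predictors <- function(slopes, deltas, diversity, lines,
                               alpha = 0.05, family_size = NULL,
                               min_lines = 10) {
  stopifnot(all(c("line_id", "group", "expected_f", "extinction_gen") %in%
                  names(lines)),
            all(c("line_id", "pi_relative") %in% names(diversity)))
  lines <- tibble::as_tibble(lines)
  merged <- lines |>
    dplyr::left_join(dplyr::select(diversity, "line_id", "pi_relative",
                                   dplyr::any_of("pi_sum")),
                     by = "line_id")
  eligible <- merged |>
    dplyr::filter(is.na(.data$extinction_gen), !is.na(.data$pi_relative))
  if (nrow(eligible) < min_lines) {
    stop(sprintf(paste0("Only %d eligible lines (non-extinct with a ",
                        "diversity estimate); at least %d required."),
                 nrow(eligible), min_lines), call. = FALSE)
  }

  responses <- list()
  if (nrow(slopes) > 0) {
    for (tr in unique(slopes$trait)) {
      responses[[paste0("slope_", tr)]] <- slopes |>
        dplyr::filter(.data$trait == tr, !is.na(.data$slope)) |>
        dplyr::select("line_id", value = "slope")
    }
  }
  if (!is.null(deltas) && nrow(deltas) > 0) {
    for (md in unique(deltas$medium)) {
      responses[[paste0("viability_", md)]] <- deltas |>
        dplyr::filter(.data$medium == md) |>
        dplyr::select("line_id", value = "delta")
    }
  }

  models <- purrr::imap_dfr(responses, function(resp, label) {
    d <- dplyr::inner_join(eligible, resp, by = "line_id")
    if (nrow(d) < min_lines) return(NULL)
    enc <- encompassing_test(d, "value", "pi_relative", "expected_f")
    single <- list(pi = enc$fit_a, expected_f = enc$fit_b)
    purrr::imap_dfr(single, function(fit, pred) {
      dropped_col <- if (pred == "pi") "pi_relative" else "expected_f"
      pt <- dplyr::filter(enc$tests, .data$dropped == dropped_col)
      tibble::tibble(
        response = label, predictor = pred, n = fit$n,
        coefficient = fit$coefficients$estimate[2],
        r_squared = fit$r_squared, f_statistic = fit$f_statistic,
        df1 = fit$df1, df2 = fit$df2, p_value = fit$p_value,
        partial_f = pt$partial_f, partial_df2 = pt$df2,
        partial_p = pt$p_value
      )
    })
  })

  # diversity contrasts: OB vs each inbred group; extinct vs survived
  with_pi <- dplyr::filter(merged, !is.na(.data$pi_relative))
  contrasts <- list()
  ob <- with_pi$pi_relative[with_pi$group == "OB"]
  for (g in intersect(c("Low", "Medium", "High"), unique(with_pi$group))) {
    smp <- with_pi$pi_relative[with_pi$group == g]
    if (length(ob) >= 2 && length(smp) >= 2) {
      contrasts[[paste0("OB_vs_", g)]] <- welch_t(ob, smp)
    }
  }
  ext <- with_pi$pi_relative[!is.na(with_pi$extinction_gen)]
  srv <- with_pi$pi_relative[is.na(with_pi$extinction_gen)]
  if (length(ext) >= 2 && length(srv) >= 2) {
    contrasts[["extinct_vs_survived"]] <- welch_t(ext, srv)
  }
  contrasts <- purrr::imap_dfr(contrasts, function(x, nm) {
    dplyr::mutate(x, contrast = nm, .before = 1)
  })
  if (nrow(contrasts) > 0) {
    m <- family_size %||% nrow(contrasts)
    contrasts$p_holm <- holm_correction(contrasts$p_value, m = m)
    contrasts$significant <- contrasts$p_holm < alpha
  }

  response_values <- purrr::imap_dfr(responses, function(resp, label) {
    dplyr::mutate(resp, response = label, .before = 1)
  })
  structure(list(models = models, contrasts = contrasts,
                 n_eligible = nrow(eligible), alpha = alpha,
                 data = merged, response_values = response_values),
            class = "predictor_comparison")
}

#' @export
print.predictor_comparison <- function(x, ...) {
  cat(sprintf("Predictor comparison over %d eligible lines\n", x$n_eligible))
  print(dplyr::select(x$models, "response", "predictor", "r_squared",
                      "f_statistic", "p_value", "partial_f", "partial_p"))
  if (nrow(x$contrasts) > 0) {
    cat("Group contrasts of relative diversity:\n")
    print(dplyr::select(x$contrasts, "contrast", "t_statistic", "df",
                        "p_value", "p_holm"))
  }
  invisible(x)
}

#' @export
tidy.predictor_comparison <- function(x, ...) x$models

#' @export
glance.predictor_comparison <- function(x, ...) {
  x$models |>
    dplyr::select("response", "predictor", "r_squared") |>
    tidyr::pivot_wider(names_from = "predictor", values_from = "r_squared",
                       names_prefix = "r_squared_") |>
    dplyr::mutate(n_eligible = x$n_eligible)
}
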