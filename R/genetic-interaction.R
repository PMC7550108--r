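#' Daily vegetative growth rates from front measurements
#'
#' Growth fronts are recorded 24 h and 48 h after inoculation; the daily
#' rate is the front advance over that second day (the first day is treated
#' as acclimation and excluded). Technical replicates are averaged within
#' each biological replicate, which is the unit of replication for all
#' downstream inference.
#'
#' @param growth Tibble with columns `strain`, `bio_rep`, `tech_rep`,
#'   `front_mm_24h`, `front_mm_48h`.
#' @return A tibble `strain`, `bio_rep`, `rate_mm_day` (one row per
#'   biological replicate).
#' @export
growth_rates <- function(growth) {
  need <- c("strain", "bio_rep", "front_mm_24h", "front_mm_48h")
  miss <- setdiff(need, names(growth))
  if (length(miss)) {
    rlang::abort(paste0("growth table is missing column(s): ",
      paste(miss, collapse = ", ")), class = "stripakr_format_error")
  }
  adv <- growth$front_mm_48h - growth$front_mm_24h
  if (any(adv <= 0, na.rm = TRUE)) {
    rlang::abort("non-positive front advance between 24 h and 48 h",
      class = "stripakr_validation_error")
  }
  growth |>
    dplyr::mutate(rate_mm_day = .data$front_mm_48h - .data$front_mm_24h) |>
    dplyr::group_by(.data$strain, .data$bio_rep) |>
    dplyr::summarise(rate_mm_day = mean(.data$rate_mm_day), .groups = "drop")
}

#' Growth rates relative to the wild type
#'
#' Every biological replicate's rate is divided by the mean rate of the
#' reference strain, so the reference strain itself has a relative rate of
#' exactly 1. The reported per-strain standard deviation is the dispersion
#' of the replicate relative rates.
#'
#' @param growth Raw growth tibble (see [growth_rates()]) or its per-
#'   biological-replicate output.
#' @param reference Reference strain label; default `"wt"`.
#' @return A tibble `strain`, `rel_rate`, `rel_sd`, `n_rep`, plus the
#'   per-replicate relative rates in the `"replicates"` attribute.
#' @export
relative_growth <- function(growth, reference = "wt") {
  rates <- if ("rate_mm_day" %in% names(growth)) growth else growth_rates(growth)
  if (!reference %in% rates$strain) {
    rlang::abort(paste0("reference strain '", reference, "' absent from growth data"),
      class = "stripakr_validation_error")
  }
  ref_mean <- mean(rates$rate_mm_day[rates$strain == reference])
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    rlang::abort("reference strain mean rate must be positive",
      class = "stripakr_validation_error")
  }
  reps <- dplyr::mutate(rates, rel_rate = .data$rate_mm_day / ref_mean)
  out <- reps |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(
      rel_rate = mean(.data$rel_rate),
      rel_sd = stats::sd(.data$rel_rate),
      n_rep = dplyr::n(), .groups = "drop"
    )
  attr(out, "replicates") <- reps
  out
}

#' Expected double-mutant fitness under the multiplicative model
#'
#' The null expectation for a double mutant's relative growth rate is the
#' product of the single mutants' relative rates (wild type = 1). Deviations
#' from this product define genetic interaction: observed above expected is
#' a positive interaction, below is negative.
#'
#' @param rel_a,rel_b Relative growth rates of the two single mutants
#'   (non-negative; vectorized).
#' @param digits Decimals for the reported value; default 3. Use `NA` for
#'   the unrounded product.
#' @return Expected relative rate(s) of the double mutant.
#' @examples
#' expected_double(0.494, 0.413)  # 0.204
#' expected_double(0.494, 0.189)  # 0.093
#' @export
expected_double <- function(rel_a, rel_b, digits = 3) {
  if (any(rel_a < 0, na.rm = TRUE) || any(rel_b < 0, na.rm = TRUE)) {
    rlang::abort("relative rates must be non-negative", class = "stripakr_validation_error")
  }
  out <- rel_a * rel_b
  if (!is.na(digits)) out <- round(out, digits)
  out
}

#' One-tailed t-test of observed double-mutant rates against the expectation
#'
#' The multiplicative expectation is a derived constant (there is no
#' replicate-level expected value), so the paired contrast reduces to a
#' one-sample t-test of the observed replicate relative rates against that
#' constant, one-tailed in the direction of the observed deviation. With all
#' observations equal to the expectation the p-value is 0.5 (null case);
#' with zero replicate variance but a non-zero deviation, the p-value is
#' reported as 0 with a degenerate-variance flag.
#'
#' @param observed_reps Numeric vector of observed replicate relative rates
#'   (at least 2).
#' @param expected Expected relative rate.
#' @param alternative `"auto"` (default) picks the tail from the sign of the
#'   observed deviation; `"greater"`/`"less"` test a pre-specified
#'   interaction direction (positive/negative GI hypothesis). Note the
#'   data-adaptive tail doubles the null rejection rate relative to a fixed
#'   tail, so calibration statements at level `alpha` hold for pre-specified
#'   directions.
#' @return A one-row tibble `observed`, `expected`, `statistic`, `df`,
#'   `p_value`, `direction` (`"above"`/`"below"`/`"equal"`), `degenerate`.
#' @export
gi_test <- function(observed_reps, expected,
                    alternative = c("auto", "greater", "less")) {
  alternative <- match.arg(alternative)
  observed_reps <- observed_reps[!is.na(observed_reps)]
  if (length(observed_reps) < 2) {
    rlang::abort("at least 2 observed replicates are required",
      class = "stripakr_insufficient_data_error")
  }
  m <- mean(observed_reps)
  s <- stats::sd(observed_reps)
  n <- length(observed_reps)
  direction <- if (m > expected) "above" else if (m < expected) "below" else "equal"
  if (s == 0) {
    degen <- m != expected
    return(tibble::tibble(
      observed = m, expected = expected,
      statistic = if (degen) Inf * sign(m - expected) else 0,
      df = n - 1,
      p_value = if (degen) 0 else 0.5,
      direction = direction, degenerate = degen
    ))
  }
  alt <- if (alternative == "auto") {
    if (direction == "below") "less" else "greater"
  } else {
    alternative
  }
  tt <- stats::t.test(observed_reps, mu = expected, alternative = alt)
  tibble::tibble(
    observed = m, expected = expected,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, direction = direction, degenerate = FALSE
  )
}

#' Classify a genetic interaction
#'
#' @param observed Mean observed relative rate of the double mutant.
#' @param expected Multiplicative expectation.
#' @param p_value One-tailed p-value from [gi_test()].
#' @param alpha Significance level; default 0.05.
#' @return `"positive"`, `"negative"`, or `"none"`.
#' @export
classify_gi <- function(observed, expected, p_value, alpha = 0.05) {
  dplyr::case_when(
    is.na(p_value) ~ NA_character_,
    p_value <= alpha & observed > expected ~ "positive",
    p_value <= alpha & observed < expected ~ "negative",
    TRUE ~ "none"
  )
}

#' Genetic-interaction analysis of growth assays
#'
#' End-to-end multiplicative genetic-interaction analysis: daily rates per
#' biological replicate, relative rates versus the wild type, multiplicative
#' expectations for each double mutant, one-tailed tests, and interaction
#' classification.
#'
#' @param growth Growth tibble (`strain`, `bio_rep`, `tech_rep`,
#'   `front_mm_24h`, `front_mm_48h`).
#' @param doubles Tibble with columns `double`, `single_a`, `single_b`
#'   naming each double-mutant strain and its two single mutants; all three
#'   must appear in `growth`.
#' @param reference Reference strain; default `"wt"`.
#' @param alpha Significance level for classification; default 0.05.
#' @return A `gi_fit` object: list with elements `rates` (relative growth
#'   tibble), `results` (one row per double mutant: expectation, observation,
#'   test, classification), `reference`, `alpha`. Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`.
#' @export
gi_analysis <- function(growth, doubles, reference = "wt", alpha = 0.05) {
  need <- c("double", "single_a", "single_b")
  miss <- setdiff(need, names(doubles))
  if (length(miss)) {
    rlang::abort(paste0("doubles table is missing column(s): ",
      paste(miss, collapse = ", ")), class = "stripakr_format_error")
  }
  rates <- relative_growth(growth, reference = reference)
  reps <- attr(rates, "replicates")
  strains_needed <- unique(c(doubles$double, doubles$single_a, doubles$single_b))
  miss_s <- setdiff(strains_needed, rates$strain)
  if (length(miss_s)) {
    rlang::abort(paste0("strain(s) absent from growth data: ",
      paste(miss_s, collapse = ", ")), class = "stripakr_validation_error")
  }
  rate_of <- function(s) rates$rel_rate[match(s, rates$strain)]
  results <- purrr::pmap_dfr(doubles, function(double, single_a, single_b, ...) {
    expected <- expected_double(rate_of(single_a), rate_of(single_b))
    obs_reps <- reps$rel_rate[reps$strain == double]
    test <- gi_test(obs_reps, expected)
    tibble::tibble(
      double = double, single_a = single_a, single_b = single_b,
      rel_a = rate_of(single_a), rel_b = rate_of(single_b),
      expected = expected,
      observed = test$observed, observed_sd = stats::sd(obs_reps),
      statistic = test$statistic, df = test$df, p_value = test$p_value,
      degenerate = test$degenerate,
      classification = classify_gi(test$observed, expected, test$p_value, alpha)
    )
  })
  structure(
    list(rates = rates, results = results, reference = reference, alpha = alpha),
    class = "gi_fit"
  )
}

#' @export
print.gi_fit <- function(x, ...) {
  cat("Genetic-interaction analysis (multiplicative model, reference '",
    x$reference, "', alpha ", x$alpha, ")\n\n", sep = "")
  print(x$results)
  invisible(x)
}

#' @rdname gi_analysis
#' @param x,object A `gi_fit` object.
#' @param ... Unused.
#' @method tidy gi_fit
#' @export
tidy.gi_fit <- function(x, ...) x$results

#' @rdname gi_analysis
#' @method glance gi_fit
#' @export
glance.gi_fit <- function(x, ...) {
  tibble::tibble(
    n_strains = nrow(x$rates),
    n_doubles = nrow(x$results),
    n_positive = sum(x$results$classification == "positive", na.rm = TRUE),
    n_negative = sum(x$results$classification == "negative", na.rm = TRUE),
    alpha = x$alpha
  )
}

#' @rdname gi_analysis
#' @method autoplot gi_fit
#' @export
autoplot.gi_fit <- function(object, ...) {
  obs <- object$rates |>
    dplyr::transmute(strain = .data$strain, value = .data$rel_rate,
      sd = .data$rel_sd, kind = "observed")
  exp <- object$results |>
    dplyr::transmute(strain = paste0(.data$double, " (expected)"),
      value = .data$expected, sd = NA_real_, kind = "expected")
  df <- dplyr::bind_rows(obs, exp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strain, y = .data$value, fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$sd, ymax = .data$value + .data$sd),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::scale_fill_manual(values = c(observed = "#1f4e79", expected = "#9dc3e6")) +
    ggplot2::labs(x = NULL, y = "relative growth rate (wild type = 1)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
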