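#' Channel correction factors from summed total intensities
#'
#' Systematic labelling bias between iTRAQ channels is corrected by a single
#' multiplicative factor per channel derived from the summed total intensity
#' of that channel: `factor_k = mean(channel totals) / total_k`. After
#' multiplying each channel by its factor, all channel sums are equal.
#'
#' @param data Quantification tibble.
#' @param channel_map Channel map.
#' @return A tibble with columns `channel`, `total_intensity`, `factor`.
#' @examples
#' tab <- tibble::tibble(protein_id = c("a", "b"), n_unique_peptides = 2,
#'   c1 = c(40, 60), c2 = c(150, 50))
#' cm <- channel_map(c("c1", "c2"), c("wt", "mut"), c(1, 1))
#' compute_channel_factors(tab, cm)  # totals 100, 200 -> factors 1.5, 0.75
#' @export
compute_channel_factors <- function(data, channel_map) {
  chans <- channel_map$channel
  miss <- setdiff(chans, names(data))
  if (length(miss)) {
    rlang::abort(paste0("missing channel column(s): ", paste(miss, collapse = ", ")),
      class = "stripakr_format_error")
  }
  totals <- vapply(chans, function(ch) sum(data[[ch]], na.rm = TRUE), numeric(1))
  if (any(totals <= 0)) {
    rlang::abort(paste0("channel(s) with zero total intensity: ",
      paste(chans[totals <= 0], collapse = ", ")),
      class = "stripakr_degenerate_error")
  }
  tibble::tibble(channel = chans, total_intensity = unname(totals),
    factor = mean(totals) / unname(totals))
}

#' Apply channel correction factors
#'
#' Multiplies each channel column by its factor. With factors from
#' [compute_channel_factors()] this equalizes channel sums exactly, making
#' downstream ratios invariant to rescaling any raw channel by a positive
#' constant.
#'
#' @param data Quantification tibble.
#' @param channel_map Channel map.
#' @param factors Factor tibble; computed from `data` when omitted. Pass the
#'   factors of the global proteome run to normalize a phosphopeptide table
#'   with the proteome-derived correction, as the study design prescribes.
#' @return `data` with normalized channel columns.
#' @export
normalize_channels <- function(data, channel_map, factors = NULL) {
  factors <- factors %||% compute_channel_factors(data, channel_map)
  for (i in seq_len(nrow(factors))) {
    ch <- factors$channel[[i]]
    if (ch %in% names(data)) data[[ch]] <- data[[ch]] * factors$factor[[i]]
  }
  data
}

phospho_feature_id <- function(data) {
  paste0(data$peptide_sequence, "@", data$site_positions)
}

#' Replicate-averaged log2 ratios of mutant versus wild type
#'
#' For each feature and each mutant condition: average the normalized
#' intensities over the condition's biological-replicate channels and over
#' the reference channels (arithmetic mean of observed values; a feature
#' missing in one replicate is averaged over the remaining ones), then take
#' `log2(condition mean / reference mean)`. The ratio is `NA` when either
#' mean is undefined; a zero reference mean yields `NA` with a warning, not
#' an error.
#'
#' Protein features are keyed by `protein_id`; phosphopeptide features by
#' peptide sequence plus its phospho-site set (multiple sites on one peptide
#' are one feature for calling, and fan out to individual sites only during
#' aggregation).
#'
#' @param data Normalized quantification tibble.
#' @param channel_map Channel map.
#' @param conditions Mutant strains to ratio against the reference; default
#'   all non-reference strains in the map.
#' @param reference Reference strain; default the map's reference.
#' @return A long tibble: `feature_id`, `protein_id`, `condition`,
#'   `log2_ratio`.
#' @export
condition_log2_ratios <- function(data, channel_map, conditions = NULL,
                                  reference = reference_strain(channel_map)) {
  strains <- unique(channel_map$strain)
  if (!reference %in% strains) {
    rlang::abort(paste0("reference strain '", reference, "' not in channel map"),
      class = "stripakr_validation_error")
  }
  conditions <- conditions %||% setdiff(strains, reference)
  bad <- setdiff(conditions, strains)
  if (length(bad)) {
    rlang::abort(paste0("condition(s) not in channel map: ", paste(bad, collapse = ", ")),
      class = "stripakr_validation_error")
  }
  level <- quant_level(data)
  feature_id <- if (level == "protein") data$protein_id else phospho_feature_id(data)
  protein_id <- data$protein_id

  ref_chans <- map_channels(channel_map, reference)
  ref_mean <- rowMeans(as.matrix(data[ref_chans]), na.rm = TRUE)
  ref_mean[is.nan(ref_mean)] <- NA_real_
  n_zero_ref <- sum(ref_mean == 0, na.rm = TRUE)
  if (n_zero_ref > 0) {
    rlang::warn(paste0(n_zero_ref, " feature(s) with zero reference mean; ",
      "their log2 ratios are reported as missing"))
    ref_mean[!is.na(ref_mean) & ref_mean == 0] <- NA_real_
  }

  purrr::map_dfr(conditions, function(cond) {
    cond_chans <- map_channels(channel_map, cond)
    cond_mean <- rowMeans(as.matrix(data[cond_chans]), na.rm = TRUE)
    cond_mean[is.nan(cond_mean)] <- NA_real_
    tibble::tibble(
      feature_id = feature_id,
      protein_id = protein_id,
      condition = cond,
      log2_ratio = log2(cond_mean / ref_mean)
    )
  })
}

#' Per-condition spread of the log2-ratio distribution
#'
#' The call threshold of the regulation rule is two sample standard
#' deviations of all features' log2 ratios within a condition, computed once
#' over the full distribution (no iterative exclusion of called features).
#'
#' @param ratios Long ratio tibble from [condition_log2_ratios()].
#' @return A tibble `condition`, `n`, `sd`, `threshold` (`= 2 * sd`).
#' @export
estimate_condition_sd <- function(ratios) {
  out <- ratios |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = sum(!is.na(.data$log2_ratio)),
      sd = stats::sd(.data$log2_ratio, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(threshold = 2 * .data$sd)
  if (any(out$n < 2)) {
    rlang::abort(paste0("fewer than 2 non-missing ratios in condition(s): ",
      paste(out$condition[out$n < 2], collapse = ", ")),
      class = "stripakr_insufficient_data_error")
  }
  out
}

#' Score ratios and call regulation by the 2xSD rule
#'
#' The regulation score is the log2 ratio divided by the condition's standard
#' deviation; a feature is regulated when `|score| >= call_threshold` with the
#' score first rounded to `digits` decimals, so that a score printing as
#' exactly 2.00 counts as regulated (inclusive comparison at printed
#' precision). A condition with `sd = 0` cannot support a call: its features
#' get `regulated = NA` and `degenerate_sd = TRUE`.
#'
#' @param ratios Long ratio tibble (`feature_id`, `condition`, `log2_ratio`,
#'   optionally `protein_id`).
#' @param stats Per-condition stats from [estimate_condition_sd()], or a
#'   tibble with columns `condition` and `sd` to impose externally fixed
#'   standard deviations (as in worked examples with published SDs). Computed
#'   from `ratios` when omitted.
#' @param call_threshold Absolute score at or above which a feature is
#'   regulated; default 2.
#' @param digits Rounding applied to the score before the comparison (and in
#'   written outputs); default 2.
#' @return `ratios` with added columns `sd`, `score`, `regulated`,
#'   `degenerate_sd`.
#' @examples
#' r <- tibble::tibble(feature_id = "S180", condition = "pro11", log2_ratio = 1.35)
#' s <- tibble::tibble(condition = "pro11", sd = 0.62)
#' score_and_call(r, s)  # score 2.18, regulated
#' @export
score_and_call <- function(ratios, stats = NULL, call_threshold = 2, digits = 2) {
  stats <- stats %||% estimate_condition_sd(ratios)
  out <- dplyr::left_join(ratios, dplyr::select(stats, "condition", "sd"),
    by = "condition")
  if (any(is.na(out$sd))) {
    rlang::abort(paste0("no SD available for condition(s): ",
      paste(unique(out$condition[is.na(out$sd)]), collapse = ", ")),
      class = "stripakr_validation_error")
  }
  out |>
    dplyr::mutate(
      degenerate_sd = .data$sd == 0,
      score = dplyr::if_else(.data$degenerate_sd, NA_real_, .data$log2_ratio / .data$sd),
      regulated = dplyr::if_else(.data$degenerate_sd, NA,
        round(abs(.data$score), digits) >= call_threshold)
    )
}

#' Gate phosphopeptide calls against the global proteome
#'
#' A phosphorylation-level change is only credible when the parent protein's
#' overall abundance did not change: a regulated phosphopeptide keeps its
#' call only if its protein is quantified in the global proteome and is not
#' regulated there in the same condition. Peptides whose protein was
#' regulated are demoted to a protein-level change; peptides whose protein
#' is absent from the proteome table are reported as "unanchored" and
#' excluded from the gated regulated set.
#'
#' @param phospho_calls Scored phosphopeptide calls (from [score_and_call()];
#'   must carry `protein_id`).
#' @param protein_calls Scored protein calls.
#' @return `phospho_calls` with columns `protein_regulated`, `gate_status`
#'   (one of `"not_regulated"`, `"regulated"`, `"protein_level"`,
#'   `"unanchored"`) and the gated call `regulated_gated`.
#' @export
gate_phospho_by_global <- function(phospho_calls, protein_calls) {
  prot <- protein_calls |>
    dplyr::select("protein_id", "condition", protein_regulated = "regulated")
  out <- dplyr::left_join(phospho_calls, prot, by = c("protein_id", "condition"))
  in_proteome <- phospho_calls$protein_id %in% unique(protein_calls$protein_id)
  out |>
    dplyr::mutate(
      gate_status = dplyr::case_when(
        !.data$regulated | is.na(.data$regulated) ~ "not_regulated",
        !in_proteome ~ "unanchored",
        .data$protein_regulated %in% TRUE ~ "protein_level",
        TRUE ~ "regulated"
      ),
      regulated_gated = .data$gate_status == "regulated"
    )
}
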