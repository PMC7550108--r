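#' Read a protein or phosphopeptide quantification table
#'
#' Parses a tab-separated reporter-ion quantification table, as exported from
#' an MS search pipeline after identification scoring. Protein-level tables
#' need columns `protein_id`, `n_unique_peptides` and one intensity column per
#' channel; phosphopeptide tables need `peptide_sequence`, `protein_id`,
#' `site_positions` (semicolon-joined, 1-based protein coordinates),
#' `site_residues` (semicolon-joined letters from S/T/Y),
#' `localization_probs` (semicolon-joined fractions), optionally `psm_rank`
#' (defaults to 1 when absent), and the channel columns.
#'
#' Blank intensity cells become `NA`, never zero: a missing reporter ion is
#' unobserved, and imputing zero would bias every downstream log ratio.
#'
#' @param path Path to a tab-separated file.
#' @param level `"protein"` or `"phosphopeptide"`.
#' @param channel_map Channel map (see [channel_map()]); every channel listed
#'   there must be a column of the file, in particular the reference-strain
#'   channels.
#' @return A tibble with the identification columns followed by one numeric
#'   intensity column per channel.
#' @export
read_quant_table <- function(path, level = c("protein", "phosphopeptide"), channel_map) {
  level <- match.arg(level)
  if (!file.exists(path)) {
    rlang::abort(paste0("quantification table not found: ", path), class = "stripakr_io_error")
  }
  data <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
    na = c("", "NA"))
  required <- setdiff(id_cols(level), "psm_rank")
  miss <- setdiff(required, names(data))
  if (length(miss)) {
    rlang::abort(
      paste0("missing required column(s) for ", level, " table: ",
        paste(miss, collapse = ", ")),
      class = "stripakr_format_error"
    )
  }
  miss_chan <- setdiff(channel_map$channel, names(data))
  if (length(miss_chan)) {
    ref <- reference_strain(channel_map)
    ref_missing <- intersect(miss_chan, map_channels(channel_map, ref))
    msg <- if (length(ref_missing)) {
      paste0("missing channel column(s) ", paste(miss_chan, collapse = ", "),
        " including reference strain '", ref, "' channel(s) ",
        paste(ref_missing, collapse = ", "))
    } else {
      paste0("missing channel column(s): ", paste(miss_chan, collapse = ", "))
    }
    rlang::abort(msg, class = "stripakr_format_error")
  }
  if (level == "phosphopeptide" && !"psm_rank" %in% names(data)) {
    data$psm_rank <- 1L
  }
  data <- dplyr::mutate(data, dplyr::across(dplyr::all_of(channel_map$channel), as.numeric))
  validate_quant_table(data, channel_map, level)
  dplyr::select(data, dplyr::all_of(id_cols(level)), dplyr::all_of(channel_map$channel),
    dplyr::everything())
}

#' Validate a quantification tibble against its channel map
#'
#' Checks the invariants the analysis relies on: identification columns
#' present, intensities numeric and non-negative where observed, unique
#' protein accessions at protein level, and consistent site annotation
#' (equal numbers of positions, residues and localization probabilities,
#' residues within S/T/Y, probabilities within \[0, 1\]).
#'
#' @inheritParams read_quant_table
#' @param data Quantification tibble.
#' @return `data`, invisibly, if valid; otherwise an error.
#' @export
validate_quant_table <- function(data, channel_map, level = quant_level(data)) {
  miss <- setdiff(setdiff(id_cols(level), "psm_rank"), names(data))
  if (length(miss)) {
    rlang::abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
      class = "stripakr_format_error")
  }
  chans <- channel_cols(data, channel_map)
  for (ch in chans) {
    v <- data[[ch]]
    if (!is.numeric(v)) {
      rlang::abort(paste0("channel column '", ch, "' is not numeric"),
        class = "stripakr_validation_error")
    }
    if (any(v < 0, na.rm = TRUE)) {
      rlang::abort(paste0("negative intensity in channel '", ch, "'"),
        class = "stripakr_validation_error")
    }
  }
  if (level == "protein") {
    if (anyDuplicated(data$protein_id)) {
      dup <- unique(data$protein_id[duplicated(data$protein_id)])
      rlang::abort(paste0("duplicate protein_id at protein level: ",
        paste(utils::head(dup, 3), collapse = ", ")),
        class = "stripakr_validation_error")
    }
    if (any(data$n_unique_peptides < 0, na.rm = TRUE)) {
      rlang::abort("n_unique_peptides must be non-negative",
        class = "stripakr_validation_error")
    }
  } else {
    pos <- split_field(data$site_positions)
    res <- split_field(data$site_residues)
    prob <- split_field(data$localization_probs)
    n_pos <- lengths(pos); n_res <- lengths(res); n_prob <- lengths(prob)
    bad <- which(n_pos != n_res | n_pos != n_prob)
    if (length(bad)) {
      rlang::abort(paste0("inconsistent site annotation in row(s) ",
        paste(utils::head(bad, 3), collapse = ", "),
        ": site_positions, site_residues and localization_probs must align"),
        class = "stripakr_validation_error")
    }
    all_res <- unlist(res)
    if (!all(all_res %in% c("S", "T", "Y"))) {
      rlang::abort("site_residues must be S, T or Y", class = "stripakr_validation_error")
    }
    all_prob <- suppressWarnings(as.numeric(unlist(prob)))
    if (any(is.na(all_prob)) || any(all_prob < 0 | all_prob > 1)) {
      rlang::abort("localization probabilities must be numbers in [0, 1]",
        class = "stripakr_validation_error")
    }
    if (any(data$psm_rank < 1, na.rm = TRUE)) {
      rlang::abort("psm_rank must be a positive integer", class = "stripakr_validation_error")
    }
  }
  invisible(data)
}

#' Apply the identification-level filters
#'
#' Protein level: keep proteins identified by at least `min_unique_peptides`
#' unique peptides. Phosphopeptide level: keep peptides whose every phospho
#' site is localized with probability at least `min_localization_prob` and
#' whose peptide-spectrum match is rank 1. These are pure identification
#' filters: intensities pass through untouched, row order is preserved, and
#' applying the filter twice changes nothing.
#'
#' @param data Quantification tibble.
#' @param min_unique_peptides Minimum unique peptide count per protein
#'   (protein level only). Default 2.
#' @param min_localization_prob Minimum per-site localization probability
#'   (phosphopeptide level only). Default 0.90.
#' @param level Table level; inferred from the columns when omitted.
#' @return The filtered tibble.
#' @examples
#' tab <- tibble::tibble(
#'   protein_id = c("a", "b", "c"), n_unique_peptides = c(1, 2, 5),
#'   `113` = c(1, 1, 1), `114` = c(2, 2, 2)
#' )
#' filter_identifications(tab)  # drops "a"
#' @export
filter_identifications <- function(data, min_unique_peptides = 2,
                                   min_localization_prob = 0.90,
                                   level = quant_level(data)) {
  stopifnot(min_unique_peptides >= 0,
    min_localization_prob >= 0, min_localization_prob <= 1)
  if (level == "protein") {
    dplyr::filter(data, .data$n_unique_peptides >= min_unique_peptides)
  } else {
    min_prob <- purrr::map_dbl(split_field(data$localization_probs),
      function(p) min(as.numeric(p)))
    keep <- min_prob >= min_localization_prob & data$psm_rank <= 1
    data[keep, , drop = FALSE]
  }
}

#' Write a results table as tab-separated text
#'
#' Deterministic output: stable column order (as given), ratio/score columns
#' rounded to a configured number of decimals, and missing values written as
#' empty cells rather than the text "NA".
#'
#' @param data Tibble of results.
#' @param path Output path.
#' @param digits Decimals for numeric columns; `NA` leaves numbers unrounded.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(data, path, digits = 4) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    rlang::abort(paste0("output directory does not exist: ", dir),
      class = "stripakr_io_error")
  }
  out <- data
  if (!is.na(digits)) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.double), ~ round(.x, digits)))
  }
  readr::write_tsv(out, path, na = "")
  invisible(path)
}
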