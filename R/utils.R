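#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# level of a quant tibble, inferred from its identification columns
quant_level <- function(data) {
  if ("peptide_sequence" %in% names(data)) "phosphopeptide" else "protein"
}

id_cols <- function(level) {
  if (level == "protein") {
    c("protein_id", "n_unique_peptides")
  } else {
    c("peptide_sequence", "protein_id", "site_positions", "site_residues",
      "localization_probs", "psm_rank")
  }
}

channel_cols <- function(data, channel_map) {
  intersect(channel_map$channel, names(data))
}

# split a semicolon-joined field into a vector
split_field <- function(x) strsplit(as.character(x), ";", fixed = TRUE)
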