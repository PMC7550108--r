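#' Build and validate an iTRAQ channel map
#'
#' A channel map assigns every reporter-ion channel of a multiplexed run to a
#' strain and a biological replicate. The study design this package targets is
#' an iTRAQ 8-plex with two biological replicates for each of four strains
#' (wild type plus three deletion mutants), but any plex size with at least
#' one channel per strain is accepted.
#'
#' @param channel Character vector of channel identifiers (e.g. `"113"`).
#'   Must be unique.
#' @param strain Character vector, the strain labelled in each channel.
#' @param replicate Positive integer vector, the biological replicate number.
#' @param reference Label of the reference strain (wild type). It must occur
#'   in `strain`.
#'
#' @return A tibble with columns `channel`, `strain`, `replicate` and the
#'   reference strain stored in the `"reference"` attribute.
#' @examples
#' channel_map(
#'   channel   = as.character(c(113:119, 121)),
#'   strain    = rep(c("wt", "pro11", "pp2Ac1pro22", "pro11pro22"), each = 2),
#'   replicate = rep(1:2, times = 4)
#' )
#' @export
channel_map <- function(channel, strain, replicate, reference = "wt") {
  channel <- as.character(channel)
  strain <- as.character(strain)
  replicate <- as.integer(replicate)
  if (anyDuplicated(channel)) {
    rlang::abort("channel identifiers must be unique", class = "stripakr_validation_error")
  }
  if (length(channel) != length(strain) || length(channel) != length(replicate)) {
    rlang::abort("channel, strain and replicate must have equal length",
      class = "stripakr_validation_error")
  }
  if (any(is.na(replicate)) || any(replicate < 1L)) {
    rlang::abort("replicate numbers must be positive integers",
      class = "stripakr_validation_error")
  }
  if (!reference %in% strain) {
    rlang::abort(
      paste0("reference strain '", reference, "' has no channel in the map"),
      class = "stripakr_validation_error"
    )
  }
  out <- tibble::tibble(channel = channel, strain = strain, replicate = replicate)
  attr(out, "reference") <- reference
  out
}

#' Default iTRAQ 8-plex channel map for the four study strains
#'
#' Channels 113-119 and 121 (the 8-plex reporter masses), two biological
#' replicates per strain, wild type as reference.
#'
#' @param strains Four strain labels; the first is used as the reference.
#' @return A channel-map tibble (see [channel_map()]).
#' @export
itraq8_channel_map <- function(strains = c("wt", "pro11", "pp2Ac1pro22", "pro11pro22")) {
  stopifnot(length(strains) == 4L)
  channel_map(
    channel   = as.character(c(113:119, 121)),
    strain    = rep(strains, each = 2),
    replicate = rep(1:2, times = 4),
    reference = strains[[1]]
  )
}

#' Read a channel map from a TSV or YAML file
#'
#' TSV files need columns `channel`, `strain`, `replicate`. YAML files carry
#' the same three parallel fields plus an optional `reference`.
#'
#' @param path File path ending in `.tsv`/`.txt` or `.yml`/`.yaml`.
#' @param reference Reference strain label; overridden by a `reference` field
#'   in a YAML file.
#' @return A channel-map tibble.
#' @export
read_channel_map <- function(path, reference = "wt") {
  if (!file.exists(path)) {
    rlang::abort(paste0("channel map file not found: ", path), class = "stripakr_io_error")
  }
  if (grepl("\\.ya?ml$", path)) {
    cfg <- yaml::read_yaml(path)
    reference <- cfg$reference %||% reference
    channel_map(cfg$channel, cfg$strain, cfg$replicate, reference = reference)
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
    need <- c("channel", "strain", "replicate")
    miss <- setdiff(need, names(tab))
    if (length(miss)) {
      rlang::abort(paste0("channel map is missing column(s): ", paste(miss, collapse = ", ")),
        class = "stripakr_format_error")
    }
    channel_map(tab$channel, tab$strain, as.integer(tab$replicate), reference = reference)
  }
}

reference_strain <- function(channel_map) {
  attr(channel_map, "reference") %||% "wt"
}

map_channels <- function(channel_map, strains) {
  channel_map$channel[channel_map$strain %in% strains]
}
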