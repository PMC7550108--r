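#' Read a run configuration from YAML
#'
#' Configuration files carry input paths, thresholds and the seed; missing
#' thresholds fall back to the analysis defaults (call score 2, localization
#' probability 0.90, minimum 2 unique peptides, 5 um processive distance,
#' alpha 0.05, co-localization tolerance 0.5 um at 0.8 overlap).
#'
#' @param path YAML file path.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path), class = "stripakr_io_error")
  }
  yaml::read_yaml(path)
}

default_thresholds <- function() {
  list(call_threshold = 2, min_localization_prob = 0.90, min_unique_peptides = 2,
    processive_min_distance = 5, alpha = 0.05, coloc_dist_tol = 0.5,
    coloc_time_overlap_min = 0.8, jitter_floor = 0.2)
}

maybe_write <- function(bundle, out_dir, tables, jsons = list()) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (nm in names(tables)) {
    write_results_table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  for (nm in names(jsons)) {
    jsonlite::write_json(jsons[[nm]], file.path(out_dir, paste0(nm, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(NULL)
}

#' Run the full differential phospho-regulation analysis
#'
#' Executes the complete calling pipeline: identification filters,
#' proteome-derived channel normalization of both tables, replicate-averaged
#' log2 ratios, per-condition SDs, ratio/SD scoring with the 2xSD rule,
#' cross-omic gating, site aggregation, and cross-strain overlap — the stage
#' funnel of a paired global-proteome / phosphoproteome experiment.
#'
#' @param proteins Protein quantification tibble or TSV path.
#' @param phospho Phosphopeptide quantification tibble or TSV path.
#' @param channel_map Channel map tibble or path (TSV/YAML).
#' @param reference Reference strain; default the map's reference.
#' @param min_unique_peptides,min_localization_prob,call_threshold Filter
#'   and call thresholds; defaults 2, 0.90, 2.
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @return A list bundle: `protein_calls`, `phospho_calls` (gated),
#'   `site_calls`, `sites_all_conditions`, `overlap` (protein-level Venn of
#'   phosphoproteins with regulated sites), `condition_stats` (global and
#'   phospho SDs side by side), `funnel` (record counts surviving each
#'   stage), `config`.
#' @export
run_regulation <- function(proteins, phospho, channel_map,
                           reference = NULL,
                           min_unique_peptides = 2,
                           min_localization_prob = 0.90,
                           call_threshold = 2,
                           out_dir = NULL) {
  if (is.character(channel_map)) channel_map <- read_channel_map(channel_map)
  reference <- reference %||% reference_strain(channel_map)
  if (is.character(proteins)) proteins <- read_quant_table(proteins, "protein", channel_map)
  if (is.character(phospho)) phospho <- read_quant_table(phospho, "phosphopeptide", channel_map)
  validate_quant_table(proteins, channel_map, "protein")
  validate_quant_table(phospho, channel_map, "phosphopeptide")

  funnel <- list(proteins_in = nrow(proteins), phospho_in = nrow(phospho))
  prot_f <- filter_identifications(proteins, min_unique_peptides = min_unique_peptides,
    level = "protein")
  phos_f <- filter_identifications(phospho, min_localization_prob = min_localization_prob,
    level = "phosphopeptide")
  funnel$proteins_filtered <- nrow(prot_f)
  funnel$phospho_filtered <- nrow(phos_f)

  factors <- compute_channel_factors(prot_f, channel_map)
  prot_n <- normalize_channels(prot_f, channel_map, factors)
  phos_n <- normalize_channels(phos_f, channel_map, factors)

  prot_ratios <- condition_log2_ratios(prot_n, channel_map, reference = reference)
  phos_ratios <- condition_log2_ratios(phos_n, channel_map, reference = reference)
  prot_stats <- estimate_condition_sd(prot_ratios)
  phos_stats <- estimate_condition_sd(phos_ratios)

  prot_calls <- score_and_call(prot_ratios, prot_stats, call_threshold = call_threshold)
  phos_calls <- score_and_call(phos_ratios, phos_stats, call_threshold = call_threshold)
  gated <- gate_phospho_by_global(phos_calls, prot_calls)
  funnel$phospho_regulated <- sum(gated$regulated, na.rm = TRUE)
  funnel$phospho_regulated_gated <- sum(gated$regulated_gated, na.rm = TRUE)
  funnel$phospho_unanchored <- sum(gated$gate_status == "unanchored")

  site_calls <- aggregate_sites(gated, phos_f)
  sites_all <- sites_regulated_in_all(site_calls)
  funnel$regulated_phosphoproteins <- length(unique(
    site_calls$protein_id[site_calls$regulated]))

  prot_overlap_input <- site_calls |>
    dplyr::group_by(.data$protein_id, .data$condition) |>
    dplyr::summarise(regulated = any(.data$regulated), .groups = "drop") |>
    dplyr::rename(feature_id = "protein_id")
  overlap <- cross_strain_overlap(prot_overlap_input)

  stats_both <- dplyr::bind_rows(
    dplyr::mutate(prot_stats, level = "protein"),
    dplyr::mutate(phos_stats, level = "phosphopeptide")
  )
  config <- c(default_thresholds()[c("call_threshold", "min_localization_prob",
    "min_unique_peptides")], list(reference = reference))
  config$call_threshold <- call_threshold
  config$min_localization_prob <- min_localization_prob
  config$min_unique_peptides <- min_unique_peptides

  bundle <- list(
    protein_calls = prot_calls, phospho_calls = gated, site_calls = site_calls,
    sites_all_conditions = sites_all, overlap = overlap,
    condition_stats = stats_both, channel_factors = factors,
    funnel = funnel, config = config
  )
  maybe_write(bundle, out_dir,
    tables = list(protein_calls = prot_calls, phospho_calls = gated,
      site_calls = site_calls, condition_stats = stats_both),
    jsons = list(
      overlap = list(regions = overlap, union = attr(overlap, "union")),
      funnel = funnel, config = config
    ))
  bundle
}

#' Run the genetic-interaction analysis
#'
#' @param growth Growth tibble or TSV path (`strain`, `bio_rep`, `tech_rep`,
#'   `front_mm_24h`, `front_mm_48h`).
#' @param doubles Tibble or TSV path with `double`, `single_a`, `single_b`.
#' @param reference Reference strain; default `"wt"`.
#' @param alpha Significance level; default 0.05.
#' @param out_dir Optional output directory.
#' @return The [gi_analysis()] fit, with `tidy()`-able results.
#' @export
run_gi <- function(growth, doubles, reference = "wt", alpha = 0.05, out_dir = NULL) {
  if (is.character(growth)) growth <- readr::read_tsv(growth, col_types = readr::cols())
  if (is.character(doubles)) doubles <- readr::read_tsv(doubles, col_types = readr::cols())
  fit <- gi_analysis(growth, doubles, reference = reference, alpha = alpha)
  maybe_write(fit, out_dir,
    tables = list(gi_results = fit$results, relative_rates = fit$rates),
    jsons = list(gi = list(results = fit$results, alpha = alpha, reference = reference)))
  fit
}

#' Run the shuttling-track analysis
#'
#' @param tracks Track tibble or CSV path.
#' @param observations Observation tibble or CSV path.
#' @param min_distance Processivity threshold, um; default 5.
#' @param jitter_floor Velocity jitter floor, um/s; default 0.2.
#' @param out_dir Optional output directory.
#' @return A list bundle: `per_hypha`, `per_condition` (summaries by
#'   condition when present), `summary`, `config`.
#' @export
run_tracks <- function(tracks, observations, min_distance = 5,
                       jitter_floor = 0.2, out_dir = NULL) {
  if (is.character(tracks)) tracks <- readr::read_csv(tracks, col_types = readr::cols())
  if (is.character(observations)) {
    observations <- readr::read_csv(observations, col_types = readr::cols())
  }
  per_hypha <- shuttle_stats(tracks, observations, min_distance = min_distance,
    jitter_floor = jitter_floor)
  per_condition <- if ("condition" %in% names(per_hypha)) {
    per_hypha |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_modify(~shuttle_summary(.x)) |>
      dplyr::ungroup()
  } else {
    NULL
  }
  bundle <- list(
    per_hypha = per_hypha, per_condition = per_condition,
    summary = shuttle_summary(per_hypha),
    config = list(min_distance = min_distance, jitter_floor = jitter_floor)
  )
  maybe_write(bundle, out_dir,
    tables = c(list(shuttle_per_hypha = per_hypha),
      if (!is.null(per_condition)) list(shuttle_per_condition = per_condition)),
    jsons = list(shuttle_summary = c(as.list(bundle$summary), bundle$config)))
  bundle
}

#' Generate a complete synthetic fixture bundle
#'
#' Writes (or returns) one simulated dataset per pipeline stage: a paired
#' proteome/phosphoproteome iTRAQ experiment, a growth assay over the four
#' genetic-interaction strains, and single-channel plus paired-channel track
#' sets. Identical seeds give byte-identical files.
#'
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @param itraq,tracks Optional replacement specs ([itraq_sim_spec()],
#'   [track_sim_spec()]); the seed is injected.
#' @return A list with elements `itraq`, `growth`, `tracks`.
#' @export
run_simulate <- function(seed = 1, out_dir = NULL, itraq = NULL, tracks = NULL) {
  itraq <- itraq %||% itraq_sim_spec(seed = seed)
  itraq$seed <- as.integer(seed)
  tracks <- tracks %||% track_sim_spec(seed = seed)
  tracks$seed <- as.integer(seed)
  sim_q <- simulate_itraq(itraq)
  growth <- simulate_growth(
    c(wt = 1, pro45 = 0.494, pro11 = 0.413, gul1 = 0.189,
      pro45pro11 = 0.204, pro45gul1 = 0.093),
    seed = seed
  )
  sim_t <- simulate_tracks(tracks)
  bundle <- list(itraq = sim_q, growth = growth, tracks = sim_t, seed = seed)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_results_table(sim_q$proteins, file.path(out_dir, "proteins.tsv"), digits = NA)
    write_results_table(sim_q$phospho, file.path(out_dir, "phospho.tsv"), digits = NA)
    write_results_table(sim_q$truth, file.path(out_dir, "phospho_truth.tsv"), digits = NA)
    write_results_table(sim_q$channel_map, file.path(out_dir, "channel_map.tsv"), digits = NA)
    write_results_table(growth, file.path(out_dir, "growth.tsv"), digits = NA)
    readr::write_csv(sim_t$tracks, file.path(out_dir, "tracks.csv"))
    readr::write_csv(sim_t$observations, file.path(out_dir, "observations.csv"))
    readr::write_csv(sim_t$truth, file.path(out_dir, "tracks_truth.csv"))
  }
  bundle
}
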