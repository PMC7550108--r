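# shared in-code fixtures for the test suite

two_strain_map <- function() {
  channel_map(
    channel = c("c1", "c2", "c3", "c4"),
    strain = c("wt", "wt", "mut", "mut"),
    replicate = c(1, 2, 1, 2)
  )
}

toy_protein_table <- function(map = two_strain_map()) {
  tab <- tibble::tibble(
    protein_id = c("P1", "P2", "P3"),
    n_unique_peptides = c(3L, 2L, 5L)
  )
  for (ch in map$channel) tab[[ch]] <- c(100, 200, 50)
  tab
}

toy_phospho_table <- function(map = two_strain_map()) {
  tab <- tibble::tibble(
    peptide_sequence = c("AAAsPK", "GGGtPR", "PPPsYK"),
    protein_id = c("P1", "P2", "P3"),
    site_positions = c("4", "10", "7;8"),
    site_residues = c("S", "T", "S;Y"),
    localization_probs = c("0.99", "0.95", "0.97;0.92"),
    psm_rank = c(1L, 1L, 1L)
  )
  for (ch in map$channel) tab[[ch]] <- c(400, 80, 120)
  tab
}

# straight constant-velocity track
constant_track <- function(v = 2, n = 21, dt = 0.5, start = 10,
                           hypha = "h1", id = "t1", channel = "A") {
  t <- seq(0, by = dt, length.out = n)
  tibble::tibble(hypha_id = hypha, track_id = id, channel = channel,
    time_s = t, position_um = start + v * t)
}

stationary_track <- function(jitter = 0.05, n = 21, dt = 0.5, start = 30,
                             hypha = "h1", id = "t2", channel = "A", seed = 7) {
  t <- seq(0, by = dt, length.out = n)
  pos <- withr::with_seed(seed, start + rnorm(n, 0, jitter))
  tibble::tibble(hypha_id = hypha, track_id = id, channel = channel,
    time_s = t, position_um = pos)
}

gul1_fixture_path <- function() {
  system.file("extdata", "gul1_site_ratios.tsv", package = "stripakr")
}

printed_scores_fixture_path <- function() {
  system.file("extdata", "regulated_peptide_scores.tsv", package = "stripakr")
}

published_sds <- function() {
  readr::read_tsv(
    system.file("extdata", "condition_sds.tsv", package = "stripakr"),
    col_types = "cd"
  )
}

# long peptide-level ratio tibble from the GUL1 site table
gul1_ratios_long <- function() {
  tab <- readr::read_tsv(gul1_fixture_path(), col_types = "ccddd")
  tab |>
    tidyr::pivot_longer(dplyr::starts_with("ratio_"),
      names_to = "condition", values_to = "log2_ratio",
      names_prefix = "ratio_") |>
    dplyr::transmute(feature_id = peptide_key, protein_id = "SMAC_07544",
      site = site, condition = condition, log2_ratio = log2_ratio)
}

# site map of the GUL1 fixture in pre-expanded form
gul1_site_map <- function() {
  tab <- readr::read_tsv(gul1_fixture_path(), col_types = "ccddd")
  tibble::tibble(
    feature_id = tab$peptide_key,
    protein_id = "SMAC_07544",
    site = tab$site,
    position = as.integer(sub("^[STY]", "", tab$site)),
    residue = substr(tab$site, 1, 1)
  )
}
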