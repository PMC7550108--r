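#' Expand phosphopeptide records into one row per phospho site
#'
#' @param records Phosphopeptide quantification tibble.
#' @return A tibble `feature_id`, `protein_id`, `position`, `residue`,
#'   `site` (e.g. `"S180"`), `localization_prob`.
#' @export
phospho_sites <- function(records) {
  tibble::tibble(
    feature_id = phospho_feature_id(records),
    protein_id = records$protein_id,
    position = split_field(records$site_positions),
    residue = split_field(records$site_residues),
    localization_prob = split_field(records$localization_probs)
  ) |>
    tidyr::unnest(c("position", "residue", "localization_prob")) |>
    dplyr::mutate(
      position = as.integer(.data$position),
      localization_prob = as.numeric(.data$localization_prob),
      site = paste0(.data$residue, .data$position)
    )
}

#' Aggregate peptide-level calls to protein phospho sites
#'
#' A site is regulated in a condition if at least one supporting peptide
#' (any peptide covering the site) is regulated there. Peptides carrying
#' several sites contribute their call to each of their sites. The returned
#' profile lists every condition for every site, so absence of support reads
#' as an explicit `FALSE`, never a missing row.
#'
#' @param calls Scored (optionally gated) peptide calls. The gated call
#'   column `regulated_gated` is used when present, otherwise `regulated`.
#' @param records Phosphopeptide quantification tibble mapping peptides to
#'   sites (or a pre-expanded site tibble from [phospho_sites()]).
#' @return A tibble `protein_id`, `site`, `position`, `condition`,
#'   `regulated`, `n_peptides`, `n_regulated_peptides`,
#'   `supporting_peptides` (semicolon-joined feature ids).
#' @export
aggregate_sites <- function(calls, records) {
  sites <- if (all(c("feature_id", "site") %in% names(records))) {
    records
  } else {
    phospho_sites(records)
  }
  call_col <- if ("regulated_gated" %in% names(calls)) "regulated_gated" else "regulated"
  calls_use <- calls |>
    dplyr::transmute(.data$feature_id, .data$condition,
      peptide_regulated = .data[[call_col]] %in% TRUE)
  dplyr::inner_join(sites, calls_use, by = "feature_id",
    relationship = "many-to-many") |>
    dplyr::group_by(.data$protein_id, .data$site, .data$position, .data$condition) |>
    dplyr::summarise(
      regulated = any(.data$peptide_regulated),
      n_peptides = dplyr::n(),
      n_regulated_peptides = sum(.data$peptide_regulated),
      supporting_peptides = paste(.data$feature_id, collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$protein_id, .data$position, .data$condition)
}

#' Sites regulated in every listed condition
#'
#' @param site_calls Output of [aggregate_sites()].
#' @param conditions Conditions that must all be regulated; default all
#'   conditions present.
#' @return A tibble `protein_id`, `site`, `position` of sites regulated in
#'   every condition.
#' @export
sites_regulated_in_all <- function(site_calls, conditions = NULL) {
  conditions <- conditions %||% unique(site_calls$condition)
  site_calls |>
    dplyr::filter(.data$condition %in% conditions) |>
    dplyr::group_by(.data$protein_id, .data$site, .data$position) |>
    dplyr::summarise(
      all_regulated = sum(.data$regulated) == length(conditions) &&
        dplyr::n() == length(conditions),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$all_regulated) |>
    dplyr::select(-"all_regulated")
}

#' Overlap of regulated feature sets across conditions (Venn regions)
#'
#' Partitions the union of regulated features into the exclusive regions of
#' the condition Venn diagram, so the region counts always sum to the union
#' count.
#'
#' @param calls A tibble with a feature identifier column, `condition`, and
#'   a logical call column (`regulated_gated` if present, else `regulated`).
#' @param conditions Conditions spanning the diagram; default all present
#'   (at least 2).
#' @param id_col Feature identifier column; default `"feature_id"`.
#' @return A tibble with one row per non-empty combination of conditions:
#'   `region` (ampersand-joined condition labels), one logical membership
#'   column per condition, and `n`; the attribute `"union"` holds the union
#'   count.
#' @export
cross_strain_overlap <- function(calls, conditions = NULL, id_col = "feature_id") {
  conditions <- conditions %||% unique(calls$condition)
  if (length(conditions) < 2) {
    rlang::abort("at least two conditions are required", class = "stripakr_validation_error")
  }
  call_col <- if ("regulated_gated" %in% names(calls)) "regulated_gated" else "regulated"
  sets <- lapply(conditions, function(cond) {
    unique(calls[[id_col]][calls$condition == cond & calls[[call_col]] %in% TRUE])
  })
  names(sets) <- conditions
  universe <- unique(unlist(sets))
  membership <- matrix(FALSE, nrow = length(universe), ncol = length(conditions),
    dimnames = list(NULL, conditions))
  for (cond in conditions) membership[, cond] <- universe %in% sets[[cond]]

  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(conditions)))
  names(combos) <- conditions
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  n <- apply(combos, 1, function(cmb) {
    if (length(universe) == 0) return(0L)
    sum(apply(membership, 1, function(m) all(m == cmb)))
  })
  out <- tibble::as_tibble(combos) |>
    dplyr::mutate(
      region = apply(combos, 1, function(cmb) paste(conditions[as.logical(cmb)], collapse = "&")),
      n = as.integer(n)
    ) |>
    dplyr::select("region", dplyr::all_of(conditions), "n") |>
    dplyr::arrange(dplyr::desc(rowSums(dplyr::pick(dplyr::all_of(conditions)))), .data$region)
  attr(out, "union") <- length(universe)
  out
}

#' Distribution of phospho sites over serine, threonine, tyrosine
#'
#' Each unique protein site (protein, position, residue) is counted once,
#' regardless of how many peptides cover it. The study-scale expectation for
#' a fungal phosphoproteome is roughly 80/19/1 percent S/T/Y.
#'
#' @param records Phosphopeptide quantification tibble (or an expanded site
#'   tibble from [phospho_sites()]).
#' @return A tibble `residue` (S, T, Y in order), `n`, `fraction`; fractions
#'   sum to 1.
#' @export
residue_distribution <- function(records) {
  sites <- if ("site" %in% names(records)) records else phospho_sites(records)
  uniq <- dplyr::distinct(sites, .data$protein_id, .data$position, .data$residue)
  if (nrow(uniq) == 0) {
    rlang::abort("no phospho sites to summarise", class = "stripakr_validation_error")
  }
  if (!all(uniq$residue %in% c("S", "T", "Y"))) {
    rlang::abort("site residues outside {S, T, Y}", class = "stripakr_validation_error")
  }
  counts <- table(factor(uniq$residue, levels = c("S", "T", "Y")))
  tibble::tibble(residue = names(counts), n = as.integer(counts),
    fraction = as.integer(counts) / sum(counts))
}

#' Extract sequence windows around phospho sites
#'
#' For motif analysis, the modified residue is reported centred in a window
#' of `flank` residues on either side (15-mer at the default of 7). Windows
#' truncated by a protein terminus are padded with `"_"` so every window has
#' length `2 * flank + 1`.
#'
#' @param records Phosphopeptide quantification tibble or expanded site
#'   tibble.
#' @param proteome Named character vector (or `Biostrings::AAStringSet`-like
#'   object coercible with `as.character`) of protein sequences, named by
#'   protein accession.
#' @param flank Number of flanking residues each side; default 7.
#' @return A tibble `protein_id`, `site`, `position`, `residue`, `window`.
#' @export
extract_flank_windows <- function(records, proteome, flank = 7) {
  sites <- if ("site" %in% names(records)) records else phospho_sites(records)
  sites <- dplyr::distinct(sites, .data$protein_id, .data$site, .data$position, .data$residue)
  seq_names <- names(proteome)
  proteome <- as.character(proteome)
  names(proteome) <- seq_names
  miss <- setdiff(unique(sites$protein_id), names(proteome))
  if (length(miss)) {
    rlang::abort(paste0("protein sequence(s) missing from proteome: ",
      paste(utils::head(miss, 3), collapse = ", ")),
      class = "stripakr_validation_error")
  }
  win <- purrr::pmap_chr(
    list(sites$protein_id, sites$position),
    function(pid, pos) {
      seq <- proteome[[pid]]
      len <- nchar(seq)
      if (pos < 1 || pos > len) {
        rlang::abort(paste0("site position ", pos, " outside protein ", pid,
          " (length ", len, ")"), class = "stripakr_coordinate_error")
      }
      lo <- pos - flank
      hi <- pos + flank
      core <- substr(seq, max(lo, 1), min(hi, len))
      paste0(
        strrep("_", max(0, 1 - lo)),
        core,
        strrep("_", max(0, hi - len))
      )
    }
  )
  dplyr::mutate(sites, window = win)
}

#' Compare two ratio sets: feature overlap and Pearson correlation
#'
#' Used to compare independent quantification experiments covering partly
#' overlapping features (e.g. two studies of the same strain). Overlap is
#' the fraction of set A's features also present in set B; the correlation
#' is Pearson's r over shared features with non-missing ratios in both.
#'
#' @param ratios_a,ratios_b Ratio tibbles with `feature_id` and `log2_ratio`
#'   (a single condition each).
#' @return A one-row tibble `n_a`, `n_b`, `n_shared`, `overlap`, `pearson`
#'   (`NA` with a message when fewer than 3 complete shared pairs exist).
#' @export
compare_ratio_sets <- function(ratios_a, ratios_b) {
  shared <- dplyr::inner_join(
    dplyr::select(ratios_a, "feature_id", ratio_a = "log2_ratio"),
    dplyr::select(ratios_b, "feature_id", ratio_b = "log2_ratio"),
    by = "feature_id"
  )
  complete <- shared[stats::complete.cases(shared$ratio_a, shared$ratio_b), ]
  pearson <- if (nrow(complete) >= 3) {
    stats::cor(complete$ratio_a, complete$ratio_b, method = "pearson")
  } else {
    rlang::inform("fewer than 3 complete shared features; correlation is NA")
    NA_real_
  }
  tibble::tibble(
    n_a = nrow(ratios_a), n_b = nrow(ratios_b), n_shared = nrow(shared),
    overlap = nrow(shared) / nrow(ratios_a), pearson = pearson
  )
}
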