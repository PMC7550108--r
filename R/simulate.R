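#' Specification for the iTRAQ experiment simulator
#'
#' Defaults emulate the study design this package targets: an iTRAQ 8-plex
#' with two biological replicates for the wild type and three deletion
#' mutants; per-channel multiplicative labelling bias; log-normal reporter
#' intensities with per-channel measurement noise (log2 scale); per-feature
#' biological ratio scatter whose spread sets the condition SD near the
#' 0.57-0.67 range typical of such experiments; a fraction of phosphosites
#' spiked with a fixed log2 effect (default three nominal ratio SDs,
#' hyperphosphorylation) in every mutant while their parent proteins stay
#' flat; phosphosite residues drawn with S/T/Y proportions 0.80/0.19/0.01;
#' and a small mass of localization probabilities below the 0.90 filter.
#'
#' @param n_proteins,n_phosphopeptides Table sizes.
#' @param channel_map Channel map; default [itraq8_channel_map()].
#' @param channel_bias Named or positional multiplicative bias per channel.
#' @param peptide_noise_sd Per-channel measurement noise, log2 units.
#' @param protein_scatter_sd,phospho_scatter_sd Per-feature, per-condition
#'   biological log2-ratio scatter for unregulated features.
#' @param regulated_fraction Fraction of phosphopeptides spiked.
#' @param effect_size Spiked log2 effect; default `3 * sqrt(phospho_scatter_sd^2
#'   + peptide_noise_sd^2)` (three nominal condition SDs).
#' @param effect_sign +1 for hyperphosphorylation (default), -1 for loss.
#' @param sty_proportions Length-3 fractions over S, T, Y summing to 1.
#' @param loc_below_fraction Mass of localization probabilities below 0.90.
#' @param rank2_fraction Fraction of peptide-spectrum matches at rank 2.
#' @param seed Integer seed; every quantity is reproducible from it.
#' @return A validated spec (list, class `itraq_sim_spec`).
#' @export
itraq_sim_spec <- function(n_proteins = 400, n_phosphopeptides = 800,
                           channel_map = itraq8_channel_map(),
                           channel_bias = c(1.05, 0.95, 1.10, 0.90, 1.00, 1.04, 0.96, 1.00),
                           peptide_noise_sd = 0.2,
                           protein_scatter_sd = 0.30,
                           phospho_scatter_sd = 0.57,
                           regulated_fraction = 0.05,
                           effect_size = NULL,
                           effect_sign = 1,
                           sty_proportions = c(S = 0.80, T = 0.19, Y = 0.01),
                           loc_below_fraction = 0.05,
                           rank2_fraction = 0.03,
                           seed = 1) {
  if (regulated_fraction < 0 || regulated_fraction > 1) {
    rlang::abort("regulated_fraction must be in [0, 1]", class = "stripakr_validation_error")
  }
  if (loc_below_fraction < 0 || loc_below_fraction > 1) {
    rlang::abort("loc_below_fraction must be in [0, 1]", class = "stripakr_validation_error")
  }
  if (length(sty_proportions) != 3 || abs(sum(sty_proportions) - 1) > 1e-8 ||
      any(sty_proportions < 0)) {
    rlang::abort("sty_proportions must be 3 non-negative fractions summing to 1",
      class = "stripakr_validation_error")
  }
  if (length(channel_bias) != nrow(channel_map)) {
    rlang::abort("channel_bias must have one factor per channel",
      class = "stripakr_validation_error")
  }
  if (any(channel_bias <= 0)) {
    rlang::abort("channel_bias factors must be positive", class = "stripakr_validation_error")
  }
  effect_size <- effect_size %||% (3 * sqrt(phospho_scatter_sd^2 + peptide_noise_sd^2))
  if (effect_size < 0) {
    rlang::abort("effect_size must be non-negative", class = "stripakr_validation_error")
  }
  structure(list(
    n_proteins = n_proteins, n_phosphopeptides = n_phosphopeptides,
    channel_map = channel_map, channel_bias = unname(channel_bias),
    peptide_noise_sd = peptide_noise_sd,
    protein_scatter_sd = protein_scatter_sd,
    phospho_scatter_sd = phospho_scatter_sd,
    regulated_fraction = regulated_fraction,
    effect_size = effect_size, effect_sign = sign(effect_sign),
    sty_proportions = sty_proportions,
    loc_below_fraction = loc_below_fraction,
    rank2_fraction = rank2_fraction,
    seed = as.integer(seed)
  ), class = "itraq_sim_spec")
}

sim_channel_matrix <- function(base, true_log2fc, channel_map, bias, noise_sd) {
  # true_log2fc: matrix features x strains (reference column = 0)
  n <- length(base)
  m <- matrix(NA_real_, nrow = n, ncol = nrow(channel_map),
    dimnames = list(NULL, channel_map$channel))
  for (j in seq_len(nrow(channel_map))) {
    strain <- channel_map$strain[[j]]
    m[, j] <- base * 2^(true_log2fc[, strain] + stats::rnorm(n, 0, noise_sd)) * bias[[j]]
  }
  m
}

#' Simulate a paired proteome / phosphoproteome iTRAQ experiment
#'
#' Produces a protein-level table, a phosphopeptide-level table sharing the
#' proteome's channel structure, and a truth table recording every spiked
#' feature, so caller sensitivity and specificity are computable. Parent
#' proteins of spiked phosphopeptides carry no expression change, which is
#' exactly the situation the cross-omic gate is designed to accept.
#' Protein, peptide and annotation random streams are separated so enlarging
#' one table does not perturb the others at a fixed seed.
#'
#' @param spec An [itraq_sim_spec()].
#' @return A list: `proteins`, `phospho` (quantification tibbles),
#'   `truth` (long tibble `feature_id`, `protein_id`, `condition`,
#'   `true_log2fc`, `regulated`), `channel_map`.
#' @export
simulate_itraq <- function(spec) {
  stopifnot(inherits(spec, "itraq_sim_spec"))
  cm <- spec$channel_map
  strains <- unique(cm$strain)
  reference <- reference_strain(cm)
  mutants <- setdiff(strains, reference)

  protein_id <- sprintf("SMP_%05d", seq_len(spec$n_proteins))

  prot_part <- withr::with_seed(spec$seed + 101L, {
    protein_len <- sample(300:1500, spec$n_proteins, replace = TRUE)
    base <- stats::rlnorm(spec$n_proteins, meanlog = log(1e6), sdlog = 1)
    fc <- matrix(0, nrow = spec$n_proteins, ncol = length(strains),
      dimnames = list(NULL, strains))
    for (s in mutants) fc[, s] <- stats::rnorm(spec$n_proteins, 0, spec$protein_scatter_sd)
    m <- sim_channel_matrix(base, fc, cm, spec$channel_bias, spec$peptide_noise_sd)
    tab <- dplyr::bind_cols(
      tibble::tibble(protein_id = protein_id,
        n_unique_peptides = pmax(2L, stats::rpois(spec$n_proteins, 6))),
      tibble::as_tibble(m)
    )
    list(tab = tab, len = protein_len)
  })
  proteins <- prot_part$tab
  protein_len <- prot_part$len

  aa <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "N", "P", "Q", "R", "V", "W")
  n_pep <- spec$n_phosphopeptides
  phospho_parts <- withr::with_seed(spec$seed + 202L, {
    parent_idx <- sample.int(spec$n_proteins, n_pep, replace = n_pep > spec$n_proteins)
    n_sites <- 1L + stats::rbinom(n_pep, 1L, 0.1)
    residues <- lapply(n_sites, function(k) {
      sample(c("S", "T", "Y"), k, replace = TRUE, prob = spec$sty_proportions)
    })
    positions <- lapply(seq_len(n_pep), function(i) {
      sort(sample.int(protein_len[parent_idx[[i]]], n_sites[[i]]))
    })
    probs <- lapply(n_sites, function(k) {
      below <- stats::runif(k) < spec$loc_below_fraction
      round(ifelse(below, stats::runif(k, 0.5, 0.9), stats::runif(k, 0.9, 1)), 3)
    })
    peptide_sequence <- vapply(seq_len(n_pep), function(i) {
      paste(sample(aa, 12, replace = TRUE), collapse = "")
    }, character(1))
    psm_rank <- ifelse(stats::runif(n_pep) < spec$rank2_fraction, 2L, 1L)
    regulated <- stats::runif(n_pep) < spec$regulated_fraction
    list(parent_idx = parent_idx, residues = residues, positions = positions,
      probs = probs, peptide_sequence = peptide_sequence, psm_rank = psm_rank,
      regulated = regulated)
  })

  phospho <- withr::with_seed(spec$seed + 303L, {
    base <- stats::rlnorm(n_pep, meanlog = log(2e5), sdlog = 1)
    fc <- matrix(0, nrow = n_pep, ncol = length(strains),
      dimnames = list(NULL, strains))
    for (s in mutants) {
      fc[, s] <- ifelse(phospho_parts$regulated,
        spec$effect_sign * spec$effect_size,
        stats::rnorm(n_pep, 0, spec$phospho_scatter_sd))
    }
    m <- sim_channel_matrix(base, fc, cm, spec$channel_bias, spec$peptide_noise_sd)
    tab <- dplyr::bind_cols(
      tibble::tibble(
        peptide_sequence = phospho_parts$peptide_sequence,
        protein_id = protein_id[phospho_parts$parent_idx],
        site_positions = vapply(phospho_parts$positions, paste, character(1), collapse = ";"),
        site_residues = vapply(phospho_parts$residues, paste, character(1), collapse = ";"),
        localization_probs = vapply(phospho_parts$probs, paste, character(1), collapse = ";"),
        psm_rank = phospho_parts$psm_rank
      ),
      tibble::as_tibble(m)
    )
    list(tab = tab, fc = fc)
  })

  truth <- purrr::map_dfr(mutants, function(s) {
    tibble::tibble(
      feature_id = phospho_feature_id(phospho$tab),
      protein_id = phospho$tab$protein_id,
      condition = s,
      true_log2fc = phospho$fc[, s],
      regulated = phospho_parts$regulated
    )
  })

  list(proteins = proteins, phospho = phospho$tab, truth = truth, channel_map = cm)
}

#' Simulate a vegetative growth assay
#'
#' Front positions at 24 h and 48 h for each strain, biological replicate
#' and technical replicate, drawn around `wt_rate_mm_day * relative rate`
#' with multiplicative noise split between a biological replicate effect and
#' technical measurement error. With `rep_noise_cv = 0` the relative rates
#' are recovered exactly.
#'
#' @param true_relative_rates Named numeric vector of relative growth rates
#'   (must include the reference strain at 1, e.g.
#'   `c(wt = 1, pro45 = 0.494, ...)`).
#' @param wt_rate_mm_day Absolute daily growth of the reference; default 30.
#' @param rep_noise_cv Coefficient of variation of the noise; default 0.05.
#' @param n_bio,n_tech Biological and technical replicates; default 3 x 3.
#' @param seed Integer seed.
#' @return A growth tibble (`strain`, `bio_rep`, `tech_rep`,
#'   `front_mm_24h`, `front_mm_48h`).
#' @export
simulate_growth <- function(true_relative_rates, wt_rate_mm_day = 30,
                            rep_noise_cv = 0.05, n_bio = 3, n_tech = 3,
                            seed = 1) {
  if (is.null(names(true_relative_rates)) || any(!nzchar(names(true_relative_rates)))) {
    rlang::abort("true_relative_rates must be a named vector",
      class = "stripakr_validation_error")
  }
  if (any(true_relative_rates <= 0)) {
    rlang::abort("relative rates must be positive", class = "stripakr_validation_error")
  }
  withr::with_seed(as.integer(seed) + 404L, {
    grid <- tidyr::expand_grid(
      strain = names(true_relative_rates),
      bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech)
    )
    rate <- wt_rate_mm_day * true_relative_rates[grid$strain]
    bio_key <- paste(grid$strain, grid$bio_rep)
    bio_eff <- stats::rnorm(length(unique(bio_key)), 1, rep_noise_cv)
    names(bio_eff) <- unique(bio_key)
    tech_eff <- stats::rnorm(nrow(grid), 1, rep_noise_cv / 2)
    day1 <- rate * stats::rnorm(nrow(grid), 1, rep_noise_cv / 2)
    day2 <- rate * bio_eff[bio_key] * tech_eff
    dplyr::mutate(grid,
      front_mm_24h = day1,
      front_mm_48h = day1 + day2
    )
  })
}

#' Specification for the kymograph track simulator
#'
#' Defaults emulate the dual-view acquisitions analysed in the shuttling
#' experiments: tracks sampled at 0.15 s over up to `duration` seconds in
#' hyphal segments of `hypha_length` um; processive tracks are run-and-
#' reverse walks with truncated-normal speeds around 2.5 um/s and guaranteed
#' range >= 5 um; non-processive signals are localisation jitter only. The
#' inhibited mode (benomyl analogue) collapses the processive fraction to
#' `inhibited_fraction`. In paired-channel mode a `coloc_fraction` of
#' processive channel-A tracks is duplicated into channel B with a constant
#' sub-tolerance offset, and the remaining B-tracks are independent.
#'
#' @param n_tracks Number of channel-A tracks.
#' @param processive_fraction Fraction of tracks that are processive.
#' @param speed_mean,speed_sd Run speed distribution, um/s.
#' @param duration Observation duration, s.
#' @param sampling_dt Sampling interval, s.
#' @param jitter_sd Positional jitter SD, um.
#' @param hypha_length Observed hyphal length, um.
#' @param n_hyphae Number of hyphae the tracks are spread over.
#' @param coloc_fraction `NULL` for single-channel mode, else the fraction
#'   of processive A-tracks duplicated into channel B.
#' @param coloc_offset_sd SD of the constant spatial offset of duplicated
#'   tracks, um (sub-tolerance; default 0.1).
#' @param inhibited Benomyl mode; replaces `processive_fraction` by
#'   `inhibited_fraction`.
#' @param inhibited_fraction Residual processive fraction under inhibition;
#'   default 0.02.
#' @param seed Integer seed.
#' @return A validated spec (list, class `track_sim_spec`).
#' @export
track_sim_spec <- function(n_tracks = 200, processive_fraction = 0.5,
                           speed_mean = 2.5, speed_sd = 0.5,
                           duration = 30, sampling_dt = 0.15,
                           jitter_sd = 0.05, hypha_length = 100,
                           n_hyphae = 10, coloc_fraction = NULL,
                           coloc_offset_sd = 0.1,
                           inhibited = FALSE, inhibited_fraction = 0.02,
                           seed = 1) {
  if (processive_fraction < 0 || processive_fraction > 1) {
    rlang::abort("processive_fraction must be in [0, 1]", class = "stripakr_validation_error")
  }
  if (!is.null(coloc_fraction) && (coloc_fraction < 0 || coloc_fraction > 1)) {
    rlang::abort("coloc_fraction must be in [0, 1]", class = "stripakr_validation_error")
  }
  if (sampling_dt <= 0 || duration <= 0) {
    rlang::abort("duration and sampling_dt must be positive",
      class = "stripakr_validation_error")
  }
  speed_floor <- max(0.3, speed_mean - 3 * speed_sd)
  min_track_duration <- 0.4 * duration
  if (6 / speed_floor + 1.5 > min_track_duration) {
    rlang::abort(
      "duration too short to guarantee a 5 um run at the given speeds",
      class = "stripakr_infeasible_error"
    )
  }
  if (inhibited) processive_fraction <- inhibited_fraction
  structure(list(
    n_tracks = n_tracks, processive_fraction = processive_fraction,
    speed_mean = speed_mean, speed_sd = speed_sd, speed_floor = speed_floor,
    duration = duration, sampling_dt = sampling_dt, jitter_sd = jitter_sd,
    hypha_length = hypha_length, n_hyphae = n_hyphae,
    coloc_fraction = coloc_fraction, coloc_offset_sd = coloc_offset_sd,
    inhibited = inhibited, seed = as.integer(seed)
  ), class = "track_sim_spec")
}

# one processive run-and-reverse track: a first uninterrupted run guarantees
# range >= min_range + 1; later samples reverse with a small hazard and
# reflect at the segment boundaries
sim_processive_positions <- function(times, speed, hypha_length, jitter_sd,
                                     min_range = 5) {
  dur <- max(times) - min(times)
  run1 <- min(dur, (min_range + 1) / speed + stats::runif(1, 0, 1.5))
  span1 <- speed * run1
  if (span1 + 2 >= hypha_length) {
    rlang::abort("hypha_length too short for a guaranteed processive run",
      class = "stripakr_infeasible_error")
  }
  d <- sample(c(-1, 1), 1)
  start <- if (d > 0) {
    stats::runif(1, 1, hypha_length - span1 - 1)
  } else {
    stats::runif(1, span1 + 1, hypha_length - 1)
  }
  t_rel <- times - min(times)
  pos <- numeric(length(times))
  pos[[1]] <- start
  for (i in seq_along(t_rel)[-1]) {
    dt <- t_rel[[i]] - t_rel[[i - 1]]
    if (t_rel[[i]] > run1 && stats::runif(1) < 0.05) d <- -d
    p <- pos[[i - 1]] + d * speed * dt
    if (p < 0) { p <- -p; d <- 1 }
    if (p > hypha_length) { p <- 2 * hypha_length - p; d <- -1 }
    pos[[i]] <- p
  }
  pos + stats::rnorm(length(pos), 0, jitter_sd)
}

#' Simulate kymograph-derived tracks
#'
#' @param spec A [track_sim_spec()].
#' @return A list: `tracks` (channel A, plus channel B in paired mode),
#'   `observations` (per-hypha metadata), `truth` (per-track tibble
#'   `hypha_id`, `track_id`, `channel`, `processive`, `speed_um_s`,
#'   `colocalized`).
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_sim_spec"))
  withr::with_seed(spec$seed + 505L, {
    n <- spec$n_tracks
    processive <- stats::runif(n) < spec$processive_fraction
    speed <- pmax(spec$speed_floor,
      stats::rnorm(n, spec$speed_mean, spec$speed_sd))
    hypha <- sprintf("h%02d", 1 + (seq_len(n) - 1L) %% spec$n_hyphae)
    track_dur <- stats::runif(n, 0.4, 0.9) * spec$duration
    t0 <- stats::runif(n, 0, spec$duration - track_dur)

    make_track <- function(i, channel, track_id, pos_offset = 0) {
      times <- seq(t0[[i]], t0[[i]] + track_dur[[i]], by = spec$sampling_dt)
      pos <- if (processive[[i]]) {
        sim_processive_positions(times, speed[[i]], spec$hypha_length, spec$jitter_sd)
      } else {
        p0 <- stats::runif(1, 1, spec$hypha_length - 1)
        p0 + stats::rnorm(length(times), 0, spec$jitter_sd)
      }
      tibble::tibble(
        hypha_id = hypha[[i]], track_id = track_id, channel = channel,
        time_s = times,
        position_um = pmin(pmax(pos + pos_offset, 0), spec$hypha_length)
      )
    }

    tracks_a <- purrr::map_dfr(seq_len(n), function(i) {
      make_track(i, "A", sprintf("A%04d", i))
    })

    coloc <- rep(NA, n)
    tracks_b <- NULL
    if (!is.null(spec$coloc_fraction)) {
      coloc <- processive & stats::runif(n) < spec$coloc_fraction
      dup <- purrr::map_dfr(which(coloc), function(i) {
        off <- stats::rnorm(1, 0, spec$coloc_offset_sd)
        base <- dplyr::filter(tracks_a, .data$track_id == sprintf("A%04d", i))
        dplyr::mutate(base, channel = "B", track_id = sprintf("B%04d", i),
          position_um = pmin(pmax(.data$position_um + off, 0), spec$hypha_length))
      })
      n_indep <- sum(processive & !coloc)
      indep <- if (n_indep > 0) {
        idx <- which(processive & !coloc)
        purrr::map_dfr(idx, function(i) {
          # independent B-track in the same hypha, freshly drawn geometry
          times <- seq(t0[[i]], t0[[i]] + track_dur[[i]], by = spec$sampling_dt)
          pos <- sim_processive_positions(times, speed[[i]], spec$hypha_length,
            spec$jitter_sd)
          tibble::tibble(hypha_id = hypha[[i]], track_id = sprintf("B%04d", i),
            channel = "B", time_s = times,
            position_um = pmin(pmax(pos, 0), spec$hypha_length))
        })
      } else NULL
      tracks_b <- dplyr::bind_rows(dup, indep)
    }

    truth <- tibble::tibble(
      hypha_id = hypha, track_id = sprintf("A%04d", seq_len(n)), channel = "A",
      processive = processive, speed_um_s = ifelse(processive, speed, NA_real_),
      colocalized = coloc
    )
    observations <- tibble::tibble(
      hypha_id = sprintf("h%02d", seq_len(spec$n_hyphae)),
      observed_length_um = spec$hypha_length,
      duration_s = spec$duration,
      condition = if (spec$inhibited) "benomyl" else "control"
    )
    list(tracks = dplyr::bind_rows(tracks_a, tracks_b),
      observations = observations, truth = truth)
  })
}
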