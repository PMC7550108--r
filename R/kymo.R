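#' Validate a track table
#'
#' Track tables come from kymograph digitisation: one row per time sample of
#' one fluorescent signal. Required columns: `hypha_id`, `track_id`,
#' `channel`, `time_s`, `position_um`. Within each track, times must be
#' strictly increasing and at least two samples are required.
#'
#' @param tracks Track tibble.
#' @return `tracks`, invisibly, if valid.
#' @export
validate_tracks <- function(tracks) {
  need <- c("hypha_id", "track_id", "channel", "time_s", "position_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) {
    rlang::abort(paste0("track table is missing column(s): ",
      paste(miss, collapse = ", ")), class = "stripakr_format_error")
  }
  bad <- tracks |>
    dplyr::group_by(.data$hypha_id, .data$channel, .data$track_id) |>
    dplyr::summarise(
      ok = dplyr::n() >= 2 && all(diff(.data$time_s) > 0),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    rlang::abort(paste0("track(s) with <2 samples or non-increasing times: ",
      paste(utils::head(bad$track_id, 3), collapse = ", ")),
      class = "stripakr_validation_error")
  }
  invisible(tracks)
}

# indices of samples spaced at least `window` seconds apart (always keeps
# the first sample; consecutive samples already spaced wider pass through)
thin_to_window <- function(time_s, window) {
  keep <- 1L
  last <- time_s[[1]]
  for (i in seq_along(time_s)[-1]) {
    if (time_s[[i]] - last >= window) {
      keep <- c(keep, i)
      last <- time_s[[i]]
    }
  }
  keep
}

#' Per-track movement summaries: range, displacement, processivity, speed
#'
#' A signal is processive when its moving distance reaches `min_distance`
#' (5 um in the standard analysis). Moving distance is by default the
#' positional range (max - min), so a back-and-forth run covering 5 um
#' counts as processive even when it ends near its origin; set
#' `method = "net"` to use absolute endpoint displacement instead. Velocity
#' is the mean instantaneous speed over segments faster than `jitter_floor`
#' (stationary jitter does not dilute the estimate); it is `NA` for tracks
#' that never move faster than the floor.
#'
#' @param tracks Track tibble (see [validate_tracks()]).
#' @param min_distance Processivity threshold in um; default 5.
#' @param method `"range"` (default) or `"net"`.
#' @param jitter_floor Speed floor in um/s separating movement from
#'   localisation jitter; default 0.2.
#' @param speed_window Minimum time span in s over which instantaneous
#'   speeds are measured; default 0.5. Densely sampled tracks are thinned to
#'   this spacing first, so localisation jitter (which grows as 1/dt when
#'   differentiating) does not inflate the speed of slow particles.
#' @return A tibble with one row per track: `hypha_id`, `channel`,
#'   `track_id`, `n_samples`, `t_start`, `t_end`, `range_um`, `net_um`,
#'   `processive`, `velocity_um_s`.
#' @export
track_stats <- function(tracks, min_distance = 5, method = c("range", "net"),
                        jitter_floor = 0.2, speed_window = 0.5) {
  method <- match.arg(method)
  validate_tracks(tracks)
  tracks |>
    dplyr::group_by(.data$hypha_id, .data$channel, .data$track_id) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      t_start = min(.data$time_s), t_end = max(.data$time_s),
      range_um = max(.data$position_um) - min(.data$position_um),
      net_um = abs(.data$position_um[dplyr::n()] - .data$position_um[1]),
      velocity_um_s = {
        keep <- thin_to_window(.data$time_s, speed_window)
        sp <- abs(diff(.data$position_um[keep])) / diff(.data$time_s[keep])
        mv <- sp[sp > jitter_floor]
        if (length(mv)) mean(mv) else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      processive = (if (method == "range") .data$range_um else .data$net_um) >= min_distance
    )
}

#' Is a single track processive?
#'
#' Convenience wrapper around [track_stats()] for one track.
#'
#' @param track Track tibble containing a single track.
#' @inheritParams track_stats
#' @return Logical scalar.
#' @export
is_processive <- function(track, min_distance = 5, method = c("range", "net")) {
  st <- track_stats(track, min_distance = min_distance, method = method)
  if (nrow(st) != 1) {
    rlang::abort("is_processive expects exactly one track", class = "stripakr_validation_error")
  }
  st$processive
}

#' Shuttling statistics per hypha
#'
#' For each observed hypha: the number of signals, how many are processive
#' (moving distance >= `min_distance`), the processive percentage, the
#' processive density per 100 um of hyphal length, and the mean velocity of
#' the processive signals (average per track, then per kymograph). The
#' percentage and the density are both reported because "percent per 100 um"
#' conflates a fraction and a density; neither is asserted to be the other.
#'
#' @param tracks Track tibble.
#' @param observations Observation metadata tibble: `hypha_id`,
#'   `observed_length_um`, `duration_s`, optionally `condition`.
#' @inheritParams track_stats
#' @return A tibble with one row per hypha: counts, `percent_processive`,
#'   `processive_per_100um`, `mean_velocity_um_s`, joined with the
#'   observation metadata.
#' @export
shuttle_stats <- function(tracks, observations, min_distance = 5,
                          method = "range", jitter_floor = 0.2) {
  if (any(observations$observed_length_um <= 0) || any(observations$duration_s <= 0)) {
    rlang::abort("observed_length_um and duration_s must be positive",
      class = "stripakr_validation_error")
  }
  st <- track_stats(tracks, min_distance = min_distance, method = method,
    jitter_floor = jitter_floor)
  per_hypha <- st |>
    dplyr::group_by(.data$hypha_id) |>
    dplyr::summarise(
      n_signals = dplyr::n(),
      n_processive = sum(.data$processive),
      mean_velocity_um_s = mean(.data$velocity_um_s[.data$processive], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_velocity_um_s = ifelse(is.nan(.data$mean_velocity_um_s),
      NA_real_, .data$mean_velocity_um_s))
  observations |>
    dplyr::left_join(per_hypha, by = "hypha_id") |>
    dplyr::mutate(
      n_signals = dplyr::coalesce(.data$n_signals, 0L),
      n_processive = dplyr::coalesce(.data$n_processive, 0L),
      percent_processive = ifelse(.data$n_signals > 0,
        100 * .data$n_processive / .data$n_signals, NA_real_),
      processive_per_100um = .data$n_processive * 100 / .data$observed_length_um
    )
}

#' Pooled shuttling summary across hyphae
#'
#' Aggregates a per-hypha [shuttle_stats()] table: pooled percentage
#' (total processive / total signals), mean per-hypha density and velocity.
#'
#' @param stats Per-hypha statistics from [shuttle_stats()].
#' @return One-row tibble `n_hyphae`, `n_signals`, `n_processive`,
#'   `percent_processive`, `mean_processive_per_100um`,
#'   `mean_velocity_um_s`.
#' @export
shuttle_summary <- function(stats) {
  tibble::tibble(
    n_hyphae = nrow(stats),
    n_signals = sum(stats$n_signals),
    n_processive = sum(stats$n_processive),
    percent_processive = ifelse(sum(stats$n_signals) > 0,
      100 * sum(stats$n_processive) / sum(stats$n_signals), NA_real_),
    mean_processive_per_100um = mean(stats$processive_per_100um, na.rm = TRUE),
    mean_velocity_um_s = mean(stats$mean_velocity_um_s, na.rm = TRUE)
  )
}

#' Contrast of processive densities between treated and control groups
#'
#' Quantifies inhibition (e.g. of microtubule-dependent transport by
#' benomyl) as the ratio of mean processive densities, treated over control.
#' A ratio near 0 indicates full inhibition; 1 indicates no effect.
#'
#' @param control,treated Per-hypha statistics from [shuttle_stats()].
#' @return One-row tibble `control_density`, `treated_density`, `ratio`,
#'   `undefined` (TRUE with a warning when the control density is 0).
#' @export
inhibition_contrast <- function(control, treated) {
  if (nrow(control) == 0 || nrow(treated) == 0) {
    rlang::abort("both groups must contain at least one hypha",
      class = "stripakr_validation_error")
  }
  cd <- mean(control$processive_per_100um, na.rm = TRUE)
  td <- mean(treated$processive_per_100um, na.rm = TRUE)
  undefined <- !is.finite(cd) || cd == 0
  if (undefined) {
    rlang::warn("control processive density is zero; inhibition ratio undefined")
  }
  tibble::tibble(
    control_density = cd, treated_density = td,
    ratio = if (undefined) NA_real_ else td / cd,
    undefined = undefined
  )
}

#' Co-localization of processive tracks across two channels
#'
#' A processive channel-A track counts as co-migrating when some processive
#' channel-B track in the same hypha stays within `dist_tol` of it for at
#' least `time_overlap_min` of their temporal overlap (channel B is linearly
#' interpolated onto channel A's sample times). The statistic is the
#' percentage of processive A-tracks with such a partner, mirroring
#' dual-view kymograph scoring.
#'
#' @param tracks_a,tracks_b Track tibbles for the two channels (shared time
#'   base of one dual-view acquisition).
#' @param dist_tol Maximum distance in um to count as co-localized;
#'   default 0.5.
#' @param time_overlap_min Minimum fraction of the temporal overlap spent
#'   within `dist_tol`; default 0.8.
#' @inheritParams track_stats
#' @return One-row tibble `n_processive_a`, `n_colocalized`,
#'   `percent_colocalized` (`NA` with a warning when there are no processive
#'   A-tracks); per-track detail in the `"per_track"` attribute.
#' @export
coloc_fraction <- function(tracks_a, tracks_b, dist_tol = 0.5,
                           time_overlap_min = 0.8, min_distance = 5,
                           method = "range") {
  st_a <- track_stats(tracks_a, min_distance = min_distance, method = method)
  st_b <- track_stats(tracks_b, min_distance = min_distance, method = method)
  proc_a <- dplyr::filter(st_a, .data$processive)
  proc_b <- dplyr::filter(st_b, .data$processive)
  if (nrow(proc_a) == 0) {
    rlang::warn("no processive tracks in channel A; co-localization undefined")
    out <- tibble::tibble(n_processive_a = 0L, n_colocalized = 0L,
      percent_colocalized = NA_real_)
    attr(out, "per_track") <- tibble::tibble()
    return(out)
  }
  b_samples <- dplyr::filter(tracks_b,
    paste(.data$hypha_id, .data$track_id) %in% paste(proc_b$hypha_id, proc_b$track_id))

  detail <- purrr::pmap_dfr(
    dplyr::select(proc_a, "hypha_id", "track_id"),
    function(hypha_id, track_id) {
      a <- dplyr::filter(tracks_a, .data$hypha_id == !!hypha_id,
        .data$track_id == !!track_id)
      partners <- dplyr::filter(proc_b, .data$hypha_id == !!hypha_id)
      coloc <- FALSE
      best <- NA_real_
      for (btid in partners$track_id) {
        b <- dplyr::filter(b_samples, .data$hypha_id == !!hypha_id,
          .data$track_id == btid)
        t0 <- max(min(a$time_s), min(b$time_s))
        t1 <- min(max(a$time_s), max(b$time_s))
        if (t1 <= t0) next
        idx <- a$time_s >= t0 & a$time_s <= t1
        if (sum(idx) < 2) next
        bpos <- stats::approx(b$time_s, b$position_um, xout = a$time_s[idx])$y
        frac <- mean(abs(a$position_um[idx] - bpos) <= dist_tol)
        best <- max(best, frac, na.rm = TRUE)
        if (frac >= time_overlap_min) {
          coloc <- TRUE
          break
        }
      }
      tibble::tibble(hypha_id = hypha_id, track_id = track_id,
        colocalized = coloc, best_overlap_fraction = best)
    }
  )
  out <- tibble::tibble(
    n_processive_a = nrow(proc_a),
    n_colocalized = sum(detail$colocalized),
    percent_colocalized = 100 * sum(detail$colocalized) / nrow(proc_a)
  )
  attr(out, "per_track") <- detail
  out
}

#' Kymograph-style plot of tracks
#'
#' Position along the hypha against time, one line per track, faceted by
#' hypha — the plotting analogue of reading a kymograph.
#'
#' @param tracks Track tibble.
#' @param colour_by Column mapped to colour; default `"channel"`.
#' @return A ggplot object.
#' @export
plot_kymograph <- function(tracks, colour_by = "channel") {
  ggplot2::ggplot(tracks, ggplot2::aes(
    x = .data$time_s, y = .data$position_um,
    group = interaction(.data$channel, .data$track_id),
    colour = .data[[colour_by]]
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~hypha_id) +
    ggplot2::labs(x = "time (s)", y = "position along hypha (μm)") +
    ggplot2::theme_minimal()
}
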