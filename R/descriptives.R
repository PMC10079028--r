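#' Descriptive FTO summaries by analysis cell
#'
#' Computes per-cell count, arithmetic mean, sample SD (n - 1; `NA` for
#' cells with fewer than two values), median (even-n median is the mean of
#' the central pair) and modal histogram bin of Floor Transfer Offsets.
#'
#' @param timing A floor-transfer tibble (within-overlaps excluded, see
#'   [filter_for_timing()]) with `fto_ms` and the grouping columns required
#'   by `scope`.
#' @param scope One of `"group"`, `"dyad"`, `"group_stage"`, `"dyad_stage"`.
#' @param stage Which stage split to use for the `*_stage` scopes:
#'   `"two_way"` (epoch2) or `"three_way"` (epoch3).
#' @param bin_width_ms Histogram bin width for the modal bin (default 100).
#' @return A tibble with one row per cell: the grouping columns, `n`,
#'   `mean_ms`, `sd_ms`, `median_ms`, `modal_bin_ms`, `modal_tie`.
#' @export
summarise_fto <- function(timing,
                          scope = c("group", "dyad", "group_stage", "dyad_stage"),
                          stage = c("two_way", "three_way"),
                          bin_width_ms = 100) {
  scope <- match.arg(scope)
  stage <- match.arg(stage)
  stage_col <- if (stage == "two_way") "epoch2" else "epoch3"
  keys <- switch(scope,
                 group = "group",
                 dyad = c("group", "dyad_id"),
                 group_stage = c("group", stage_col),
                 dyad_stage = c("group", "dyad_id", stage_col))
  missing <- setdiff(c(keys, "fto_ms"), names(timing))
  if (length(missing)) {
    abort(paste0("timing table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  timing |>
    filter(!is.na(.data$fto_ms)) |>
    group_by(across(all_of(keys))) |>
    summarise(n = dplyr::n(),
              mean_ms = mean(.data$fto_ms),
              sd_ms = if (dplyr::n() >= 2L) sd(.data$fto_ms) else NA_real_,
              median_ms = median(.data$fto_ms),
              modal_bin_ms = modal_bin(.data$fto_ms, bin_width_ms),
              modal_tie = attr(modal_bin(.data$fto_ms, bin_width_ms), "tie"),
              .groups = "drop")
}

#' Modal histogram bin of an FTO sample
#'
#' Bins are centred, half-open intervals `[c - w/2, c + w/2)` with centres
#' `c` at integer multiples of the bin width `w`, so e.g. values in
#' `[150, 250)` fall in the 200 ms bin. Ties are broken towards the lower
#' centre and flagged.
#'
#' @param ftos Numeric vector of FTO values (ms); must be non-empty.
#' @param bin_width_ms Bin width in ms (default 100).
#' @return The centre (ms) of the most populated bin, with a logical
#'   attribute `"tie"`.
#' @export
modal_bin <- function(ftos, bin_width_ms = 100) {
  ftos <- ftos[!is.na(ftos)]
  if (!length(ftos)) abort("modal_bin() needs at least one FTO value")
  centres <- floor(ftos / bin_width_ms + 0.5) * bin_width_ms
  tab <- table(centres)
  best <- tab[tab == max(tab)]
  out <- min(as.numeric(names(best)))
  attr(out, "tie") <- length(best) > 1L
  out
}

#' Histogram bin table of an FTO sample
#'
#' Same bin convention as [modal_bin()]; only occupied bins are returned.
#'
#' @inheritParams modal_bin
#' @return A tibble with `centre_ms`, `count`, `proportion` (summing to 1).
#' @export
fto_histogram <- function(ftos, bin_width_ms = 100) {
  ftos <- ftos[!is.na(ftos)]
  if (!length(ftos)) abort("fto_histogram() needs at least one FTO value")
  centres <- floor(ftos / bin_width_ms + 0.5) * bin_width_ms
  tab <- table(centres)
  tibble(centre_ms = as.numeric(names(tab)),
         count = as.integer(tab),
         proportion = as.integer(tab) / length(ftos))
}

#' Leave-one-dyad-out robustness check
#'
#' Re-computes the group-level mean FTO after omitting each dyad in turn, to
#' check that no single dyad drives the group-level pattern.
#'
#' @param timing A floor-transfer tibble with `group`, `dyad_id`, `fto_ms`.
#' @return A tibble with one row per (omitted dyad, group): `omitted_dyad`,
#'   `group`, `n`, `mean_ms`, and `delta_ms` (change from the full-corpus
#'   group mean). The largest absolute change is attached as attribute
#'   `"max_abs_delta_ms"`.
#' @export
leave_one_dyad_out <- function(timing) {
  dyads_per_group <- timing |> distinct(.data$group, .data$dyad_id) |>
    count(.data$group)
  if (any(dyads_per_group$n < 2L)) {
    abort("leave_one_dyad_out() needs at least two dyads per group")
  }
  full <- timing |> group_by(.data$group) |>
    summarise(full_mean = mean(.data$fto_ms), .groups = "drop")
  dyads <- unique(timing$dyad_id)
  out <- purrr::list_rbind(lapply(dyads, function(d) {
    timing |>
      filter(.data$dyad_id != d) |>
      group_by(.data$group) |>
      summarise(n = dplyr::n(), mean_ms = mean(.data$fto_ms), .groups = "drop") |>
      mutate(omitted_dyad = d, .before = 1L)
  }))
  out <- out |>
    left_join(full, by = "group") |>
    mutate(delta_ms = .data$mean_ms - .data$full_mean) |>
    select(!"full_mean")
  attr(out, "max_abs_delta_ms") <- max(abs(out$delta_ms))
  out
}

#' Mean FTO by floor-transfer index
#'
#' For each group and each transfer index `i` (1-based within dialogue),
#' averages the `i`-th FTO over all dialogues of that group that contain at
#' least `i` floor transfers, optionally adding a moving-average smooth
#' (window truncated at the edges).
#'
#' @param timing A floor-transfer tibble with `group`, `dyad_id`, `task`,
#'   `index`, `fto_ms`.
#' @param max_index Largest transfer index to report (default 100).
#' @param window Moving-average window (odd integer; 1 = no smoothing).
#' @return A tibble: `group`, `index`, `n_dialogues`, `mean_fto_ms`,
#'   `smoothed_ms`.
#' @export
fto_by_index <- function(timing, max_index = 100, window = 1) {
  stopifnot(window >= 1, window %% 2 == 1)
  out <- timing |>
    filter(!is.na(.data$index), .data$index <= max_index) |>
    group_by(.data$group, .data$index) |>
    summarise(n_dialogues = dplyr::n(), mean_fto_ms = mean(.data$fto_ms),
              .groups = "drop") |>
    arrange(.data$group, .data$index)
  half <- (window - 1) / 2
  out |>
    group_by(.data$group) |>
    mutate(smoothed_ms = vapply(seq_along(.data$mean_fto_ms), function(i) {
      lo <- max(1L, i - half); hi <- min(length(.data$mean_fto_ms), i + half)
      mean(.data$mean_fto_ms[lo:hi])
    }, 0)) |>
    ungroup()
}
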