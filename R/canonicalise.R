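#' Canonicalise one speaker channel under the minimum-pause rule
#'
#' An interpausal unit (IPU) is a stretch of one speaker's speech bounded by
#' silences of at least `min_pause_ms`. Raw annotations may contain shorter
#' silences; canonicalisation merges any two consecutive same-speaker IPUs
#' separated by less than the threshold (labels concatenated with a space)
#' until every remaining within-channel silence is at least `min_pause_ms`.
#' A pause of exactly `min_pause_ms` is a valid pause and is kept.
#'
#' Merging is conservative about the filled-pause flag: the merged IPU is
#' flagged as filled-pause-only iff every merged part was.
#'
#' @param channel Data frame of one speaker's IPUs (`speaker`, `start`,
#'   `end`, `label`, optional `filled_pause`). IPUs may touch but not
#'   overlap.
#' @param min_pause_ms Minimum within-speaker pause in milliseconds
#'   (default 200).
#' @return A tibble of IPUs satisfying the canonical invariants, with an
#'   attribute `min_pause_ms`.
#' @export
#' @examples
#' ch <- tibble::tibble(speaker = "A", start = c(0, 1.15), end = c(1, 2),
#'                      label = c("so", "yes"))
#' canonicalise_channel(ch, 200)  # 150 ms pause < 200 ms: merged
canonicalise_channel <- function(channel, min_pause_ms = 200) {
  stopifnot(is.numeric(min_pause_ms), min_pause_ms > 0)
  channel <- as_ipu_tibble(channel)
  if (length(unique(channel$speaker)) > 1L) {
    abort("canonicalise_channel() expects a single speaker's IPUs")
  }
  n <- nrow(channel)
  if (n <= 1L) {
    attr(channel, "min_pause_ms") <- min_pause_ms
    return(channel)
  }
  channel <- arrange(channel, .data$start)
  gap_s <- channel$start[-1] - channel$end[-n]
  ov <- which(gap_s < -1e-9)
  if (length(ov)) {
    abort(sprintf("speaker %s: IPUs %d (%.4f-%.4f) and %d (%.4f-%.4f) overlap",
                  channel$speaker[1],
                  ov[1], channel$start[ov[1]], channel$end[ov[1]],
                  ov[1] + 1L, channel$start[ov[1] + 1L], channel$end[ov[1] + 1L]))
  }
  # strict comparison with a small guard so an exactly-threshold pause
  # survives floating-point noise
  merge_prev <- gap_s < min_pause_ms / 1000 - 1e-9
  grp <- cumsum(c(TRUE, !merge_prev))
  out <- channel |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    summarise(speaker = .data$speaker[1],
              start = min(.data$start), end = max(.data$end),
              label = paste(.data$label, collapse = " "),
              filled_pause = all(.data$filled_pause),
              .groups = "drop") |>
    select(!".grp")
  attr(out, "min_pause_ms") <- min_pause_ms
  out
}

#' Canonicalise both channels of a dialogue
#'
#' Applies [canonicalise_channel()] to each speaker channel of a dialogue
#' record. Total speech time is unchanged; only sub-threshold within-speaker
#' silences are absorbed into merged IPUs.
#'
#' @param dialogue A [dialogue_record()].
#' @inheritParams canonicalise_channel
#' @return The dialogue with canonical channels.
#' @export
canonicalise_dialogue <- function(dialogue, min_pause_ms = 200) {
  stopifnot(inherits(dialogue, "dialogue"))
  chans <- lapply(split(dialogue$ipus, dialogue$ipus$speaker),
                  canonicalise_channel, min_pause_ms = min_pause_ms)
  dialogue$ipus <- arrange(bind_rows(chans), .data$speaker, .data$start)
  dialogue$min_pause_ms <- min_pause_ms
  dialogue
}
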