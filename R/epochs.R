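#' Assign dialogue-stage labels to transitions
#'
#' Dialogue stages are defined by the first Mismatch of the Map Task: a
#' two-way split into the *beginning* (all dialogue preceding its detection)
#' and the *remainder*, and a three-way split into *before_detection*,
#' *during_discussion* (from detection up to resolution) and
#' *after_resolution*. A transition is located by the onset of its incoming
#' turn (`anchor_time`); a transition exactly at a mark belongs to the later
#' stage.
#'
#' @param transitions A transition tibble with an `anchor_time` column.
#' @param detection_time Time (s) of first mention of the first Mismatch;
#'   `NA` leaves all stage labels `NA`.
#' @param resolution_time Time (s) at which its discussion ends; `NA` leaves
#'   the three-way label `NA` (the two-way label is still assigned).
#' @return `transitions` with factor columns `epoch2`
#'   (beginning/remainder) and `epoch3`
#'   (before_detection/during_discussion/after_resolution).
#' @export
assign_epochs <- function(transitions, detection_time = NA_real_,
                          resolution_time = NA_real_) {
  lv2 <- c("beginning", "remainder")
  lv3 <- c("before_detection", "during_discussion", "after_resolution")
  t <- transitions$anchor_time
  if (is.na(detection_time)) {
    e2 <- factor(rep(NA_character_, length(t)), levels = lv2)
    e3 <- factor(rep(NA_character_, length(t)), levels = lv3)
  } else {
    if (!is.na(resolution_time) && detection_time > resolution_time) {
      abort("detection_time is after resolution_time")
    }
    e2 <- factor(ifelse(t < detection_time, "beginning", "remainder"), levels = lv2)
    if (is.na(resolution_time)) {
      e3 <- factor(rep(NA_character_, length(t)), levels = lv3)
    } else {
      e3 <- factor(ifelse(t < detection_time, "before_detection",
                          ifelse(t < resolution_time, "during_discussion",
                                 "after_resolution")), levels = lv3)
    }
  }
  transitions$epoch2 <- e2
  transitions$epoch3 <- e3
  transitions
}

#' Average floor-transfer index at detection and resolution
#'
#' For each dialogue with epoch marks, finds the index of the first floor
#' transfer at or after the detection (resolution) mark, and averages these
#' over dialogues.
#'
#' @param corpus A corpus tibble with a `dialogue` list-column, or a
#'   classified transition tibble containing `dyad_id`, `task`, `index`,
#'   `anchor_time`, `epoch2`/`epoch3` columns together with `marks` supplied
#'   via attributes is not supported -- pass the corpus.
#' @return A one-row tibble: `n_dialogues`, `mean_detection_index`,
#'   `mean_resolution_index` (`NA` when no dialogue carries the relevant
#'   mark).
#' @export
epoch_index_summary <- function(corpus) {
  stopifnot("dialogue" %in% names(corpus))
  det <- res <- numeric(0)
  n_used <- 0L
  for (d in corpus$dialogue) {
    if (is.na(d$detection_time)) next
    tr <- classify_transitions(canonicalise_dialogue(d))$transitions
    ft <- tr[tr$kind != "within_overlap", , drop = FALSE]
    if (!nrow(ft)) next
    n_used <- n_used + 1L
    i_det <- which(ft$anchor_time >= d$detection_time)
    if (length(i_det)) det <- c(det, min(ft$index[i_det]))
    if (!is.na(d$resolution_time)) {
      i_res <- which(ft$anchor_time >= d$resolution_time)
      if (length(i_res)) res <- c(res, min(ft$index[i_res]))
    }
  }
  tibble(n_dialogues = n_used,
         mean_detection_index = if (length(det)) mean(det) else NA_real_,
         mean_resolution_index = if (length(res)) mean(res) else NA_real_)
}
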