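#' Construct a dialogue record
#'
#' A dialogue record bundles the two speaker channels of one task of a dyad
#' together with its metadata: dyad identifier, group label, epoch marks
#' (time of first detection, and optionally resolution, of the first
#' Mismatch) and the analysed task span. All times are in seconds.
#'
#' @param ipus Data frame of IPUs with columns `speaker`, `start`, `end`,
#'   `label` and optionally `filled_pause` (logical; defaults to `FALSE`).
#'   Exactly two distinct speakers are expected.
#' @param dyad_id Dyad identifier (scalar character).
#' @param group Group label, `"ASD"` or `"CTR"`.
#' @param task Task identifier within the dyad (default `1L`).
#' @param detection_time Time (s) at which the first Mismatch is first
#'   mentioned, or `NA` if unknown.
#' @param resolution_time Time (s) at which its discussion ends, or `NA`.
#' @param task_span Numeric length-2 vector, start and end (s) of the
#'   analysed dialogue. Defaults to the span of the IPUs.
#'
#' @return An object of class `dialogue`: a list with the elements above,
#'   `ipus` stored as a tibble sorted by speaker and onset.
#' @export
dialogue_record <- function(ipus, dyad_id, group, task = 1L,
                            detection_time = NA_real_,
                            resolution_time = NA_real_,
                            task_span = NULL) {
  ipus <- as_ipu_tibble(ipus)
  group <- as.character(group)
  if (!group %in% c("ASD", "CTR")) {
    abort(sprintf("unknown group label '%s' (expected 'ASD' or 'CTR')", group))
  }
  speakers <- unique(ipus$speaker)
  if (length(speakers) > 2L) {
    abort(sprintf("dialogue has %d speakers (%s); exactly two are supported",
                  length(speakers), paste(speakers, collapse = ", ")))
  }
  if (is.null(task_span)) {
    task_span <- if (nrow(ipus)) c(min(ipus$start), max(ipus$end)) else c(0, 0)
  }
  structure(
    list(ipus = arrange(ipus, .data$speaker, .data$start),
         dyad_id = as.character(dyad_id), group = group,
         task = as.integer(task),
         detection_time = as.numeric(detection_time),
         resolution_time = as.numeric(resolution_time),
         task_span = as.numeric(task_span),
         speakers = speakers),
    class = "dialogue")
}

as_ipu_tibble <- function(ipus) {
  ipus <- as_tibble(ipus)
  needed <- c("speaker", "start", "end", "label")
  missing <- setdiff(needed, names(ipus))
  if (length(missing)) {
    abort(paste0("IPU table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!is.numeric(ipus$start) || !is.numeric(ipus$end)) {
    abort("IPU start/end times must be numeric seconds")
  }
  if (!"filled_pause" %in% names(ipus)) ipus$filled_pause <- FALSE
  bad <- which(ipus$end <= ipus$start)
  if (length(bad)) {
    abort(sprintf("IPU %d has end <= start (%.4f <= %.4f)",
                  bad[1], ipus$end[bad[1]], ipus$start[bad[1]]))
  }
  ipus[needed] <- lapply(ipus[needed], function(x) x)
  ipus$speaker <- as.character(ipus$speaker)
  ipus$label <- as.character(ipus$label)
  ipus[c("speaker", "start", "end", "label", "filled_pause")]
}

#' @export
print.dialogue <- function(x, ...) {
  cat(sprintf("<dialogue> dyad %s (%s), task %d: %d IPUs, %d speaker(s), span [%.2f, %.2f] s\n",
              x$dyad_id, x$group, x$task, nrow(x$ipus),
              length(x$speakers), x$task_span[1], x$task_span[2]))
  invisible(x)
}

#' Validate a dialogue record
#'
#' Checks the structural invariants a dialogue must satisfy before
#' transition analysis: exactly two speakers, within-channel IPUs strictly
#' non-overlapping, all IPUs inside the task span, and coherent epoch marks
#' (detection before resolution, both inside the task span).
#'
#' @param dialogue A [dialogue_record()].
#' @param min_pause_ms Minimum within-speaker pause (ms) used to flag
#'   sub-threshold pauses that [canonicalise_channel()] would merge.
#' @return A tibble with columns `rule` and `detail`, one row per violation;
#'   zero rows when the record is analysable.
#' @export
validate_dialogue <- function(dialogue, min_pause_ms = 200) {
  stopifnot(inherits(dialogue, "dialogue"))
  out <- list()
  add <- function(rule, detail) out[[length(out) + 1L]] <<- tibble(rule = rule, detail = detail)

  if (length(dialogue$speakers) != 2L) {
    add("two_speakers", sprintf("found %d speaker(s)", length(dialogue$speakers)))
  }
  span <- dialogue$task_span
  ip <- dialogue$ipus
  if (nrow(ip)) {
    if (any(ip$start < span[1] - 1e-9) || any(ip$end > span[2] + 1e-9)) {
      add("ipus_in_span", "IPU outside task_span")
    }
    for (s in unique(ip$speaker)) {
      ch <- arrange(filter(ip, .data$speaker == s), .data$start)
      if (nrow(ch) > 1L) {
        gaps <- ch$start[-1] - ch$end[-nrow(ch)]
        ov <- which(gaps < -1e-9)
        if (length(ov)) {
          add("channel_overlap",
              sprintf("speaker %s: IPUs %d and %d overlap", s, ov[1], ov[1] + 1L))
        }
        sub <- which(gaps >= -1e-9 & gaps < min_pause_ms / 1000 - 1e-9)
        if (length(sub)) {
          add("sub_threshold_pause",
              sprintf("speaker %s: %d pause(s) below %d ms (channel not canonical)",
                      s, length(sub), as.integer(min_pause_ms)))
        }
      }
    }
  }
  dt <- dialogue$detection_time
  rt <- dialogue$resolution_time
  if (!is.na(dt) && !is.na(rt) && dt > rt) {
    add("epoch_order", sprintf("detection_time %.3f > resolution_time %.3f", dt, rt))
  }
  for (m in c(detection_time = dt, resolution_time = rt)) {
    if (!is.na(m) && (m < span[1] - 1e-9 || m > span[2] + 1e-9)) {
      add("mark_in_span", sprintf("epoch mark %.3f outside task_span", m))
    }
  }
  if (length(out)) bind_rows(out) else tibble(rule = character(), detail = character())
}
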