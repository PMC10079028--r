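#' Read a dialogue from a delimited IPU table
#'
#' Expects a header row with columns `speaker`, `start`, `end`, `label`
#' (optionally `filled_pause`); the delimiter (tab or comma) is
#' auto-detected. Metadata (dyad, group, epoch marks, task span) comes from
#' a YAML sidecar or a named list. The in-memory result is identical to the
#' TextGrid route given equivalent content.
#'
#' @param path Path to the delimited file.
#' @param meta Sidecar path or named list (see [read_textgrid_dialogue()]).
#'   Defaults to `<path without extension>.yaml`.
#' @return A [dialogue_record()].
#' @export
read_ipu_table <- function(path, meta = NULL) {
  if (is.null(meta)) meta <- paste0(tools::file_path_sans_ext(path), ".yaml")
  m <- read_meta(meta)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  needed <- c("speaker", "start", "end", "label")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    abort(paste0(path, " lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!is.numeric(tab$start) || !is.numeric(tab$end)) {
    abort(paste0(path, ": start/end must be numeric seconds"))
  }
  tab$label <- as.character(tab$label)
  tab$label[is.na(tab$label)] <- ""
  dialogue_record(tab, dyad_id = m$dyad_id, group = m$group,
                  task = m$task %||% 1L,
                  detection_time = m$detection_time %||% NA_real_,
                  resolution_time = m$resolution_time %||% NA_real_,
                  task_span = m$task_span)
}

#' Write a dialogue to a delimited IPU table plus YAML sidecar
#'
#' @param dialogue A [dialogue_record()].
#' @param path Output path for the IPU table (tab-separated). The sidecar is
#'   written next to it as `<path without extension>.yaml`.
#' @return `path`, invisibly.
#' @export
write_ipu_table <- function(dialogue, path) {
  readr::write_tsv(dialogue$ipus, path, progress = FALSE)
  meta <- list(dyad_id = dialogue$dyad_id, group = dialogue$group,
               task = dialogue$task,
               detection_time = if (is.na(dialogue$detection_time)) NULL else dialogue$detection_time,
               resolution_time = if (is.na(dialogue$resolution_time)) NULL else dialogue$resolution_time,
               task_span = dialogue$task_span)
  yaml::write_yaml(meta[!vapply(meta, is.null, TRUE)],
                   paste0(tools::file_path_sans_ext(path), ".yaml"),
                   precision = 12L)
  invisible(path)
}

#' Write a corpus to a directory of IPU tables
#'
#' One `<dyad>_task<k>.tsv` + `.yaml` pair per dialogue.
#'
#' @param corpus A corpus tibble with a `dialogue` list-column.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus_tables <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (d in corpus$dialogue) {
    write_ipu_table(d, file.path(dir, sprintf("%s_task%02d.tsv", d$dyad_id, d$task)))
  }
  invisible(dir)
}

#' Read a directory of IPU tables back into a corpus
#'
#' @param dir Directory containing `.tsv` + `.yaml` pairs written by
#'   [write_corpus_tables()].
#' @return A corpus tibble: `dyad_id`, `group`, `task`, `dialogue`
#'   (list-column).
#' @export
read_corpus_tables <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) abort(sprintf("no .tsv IPU tables found in %s", dir))
  dialogues <- lapply(files, read_ipu_table)
  tibble(dyad_id = vapply(dialogues, function(d) d$dyad_id, ""),
         group = vapply(dialogues, function(d) d$group, ""),
         task = vapply(dialogues, function(d) d$task, 1L),
         dialogue = dialogues)
}

#' Write a transition table to a delimited file
#'
#' One row per transition: `dyad`, `group`, `task`, `index`, `type`,
#' `fto_ms` (integer-rounded; empty for within-overlaps), `outgoing`,
#' `incoming`, `time_s` (full precision), `duration_ms`, `label`, `epoch2`,
#' `epoch3`. Reading the file back with [read_transitions()] reproduces the
#' written values.
#'
#' @param transitions A classified transition tibble (see
#'   [classify_dialogue()]).
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_transitions <- function(transitions, path) {
  out <- tibble(
    dyad = transitions$dyad_id %||% NA_character_,
    group = transitions$group %||% NA_character_,
    task = transitions$task %||% NA_integer_,
    index = transitions$index,
    type = transitions$kind,
    fto_ms = round(transitions$fto_ms),
    outgoing = transitions$outgoing,
    incoming = transitions$incoming,
    time_s = transitions$anchor_time,
    duration_ms = transitions$duration_ms,
    label = transitions$label,
    epoch2 = as.character(transitions$epoch2 %||% NA),
    epoch3 = as.character(transitions$epoch3 %||% NA))
  readr::write_tsv(out, path, progress = FALSE, num_threads = 1L)
  invisible(path)
}

#' Read a transition table written by [write_transitions()]
#'
#' @param path Path to the delimited transition file.
#' @return A tibble in the on-disk schema (see [write_transitions()]).
#' @export
read_transitions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    dyad = readr::col_character(),
                    group = readr::col_character(),
                    task = readr::col_integer(),
                    index = readr::col_integer(),
                    type = readr::col_character(),
                    fto_ms = readr::col_double(),
                    outgoing = readr::col_character(),
                    incoming = readr::col_character(),
                    time_s = readr::col_double(),
                    duration_ms = readr::col_double(),
                    label = readr::col_character(),
                    epoch2 = readr::col_character(),
                    epoch3 = readr::col_character()))
}
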