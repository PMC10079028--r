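#' Read interval tiers from a Praat TextGrid
#'
#' Parses both TextGrid dialects ("long", with `item [k]:` blocks and
#' `xmin = ...` lines, and "short", with bare values), in UTF-8 or UTF-16
#' (Praat's default) encoding. Non-empty intervals become IPUs; intervals
#' whose label is empty -- or matches one of `silence_labels` -- are silence
#' and are dropped. Labels made up entirely of filled-pause tokens (e.g.
#' `"<uhm>"`) are kept as speech but flagged, so they can be filtered
#' downstream if desired.
#'
#' @param path Path to a TextGrid file.
#' @param tier_names Character vector of interval-tier names to extract
#'   (default: all interval tiers). Each named tier becomes one speaker
#'   channel, with the tier name as speaker ID.
#' @param silence_labels Labels (besides the empty string) to treat as
#'   silence.
#' @param filled_pause_labels Tokens that count as filled pauses.
#' @return A named list of IPU tibbles (one per requested tier).
#' @export
read_textgrid <- function(path, tier_names = NULL,
                          silence_labels = c("<sil>", "<p:>"),
                          filled_pause_labels = c("<uhm>", "<uh>", "<hm>", "<mm>")) {
  lines <- read_textgrid_lines(path)
  tiers <- parse_textgrid(lines, path)
  have <- vapply(tiers, function(t) t$name, "")
  if (is.null(tier_names)) tier_names <- have
  miss <- setdiff(tier_names, have)
  if (length(miss)) {
    abort(sprintf("tier(s) %s not found in %s; available tiers: %s",
                  paste(sQuote(miss), collapse = ", "), path,
                  paste(sQuote(have), collapse = ", ")))
  }
  out <- lapply(tier_names, function(nm) {
    t <- tiers[[match(nm, have)]]
    iv <- t$intervals
    keep <- nzchar(trimws(iv$text)) & !(trimws(iv$text) %in% silence_labels)
    iv <- iv[keep, , drop = FALSE]
    lab <- trimws(iv$text)
    fp <- vapply(strsplit(tolower(lab), "\\s+"), function(tok) {
      length(tok) > 0 && all(tok %in% tolower(filled_pause_labels))
    }, TRUE)
    tibble(speaker = nm, start = iv$xmin, end = iv$xmax,
           label = lab, filled_pause = fp)
  })
  setNames(out, tier_names)
}

#' Read a dialogue from a TextGrid plus a metadata sidecar
#'
#' @inheritParams read_textgrid
#' @param tier_names The two interval tiers holding the speakers' IPUs.
#' @param meta Either the path to a YAML sidecar or a named list with
#'   `dyad_id`, `group` and optionally `task`, `detection_time`,
#'   `resolution_time`, `task_span`.
#' @return A [dialogue_record()].
#' @export
read_textgrid_dialogue <- function(path, tier_names, meta, ...) {
  channels <- read_textgrid(path, tier_names, ...)
  m <- read_meta(meta)
  dialogue_record(bind_rows(channels),
                  dyad_id = m$dyad_id, group = m$group,
                  task = m$task %||% 1L,
                  detection_time = m$detection_time %||% NA_real_,
                  resolution_time = m$resolution_time %||% NA_real_,
                  task_span = m$task_span)
}

read_meta <- function(meta) {
  if (is.character(meta) && length(meta) == 1L) meta <- yaml::read_yaml(meta)
  if (is.null(meta$dyad_id) || is.null(meta$group)) {
    abort("metadata must supply at least dyad_id and group")
  }
  if (!is.null(meta$task_span)) meta$task_span <- as.numeric(unlist(meta$task_span))
  meta
}

#' Write a dialogue's channels to a long-format TextGrid
#'
#' One interval tier per speaker; silences are written as empty-label
#' intervals so the file round-trips through [read_textgrid()].
#'
#' @param dialogue A [dialogue_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(dialogue, path) {
  span <- dialogue$task_span
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('File type = "ooTextFile"')
  w('Object class = "TextGrid"')
  w("")
  w("xmin = %s", num(span[1]))
  w("xmax = %s", num(span[2]))
  w("tiers? <exists>")
  w("size = %d", length(dialogue$speakers))
  w("item []:")
  for (k in seq_along(dialogue$speakers)) {
    s <- dialogue$speakers[k]
    ch <- dialogue$ipus[dialogue$ipus$speaker == s, , drop = FALSE]
    ch <- ch[order(ch$start), , drop = FALSE]
    # interleave silences to tile the span
    xmin <- numeric(0); xmax <- numeric(0); text <- character(0)
    cur <- span[1]
    for (i in seq_len(nrow(ch))) {
      if (ch$start[i] > cur + 1e-12) {
        xmin <- c(xmin, cur); xmax <- c(xmax, ch$start[i]); text <- c(text, "")
      }
      xmin <- c(xmin, ch$start[i]); xmax <- c(xmax, ch$end[i]); text <- c(text, ch$label[i])
      cur <- ch$end[i]
    }
    if (cur < span[2] - 1e-12) {
      xmin <- c(xmin, cur); xmax <- c(xmax, span[2]); text <- c(text, "")
    }
    w("    item [%d]:", k)
    w('        class = "IntervalTier"')
    w('        name = "%s"', s)
    w("        xmin = %s", num(span[1]))
    w("        xmax = %s", num(span[2]))
    w("        intervals: size = %d", length(xmin))
    for (i in seq_along(xmin)) {
      w("        intervals [%d]:", i)
      w("            xmin = %s", num(xmin[i]))
      w("            xmax = %s", num(xmax[i]))
      w('            text = "%s"', gsub('"', '""', text[i]))
    }
  }
  invisible(path)
}

read_textgrid_lines <- function(path) {
  bom <- readBin(path, "raw", n = 2L)
  enc <- if (length(bom) == 2L &&
             ((bom[1] == as.raw(0xFE) && bom[2] == as.raw(0xFF)) ||
              (bom[1] == as.raw(0xFF) && bom[2] == as.raw(0xFE)))) "UTF-16" else "UTF-8"
  con <- file(path, encoding = enc)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

parse_textgrid <- function(lines, path = "<textgrid>") {
  strip <- trimws(lines)
  if (!length(strip) || !grepl("ooTextFile", strip[1])) {
    abort(sprintf("%s: not a TextGrid (line 1: %s)", path,
                  if (length(strip)) sQuote(strip[1]) else "<empty>"))
  }
  if (!any(grepl("TextGrid", strip[seq_len(min(3, length(strip)))]))) {
    abort(sprintf("%s: Object class is not TextGrid", path))
  }
  long <- any(grepl("^item\\s*\\[?\\]?:?", strip))
  if (long) parse_textgrid_long(strip, path) else parse_textgrid_short(strip, path)
}

tg_num <- function(x) as.numeric(gsub("[^0-9eE+.-]", "", x))
tg_str <- function(x) {
  m <- regmatches(x, regexpr('"(?:[^"]|"")*"', x))
  if (!length(m)) return(NA_character_)
  gsub('""', '"', substr(m, 2L, nchar(m) - 1L))
}

parse_textgrid_long <- function(strip, path) {
  item_rows <- grep("^item\\s*\\[[0-9]+\\]:", strip)
  tiers <- vector("list", length(item_rows))
  bounds <- c(item_rows, length(strip) + 1L)
  for (k in seq_along(item_rows)) {
    block <- strip[bounds[k]:(bounds[k + 1L] - 1L)]
    cls <- tg_str(block[grep("^class\\s*=", block)[1]])
    nm <- tg_str(block[grep("^name\\s*=", block)[1]])
    if (is.na(cls)) {
      abort(sprintf("%s: tier %d has no class line (near line %d)", path, k, bounds[k]))
    }
    iv_rows <- grep("^intervals\\s*\\[[0-9]+\\]:", block)
    xmin <- xmax <- numeric(length(iv_rows)); text <- character(length(iv_rows))
    for (i in seq_along(iv_rows)) {
      sub <- block[iv_rows[i]:min(iv_rows[i] + 3L, length(block))]
      xm <- grep("^xmin\\s*=", sub, value = TRUE)
      xx <- grep("^xmax\\s*=", sub, value = TRUE)
      tx <- grep("^text\\s*=", sub, value = TRUE)
      if (!length(xm) || !length(xx) || !length(tx)) {
        abort(sprintf("%s: malformed interval %d of tier '%s' (near line %d)",
                      path, i, nm, bounds[k] + iv_rows[i] - 1L))
      }
      xmin[i] <- tg_num(sub("^xmin\\s*=", "", xm[1]))
      xmax[i] <- tg_num(sub("^xmax\\s*=", "", xx[1]))
      text[i] <- tg_str(tx[1]) %||% ""
    }
    tiers[[k]] <- list(name = nm, class = cls,
                       intervals = tibble(xmin = xmin, xmax = xmax, text = text))
  }
  keep_interval_tiers(tiers, path)
}

parse_textgrid_short <- function(strip, path) {
  body <- strip[nzchar(strip)]
  # header: ooTextFile, TextGrid, xmin, xmax, <exists>, ntiers
  ex <- grep("exists", body)
  if (!length(ex)) abort(sprintf("%s: short TextGrid lacks '<exists>' flag", path))
  i <- ex[1] + 1L
  ntier <- as.integer(tg_num(body[i])); i <- i + 1L
  tiers <- vector("list", ntier)
  for (k in seq_len(ntier)) {
    cls <- tg_str(body[i]) %||% body[i]; i <- i + 1L
    nm <- tg_str(body[i]) %||% body[i]; i <- i + 1L
    i <- i + 2L  # tier xmin, xmax
    n <- as.integer(tg_num(body[i])); i <- i + 1L
    if (is.na(n)) abort(sprintf("%s: malformed interval count for tier %d", path, k))
    xmin <- xmax <- numeric(n); text <- character(n)
    if (grepl("IntervalTier", cls)) {
      for (j in seq_len(n)) {
        if (i + 2L > length(body)) {
          abort(sprintf("%s: file truncated inside tier '%s' (interval %d)", path, nm, j))
        }
        xmin[j] <- tg_num(body[i]); xmax[j] <- tg_num(body[i + 1L])
        text[j] <- tg_str(body[i + 2L]) %||% ""
        i <- i + 3L
      }
    } else {
      i <- i + 2L * n  # point tier: time + mark per point
    }
    tiers[[k]] <- list(name = nm, class = cls,
                       intervals = tibble(xmin = xmin, xmax = xmax, text = text))
  }
  keep_interval_tiers(tiers, path)
}

keep_interval_tiers <- function(tiers, path) {
  keep <- vapply(tiers, function(t) grepl("IntervalTier", t$class), TRUE)
  if (!any(keep)) abort(sprintf("%s: no interval tiers found", path))
  tiers[keep]
}
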