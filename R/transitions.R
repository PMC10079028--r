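#' Build the joint two-speaker state timeline
#'
#' Tiles the task span with maximal intervals labelled by who is vocalising:
#' one of the two speaker IDs, `"both"`, or `"neither"`. Adjacent intervals
#' always carry distinct labels. This is the scaffolding on which turn
#' transitions are classified.
#'
#' @param dialogue A [dialogue_record()] with canonical channels.
#' @return A tibble with columns `start`, `end`, `label`.
#' @export
build_state_timeline <- function(dialogue) {
  stopifnot(inherits(dialogue, "dialogue"))
  ip <- dialogue$ipus
  span <- dialogue$task_span
  spk <- dialogue$speakers
  bp <- sort(unique(c(span, ip$start, ip$end)))
  bp <- bp[bp >= span[1] - 1e-12 & bp <= span[2] + 1e-12]
  if (length(bp) < 2L) {
    return(tibble(start = span[1], end = span[2], label = "neither"))
  }
  mid <- (bp[-1] + bp[-length(bp)]) / 2
  active <- function(s) {
    ch <- ip[ip$speaker == s, , drop = FALSE]
    if (!nrow(ch)) return(rep(FALSE, length(mid)))
    idx <- findInterval(mid, ch$start)
    idx > 0 & mid < ch$end[pmax(idx, 1L)]
  }
  a <- active(spk[1])
  b <- if (length(spk) > 1L) active(spk[2]) else rep(FALSE, length(mid))
  label <- ifelse(a & b, "both",
                  ifelse(a, spk[1], ifelse(b, spk[2], "neither")))
  r <- rle(label)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  tibble(start = bp[starts], end = bp[ends + 1L], label = r$values)
}

#' Classify all turn transitions of a dialogue
#'
#' Derives turns and classifies every between-speaker event following the
#' gap / between-overlap / within-overlap taxonomy:
#' \itemize{
#'   \item A \emph{floor transfer} occurs wherever the sequence of
#'     single-speaker stretches changes speaker. Its Floor Transfer Offset
#'     (FTO) is the onset of the incoming turn's first IPU minus the offset
#'     of the outgoing turn's last IPU: positive for silent \emph{gaps}
#'     (FTO = 0, perfect latching, counts as a gap), negative for
#'     \emph{between-overlaps}.
#'   \item A \emph{within-overlap} is a stretch of overlapping speech not
#'     followed by a change of speaker: the interlocutor vocalises inside
#'     the floor-holder's ongoing turn. It is an event, not a floor
#'     transfer, and carries no FTO; its duration is that of the embedded
#'     vocalisation.
#'   \item A silence between two stretches of the \emph{same} speaker is a
#'     within-speaker pause, not a transition.
#' }
#' An interlocutor vocalisation falling entirely inside the floor-holder's
#' silent pause creates two genuine floor transfers (two short turns), since
#' a within-overlap requires overlapping speech.
#'
#' @param dialogue A [dialogue_record()] whose channels are canonical (see
#'   [canonicalise_dialogue()]); channels are trusted, not re-canonicalised.
#' @return A list with `transitions` (tibble: `index`, `kind`, `fto_ms`,
#'   `outgoing`, `incoming`, `anchor_time`, `duration_ms`, `label`) and
#'   `turns` (tibble: `speaker`, `onset`, `offset`, `n_ipus`). Floor
#'   transfers are indexed consecutively from 1; within-overlaps have
#'   `index = NA`.
#' @export
classify_transitions <- function(dialogue) {
  stopifnot(inherits(dialogue, "dialogue"))
  ip <- dialogue$ipus
  spk <- dialogue$speakers
  empty <- list(
    transitions = tibble(index = integer(), kind = character(),
                         fto_ms = numeric(), outgoing = character(),
                         incoming = character(), anchor_time = numeric(),
                         duration_ms = numeric(), label = character()),
    turns = tibble(speaker = character(), onset = numeric(),
                   offset = numeric(), n_ipus = integer()))
  if (!nrow(ip) || length(spk) < 2L) {
    if (nrow(ip)) {
      empty$turns <- tibble(speaker = spk[1], onset = min(ip$start),
                            offset = max(ip$end), n_ipus = nrow(ip))
    }
    return(empty)
  }
  tl <- build_state_timeline(dialogue)
  chan <- lapply(setNames(spk, spk), function(s) {
    ch <- ip[ip$speaker == s, , drop = FALSE]
    ch[order(ch$start), , drop = FALSE]
  })
  other <- setNames(rev(spk), spk)
  # IPU covering time t for speaker s (t strictly inside or at onset)
  covering <- function(s, t) {
    ch <- chan[[s]]
    idx <- findInterval(t + 1e-12, ch$start)
    if (idx < 1L || t >= ch$end[idx] - 1e-12) return(NA_integer_)
    idx
  }

  singles <- which(tl$label %in% spk)
  if (!length(singles)) {
    # degenerate: speakers only ever talk simultaneously; no floor transfers
    return(empty)
  }
  sl <- tl$label[singles]
  runs <- rle(sl)
  run_end <- cumsum(runs$lengths)
  run_start <- c(1L, head(run_end, -1L) + 1L)
  run_spk <- runs$values
  n_run <- length(run_spk)
  # timeline row of the first / last single interval of each floor run
  first_row <- singles[run_start]
  last_row <- singles[run_end]

  # first turn onset: first IPU of the first floor-holder; if the dialogue
  # opens with simultaneous speech the earlier-starting speaker holds first
  turn_onset <- numeric(n_run)
  turn_offset <- numeric(n_run)
  turn_onset[1] <- chan[[run_spk[1]]]$start[1]
  if (first_row[1] > 1L && tl$label[1] == "both") {
    starts1 <- vapply(spk, function(s) chan[[s]]$start[1], 0)
    turn_onset[1] <- min(starts1)
  }

  nt <- n_run - 1L
  tr_fto <- tr_anchor <- numeric(nt)
  tr_out <- tr_in <- character(nt)
  tr_kin <- tr_kout <- integer(nt)
  for (j in seq_len(nt)) {
    s_out <- run_spk[j]
    s_in <- run_spk[j + 1L]
    t_in <- tl$start[first_row[j + 1L]]   # start of incoming run's first single interval
    u_out <- tl$end[last_row[j]]          # end of outgoing run's last single interval
    ch_in <- chan[[s_in]]
    ch_out <- chan[[s_out]]
    # incoming turn's first IPU: earliest incoming IPU still live after the
    # outgoing speaker's single-activity ended (it reaches into the run)
    k_in <- covering(s_in, t_in)
    if (is.na(k_in)) k_in <- findInterval(t_in + 1e-12, ch_in$start)
    while (k_in > 1L && ch_in$end[k_in - 1L] > u_out + 1e-12) k_in <- k_in - 1L
    onset_in <- ch_in$start[k_in]
    # outgoing turn's last IPU: the one live just before its single run ended
    k_out <- findInterval(u_out - 1e-12, ch_out$start)
    offset_out <- ch_out$end[k_out]
    tr_fto[j] <- onset_in - offset_out
    tr_out[j] <- s_out; tr_in[j] <- s_in
    tr_anchor[j] <- onset_in
    tr_kin[j] <- k_in; tr_kout[j] <- k_out
    turn_onset[j + 1L] <- onset_in
    turn_offset[j] <- offset_out
  }
  turn_offset[n_run] <- max(chan[[run_spk[n_run]]]$end)
  transfers <- tibble(
    index = seq_len(nt),
    kind = as.character(ifelse(tr_fto >= -1e-12, "gap", "between_overlap")),
    fto_ms = tr_fto * 1000, outgoing = tr_out, incoming = tr_in,
    anchor_time = tr_anchor, duration_ms = NA_real_, label = NA_character_)

  # within-overlaps: overlapping speech that is not part of any floor
  # transfer. The floor holder at an overlap's onset is the incoming speaker
  # of the latest transfer anchored at or before it (or the first
  # floor-holder); the interlocutor's overlapped IPU is a within-overlap
  # event unless it is a transfer's incoming-first or outgoing-last IPU.
  transfer_ipus <- lapply(setNames(spk, spk), function(s) {
    c(tr_kin[tr_in == s], tr_kout[tr_out == s])
  })
  both_rows <- which(tl$label == "both")
  within <- list()
  for (r in both_rows) {
    bs <- tl$start[r]
    j <- if (nt > 0L) findInterval(bs + 1e-12, tr_anchor) else 0L
    holder <- if (j >= 1L) tr_in[j] else run_spk[1]
    emb_s <- other[[holder]]
    k <- covering(emb_s, bs)
    if (is.na(k) || k %in% transfer_ipus[[emb_s]]) next
    ch <- chan[[emb_s]]
    within[[length(within) + 1L]] <- list(
      index = NA_integer_, kind = "within_overlap", fto_ms = NA_real_,
      outgoing = holder, incoming = emb_s,
      anchor_time = ch$start[k],
      duration_ms = (ch$end[k] - ch$start[k]) * 1000,
      label = ch$label[k])
  }
  within_tbl <- if (length(within)) distinct(bind_rows(within)) else NULL

  transitions <- bind_rows(transfers, within_tbl)
  if (nrow(transitions)) transitions <- arrange(transitions, .data$anchor_time)

  # embedded within-overlap IPUs do not count towards the host's turn size
  emb_key <- if (length(within)) {
    paste(within_tbl$incoming, format(within_tbl$anchor_time, digits = 15))
  } else character(0)
  n_ipus <- vapply(seq_len(n_run), function(j) {
    s <- run_spk[j]
    ch <- chan[[s]]
    sel <- ch$start >= turn_onset[j] - 1e-12 & ch$end <= turn_offset[j] + 1e-12
    sum(sel & !(paste(s, format(ch$start, digits = 15)) %in% emb_key))
  }, 0L)
  turns <- tibble(speaker = run_spk, onset = turn_onset,
                  offset = turn_offset, n_ipus = as.integer(n_ipus))
  list(transitions = transitions, turns = turns)
}

#' Classify a dialogue into a tidy transition table
#'
#' Convenience wrapper: canonicalises both channels, classifies transitions,
#' assigns dialogue-stage labels from the record's epoch marks, and returns
#' one tidy tibble carrying the dialogue's metadata.
#'
#' @inheritParams canonicalise_dialogue
#' @return A tibble of transitions with columns `dyad_id`, `group`, `task`,
#'   `index`, `kind`, `fto_ms`, `outgoing`, `incoming`, `anchor_time`,
#'   `duration_ms`, `label`, `epoch2`, `epoch3`.
#' @export
classify_dialogue <- function(dialogue, min_pause_ms = 200) {
  d <- canonicalise_dialogue(dialogue, min_pause_ms)
  tr <- classify_transitions(d)$transitions
  tr <- assign_epochs(tr, detection_time = d$detection_time,
                      resolution_time = d$resolution_time)
  bind_cols(tibble(dyad_id = d$dyad_id, group = d$group, task = d$task,
                   .rows = nrow(tr)), tr)
}

#' Classify every dialogue of a corpus
#'
#' @param corpus A corpus tibble with a `dialogue` list-column (as produced
#'   by [simulate_corpus()] or [read_corpus_tables()]).
#' @inheritParams canonicalise_dialogue
#' @return A tidy transition tibble over all dialogues (see
#'   [classify_dialogue()]).
#' @export
classify_corpus <- function(corpus, min_pause_ms = 200) {
  stopifnot("dialogue" %in% names(corpus))
  purrr::list_rbind(lapply(corpus$dialogue, classify_dialogue,
                           min_pause_ms = min_pause_ms))
}

#' Restrict a transition table to floor transfers
#'
#' Within-overlaps do not involve a change of speaker and are excluded from
#' all turn-timing statistics. The counts of all three transition kinds are
#' retained in an accounting record attached as attribute `"accounting"`
#' (also available via [transition_accounting()]).
#'
#' @param transitions A transition tibble with a `kind` column.
#' @return The floor-transfer rows (gaps and between-overlaps), with the
#'   accounting record as attribute `"accounting"`.
#' @export
filter_for_timing <- function(transitions) {
  acc <- transition_accounting(transitions)
  out <- filter(transitions, .data$kind != "within_overlap")
  attr(out, "accounting") <- acc
  out
}

#' Transition accounting record
#'
#' @param transitions A transition tibble with a `kind` column.
#' @return A one-row tibble: `n_gap`, `n_between`, `n_within`, `n_total`,
#'   `gap_share` (of all transitions), `n_timing` (after excluding
#'   within-overlaps) and `timing_gap_share` / `timing_overlap_share`
#'   (within the timing set).
#' @export
transition_accounting <- function(transitions) {
  n_gap <- sum(transitions$kind == "gap")
  n_between <- sum(transitions$kind == "between_overlap")
  n_within <- sum(transitions$kind == "within_overlap")
  n_total <- n_gap + n_between + n_within
  n_timing <- n_gap + n_between
  tibble(n_gap = n_gap, n_between = n_between, n_within = n_within,
         n_total = n_total,
         gap_share = if (n_total) n_gap / n_total else NA_real_,
         n_timing = n_timing,
         timing_gap_share = if (n_timing) n_gap / n_timing else NA_real_,
         timing_overlap_share = if (n_timing) n_between / n_timing else NA_real_)
}

#' Profile within-overlap events
#'
#' Within-overlaps are typically very short and mostly consist of
#' backchannel tokens (listener signals such as "mhm" or "yeah"). A label is
#' counted as a backchannel when, lower-cased and stripped of punctuation,
#' it matches an entry of the lexicon as a whole.
#'
#' @param transitions A transition tibble.
#' @param backchannel_lexicon Character vector of backchannel forms.
#' @return A one-row tibble: `n`, `mean_duration_ms`, `backchannel_prop`
#'   (both `NA` when there are no within-overlaps), plus the input table's
#'   within-overlap rows with an `is_backchannel` flag as attribute
#'   `"events"`.
#' @export
within_overlap_profile <- function(transitions,
                                   backchannel_lexicon = default_backchannels()) {
  stopifnot(length(backchannel_lexicon) > 0)
  w <- filter(transitions, .data$kind == "within_overlap")
  norm <- function(x) gsub("[[:punct:]]", "", tolower(trimws(x)))
  lex <- norm(backchannel_lexicon)
  w$is_backchannel <- !is.na(w$label) & norm(w$label) %in% lex
  out <- tibble(
    n = nrow(w),
    mean_duration_ms = if (nrow(w)) mean(w$duration_ms) else NA_real_,
    backchannel_prop = if (nrow(w)) mean(w$is_backchannel) else NA_real_)
  attr(out, "events") <- w
  out
}

#' Default backchannel lexicon
#'
#' Short listener signals common in German conversation (plus a few
#' English-origin forms that occur in German speech).
#' @return A character vector.
#' @export
default_backchannels <- function() {
  c("mhm", "mmhm", "hm", "hmm", "mhmh", "ja", "jaja", "okay", "ok",
    "genau", "yeah", "aha", "achso", "gut", "stimmt")
}
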