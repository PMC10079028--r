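# Independent oracles used across the suite. These deliberately re-derive
# results by brute force (1 ms grid, explicit floor tracking, scan-merge
# loops) and share no code with the package internals they check.

# --- brute-force scan-merge canonicalisation -------------------------------
oracle_merge_channel <- function(channel, min_pause_ms = 200) {
  ch <- channel[order(channel$start), , drop = FALSE]
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(ch)) {
      gap <- ch$start[i + 1L] - ch$end[i]
      if (gap < min_pause_ms / 1000 - 1e-9) {
        ch$end[i] <- ch$end[i + 1L]
        ch$label[i] <- paste(ch$label[i], ch$label[i + 1L])
        ch$filled_pause[i] <- ch$filled_pause[i] && ch$filled_pause[i + 1L]
        ch <- ch[-(i + 1L), , drop = FALSE]
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  ch
}

# --- 1 ms-grid classifier with explicit floor tracking ---------------------
oracle_classify <- function(dialogue) {
  ip <- dialogue$ipus
  spk <- dialogue$speakers
  ms <- function(x) as.integer(round(x * 1000))
  end_ms <- max(ms(ip$end)) + 2L
  act <- sapply(spk, function(s) {
    v <- logical(end_ms)
    ch <- ip[ip$speaker == s, , drop = FALSE]
    for (i in seq_len(nrow(ch))) {
      a <- ms(ch$start[i]); b <- ms(ch$end[i])
      if (b > a) v[(a + 1L):b] <- TRUE
    }
    v
  })
  lab <- ifelse(act[, 1] & act[, 2], "both",
                ifelse(act[, 1], spk[1], ifelse(act[, 2], spk[2], "neither")))
  r <- rle(lab)
  rends <- cumsum(r$lengths)
  rstarts <- c(1L, head(rends, -1L) + 1L)
  chan <- lapply(setNames(spk, spk), function(s) {
    ch <- ip[ip$speaker == s, , drop = FALSE]
    ch <- ch[order(ch$start), , drop = FALSE]
    ch$start_ms <- ms(ch$start); ch$end_ms <- ms(ch$end)
    ch
  })
  other <- setNames(rev(spk), spk)

  floor <- NA_character_
  lse <- NA_integer_  # floor speaker's last single-activity cell
  first_floor <- NA_character_
  transfers <- list()
  transfer_keys <- character(0)
  anchors <- numeric(0)
  incomings <- character(0)
  for (k in seq_along(r$values)) {
    L <- r$values[k]
    if (L %in% spk) {
      if (is.na(floor)) {
        floor <- L; first_floor <- L; lse <- rends[k]
      } else if (L == floor) {
        lse <- rends[k]
      } else {
        chS <- chan[[L]]
        kin <- min(which(chS$end_ms > lse))
        chF <- chan[[floor]]
        kout <- max(which(chF$start_ms < lse))
        transfers[[length(transfers) + 1L]] <- data.frame(
          kind = if (chS$start[kin] >= chF$end[kout]) "gap" else "between_overlap",
          fto_ms = (chS$start[kin] - chF$end[kout]) * 1000,
          outgoing = floor, incoming = L, anchor_time = chS$start[kin])
        transfer_keys <- c(transfer_keys, paste(L, kin), paste(floor, kout))
        anchors <- c(anchors, chS$start[kin])
        incomings <- c(incomings, L)
        floor <- L; lse <- rends[k]
      }
    }
  }
  within <- list()
  for (k in which(r$values == "both")) {
    cell <- rstarts[k]
    bs <- (cell - 1L) / 1000
    prior <- which(anchors <= bs + 1e-9)
    f <- if (length(prior)) incomings[max(prior)] else first_floor
    if (is.na(f)) next
    emb <- other[[f]]
    chE <- chan[[emb]]
    j <- which(chE$start_ms < cell & chE$end_ms >= cell)
    if (!length(j)) next
    j <- j[1]
    if (!paste(emb, j) %in% transfer_keys) {
      within[[length(within) + 1L]] <- data.frame(
        kind = "within_overlap", outgoing = f, incoming = emb,
        anchor_time = chE$start[j],
        duration_ms = (chE$end[j] - chE$start[j]) * 1000,
        label = chE$label[j])
    }
  }
  w <- if (length(within)) unique(do.call(rbind, within)) else
    data.frame(kind = character(), outgoing = character(),
               incoming = character(), anchor_time = numeric(),
               duration_ms = numeric(), label = character())
  list(transfers = if (length(transfers)) do.call(rbind, transfers) else
    data.frame(kind = character(), fto_ms = numeric(), outgoing = character(),
               incoming = character(), anchor_time = numeric()),
    within = w[order(w$anchor_time), , drop = FALSE])
}

# --- adversarial random dialogues on a 1 ms grid ---------------------------
# Independent channels plus deliberate boundary alignments: touching starts,
# simultaneous stops, nested overlaps, interjections inside pauses.
random_dialogue <- function(seed) {
  set.seed(seed)
  span <- sample(8000:16000, 1)
  gen <- function() {
    t <- sample(0:600, 1)
    s <- e <- integer(0)
    while (t < span - 400L) {
      d <- sample(80:1600, 1)
      s <- c(s, t); e <- c(e, t + d)
      pause <- sample(c(200L, 200L, sample(200:1400, 1)), 1)
      t <- t + d + pause
    }
    cbind(s, e)
  }
  a <- gen()
  b <- gen()
  # snap some B boundaries onto A boundaries to force degenerate alignments
  for (i in seq_len(nrow(b))) {
    if (runif(1) < 0.15 && nrow(a)) {
      tgt <- sample(c(a[, 1], a[, 2]), 1)
      b[i, ] <- b[i, ] + (tgt - b[i, 1])
    } else if (runif(1) < 0.10 && nrow(a)) {
      tgt <- sample(a[, 2], 1)
      if (tgt > b[i, 1]) b[i, 2] <- tgt
    }
  }
  b <- b[order(b[, 1]), , drop = FALSE]
  # repair channel B: drop IPUs violating the canonical invariants
  keep <- rep(TRUE, nrow(b))
  last_e <- -1000L
  for (i in seq_len(nrow(b))) {
    if (b[i, 1] - last_e < 200L || b[i, 2] <= b[i, 1] || b[i, 2] > span) {
      keep[i] <- FALSE
    } else {
      last_e <- b[i, 2]
    }
  }
  b <- b[keep, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) return(random_dialogue(seed + 10000L))
  ipus <- tibble::tibble(
    speaker = c(rep("A", nrow(a)), rep("B", nrow(b))),
    start = c(a[, 1], b[, 1]) / 1000,
    end = c(a[, 2], b[, 2]) / 1000,
    label = paste0("u", seq_len(nrow(a) + nrow(b))))
  dialogue_record(ipus, dyad_id = "RND", group = "CTR",
                  task_span = c(0, span / 1000))
}

expect_classification_matches_oracle <- function(dialogue) {
  got <- classify_transitions(dialogue)$transitions
  want <- oracle_classify(dialogue)
  gt <- got[got$kind != "within_overlap", , drop = FALSE]
  expect_equal(nrow(gt), nrow(want$transfers))
  if (nrow(gt)) {
    expect_identical(unname(gt$kind), unname(want$transfers$kind))
    expect_equal(gt$fto_ms, want$transfers$fto_ms, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_identical(unname(gt$outgoing), unname(want$transfers$outgoing))
    expect_identical(unname(gt$incoming), unname(want$transfers$incoming))
    expect_equal(gt$anchor_time, want$transfers$anchor_time, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  gw <- got[got$kind == "within_overlap", , drop = FALSE]
  expect_equal(nrow(gw), nrow(want$within))
  if (nrow(gw)) {
    expect_equal(gw$anchor_time, want$within$anchor_time, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(gw$duration_ms, want$within$duration_ms, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_identical(unname(gw$incoming), unname(want$within$incoming))
  }
  invisible(TRUE)
}
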