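two_speaker <- function(a_start, a_end, b_start, b_end, b_label = NULL) {
  n_a <- length(a_start); n_b <- length(b_start)
  dialogue_record(tibble::tibble(
    speaker = c(rep("A", n_a), rep("B", n_b)),
    start = c(a_start, b_start), end = c(a_end, b_end),
    label = c(paste0("a", seq_len(n_a)),
              b_label %||% paste0("b", seq_len(n_b)))),
    dyad_id = "D1", group = "ASD")
}

test_that("the state timeline tiles the span with alternating labels", {
  d <- two_speaker(0, 1, 2, 3)
  tl <- build_state_timeline(d)
  expect_identical(tl$label, c("A", "neither", "B"))
  expect_equal(tl$start, c(0, 1, 2))
  expect_equal(tl$end, c(1, 2, 3))
  d2 <- two_speaker(0, 2, 1, 3)
  expect_identical(build_state_timeline(d2)$label, c("A", "both", "B"))
  # intervals tile exactly and neighbours always differ
  tl2 <- build_state_timeline(d2)
  expect_equal(tl2$start[-1], tl2$end[-nrow(tl2)])
  expect_true(all(tl2$label[-1] != tl2$label[-nrow(tl2)]))
})

test_that("gaps, between-overlaps and within-overlaps follow the taxonomy", {
  # A ends at 1.0, B starts at 1.6: silent gap with FTO +600 ms
  gap <- classify_transitions(two_speaker(0, 1, 1.6, 2.6))$transitions
  expect_identical(gap$kind, "gap")
  expect_equal(gap$fto_ms, 600)
  expect_equal(gap$anchor_time, 1.6)

  # B starts 400 ms before A's turn ends and keeps the floor: FTO -400 ms
  ov <- classify_transitions(two_speaker(0, 2, 1.6, 3))$transitions
  expect_identical(ov$kind, "between_overlap")
  expect_equal(ov$fto_ms, -400)

  # B utters 300 ms fully inside A's IPU and A continues: one
  # within-overlap, no floor transfer, no FTO
  wi <- classify_transitions(two_speaker(0, 3, 1.0, 1.3, "mhm"))$transitions
  expect_identical(wi$kind, "within_overlap")
  expect_true(is.na(wi$fto_ms))
  expect_equal(wi$duration_ms, 300)
  expect_identical(wi$label, "mhm")

  # perfect latching (FTO exactly 0) counts as a gap
  latch <- classify_transitions(two_speaker(0, 1, 1, 2))$transitions
  expect_identical(latch$kind, "gap")
  expect_equal(latch$fto_ms, 0)
})

test_that("an interjection inside the floor-holder's pause makes two floor transfers", {
  # A pauses 1.0-2.0; B speaks 1.2-1.6 entirely in the clear
  d <- two_speaker(c(0, 2), c(1, 3), 1.2, 1.6)
  tr <- classify_transitions(d)$transitions
  expect_identical(tr$kind, c("gap", "gap"))
  expect_equal(tr$fto_ms, c(200, 400))
  expect_identical(tr$incoming, c("B", "A"))
})

test_that("overlap then joint silence then resumption is one transfer with negative FTO", {
  # A 0-2, B 1.5-2 (simultaneous stop), B resumes 2.5: FTO = 1.5 - 2 = -500
  d <- two_speaker(0, 2, c(1.5, 2.5), c(2, 3))
  tr <- classify_transitions(d)$transitions
  expect_equal(nrow(tr), 1L)
  expect_identical(tr$kind, "between_overlap")
  expect_equal(tr$fto_ms, -500)
  expect_equal(tr$anchor_time, 1.5)
})

test_that("turns alternate and floor-transfer indices are consecutive", {
  res <- classify_transitions(canonicalise_dialogue(
    simulate_dialogue(default_params(), "CTR", seed = 21,
                      n_transitions = 80)$dialogue))
  ft <- res$transitions[res$transitions$kind != "within_overlap", ]
  expect_equal(ft$index, seq_len(nrow(ft)))
  expect_true(all(ft$incoming[-1] == ft$outgoing[-nrow(ft)]))
  expect_true(all(res$turns$speaker[-1] != res$turns$speaker[-nrow(res$turns)]))
  # sign law
  expect_true(all(ft$fto_ms[ft$kind == "gap"] >= 0))
  expect_true(all(ft$fto_ms[ft$kind == "between_overlap"] < 0))
})

test_that("classification is invariant to time shifts and symmetric in speakers", {
  d <- random_dialogue(77)
  base <- classify_transitions(d)$transitions
  shifted <- d
  shifted$ipus$start <- shifted$ipus$start + 5
  shifted$ipus$end <- shifted$ipus$end + 5
  shifted$task_span <- shifted$task_span + 5
  got <- classify_transitions(shifted)$transitions
  expect_identical(unname(got$kind), unname(base$kind))
  expect_equal(got$fto_ms, base$fto_ms, tolerance = 1e-9)
  expect_equal(got$anchor_time, base$anchor_time + 5, tolerance = 1e-9)

  swapped <- d
  swapped$ipus$speaker <- ifelse(swapped$ipus$speaker == "A", "B", "A")
  swapped$ipus <- dplyr::arrange(swapped$ipus, speaker, start)
  swapped$speakers <- c("A", "B")
  sw <- classify_transitions(swapped)$transitions
  expect_identical(unname(sw$kind), unname(base$kind))
  expect_equal(sw$fto_ms, base$fto_ms, tolerance = 1e-9)
  expect_identical(unname(sw$outgoing),
                   unname(ifelse(base$outgoing == "A", "B", "A")))
})

test_that("classification equals the millisecond-grid floor-tracking oracle", {
  for (s in 1:150) {
    expect_classification_matches_oracle(random_dialogue(s))
  }
})

test_that("filtering for timing keeps counts in an accounting record", {
  tr <- classify_dialogue(simulate_dialogue(default_params(), "ASD", seed = 5,
                                            n_transitions = 100)$dialogue)
  ft <- filter_for_timing(tr)
  acc <- attr(ft, "accounting")
  expect_equal(acc$n_total, acc$n_gap + acc$n_between + acc$n_within)
  expect_equal(nrow(ft), acc$n_timing)
  expect_false(any(ft$kind == "within_overlap"))
  # all-gap input is passed through unchanged
  gaps <- tr[tr$kind == "gap", ]
  expect_equal(nrow(filter_for_timing(gaps)), nrow(gaps))
})

test_that("within-overlap profiling counts backchannels by normalised label", {
  tr <- tibble::tibble(kind = rep("within_overlap", 2),
                       duration_ms = c(300, 500),
                       label = c("Mhm!", "so I think"))
  prof <- within_overlap_profile(tr)
  expect_equal(prof$backchannel_prop, 0.5)
  expect_equal(prof$mean_duration_ms, 400)
  none <- within_overlap_profile(tr[0, ])
  expect_equal(none$n, 0L)
  expect_true(is.na(none$mean_duration_ms))
  expect_true(is.na(none$backchannel_prop))
})
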