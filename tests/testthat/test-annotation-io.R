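long_textgrid <- function(path) {
  writeLines(c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    '',
    'xmin = 0',
    'xmax = 2',
    'tiers? <exists>',
    'size = 2',
    'item []:',
    '    item [1]:',
    '        class = "IntervalTier"',
    '        name = "left"',
    '        xmin = 0',
    '        xmax = 2',
    '        intervals: size = 3',
    '        intervals [1]:',
    '            xmin = 0',
    '            xmax = 1',
    '            text = "hello"',
    '        intervals [2]:',
    '            xmin = 1',
    '            xmax = 1.2',
    '            text = ""',
    '        intervals [3]:',
    '            xmin = 1.2',
    '            xmax = 1.5',
    '            text = "yes"',
    '    item [2]:',
    '        class = "IntervalTier"',
    '        name = "right"',
    '        xmin = 0',
    '        xmax = 2',
    '        intervals: size = 1',
    '        intervals [1]:',
    '            xmin = 0',
    '            xmax = 2',
    '            text = ""'
  ), path)
  path
}

short_textgrid <- function(path) {
  writeLines(c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    '',
    '0',
    '2',
    '<exists>',
    '2',
    '"IntervalTier"',
    '"left"',
    '0',
    '2',
    '3',
    '0',
    '1',
    '"hello"',
    '1',
    '1.2',
    '""',
    '1.2',
    '1.5',
    '"yes"',
    '"IntervalTier"',
    '"right"',
    '0',
    '2',
    '1',
    '0',
    '2',
    '""'
  ), path)
  path
}

test_that("long and short TextGrid dialects parse to identical IPUs", {
  fl <- long_textgrid(withr::local_tempfile(fileext = ".TextGrid"))
  fs <- short_textgrid(withr::local_tempfile(fileext = ".TextGrid"))
  a <- read_textgrid(fl, "left")$left
  b <- read_textgrid(fs, "left")$left
  expect_equal(nrow(a), 2L)                # empty intervals are silence
  expect_equal(a$start, c(0, 1.2))
  expect_equal(a$end, c(1, 1.5))
  expect_identical(a$label, c("hello", "yes"))
  expect_equal(a, b)
  # a tier with no non-empty intervals yields an empty IPU set
  expect_equal(nrow(read_textgrid(fl, "right")$right), 0L)
})

test_that("missing tiers and malformed files give informative errors", {
  fl <- long_textgrid(withr::local_tempfile(fileext = ".TextGrid"))
  expect_error(read_textgrid(fl, "nope"), "available tiers.*left.*right")
  bad <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines("not a textgrid at all", bad)
  expect_error(read_textgrid(bad), "not a TextGrid")
})

test_that("filled-pause-only labels are flagged but kept as speech", {
  f <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', '',
    'xmin = 0', 'xmax = 2', 'tiers? <exists>', 'size = 1', 'item []:',
    '    item [1]:', '        class = "IntervalTier"',
    '        name = "left"', '        xmin = 0', '        xmax = 2',
    '        intervals: size = 2',
    '        intervals [1]:', '            xmin = 0',
    '            xmax = 1', '            text = "<uhm>"',
    '        intervals [2]:', '            xmin = 1.3',
    '            xmax = 2', '            text = "so"'), f)
  ch <- read_textgrid(f, "left")$left
  expect_equal(nrow(ch), 2L)
  expect_identical(ch$filled_pause, c(TRUE, FALSE))
})

test_that("dialogues round-trip through TextGrid files", {
  sim <- simulate_dialogue(default_params(), "ASD", dyad_id = "RT01",
                           seed = 14, n_transitions = 40)
  d <- sim$dialogue
  f <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(d, f)
  back <- read_textgrid_dialogue(f, tier_names = d$speakers,
                                 meta = list(dyad_id = d$dyad_id,
                                             group = d$group,
                                             task_span = d$task_span))
  expect_equal(back$ipus$start, d$ipus$start, tolerance = 1e-6)
  expect_equal(back$ipus$end, d$ipus$end, tolerance = 1e-6)
  expect_identical(back$ipus$label, d$ipus$label)
})

test_that("IPU tables round-trip with their YAML sidecar", {
  sim <- simulate_dialogue(default_params(), "CTR", dyad_id = "RT02",
                           seed = 15, n_transitions = 40)
  d <- sim$dialogue
  dir <- withr::local_tempdir()
  f <- file.path(dir, "rt02.tsv")
  write_ipu_table(d, f)
  back <- read_ipu_table(f)
  expect_equal(back$ipus$start, d$ipus$start, tolerance = 1e-9)
  expect_equal(back$ipus$end, d$ipus$end, tolerance = 1e-9)
  expect_identical(back$dyad_id, d$dyad_id)
  expect_identical(back$group, d$group)
  expect_equal(back$detection_time, d$detection_time, tolerance = 1e-9)
  expect_equal(back$task_span, d$task_span, tolerance = 1e-9)
  # the tabular route and the in-memory record classify identically
  expect_equal(classify_dialogue(back)$fto_ms, classify_dialogue(d)$fto_ms,
               tolerance = 1e-6)
})

test_that("IPU tables with bad content are rejected", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")
  writeLines(c("speaker,start,end,label", "A,0,1,x", "B,1,2,y", "C,2,3,z"), f)
  meta <- list(dyad_id = "D1", group = "ASD")
  expect_error(read_ipu_table(f, meta), "speakers")
  expect_error(read_ipu_table(f, list(dyad_id = "D1", group = "XXX")), "group")
  f2 <- file.path(dir, "bad2.csv")
  writeLines(c("speaker,start,end,label", "A,zero,1,x"), f2)
  expect_error(read_ipu_table(f2, meta), "numeric")
  f3 <- file.path(dir, "bad3.csv")
  writeLines(c("speaker,begin,finish,label", "A,0,1,x"), f3)
  expect_error(read_ipu_table(f3, meta), "lacks column")
})

test_that("transition tables round-trip and encode the schema", {
  # empty in, header-only file out
  tr0 <- classify_dialogue(simulate_dialogue(default_params(), "ASD",
                                             seed = 16,
                                             n_transitions = 50)$dialogue)
  dir <- withr::local_tempdir()
  f0 <- file.path(dir, "empty.tsv")
  write_transitions(tr0[0, ], f0)
  expect_equal(nrow(read_transitions(f0)), 0L)

  f <- file.path(dir, "tr.tsv")
  write_transitions(tr0, f)
  back <- read_transitions(f)
  expect_equal(nrow(back), nrow(tr0))
  expect_identical(back$type, tr0$kind)
  expect_equal(back$fto_ms, round(tr0$fto_ms))        # ms are integer-rounded
  expect_equal(back$time_s, tr0$anchor_time, tolerance = 1e-6)
  expect_identical(back$epoch2, as.character(tr0$epoch2))
  expect_true(all(is.na(back$fto_ms[back$type == "within_overlap"])))

  # a +600 ms gap is written as type "gap", fto_ms 600
  one <- tibble::tibble(dyad_id = "D1", group = "ASD", task = 1L, index = 1L,
                        kind = "gap", fto_ms = 600.2, outgoing = "A",
                        incoming = "B", anchor_time = 1.6,
                        duration_ms = NA_real_, label = NA_character_,
                        epoch2 = factor("beginning"), epoch3 = NA)
  f1 <- file.path(dir, "one.tsv")
  write_transitions(one, f1)
  row <- read_transitions(f1)
  expect_identical(row$type, "gap")
  expect_equal(row$fto_ms, 600)
})

test_that("a corpus survives the write/read directory round trip", {
  corp <- small_corpus()
  dir <- withr::local_tempdir()
  write_corpus_tables(corp, dir)
  back <- read_corpus_tables(dir)
  expect_equal(nrow(back), nrow(corp))
  tr_a <- dplyr::arrange(classify_corpus(corp), dyad_id, task, anchor_time)
  tr_b <- dplyr::arrange(classify_corpus(back), dyad_id, task, anchor_time)
  expect_equal(tr_a$fto_ms, tr_b$fto_ms, tolerance = 1e-6)
  expect_identical(tr_a$kind, tr_b$kind)
  expect_identical(as.character(tr_a$epoch3), as.character(tr_b$epoch3))
})
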