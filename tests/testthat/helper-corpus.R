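# Shared, lazily built fixtures. The calibrated corpus matches the study
# design (7 disposition-matched dyads per group) with several Map-Task
# dialogues per dyad so that each group pools >= 2000 floor transfers
# (>= 2000 of them in the beginning epoch across the corpus scale used for
# group contrasts).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

calibrated_corpus <- function() {
  cached("corpus", function() {
    params <- default_params()
    corpus <- simulate_corpus(params, n_dyads_per_group = 7, n_tasks = 8,
                              seed = 20230406)
    transitions <- classify_corpus(corpus)
    timing <- filter_for_timing(transitions)
    list(params = params, corpus = corpus, transitions = transitions,
         timing = timing)
  })
}

small_corpus <- function() {
  cached("small_corpus", function() {
    params <- default_params()
    simulate_corpus(params, n_dyads_per_group = 2, n_tasks = 1,
                    seed = 11, n_transitions = 120)
  })
}
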