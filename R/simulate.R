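#' Default parameters for the synthetic dialogue generator
#'
#' Builds a full [simulate_corpus()] parameter set. With
#' `calibration = "paper"` the per-cell FTO mixtures (group x dialogue
#' stage) are solved numerically so that each cell's implied FTO mean and SD
#' match the reference Map-Task corpus cells -- ASD beginning 511 (SD 799),
#' ASD remainder 299 (576), CTR beginning 191 (530), CTR remainder 243
#' (558) ms -- with a 28\% overlap (negative-FTO) share and a modal gap
#' near +200 ms.
#'
#' The FTO mixture of a cell has three components:
#' \itemize{
#'   \item with probability `p_neg` an overlap: FTO = -L with L lognormal
#'     (`neg_meanlog`, `neg_sdlog`);
#'   \item otherwise a "core" short gap: lognormal with mode `core_mode_ms`
#'     and log-SD `core_sdlog` (shared across cells), the near-universal
#'     ~200 ms transition;
#'   \item or, with conditional weight `long_weight`, a "long gap"
#'     lognormal (`long_meanlog`, `long_sdlog`), whose per-cell weight and
#'     median are solved in closed form from the cell's target mean and SD.
#' }
#' Cells whose targets cannot be reached by any admissible weight/median
#' raise an explicit error.
#'
#' @param calibration `"paper"` (the built-in reference cell targets) or a tibble
#'   with columns `group`, `stage` (`beginning`/`remainder`), `mean_ms`,
#'   `sd_ms`.
#' @param p_neg Overlap share of floor transfers.
#' @param neg_median_ms,neg_sdlog Overlap-magnitude lognormal: median (ms)
#'   and log-SD.
#' @param core_mode_ms,core_sdlog Core gap lognormal: mode (ms) and log-SD.
#' @param long_sdlog Long-gap lognormal log-SD (median solved per cell).
#' @param within_rate Expected within-overlap insertions per turn (Poisson).
#' @param within_mean_ms,within_sdlog Within-overlap duration lognormal:
#'   mean (ms) and log-SD.
#' @param backchannel_prob Probability that a within-overlap is labelled
#'   with a backchannel token.
#' @param detection_fraction,resolution_fraction Position of the first
#'   Mismatch's detection / resolution as a fraction of the dialogue's
#'   floor transfers.
#' @param dyad_shift_sd_ms SD (ms) of the dyad-level additive FTO shift.
#' @param n_transitions_mean Expected floor transfers per dialogue.
#' @param turn_ipus_mean Expected IPUs per turn (shifted geometric).
#' @param ipu_median_s,ipu_sdlog IPU duration lognormal: median (s), log-SD.
#' @param pause_excess_median_s,pause_excess_sdlog Within-speaker pause
#'   beyond the 200 ms minimum: lognormal median (s) and log-SD.
#' @param min_pause_ms Minimum within-speaker pause (ms).
#' @param backchannel_lexicon Labels used for backchannel tokens.
#' @return A list of class `fto_sim_params`; `$cells` holds the solved
#'   per-cell mixtures.
#' @export
default_params <- function(calibration = "paper",
                           p_neg = 0.28,
                           neg_median_ms = 250, neg_sdlog = 0.8,
                           core_mode_ms = 200, core_sdlog = 0.35,
                           long_sdlog = 0.5,
                           within_rate = 0.2,
                           within_mean_ms = 380, within_sdlog = 0.5,
                           backchannel_prob = 0.70,
                           detection_fraction = 0.095,
                           resolution_fraction = 0.225,
                           dyad_shift_sd_ms = 90,
                           n_transitions_mean = 400,
                           turn_ipus_mean = 3.25,
                           ipu_median_s = 0.7, ipu_sdlog = 0.6,
                           pause_excess_median_s = 0.15, pause_excess_sdlog = 0.8,
                           min_pause_ms = 200,
                           backchannel_lexicon = default_backchannels()) {
  targets <- if (is.character(calibration) && identical(calibration, "paper")) {
    tibble(group = rep(c("ASD", "CTR"), each = 2),
           stage = rep(c("beginning", "remainder"), 2),
           mean_ms = c(511, 299, 191, 243),
           sd_ms = c(799, 576, 530, 558))
  } else {
    as_tibble(calibration)
  }
  stopifnot(all(c("group", "stage", "mean_ms", "sd_ms") %in% names(targets)),
            p_neg >= 0, p_neg < 1)
  cells <- targets
  sol <- purrr::pmap(targets[c("mean_ms", "sd_ms")], function(mean_ms, sd_ms) {
    solve_gap_mixture(mean_ms, sd_ms, p_neg = p_neg,
                      neg_meanlog = log(neg_median_ms), neg_sdlog = neg_sdlog,
                      core_mode_ms = core_mode_ms, core_sdlog = core_sdlog,
                      long_sdlog = long_sdlog)
  })
  cells$p_neg <- p_neg
  cells$neg_meanlog <- log(neg_median_ms)
  cells$neg_sdlog <- neg_sdlog
  cells$core_meanlog <- log(core_mode_ms) + core_sdlog^2
  cells$core_sdlog <- core_sdlog
  cells$long_meanlog <- vapply(sol, `[[`, 0, "long_meanlog")
  cells$long_sdlog <- long_sdlog
  cells$long_weight <- vapply(sol, `[[`, 0, "long_weight")
  structure(list(
    cells = cells,
    within_rate = within_rate,
    within_meanlog = log(within_mean_ms) - within_sdlog^2 / 2,
    within_sdlog = within_sdlog,
    backchannel_prob = backchannel_prob,
    detection_fraction = detection_fraction,
    resolution_fraction = resolution_fraction,
    dyad_shift_sd_ms = dyad_shift_sd_ms,
    n_transitions_mean = n_transitions_mean,
    turn_ipus_mean = turn_ipus_mean,
    ipu_meanlog = log(ipu_median_s), ipu_sdlog = ipu_sdlog,
    pause_excess_meanlog = log(pause_excess_median_s),
    pause_excess_sdlog = pause_excess_sdlog,
    min_pause_ms = min_pause_ms,
    backchannel_lexicon = backchannel_lexicon), class = "fto_sim_params")
}

# Solve the long-gap weight q and median so the three-component mixture hits
# the cell's target mean and SD exactly (in expectation). Writing A and B for
# the mean and second-moment excess of the positive part over the core
# component, q*m_l = A and q*m_l^2*e^{s^2} = B + q*E2_c - ... reduce to a
# quadratic in the long-component mean m_l.
solve_gap_mixture <- function(mean_ms, sd_ms, p_neg, neg_meanlog, neg_sdlog,
                              core_mode_ms, core_sdlog, long_sdlog) {
  m_n <- exp(neg_meanlog + neg_sdlog^2 / 2)
  E2_n <- exp(2 * neg_meanlog + 2 * neg_sdlog^2)
  core_meanlog <- log(core_mode_ms) + core_sdlog^2
  m_c <- exp(core_meanlog + core_sdlog^2 / 2)
  E2_c <- exp(2 * core_meanlog + 2 * core_sdlog^2)
  m_pos <- (mean_ms + p_neg * m_n) / (1 - p_neg)
  E2_pos <- (sd_ms^2 + mean_ms^2 - p_neg * E2_n) / (1 - p_neg)
  A <- m_pos - m_c
  B <- E2_pos - E2_c
  fail <- function(why) {
    abort(sprintf(
      "infeasible FTO cell target (mean %g, SD %g): %s", mean_ms, sd_ms, why))
  }
  if (A <= 0) fail("target mean below the core gap component's mean")
  if (B <= 0) fail("target SD too small for the core gap component")
  es <- exp(long_sdlog^2)
  disc <- B^2 - 4 * A * es * (B * m_c - A * E2_c)
  if (disc < 0) fail("no real long-gap solution")
  m_l <- (B + sqrt(disc)) / (2 * A * es)
  q <- A / (m_l - m_c)
  if (!is.finite(q) || q <= 0 || q > 1 || m_l <= m_c) {
    fail("long-gap weight outside (0, 1]")
  }
  list(long_weight = q, long_meanlog = log(m_l) - long_sdlog^2 / 2)
}

#' Implied FTO moments of a generator cell
#'
#' Closed-form mean and SD of the three-component FTO mixture of one
#' generator cell (before any dyad shift), plus the negative-FTO share.
#'
#' @param params An [default_params()] object.
#' @param group,stage Cell selectors.
#' @return A one-row tibble: `mean_ms`, `sd_ms`, `p_negative`.
#' @export
cell_fto_moments <- function(params, group, stage) {
  mixture_moments(sim_cell(params, group, stage))
}

# closed-form moments of one cell's three-component FTO mixture
mixture_moments <- function(cp) {
  m_n <- exp(cp$neg_meanlog + cp$neg_sdlog^2 / 2)
  E2_n <- exp(2 * cp$neg_meanlog + 2 * cp$neg_sdlog^2)
  m_c <- exp(cp$core_meanlog + cp$core_sdlog^2 / 2)
  E2_c <- exp(2 * cp$core_meanlog + 2 * cp$core_sdlog^2)
  m_l <- exp(cp$long_meanlog + cp$long_sdlog^2 / 2)
  E2_l <- exp(2 * cp$long_meanlog + 2 * cp$long_sdlog^2)
  q <- cp$long_weight; p <- cp$p_neg
  mean_ms <- -p * m_n + (1 - p) * ((1 - q) * m_c + q * m_l)
  E2 <- p * E2_n + (1 - p) * ((1 - q) * E2_c + q * E2_l)
  tibble(mean_ms = mean_ms, sd_ms = sqrt(E2 - mean_ms^2), p_negative = p)
}

sim_cell <- function(params, group, stage) {
  i <- which(params$cells$group == group & params$cells$stage == stage)
  if (!length(i)) abort(sprintf("no generator cell for %s/%s", group, stage))
  as.list(params$cells[i[1], ])
}

# Dyad-level FTO heterogeneity: shift the cell's mean by `shift_ms` and
# re-solve the long-gap component, so each dyad keeps the shared ~200 ms
# modal gap (dyads differ in how often and how long they pause, not in the
# location of the short-gap mode). Shifts too extreme for the mixture family
# are shrunk towards zero until feasible.
dyad_cell <- function(params, group, stage, shift_ms = 0) {
  cp <- sim_cell(params, group, stage)
  if (shift_ms == 0) return(cp)
  core_mode <- exp(cp$core_meanlog - cp$core_sdlog^2)
  s <- shift_ms
  for (k in 1:25) {
    sol <- tryCatch(
      solve_gap_mixture(cp$mean_ms + s, cp$sd_ms, p_neg = cp$p_neg,
                        neg_meanlog = cp$neg_meanlog, neg_sdlog = cp$neg_sdlog,
                        core_mode_ms = core_mode, core_sdlog = cp$core_sdlog,
                        long_sdlog = cp$long_sdlog),
      error = function(e) NULL)
    if (is.null(sol)) {
      # shifted mean outside the core+long family: describe the whole
      # positive part with a single lognormal matched to its mean and SD
      # (extreme dyads may then sit off the shared 200 ms mode, as a few
      # real dyads do)
      m_n <- exp(cp$neg_meanlog + cp$neg_sdlog^2 / 2)
      E2_n <- exp(2 * cp$neg_meanlog + 2 * cp$neg_sdlog^2)
      mt <- cp$mean_ms + s
      m_pos <- (mt + cp$p_neg * m_n) / (1 - cp$p_neg)
      E2_pos <- (cp$sd_ms^2 + mt^2 - cp$p_neg * E2_n) / (1 - cp$p_neg)
      if (m_pos > 0 && E2_pos > m_pos^2 * 1.0001) {
        sdl <- sqrt(log(E2_pos / m_pos^2))
        sol <- list(long_weight = 1,
                    long_meanlog = log(m_pos) - sdl^2 / 2,
                    long_sdlog = sdl)
      }
    }
    if (!is.null(sol)) {
      cp$mean_ms <- cp$mean_ms + s
      cp$long_meanlog <- sol$long_meanlog
      cp$long_weight <- sol$long_weight
      cp$long_sdlog <- sol$long_sdlog %||% cp$long_sdlog
      return(cp)
    }
    s <- s * 0.8
  }
  cp
}

#' Sample FTO values from one generator cell
#'
#' @inheritParams cell_fto_moments
#' @param n Number of draws.
#' @return Numeric vector of FTO values in ms.
#' @export
sample_cell_fto <- function(params, group, stage, n) {
  sample_from_cell(sim_cell(params, group, stage), n)
}

sample_from_cell <- function(cp, n) {
  u <- runif(n)
  out <- numeric(n)
  neg <- u < cp$p_neg
  long <- !neg & (u < cp$p_neg + (1 - cp$p_neg) * cp$long_weight)
  core <- !neg & !long
  out[neg] <- -rlnorm(sum(neg), cp$neg_meanlog, cp$neg_sdlog)
  out[long] <- rlnorm(sum(long), cp$long_meanlog, cp$long_sdlog)
  out[core] <- rlnorm(sum(core), cp$core_meanlog, cp$core_sdlog)
  out
}

#' Simulate one synthetic Map-Task-like dialogue
#'
#' Builds a two-speaker dialogue by alternating turns: each turn is a run of
#' IPUs separated by super-threshold within-speaker pauses; each floor
#' transfer's FTO is drawn from the current stage's mixture (plus the dyad
#' shift) and places the next speaker's turn; within-overlaps are inserted
#' strictly inside host IPUs without creating floor transfers. The epoch
#' marks are placed just before the floor transfer at the detection
#' (resolution) fraction, so by construction the ground truth records every
#' intended transition kind, FTO, and stage. Channels satisfy the canonical
#' invariants by construction.
#'
#' @param params An [default_params()] object.
#' @param group `"ASD"` or `"CTR"`.
#' @param dyad_id Dyad identifier.
#' @param task Task number.
#' @param dyad_shift_ms Dyad-level mean FTO shift (ms), realised by
#'   re-solving the gap mixture at the shifted mean so the dyad keeps the
#'   shared short-gap mode.
#' @param seed Optional integer seed.
#' @param n_transitions Number of floor transfers; default draws
#'   Poisson(`n_transitions_mean`).
#' @return A list: `dialogue` (a [dialogue_record()]) and `truth` (tibble of
#'   intended transitions: `index`, `kind`, `fto_ms`, `outgoing`,
#'   `incoming`, `anchor_time`, `duration_ms`, `label`, `stage`).
#' @export
simulate_dialogue <- function(params, group, dyad_id = "DY01", task = 1L,
                              dyad_shift_ms = 0, seed = NULL,
                              n_transitions = NULL) {
  stopifnot(inherits(params, "fto_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  n_tr <- n_transitions %||% max(10L, rpois(1, params$n_transitions_mean))
  k_det <- max(1L, round(params$detection_fraction * n_tr))
  k_res <- min(n_tr, max(k_det, round(params$resolution_fraction * n_tr)))
  spk <- paste0(dyad_id, "_S", 1:2)
  min_pause_s <- params$min_pause_ms / 1000
  margin <- 0.002

  ipu_s <- ipu_e <- numeric(0); ipu_spk <- ipu_lab <- character(0)
  truth <- vector("list", 2L * n_tr + 8L); n_truth <- 0L
  last_end <- c(0, 0) - 1  # per-speaker channel end
  names(last_end) <- spk
  cur <- 1L
  onset <- 0.2
  anchors <- numeric(n_tr)

  rand_label <- function(n) sprintf("tok%03d", sample.int(500L, n, replace = TRUE))
  cp_stage <- list(
    beginning = dyad_cell(params, group, "beginning", dyad_shift_ms),
    remainder = dyad_cell(params, group, "remainder", dyad_shift_ms))

  carry_overlap <- 0  # part of the previous speaker's last IPU still to outlast

  for (j in seq_len(n_tr + 1L)) {
    s_cur <- spk[cur]; s_oth <- spk[3L - cur]
    n_ipu <- 1L + rgeom(1L, 1 / params$turn_ipus_mean)
    durs <- rlnorm(n_ipu, params$ipu_meanlog, params$ipu_sdlog)
    # plan this turn's within-overlap insertions up front so that a host IPU
    # long enough for the longest embedded vocalisation is guaranteed
    n_w <- if (j <= n_tr) rpois(1L, params$within_rate) else 0L
    dur_w <- if (n_w > 0L)
      rlnorm(n_w, params$within_meanlog, params$within_sdlog) / 1000 else numeric(0)
    if (n_w > 0L && max(durs) < max(dur_w) + 4 * margin) {
      i_max <- which.max(durs)
      durs[i_max] <- max(dur_w) + 4 * margin + durs[i_max]
    }
    if (carry_overlap > 0) {
      # after a between-overlap the incoming turn's first IPU must extend
      # beyond the outgoing IPU's end, or no floor transfer would occur
      if (durs[1] <= carry_overlap + margin) {
        durs[1] <- carry_overlap + margin + durs[1]
      }
      carry_overlap <- 0
    }
    pauses <- if (n_ipu > 1L)
      min_pause_s + rlnorm(n_ipu - 1L, params$pause_excess_meanlog,
                           params$pause_excess_sdlog) else numeric(0)
    starts <- onset + cumsum(c(0, durs[-n_ipu] + pauses))
    ends <- starts + durs
    ipu_s <- c(ipu_s, starts); ipu_e <- c(ipu_e, ends)
    ipu_spk <- c(ipu_spk, rep(s_cur, n_ipu))
    ipu_lab <- c(ipu_lab, rand_label(n_ipu))
    offset <- ends[n_ipu]
    last_end[s_cur] <- offset
    if (j > n_tr) break

    stage <- if (j < k_det) "beginning" else "remainder"
    fto_s <- sample_from_cell(cp_stage[[stage]], 1L) / 1000
    # realise the sampled FTO exactly: if it is infeasible where the turn
    # currently ends (the incoming speaker's channel pause would drop below
    # the minimum, or an overlap would be deeper than the final IPU), extend
    # the outgoing turn's final IPU instead of censoring the draw
    delta <- max(0,
                 last_end[s_oth] + min_pause_s + margin - fto_s - offset,
                 if (fto_s < 0) -fto_s + margin - durs[n_ipu] else 0)
    if (delta > 0) {
      durs[n_ipu] <- durs[n_ipu] + delta
      ends[n_ipu] <- ends[n_ipu] + delta
      ipu_e[length(ipu_e)] <- ends[n_ipu]
      offset <- ends[n_ipu]
      last_end[s_cur] <- offset
    }
    nxt_onset <- offset + fto_s
    n_truth <- n_truth + 1L
    truth[[n_truth]] <- list(index = j,
                             kind = if (fto_s >= 0) "gap" else "between_overlap",
                             fto_ms = fto_s * 1000, outgoing = s_cur,
                             incoming = s_oth, anchor_time = nxt_onset,
                             duration_ms = NA_real_, label = NA_character_,
                             stage = stage)
    anchors[j] <- nxt_onset

    # within-overlaps embedded in this turn's IPUs (spoken by the interlocutor)
    for (k in seq_len(n_w)) {
      placed <- FALSE
      for (i in seq_len(n_ipu)) {
        lo <- max(starts[i] + margin, last_end[s_oth] + min_pause_s + margin)
        hi <- min(ends[i] - margin, nxt_onset - min_pause_s - margin) - dur_w[k]
        if (hi > lo) {
          b0 <- runif(1, lo, hi)
          lab <- if (runif(1) < params$backchannel_prob)
            sample(params$backchannel_lexicon, 1L) else rand_label(1L)
          ipu_s <- c(ipu_s, b0); ipu_e <- c(ipu_e, b0 + dur_w[k])
          ipu_spk <- c(ipu_spk, s_oth); ipu_lab <- c(ipu_lab, lab)
          last_end[s_oth] <- b0 + dur_w[k]
          n_truth <- n_truth + 1L
          truth[[n_truth]] <- list(index = NA_integer_, kind = "within_overlap",
                                   fto_ms = NA_real_, outgoing = s_cur,
                                   incoming = s_oth, anchor_time = b0,
                                   duration_ms = dur_w[k] * 1000, label = lab,
                                   stage = stage)
          placed <- TRUE
          break
        }
      }
      if (!placed) next
    }
    carry_overlap <- max(0, -fto_s)
    cur <- 3L - cur
    onset <- nxt_onset
  }

  truth <- bind_rows(truth[seq_len(n_truth)])
  truth <- arrange(truth, .data$anchor_time)
  det_t <- if (k_det <= n_tr) anchors[k_det] - 1e-6 else NA_real_
  res_t <- if (k_res <= n_tr) anchors[k_res] - 1e-6 else NA_real_
  d <- dialogue_record(
    tibble(speaker = ipu_spk, start = ipu_s, end = ipu_e, label = ipu_lab),
    dyad_id = dyad_id, group = group, task = task,
    detection_time = det_t, resolution_time = res_t,
    task_span = c(0, max(ipu_e) + 0.3))
  list(dialogue = d, truth = truth)
}

#' Simulate a corpus of disposition-matched dyads
#'
#' Draws one mean-FTO shift per dyad -- Normal(0, `dyad_shift_sd_ms`),
#' centred to mean zero within each group so that group contrasts are
#' identified in expectation even at small dyad counts -- and simulates
#' `n_tasks` dialogues per dyad with deterministic per-dialogue seeds
#' derived from the corpus seed.
#'
#' @param params An [default_params()] object.
#' @param n_dyads_per_group Dyads per group (default 7).
#' @param n_tasks Dialogues per dyad.
#' @param seed Integer seed for the whole corpus.
#' @param n_transitions Floor transfers per dialogue (default: Poisson
#'   around `params$n_transitions_mean`).
#' @return A corpus tibble: `dyad_id`, `group`, `task`, `dyad_shift_ms`,
#'   `dialogue` (list-column), `truth` (list-column).
#' @export
simulate_corpus <- function(params, n_dyads_per_group = 7, n_tasks = 1,
                            seed = NULL, n_transitions = NULL) {
  stopifnot(n_dyads_per_group >= 1, n_tasks >= 1)
  if (!is.null(seed)) set.seed(seed)
  groups <- c("ASD", "CTR")
  plan <- purrr::list_rbind(lapply(groups, function(g) {
    shifts <- rnorm(n_dyads_per_group, 0, params$dyad_shift_sd_ms)
    if (n_dyads_per_group > 1) shifts <- shifts - mean(shifts)
    tibble(dyad_id = sprintf("%s%02d", g, seq_len(n_dyads_per_group)),
           group = g, dyad_shift_ms = shifts)
  }))
  plan <- tidyr::crossing(plan, task = seq_len(n_tasks)) |>
    arrange(.data$group, .data$dyad_id, .data$task)
  plan$sim_seed <- sample.int(.Machine$integer.max - 1L, nrow(plan))
  sims <- purrr::pmap(plan, function(dyad_id, group, dyad_shift_ms, task, sim_seed) {
    simulate_dialogue(params, group = group, dyad_id = dyad_id, task = task,
                      dyad_shift_ms = dyad_shift_ms, seed = sim_seed,
                      n_transitions = n_transitions)
  })
  plan |>
    mutate(dialogue = lapply(sims, `[[`, "dialogue"),
           truth = lapply(sims, `[[`, "truth")) |>
    select("dyad_id", "group", "task", "dyad_shift_ms", "dialogue", "truth")
}
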