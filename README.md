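# turntiming

Conversational turn-timing analysis from dual-speaker interval
annotations: from interpausal units (IPUs) to Floor Transfer Offset (FTO)
distributions, dialogue-stage contrasts, and Bayesian hierarchical group
comparisons — with a seeded synthetic dialogue generator so every stage of
the pipeline can be validated against ground truth without recordings.

## The problem

In dyadic conversation the most common transition between speakers is a
silent gap of roughly 200 ms, a strikingly stable property across
languages and populations. Clinical speech research asks whether specific
groups — here, dyads in which both partners are autistic adults (ASD)
versus control dyads (CTR) — deviate from this organisation, and *when*
during a dialogue they do. The package is written for researchers who have
two channels of IPU annotations per dialogue (Praat TextGrids or delimited
tables) and want a reproducible path from those intervals to posterior
group contrasts.

The core quantity is the **Floor Transfer Offset**: for every change of
speaker (floor transfer),

```
FTO = onset(incoming turn's first IPU) − offset(outgoing turn's last IPU)
```

positive for silent gaps, negative for between-speaker overlaps. Overlaps
*not* followed by a change of speaker (within-overlaps, typically short
backchannels like "mhm") carry no FTO and are excluded from timing
statistics, with their counts retained in an accounting record. Group and
dialogue-stage effects are estimated with a hierarchical Gaussian model

```
fto_ms ~ Group × Stage cell means + (1 | Dyad)
```

fitted by a blocked Gibbs sampler (conjugate normal updates, slice steps
for the half-normal-prior SDs, and a group-wise translation move for good
mixing), reported as posterior means, equal-tailed 95% credible intervals
and P(δ > 0), with split rank-normalised R-hat and bulk ESS diagnostics.

## Worked example

Simulate a corpus of 7 disposition-matched dyads per group (two Map-Task
dialogues each), classify every transition, and contrast the dialogue
stages:

```r
library(turntiming)
library(dplyr)

params <- default_params()                 # calibrated generator defaults
corpus <- simulate_corpus(params, n_dyads_per_group = 7, n_tasks = 2, seed = 42)
transitions <- classify_corpus(corpus)     # canonicalise + classify + stage labels
timing <- filter_for_timing(transitions)   # drop within-overlaps, keep accounting

attr(timing, "accounting")
#>   n_gap n_between n_within n_total gap_share n_timing timing_gap_share timing_overlap_share
#> 1  8081      3178     1974   13233     0.611    11259            0.718                0.282

summarise_fto(timing, scope = "group_stage", stage = "two_way")
#>   group epoch2        n mean_ms sd_ms median_ms modal_bin_ms modal_tie
#> 1 ASD   beginning   529    512.  826.      330.          200 FALSE
#> 2 ASD   remainder  5184    316.  575.      262.          200 FALSE
#> 3 CTR   beginning   513    198.  511.      207.          200 FALSE
#> 4 CTR   remainder  5033    238.  541.      218.          200 FALSE
```

Both groups share the canonical 200 ms modal bin, but in the dialogue
*beginning* (before the first Mismatch is detected) the ASD cell mean is
~315 ms higher than the CTR one, while the remainder cells are close. The
hierarchical model turns that into a posterior contrast:

```r
fit <- fit_fto(timing, stage = "two_way", chains = 4, iter = 4000,
               warmup = 2000, seed = 1)
contrast_cells(fit, from = "ASD:beginning", to = "CTR:beginning")
#>   contrast                      mean_ms ci_lower ci_upper p_gt_0
#> 1 CTR:beginning - ASD:beginning   -315.    -455.    -170.      0

glance(fit)
#>   n_obs n_dyads n_cells chains iter warmup max_rhat min_ess_bulk sigma_ms tau_ms
#> 1 11259      14       4      4  4000   2000     1.00        5172.     564.   114.
```

So controls' pre-detection FTOs are ~315 ms shorter (95% CI [−455, −170],
P(δ > 0) = 0): the simulated ASD dyads start dialogues with markedly longer
gaps and converge to control-like timing later — the pattern the generator
is calibrated to. `tidy(fit)` gives per-parameter posterior summaries,
`autoplot(fit)` an interval plot; `plot_fto_histogram()`,
`plot_fto_by_index()` and `plot_dyad_distributions()` cover the
descriptive figures; `leave_one_dyad_out()` checks that no single dyad
drives a group mean.

Real annotations enter through `read_textgrid_dialogue()` (long and short
Praat dialects, UTF-8/UTF-16) or `read_ipu_table()` with a YAML metadata
sidecar (dyad, group, detection/resolution times), and behave identically
to simulated records from there on.

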