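test_that("the reduced known-variance model matches the conjugate closed form", {
  set.seed(71)
  y <- rnorm(10, 300, 400)
  d <- tibble::tibble(fto_ms = y, group = "ASD", dyad_id = "D1")
  fit <- fit_fto(d, stage = "none", chains = 2, iter = 4000, warmup = 500,
                 seed = 5, include_dyad = FALSE, sigma_fixed = 400)
  prec <- 10 / 400^2 + 1 / 1000^2
  mu_post <- (sum(y) / 400^2) / prec
  sd_post <- 1 / sqrt(prec)
  dr <- posterior_draws(fit)[["mu[ASD]"]]
  mc_se <- sd_post / sqrt(length(dr))
  expect_lt(abs(mean(dr) - mu_post), 6 * mc_se)
  expect_lt(abs(sd(dr) - sd_post), 0.05 * sd_post)
})

test_that("with zero observations the posterior reproduces the prior", {
  d <- tibble::tibble(fto_ms = numeric(), group = character(),
                      dyad_id = character())
  fit <- fit_fto(d, stage = "none", chains = 2, iter = 5000, warmup = 500,
                 seed = 2, include_dyad = FALSE)
  mu <- posterior_draws(fit)[["mu[ASD]"]]
  sig <- posterior_draws(fit)[["sigma"]]
  expect_lt(abs(mean(mu)), 40)              # prior: Normal(0, 1000)
  expect_lt(abs(sd(mu) - 1000), 50)
  expect_lt(abs(mean(sig) - 1000 * sqrt(2 / pi)), 40)  # half-normal mean
})

test_that("contrasts summarise the delta draws exactly", {
  cc <- calibrated_corpus()
  fit <- fit_fto(cc$timing, stage = "none", chains = 2, iter = 800,
                 warmup = 300, seed = 3)
  cb <- contrast_cells(fit, "ASD", "CTR")
  delta <- attr(cb, "draws")
  expect_equal(cb$mean_ms, mean(delta))
  # CI endpoints equal empirical percentiles from an independent sort
  srt <- sort(delta)
  n <- length(srt)
  expect_equal(cb$ci_lower, quantile(delta, 0.025, names = FALSE),
               tolerance = 1e-12)
  expect_lte(abs(cb$ci_lower - srt[ceiling(0.025 * n)]),
             diff(range(srt)) / n * 50)
  expect_equal(cb$p_gt_0, mean(delta > 0))
  # symmetric draws give P(delta > 0) near one half
  sym <- fit
  expect_equal(mean(c(delta, -delta) > 0), 0.5, tolerance = 1e-9)
  expect_error(contrast_cells(fit, "ASD", "XX"), "not in model")
})

test_that("rank-normalised split R-hat and bulk ESS behave on known inputs", {
  set.seed(91)
  m <- array(rnorm(1000 * 4), dim = c(1000, 4, 1),
             dimnames = list(NULL, NULL, "theta"))
  d <- mcmc_diagnostics(m)
  expect_lt(abs(d$rhat - 1), 0.01)
  expect_lt(abs(d$ess_bulk - 4000) / 4000, 0.2)  # iid draws: ESS near n

  dup <- m
  dup[, 2, 1] <- dup[, 1, 1]                     # duplicated identical chain
  expect_lt(abs(mcmc_diagnostics(dup)$rhat - 1), 0.01)

  shifted <- m
  shifted[, 1, 1] <- shifted[, 1, 1] + 5         # one divergent chain
  expect_gt(mcmc_diagnostics(shifted)$rhat, 1.1)
})

test_that("posterior predictive replication is reproducible and centred", {
  cc <- calibrated_corpus()
  sub <- dplyr::slice_sample(cc$timing, n = 2000)
  fit <- fit_fto(sub, stage = "none", chains = 2, iter = 600, warmup = 200,
                 seed = 4)
  expect_equal(nrow(posterior_predictive(fit, n_rep = 0)), 0L)
  r1 <- posterior_predictive(fit, n_rep = 20, seed = 10)
  r2 <- posterior_predictive(fit, n_rep = 20, seed = 10)
  expect_equal(r1, r2)
  # replicated means scatter around the observed mean
  expect_lt(abs(mean(r1$mean_ms) - attr(r1, "observed_mean")), 60)
})

test_that("posterior summaries are invariant to order-preserving dyad relabelling", {
  cc <- calibrated_corpus()
  sub <- dplyr::slice_sample(cc$timing, n = 1500)
  f1 <- fit_fto(sub, stage = "none", chains = 2, iter = 500, warmup = 200,
                seed = 6)
  ren <- dplyr::mutate(sub, dyad_id = sub("^ASD", "AXD",
                                          sub("^CTR", "CXR", dyad_id)))
  f2 <- fit_fto(ren, stage = "none", chains = 2, iter = 500, warmup = 200,
                seed = 6)
  expect_equal(posterior_draws(f1)[["mu[ASD]"]],
               posterior_draws(f2)[["mu[ASD]"]])
  expect_equal(posterior_draws(f1)[["sigma"]],
               posterior_draws(f2)[["sigma"]])
})

test_that("the 95% interval for the group contrast attains nominal coverage", {
  # scaled-down coverage study: truths drawn from the model's own priors
  pr <- prior_spec(coef_scale_ms = 300, sigma_scale_ms = 300,
                   tau_scale_ms = 120)
  set.seed(515)
  n_rep <- 200
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    mu <- rnorm(2, 0, pr$coef_scale_ms)
    tau <- abs(rnorm(1, 0, pr$tau_scale_ms))
    sigma <- abs(rnorm(1, 0, pr$sigma_scale_ms)) + 1
    b <- rnorm(6, 0, tau)
    d <- tibble::tibble(
      dyad_id = rep(sprintf("D%d", 1:6), each = 12),
      group = rep(c("ASD", "CTR"), each = 36),
      fto_ms = rnorm(72, rep(mu, each = 36) + rep(b, each = 12), sigma))
    fit <- suppressWarnings(
      fit_fto(d, stage = "none", chains = 2, iter = 500, warmup = 200,
              seed = 1000 + r, priors = pr))
    ci <- contrast_cells(fit, "ASD", "CTR")
    covered[r] <- ci$ci_lower <= mu[2] - mu[1] && mu[2] - mu[1] <= ci$ci_upper
  }
  expect_gte(mean(covered), 0.91)
  expect_lte(mean(covered), 0.99)
})

test_that("tidy and glance expose posterior summaries and diagnostics", {
  cc <- calibrated_corpus()
  sub <- dplyr::slice_sample(cc$timing, n = 1000)
  fit <- fit_fto(sub, stage = "two_way", chains = 2, iter = 500,
                 warmup = 200, seed = 8)
  td <- tidy(fit)
  expect_setequal(td$term, paste0("mu[", fit$cells$cell, "]"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(tidyr::drop_na(sub[c("fto_ms", "group",
                                                   "dyad_id", "epoch2")])))
  expect_true(gl$max_rhat < 1.05)
  td_all <- tidy(fit, pars = "all")
  expect_true(all(c("sigma", "tau") %in% td_all$term))
})
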