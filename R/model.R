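#' Prior specification for the hierarchical FTO model
#'
#' Weakly informative priors on the millisecond FTO scale, all centred at
#' zero: Normal(0, `coef_scale_ms`) for every cell mean, and Half-Normal
#' scale priors for the residual SD and the dyad random-intercept SD.
#' The defaults (1000 ms) are broad relative to observed FTO magnitudes
#' (|FTO| rarely exceeds ~3000 ms) while still regularising.
#'
#' @param coef_scale_ms SD of the zero-centred normal prior on cell means.
#' @param sigma_scale_ms Scale of the half-normal prior on the residual SD.
#' @param tau_scale_ms Scale of the half-normal prior on the dyad SD.
#' @return A list of class `fto_priors`.
#' @export
prior_spec <- function(coef_scale_ms = 1000, sigma_scale_ms = 1000,
                       tau_scale_ms = 1000) {
  stopifnot(coef_scale_ms > 0, sigma_scale_ms > 0, tau_scale_ms > 0)
  structure(list(coef_scale_ms = coef_scale_ms,
                 sigma_scale_ms = sigma_scale_ms,
                 tau_scale_ms = tau_scale_ms), class = "fto_priors")
}

#' Fit the Bayesian hierarchical Gaussian FTO model
#'
#' Models FTO (ms) with a Gaussian likelihood, a cell-means fixed part over
#' Group (optionally crossed with dialogue stage) and dyad random
#' intercepts:
#' \deqn{y_i = \mu_{cell(i)} + b_{dyad(i)} + \epsilon_i,\quad
#'       b_d \sim N(0, \tau^2),\ \epsilon_i \sim N(0, \sigma^2)}
#' with priors from [prior_spec()]. The cell-means parameterisation makes
#' per-stage group differences direct contrasts (see [contrast_cells()]).
#'
#' Sampling uses a blocked Gibbs scheme: cell means and dyad intercepts have
#' conjugate normal full conditionals; the half-normal-prior SDs
#' \eqn{\sigma} and \eqn{\tau} are updated by univariate slice steps on the
#' log scale; an extra group-wise translation move (shifting a group's cell
#' means against its dyad intercepts, which leaves the likelihood invariant)
#' removes the random-walk behaviour of the weakly identified
#' group-level/dyad-level split. Unbalanced dyad sizes are handled by the
#' hierarchical likelihood itself; no weighting is applied.
#'
#' @param data Data frame with columns `fto_ms`, `group`, `dyad_id` and --
#'   for staged models -- `epoch2` or `epoch3`. Rows with missing values in
#'   the used columns are dropped.
#' @param stage `"none"` (group-only model), `"two_way"` (group x
#'   beginning/remainder) or `"three_way"`.
#' @param chains Number of MCMC chains (>= 2 for convergence diagnostics).
#' @param iter Total iterations per chain, including warm-up.
#' @param warmup Warm-up (discarded) iterations per chain.
#' @param seed Integer seed; chain `k` uses `seed + k - 1`.
#' @param priors A [prior_spec()].
#' @param include_dyad Set `FALSE` to drop the dyad random intercept
#'   (reduced model, mainly for validation against closed forms).
#' @param sigma_fixed Optional known residual SD; when supplied the residual
#'   SD is not sampled (reduced model for conjugate closed-form checks).
#' @return An object of class `fto_fit`; see [tidy.fto_fit()],
#'   [glance.fto_fit()], [contrast_cells()], [mcmc_diagnostics()],
#'   [posterior_predictive()].
#' @export
fit_fto <- function(data, stage = c("none", "two_way", "three_way"),
                    chains = 4, iter = 4000, warmup = 2000, seed = NULL,
                    priors = prior_spec(), include_dyad = TRUE,
                    sigma_fixed = NULL) {
  stage <- match.arg(stage)
  stopifnot(warmup < iter, chains >= 1)
  stage_col <- switch(stage, none = NULL, two_way = "epoch2", three_way = "epoch3")
  cols <- c("fto_ms", "group", "dyad_id", stage_col)
  miss <- setdiff(cols, names(data))
  if (length(miss)) abort(paste0("data lacks column(s): ", paste(miss, collapse = ", ")))
  d <- as_tibble(data)[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  y <- as.numeric(d$fto_ms)
  n <- length(y)
  grp <- as.character(d$group)
  dyad <- factor(as.character(d$dyad_id))
  if (n) {
    map <- distinct(tibble(dyad = as.character(d$dyad_id), group = grp))
    if (anyDuplicated(map$dyad)) abort("each dyad must belong to exactly one group")
    if (nlevels(dyad) < 2 && include_dyad) abort("need at least 2 dyads")
  } else {
    map <- tibble(dyad = character(), group = character())
  }
  cell_lab <- if (is.null(stage_col)) grp else paste(grp, as.character(d[[stage_col]]), sep = ":")
  cell_levels <- if (n) sort(unique(cell_lab)) else
    if (is.null(stage_col)) c("ASD", "CTR") else
      as.vector(outer(c("ASD", "CTR"),
                      if (stage == "two_way") c("beginning", "remainder")
                      else c("before_detection", "during_discussion", "after_resolution"),
                      paste, sep = ":"))
  cell <- factor(cell_lab, levels = cell_levels)
  C <- length(cell_levels)
  D <- nlevels(dyad)
  if (n == 0) include_dyad <- FALSE  # nothing to partition; prior sampling only

  # sufficient statistics: per-iteration cost depends on C x D, not on n
  if (n) {
    n_cd <- unclass(table(cell, dyad))
    S_cd <- unclass(xtabs(y ~ cell + dyad))
  } else {
    n_cd <- matrix(0, C, max(D, 1L)); S_cd <- matrix(0, C, max(D, 1L))
    D <- max(D, 1L)
  }
  SStot <- sum(y^2)
  n_c <- rowSums(n_cd); S_c <- rowSums(S_cd)
  n_d <- colSums(n_cd); S_d <- colSums(S_cd)
  cell_group <- sub(":.*$", "", cell_levels)
  dyad_group <- if (nrow(map)) map$group[match(colnames(n_cd), map$dyad)] else character(D)
  groups <- unique(cell_group)

  s_mu <- priors$coef_scale_ms
  s_sig <- priors$sigma_scale_ms
  s_tau <- priors$tau_scale_ms
  n_keep <- iter - warmup
  par_names <- c(paste0("mu[", cell_levels, "]"),
                 if (include_dyad) paste0("b[", colnames(n_cd), "]"),
                 if (is.null(sigma_fixed)) "sigma",
                 if (include_dyad) "tau")
  draws <- array(NA_real_, dim = c(n_keep, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))

  for (ch in seq_len(chains)) {
    if (!is.null(seed)) set.seed(seed + ch - 1L)
    mu <- ifelse(n_c > 0, S_c / pmax(n_c, 1), 0)
    b <- rep(0, D)
    sigma <- if (!is.null(sigma_fixed)) sigma_fixed else
      max(if (n > 1) sd(y) else s_sig / 2, 1e-6)
    tau <- s_tau / 10
    for (it in seq_len(iter)) {
      # cell means | b, sigma
      resid_c <- S_c - if (include_dyad) as.vector(n_cd %*% b) else 0
      prec <- n_c / sigma^2 + 1 / s_mu^2
      mu <- rnorm(C, (resid_c / sigma^2) / prec, 1 / sqrt(prec))
      if (include_dyad) {
        # dyad intercepts | mu, sigma, tau
        resid_d <- S_d - as.vector(crossprod(n_cd, mu))
        prec_d <- n_d / sigma^2 + 1 / tau^2
        b <- rnorm(D, (resid_d / sigma^2) / prec_d, 1 / sqrt(prec_d))
        # group-wise translation move (likelihood-invariant)
        for (g in groups) {
          ic <- which(cell_group == g); id <- which(dyad_group == g)
          if (!length(id)) next
          P <- length(ic) / s_mu^2 + length(id) / tau^2
          m <- (-sum(mu[ic]) / s_mu^2 + sum(b[id]) / tau^2) / P
          s <- rnorm(1, m, 1 / sqrt(P))
          mu[ic] <- mu[ic] + s
          b[id] <- b[id] - s
        }
        # tau | b : half-normal prior, slice step on log tau
        SSB <- sum(b^2)
        lp_tau <- function(x) -(D - 1) * x - SSB / (2 * exp(2 * x)) -
          exp(2 * x) / (2 * s_tau^2)
        tau <- exp(slice_step(log(tau), lp_tau))
      }
      if (is.null(sigma_fixed)) {
        # sigma | mu, b : half-normal prior, slice step on log sigma
        SSR <- if (include_dyad) {
          M <- outer(mu, b, "+")
          SStot - 2 * sum(M * S_cd) + sum(n_cd * M^2)
        } else {
          SStot - 2 * sum(mu * S_c) + sum(n_c * mu^2)
        }
        SSR <- max(SSR, 0)
        lp_sig <- function(x) -(n - 1) * x - SSR / (2 * exp(2 * x)) -
          exp(2 * x) / (2 * s_sig^2)
        sigma <- exp(slice_step(log(sigma), lp_sig))
      }
      if (it > warmup) {
        draws[it - warmup, ch, ] <- c(mu, if (include_dyad) b,
                                      if (is.null(sigma_fixed)) sigma,
                                      if (include_dyad) tau)
      }
    }
  }

  fit <- structure(list(
    draws = draws, cells = tibble(cell = cell_levels, group = cell_group),
    dyads = tibble(dyad = colnames(n_cd), group = dyad_group),
    stage = stage, priors = priors, chains = chains, iter = iter,
    warmup = warmup, seed = seed, n_obs = n, include_dyad = include_dyad,
    sigma_fixed = sigma_fixed,
    data = d, cell_index = cell, dyad_index = dyad), class = "fto_fit")

  if (chains >= 2 && n > 0) {
    diag <- mcmc_diagnostics(fit)
    bad <- diag[!is.na(diag$rhat) & diag$rhat > 1.01, , drop = FALSE]
    if (nrow(bad)) {
      warn(paste0("possible non-convergence (split R-hat > 1.01): ",
                  paste(sprintf("%s (R-hat %.3f)", bad$parameter, bad$rhat),
                        collapse = ", ")))
    }
  }
  fit
}

# univariate slice sampler with stepping out and shrinkage (Neal 2003)
slice_step <- function(x0, logf, w = 0.5, max_step = 100L) {
  y <- logf(x0) - stats::rexp(1)
  L <- x0 - runif(1) * w
  R <- L + w
  k <- max_step
  while (k > 0L && logf(L) > y) { L <- L - w; k <- k - 1L }
  k <- max_step
  while (k > 0L && logf(R) > y) { R <- R + w; k <- k - 1L }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' @export
print.fto_fit <- function(x, ...) {
  cat(sprintf("<fto_fit> %s model: %d obs, %d dyads, %d cells; %d chains x %d iter (%d warmup)\n",
              x$stage, x$n_obs, nrow(x$dyads), nrow(x$cells),
              x$chains, x$iter, x$warmup))
  print(tidy(x))
  invisible(x)
}

#' Extract posterior draws as a tidy tibble
#'
#' @param fit An [fit_fto()] object.
#' @return A tibble with `.chain`, `.iteration` and one column per
#'   parameter.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "fto_fit"))
  dm <- dim(fit$draws)
  flat <- matrix(fit$draws, nrow = dm[1] * dm[2], ncol = dm[3])
  colnames(flat) <- dimnames(fit$draws)[[3]]
  bind_cols(tibble(.chain = rep(seq_len(dm[2]), each = dm[1]),
                   .iteration = rep(seq_len(dm[1]), dm[2])),
            as_tibble(flat))
}

param_draws <- function(fit, name) {
  as.vector(fit$draws[, , name])
}

#' Posterior contrast between two cells
#'
#' Computes the per-draw difference \eqn{\delta} = mean(`to`) - mean(`from`)
#' between two cell means, its posterior mean, equal-tailed 95\% credible
#' interval, and the posterior probability that it is positive. Group
#' differences in this package follow the convention of reporting
#' CTR - ASD (ASD as the reference level).
#'
#' @param fit An [fit_fto()] object.
#' @param from,to Cell names as in `fit$cells$cell` (e.g. `"ASD:beginning"`).
#' @return A one-row tibble: `contrast`, `mean_ms`, `ci_lower`, `ci_upper`,
#'   `p_gt_0`, with the per-draw delta vector attached as attribute
#'   `"draws"`.
#' @export
contrast_cells <- function(fit, from, to) {
  stopifnot(inherits(fit, "fto_fit"))
  for (cl in c(from, to)) {
    if (!cl %in% fit$cells$cell) {
      abort(sprintf("cell '%s' not in model (cells: %s)", cl,
                    paste(fit$cells$cell, collapse = ", ")))
    }
  }
  delta <- param_draws(fit, paste0("mu[", to, "]")) -
    param_draws(fit, paste0("mu[", from, "]"))
  ci <- unname(quantile(delta, c(0.025, 0.975), type = 7))
  out <- tibble(contrast = paste0(to, " - ", from),
                mean_ms = mean(delta), ci_lower = ci[1], ci_upper = ci[2],
                p_gt_0 = mean(delta > 0))
  attr(out, "draws") <- delta
  out
}

#' Posterior predictive replication
#'
#' Draws `n_rep` replicated datasets of the original size from the fitted
#' model (each replicate uses one randomly chosen posterior draw of all
#' parameters) and summarises them against the observed data, for a
#' mean/SD-level posterior predictive check.
#'
#' @param fit An [fit_fto()] object.
#' @param n_rep Number of replicated datasets.
#' @param seed Optional integer seed.
#' @return A tibble with one row per replicate: `rep`, `mean_ms`, `sd_ms`;
#'   observed mean/SD attached as attributes `"observed_mean"` /
#'   `"observed_sd"`.
#' @export
posterior_predictive <- function(fit, n_rep = 100, seed = NULL) {
  stopifnot(inherits(fit, "fto_fit"))
  if (!is.null(seed)) set.seed(seed)
  out <- tibble(rep = integer(), mean_ms = numeric(), sd_ms = numeric())
  if (n_rep >= 1) {
    dm <- dim(fit$draws)
    mu_cols <- paste0("mu[", fit$cells$cell, "]")
    ci <- as.integer(fit$cell_index)
    di <- as.integer(fit$dyad_index)
    reps <- lapply(seq_len(n_rep), function(r) {
      it <- sample.int(dm[1], 1); ch <- sample.int(dm[2], 1)
      mu <- fit$draws[it, ch, mu_cols]
      bvec <- if (fit$include_dyad)
        fit$draws[it, ch, paste0("b[", fit$dyads$dyad, "]")] else
          rep(0, max(nrow(fit$dyads), 1L))
      sig <- if (is.null(fit$sigma_fixed)) fit$draws[it, ch, "sigma"] else fit$sigma_fixed
      yrep <- rnorm(fit$n_obs, mu[ci] + bvec[di], sig)
      tibble(rep = r, mean_ms = mean(yrep), sd_ms = sd(yrep))
    })
    out <- purrr::list_rbind(reps)
  }
  attr(out, "observed_mean") <- if (fit$n_obs) mean(fit$data$fto_ms) else NA_real_
  attr(out, "observed_sd") <- if (fit$n_obs > 1) sd(fit$data$fto_ms) else NA_real_
  out
}
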