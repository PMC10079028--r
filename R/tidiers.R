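#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted FTO model
#'
#' @param x An [fit_fto()] object.
#' @param pars `"cells"` (cell means only) or `"all"` (plus dyad
#'   intercepts and SDs).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `conf.low`/`conf.high` (equal-tailed 95\% credible
#'   interval), `rhat`, `ess_bulk`.
#' @export
tidy.fto_fit <- function(x, pars = c("cells", "all"), ...) {
  pars <- match.arg(pars)
  keep <- if (pars == "cells") paste0("mu[", x$cells$cell, "]") else
    dimnames(x$draws)[[3]]
  diag <- mcmc_diagnostics(x)
  out <- lapply(keep, function(p) {
    dr <- param_draws(x, p)
    ci <- unname(quantile(dr, c(0.025, 0.975)))
    tibble(term = p, estimate = mean(dr), std.error = sd(dr),
           conf.low = ci[1], conf.high = ci[2])
  })
  left_join(purrr::list_rbind(out),
            rename(diag, term = "parameter"), by = "term")
}

#' One-row model overview
#'
#' @param x An [fit_fto()] object.
#' @param ... Unused.
#' @return A one-row tibble: sizes, sampler settings, worst R-hat, smallest
#'   bulk ESS, posterior mean residual and dyad SDs.
#' @export
glance.fto_fit <- function(x, ...) {
  diag <- mcmc_diagnostics(x)
  tibble(n_obs = x$n_obs, n_dyads = nrow(x$dyads), n_cells = nrow(x$cells),
         chains = x$chains, iter = x$iter, warmup = x$warmup,
         max_rhat = suppressWarnings(max(diag$rhat, na.rm = TRUE)),
         min_ess_bulk = suppressWarnings(min(diag$ess_bulk, na.rm = TRUE)),
         sigma_ms = if ("sigma" %in% dimnames(x$draws)[[3]])
           mean(param_draws(x, "sigma")) else x$sigma_fixed,
         tau_ms = if ("tau" %in% dimnames(x$draws)[[3]])
           mean(param_draws(x, "tau")) else NA_real_)
}
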