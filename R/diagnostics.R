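#' MCMC convergence diagnostics
#'
#' Split-chain, rank-normalised R-hat and bulk effective sample size for
#' every sampled parameter. Each chain is split in half, pooled draws are
#' rank-normalised, R-hat compares between- to within-half variance, and
#' ESS is computed from chain-averaged autocorrelations combined with
#' Geyer's initial-monotone-sequence truncation.
#'
#' @param fit An [fit_fto()] object (or a draws array `iterations x chains
#'   x parameters`).
#' @return A tibble with `parameter`, `rhat`, `ess_bulk`. Parameters with
#'   (numerically) zero variance yield `NA`.
#' @export
mcmc_diagnostics <- function(fit) {
  draws <- if (inherits(fit, "fto_fit")) fit$draws else fit
  stopifnot(length(dim(draws)) == 3L)
  pars <- dimnames(draws)[[3]] %||% paste0("par", seq_len(dim(draws)[3]))
  out <- lapply(seq_len(dim(draws)[3]), function(p) {
    m <- draws[, , p, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
    tibble(parameter = pars[p],
           rhat = rhat_split(m),
           ess_bulk = ess_bulk(m))
  })
  purrr::list_rbind(out)
}

split_chains <- function(m) {
  n <- nrow(m)
  h <- floor(n / 2)
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1):n, , drop = FALSE])
}

rank_normalise <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(m), ncol = ncol(m))
}

rhat_basic <- function(m) {
  n <- nrow(m); M <- ncol(m)
  if (n < 2L) return(NA_real_)
  means <- colMeans(m)
  vars <- apply(m, 2, var)
  W <- mean(vars)
  if (!is.finite(W) || W < .Machine$double.eps) return(NA_real_)
  B <- if (M > 1) n * var(means) else 0
  sqrt(((n - 1) / n * W + B / n) / W)
}

rhat_split <- function(m) {
  s <- split_chains(m)
  if (all(abs(s - s[1]) < 1e-12)) return(NA_real_)
  rhat_basic(rank_normalise(s))
}

ess_bulk <- function(m) {
  s <- split_chains(m)
  if (all(abs(s - s[1]) < 1e-12)) return(NA_real_)
  ess_mean(rank_normalise(s))
}

# ESS of the mean from chain-averaged autocorrelations (Geyer-truncated)
ess_mean <- function(m) {
  n <- nrow(m); M <- ncol(m)
  if (n < 4L) return(NA_real_)
  vars <- apply(m, 2, var)
  W <- mean(vars)
  means <- colMeans(m)
  B <- if (M > 1) n * var(means) else 0
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus < .Machine$double.eps) return(NA_real_)
  # chain autocovariances
  acov <- vapply(seq_len(M), function(j) {
    a <- acf(m[, j], lag.max = n - 1L, type = "covariance", plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  }, numeric(n))
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer initial positive + monotone sequence over lag pairs
  max_pairs <- floor((n - 1) / 2)
  tau <- 1
  prev <- Inf
  for (k in seq_len(max_pairs)) {
    g <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(g) || g < 0) break
    g <- min(g, prev)
    prev <- g
    tau <- tau + 2 * g
  }
  max(M * n / tau, 1e-3)
}
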