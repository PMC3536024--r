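# Convergence and Monte-Carlo-error diagnostics. Implemented from the
# standard formulas (split R-hat: Gelman et al.; ESS: Geyer's initial
# monotone positive sequence on chain-averaged autocorrelations).

split_chains <- function(chains) {
  out <- list()
  for (x in chains) {
    n <- length(x)
    h <- n %/% 2L
    out <- c(out, list(x[seq_len(h)], x[(n - h + 1L):n]))
  }
  out
}

rhat_split <- function(chains) {
  ch <- split_chains(chains)
  M <- length(ch); N <- length(ch[[1L]])
  if (N < 4L) return(NA_real_)
  means <- vapply(ch, mean, 0)
  vars <- vapply(ch, var, 0)
  W <- mean(vars)
  B <- N * var(means)
  if (W <= 0) return(if (B <= 1e-300) 1 else Inf)
  sqrt(((N - 1) / N * W + B / N) / W)
}

chain_autocov <- function(x, max_lag) {
  n <- length(x)
  x <- x - mean(x)
  vapply(0:max_lag, function(t) sum(x[1:(n - t)] * x[(1 + t):n]) / n, 0)
}

ess_geyer <- function(chains) {
  M <- length(chains); N <- length(chains[[1L]])
  if (N < 8L) return(NA_real_)
  max_lag <- min(N - 2L, 500L)
  acov <- sapply(chains, chain_autocov, max_lag = max_lag)
  acov <- rowMeans(as.matrix(acov))
  W <- acov[1L] * N / (N - 1)
  B <- if (M > 1L) N * var(vapply(chains, mean, 0)) else 0
  var_plus <- W * (N - 1) / N + B / N # total-variance estimate
  if (var_plus <= 0) return(M * N) # constant chain
  rho <- 1 - (W - acov[-1L]) / var_plus
  # pair sums; keep while positive, enforce monotone decrease
  P <- rho[seq(1L, length(rho) - 1L, by = 2L)] +
    rho[seq(2L, length(rho), by = 2L)]
  keep <- which(P <= 0)
  if (length(keep)) P <- P[seq_len(keep[1L] - 1L)]
  if (length(P) > 1L) P <- cummin(P)
  tau_int <- 1 + 2 * sum(pmax(P, 0))
  ess <- M * N / max(tau_int, 1 / (M * N))
  min(ess, M * N)
}

#' MCMC diagnostics report
#'
#' Per scalar parameter: posterior mean and SD, split R-hat, effective sample
#' size, Monte-Carlo standard error (SD / sqrt(ESS)) and a flag when the
#' MCSE exceeds 5% of the posterior SD — the convergence target used when
#' deciding whether a run is long enough.
#'
#' @param fit an `iso_fit` from [fit_gene()].
#' @param mcse_target flag threshold as a fraction of the posterior SD.
#' @return data.frame, one row per parameter, plus attribute "n_flagged".
#' @export
mcmc_diagnostics <- function(fit, mcse_target = 0.05) {
  stopifnot(inherits(fit, "iso_fit"))
  single <- length(fit$chains) < 2L
  if (single) warning("single chain: split R-hat omitted")
  blocks <- c("beta", "tau", "tau0")
  rows <- list()
  for (b in blocks) {
    cols <- colnames(fit$chains[[1L]][[b]])
    for (j in seq_along(cols)) {
      per_chain <- lapply(fit$chains, function(ch) as.numeric(ch[[b]][, j]))
      x <- unlist(per_chain)
      sdx <- sd(x)
      ess <- ess_geyer(per_chain)
      mcse <- if (is.na(ess) || ess <= 0) NA_real_ else sdx / sqrt(ess)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = paste0(b, "[", cols[j], "]"),
        mean = mean(x), sd = sdx,
        rhat = if (single) NA_real_ else rhat_split(per_chain),
        ess = ess, mcse = mcse,
        flagged = !is.na(mcse) && sdx > 0 && mcse > mcse_target * sdx,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_flagged") <- sum(out$flagged, na.rm = TRUE)
  out
}
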