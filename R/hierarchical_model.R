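#' Hyperparameters of the hierarchical isoform model
#'
#' The model for one gene g: observed segment expression
#' \eqn{y_{il} = \sum_k I_{kl} \beta_{kl} X_{ik} + \epsilon_{il}}, with
#' \eqn{Y_l} multivariate normal around \eqn{X \beta^*_l}, each element
#' truncated below at zero, noise precision \eqn{\tau_l \sim Gamma(\alpha_1,
#' \alpha_2)} per gene-by-sample, isoform effects \eqn{\beta_{kl} \sim
#' N(\mu_{k0}, 1/\tau_{k0})} truncated at zero with \eqn{\tau_{k0} \sim
#' Gamma(\alpha_1^0, \alpha_2^0)} pooling the isoform across samples, and
#' presence indicators \eqn{I_{kl} \sim Bernoulli(p)} (spike-and-slab).
#'
#' Defaults are diffuse (all Gamma parameters 0.01) with an uninformative
#' presence prior p = 0.5; inference is reported to be insensitive to
#' reasonable choices. `mu0 = NULL` anchors the prior mean at the 10%-trimmed
#' mean of the gene's observed values. `tau_fixed` / `tau0_fixed` clamp the
#' corresponding precisions (their updates are skipped) — useful for oracle
#' validation against low-dimensional enumeration.
#'
#' @param a1,a2 Gamma shape/rate for the exon-noise precision tau_l.
#' @param a10,a20 Gamma shape/rate for the isoform-level precision tau_k0.
#' @param mu0 prior mean of isoform expression: NULL (data anchor), a scalar,
#'   or a per-isoform vector.
#' @param p prior presence probability, in (0, 1).
#' @param tau_fixed,tau0_fixed optional fixed precision values (NA = free).
#' @return object of class `iso_hyper`.
#' @export
hyperparams <- function(a1 = 0.01, a2 = 0.01, a10 = 0.01, a20 = 0.01,
                        mu0 = NULL, p = 0.5,
                        tau_fixed = NA_real_, tau0_fixed = NA_real_) {
  stopifnot(a1 > 0, a2 > 0, a10 > 0, a20 > 0, p > 0, p < 1)
  if (!is.na(tau_fixed)) stopifnot(tau_fixed > 0)
  if (!is.na(tau0_fixed)) stopifnot(tau0_fixed > 0)
  structure(list(a1 = a1, a2 = a2, a10 = a10, a20 = a20, mu0 = mu0, p = p,
                 tau_fixed = tau_fixed, tau0_fixed = tau0_fixed),
            class = "iso_hyper")
}

#' MCMC settings
#'
#' @param chains number of parallel chains (>= 2 for convergence checks).
#' @param iterations post-burn-in draws kept per chain.
#' @param burn_in discarded initial iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed; every chain derives its own stream from it.
#' @return object of class `iso_mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 2L, iterations = 8000L, burn_in = 2000L,
                          thin = 1L, seed = 1L) {
  stopifnot(chains >= 1L, iterations >= 1L, burn_in >= 0L, thin >= 1L)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "iso_mcmc_settings")
}

#' Bundle a gene's partition with its expression slice
#'
#' @param partition a [build_pseudo_exons()] result.
#' @param y numeric matrix of normalized expression, one row per segment of
#'   the partition, one column per sample.
#' @return object of class `iso_gene_data`.
#' @export
gene_data <- function(partition, y) {
  stopifnot(inherits(partition, "pseudo_exon_partition"))
  y <- as.matrix(y)
  if (nrow(y) != nrow(partition$segments))
    stop("y has ", nrow(y), " rows but the partition has ",
         nrow(partition$segments), " segments (gene ", partition$gene_id, ")")
  if (any(y < 0)) stop("negative expression values (gene ", partition$gene_id, ")")
  if (any(!is.finite(y))) stop("non-finite expression values")
  if (is.null(colnames(y))) colnames(y) <- paste0("S", seq_len(ncol(y)))
  structure(list(partition = partition, y = y), class = "iso_gene_data")
}

#' Truncated-normal log-likelihood of one sample
#'
#' \eqn{\sum_i [\log\phi((y_i - \mu_i)\sqrt{\tau}) + \frac12\log\tau -
#' \log\Phi(\mu_i\sqrt{\tau})]} with \eqn{\mu = X \beta^*_l}; independent
#' normals truncated below at zero.
#'
#' @param data an [gene_data()] object.
#' @param state list with `beta` (s x L), `I` (s x L), `tau` (length L).
#' @param sample column index or name.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(data, state, sample = 1L) {
  stopifnot(inherits(data, "iso_gene_data"))
  l <- if (is.character(sample)) match(sample, colnames(data$y)) else sample
  y <- data$y[, l]
  X <- data$partition$design
  bstar <- state$beta[, l] * state$I[, l]
  mu <- as.vector(X %*% bstar)
  tau <- state$tau[l]
  if (any(!is.finite(c(y, mu, tau)))) stop("non-finite inputs")
  sum(dnorm(y, mu, 1 / sqrt(tau), log = TRUE) -
        pnorm(mu * sqrt(tau), log.p = TRUE))
}

#' Full-conditional update of one presence indicator
#'
#' Kuo-Mallick scheme: because beta_kl is drawn from its prior while
#' I_kl = 0, the indicator's full conditional is the exact Bernoulli with
#' odds p L(I=1) / ((1-p) L(I=0)), L the truncated-normal likelihood at the
#' current beta value.
#'
#' @param state list with `beta`, `I`, `tau` as in [log_likelihood()].
#' @param data an [gene_data()] object.
#' @param k isoform index; @param l sample index.
#' @param hyper an [hyperparams()] object (supplies p).
#' @param draw logical; also draw the indicator.
#' @return list with `prob` (P(I=1 | rest)) and, if `draw`, `value`.
#' @export
update_indicator <- function(state, data, k, l, hyper, draw = TRUE) {
  s1 <- state; s1$I[k, l] <- 1L
  s0 <- state; s0$I[k, l] <- 0L
  d <- log_likelihood(data, s1, l) - log_likelihood(data, s0, l)
  logit <- log(hyper$p) - log1p(-hyper$p) + d
  prob <- 1 / (1 + exp(-logit))
  list(prob = prob, value = if (draw) as.integer(runif(1) < prob) else NA_integer_)
}

trimmed_mean <- function(x, trim = 0.1) mean(x, trim = trim)

#' Fit the hierarchical model to one gene by MCMC
#'
#' Runs `chains` Metropolis-within-Gibbs chains (see the package vignette for
#' the update scheme) over all samples of the gene jointly and returns the
#' pooled posterior draws of beta_kl, I_kl, tau_l and tau_k0. Chains start
#' from randomized initial values; a fixed `seed` makes the run repeatable.
#' Genes with duplicate design-matrix columns are sampled anyway, with an
#' unidentifiability warning recorded in the result; all-zero genes proceed
#' (the posterior concentrates near I = 0) and are flagged.
#'
#' @param data an [gene_data()] object.
#' @param hyper an [hyperparams()] object.
#' @param mcmc an [mcmc_settings()] object.
#' @param likelihood internal switch; FALSE samples the prior (validation).
#' @return object of class `iso_fit`: per-chain draw matrices `beta`, `I`
#'   (columns "k:l" with k the isoform, l the sample), `tau`, `tau0`, plus
#'   metadata (gene id, design, segment lengths, sample/isoform ids, notes).
#' @export
fit_gene <- function(data, hyper = hyperparams(), mcmc = mcmc_settings(),
                     likelihood = TRUE) {
  stopifnot(inherits(data, "iso_gene_data"), inherits(hyper, "iso_hyper"),
            inherits(mcmc, "iso_mcmc_settings"))
  X <- data$partition$design
  y <- data$y
  m <- nrow(X); s <- ncol(X); L <- ncol(y)
  notes <- character()
  if (anyDuplicated(t(X))) {
    notes <- c(notes, "unidentifiable: duplicate design columns (label switching possible)")
    warning("gene ", data$partition$gene_id,
            ": duplicate design columns; isoforms not separately identifiable")
  }
  if (all(y == 0)) notes <- c(notes, "all-zero expression")

  mu0 <- hyper$mu0
  if (is.null(mu0)) {
    # data-scale anchor: trimmed mean of the gene's values, deflated by the
    # average isoform multiplicity of its segments (values on shared
    # segments are isoform sums)
    mu0 <- max(trimmed_mean(as.vector(y)) / mean(rowSums(X)), 1e-3)
  }
  mu0 <- rep_len(as.numeric(mu0), s)

  chains <- vector("list", mcmc$chains)
  gseed <- string_seed(data$partition$gene_id, mcmc$seed)
  for (ch in seq_len(mcmc$chains)) {
    set.seed((gseed + 104729 * ch) %% 2147483647)
    yvar <- var(as.vector(y))
    if (!is.finite(yvar)) yvar <- max(mean(y)^2, 1) # single-cell gene
    tau0_init <- if (!is.na(hyper$tau0_fixed)) rep(hyper$tau0_fixed, s) else
      rep(1 / max(yvar, 1e-4), s) * runif(s, 0.5, 2)
    beta_init <- pmin(vapply(seq_len(s), function(k)
      abs(rnorm(1, mu0[k], 1 / sqrt(tau0_init[k]))), 0), max(max(y), 1))
    beta_init <- matrix(rep(beta_init, L), nrow = s)
    I_init <- matrix(1L, s, L)
    resid <- y - X %*% (beta_init * I_init)
    tau_init <- if (!is.na(hyper$tau_fixed)) rep(hyper$tau_fixed, L) else
      pmin(pmax(1 / pmax(apply(resid, 2L, function(r) mean(r^2)), 1e-4), 1e-4), 1e4) *
        runif(L, 0.5, 2)
    raw <- .gene_gibbs(y, X, hyper$a1, hyper$a2, hyper$a10, hyper$a20,
                       mu0, hyper$p,
                       mcmc$iterations, mcmc$burn_in, mcmc$thin,
                       ifelse(is.na(hyper$tau_fixed), -1, hyper$tau_fixed),
                       ifelse(is.na(hyper$tau0_fixed), -1, hyper$tau0_fixed),
                       isTRUE(likelihood),
                       beta_init, I_init, as.numeric(tau_init),
                       as.numeric(tau0_init))
    kl <- as.vector(outer(colnames(X), colnames(y), paste, sep = ":"))
    colnames(raw$beta) <- kl; colnames(raw$I) <- kl
    colnames(raw$tau) <- colnames(y); colnames(raw$tau0) <- colnames(X)
    chains[[ch]] <- raw
  }
  structure(list(gene_id = data$partition$gene_id,
                 chains = chains,
                 design = X,
                 lengths = data$partition$segments$length,
                 samples = colnames(y), isoforms = colnames(X),
                 m = m, s = s,
                 hyper = hyper, settings = mcmc, mu0 = mu0,
                 notes = notes),
            class = "iso_fit")
}

#' @export
print.iso_fit <- function(x, ...) {
  cat("iso_fit", x$gene_id, ":", x$s, "isoform(s) x", length(x$samples),
      "sample(s),", length(x$chains), "chain(s) x",
      nrow(x$chains[[1]]$beta), "draws\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# pooled draws of one block ("beta", "I", "tau", "tau0") across chains
pool_draws <- function(fit, what) {
  do.call(rbind, lapply(fit$chains, `[[`, what))
}

# pooled draws of beta* = beta x I, columns "k:l"
bstar_draws <- function(fit) {
  pool_draws(fit, "beta") * pool_draws(fit, "I")
}

#' Fit many genes
#'
#' Genes are conditionally independent given the hyperparameters; each gene
#' gets an RNG stream derived from the run seed and its gene id, so results
#' do not depend on processing order.
#'
#' @param gene_data_list list of [gene_data()] objects.
#' @param hyper,mcmc shared settings.
#' @return named list of `iso_fit` objects.
#' @export
fit_genes <- function(gene_data_list, hyper = hyperparams(),
                      mcmc = mcmc_settings()) {
  out <- lapply(gene_data_list, fit_gene, hyper = hyper, mcmc = mcmc)
  names(out) <- vapply(out, `[[`, "", "gene_id")
  out
}

#' Assemble per-gene data from a partition list and an expression matrix
#'
#' Matches the rows of a normalized expression matrix to partitions by
#' (gene_id, segment_index) and returns the per-gene [gene_data()] list.
#'
#' @param partitions named list of partitions.
#' @param em an `expr_matrix` (or `count_matrix` for raw-count fits).
#' @return list of `iso_gene_data`.
#' @export
split_gene_data <- function(partitions, em) {
  v <- if (inherits(em, "count_matrix")) em$counts else em$values
  rows <- em$rows
  lapply(partitions, function(p) {
    idx <- which(rows$gene_id == p$gene_id)
    if (length(idx) == 0L)
      stop("no expression rows for gene ", p$gene_id)
    idx <- idx[order(rows$segment_index[idx])]
    if (length(idx) != nrow(p$segments))
      stop("gene ", p$gene_id, ": expression has ", length(idx),
           " rows, partition has ", nrow(p$segments), " segments")
    gene_data(p, v[idx, , drop = FALSE])
  })
}
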