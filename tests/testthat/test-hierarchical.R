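fx_gd_single <- function(y = matrix(c(5, 5, 5), ncol = 1)) {
  gene_data(build_pseudo_exons(fx_single_iso3()), y)
}

test_that("truncated-normal log-likelihood matches its closed forms", {
  gd <- fx_gd_single(matrix(c(8, 8, 8), ncol = 1))
  st <- list(beta = matrix(8), I = matrix(1L), tau = 1)
  # zero residuals, truncation negligible at mu/sigma = 8
  expect_equal(log_likelihood(gd, st, 1), -3 / 2 * log(2 * pi),
               tolerance = 1e-8)
  # mu = 0, tau = 1: each exon contributes log phi(y) + log 2
  y <- c(0.3, 1.1, 2.4)
  gd0 <- fx_gd_single(matrix(y, ncol = 1))
  st0 <- list(beta = matrix(5), I = matrix(0L), tau = 1)
  expect_equal(log_likelihood(gd0, st0, 1),
               sum(dnorm(y, log = TRUE)) + 3 * log(2))
  # all indicators off is the same as beta* = 0
  stb <- list(beta = matrix(99), I = matrix(0L), tau = 1)
  expect_equal(log_likelihood(gd0, stb, 1), log_likelihood(gd0, st0, 1))
  expect_error(log_likelihood(gd0, list(beta = matrix(Inf), I = matrix(1L),
                                        tau = 1), 1),
               "non-finite")
})

test_that("indicator full conditional reduces to the prior and to direct odds", {
  gd <- fx_gd_single(matrix(c(4, 6, 5), ncol = 1))
  hy <- hyperparams(p = 0.3)
  st <- list(beta = matrix(0), I = matrix(1L), tau = 1)
  # beta = 0: likelihoods equal, prior recovered
  expect_equal(update_indicator(st, gd, 1, 1, hy, draw = FALSE)$prob, 0.3)
  # p near 1 forces presence
  hy1 <- hyperparams(p = 1 - 1e-12)
  st2 <- list(beta = matrix(5), I = matrix(1L), tau = 1)
  expect_gt(update_indicator(st2, gd, 1, 1, hy1, draw = FALSE)$prob,
            1 - 1e-6)
  # one-exon toy case against hand-computed odds
  gd1 <- gene_data(build_pseudo_exons(
    fx_gene("one", list(k = data.frame(start = 1, end = 100)))),
    matrix(2, 1, 1))
  st1 <- list(beta = matrix(1.5), I = matrix(1L), tau = 1)
  l1 <- dnorm(2 - 1.5) / pnorm(1.5)
  l0 <- dnorm(2) / pnorm(0)
  odds <- (0.4 / 0.6) * (l1 / l0)
  expect_equal(update_indicator(st1, gd1, 1, 1, hyperparams(p = 0.4),
                                draw = FALSE)$prob,
               odds / (1 + odds))
})

test_that("single-isoform gene recovers its expression level", {
  fit <- fit_gene(fx_gd_single(), hyperparams(),
                  mcmc_settings(chains = 2, iterations = 3000,
                                burn_in = 800, seed = 42))
  sm <- summarize_isoforms(fit)
  dg <- mcmc_diagnostics(fit)
  mcse_beta <- dg$mcse[dg$parameter == "beta[k:S1]"]
  expect_lt(abs(sm$expr_mean - 5), 2 * mcse_beta + 0.05)
  expect_gt(sm$presence_prob, 0.95)
  # all-zero gene: presence cannot exceed the prior
  fit0 <- fit_gene(fx_gd_single(matrix(0, 3, 1)), hyperparams(p = 0.5),
                   mcmc_settings(chains = 2, iterations = 2000,
                                 burn_in = 500, seed = 7))
  expect_lte(summarize_isoforms(fit0)$presence_prob, 0.5 + 0.05)
  expect_match(paste(fit0$notes, collapse = ";"), "all-zero")
})

test_that("prior sampling reproduces the Gamma precision moments", {
  fit <- fit_gene(fx_gd_single(), hyperparams(a1 = 2, a2 = 0.5,
                                              a10 = 3, a20 = 1.5),
                  mcmc_settings(chains = 2, iterations = 6000,
                                burn_in = 500, seed = 11),
                  likelihood = FALSE)
  tau <- as.vector(do.call(rbind, lapply(fit$chains, `[[`, "tau")))
  expect_equal(mean(tau), 2 / 0.5, tolerance = 0.05)
  expect_equal(var(tau), 2 / 0.5^2, tolerance = 0.15)
  tau0 <- as.vector(do.call(rbind, lapply(fit$chains, `[[`, "tau0")))
  expect_equal(mean(tau0), 3 / 1.5, tolerance = 0.1)
  # indicators follow Bernoulli(p) with the likelihood off
  I <- as.vector(do.call(rbind, lapply(fit$chains, `[[`, "I")))
  expect_equal(mean(I), 0.5, tolerance = 0.05)
})

test_that("fits are deterministic in the seed and invariant to gene order", {
  gd1 <- fx_gd_single()
  gd2 <- gene_data(build_pseudo_exons(fx_two_iso()),
                   matrix(c(3, 8), ncol = 1))
  ms <- mcmc_settings(chains = 2, iterations = 400, burn_in = 100, seed = 5)
  fa <- fit_genes(list(gd1, gd2), mcmc = ms)
  fb <- fit_genes(list(gd2, gd1), mcmc = ms)
  expect_equal(fa$gs$chains, fb$gs$chains)
  expect_equal(fa$gx$chains, fb$gx$chains)
  # identical seed, identical draws; different seed, different draws
  fc <- fit_gene(gd1, mcmc = ms)
  fd <- fit_gene(gd1, mcmc = ms)
  fe <- fit_gene(gd1, mcmc = mcmc_settings(chains = 2, iterations = 400,
                                           burn_in = 100, seed = 6))
  expect_identical(fc$chains, fd$chains)
  expect_false(identical(fc$chains, fe$chains))
})

test_that("unidentifiable designs are sampled with a warning", {
  g <- fx_gene("dup", list(i1 = data.frame(start = 1, end = 100),
                           i2 = data.frame(start = 1, end = 100)))
  gd <- gene_data(build_pseudo_exons(g), matrix(10, 1, 1))
  expect_warning(
    fit <- fit_gene(gd, mcmc = mcmc_settings(chains = 2, iterations = 300,
                                             burn_in = 100, seed = 1)),
    "duplicate design")
  expect_match(paste(fit$notes, collapse = ";"), "unidentifiable")
})

test_that("diagnostics separate well-mixed from disjoint chains", {
  set.seed(3)
  mk <- function(shift) list(
    beta = matrix(rnorm(2000, shift), ncol = 1,
                  dimnames = list(NULL, "k:S1")),
    I = matrix(1L, 2000, 1, dimnames = list(NULL, "k:S1")),
    tau = matrix(rgamma(2000, 5, 5), ncol = 1, dimnames = list(NULL, "S1")),
    tau0 = matrix(rgamma(2000, 5, 5), ncol = 1, dimnames = list(NULL, "k")))
  good <- fx_fake_fit("g", "k", "S1", 1, NULL, NULL, NULL, NULL)
  good$chains <- list(mk(0), mk(0))
  dg <- mcmc_diagnostics(good)
  expect_lt(max(abs(dg$rhat - 1), na.rm = TRUE), 0.02)
  # iid draws: MCSE matches s/sqrt(n) within 10%
  b <- dg[dg$parameter == "beta[k:S1]", ]
  expect_equal(b$mcse, b$sd / sqrt(4000), tolerance = 0.1)
  expect_equal(attr(dg, "n_flagged"), 0L)
  # disjoint supports: R-hat far above 1 and flagged
  badf <- good
  badf$chains <- list(mk(0), mk(50))
  db <- mcmc_diagnostics(badf)
  expect_gt(db$rhat[db$parameter == "beta[k:S1]"], 3)
  expect_true(db$flagged[db$parameter == "beta[k:S1]"])
  # single chain: R-hat omitted with a warning
  single <- good
  single$chains <- list(mk(0))
  expect_warning(ds <- mcmc_diagnostics(single), "single chain")
  expect_true(all(is.na(ds$rhat)))
})

test_that("gene bundles validate dimensions and expression values", {
  p <- build_pseudo_exons(fx_single_iso3())
  expect_error(gene_data(p, matrix(1, 2, 1)), "segments")
  expect_error(gene_data(p, matrix(-1, 3, 1)), "negative")
  expect_error(hyperparams(p = 0), "p > 0")
  expect_error(mcmc_settings(chains = 0), "chains")
})
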