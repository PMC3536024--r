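# fake fit with one isoform, two samples and prescribed draw columns
fx_fit_2s <- function(gene_id, b1, b2, tau1 = NULL, tau2 = NULL,
                      I1 = NULL, I2 = NULL, m = 3L) {
  n <- length(b1)
  if (is.null(tau1)) tau1 <- rep(1, n)
  if (is.null(tau2)) tau2 <- rep(1, n)
  if (is.null(I1)) I1 <- rep(1L, n)
  if (is.null(I2)) I2 <- rep(1L, n)
  kl <- c("k:S1", "k:S2")
  fx_fake_fit(gene_id, "k", c("S1", "S2"), m,
              beta = matrix(c(b1, b2), ncol = 2, dimnames = list(NULL, kl)),
              I = matrix(c(I1, I2), ncol = 2, dimnames = list(NULL, kl)),
              tau = matrix(c(tau1, tau2), ncol = 2,
                           dimnames = list(NULL, c("S1", "S2"))),
              tau0 = matrix(rep(1, n), ncol = 1, dimnames = list(NULL, "k")))
}

test_that("high/low calls equal a direct recomputation of the rule", {
  set.seed(21)
  n <- 100
  sm <- data.frame(gene_id = sprintf("g%03d", 1:n),
                   isoform_id = sprintf("g%03d.1", 1:n),
                   sample_id = "S1",
                   presence_prob = runif(n),
                   expr_mean = rlnorm(n, 2, 1))
  sm$expr_sd <- 0.3 * sm$expr_mean
  sm$q5 <- sm$expr_mean - 1.6 * sm$expr_sd
  sm$q95 <- sm$expr_mean + 1.6 * sm$expr_sd
  sm$q2.5 <- sm$q5 - 0.1
  sm$q97.5 <- sm$q95 + 0.1
  out <- call_high_low(sm)
  lens <- sort(sm$expr_mean)
  p10 <- lens[ceiling(0.10 * n)]
  p90 <- lens[ceiling(0.90 * n)]
  expect_equal(out$label,
               ifelse(sm$q95 < p10, "low",
                      ifelse(sm$q5 > p90, "high", "none")))
  # mutual exclusivity is structural
  expect_false(any(out$q95 < p10 & out$q5 > p90))
  # PPI pinned at zero with positive references -> low
  sm2 <- sm
  sm2[1, c("expr_mean", "q2.5", "q5", "q95", "q97.5")] <- 0
  expect_equal(call_high_low(sm2)$label[1], "low")
  # PPI 5th percentile above every mean -> high
  sm3 <- sm
  sm3$q5[2] <- max(sm$expr_mean) + 1
  expect_equal(call_high_low(sm3)$label[2], "high")
  expect_error(call_high_low(sm[1, ]), "two isoforms")
})

test_that("bayesian t draws follow the contrast formula and its symmetries", {
  set.seed(4)
  b1 <- rnorm(1000, 10); b2 <- rnorm(1000, 4)
  t1 <- rgamma(1000, 5, 5); t2 <- rgamma(1000, 5, 5)
  fit <- fx_fit_2s("g1", b1, b2, t1, t2)
  td <- bayesian_t(fit, "k", c("S1", "S2"))
  expect_equal(td, (b1 - b2) / sqrt(1 / (3 * t1) + 1 / (3 * t2)))
  # same sample: identically zero
  expect_true(all(bayesian_t(fit, "k", c("S1", "S1")) == 0))
  # antisymmetry under pair swap
  expect_equal(bayesian_t(fit, "k", c("S2", "S1")), -td)
})

test_that("differential rules call a strong synthetic contrast correctly", {
  set.seed(14)
  n <- 1000
  fits <- c(
    list(fx_fit_2s("gup", rnorm(n, 10, 0.5), rep(0, n),
                   I2 = rep(0L, n))),
    lapply(1:12, function(i)
      fx_fit_2s(sprintf("gnull%02d", i), rnorm(n, 5, 1), rnorm(n, 5, 1))))
  dc <- differential_calls(fits, c("S1", "S2"))
  up <- dc[dc$gene_id == "gup", ]
  expect_equal(up$verdict[up$rule == "ppi"], "up")
  expect_gt(up$t_lo[up$rule == "ppi"], 0)
  expect_equal(up$verdict[up$rule == "decile"], "up")
  expect_equal(up$verdict[up$rule == "tcrit"], "up")
  # null genes stay uncalled under the PPI rule
  expect_true(all(dc$verdict[dc$rule == "ppi" & dc$gene_id != "gup"] == "none"))
  # single-exon gene: t-critical rule skipped with a notice
  f1 <- fx_fit_2s("g1ex", rnorm(n, 8), rnorm(n, 1), m = 1L)
  d1 <- differential_calls(c(list(f1), fits[2:5]), c("S1", "S2"))
  r3 <- d1[d1$gene_id == "g1ex" & d1$rule == "tcrit", ]
  expect_true(is.na(r3$verdict))
  expect_match(r3$note, "single-exon")
})

test_that("indicator differential rule matches exhaustive grid evaluation", {
  ps <- seq(0, 1, by = 0.05)
  for (p1 in ps) for (p2 in ps) {
    v <- indicator_differential(c(p1, p2), conf = 0.95)$verdict
    expected <- if (p1 >= 0.95 && p2 <= 0.05) "up"
    else if (p2 >= 0.95 && p1 <= 0.05) "down" else "none"
    expect_identical(v, expected)
  }
  # fit-based form agrees with the probability form
  fit <- fx_fit_2s("g", rep(5, 400), rep(5, 400),
                   I1 = rep(1L, 400), I2 = rep(0L, 400))
  expect_equal(indicator_differential(fit, "k", c("S1", "S2"))$verdict, "up")
})

test_that("variability classes sit at the nearest-rank 35/65/90 thresholds", {
  v <- sample(1:100)
  fits <- lapply(seq_along(v), function(i)
    fx_fake_fit(sprintf("g%03d", i), sprintf("g%03d.1", i), "S1", 2,
                beta = matrix(1, 4, 1, dimnames = list(NULL, "k:S1")),
                I = matrix(1L, 4, 1, dimnames = list(NULL, "k:S1")),
                tau = matrix(1, 4, 1, dimnames = list(NULL, "S1")),
                tau0 = matrix(1 / v[i], 4, 1,
                              dimnames = list(NULL, sprintf("g%03d.1", i)))))
  vc <- variability_classify(fits)
  s <- sort(v)
  expect_equal(unname(vc$thresholds),
               s[ceiling(c(0.35, 0.65, 0.90) * 100)])
  expect_setequal(round(vc$table$variability[vc$table$class == "low"], 6),
                  as.numeric(v[round(v - vc$thresholds[["p35"]], 6) < 0]))
  expect_setequal(round(vc$table$variability[vc$table$class == "high"], 6),
                  as.numeric(v[round(v - vc$thresholds[["p90"]], 6) > 0]))
  # ties under a constant distribution: nothing is extreme
  fits_c <- lapply(fits, function(f) {
    f$chains[[1]]$tau0[] <- 0.5
    f
  })
  expect_warning(vcc <- variability_classify(fits_c), "degenerate")
  expect_true(all(vcc$table$class == "mid"))
  expect_error(variability_classify(fits[1:5]), ">= 10 isoforms")
})

test_that("Gamma fit of variabilities recovers known shape and a unit QQ slope", {
  set.seed(31)
  x <- rgamma(1000, shape = 2, rate = 1)
  gf <- gamma_mle(x)
  expect_lt(abs(gf$shape - 2) / 2, 0.2)
  fits <- lapply(seq_along(x), function(i)
    fx_fake_fit(sprintf("g%04d", i), sprintf("g%04d.1", i), "S1", 2,
                beta = matrix(1, 2, 1, dimnames = list(NULL, "k:S1")),
                I = matrix(1L, 2, 1, dimnames = list(NULL, "k:S1")),
                tau = matrix(1, 2, 1, dimnames = list(NULL, "S1")),
                tau0 = matrix(1 / x[i], 2, 1,
                              dimnames = list(NULL, sprintf("g%04d.1", i)))))
  vc <- variability_classify(fits)
  qq <- vc$qq[vc$qq$prob >= 0.05 & vc$qq$prob <= 0.95, ]
  slope <- coef(lm(observed ~ theoretical, data = qq))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
  expect_lt(vc$tail_exceedance, 0.10)
})

test_that("pairwise overlap table equals brute-force set intersections", {
  set.seed(17)
  iso <- sprintf("i%02d", 1:30)
  labels <- expand.grid(isoform_id = iso,
                        sample_id = c("A", "B", "C"),
                        stringsAsFactors = FALSE)
  labels$gene_id <- sub("\\..*", "", labels$isoform_id)
  labels$label <- sample(c("high", "low", "none"), nrow(labels),
                         replace = TRUE)
  M <- pairwise_overlap_table(labels)
  key <- function(cc, lab) with(labels,
    paste(gene_id, isoform_id)[sample_id == cc & label == lab])
  for (a in c("A", "B", "C")) for (b in c("A", "B", "C")) {
    i <- match(a, c("A", "B", "C")); j <- match(b, c("A", "B", "C"))
    if (i < j) expect_equal(M[a, b], length(intersect(key(a, "high"),
                                                      key(b, "high"))))
    if (i > j) expect_equal(M[a, b], length(intersect(key(a, "low"),
                                                      key(b, "low"))))
  }
  expect_equal(unname(M[, "total"][1:3]),
               unname(vapply(c("A", "B", "C"),
                             function(cc) length(key(cc, "high")), 0)))
  # identical label sets: overlap equals the per-condition count
  lab2 <- labels[labels$sample_id == "A", ]
  lab2b <- lab2; lab2b$sample_id <- "B"
  M2 <- pairwise_overlap_table(rbind(lab2, lab2b))
  expect_equal(M2["A", "B"], sum(lab2$label == "high"))
  expect_equal(M2["B", "A"], sum(lab2$label == "low"))
})

test_that("gene-level summaries add isoforms draw-wise", {
  set.seed(12)
  n <- 2000
  b1 <- rnorm(n, 3, 0.2); b2 <- rnorm(n, 4, 0.2)
  kl <- c("k1:S1", "k2:S1")
  fit <- fx_fake_fit("g", c("k1", "k2"), "S1", 2,
                     beta = matrix(c(b1, b2), ncol = 2,
                                   dimnames = list(NULL, kl)),
                     I = matrix(1L, n, 2, dimnames = list(NULL, kl)),
                     tau = matrix(1, n, 1, dimnames = list(NULL, "S1")),
                     tau0 = matrix(1, n, 2,
                                   dimnames = list(NULL, c("k1", "k2"))))
  gs <- gene_level_summary(fit)
  expect_equal(gs$mean, mean(b1 + b2))
  expect_equal(gs$sd, sd(b1 + b2))
  # single isoform: gene summary equals the isoform summary
  f1 <- fx_fit_2s("g1", b1, b2)
  gs1 <- gene_level_summary(f1)
  sm1 <- summarize_isoforms(f1)
  expect_equal(gs1$mean, sm1$expr_mean)
  # all-absent gene: mean at zero
  f0 <- fx_fit_2s("g0", b1, b2, I1 = rep(0L, n), I2 = rep(0L, n))
  expect_equal(gene_level_summary(f0)$mean, c(0, 0))
})
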