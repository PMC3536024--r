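# Classical count-based tests and GLMs for two-library differential
# expression, provided as the comparison baselines for the Bayesian model.
# All two-sample tests take per-gene counts n1, n2 with positive normalizing
# constants C1, C2 (depth/length factors); only the ratio C1/(C1+C2) matters.

two_sided_from_tails <- function(lower, upper) min(1, 2 * min(lower, upper))

#' Exact binomial test for two-library counts
#'
#' Conditional on the total, n1 | n1 + n2 ~ Binomial(n1 + n2,
#' C1/(C1+C2)) under the null of equal normalized expression. Two-sided by
#' doubling the smaller tail (capped at 1). Returns NA (no call) when both
#' counts are zero — the degenerate case that breaks t-style statistics.
#'
#' @param n1,n2 non-negative counts.
#' @param C1,C2 positive normalizing constants.
#' @return two-sided p-value, or NA for a (0, 0) input.
#' @export
binomial_count_test <- function(n1, n2, C1 = 1, C2 = 1) {
  stopifnot(n1 >= 0, n2 >= 0, C1 > 0, C2 > 0)
  n <- n1 + n2
  if (n == 0) return(NA_real_)
  p0 <- C1 / (C1 + C2)
  two_sided_from_tails(pbinom(n1, n, p0),
                       pbinom(n1 - 1, n, p0, lower.tail = FALSE))
}

#' Audic-Claverie (negative binomial) test
#'
#' Under the null, n2 | n1 ~ NegativeBinomial(size = n1 + 1,
#' prob = C1/(C1+C2)); two-sided by doubling the smaller tail of n2.
#'
#' @inheritParams binomial_count_test
#' @return two-sided p-value, or NA for a (0, 0) input.
#' @export
audic_claverie_test <- function(n1, n2, C1 = 1, C2 = 1) {
  stopifnot(n1 >= 0, n2 >= 0, C1 > 0, C2 > 0)
  if (n1 + n2 == 0) return(NA_real_)
  p0 <- C1 / (C1 + C2)
  two_sided_from_tails(pnbinom(n2, size = n1 + 1, prob = p0),
                       pnbinom(n2 - 1, size = n1 + 1, prob = p0,
                               lower.tail = FALSE))
}

#' Chi-square goodness-of-fit test for Poisson counts
#'
#' Statistic \eqn{\sum_{i=1,2} (n_i - m_i)^2 / m_i} with expected counts
#' under the null \eqn{m_i = C_i (n_1 + n_2) / (C_1 + C_2)}; asymptotically
#' chi-square on 1 df.
#'
#' @inheritParams binomial_count_test
#' @return list with `statistic` and `p_value` (NA for a (0, 0) input).
#' @export
chisq_poisson_test <- function(n1, n2, C1 = 1, C2 = 1) {
  stopifnot(n1 >= 0, n2 >= 0, C1 > 0, C2 > 0)
  if (n1 + n2 == 0) return(list(statistic = NA_real_, p_value = NA_real_))
  m <- c(C1, C2) * (n1 + n2) / (C1 + C2)
  if (any(m <= 0)) stop("zero expected count")
  stat <- sum((c(n1, n2) - m)^2 / m)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Run a two-sample count test over a table of genes
#'
#' @param df data.frame with columns gene (optional), n1, n2, C1, C2
#'   (constants default to 1).
#' @param method "binomial", "audic_claverie" or "chisq".
#' @return `df` with added columns `statistic` (chisq only) and `p_value`.
#' @export
two_sample_count_tests <- function(df, method = c("binomial",
                                                  "audic_claverie", "chisq")) {
  method <- match.arg(method)
  if (is.null(df$C1)) df$C1 <- 1
  if (is.null(df$C2)) df$C2 <- 1
  if (method == "chisq") {
    res <- mapply(function(a, b, c1, c2) unlist(chisq_poisson_test(a, b, c1, c2)),
                  df$n1, df$n2, df$C1, df$C2)
    df$statistic <- res["statistic", ]
    df$p_value <- res["p_value", ]
  } else {
    fn <- if (method == "binomial") binomial_count_test else audic_claverie_test
    df$p_value <- mapply(fn, df$n1, df$n2, df$C1, df$C2)
  }
  df
}

#' Fisher's exact test on a two-library 2x2 table
#'
#' Thin review-level helper: contrasts a gene's counts against the remaining
#' library totals.
#'
#' @param n1,n2 gene counts; @param N1,N2 library totals (>= gene counts).
#' @return two-sided p-value.
#' @export
fisher_count_test <- function(n1, n2, N1, N2) {
  stopifnot(N1 >= n1, N2 >= n2)
  stats::fisher.test(matrix(c(n1, N1 - n1, n2, N2 - n2), 2L))$p.value
}

#' Poisson-log or Gaussian GLM for expression estimation
#'
#' The depth-offset GLM baseline: `log E(n_i) = log d_i + lambda_a(i) +
#' theta_i`, fitted in the condition-mean parameterization (no intercept).
#' Without technical replicates the condition map a(i) is the sample index
#' and the per-sample MLE has the closed form log(n_i / d_i). The Gaussian
#' family fits normalized continuous expression y on the exon-by-isoform
#' design instead (the estimator the Bayesian model is compared against):
#' one linear model per sample, `y ~ 0 + X`.
#'
#' @param counts for "poisson-log": numeric vector of per-sample gene counts.
#'   For "gaussian": an m x L matrix of normalized segment expression.
#' @param offsets per-sample depths d_i (poisson-log only).
#' @param condition factor mapping samples to biological conditions
#'   (default: each sample its own condition).
#' @param design exon-by-isoform matrix X (gaussian only).
#' @param family "poisson-log" or "gaussian".
#' @return data.frame of coefficient estimates with standard errors.
#' @export
fit_expression_glm <- function(counts, offsets = NULL, condition = NULL,
                               design = NULL,
                               family = c("poisson-log", "gaussian")) {
  family <- match.arg(family)
  if (family == "poisson-log") {
    n <- as.numeric(counts)
    if (is.null(offsets)) offsets <- rep(1, length(n))
    stopifnot(all(offsets > 0), length(offsets) == length(n))
    if (is.null(condition)) condition <- factor(seq_along(n))
    condition <- droplevels(as.factor(condition))
    if (nlevels(condition) == 1L) {
      fit <- glm(n ~ 1, family = poisson(), offset = log(offsets))
      sm <- summary(fit)$coefficients
      rownames(sm) <- paste0("condition", levels(condition))
    } else {
      mm <- stats::model.matrix(~ 0 + condition)
      if (qr(mm)$rank < ncol(mm))
        stop("rank-deficient condition design; confounded levels: ",
             paste(levels(condition), collapse = ", "))
      fit <- glm(n ~ 0 + condition, family = poisson(),
                 offset = log(offsets))
      sm <- summary(fit)$coefficients
    }
    data.frame(term = sub("^condition", "", rownames(sm)),
               estimate = sm[, 1L], std_error = sm[, 2L],
               family = family, stringsAsFactors = FALSE, row.names = NULL)
  } else {
    y <- as.matrix(counts)
    X <- as.matrix(design)
    stopifnot(nrow(y) == nrow(X))
    if (qr(X)$rank < ncol(X))
      stop("rank-deficient design; confounded columns: ",
           paste(colnames(X), collapse = ", "))
    out <- do.call(rbind, lapply(seq_len(ncol(y)), function(l) {
      fit <- lm(y[, l] ~ 0 + X)
      sm <- suppressWarnings(summary(fit))$coefficients # zero-residual fits are fine
      est <- coef(fit)
      se <- rep(NA_real_, length(est))
      se[match(rownames(sm), names(est))] <- sm[, 2L]
      se[is.nan(se)] <- 0
      data.frame(sample = colnames(y)[l] %||% as.character(l),
                 term = sub("^X", "", names(est)),
                 estimate = unname(est), std_error = unname(se),
                 family = family, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Length-bias inflation of the two-sample t statistic
#'
#' Scaling both expression rates by a length factor L scales the t statistic
#' \eqn{T = (\lambda_1 - \lambda_2)/\sqrt{\lambda_1 + \lambda_2}} by exactly
#' \eqn{\sqrt{L}}: longer regions inflate apparent significance with no
#' change in relative expression.
#'
#' @param lambda1,lambda2 expression rates (>= 0, not both zero).
#' @param L length fold-change (> 0).
#' @return list with `t` (the statistic at scale L) and `inflation`
#'   (T(L)/T(1) = sqrt(L)).
#' @export
length_bias_t <- function(lambda1, lambda2, L = 1) {
  stopifnot(L > 0, lambda1 >= 0, lambda2 >= 0)
  if (lambda1 + lambda2 == 0) stop("undefined for lambda1 = lambda2 = 0")
  list(t = (lambda1 - lambda2) / sqrt(lambda1 + lambda2) * sqrt(L),
       inflation = sqrt(L))
}
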