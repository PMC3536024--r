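#' Posterior summaries per isoform and sample
#'
#' One row per isoform x sample: posterior presence probability (mean of
#' I_kl), posterior mean/SD of the effective expression beta* = I x beta,
#' and its 2.5 / 5 / 95 / 97.5 posterior-probability-interval bounds.
#'
#' @param fits list of `iso_fit` objects (or a single fit).
#' @return data.frame.
#' @export
summarize_isoforms <- function(fits) {
  if (inherits(fits, "iso_fit")) fits <- list(fits)
  out <- do.call(rbind, lapply(fits, function(fit) {
    bs <- bstar_draws(fit)
    im <- pool_draws(fit, "I")
    kl <- expand.grid(isoform_id = fit$isoforms, sample_id = fit$samples,
                      stringsAsFactors = FALSE)
    qs <- apply(bs, 2L, quantile, probs = c(0.025, 0.05, 0.95, 0.975),
                names = FALSE)
    data.frame(gene_id = fit$gene_id,
               isoform_id = kl$isoform_id, sample_id = kl$sample_id,
               presence_prob = colMeans(im),
               expr_mean = colMeans(bs), expr_sd = apply(bs, 2L, sd),
               q2.5 = qs[1L, ], q5 = qs[2L, ], q95 = qs[3L, ], q97.5 = qs[4L, ],
               n_exons = fit$m, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' High / low expression calls
#'
#' An isoform has low/no expression in a sample if the 95th percentile of its
#' expression PPI falls below the 10th percentile of all mean isoform
#' expressions; high expression if the 5th percentile of its PPI exceeds the
#' 90th percentile of mean isoform expressions. The reference percentiles are
#' nearest-rank over all isoform x sample means in the run.
#'
#' @param summaries output of [summarize_isoforms()] (>= 2 isoforms).
#' @return `summaries` with columns `label` in {high, low, none} and the
#'   reference thresholds as attributes.
#' @export
call_high_low <- function(summaries) {
  if (length(unique(paste(summaries$gene_id, summaries$isoform_id))) < 2L)
    stop("need at least two isoforms to anchor reference percentiles")
  ref <- nearest_rank_quantile(summaries$expr_mean, c(10, 90))
  lab <- rep("none", nrow(summaries))
  lab[summaries$q95 < ref[1L]] <- "low"
  lab[summaries$q5 > ref[2L]] <- "high"
  summaries$label <- lab
  attr(summaries, "ref_p10") <- ref[1L]
  attr(summaries, "ref_p90") <- ref[2L]
  summaries
}

#' Posterior draws of the Bayesian t contrast
#'
#' Per posterior draw,
#' \eqn{t = (\beta^*_{k l_1} - \beta^*_{k l_2}) /
#' \sqrt{1/(m_g \tau_{l_1}) + 1/(m_g \tau_{l_2})}}
#' with m_g the gene's segment count — the posterior analogue of a two-sample
#' t statistic whose critical value depends on the number of exons.
#'
#' @param fit an `iso_fit`.
#' @param isoform isoform id or index.
#' @param pair length-2 vector of sample ids or indices (l1, l2).
#' @return numeric vector of posterior t draws.
#' @export
bayesian_t <- function(fit, isoform, pair) {
  stopifnot(inherits(fit, "iso_fit"), length(pair) == 2L)
  k <- if (is.character(isoform)) match(isoform, fit$isoforms) else isoform
  l1 <- if (is.character(pair[1L])) match(pair[1L], fit$samples) else pair[1L]
  l2 <- if (is.character(pair[2L])) match(pair[2L], fit$samples) else pair[2L]
  if (anyNA(c(k, l1, l2))) stop("unknown isoform or sample id")
  bs <- bstar_draws(fit)
  tau <- pool_draws(fit, "tau")
  num <- bs[, (l1 - 1L) * fit$s + k] - bs[, (l2 - 1L) * fit$s + k]
  den <- sqrt(1 / (fit$m * tau[, l1]) + 1 / (fit$m * tau[, l2]))
  num / den
}

#' Differential expression calls from posterior t draws
#'
#' Three decision rules per isoform and sample pair:
#' \describe{
#'   \item{R1 "ppi"}{up/down when the 95% symmetric PPI of t excludes zero.}
#'   \item{R2 "decile"}{up/down when the whole 95% PPI lies above the 90th /
#'     below the 10th percentile of all posterior-mean t statistics of the
#'     comparison (rank-based extreme-decile rule).}
#'   \item{R3 "tcrit"}{posterior-mean t compared with the two-sided 5%
#'     t-critical value on 2(m_g - 1) degrees of freedom; only defined for
#'     genes with at least two exons (m_g >= 2).}
#' }
#'
#' @param fits list of `iso_fit` objects.
#' @param pair length-2 sample id vector.
#' @param rules subset of c("ppi", "decile", "tcrit").
#' @param level PPI level for R1/R2 (default 0.95).
#' @return data.frame, one row per isoform x rule.
#' @export
differential_calls <- function(fits, pair, rules = c("ppi", "decile", "tcrit"),
                               level = 0.95) {
  if (inherits(fits, "iso_fit")) fits <- list(fits)
  rules <- match.arg(rules, several.ok = TRUE)
  a <- (1 - level) / 2
  per <- list()
  for (fit in fits) {
    for (k in seq_len(fit$s)) {
      td <- bayesian_t(fit, k, pair)
      if (length(td) < 500L)
        warning("fewer than 500 post-burn-in draws for the t contrast")
      per[[length(per) + 1L]] <- list(
        gene_id = fit$gene_id, isoform_id = fit$isoforms[k], m = fit$m,
        t_mean = mean(td),
        t_lo = unname(quantile(td, a)), t_hi = unname(quantile(td, 1 - a)))
    }
  }
  tm_all <- vapply(per, `[[`, 0, "t_mean")
  dec <- nearest_rank_quantile(tm_all, c(10, 90))
  out <- list()
  for (x in per) {
    for (r in rules) {
      verdict <- "none"; note <- ""
      if (r == "ppi") {
        if (x$t_lo > 0) verdict <- "up" else if (x$t_hi < 0) verdict <- "down"
      } else if (r == "decile") {
        if (x$t_lo > dec[2L]) verdict <- "up"
        else if (x$t_hi < dec[1L]) verdict <- "down"
      } else { # tcrit
        if (x$m < 2L) {
          note <- "skipped: single-exon gene"
          verdict <- NA_character_
        } else {
          tc <- qt(0.975, df = 2 * (x$m - 1L))
          if (x$t_mean > tc) verdict <- "up"
          else if (x$t_mean < -tc) verdict <- "down"
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = x$gene_id, isoform_id = x$isoform_id,
        sample_1 = as.character(pair[1L]), sample_2 = as.character(pair[2L]),
        rule = r, t_mean = x$t_mean, t_lo = x$t_lo, t_hi = x$t_hi,
        n_exons = x$m, verdict = verdict, note = note,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Indicator-based differential call
#'
#' Declares an isoform differentially expressed between two samples whenever
#' the presence indicators say, with high confidence, that it is expressed in
#' one and not in the other — irrespective of the expression amount. This is
#' the rule that rescues comparisons a classical t statistic cannot make
#' (zero counts in one sample).
#'
#' @param fit an `iso_fit` (or a length-2 numeric vector of presence
#'   probabilities, for direct rule evaluation).
#' @param isoform isoform id/index (ignored for the vector form).
#' @param pair sample pair (l1, l2).
#' @param conf confidence threshold (default 0.95).
#' @return list with `verdict` in {up, down, none} and the two presence
#'   probabilities.
#' @export
indicator_differential <- function(fit, isoform = NULL, pair = NULL,
                                   conf = 0.95) {
  if (is.numeric(fit) && length(fit) == 2L) {
    p1 <- fit[1L]; p2 <- fit[2L]
  } else {
    stopifnot(inherits(fit, "iso_fit"))
    k <- if (is.character(isoform)) match(isoform, fit$isoforms) else isoform
    l1 <- if (is.character(pair[1L])) match(pair[1L], fit$samples) else pair[1L]
    l2 <- if (is.character(pair[2L])) match(pair[2L], fit$samples) else pair[2L]
    im <- pool_draws(fit, "I")
    p1 <- mean(im[, (l1 - 1L) * fit$s + k])
    p2 <- mean(im[, (l2 - 1L) * fit$s + k])
  }
  verdict <- "none"
  if (p1 >= conf && p2 <= 1 - conf) verdict <- "up"
  if (p2 >= conf && p1 <= 1 - conf) verdict <- "down"
  list(verdict = verdict, p1 = p1, p2 = p2)
}

#' Cross-condition variability classes
#'
#' The hierarchy models an isoform's expression variability across samples
#' through tau_k0; the working variability measure is the posterior mean of
#' the variance 1/tau_k0 (option: the precision itself). Isoforms are
#' classified against the nearest-rank 35th / 65th / 90th percentiles of all
#' variabilities, with strict inequalities (ties fall in the middle class):
#' low (< 35th), mid, moderate (> 65th), high (> 90th). A Gamma distribution
#' is fitted to the variabilities by maximum likelihood, with a theoretical
#' vs observed percentile (QQ) table and the fraction of isoforms beyond the
#' fitted upper tail.
#'
#' @param fits list of `iso_fit` objects.
#' @param measure "variance" (1/tau0, default) or "precision".
#' @param tail_prob upper-tail probability of the fitted Gamma used for the
#'   exceedance fraction (default 0.95 quantile).
#' @return list with `table` (per-isoform class), `thresholds`, `gamma_fit`,
#'   `qq` and `tail_exceedance`.
#' @export
variability_classify <- function(fits, measure = c("variance", "precision"),
                                 tail_prob = 0.95) {
  measure <- match.arg(measure)
  if (inherits(fits, "iso_fit")) fits <- list(fits)
  tab <- do.call(rbind, lapply(fits, function(fit) {
    t0 <- pool_draws(fit, "tau0")
    v <- if (measure == "variance") colMeans(1 / t0) else colMeans(t0)
    data.frame(gene_id = fit$gene_id, isoform_id = fit$isoforms,
               variability = unname(v), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  if (nrow(tab) < 10L) stop("need >= 10 isoforms for percentile classes")
  thr <- nearest_rank_quantile(tab$variability, c(35, 65, 90))
  cls <- rep("mid", nrow(tab))
  cls[tab$variability < thr[1L]] <- "low"
  cls[tab$variability > thr[2L]] <- "moderate"
  cls[tab$variability > thr[3L]] <- "high"
  tab$class <- cls
  gf <- NULL; qq <- NULL; exceed <- NA_real_
  if (thr[1L] == thr[3L] || sd(tab$variability) < 1e-12) {
    warning("degenerate variability distribution; Gamma fit skipped")
  } else {
    gf <- gamma_mle(tab$variability)
    pr <- (1:99) / 100
    qq <- data.frame(prob = pr,
                     theoretical = qgamma(pr, shape = gf$shape, rate = gf$rate),
                     observed = as.numeric(quantile(tab$variability, pr)))
    exceed <- mean(tab$variability >
                     qgamma(tail_prob, shape = gf$shape, rate = gf$rate))
  }
  list(table = tab,
       thresholds = stats::setNames(thr, c("p35", "p65", "p90")),
       gamma_fit = gf, qq = qq, tail_exceedance = exceed)
}

#' Pairwise overlap of condition-specific high/low lists
#'
#' Upper triangle: number of isoforms commonly called high in both
#' conditions; lower triangle: commonly low; diagonal NA. A `total` row and
#' column carry the per-condition list sizes (high along the column margin,
#' low along the row margin).
#'
#' @param labels output of [call_high_low()].
#' @return square matrix with totals margins.
#' @export
pairwise_overlap_table <- function(labels) {
  conds <- unique(labels$sample_id)
  if (length(conds) < 2L) stop("need >= 2 conditions")
  key <- function(d) paste(d$gene_id, d$isoform_id)
  hi <- lapply(conds, function(cc) key(labels[labels$sample_id == cc & labels$label == "high", ]))
  lo <- lapply(conds, function(cc) key(labels[labels$sample_id == cc & labels$label == "low", ]))
  names(hi) <- names(lo) <- conds
  n <- length(conds)
  M <- matrix(NA_real_, n + 1L, n + 1L,
              dimnames = list(c(conds, "total"), c(conds, "total")))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) M[i, j] <- length(intersect(hi[[i]], hi[[j]]))
    if (i > j) M[i, j] <- length(intersect(lo[[i]], lo[[j]]))
  }
  M[seq_len(n), n + 1L] <- vapply(hi, length, 0L)
  M[n + 1L, seq_len(n)] <- vapply(lo, length, 0L)
  M
}

#' Gene-level expression summary
#'
#' Posterior of the per-sample gene expression, the isoform sum
#' \eqn{\sum_k \beta^*_{kl}}, computed draw-wise so isoform dependence is
#' respected.
#'
#' @param fit an `iso_fit`.
#' @return data.frame, one row per sample.
#' @export
gene_level_summary <- function(fit) {
  stopifnot(inherits(fit, "iso_fit"))
  bs <- bstar_draws(fit)
  out <- do.call(rbind, lapply(seq_along(fit$samples), function(l) {
    g <- rowSums(bs[, (l - 1L) * fit$s + seq_len(fit$s), drop = FALSE])
    data.frame(gene_id = fit$gene_id, sample_id = fit$samples[l],
               mean = mean(g), sd = sd(g),
               q2.5 = unname(quantile(g, 0.025)),
               q97.5 = unname(quantile(g, 0.975)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
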