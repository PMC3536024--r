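#' Simulation configuration
#'
#' The stated world of the generator: a multi-condition bulk mRNA-seq
#' experiment on a compact plant-like genome, with mostly single-isoform
#' genes (84%, the rest carrying 2-4 skipped-exon isoforms), 1-10 exons per
#' gene with log-normal exon lengths clipped to 50-2000 b, six samples with
#' unequal library sizes of which one ("HS"-like) has a heavy upper tail
#' (its top 1% of segment rates multiplied by 100), Bernoulli(0.5) isoform
#' presence, truncated-normal expression with prior mean about five noise
#' SDs above zero, and Poisson read sampling with length-proportional rates.
#'
#' @param n_genes number of genes.
#' @param n_samples number of samples.
#' @param isoform_probs probability of 1, 2, 3, 4 isoforms per gene.
#' @param exon_range inclusive range of exon counts per gene (uniform).
#' @param exon_meanlog,exon_sdlog log-normal exon-length parameters (bases).
#' @param exon_min,exon_max clipping bounds for exon lengths.
#' @param p_true presence probability.
#' @param beta_mu prior mean of isoform expression (normalized units).
#' @param tau0_true precision of isoform expression across samples.
#' @param tau_true exon-noise precision (noise SD = 1/sqrt(tau_true)).
#' @param lib_sizes per-sample library sizes (reads); recycled/truncated.
#' @param heavy_sample index of the heavy-tailed sample (NA for none).
#' @param heavy_factor multiplier applied to that sample's top rates.
#' @param heavy_top fraction of segment rates inflated (default 1%).
#' @param read_rate_scale global factor converting expression x length x
#'   library size into a Poisson mean.
#' @param seed integer seed, recorded in every output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L, n_samples = 6L,
                       isoform_probs = c(0.84, 0.08, 0.05, 0.03),
                       exon_range = c(1L, 10L),
                       exon_meanlog = log(300), exon_sdlog = 0.6,
                       exon_min = 50L, exon_max = 2000L,
                       p_true = 0.5, beta_mu = 10, tau0_true = 0.25,
                       tau_true = 0.25,
                       lib_sizes = c(12e4, 9e4, 15e4, 11e4, 13e4, 10e4),
                       heavy_sample = 4L, heavy_factor = 100,
                       heavy_top = 0.01,
                       read_rate_scale = 2e-6, seed = 1L) {
  stopifnot(n_genes >= 1L, n_samples >= 1L,
            abs(sum(isoform_probs) - 1) < 1e-8, all(isoform_probs >= 0),
            p_true >= 0, p_true <= 1, tau0_true > 0, tau_true > 0,
            heavy_top > 0, heavy_top <= 1)
  lib_sizes <- rep_len(lib_sizes, n_samples)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 isoform_probs = isoform_probs,
                 exon_range = as.integer(exon_range),
                 exon_meanlog = exon_meanlog, exon_sdlog = exon_sdlog,
                 exon_min = exon_min, exon_max = exon_max,
                 p_true = p_true, beta_mu = beta_mu,
                 tau0_true = tau0_true, tau_true = tau_true,
                 lib_sizes = lib_sizes,
                 heavy_sample = heavy_sample, heavy_factor = heavy_factor,
                 heavy_top = heavy_top,
                 read_rate_scale = read_rate_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rtnorm0_r <- function(n, mu, sd) {
  plo <- pnorm(0, mu, sd)
  qnorm(runif(n, plo, 1), mu, sd)
}

#' Simulate a gene annotation
#'
#' Random gene models on one synthetic chromosome. Every gene's first
#' isoform carries all of its exons; each additional isoform skips one
#' distinct exon (cassette-exon events), so isoform exon sets are unique and
#' the resulting design matrices have no duplicate columns (identifiable by
#' construction). Multi-isoform status requires at least two exons, and the
#' isoform count is capped at one plus the exon count.
#'
#' @param config a [sim_config()].
#' @return list with `models` (gene_model list) and `partitions`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pos <- 1000L
  models <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%04d", g)
    n_ex <- sample(seq(config$exon_range[1L], config$exon_range[2L]), 1L)
    lens <- pmin(pmax(round(rlnorm(n_ex, config$exon_meanlog,
                                   config$exon_sdlog)),
                      config$exon_min), config$exon_max)
    gaps <- round(rlnorm(n_ex, log(200), 0.4))
    starts <- pos + cumsum(gaps) + c(0, cumsum(lens[-n_ex]))
    ends <- starts + lens - 1L
    pos <- ends[n_ex] + 2000L
    exons <- data.frame(start = as.integer(starts), end = as.integer(ends))
    n_iso <- sample(seq_along(config$isoform_probs), 1L,
                    prob = config$isoform_probs)
    if (n_ex == 1L) n_iso <- 1L
    n_iso <- min(n_iso, n_ex + 1L)
    isoforms <- list(exons)
    if (n_iso > 1L) {
      skipped <- sample(n_ex, n_iso - 1L)
      for (k in 2:n_iso)
        isoforms[[k]] <- exons[-skipped[k - 1L], , drop = FALSE]
    }
    names(isoforms) <- sprintf("%s.%d", gid, seq_along(isoforms))
    models[[g]] <- gene_model(gid, "chrS1", sample(c("+", "-"), 1L), isoforms)
  }
  names(models) <- vapply(models, `[[`, "", "gene_id")
  list(models = models, partitions = partition_genes(models))
}

#' Simulate isoform expression truth and segment-level expression
#'
#' The generative direction of the hierarchical model itself: presence
#' I ~ Bernoulli(p_true), isoform expression beta ~ Normal(beta_mu,
#' 1/tau0_true) truncated at zero, observed segment expression
#' y ~ Normal(X beta*, 1/tau_true) truncated at zero, elementwise.
#'
#' @param partitions partitions from [simulate_annotation()].
#' @param config a [sim_config()].
#' @return list with `truth` (data.frames `isoform` and `gene_sample`) and
#'   `y` (list of per-gene expression matrices).
#' @export
simulate_expression <- function(partitions, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  sample_ids <- sprintf("S%d", seq_len(config$n_samples))
  iso_rows <- list(); y <- list()
  for (p in partitions) {
    s <- ncol(p$design); m <- nrow(p$design)
    I <- matrix(rbinom(s * config$n_samples, 1L, config$p_true),
                nrow = s)
    B <- matrix(rtnorm0_r(s * config$n_samples, config$beta_mu,
                          1 / sqrt(config$tau0_true)), nrow = s)
    mu <- p$design %*% (I * B)
    ym <- matrix(rtnorm0_r(m * config$n_samples, as.vector(mu),
                           1 / sqrt(config$tau_true)), nrow = m)
    colnames(ym) <- sample_ids
    y[[p$gene_id]] <- ym
    iso_rows[[p$gene_id]] <- data.frame(
      gene_id = p$gene_id,
      isoform_id = rep(colnames(p$design), config$n_samples),
      sample_id = rep(sample_ids, each = s),
      I_true = as.vector(I), beta_true = as.vector(B),
      stringsAsFactors = FALSE)
  }
  truth_iso <- do.call(rbind, iso_rows)
  rownames(truth_iso) <- NULL
  list(truth = list(isoform = truth_iso,
                    tau_true = config$tau_true,
                    tau0_true = config$tau0_true),
       y = y, sample_ids = sample_ids)
}

#' Simulate read counts from the expression truth
#'
#' Poisson counts with per-segment rate proportional to the beta*-weighted
#' isoform membership, the segment length (the documented length bias: a
#' segment twice as long draws twice the reads at equal expression) and the
#' sample's library size. In the heavy-tailed sample, the top `heavy_top`
#' fraction of rates is multiplied by `heavy_factor`.
#'
#' @param partitions partitions from [simulate_annotation()].
#' @param expr output of [simulate_expression()].
#' @param config a [sim_config()].
#' @return a [count_matrix()].
#' @export
simulate_counts <- function(partitions, expr, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  iso <- expr$truth$isoform
  rates <- list(); rows <- list()
  for (p in partitions) {
    sub <- iso[iso$gene_id == p$gene_id, ]
    bstar <- matrix(sub$I_true * sub$beta_true, nrow = ncol(p$design))
    mu <- p$design %*% bstar # m x L expression per segment
    r <- mu * p$segments$length
    rates[[p$gene_id]] <- r
    rows[[p$gene_id]] <- data.frame(gene_id = p$gene_id,
                                    segment_index = seq_len(nrow(r)),
                                    length = p$segments$length,
                                    stringsAsFactors = FALSE)
  }
  R <- do.call(rbind, rates)
  R <- sweep(R, 2L, config$lib_sizes * config$read_rate_scale, "*")
  if (!is.na(config$heavy_sample) && config$heavy_sample <= ncol(R)) {
    j <- config$heavy_sample
    pos <- which(R[, j] > 0)
    if (length(pos)) {
      k <- max(1L, ceiling(length(pos) * config$heavy_top))
      top <- pos[order(R[pos, j], decreasing = TRUE)[seq_len(k)]]
      R[top, j] <- R[top, j] * config$heavy_factor
    }
  }
  cnt <- matrix(rpois(length(R), as.vector(R)), nrow = nrow(R))
  colnames(cnt) <- expr$sample_ids
  meta <- do.call(rbind, rows)
  count_matrix(cnt, meta$gene_id, meta$segment_index, meta$length)
}

#' Monte-Carlo demonstration of the length-bias t inflation
#'
#' Simulates `n_genes` two-condition genes with rates (lambda1, lambda2),
#' draws Poisson counts at length scale 1 and at scale L, computes the
#' count t statistic \eqn{(n_1 - n_2)/\sqrt{n_1 + n_2}} for each, and
#' returns the per-scale statistics; the median |t| ratio approximates
#' sqrt(L).
#'
#' @param n_genes number of simulated genes.
#' @param L length fold-change.
#' @param lambda_range base rate range for condition 2 (uniform); condition
#'   1 doubles it.
#' @param seed RNG seed.
#' @return data.frame with columns t1 (scale 1), tL (scale L).
#' @export
simulate_length_bias <- function(n_genes = 500L, L = 4,
                                 lambda_range = c(10, 50), seed = 1L) {
  set.seed(seed)
  lam2 <- runif(n_genes, lambda_range[1L], lambda_range[2L])
  lam1 <- 2 * lam2
  tstat <- function(a, b) ifelse(a + b == 0, NA_real_, (a - b) / sqrt(a + b))
  n1 <- rpois(n_genes, lam1); n2 <- rpois(n_genes, lam2)
  N1 <- rpois(n_genes, lam1 * L); N2 <- rpois(n_genes, lam2 * L)
  data.frame(t1 = tstat(n1, n2), tL = tstat(N1, N2))
}

#' Write a synthetic GFF3 annotation
#'
#' Deterministic plain-text writer (gene / mRNA / exon features with
#' ID/Parent attributes) for the simulated models; read back with
#' [read_gene_models()].
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (g in models) {
    gstart <- min(vapply(g$isoforms, function(e) min(e$start), 0))
    gend <- max(vapply(g$isoforms, function(e) max(e$end), 0))
    strand <- if (g$strand == "*") "." else g$strand
    lines <- c(lines, sprintf("%s\tisodecon\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom, gstart, gend, strand, g$gene_id))
    for (tx in names(g$isoforms)) {
      ex <- g$isoforms[[tx]]
      lines <- c(lines,
                 sprintf("%s\tisodecon\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$chrom, min(ex$start), max(ex$end), strand, tx,
                         g$gene_id),
                 sprintf("%s\tisodecon\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         g$chrom, ex$start, ex$end, strand, tx,
                         seq_len(nrow(ex)), tx))
    }
  }
  write_lines_atomic(lines, path)
  invisible(path)
}

#' Write a complete synthetic fixture bundle
#'
#' GFF3 annotation, counts TSV, truth TSVs, config JSON and a manifest with
#' md5 checksums — the formats every other stage of the pipeline reads.
#'
#' @param outdir output directory (created if needed).
#' @param config a [sim_config()].
#' @return named vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(outdir, config = sim_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(config)
  expr <- simulate_expression(ann$partitions, config)
  counts <- simulate_counts(ann$partitions, expr, config)
  paths <- c(annotation = file.path(outdir, "annotation.gff3"),
             counts = file.path(outdir, "counts.tsv"),
             truth_isoform = file.path(outdir, "truth_isoform.tsv"),
             config = file.path(outdir, "config.json"),
             manifest = file.path(outdir, "manifest.tsv"))
  write_gff3(ann$models, paths[["annotation"]])
  write_counts_table(counts, paths[["counts"]],
                     meta = list(seed = config$seed, source = "simulate_counts"))
  write_tsv_atomic(expr$truth$isoform, paths[["truth_isoform"]],
                   meta = list(seed = config$seed,
                               tau_true = config$tau_true,
                               tau0_true = config$tau0_true))
  write_lines_atomic(
    jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                     pretty = TRUE),
    paths[["config"]])
  files <- setdiff(names(paths), "manifest")
  md5 <- tools::md5sum(unname(paths[files]))
  write_tsv_atomic(data.frame(file = basename(names(md5)), md5 = unname(md5),
                              stringsAsFactors = FALSE),
                   paths[["manifest"]])
  invisible(paths)
}
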