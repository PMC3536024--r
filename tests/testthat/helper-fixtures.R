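# Shared fixture builders: tiny gene models, annotation files and fake fits.

fx_gene <- function(id = "g1", isoforms) {
  gene_model(id, "chr1", "+", isoforms)
}

# two-isoform gene used across MCMC tests: X = [[1,0],[1,1]]
fx_two_iso <- function() {
  fx_gene("gx", list(k1 = data.frame(start = c(1, 201), end = c(100, 300)),
                     k2 = data.frame(start = 201, end = 300)))
}

# single-isoform gene with three gapped exons (segments stay separate)
fx_single_iso3 <- function(id = "gs") {
  fx_gene(id, list(k = data.frame(start = c(1, 201, 401),
                                  end = c(100, 300, 500))))
}

fx_gff3_lines <- function() {
  c("##gff-version 3",
    "chr1\ttest\tgene\t1\t300\t.\t+\t.\tID=gene1",
    "chr1\ttest\tmRNA\t1\t300\t.\t+\t.\tID=tx1;Parent=gene1",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tID=tx1.e1;Parent=tx1",
    "chr1\ttest\texon\t201\t300\t.\t+\t.\tID=tx1.e2;Parent=tx1",
    "chr1\ttest\tmRNA\t1\t300\t.\t+\t.\tID=tx2;Parent=gene1",
    "chr1\ttest\texon\t1\t150\t.\t+\t.\tID=tx2.e1;Parent=tx2",
    "chr1\ttest\texon\t201\t300\t.\t+\t.\tID=tx2.e2;Parent=tx2")
}

fx_gtf_lines <- function() {
  a <- function(tx) sprintf("gene_id \"gene1\"; transcript_id \"%s\";", tx)
  c(sprintf("chr1\ttest\texon\t1\t100\t.\t+\t.\t%s", a("tx1")),
    sprintf("chr1\ttest\texon\t201\t300\t.\t+\t.\t%s", a("tx1")),
    sprintf("chr1\ttest\texon\t1\t150\t.\t+\t.\t%s", a("tx2")),
    sprintf("chr1\ttest\texon\t201\t300\t.\t+\t.\t%s", a("tx2")))
}

# brute-force per-base membership partition oracle (gap-aware)
fx_partition_oracle <- function(gene) {
  maxpos <- max(vapply(gene$isoforms, function(e) max(e$end), 0))
  memb <- matrix(0L, maxpos, length(gene$isoforms),
                 dimnames = list(NULL, names(gene$isoforms)))
  for (k in seq_along(gene$isoforms)) {
    ex <- gene$isoforms[[k]]
    for (i in seq_len(nrow(ex))) memb[ex$start[i]:ex$end[i], k] <- 1L
  }
  covered <- rowSums(memb) > 0
  key <- apply(memb, 1L, paste, collapse = "")
  key[!covered] <- NA
  segs <- list(); X <- list()
  run_start <- NA
  for (pos in seq_len(maxpos + 1L)) {
    k <- if (pos <= maxpos) key[pos] else NA
    prev <- if (pos > 1L) key[pos - 1L] else NA
    new_run <- !identical(k, prev)
    if (!is.na(prev) && new_run) {
      segs[[length(segs) + 1L]] <- c(run_start, pos - 1L)
      X[[length(X) + 1L]] <- memb[pos - 1L, ]
    }
    if (!is.na(k) && new_run) run_start <- pos
  }
  list(segments = do.call(rbind, segs),
       design = do.call(rbind, X))
}

# random small gene model for the partition property test
fx_random_gene <- function(id, n_iso = sample(1:5, 1)) {
  isoforms <- list()
  for (k in seq_len(n_iso)) {
    n_ex <- sample(1:4, 1)
    bounds <- sort(sample(seq(1, 999, by = 2), 2 * n_ex))
    isoforms[[sprintf("i%d", k)]] <-
      data.frame(start = bounds[seq(1, 2 * n_ex, by = 2)],
                 end = bounds[seq(2, 2 * n_ex, by = 2)])
  }
  gene_model(id, "chr1", "+", isoforms)
}

# minimal fake iso_fit carrying prescribed draw matrices (for decision-rule
# oracles that do not need a real MCMC run)
fx_fake_fit <- function(gene_id, isoforms, samples, m, beta, I, tau, tau0,
                        chains = 1L) {
  ch <- list(beta = beta, I = I, tau = tau, tau0 = tau0)
  structure(list(gene_id = gene_id, chains = rep(list(ch), chains),
                 design = NULL, lengths = rep(100, m), samples = samples,
                 isoforms = isoforms, m = m, s = length(isoforms),
                 hyper = NULL, settings = NULL, mu0 = NULL,
                 notes = character()),
            class = "iso_fit")
}

# wrap a plain matrix as a globally-normalized expression matrix
new_em_for_test <- function(m) {
  isodecon:::new_expr_matrix(
    m, data.frame(gene_id = sprintf("g%d", seq_len(nrow(m))),
                  segment_index = rep(1L, nrow(m)),
                  length = rep(100, nrow(m)), stringsAsFactors = FALSE),
    method = "global", factors = stats::setNames(rep(1, ncol(m)), colnames(m)))
}
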