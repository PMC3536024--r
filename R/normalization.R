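#' Count matrix container
#'
#' Per-pseudo-exon read counts across samples, with the row metadata the
#' normalizers need (gene, segment index, segment length in bases).
#'
#' @param counts non-negative numeric matrix, one row per segment, one column
#'   per sample (unique column names required).
#' @param gene_id,segment_index,length row metadata vectors.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_id, segment_index, length) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("sample (column) names must be present and unique")
  if (any(counts < 0)) stop("negative counts")
  if (any(length <= 0)) stop("non-positive segment length")
  stopifnot(nrow(counts) == length(gene_id),
            nrow(counts) == length(segment_index),
            nrow(counts) == base::length(length))
  structure(list(counts = counts,
                 rows = data.frame(gene_id = as.character(gene_id),
                                   segment_index = as.integer(segment_index),
                                   length = as.numeric(length),
                                   stringsAsFactors = FALSE)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "segments x", ncol(x$counts),
      "samples,", length(unique(x$rows$gene_id)), "genes\n")
  invisible(x)
}

new_expr_matrix <- function(values, rows, method, factors, extra = list()) {
  structure(c(list(values = values, rows = rows, method = method,
                   factors = factors), extra),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix (", x$method, "): ", nrow(x$values), " segments x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

sample_totals <- function(m) colSums(m)

#' RPKM normalization
#'
#' Reads per kilobase of segment per million mapped reads:
#' \eqn{RPKM_{il} = n_{il} / (\ell_i N_l) \times 10^9}, with \eqn{\ell_i} the
#' segment length in bases and \eqn{N_l} the sample's total mapped reads.
#'
#' @param counts a [count_matrix()].
#' @return an `expr_matrix` with provenance "rpkm".
#' @export
rpkm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  N <- sample_totals(counts$counts)
  if (any(N <= 0))
    stop("sample(s) with zero total mapped reads: ",
         paste(colnames(counts$counts)[N <= 0], collapse = ", "))
  v <- sweep(counts$counts, 1L, counts$rows$length, "/")
  v <- sweep(v, 2L, N, "/") * 1e9
  new_expr_matrix(v, counts$rows, "rpkm", stats::setNames(1e9 / (N), names(N)))
}

#' Global (total-count) normalization
#'
#' Scales every sample so its column total equals a common reference total:
#' sample l is multiplied by reference_total / N_l. The reference is the
#' across-sample mean total by default, or a named sample.
#'
#' @param counts a [count_matrix()] or `expr_matrix`.
#' @param reference "mean-total" or the name of a reference sample.
#' @return an `expr_matrix` with provenance "global".
#' @export
global_normalize <- function(counts, reference = "mean-total") {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts$values
  rows <- counts$rows
  N <- sample_totals(m)
  if (any(N <= 0))
    stop("sample(s) with zero total: ",
         paste(colnames(m)[N <= 0], collapse = ", "))
  ref <- if (identical(reference, "mean-total")) mean(N) else {
    if (!reference %in% colnames(m))
      stop("reference sample not found: ", reference)
    N[[reference]]
  }
  f <- ref / N
  new_expr_matrix(sweep(m, 2L, f, "*"), rows, "global", f,
                  extra = list(reference = reference))
}

#' Percentile (10th-90th) normalization
#'
#' Equalizes the central body of the per-sample expression distributions
#' while leaving extreme tails untouched. Per sample the scale summary is the
#' trimmed mean of the values strictly between that sample's lo-th and hi-th
#' nearest-rank percentiles (zeros included when computing the percentiles);
#' each sample is divided by (its trimmed mean / the across-sample mean of
#' trimmed means). Column totals are deliberately NOT re-equalized: a sample
#' whose extreme top tail is genuinely inflated keeps that tail.
#'
#' @param values an `expr_matrix`, normally with provenance "global"; any
#'   other provenance triggers a warning, not an error.
#' @param lo_pct,hi_pct trimming percentiles (defaults 10 and 90).
#' @return an `expr_matrix` with provenance "percentile".
#' @export
percentile_normalize <- function(values, lo_pct = 10, hi_pct = 90) {
  stopifnot(inherits(values, "expr_matrix"))
  if (lo_pct >= hi_pct) stop("lo_pct must be < hi_pct")
  if (!values$method %in% c("global", "percentile"))
    warning("percentile_normalize expects globally normalized input; got '",
            values$method, "'")
  m <- values$values
  tm <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    if (all(x == 0)) stop("all-zero sample: ", colnames(m)[j])
    q <- nearest_rank_quantile(x, c(lo_pct, hi_pct))
    body <- x[x > q[1] & x < q[2]]
    if (length(body) == 0L) body <- x[x >= q[1] & x <= q[2]]
    mean(body)
  }, 0)
  ref <- mean(tm)
  f <- ref / tm
  names(f) <- colnames(m)
  new_expr_matrix(sweep(m, 2L, f, "*"), values$rows, "percentile", f,
                  extra = list(lo_pct = lo_pct, hi_pct = hi_pct))
}

#' Per-sample decile profile
#'
#' Nearest-rank deciles (10th..90th, optionally the 100th) per sample plus
#' the mean expression within each decile bin — the diagnostic used to judge
#' whether a normalization leaves the central bodies of all samples
#' comparable. The top decile is reported but flagged: it is dominated by a
#' handful of very highly expressed segments.
#'
#' @param values numeric matrix or `expr_matrix`.
#' @param include_top include the 100th percentile row.
#' @return data.frame with columns sample, decile, value, bin_mean, top_flag.
#' @export
percentile_profile <- function(values, include_top = FALSE) {
  m <- if (inherits(values, "expr_matrix")) values$values else as.matrix(values)
  if (ncol(m) < 1L) stop("need at least one sample")
  dec <- seq(10, if (include_top) 100 else 90, by = 10)
  out <- do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    qs <- nearest_rank_quantile(x, dec)
    lo <- c(-Inf, qs[-length(qs)])
    bm <- vapply(seq_along(qs), function(d)
      mean(x[x > lo[d] & x <= qs[d]]), 0)
    data.frame(sample = colnames(m)[j], decile = dec, value = qs,
               bin_mean = bm, top_flag = dec == 100,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-sample decile discrepancy
#'
#' Summarizes how far the per-sample decile profiles diverge: for every
#' decile that is positive in every sample (the common distribution body —
#' zero-saturated deciles carry no calibration information and would
#' saturate a relative-range metric), the relative range
#' (max - min) / mean across samples; the maximum over those deciles is
#' returned. Smaller is better (samples' central bodies agree).
#'
#' @param values matrix or `expr_matrix`.
#' @param deciles which deciles to include (default mid-body 10..80).
#' @return a single number (0 when no decile qualifies).
#' @export
decile_discrepancy <- function(values, deciles = seq(10, 80, by = 10)) {
  prof <- percentile_profile(values)
  prof <- prof[prof$decile %in% deciles, ]
  per <- vapply(split(prof, prof$decile), function(d) {
    if (min(d$value) <= 0) return(NA_real_)
    (max(d$value) - min(d$value)) / mean(d$value)
  }, 0)
  if (all(is.na(per))) return(0)
  max(per, na.rm = TRUE)
}
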