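#' Nearest-rank percentile
#'
#' The percentile estimator used throughout the package (segment length
#' classes, percentile normalization, high/low and variability thresholds):
#' the p-th percentile of `x` is the value at sorted rank `ceiling(p/100 * n)`.
#' Reproducible and estimator-free, at the cost of being a step function.
#'
#' @param x numeric vector (NAs removed).
#' @param p percentile(s) in (0, 100].
#' @return numeric vector of the same length as `p`.
#' @export
#' @examples
#' nearest_rank_quantile(1:100, c(5, 95))
nearest_rank_quantile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) stop("nearest_rank_quantile: empty input")
  stopifnot(all(p > 0), all(p <= 100))
  x[pmax(1L, ceiling(p / 100 * n))]
}

#' Signal-to-noise ratio of read densities
#'
#' Ratio of per-base read density in transcribed (exonic) regions to the
#' density in non-transcribed background. Typical mRNA-seq orders of
#' magnitude (about 1e-1 exonic vs 1e-4 background) give a ratio near 1e3,
#' the figure of merit that motivates count-based expression inference.
#'
#' @param signal_density reads per base in transcribed regions.
#' @param background_density reads per base in non-transcribed regions.
#' @return the density ratio (dimensionless).
#' @export
density_snr <- function(signal_density = 1e-1, background_density = 1e-4) {
  stopifnot(signal_density > 0, background_density > 0)
  signal_density / background_density
}

#' Maximum-likelihood fit of a Gamma distribution
#'
#' Newton iteration on the shape profile equation
#' \eqn{\log a - \psi(a) = \log \bar x - \overline{\log x}}.
#'
#' @param x positive observations.
#' @return list with `shape`, `rate`, `loglik`.
#' @export
gamma_mle <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L || any(x <= 0)) stop("gamma_mle needs >= 2 positive values")
  s <- log(mean(x)) - mean(log(x))
  if (s < .Machine$double.eps) stop("gamma_mle: degenerate (constant) sample")
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s) # Minka's starting value
  for (i in 1:50) {
    step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-10 * a) { a <- a_new; break }
    a <- a_new
  }
  rate <- a / mean(x)
  list(shape = a, rate = rate,
       loglik = sum(stats::dgamma(x, shape = a, rate = rate, log = TRUE)))
}

# deterministic 31-adic string hash into [0, 2^31 - 2]; used to derive
# per-gene RNG streams that do not depend on gene processing order
string_seed <- function(id, base_seed = 0L) {
  h <- 0
  for (v in utf8ToInt(as.character(id))) h <- (h * 31 + v) %% 2147483647
  as.integer((h + as.numeric(base_seed)) %% 2147483647)
}

# atomic text write: temp file in the destination directory, then rename
write_lines_atomic <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

# fixed 6-significant-digit formatting for numeric table columns
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.numeric(v) && v == round(v) && abs(v) < 1e15) return(format(v, scientific = FALSE))
    sprintf("%.6g", v)
  }, character(1))
  out
}

# serialize a data.frame as TSV lines with optional '# key: value' header
df_to_tsv_lines <- function(df, meta = NULL) {
  cols <- lapply(df, function(col) if (is.numeric(col)) fmt_num(col) else as.character(col))
  body <- do.call(paste, c(cols, sep = "\t"))
  hdr <- paste(names(df), collapse = "\t")
  c(if (length(meta)) paste0("# ", names(meta), ": ", unlist(meta)), hdr, body)
}

write_tsv_atomic <- function(df, path, meta = NULL) {
  write_lines_atomic(df_to_tsv_lines(df, meta), path)
}

read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
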