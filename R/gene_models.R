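#' Construct a gene model
#'
#' A gene model is the unit the isoform sampler works on: a gene with its set
#' of known transcript isoforms, each a sorted list of non-overlapping exon
#' intervals (1-based, closed, genomic coordinates).
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome / sequence name.
#' @param strand "+", "-" or "*" (unknown). Recorded but ignored by the
#'   partitioning, which is strand-agnostic.
#' @param isoforms named list; each element a two-column matrix or data.frame
#'   of exon `start`, `end` coordinates.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand = "*", isoforms) {
  if (length(isoforms) < 1L) stop("gene ", gene_id, " has no isoforms")
  ids <- names(isoforms)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("isoforms must carry unique non-empty names (gene ", gene_id, ")")
  isoforms <- lapply(isoforms, function(ex) {
    ex <- as.data.frame(ex)[, 1:2]
    names(ex) <- c("start", "end")
    if (nrow(ex) == 0L) stop("isoform with zero exons in gene ", gene_id)
    if (any(ex$end < ex$start))
      stop("exon with end < start in gene ", gene_id)
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping exons within one isoform of gene ", gene_id)
    rownames(ex) <- NULL
    ex
  })
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 isoforms = isoforms),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, "(", x$chrom, x$strand, "):",
      length(x$isoforms), "isoform(s),",
      sum(vapply(x$isoforms, nrow, 0L)), "exon records\n")
  invisible(x)
}

#' Read gene models from a GFF3 or GTF annotation
#'
#' Parses the annotation with `rtracklayer::import()` and assembles one
#' [gene_model()] per gene from its exon features. For GFF3 the
#' exon -> mRNA (`Parent`) -> gene (`Parent`) chain is followed; for GTF the
#' `gene_id` / `transcript_id` attributes are used directly. Transcripts
#' without exon records are dropped with a warning.
#'
#' @param path annotation file.
#' @param format "auto" (by extension), "gff3" or "gtf".
#' @return named list of `gene_model` objects, ordered by gene id.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3"),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  is_exon <- type == "exon"
  if (!any(is_exon)) stop("no exon features found in ", path)

  if (format == "gtf") {
    tx_of_exon <- as.character(md$transcript_id[is_exon])
    gene_of_exon <- as.character(md$gene_id[is_exon])
  } else {
    parent <- md$Parent
    tx_of_exon <- vapply(as.list(parent[is_exon]), function(p) {
      if (length(p) < 1L) NA_character_ else as.character(p[[1L]])
    }, character(1))
    # map transcript feature ID -> its gene Parent
    is_tx <- type %in% c("mRNA", "transcript")
    tx_ids <- as.character(md$ID[is_tx])
    tx_parent <- vapply(as.list(parent[is_tx]), function(p) {
      if (length(p) < 1L) NA_character_ else as.character(p[[1L]])
    }, character(1))
    gene_of_tx <- stats::setNames(tx_parent, tx_ids)
    gene_of_exon <- unname(gene_of_tx[tx_of_exon])
    gene_of_exon[is.na(gene_of_exon)] <- tx_of_exon[is.na(gene_of_exon)]
  }
  if (anyNA(tx_of_exon))
    stop("exon feature without transcript identifier in ", path)

  exdf <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon],
    end = GenomicRanges::end(gr)[is_exon],
    strand = as.character(GenomicRanges::strand(gr))[is_exon],
    tx = tx_of_exon, gene = gene_of_exon,
    stringsAsFactors = FALSE)

  # GFF3 may declare transcripts that have no exon rows
  if (format == "gff3") {
    declared <- tx_ids
    missing_tx <- setdiff(declared, unique(exdf$tx))
    if (length(missing_tx))
      warning("dropping ", length(missing_tx),
              " transcript(s) with zero exon records: ",
              paste(utils::head(missing_tx, 5L), collapse = ", "))
  }

  out <- lapply(split(exdf, exdf$gene), function(g) {
    isoforms <- lapply(split(g[, c("start", "end")], g$tx), identity)
    gene_model(g$gene[1L], g$chrom[1L],
               if (g$strand[1L] %in% c("+", "-")) g$strand[1L] else "*",
               isoforms)
  })
  out[order(names(out))]
}

#' Partition a gene into pseudo-exons
#'
#' Cuts the union of all exon intervals of all isoforms at every exon
#' boundary of every isoform, yielding atomic segments each wholly inside or
#' wholly outside every isoform, then merges abutting segments with identical
#' isoform membership (minimal partition). Emits the binary design matrix
#' `X[i, k] = 1` iff segment i belongs to isoform k, segments in ascending
#' genomic order.
#'
#' @param gene a [gene_model()].
#' @return object of class `pseudo_exon_partition`: list with `gene_id`,
#'   `chrom`, `segments` (data.frame start/end/length), `design` (m x s binary
#'   matrix, columns named by isoform), `identifiable` (FALSE when two
#'   isoforms have identical design columns).
#' @export
build_pseudo_exons <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  iso_ir <- lapply(gene$isoforms, function(ex)
    IRanges::IRanges(start = ex$start, end = ex$end))
  all_ir <- do.call(c, unname(iso_ir))
  atoms <- IRanges::disjoin(all_ir)
  atoms <- atoms[order(IRanges::start(atoms))]
  s <- length(iso_ir)
  X <- vapply(iso_ir, function(ir)
    as.integer(IRanges::countOverlaps(atoms, ir, type = "within") > 0L),
    integer(length(atoms)))
  X <- matrix(X, nrow = length(atoms), ncol = s,
              dimnames = list(NULL, names(iso_ir)))

  # merge abutting atoms with identical membership
  key <- apply(X, 1L, paste, collapse = "")
  st <- IRanges::start(atoms); en <- IRanges::end(atoms)
  grp <- cumsum(c(TRUE, !(key[-1] == key[-length(key)] &
                            st[-1] == en[-length(en)] + 1L)))
  seg_start <- tapply(st, grp, min)
  seg_end <- tapply(en, grp, max)
  Xm <- X[!duplicated(grp), , drop = FALSE]

  segments <- data.frame(start = as.integer(seg_start),
                         end = as.integer(seg_end))
  segments$length <- segments$end - segments$start + 1L
  rownames(segments) <- NULL
  ident <- !anyDuplicated(t(Xm)) && all(rowSums(Xm) >= 1L)
  structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                 segments = segments, design = Xm,
                 identifiable = ident),
            class = "pseudo_exon_partition")
}

#' @export
print.pseudo_exon_partition <- function(x, ...) {
  cat("pseudo_exon_partition", x$gene_id, ":", nrow(x$segments),
      "segment(s) x", ncol(x$design), "isoform(s)",
      if (!x$identifiable) "[unidentifiable design]" else "", "\n")
  invisible(x)
}

#' Partition many genes
#'
#' @param models list of [gene_model()] objects.
#' @return named list of partitions.
#' @export
partition_genes <- function(models) {
  out <- lapply(models, build_pseudo_exons)
  names(out) <- vapply(out, `[[`, "", "gene_id")
  out
}

#' Classify pseudo-exon segment lengths
#'
#' Labels every segment short / medium / long by the 5th and 95th
#' nearest-rank percentiles of the pooled segment-length distribution.
#' Degenerate distributions (5th percentile equal to the 95th) are labeled
#' medium throughout. Also reports, per isoform, the fraction of its
#' segments that are short or long.
#'
#' @param partitions list of [build_pseudo_exons()] results.
#' @return list with `table` (gene_id, segment_index, length, class),
#'   `thresholds` (5th/95th percentile) and `isoform_fractions`.
#' @export
classify_segment_lengths <- function(partitions) {
  if (length(partitions) == 0L) stop("no partitions supplied")
  tab <- do.call(rbind, lapply(partitions, function(p)
    data.frame(gene_id = p$gene_id,
               segment_index = seq_len(nrow(p$segments)),
               length = p$segments$length, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  thr <- nearest_rank_quantile(tab$length, c(5, 95))
  if (thr[1] == thr[2]) {
    tab$class <- "medium"
  } else {
    tab$class <- ifelse(tab$length <= thr[1], "short",
                        ifelse(tab$length >= thr[2], "long", "medium"))
  }
  fr <- do.call(rbind, lapply(partitions, function(p) {
    idx <- match(paste(p$gene_id, seq_len(nrow(p$segments))),
                 paste(tab$gene_id, tab$segment_index))
    cls <- tab$class[idx]
    do.call(rbind, lapply(colnames(p$design), function(k) {
      on <- p$design[, k] == 1L
      data.frame(gene_id = p$gene_id, isoform_id = k,
                 n_segments = sum(on),
                 frac_short = mean(cls[on] == "short"),
                 frac_long = mean(cls[on] == "long"),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(fr) <- NULL
  list(table = tab, thresholds = stats::setNames(thr, c("p5", "p95")),
       isoform_fractions = fr)
}

#' Write / read a pseudo-exon partition table
#'
#' TSV with columns gene_id, segment_index, chrom, start, end, length,
#' isoform_memberships (comma-separated isoform ids), plus a design-matrix
#' sidecar in MTX-like coordinate-triplet text (`<path>.design.mtx`).
#'
#' @param partitions list of partitions.
#' @param path output TSV path.
#' @param meta optional named list written as `# key: value` headers.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partitions, path, meta = NULL) {
  df <- do.call(rbind, lapply(partitions, function(p) {
    memb <- apply(p$design, 1L, function(r)
      paste(colnames(p$design)[r == 1L], collapse = ","))
    data.frame(gene_id = p$gene_id,
               segment_index = seq_len(nrow(p$segments)),
               chrom = p$chrom, start = p$segments$start,
               end = p$segments$end, length = p$segments$length,
               isoform_memberships = memb, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  write_tsv_atomic(df, path, meta)
  # coordinate-triplet sidecar: row (global segment), col (global isoform), 1
  iso_all <- unlist(lapply(partitions, function(p) paste0(p$gene_id, ":", colnames(p$design))))
  ent <- list(); ri <- 0L
  for (p in partitions) {
    for (i in seq_len(nrow(p$design))) {
      ri <- ri + 1L
      for (k in which(p$design[i, ] == 1L))
        ent[[length(ent) + 1L]] <- c(ri, match(paste0(p$gene_id, ":", colnames(p$design)[k]), iso_all))
    }
  }
  trip <- do.call(rbind, ent)
  write_lines_atomic(
    c("%%MatrixMarket matrix coordinate integer general",
      paste(ri, length(iso_all), nrow(trip)),
      paste(trip[, 1], trip[, 2], 1L)),
    paste0(path, ".design.mtx"))
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("gene_id", "segment_index", "chrom", "start", "end", "length",
            "isoform_memberships")
  if (!all(need %in% names(df)))
    stop("partition table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- lapply(split(df, df$gene_id), function(g) {
    g <- g[order(g$segment_index), , drop = FALSE]
    isos <- sort(unique(unlist(strsplit(g$isoform_memberships, ","))))
    X <- vapply(isos, function(k)
      as.integer(vapply(strsplit(g$isoform_memberships, ","),
                        function(v) k %in% v, TRUE)),
      integer(nrow(g)))
    X <- matrix(X, nrow = nrow(g), dimnames = list(NULL, isos))
    structure(list(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
                   segments = data.frame(start = g$start, end = g$end,
                                         length = g$length),
                   design = X,
                   identifiable = !anyDuplicated(t(X)) && all(rowSums(X) >= 1L)),
              class = "pseudo_exon_partition")
  })
  out[unique(df$gene_id)]
}
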