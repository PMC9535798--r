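#' Read ChIP peaks from an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand, then
#' signalValue, pValue (-log10), qValue (-log10), and the summit offset
#' (\code{peak}, bp from the interval start, -1 when absent). Coordinates on
#' disk are 0-based half-open and are converted to 1-based closed ranges.
#' "." score fields are tolerated (read as NA).
#'
#' @param path Path to a narrowPeak file; may be empty.
#' @param label Optional label (replicate/factor name) stored in the result's
#'   metadata.
#' @return A \code{GRanges} sorted by (chrom, start) with metadata columns
#'   \code{name}, \code{score}, \code{signalValue}, \code{pValue},
#'   \code{qValue} (-log10 of the MACS2 q-value), and \code{peak}.
#' @export
read_narrowpeak <- function(path, label = NULL) {
  if (!file.exists(path)) stop("narrowPeak file not found: ", path)
  if (file.size(path) == 0 || length(readLines(path, n = 1)) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = character(0), score = numeric(0), signalValue = numeric(0),
      pValue = numeric(0), qValue = numeric(0), peak = integer(0))
  } else {
    first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
    if (length(first) != 10)
      stop(sprintf("narrowPeak line 1: expected 10 columns, found %d",
                   length(first)))
    gr <- rtracklayer::import(path, format = "BED",
                              extraCols = c(signalValue = "numeric",
                                            pValue = "numeric",
                                            qValue = "numeric",
                                            peak = "integer"))
    GenomicRanges::strand(gr) <- "*"  # peaks are strandless
    if (any(gr$qValue < 0, na.rm = TRUE))
      stop("negative -log10(q) in narrowPeak file")
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  }
  if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
  gr
}

#' Write peaks to a narrowPeak file
#'
#' Inverse of \code{\link{read_narrowpeak}}: emits BED6+4 with 0-based
#' half-open coordinates, bit-exact column order.
#'
#' @param peaks A peak \code{GRanges} as returned by
#'   \code{\link{read_narrowpeak}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  sc <- peaks$score
  sc <- ifelse(is.na(sc), ".", format(sc, trim = TRUE, scientific = FALSE))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.\t%s\t%s\t%s\t%d",
                   as.character(GenomicRanges::seqnames(peaks)),
                   GenomicRanges::start(peaks) - 1L,
                   GenomicRanges::end(peaks),
                   peaks$name, sc,
                   format(peaks$signalValue, trim = TRUE, scientific = FALSE),
                   format(peaks$pValue, trim = TRUE, scientific = FALSE),
                   format(peaks$qValue, trim = TRUE, scientific = FALSE),
                   as.integer(peaks$peak))
  writeLines(lines, path)
  invisible(path)
}

#' Remove hyper-significant artifact peaks by q-value
#'
#' Drops peaks whose -log10(q) exceeds \code{max_neg_log10_q} (strict
#' inequality: a peak at exactly the threshold is retained). Such
#' hyper-significant peaks typically arise from collapsed repeats or
#' blacklist-type artifact regions. Order is preserved.
#'
#' @param peaks A peak \code{GRanges} with a \code{qValue} column.
#' @param max_neg_log10_q Threshold (default 100).
#' @return The filtered \code{GRanges}.
#' @export
filter_peaks_by_q <- function(peaks, max_neg_log10_q = 100) {
  stopifnot(!is.null(peaks$qValue))
  peaks[peaks$qValue <= max_neg_log10_q]
}

#' Common peaks between two replicates
#'
#' Reconciles duplicate ChIP replicates by interval intersection: each
#' overlapping rep1 x rep2 pair yields one common peak equal to the
#' intersection of the two intervals (so one rep1 peak overlapping two rep2
#' peaks yields two common peaks). The -log10(q) of a common peak is the
#' minimum of the pair (the weaker evidence); abutting intervals with zero
#' overlap are excluded. This is "common peaks, not merged peaks": the
#' geometry never extends beyond either input.
#'
#' @param rep1,rep2 Peak \code{GRanges} (sorted; strand ignored).
#' @return A sorted \code{GRanges} of intersections with the standard peak
#'   metadata columns; \code{name} concatenates the pair's names and
#'   \code{peak} is -1 (the summit is undefined after intersection).
#' @export
common_peaks <- function(rep1, rep2) {
  hits <- GenomicRanges::findOverlaps(rep1, rep2, minoverlap = 1L,
                                      ignore.strand = TRUE)
  q1 <- rep1[S4Vectors::queryHits(hits)]
  q2 <- rep2[S4Vectors::subjectHits(hits)]
  out <- GenomicRanges::pintersect(GenomicRanges::granges(q1),
                                   GenomicRanges::granges(q2))
  out$hit <- NULL
  out$name <- if (length(out)) paste(q1$name, q2$name, sep = "|")
              else character(0)
  out$score <- pmin(q1$score, q2$score)
  out$signalValue <- pmin(q1$signalValue, q2$signalValue)
  out$pValue <- pmin(q1$pValue, q2$pValue)
  out$qValue <- pmin(q1$qValue, q2$qValue)
  out$peak <- rep(-1L, length(out))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Classify each gene's binding status
#'
#' Every gene in the universe receives exactly one binding class per
#' factor: \code{promoter} if any peak overlaps any promoter window of the
#' gene (350 bp upstream to 100 bp downstream of any transcript TSS, by
#' default); else \code{nonpromoter_genic} if any peak overlaps the gene
#' span (introns included); else \code{unbound}. A single peak may support
#' calls for several genes. Promoter precedence means additional genic
#' overlaps never demote a promoter call.
#'
#' @param x A \code{gene_models} object (the gene universe).
#' @param peaks A peak \code{GRanges} (typically \code{\link{common_peaks}}
#'   output after \code{\link{filter_peaks_by_q}}).
#' @param factor_name Label recorded in the output (default from the peak
#'   set's metadata, else \code{"factor"}).
#' @param upstream_bp,downstream_bp Promoter window geometry passed to
#'   \code{\link{promoter_windows}}.
#' @param chrom_lengths Optional chromosome lengths for window clipping.
#' @return A data.frame of class \code{binding_calls}: one row per gene with
#'   \code{gene_id}, \code{factor}, \code{binding_class} (factor with levels
#'   promoter, nonpromoter_genic, unbound), \code{n_peaks},
#'   \code{supporting_peaks} (comma-separated peak names) and
#'   \code{min_tss_distance} (bp; NA for unbound genes).
#' @export
assign_binding_class <- function(x, peaks, factor_name = NULL,
                                 upstream_bp = 350, downstream_bp = 100,
                                 chrom_lengths = NULL) {
  stopifnot(inherits(x, "gene_models"))
  if (is.null(factor_name))
    factor_name <- S4Vectors::metadata(peaks)$label %||% "factor"
  known <- unique(x$genes$chrom)
  pk_chrom <- as.character(GenomicRanges::seqnames(peaks))
  if (length(peaks) && !all(pk_chrom %in% known)) {
    warning(sprintf(
      "%d peak(s) on chromosome(s) absent from the annotation ignored: %s",
      sum(!pk_chrom %in% known),
      paste(setdiff(unique(pk_chrom), known), collapse = ", ")))
    peaks <- peaks[pk_chrom %in% known]
  }
  prom <- promoter_windows(x, upstream_bp, downstream_bp, chrom_lengths)
  span <- gene_granges(x)
  ph <- GenomicRanges::findOverlaps(prom, peaks, ignore.strand = TRUE)
  sh <- GenomicRanges::findOverlaps(span, peaks, ignore.strand = TRUE)
  prom_support <- split(peaks$name[S4Vectors::subjectHits(ph)],
                        prom$gene_id[S4Vectors::queryHits(ph)])
  span_support <- split(peaks$name[S4Vectors::subjectHits(sh)],
                        span$gene_id[S4Vectors::queryHits(sh)])
  ids <- x$genes$gene_id
  cls <- rep("unbound", length(ids))
  cls[ids %in% names(span_support)] <- "nonpromoter_genic"
  cls[ids %in% names(prom_support)] <- "promoter"
  support <- lapply(ids, function(g) {
    s <- unique(c(prom_support[[g]], span_support[[g]]))
    if (is.null(s)) character(0) else s
  })
  # min distance from any supporting peak to the gene's nearest TSS,
  # vectorised over all (supporting peak, TSS) pairs
  tss <- tss_granges(x)
  min_d <- rep(NA_real_, length(ids))
  pair <- unique(rbind(
    data.frame(gene_id = prom$gene_id[S4Vectors::queryHits(ph)],
               pk = S4Vectors::subjectHits(ph)),
    data.frame(gene_id = span$gene_id[S4Vectors::queryHits(sh)],
               pk = S4Vectors::subjectHits(sh))))
  if (nrow(pair)) {
    tdf <- data.frame(gene_id = tss$gene_id, ti = seq_along(tss))
    m <- merge(pair, tdf, by = "gene_id")
    d <- GenomicRanges::distance(tss[m$ti], peaks[m$pk], ignore.strand = TRUE)
    dmin <- tapply(d, m$gene_id, min)
    min_d[match(names(dmin), ids)] <- as.numeric(dmin)
  }
  out <- data.frame(
    gene_id = ids,
    factor = factor_name,
    binding_class = factor(cls, levels = c("promoter", "nonpromoter_genic",
                                           "unbound")),
    n_peaks = lengths(support),
    supporting_peaks = vapply(support, paste, "", collapse = ","),
    min_tss_distance = min_d,
    stringsAsFactors = FALSE)
  class(out) <- c("binding_calls", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.binding_calls <- function(x, ...) {
  tab <- table(x$binding_class)
  cat(sprintf("binding_calls for factor '%s': %d genes\n", x$factor[1],
              nrow(x)))
  for (k in names(tab))
    cat(sprintf("  %-18s %6d (%.1f%%)\n", k, tab[[k]],
                100 * tab[[k]] / nrow(x)))
  invisible(x)
}

#' Write binding calls to TSV
#'
#' @param calls A \code{binding_calls} data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_binding_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bin bound genes by distance from peaks to the nearest TSS
#'
#' For every gene, the distance from its transcript TSSs to the nearest peak
#' is computed (0 when a TSS lies inside a peak, otherwise the gap to the
#' nearest peak edge), minimised over TSSs, and the gene is assigned the bin
#' of \code{bin_edges} containing that distance. Genes whose distance falls
#' beyond the last edge are reported as \code{NA}.
#'
#' @param x A \code{gene_models} object.
#' @param peaks A peak \code{GRanges}.
#' @param bin_edges Strictly increasing vector of bin edges (bp); bin i is
#'   [edge i, edge i+1).
#' @return A data.frame with \code{gene_id}, \code{distance} (bp; NA when
#'   the gene's chromosome has no peak) and \code{bin} (factor of interval
#'   labels).
#' @export
classify_by_tss_distance <- function(x, peaks, bin_edges) {
  stopifnot(inherits(x, "gene_models"), length(bin_edges) >= 2,
            all(diff(bin_edges) > 0))
  tss <- tss_granges(x)
  dtn <- GenomicRanges::distanceToNearest(tss, peaks, ignore.strand = TRUE)
  d_tx <- rep(NA_real_, length(tss))
  d_tx[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
  d <- tapply(d_tx, tss$gene_id, function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  ids <- x$genes$gene_id
  d <- as.numeric(d[ids])
  labs <- sprintf("[%s,%s)", bin_edges[-length(bin_edges)], bin_edges[-1])
  bin <- cut(d, breaks = bin_edges, right = FALSE, labels = labs)
  data.frame(gene_id = ids, distance = d, bin = bin,
             stringsAsFactors = FALSE)
}

#' Pearson correlation between replicate signals
#'
#' Standard Pearson correlation between paired per-region read counts (or
#' any paired coverage summaries) of two replicates, e.g. counts on merged
#' peaks. A zero-variance vector makes the coefficient undefined; this is
#' flagged with a warning and \code{NA} is returned.
#'
#' @param cov1,cov2 Equal-length numeric vectors over the same regions.
#' @return Pearson r in [-1, 1], or NA when undefined.
#' @export
replicate_correlation <- function(cov1, cov2) {
  stopifnot(length(cov1) == length(cov2), length(cov1) >= 2)
  if (stats::var(cov1) == 0 || stats::var(cov2) == 0) {
    warning("zero variance in a replicate vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(cov1, cov2)
}
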