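#' Read a per-base coverage track from bedGraph
#'
#' bedGraph intervals (0-based half-open on disk) are expanded to dense
#' per-base coverage; uncovered bases are 0. Overlapping intervals make the
#' track ill-formed and raise an error.
#'
#' @param path Path to a bedGraph file; may be empty.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @return An object of class \code{coverage_track}: an
#'   \code{RleList}-backed list with one numeric-valued \code{Rle} per
#'   chromosome in \code{chrom_sizes}.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  stopifnot(!is.null(names(chrom_sizes)))
  if (file.size(path) == 0 || length(readLines(path, n = 1)) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$score <- numeric(0)
  } else {
    gr <- rtracklayer::import(path, format = "bedGraph")
  }
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (length(gr)) {
    if (!all(chrom %in% names(chrom_sizes)))
      stop("bedGraph chromosome absent from chrom_sizes: ",
           paste(setdiff(unique(chrom), names(chrom_sizes)), collapse = ", "))
    if (any(GenomicRanges::end(gr) > chrom_sizes[chrom]))
      stop("bedGraph interval beyond chromosome end")
    if (!IRanges::isDisjoint(gr))
      stop("overlapping bedGraph intervals: ill-formed track")
  }
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  structure(list(coverage = cov, chrom_sizes = chrom_sizes),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- vapply(x$coverage, function(r) sum(as.numeric(r)), 0)
  cat(sprintf("coverage_track: %d chromosome(s), %.3g signal-bases total\n",
              length(x$coverage), sum(tot)))
  invisible(x)
}

#' Write a coverage track to bedGraph
#'
#' Emits one line per constant-value run with non-zero signal, 0-based
#' half-open, deterministically ordered; round-trips through
#' \code{\link{read_bedgraph}}.
#'
#' @param track A \code{coverage_track}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  lines <- unlist(lapply(names(track$coverage), function(ch) {
    r <- track$coverage[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)  # 0-based starts
    val <- S4Vectors::runValue(r)
    keep <- val != 0
    if (!any(keep)) return(character(0))
    sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
            format(val[keep], trim = TRUE, scientific = FALSE, digits = 15))
  }))
  writeLines(lines, path)
  invisible(path)
}

# mean of a step function over [a, b) in continuous coordinates where base i
# (1-based) occupies [i-1, i); v is the per-base vector, csum = c(0, cumsum(v))
.step_integral <- function(csum, v, a, b) {
  f <- function(x) {
    i <- floor(x)
    csum[pmin(i, length(v)) + 1] +
      (x - i) * v[pmin(i + 1, length(v))] * (i < length(v))
  }
  f(b) - f(a)
}

#' Scale-regions coverage matrix over gene bodies with flanks
#'
#' Computes, per gene, the coverage profile of a fixed-width upstream flank
#' (binned at \code{bin_bp} from the TSS outward), the gene body resampled
#' to a constant target length (each of \code{body_bins} bins averages an
#' equal fraction of the gene length, partial bases weighted fractionally),
#' and a fixed-width downstream flank from the TES. Rows of minus-strand
#' genes are orientation-flipped so column 1 is always 5'-most. Flanks
#' beyond chromosome ends are padded with zeros. With the defaults (3 kb
#' flanks, 5 kb body target, 50 bp bins, 100 body bins) each row has
#' 60 + 100 + 60 = 220 columns.
#'
#' @param track A \code{coverage_track}.
#' @param x A \code{gene_models} object.
#' @param upstream_bp,downstream_bp Flank widths (default 3000).
#' @param body_target_bp Constant body length the genes are scaled to
#'   (default 5000; with \code{bin_bp} it fixes \code{body_bins}).
#' @param bin_bp Flank bin width (default 50).
#' @param body_bins Number of body bins (default
#'   \code{body_target_bp / bin_bp} = 100).
#' @param sort_rows Order rows by descending row mean, the heatmap
#'   convention (default TRUE); original gene ids are retained as rownames.
#' @return A numeric matrix of class \code{meta_matrix} (genes x bins) with
#'   attributes \code{bin_scheme} and \code{region_cols} marking the
#'   upstream/body/downstream column blocks.
#' @export
scale_regions_matrix <- function(track, x, upstream_bp = 3000,
                                 downstream_bp = 3000,
                                 body_target_bp = 5000, bin_bp = 50,
                                 body_bins = body_target_bp %/% bin_bp,
                                 sort_rows = TRUE) {
  stopifnot(inherits(track, "coverage_track"), inherits(x, "gene_models"),
            upstream_bp %% bin_bp == 0, downstream_bp %% bin_bp == 0)
  g <- x$genes
  if (!all(g$chrom %in% names(track$coverage)))
    stop("gene chromosome absent from coverage track")
  up_bins <- upstream_bp %/% bin_bp
  dn_bins <- downstream_bp %/% bin_bp
  ncol_out <- up_bins + body_bins + dn_bins
  mat <- matrix(0, nrow(g), ncol_out)
  rownames(mat) <- g$gene_id
  for (i in seq_len(nrow(g))) {
    ch <- g$chrom[i]
    clen <- track$chrom_sizes[[ch]]
    s <- g$start[i]; e <- g$end[i]
    lo <- s - upstream_bp; hi <- e + downstream_bp
    # extract with zero padding outside [1, clen]
    core <- as.numeric(S4Vectors::window(
      track$coverage[[ch]], max(lo, 1L), min(hi, clen)))
    v <- c(numeric(max(0L, 1L - lo)), core, numeric(max(0L, hi - clen)))
    if (g$strand[i] == "-") v <- rev(v)
    L <- e - s + 1
    # flank bins: fixed bin_bp, already 5'->3' oriented
    upv <- v[seq_len(upstream_bp)]
    bodyv <- v[upstream_bp + seq_len(L)]
    dnv <- v[upstream_bp + L + seq_len(downstream_bp)]
    row <- numeric(ncol_out)
    row[seq_len(up_bins)] <- colMeans(matrix(upv, nrow = bin_bp))
    csum <- c(0, cumsum(bodyv))
    edges <- seq(0, L, length.out = body_bins + 1)
    ints <- .step_integral(csum, bodyv, edges[-(body_bins + 1)], edges[-1])
    row[up_bins + seq_len(body_bins)] <- ints / (L / body_bins)
    row[up_bins + body_bins + seq_len(dn_bins)] <-
      colMeans(matrix(dnv, nrow = bin_bp))
    mat[i, ] <- row
  }
  if (sort_rows) mat <- mat[order(-rowMeans(mat)), , drop = FALSE]
  structure(mat,
            bin_scheme = list(upstream_bp = upstream_bp,
                              downstream_bp = downstream_bp,
                              body_target_bp = body_target_bp,
                              bin_bp = bin_bp, body_bins = body_bins),
            region_cols = list(upstream = seq_len(up_bins),
                               body = up_bins + seq_len(body_bins),
                               downstream = up_bins + body_bins +
                                 seq_len(dn_bins)),
            class = c("meta_matrix", "matrix", "array"))
}

#' Average metaprofile across genes
#'
#' @param m A \code{meta_matrix} (or any numeric matrix with >= 1 row).
#' @return Numeric vector of per-bin column means.
#' @export
summary_profile <- function(m) {
  if (nrow(m) == 0) stop("empty matrix")
  colMeans(m)
}

#' @export
print.meta_matrix <- function(x, ...) {
  sc <- attr(x, "bin_scheme")
  cat(sprintf(
    "meta_matrix: %d genes x %d bins (%d bp flanks, body scaled to %d bp, %d bp bins)\n",
    nrow(x), ncol(x), sc$upstream_bp, sc$body_target_bp, sc$bin_bp))
  invisible(x)
}

#' Plot the average metaprofile
#'
#' Line plot of the per-bin mean signal with TSS/TES boundaries marked.
#'
#' @param x A \code{meta_matrix}.
#' @param ... Passed to \code{matplot}.
#' @return Invisibly, the summary profile.
#' @export
#' @method plot meta_matrix
plot.meta_matrix <- function(x, ...) {
  prof <- summary_profile(x)
  rc <- attr(x, "region_cols")
  graphics::matplot(seq_along(prof), prof, type = "l", lty = 1,
                    xlab = "bin (5' to 3')", ylab = "mean signal",
                    xaxt = "n", ...)
  graphics::abline(v = c(min(rc$body) - 0.5, max(rc$body) + 0.5),
                   lty = 2, col = "grey40")
  graphics::axis(1, at = c(1, min(rc$body), max(rc$body), length(prof)),
                 labels = c(sprintf("-%d bp", attr(x, "bin_scheme")$upstream_bp),
                            "TSS", "TES",
                            sprintf("+%d bp", attr(x, "bin_scheme")$downstream_bp)))
  invisible(prof)
}

#' Write a metaprofile matrix to TSV
#'
#' @param m A \code{meta_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_meta_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), as.data.frame(unclass(m)[, ]),
                   check.names = FALSE)
  colnames(df) <- c("gene_id", sprintf("bin_%03d", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
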