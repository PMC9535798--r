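#' Gene models: genes, transcripts, TSS/TES
#'
#' A \code{gene_models} object holds a set of protein-coding (or otherwise
#' filtered) genes together with their transcripts. Coordinates are 1-based
#' closed intervals, the native convention of GTF and of
#' \pkg{GenomicRanges}; BED-family formats are converted at the I/O
#' boundary. The transcription start site (TSS) of a transcript is its
#' 5'-most base: \code{start} on the \code{+} strand, \code{end} on the
#' \code{-} strand; the transcription end site (TES) is the opposite end.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{name},
#'   \code{biotype}, \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @param transcripts data.frame with columns \code{transcript_id},
#'   \code{gene_id}, \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @return An object of class \code{gene_models}: a list with elements
#'   \code{genes} and \code{transcripts} (each a data.frame, with derived
#'   \code{tss} and \code{tes} columns on the transcripts), sorted by
#'   chromosome, start, then gene id.
#' @export
gene_models <- function(genes, transcripts) {
  need_g <- c("gene_id", "name", "biotype", "chrom", "start", "end", "strand")
  need_t <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  stopifnot(all(need_g %in% names(genes)), all(need_t %in% names(transcripts)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene table")
  if (any(genes$start > genes$end) || any(transcripts$start > transcripts$end))
    stop("interval with start > end")
  if (!all(transcripts$gene_id %in% genes$gene_id))
    stop("transcript refers to unknown gene_id")
  # reject transcripts whose strand or chromosome conflicts with their gene
  gidx <- match(transcripts$gene_id, genes$gene_id)
  bad <- transcripts$strand != genes$strand[gidx] |
    transcripts$chrom != genes$chrom[gidx]
  if (any(bad)) {
    warning(sprintf(
      "rejected %d transcript(s) with strand/chrom conflicting their gene: %s",
      sum(bad), paste(utils::head(transcripts$transcript_id[bad], 5),
                      collapse = ", ")))
    transcripts <- transcripts[!bad, , drop = FALSE]
  }
  if (!all(genes$gene_id %in% transcripts$gene_id))
    stop("gene without any transcript")
  transcripts$tss <- ifelse(transcripts$strand == "+",
                            transcripts$start, transcripts$end)
  transcripts$tes <- ifelse(transcripts$strand == "+",
                            transcripts$end, transcripts$start)
  # gene span = union of its transcripts
  sp_start <- tapply(transcripts$start, transcripts$gene_id, min)
  sp_end <- tapply(transcripts$end, transcripts$gene_id, max)
  genes$start <- pmin(genes$start, as.integer(sp_start[genes$gene_id]))
  genes$end <- pmax(genes$end, as.integer(sp_end[genes$gene_id]))
  o <- order(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  rownames(genes) <- NULL
  ot <- order(match(transcripts$gene_id, genes$gene_id), transcripts$start,
              transcripts$transcript_id)
  transcripts <- transcripts[ot, , drop = FALSE]
  rownames(transcripts) <- NULL
  structure(list(genes = genes, transcripts = transcripts),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d transcripts on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$transcripts),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' @export
length.gene_models <- function(x) nrow(x$genes)

#' Genomic ranges of gene spans
#'
#' @param x A \code{gene_models} object.
#' @return A \code{GRanges} of gene spans, named by gene id.
#' @export
gene_granges <- function(x) {
  stopifnot(inherits(x, "gene_models"))
  g <- x$genes
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                               strand = g$strand, gene_id = g$gene_id)
  names(gr) <- g$gene_id
  gr
}

#' Genomic positions of transcript TSSs
#'
#' One single-base range per transcript, at the 5'-most transcribed base.
#'
#' @param x A \code{gene_models} object.
#' @return A \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{transcript_id}.
#' @export
tss_granges <- function(x) {
  stopifnot(inherits(x, "gene_models"))
  tx <- x$transcripts
  GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$tss, tx$tss),
                         strand = tx$strand, gene_id = tx$gene_id,
                         transcript_id = tx$transcript_id)
}

#' Read gene models from a GTF file
#'
#' Parses a GTF annotation (1-based closed coordinates, attribute dialect
#' \code{key "value";}) into a \code{\link{gene_models}} object. Transcript
#' records (\code{type == "transcript"} or \code{"mRNA"}) define the
#' transcripts; if a gene record is absent for some gene id, the gene is
#' reconstructed as the union of its transcripts. Genes are filtered by
#' biotype when the annotation carries a \code{gene_biotype} or
#' \code{gene_type} attribute.
#'
#' @param path Path to a GTF file.
#' @param biotype_filter Character vector of biotypes to keep (default
#'   \code{"protein_coding"}), or \code{NULL} to keep everything. Ignored
#'   with a message when the annotation has no biotype attribute.
#' @return A \code{\link{gene_models}} object, deterministically ordered by
#'   chromosome, start, then gene id.
#' @export
read_gtf_genes <- function(path, biotype_filter = "protein_coding") {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(S4Vectors::mcols(gr))
  biocol <- intersect(c("gene_biotype", "gene_type"), names(md))[1]
  if (is.null(md$gene_id)) stop("GTF records carry no gene_id attribute")
  is_tx <- as.character(gr$type) %in% c("transcript", "mRNA")
  if (!any(is_tx)) stop("GTF contains no transcript records")
  tx <- data.frame(
    transcript_id = as.character(md$transcript_id[is_tx]),
    gene_id = as.character(md$gene_id[is_tx]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_tx]),
    start = GenomicRanges::start(gr)[is_tx],
    end = GenomicRanges::end(gr)[is_tx],
    strand = as.character(GenomicRanges::strand(gr)[is_tx]),
    stringsAsFactors = FALSE)
  if (anyNA(tx$transcript_id)) stop("transcript record without transcript_id")
  is_g <- as.character(gr$type) == "gene"
  gtab <- data.frame(
    gene_id = as.character(md$gene_id[is_g]),
    name = if (!is.null(md$gene_name)) as.character(md$gene_name[is_g])
           else as.character(md$gene_id[is_g]),
    biotype = if (!is.na(biocol)) as.character(md[[biocol]][is_g])
              else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)[is_g]),
    start = GenomicRanges::start(gr)[is_g],
    end = GenomicRanges::end(gr)[is_g],
    strand = as.character(GenomicRanges::strand(gr)[is_g]),
    stringsAsFactors = FALSE)
  # genes lacking an explicit gene record: derive from transcripts
  orphan <- setdiff(tx$gene_id, gtab$gene_id)
  if (length(orphan)) {
    otx <- tx[tx$gene_id %in% orphan, , drop = FALSE]
    add <- data.frame(
      gene_id = orphan,
      name = orphan,
      biotype = if (!is.na(biocol))
        as.character(tapply(md[[biocol]][is_tx], tx$gene_id, `[`, 1)[orphan])
        else NA_character_,
      chrom = tapply(otx$chrom, otx$gene_id, `[`, 1)[orphan],
      start = as.integer(tapply(otx$start, otx$gene_id, min)[orphan]),
      end = as.integer(tapply(otx$end, otx$gene_id, max)[orphan]),
      strand = tapply(otx$strand, otx$gene_id, `[`, 1)[orphan],
      stringsAsFactors = FALSE)
    gtab <- rbind(gtab, add)
  }
  if (!is.null(biotype_filter)) {
    if (is.na(biocol) && all(is.na(gtab$biotype))) {
      message("annotation carries no biotype attribute; biotype filter skipped")
    } else {
      keep <- gtab$biotype %in% biotype_filter
      gtab <- gtab[keep, , drop = FALSE]
      tx <- tx[tx$gene_id %in% gtab$gene_id, , drop = FALSE]
    }
  }
  gene_models(gtab, tx)
}

#' Write gene models to a GTF file
#'
#' Emits one \code{gene} and one \code{transcript} record per model, with
#' \code{gene_id}, \code{gene_name}, \code{gene_biotype} and
#' \code{transcript_id} attributes. The output is byte-deterministic for a
#' given object and round-trips through \code{\link{read_gtf_genes}}.
#'
#' @param x A \code{gene_models} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gtf_genes <- function(x, path) {
  stopifnot(inherits(x, "gene_models"))
  g <- x$genes
  tx <- x$transcripts
  glines <- sprintf(
    "%s\tcrossreg\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\"; gene_biotype \"%s\";",
    g$chrom, g$start, g$end, g$strand, g$gene_id, g$name, g$biotype)
  gi <- match(tx$gene_id, g$gene_id)
  tlines <- sprintf(
    "%s\tcrossreg\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\"; gene_biotype \"%s\";",
    tx$chrom, tx$start, tx$end, tx$strand, tx$gene_id, tx$transcript_id,
    g$name[gi], g$biotype[gi])
  # interleave: each gene followed by its transcripts, in object order
  tsplit <- split(tlines, factor(tx$gene_id, levels = g$gene_id))
  out <- as.character(unlist(mapply(function(gl, tl) c(gl, tl), glines,
                                    tsplit, SIMPLIFY = FALSE),
                             use.names = FALSE))
  writeLines(out, path)
  invisible(path)
}

#' Promoter windows around transcript TSSs
#'
#' The promoter window of a TSS spans \code{upstream_bp} bases upstream of
#' the TSS through \code{downstream_bp} bases downstream, where "downstream"
#' includes the TSS base itself, for a total width of
#' \code{upstream_bp + downstream_bp} (450 bp at the defaults of 350/100).
#' One window is returned per distinct transcript TSS of each gene; windows
#' are clipped at position 1 and, when chromosome lengths are supplied, at
#' the chromosome end.
#'
#' @param x A \code{gene_models} object.
#' @param upstream_bp Bases upstream of the TSS (default 350).
#' @param downstream_bp Bases downstream of the TSS, TSS base included
#'   (default 100).
#' @param chrom_lengths Optional named vector of chromosome lengths (bp) for
#'   end clipping.
#' @return A \code{GRanges} of promoter windows with metadata columns
#'   \code{gene_id}, \code{transcript_id} and \code{tss}.
#' @export
promoter_windows <- function(x, upstream_bp = 350, downstream_bp = 100,
                             chrom_lengths = NULL) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 1)
  tss <- tss_granges(x)
  # drop duplicate TSSs within a gene (transcripts sharing a start)
  key <- paste(tss$gene_id, GenomicRanges::start(tss))
  tss <- tss[!duplicated(key)]
  win <- GenomicRanges::promoters(tss, upstream = upstream_bp,
                                  downstream = downstream_bp)
  win$tss <- GenomicRanges::start(tss)
  st <- pmax(GenomicRanges::start(win), 1L)
  en <- GenomicRanges::end(win)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[as.character(GenomicRanges::seqnames(win))]
    if (anyNA(lim)) stop("chrom_lengths missing a chromosome used by genes")
    en <- pmin(en, as.integer(lim))
  }
  IRanges::ranges(win) <- IRanges::IRanges(st, en)
  win
}

#' Distance from a position to the nearest transcript TSS
#'
#' Scans every transcript TSS of every gene and returns the closest one.
#' Ties are broken by smaller distance first, then lexicographic gene id,
#' then transcript id.
#'
#' @param pos 1-based genomic position.
#' @param chrom Chromosome of \code{pos}.
#' @param x A \code{gene_models} object.
#' @return A list with \code{gene_id}, \code{transcript_id}, and
#'   \code{distance} (bp, >= 0; absolute).
#' @export
nearest_tss_distance <- function(pos, chrom, x) {
  stopifnot(inherits(x, "gene_models"), length(pos) == 1)
  tx <- x$transcripts[x$transcripts$chrom == chrom, , drop = FALSE]
  if (nrow(tx) == 0) stop("no transcripts on chromosome ", chrom)
  d <- abs(tx$tss - pos)
  o <- order(d, tx$gene_id, tx$transcript_id)
  i <- o[1]
  list(gene_id = tx$gene_id[i], transcript_id = tx$transcript_id[i],
       distance = d[i])
}
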