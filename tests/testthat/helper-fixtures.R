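# Hand-built three-gene toy annotation on one chromosome: a + strand gene
# with two TSSs, a - strand gene, and a short + strand gene far downstream.
tiny_genes <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    name = c("alpha", "beta", "gamma"),
    biotype = "protein_coding",
    chrom = "chr2L",
    start = c(10000L, 30000L, 60000L),
    end = c(18000L, 38000L, 61500L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  tx <- data.frame(
    transcript_id = c("gA.t1", "gA.t2", "gB.t1", "gC.t1"),
    gene_id = c("gA", "gA", "gB", "gC"),
    chrom = "chr2L",
    start = c(10000L, 10150L, 30000L, 60000L),
    end = c(18000L, 18000L, 38000L, 61500L),
    strand = c("+", "+", "-", "+"),
    stringsAsFactors = FALSE)
  gene_models(genes, tx)
}

# a peak GRanges with the standard narrowPeak metadata columns
make_peaks <- function(chrom, starts, ends, q = 10,
                       names = sprintf("p%d", seq_along(starts))) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
  gr$name <- names
  gr$score <- rep(100, length(gr))
  gr$signalValue <- rep(5, length(gr))
  gr$pValue <- rep(12, length(gr))
  gr$qValue <- rep(q, length.out = length(gr))
  gr$peak <- as.integer(GenomicRanges::width(gr) %/% 2)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

# data.frames ignoring row names and row order (sorted by `by`)
expect_same_table <- function(a, b, by) {
  a <- a[do.call(order, a[by]), , drop = FALSE]
  b <- b[do.call(order, b[by]), , drop = FALSE]
  rownames(a) <- NULL
  rownames(b) <- NULL
  expect_equal(a, b)
}
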