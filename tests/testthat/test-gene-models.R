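test_that("gene models derive strand-aware TSS/TES and union spans", {
  gm <- tiny_genes()
  tx <- gm$transcripts
  expect_equal(tx$tss[tx$transcript_id == "gA.t1"], 10000)
  expect_equal(tx$tss[tx$transcript_id == "gA.t2"], 10150)
  expect_equal(tx$tes[tx$transcript_id == "gA.t1"], 18000)
  # minus strand: TSS is the interval end
  expect_equal(tx$tss[tx$transcript_id == "gB.t1"], 38000)
  expect_equal(tx$tes[tx$transcript_id == "gB.t1"], 30000)
  # span covers every transcript (union)
  g2 <- gm$genes
  expect_equal(g2$start[g2$gene_id == "gA"], 10000)
  expect_equal(g2$end[g2$gene_id == "gA"], 18000)
  # conflicting-strand transcript is rejected with a report
  genes <- gm$genes
  bad_tx <- rbind(gm$transcripts[, 1:6],
                  data.frame(transcript_id = "gA.bad", gene_id = "gA",
                             chrom = "chr2L", start = 10000L, end = 12000L,
                             strand = "-"))
  expect_warning(gm2 <- gene_models(genes, bad_tx), "rejected")
  expect_false("gA.bad" %in% gm2$transcripts$transcript_id)
})

test_that("GTF write-then-parse round trip preserves every coordinate", {
  gm <- tiny_genes()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_genes(gm, path)
  # GTF is 1-based closed on disk: the gA gene line carries its own coords
  lines <- readLines(path)
  expect_true(any(grepl("\tgene\t10000\t18000\t.\t\\+", lines)))
  gm2 <- read_gtf_genes(path)
  expect_same_table(gm$genes, gm2$genes, "gene_id")
  expect_same_table(gm$transcripts, gm2$transcripts, "transcript_id")

  # and on a larger generated annotation
  sim <- simulate_genome(n_genes = 200, n_chroms = 2, chrom_length = 2.5e6,
                         seed = 421)
  path2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_genes(sim$genes, path2)
  back <- read_gtf_genes(path2)
  expect_equal(length(back), 200)
  expect_same_table(sim$genes$genes, back$genes, "gene_id")
  expect_same_table(sim$genes$transcripts, back$transcripts, "transcript_id")
  # no overlapping spans within a chromosome
  for (ch in unique(back$genes$chrom)) {
    g <- back$genes[back$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
})

test_that("promoter windows are 450 bp, contain the TSS, and mirror by strand", {
  genes <- data.frame(gene_id = c("p", "m"), name = c("p", "m"),
                      biotype = "pc", chrom = "chrX",
                      start = c(10000L, 5000L), end = c(15000L, 10000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = c("p.t", "m.t"), gene_id = c("p", "m"),
                   chrom = "chrX", start = c(10000L, 5000L),
                   end = c(15000L, 10000L), strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  gm <- gene_models(genes, tx)
  win <- promoter_windows(gm)
  wp <- win[win$gene_id == "p"]
  wm <- win[win$gene_id == "m"]
  # + strand TSS 10000: 350 bp upstream through 100 bp downstream incl. TSS
  expect_equal(GenomicRanges::start(wp), 9650)
  expect_equal(GenomicRanges::end(wp), 10099)
  # - strand TSS 10000: reflection
  expect_equal(GenomicRanges::start(wm), 9901)
  expect_equal(GenomicRanges::end(wm), 10350)
  expect_equal(GenomicRanges::width(wp), 450)
  expect_equal(GenomicRanges::width(wm), 450)
  # both contain the TSS base
  expect_true(GenomicRanges::start(wp) <= 10000 &&
                GenomicRanges::end(wp) >= 10000)
  expect_true(GenomicRanges::start(wm) <= 10000 &&
                GenomicRanges::end(wm) >= 10000)
  # one window per distinct TSS: gA of the toy has two
  expect_equal(sum(promoter_windows(tiny_genes())$gene_id == "gA"), 2)
})

test_that("promoter windows clip at chromosome boundaries", {
  genes <- data.frame(gene_id = "e", name = "e", biotype = "pc",
                      chrom = "chrX", start = 100L, end = 5000L,
                      strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = "e.t", gene_id = "e", chrom = "chrX",
                   start = 100L, end = 5000L, strand = "+",
                   stringsAsFactors = FALSE)
  gm <- gene_models(genes, tx)
  win <- promoter_windows(gm, chrom_lengths = c(chrX = 50000))
  expect_equal(GenomicRanges::start(win), 1)
  expect_equal(GenomicRanges::end(win), 199)
  # clipping at the right end
  genes$start <- 49950L; genes$end <- 49990L
  tx$start <- 49950L; tx$end <- 49990L
  win2 <- promoter_windows(gene_models(genes, tx),
                           chrom_lengths = c(chrX = 50000))
  expect_equal(GenomicRanges::end(win2), 50000)
})

test_that("nearest TSS distance equals an exhaustive brute-force scan", {
  sim <- simulate_genome(n_genes = 50, n_chroms = 1, chrom_length = 1.5e6,
                         seed = 99)
  gm <- sim$genes
  # identity: querying an exact TSS gives distance 0
  one <- gm$transcripts[7, ]
  hit <- nearest_tss_distance(one$tss, one$chrom, gm)
  expect_equal(hit$distance, 0)
  # two-TSS arithmetic
  genes <- data.frame(gene_id = c("a", "b"), name = c("a", "b"),
                      biotype = "pc", chrom = "c1",
                      start = c(10000L, 12000L), end = c(11000L, 13000L),
                      strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = c("a.t", "b.t"), gene_id = c("a", "b"),
                   chrom = "c1", start = c(10000L, 12000L),
                   end = c(11000L, 13000L), strand = "+",
                   stringsAsFactors = FALSE)
  two <- gene_models(genes, tx)
  expect_equal(nearest_tss_distance(10500, "c1", two),
               list(gene_id = "a", transcript_id = "a.t", distance = 500))
  # randomized queries against the brute-force minimum
  set.seed(17)
  queries <- sample.int(1.5e6, 1000)
  all_tss <- gm$transcripts$tss
  for (q in queries[1:1000]) {
    expect_equal(nearest_tss_distance(q, "chr1", gm)$distance,
                 min(abs(all_tss - q)))
  }
})
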