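test_that("narrowPeak fields map onto 1-based ranges and round-trip", {
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr2L\t100\t200\tp1\t50\t.\t3.1\t5.2\t4.8\t60", path)
  pk <- read_narrowpeak(path)
  expect_equal(GenomicRanges::start(pk), 101)  # 0-based 100 -> 1-based 101
  expect_equal(GenomicRanges::end(pk), 200)
  expect_equal(pk$qValue, 4.8)
  expect_equal(pk$peak, 60L)
  expect_equal(pk$name, "p1")

  # empty file -> empty peak set
  empty <- withr::local_tempfile(fileext = ".narrowPeak")
  file.create(empty)
  expect_length(read_narrowpeak(empty), 0)

  # wrong column count is a parse error naming the line
  bad <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr2L\t100\t200\tp1\t50\t.", bad)
  expect_error(read_narrowpeak(bad), "10 columns")

  # 100-peak synthetic round trip
  set.seed(3)
  st <- sort(sample.int(1e6, 100))
  pk0 <- make_peaks("chr3R", st, st + sample(50:500, 100, replace = TRUE),
                    q = round(runif(100, 0, 99), 3))
  out <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk0, out)
  back <- read_narrowpeak(out)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(pk0))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(pk0))
  expect_equal(back$qValue, pk0$qValue)
  expect_equal(back$name, pk0$name)
})

test_that("the q-value filter removes hyper-significant peaks, strict inequality", {
  pk <- make_peaks("chr2L", c(100, 300, 500), c(200, 400, 600),
                   q = c(150, 100, 4.5))
  kept <- filter_peaks_by_q(pk)
  expect_equal(kept$qValue, c(150, 100, 4.5)[c(FALSE, TRUE, TRUE)])
  # exactly at the threshold is retained
  expect_true(100 %in% kept$qValue)
  # brute-force subset oracle on a mixed set, order preserved
  set.seed(11)
  q <- runif(10, 0, 200)
  pk10 <- make_peaks("chrX", seq(1000, by = 1000, length.out = 10),
                     seq(1200, by = 1000, length.out = 10), q = q)
  expect_equal(filter_peaks_by_q(pk10)$name, pk10$name[pk10$qValue <= 100])
})

test_that("common peaks are pairwise intersections with the min q", {
  r1 <- make_peaks("chr2L", 101, 200, q = 8, names = "a1")
  r2 <- make_peaks("chr2L", 151, 250, q = 5, names = "b1")
  cp <- common_peaks(r1, r2)
  expect_equal(GenomicRanges::start(cp), 151)
  expect_equal(GenomicRanges::end(cp), 200)
  expect_equal(cp$qValue, 5)  # weaker replicate evidence
  # abutting intervals share no base: no common peak
  r3 <- make_peaks("chr2L", 201, 300, q = 5)
  expect_length(common_peaks(r1, r3), 0)
  # one rep1 peak over two rep2 peaks yields two common peaks
  r4 <- make_peaks("chr2L", c(110, 180), c(140, 220), q = c(3, 4))
  expect_length(common_peaks(r1, r4), 2)
})

test_that("common peaks equal the all-pairs intersection oracle", {
  set.seed(23)
  mk <- function(n) {
    st <- sample.int(5e4, n)
    make_peaks("c1", st, st + sample(50:400, n, replace = TRUE),
               q = round(runif(n, 0, 60), 2))
  }
  r1 <- mk(200); r2 <- mk(200)
  cp <- common_peaks(r1, r2)
  # O(n^2) brute force, independent of findOverlaps
  oracle <- list()
  for (i in seq_along(r1)) for (j in seq_along(r2)) {
    s <- max(GenomicRanges::start(r1)[i], GenomicRanges::start(r2)[j])
    e <- min(GenomicRanges::end(r1)[i], GenomicRanges::end(r2)[j])
    if (s <= e)
      oracle[[length(oracle) + 1]] <-
        c(s, e, min(r1$qValue[i], r2$qValue[j]))
  }
  om <- do.call(rbind, oracle)
  om <- om[order(om[, 1], om[, 2], om[, 3]), , drop = FALSE]
  got <- cbind(GenomicRanges::start(cp), GenomicRanges::end(cp), cp$qValue)
  got <- got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE]
  expect_equal(unname(got), unname(om))
  # commutative up to interval identity, and contained in both inputs
  cp_rev <- common_peaks(r2, r1)
  expect_equal(GenomicRanges::granges(cp_rev), GenomicRanges::granges(cp))
  expect_true(all(IRanges::overlapsAny(cp, r1, type = "within")))
  expect_true(all(IRanges::overlapsAny(cp, r2, type = "within")))
})

test_that("binding classes follow promoter precedence and partition the universe", {
  gm <- tiny_genes()
  # one peak inside gA's promoter window; the same peak construction also
  # drops a second peak into gB's body (an intron-like position)
  pk <- make_peaks("chr2L", c(9900, 33000), c(10050, 33400), q = c(9, 7),
                   names = c("prom_pk", "body_pk"))
  calls <- assign_binding_class(gm, pk, "fac")
  cls <- setNames(as.character(calls$binding_class), calls$gene_id)
  expect_equal(cls[["gA"]], "promoter")
  expect_equal(cls[["gB"]], "nonpromoter_genic")
  expect_equal(cls[["gC"]], "unbound")  # no peak within 10 kb
  expect_equal(calls$n_peaks[calls$gene_id == "gC"], 0)
  expect_true(is.na(calls$min_tss_distance[calls$gene_id == "gC"]))
  # partition: one call per universe gene
  expect_equal(sort(calls$gene_id), sort(gm$genes$gene_id))
  # precedence/monotonicity: adding a genic peak cannot demote gA
  pk2 <- c(pk, make_peaks("chr2L", 15000, 15500, names = "extra"))
  calls2 <- assign_binding_class(gm, pk2, "fac")
  expect_equal(as.character(
    calls2$binding_class[calls2$gene_id == "gA"]), "promoter")
  # a peak spanning one gene's promoter and another gene's body supports both
  expect_true(all(calls$n_peaks[calls$gene_id %in% c("gA", "gB")] >= 1))
  # unknown chromosome peaks are ignored with a warning
  pk3 <- suppressWarnings(c(pk, make_peaks("chrUn", 100, 200,
                                           names = "off")))
  expect_warning(calls3 <- assign_binding_class(gm, pk3, "fac"),
                 "absent from the annotation")
  expect_equal(as.character(calls3$binding_class),
               as.character(calls$binding_class))
})

test_that("noise-free planted binding classes are recovered perfectly", {
  sim <- simulate_genome(n_genes = 300, n_chroms = 2, chrom_length = 2.5e6,
                         seed = 5)
  chip <- simulate_chip(sim, "fac", noise_peaks_per_mb = 0,
                        replicate_jitter = 0, n_artifact = 0, seed = 6)
  cp <- common_peaks(filter_peaks_by_q(chip$rep1),
                     filter_peaks_by_q(chip$rep2))
  calls <- assign_binding_class(sim$genes, cp, "fac",
                                chrom_lengths = sim$chrom_sizes)
  expect_equal(as.character(calls$binding_class), chip$truth$binding_class)
  # classes partition the universe and counts sum to it
  expect_equal(sum(table(calls$binding_class)), length(sim$genes))
})

test_that("TSS-distance bins match gap arithmetic and a brute-force scan", {
  gm <- tiny_genes()
  # gA TSS 10000 inside a peak -> distance 0 -> first bin
  pk <- make_peaks("chr2L", 9950, 10050)
  bins <- classify_by_tss_distance(gm, pk, c(0, 100, 1000, 1e5))
  expect_equal(bins$distance[bins$gene_id == "gA"], 0)
  expect_equal(as.character(bins$bin[bins$gene_id == "gA"]), "[0,100)")
  # gap arithmetic: peak then TSS 500 bp past its edge
  genes <- data.frame(gene_id = "g", name = "g", biotype = "pc",
                      chrom = "c1", start = 1601L, end = 3000L,
                      strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = "g.t", gene_id = "g", chrom = "c1",
                   start = 1601L, end = 3000L, strand = "+",
                   stringsAsFactors = FALSE)
  one <- gene_models(genes, tx)
  pk2 <- make_peaks("c1", 1001, 1100)
  d <- classify_by_tss_distance(one, pk2, c(0, 100, 1000))
  expect_equal(d$distance, 500)
  expect_equal(as.character(d$bin), "[100,1000)")
  # random layout equals the exhaustive min-distance oracle
  sim <- simulate_genome(n_genes = 60, n_chroms = 1, chrom_length = 1.5e6,
                         seed = 31)
  set.seed(32)
  st <- sample.int(1.45e6, 150)
  pk3 <- make_peaks("chr1", st, st + 200)
  got <- classify_by_tss_distance(sim$genes, pk3, c(0, 1e7))
  tx3 <- sim$genes$transcripts
  for (g in sim$genes$genes$gene_id) {
    tsss <- tx3$tss[tx3$gene_id == g]
    oracle <- min(vapply(tsss, function(t)
      min(ifelse(t >= GenomicRanges::start(pk3) &
                   t <= GenomicRanges::end(pk3), 0,
                 pmin(abs(t - GenomicRanges::start(pk3)),
                      abs(t - GenomicRanges::end(pk3))) - 1)), 0))
    expect_equal(got$distance[got$gene_id == g], oracle)
  }
})

test_that("replicate correlation matches the textbook formula", {
  x <- c(1, 5, 3, 8, 2)
  expect_equal(replicate_correlation(x, x), 1)
  expect_equal(replicate_correlation(x, -x), -1)
  set.seed(8)
  mu <- runif(300, 10, 100)
  a <- mu + rnorm(300); b <- mu + rnorm(300)
  # independent textbook oracle
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(replicate_correlation(a, b), oracle, tolerance = 1e-12)
  expect_warning(r <- replicate_correlation(rep(1, 5), x), "zero variance")
  expect_true(is.na(r))
})
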