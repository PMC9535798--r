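make_binding <- function(ids, cls, fac = "fac") {
  out <- data.frame(gene_id = ids, factor = fac,
                    binding_class = factor(cls, levels = c(
                      "promoter", "nonpromoter_genic", "unbound")),
                    n_peaks = as.integer(cls != "unbound"),
                    supporting_peaks = ifelse(cls != "unbound", "p", ""),
                    min_tss_distance = ifelse(cls != "unbound", 0, NA),
                    stringsAsFactors = FALSE)
  class(out) <- c("binding_calls", "data.frame")
  out
}

make_de <- function(ids, cls) {
  out <- data.frame(gene_id = ids, base_mean = 10,
                    log2fc = ifelse(cls == "up", 2,
                                    ifelse(cls == "down", -2, 0)),
                    stat = 0, p_value = 0.5, q_value = 0.5,
                    expr_class = factor(cls, levels = c("up", "down",
                                                        "unchanged")),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  attr(out, "fdr_threshold") <- 0.01
  out
}

test_that("cross-classification enumerates the 3x3 table exactly", {
  b <- make_binding(c("g1", "g2", "g3", "g4"),
                    c("promoter", "promoter", "unbound",
                      "nonpromoter_genic"))
  e <- make_de(c("g1", "g2", "g3", "g4"),
               c("up", "unchanged", "up", "down"))
  rt <- cross_classify(b, e)
  expect_equal(unname(rt$counts),
               matrix(c(1L, 0L, 1L,   # up column
                        0L, 1L, 0L,   # down column
                        1L, 0L, 0L),  # unchanged column
                      3, 3))
  expect_equal(sum(rt$counts), rt$universe_size)
  # all unbound & unchanged: a single nonzero cell of size |universe|
  b2 <- make_binding(sprintf("g%d", 1:7), rep("unbound", 7))
  e2 <- make_de(sprintf("g%d", 1:7), rep("unchanged", 7))
  rt2 <- cross_classify(b2, e2)
  expect_equal(rt2$counts["unbound", "unchanged"], 7L)
  expect_equal(sum(rt2$counts), 7L)
  # permutation invariance of counts
  perm <- c(3, 1, 4, 2)
  rt3 <- cross_classify(b[perm, ], e[perm, ], universe = b$gene_id[perm])
  expect_equal(rt3$counts, rt$counts)
  # duplicates rejected; missing DE gene defaults to unchanged with message
  expect_error(cross_classify(rbind(b, b[1, ]), e), "duplicate")
  expect_message(rt4 <- cross_classify(b, e[-2, ]), "unchanged")
  expect_equal(rt4$counts["promoter", "unchanged"], 1L)
})

test_that("group percentages reproduce printed bookkeeping exactly", {
  # every (count, group, %) triple quoted in the study's results text
  triples <- rbind(
    c(8525, 13951, 61.1), c(7460, 13951, 53.5), c(1065, 13951, 7.6),
    c(5426, 13951, 38.9), c(1202, 7460, 16.1), c(1044, 7460, 14.0),
    c(7447, 13951, 53.4), c(827, 7447, 11.1), c(663, 7447, 8.9),
    c(5957, 7447, 80.0), c(924, 13951, 6.6), c(154, 924, 16.7),
    c(5580, 13951, 40.0), c(231, 5580, 4.1))
  expect_equal(percent_of_group(triples[, 1], triples[, 2]), triples[, 3])
  expect_equal(percent_of_group(0, 100), 0.0)
  expect_error(percent_of_group(1, 0), "positive")
  expect_error(percent_of_group(5, 4), "outside")
  # half-away-from-zero at one decimal: 13.995 rounds up to 14.0
  expect_equal(percent_of_group(1044, 7460), 14.0)
})

test_that("regulated gene sets take bound genes of the requested direction", {
  b <- make_binding(c("g1", "g2", "g3", "g4"),
                    c("promoter", "promoter", "unbound",
                      "nonpromoter_genic"))
  e <- make_de(c("g1", "g2", "g3", "g4"),
               c("up", "unchanged", "up", "down"))
  rt <- cross_classify(b, e)
  # bound & up: only g1 (the unbound upregulated g3 is excluded)
  expect_equal(regulated_gene_set(rt, "up"), "g1")
  expect_equal(regulated_gene_set(rt, "down"), "g4")
  # no unbound gene ever appears
  expect_false(any(c(regulated_gene_set(rt, "up"),
                     regulated_gene_set(rt, "down")) %in% "g3"))
  # planted bound-up genes are recovered exactly
  set.seed(44)
  n <- 400
  cls <- sample(c("promoter", "nonpromoter_genic", "unbound"), n, TRUE)
  ids <- sprintf("g%03d", seq_len(n))
  bound <- ids[cls != "unbound"]
  planted <- sample(bound, 50)
  ecls <- ifelse(ids %in% planted, "up", "unchanged")
  rt2 <- cross_classify(make_binding(ids, cls), make_de(ids, ecls))
  expect_setequal(regulated_gene_set(rt2, "up"), planted)
})

test_that("set overlaps reproduce the two-factor Venn arithmetic", {
  # 1443 vs 981 with 816 shared -> 627 and 165 exclusive
  a <- sprintf("g%04d", 1:1443)
  b <- c(sprintf("g%04d", 1:816), sprintf("h%03d", 1:165))
  ov <- overlap_sets(a, b)
  expect_length(ov$only_a, 627)
  expect_length(ov$shared, 816)
  expect_length(ov$only_b, 165)
  # disjointness and size bookkeeping
  expect_length(intersect(ov$only_a, ov$shared), 0)
  expect_length(intersect(ov$only_b, ov$shared), 0)
  expect_equal(length(ov$only_a) + length(ov$shared), length(unique(a)))
  # a = b: nothing exclusive
  same <- overlap_sets(a, a)
  expect_length(same$only_a, 0)
  expect_length(same$only_b, 0)
  # random sets against a brute-force membership scan
  set.seed(66)
  x <- sample(letters, 15); y <- sample(letters, 12)
  ov2 <- overlap_sets(x, y)
  expect_setequal(ov2$shared, x[vapply(x, `%in%`, TRUE, y)])
  expect_setequal(ov2$only_a, x[!vapply(x, `%in%`, TRUE, y)])
  expect_setequal(ov2$only_b, y[!vapply(y, `%in%`, TRUE, x)])
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  uni <- sprintf("g%02d", 1:20)
  # query = term = universe: overlap forced, p = 1
  full <- hypergeometric_enrichment(uni, list(t = uni), uni)
  expect_equal(full$p_value, 1)
  # universe 20, term 5, query 5, overlap 5: p = 1/C(20,5)
  res <- hypergeometric_enrichment(uni[1:5], list(t = uni[1:5]), uni)
  expect_equal(res$p_value, 1 / choose(20, 5))
  # random annotation vs direct combinatorial enumeration of the tail
  set.seed(21)
  for (i in 1:20) {
    N <- sample(8:20, 1)
    u <- sprintf("u%02d", seq_len(N))
    K <- sample.int(N, 1); n <- sample.int(N, 1)
    term <- sample(u, K); query <- sample(u, n)
    k <- length(intersect(term, query))
    oracle <- sum(vapply(k:min(K, n), function(i)
      choose(K, i) * choose(N - K, n - i), 0)) / choose(N, n)
    got <- hypergeometric_enrichment(query, list(t = term), u)
    expect_equal(got$p_value, oracle, tolerance = 1e-12)
    expect_true(got$p_value > 0 && got$p_value <= 1)
  }
  # zero-membership terms skipped; BH agrees with bh_adjust
  many <- hypergeometric_enrichment(
    uni[1:6], list(a = uni[1:5], b = uni[6:15], c = "absent"), uni)
  expect_equal(nrow(many), 2)
  expect_equal(many$q_value, bh_adjust(many$p_value))
  expect_error(hypergeometric_enrichment("zzz", list(a = uni), uni),
               "outside the universe")
})

test_that("spheroid lobe volume follows V = 4/3 pi a b^2", {
  expect_equal(ellipsoid_volume(1, 1), 4 * pi / 3)
  expect_equal(ellipsoid_volume(3, 2), 16 * pi)
  expect_equal(ellipsoid_volume(5, 0), 0)
  expect_error(ellipsoid_volume(-1, 1), "non-negative")
})
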