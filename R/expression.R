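#' Count matrix container
#'
#' Bundles a gene x sample matrix of raw counts with per-sample condition
#' labels and library sizes (total mapped reads; at least the column sums
#' of the counted genes).
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param condition Factor or character vector of condition labels, one per
#'   sample.
#' @param library_sizes Optional numeric vector of total mapped reads per
#'   sample; defaults to the column sums.
#' @return An object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, condition,
                         library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            length(condition) == ncol(counts),
            length(library_sizes) == ncol(counts))
  if (any(counts < 0)) stop("negative counts")
  if (any(library_sizes < colSums(counts) - 1e-8))
    stop("library_sizes smaller than column count sums")
  structure(list(counts = counts,
                 condition = setNames(as.character(condition),
                                      colnames(counts)),
                 library_sizes = setNames(as.numeric(library_sizes),
                                          colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x$counts),
              ncol(x$counts)))
  cat("  conditions:", paste(sprintf("%s (n=%d)",
      names(table(x$condition)), table(x$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and condition map from TSV
#'
#' The counts file is genes x samples with a header row of sample ids and
#' gene ids in the first column; the condition map is a two-column TSV
#' (sample_id, condition) with header.
#'
#' @param counts_path Path to the counts TSV.
#' @param conditions_path Path to the condition map TSV.
#' @return A \code{\link{count_matrix}}.
#' @export
read_counts_tsv <- function(counts_path, conditions_path) {
  tab <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE,
                           comment.char = "#")
  cond <- utils::read.table(conditions_path, header = TRUE, sep = "\t",
                            check.names = FALSE, comment.char = "#",
                            colClasses = "character")
  if (!all(colnames(tab) %in% cond[[1]]))
    stop("condition map missing samples: ",
         paste(setdiff(colnames(tab), cond[[1]]), collapse = ", "))
  count_matrix(as.matrix(tab),
               cond[[2]][match(colnames(tab), cond[[1]])])
}

#' Reads per million mapped reads
#'
#' \code{RPM = count * 1e6 / library_size}.
#'
#' @param x A \code{count_matrix}.
#' @return Numeric matrix of RPM values, same shape as the counts.
#' @export
rpm_normalize <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (any(x$library_sizes <= 0)) stop("zero library size")
  sweep(x$counts, 2, x$library_sizes, "/") * 1e6
}

#' Fragments per kilobase of transcript per million mapped reads
#'
#' \code{FPKM = count * 1e9 / (library_size * gene_length)}, so that
#' \code{FPKM * length/1000 = RPM} gene by gene.
#'
#' @param x A \code{count_matrix}.
#' @param gene_lengths Named numeric vector of gene lengths (bp) covering
#'   every gene in the matrix.
#' @return Numeric matrix of FPKM values.
#' @export
fpkm <- function(x, gene_lengths) {
  stopifnot(inherits(x, "count_matrix"))
  len <- gene_lengths[rownames(x$counts)]
  if (anyNA(len)) stop("gene_lengths missing: ",
                       paste(utils::head(rownames(x$counts)[is.na(len)], 5),
                             collapse = ", "))
  if (any(len <= 0)) stop("non-positive gene length")
  rpm_normalize(x) * 1e3 / as.numeric(len)
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalisation: each sample's size factor is the median ratio
#' of its counts to the per-gene geometric means, over genes with finite
#' geometric means. When no gene is expressed in every sample (degenerate
#' geometric means), the fall-back is library-size scaling normalised to a
#' geometric mean of 1.
#'
#' @param counts Non-negative count matrix (genes x samples).
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) {
    ls <- colSums(counts)
    if (any(ls == 0)) stop("sample with all-zero counts")
    return(ls / exp(mean(log(ls))))
  }
  apply(counts, 2, function(cnt)
    exp(stats::median((log(cnt) - logg)[use & cnt > 0])))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per gene and per condition, \code{alpha = (var - mean) / mean^2} on
#' normalised counts (the NB relationship \code{var = mu + alpha mu^2}
#' solved for alpha), floored at \code{alpha_floor}; per-gene values are
#' pooled across conditions by a normalised-count-weighted average. Genes
#' with all-zero counts get \code{NA} and are excluded from testing.
#'
#' @param norm_counts Matrix of normalised counts (genes x samples).
#' @param condition Condition label per sample (each condition needs >= 2
#'   replicates).
#' @param alpha_floor Lower bound for alpha (default 1e-8).
#' @return Numeric vector of dispersions, one per gene (NA for all-zero
#'   genes).
#' @export
estimate_dispersion <- function(norm_counts, condition, alpha_floor = 1e-8) {
  norm_counts <- as.matrix(norm_counts)
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(norm_counts))
  conds <- unique(condition)
  if (any(table(condition) < 2))
    stop("each condition needs at least 2 replicates")
  alpha_c <- matrix(NA_real_, nrow(norm_counts), length(conds))
  wt <- matrix(0, nrow(norm_counts), length(conds))
  for (j in seq_along(conds)) {
    sub <- norm_counts[, condition == conds[j], drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    a <- pmax(alpha_floor, (v - m) / m^2)
    a[m == 0] <- NA_real_
    alpha_c[, j] <- a
    wt[, j] <- rowSums(sub)
  }
  num <- rowSums(alpha_c * wt, na.rm = TRUE)
  den <- rowSums(wt * !is.na(alpha_c))
  alpha <- ifelse(den > 0, pmax(alpha_floor, num / den), NA_real_)
  alpha[rowSums(norm_counts) == 0] <- NA_real_
  unname(alpha)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone in rank,
#' stable under ties). NAs are passed through unadjusted and do not count
#' toward the number of tests.
#'
#' @param p Numeric vector of p-values in [0, 1] (NAs allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test of knockdown versus control
#'
#' A documented simplification of the DESeq2-style analysis. Counts are
#' normalised with median-of-ratios size factors
#' (\code{\link{size_factors}}); per-gene dispersions come from
#' \code{\link{estimate_dispersion}} and, with few replicates, are
#' moderated by flooring each gene's estimate at the across-gene median of
#' the informative (above-floor) estimates - the small-sample stabilisation
#' in the spirit of dispersion sharing, without which a Wald z with a
#' 3-versus-3 method-of-moments variance is anticonservative. The log2 fold
#' change is \code{log2((mean_B + pc) / (mean_A + pc))} with pseudocount
#' \code{pc}; its standard error propagates the NB variance
#' \code{mu + alpha mu^2} of each group mean through the log-ratio (delta
#' method), giving a Wald z and a two-sided normal p-value. Genes with all
#' zero counts are flagged (NA p) and excluded from the BH adjustment.
#'
#' Classification: \code{up} iff \code{q < fdr_threshold} and
#' \code{log2fc > 0}; \code{down} iff \code{q < fdr_threshold} and
#' \code{log2fc < 0}; everything else \code{unchanged} (no extra
#' fold-change cutoff).
#'
#' @param x A \code{count_matrix}.
#' @param group_a Sample ids (or a condition label) of the reference group,
#'   e.g. control.
#' @param group_b Sample ids (or a condition label) of the contrast group,
#'   e.g. knockdown.
#' @param fdr_threshold FDR threshold for up/down classification (default
#'   0.01).
#' @param pseudocount Pseudocount for fold changes of zero-count genes
#'   (default 0.5).
#' @param moderate_dispersion Floor per-gene dispersions at the across-gene
#'   median of informative estimates (default TRUE).
#' @param alpha_floor Dispersion floor passed to
#'   \code{\link{estimate_dispersion}}.
#' @return A data.frame of class \code{de_result}: \code{gene_id},
#'   \code{base_mean} (mean normalised count over both groups),
#'   \code{log2fc} (B over A), \code{stat} (Wald z), \code{p_value},
#'   \code{q_value}, \code{expr_class} (factor: up, down, unchanged).
#'   Attributes record the groups and thresholds.
#' @export
de_test <- function(x, group_a, group_b, fdr_threshold = 0.01,
                    pseudocount = 0.5, moderate_dispersion = TRUE,
                    alpha_floor = 1e-8) {
  stopifnot(inherits(x, "count_matrix"))
  resolve <- function(g) {
    if (all(g %in% colnames(x$counts))) return(g)
    hit <- names(x$condition)[x$condition %in% g]
    if (length(hit) == 0) stop("unknown samples or condition: ",
                               paste(g, collapse = ", "))
    hit
  }
  a <- resolve(group_a); b <- resolve(group_b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 samples")
  if (length(intersect(a, b))) stop("groups overlap")
  cnt <- x$counts[, c(a, b), drop = FALSE]
  sf <- size_factors(cnt)
  norm <- sweep(cnt, 2, sf, "/")
  cond <- rep(c("A", "B"), c(length(a), length(b)))
  alpha <- estimate_dispersion(norm, cond, alpha_floor = alpha_floor)
  if (moderate_dispersion) {
    informative <- alpha[!is.na(alpha) & alpha > alpha_floor * 1.01]
    prior <- if (length(informative)) stats::median(informative) else 0
    alpha <- pmax(alpha, prior)
  }
  muA <- rowMeans(norm[, cond == "A", drop = FALSE])
  muB <- rowMeans(norm[, cond == "B", drop = FALSE])
  nA <- sum(cond == "A"); nB <- sum(cond == "B")
  log2fc <- log2((muB + pseudocount) / (muA + pseudocount))
  varA <- (muA + alpha * muA^2) / nA
  varB <- (muB + alpha * muB^2) / nB
  se2 <- (varA / (muA + pseudocount)^2 + varB / (muB + pseudocount)^2) /
    log(2)^2
  z <- ifelse(se2 > 0, log2fc / sqrt(se2), 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[is.na(alpha)] <- NA_real_  # all-zero genes: flagged, not tested
  q <- bh_adjust(p)
  cls <- rep("unchanged", nrow(cnt))
  cls[!is.na(q) & q < fdr_threshold & log2fc > 0] <- "up"
  cls[!is.na(q) & q < fdr_threshold & log2fc < 0] <- "down"
  out <- data.frame(
    gene_id = rownames(cnt),
    base_mean = (muA * nA + muB * nB) / (nA + nB),
    log2fc = log2fc,
    stat = z,
    p_value = p,
    q_value = q,
    expr_class = factor(cls, levels = c("up", "down", "unchanged")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "group_a") <- a
  attr(out, "group_b") <- b
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf(
    "de_result: %d genes tested (%d not testable), FDR threshold %g\n",
    sum(!is.na(x$p_value)), sum(is.na(x$p_value)),
    attr(x, "fdr_threshold")))
  tab <- table(x$expr_class)
  cat(sprintf("  up %d, down %d, unchanged %d\n",
              tab[["up"]], tab[["down"]], tab[["unchanged"]]))
  invisible(x)
}

#' @export
#' @method summary de_result
summary.de_result <- function(object, ...) {
  cat(sprintf("Differential expression: %s vs %s\n",
              paste(attr(object, "group_b"), collapse = ","),
              paste(attr(object, "group_a"), collapse = ",")))
  print.de_result(object)
  sig <- object[!is.na(object$q_value) &
                object$q_value < attr(object, "fdr_threshold"), ]
  sig <- sig[order(sig$q_value), ]
  if (nrow(sig)) {
    cat("Top genes by q-value:\n")
    print(utils::head(as.data.frame(sig)[, c("gene_id", "base_mean",
                                             "log2fc", "q_value")], 10),
          digits = 4)
  }
  invisible(object)
}

#' Write differential-expression results to TSV
#'
#' @param de A \code{de_result}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_de_results <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
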