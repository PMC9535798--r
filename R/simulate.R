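#' Seeded synthetic gene annotation
#'
#' Generates a toy genome of non-overlapping protein-coding genes:
#' lengths log-uniform between \code{len_range} (1-20 kb by default, the
#' bulk of fly gene lengths), strands Bernoulli(0.5), a minimum intergenic
#' gap, and 1-3 transcripts per gene whose extra TSSs jitter at most
#' \code{tss_jitter} bp into the gene. Fully deterministic for a given
#' seed.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_chroms Number of chromosomes (default 4).
#' @param chrom_length Length of each chromosome in bp (default 5.5e6).
#' @param min_gap Minimum intergenic gap in bp (default 1000).
#' @param len_range Gene length range in bp, sampled log-uniformly
#'   (default c(1000, 20000)).
#' @param max_transcripts Maximum transcripts per gene (default 3).
#' @param tss_jitter Maximum 5' offset of secondary transcripts (default
#'   200 bp).
#' @param seed Integer seed.
#' @return A list of class \code{synthetic_genome}: \code{genes} (a
#'   \code{\link{gene_models}}), \code{chrom_sizes} (named vector), and
#'   \code{params}.
#' @export
simulate_genome <- function(n_genes = 2000, n_chroms = 4,
                            chrom_length = 5.5e6, min_gap = 1000,
                            len_range = c(1000, 20000),
                            max_transcripts = 3, tss_jitter = 200,
                            seed = 1) {
  stopifnot(n_genes >= 0, n_chroms >= 1, chrom_length > 0)
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chroms))
  chrom_sizes <- setNames(rep(as.integer(chrom_length), n_chroms), chroms)
  per <- diff(round(seq(0, n_genes, length.out = n_chroms + 1)))
  grows <- list(); trows <- list(); gi <- 0
  for (ci in seq_len(n_chroms)) {
    k <- per[ci]
    if (k == 0) next
    len <- round(exp(stats::runif(k, log(len_range[1]), log(len_range[2]))))
    need <- sum(len) + (k + 1) * min_gap
    if (need > chrom_length)
      stop(sprintf(
        "cannot place %d genes of total length %d on a %d bp chromosome; increase chrom_length or reduce n_genes",
        k, sum(len), as.integer(chrom_length)))
    slack <- chrom_length - need
    extra <- floor(slack * diff(c(0, sort(stats::runif(k)), 1)))[seq_len(k)]
    gaps <- min_gap + extra
    starts <- cumsum(gaps + c(0, len[-k])) + 1
    strand <- ifelse(stats::runif(k) < 0.5, "+", "-")
    for (j in seq_len(k)) {
      gi <- gi + 1
      id <- sprintf("SYNG%05d", gi)
      s <- as.integer(starts[j]); e <- as.integer(starts[j] + len[j] - 1)
      grows[[gi]] <- data.frame(
        gene_id = id, name = id, biotype = "protein_coding",
        chrom = chroms[ci], start = s, end = e, strand = strand[j],
        stringsAsFactors = FALSE)
      ntx <- sample.int(max_transcripts, 1)
      txs <- data.frame(
        transcript_id = sprintf("%s.t%d", id, seq_len(ntx)),
        gene_id = id, chrom = chroms[ci],
        start = s, end = e, strand = strand[j],
        stringsAsFactors = FALSE)
      if (ntx > 1) {
        jit <- sample.int(tss_jitter + 1, ntx - 1, replace = TRUE) - 1
        if (strand[j] == "+") txs$start[-1] <- s + jit
        else txs$end[-1] <- e - jit
      }
      trows[[length(trows) + 1]] <- txs
    }
  }
  genes <- if (gi == 0) {
    empty_g <- data.frame(gene_id = character(0), name = character(0),
                          biotype = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0))
    empty_t <- data.frame(transcript_id = character(0), gene_id = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0))
    empty_t$tss <- integer(0); empty_t$tes <- integer(0)
    structure(list(genes = empty_g, transcripts = empty_t),
              class = "gene_models")
  } else {
    gene_models(do.call(rbind, grows), do.call(rbind, trows))
  }
  structure(list(genes = genes, chrom_sizes = chrom_sizes,
                 params = list(n_genes = n_genes, n_chroms = n_chroms,
                               chrom_length = chrom_length,
                               min_gap = min_gap, len_range = len_range,
                               max_transcripts = max_transcripts,
                               tss_jitter = tss_jitter, seed = seed)),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d genes on %d chromosome(s) of %g bp (seed %d)\n",
              nrow(x$genes$genes), length(x$chrom_sizes),
              x$params$chrom_length, x$params$seed))
  invisible(x)
}

# uniform positions within a set of intervals, weighted by width
.sample_in_intervals <- function(n, starts, ends) {
  w <- ends - starts + 1
  if (n == 0 || length(w) == 0 || sum(w) <= 0) return(integer(0))
  iv <- sample.int(length(w), n, replace = TRUE, prob = w)
  starts[iv] + floor(stats::runif(n) * w[iv])
}

#' Seeded synthetic ChIP peak replicates with planted binding classes
#'
#' Plants a binding class per gene mirroring the promoter / nonpromoter
#' genic / unbound structure: promoter-class genes receive a peak centred
#' near a transcript TSS (overlapping a promoter window) in both
#' replicates; genic-class genes a peak inside the gene span clear of all
#' of the gene's own promoter windows; unbound genes none. Replicates
#' differ by a bounded positional jitter. Noise peaks are drawn
#' independently per replicate as a Poisson process over intergenic space
#' (so they rarely survive common-peak reconciliation), and a few
#' "artifact" peaks with -log10(q) above 100 are planted identically in
#' both replicates, in intergenic space clear of promoter windows, to
#' exercise the q-value filter. -log10(q) scores of genuine peaks are
#' gamma(4, scale 8) capped at 99; noise peaks gamma(2, scale 5).
#'
#' @param genome A \code{synthetic_genome}.
#' @param factor_name Factor label (default "factorA").
#' @param frac_promoter,frac_genic Planted class fractions (defaults 0.535
#'   and 0.076, the promoter/genic binding rates reported for the 13,951
#'   fly protein-coding genes; must sum to <= 1).
#' @param noise_peaks_per_mb Poisson rate of intergenic noise peaks per
#'   megabase per replicate (default 5).
#' @param peak_width Width range in bp (default c(150, 400)).
#' @param replicate_jitter Maximum per-replicate positional shift in bp
#'   (default 20).
#' @param n_artifact Number of planted hyper-significant artifact peaks
#'   (default 2).
#' @param seed Integer seed.
#' @return A list of class \code{synthetic_chip}: \code{rep1}, \code{rep2}
#'   (peak \code{GRanges}), \code{truth} (data.frame gene_id,
#'   binding_class), \code{factor}, \code{params}.
#' @export
simulate_chip <- function(genome, factor_name = "factorA",
                          frac_promoter = 0.535, frac_genic = 0.076,
                          noise_peaks_per_mb = 5,
                          peak_width = c(150, 400), replicate_jitter = 20,
                          n_artifact = 2, seed = 1) {
  stopifnot(inherits(genome, "synthetic_genome"),
            frac_promoter + frac_genic <= 1)
  set.seed(seed)
  g <- genome$genes$genes
  n <- nrow(g)
  n_prom <- round(frac_promoter * n)
  n_gen <- round(frac_genic * n)
  perm <- sample.int(n)
  cls <- rep("unbound", n)
  cls[perm[seq_len(n_prom)]] <- "promoter"
  if (n_gen > 0) cls[perm[n_prom + seq_len(n_gen)]] <- "nonpromoter_genic"
  prom <- promoter_windows(genome$genes, chrom_lengths = genome$chrom_sizes)
  wmin <- peak_width[1]; wmax <- peak_width[2]
  margin <- replicate_jitter + 1
  base <- list()  # peaks shared by construction between replicates
  for (i in which(cls != "unbound")) {
    own <- prom[prom$gene_id == g$gene_id[i]]
    w <- round(stats::runif(1, wmin, wmax))
    if (cls[i] == "promoter") {
      tss <- genome$genes$transcripts$tss[
        genome$genes$transcripts$gene_id == g$gene_id[i]][1]
      center <- tss + round(stats::runif(1, -50, 50))
      s <- center - w %/% 2
    } else {
      # body region clear of the gene's own promoter windows
      if (g$strand[i] == "+") {
        lo <- max(GenomicRanges::end(own)) + margin
        hi <- g$end[i]
      } else {
        lo <- g$start[i]
        hi <- min(GenomicRanges::start(own)) - margin
      }
      avail <- hi - lo + 1
      if (avail < 2 * margin + 30) {  # degenerate short gene: demote
        cls[i] <- "unbound"
        next
      }
      w <- min(w, avail - 2 * margin)
      s <- lo + margin + floor(stats::runif(1) * (avail - w - 2 * margin))
    }
    base[[length(base) + 1]] <- data.frame(
      chrom = g$chrom[i], start = s, width = w,
      q = min(stats::rgamma(1, shape = 4, scale = 8), 99),
      stringsAsFactors = FALSE)
  }
  base <- if (length(base)) do.call(rbind, base) else
    data.frame(chrom = character(0), start = integer(0), width = integer(0),
               q = numeric(0))
  # intergenic space per chromosome (complement of gene spans)
  intergenic <- lapply(setNames(nm = names(genome$chrom_sizes)), function(ch) {
    sp <- g[g$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(sp$start, sp$end)
    gaps <- IRanges::gaps(ir, start = 1, end = genome$chrom_sizes[[ch]])
    data.frame(start = IRanges::start(gaps), end = IRanges::end(gaps))
  })
  # artifact peaks: intergenic, clear of promoter windows, same in both reps
  artifacts <- list()
  if (n_artifact > 0) {
    for (a in seq_len(n_artifact)) {
      ch <- sample(names(genome$chrom_sizes), 1)
      iv <- intergenic[[ch]]
      wide <- iv[iv$end - iv$start + 1 > 2000, , drop = FALSE]
      if (nrow(wide) == 0) next
      pos <- .sample_in_intervals(1, wide$start + 800, wide$end - 800)
      artifacts[[a]] <- data.frame(
        chrom = ch, start = pos, width = round(stats::runif(1, wmin, wmax)),
        q = stats::runif(1, 150, 300), stringsAsFactors = FALSE)
    }
  }
  artifacts <- if (length(artifacts)) do.call(rbind, artifacts) else NULL
  mk_rep <- function(repname) {
    jit <- sample.int(2 * replicate_jitter + 1, nrow(base), replace = TRUE) -
      replicate_jitter - 1
    pk <- data.frame(chrom = base$chrom, start = base$start + jit,
                     width = base$width, q = base$q)
    # independent intergenic noise for this replicate
    noise <- do.call(rbind, lapply(names(intergenic), function(ch) {
      iv <- intergenic[[ch]]
      mb <- sum(iv$end - iv$start + 1) / 1e6
      nn <- stats::rpois(1, noise_peaks_per_mb * mb)
      if (nn == 0) return(NULL)
      data.frame(chrom = ch,
                 start = .sample_in_intervals(nn, iv$start, iv$end),
                 width = round(stats::runif(nn, wmin, wmax)),
                 q = pmin(stats::rgamma(nn, shape = 2, scale = 5), 99))
    }))
    pk <- rbind(pk, noise, artifacts)
    pk$start <- pmax(1L, as.integer(pk$start))
    ends <- pmin(as.integer(pk$start + pk$width - 1),
                 genome$chrom_sizes[pk$chrom])
    gr <- GenomicRanges::GRanges(pk$chrom,
                                 IRanges::IRanges(pk$start, ends))
    gr$name <- sprintf("%s_%s_p%d", factor_name, repname,
                       seq_along(gr))
    gr$score <- round(stats::runif(length(gr), 20, 1000))
    gr$signalValue <- round(stats::runif(length(gr), 5, 50), 3)
    gr$pValue <- round(pk$q + 2, 3)
    gr$qValue <- round(pk$q, 3)
    gr$peak <- as.integer(pk$width %/% 2)
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    S4Vectors::metadata(gr)$label <- paste(factor_name, repname, sep = "_")
    gr
  }
  rep1 <- mk_rep("rep1")
  rep2 <- mk_rep("rep2")
  structure(list(
    rep1 = rep1, rep2 = rep2,
    truth = data.frame(gene_id = g$gene_id, binding_class = cls,
                       stringsAsFactors = FALSE),
    factor = factor_name,
    params = list(frac_promoter = frac_promoter, frac_genic = frac_genic,
                  noise_peaks_per_mb = noise_peaks_per_mb,
                  peak_width = peak_width,
                  replicate_jitter = replicate_jitter,
                  n_artifact = n_artifact, seed = seed)),
    class = "synthetic_chip")
}

#' Plant knockdown effects on bound genes
#'
#' The derepression rule: a fraction of the genes bound by the factor
#' (promoter or nonpromoter genic) are planted as upregulated upon
#' knockdown (log2 fold change \code{+effect_log2fc}), a fraction as
#' downregulated (\code{-effect_log2fc}); unbound genes and the remaining
#' bound genes are unaffected. Default fractions 0.16 up / 0.14 down echo
#' the response rates observed among promoter-bound genes.
#'
#' @param binding_truth Data.frame with \code{gene_id} and
#'   \code{binding_class} (as in \code{synthetic_chip$truth}).
#' @param frac_up,frac_down Fractions of bound genes planted up/down
#'   (defaults 0.16, 0.14).
#' @param effect_log2fc Magnitude of the planted effect (default 2, i.e.
#'   4-fold).
#' @param seed Integer seed.
#' @return Named numeric vector of planted log2 fold changes (KD over
#'   control), one per gene.
#' @export
plant_effects <- function(binding_truth, frac_up = 0.16, frac_down = 0.14,
                          effect_log2fc = 2, seed = 1) {
  stopifnot(frac_up + frac_down <= 1)
  set.seed(seed)
  lfc <- setNames(numeric(nrow(binding_truth)), binding_truth$gene_id)
  bound <- binding_truth$gene_id[
    binding_truth$binding_class %in% c("promoter", "nonpromoter_genic")]
  n_up <- round(frac_up * length(bound))
  n_dn <- round(frac_down * length(bound))
  perm <- sample(bound)
  lfc[perm[seq_len(n_up)]] <- effect_log2fc
  if (n_dn > 0) lfc[perm[n_up + seq_len(n_dn)]] <- -effect_log2fc
  lfc
}

#' Seeded synthetic RNA-seq counts for control and knockdown
#'
#' Counts are negative binomial with mean \code{baseline * 2^(lfc)} in the
#' knockdown samples and \code{baseline} in controls, scaled per sample by
#' a library-size factor drawn uniformly from \code{libsize_range};
#' baselines are log-normal. The NB size parameter is \code{1/alpha}.
#'
#' @param log2fc Named vector of planted log2 fold changes (names = gene
#'   ids).
#' @param n_rep Replicates per condition (default 3).
#' @param alpha NB dispersion (default 0.05).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters
#'   (defaults log(150) and 1).
#' @param baselines Optional explicit baseline means (overrides the
#'   log-normal draw; recycled names must match \code{log2fc}).
#' @param libsize_range Per-sample scaling factor range (default
#'   c(0.8, 1.25)).
#' @param condition_labels Length-2 labels (default c("control", "kd")).
#' @param seed Integer seed.
#' @return A \code{\link{count_matrix}} with \code{2 n_rep} samples and an
#'   attribute \code{truth} holding the planted log2fc and baselines.
#' @export
simulate_counts <- function(log2fc, n_rep = 3, alpha = 0.05,
                            baseline_meanlog = log(150),
                            baseline_sdlog = 1, baselines = NULL,
                            libsize_range = c(0.8, 1.25),
                            condition_labels = c("control", "kd"),
                            seed = 1) {
  stopifnot(!is.null(names(log2fc)), n_rep >= 2)
  set.seed(seed)
  ng <- length(log2fc)
  if (is.null(baselines))
    baselines <- stats::rlnorm(ng, baseline_meanlog, baseline_sdlog)
  stopifnot(length(baselines) == ng)
  sfs <- stats::runif(2 * n_rep, libsize_range[1], libsize_range[2])
  cond <- rep(condition_labels, each = n_rep)
  # mu[g, j] = baseline_g * 2^(lfc_g * is_kd_j) * sf_j
  mu <- vapply(seq_len(2 * n_rep), function(j) {
    eff <- if (cond[j] == condition_labels[2]) 2^log2fc else rep(1, ng)
    baselines * eff * sfs[j]
  }, numeric(ng))
  counts <- matrix(stats::rnbinom(ng * 2 * n_rep, mu = mu, size = 1 / alpha),
                   ng, 2 * n_rep)
  rownames(counts) <- names(log2fc)
  colnames(counts) <- sprintf("%s_%d", cond, rep(seq_len(n_rep), 2))
  cm <- count_matrix(counts, cond)
  attr(cm, "truth") <- list(log2fc = log2fc, baselines = baselines,
                            alpha = alpha, sample_factors = sfs, seed = seed)
  cm
}

#' Seeded synthetic co-IP quantification table
#'
#' Builds a protein table shaped like the co-IP candidate funnel: planted
#' interactors pass both thresholds (control/KD abundance ratio > 4, PSM
#' >= 2), a stated number of them flagged ribosomal or bait so the
#' exclusion step is exercised, and background proteins whose ratios are
#' log-normal around 1 and capped below the threshold. A stated number of
#' the unflagged interactors carry target annotation categories
#' ("DNA binding" / "chromatin regulation"); the rest are "other".
#'
#' @param n_background Background proteins (default 79).
#' @param n_interactors Threshold-passing proteins (default 21).
#' @param n_ribosomal_passing Ribosomal-flagged among the interactors
#'   (default 3).
#' @param n_bait_passing Bait records among the interactors (default 1).
#' @param n_target_annotated Unflagged interactors with target categories
#'   (default 7).
#' @param n_zero_kd Interactors detected only in the control (KD abundance
#'   0; default 2).
#' @param seed Integer seed.
#' @return A list of class \code{synthetic_quant}: \code{table} (shaped as
#'   \code{\link{read_protein_quant}} output) and \code{truth} (planted
#'   interactor and annotated ids).
#' @export
simulate_quant_table <- function(n_background = 79, n_interactors = 21,
                                 n_ribosomal_passing = 3,
                                 n_bait_passing = 1,
                                 n_target_annotated = 7, n_zero_kd = 2,
                                 seed = 1) {
  stopifnot(n_ribosomal_passing + n_bait_passing <= n_interactors,
            n_target_annotated <=
              n_interactors - n_ribosomal_passing - n_bait_passing)
  set.seed(seed)
  ni <- n_interactors; nb <- n_background
  id <- c(sprintf("INT%03d", seq_len(ni)), sprintf("BG%03d", seq_len(nb)))
  is_int <- c(rep(TRUE, ni), rep(FALSE, nb))
  ctrl <- stats::rlnorm(ni + nb, log(1e6), 1.2)
  ratio <- numeric(ni + nb)
  ratio[is_int] <- stats::runif(ni, 4.5, 30)
  ratio[!is_int] <- pmin(stats::rlnorm(nb, 0, 0.5), 3.9)
  kd <- ctrl / ratio
  if (n_zero_kd > 0) kd[seq_len(n_zero_kd)] <- 0
  psm <- integer(ni + nb)
  psm[is_int] <- sample(2:40, ni, replace = TRUE)
  psm[!is_int] <- sample(0:40, nb, replace = TRUE)
  flags_r <- rep(FALSE, ni + nb); flags_b <- rep(FALSE, ni + nb)
  fl <- sample.int(ni, n_ribosomal_passing + n_bait_passing)
  if (n_ribosomal_passing > 0) flags_r[fl[seq_len(n_ribosomal_passing)]] <- TRUE
  if (n_bait_passing > 0)
    flags_b[fl[n_ribosomal_passing + seq_len(n_bait_passing)]] <- TRUE
  # a few ribosomal proteins among the background too
  nrb <- min(5L, nb)
  flags_r[ni + sample.int(nb, nrb)] <- TRUE
  cats <- rep("other", ni + nb)
  unflagged <- which(is_int & !flags_r & !flags_b)
  ann <- sample(unflagged, n_target_annotated)
  cats[ann] <- sample(c("DNA binding", "chromatin regulation"),
                      n_target_annotated, replace = TRUE)
  tab <- data.frame(
    protein_id = id,
    sum_pep_score = round(stats::runif(ni + nb, 5, 600), 2),
    psm = psm,
    abundance_control = round(ctrl, 1),
    abundance_kd = round(kd, 1),
    is_ribosomal = flags_r,
    is_bait = flags_b,
    stringsAsFactors = FALSE)
  tab$categories <- as.list(cats)
  structure(list(
    table = tab,
    truth = list(interactors = id[is_int & !flags_r & !flags_b],
                 target_annotated = id[ann],
                 params = list(n_background = n_background,
                               n_interactors = n_interactors,
                               n_ribosomal_passing = n_ribosomal_passing,
                               n_bait_passing = n_bait_passing,
                               n_target_annotated = n_target_annotated,
                               n_zero_kd = n_zero_kd, seed = seed))),
    class = "synthetic_quant")
}

#' Write a protein quantification table to TSV
#'
#' @param tab Data.frame shaped as \code{\link{read_protein_quant}} output.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_protein_quant <- function(tab, path) {
  out <- tab
  out$categories <- vapply(out$categories, paste, "", collapse = ";")
  out$is_ribosomal <- as.integer(out$is_ribosomal)
  out$is_bait <- as.integer(out$is_bait)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate and write a complete synthetic study
#'
#' Emulates the deposited study structure at desk scale: one gene
#' annotation; for each of two chromatin factors, duplicate ChIP peak
#' replicates (narrowPeak) plus a coverage bedGraph; one RNA-seq count
#' matrix with triplicate control and triplicate knockdown samples per
#' factor; one co-IP quantification table; and the full planted truth.
#' Everything is deterministic in \code{seed}.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param n_genes,n_chroms,chrom_length Passed to
#'   \code{\link{simulate_genome}}.
#' @param factors Length-2 character vector of factor names (default
#'   c("factorA", "factorB")).
#' @param frac_promoter,frac_genic,noise_peaks_per_mb Passed to
#'   \code{\link{simulate_chip}}.
#' @param frac_up,frac_down,effect_log2fc Passed to
#'   \code{\link{plant_effects}}.
#' @param alpha NB dispersion of the simulated counts (default 0.05).
#' @param n_rep RNA-seq replicates per condition (default 3).
#' @param write Write the study files (default TRUE); with FALSE only the
#'   in-memory objects are returned.
#' @return Invisibly, a list of class \code{synthetic_study} with elements
#'   \code{genome}, \code{chip} (per factor), \code{counts}
#'   (\code{count_matrix} over all conditions), \code{quant},
#'   \code{truth}, \code{paths} and \code{config} (a \code{\link{run_study}}
#'   configuration).
#' @export
simulate_study <- function(dir, seed = 1, n_genes = 2000, n_chroms = 4,
                           chrom_length = 5.5e6,
                           factors = c("factorA", "factorB"),
                           frac_promoter = 0.535, frac_genic = 0.076,
                           noise_peaks_per_mb = 5, frac_up = 0.16,
                           frac_down = 0.14, effect_log2fc = 2,
                           alpha = 0.05, n_rep = 3, write = TRUE) {
  stopifnot(length(factors) == 2)
  dseed <- function(k) (seed + k) %% 2147483647L
  genome <- simulate_genome(n_genes = n_genes, n_chroms = n_chroms,
                            chrom_length = chrom_length, seed = dseed(0))
  chip <- list(); lfc <- list()
  for (i in seq_along(factors)) {
    chip[[factors[i]]] <- simulate_chip(
      genome, factors[i], frac_promoter = frac_promoter,
      frac_genic = frac_genic, noise_peaks_per_mb = noise_peaks_per_mb,
      seed = dseed(i))
    lfc[[factors[i]]] <- plant_effects(
      chip[[factors[i]]]$truth, frac_up = frac_up, frac_down = frac_down,
      effect_log2fc = effect_log2fc, seed = dseed(10 + i))
  }
  # shared control; per-factor knockdown, all from one baseline draw
  gene_ids <- genome$genes$genes$gene_id
  set.seed(dseed(20))
  baselines <- stats::rlnorm(length(gene_ids), log(150), 1)
  sample_mat <- NULL; cond <- character(0)
  gen_cond <- function(label, lfc_vec, k) {
    set.seed(dseed(30 + k))
    sfs <- stats::runif(n_rep, 0.8, 1.25)
    mu <- outer(baselines * 2^lfc_vec, sfs)
    m <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / alpha),
                nrow = length(gene_ids))
    colnames(m) <- sprintf("%s_%d", label, seq_len(n_rep))
    m
  }
  zero <- setNames(numeric(length(gene_ids)), gene_ids)
  blocks <- c(list(control = gen_cond("control", zero, 0)),
              setNames(lapply(seq_along(factors), function(i)
                gen_cond(paste0(factors[i], "_kd"), lfc[[factors[i]]], i)),
                factors))
  counts <- do.call(cbind, blocks)
  rownames(counts) <- gene_ids
  cond <- rep(c("control", paste0(factors, "_kd")), each = n_rep)
  cm <- count_matrix(counts, cond)
  quant <- simulate_quant_table(seed = dseed(40))
  truth <- list(
    seed = seed,
    binding = setNames(lapply(chip, `[[`, "truth"), factors),
    log2fc = lfc,
    interactors = quant$truth$interactors,
    target_annotated = quant$truth$target_annotated,
    params = list(n_genes = n_genes, n_chroms = n_chroms,
                  chrom_length = chrom_length, factors = factors,
                  frac_promoter = frac_promoter, frac_genic = frac_genic,
                  noise_peaks_per_mb = noise_peaks_per_mb,
                  frac_up = frac_up, frac_down = frac_down,
                  effect_log2fc = effect_log2fc, alpha = alpha,
                  n_rep = n_rep))
  paths <- NULL; config <- NULL
  if (write) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    write_gtf_genes(genome$genes, p("genome.gtf"))
    writeLines(sprintf("%s\t%d", names(genome$chrom_sizes),
                       genome$chrom_sizes), p("chrom.sizes"))
    peak_paths <- list()
    for (f in factors) {
      r1 <- p(sprintf("%s_rep1.narrowPeak", f))
      r2 <- p(sprintf("%s_rep2.narrowPeak", f))
      write_narrowpeak(chip[[f]]$rep1, r1)
      write_narrowpeak(chip[[f]]$rep2, r2)
      peak_paths[[f]] <- c(r1, r2)
      # coverage: replicate-1 peaks as boxes weighted by signal
      pk1 <- chip[[f]]$rep1
      GenomeInfoDb::seqlevels(pk1) <- names(genome$chrom_sizes)
      GenomeInfoDb::seqlengths(pk1) <- genome$chrom_sizes
      cov <- GenomicRanges::coverage(pk1, weight = pk1$signalValue)
      trk <- structure(list(coverage = cov,
                            chrom_sizes = genome$chrom_sizes),
                       class = "coverage_track")
      write_bedgraph(trk, p(sprintf("coverage_%s.bedGraph", f)))
    }
    cnt_out <- data.frame(gene_id = rownames(counts), counts,
                          check.names = FALSE)
    utils::write.table(cnt_out, p("counts.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = colnames(counts), condition = cond),
      p("conditions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_protein_quant(quant$table, p("quant.tsv"))
    jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    config <- list(
      gtf = p("genome.gtf"), chrom_sizes = p("chrom.sizes"),
      peaks = peak_paths,
      coverage = setNames(as.list(
        p(sprintf("coverage_%s.bedGraph", factors))), factors),
      counts = p("counts.tsv"), conditions = p("conditions.tsv"),
      contrasts = setNames(as.list(paste0(factors, "_kd")), factors),
      control_condition = "control",
      quant = p("quant.tsv"),
      params = list(promoter_upstream = 350, promoter_downstream = 100,
                    q_filter = 100, fdr_threshold = 0.01,
                    pseudocount = 0.5, ratio_min = 4,
                    psm_min_exclusive = 1,
                    target_categories = c("DNA binding",
                                          "chromatin regulation")),
      outdir = file.path(dir, "results"))
    jsonlite::write_json(config, p("config.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(list(dir = dir, gtf = p("genome.gtf"),
                    chrom_sizes = p("chrom.sizes"), counts = p("counts.tsv"),
                    conditions = p("conditions.tsv"), quant = p("quant.tsv"),
                    truth = p("truth.json"), config = p("config.json")),
               peaks = list(peak_paths))
  }
  invisible(structure(list(genome = genome, chip = chip, counts = cm,
                           quant = quant, truth = truth, paths = paths,
                           config = config),
                      class = "synthetic_study"))
}
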