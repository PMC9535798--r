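#' Run the integrative study pipeline end to end
#'
#' Orchestrates all stages: per factor, read the duplicate narrowPeak
#' replicates, drop hyper-significant artifact peaks
#' (\code{\link{filter_peaks_by_q}}), reconcile into common peaks
#' (\code{\link{common_peaks}}), and classify every gene's binding
#' (\code{\link{assign_binding_class}}); test knockdown versus control
#' expression (\code{\link{de_test}}); cross the two classifications
#' (\code{\link{cross_classify}}); collect the factor-regulated
#' (bound-and-upregulated) gene sets and their two-factor overlap; and,
#' when inputs are provided, compute coverage metaprofiles
#' (\code{\link{scale_regions_matrix}}), the co-IP candidate funnel
#' (\code{\link{select_candidates}}), and hypergeometric enrichment of the
#' shared regulated genes. All tabular outputs are TSV; a single
#' \code{summary.json} mirrors the regulation-table tree (per binding
#' class: n, \%, up/down/unchanged n and \%) plus the two-factor Venn
#' counts. Rerunning with the same inputs writes byte-identical outputs.
#'
#' @param config A configuration list, or the path of a JSON file holding
#'   one. Required fields: \code{gtf}, \code{chrom_sizes}, \code{peaks}
#'   (named list: factor -> character vector of 2 narrowPeak paths),
#'   \code{counts}, \code{conditions}, \code{contrasts} (named list:
#'   factor -> knockdown condition label), \code{control_condition},
#'   \code{outdir}. Optional: \code{coverage} (factor -> bedGraph path),
#'   \code{quant}, \code{annotation} (two-column TSV term_id, gene_id),
#'   \code{params} (promoter_upstream, promoter_downstream, q_filter,
#'   fdr_threshold, pseudocount, ratio_min, psm_min_exclusive,
#'   target_categories).
#' @return Invisibly, a list with the per-stage objects (\code{genes},
#'   \code{binding}, \code{de}, \code{tables}, \code{regulated_up},
#'   \code{overlap}, \code{metaprofiles}, \code{candidates},
#'   \code{enrichment}, \code{summary}).
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  req <- c("gtf", "chrom_sizes", "peaks", "counts", "conditions",
           "contrasts", "control_condition", "outdir")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config missing field(s): ",
                         paste(miss, collapse = ", "))
  prm <- config$params %||% list()
  up <- prm$promoter_upstream %||% 350
  dn <- prm$promoter_downstream %||% 100
  qmax <- prm$q_filter %||% 100
  fdr <- prm$fdr_threshold %||% 0.01
  pc <- prm$pseudocount %||% 0.5
  # validate every referenced input before any computation
  files <- c(config$gtf, config$chrom_sizes, unlist(config$peaks),
             config$counts, config$conditions,
             unlist(config$coverage), config$quant, config$annotation)
  absent <- files[!file.exists(files)]
  if (length(absent)) stop("input file(s) not found: ",
                           paste(absent, collapse = ", "))
  factors <- names(config$peaks)
  if (!all(factors %in% names(config$contrasts)))
    stop("contrasts missing for factor(s): ",
         paste(setdiff(factors, names(config$contrasts)), collapse = ", "))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message("[run_study] ", sprintf(...))
  log("promoter window -%d/+%d bp; q filter %g; FDR %g", up, dn, qmax, fdr)

  cs <- utils::read.table(config$chrom_sizes, sep = "\t",
                          col.names = c("chrom", "length"))
  chrom_sizes <- setNames(cs$length, cs$chrom)
  genes <- read_gtf_genes(config$gtf)
  log("gene universe: %d genes", length(genes))
  cm <- read_counts_tsv(config$counts, config$conditions)

  binding <- list(); de <- list(); tables <- list(); reg_up <- list()
  metas <- list()
  for (f in factors) {
    pp <- config$peaks[[f]]
    if (length(pp) != 2) stop("factor ", f, " needs exactly 2 replicates")
    r1 <- filter_peaks_by_q(read_narrowpeak(pp[1]), qmax)
    r2 <- filter_peaks_by_q(read_narrowpeak(pp[2]), qmax)
    cp <- common_peaks(r1, r2)
    log("%s: %d + %d replicate peaks -> %d common peaks", f,
        length(r1), length(r2), length(cp))
    binding[[f]] <- assign_binding_class(genes, cp, factor_name = f,
                                         upstream_bp = up,
                                         downstream_bp = dn,
                                         chrom_lengths = chrom_sizes)
    write_binding_calls(binding[[f]],
                        file.path(outdir, sprintf("binding_%s.tsv", f)))
    de[[f]] <- de_test(cm, config$control_condition,
                       config$contrasts[[f]], fdr_threshold = fdr,
                       pseudocount = pc)
    write_de_results(de[[f]], file.path(outdir, sprintf("de_%s.tsv", f)))
    tables[[f]] <- cross_classify(binding[[f]], de[[f]],
                                  universe = genes$genes$gene_id,
                                  factor_name = f)
    write_regulation_report(
      tables[[f]],
      tsv_path = file.path(outdir, sprintf("regulation_%s.tsv", f)),
      json_path = NULL)
    reg_up[[f]] <- regulated_gene_set(tables[[f]], "up")
    log("%s: %d regulated (bound & up) genes", f, length(reg_up[[f]]))
    if (!is.null(config$coverage[[f]])) {
      trk <- read_bedgraph(config$coverage[[f]], chrom_sizes)
      metas[[f]] <- scale_regions_matrix(trk, genes)
      write_meta_matrix(metas[[f]],
                        file.path(outdir, sprintf("metaprofile_%s.tsv", f)))
      utils::write.table(
        data.frame(bin = seq_len(ncol(metas[[f]])),
                   mean_signal = summary_profile(metas[[f]])),
        file.path(outdir, sprintf("metaprofile_%s_summary.tsv", f)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ov <- NULL
  if (length(factors) == 2) {
    ov <- overlap_sets(reg_up[[factors[1]]], reg_up[[factors[2]]],
                       labels = factors)
    log("overlap: %d only %s, %d shared, %d only %s",
        length(ov$only_a), factors[1], length(ov$shared),
        length(ov$only_b), factors[2])
  }

  cands <- NULL
  if (!is.null(config$quant)) {
    qt <- read_protein_quant(config$quant)
    cands <- select_candidates(qt, ratio_min = prm$ratio_min %||% 4,
                               psm_min_exclusive =
                                 prm$psm_min_exclusive %||% 1)
    tc <- prm$target_categories
    if (!is.null(tc)) {
      tagged <- categorize_candidates(cands, target_categories = tc)
      attr(cands, "tagged") <- tagged
    }
    write_candidates(cands, file.path(outdir, "candidates.tsv"))
    log("co-IP funnel: %d records -> %d candidates", nrow(qt), nrow(cands))
  }

  enrich <- NULL
  if (!is.null(config$annotation) && !is.null(ov)) {
    ann_tab <- utils::read.table(config$annotation, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
    ann <- split(ann_tab[[2]], ann_tab[[1]])
    enrich <- hypergeometric_enrichment(ov$shared, ann,
                                        genes$genes$gene_id)
    utils::write.table(as.data.frame(enrich),
                       file.path(outdir, "enrichment_shared.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    universe_size = length(genes),
    parameters = list(promoter_upstream = up, promoter_downstream = dn,
                      q_filter = qmax, fdr_threshold = fdr,
                      pseudocount = pc),
    factors = lapply(setNames(nm = factors), function(f)
      write_regulation_report(tables[[f]])),
    regulated_up = lapply(reg_up, length))
  if (!is.null(ov))
    summary$venn <- list(labels = ov$labels,
                         only_a = length(ov$only_a),
                         shared = length(ov$shared),
                         only_b = length(ov$only_b))
  if (!is.null(cands)) {
    summary$coip <- list(candidates = nrow(cands))
    if (!is.null(attr(cands, "tagged")))
      summary$coip$target_annotated <- nrow(attr(cands, "tagged"))
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("summary written to %s", file.path(outdir, "summary.json"))
  invisible(list(genes = genes, binding = binding, de = de,
                 tables = tables, regulated_up = reg_up, overlap = ov,
                 metaprofiles = metas, candidates = cands,
                 enrichment = enrich, summary = summary))
}
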