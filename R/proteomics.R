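#' Read a co-IP protein quantification table
#'
#' TSV with header columns \code{protein_id}, \code{sum_pep_score} (sum of
#' -log posterior error probability), \code{psm} (peptide-spectrum match
#' count), \code{abundance_control}, \code{abundance_kd},
#' \code{is_ribosomal}, \code{is_bait} (0/1 or TRUE/FALSE), and
#' \code{categories} (semicolon-separated annotation labels, may be empty).
#'
#' @param path Path to the TSV.
#' @return A data.frame with the columns above (\code{categories} as a list
#'   column of character vectors).
#' @export
read_protein_quant <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("protein_id", "sum_pep_score", "psm", "abundance_control",
            "abundance_kd", "is_ribosomal", "is_bait", "categories")
  if (!all(need %in% names(tab)))
    stop("quant table missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab$is_ribosomal <- as.logical(tab$is_ribosomal)
  tab$is_bait <- as.logical(tab$is_bait)
  tab$categories <- strsplit(ifelse(is.na(tab$categories), "",
                                    tab$categories), ";", fixed = TRUE)
  tab
}

#' Select co-purification candidates
#'
#' The quantitative candidate funnel for bait co-IP mass spectrometry
#' against a bait-depleted control: keep proteins whose abundance ratio
#' control / knockdown strictly exceeds \code{ratio_min} (a protein
#' detected only with the bait present, \code{abundance_kd = 0} with
#' positive control abundance, passes as an infinite ratio) and whose PSM
#' count strictly exceeds \code{psm_min_exclusive}; then exclude ribosomal
#' proteins and the bait itself. Records with both abundances zero are
#' skipped with a warning. The result is ordered by descending Sum Pep
#' Score, ties broken by protein id.
#'
#' @param records Data.frame as from \code{\link{read_protein_quant}}.
#' @param ratio_min Strict lower bound on the control/KD abundance ratio
#'   (default 4).
#' @param psm_min_exclusive Strict lower bound on PSM (default 1, i.e.
#'   \code{psm >= 2}).
#' @param zero_kd Either \code{"pass"} (default: zero KD abundance with
#'   positive control abundance counts as an infinite ratio) or
#'   \code{"skip"} (such records are dropped).
#' @return The candidate subset of \code{records}, ordered, with an added
#'   \code{ratio} column.
#' @export
select_candidates <- function(records, ratio_min = 4,
                              psm_min_exclusive = 1,
                              zero_kd = c("pass", "skip")) {
  zero_kd <- match.arg(zero_kd)
  both_zero <- records$abundance_control == 0 & records$abundance_kd == 0
  if (any(both_zero)) {
    warning(sum(both_zero), " record(s) with both abundances zero skipped")
    records <- records[!both_zero, , drop = FALSE]
  }
  ratio <- records$abundance_control / records$abundance_kd
  ratio[records$abundance_kd == 0] <-
    if (zero_kd == "pass") Inf else NA_real_
  records$ratio <- ratio
  keep <- !is.na(ratio) & ratio > ratio_min &
    records$psm > psm_min_exclusive &
    !records$is_ribosomal & !records$is_bait
  out <- records[keep, , drop = FALSE]
  out <- out[order(-out$sum_pep_score, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tag candidates by annotation category
#'
#' Returns the candidates whose annotation categories intersect
#' \code{target_categories} (e.g. DNA-binding and chromatin-regulation
#' factors). Candidates with no annotation at all are reported in the
#' \code{unannotated} attribute rather than dropped silently.
#'
#' @param candidates Data.frame from \code{\link{select_candidates}}.
#' @param annotation Optional named list protein_id -> character vector of
#'   categories, overriding the table's own \code{categories} column.
#' @param target_categories Character vector of categories of interest.
#' @return The tagged subset, with a \code{matched_categories} column;
#'   attribute \code{unannotated} lists candidates without annotation.
#' @export
categorize_candidates <- function(candidates, annotation = NULL,
                                  target_categories) {
  cats <- if (!is.null(annotation)) {
    lapply(candidates$protein_id, function(p)
      as.character(annotation[[p]] %||% character(0)))
  } else {
    lapply(candidates$categories, function(cc)
      cc[nzchar(cc)])
  }
  unann <- candidates$protein_id[lengths(cats) == 0]
  if (length(unann))
    message(length(unann), " candidate(s) without annotation: ",
            paste(utils::head(unann, 5), collapse = ", "))
  matched <- lapply(cats, intersect, y = target_categories)
  keep <- lengths(matched) > 0
  out <- candidates[keep, , drop = FALSE]
  out$matched_categories <- vapply(matched[keep], paste, "", collapse = ";")
  rownames(out) <- NULL
  attr(out, "unannotated") <- unann
  out
}

#' Write a candidate report to TSV
#'
#' @param candidates Data.frame from \code{\link{select_candidates}} or
#'   \code{\link{categorize_candidates}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  out <- candidates
  out$categories <- vapply(out$categories, paste, "", collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
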