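#' Cross binding classification with expression response
#'
#' Assigns every gene of the universe to one cell of the 3x3 table
#' (binding class: promoter / nonpromoter_genic / unbound) x (expression
#' class: up / down / unchanged). Every universe gene must carry a binding
#' call; genes missing from the DE results (e.g. not testable) are classed
#' \code{unchanged} with a message, so the table always partitions the full
#' universe.
#'
#' @param binding A \code{binding_calls} data.frame
#'   (\code{\link{assign_binding_class}}).
#' @param expr A \code{de_result} (\code{\link{de_test}}).
#' @param universe Character vector of gene ids; defaults to the binding
#'   calls' genes.
#' @param factor_name Label for the table (default from the binding calls).
#' @return An object of class \code{regulation_table}: list with
#'   \code{factor}, \code{per_gene} (data.frame gene_id, binding_class,
#'   expr_class), \code{counts} (3x3 integer matrix, rows binding classes,
#'   columns up/down/unchanged), and \code{universe_size}.
#' @export
cross_classify <- function(binding, expr, universe = binding$gene_id,
                           factor_name = binding$factor[1]) {
  if (anyDuplicated(universe)) stop("duplicate gene ids in universe")
  if (anyDuplicated(binding$gene_id)) stop("duplicate gene ids in binding calls")
  if (anyDuplicated(expr$gene_id)) stop("duplicate gene ids in DE results")
  bi <- match(universe, binding$gene_id)
  if (anyNA(bi))
    stop("universe gene(s) without binding call: ",
         paste(utils::head(universe[is.na(bi)], 5), collapse = ", "))
  bcls <- as.character(binding$binding_class)[bi]
  ei <- match(universe, expr$gene_id)
  ecls <- as.character(expr$expr_class)[ei]
  if (anyNA(ei)) {
    message(sum(is.na(ei)),
            " gene(s) absent from DE results classed 'unchanged'")
    ecls[is.na(ei)] <- "unchanged"
  }
  per_gene <- data.frame(
    gene_id = universe,
    binding_class = factor(bcls, levels = c("promoter", "nonpromoter_genic",
                                            "unbound")),
    expr_class = factor(ecls, levels = c("up", "down", "unchanged")),
    stringsAsFactors = FALSE)
  counts <- table(per_gene$binding_class, per_gene$expr_class)
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = dimnames(counts))
  structure(list(factor = factor_name, per_gene = per_gene, counts = counts,
                 universe_size = length(universe)),
            class = "regulation_table")
}

#' @export
print.regulation_table <- function(x, ...) {
  cat(sprintf("regulation_table for factor '%s': %d genes\n", x$factor,
              x$universe_size))
  rs <- rowSums(x$counts)
  for (b in rownames(x$counts)) {
    cat(sprintf("  %-18s %6d (%s%%)\n", b, rs[[b]],
                format(percent_of_group(rs[[b]], x$universe_size),
                       nsmall = 1)))
    if (rs[[b]] > 0)
      for (e in colnames(x$counts))
        cat(sprintf("    %-12s %6d (%s%% of class)\n", e, x$counts[b, e],
                    format(percent_of_group(x$counts[b, e], rs[[b]]),
                           nsmall = 1)))
  }
  invisible(x)
}

#' @export
#' @method summary regulation_table
summary.regulation_table <- function(object, ...) {
  print.regulation_table(object)
  invisible(object)
}

#' @export
#' @method as.data.frame regulation_table
as.data.frame.regulation_table <- function(x, ...) x$per_gene

#' Percentage of a group, rounded to one decimal
#'
#' \code{round(100 k / n)} to one decimal, rounding halves away from zero -
#' the convention that reproduces printed bookkeeping such as 1202/7460 =
#' 16.1\% or 1044/7460 = 14.0\%.
#'
#' @param k Count (0 <= k <= n). Vectorised.
#' @param n Group size (> 0).
#' @return Percentage(s) with one decimal.
#' @export
percent_of_group <- function(k, n) {
  if (any(n <= 0)) stop("group size must be positive")
  if (any(k < 0 | k > n)) stop("count outside [0, n]")
  x <- 100 * k / n
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Genes regulated by a factor
#'
#' The genes bound by the factor anywhere (promoter or nonpromoter genic
#' binding) whose expression responded in the given direction upon
#' knockdown - the "under the control of the factor" set.
#'
#' @param table A \code{regulation_table}.
#' @param direction \code{"up"} or \code{"down"}.
#' @return Character vector of gene ids.
#' @export
regulated_gene_set <- function(table, direction = c("up", "down")) {
  stopifnot(inherits(table, "regulation_table"))
  direction <- match.arg(direction)
  pg <- table$per_gene
  pg$gene_id[pg$binding_class %in% c("promoter", "nonpromoter_genic") &
             pg$expr_class == direction]
}

#' Two-set overlap (Venn partition)
#'
#' @param a,b Character vectors (gene sets).
#' @param labels Length-2 character vector naming the sets.
#' @return An object of class \code{gene_set_overlap}: list with
#'   \code{only_a}, \code{shared}, \code{only_b} (pairwise disjoint sets)
#'   and \code{labels}.
#' @export
overlap_sets <- function(a, b, labels = c("A", "B")) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  structure(list(only_a = setdiff(a, b), shared = intersect(a, b),
                 only_b = setdiff(b, a), labels = labels),
            class = "gene_set_overlap")
}

#' @export
print.gene_set_overlap <- function(x, ...) {
  cat(sprintf("overlap %s vs %s: |%s only| = %d, |shared| = %d, |%s only| = %d\n",
              x$labels[1], x$labels[2], x$labels[1], length(x$only_a),
              length(x$shared), x$labels[2], length(x$only_b)))
  invisible(x)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test per term: the probability of drawing at
#' least the observed overlap when \code{|query|} genes are sampled without
#' replacement from the universe containing \code{|term|} term members.
#' Terms with zero universe membership are skipped; p-values are BH-adjusted
#' across the tested terms. The background is the classification universe,
#' not the whole annotation.
#'
#' @param query Character vector of genes, a subset of \code{universe}.
#' @param annotation Named list: term id -> character vector of member
#'   genes.
#' @param universe Character vector of background genes.
#' @return A data.frame of class \code{enrichment_result}: \code{term_id},
#'   \code{term_size} (in-universe members), \code{overlap},
#'   \code{expected}, \code{p_value}, \code{q_value}, sorted by p-value.
#' @export
hypergeometric_enrichment <- function(query, annotation, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  query <- unique(as.character(query))
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  N <- length(universe); n <- length(query)
  res <- lapply(names(annotation), function(term) {
    members <- intersect(unique(annotation[[term]]), universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, query))
    data.frame(term_id = term, term_size = K, overlap = k,
               expected = n * K / N,
               p_value = stats::phyper(k - 1, K, N - K, n,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(term_id = character(0), term_size = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      p_value = numeric(0))
  res$q_value <- bh_adjust(res$p_value)
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Volume of a brain lobe modelled as a spheroid
#'
#' \code{V = (4/3) pi a b^2}, where \code{a} is the major semiaxis and
#' \code{b} the minor semiaxis of the lobe (a prolate spheroid with the two
#' minor axes assumed equal). Units: if a and b are in micrometres, V is in
#' cubic micrometres.
#'
#' @param a Major semiaxis (>= 0). Vectorised.
#' @param b Minor semiaxis (>= 0, <= a).
#' @return Volume(s).
#' @export
ellipsoid_volume <- function(a, b) {
  if (any(a < 0 | b < 0)) stop("semiaxes must be non-negative")
  if (any(b > a)) warning("minor semiaxis exceeds major semiaxis")
  4 / 3 * pi * a * b^2
}

#' Write a regulation table report
#'
#' Writes the per-gene assignments as TSV and the count/percentage summary
#' (per binding class: n, %, and up/down/unchanged n and % within the
#' class) as JSON.
#'
#' @param table A \code{regulation_table}.
#' @param tsv_path,json_path Output paths (either may be NULL to skip).
#' @return The summary list, invisibly.
#' @export
write_regulation_report <- function(table, tsv_path = NULL,
                                    json_path = NULL) {
  stopifnot(inherits(table, "regulation_table"))
  if (!is.null(tsv_path))
    utils::write.table(table$per_gene, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  rs <- rowSums(table$counts)
  summary <- list(
    factor = table$factor,
    universe_size = table$universe_size,
    classes = lapply(setNames(nm = rownames(table$counts)), function(b) {
      cell <- function(e) list(
        n = table$counts[b, e],
        pct_of_class = if (rs[[b]] > 0)
          percent_of_group(table$counts[b, e], rs[[b]]) else NA)
      list(n = rs[[b]],
           pct_of_universe = percent_of_group(rs[[b]], table$universe_size),
           up = cell("up"), down = cell("down"),
           unchanged = cell("unchanged"))
    }))
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(summary)
}
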