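## Two-group differential expression (deficient vs wild type) on
## log2-scale matrices, with BH correction shared with the genome
## scanner, operon-level aggregation, and affected-gene partitioning.

#' Two-group differential expression
#'
#' Per-gene log2 fold-change (test minus control group mean) with a
#' two-sided Welch (unequal-variance) t-test and Benjamini-Hochberg
#' adjusted p-values. Input is assumed already log2-scale (set
#' `log2_transform = TRUE` for linear intensities). Genes with zero
#' variance in both groups and equal means get p = 1 by convention.
#'
#' @param values Numeric matrix, genes x samples (rownames = gene ids),
#'   or an `expression_sim` from [simulate_expression()].
#' @param groups Character vector per sample, values "test"/"control"
#'   (taken from the simulation object when omitted).
#' @param operon_map Optional named character gene_id -> operon_id.
#' @param log2_transform Apply log2(x + 1) first (default FALSE).
#' @return `data.frame` with columns gene_id, logfc, p_value, adj_p,
#'   operon_id.
#' @export
differential_expression <- function(values, groups = NULL,
                                    operon_map = NULL,
                                    log2_transform = FALSE) {
  if (inherits(values, "expression_sim")) {
    if (is.null(groups)) groups <- values$groups
    if (is.null(operon_map)) operon_map <- values$operon_map
    values <- values$values
  }
  if (is.null(groups) || length(groups) != ncol(values))
    stop("'groups' must label every sample column")
  if (!all(groups %in% c("test", "control")))
    stop("group labels must be 'test' or 'control'")
  if (min(table(groups)) < 2)
    stop("need at least 2 samples per group")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids")
  if (log2_transform) values <- log2(values + 1)

  a <- values[, groups == "test", drop = FALSE]
  b <- values[, groups == "control", drop = FALSE]
  logfc <- rowMeans(a) - rowMeans(b)
  p <- vapply(seq_len(nrow(values)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) return(1)
      return(.Machine$double.xmin)  # identical within, different between
    }
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }, numeric(1))
  gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d",
                                             seq_len(nrow(values)))
  data.frame(
    gene_id = gene_ids,
    logfc = unname(logfc),
    p_value = p,
    adj_p = benjamini_hochberg(p),
    operon_id = if (is.null(operon_map)) NA_character_ else
      unname(operon_map[gene_ids]),
    stringsAsFactors = FALSE)
}

#' Summarize differential expression per operon
#'
#' Groups genes by operon and reports member count, median log2
#' fold-change, a direction label (up when the median is positive), and
#' the fraction of members significant at `adjp_threshold`. Genes absent
#' from the map are collected under "unmapped".
#'
#' @param rows `data.frame` from [differential_expression()].
#' @param operon_map Named character gene_id -> operon_id; defaults to
#'   the `operon_id` column of `rows`.
#' @param adjp_threshold Significance cut for the member fraction
#'   (default 0.05).
#' @return `data.frame` with columns operon_id, n_members, median_logfc,
#'   direction, frac_significant.
#' @export
operon_summarize <- function(rows, operon_map = NULL,
                             adjp_threshold = 0.05) {
  ops <- if (!is.null(operon_map)) unname(operon_map[rows$gene_id]) else
    rows$operon_id
  ops[is.na(ops)] <- "unmapped"
  sp <- split(seq_len(nrow(rows)), ops)
  out <- do.call(rbind, lapply(names(sp), function(op) {
    idx <- sp[[op]]
    med <- stats::median(rows$logfc[idx])
    data.frame(operon_id = op, n_members = length(idx),
               median_logfc = med,
               direction = if (med > 0) "up" else if (med < 0) "down"
                           else "flat",
               frac_significant = mean(rows$adj_p[idx] < adjp_threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Partition genes into up/down/unchanged
#'
#' A gene is affected when |logFC| >= `logfc_threshold` and adjusted
#' p <= `adjp_threshold`; affected genes are split by sign and the
#' up/down fractions of the affected set reported.
#'
#' @param rows `data.frame` from [differential_expression()].
#' @param logfc_threshold Absolute log2 fold-change cut (default 1).
#' @param adjp_threshold Adjusted-p cut (default 0.05).
#' @return List with `upregulated`, `downregulated`, `unchanged`
#'   (row subsets), `counts`, and `fractions` (share of the affected
#'   set that is up/down).
#' @export
affected_gene_report <- function(rows, logfc_threshold = 1,
                                 adjp_threshold = 0.05) {
  if (logfc_threshold <= 0 || adjp_threshold <= 0)
    stop("thresholds must be positive")
  affected <- abs(rows$logfc) >= logfc_threshold &
    rows$adj_p <= adjp_threshold
  up <- affected & rows$logfc > 0
  down <- affected & rows$logfc < 0
  n_aff <- sum(up) + sum(down)
  list(
    upregulated = rows[up, , drop = FALSE],
    downregulated = rows[down, , drop = FALSE],
    unchanged = rows[!affected, , drop = FALSE],
    counts = c(up = sum(up), down = sum(down),
               unchanged = sum(!affected)),
    fractions = c(up = if (n_aff) sum(up) / n_aff else NA_real_,
                  down = if (n_aff) sum(down) / n_aff else NA_real_))
}
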