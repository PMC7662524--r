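## Genome scanning: exact PWM p-values by dynamic programming, FIMO-style
## both-strand scans with BH q-values, and TSS/operon/promoter annotation.

#' Exact score distribution of a PWM under the background model
#'
#' Column log-odds scores are quantized to integer multiples of
#' `granularity` and the per-column probability mass functions convolved,
#' yielding the exact distribution of the total (quantized) score of a
#' random background sequence. This is the dynamic program behind
#' FIMO-style p-values.
#'
#' @param x A [pwm].
#' @param granularity Quantization step in log2 units (default 1/1000).
#' @return A list of class `score_distribution` with `support` (integer
#'   scores, units of `granularity`), `pmf`, `tail` (right-tail cumulative
#'   P(S >= s)), `granularity`, and `int_scores` (width x 4 quantized
#'   column score matrix).
#' @export
score_distribution <- function(x, granularity = 1e-3) {
  stopifnot(inherits(x, "pwm"))
  if (granularity <= 0) stop("granularity must be positive")
  lo <- log_odds(x)
  is_mat <- matrix(as.integer(round(lo / granularity)),
                   nrow = x$width, ncol = 4)
  lo_min <- cumsum(apply(is_mat, 1, min))
  lo_max <- cumsum(apply(is_mat, 1, max))
  ## pmf vector indexed by score offset from running minimum
  pmf <- 1
  base_off <- 0L  # support of pmf is base_off:(base_off + length(pmf) - 1)
  bg <- x$background
  for (j in seq_len(x$width)) {
    s <- is_mat[j, ]
    new_off <- base_off + min(s)
    new_len <- (base_off + length(pmf) - 1L + max(s)) - new_off + 1L
    new <- numeric(new_len)
    for (b in 1:4) {
      sh <- base_off + s[b] - new_off  # 0-based shift into new
      idx <- (sh + 1L):(sh + length(pmf))
      new[idx] <- new[idx] + pmf * bg[b]
    }
    pmf <- new
    base_off <- new_off
  }
  support <- base_off + seq_along(pmf) - 1L
  tail <- rev(cumsum(rev(pmf)))
  structure(list(support = support, pmf = pmf, tail = tail,
                 granularity = granularity, int_scores = is_mat),
            class = "score_distribution")
}

## Right-tail probability P(S >= int_score) from a score_distribution.
dist_tail_at <- function(dist, int_score) {
  i <- int_score - dist$support[1] + 1L
  n <- length(dist$tail)
  out <- numeric(length(i))
  out[i <= 1L] <- 1
  inside <- i >= 1L & i <= n
  out[inside] <- dist$tail[i[inside]]
  out[i > n] <- 0
  out
}

#' Exact p-value of a PWM score
#'
#' P(random background sequence of the PWM width scores >= `threshold`),
#' computed from the quantized-score dynamic program of
#' [score_distribution()]. Deterministic; accuracy is bounded by the
#' quantization step.
#'
#' @param x A [pwm], or a precomputed [score_distribution()].
#' @param threshold Log-odds score (log2 units).
#' @param granularity Quantization step (ignored when `x` is already a
#'   score distribution).
#' @return Probability in (0, 1].
#' @export
exact_pvalue <- function(x, threshold, granularity = 1e-3) {
  dist <- if (inherits(x, "score_distribution")) x
          else score_distribution(x, granularity)
  dist_tail_at(dist, as.integer(round(threshold / dist$granularity)))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard BH: q for the i-th order statistic is
#' min over j >= i of m * p_(j) / j, capped at 1. Order-preserving and
#' invariant under permutation of the input.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param m Number of tests (default `length(p)`; supply the full test
#'   count when `p` holds only a significant subset that is known to
#'   contain the smallest `length(p)` p-values of the family).
#' @return Numeric vector of q-values aligned with `p`.
#' @export
benjamini_hochberg <- function(p, m = length(p)) {
  if (length(p) == 0) return(numeric(0))
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  o <- order(p)
  ranked <- m * p[o] / seq_along(p)
  q <- rev(cummin(rev(ranked)))
  q <- pmin(q, 1)
  out <- numeric(length(p))
  out[o] <- q
  out
}

## Vectorized window scores of an integer-coded sequence under integer
## column scores (width x 4). Windows containing NA codes score NA.
window_int_scores <- function(codes, is_mat) {
  w <- nrow(is_mat)
  n <- length(codes) - w + 1L
  if (n < 1L) return(integer(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    v <- is_mat[j, ][codes[j:(j + n - 1L)]]
    sc <- sc + v
  }
  sc
}

#' Scan a genome with a PWM and assign exact p- and q-values
#'
#' Slides the PWM over both strands; a window is reported when its exact
#' dynamic-programming p-value is below `p_threshold`. For a palindromic
#' PWM the + and - strand windows at a locus have identical scores and
#' are merged into a single record keeping the + strand representation.
#' q-values are Benjamini-Hochberg over all tested windows (both
#' strands).
#'
#' @param x A [pwm].
#' @param genome DNA string, `Biostrings::DNAString`, or a path to a
#'   FASTA file (first record used).
#' @param p_threshold Report windows with p-value strictly below this
#'   (default 1e-4).
#' @param strand_mode "both" (default) or "forward".
#' @param granularity Score quantization for the p-value DP.
#' @return A `data.frame` with columns start, end (1-based inclusive),
#'   strand, matched_sequence (strand-oriented), score, p_value, q_value,
#'   plus attributes `n_windows` (tested window count) and `pwm_width`.
#' @export
scan_genome <- function(x, genome, p_threshold = 1e-4,
                        strand_mode = c("both", "forward"),
                        granularity = 1e-3) {
  stopifnot(inherits(x, "pwm"))
  strand_mode <- match.arg(strand_mode)
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must lie in (0, 1)")
  seqtxt <- as_genome_string(genome)
  if (nchar(seqtxt) < x$width) {
    warning("genome shorter than PWM width; no windows tested")
    out <- empty_hits()
    attr(out, "n_windows") <- 0L
    attr(out, "pwm_width") <- x$width
    return(out)
  }
  codes <- encode_dna(seqtxt)
  dist <- score_distribution(x, granularity)
  pal <- is_palindromic(x)

  fw <- window_int_scores(codes, dist$int_scores)
  starts <- seq_along(fw)
  ok <- !is.na(fw)
  res <- list(data.frame(start = starts[ok], strand = "+",
                         int_score = fw[ok]))
  n_windows <- sum(ok)
  if (strand_mode == "both") {
    rc_dist_scores <- score_distribution(revcomp_pwm(x),
                                         granularity)$int_scores
    rv <- window_int_scores(codes, rc_dist_scores)
    okr <- !is.na(rv)
    n_windows <- n_windows + sum(okr)
    if (!pal)
      res[[2]] <- data.frame(start = starts[okr], strand = "-",
                             int_score = rv[okr])
    ## palindromic: - strand windows duplicate + strand scores; counted
    ## as tested (they were) but merged out of the report.
  }
  windows <- do.call(rbind, res)
  windows$p_value <- dist_tail_at(dist, windows$int_score)
  ## BH over every tested window; for a palindromic matrix the merged-out
  ## minus-strand windows still count as (duplicate) tests.
  all_p <- c(windows$p_value,
             if (pal && strand_mode == "both") windows$p_value)
  qv <- benjamini_hochberg(all_p, m = n_windows)
  windows$q_value <- qv[seq_len(nrow(windows))]
  hits <- windows[windows$p_value < p_threshold, , drop = FALSE]
  w <- x$width
  out <- data.frame(
    start = hits$start,
    end = hits$start + w - 1L,
    strand = hits$strand,
    matched_sequence = vapply(seq_len(nrow(hits)), function(i) {
      s <- substr(seqtxt, hits$start[i], hits$start[i] + w - 1L)
      if (hits$strand[i] == "-") revcomp(s) else s
    }, character(1)),
    score = hits$int_score * dist$granularity,
    p_value = hits$p_value,
    q_value = hits$q_value,
    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_windows") <- n_windows
  attr(out, "pwm_width") <- w
  out
}

empty_hits <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             matched_sequence = character(0), score = numeric(0),
             p_value = numeric(0), q_value = numeric(0),
             stringsAsFactors = FALSE)
}

as_genome_string <- function(genome) {
  if (inherits(genome, "DNAString")) return(as.character(genome))
  if (inherits(genome, "DNAStringSet")) return(as.character(genome[[1]]))
  if (is.character(genome) && length(genome) == 1 &&
      file.exists(genome) && !grepl("^[ACGTNacgtn]+$", genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    return(as.character(ss[[1]]))
  }
  toupper(as.character(genome)[1])
}

## ---- annotation -----------------------------------------------------------

#' TSS-relative location of a binding-site interval
#'
#' Signed distance of the hit edge nearest the transcription start site,
#' measured in the gene's reading direction: negative upstream of the
#' TSS, positive downstream, and the upstream edge (<= 0) when the hit
#' spans the TSS. Isolated here because the anchoring convention is a
#' modelling choice.
#'
#' @param start,end 1-based inclusive hit coordinates (forward strand).
#' @param tss TSS coordinate of the gene.
#' @param gene_strand "+" or "-".
#' @return Signed integer distance.
#' @export
tss_relative_loc <- function(start, end, tss, gene_strand) {
  n <- max(length(start), length(end), length(tss), length(gene_strand))
  start <- rep_len(start, n); end <- rep_len(end, n)
  tss <- rep_len(tss, n)
  plus <- rep_len(gene_strand == "+", n)
  d1 <- ifelse(plus, start - tss, tss - end)  # d1 <= d2, reading direction
  d2 <- ifelse(plus, end - tss, tss - start)
  ## entirely upstream -> d2 (negative, nearest edge); entirely
  ## downstream -> d1 (positive, nearest edge); spanning -> d1 (<= 0)
  ifelse(d2 < 0, d2, d1)
}

#' Annotate motif hits against TSS, operon, and promoter tracks
#'
#' For each hit, the nearest gene on each strand (by absolute TSS-relative
#' location, within `max_distance`) receives one annotation; a site in a
#' bidirectional intergenic region is therefore reported once per flanking
#' gene. Promoter classification is by interval overlap against that
#' gene's -35/-10/+1 elements with precedence overlapping_core >
#' upstream_of_minus35 > downstream_of_minus10. The proximal flag marks
#' sites within `window` of the TSS; the candidate flag additionally
#' requires the gene to head its operon ("1/n") or be a single
#' transcriptional unit ("S").
#'
#' @param hits Hits `data.frame` from [scan_genome()] (columns start, end
#'   at minimum).
#' @param genes `data.frame` with columns gene_id, strand, tss, operon_id,
#'   operon_pos (labels like "1/3" or "S").
#' @param elements Optional `data.frame` with columns gene_id,
#'   element_type (minus35/minus10/plus1), start, end (1-based inclusive).
#' @param window Proximal window relative to the TSS, default c(-200, 20).
#' @param max_distance Maximum |loc| for a gene to be annotated
#'   (default 1000).
#' @return `data.frame` with one row per (hit, gene): hit coordinates,
#'   gene_id, loc, operon_pos, promoter_class, proximal, candidate.
#'   Hits with no gene in range yield gene_id NA.
#' @export
annotate_hits <- function(hits, genes, elements = NULL,
                          window = c(-200, 20), max_distance = 1000) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "strand", "tss") %in% names(genes)))
  if (!"operon_pos" %in% names(genes)) genes$operon_pos <- "S"
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]; e <- hits$end[i]
    found <- FALSE
    for (str in c("+", "-")) {
      g <- genes[genes$strand == str, , drop = FALSE]
      if (nrow(g) == 0) next
      locs <- tss_relative_loc(s, e, g$tss, str)
      k <- which.min(abs(locs))
      if (abs(locs[k]) > max_distance) next
      found <- TRUE
      gene <- g[k, ]
      cls <- classify_promoter(s, e, gene$gene_id, gene$strand, elements)
      loc <- locs[k]
      prox <- loc >= window[1] & loc <= window[2]
      first <- grepl("^1(/|$)", gene$operon_pos) | gene$operon_pos == "S"
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = e, gene_id = gene$gene_id, loc = loc,
        operon_pos = gene$operon_pos, promoter_class = cls,
        proximal = prox, candidate = prox && first,
        stringsAsFactors = FALSE)
    }
    if (!found)
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = e, gene_id = NA_character_, loc = NA_integer_,
        operon_pos = NA_character_, promoter_class = "no_promoter_found",
        proximal = FALSE, candidate = FALSE, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0),
               gene_id = character(0), loc = integer(0),
               operon_pos = character(0), promoter_class = character(0),
               proximal = logical(0), candidate = logical(0))
  rownames(out) <- NULL
  out
}

classify_promoter <- function(s, e, gene_id, gene_strand, elements) {
  if (is.null(elements)) return("no_promoter_found")
  el <- elements[elements$gene_id == gene_id, , drop = FALSE]
  if (nrow(el) == 0) return("no_promoter_found")
  overlaps <- el$start <= e & el$end >= s
  if (any(overlaps)) return("overlapping_core")
  m35 <- el[el$element_type == "minus35", , drop = FALSE]
  if (nrow(m35) > 0) {
    up <- if (gene_strand == "+") e < min(m35$start) else s > max(m35$end)
    if (up) return("upstream_of_minus35")
  }
  m10 <- el[el$element_type == "minus10", , drop = FALSE]
  if (nrow(m10) > 0) {
    down <- if (gene_strand == "+") s > max(m10$end) else e < min(m10$start)
    if (down) return("downstream_of_minus10")
  }
  "no_promoter_found"
}

#' Filter annotations to the proximal promoter window
#'
#' Convenience wrapper applying the activator-typical TSS window
#' (default -200..+20) to a table with a `loc` column, as used when
#' shortlisting candidate regulated genes.
#'
#' @param annotations `data.frame` with a numeric `loc` column.
#' @param window Length-2 numeric, inclusive bounds.
#' @return The retained rows.
#' @export
filter_proximal <- function(annotations, window = c(-200, 20)) {
  keep <- !is.na(annotations$loc) &
    annotations$loc >= window[1] & annotations$loc <= window[2]
  annotations[keep, , drop = FALSE]
}
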