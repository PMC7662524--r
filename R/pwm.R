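DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' A `pwm` holds per-column base probabilities for a DNA motif, a 0-order
#' background model, and the pseudocount that was used when the matrix was
#' estimated from counts. Columns of the motif are rows of `probs` (one row
#' per motif position, columns ordered A, C, G, T).
#'
#' @param probs Numeric matrix, width x 4, rows summing to 1. Column names
#'   are forced to A, C, G, T.
#' @param background Numeric vector of 4 background base probabilities
#'   (A, C, G, T), summing to 1. Default uniform.
#' @param pseudocount Pseudocount per base per column recorded with the
#'   model (used when re-estimating from sites).
#' @return An object of class `pwm` with elements `probs`, `background`,
#'   `width`, `pseudocount`.
#' @examples
#' p <- pwm_from_consensus("TGTATTCTAGAATACA")
#' p$width
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = 0.25) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L)
    stop("'probs' must have 4 columns (A, C, G, T)")
  if (any(probs < 0))
    stop("probabilities must be non-negative")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-9))
    stop("each pwm column must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9)
    stop("'background' must be 4 probabilities summing to 1")
  if (any(background <= 0))
    stop("background probabilities must be strictly positive")
  colnames(probs) <- DNA_BASES
  background <- stats::setNames(as.numeric(background), DNA_BASES)
  structure(
    list(probs = probs, background = background,
         width = nrow(probs), pseudocount = pseudocount),
    class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("Position weight matrix, width %d\n", x$width))
  cat(sprintf("Consensus: %s\n", consensus_string(x)))
  cat(sprintf("Information content: %.2f bits\n",
              information_content(x)$total))
  invisible(x)
}

#' Build a PWM from a consensus sequence
#'
#' Each consensus base receives probability `major`; the remainder is
#' spread uniformly over the other three bases.
#'
#' @param consensus DNA string (A/C/G/T).
#' @param major Probability assigned to the consensus base per column.
#' @inheritParams pwm
#' @return A [pwm].
#' @export
pwm_from_consensus <- function(consensus, major = 0.91,
                               background = rep(0.25, 4),
                               pseudocount = 0.25) {
  codes <- encode_dna(consensus)
  if (anyNA(codes)) stop("consensus must contain only A/C/G/T")
  probs <- matrix((1 - major) / 3, nrow = length(codes), ncol = 4)
  probs[cbind(seq_along(codes), codes)] <- major
  pwm(probs, background, pseudocount)
}

#' Estimate a PWM from aligned binding sites
#'
#' @param sites Character vector of equal-length DNA strings.
#' @param weights Optional per-site weights (e.g. EM posteriors).
#' @inheritParams pwm
#' @return A [pwm].
#' @export
pwm_from_sites <- function(sites, weights = NULL,
                           background = rep(0.25, 4), pseudocount = 0.25) {
  m <- encode_dna_matrix(sites)
  if (is.null(weights)) weights <- rep(1, nrow(m))
  w <- ncol(m)
  counts <- matrix(pseudocount, nrow = w, ncol = 4)
  for (j in seq_len(w)) {
    for (b in 1:4) counts[j, b] <- counts[j, b] + sum(weights[m[, j] == b])
  }
  pwm(counts / rowSums(counts), background, pseudocount)
}

## ---- sequence encoding ----------------------------------------------------

#' Encode a DNA string as integer codes A=1, C=2, G=3, T=4
#'
#' Non-ACGT characters become NA.
#' @param x A single DNA string.
#' @return Integer vector of codes.
#' @export
encode_dna <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  match(chars, DNA_BASES)
}

#' Decode integer base codes back to a DNA string
#' @param codes Integer vector of codes (1..4).
#' @return DNA string.
#' @export
decode_dna <- function(codes) paste(DNA_BASES[codes], collapse = "")

## Encode equal-length DNA strings into an n x L integer matrix.
encode_dna_matrix <- function(x) {
  lens <- nchar(x)
  if (length(unique(lens)) != 1L)
    stop("sequences must have equal length")
  m <- matrix(match(unlist(strsplit(toupper(x), "", fixed = TRUE)),
                    DNA_BASES),
              nrow = length(x), ncol = lens[1], byrow = TRUE)
  m
}

#' Reverse complement of a DNA string
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## ---- PWM algebra ----------------------------------------------------------

#' Reverse complement a PWM
#'
#' Columns are reversed and the A/T and C/G probabilities swapped, so that
#' scanning the reverse strand with the original matrix is equivalent to
#' scanning the forward strand with its reverse complement. The operation
#' is an involution.
#'
#' @param x A [pwm].
#' @return A [pwm].
#' @export
revcomp_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  probs <- x$probs[rev(seq_len(x$width)), c(4, 3, 2, 1), drop = FALSE]
  bg <- x$background[c(4, 3, 2, 1)]
  pwm(probs, as.numeric(bg), x$pseudocount)
}

#' Impose reverse-complement (palindromic) symmetry on a PWM
#'
#' Averages the matrix with its reverse complement column-wise; the result
#' is exactly self-reverse-complementary, modelling a homodimer binding a
#' palindromic site (as CRP-family regulators do). Idempotent.
#'
#' @param x A [pwm].
#' @return A palindromic [pwm].
#' @export
palindromize <- function(x) {
  stopifnot(inherits(x, "pwm"))
  rc <- revcomp_pwm(x)
  pwm((x$probs + rc$probs) / 2, as.numeric(x$background), x$pseudocount)
}

#' Is a PWM palindromic (self-reverse-complementary)?
#' @param x A [pwm].
#' @param tol Numeric tolerance.
#' @return Logical.
#' @export
is_palindromic <- function(x, tol = 1e-9) {
  max(abs(x$probs - revcomp_pwm(x)$probs)) <= tol
}

## Log-odds matrix (log2 p / background), width x 4.
log_odds <- function(x) {
  lo <- log2(sweep(x$probs, 2, x$background, "/"))
  lo
}

#' Log-odds score of a sequence under a PWM
#'
#' Sum over positions of log2(p_j(base_j) / background(base_j)).
#'
#' @param x A [pwm].
#' @param sequence DNA string of exactly the PWM width.
#' @return Log-odds score in log2 units.
#' @export
score_sequence <- function(x, sequence) {
  codes <- encode_dna(sequence)
  if (length(codes) != x$width)
    stop("sequence length (", length(codes), ") must equal pwm width (",
         x$width, ")")
  if (anyNA(codes))
    stop("sequence contains ambiguous (non-ACGT) bases")
  lo <- log_odds(x)
  sum(lo[cbind(seq_len(x$width), codes)])
}

#' Maximum achievable log-odds score of a PWM
#' @param x A [pwm].
#' @return Numeric score (log2 units).
#' @export
max_score <- function(x) sum(apply(log_odds(x), 1, max))

#' Argmax consensus sequence of a PWM
#'
#' The plain top-base string (ties broken toward the first of A,C,G,T).
#' See [consensus_string()] for the degeneracy-aware notation.
#' @param x A [pwm].
#' @return DNA string of the PWM width.
#' @export
argmax_consensus <- function(x) {
  decode_dna(apply(x$probs, 1, which.max))
}

#' Information content of a PWM
#'
#' Per-column relative entropy (bits) against the background; under a
#' uniform background this is the familiar 2 + sum p log2 p logo height.
#'
#' @param x A [pwm].
#' @return List with `per_column` (bits) and `total`.
#' @export
information_content <- function(x) {
  p <- x$probs
  term <- p * log2(sweep(p, 2, x$background, "/"))
  term[p == 0] <- 0
  per_col <- rowSums(term)
  list(per_column = per_col, total = sum(per_col))
}

## ---- consensus notation ---------------------------------------------------

IUPAC_FROM_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W",
  "GT" = "K", "AC" = "M", "CGT" = "B", "AGT" = "D",
  "ACT" = "H", "ACG" = "V", "ACGT" = "N")

#' Thresholds for mixed-case/IUPAC consensus notation
#'
#' Controls how [consensus_string()] renders each PWM column:
#' a dominant base is written as an uppercase letter; a clearly two-base
#' column as "(X/y)" (the second base lowercased when much rarer than the
#' first); a near-uniform column as "N"; anything else as the minimal
#' IUPAC degeneracy code covering the non-negligible bases.
#'
#' @param major_threshold Minimum top-base frequency for a plain uppercase
#'   call (default 0.75).
#' @param pair_threshold Minimum combined frequency of the top two bases
#'   for a "(X/y)" call (default 0.75).
#' @param minor_floor Minimum frequency for a base to be considered at all
#'   (default 0.20).
#' @param n_floor Top-base frequency below which the column is written "N"
#'   (default 0.40).
#' @return A list of class `consensus_spec`.
#' @export
consensus_spec <- function(major_threshold = 0.75, pair_threshold = 0.75,
                           minor_floor = 0.20, n_floor = 0.40) {
  vals <- c(major_threshold, pair_threshold, minor_floor, n_floor)
  if (any(vals <= 0) || any(vals > 1))
    stop("all consensus thresholds must lie in (0, 1]")
  structure(list(major_threshold = major_threshold,
                 pair_threshold = pair_threshold,
                 minor_floor = minor_floor, n_floor = n_floor),
            class = "consensus_spec")
}

#' Mixed-case/IUPAC consensus string of a PWM
#'
#' @param x A [pwm].
#' @param spec A [consensus_spec()].
#' @return A single string, e.g. `"TGT(A/g)N..."`.
#' @export
consensus_string <- function(x, spec = consensus_spec()) {
  out <- character(x$width)
  for (j in seq_len(x$width)) {
    p <- x$probs[j, ]
    ord <- order(p, decreasing = TRUE)
    top <- p[ord[1]]; second <- p[ord[2]]
    if (top >= spec$major_threshold) {
      out[j] <- DNA_BASES[ord[1]]
    } else if (top + second >= spec$pair_threshold &&
               second >= spec$minor_floor) {
      second_chr <- DNA_BASES[ord[2]]
      if (second < spec$major_threshold * top)
        second_chr <- tolower(second_chr)
      out[j] <- sprintf("(%s/%s)", DNA_BASES[ord[1]], second_chr)
    } else if (top < spec$n_floor) {
      out[j] <- "N"
    } else {
      keep <- sort(DNA_BASES[p >= spec$minor_floor])
      if (length(keep) == 0) keep <- DNA_BASES[ord[1]]
      out[j] <- IUPAC_FROM_SET[[paste(keep, collapse = "")]]
    }
  }
  paste(out, collapse = "")
}
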