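## Motif discovery: ZOOPS (zero-or-one occurrence per sequence)
## expectation-maximization over both strands, with an optional
## palindromic constraint applied after every M-step, multi-start from
## data-derived seed w-mers, and width selection by E-value.

#' Discover a motif by expectation-maximization
#'
#' Fits a ZOOPS model per candidate width: the E-step computes the
#' posterior site location (and strand) per sequence under the current
#' PWM versus the background; the M-step re-estimates the PWM (with
#' pseudocounts) and the per-sequence site prior gamma. With
#' `palindromic = TRUE` the matrix is symmetrized ([palindromize()])
#' after each M-step, modelling a homodimer site. Each width is fit from
#' `n_starts` seed w-mers drawn from the data; the best start is run to
#' convergence (log-likelihood gain below `tol` or `max_iter`
#' iterations). The best width is the one minimizing the motif
#' [evalue()].
#'
#' @param sequences Character vector (>= 2) of DNA strings.
#' @param width_range Integer c(min, max); must fit the shortest
#'   sequence.
#' @param palindromic Impose reverse-complement symmetry (default FALSE).
#' @param n_starts Seed w-mers tried per width (default 10).
#' @param seed Integer RNG seed for start selection; NULL leaves the RNG
#'   state alone.
#' @param strand_mode "both" (default; posteriors summed over strands) or
#'   "forward".
#' @param mode "zoops" (default) or "oops" (exactly one site per
#'   sequence).
#' @param background Optional 4-vector of background base probabilities;
#'   estimated from the input when NULL.
#' @param pseudocount Pseudocount per base per column (default 0.25).
#' @param max_iter,tol EM stopping rule (default 200 iterations, 1e-6
#'   log-likelihood gain).
#' @param start_iters EM iterations given to each start before the best
#'   is selected (default 4).
#' @return A `motif_model` list: `pwm`, `site_prob` (gamma), `n_sites`
#'   (expected site count), `log_likelihood` (nats, up to a data
#'   constant), `ll_trace` (the penalized Dirichlet-MAP EM objective,
#'   guaranteed non-decreasing), `e_value`, `log10_evalue`, `width`,
#'   `strand_mode`, `low_complexity`, and a `width_table` attribute with
#'   the per-width E-values.
#' @export
discover_motif <- function(sequences, width_range = c(6, 24),
                           palindromic = FALSE, n_starts = 10,
                           seed = NULL,
                           strand_mode = c("both", "forward"),
                           mode = c("zoops", "oops"),
                           background = NULL, pseudocount = 0.25,
                           max_iter = 200, tol = 1e-6, start_iters = 4) {
  strand_mode <- match.arg(strand_mode)
  mode <- match.arg(mode)
  if (length(sequences) < 2) stop("need at least 2 sequences")
  lens <- nchar(sequences)
  wmin <- width_range[1]; wmax <- width_range[length(width_range)]
  if (wmin > wmax) stop("width_range min exceeds max")
  if (wmax > min(lens))
    stop("maximum width (", wmax, ") exceeds shortest sequence (",
         min(lens), ")")
  if (!is.null(seed)) set.seed(seed)

  dat <- em_encode(sequences, strand_mode)
  if (is.null(background)) {
    ## floor the estimated background so skewed input cannot zero it out
    background <- pmax(dat$base_freq, 0.01)
    background <- background / sum(background)
  }
  low_complexity <- max(dat$base_freq) >= 0.9

  best <- NULL
  tab <- data.frame(width = integer(0), log10_evalue = numeric(0),
                    log_likelihood = numeric(0))
  for (w in wmin:wmax) {
    fit <- em_fit_width(dat, w, palindromic, n_starts, strand_mode, mode,
                        background, pseudocount, max_iter, tol,
                        start_iters)
    ev <- evalue_internal(fit$pwm, fit$total_llr, fit$n_sites,
                          dat$n_placements(w))
    fit$e_value <- ev$e_value
    fit$log10_evalue <- ev$log10_evalue
    tab <- rbind(tab, data.frame(width = w, log10_evalue = ev$log10_evalue,
                                 log_likelihood = fit$log_likelihood))
    if (is.null(best) || ev$log10_evalue < best$log10_evalue) best <- fit
  }
  best$strand_mode <- strand_mode
  best$low_complexity <- low_complexity
  best$width <- best$pwm$width
  attr(best, "width_table") <- tab
  class(best) <- "motif_model"
  best
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("Motif model: width %d, consensus %s\n", x$width,
              consensus_string(x$pwm)))
  cat(sprintf("  expected sites %.1f of %d sequences (gamma = %.3f)\n",
              x$n_sites, x$n_sequences, x$site_prob))
  cat(sprintf("  log10 E-value %.1f\n", x$log10_evalue))
  if (isTRUE(x$low_complexity))
    cat("  flag: low-complexity input\n")
  invisible(x)
}

## Encode sequences (both orientations) with sentinel code 5 for padding
## or ambiguous bases; windows touching a sentinel get -Inf scores.
## Per-base indicator matrices turn window scoring and posterior base
## counting into BLAS matrix products.
em_encode <- function(sequences, strand_mode) {
  n <- length(sequences)
  lens <- nchar(sequences)
  lmax <- max(lens)
  pad_encode <- function(seqs) {
    m <- matrix(5L, nrow = n, ncol = lmax)
    for (i in seq_len(n)) {
      v <- match(strsplit(toupper(seqs[i]), "", fixed = TRUE)[[1]],
                 DNA_BASES)
      v[is.na(v)] <- 5L
      m[i, seq_len(lens[i])] <- v
    }
    list(codes = m,
         ind = lapply(1:5, function(b) (m == b) * 1))
  }
  fwd <- pad_encode(sequences)
  rc <- if (strand_mode == "both") pad_encode(revcomp(sequences)) else NULL
  tab <- tabulate(fwd$codes[fwd$codes <= 4L], 4)
  list(fwd = fwd, rc = rc, n = n, lens = lens, lmax = lmax,
       base_freq = tab / sum(tab),
       n_placements = function(w) {
         sum(pmax(lens - w + 1L, 0L)) *
           (if (strand_mode == "both") 2L else 1L)
       })
}

## L x P banded matrix carrying v[j] on the j-th superdiagonal, so that
## (indicator %*% band)[i, p] = sum_j v[j] [base at p + j - 1].
em_band <- function(v, l, p) {
  w <- length(v)
  m <- matrix(0, nrow = l, ncol = p)
  for (j in seq_len(w)) m[cbind(j:(j + p - 1L), seq_len(p))] <- v[j]
  m
}

## Window-validity mask: windows containing a sentinel are unusable.
em_valid_mask <- function(enc, w) {
  p <- ncol(enc$codes) - w + 1L
  enc$ind[[5]] %*% em_band(rep(1, w), ncol(enc$codes), p) == 0
}

## Window scores (n x P) as indicator-times-band products.
em_window_scores <- function(enc, lo, valid) {
  l <- ncol(enc$codes)
  p <- ncol(valid)
  s <- matrix(0, nrow = nrow(enc$codes), ncol = p)
  for (b in 1:4)
    s <- s + enc$ind[[b]] %*% em_band(lo[, b], l, p)
  ## finite sentinel: 2^-1e4 underflows to exactly 0, while products with
  ## zero posteriors stay finite
  s[!valid] <- -1e4
  s
}

## Posterior-weighted base counts: counts[j, b] = sum over windows of
## post[i, p] [base at p + j - 1 == b] = banded sums of crossprod.
em_counts <- function(enc, post, w) {
  p <- ncol(post)
  counts <- matrix(0, nrow = w, ncol = 4)
  for (b in 1:4) {
    cp <- crossprod(post, enc$ind[[b]])  # P x L
    for (j in seq_len(w))
      counts[j, b] <- sum(cp[cbind(seq_len(p), j:(j + p - 1L))])
  }
  counts
}

em_fit_width <- function(dat, w, palindromic, n_starts, strand_mode, mode,
                         background, pseudocount, max_iter, tol,
                         start_iters) {
  ## seed starts: random w-mers from the data
  starts <- list()
  tries <- 0
  while (length(starts) < n_starts && tries < 50 * n_starts) {
    tries <- tries + 1
    i <- sample.int(dat$n, 1)
    if (dat$lens[i] < w) next
    p0 <- sample.int(dat$lens[i] - w + 1L, 1)
    src <- if (strand_mode == "both" && stats::runif(1) < 0.5)
      dat$rc$codes else dat$fwd$codes
    codes <- src[i, p0:(p0 + w - 1L)]
    if (any(codes > 4L)) next
    probs <- matrix(0.1, nrow = w, ncol = 4)
    probs[cbind(seq_len(w), codes)] <- 0.7
    pm <- pwm(probs, background, pseudocount)
    if (palindromic) pm <- palindromize(pm)
    starts[[length(starts) + 1L]] <- pm
  }
  if (length(starts) == 0) stop("could not draw seed w-mers of width ", w)

  valid <- list(fwd = em_valid_mask(dat$fwd, w),
                rc = if (strand_mode == "both")
                  em_valid_mask(dat$rc, w) else NULL)
  short <- lapply(starts, function(pm)
    em_run(dat, pm, gamma0 = 0.5, palindromic, strand_mode, mode,
           background, pseudocount, n_iter = start_iters, tol = 0,
           valid = valid))
  lls <- vapply(short, function(f) f$log_likelihood, numeric(1))
  pick <- short[[which.max(lls)]]
  em_run(dat, pick$pwm, pick$gamma, palindromic, strand_mode, mode,
         background, pseudocount, n_iter = max_iter, tol = tol,
         ll_trace0 = pick$ll_trace, valid = valid)
}

em_run <- function(dat, pm, gamma0, palindromic, strand_mode, mode,
                   background, pseudocount, n_iter, tol,
                   ll_trace0 = numeric(0), valid = NULL) {
  gamma <- if (mode == "oops") 1 else gamma0
  w <- pm$width
  if (is.null(valid))
    valid <- list(fwd = em_valid_mask(dat$fwd, w),
                  rc = if (strand_mode == "both")
                    em_valid_mask(dat$rc, w) else NULL)
  n_pos <- pmax(dat$lens - w + 1L, 0L)
  strands <- if (strand_mode == "both") 2L else 1L
  denom <- pmax(n_pos * strands, 1L)
  ll_trace <- ll_trace0
  prev_ll <- if (length(ll_trace)) ll_trace[length(ll_trace)] else -Inf
  total_llr <- 0
  n_sites <- 0

  for (iter in seq_len(n_iter)) {
    lo <- log_odds(pm)
    s_fwd <- em_window_scores(dat$fwd, lo, valid$fwd)
    w_fwd <- 2^s_fwd
    if (strand_mode == "both") {
      s_rc <- em_window_scores(dat$rc, lo, valid$rc)
      w_rc <- 2^s_rc
      wsum <- rowSums(w_fwd) + rowSums(w_rc)
    } else {
      wsum <- rowSums(w_fwd)
    }
    prior <- gamma / denom
    z <- (1 - gamma) * (mode == "zoops") + prior * wsum
    z[z == 0] <- .Machine$double.xmin
    post_fwd <- (prior / z) * w_fwd
    ll <- sum(log(z))
    ## with pseudocounts the M-step is MAP under a Dirichlet prior, so
    ## the monotone EM objective is the penalized log-likelihood
    pen_ll <- ll + pseudocount * sum(log(pm$probs))
    ll_trace <- c(ll_trace, pen_ll)

    counts <- em_counts(dat$fwd, post_fwd, w)
    site_post <- rowSums(post_fwd)
    sc_sum <- sum(post_fwd * s_fwd)
    if (strand_mode == "both") {
      post_rc <- (prior / z) * w_rc
      counts <- counts + em_counts(dat$rc, post_rc, w)
      site_post <- site_post + rowSums(post_rc)
      sc_sum <- sc_sum + sum(post_rc * s_rc)
    }
    n_sites <- sum(site_post)
    total_llr <- sc_sum
    if (mode == "zoops") gamma <- min(max(n_sites / dat$n, 1e-6), 1 - 1e-6)
    counts <- counts + pseudocount
    pm <- pwm(counts / rowSums(counts), background, pseudocount)
    if (palindromic) pm <- palindromize(pm)

    if (is.finite(prev_ll) && pen_ll - prev_ll < tol && iter > 1) break
    prev_ll <- pen_ll
  }
  list(pwm = pm, gamma = gamma, site_prob = gamma, n_sites = n_sites,
       total_llr = total_llr, log_likelihood = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, n_sequences = dat$n)
}

## ---- E-value --------------------------------------------------------------

## Chernoff (optimized exponential-bound) log tail probability of the sum
## of n i.i.d. background site scores exceeding total_llr, from the exact
## quantized per-site score distribution. Works entirely in log space;
## the resulting E-values routinely underflow doubles.
chernoff_log_tail <- function(pm, total_llr, n_sites,
                              granularity = 0.02) {
  n <- max(n_sites, 1)
  if (total_llr <= 0) return(0)  # log(1): bound vacuous at/below the mean
  dist <- score_distribution(pm, granularity)
  s <- dist$support * granularity      # log2-unit scores
  lp <- log(dist$pmf)
  keep <- is.finite(lp)
  s <- s[keep]; lp <- lp[keep]
  obj <- function(theta) {
    k <- logsumexp(lp + theta * s)     # cumulant generating function
    n * k - theta * total_llr
  }
  opt <- stats::optimize(obj, interval = c(0, 500))
  min(opt$objective, 0)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

evalue_internal <- function(pm, total_llr, n_sites, n_placements) {
  log_tail <- chernoff_log_tail(pm, total_llr, n_sites)
  log10e <- log10(max(n_placements, 1)) + log_tail / log(10)
  list(log10_evalue = log10e, e_value = 10^log10e)
}

#' E-value of a fitted motif model
#'
#' Expected number of equally strong motifs in random background data:
#' the number of possible motif placements times the tail probability
#' that the summed site log-likelihood-ratio of `n_sites` random
#' background sites reaches the observed total. The tail is an optimized
#' exponential (Chernoff) bound computed from the same quantized
#' score-distribution dynamic program used for scan p-values, evaluated
#' in log space (these E-values routinely underflow doubles; compare
#' `log10_evalue`). Monotone decreasing in the observed total score.
#'
#' @param model A `motif_model` from [discover_motif()].
#' @param n_sequences Number of sequences searched.
#' @param alphabet_positions Sequence length (positions per sequence).
#' @return List with `e_value` (0 on underflow) and `log10_evalue`.
#' @export
evalue <- function(model, n_sequences, alphabet_positions) {
  placements <- n_sequences *
    max(alphabet_positions - model$pwm$width + 1, 1) *
    (if (identical(model$strand_mode, "forward")) 1 else 2)
  evalue_internal(model$pwm, model$total_llr, model$n_sites, placements)
}
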