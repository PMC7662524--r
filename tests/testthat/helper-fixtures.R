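# Shared fixtures and independent oracles used across the suite.

# Random PWM with Dirichlet(1) columns.
random_pwm <- function(width, background = rep(0.25, 4)) {
  g <- matrix(stats::rgamma(width * 4, shape = 1), nrow = width)
  pwm(g / rowSums(g), background)
}

random_dna <- function(n, len, prob = rep(0.25, 4)) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE,
                     prob = prob), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# Brute-force tail probability over all 4^w sequences using the same
# quantized integer column scores as the dynamic program: an
# enumeration oracle for the convolution machinery.
enumerate_tail <- function(pm, granularity = 1e-3) {
  dist <- score_distribution(pm, granularity)
  is_mat <- dist$int_scores
  total <- 0
  prob <- 1
  for (j in seq_len(pm$width)) {
    total <- as.vector(outer(total, is_mat[j, ], "+"))
    prob <- as.vector(outer(prob, pm$background, "*"))
  }
  function(int_threshold) sum(prob[total >= int_threshold])
}

# Brute-force Hamming search used as the flank-alignment oracle.
brute_hamming_find <- function(pattern, subject, max_mismatch) {
  pl <- nchar(pattern)
  pv <- strsplit(pattern, "")[[1]]
  for (i in seq_len(nchar(subject) - pl + 1)) {
    sv <- strsplit(substr(subject, i, i + pl - 1), "")[[1]]
    if (sum(pv != sv) <= max_mismatch) return(i)
  }
  NA_integer_
}

expect_palindromic <- function(pm, tol = 1e-12) {
  expect_lte(max(abs(pm$probs - revcomp_pwm(pm)$probs)), tol)
}
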