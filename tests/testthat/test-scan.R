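test_that("exact_pvalue has the forced boundary values", {
  set.seed(10)
  p <- random_pwm(5)
  dist <- score_distribution(p)
  expect_equal(sum(dist$pmf), 1, tolerance = 1e-9)
  # threshold at the minimum achievable score -> p = 1
  min_sc <- sum(apply(dist$int_scores, 1, min)) * dist$granularity
  expect_equal(exact_pvalue(p, min_sc), 1)
  # strict per-column maximum, uniform background: p(max) = (1/4)^w
  q <- pwm_from_consensus("ACGT", major = 0.97)
  expect_equal(exact_pvalue(q, max_score(q)), 0.25^4)
})

test_that("exact_pvalue equals brute-force enumeration for small widths", {
  set.seed(11)
  for (rep in 1:25) {
    w <- sample(2:8, 1)
    p <- random_pwm(w)
    dist <- score_distribution(p)
    oracle <- enumerate_tail(p)
    thresholds <- sample(dist$support, min(20, length(dist$support)))
    for (t in thresholds) {
      expect_equal(dist_p <- exact_pvalue(p, t * dist$granularity),
                   oracle(t), tolerance = 1e-9)
    }
  }
})

test_that("exact_pvalue handles non-uniform backgrounds", {
  set.seed(12)
  bg <- c(0.155, 0.345, 0.345, 0.155)
  p <- random_pwm(6, background = bg)
  oracle <- enumerate_tail(p)
  dist <- score_distribution(p)
  for (t in sample(dist$support, 10))
    expect_equal(exact_pvalue(p, t * dist$granularity), oracle(t),
                 tolerance = 1e-9)
})

test_that("benjamini_hochberg reproduces hand-computed step-up cases", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(rep(0.02, 5)), rep(0.02, 5))
  # hand-computed: q = min_j>=i (m p_(j) / j) = 0.04 throughout
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(numeric(0)), numeric(0))
  expect_error(benjamini_hochberg(c(0.1, 0)), "\\(0, 1\\]")
})

test_that("benjamini_hochberg is permutation-invariant and matches p.adjust", {
  set.seed(13)
  for (i in 1:10) {
    p <- stats::runif(50)
    q <- benjamini_hochberg(p)
    perm <- sample(50)
    expect_equal(benjamini_hochberg(p[perm]), q[perm])
    expect_equal(q, stats::p.adjust(p, method = "BH"))
  }
})

test_that("scan_genome recovers a planted consensus site exactly", {
  pm <- tthb099_pwm()
  sites <- data.frame(sequence = tthb099_consensus(), start = 2501,
                      strand = "+")
  gen <- build_synthetic_genome(6000, planted_sites = sites, seed = 21)
  hits <- scan_genome(pm, gen$sequence, p_threshold = 1e-4)
  expect_true(any(hits$start == 2501 & hits$end == 2516))
  top <- hits[which.min(hits$p_value), ]
  expect_equal(top$start, 2501)
  expect_equal(top$matched_sequence, tthb099_consensus())
  # every hit spans exactly the PWM width
  expect_true(all(hits$end - hits$start + 1 == pm$width))
  expect_true(all(hits$p_value > 0 & hits$p_value <= 1))
  expect_true(all(hits$q_value > 0 & hits$q_value <= 1))
})

test_that("palindromic hits are reported once, not per strand", {
  pm <- tthb099_pwm()
  sites <- data.frame(sequence = tthb099_consensus(), start = 501,
                      strand = "+")
  gen <- build_synthetic_genome(2000, planted_sites = sites, seed = 22)
  hits <- scan_genome(pm, gen$sequence, p_threshold = 1e-4)
  expect_equal(sum(hits$start == 501), 1)
  expect_true(all(hits$strand == "+"))
  # both strands still count as tested windows
  expect_equal(attr(hits, "n_windows"), 2 * (2000 - 16 + 1))
})

test_that("scanning is strand-consistent under genome reverse complement", {
  set.seed(23)
  pm <- random_pwm(8)  # deliberately non-palindromic
  genome <- random_dna(1, 3000)
  len <- nchar(genome)
  h1 <- scan_genome(pm, genome, p_threshold = 1e-3)
  h2 <- scan_genome(pm, revcomp(genome), p_threshold = 1e-3)
  # mirrored coordinates: start' = len - end + 1
  k1 <- sort(paste(h1$start, h1$strand))
  k2 <- sort(paste(len - h2$end + 1,
                   ifelse(h2$strand == "+", "-", "+")))
  expect_equal(k1, k2)
  expect_equal(sort(h1$p_value), sort(h2$p_value))
})

test_that("a genome shorter than the PWM yields an empty result with warning", {
  pm <- tthb099_pwm()
  expect_warning(hits <- scan_genome(pm, "ACGTACGT"), "shorter")
  expect_equal(nrow(hits), 0)
})

test_that("TSS-relative location follows the nearest-edge convention", {
  # upstream site on a + gene: negative, nearest edge
  expect_equal(tss_relative_loc(900, 915, 1000, "+"), -85)
  # downstream: positive
  expect_equal(tss_relative_loc(1010, 1025, 1000, "+"), 10)
  # spanning the TSS: upstream-edge distance, <= 0
  expect_lte(tss_relative_loc(990, 1005, 1000, "+"), 0)
  # - strand gene mirrors: upstream means larger coordinates
  expect_equal(tss_relative_loc(1040, 1055, 1030, "-"), -10)
  expect_equal(tss_relative_loc(1010, 1025, 1030, "-"), 5)
  expect_equal(tss_relative_loc(900, 915, 1000, "-"), 85)
  # vectorized over gene tables
  expect_equal(tss_relative_loc(100, 115, c(200, 90), "+"), c(-85, 10))
})

test_that("annotate_hits classifies promoter overlap with precedence", {
  genes <- data.frame(gene_id = c("gA", "gB"), strand = c("+", "-"),
                      tss = c(1000, 950),
                      operon_id = c("o1", "o2"),
                      operon_pos = c("1/2", "S"))
  elements <- data.frame(
    gene_id = c("gA", "gA", "gA"),
    element_type = c("minus35", "minus10", "plus1"),
    start = c(965, 988, 1000), end = c(970, 993, 1002))
  # hit overlapping the +1 element
  ann <- annotate_hits(data.frame(start = 990, end = 1005), genes,
                       elements)
  a <- ann[ann$gene_id == "gA", ]
  expect_equal(a$promoter_class, "overlapping_core")
  expect_lte(a$loc, 0)
  expect_true(a$proximal && a$candidate)
  # bidirectional region: one annotation per flanking gene
  expect_equal(nrow(ann), 2)
  # hit fully upstream of the -35 box
  ann2 <- annotate_hits(data.frame(start = 940, end = 955), genes,
                        elements)
  expect_equal(ann2$promoter_class[ann2$gene_id == "gA"],
               "upstream_of_minus35")
  # hit downstream of the -10 box but clear of all elements
  ann3 <- annotate_hits(data.frame(start = 1005, end = 1020), genes,
                        elements)
  expect_equal(ann3$promoter_class[ann3$gene_id == "gA"],
               "downstream_of_minus10")
  # no elements for the gene
  expect_equal(ann$promoter_class[ann$gene_id == "gB"],
               "no_promoter_found")
})

test_that("hits far from every TSS are annotated as gene-less", {
  genes <- data.frame(gene_id = "gA", strand = "+", tss = 10000,
                      operon_id = "o1", operon_pos = "S")
  ann <- annotate_hits(data.frame(start = 100, end = 115), genes)
  expect_true(is.na(ann$gene_id))
  expect_false(ann$proximal)
})

test_that("the published site table round-trips the proximal-window filter", {
  tab <- tthb099_genome_sites()
  expect_equal(nrow(tab), 25)
  # printed spans are all 16 bp (1-based inclusive coordinates)
  expect_true(all(tab$end - tab$start + 1 == 16))
  # paired rows at one locus are reverse complements of each other
  locus <- tab[tab$start == 81408, ]
  expect_equal(revcomp(locus$sequence[1]), locus$sequence[2])
  expect_equal(nrow(filter_proximal(tab)), 16)
})

test_that("planted operon-position labels survive annotation", {
  # genome mimicking a site table: sites at known Loc upstream of TSSs
  pm_w <- 16L
  locs <- c(-48, -26, -10, 13)
  ops <- c("1/3", "S", "1/2", "S")
  tss <- c(2000, 4000, 6000, 8000)
  start <- ifelse(locs < 0, tss + locs - pm_w + 1L, tss + locs)
  genes <- data.frame(gene_id = sprintf("g%d", 1:4), strand = "+",
                      tss = tss, operon_id = sprintf("o%d", 1:4),
                      operon_pos = ops)
  hits <- data.frame(start = start, end = start + pm_w - 1L)
  ann <- annotate_hits(hits, genes)
  expect_equal(ann$loc, locs)
  expect_equal(ann$operon_pos, ops)
  expect_true(all(ann$proximal))
})

test_that("BED conversion is exact in both directions", {
  hits <- data.frame(start = 81408, end = 81423, strand = "+",
                     score = 12.5)
  bed <- hits_to_bed(hits)
  expect_equal(bed$chromStart, 81407)
  expect_equal(bed$chromEnd, 81423)
  back <- bed_to_hits(bed)
  expect_equal(back$start, 81408)
  expect_equal(back$end, 81423)
})
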