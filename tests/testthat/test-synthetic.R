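test_that("selection without cleavage pressure leaves the pool composition alone", {
  cfg <- repsa_rounds(cleavage_efficiency = c(A = 0, B = 0),
                      rounds = c("A", "A", "B"))
  sel <- simulate_selection(selection_library(pool_size = 2000), cfg,
                            tthb099_pwm(), motif_fraction = 0.3, seed = 1)
  f <- sel$motif_fraction
  # resampling noise only: no systematic enrichment
  expect_true(all(abs(f - f[1]) < 0.05))
})

test_that("unprotected pools go extinct under complete cleavage", {
  cfg <- repsa_rounds(protein_concentration = 0,
                      cleavage_efficiency = c(A = 1, B = 1),
                      resistant_fraction = 0,
                      rounds = c("A", "A"))
  expect_error(
    simulate_selection(selection_library(pool_size = 500), cfg,
                       tthb099_pwm(), motif_fraction = 0.01, seed = 2),
    "round 1")
})

test_that("seven-round selection enriches the motif and the enzyme switch purges resistants", {
  sel <- simulate_selection(selection_library(pool_size = 5000),
                            repsa_rounds(), tthb099_pwm(),
                            motif_fraction = 0.01, seed = 3)
  f <- sel$motif_fraction
  r <- sel$resistant_fraction
  expect_length(f, 8)  # initial pool + 7 rounds
  # strong overall enrichment
  expect_gt(f[8], 0.9)
  expect_gt(f[8], f[1])
  # enzyme-A-resistant contaminant grows under enzyme A (rounds 1-4),
  # collapses after the switch to enzyme B (rounds 5-7)
  expect_gt(r[5], r[1])
  expect_lt(r[8], r[5] / 2)
  # trajectory is fixed by the seed
  sel2 <- simulate_selection(selection_library(pool_size = 5000),
                             repsa_rounds(), tthb099_pwm(),
                             motif_fraction = 0.01, seed = 3)
  expect_identical(sel$motif_fraction, sel2$motif_fraction)
  expect_identical(sel$cassettes, sel2$cassettes)
})

test_that("enrichment is monotone without the resistant contaminant", {
  cfg <- repsa_rounds(resistant_fraction = 0,
                      rounds = c("A", "A", "A", "A"))
  for (s in 1:5) {
    sel <- simulate_selection(selection_library(pool_size = 3000), cfg,
                              tthb099_pwm(), motif_fraction = 0.05,
                              seed = s)
    f <- sel$motif_fraction
    # allow resampling jitter once the pool saturates
    expect_true(all(diff(f) > -0.02))
    expect_gt(f[length(f)], f[1])
  }
})

test_that("a motif wider than the cassette is rejected", {
  lib <- selection_library(cassette_length = 10)
  expect_error(simulate_selection(lib, repsa_rounds(), tthb099_pwm()),
               "exceeds cassette length")
})

test_that("noise-free sensorgrams satisfy the Langmuir closed forms", {
  kon <- 131308; koff <- 2.907e-4; rmax <- 1.4
  sg <- simulate_sensorgram(kon, koff, rmax, t_assoc = 200,
                            t_dissoc = 150, dt = 0.5)
  kd <- koff / kon
  for (cc in unique(sg$concentration_M)) {
    tr <- sg[sg$concentration_M == cc, ]
    assoc <- tr[tr$phase == "association", ]
    kobs <- kon * cc + koff
    req <- rmax * cc / (cc + kd)
    expect_equal(assoc$response, req * (1 - exp(-kobs * assoc$time_s)),
                 tolerance = 1e-10)
    dis <- tr[tr$phase == "dissociation", ]
    rend <- req * (1 - exp(-kobs * 200))
    expect_equal(dis$response, rend * exp(-koff * (dis$time_s - 200)),
                 tolerance = 1e-10)
  }
})

test_that("association at C = KD plateaus at Rmax/2", {
  kon <- 1e5; koff <- 1e-3  # KD = 10 nM
  sg <- simulate_sensorgram(kon, koff, rmax = 2, concentrations = 1e-8,
                            t_assoc = 5e4, t_dissoc = 100, dt = 100)
  plateau <- max(sg$response[sg$phase == "association"])
  expect_equal(plateau, 1, tolerance = 1e-6)
})

test_that("the observed association rate constant matches kon*C + koff", {
  # published consensus-probe rates at the top analyte concentration
  kon <- 131308; koff <- 2.907e-4; cc <- 450e-9
  expect_equal(kon * cc + koff, 5.936e-2, tolerance = 1e-3)
  # and the simulated trace relaxes with exactly that constant
  sg <- simulate_sensorgram(kon, koff, 1, concentrations = cc,
                            t_assoc = 300, t_dissoc = 10, dt = 1)
  a <- sg[sg$phase == "association" & sg$time_s > 0, ]
  req <- max(a$response) / (1 - exp(-(kon * cc + koff) * 300))
  kobs_emp <- -stats::coef(stats::lm(
    log(1 - a$response[1:50] / req) ~ a$time_s[1:50] - 1))[[1]]
  expect_equal(kobs_emp, kon * cc + koff, tolerance = 1e-6)
})

test_that("seeded sensorgram noise is bit-identical across runs", {
  s1 <- simulate_sensorgram(1e5, 1e-3, 1, noise_sd = 0.02, seed = 7)
  s2 <- simulate_sensorgram(1e5, 1e-3, 1, noise_sd = 0.02, seed = 7)
  expect_identical(s1, s2)
  expect_error(simulate_sensorgram(1e5, 1e-3, dt = 0), "dt")
  expect_error(simulate_sensorgram(1e5, 1e-3,
                                   concentrations = c(1e-8, 1e-8)),
               "distinct")
})

test_that("genome building plants sequences with strand semantics", {
  cons <- tthb099_consensus()
  g1 <- build_synthetic_genome(3000, data.frame(
    sequence = cons, start = 1001, strand = "+"), seed = 4)
  expect_equal(substr(g1$sequence, 1001, 1016), cons)
  # palindrome planted on the minus strand gives the identical text
  g2 <- build_synthetic_genome(3000, data.frame(
    sequence = cons, start = 1001, strand = "-"), seed = 4)
  expect_equal(substr(g2$sequence, 1001, 1016), cons)
  # non-palindromic minus-strand plant appears reverse-complemented
  g3 <- build_synthetic_genome(3000, data.frame(
    sequence = "AAAACCCC", start = 51, strand = "-"), seed = 4)
  expect_equal(substr(g3$sequence, 51, 58), revcomp("AAAACCCC"))
  # overlap and bounds checks
  expect_error(build_synthetic_genome(3000, data.frame(
    sequence = c(cons, cons), start = c(100, 110),
    strand = c("+", "+"))), "verlapping")
  expect_error(build_synthetic_genome(100, data.frame(
    sequence = cons, start = 95, strand = "+")), "outside")
})

test_that("expression simulation plants group-mean differences", {
  sim <- simulate_expression(50, planted_logfc = c(gene0007 = 2.62),
                             noise_sd = 0.2, seed = 5)
  expect_equal(dim(sim$values), c(50, 6))
  # averaged over many seeds the estimate is centred on the truth
  est <- vapply(1:30, function(s) {
    x <- simulate_expression(50, planted_logfc = c(gene0007 = 2.62),
                             noise_sd = 0.2, seed = s)
    mean(x$values["gene0007", 1:3]) - mean(x$values["gene0007", 4:6])
  }, numeric(1))
  expect_equal(mean(est), 2.62, tolerance = 3 * 0.2 / sqrt(30))
  # null genes centred on zero
  expect_lt(abs(mean(sim$values[1, 1:3]) - mean(sim$values[1, 4:6])), 1)
  # reproducible; invalid specs rejected
  expect_identical(simulate_expression(10, seed = 9)$values,
                   simulate_expression(10, seed = 9)$values)
  expect_error(simulate_expression(10, samples_per_group = 1), "2 samples")
  expect_error(simulate_expression(10, noise_sd = 0), "noise_sd")
  expect_error(simulate_expression(10, planted_logfc = c(nope = 1)),
               "not among gene ids")
})
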