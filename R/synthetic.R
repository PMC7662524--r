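## Synthetic-data generators: selection-round simulation with known
## ground truth, read pools with planted motif instances, genomes with
## planted sites and annotation tracks, 1:1 Langmuir sensorgrams, and
## two-group expression matrices. Every generator is a pure function of
## (spec, seed).

#' Selection-library configuration
#'
#' Architecture of the randomized selection template: fixed 5' and 3'
#' primer-binding flanks around a randomized cassette. Flank sequences
#' default to synthetic 18-mers; real library primers can be supplied.
#'
#' @param flank5,flank3 Non-empty A/C/G/T strings.
#' @param cassette_length Randomized cassette length in bp (default 24).
#' @param pool_size Number of molecules carried per selection round
#'   (default 10000).
#' @param base_comp Cassette base composition (A, C, G, T), default
#'   uniform. `gc_rich_background()` gives a GC-rich preset.
#' @param seed Integer seed recorded with the configuration.
#' @return List of class `selection_library`.
#' @export
selection_library <- function(flank5 = "ACGTGACTGCAGTCAGGT",
                              flank3 = "TGACCTGATCGATCCAGT",
                              cassette_length = 24L,
                              pool_size = 10000L,
                              base_comp = rep(0.25, 4),
                              seed = 1L) {
  if (cassette_length <= 0) stop("cassette_length must be positive")
  for (f in c(flank5, flank3))
    if (nchar(f) == 0 || !grepl("^[ACGT]+$", f))
      stop("flanks must be non-empty A/C/G/T strings")
  if (abs(sum(base_comp) - 1) > 1e-9)
    stop("base_comp must sum to 1")
  structure(list(flank5 = flank5, flank3 = flank3,
                 cassette_length = as.integer(cassette_length),
                 pool_size = as.integer(pool_size),
                 base_comp = stats::setNames(base_comp, DNA_BASES),
                 seed = as.integer(seed)),
            class = "selection_library")
}

#' GC-rich background composition preset
#'
#' Thermophile-like composition with 0.345 G and 0.345 C per strand pair
#' (69% GC overall), for use as `base_comp` in the generators.
#' @return Named numeric 4-vector.
#' @export
gc_rich_background <- function() {
  stats::setNames(c(0.155, 0.345, 0.345, 0.155), DNA_BASES)
}

#' Selection-round configuration
#'
#' Parameters of one iterative-selection experiment: protein occupancy
#' protects a cassette from type IIS endonuclease cleavage; unprotected
#' molecules are cleaved with the enzyme's efficiency; a small fraction
#' of the pool is intrinsically resistant to enzyme A (the
#' cleavage-resistant artifact that motivates switching to enzyme B in
#' later rounds).
#'
#' @param protein_concentration Molar protein concentration.
#' @param reference_kd Dissociation constant of the consensus site (M).
#' @param energy_scale Dimensionless conversion from best-site log-odds
#'   deficit (log2 units) to binding free-energy penalty in kT
#'   (default 1): KD(s) = reference_kd * exp(energy_scale * deficit).
#' @param cleavage_efficiency Named fractions per enzyme label, e.g.
#'   c(A = 0.95, B = 0.8).
#' @param resistant_fraction Fraction of the initial pool intrinsically
#'   uncleavable by enzyme A (in [0, 1)).
#' @param rounds Character vector of enzyme labels, one per round, each
#'   in names(cleavage_efficiency).
#' @return List of class `repsa_rounds`.
#' @export
repsa_rounds <- function(protein_concentration = 50.6e-9,
                         reference_kd = 2.214e-9,
                         energy_scale = 1,
                         cleavage_efficiency = c(A = 0.95, B = 0.8),
                         resistant_fraction = 0.001,
                         rounds = c("A", "A", "A", "A", "B", "B", "B")) {
  if (any(cleavage_efficiency < 0 | cleavage_efficiency > 1))
    stop("cleavage_efficiency values must lie in [0, 1]")
  if (resistant_fraction < 0 || resistant_fraction >= 1)
    stop("resistant_fraction must lie in [0, 1)")
  if (!all(rounds %in% names(cleavage_efficiency)))
    stop("every round label needs a cleavage_efficiency entry")
  structure(list(protein_concentration = protein_concentration,
                 reference_kd = reference_kd,
                 energy_scale = energy_scale,
                 cleavage_efficiency = cleavage_efficiency,
                 resistant_fraction = resistant_fraction,
                 rounds = rounds),
            class = "repsa_rounds")
}

## Draw n site sequences from a PWM (each column independently).
sample_sites <- function(pm, n) {
  w <- pm$width
  m <- matrix(0L, nrow = n, ncol = w)
  for (j in seq_len(w))
    m[, j] <- sample.int(4L, n, replace = TRUE, prob = pm$probs[j, ])
  apply(m, 1, decode_dna)
}

random_cassettes <- function(n, len, base_comp) {
  m <- matrix(sample.int(4L, n * len, replace = TRUE, prob = base_comp),
              nrow = n)
  apply(m, 1, decode_dna)
}

## Plant PWM-drawn sites into cassettes at random offsets and strands.
plant_sites <- function(cassettes, pm, which_rows) {
  len <- nchar(cassettes[1])
  w <- pm$width
  if (w > len) stop("motif width exceeds cassette length")
  n <- length(which_rows)
  if (n == 0) return(cassettes)
  sites <- sample_sites(pm, n)
  flip <- stats::runif(n) < 0.5
  sites[flip] <- revcomp(sites[flip])
  offs <- sample.int(len - w + 1L, n, replace = TRUE)
  for (k in seq_len(n)) {
    i <- which_rows[k]
    substr(cassettes[i], offs[k], offs[k] + w - 1L) <- sites[k]
  }
  cassettes
}

#' Simulate a selection-round read pool with planted motif instances
#'
#' Generates `n` full-length reads (flank5 + randomized cassette +
#' flank3) in which a fraction of cassettes carry one motif instance
#' drawn from `pm` at a uniform offset and strand — the composition of a
#' late selection round, generated directly rather than by running the
#' round dynamics.
#'
#' @param n Number of reads.
#' @param library A [selection_library()].
#' @param pm A [pwm] to draw planted sites from.
#' @param plant_fraction Fraction of cassettes carrying a site
#'   (default 0.6).
#' @param seed Integer seed.
#' @return List with `reads`, `cassettes`, and logical `planted` ground
#'   truth.
#' @export
simulate_read_pool <- function(n, library = selection_library(), pm,
                               plant_fraction = 0.6, seed = 1L) {
  set.seed(seed)
  cass <- random_cassettes(n, library$cassette_length, library$base_comp)
  planted <- stats::runif(n) < plant_fraction
  cass <- plant_sites(cass, pm, which(planted))
  reads <- paste0(library$flank5, cass, library$flank3)
  list(reads = reads, cassettes = cass, planted = planted)
}

#' Simulate iterative selection (binding, cleavage, amplification)
#'
#' Each round, a cassette survives with probability
#' `occupancy + (1 - occupancy) * (1 - cleavage_efficiency)`, where
#' occupancy follows the protein concentration and a per-cassette KD set
#' by its best site on either strand:
#' `KD(s) = reference_kd * exp(energy_scale * deficit)` with deficit the
#' best-site log-odds shortfall versus the consensus. Molecules flagged
#' resistant ignore enzyme-A cleavage entirely. Survivors are resampled
#' with replacement to the configured pool size (uniform-multinomial
#' PCR; no amplification bias).
#'
#' @param library A [selection_library()].
#' @param round_cfg A [repsa_rounds()].
#' @param pm A [pwm]; its width must not exceed the cassette length.
#' @param motif_fraction Fraction of the initial pool seeded with one
#'   planted site drawn from `pm` (default 0.01); the planted flag is the
#'   tracked ground truth.
#' @param seed Integer seed.
#' @return List of class `selection_pools`: `motif_fraction` and
#'   `resistant_fraction` per round (index 1 = initial pool), `reads`
#'   (list of per-round read vectors), `cassettes` (final pool), and the
#'   configurations.
#' @export
simulate_selection <- function(library = selection_library(),
                               round_cfg = repsa_rounds(), pm,
                               motif_fraction = 0.01, seed = 1L) {
  if (pm$width > library$cassette_length)
    stop("motif width (", pm$width, ") exceeds cassette length (",
         library$cassette_length, ")")
  set.seed(seed)
  n <- library$pool_size
  cass <- random_cassettes(n, library$cassette_length, library$base_comp)
  planted <- stats::runif(n) < motif_fraction
  cass <- plant_sites(cass, pm, which(planted))
  resistant <- stats::runif(n) < round_cfg$resistant_fraction

  smax <- max_score(pm)
  conc <- round_cfg$protein_concentration
  frac_motif <- mean(planted)
  frac_res <- mean(resistant)
  reads <- list(paste0(library$flank5, cass, library$flank3))

  for (r in seq_along(round_cfg$rounds)) {
    enz <- round_cfg$rounds[r]
    eff <- round_cfg$cleavage_efficiency[[enz]]
    best <- best_site_scores(cass, pm)
    kd <- round_cfg$reference_kd *
      exp(round_cfg$energy_scale * (smax - best))
    occ <- conc / (conc + kd)
    p_survive <- occ + (1 - occ) * (1 - eff)
    if (enz == "A") p_survive[resistant] <- 1
    alive <- stats::runif(n) < p_survive
    if (!any(alive))
      stop("selection pool extinct after round ", r, " (enzyme ", enz, ")")
    idx <- sample(which(alive), n, replace = TRUE)
    cass <- cass[idx]; planted <- planted[idx]; resistant <- resistant[idx]
    frac_motif <- c(frac_motif, mean(planted))
    frac_res <- c(frac_res, mean(resistant))
    reads[[r + 1L]] <- paste0(library$flank5, cass, library$flank3)
  }
  structure(list(motif_fraction = frac_motif,
                 resistant_fraction = frac_res,
                 reads = reads, cassettes = cass,
                 library = library, round_cfg = round_cfg),
            class = "selection_pools")
}

## Best-site log-odds score over both strands for each cassette.
best_site_scores <- function(cassettes, pm) {
  m <- encode_dna_matrix(cassettes)
  lo <- log_odds(pm)
  g <- 1e-6
  is_mat <- matrix(as.integer(round(lo / g)), nrow = pm$width)
  score_best <- function(mm) {
    w <- pm$width
    p <- ncol(mm) - w + 1L
    s <- matrix(0, nrow = nrow(mm), ncol = p)
    for (j in seq_len(w))
      s <- s + matrix(is_mat[j, ][mm[, j:(j + p - 1L), drop = FALSE]],
                      nrow = nrow(mm))
    apply(s, 1, max) * g
  }
  pmax(score_best(m), score_best(encode_dna_matrix(revcomp(cassettes))))
}

## ---- sensorgrams ----------------------------------------------------------

#' Simulate 1:1 Langmuir sensorgrams
#'
#' Noise-free association phase
#' `R(t) = Rmax * C / (C + KD) * (1 - exp(-(kon*C + koff) * t))` and
#' dissociation `R(t') = R_end * exp(-koff * t')`, with additive Gaussian
#' noise. One trace per analyte concentration.
#'
#' @param kon Association rate constant (1/(M s)).
#' @param koff Dissociation rate constant (1/s).
#' @param rmax Maximal response (response units).
#' @param concentrations Distinct analyte concentrations (M); default the
#'   four-point dilution series 17, 50, 150, 450 nM.
#' @param t_assoc,t_dissoc Phase durations (s).
#' @param dt Sampling interval (s), must be positive.
#' @param noise_sd Gaussian noise SD (response units).
#' @param seed Integer seed.
#' @return `data.frame` with columns time_s, response, concentration_M,
#'   phase ("association"/"dissociation"); the phase boundary is
#'   `t_assoc`.
#' @export
simulate_sensorgram <- function(kon, koff, rmax = 1,
                                concentrations = c(17, 50, 150, 450) * 1e-9,
                                t_assoc = 300, t_dissoc = 300, dt = 1,
                                noise_sd = 0, seed = 1L) {
  if (dt <= 0) stop("dt must be positive")
  if (kon <= 0 || koff <= 0 || rmax <= 0 || t_assoc <= 0 || t_dissoc <= 0)
    stop("rates, rmax, and phase durations must be positive")
  if (anyDuplicated(concentrations))
    stop("concentrations must be distinct")
  set.seed(seed)
  kd <- koff / kon
  out <- lapply(concentrations, function(cc) {
    ta <- seq(0, t_assoc, by = dt)
    td <- seq(dt, t_dissoc, by = dt)
    req <- rmax * cc / (cc + kd)
    kobs <- kon * cc + koff
    ra <- req * (1 - exp(-kobs * ta))
    rend <- req * (1 - exp(-kobs * t_assoc))
    rd <- rend * exp(-koff * td)
    data.frame(
      time_s = c(ta, t_assoc + td),
      response = c(ra, rd) +
        if (noise_sd > 0) stats::rnorm(length(ta) + length(td),
                                       sd = noise_sd) else 0,
      concentration_M = cc,
      phase = c(rep("association", length(ta)),
                rep("dissociation", length(td))),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "phase_boundary") <- t_assoc
  res
}

## ---- genomes --------------------------------------------------------------

#' Build a synthetic genome with planted sites and annotation tracks
#'
#' Background sequence is drawn from `base_comp`; planted site sequences
#' are written at their stated 1-based coordinates (reverse-complemented
#' first when strand is "-"). Gene models (TSS, operon position) and
#' promoter elements are carried through as annotation tables.
#'
#' @param length Genome length (bp).
#' @param planted_sites Optional `data.frame` with columns sequence,
#'   start, strand. Overlapping planted sites are an error.
#' @param genes Optional `data.frame` with columns gene_id, strand, tss,
#'   operon_id, operon_pos.
#' @param elements Optional `data.frame` with columns gene_id,
#'   element_type, start, end (start <= end required).
#' @param base_comp Background base composition (default uniform).
#' @param seed Integer seed.
#' @return List of class `synthetic_genome`: `sequence` (string),
#'   `genes`, `elements`, `planted_sites`.
#' @export
build_synthetic_genome <- function(length, planted_sites = NULL,
                                   genes = NULL, elements = NULL,
                                   base_comp = rep(0.25, 4), seed = 1L) {
  set.seed(seed)
  genome <- random_cassettes(1L, length, base_comp)
  if (!is.null(planted_sites) && nrow(planted_sites) > 0) {
    ps <- planted_sites
    ps$end <- ps$start + nchar(ps$sequence) - 1L
    if (any(ps$start < 1L | ps$end > length))
      stop("planted site coordinates fall outside the genome")
    o <- order(ps$start)
    if (nrow(ps) > 1) {
      so <- ps[o, ]
      bad <- which(so$start[-1] <= so$end[-nrow(so)])
      if (length(bad))
        stop("overlapping planted sites at starts: ",
             paste(so$start[c(bad, bad + 1L)], collapse = ", "))
    }
    for (i in seq_len(nrow(ps))) {
      sq <- toupper(ps$sequence[i])
      if (identical(ps$strand[i], "-")) sq <- revcomp(sq)
      substr(genome, ps$start[i], ps$end[i]) <- sq
    }
  }
  if (!is.null(elements) && nrow(elements) > 0 &&
      any(elements$start > elements$end))
    stop("promoter element intervals must satisfy start <= end")
  structure(list(sequence = genome, genes = genes, elements = elements,
                 planted_sites = planted_sites),
            class = "synthetic_genome")
}

## ---- expression -----------------------------------------------------------

#' Simulate a two-group log2 expression matrix with planted fold-changes
#'
#' Emulates a deficient-versus-wild-type microarray comparison: per-gene
#' baseline log2 intensities, group means separated by the planted log2
#' fold-change (test minus control), i.i.d. Gaussian noise.
#'
#' @param n_genes Number of genes.
#' @param samples_per_group Samples per group (>= 2; default 3).
#' @param planted_logfc Named numeric: log2 fold-changes for a subset of
#'   gene ids ("gene0001" style names); unnamed genes get 0.
#' @param noise_sd Log2-scale noise SD (> 0; default 0.2).
#' @param operon_map Optional named character: gene_id -> operon_id.
#' @param seed Integer seed.
#' @return List of class `expression_sim`: `values` (genes x samples),
#'   `groups` ("test"/"control" per sample), `truth` (per-gene planted
#'   logFC), `operon_map`.
#' @export
simulate_expression <- function(n_genes, samples_per_group = 3,
                                planted_logfc = numeric(0),
                                noise_sd = 0.2, operon_map = NULL,
                                seed = 1L) {
  if (samples_per_group < 2) stop("need at least 2 samples per group")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  set.seed(seed)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  unknown <- setdiff(names(planted_logfc), gene_ids)
  if (length(unknown))
    stop("planted_logfc names not among gene ids: ",
         paste(unknown, collapse = ", "))
  truth <- stats::setNames(rep(0, n_genes), gene_ids)
  truth[names(planted_logfc)] <- planted_logfc
  baseline <- stats::rnorm(n_genes, mean = 8, sd = 1.5)
  k <- samples_per_group
  values <- cbind(
    matrix(stats::rnorm(n_genes * k, mean = baseline + truth,
                        sd = noise_sd), nrow = n_genes),
    matrix(stats::rnorm(n_genes * k, mean = baseline, sd = noise_sd),
           nrow = n_genes))
  rownames(values) <- gene_ids
  colnames(values) <- c(sprintf("test_%d", seq_len(k)),
                        sprintf("control_%d", seq_len(k)))
  structure(list(values = values,
                 groups = rep(c("test", "control"), each = k),
                 truth = truth, operon_map = operon_map),
            class = "expression_sim")
}
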