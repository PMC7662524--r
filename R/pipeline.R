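## End-to-end orchestration: simulate -> prep -> discover -> scan/annotate
## -> kinetic fit -> differential expression, with plain-file handoffs
## between stages and a reproducible run manifest.

#' Pipeline configuration
#'
#' Per-stage parameter blocks with a global seed. Every stochastic stage
#' derives its seed from the global one, so a rerun with the same
#' configuration is bit-identical. `validate_pipeline_config()` is run
#' before execution and fails fast on missing inputs.
#'
#' @param outdir Output directory for stage files.
#' @param seed Global integer seed.
#' @param n_reads Reads simulated for the selection pool.
#' @param plant_fraction Fraction of cassettes carrying a planted site.
#' @param library A [selection_library()].
#' @param generating_pwm PWM used to plant sites (default
#'   [tthb099_pwm()]).
#' @param width_range,n_starts Motif-discovery controls.
#' @param sample_n Cassettes sampled for discovery (NULL = all).
#' @param genome_length,n_genome_sites Synthetic genome controls.
#' @param p_threshold Scan report threshold.
#' @param window Proximal annotation window.
#' @param kinetics List with kon, koff, rmax, noise_sd for the simulated
#'   sensorgrams.
#' @param n_genes,planted_logfc,noise_sd Expression-stage controls.
#' @param genome_fasta Optional path to a genome FASTA; when given, the
#'   synthetic-genome stage is skipped and this file is scanned instead
#'   (gene annotations then come from `genes_tsv`).
#' @param genes_tsv Optional path to a gene-annotation TSV.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("repsamotif_run_"),
                            seed = 1L,
                            n_reads = 1000,
                            plant_fraction = 0.6,
                            library = selection_library(),
                            generating_pwm = tthb099_pwm(),
                            width_range = c(6, 24),
                            n_starts = 10,
                            sample_n = NULL,
                            genome_length = 20000L,
                            n_genome_sites = 5L,
                            p_threshold = 1e-4,
                            window = c(-200, 20),
                            kinetics = list(kon = 131308,
                                            koff = 2.907e-4,
                                            rmax = 1, noise_sd = 0),
                            n_genes = 200L,
                            planted_logfc = c(gene0001 = 2.62),
                            noise_sd = 0.2,
                            genome_fasta = NULL,
                            genes_tsv = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("genome_fasta", "genes_tsv")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("configured file does not exist: ", f, " = ", p)
  }
  if (!is.null(config$genome_fasta) && is.null(config$genes_tsv))
    stop("genes_tsv is required when genome_fasta is supplied")
  if (config$width_range[1] > config$width_range[2])
    stop("width_range min exceeds max")
  invisible(TRUE)
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML document override [pipeline_config()]
#' defaults.
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Executes simulate -> prep -> discover -> scan/annotate -> kinetic fit
#' -> differential expression. Each stage writes its output under
#' `config$outdir` and the next stage consumes the serialized file, so
#' any stage can be rerun alone from its inputs. Returns a manifest
#' recording per-stage parameters, output files and their MD5 hashes.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return List of class `run_manifest`: `stages` (per-stage file/hash
#'   records), `results` (in-memory stage outputs), `seed`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  validate_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- list()
  results <- list()
  record <- function(stage, files, params) {
    stages[[stage]] <<- list(
      files = files,
      md5 = tools::md5sum(files),
      params = params,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }

  ## 1. simulate selection reads
  pool <- simulate_read_pool(config$n_reads, config$library,
                             config$generating_pwm,
                             config$plant_fraction, seed = seed)
  reads_fa <- file.path(config$outdir, "reads.fasta")
  write_fasta(pool$reads, reads_fa)
  record("simulate", reads_fa,
         list(n_reads = config$n_reads,
              plant_fraction = config$plant_fraction))
  results$pool <- pool
  say("simulate: %d reads (%.0f%% with planted site)",
      config$n_reads, 100 * mean(pool$planted))

  ## 2. read preparation
  reads_in <- read_fasta(reads_fa)
  prepped <- prep_reads(reads_in, config$library)
  cass_fa <- file.path(config$outdir, "cassettes.fasta")
  write_fasta(prepped$sequences, cass_fa)
  record("prep", cass_fa, list(stats = prepped$stats))
  results$cassettes <- prepped
  say("prep: %d/%d reads yielded %d unique cassettes",
      prepped$stats[["length_passed"]], prepped$stats[["input"]],
      prepped$stats[["deduplicated"]])

  ## 3. motif discovery (palindromic, both strands)
  cass <- read_fasta(cass_fa)
  disc_in <- if (!is.null(config$sample_n))
    sample_reads(unname(cass), config$sample_n, seed = seed + 1L)
    else unname(cass)
  model <- discover_motif(disc_in, width_range = config$width_range,
                          palindromic = TRUE,
                          n_starts = config$n_starts, seed = seed + 2L)
  motif_file <- file.path(config$outdir, "motif.meme")
  write_meme(model, motif_file, name = "selected_motif")
  record("discover", motif_file,
         list(width = model$width,
              log10_evalue = model$log10_evalue,
              consensus = consensus_string(model$pwm)))
  results$model <- model
  say("discover: width %d, consensus %s, log10 E %.1f", model$width,
      argmax_consensus(model$pwm), model$log10_evalue)

  ## 4. genome scan + annotation
  if (is.null(config$genome_fasta)) {
    gen <- pipeline_synthetic_genome(config, seed + 3L)
    genome_fa <- file.path(config$outdir, "genome.fasta")
    write_fasta(c(genome = gen$sequence), genome_fa)
    genes_tsv <- file.path(config$outdir, "genes.tsv")
    write_tsv_table(gen$genes, genes_tsv)
    results$genome <- gen
  } else {
    genome_fa <- config$genome_fasta
    genes_tsv <- config$genes_tsv
  }
  scan_pwm <- read_meme(motif_file)
  hits <- scan_genome(scan_pwm, genome_fa,
                      p_threshold = config$p_threshold)
  genes <- read_tsv_table(genes_tsv)
  ann <- annotate_hits(hits, genes, window = config$window)
  hits_tsv <- file.path(config$outdir, "hits.tsv")
  write_tsv_table(hits, hits_tsv)
  ann_tsv <- file.path(config$outdir, "annotations.tsv")
  write_tsv_table(ann, ann_tsv)
  record("scan", c(hits_tsv, ann_tsv),
         list(p_threshold = config$p_threshold,
              n_hits = nrow(hits),
              n_proximal = sum(ann$proximal)))
  results$hits <- hits
  results$annotations <- ann
  say("scan: %d hits, %d proximal annotations", nrow(hits),
      sum(ann$proximal))

  ## 5. kinetic fit on simulated sensorgrams
  kin <- config$kinetics
  sg <- simulate_sensorgram(kin$kon, kin$koff, kin$rmax,
                            noise_sd = kin$noise_sd, seed = seed + 4L)
  sg_csv <- file.path(config$outdir, "sensorgrams.csv")
  write_sensorgrams(sg, sg_csv)
  fit <- fit_global(read_sensorgrams(sg_csv))
  record("blifit", sg_csv,
         list(kon = fit$kon, koff = fit$koff, kd = fit$kd,
              r_squared = fit$r_squared))
  results$fit <- fit
  say("blifit: kon %.4g, koff %.4g, KD %.4g M, R^2 %.4f",
      fit$kon, fit$koff, fit$kd, fit$r_squared)

  ## 6. differential expression
  sim <- simulate_expression(config$n_genes,
                             planted_logfc = config$planted_logfc,
                             noise_sd = config$noise_sd,
                             seed = seed + 5L)
  expr_tsv <- file.path(config$outdir, "expression.tsv")
  write_expression_tsv(sim, expr_tsv)
  mat <- read_expression_tsv(expr_tsv)
  dge <- differential_expression(mat$values, mat$groups)
  dge_tsv <- file.path(config$outdir, "dge.tsv")
  write_tsv_table(dge, dge_tsv)
  record("dge", c(expr_tsv, dge_tsv),
         list(n_genes = config$n_genes,
              n_significant = sum(dge$adj_p < 0.05)))
  results$dge <- dge
  say("dge: %d genes, %d significant at adj p < 0.05",
      nrow(dge), sum(dge$adj_p < 0.05))

  structure(list(stages = stages, results = results, seed = seed,
                 config = config),
            class = "run_manifest")
}

## Synthetic genome for the scan stage: plants consensus-model draws in
## bidirectional promoter regions upstream of annotated TSSs.
pipeline_synthetic_genome <- function(config, seed) {
  set.seed(seed)
  n <- config$n_genome_sites
  len <- config$genome_length
  spacing <- floor(len / (n + 1))
  starts <- spacing * seq_len(n)
  sites <- data.frame(
    sequence = sample_sites(config$generating_pwm, n),
    start = starts,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  w <- config$generating_pwm$width
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    strand = "+",
    tss = starts + w - 1L + 50L,   # sites sit at Loc ~ -50
    operon_id = sprintf("op%03d", seq_len(n)),
    operon_pos = "1/2",
    stringsAsFactors = FALSE)
  build_synthetic_genome(len, planted_sites = sites, genes = genes,
                         base_comp = config$library$base_comp,
                         seed = seed)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d): %d stages\n", x$seed,
              length(x$stages)))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-9s %s\n", nm,
                paste(basename(st$files), collapse = ", ")))
  }
  invisible(x)
}

## ---- expression TSV with two header rows ----------------------------------

#' Write/read a two-group expression matrix TSV
#'
#' Genes x samples, header row of sample ids, second header row of group
#' labels ("test"/"control"), then one row per gene.
#'
#' @param x An `expression_sim` or a list with `values` and `groups`.
#' @param path File path.
#' @return `path` invisibly; `read_expression_tsv` returns a list with
#'   `values` and `groups`.
#' @export
write_expression_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x$values)), collapse = "\t"),
             con)
  writeLines(paste(c("group", x$groups), collapse = "\t"), con)
  utils::write.table(
    cbind(gene_id = rownames(x$values), as.data.frame(x$values)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  grp <- strsplit(lines[2], "\t")[[1]]
  d <- utils::read.delim(text = lines[-2], stringsAsFactors = FALSE)
  values <- as.matrix(d[, -1, drop = FALSE])
  rownames(values) <- d[[1]]
  colnames(values) <- hdr[-1]
  list(values = values, groups = grp[-1])
}
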