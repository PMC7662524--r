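## File formats: FASTA (via Biostrings), MEME minimal motif exchange
## format, sensorgram CSV, annotation/expression TSV, BED conversion,
## and accessors for the bundled published reference tables.

#' Read sequences from a FASTA/FASTQ file
#' @param path File path.
#' @return Named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq"
         else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(ss), names(ss))
}

#' Write sequences to a FASTA file
#' @param sequences Named (or unnamed) character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  nm <- names(sequences)
  if (is.null(nm)) nm <- sprintf("seq%06d", seq_along(sequences))
  ss <- Biostrings::DNAStringSet(unname(sequences))
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## ---- MEME minimal format --------------------------------------------------

#' Write a PWM in MEME minimal motif format
#'
#' Version header, alphabet, strand line, background frequencies, and a
#' letter-probability matrix block with nsites and E-value fields — the
#' interchange format consumed by motif scanners.
#'
#' @param x A [pwm] or `motif_model`.
#' @param path Output path.
#' @param name Motif name (default "MOTIF1").
#' @param nsites,e_value Fields for the letter-probability header; taken
#'   from a `motif_model` automatically.
#' @return `path`, invisibly.
#' @export
write_meme <- function(x, path, name = "MOTIF1", nsites = 20,
                       e_value = 0) {
  if (inherits(x, "motif_model")) {
    nsites <- max(1, round(x$n_sites))
    e_value <- x$e_value
    x <- x$pwm
  }
  stopifnot(inherits(x, "pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 5",
    "",
    "ALPHABET= ACGT",
    "",
    "strands: + -",
    "",
    "Background letter frequencies",
    paste(sprintf("%s %.8f", DNA_BASES, x$background), collapse = " "),
    "",
    paste("MOTIF", name),
    sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= %.3g",
      x$width, nsites, e_value)),
    con)
  for (j in seq_len(x$width))
    writeLines(paste(sprintf("%12.8f", x$probs[j, ]), collapse = " "),
               con)
  invisible(path)
}

#' Read a PWM from a MEME minimal motif file
#'
#' @param path File path.
#' @return A [pwm] with attributes `name`, `nsites`, `e_value`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bg <- vals[!is.na(vals)][1:4]
    bg <- bg / sum(bg)
  }
  hdr_at <- grep("^letter-probability matrix:", lines)
  if (!length(hdr_at))
    stop("no letter-probability matrix block in ", path)
  hdr <- lines[hdr_at[1]]
  get_field <- function(key, default) {
    m <- regmatches(hdr, regexec(paste0(key, "=\\s*([0-9.eE+-]+)"), hdr))[[1]]
    if (length(m) == 2) as.numeric(m[2]) else default
  }
  w <- as.integer(get_field("w", NA))
  if (is.na(w)) stop("malformed matrix header at line ", hdr_at[1])
  rows <- lines[(hdr_at[1] + 1):(hdr_at[1] + w)]
  probs <- do.call(rbind, lapply(seq_along(rows), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]),
                                              "\\s+")[[1]]))
    if (length(v) != 4 || anyNA(v))
      stop("malformed matrix row at line ", hdr_at[1] + i)
    v
  }))
  probs <- probs / rowSums(probs)
  name_at <- grep("^MOTIF\\b", lines)
  out <- pwm(probs, bg)
  attr(out, "name") <- if (length(name_at))
    sub("^MOTIF\\s+", "", lines[name_at[1]]) else NA_character_
  attr(out, "nsites") <- get_field("nsites", NA)
  attr(out, "e_value") <- get_field("E", NA)
  out
}

## ---- tabular formats ------------------------------------------------------

#' Read sensorgrams from CSV
#'
#' Expected columns: time_s, response, concentration_M, phase.
#' @param path File path.
#' @return `data.frame`.
#' @export
read_sensorgrams <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "response", "concentration_M", "phase")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("sensorgram CSV missing columns: ", paste(miss, collapse = ", "))
  d
}

#' Write sensorgrams to CSV
#' @param sensorgrams `data.frame` with the sensorgram columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensorgrams <- function(sensorgrams, path) {
  utils::write.csv(sensorgrams, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a TSV table
#'
#' Plain tab-separated exchange for annotation tables, hit lists and
#' differential-expression output.
#' @param path File path.
#' @return `data.frame` (`read_tsv_table`) or `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param x `data.frame` to write.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Convert 1-based inclusive hits to BED6 (0-based half-open) and back
#'
#' @param hits Hits `data.frame` with start, end, strand and optionally
#'   matched_sequence, score.
#' @param name_prefix Feature-name prefix for BED output.
#' @return `hits_to_bed`: BED6 `data.frame` (chrom, chromStart,
#'   chromEnd, name, score, strand); `bed_to_hits`: the 1-based inclusive
#'   converse.
#' @export
hits_to_bed <- function(hits, name_prefix = "site") {
  data.frame(
    chrom = if ("chrom" %in% names(hits)) hits$chrom else "genome",
    chromStart = hits$start - 1L,
    chromEnd = hits$end,
    name = sprintf("%s%04d", name_prefix, seq_len(nrow(hits))),
    score = if ("score" %in% names(hits)) round(hits$score, 3) else 0,
    strand = if ("strand" %in% names(hits)) hits$strand else "+",
    stringsAsFactors = FALSE)
}

#' @rdname hits_to_bed
#' @param bed BED6 `data.frame`.
#' @export
bed_to_hits <- function(bed) {
  data.frame(start = bed$chromStart + 1L, end = bed$chromEnd,
             strand = bed$strand, score = bed$score,
             stringsAsFactors = FALSE)
}

## ---- bundled reference tables --------------------------------------------

ref_table <- function(fname) {
  path <- system.file("extdata", fname, package = "repsamotif")
  if (path == "") path <- file.path("inst", "extdata", fname)
  read_tsv_table(path)
}

#' Published TTHB099 reference tables
#'
#' Transcriptions of the published measurements bundled with the
#' package: `tthb099_consensus_kinetics()` — biolayer-interferometry rate
#' constants for the consensus probe, its point mutants, and the
#' consensus-plus-cAMP control; `tthb099_site_kinetics()` — rate
#' constants for the genome-identified promoter-site probes (a dash row
#' means no apparent binding); `tthb099_genome_sites()` — the top 25
#' genome-scan matches with TSS-relative location (Loc) and operon
#' position per annotated gene.
#'
#' @return `data.frame` of the requested table.
#' @export
tthb099_consensus_kinetics <- function() {
  ref_table("tthb099_consensus_kinetics.tsv")
}

#' @rdname tthb099_consensus_kinetics
#' @export
tthb099_site_kinetics <- function() ref_table("tthb099_site_kinetics.tsv")

#' @rdname tthb099_consensus_kinetics
#' @export
tthb099_genome_sites <- function() ref_table("tthb099_genome_sites.tsv")

#' The published TTHB099 consensus binding site
#'
#' The 16-bp palindromic consensus `TGTATTCTAGAATACA`.
#' @return A single string.
#' @export
tthb099_consensus <- function() "TGTATTCTAGAATACA"

#' Degenerate motif model of the TTHB099 binding site
#'
#' A palindromic 16-column PWM encoding the published degeneracy
#' pattern TGT(A/g)n(t/c)c(t/c)(a/g)g(a/g)n(T/c)ACA: strongly conserved
#' outer TGT/ACA trimers, a weakly preferred central core, and
#' near-uniform spacer positions given a slight tilt toward the
#' consensus base (a learned matrix is never exactly uniform). The
#' argmax consensus equals [tthb099_consensus()]. Used as the generating
#' model when planting sites in synthetic pools.
#'
#' @param background Background base probabilities (default uniform).
#' @return A palindromic [pwm].
#' @export
tthb099_pwm <- function(background = rep(0.25, 4)) {
  col_upper <- function(b) { p <- rep(0.03, 4); p[b] <- 0.91; p }
  col_pair <- function(b1, b2, p1 = 0.55, p2 = 0.30) {
    p <- rep((1 - p1 - p2) / 2, 4); p[b1] <- p1; p[b2] <- p2; p
  }
  col_weak <- function(b) { p <- rep(0.15, 4); p[b] <- 0.55; p }
  col_spacer <- function(b) { p <- rep(0.23, 4); p[b] <- 0.31; p }
  A <- 1L; C <- 2L; G <- 3L; T <- 4L
  half <- rbind(
    col_upper(T),        # 1  T
    col_upper(G),        # 2  G
    col_upper(T),        # 3  T
    col_pair(A, G),      # 4  (A/g)
    col_spacer(T),       # 5  n, tilted to consensus T
    col_pair(T, C),      # 6  (t/c)
    col_weak(C),         # 7  c
    col_pair(T, C))      # 8  (t/c)
  probs <- rbind(half, half[8:1, c(4, 3, 2, 1)])
  palindromize(pwm(probs, background))
}
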