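## Read preparation: mismatch-tolerant flank location, cassette
## extraction with orientation rescue, deduplication, and seeded
## subsampling.

## Hamming-tolerant first match of `pattern` in `subject` (plain
## character strings, no indels); returns start or NA.
hamming_find <- function(pattern, subject, max_mismatch) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                   max.mismatch = max_mismatch,
                                   with.indels = FALSE)
  if (length(hits) == 0) return(NA_integer_)
  Biostrings::start(hits)[1]
}

#' Extract the randomized cassette from a selection read
#'
#' Locates the 5' and 3' flanks with at most `max_mismatch` substitutions
#' each (no indels) and returns the between-flank substring if it has the
#' configured cassette length. If the forward orientation fails, the
#' reverse complement of the read is tried (sequencing orientation of a
#' double-stranded cassette is arbitrary).
#'
#' @param read DNA string.
#' @param library A [selection_library()].
#' @param max_mismatch Maximum substitutions per flank (default 1).
#' @return List with `cassette` (string or NA), `status` ("ok",
#'   "flank5_not_found", "flank3_not_found", or "bad_length"), and
#'   `orientation` ("forward"/"reverse" or NA).
#' @export
extract_cassette <- function(read, library = selection_library(),
                             max_mismatch = 1) {
  if (max_mismatch < 0) stop("max_mismatch must be >= 0")
  try_one <- function(sq) {
    p5 <- hamming_find(library$flank5, sq, max_mismatch)
    if (is.na(p5)) return(list(status = "flank5_not_found"))
    cass_start <- p5 + nchar(library$flank5)
    rest_from <- cass_start
    if (rest_from > nchar(sq)) return(list(status = "flank3_not_found"))
    p3rel <- hamming_find(library$flank3,
                          substr(sq, rest_from, nchar(sq)), max_mismatch)
    if (is.na(p3rel)) return(list(status = "flank3_not_found"))
    cass <- substr(sq, cass_start, rest_from + p3rel - 2L)
    if (nchar(cass) != library$cassette_length)
      return(list(status = "bad_length"))
    list(status = "ok", cassette = cass)
  }
  fwd <- try_one(read)
  if (identical(fwd$status, "ok"))
    return(list(cassette = fwd$cassette, status = "ok",
                orientation = "forward"))
  rev <- try_one(revcomp(read))
  if (identical(rev$status, "ok"))
    return(list(cassette = rev$cassette, status = "ok",
                orientation = "reverse"))
  list(cassette = NA_character_, status = fwd$status,
       orientation = NA_character_)
}

#' Prepare selection reads for motif discovery
#'
#' Runs [extract_cassette()] over a read set, optionally applies a mean
#' base-quality filter, deduplicates, and reports per-stage counts. This
#' is the conversion of raw selection-round sequencing into the
#' deduplicated cassette set used for consensus determination.
#'
#' @param reads Character vector of read sequences, or a named list with
#'   `sequence` and optional `quality` (per-base Phred scores) elements.
#' @param library A [selection_library()].
#' @param max_mismatch Per-flank substitution tolerance (default 1).
#' @param dedup_mode "exact" (default) or "strand_collapsed"; see
#'   [deduplicate()].
#' @param min_mean_quality Optional mean Phred score threshold (default
#'   NULL: no quality filtering).
#' @return A `cassette_set` list: `sequences` (deduplicated cassettes),
#'   `provenance` (cassette -> source read ids), `stats` (input,
#'   quality_passed, flank_matched, length_passed, deduplicated counts),
#'   and `rejections` (reason per rejected read).
#' @export
prep_reads <- function(reads, library = selection_library(),
                       max_mismatch = 1,
                       dedup_mode = c("exact", "strand_collapsed"),
                       min_mean_quality = NULL) {
  dedup_mode <- match.arg(dedup_mode)
  if (is.list(reads) && !is.null(reads$sequence)) {
    seqs <- reads$sequence
    quals <- reads$quality
  } else {
    seqs <- as.character(reads)
    quals <- NULL
  }
  ids <- if (!is.null(names(seqs))) names(seqs) else
    sprintf("read%06d", seq_along(seqs))
  n_input <- length(seqs)

  if (!is.null(min_mean_quality) && !is.null(quals)) {
    keep <- vapply(quals, function(q) mean(q) >= min_mean_quality,
                   logical(1))
  } else keep <- rep(TRUE, n_input)
  n_qual <- sum(keep)

  status <- rep("quality_failed", n_input)
  cass <- rep(NA_character_, n_input)
  for (i in which(keep)) {
    r <- extract_cassette(seqs[i], library, max_mismatch)
    status[i] <- r$status
    cass[i] <- r$cassette
  }
  ok <- status == "ok"
  n_flank <- sum(status %in% c("ok", "bad_length"))
  n_len <- sum(ok)

  dd <- deduplicate(cass[ok], mode = dedup_mode)
  prov <- lapply(dd$provenance, function(idx) ids[which(ok)[idx]])

  structure(list(
    sequences = dd$sequences,
    provenance = prov,
    stats = c(input = n_input, quality_passed = n_qual,
              flank_matched = n_flank, length_passed = n_len,
              deduplicated = length(dd$sequences)),
    rejections = stats::setNames(status[!ok], ids[!ok])),
    class = "cassette_set")
}

#' Deduplicate cassette sequences
#'
#' `exact` keeps the first occurrence of each distinct string.
#' `strand_collapsed` additionally identifies a sequence with its reverse
#' complement — the cassette is double-stranded, so sequencing
#' orientation is arbitrary — keeping the lexicographically smaller
#' representative. A palindrome is its own representative in both modes.
#'
#' @param cassettes Character vector.
#' @param mode "exact" (default) or "strand_collapsed".
#' @return List with `sequences` (representatives, in first-occurrence
#'   order) and `provenance` (representative -> input indices).
#' @export
deduplicate <- function(cassettes, mode = c("exact", "strand_collapsed")) {
  mode <- match.arg(mode)
  if (length(cassettes) == 0)
    return(list(sequences = character(0), provenance = list()))
  key <- if (mode == "exact") cassettes else
    pmin(cassettes, revcomp(cassettes))
  first <- !duplicated(key)
  reps <- key[first]
  prov <- split(seq_along(cassettes), factor(key, levels = reps))
  names(prov) <- reps
  list(sequences = reps, provenance = prov)
}

#' Sample cassettes without replacement
#'
#' Uniform, seed-reproducible subsample (the motif-discovery input is a
#' random subset of the prepared reads).
#'
#' @param x A `cassette_set` from [prep_reads()] or a character vector.
#' @param n Sample size; must not exceed the available count.
#' @param seed Integer seed.
#' @return Character vector of length `n`.
#' @export
sample_reads <- function(x, n, seed = 1L) {
  seqs <- if (inherits(x, "cassette_set")) x$sequences else
    as.character(x)
  if (n > length(seqs))
    stop("requested ", n, " sequences but only ", length(seqs),
         " available")
  set.seed(seed)
  seqs[sample.int(length(seqs), n)]
}
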