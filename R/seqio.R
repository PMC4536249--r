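# Sequence and annotation I/O. All coordinate conventions for the package are
# fixed here: internally everything is 0-based, half-open; writers that
# produce user-facing tables print 1-based positions.

#' Read a FASTA file
#'
#' Sequences are uppercased and must be over the alphabet A/C/G/T/N. Record
#' ids must be non-empty and unique within the file.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    # invalid one-letter codes only warn in the underlying parser; treat
    # them as parse errors so no base is silently dropped
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) .fasta_diagnose(path, conditionMessage(e)),
    warning = function(w) .fasta_diagnose(path, conditionMessage(w))
  )
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) .fasta_diagnose(path, "empty record id")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(Biostrings::width(set) == 0)) .fasta_diagnose(path, "empty sequence")
  seqs <- unname(toupper(as.character(set)))
  assert_dna(seqs, what = paste0("FASTA ", path))
  tibble::tibble(id = ids, seq = seqs, length = nchar(seqs))
}

# Scan the raw lines to attach a line number to a parse failure.
.fasta_diagnose <- function(path, fallback) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1]) {
    stop(sprintf("FASTA parse error at line 1 of %s: expected '>' header", path),
         call. = FALSE)
  }
  for (i in which(hdr)) {
    if (!nzchar(sub("^>\\s*", "", lines[i]))) {
      stop(sprintf("FASTA parse error at line %d of %s: empty header", i, path),
           call. = FALSE)
    }
    nxt <- if (i < length(lines)) lines[i + 1] else ""
    if (grepl("^>", nxt) || !nzchar(nxt)) {
      stop(sprintf("FASTA parse error at line %d of %s: header with empty sequence",
                   i, path), call. = FALSE)
    }
  }
  bad <- which(!hdr & grepl("[^ACGTNacgtn[:space:]]", lines))
  if (length(bad)) {
    stop(sprintf(
      "FASTA parse error at line %d of %s: sequence character outside A/C/G/T/N",
      bad[1], path), call. = FALSE)
  }
  stop(sprintf("FASTA parse error in %s: %s", path, fallback), call. = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x Data frame with `id` and `seq` columns.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  set <- Biostrings::DNAStringSet(x$seq)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Four-line FASTQ with Phred+33 qualities. The whole file is materialised as
#' a tibble; qualities are kept as the encoded string (see [phred_scores()]).
#'
#' @param path Path to a FASTQ file.
#' @param sample_id Sample label attached to every read.
#' @return Tibble with columns `id`, `seq`, `qual`, `sample_id`.
#' @export
read_fastq <- function(path, sample_id) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(tibble::tibble(id = character(), seq = character(),
                          qual = character(), sample_id = character()))
  }
  lines <- readLines(path, warn = FALSE)
  perr <- function(fmt, ...) {
    stop(sprintf("FASTQ parse error in %s: %s", path, sprintf(fmt, ...)),
         call. = FALSE)
  }
  if (length(lines) %% 4 != 0) perr("truncated record at end of file")
  hdr <- lines[seq(1, length(lines), 4)]
  seqs <- toupper(lines[seq(2, length(lines), 4)])
  plus <- lines[seq(3, length(lines), 4)]
  quals <- lines[seq(4, length(lines), 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) perr("line %d: expected '@' header", 4L * (bad[1] - 1L) + 1L)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) perr("line %d: expected '+' separator", 4L * (bad[1] - 1L) + 3L)
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad)) {
    perr("record %d: sequence/quality length mismatch", bad[1])
  }
  assert_dna(seqs, what = paste0("FASTQ ", path))
  tibble::tibble(id = sub("\\s.*$", "", sub("^@", "", hdr)), seq = seqs,
                 qual = quals, sample_id = sample_id)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Tibble with `id`, `seq`, `qual` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), 4)] <- reads$seq
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Decode Phred+33 quality strings
#'
#' @param qual Character vector of encoded quality strings.
#' @return List of integer vectors of per-base Phred scores.
#' @examples
#' phred_scores("IIII")
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Quality-filter reads
#'
#' Retains exactly the reads in which at least `min_fraction` of bases have a
#' Phred score of at least `cutoff` (the read-retention rule used with a
#' cutoff quality score of 20).
#'
#' @param reads Tibble from [read_fastq()].
#' @param cutoff Minimum per-base Phred score counted as high quality.
#' @param min_fraction Minimum fraction of high-quality bases for retention.
#' @return The retained subset of `reads`, original order preserved.
#' @export
quality_filter_reads <- function(reads, cutoff = 20, min_fraction = 0.70) {
  stopifnot(cutoff >= 0, min_fraction > 0, min_fraction <= 1)
  if (nrow(reads) == 0) return(reads)
  len <- nchar(reads$qual)
  if (cutoff == 0) {
    n_below <- integer(nrow(reads))
  } else {
    # bases strictly below the cutoff have ASCII codes 33 .. 33+cutoff-1
    cls <- sprintf("[\\x21-\\x%02X]", 32L + as.integer(cutoff))
    n_below <- stringi::stri_count_charclass(reads$qual, cls)
  }
  keep <- (len - n_below) / len >= min_fraction
  reads[keep, , drop = FALSE]
}

#' Read sample-to-group metadata
#'
#' @param path TSV with header columns `sample_id` and `group`.
#' @return Tibble with those two columns.
#' @export
read_groups <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group") %in% names(g)))
  tibble::as_tibble(g[, c("sample_id", "group")])
}
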