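# Internal helpers shared across modules.

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}`.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAN"))
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' GC content of DNA strings
#'
#' @param x Character vector of DNA strings (A/C/G/T; N counts toward length
#'   but not toward GC).
#' @return Numeric vector of GC percentages in `[0, 100]`.
#' @export
gc_content <- function(x) {
  gc <- stringi::stri_count_charclass(x, "[GCgc]")
  100 * gc / nchar(x)
}

# Round half away from zero, the convention used in the report tables
# (base round() goes half-to-even).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# 0-based internal coordinates <-> 1-based printed coordinates.
to1 <- function(start0) start0 + 1L

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- stringi::stri_detect_regex(x, pat)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside %s (first offender: '%s')",
                 what, if (allow_n) "A/C/G/T/N" else "A/C/G/T",
                 x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

# Coerce a genome argument (tibble from read_fasta, named character vector,
# or single string) to a tibble with id/seq columns.
as_genome_tbl <- function(genome) {
  if (is.data.frame(genome)) {
    stopifnot(all(c("id", "seq") %in% names(genome)))
    return(tibble::as_tibble(genome[, c("id", "seq")]))
  }
  if (is.character(genome)) {
    ids <- names(genome)
    if (is.null(ids)) ids <- paste0("seq", seq_along(genome))
    return(tibble::tibble(id = ids, seq = unname(toupper(genome))))
  }
  stop("genome must be a data frame with id/seq columns or a character vector",
       call. = FALSE)
}
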