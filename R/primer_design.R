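# Sliding-window tiling primer design. A pair is a 20-bp forward primer, a
# 20-bp gap, and a 20-bp reverse primer (reverse complement of the template),
# so the reference product is 60 bp. The window advances by 20 bp, so the
# next forward primer sits on the 20-bp region upstream of the previous
# reverse primer and consecutive reference products overlap by 40 bp.

#' Design tiling e-PCR primer pairs over a template genome
#'
#' Slides a `2 * primer_len + gap_len` window along each template sequence in
#' steps of `step` bp, emitting one forward/reverse primer pair per window.
#' Windows that would run past the template end are discarded (no truncated
#' final window). Pairs whose primers contain `N` are emitted but flagged
#' `usable = FALSE`; they are excluded from mapping since `N` never matches a
#' primer base.
#'
#' @param genome Tibble with `id`/`seq` columns (see [read_fasta()]), a named
#'   character vector, or a single string.
#' @param primer_len Primer length in bp.
#' @param gap_len Gap between the primers in bp.
#' @param step Window step in bp.
#' @return Tibble with one row per pair: `pair_id` (`"chrom-<1-based
#'   forward start>"`), `chrom`, `f_start` (0-based), `f_seq`, `r_start`
#'   (0-based start of the reverse-primer footprint), `r_seq` (reverse
#'   complement of the footprint), `product_start`, `product_end` (0-based
#'   half-open reference product), `usable`.
#' @export
design_sliding_window_primers <- function(genome, primer_len = 20L,
                                          gap_len = 20L, step = 20L) {
  g <- as_genome_tbl(genome)
  win <- 2L * primer_len + gap_len
  out <- purrr::pmap_dfr(g, function(id, seq, ...) {
    L <- nchar(seq)
    if (L < win) {
      warning(sprintf("template '%s' (%d bp) shorter than one %d-bp window; no pairs",
                      id, L, win), call. = FALSE)
      return(NULL)
    }
    f_start <- seq.int(0L, L - win, by = step)
    r_start <- f_start + primer_len + gap_len
    f_seq <- substring(seq, f_start + 1L, f_start + primer_len)
    r_seq <- revcomp(substring(seq, r_start + 1L, r_start + primer_len))
    tibble::tibble(
      pair_id = paste0(id, "-", f_start + 1L),
      chrom = id,
      f_start = f_start,
      f_seq = f_seq,
      r_start = r_start,
      r_seq = r_seq,
      product_start = f_start,
      product_end = f_start + win,
      usable = !stringi::stri_detect_fixed(f_seq, "N") &
               !stringi::stri_detect_fixed(r_seq, "N"))
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(pair_id = character(), chrom = character(),
                          f_start = integer(), f_seq = character(),
                          r_start = integer(), r_seq = character(),
                          product_start = integer(), product_end = integer(),
                          usable = logical())
  }
  out
}

#' Closed-form count of sliding-window primer pairs
#'
#' The number of pairs designed on a template of length `L`:
#' `floor((L - (2 * primer_len + gap_len)) / step) + 1` when `L` admits at
#' least one full window, else 0. Agrees with
#' [design_sliding_window_primers()] on any concrete sequence.
#'
#' @param L Integer vector of template lengths (bp).
#' @inheritParams design_sliding_window_primers
#' @return Numeric vector of pair counts.
#' @examples
#' expected_pair_count(c(60, 79, 80))
#' sum(expected_pair_count(rice_chromosome_lengths))
#' @export
expected_pair_count <- function(L, primer_len = 20L, gap_len = 20L, step = 20L) {
  stopifnot(all(L >= 0))
  win <- 2 * primer_len + gap_len
  ifelse(L >= win, (L - win) %/% step + 1, 0)
}

#' Rice (Oryza sativa) chromosome lengths, MSU Release 7
#'
#' Assembled lengths in bp of the 12 rice chromosomes of the Nipponbare
#' reference (MSU Rice Genome Annotation Project, Release 7), named
#' `chr01`..`chr12`.
#'
#' @format Named numeric vector of length 12.
#' @export
rice_chromosome_lengths <- c(
  chr01 = 43270923, chr02 = 35937250, chr03 = 36413819, chr04 = 35502694,
  chr05 = 29958434, chr06 = 31248787, chr07 = 29697621, chr08 = 28443022,
  chr09 = 23012720, chr10 = 23207287, chr11 = 29021106, chr12 = 27531856)

#' Write a primer-pair table as TSV
#'
#' Positions are printed 1-based (`f_start`, `product_start` inclusive,
#' `product_end` the last covered base).
#'
#' @param pairs Tibble from [design_sliding_window_primers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(pairs, path) {
  out <- tibble::tibble(
    pair_id = pairs$pair_id, chrom = pairs$chrom,
    f_start = to1(pairs$f_start), f_seq = pairs$f_seq, r_seq = pairs$r_seq,
    product_start = to1(pairs$product_start), product_end = pairs$product_end,
    usable = pairs$usable)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer-pair table written by [write_primer_table()]
#'
#' @param path TSV path.
#' @return Tibble in the internal (0-based) representation.
#' @export
read_primer_table <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  primer_len <- nchar(x$f_seq[1])
  tibble::tibble(
    pair_id = as.character(x$pair_id), chrom = as.character(x$chrom),
    f_start = as.integer(x$f_start - 1L), f_seq = x$f_seq,
    r_start = as.integer(x$product_end - primer_len), r_seq = x$r_seq,
    product_start = as.integer(x$product_start - 1L),
    product_end = as.integer(x$product_end),
    usable = as.logical(x$usable))
}
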