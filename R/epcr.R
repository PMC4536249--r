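# In-silico PCR. A primer site is an ungapped full-length match of a 20-mer
# within a Hamming-distance budget; an amplicon is a properly oriented
# (forward hit ... reverse-footprint hit) configuration on either strand of
# the target. The multi-pattern matcher decomposes the mismatch budget by
# pigeonhole over exact "trusted band" blocks (a k-mismatch match of a
# 20-mer must contain an exact block of length floor(20/(k+1))), so an
# Aho-Corasick dictionary scan per block enumerates all candidates; every
# candidate is then verified by exact mismatch counting. This agrees exactly
# with a naive scan.

# Multi-pattern mismatch-tolerant search.
# subject: DNAString; patterns: DNAStringSet of constant width (no N).
# Returns a data.frame(pat, start, mm) with 1-based starts.
.match_sites <- function(subject, patterns, max_mm) {
  w <- unique(Biostrings::width(patterns))
  stopifnot(length(w) == 1)
  n <- length(patterns)
  empty <- data.frame(pat = integer(), start = integer(), mm = integer())
  if (n == 0 || length(subject) < w) return(empty)

  if (max_mm == 0) {
    pd <- Biostrings::PDict(patterns)
    m <- Biostrings::matchPDict(pd, subject)
    st <- Biostrings::startIndex(m)
    cnt <- lengths(st)
    if (sum(cnt) == 0) return(empty)
    return(data.frame(pat = rep.int(seq_len(n), cnt),
                      start = unlist(st, use.names = FALSE), mm = 0L))
  }

  nb <- max_mm + 1L
  sizes <- rep(w %/% nb, nb)
  extra <- w - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L

  acc <- vector("list", nb)
  for (b in seq_len(nb)) {
    pd <- Biostrings::PDict(patterns, tb.start = starts[b], tb.end = ends[b])
    m <- Biostrings::matchPDict(pd, subject, max.mismatch = max_mm)
    st <- Biostrings::startIndex(m)
    cnt <- lengths(st)
    acc[[b]] <- data.frame(pat = rep.int(seq_len(n), cnt),
                           start = unlist(st, use.names = FALSE))
  }
  h <- unique(do.call(rbind, acc))
  if (nrow(h) == 0) return(empty)
  h <- h[h$start >= 1L & h$start + w - 1L <= length(subject), , drop = FALSE]
  if (nrow(h) == 0) return(empty)

  # exact verification of the mismatch count per candidate
  h <- h[order(h$pat, h$start), , drop = FALSE]
  sp <- split(h$start, h$pat)
  mm <- unlist(lapply(names(sp), function(p) {
    Biostrings::neditStartingAt(patterns[[as.integer(p)]], subject,
                                starting.at = sp[[p]], fixed = TRUE)
  }), use.names = FALSE)
  h$mm <- mm
  h[h$mm <= max_mm, , drop = FALSE]
}

#' Find approximate primer binding sites in a target sequence
#'
#' Reports every position, on both strands, where the primer matches the
#' target over its full length, ungapped, with at most `max_mm` mismatches
#' (Hamming distance). An `N` in the target never matches a primer base.
#'
#' @param target A DNA string.
#' @param primer A 20-mer primer without `N`.
#' @param max_mm Mismatch budget, 0 to 3.
#' @return Tibble with `pos` (0-based start of the matched 20-mer on the
#'   forward strand of the target), `strand` (`"+"` if the primer itself
#'   matches there, `"-"` if its reverse complement does), `mismatches`;
#'   sorted by `pos`.
#' @export
find_primer_sites <- function(target, primer, max_mm = 3L) {
  if (nchar(primer) != 20L) stop("primer must be a 20-mer", call. = FALSE)
  assert_dna(primer, "primer", allow_n = FALSE)
  stopifnot(max_mm %in% 0:3)
  subject <- Biostrings::DNAString(target)
  fwd <- .match_sites(subject, Biostrings::DNAStringSet(primer), max_mm)
  rev <- .match_sites(subject, Biostrings::DNAStringSet(revcomp(primer)), max_mm)
  out <- tibble::tibble(
    pos = c(fwd$start, rev$start) - 1L,
    strand = rep(c("+", "-"), c(nrow(fwd), nrow(rev))),
    mismatches = c(fwd$mm, rev$mm))
  dplyr::arrange(out, .data$pos, .data$strand)
}

# Expand usable pairs into the four search patterns per pair.
# Configuration "+": the target forward strand carries f_seq upstream of the
# plus-strand reverse footprint (revcomp(r_seq)); configuration "-" is the
# mirror (the pair amplifies the reverse complement of the target).
.pair_patterns <- function(pairs) {
  n <- nrow(pairs)
  tibble::tibble(
    pair_pos = rep(seq_len(n), 4L),
    config = rep(c("+", "+", "-", "-"), each = n),
    side = rep(c("L", "R", "L", "R"), each = n),
    pattern = c(pairs$f_seq, revcomp(pairs$r_seq),
                pairs$r_seq, revcomp(pairs$f_seq)))
}

# Assemble amplicons from a hit table on one subject.
# hits: data.frame(pat, start, mm) over the patterns of .pair_patterns();
# extra_key: optional integer vector parallel to hits (e.g. read index) that
# both primers must share.
.assemble_amplicons <- function(hits, pats, w, min_len, max_len,
                                extra_key = NULL) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(pair_pos = integer(), config = character(),
                          key = integer(), l_start = integer(),
                          r_start = integer(), l_mm = integer(),
                          r_mm = integer(), length = integer()))
  }
  tb <- tibble::tibble(
    pair_pos = pats$pair_pos[hits$pat],
    config = pats$config[hits$pat],
    side = pats$side[hits$pat],
    start = hits$start,
    mm = hits$mm,
    key = if (is.null(extra_key)) 0L else extra_key)
  left <- dplyr::filter(tb, .data$side == "L")
  right <- dplyr::filter(tb, .data$side == "R")
  amp <- dplyr::inner_join(
    dplyr::select(left, "pair_pos", "config", "key",
                  l_start = "start", l_mm = "mm"),
    dplyr::select(right, "pair_pos", "config", "key",
                  r_start = "start", r_mm = "mm"),
    by = c("pair_pos", "config", "key"), relationship = "many-to-many")
  amp <- dplyr::mutate(amp, length = .data$r_start + w - .data$l_start)
  dplyr::filter(amp, .data$r_start - .data$l_start >= w,
                .data$length >= min_len, .data$length <= max_len)
}

#' In-silico amplification of primer pairs against a genome
#'
#' Predicts every amplicon a pair would produce on the target: a forward
#' primer hit with a properly oriented reverse-footprint hit downstream on
#' the same strand, each within `max_mm` mismatches, with non-overlapping
#' primer footprints and a product length within `[min_len, max_len]`. Both
#' strand configurations are searched. Pairs flagged unusable (primer
#' containing `N`) are skipped.
#'
#' @param pairs Primer-pair tibble from [design_sliding_window_primers()].
#' @param genome Target genome (tibble with `id`/`seq`, named character
#'   vector, or single string).
#' @param max_mm Per-primer mismatch budget.
#' @param min_len,max_len Product length bounds in bp; the default lower
#'   bound 40 forbids overlapping primer footprints, the upper bound 400
#'   tolerates InDels between diverged references.
#' @return Tibble with `pair_id`, `source_id`, `start`, `end` (0-based
#'   half-open on the target forward strand), `length`, `seq` (product 5'->3'
#'   from the forward primer), `strand`, `f_mm`, `r_mm`.
#' @export
epcr_template <- function(pairs, genome, max_mm = 3L, min_len = 40L,
                          max_len = 400L) {
  g <- as_genome_tbl(genome)
  use <- if ("usable" %in% names(pairs)) pairs[pairs$usable, , drop = FALSE] else pairs
  empty <- tibble::tibble(pair_id = character(), source_id = character(),
                          start = integer(), end = integer(),
                          length = integer(), seq = character(),
                          strand = character(), f_mm = integer(),
                          r_mm = integer())
  if (nrow(use) == 0) return(empty)
  pats <- .pair_patterns(use)
  patterns <- Biostrings::DNAStringSet(pats$pattern)
  w <- nchar(use$f_seq[1])

  out <- purrr::pmap_dfr(g, function(id, seq, ...) {
    subject <- Biostrings::DNAString(seq)
    hits <- .match_sites(subject, patterns, max_mm)
    amp <- .assemble_amplicons(hits, pats, w, min_len, max_len)
    if (nrow(amp) == 0) return(NULL)
    start0 <- amp$l_start - 1L
    end0 <- amp$r_start + w - 1L
    prod <- substring(seq, start0 + 1L, end0)
    minus <- amp$config == "-"
    prod[minus] <- revcomp(prod[minus])
    tibble::tibble(
      pair_id = use$pair_id[amp$pair_pos],
      source_id = id,
      start = start0, end = end0, length = amp$length,
      seq = prod, strand = amp$config,
      f_mm = ifelse(minus, amp$r_mm, amp$l_mm),
      r_mm = ifelse(minus, amp$l_mm, amp$r_mm))
  })
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(dplyr::distinct(out, .data$pair_id, .data$source_id,
                                 .data$start, .data$end, .data$strand,
                                 .keep_all = TRUE),
                 .data$source_id, .data$start, .data$pair_id)
}

#' Classify primer pairs by amplification uniqueness in two genomes
#'
#' A pair is unique when it predicts exactly one amplicon in each of the two
#' reference genomes. Unusable pairs (primer containing `N`) are never
#' unique and report zero products.
#'
#' @inheritParams epcr_template
#' @param genome_a,genome_b The two reference genomes.
#' @return Tibble with `pair_id`, `n_products_a`, `n_products_b`, `unique`.
#' @export
classify_unique_pairs <- function(pairs, genome_a, genome_b, max_mm = 3L,
                                  min_len = 40L, max_len = 400L) {
  amp_a <- epcr_template(pairs, genome_a, max_mm, min_len, max_len)
  amp_b <- epcr_template(pairs, genome_b, max_mm, min_len, max_len)
  ca <- dplyr::count(amp_a, .data$pair_id, name = "n_products_a")
  cb <- dplyr::count(amp_b, .data$pair_id, name = "n_products_b")
  out <- tibble::tibble(pair_id = pairs$pair_id)
  out <- dplyr::left_join(out, ca, by = "pair_id")
  out <- dplyr::left_join(out, cb, by = "pair_id")
  out$n_products_a <- dplyr::coalesce(out$n_products_a, 0L)
  out$n_products_b <- dplyr::coalesce(out$n_products_b, 0L)
  out$unique <- out$n_products_a == 1L & out$n_products_b == 1L
  out
}

#' In-silico amplification of primer pairs against sequencing reads
#'
#' A product is emitted whenever a single read contains the forward primer
#' and, downstream on the same strand, the reverse-primer footprint, each
#' within `max_mm` mismatches; both read orientations are searched and the
#' product must lie entirely inside the read. Reads are treated
#' independently, so insertions longer than `read length - 2 * primer
#' length` are undetectable by construction.
#'
#' @inheritParams epcr_template
#' @param reads Read tibble (see [read_fastq()]); should be quality-filtered.
#' @param max_mm Per-primer mismatch budget (default 1 for reads).
#' @param max_len Upper product-length bound; `Inf` means limited only by
#'   read length.
#' @return Tibble with `pair_id`, `sample_id`, `read_id`, `product_length`,
#'   `product_seq`, `strand`, `f_mm`, `r_mm`; one row per (read, pair,
#'   configuration) product.
#' @export
epcr_reads <- function(pairs, reads, max_mm = 1L, min_len = 40L,
                       max_len = Inf) {
  use <- if ("usable" %in% names(pairs)) pairs[pairs$usable, , drop = FALSE] else pairs
  empty <- tibble::tibble(pair_id = character(), sample_id = character(),
                          read_id = character(), product_length = integer(),
                          product_seq = character(), strand = character(),
                          f_mm = integer(), r_mm = integer())
  if (nrow(use) == 0 || nrow(reads) == 0) return(empty)
  pats <- .pair_patterns(use)
  patterns <- Biostrings::DNAStringSet(pats$pattern)
  w <- nchar(use$f_seq[1])

  # concatenate all reads, separated by an N spacer; hits crossing a read
  # boundary are discarded by the containment check below
  spacer <- 20L
  rl <- nchar(reads$seq)
  start_off <- c(0, cumsum(rl + spacer))[seq_len(nrow(reads))]
  subject <- Biostrings::DNAString(
    paste(reads$seq, collapse = strrep("N", spacer)))
  hits <- .match_sites(subject, patterns, max_mm)
  if (nrow(hits) == 0) return(empty)

  ridx <- findInterval(hits$start - 1L, start_off)
  local0 <- hits$start - 1L - start_off[ridx]
  inside <- local0 >= 0L & local0 + w <= rl[ridx]
  hits <- hits[inside, , drop = FALSE]
  ridx <- ridx[inside]
  if (nrow(hits) == 0) return(empty)
  hits$start <- local0[inside] + 1L  # 1-based within the read

  amp <- .assemble_amplicons(hits, pats, w, min_len, max_len,
                             extra_key = ridx)
  if (nrow(amp) == 0) return(empty)
  prod <- substring(reads$seq[amp$key], amp$l_start,
                    amp$r_start + w - 1L)
  minus <- amp$config == "-"
  prod[minus] <- revcomp(prod[minus])
  tibble::tibble(
    pair_id = use$pair_id[amp$pair_pos],
    sample_id = reads$sample_id[amp$key],
    read_id = reads$id[amp$key],
    product_length = as.integer(amp$length),
    product_seq = prod,
    strand = amp$config,
    f_mm = as.integer(ifelse(minus, amp$r_mm, amp$l_mm)),
    r_mm = as.integer(ifelse(minus, amp$l_mm, amp$r_mm)))
}
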