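# Amplicon-length genotyping. Allele identity is the product length in bp
# (length polymorphisms scored on gels); two same-length products that
# differ only by substitutions collapse to one allele. Each sample
# contributes one consensus product per locus (inbred lines assumed).

#' Consensus product of one (locus, sample) multiset
#'
#' The most frequent product length wins; ties are broken toward the smaller
#' length. The representative sequence is the most frequent sequence of the
#' winning length, ties broken lexicographically.
#'
#' @param products Tibble with `product_length` (and optionally
#'   `product_seq`) columns, or a bare numeric vector of lengths.
#' @return One-row tibble with `product_length`, `product_seq`; zero rows if
#'   the input is empty (missing genotype).
#' @export
consensus_product <- function(products) {
  if (is.numeric(products)) {
    products <- tibble::tibble(product_length = as.integer(products),
                               product_seq = NA_character_)
  }
  if (nrow(products) == 0) {
    return(tibble::tibble(product_length = integer(),
                          product_seq = character()))
  }
  tab <- table(products$product_length)
  winners <- as.integer(names(tab)[tab == max(tab)])
  len <- min(winners)
  seqs <- products$product_seq[products$product_length == len]
  seqs <- seqs[!is.na(seqs)]
  rep_seq <- if (length(seqs)) {
    st <- table(seqs)
    cands <- names(st)[st == max(st)]
    min(cands)
  } else NA_character_
  tibble::tibble(product_length = len, product_seq = rep_seq)
}

# modal length, ties toward the smaller length
.consensus_length <- function(lengths) {
  tab <- table(lengths)
  min(as.integer(names(tab)[tab == max(tab)]))
}

#' Build a locus-by-sample genotype matrix of consensus product lengths
#'
#' @param products A long tibble of per-read products (from [epcr_reads()]),
#'   with `pair_id`, `sample_id`, `product_length` (and optionally
#'   `product_seq`); or a named list of such tibbles, one per sample
#'   (duplicate sample names are an error).
#' @param samples Optional character vector of sample ids to force as
#'   columns (samples with no products appear as all-missing).
#' @param loci Optional character vector of locus ids to force as rows.
#' @return A `genotype_matrix`: a tibble whose first column is `pair_id` and
#'   remaining columns are samples, cells holding the consensus product
#'   length (`NA` = missing). Cell values depend only on the per-cell
#'   multisets, not on input order.
#' @export
build_matrix <- function(products, samples = NULL, loci = NULL) {
  if (is.list(products) && !is.data.frame(products)) {
    nm <- names(products)
    if (is.null(nm) || anyDuplicated(nm)) {
      stop("duplicate (or unnamed) per-sample product tables", call. = FALSE)
    }
    products <- dplyr::bind_rows(products)
  }
  stopifnot(all(c("pair_id", "sample_id", "product_length") %in% names(products)))
  # a missing genotype is the absence of products, never an NA product
  products <- products[!is.na(products$product_length), , drop = FALSE]
  cons <- products |>
    dplyr::group_by(.data$pair_id, .data$sample_id) |>
    dplyr::summarise(product_length = .consensus_length(.data$product_length),
                     .groups = "drop")

  sample_ids <- sort(unique(c(cons$sample_id, samples)))
  locus_ids <- unique(c(cons$pair_id, loci))
  wide <- tidyr::pivot_wider(cons, names_from = "sample_id",
                             values_from = "product_length")
  missing_samples <- setdiff(sample_ids, names(wide))
  for (s in missing_samples) wide[[s]] <- NA_integer_
  missing_loci <- setdiff(locus_ids, wide$pair_id)
  if (length(missing_loci)) {
    pad <- tibble::tibble(pair_id = missing_loci)
    wide <- dplyr::bind_rows(wide, pad)
  }
  wide <- wide[match(locus_ids, wide$pair_id), c("pair_id", sample_ids)]
  class(wide) <- c("genotype_matrix", class(tibble::tibble()))
  wide
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>", nrow(x), "loci x", ncol(x) - 1L, "samples;",
      sprintf("%.1f%% missing\n",
              100 * mean(is.na(as.matrix(x[-1])))))
  NextMethod()
}

#' Tidy a genotype matrix into long form
#'
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @return Long tibble with `pair_id`, `sample_id`, `product_length`.
#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"pair_id",
                      names_to = "sample_id", values_to = "product_length")
}

#' One-row summary of a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @return Tibble with locus/sample counts and the missing-cell rate.
#' @method glance genotype_matrix
#' @export
glance.genotype_matrix <- function(x, ...) {
  m <- as.matrix(x[-1])
  tibble::tibble(n_loci = nrow(x), n_samples = ncol(m),
                 missing_rate = mean(is.na(m)))
}

#' Polymorphism information content
#'
#' `PIC = 1 - sum(p_j^2)` over the pattern frequencies `p_j` of a marker.
#' Full precision is returned; report tables round to 2 decimals.
#'
#' @param counts Numeric vector of pattern counts (names irrelevant), or a
#'   `table`.
#' @return PIC in `[0, 1)`.
#' @examples
#' compute_pic(c(5, 5))      # 0.5
#' compute_pic(rep(1, 20))   # 0.95
#' @export
compute_pic <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0 || sum(counts) < 1) {
    stop("compute_pic needs at least one observation", call. = FALSE)
  }
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Major allele difference
#'
#' Absolute size difference (bp) between the most frequent and second most
#' frequent product-length alleles. Alleles are ranked by count descending,
#' then by length ascending (deterministic tie-break).
#'
#' @param alleles Named numeric vector `length -> count` (names are allele
#'   lengths in bp).
#' @return Integer bp difference (>= 1 for distinct lengths).
#' @export
major_allele_difference <- function(alleles) {
  if (length(alleles) < 2) {
    stop("major_allele_difference needs at least two alleles", call. = FALSE)
  }
  len <- as.integer(names(alleles))
  ord <- order(-as.numeric(alleles), len)
  abs(len[ord[1]] - len[ord[2]])
}

#' Call InDel markers from a genotype matrix
#'
#' A locus becomes a marker iff it is typed in at least `min_samples`
#' samples and carries at least two length alleles (equivalently PIC > 0).
#' Monomorphic or under-typed loci are reported with reasons via
#' [excluded_loci()].
#'
#' @param gm A [build_matrix()] result.
#' @param pairs Optional primer-pair tibble; when given, `chrom`,
#'   `product_start`, `product_end` are attached to each marker.
#' @param min_samples Minimum number of typed samples (the >= 20 genomes
#'   rule).
#' @return An `indel_markers` tibble: `pair_id`, `n_typed`, `alleles`
#'   (compact `"len:count"` string, ranked by count desc then length asc),
#'   `allele_counts` (list column of named counts), `allele_number`, `pic`,
#'   `major_allele_diff`, `size_range`, plus coordinates when `pairs` is
#'   supplied.
#' @export
call_indels <- function(gm, pairs = NULL, min_samples = 20L) {
  long <- tidy.genotype_matrix(gm)
  per <- long |>
    dplyr::filter(!is.na(.data$product_length)) |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarise(n_typed = dplyr::n(),
                     allele_counts = list(table(.data$product_length)),
                     .groups = "drop")
  # loci absent from `per` were typed in zero samples
  untyped <- setdiff(gm$pair_id, per$pair_id)

  per$allele_number <- vapply(per$allele_counts, length, integer(1))
  ok <- per$n_typed >= min_samples & per$allele_number >= 2L

  excl <- dplyr::bind_rows(
    tibble::tibble(pair_id = untyped, n_typed = 0L, allele_number = 0L,
                   reason = "untyped"),
    per[!ok, c("pair_id", "n_typed", "allele_number")] |>
      dplyr::mutate(reason = as.character(ifelse(.data$n_typed < min_samples,
                                                 "under_min_samples",
                                                 "monomorphic"))))

  mk <- per[ok, , drop = FALSE]
  mk$allele_counts <- lapply(mk$allele_counts, function(tab) {
    cnt <- as.integer(tab)
    names(cnt) <- names(tab)
    len <- as.integer(names(tab))
    cnt[order(-cnt, len)]
  })
  mk$alleles <- vapply(mk$allele_counts, function(cnt) {
    paste(sprintf("%s:%d", names(cnt), cnt), collapse = ",")
  }, character(1))
  mk$pic <- vapply(mk$allele_counts, compute_pic, numeric(1))
  mk$major_allele_diff <- vapply(mk$allele_counts, major_allele_difference,
                                 numeric(1))
  mk$size_range <- vapply(mk$allele_counts, function(cnt) {
    len <- as.integer(names(cnt))
    max(len) - min(len)
  }, integer(1))

  if (!is.null(pairs)) {
    mk <- dplyr::left_join(
      mk, pairs[, c("pair_id", "chrom", "product_start", "product_end")],
      by = "pair_id")
    mk <- dplyr::relocate(mk, "pair_id", "chrom", "product_start",
                          "product_end")
  }
  mk <- dplyr::relocate(mk, "alleles", .after = "n_typed")
  attr(mk, "excluded") <- excl
  attr(mk, "min_samples") <- min_samples
  class(mk) <- c("indel_markers", class(tibble::tibble()))
  mk
}

#' Loci excluded by the marker-calling filters
#'
#' @param markers An `indel_markers` object from [call_indels()].
#' @return Tibble with `pair_id`, `n_typed`, `allele_number`, `reason`
#'   (`"untyped"`, `"under_min_samples"` or `"monomorphic"`).
#' @export
excluded_loci <- function(markers) {
  attr(markers, "excluded") %||% tibble::tibble()
}

#' One-row summary of a marker set
#'
#' @param x An `indel_markers` tibble.
#' @param ... Unused.
#' @return Tibble with marker count and mean/max PIC, mean allele number and
#'   mean major allele difference.
#' @method glance indel_markers
#' @export
glance.indel_markers <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x),
    mean_pic = mean(x$pic),
    max_pic = if (nrow(x)) max(x$pic) else NA_real_,
    mean_allele_number = mean(x$allele_number),
    mean_major_allele_diff = mean(x$major_allele_diff))
}

#' Per-group frequency of the global major allele
#'
#' For each marker, the globally most frequent allele (count desc, length
#' asc tie-break) is taken, and its frequency is computed among the typed
#' samples of each group. Groups with no typed samples at a marker are
#' absent from the output.
#'
#' @param gm A `genotype_matrix`.
#' @param markers An `indel_markers` tibble (defines the loci and their
#'   major alleles).
#' @param groups Tibble with `sample_id`, `group`.
#' @return Tibble with `pair_id`, `group`, `n_typed`, `major_allele`,
#'   `major_allele_freq`.
#' @export
group_major_allele_freq <- function(gm, markers, groups) {
  major <- tibble::tibble(
    pair_id = markers$pair_id,
    major_allele = vapply(markers$allele_counts,
                          function(cnt) as.integer(names(cnt)[1]), integer(1)))
  long <- tidy.genotype_matrix(gm) |>
    dplyr::filter(!is.na(.data$product_length)) |>
    dplyr::inner_join(major, by = "pair_id") |>
    dplyr::inner_join(groups, by = "sample_id")
  long |>
    dplyr::group_by(.data$pair_id, .data$group) |>
    dplyr::summarise(
      n_typed = dplyr::n(),
      major_allele = .data$major_allele[1],
      major_allele_freq = mean(.data$product_length == .data$major_allele),
      .groups = "drop")
}

#' Write a marker table as TSV (1-based positions)
#'
#' @param markers An `indel_markers` tibble.
#' @param path Output path.
#' @param group_freqs Optional [group_major_allele_freq()] result, spread
#'   into one `freq_<group>` column per group.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path, group_freqs = NULL) {
  out <- tibble::as_tibble(markers)
  out$allele_counts <- NULL
  if (all(c("product_start", "product_end") %in% names(out))) {
    out$pos_1based <- to1(out$product_start)
    out$product_start <- NULL
    out$product_end <- NULL
    out <- dplyr::relocate(out, "pos_1based", .after = "chrom")
  }
  out$pic <- round_half_up(out$pic, 2)
  if (!is.null(group_freqs)) {
    wide <- tidyr::pivot_wider(
      group_freqs[, c("pair_id", "group", "major_allele_freq")],
      names_from = "group", values_from = "major_allele_freq",
      names_prefix = "freq_")
    out <- dplyr::left_join(out, wide, by = "pair_id")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write marker intervals as BED (0-based half-open)
#'
#' @param markers An `indel_markers` tibble carrying coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_bed <- function(markers, path) {
  stopifnot(all(c("chrom", "product_start", "product_end") %in% names(markers)))
  bed <- data.frame(markers$chrom, markers$product_start, markers$product_end,
                    markers$pair_id, round_half_up(markers$pic, 2),
                    rep(".", nrow(markers)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
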