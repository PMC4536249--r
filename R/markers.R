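# Marker reporting and panel construction: region/chromosome summary tables,
# gel-tier marker selection, validation-primer design under nearest-neighbor
# melting-temperature constraints, and validation-panel statistics.

#' Summarise counts, densities and proportions per genomic region
#'
#' Density is the item count per 1000 bp of the (reduced) region length;
#' proportion is the percentage of all items; spacing is region length /
#' count. All reported to 2 decimals, rounding half away from zero.
#'
#' @param assigned Tibble with a `category` column (see [assign_region()]).
#' @param region_index The [build_region_index()] used for assignment.
#' @return Tibble with one row per category plus a `total` row.
#' @export
summarize_regions <- function(assigned, region_index) {
  stopifnot(inherits(region_index, "region_index"))
  counts <- table(factor(assigned$category, levels = REGION_CATEGORIES))
  tot_len <- sum(region_index$chrom_lengths)
  tb <- tibble::tibble(
    category = REGION_CATEGORIES,
    count = as.integer(counts[REGION_CATEGORIES]),
    length_bp = as.numeric(region_index$totals[REGION_CATEGORIES]))
  tb <- dplyr::bind_rows(tb, tibble::tibble(
    category = "total", count = nrow(assigned), length_bp = tot_len))
  .finish_summary(tb)
}

#' Summarise counts and densities per chromosome
#'
#' @param x Tibble with a `chrom` column (markers or primer pairs).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return Tibble with one row per chromosome plus a `total` row, carrying
#'   `count`, `length_bp`, `density_per_kb`, `proportion_pct`,
#'   `avg_spacing_bp`.
#' @examples
#' # one item in a 1-kb chromosome has density 1.00 per kb
#' summarize_chromosomes(data.frame(chrom = "c"), c(c = 1000))
#' @export
summarize_chromosomes <- function(x, chrom_lengths) {
  counts <- table(factor(x$chrom, levels = names(chrom_lengths)))
  tb <- tibble::tibble(
    chrom = names(chrom_lengths),
    count = as.integer(counts[names(chrom_lengths)]),
    length_bp = as.numeric(chrom_lengths))
  tb <- dplyr::bind_rows(tb, tibble::tibble(
    chrom = "total", count = nrow(x), length_bp = sum(chrom_lengths)))
  .finish_summary(tb)
}

#' Summary arithmetic for count tables
#'
#' Given item counts over regions (or chromosomes) with their lengths,
#' appends `density_per_kb` (`count / length_bp * 1000`),
#' `proportion_pct` (percentage of the total count) and `avg_spacing_bp`
#' (`length_bp / count`), each reported to 2 decimals, rounding half away
#' from zero. Zero-length regions get `NA` density; zero counts get `NA`
#' spacing.
#'
#' @param tb Tibble with `count` and `length_bp` columns; if the last row is
#'   a `total` row it defines the proportion denominator, otherwise the
#'   column sum does.
#' @return `tb` with the three derived columns appended.
#' @examples
#' summarize_counts(tibble::tibble(chrom = "chr1", count = 299457,
#'                                 length_bp = 43270923))
#' @export
summarize_counts <- function(tb) {
  id <- tb[[1]]
  total <- if (length(id) && identical(id[length(id)], "total"))
    tb$count[nrow(tb)] else sum(tb$count)
  tb$density_per_kb <- ifelse(tb$length_bp > 0,
                              round_half_up(tb$count / tb$length_bp * 1000, 2),
                              NA_real_)
  tb$proportion_pct <- if (total > 0)
    round_half_up(100 * tb$count / total, 2) else NA_real_
  tb$avg_spacing_bp <- ifelse(tb$count > 0,
                              round_half_up(tb$length_bp / tb$count, 2),
                              NA_real_)
  tb
}

#' Percentage of a total, report-rounded
#'
#' The proportion convention used throughout the summary tables: percent to
#' 2 decimals, rounding half away from zero.
#'
#' @param count,total Numerators and denominator.
#' @return `100 * count / total` rounded to 2 decimals.
#' @examples
#' proportion_pct(89, 93)
#' @export
proportion_pct <- function(count, total) {
  round_half_up(100 * count / total, 2)
}

.finish_summary <- summarize_counts

#' Select gel-tier marker sets
#'
#' Both tiers require PIC >= `min_pic`. The PAGE tier (polyacrylamide gels
#' resolving small differences in short products) additionally requires a
#' major allele difference of at least 3 bp; the agarose tier requires at
#' least 8 bp. The corresponding product-length windows (60-100 bp and
#' 150-300 bp) are enforced downstream by [design_validation_primers()].
#'
#' @param markers An `indel_markers` tibble.
#' @param mode `"page"` or `"agarose"`.
#' @param min_pic PIC cutoff.
#' @return The selected subset of `markers`.
#' @export
select_marker_sets <- function(markers, mode = c("page", "agarose"),
                               min_pic = 0.5) {
  mode <- match.arg(mode)
  min_diff <- switch(mode, page = 3, agarose = 8)
  markers[markers$pic >= min_pic & markers$major_allele_diff >= min_diff, ,
          drop = FALSE]
}

#' Extract PCR templates around marker loci
#'
#' Returns, per marker, the sequence of `indel_window` bp centred on the
#' variable (inter-primer) region of the reference product plus `flank` bp
#' on each side — 100 bp at the defaults, 320 bp with the 150-bp flanks used
#' for agarose-tier products. Windows are truncated (with a warning) at
#' chromosome ends.
#'
#' @param markers Tibble with `pair_id`, `chrom`, `product_start`,
#'   `product_end`.
#' @param genome Reference genome.
#' @param flank Flank size per side, bp.
#' @param indel_window Width of the central variable window, bp.
#' @return Tibble with `pair_id`, `template`, `t_start`, `t_end` (0-based
#'   half-open genomic window) and `var_start`, `var_end` (0-based offsets
#'   of the variable window inside the template).
#' @export
extract_template <- function(markers, genome, flank = 40L,
                             indel_window = 20L) {
  g <- as_genome_tbl(genome)
  lens <- stats::setNames(nchar(g$seq), g$id)
  half <- indel_window %/% 2L
  centre <- (markers$product_start + markers$product_end) %/% 2L
  t_start <- centre - half - flank
  t_end <- centre + (indel_window - half) + flank
  L <- lens[markers$chrom]
  clipped <- t_start < 0 | t_end > L
  if (any(clipped)) {
    warning(sprintf("%d template window(s) truncated at chromosome ends",
                    sum(clipped)), call. = FALSE)
  }
  t_start2 <- pmax(0L, t_start)
  t_end2 <- pmin(as.integer(L), t_end)
  seqs <- substring(g$seq[match(markers$chrom, g$id)], t_start2 + 1L, t_end2)
  tibble::tibble(
    pair_id = markers$pair_id,
    template = seqs,
    t_start = as.integer(t_start2), t_end = as.integer(t_end2),
    var_start = as.integer((centre - half) - t_start2),
    var_end = as.integer((centre - half) - t_start2 + indel_window))
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), for 5'->3' dinucleotide steps.
.NN_DH <- c(AA = -7.9, AT = -7.2, AG = -7.8, AC = -8.4,
            TA = -7.2, TT = -7.9, TG = -8.5, TC = -8.2,
            GA = -8.2, GT = -8.4, GG = -8.0, GC = -9.8,
            CA = -8.5, CT = -7.8, CG = -10.6, CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, AG = -21.0, AC = -22.4,
            TA = -21.3, TT = -22.2, TG = -22.7, TC = -22.2,
            GA = -22.2, GT = -22.4, GG = -19.9, GC = -24.4,
            CA = -22.7, CT = -21.0, CG = -27.2, CC = -19.9)

#' Nearest-neighbor melting temperature of an oligo
#'
#' Unified nearest-neighbor thermodynamics (SantaLucia 1998) with terminal
#' initiation corrections, the entropy salt correction
#' `0.368 (N-1) ln[Na+]` at 50 mM monovalent salt, and duplex concentration
#' `CT/4` at 250 nM total oligo:
#' `Tm = 1000 dH / (dS + dS_salt + R ln(CT/4)) - 273.15`.
#'
#' @param seq Character vector of primer sequences over A/C/G/T, length >= 8.
#' @param Na Monovalent cation concentration, mol/L.
#' @param oligo_nM Total oligo concentration, nM.
#' @return Numeric vector of Tm in degrees Celsius.
#' @export
melting_temperature <- function(seq, Na = 0.05, oligo_nM = 250) {
  seq <- toupper(seq)
  assert_dna(seq, "primer", allow_n = FALSE)
  if (any(nchar(seq) < 8)) stop("Tm needs length >= 8", call. = FALSE)
  R <- 1.987
  ct_term <- R * log(oligo_nM * 1e-9 / 4)
  vapply(seq, function(s) {
    n <- nchar(s)
    steps <- substring(s, 1:(n - 1), 2:n)
    dh <- sum(.NN_DH[steps])
    ds <- sum(.NN_DS[steps]) + 0.368 * (n - 1) * log(Na)
    ends <- substring(s, c(1, n), c(1, n))
    dh <- dh + sum(ifelse(ends %in% c("A", "T"), 2.3, 0.1))
    ds <- ds + sum(ifelse(ends %in% c("A", "T"), 4.1, -2.8))
    1000 * dh / (ds + ct_term) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Design the best validation PCR primer pair on a template
#'
#' Enumerates every candidate primer of length 20-28 nt on the flank
#' upstream and downstream of the variable window, keeps candidates with
#' Tm in `tm_range`, GC in `gc_range` and a G or C 3' terminus, forms every
#' pair whose product spans the variable window with a length inside the
#' mode window (60-100 bp for `"page"`, 150-300 bp for `"agarose"`), and
#' returns the minimal-penalty pair with
#' `penalty = w_len (|lf-23| + |lr-23|) + w_tm (|Tmf-63| + |Tmr-63|) +
#'  w_gc (|GCf-50| + |GCr-50|) + w_dtm |Tmf - Tmr|`.
#' Ties go to the leftmost forward primer, then the shortest product.
#'
#' @param templates Tibble from [extract_template()] (needs `pair_id`,
#'   `template`, `var_start`, `var_end`), or a single template string whose
#'   central 20 bp are taken as the variable window.
#' @param mode `"page"` (60-100 bp products) or `"agarose"` (150-300 bp).
#' @param tm_range,tm_opt Allowed and optimal Tm, degrees C.
#' @param gc_range,gc_opt Allowed and optimal GC, percent.
#' @param len_range,len_opt Allowed and optimal primer length, nt.
#' @param weights Penalty weights `c(len, tm, gc, dtm)`.
#' @param gc_clamp If `TRUE`, additionally require >= 2 G/C among the last
#'   5 bases of each primer.
#' @return Tibble with one row per template that admits a pair: `pair_id`,
#'   `f_seq`, `r_seq`, `f_tm`, `r_tm`, `gc_f`, `gc_r`, `product_len`,
#'   `product_offset` (0-based product start within the template),
#'   `penalty`. Templates with no admissible pair are absent.
#' @export
design_validation_primers <- function(templates, mode = c("page", "agarose"),
                                      tm_range = c(60, 65), tm_opt = 63,
                                      gc_range = c(30, 70), gc_opt = 50,
                                      len_range = c(20L, 28L), len_opt = 23,
                                      weights = c(len = 1, tm = 2,
                                                  gc = 0.5, dtm = 2),
                                      gc_clamp = FALSE) {
  mode <- match.arg(mode)
  prod_range <- switch(mode, page = c(60L, 100L), agarose = c(150L, 300L))
  if (is.character(templates)) {
    L <- nchar(templates)
    vs <- (L - 20L) %/% 2L
    templates <- tibble::tibble(pair_id = paste0("template", seq_along(templates)),
                                template = templates,
                                var_start = vs, var_end = vs + 20L)
  }
  purrr::pmap_dfr(templates[, c("pair_id", "template", "var_start", "var_end")],
                  function(pair_id, template, var_start, var_end) {
    best <- .best_primer_pair(template, var_start, var_end, prod_range,
                              tm_range, tm_opt, gc_range, gc_opt, len_range,
                              len_opt, weights, gc_clamp)
    if (is.null(best)) return(NULL)
    dplyr::bind_cols(tibble::tibble(pair_id = pair_id), best)
  })
}

# Enumerate candidates on one flank. side "F": primer = template substring,
# must end at or before `limit` (0-based exclusive). side "R": footprint must
# start at or after `limit0`; primer = revcomp(footprint).
.flank_candidates <- function(template, side, limit, len_range, tm_range,
                              gc_range, gc_clamp) {
  L <- nchar(template)
  cand <- NULL
  for (len in seq(len_range[1], len_range[2])) {
    if (side == "F") {
      ends <- seq_len(max(0L, limit - len + 1L)) + len - 1L  # 1-based end
      if (!length(ends)) next
      start1 <- ends - len + 1L
      seqs <- substring(template, start1, ends)
      primer <- seqs
      fp_start0 <- start1 - 1L
    } else {
      starts <- seq(limit + 1L, L - len + 1L)
      starts <- starts[starts >= 1L]
      if (!length(starts)) next
      seqs <- substring(template, starts, starts + len - 1L)
      primer <- revcomp(seqs)
      fp_start0 <- starts - 1L
    }
    cand <- rbind(cand, data.frame(fp_start0 = fp_start0, len = len,
                                   primer = primer))
  }
  if (is.null(cand) || nrow(cand) == 0) return(NULL)
  cand <- cand[!stringi::stri_detect_regex(cand$primer, "[^ACGT]"), ,
               drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  last <- substring(cand$primer, cand$len, cand$len)
  cand <- cand[last %in% c("G", "C"), , drop = FALSE]
  if (gc_clamp && nrow(cand)) {
    tail5 <- substring(cand$primer, cand$len - 4L, cand$len)
    cand <- cand[stringi::stri_count_charclass(tail5, "[GC]") >= 2, ,
                 drop = FALSE]
  }
  if (nrow(cand) == 0) return(NULL)
  cand$gc <- gc_content(cand$primer)
  cand <- cand[cand$gc >= gc_range[1] & cand$gc <= gc_range[2], , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand$tm <- melting_temperature(cand$primer)
  cand <- cand[cand$tm >= tm_range[1] & cand$tm <= tm_range[2], , drop = FALSE]
  if (nrow(cand) == 0) NULL else cand
}

.best_primer_pair <- function(template, var_start, var_end, prod_range,
                              tm_range, tm_opt, gc_range, gc_opt, len_range,
                              len_opt, weights, gc_clamp) {
  fw <- .flank_candidates(template, "F", var_start, len_range, tm_range,
                          gc_range, gc_clamp)
  rv <- .flank_candidates(template, "R", var_end, len_range, tm_range,
                          gc_range, gc_clamp)
  if (is.null(fw) || is.null(rv)) return(NULL)
  idx <- expand.grid(f = seq_len(nrow(fw)), r = seq_len(nrow(rv)))
  f <- fw[idx$f, ]; r <- rv[idx$r, ]
  prod_len <- r$fp_start0 + r$len - f$fp_start0
  ok <- prod_len >= prod_range[1] & prod_len <= prod_range[2]
  if (!any(ok)) return(NULL)
  f <- f[ok, ]; r <- r[ok, ]; prod_len <- prod_len[ok]
  penalty <- weights[["len"]] * (abs(f$len - len_opt) + abs(r$len - len_opt)) +
    weights[["tm"]] * (abs(f$tm - tm_opt) + abs(r$tm - tm_opt)) +
    weights[["gc"]] * (abs(f$gc - gc_opt) + abs(r$gc - gc_opt)) +
    weights[["dtm"]] * abs(f$tm - r$tm)
  ord <- order(penalty, f$fp_start0, prod_len, r$fp_start0)
  i <- ord[1]
  tibble::tibble(
    f_seq = f$primer[i], r_seq = r$primer[i],
    f_len = f$len[i], r_len = r$len[i],
    f_tm = f$tm[i], r_tm = r$tm[i],
    gc_f = f$gc[i], gc_r = r$gc[i],
    product_len = as.integer(prod_len[i]),
    product_offset = as.integer(f$fp_start0[i]),
    penalty = penalty[i])
}

#' Validation-panel statistics
#'
#' Success rate is the percentage of tested markers amplifying in both
#' parents; accuracy is the percentage of those that are polymorphic.
#' When per-marker gel patterns are supplied, per-marker PIC (via
#' [compute_pic()] on the gel patterns) and the mean allele number are also
#' reported.
#'
#' @param n_tested,n_amplified,n_polymorphic Panel counts; must satisfy
#'   `n_polymorphic <= n_amplified <= n_tested`.
#' @param gel_patterns Optional tibble with `marker_id` and `pattern`
#'   columns, one row per (marker, sample) gel call.
#' @return One-row tibble with `n_tested`, `n_amplified`, `n_polymorphic`,
#'   `success_pct`, `accuracy_pct` (NA when nothing amplified) and, with gel
#'   patterns, `mean_pic` and `mean_allele_number`; the per-marker table is
#'   attached as attribute `"per_marker"`.
#' @examples
#' panel_statistics(100, 93, 89)  # success 93.00, accuracy 95.70
#' @export
panel_statistics <- function(n_tested, n_amplified, n_polymorphic,
                             gel_patterns = NULL) {
  stopifnot(n_polymorphic <= n_amplified, n_amplified <= n_tested,
            n_polymorphic >= 0)
  out <- tibble::tibble(
    n_tested = n_tested, n_amplified = n_amplified,
    n_polymorphic = n_polymorphic,
    success_pct = round_half_up(100 * n_amplified / n_tested, 2),
    accuracy_pct = if (n_amplified == 0) NA_real_ else
      round_half_up(100 * n_polymorphic / n_amplified, 2))
  if (!is.null(gel_patterns)) {
    per <- gel_patterns |>
      dplyr::group_by(marker_id = .data$marker_id) |>
      dplyr::summarise(pic = compute_pic(table(.data$pattern)),
                       allele_number = length(unique(.data$pattern)),
                       .groups = "drop")
    out$mean_pic <- round_half_up(mean(per$pic), 2)
    out$mean_allele_number <- round_half_up(mean(per$allele_number), 2)
    attr(out, "per_marker") <- per
  }
  out
}
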