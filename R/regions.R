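# Genomic region categories. Seven categories are built from a GFF3
# annotation: 0.5-kb windows upstream of the transcription start site
# (TSS_up_0.5kb) and downstream of the transcription end site
# (TES_down_0.5kb), 5'-UTR, CDS, intron, 3'-UTR, and intergenic (the
# complement of every gene-derived interval, flanks included). Categories may
# overlap one another; markers are placed into exactly one category later by
# a precedence rule (see assign_region()).

REGION_CATEGORIES <- c("TSS_up_0.5kb", "five_prime_UTR", "CDS", "intron",
                       "three_prime_UTR", "TES_down_0.5kb", "intergenic")

# Precedence used when a marker midpoint falls into several categories.
REGION_PRECEDENCE <- c("CDS", "five_prime_UTR", "three_prime_UTR", "intron",
                       "TSS_up_0.5kb", "TES_down_0.5kb", "intergenic")

#' Build an interval index of genomic region categories
#'
#' Parses a GFF3 annotation and derives the seven region categories used for
#' marker classification. `TSS_up` is the `flank` bp upstream of each gene's
#' transcription start on its coding strand, `TES_down` the `flank` bp
#' downstream of its end; introns are gene spans minus exons; intergenic is
#' the complement of the union of all gene-derived intervals (flanks
#' included). Flanks are truncated at chromosome ends.
#'
#' @param gff3 Path to a GFF3 file, or a `GRanges` as returned by
#'   `rtracklayer::import()`.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param flank Flank size in bp for the TSS/TES windows.
#' @return An object of class `region_index`.
#' @export
build_region_index <- function(gff3, chrom_lengths, flank = 500L) {
  gr <- if (is.character(gff3)) rtracklayer::import(gff3) else gff3
  stopifnot(!is.null(names(chrom_lengths)))
  chrom_lengths <- vapply(chrom_lengths, as.numeric, numeric(1))

  type <- as.character(gr$type)
  chr <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chr), names(chrom_lengths))
  if (length(unknown)) {
    stop("GFF3 features on chromosomes absent from chrom_lengths: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  over <- GenomicRanges::end(gr) > chrom_lengths[chr]
  if (any(over)) {
    stop(sprintf("feature beyond chromosome end: %s:%d-%d",
                 chr[which(over)[1]],
                 GenomicRanges::start(gr)[which(over)[1]],
                 GenomicRanges::end(gr)[which(over)[1]]), call. = FALSE)
  }

  genes <- gr[type == "gene"]
  if (any(as.character(GenomicRanges::strand(genes)) == "*")) {
    stop("gene feature with missing strand", call. = FALSE)
  }
  gene_ids <- .feature_gene_id(genes)

  si <- GenomeInfoDb::Seqinfo(seqnames = names(chrom_lengths),
                              seqlengths = as.integer(chrom_lengths))
  keep_si <- function(g) {
    GenomeInfoDb::seqlevels(g) <- names(chrom_lengths)
    GenomeInfoDb::seqinfo(g) <- si
    g
  }
  genes <- keep_si(genes)

  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  tss <- ifelse(plus, GenomicRanges::start(genes), GenomicRanges::end(genes))
  tes <- ifelse(plus, GenomicRanges::end(genes), GenomicRanges::start(genes))
  mk <- function(start, end, ids) {
    ok <- end >= start
    g <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(genes))[ok],
      IRanges::IRanges(start[ok], end[ok]), seqinfo = si)
    g$gene_id <- ids[ok]
    GenomicRanges::trim(g)
  }
  # 1-based closed intervals here; TSS_up = [TSS-flank, TSS-1], TES_down =
  # [TES+1, TES+flank] on the coding strand.
  tss_up <- mk(ifelse(plus, pmax(1, tss - flank), tss + 1),
               ifelse(plus, tss - 1, tss + flank), gene_ids)
  tes_down <- mk(ifelse(plus, tes + 1, pmax(1, tes - flank)),
                 ifelse(plus, tes + flank, tes - 1), gene_ids)

  # sub-gene features name their mRNA as Parent; resolve to the gene id
  mrna <- gr[type %in% c("mRNA", "transcript")]
  mrna_gene <- stats::setNames(.feature_parent(mrna), .feature_id(mrna))
  grab <- function(what) {
    sub <- keep_si(gr[type == what])
    ids <- .feature_gene_id(sub)
    via <- !is.na(ids) & ids %in% names(mrna_gene)
    ids[via] <- unname(mrna_gene[ids[via]])
    sub$gene_id <- ids
    GenomicRanges::granges(sub, use.mcols = TRUE)
  }
  cds <- grab("CDS")
  utr5 <- grab("five_prime_UTR")
  utr3 <- grab("three_prime_UTR")
  exons <- grab("exon")

  gene_spans <- GenomicRanges::granges(genes)
  gene_spans$gene_id <- gene_ids
  introns <- GenomicRanges::setdiff(gene_spans, GenomicRanges::reduce(exons),
                                    ignore.strand = TRUE)
  hit <- GenomicRanges::findOverlaps(introns, gene_spans, select = "first")
  introns$gene_id <- gene_ids[hit]

  gene_derived <- GenomicRanges::reduce(c(
    GenomicRanges::granges(gene_spans), GenomicRanges::granges(tss_up),
    GenomicRanges::granges(tes_down), GenomicRanges::granges(cds),
    GenomicRanges::granges(utr5), GenomicRanges::granges(utr3)),
    ignore.strand = TRUE)
  full <- GenomicRanges::GRanges(names(chrom_lengths),
                                 IRanges::IRanges(1, as.integer(chrom_lengths)),
                                 seqinfo = si)
  intergenic <- GenomicRanges::setdiff(full, gene_derived, ignore.strand = TRUE)
  intergenic$gene_id <- NA_character_

  cats <- list(TSS_up_0.5kb = tss_up, five_prime_UTR = utr5, CDS = cds,
               intron = introns, three_prime_UTR = utr3,
               TES_down_0.5kb = tes_down, intergenic = intergenic)
  totals <- vapply(cats, function(g)
    sum(GenomicRanges::width(GenomicRanges::reduce(GenomicRanges::granges(g),
                                                   ignore.strand = TRUE))),
    numeric(1))
  structure(list(categories = cats, totals = totals,
                 chrom_lengths = chrom_lengths, flank = flank),
            class = "region_index")
}

.mcol_chr <- function(g, col) {
  m <- S4Vectors::mcols(g)
  if (!col %in% names(m)) return(rep(NA_character_, length(g)))
  v <- m[[col]]
  if (methods::is(v, "List") || is.list(v)) {
    v <- vapply(v, function(x) if (length(x)) as.character(x[1]) else NA_character_,
                character(1))
  }
  as.character(v)
}

.feature_id <- function(g) .mcol_chr(g, "ID")

.feature_parent <- function(g) .mcol_chr(g, "Parent")

.feature_gene_id <- function(g) {
  m <- S4Vectors::mcols(g)
  for (col in c("gene_id", "ID", "Parent", "Name")) {
    if (col %in% names(m)) {
      v <- m[[col]]
      if (methods::is(v, "List") || is.list(v)) {
        v <- vapply(v, function(x) if (length(x)) as.character(x[1]) else NA_character_,
                    character(1))
      }
      if (!all(is.na(v))) return(as.character(v))
    }
  }
  rep(NA_character_, length(g))
}

#' @export
print.region_index <- function(x, ...) {
  cat("<region_index>", length(x$chrom_lengths), "chromosome(s),",
      sum(x$chrom_lengths), "bp; flank", x$flank, "bp\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a region index into an interval table
#'
#' @param x A `region_index`.
#' @param ... Unused.
#' @return Tibble with `chrom`, `start` (0-based), `end` (half-open exclusive),
#'   `category`, `gene_id`.
#' @method tidy region_index
#' @export
tidy.region_index <- function(x, ...) {
  purrr::imap_dfr(x$categories, function(g, cat) {
    if (length(g) == 0) return(NULL)
    tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g) - 1L,
      end = GenomicRanges::end(g),
      category = cat,
      gene_id = if ("gene_id" %in% names(S4Vectors::mcols(g)))
        as.character(g$gene_id) else NA_character_)
  })
}

#' Assign each marker to a single genomic region category
#'
#' The category of a marker is the category of its reference-product
#' midpoint; overlaps between categories are resolved by the precedence
#' CDS > 5'-UTR > 3'-UTR > intron > TSS_up > TES_down > intergenic. The
#' owning gene id is attached when the category is gene-derived.
#'
#' @param x Tibble carrying `chrom`, `product_start`, `product_end`
#'   (0-based, half-open), e.g. markers from [call_indels()] or primer pairs
#'   from [design_sliding_window_primers()].
#' @param region_index A [build_region_index()] result.
#' @return `x` with `category` and `gene_id` columns appended.
#' @export
assign_region <- function(x, region_index) {
  stopifnot(inherits(region_index, "region_index"))
  mid0 <- (x$product_start + x$product_end) %/% 2L
  len <- region_index$chrom_lengths[x$chrom]
  if (any(is.na(len)) || any(mid0 >= len) || any(mid0 < 0)) {
    stop("marker midpoint beyond chromosome end", call. = FALSE)
  }
  q <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(mid0 + 1L, width = 1L))
  category <- rep(NA_character_, nrow(x))
  gene_id <- rep(NA_character_, nrow(x))
  for (cat in REGION_PRECEDENCE) {
    g <- region_index$categories[[cat]]
    if (length(g) == 0) next
    todo <- which(is.na(category))
    if (!length(todo)) break
    hit <- GenomicRanges::findOverlaps(q[todo], g, select = "first",
                                       ignore.strand = TRUE)
    found <- !is.na(hit)
    category[todo[found]] <- cat
    if ("gene_id" %in% names(S4Vectors::mcols(g)) && cat != "intergenic") {
      gene_id[todo[found]] <- as.character(g$gene_id[hit[found]])
    }
  }
  # any base not covered by a category can only arise from an annotation gap;
  # fall back to intergenic
  category[is.na(category)] <- "intergenic"
  x$category <- category
  x$gene_id <- gene_id
  x
}
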