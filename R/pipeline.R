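# End-to-end orchestration: design -> uniqueness filter -> read e-PCR ->
# genotyping -> annotation -> summaries -> marker selection -> validation
# primers, with a JSON run manifest of parameters and per-stage counts.
# Stage outputs are pure functions of the inputs and the configuration.

#' Pipeline configuration
#'
#' Defaults reproduce the canonical settings: 3 genome mismatches, 1 read
#' mismatch, the >= 20 typed-genomes rule, Q20/70 % read filtering and
#' 40-400 bp genomic product bounds.
#'
#' @param ref_a,ref_b Paths to the template and comparison reference FASTA.
#' @param reads_dir Directory of per-sample FASTQ files (`<sample>.fq` or
#'   `.fastq`; the file stem is the sample id).
#' @param out_dir Output directory.
#' @param gff3 Optional GFF3 annotation path (enables region annotation).
#' @param groups Optional sample-group TSV path (see [read_groups()]).
#' @param max_mm_genome,max_mm_reads Mismatch budgets for the uniqueness
#'   filter and for read amplification.
#' @param min_samples Minimum typed samples per marker.
#' @param quality_cutoff,quality_min_fraction Read quality filter settings.
#' @param product_min,product_max Genomic product-length bounds, bp.
#' @param mode Marker-selection tier, `"page"` or `"agarose"`.
#' @param flank Validation-template flank, bp; defaults to 40 for page and
#'   150 for agarose.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ref_a, ref_b, reads_dir, out_dir,
                            gff3 = NULL, groups = NULL,
                            max_mm_genome = 3L, max_mm_reads = 1L,
                            min_samples = 20L, quality_cutoff = 20,
                            quality_min_fraction = 0.70,
                            product_min = 40L, product_max = 400L,
                            mode = c("page", "agarose"), flank = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(flank)) flank <- if (mode == "page") 40L else 150L
  structure(list(ref_a = ref_a, ref_b = ref_b, reads_dir = reads_dir,
                 out_dir = out_dir, gff3 = gff3, groups = groups,
                 max_mm_genome = max_mm_genome, max_mm_reads = max_mm_reads,
                 min_samples = min_samples, quality_cutoff = quality_cutoff,
                 quality_min_fraction = quality_min_fraction,
                 product_min = product_min, product_max = product_max,
                 mode = mode, flank = flank, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the marker-discovery pipeline
#'
#' Stages run in order: design, unique, epcr, genotype, annotate (if a GFF3
#' is configured), summarize, select, primers. Tables are written as TSV/BED
#' under `config$out_dir` together with `manifest.json` (parameters, seed,
#' per-stage counts). Re-running with the same inputs and configuration
#' reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[indelscout] ", sprintf(...))
  counts <- list()

  ref_a <- .stage("design", read_fasta(config$ref_a))
  ref_b <- .stage("unique", read_fasta(config$ref_b))

  pairs <- .stage("design", design_sliding_window_primers(ref_a))
  counts$primer_pairs <- nrow(pairs)
  log_stage("design: %d primer pairs", nrow(pairs))

  verdicts <- .stage("unique", classify_unique_pairs(
    pairs, ref_a, ref_b, max_mm = config$max_mm_genome,
    min_len = config$product_min, max_len = config$product_max))
  unique_pairs <- pairs[pairs$pair_id %in%
                          verdicts$pair_id[verdicts$unique], , drop = FALSE]
  counts$unique_pairs <- nrow(unique_pairs)
  log_stage("unique: %d unique pairs (%.2f%%)", nrow(unique_pairs),
            100 * nrow(unique_pairs) / max(1, nrow(pairs)))
  write_primer_table(unique_pairs, file.path(config$out_dir, "unique_pairs.tsv"))

  fq <- .stage("epcr", {
    files <- list.files(config$reads_dir, pattern = "\\.(fq|fastq)$",
                        full.names = TRUE)
    if (!length(files)) stop("no FASTQ files in ", config$reads_dir)
    dplyr::bind_rows(lapply(files, function(f) {
      read_fastq(f, sample_id = sub("\\.(fq|fastq)$", "", basename(f)))
    }))
  })
  counts$reads_total <- nrow(fq)
  fq <- quality_filter_reads(fq, config$quality_cutoff,
                             config$quality_min_fraction)
  counts$reads_passing_qc <- nrow(fq)
  log_stage("epcr: %d reads pass QC", nrow(fq))

  products <- .stage("epcr", epcr_reads(unique_pairs, fq,
                                        max_mm = config$max_mm_reads))
  counts$read_products <- nrow(products)
  log_stage("epcr: %d read products", nrow(products))

  gm <- .stage("genotype", build_matrix(products,
                                        samples = unique(fq$sample_id)))
  markers <- .stage("genotype", call_indels(gm, pairs = unique_pairs,
                                            min_samples = config$min_samples))
  counts$loci_typed <- nrow(gm)
  counts$indel_markers <- nrow(markers)
  log_stage("genotype: %d loci typed, %d InDel markers", nrow(gm),
            nrow(markers))

  group_freqs <- NULL
  if (!is.null(config$groups)) {
    grp <- .stage("genotype", read_groups(config$groups))
    group_freqs <- group_major_allele_freq(gm, markers, grp)
  }
  write_marker_table(markers, file.path(config$out_dir, "markers.tsv"),
                     group_freqs = group_freqs)
  write_marker_bed(markers, file.path(config$out_dir, "markers.bed"))

  chrom_lengths <- stats::setNames(ref_a$length, ref_a$id)
  if (!is.null(config$gff3)) {
    if (!file.exists(config$gff3)) {
      stop("pipeline stage 'annotate' failed: no such GFF3: ", config$gff3,
           call. = FALSE)
    }
    ridx <- .stage("annotate", build_region_index(config$gff3, chrom_lengths))
    markers <- .stage("annotate", assign_region(markers, ridx))
    utils::write.table(
      summarize_regions(markers, ridx),
      file.path(config$out_dir, "summary_regions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    summarize_chromosomes(markers, chrom_lengths),
    file.path(config$out_dir, "summary_chromosomes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  selected <- .stage("select", select_marker_sets(markers, config$mode))
  counts$selected_markers <- nrow(selected)
  log_stage("select (%s): %d markers", config$mode, nrow(selected))

  primers <- .stage("primers", {
    tpl <- extract_template(selected, ref_a, flank = config$flank)
    design_validation_primers(tpl, mode = config$mode)
  })
  counts$validation_primers <- nrow(primers)
  log_stage("primers: %d validation pairs", nrow(primers))
  utils::write.table(primers, file.path(config$out_dir, "validation_primers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "indelscout",
    version = as.character(utils::packageVersion("indelscout")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("ref_a", "ref_b", "reads_dir", "out_dir",
                                  "gff3", "groups"))],
    counts = counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
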