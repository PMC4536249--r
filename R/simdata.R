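# Seeded simulator: a random reference genome, a diverged second reference
# with planted InDels and background SNPs, a population drawing alleles at
# known frequencies, and uniform-coverage reads. Each planted InDel sits
# entirely inside the 20-bp inter-primer gap of exactly one tiling pair
# (its "owning" pair), at least 100 bp from any other locus and from the
# chromosome ends, so truth matching is unambiguous.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of low-coverage rice resequencing:
#' 87-bp reads (the observed average read length, rounded up), 2x depth,
#' geometric InDel lengths dominated by 1-2 bp differences, and ~0.5 %
#' background SNP divergence between the two references.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Chromosome length, bp.
#' @param gc GC fraction of the reference.
#' @param n_loci Number of planted InDel loci per genome.
#' @param indel_geom_p Success probability of the geometric length
#'   distribution (lengths 1..`indel_len_range[2]`).
#' @param indel_len_range Inclusive truncation bounds on InDel length, bp.
#'   Deletions are additionally capped at the inter-primer gap (20 bp) so
#'   each planted deletion stays inside one pair's variable region.
#' @param allele_freq Population frequency of the alternate (InDel) allele;
#'   scalar or per-locus vector.
#' @param snp_rate Per-bp substitution rate between the two references.
#' @param n_samples Number of population samples.
#' @param read_len Read length, bp (>= 60).
#' @param depth Expected per-sample coverage.
#' @param base_error_rate Per-base sequencing error rate.
#' @param insertion_prob Probability that a planted locus is an insertion
#'   (vs a deletion).
#' @param groups Group labels samples are assigned to, uniformly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chroms = 1L, chrom_len = 10000L,
                       gc = 0.44, n_loci = 40L, indel_geom_p = 0.4,
                       indel_len_range = c(1L, 50L), allele_freq = 0.5,
                       snp_rate = 0.005, n_samples = 200L, read_len = 87L,
                       depth = 2, base_error_rate = 0.005,
                       insertion_prob = 0.5,
                       groups = c("japonica", "indica")) {
  stopifnot(read_len >= 60, gc >= 0, gc <= 1, snp_rate >= 0, snp_rate <= 1,
            all(allele_freq >= 0), all(allele_freq <= 1),
            base_error_rate >= 0, base_error_rate < 1, depth > 0,
            indel_len_range[1] >= 1, indel_len_range[2] >= indel_len_range[1])
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_len = as.integer(chrom_len), gc = gc,
                 n_loci = as.integer(n_loci), indel_geom_p = indel_geom_p,
                 indel_len_range = as.integer(indel_len_range),
                 allele_freq = allele_freq, snp_rate = snp_rate,
                 n_samples = as.integer(n_samples),
                 read_len = as.integer(read_len), depth = depth,
                 base_error_rate = base_error_rate,
                 insertion_prob = insertion_prob, groups = groups),
            class = "sim_config")
}

.random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# truncated geometric on [lo, hi]
.rindel_len <- function(n, p, lo, hi) {
  lens <- integer(0)
  while (length(lens) < n) {
    draw <- stats::rgeom(2L * n + 10L, p) + 1L
    lens <- c(lens, draw[draw >= lo & draw <= hi])
  }
  lens[seq_len(n)]
}

# apply edits (tibble: pos0, type, len, alt) to a sequence, descending pos
.apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0) return(seq)
  edits <- edits[order(-edits$pos0), , drop = FALSE]
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos0[i]
    seq <- switch(edits$type[i],
      del = paste0(substring(seq, 1L, p), substring(seq, p + edits$len[i] + 1L)),
      ins = paste0(substring(seq, 1L, p), edits$alt[i], substring(seq, p + 1L)),
      snp = paste0(substring(seq, 1L, p), edits$alt[i], substring(seq, p + 2L)))
  }
  seq
}

#' Simulate two reference genomes with a planted-InDel truth table
#'
#' Genome A is random with the configured GC; genome B is genome A with one
#' planted InDel per truth locus plus background substitutions at
#' `snp_rate`. Every locus falls inside the inter-primer gap of a distinct
#' tiling pair, >= 100 bp from every other locus and from chromosome ends.
#' Deterministic under `config$seed` (the seed is set here; downstream
#' stages continue the same stream).
#'
#' @param config A [sim_config()].
#' @return List with `genome_a`, `genome_b` (tibbles with `id`/`seq`) and
#'   `truth` (tibble: `locus_id`, `chrom`, `pair_id`, `pos0`, `type`,
#'   `indel_len`, `ref_product_len`, `alt_product_len`, `alt_freq`).
#' @export
simulate_references <- function(config) {
  set.seed(config$seed)
  gap <- 20L
  win <- 60L
  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome_a <- tibble::tibble(
    id = chroms,
    seq = vapply(chroms, function(.) .random_dna(config$chrom_len, config$gc),
                 character(1), USE.NAMES = FALSE))

  # candidate gaps: pair k (0-based) has gap [20k+20, 20k+40); keep gaps with
  # centre >= 100 bp from both ends
  n_pairs <- expected_pair_count(config$chrom_len)
  ks <- 0:(n_pairs - 1)
  centre <- 20L * ks + 30L
  ks <- ks[centre >= 100 & centre <= config$chrom_len - 100]
  per_chrom <- .spread_loci(ks, config$n_loci, config$n_chroms)

  freq <- rep_len(config$allele_freq, config$n_loci * config$n_chroms)
  truth <- purrr::imap_dfr(per_chrom, function(kk, ci) {
    n <- length(kk)
    if (n == 0) return(NULL)
    type <- ifelse(stats::runif(n) < config$insertion_prob, "ins", "del")
    len <- .rindel_len(n, config$indel_geom_p, config$indel_len_range[1],
                       config$indel_len_range[2])
    len[type == "del"] <- pmin(len[type == "del"], gap)
    gap_start <- 20L * kk + 20L
    pos0 <- integer(n)
    for (i in seq_len(n)) {
      pos0[i] <- if (type[i] == "del") {
        gap_start[i] + sample.int(gap - len[i] + 1L, 1L) - 1L
      } else {
        gap_start[i] + sample.int(gap - 1L, 1L)  # strictly inside the gap
      }
    }
    tibble::tibble(
      chrom = chroms[ci], gap_index = kk, pos0 = pos0, type = type,
      indel_len = len,
      pair_id = paste0(chroms[ci], "-", 20L * kk + 1L),
      ref_product_len = win,
      alt_product_len = win + ifelse(type == "ins", len, -len))
  })
  if (nrow(truth) == 0) {
    truth <- tibble::tibble(chrom = character(), gap_index = integer(),
                            pos0 = integer(), type = character(),
                            indel_len = integer(), pair_id = character(),
                            ref_product_len = integer(),
                            alt_product_len = integer())
  }
  truth$locus_id <- paste0("locus", seq_len(nrow(truth)))
  truth$alt_freq <- freq[seq_len(nrow(truth))]
  truth$alt_seq <- ifelse(truth$type == "ins",
                          vapply(truth$indel_len,
                                 function(l) .random_dna(l, config$gc),
                                 character(1)),
                          NA_character_)

  genome_b <- genome_a
  for (ci in seq_len(nrow(genome_b))) {
    s <- genome_b$seq[ci]
    if (config$snp_rate > 0) {
      n_snp <- stats::rbinom(1L, nchar(s), config$snp_rate)
      if (n_snp > 0) {
        pos <- sample.int(nchar(s), n_snp) - 1L
        ref <- substring(s, pos + 1L, pos + 1L)
        alt <- vapply(ref, function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        s <- .apply_edits(s, tibble::tibble(pos0 = pos, type = "snp",
                                            len = 1L, alt = alt))
      }
    }
    tt <- truth[truth$chrom == genome_b$id[ci], , drop = FALSE]
    s <- .apply_edits(s, tibble::tibble(pos0 = tt$pos0, type = tt$type,
                                        len = tt$indel_len, alt = tt$alt_seq))
    genome_b$seq[ci] <- s
  }
  list(genome_a = genome_a, genome_b = genome_b,
       truth = truth[, c("locus_id", "chrom", "pair_id", "gap_index", "pos0",
                         "type", "indel_len", "alt_seq", "ref_product_len",
                         "alt_product_len", "alt_freq")])
}

# Pick loci >= 6 gap indices apart (gap starts >= 120 bp apart, so any two
# in-gap positions are > 100 bp apart) per chromosome.
.spread_loci <- function(ks, n_loci, n_chroms) {
  lapply(seq_len(n_chroms), function(.) {
    if (n_loci == 0) return(integer(0))
    chosen <- integer(0)
    for (k in sample(ks)) {
      if (all(abs(k - chosen) >= 6L)) chosen <- c(chosen, k)
      if (length(chosen) == n_loci) break
    }
    if (length(chosen) < n_loci) {
      stop("loci too dense for the 100-bp spacing constraint", call. = FALSE)
    }
    sort(chosen)
  })
}

#' Simulate a population of sample genomes
#'
#' Each sample draws, independently per locus, the alternate allele with the
#' locus's `alt_freq`; its genome is genome A with the drawn InDels applied.
#' Samples vary only at the planted loci.
#'
#' @param refs A [simulate_references()] result.
#' @param config The same [sim_config()].
#' @return List with `genomes` (tibble `sample_id`, `chrom`, `seq`),
#'   `genotypes` (long tibble `sample_id`, `locus_id`, `allele`), and
#'   `truth` with a realized `alt_count` column appended.
#' @export
simulate_population <- function(refs, config) {
  truth <- refs$truth
  samples <- sprintf("s%03d", seq_len(config$n_samples))
  draw <- matrix(stats::runif(nrow(truth) * config$n_samples) <
                   rep(truth$alt_freq, config$n_samples),
                 nrow = nrow(truth))
  genotypes <- tibble::tibble(
    sample_id = rep(samples, each = nrow(truth)),
    locus_id = rep(truth$locus_id, config$n_samples),
    allele = ifelse(as.vector(draw), "alt", "ref"))
  genomes <- purrr::map_dfr(seq_along(samples), function(si) {
    purrr::map_dfr(seq_len(nrow(refs$genome_a)), function(ci) {
      tt <- truth[truth$chrom == refs$genome_a$id[ci] & draw[, si], ,
                  drop = FALSE]
      tibble::tibble(
        sample_id = samples[si], chrom = refs$genome_a$id[ci],
        seq = .apply_edits(refs$genome_a$seq[ci],
                           tibble::tibble(pos0 = tt$pos0, type = tt$type,
                                          len = tt$indel_len,
                                          alt = tt$alt_seq)))
    })
  })
  truth$alt_count <- rowSums(draw)
  list(genomes = genomes, genotypes = genotypes, truth = truth)
}

#' Simulate uniform-coverage reads from sample genomes
#'
#' Read starts are uniform, strands equiprobable, length fixed at
#' `config$read_len`; each base is substituted independently at
#' `config$base_error_rate`, and every base gets the Phred score implied by
#' that error rate (Q40 when the rate is 0).
#'
#' @param genomes Tibble with `sample_id`, `chrom`, `seq` (or `id`/`seq`
#'   for a bare genome, in which case `sample_id` defaults to the id).
#' @param config A [sim_config()].
#' @return Read tibble (`id`, `seq`, `qual`, `sample_id`) as from
#'   [read_fastq()].
#' @export
simulate_reads <- function(genomes, config) {
  if (!"sample_id" %in% names(genomes)) {
    genomes <- as_genome_tbl(genomes)
    genomes$sample_id <- genomes$id
    genomes$chrom <- genomes$id
  }
  rl <- config$read_len
  q <- if (config$base_error_rate <= 0) 40L else
    as.integer(round(-10 * log10(config$base_error_rate)))
  qchar <- strrep(intToUtf8(q + 33L), rl)
  purrr::pmap_dfr(genomes[, c("sample_id", "chrom", "seq")],
                  function(sample_id, chrom, seq) {
    L <- nchar(seq)
    n <- as.integer(round(config$depth * L / rl))
    if (L < rl || n == 0) return(NULL)
    start0 <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
    rd <- substring(seq, start0 + 1L, start0 + rl)
    minus <- stats::runif(n) < 0.5
    rd[minus] <- revcomp(rd[minus])
    if (config$base_error_rate > 0) {
      rd <- .add_errors(rd, config$base_error_rate)
    }
    tibble::tibble(
      id = sprintf("%s_%s_%d", sample_id, chrom, seq_len(n)),
      seq = rd, qual = qchar, sample_id = sample_id)
  })
}

.add_errors <- function(reads, rate) {
  chars <- strsplit(reads, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    flat[hit] <- vapply(flat[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  }
  vapply(split(flat, rep(seq_along(lens), lens)), paste, character(1),
         collapse = "")
}

#' Simulate a complete dataset
#'
#' Runs [simulate_references()], [simulate_population()] and
#' [simulate_reads()] under one seeded RNG stream and assigns samples to
#' groups uniformly.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset`: `config`, `genome_a`, `genome_b`,
#'   `truth`, `genotypes`, `genomes`, `reads`, `groups`.
#' @export
simulate_dataset <- function(config) {
  refs <- simulate_references(config)
  pop <- simulate_population(refs, config)
  reads <- simulate_reads(pop$genomes, config)
  samples <- unique(pop$genomes$sample_id)
  groups <- tibble::tibble(
    sample_id = samples,
    group = sample(config$groups, length(samples), replace = TRUE))
  structure(list(config = config, genome_a = refs$genome_a,
                 genome_b = refs$genome_b, truth = pop$truth,
                 genotypes = pop$genotypes, genomes = pop$genomes,
                 reads = reads, groups = groups),
            class = "sim_dataset")
}

#' Write a simulated dataset to a directory
#'
#' Writes `ref_a.fa`, `ref_b.fa`, `truth.tsv`, `groups.tsv` and one FASTQ
#' per sample under `samples/`.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(file.path(dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genome_a, file.path(dir, "ref_a.fa"))
  write_fasta(sim$genome_b, file.path(dir, "ref_b.fa"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$groups, file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in unique(sim$reads$sample_id)) {
    write_fastq(sim$reads[sim$reads$sample_id == s, ],
                file.path(dir, "samples", paste0(s, ".fq")))
  }
  invisible(dir)
}
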