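test_that("primer-site search finds exact, mismatched and reverse hits", {
  set.seed(20)
  g <- random_dna(200)
  primer <- substr(g, 11, 30)

  hit <- find_primer_sites(g, primer, 0)
  expect_true(nrow(hit) >= 1)
  self <- hit[hit$pos == 10, ]
  expect_equal(self$strand, "+")
  expect_equal(self$mismatches, 0L)

  # two planted mismatches: invisible at max_mm=1, found at max_mm=2
  p2 <- primer
  substr(p2, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(p2, 3, 3))[1]
  substr(p2, 17, 17) <- setdiff(c("A", "C", "G", "T"), substr(p2, 17, 17))[1]
  expect_false(10 %in% find_primer_sites(g, p2, 1)$pos)
  h2 <- find_primer_sites(g, p2, 2)
  expect_true(any(h2$pos == 10 & h2$mismatches == 2))

  # reverse complement planted at pos 50 is reported on the minus strand
  g2 <- paste0(substr(g, 1, 50), naive_revcomp(primer), substr(g, 71, 200))
  hrc <- find_primer_sites(g2, primer, 0)
  expect_true(any(hrc$pos == 50 & hrc$strand == "-"))

  expect_error(find_primer_sites(g, "ACGT", 1), "20-mer")
  expect_error(find_primer_sites(g, paste0("N", substr(primer, 2, 20)), 1),
               "A/C/G/T")
})

test_that("indexed search agrees with the naive Hamming scan and is monotone", {
  set.seed(21)
  for (rep in 1:25) {
    L <- sample(50:1500, 1)
    g <- random_dna(L)
    mm <- sample(0:3, 1)
    primer <- if (rep %% 2 == 0) {
      random_dna(20)
    } else {
      # plant a mutated copy so hits actually occur
      p <- substr(g, 8, 27)
      for (k in sample(20, sample(0:3, 1))) {
        substr(p, k, k) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(p, k, k)), 1)
      }
      p
    }
    got <- as.data.frame(find_primer_sites(g, primer, mm))
    want <- naive_primer_sites(g, primer, mm)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got$pos, want$pos)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
    if (mm < 3) {
      more <- find_primer_sites(g, primer, mm + 1)
      expect_true(all(paste(got$pos, got$strand) %in%
                        paste(more$pos, more$strand)))
    }
  }
})

test_that("template e-PCR: self-amplification, deletions, duplications", {
  set.seed(22)
  g <- random_dna(400)
  pairs <- design_sliding_window_primers(c(x = g))

  # every pair amplifies its own template exactly once at its reference
  # interval with zero mismatches
  amp <- epcr_template(pairs, c(x = g), max_mm = 3)
  expect_equal(nrow(amp), nrow(pairs))
  amp <- amp[match(pairs$pair_id, amp$pair_id), ]
  expect_equal(amp$start, pairs$product_start)
  expect_equal(amp$end, pairs$product_end)
  expect_true(all(amp$length == 60 & amp$f_mm == 0 & amp$r_mm == 0))
  expect_equal(amp$seq, substring(g, pairs$product_start + 1,
                                  pairs$product_end))

  # a 5-bp deletion inside the gap of pair 2 (gap [40, 60)) gives a 55-bp
  # product for that pair
  gdel <- paste0(substr(g, 1, 45), substr(g, 51, 400))
  adel <- epcr_template(pairs[2, ], c(x = gdel), max_mm = 3)
  expect_equal(adel$length, 55L)

  # copy-pasting pair 2's product elsewhere yields two products
  gdup <- paste0(g, random_dna(30), substr(g, 21, 80), random_dna(30))
  adup <- epcr_template(pairs[2, ], c(x = gdup), max_mm = 3)
  expect_equal(nrow(adup), 2L)

  # product length bounds are enforced
  expect_equal(nrow(epcr_template(pairs[2, ], c(x = gdel), max_mm = 3,
                                  min_len = 56)), 0L)
})

test_that("uniqueness verdicts require exactly one product in each genome", {
  set.seed(23)
  g <- random_dna(300)
  pairs <- design_sliding_window_primers(c(x = g))
  pid <- pairs$pair_id[4]

  v <- classify_unique_pairs(pairs, c(x = g), c(x = g))
  expect_true(all(v$unique))
  expect_true(all(v$n_products_a == 1 & v$n_products_b == 1))

  # duplication in genome B breaks uniqueness for the duplicated pair
  # (the copy sits beyond max_len so no bridging product forms)
  gdup <- paste0(g, random_dna(400), substr(g, 61, 120), random_dna(25))
  v2 <- classify_unique_pairs(pairs, c(x = g), c(x = gdup))
  expect_false(v2$unique[v2$pair_id == pid])
  expect_equal(v2$n_products_b[v2$pair_id == pid], 2L)

  # a pair absent from genome B (diverged) has n_b = 0 and is not unique
  v3 <- classify_unique_pairs(pairs[4, ], c(x = g), c(x = random_dna(300)))
  expect_equal(v3$n_products_b, 0L)
  expect_false(v3$unique)
})

test_that("read e-PCR requires the whole product inside one read", {
  set.seed(24)
  g <- random_dna(300)
  pairs <- design_sliding_window_primers(c(x = g))
  pair <- pairs[3, ]  # product [40, 100)

  mkreads <- function(seqs) {
    tibble::tibble(id = paste0("r", seq_along(seqs)), seq = seqs,
                   qual = strrep("I", nchar(seqs)), sample_id = "s1")
  }

  # a 90-bp read containing the whole 60-bp product -> one length-60 product
  rd <- substr(g, 26, 115)
  out <- epcr_reads(pair, mkreads(rd), max_mm = 1)
  expect_equal(out$product_length, 60L)
  expect_equal(out$product_seq, substr(g, 41, 100))

  # reverse-complement read gives the same product
  out_rc <- epcr_reads(pair, mkreads(naive_revcomp(rd)), max_mm = 1)
  expect_equal(out_rc$product_length, 60L)
  expect_equal(out_rc$product_seq, substr(g, 41, 100))

  # read containing only the forward primer (product truncated) -> nothing
  expect_equal(nrow(epcr_reads(pair, mkreads(substr(g, 26, 95)), max_mm = 1)),
               0L)

  # one mismatch in the forward primer: found at max_mm=1, not at max_mm=0
  rd_mm <- rd
  substr(rd_mm, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                   substr(rd_mm, 20, 20))[1]  # inside f
  expect_equal(epcr_reads(pair, mkreads(rd_mm), max_mm = 1)$f_mm, 1L)
  expect_equal(nrow(epcr_reads(pair, mkreads(rd_mm), max_mm = 0)), 0L)

  # hits never cross read boundaries: two reads that each hold half the
  # product yield nothing
  halves <- mkreads(c(substr(g, 26, 80), substr(g, 81, 130)))
  expect_equal(nrow(epcr_reads(pair, halves, max_mm = 1)), 0L)
})

test_that("error-free simulated reads only yield template product lengths", {
  set.seed(25)
  cfg <- sim_config(seed = 25, chrom_len = 3000L, n_loci = 6L,
                    indel_len_range = c(3L, 8L), snp_rate = 0,
                    n_samples = 4L, depth = 20, base_error_rate = 0)
  sim <- simulate_dataset(cfg)
  pairs <- design_sliding_window_primers(sim$genome_a)
  prods <- epcr_reads(pairs, sim$reads, max_mm = 1)
  # every observed (pair, sample, length) must be a product the pair finds
  # on that sample's genome directly
  combos <- unique(prods[, c("pair_id", "sample_id", "product_length")])
  direct <- dplyr::bind_rows(lapply(unique(combos$sample_id), function(sid) {
    s <- sim$genomes$seq[sim$genomes$sample_id == sid]
    tmpl <- epcr_template(pairs, c(x = s), max_mm = 1)
    tibble::tibble(pair_id = tmpl$pair_id, sample_id = sid,
                   product_length = tmpl$length)
  }))
  left_over <- dplyr::anti_join(
    combos, direct, by = c("pair_id", "sample_id", "product_length"))
  expect_equal(nrow(left_over), 0L)
})
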