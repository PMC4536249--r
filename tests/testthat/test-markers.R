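test_that("summary arithmetic reproduces density, proportion and spacing", {
  s <- summarize_counts(tibble::tibble(chrom = "chr1", count = 1,
                                       length_bp = 1000))
  expect_equal(s$density_per_kb, 1.00)

  # density x length / 1000 recovers the count within rounding
  set.seed(40)
  tb <- tibble::tibble(chrom = paste0("c", 1:8),
                       count = sample(1e3:1e6, 8),
                       length_bp = sample(1e6:1e8, 8))
  s2 <- summarize_counts(tb)
  expect_true(all(abs(s2$density_per_kb * s2$length_bp / 1000 - s2$count) /
                    s2$count < 0.01))

  # zero-length region has NA density
  expect_true(is.na(summarize_counts(
    tibble::tibble(x = "a", count = 0, length_bp = 0))$density_per_kb))

  # category counts sum to the total row in a region summary
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_fixture_gff3(gff)
  ridx <- build_region_index(gff, c(chrA = 10000))
  set.seed(41)
  mk <- tibble::tibble(pair_id = paste0("m", 1:50), chrom = "chrA",
                       product_start = sample(0:9900, 50))
  mk$product_end <- mk$product_start + 60
  sr <- summarize_regions(assign_region(mk, ridx), ridx)
  expect_equal(sum(sr$count[sr$category != "total"]),
               sr$count[sr$category == "total"])
  expect_equal(sr$count[sr$category == "total"], 50L)
})

test_that("marker tier selection applies PIC and size-difference cutoffs", {
  mk <- tibble::tibble(
    pair_id = paste0("m", 1:4),
    pic = c(0.55, 0.49, 0.60, 0.52),
    major_allele_diff = c(3, 10, 8, 2))
  page <- select_marker_sets(mk, "page")
  agarose <- select_marker_sets(mk, "agarose")
  expect_equal(page$pair_id, c("m1", "m3"))     # PIC>=0.5 & diff>=3
  expect_equal(agarose$pair_id, "m3")           # PIC>=0.5 & diff>=8
  # the PIC 0.49 / diff 10 marker is in neither set
  expect_false("m2" %in% c(page$pair_id, agarose$pair_id))

  # monotonicity: raising the PIC cutoff never grows the set; the agarose
  # tier is a subset of the page tier
  expect_true(all(select_marker_sets(mk, "page", min_pic = 0.6)$pair_id %in%
                    page$pair_id))
  expect_true(all(agarose$pair_id %in% page$pair_id))
})

test_that("template extraction centers 100 bp on the variable region", {
  set.seed(42)
  g <- random_dna(2000)
  mk <- tibble::tibble(pair_id = "m1", chrom = "x",
                       product_start = 800L, product_end = 860L)
  tpl <- extract_template(mk, c(x = g))
  expect_equal(nchar(tpl$template), 100L)
  # product [800, 860): gap centre 830; window [780, 880)
  expect_equal(c(tpl$t_start, tpl$t_end), c(780L, 880L))
  expect_equal(tpl$template, substr(g, 781, 880))
  expect_equal(c(tpl$var_start, tpl$var_end), c(40L, 60L))

  # agarose flanks give 320 bp
  tpl2 <- extract_template(mk, c(x = g), flank = 150)
  expect_equal(nchar(tpl2$template), 320L)

  # a marker near the chromosome start is truncated with a warning
  mk_edge <- tibble::tibble(pair_id = "m2", chrom = "x",
                            product_start = 10L, product_end = 70L)
  expect_warning(tpl3 <- extract_template(mk_edge, c(x = g)), "truncated")
  expect_lt(nchar(tpl3$template), 100L)
  expect_equal(tpl3$t_start, 0L)
})

test_that("nearest-neighbor Tm matches published-parameter reference values", {
  # reference values computed with an independent implementation of the
  # unified NN parameters (50 mM Na+, 250 nM oligo, CT/4), frozen here
  ref <- c(ACGTACGTACGTACGTACGT = 55.2220,
           GCGCGCGCGCGCGCGCGCGC = 79.2075,
           ATATATATATATATATATAT = 26.3470,
           AGCTTGCATGCAAGTCCGATAGC = 59.9926,
           TTGACCTAGGCATTGACCTAGGCATTGA = 61.2085,
           CCTTGAGGTCAAATGGCAGT = 54.4647)
  expect_equal(melting_temperature(names(ref)), unname(ref),
               tolerance = 1e-4)

  # Tm of a duplex equals Tm of its reverse complement
  set.seed(43)
  for (len in c(20, 23, 28)) {
    s <- random_dna(len)
    expect_equal(melting_temperature(s),
                 melting_temperature(naive_revcomp(s)), tolerance = 1e-10)
  }

  # raising GC at fixed length never lowers Tm (A->G substitutions)
  s <- random_dna(23, gc = 0.3)
  pos_a <- which(strsplit(s, "")[[1]] == "A")
  tm <- melting_temperature(s)
  for (k in pos_a[seq_len(min(5, length(pos_a)))]) {
    s2 <- s
    substr(s2, k, k) <- "G"
    tm2 <- melting_temperature(s2)
    expect_gte(tm2, tm)
    s <- s2
    tm <- tm2
  }

  expect_error(melting_temperature("ACGTNACGTT"), "A/C/G/T")
  expect_error(melting_temperature("ACGT"), "length")
})

test_that("validation primers satisfy constraints or are absent", {
  # a template with no G/C anywhere upstream admits no forward primer
  tpl_at <- paste0(strrep("AT", 20), random_dna(60, gc = 0.5))
  none <- design_validation_primers(tpl_at, mode = "page")
  expect_equal(nrow(none), 0L)

  # search a batch of random templates; any returned pair obeys every
  # constraint
  set.seed(44)
  tpl <- vapply(1:12, function(i) random_dna(100, gc = 0.55), character(1))
  got <- design_validation_primers(tpl, mode = "page")
  if (nrow(got) > 0) {
    expect_true(all(nchar(got$f_seq) >= 20 & nchar(got$f_seq) <= 28))
    expect_true(all(got$f_tm >= 60 & got$f_tm <= 65))
    expect_true(all(got$r_tm >= 60 & got$r_tm <= 65))
    expect_true(all(got$gc_f >= 30 & got$gc_f <= 70))
    expect_true(all(got$product_len >= 60 & got$product_len <= 100))
    expect_true(all(substr(got$f_seq, nchar(got$f_seq),
                           nchar(got$f_seq)) %in% c("G", "C")))
    expect_true(all(substr(got$r_seq, nchar(got$r_seq),
                           nchar(got$r_seq)) %in% c("G", "C")))
  }
})

test_that("panel statistics reproduce success and accuracy percentages", {
  ps <- panel_statistics(100, 93, 89)
  expect_equal(ps$success_pct, 93.00)
  expect_equal(ps$accuracy_pct, 95.70)
  expect_equal(panel_statistics(50, 50, 50)$accuracy_pct, 100.00)
  expect_equal(panel_statistics(10, 10, 0)$accuracy_pct, 0.00)
  expect_true(is.na(panel_statistics(10, 0, 0)$accuracy_pct))
  expect_error(panel_statistics(10, 11, 5))

  # gel patterns feed per-marker PIC and allele numbers
  gels <- tibble::tibble(
    marker_id = rep(c("m1", "m2"), each = 4),
    pattern = c("a", "a", "b", "b", "a", "a", "a", "c"))
  ps2 <- panel_statistics(2, 2, 2, gel_patterns = gels)
  per <- attr(ps2, "per_marker")
  expect_equal(per$pic[per$marker_id == "m1"], 0.5)
  expect_equal(ps2$mean_allele_number, 2.00)
})
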