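test_that("consensus product takes the modal length with pinned tie-breaks", {
  p <- function(lens, seqs = NA_character_) {
    tibble::tibble(product_length = lens,
                   product_seq = rep_len(seqs, length(lens)))
  }
  expect_equal(consensus_product(p(c(60, 60, 60, 55)))$product_length, 60L)
  # tied counts break toward the smaller length
  expect_equal(consensus_product(p(c(60, 60, 55, 55)))$product_length, 55L)
  # empty multiset is a missing genotype
  expect_equal(nrow(consensus_product(p(integer(0)))), 0L)
  # representative sequence: most frequent, then lexicographically smallest
  got <- consensus_product(p(c(60, 60, 60), c("TTT", "AAA", "TTT")))
  expect_equal(got$product_seq, "TTT")
  got2 <- consensus_product(p(c(60, 60), c("TTT", "AAA")))
  expect_equal(got2$product_seq, "AAA")
})

test_that("genotype matrix assembly is order-invariant and validates input", {
  prods <- tibble::tibble(
    pair_id = "L1",
    sample_id = c("a", "a", "b", "c"),
    product_length = c(60L, 60L, 60L, 55L))
  gm <- build_matrix(prods)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(unlist(gm[1, c("a", "b", "c")], use.names = FALSE),
               c(60L, 60L, 55L))

  # sample with no products at a locus -> missing cell
  gm2 <- build_matrix(prods, samples = c("a", "b", "c", "d"))
  expect_true(is.na(gm2$d))

  # permuting input rows changes nothing
  set.seed(30)
  gm3 <- build_matrix(prods[sample(nrow(prods)), ])
  expect_equal(gm3, gm)

  # duplicate per-sample tables are rejected
  expect_error(build_matrix(list(a = prods, a = prods)), "duplicate")
})

test_that("PIC matches the 1 - sum(p^2) definition", {
  expect_equal(compute_pic(c(5, 5)), 0.5)
  expect_equal(compute_pic(rep(1, 20)), 0.95)
  expect_equal(compute_pic(c(7, 2, 1)), 1 - (0.49 + 0.04 + 0.01))
  expect_error(compute_pic(numeric(0)), "observation")
  # invariant under pattern relabeling (counts permuted)
  set.seed(31)
  for (i in 1:20) {
    cnt <- sample(1:50, sample(2:8, 1), replace = TRUE)
    expect_equal(compute_pic(cnt), compute_pic(sample(cnt)))
  }
})

test_that("major allele difference uses count-desc, length-asc ranking", {
  expect_equal(major_allele_difference(c(`60` = 10, `57` = 5, `52` = 3)), 3)
  expect_equal(major_allele_difference(c(`60` = 5, `52` = 5)), 8)
  # tied counts rank by smaller length: top two are 58 and 60
  expect_equal(major_allele_difference(c(`60` = 4, `58` = 4, `50` = 1)), 2)
  expect_error(major_allele_difference(c(`60` = 5)), "two alleles")
})

test_that("marker calling applies the >=20-genomes and polymorphism rules", {
  mat <- function(lens) {
    build_matrix(tibble::tibble(
      pair_id = "L1", sample_id = paste0("s", seq_along(lens)),
      product_length = lens))
  }
  # 19 typed samples, 2 alleles -> under min_samples
  mk <- call_indels(mat(rep(c(60L, 57L), c(10, 9))), min_samples = 20)
  expect_equal(nrow(mk), 0L)
  expect_equal(excluded_loci(mk)$reason, "under_min_samples")

  # 25 typed, monomorphic -> excluded with PIC undefined (no marker)
  mk2 <- call_indels(mat(rep(60L, 25)), min_samples = 20)
  expect_equal(nrow(mk2), 0L)
  expect_equal(excluded_loci(mk2)$reason, "monomorphic")

  # 30 typed, {60:20, 57:10} -> marker with PIC 1-(4/9+1/9), diff 3
  mk3 <- call_indels(mat(rep(c(60L, 57L), c(20, 10))), min_samples = 20)
  expect_equal(nrow(mk3), 1L)
  expect_equal(mk3$n_typed, 30L)
  expect_equal(mk3$pic, 1 - (4 / 9 + 1 / 9))
  expect_equal(mk3$major_allele_diff, 3)
  expect_equal(mk3$size_range, 3L)
  expect_equal(mk3$alleles, "60:20,57:10")
})

test_that("allele counts conserve and PIC is bounded by 1 - 1/n", {
  set.seed(32)
  lens <- sample(c(55L, 58L, 60L, NA), 120, TRUE, prob = c(.3, .2, .4, .1))
  gm <- build_matrix(tibble::tibble(
    pair_id = "L", sample_id = paste0("s", 1:120), product_length = lens))
  mk <- call_indels(gm, min_samples = 20)
  n_typed <- sum(!is.na(lens))
  expect_equal(mk$n_typed, n_typed)
  expect_equal(sum(mk$allele_counts[[1]]), n_typed)
  expect_gte(mk$pic, 0)
  expect_lte(mk$pic, 1 - 1 / n_typed)
})

test_that("group frequencies report the global major allele per group", {
  gm <- build_matrix(tibble::tibble(
    pair_id = "L1",
    sample_id = paste0("s", 1:6),
    product_length = c(60L, 60L, 60L, 57L, 60L, 57L)))
  mk <- call_indels(gm, min_samples = 2)
  groups <- tibble::tibble(sample_id = paste0("s", 1:6),
                           group = c("G", "G", "G", "G", "H", "H"))
  gf <- group_major_allele_freq(gm, mk, groups)
  # group G typed {60,60,60,57}: major allele 60 at 3/4
  expect_equal(gf$major_allele_freq[gf$group == "G"], 0.75)
  expect_equal(gf$major_allele_freq[gf$group == "H"], 0.5)

  # a group with only missing genotypes is absent
  gm2 <- build_matrix(tibble::tibble(
    pair_id = "L1", sample_id = paste0("s", 1:3),
    product_length = c(60L, 60L, 57L)), samples = paste0("s", 1:4))
  gf2 <- group_major_allele_freq(
    gm2, call_indels(gm2, min_samples = 2),
    tibble::tibble(sample_id = paste0("s", 1:4),
                   group = c("G", "G", "G", "empty")))
  expect_false("empty" %in% gf2$group)
  # single group covering all samples reproduces the global frequency
  gf3 <- group_major_allele_freq(
    gm, mk, tibble::tibble(sample_id = paste0("s", 1:6), group = "all"))
  expect_equal(gf3$major_allele_freq, 4 / 6)
})

test_that("estimated PIC converges to 2p(1-p) for planted biallelic loci", {
  # direct population simulation: 200 samples, alt frequency 0.5
  cfg <- sim_config(seed = 33, chrom_len = 8000L, n_loci = 25L,
                    indel_len_range = c(3L, 10L), allele_freq = 0.5,
                    snp_rate = 0, n_samples = 200L)
  refs <- simulate_references(cfg)
  pop <- simulate_population(refs, cfg)
  p_alt <- pop$truth$alt_count / cfg$n_samples
  pic_real <- 1 - (p_alt^2 + (1 - p_alt)^2)  # realized PIC at full typing
  # the plug-in estimator has expectation 2p(1-p)(1 - 1/n); the mean over
  # loci must sit within 3 standard errors of it, and near 2p(1-p) itself
  n <- cfg$n_samples
  expect_lt(abs(mean(pic_real) - 2 * 0.5 * 0.5 * (1 - 1 / n)),
            3 * stats::sd(pic_real) / sqrt(length(pic_real)) + 1e-12)
  expect_lt(abs(mean(pic_real) - 0.5), 0.01)
})
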