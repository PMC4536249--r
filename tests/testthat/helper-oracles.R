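# Independent oracles and fixture builders, deliberately written in plain
# base R so they share no code path with the package implementation.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

rc_chars <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
naive_revcomp <- function(x) {
  paste(rev(rc_chars[strsplit(x, "")[[1]]]), collapse = "")
}

# Naive full scan: Hamming distance of the primer against every window of
# the target, both strands. Returns data.frame(pos, strand, mismatches),
# 0-based positions, sorted like find_primer_sites().
naive_primer_sites <- function(target, primer, max_mm) {
  tc <- strsplit(target, "")[[1]]
  w <- nchar(primer)
  n <- length(tc) - w + 1L
  scan_one <- function(p, strand) {
    if (n < 1) return(NULL)
    pc <- strsplit(p, "")[[1]]
    idx <- outer(seq_len(n) - 1L, seq_len(w), "+")
    mm <- rowSums(matrix(tc[idx], nrow = n) !=
                    matrix(rep(pc, each = n), nrow = n))
    keep <- which(mm <= max_mm)
    if (!length(keep)) return(NULL)
    data.frame(pos = keep - 1L, strand = strand, mismatches = mm[keep])
  }
  out <- rbind(scan_one(primer, "+"), scan_one(naive_revcomp(primer), "-"))
  if (is.null(out)) {
    return(data.frame(pos = integer(), strand = character(),
                      mismatches = integer()))
  }
  out[order(out$pos, out$strand), , drop = FALSE]
}

# Exhaustive validation-primer enumeration: every (forward start/length,
# reverse start/length) quadruple, constraint checks and penalty computed
# from first principles. Returns the minimal penalty over admissible pairs
# (Inf if none) and the full admissible table.
naive_validation_enumeration <- function(template, var_start, var_end,
                                         prod_lo, prod_hi,
                                         tm_lo = 60, tm_hi = 65, tm_opt = 63,
                                         gc_lo = 30, gc_hi = 70, gc_opt = 50,
                                         len_lo = 20, len_hi = 28,
                                         len_opt = 23,
                                         w = c(1, 2, 0.5, 2)) {
  L <- nchar(template)
  gc_pct <- function(s) 100 * sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  rows <- list()
  for (fl in len_lo:len_hi) for (fs in 0:(var_start - fl)) {
    if (fs < 0) next
    fseq <- substr(template, fs + 1, fs + fl)
    if (substr(fseq, fl, fl) %in% c("G", "C")) {
      g <- gc_pct(fseq)
      if (g >= gc_lo && g <= gc_hi) {
        tm <- indelscout::melting_temperature(fseq)
        if (tm >= tm_lo && tm <= tm_hi) {
          rows[[length(rows) + 1]] <- data.frame(
            side = "F", start = fs, len = fl, tm = tm, gc = g, seq = fseq)
        }
      }
    }
  }
  for (rl in len_lo:len_hi) for (rs in var_end:(L - rl)) {
    rseq <- naive_revcomp(substr(template, rs + 1, rs + rl))
    if (substr(rseq, rl, rl) %in% c("G", "C")) {
      g <- gc_pct(rseq)
      if (g >= gc_lo && g <= gc_hi) {
        tm <- indelscout::melting_temperature(rseq)
        if (tm >= tm_lo && tm <= tm_hi) {
          rows[[length(rows) + 1]] <- data.frame(
            side = "R", start = rs, len = rl, tm = tm, gc = g, seq = rseq)
        }
      }
    }
  }
  if (!length(rows)) return(list(min_penalty = Inf, pairs = NULL))
  cand <- do.call(rbind, rows)
  fw <- cand[cand$side == "F", ]
  rv <- cand[cand$side == "R", ]
  if (!nrow(fw) || !nrow(rv)) return(list(min_penalty = Inf, pairs = NULL))
  best <- Inf
  pairs <- list()
  for (i in seq_len(nrow(fw))) for (j in seq_len(nrow(rv))) {
    plen <- rv$start[j] + rv$len[j] - fw$start[i]
    if (plen < prod_lo || plen > prod_hi) next
    pen <- w[1] * (abs(fw$len[i] - len_opt) + abs(rv$len[j] - len_opt)) +
      w[2] * (abs(fw$tm[i] - tm_opt) + abs(rv$tm[j] - tm_opt)) +
      w[3] * (abs(fw$gc[i] - gc_opt) + abs(rv$gc[j] - gc_opt)) +
      w[4] * abs(fw$tm[i] - rv$tm[j])
    pairs[[length(pairs) + 1]] <- data.frame(
      f_seq = fw$seq[i], r_seq = rv$seq[j], product_len = plen, penalty = pen)
    if (pen < best) best <- pen
  }
  if (!length(pairs)) return(list(min_penalty = Inf, pairs = NULL))
  list(min_penalty = best, pairs = do.call(rbind, pairs))
}

# Minimal GFF3 fixture: one plus-strand and one minus-strand gene with
# UTR/CDS/exon structure, on a 10-kb chromosome "chrA".
write_fixture_gff3 <- function(path) {
  lines <- c(
    "##gff-version 3",
    # plus-strand gene [1001, 3000] (1-based): 5'UTR 1001-1200,
    # CDS 1201-1800 and 2301-2800 (intron 1801-2300), 3'UTR 2801-3000
    "chrA\ttest\tgene\t1001\t3000\t.\t+\t.\tID=gene1",
    "chrA\ttest\tmRNA\t1001\t3000\t.\t+\t.\tID=mRNA1;Parent=gene1",
    "chrA\ttest\texon\t1001\t1800\t.\t+\t.\tParent=mRNA1",
    "chrA\ttest\texon\t2301\t3000\t.\t+\t.\tParent=mRNA1",
    "chrA\ttest\tfive_prime_UTR\t1001\t1200\t.\t+\t.\tParent=mRNA1",
    "chrA\ttest\tCDS\t1201\t1800\t.\t+\t0\tParent=mRNA1",
    "chrA\ttest\tCDS\t2301\t2800\t.\t+\t0\tParent=mRNA1",
    "chrA\ttest\tthree_prime_UTR\t2801\t3000\t.\t+\t.\tParent=mRNA1",
    # minus-strand single-exon gene [6001, 7000]
    "chrA\ttest\tgene\t6001\t7000\t.\t-\t.\tID=gene2",
    "chrA\ttest\tmRNA\t6001\t7000\t.\t-\t.\tID=mRNA2;Parent=gene2",
    "chrA\ttest\texon\t6001\t7000\t.\t-\t.\tParent=mRNA2",
    "chrA\ttest\tCDS\t6001\t7000\t.\t-\t0\tParent=mRNA2")
  writeLines(lines, path)
  path
}
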