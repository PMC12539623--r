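# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the package's own code paths.

# two-sided exact binomial p-value (null p = 0.5) by full enumeration:
# sum of all outcome probabilities no larger than the observed one
oracle_binom_p <- function(a1, a2) {
  n <- a1 + a2
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[a1 + 1] * (1 + 1e-12)])
}

oracle_allelic_score <- function(a1, a2) {
  p <- oracle_binom_p(a1, a2)
  s <- if (a1 > a2) 1 else if (a1 < a2) -1 else 0
  s * -log10(p)
}

# direct evaluation of the linkage-score equations
oracle_score_linkage <- function(as1, as2, ar1, ar2) {
  dar <- abs(ar1 - 0.5) - abs(ar2 - 0.5)
  list(delta_ar = dar,
       linkage_score = log10(min(abs(as1), abs(as2)) + 1) * (1 - abs(dar)))
}

# O(n^2) all-pairs window linking: returns sorted "i:j" index pairs
oracle_pair_keys <- function(df, window_bp) {
  n <- nrow(df)
  keys <- character(0)
  if (n < 2) return(keys)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (df$chrom[i] != df$chrom[j]) next
      gap <- max(0, max(df$start[i], df$start[j]) - min(df$end[i], df$end[j]))
      if (gap <= window_bp) keys <- c(keys, paste(i, j, sep = ":"))
    }
  }
  sort(keys)
}

# brute-force ncRNA-centric proximity percentages
oracle_proximity <- function(table, params, window_bp) {
  allelic <- !is.na(table$allelic_ratio) &
    table$total_reads >= params$min_total_reads &
    (table$allelic_ratio >= params$ar_high |
       table$allelic_ratio <= params$ar_low)
  informative <- !is.na(table$allelic_ratio) &
    table$total_reads >= params$min_total_reads
  nc <- which(allelic & table$biotype == "ncRNA")
  pc_a <- which(allelic & table$biotype == "pcGene")
  pc_b <- which(informative & !allelic & table$biotype == "pcGene")
  near <- function(i, js) {
    any(vapply(js, function(j) {
      table$chrom[i] == table$chrom[j] &&
        max(0, max(table$start[i], table$start[j]) -
              min(table$end[i], table$end[j])) <= window_bp
    }, logical(1)))
  }
  if (length(nc) == 0) return(c(NA_real_, NA_real_))
  c(100 * mean(vapply(nc, near, logical(1), js = pc_a)),
    100 * mean(vapply(nc, near, logical(1), js = pc_b)))
}

# random locus table for property tests
random_locus_table <- function(n, seed, n_chrom = 2, span = 2e6) {
  withr::with_seed(seed, {
    chrom <- sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE)
    start <- sample.int(span, n)
    len <- sample(500:20000, n, replace = TRUE)
    total <- sample(0:200, n, replace = TRUE)
    a1 <- rbinom(n, total, runif(n))
    defined <- total > 0
    as_score <- rep(NA_real_, n)
    as_score[defined] <- allelic_score(a1[defined], total[defined] - a1[defined])
    data.frame(
      locus_name = sprintf("L%04d", seq_len(n)), chrom = chrom,
      start = start, end = start + len,
      strand = sample(c("+", "-", "."), n, replace = TRUE),
      biotype = sample(c("ncRNA", "pcGene", "other"), n, replace = TRUE),
      total_reads = total, a1_reads = a1, a2_reads = total - a1,
      n_snps = pmin(total, sample(1:5, n, replace = TRUE)),
      allelic_ratio = ifelse(defined, a1 / total, NA_real_),
      allelic_score = as_score,
      stringsAsFactors = FALSE)
  })
}

# minimal locus-table constructor for hand-built fixtures
locus_row <- function(name, chrom, start, end, biotype, a1, a2,
                      strand = "+") {
  total <- a1 + a2
  data.frame(locus_name = name, chrom = chrom, start = start, end = end,
             strand = strand, biotype = biotype, total_reads = total,
             a1_reads = a1, a2_reads = a2, n_snps = 1L,
             allelic_ratio = if (total > 0) a1 / total else NA_real_,
             allelic_score = if (total > 0) allelic_score(a1, a2) else NA_real_,
             stringsAsFactors = FALSE)
}

# hand-written SAM fixture: reads as a character vector of alignment lines
write_sam <- function(path, lines, chroms = c(chr1 = 100000L)) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  writeLines(c(header, lines), path)
  path
}

sam_line <- function(qname, chrom, pos1, seq, flag = 0L,
                     cigar = paste0(nchar(seq), "M")) {
  paste(qname, flag, chrom, pos1, 60L, cigar, "*", 0L, 0L, seq,
        strrep("I", nchar(seq)), sep = "\t")
}
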