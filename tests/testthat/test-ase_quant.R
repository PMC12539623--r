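test_that("allelic score matches exact enumeration and the sign convention", {
  expect_equal(allelic_score(5, 5), 0)
  expect_equal(allelic_score(10, 0), 2.70927, tolerance = 1e-5)
  expect_equal(allelic_score(0, 20), -5.71957, tolerance = 1e-5)
  # independent checks of the frozen values
  expect_equal(10^(-allelic_score(10, 0)), 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(10^(allelic_score(0, 20)), 2 * 0.5^20, tolerance = 1e-12)
  expect_error(allelic_score(0, 0), "undefined")
})

test_that("allelic score agrees with the enumeration oracle for all n <= 25", {
  for (n in 1:25) {
    for (a1 in 0:n) {
      expect_equal(allelic_score(a1, n - a1), oracle_allelic_score(a1, n - a1),
                   tolerance = 1e-9,
                   info = sprintf("a1=%d a2=%d", a1, n - a1))
    }
  }
})

test_that("allelic score is finite and accurate at very deep coverage", {
  expect_equal(allelic_score(1e6, 0), -(log(2) + 1e6 * log(0.5)) / log(10),
               tolerance = 1e-9)
  expect_true(is.finite(allelic_score(6e5, 4e5)))
})

test_that("allelic ratio is monotone and |AS| grows with depth at fixed AR", {
  withr::with_seed(11, {
    for (k in 1:200) {
      a1 <- sample(0:100, 1); a2 <- sample(0:100, 1)
      if (a1 + a2 == 0) a2 <- 1
      ar0 <- a1 / (a1 + a2)
      ar1 <- (a1 + 1) / (a1 + a2 + 1)
      expect_gte(ar1, ar0)
    }
  })
  for (ar in c(0.7, 0.9, 0.2)) {
    totals <- c(20, 50, 100, 400, 1000)
    as_abs <- abs(allelic_score(round(ar * totals), totals - round(ar * totals)))
    expect_true(all(diff(as_abs) > 0))
  }
})

quant_fixture <- function() {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t2000\tGeneA\t0\t+", bed)
  snps <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1199\t1200\tC/T", "chr1\t1499\t1500\tG/A"), snps)
  list(ann = read_annotation(bed, c(GeneA = "pcGene")),
       snps = read_phased_snps(snps))
}

test_that("reads are assigned by majority vote with tie and third-allele rules", {
  fx <- quant_fixture()
  seq50 <- function(snp_off, base) {
    s <- rep("A", 50); s[snp_off] <- base; paste(s, collapse = "")
  }
  sam <- write_sam(tempfile(fileext = ".sam"), c(
    sam_line("r_a1", "chr1", 1191, seq50(10, "C")),      # SNP1 base C -> allele1
    sam_line("r_a2", "chr1", 1191, seq50(10, "T")),      # SNP1 base T -> allele2
    sam_line("r_un", "chr1", 1191, seq50(10, "G")),      # third allele
    # spans both SNPs: votes allele1 at SNP1 (C), allele2 at SNP2 ('A' of G/A)
    sam_line("r_cf", "chr1", 1195, {
      s <- rep("A", 310); s[6] <- "C"; paste(s, collapse = "")
    }, cigar = "310M"),
    # deletion removes the SNP base: no covered SNP, read ignored
    sam_line("r_del", "chr1", 1197, paste(rep("A", 49), collapse = ""),
             cigar = "3M1D46M")))
  aln <- aselink:::read_alignments(sam)
  calls <- assign_read_alleles(aln, fx$snps)
  calls <- calls[order(calls$read_id), ]
  expect_equal(calls$read_id, c("r_a1", "r_a2", "r_cf", "r_un"))
  expect_equal(calls$call, c("allele1", "allele2", "conflict", "unassigned"))
  expect_equal(calls$n_snps_covered[calls$read_id == "r_cf"], 2L)
})

test_that("a planted SAM fixture recounts to the expected allele totals", {
  # 20 reads: 12 allele1, 6 allele2, 1 conflict, 1 unassigned -> a1=12 a2=6
  fx <- quant_fixture()
  seq50 <- function(base) {
    s <- rep("A", 50); s[10] <- base; paste(s, collapse = "")
  }
  lines <- c(
    vapply(1:12, function(i) sam_line(paste0("a1_", i), "chr1", 1191,
                                      seq50("C")), ""),
    vapply(1:6, function(i) sam_line(paste0("a2_", i), "chr1", 1191,
                                     seq50("T")), ""),
    sam_line("cf", "chr1", 1195, {
      s <- rep("A", 310); s[6] <- "C"; paste(s, collapse = "")
    }, cigar = "310M"),
    sam_line("un", "chr1", 1191, seq50("G")))
  sam <- write_sam(tempfile(fileext = ".sam"), lines)
  tab <- quantify_sample(sam, fx$ann, fx$snps, quant_params())
  expect_equal(tab$a1_reads, 12L)
  expect_equal(tab$a2_reads, 6L)
  expect_equal(tab$total_reads, 18L)
  expect_equal(tab$allelic_ratio, 12 / 18)
  # conservation: assigned + conflict + unassigned = 20 planted reads
  log <- attr(tab, "log")
  expect_true(any(grepl("allele1 12, allele2 6, conflict 1, unassigned 1",
                        log)))
})

test_that("loci with no assigned reads report blank ratio and score", {
  fx <- quant_fixture()
  sam <- write_sam(tempfile(fileext = ".sam"), character(0))
  tab <- quantify_sample(sam, fx$ann, fx$snps, quant_params())
  expect_equal(tab$total_reads, 0L)
  expect_true(is.na(tab$allelic_ratio))
  expect_true(is.na(tab$allelic_score))
  expect_error(quantify_sample(sam, fx$ann[integer(0), ], fx$snps),
               "empty annotation")
})

test_that("per-SNP read minimum excludes weak SNPs and their reads", {
  fx <- quant_fixture()
  seq50 <- function(off, base) {
    s <- rep("A", 50); s[off] <- base; paste(s, collapse = "")
  }
  lines <- c(
    vapply(1:5, function(i) sam_line(paste0("s1_", i), "chr1", 1191,
                                     seq50(10, "C")), ""),
    sam_line("s2_1", "chr1", 1491, seq50(10, "G")))   # lone read at SNP2
  sam <- write_sam(tempfile(fileext = ".sam"), lines)
  tab2 <- quantify_sample(sam, fx$ann, fx$snps,
                          quant_params(min_reads_per_snp = 2L))
  expect_equal(tab2$a1_reads, 5L)     # SNP2's lone read discarded
  expect_equal(tab2$n_snps, 1L)
  tab1 <- quantify_sample(sam, fx$ann, fx$snps, quant_params())
  expect_equal(tab1$a1_reads, 6L)
  expect_equal(tab1$n_snps, 2L)
})

test_that("stranded orientations gate reads by implied transcript strand", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t2000\tFwd\t0\t+",
               "chr1\t1000\t2000\tRev\t0\t-"), bed)
  # same interval on both strands is legitimate for strand-split annotation
  ann <- suppressWarnings(read_annotation(bed))
  snpf <- tempfile(fileext = ".bed")
  writeLines("chr1\t1199\t1200\tC/T", snpf)
  snps <- read_phased_snps(snpf)
  mkseq <- function(base) {
    s <- rep("A", 50); s[10] <- base; paste(s, collapse = "")
  }
  sam <- write_sam(tempfile(fileext = ".sam"), c(
    sam_line("plus", "chr1", 1191, mkseq("C"), flag = 0L),    # allele1
    sam_line("minus", "chr1", 1191, mkseq("T"), flag = 16L))) # allele2
  fwd <- quantify_sample(sam, ann, snps,
                         quant_params(library_orientation = "forward"))
  expect_equal(fwd$a1_reads[fwd$locus_name == "Fwd"], 1L)  # plus read only
  expect_equal(fwd$a2_reads[fwd$locus_name == "Fwd"], 0L)
  expect_equal(fwd$a2_reads[fwd$locus_name == "Rev"], 1L)  # minus read only
  rev <- quantify_sample(sam, ann, snps,
                         quant_params(library_orientation = "reverse"))
  expect_equal(rev$a2_reads[rev$locus_name == "Fwd"], 1L)  # minus read
  expect_equal(rev$a1_reads[rev$locus_name == "Rev"], 1L)  # plus read
  expect_equal(rev$a1_reads[rev$locus_name == "Fwd"], 0L)
  un <- quantify_sample(sam, ann, snps, quant_params())
  expect_equal(un$total_reads, c(2L, 2L))
})

test_that("excluded chromosomes are dropped from the locus table", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tA\t0\t+", "chrX\t0\t100\tX\t0\t+"), bed)
  ann <- read_annotation(bed)
  sam <- write_sam(tempfile(fileext = ".sam"), character(0),
                   chroms = c(chr1 = 1000L, chrX = 1000L))
  snpf <- tempfile(fileext = ".bed"); writeLines("chr1\t10\t11\tA/C", snpf)
  tab <- quantify_sample(sam, ann, read_phased_snps(snpf),
                         quant_params(excluded_chroms = "chrX"))
  expect_equal(tab$locus_name, "A")
})

test_that("strand merge concatenates disjoint tables and rejects overlap", {
  t1 <- do.call(rbind, lapply(1:10, function(i)
    locus_row(paste0("F", i), "chr1", i * 1000, i * 1000 + 500, "pcGene", 10, 5)))
  t2 <- do.call(rbind, lapply(1:12, function(i)
    locus_row(paste0("R", i), "chr1", i * 1000, i * 1000 + 500, "pcGene", 3, 8,
              strand = "-")))
  expect_equal(nrow(merge_strands(t1, t2)), 22L)
  expect_equal(merge_strands(t1, t2[integer(0), ]), t1)
  expect_error(merge_strands(t1, t1[1, ]), "both strand tables")
})

test_that("replicate merging uses median ratio, minimum score, and the all-replicates rule", {
  mk <- function(a1, a2) locus_row("G", "chr1", 0, 1000, "pcGene", a1, a2)
  reps <- list(mk(16, 4), mk(27, 3), mk(40, 0))     # ARs 0.8, 0.9, 1.0
  m <- merge_replicates(reps, "all_samples", min_total_reads = 20L)
  expect_equal(m$allelic_ratio, 0.9)
  expect_equal(m$total_reads, 30)
  expect_equal(m$allelic_score, min(abs(sapply(reps, `[[`, "allelic_score"))))
  expect_gt(m$allelic_score, 0)                      # sign from median AR

  # totals {19, 25, 30}: fails the >=20-in-all-replicates rule
  reps2 <- list(locus_row("G", "chr1", 0, 1000, "pcGene", 15, 4),
                locus_row("G", "chr1", 0, 1000, "pcGene", 20, 5),
                locus_row("G", "chr1", 0, 1000, "pcGene", 25, 5))
  expect_equal(nrow(merge_replicates(reps2, "all_samples", 20L)), 0L)
  expect_equal(nrow(merge_replicates(reps2, "any_sample", 20L)), 1L)
  expect_error(merge_replicates(list()), "no locus tables")
})

test_that("raising the read cut-off never increases informative loci", {
  tabs <- lapply(1:3, function(i) random_locus_table(80, seed = 100 + i))
  n_prev <- Inf
  for (cut in c(5L, 20L, 50L, 100L)) {
    n <- nrow(merge_replicates(tabs, "all_samples", min_total_reads = cut))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})
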