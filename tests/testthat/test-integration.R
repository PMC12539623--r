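mk_linkage <- function(src = "ncA", tgt = "GENE1", chrom = "chr1",
                       s_start = 4000, s_end = 6000,
                       t_start = 20000, t_end = 30000,
                       mechanism = "enhancing") {
  data.frame(source_name = src, target_name = tgt, chrom = chrom,
             source_start = s_start, source_end = s_end,
             source_strand = "+", source_biotype = "ncRNA",
             target_start = t_start, target_end = t_end,
             target_strand = "+", target_biotype = "pcGene",
             mechanism = mechanism, linkage_score = 1,
             stringsAsFactors = FALSE)
}

test_that("eQTL confirmation requires ncRNA overlap, target match, tissue split", {
  lk <- mk_linkage()
  eq <- function(pos, gene, tissue) {
    data.frame(chrom = "chr1", pos = pos, target_gene = gene,
               tissue = tissue, stringsAsFactors = FALSE)
  }
  expect_equal(confirm_with_eqtl(lk, eq(5000, "GENE1", "liver"), "liver"),
               "confirmed_same_tissue")
  expect_equal(confirm_with_eqtl(lk, eq(5000, "GENE1", "brain"), "liver"),
               "confirmed_other_tissue")
  expect_equal(confirm_with_eqtl(lk, eq(5000, "GENE2", "liver"), "liver"),
               "unconfirmed")
  # eQTL inside the target body but not the ncRNA does not confirm
  expect_equal(confirm_with_eqtl(lk, eq(25000, "GENE1", "liver"), "liver"),
               "unconfirmed")
  # same tissue takes precedence when both kinds overlap
  both <- rbind(eq(5000, "GENE1", "brain"), eq(5100, "GENE1", "liver"))
  expect_equal(confirm_with_eqtl(lk, both, "liver"), "confirmed_same_tissue")
  # adding eQTLs never un-confirms (monotonicity)
  more <- rbind(eq(5000, "GENE1", "liver"), eq(5500, "GENE9", "lung"))
  expect_equal(confirm_with_eqtl(lk, more, "liver"), "confirmed_same_tissue")
})

test_that("GWAS intersection is strict at the threshold and partitions linkages", {
  lk <- mk_linkage()
  gv <- function(pos, p) {
    data.frame(rsid = paste0("rs", pos), chrom = "chr1", pos = pos,
               pvalue = p, trait = "t", stringsAsFactors = FALSE)
  }
  expect_equal(intersect_gwas(lk, gv(5000, 5e-8))$category, "none")  # strict <
  expect_equal(intersect_gwas(lk, gv(5000, 4.9e-8))$category, "ncRNA_only")
  expect_equal(intersect_gwas(lk, gv(25000, 1e-9))$category, "pcGene_only")
  expect_equal(intersect_gwas(lk, rbind(gv(5000, 1e-9), gv(25000, 1e-9)))$category,
               "both")
  lks <- rbind(mk_linkage(), mk_linkage(src = "ncB", chrom = "chr2"))
  res <- intersect_gwas(lks, gv(5000, 1e-9))
  expect_equal(length(res$category), 2L)
  expect_equal(sum(table(factor(res$category,
                                c("ncRNA_only", "pcGene_only", "both", "none")))),
               2L)
})

test_that("TAD co-localization requires full containment in one TAD", {
  tads <- data.frame(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6))
  inside <- mk_linkage()
  expect_true(tad_colocalization(inside, tads)$same_tad)
  adjacent <- mk_linkage(t_start = 1.2e6, t_end = 1.3e6)
  expect_false(tad_colocalization(adjacent, tads)$same_tad)
  straddle <- mk_linkage(t_start = 0.9e6, t_end = 1.1e6)
  expect_false(tad_colocalization(straddle, tads)$same_tad)
  res <- tad_colocalization(rbind(inside, adjacent), tads)
  expect_equal(res$fraction, 0.5)
  bad <- data.frame(chrom = "chr1", start = c(0, 5e5), end = c(1e6, 2e6))
  expect_error(tad_colocalization(inside, bad), "overlapping TADs")
})

test_that("enhancer co-occurrence marks pairs near enhancing peak links only", {
  pair <- mk_linkage(src = "ncA", tgt = "pc1")
  peak_enh <- mk_linkage(src = "peak1", tgt = "pc1", mechanism = "enhancing")
  peak_rep <- mk_linkage(src = "peak2", tgt = "pc1", mechanism = "repressive")
  none <- mk_linkage(src = "peak3", tgt = "pc9", mechanism = "enhancing")
  expect_equal(enhancer_cooccurrence(pair, peak_enh), "enhancer_cooccurring")
  expect_equal(enhancer_cooccurrence(pair, none), "ncRNA_candidate")
  expect_equal(enhancer_cooccurrence(pair, peak_rep), "ncRNA_candidate")
  # a peak targeting the ncRNA member also counts
  peak_nc <- mk_linkage(src = "peak4", tgt = "ncA", mechanism = "enhancing")
  expect_equal(enhancer_cooccurrence(pair, peak_nc), "enhancer_cooccurring")
})

test_that("mechanism consistency classifies at the 75% cut-off", {
  calls <- function(ne, nr) {
    data.frame(source_name = "a", target_name = "b",
               mechanism = c(rep("enhancing", ne), rep("repressive", nr)),
               stringsAsFactors = FALSE)
  }
  expect_equal(mechanism_consistency(calls(3, 1))$call, "enhancing")
  expect_equal(mechanism_consistency(calls(3, 1))$fraction_enhancing, 0.75)
  expect_equal(mechanism_consistency(calls(2, 2))$call, "unclassified")
  expect_equal(mechanism_consistency(calls(0, 5))$call, "repressive")
  # relabelling enhancing <-> repressive mirrors fractions and calls
  withr::with_seed(41, {
    big <- data.frame(
      source_name = sample(letters[1:5], 60, TRUE),
      target_name = sample(LETTERS[1:3], 60, TRUE),
      mechanism = sample(c("enhancing", "repressive"), 60, TRUE),
      stringsAsFactors = FALSE)
  })
  a <- mechanism_consistency(big)
  flipped <- big
  flipped$mechanism <- ifelse(big$mechanism == "enhancing",
                              "repressive", "enhancing")
  b <- mechanism_consistency(flipped)
  expect_equal(a$fraction_enhancing, 1 - b$fraction_enhancing)
  swap <- c(enhancing = "repressive", repressive = "enhancing",
            unclassified = "unclassified")
  expect_equal(unname(swap[a$call]), b$call)
})

test_that("saturation curves are exact on degenerate cohorts", {
  same <- replicate(3, paste0("k", 1:5), simplify = FALSE)
  sc <- saturation_curve(same, iterations = 50, seed = 1)
  expect_equal(sc$mean_unique, rep(5, 3))
  expect_equal(sc$sd_unique, rep(0, 3))
  disjoint <- list(paste0("a", 1:2), paste0("b", 1:3), paste0("c", 1:4))
  sc2 <- saturation_curve(disjoint, iterations = 50, seed = 1)
  expect_equal(sc2$mean_unique[3], 9)
  expect_equal(sc2$sd_unique[3], 0)
  expect_error(saturation_curve(same, iterations = 0, seed = 1), "iterations")
  expect_error(saturation_curve(list(), seed = 1), "at least one")
  # reproducibility under a fixed seed
  r1 <- saturation_curve(disjoint, iterations = 20, seed = 7)
  r2 <- saturation_curve(disjoint, iterations = 20, seed = 7)
  expect_identical(r1, r2)
})

test_that("saturation means are non-decreasing on random cohorts", {
  withr::with_seed(51, {
    for (rep in 1:20) {
      sets <- lapply(1:5, function(i)
        sample(paste0("k", 1:30), sample(3:15, 1)))
      sc <- saturation_curve(sets, iterations = 40, seed = rep)
      expect_true(all(diff(sc$mean_unique) >= -1e-9))
      expect_equal(sc$mean_unique[5],
                   length(unique(unlist(sets))))
      expect_equal(sc$sd_unique[5], 0)
    }
  })
})

test_that("sharing across groups counts keys once per group", {
  df <- data.frame(
    source_name = c("a", "a", "a", "b", "b", "c"),
    target_name = c("x", "x", "x", "y", "y", "z"),
    group = c("t1", "t2", "t2", "t1", "t2", "t3"),
    stringsAsFactors = FALSE)
  res <- sharing_across_groups(df)
  counts <- setNames(res$per_key$n_groups,
                     paste(res$per_key$source_name, res$per_key$target_name))
  expect_equal(counts[["a x"]], 2L)   # duplicate within t2 counted once
  expect_equal(counts[["b y"]], 2L)
  expect_equal(counts[["c z"]], 1L)
  expect_equal(res$specific_fraction, 1 / 3)
  all_shared <- data.frame(source_name = "a", target_name = "x",
                           group = c("t1", "t2"))
  expect_equal(sharing_across_groups(all_shared)$specific_fraction, 0)
})

test_that("precision and recall follow the stated conventions", {
  pred <- data.frame(source_name = c("A", "A"), target_name = c("B", "C"))
  truth <- data.frame(source_name = "A", target_name = "B")
  ev <- evaluate_against_truth(pred, truth)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 1)
  ev2 <- evaluate_against_truth(truth, truth)
  expect_equal(c(ev2$precision, ev2$recall), c(1, 1))
  ev3 <- evaluate_against_truth(pred[integer(0), ], truth)
  expect_equal(c(ev3$precision, ev3$recall), c(1, 0))
  expect_error(evaluate_against_truth(pred, truth[integer(0), ]), "non-empty")
})
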