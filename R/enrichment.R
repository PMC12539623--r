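#' Proximity enrichment of allele-specific ncRNAs around pcGenes
#'
#' Computes the percentage of allele-specific ncRNAs that have at least
#' one allele-specific pcGene within the window (interval gap, inclusive,
#' overlap counts as gap 0), and the analogous percentage for biallelic
#' pcGenes as the control. "Biallelic" means informative (total reads at
#' or above the read cut-off) but not allele-specific. With
#' `denominator = "pcGene"` the roles are swapped: percentages of
#' allelic/biallelic pcGenes near an allele-specific ncRNA.
#'
#' @param table Locus table with biotypes.
#' @param params [link_params()] supplying the allele-specific cut-offs.
#' @param window_bp Window size in bp (default from `params`).
#' @param denominator `"ncRNA"` (default, ncRNA-centric) or `"pcGene"`.
#' @return A one-row data.frame: `window_bp`, `pct_near_allelic`,
#'   `pct_near_biallelic`, `n_allelic_ncRNA`, `n_allelic_pcGene`,
#'   `n_biallelic_pcGene`, `defined` (FALSE when the denominator set is
#'   empty, in which case the percentages are `NA`).
#' @export
proximity_enrichment <- function(table, params = link_params(),
                                 window_bp = params$window_bp,
                                 denominator = c("ncRNA", "pcGene")) {
  denominator <- match.arg(denominator)
  allelic <- filter_allele_specific(table, params)
  informative <- !is.na(table$allelic_ratio) &
    table$total_reads >= params$min_total_reads
  biallelic <- table[informative &
                       !table$locus_name %in% allelic$locus_name, , drop = FALSE]

  nc_allelic <- allelic[allelic$biotype == "ncRNA", , drop = FALSE]
  pc_allelic <- allelic[allelic$biotype == "pcGene", , drop = FALSE]
  pc_biallelic <- biallelic[biallelic$biotype == "pcGene", , drop = FALSE]

  if (denominator == "ncRNA") {
    denom <- nc_allelic
    near_a <- pc_allelic
    near_b <- pc_biallelic
    pct <- function(set, near) {
      if (nrow(set) == 0L) return(NA_real_)
      100 * sum(has_neighbor(set, near, window_bp)) / nrow(set)
    }
    pa <- pct(denom, near_a)
    pb <- pct(denom, near_b)
  } else {
    pa <- if (nrow(pc_allelic)) {
      100 * sum(has_neighbor(pc_allelic, nc_allelic, window_bp)) / nrow(pc_allelic)
    } else NA_real_
    pb <- if (nrow(pc_biallelic)) {
      100 * sum(has_neighbor(pc_biallelic, nc_allelic, window_bp)) / nrow(pc_biallelic)
    } else NA_real_
  }
  data.frame(window_bp = window_bp, pct_near_allelic = pa,
             pct_near_biallelic = pb,
             n_allelic_ncRNA = nrow(nc_allelic),
             n_allelic_pcGene = nrow(pc_allelic),
             n_biallelic_pcGene = nrow(pc_biallelic),
             defined = !is.na(pa) || !is.na(pb))
}

# for each row of `set`, TRUE when >=1 row of `near` lies within the gap
has_neighbor <- function(set, near, window_bp) {
  if (nrow(set) == 0L) return(logical(0))
  if (nrow(near) == 0L) return(rep(FALSE, nrow(set)))
  if (is.infinite(window_bp)) {
    return(set$chrom %in% unique(near$chrom))
  }
  gr1 <- as_granges(set[, c("chrom", "start", "end")])
  gr2 <- as_granges(near[, c("chrom", "start", "end")])
  levels <- union(GenomeInfoDb::seqlevels(gr1), GenomeInfoDb::seqlevels(gr2))
  GenomeInfoDb::seqlevels(gr1) <- levels
  GenomeInfoDb::seqlevels(gr2) <- levels
  IRanges::overlapsAny(gr1, gr2, maxgap = window_bp,
                       ignore.strand = TRUE)
}

#' Compare allelic vs biallelic proximity percentages
#'
#' Wilcoxon test on per-group (tissue or sample) enrichment percentages.
#' Paired by default: each group contributes one allelic and one
#' biallelic percentage, tested with the signed-rank test; `paired =
#' FALSE` uses the rank-sum test. When every paired difference is zero
#' the test is degenerate and p = 1 is returned with a flag.
#'
#' @param pct_allelic,pct_biallelic Numeric vectors of percentages.
#' @param paired Logical, default `TRUE`.
#' @return list with `p_value`, `degenerate`, and the underlying `htest`
#'   (NULL when degenerate).
#' @export
compare_enrichment <- function(pct_allelic, pct_biallelic, paired = TRUE) {
  if (paired) {
    stopifnot(length(pct_allelic) == length(pct_biallelic))
    if (length(pct_allelic) < 3L) {
      stop("paired comparison needs at least 3 observation pairs")
    }
    if (all(pct_allelic == pct_biallelic)) {
      return(list(p_value = 1, degenerate = TRUE, htest = NULL))
    }
  }
  ht <- suppressWarnings(
    stats::wilcox.test(pct_allelic, pct_biallelic, paired = paired,
                       exact = FALSE))
  list(p_value = ht$p.value, degenerate = FALSE, htest = ht)
}

#' Classify linkages by TSS distance and gene-body overlap
#'
#' Mutually exclusive categories assigned in priority order:
#' `shared_promoter` when the two TSSs are within 2 kb (a shared
#' promoter region), else `overlapping` when the gene bodies intersect,
#' else `distant`.
#'
#' @param linkages Linkage data.frame from [link_loci()].
#' @param promoter_bp TSS-distance cut-off for the shared-promoter call
#'   (default 2000).
#' @return `linkages` with an added `distance_category` column.
#' @export
distance_profile <- function(linkages, promoter_bp = 2000L) {
  if (nrow(linkages) == 0L) {
    linkages$distance_category <- character(0)
    return(linkages)
  }
  overlapping <- linkages$source_start < linkages$target_end &
    linkages$target_start < linkages$source_end
  cat <- ifelse(linkages$tss_distance_bp <= promoter_bp, "shared_promoter",
                ifelse(overlapping, "overlapping", "distant"))
  linkages$distance_category <- cat
  linkages
}
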