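#' Linkage parameters
#'
#' @param ar_high,ar_low Inclusive allelic-ratio cut-offs for calling a
#'   locus allele-specific (AR >= `ar_high` or AR <= `ar_low`).
#'   Defaults 0.7 / 0.3.
#' @param min_total_reads Minimum total SNP-overlapping reads. Default 20.
#' @param window_bp Maximum gap (bp) between two locus intervals for
#'   linking; overlapping loci have gap 0 and the boundary is inclusive.
#'   `Inf` gives a chromosome-wide window (X-inactivation style runs);
#'   4e6 suits multi-megabase imprinted clusters. Default 1e5.
#' @param biotype_filter `"none"` (link all biotypes),
#'   `"ncRNA_to_pcGene"` (keep ncRNA-pcGene pairs, ncRNA as source) or
#'   `"enhancing_peak_to_gene"` (keep enhancing peak-gene pairs, peak as
#'   source).
#' @return A list of class `link_params`.
#' @export
link_params <- function(ar_high = 0.7, ar_low = 0.3, min_total_reads = 20L,
                        window_bp = 1e5,
                        biotype_filter = c("none", "ncRNA_to_pcGene",
                                           "enhancing_peak_to_gene")) {
  biotype_filter <- match.arg(biotype_filter)
  stopifnot(ar_high > 0.5, ar_high <= 1, ar_low >= 0, ar_low < 0.5,
            window_bp > 0)
  structure(list(ar_high = ar_high, ar_low = ar_low,
                 min_total_reads = as.integer(min_total_reads),
                 window_bp = window_bp, biotype_filter = biotype_filter),
            class = "link_params")
}

#' Filter a locus table to allele-specific loci
#'
#' A locus is allele-specific when its total SNP-overlapping reads meet
#' the read cut-off and its allelic ratio is at or beyond either
#' cut-off (AR >= `ar_high` or AR <= `ar_low`, boundaries inclusive).
#' Loci with undefined allelic ratio are dropped.
#'
#' @param table Locus table.
#' @param params A [link_params()] object.
#' @return The allele-specific subset of `table`.
#' @export
filter_allele_specific <- function(table, params = link_params()) {
  keep <- !is.na(table$allelic_ratio) &
    table$total_reads >= params$min_total_reads &
    (table$allelic_ratio >= params$ar_high |
       table$allelic_ratio <= params$ar_low)
  table[keep, , drop = FALSE]
}

#' Classify a candidate pair as enhancing or repressive
#'
#' Enhancing when both loci are biased toward the same allele (allelic
#' correlation), repressive when toward opposite alleles
#' (anti-correlation).
#'
#' @param ar1,ar2 Allelic ratios of the two loci (vectorized); neither
#'   may equal 0.5.
#' @return Character vector, `"enhancing"` or `"repressive"`.
#' @export
classify_mechanism <- function(ar1, ar2) {
  if (any(ar1 == 0.5) || any(ar2 == 0.5)) {
    stop("mechanism undefined for a balanced locus (AR = 0.5)")
  }
  ifelse((ar1 - 0.5) * (ar2 - 0.5) > 0, "enhancing", "repressive")
}

#' Linkage score and allelic-ratio difference
#'
#' The centered allelic-ratio difference is
#' `dAR = |AR1 - 0.5| - |AR2 - 0.5|`: small |dAR| means the two loci
#' carry closely matched imbalance strengths regardless of direction.
#' The linkage score is `LS = log10(min(|AS1|, |AS2|) + 1) * (1 - |dAR|)`,
#' so a pair is ranked by its weaker allelic score, damped when the
#' imbalance strengths are mismatched. LS is symmetric under swapping
#' the two loci and non-negative.
#'
#' @param as1,as2 Signed allelic scores (vectorized).
#' @param ar1,ar2 Allelic ratios in `[0, 1]`.
#' @return data.frame with columns `delta_ar` (signed, locus-1 minus
#'   locus-2 magnitude) and `linkage_score`.
#' @export
score_linkage <- function(as1, as2, ar1, ar2) {
  stopifnot(all(is.finite(as1)), all(is.finite(as2)),
            all(ar1 >= 0 & ar1 <= 1), all(ar2 >= 0 & ar2 <= 1))
  delta_ar <- abs(ar1 - 0.5) - abs(ar2 - 0.5)
  ls <- log10(pmin(abs(as1), abs(as2)) + 1) * (1 - abs(delta_ar))
  data.frame(delta_ar = delta_ar, linkage_score = ls)
}

# all same-chromosome pairs with interval gap <= window (indices into df)
candidate_pairs <- function(df, window_bp) {
  if (nrow(df) < 2L) return(data.frame(i = integer(), j = integer()))
  if (is.infinite(window_bp)) {
    by_chr <- split(seq_len(nrow(df)), df$chrom)
    pairs <- lapply(by_chr, function(idx) {
      if (length(idx) < 2L) return(NULL)
      cmb <- utils::combn(idx, 2L)
      data.frame(i = cmb[1L, ], j = cmb[2L, ])
    })
    return(do.call(rbind, c(pairs, list(data.frame(i = integer(), j = integer())))))
  }
  gr <- as_granges(df[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(gr, maxgap = window_bp,
                                      drop.self = TRUE, drop.redundant = TRUE,
                                      ignore.strand = TRUE)
  data.frame(i = S4Vectors::queryHits(hits), j = S4Vectors::subjectHits(hits))
}

interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

#' Link allele-specific loci within a genomic window
#'
#' Every unordered pair of allele-specific loci on the same chromosome
#' whose interval gap is at most `window_bp` becomes one candidate
#' linkage with a mechanism call ([classify_mechanism()]), score
#' ([score_linkage()]), interval gap and TSS distance. Under
#' `biotype_filter = "ncRNA_to_pcGene"` only ncRNA-pcGene pairs are kept
#' with the ncRNA as source; under `"enhancing_peak_to_gene"` only
#' enhancing peak-gene pairs with the peak as source; otherwise the
#' lexicographically smaller locus name is the source (the score and
#' mechanism are symmetric, so orientation is presentational).
#'
#' @param allelic Filtered locus table from [filter_allele_specific()];
#'   must carry a `tss` column or derivable strand information.
#' @param params A [link_params()] object.
#' @return Linkage data.frame, one row per retained pair.
#' @export
link_loci <- function(allelic, params = link_params()) {
  df <- allelic
  if (!"tss" %in% names(df)) {
    df$tss <- ifelse(df$strand == "-", df$end - 1L, df$start)
  }
  pairs <- candidate_pairs(df, params$window_bp)
  empty <- data.frame(source_name = character(), target_name = character(),
                      chrom = character(),
                      source_start = integer(), source_end = integer(),
                      source_strand = character(), source_biotype = character(),
                      target_start = integer(), target_end = integer(),
                      target_strand = character(), target_biotype = character(),
                      source_ar = numeric(), target_ar = numeric(),
                      source_as = numeric(), target_as = numeric(),
                      mechanism = character(), delta_ar = numeric(),
                      linkage_score = numeric(), distance_bp = integer(),
                      tss_distance_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)

  i <- pairs$i; j <- pairs$j
  # orient source/target
  swap <- switch(params$biotype_filter,
    none = df$locus_name[j] < df$locus_name[i],
    ncRNA_to_pcGene = df$biotype[j] == "ncRNA",
    enhancing_peak_to_gene = df$biotype[j] == "peak")
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp

  keep <- switch(params$biotype_filter,
    none = rep(TRUE, length(i)),
    ncRNA_to_pcGene = df$biotype[i] == "ncRNA" & df$biotype[j] == "pcGene",
    enhancing_peak_to_gene = df$biotype[i] == "peak" &
      df$biotype[j] %in% c("ncRNA", "pcGene", "other"))
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) return(empty)

  sc <- score_linkage(df$allelic_score[i], df$allelic_score[j],
                      df$allelic_ratio[i], df$allelic_ratio[j])
  out <- data.frame(
    source_name = df$locus_name[i], target_name = df$locus_name[j],
    chrom = df$chrom[i],
    source_start = df$start[i], source_end = df$end[i],
    source_strand = df$strand[i], source_biotype = df$biotype[i],
    target_start = df$start[j], target_end = df$end[j],
    target_strand = df$strand[j], target_biotype = df$biotype[j],
    source_ar = df$allelic_ratio[i], target_ar = df$allelic_ratio[j],
    source_as = df$allelic_score[i], target_as = df$allelic_score[j],
    mechanism = classify_mechanism(df$allelic_ratio[i], df$allelic_ratio[j]),
    delta_ar = sc$delta_ar, linkage_score = sc$linkage_score,
    distance_bp = interval_gap(df$start[i], df$end[i], df$start[j], df$end[j]),
    tss_distance_bp = abs(df$tss[i] - df$tss[j]),
    stringsAsFactors = FALSE)
  if (params$biotype_filter == "enhancing_peak_to_gene") {
    out <- out[out$mechanism == "enhancing", , drop = FALSE]
  }
  rank_linkages(out)
}

#' Run the full linkage pipeline on a locus table
#'
#' Filter to allele-specific loci, link within the window, classify and
#' score, rank by linkage score, and optionally write the ranked table,
#' BEDPE/BED tracks and run log.
#'
#' @param table Locus table (typically replicate-merged).
#' @param params A [link_params()] object.
#' @param out_prefix Optional output prefix passed to
#'   [write_linkage_outputs()].
#' @return Ranked linkage data.frame with a `log` attribute recording
#'   parameters and per-stage counts.
#' @export
run_link <- function(table, params = link_params(), out_prefix = NULL) {
  allelic <- filter_allele_specific(table, params)
  linkages <- link_loci(allelic, params)
  log <- c(sprintf("parameters: ar_high=%g ar_low=%g min_total_reads=%d window_bp=%s biotype_filter=%s",
                   params$ar_high, params$ar_low, params$min_total_reads,
                   format(params$window_bp), params$biotype_filter),
           sprintf("input loci: %d", nrow(table)),
           sprintf("allele-specific loci: %d", nrow(allelic)),
           sprintf("linkages: %d (enhancing %d, repressive %d)",
                   nrow(linkages), sum(linkages$mechanism == "enhancing"),
                   sum(linkages$mechanism == "repressive")))
  if (!is.null(out_prefix)) {
    write_linkage_outputs(linkages, out_prefix, log_lines = log)
  }
  attr(linkages, "log") <- log
  linkages
}
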