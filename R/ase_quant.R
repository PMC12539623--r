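#' Quantification parameters
#'
#' @param min_reads_per_snp Minimum number of allele-assigned reads a SNP
#'   must collect at a locus to contribute; SNPs below the cut-off are
#'   excluded and their reads discarded from that locus. Default 1.
#' @param min_total_reads Informativeness cut-off on total SNP-overlapping
#'   reads, applied at replicate merging. Default 20.
#' @param library_orientation `"unstranded"`, `"forward"` (read strand
#'   equals transcript strand) or `"reverse"` (dUTP-style, read strand
#'   opposite the transcript).
#' @param excluded_chroms Chromosomes dropped from the output (e.g.
#'   `"chrX"` for mouse runs, where skewed X-inactivation confounds ASE).
#' @return A list of class `quant_params`.
#' @export
quant_params <- function(min_reads_per_snp = 1L, min_total_reads = 20L,
                         library_orientation = c("unstranded", "forward", "reverse"),
                         excluded_chroms = character()) {
  library_orientation <- match.arg(library_orientation)
  stopifnot(min_reads_per_snp >= 1L, min_total_reads >= 1L)
  structure(list(min_reads_per_snp = as.integer(min_reads_per_snp),
                 min_total_reads = as.integer(min_total_reads),
                 library_orientation = library_orientation,
                 excluded_chroms = excluded_chroms),
            class = "quant_params")
}

#' Signed binomial allelic score
#'
#' The allelic score is the signed negative log10 of the two-sided exact
#' binomial p-value of the allele-1 count against a balanced null
#' (p = 0.5), using the minimum-likelihood tail definition: the p-value
#' sums all outcomes no more probable than the observed one. Under the
#' symmetric null this equals twice the smaller tail, so it is computed
#' via `pbinom(..., log.p = TRUE)` and stays finite and accurate for
#' totals up to millions of reads. The sign follows the allelic ratio:
#' positive when allele 1 dominates (AR > 0.5), negative when allele 2
#' does, zero at exact balance.
#'
#' @param a1,a2 Non-negative integer read counts for alleles 1 and 2
#'   (vectorized; `a1 + a2` must be >= 1).
#' @return Numeric vector of signed allelic scores.
#' @examples
#' allelic_score(5, 5)   # 0
#' allelic_score(10, 0)  # +2.709
#' @export
allelic_score <- function(a1, a2) {
  stopifnot(length(a1) == length(a2), all(a1 >= 0), all(a2 >= 0))
  n <- a1 + a2
  if (any(n < 1)) stop("allelic_score undefined for a1 + a2 = 0")
  m <- pmin(a1, a2)
  # minlike two-sided p under p0 = 0.5: all k with P(k) <= P(observed),
  # i.e. k <= min or k >= n - min; ties are symmetric so p = 2 * lower tail
  log10_p <- (log(2) + stats::pbinom(m, n, 0.5, log.p = TRUE)) / log(10)
  log10_p <- pmin(log10_p, 0)          # a1 == a2 (mode observed) => p = 1
  as <- -log10_p * sign(a1 - a2)
  as[a1 == a2] <- 0
  as
}

#' Two-sided exact binomial p-value against a balanced null
#'
#' Convenience companion of [allelic_score()] returning the p-value
#' itself (underflows to 0 below ~1e-308; use the score for ranking).
#'
#' @inheritParams allelic_score
#' @return Numeric vector of p-values.
#' @export
binomial_ase_pvalue <- function(a1, a2) {
  10^(-abs(allelic_score(a1, a2)))
}

#' Assign reads to phased alleles by majority vote over covered SNPs
#'
#' For every SNP position covered by an aligned (match/mismatch) base of
#' a read, the read base is compared with the two phased alleles.
#' Deleted or intron-skipped positions do not cover a SNP; soft-clipped
#' and inserted bases never map to reference positions. A read's call is
#' the majority vote across its covered SNPs: a tie is a `conflict`, a
#' read whose bases match neither allele at every covered SNP is
#' `unassigned`, and reads covering no SNP are not reported.
#'
#' @param alignments A [GenomicAlignments::GAlignments] object carrying
#'   `qname` and `seq` metadata columns.
#' @param snps Phased-SNP data.frame from [read_phased_snps()].
#' @return data.frame with one row per (read, covered SNP count):
#'   `read_id`, `call` (`allele1`/`allele2`/`conflict`/`unassigned`),
#'   `n_snps_covered`, plus the alignment index `aln_idx`.
#' @export
assign_read_alleles <- function(alignments, snps) {
  stopifnot(methods::is(alignments, "GAlignments"))
  if (length(alignments) == 0L || nrow(snps) == 0L) {
    return(data.frame(read_id = character(), call = character(),
                      n_snps_covered = integer(), aln_idx = integer(),
                      stringsAsFactors = FALSE))
  }
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(snp_gr, alignments, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(data.frame(read_id = character(), call = character(),
                      n_snps_covered = integer(), aln_idx = integer(),
                      stringsAsFactors = FALSE))
  }
  si <- S4Vectors::queryHits(hits)
  ai <- S4Vectors::subjectHits(hits)
  # lay the query sequence out in reference space: insertions removed,
  # deletions "-", intron skips ".", clips dropped
  ref_seq <- GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(alignments)$seq[ai],
    GenomicAlignments::cigar(alignments)[ai])
  offset <- snps$pos[si] + 1L - GenomicRanges::start(alignments)[ai] + 1L
  base <- as.character(Biostrings::subseq(ref_seq, start = offset, width = 1L))
  covered <- base %in% c("A", "C", "G", "T")
  si <- si[covered]; ai <- ai[covered]; base <- base[covered]
  vote <- integer(length(base))            # +1 allele1, -1 allele2, 0 neither
  vote[base == snps$allele1[si]] <- 1L
  vote[base == snps$allele2[si]] <- -1L
  votes <- rowsum(vote, ai)
  n_cov <- rowsum(rep(1L, length(ai)), ai)
  idx <- as.integer(rownames(votes))
  call <- ifelse(votes[, 1L] > 0L, "allele1",
                 ifelse(votes[, 1L] < 0L, "allele2", "conflict"))
  # all-neither reads have vote sum 0 but no allele votes at all
  any_allele <- rowsum(as.integer(vote != 0L), ai)[, 1L] > 0L
  call[!any_allele] <- "unassigned"
  data.frame(read_id = S4Vectors::mcols(alignments)$qname[idx],
             call = call, n_snps_covered = n_cov[, 1L], aln_idx = idx,
             stringsAsFactors = FALSE)
}

read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(what = c("qname", "seq")))
}

#' Quantify allele-specific expression for one sample
#'
#' Assigns every SNP-overlapping read to a phased allele
#' ([assign_read_alleles()]) and aggregates counts per annotated locus.
#' A read contributes to a locus when it covers at least one passing SNP
#' inside the locus interval; a read overlapping two loci contributes to
#' both. Conflicting and unassigned reads are excluded from the allele
#' counts but tallied in the log attribute. For stranded libraries a
#' read only counts toward loci on the transcript strand implied by its
#' orientation. Every locus in the annotation is reported; loci with no
#' SNP-overlapping reads carry `NA` allelic ratio and score.
#'
#' @param alignments Path to a SAM or BAM file, or a `GAlignments`
#'   object with `qname` and `seq` metadata.
#' @param annotation Annotation data.frame from [read_annotation()].
#' @param snps Phased-SNP data.frame from [read_phased_snps()].
#' @param params A [quant_params()] object.
#' @return A locus table (see [read_locus_table()]) with a `log`
#'   attribute: a character vector of per-stage counts, including the
#'   read-conservation tally.
#' @export
quantify_sample <- function(alignments, annotation, snps,
                            params = quant_params()) {
  if (nrow(annotation) == 0L) stop("empty annotation")
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  log <- c(sprintf("parameters: min_reads_per_snp=%d min_total_reads=%d orientation=%s excluded_chroms=%s",
                   params$min_reads_per_snp, params$min_total_reads,
                   params$library_orientation,
                   paste(params$excluded_chroms, collapse = ",")),
           sprintf("alignments: %d", length(alignments)),
           sprintf("annotation loci: %d", nrow(annotation)),
           sprintf("phased SNPs: %d", nrow(snps)))

  ann <- annotation[!annotation$chrom %in% params$excluded_chroms, , drop = FALSE]
  log <- c(log, sprintf("loci after chromosome exclusion: %d", nrow(ann)))

  calls <- assign_read_alleles(alignments, snps)
  log <- c(log, sprintf("SNP-overlapping reads: %d (allele1 %d, allele2 %d, conflict %d, unassigned %d)",
                        nrow(calls), sum(calls$call == "allele1"),
                        sum(calls$call == "allele2"),
                        sum(calls$call == "conflict"),
                        sum(calls$call == "unassigned")))

  out <- data.frame(locus_name = ann$name, chrom = ann$chrom,
                    start = ann$start, end = ann$end, strand = ann$strand,
                    biotype = ann$biotype,
                    total_reads = 0L, a1_reads = 0L, a2_reads = 0L,
                    n_snps = 0L, allelic_ratio = NA_real_,
                    allelic_score = NA_real_, stringsAsFactors = FALSE)

  if (nrow(calls) > 0L) {
    snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                     IRanges::IRanges(snps$pos + 1L, width = 1L))
    ann_gr <- as_granges(ann[, c("chrom", "start", "end", "strand")])
    snp_in_locus <- GenomicRanges::findOverlaps(snp_gr, ann_gr,
                                                ignore.strand = TRUE)
    # (read, SNP) coverage pairs restricted to assigned-call reads
    aln <- alignments[calls$aln_idx]
    cov_hits <- GenomicRanges::findOverlaps(snp_gr, aln, ignore.strand = TRUE)
    cov_snp <- S4Vectors::queryHits(cov_hits)
    cov_read <- S4Vectors::subjectHits(cov_hits)      # row index into calls

    # strand compatibility of each read with each locus
    read_strand <- as.character(GenomicRanges::strand(aln))
    locus_for_snp <- split(S4Vectors::subjectHits(snp_in_locus),
                           S4Vectors::queryHits(snp_in_locus))

    pairs <- data.frame(snp = cov_snp, read = cov_read)
    # expand to (read, locus) via SNP membership
    li <- locus_for_snp[as.character(pairs$snp)]
    reps <- lengths(li)
    expanded <- data.frame(read = rep(pairs$read, reps),
                           snp = rep(pairs$snp, reps),
                           locus = unlist(li, use.names = FALSE))
    expanded <- unique(expanded)

    if (params$library_orientation != "unstranded" && nrow(expanded)) {
      implied <- read_strand[expanded$read]
      if (params$library_orientation == "reverse") {
        implied <- ifelse(implied == "+", "-", ifelse(implied == "-", "+", implied))
      }
      locus_strand <- ann$strand[expanded$locus]
      keep <- locus_strand == "." | implied == locus_strand
      expanded <- expanded[keep, , drop = FALSE]
    }

    assigned <- calls$call[expanded$read] %in% c("allele1", "allele2")
    exp_assigned <- expanded[assigned, , drop = FALSE]

    if (nrow(exp_assigned)) {
      # per-(locus, SNP) assigned-read counts; drop failing SNPs and their reads
      key <- paste(exp_assigned$locus, exp_assigned$snp)
      per_snp <- table(key)
      pass <- names(per_snp)[per_snp >= params$min_reads_per_snp]
      exp_pass <- exp_assigned[key %in% pass, , drop = FALSE]

      if (nrow(exp_pass)) {
        # one contribution per (read, locus)
        rl <- unique(exp_pass[, c("read", "locus")])
        call_rl <- calls$call[rl$read]
        a1 <- tapply(call_rl == "allele1", rl$locus, sum)
        a2 <- tapply(call_rl == "allele2", rl$locus, sum)
        n_snps <- tapply(exp_pass$snp, exp_pass$locus,
                         function(s) length(unique(s)))
        idx <- as.integer(names(a1))
        out$a1_reads[idx] <- as.integer(a1)
        out$a2_reads[idx] <- as.integer(a2)
        out$n_snps[idx] <- as.integer(n_snps[names(a1)])
      }
    }
    out$total_reads <- out$a1_reads + out$a2_reads
    defined <- out$total_reads >= 1L
    out$allelic_ratio[defined] <- out$a1_reads[defined] / out$total_reads[defined]
    out$allelic_score[defined] <- allelic_score(out$a1_reads[defined],
                                                out$a2_reads[defined])
  }
  log <- c(log, sprintf("loci with defined allelic ratio: %d",
                        sum(!is.na(out$allelic_ratio))),
           sprintf("read tally: a1=%d a2=%d conflict=%d unassigned=%d",
                   sum(out$a1_reads), sum(out$a2_reads),
                   sum(calls$call == "conflict"),
                   sum(calls$call == "unassigned")))
  attr(out, "log") <- log
  out
}

#' Merge forward- and reverse-strand locus tables
#'
#' Stranded libraries are quantified once per strand against a
#' strand-split annotation; the two tables partition the annotation and
#' are concatenated here.
#'
#' @param table_fwd,table_rev Locus tables over disjoint locus sets.
#' @return The combined locus table.
#' @export
merge_strands <- function(table_fwd, table_rev) {
  shared <- intersect(table_fwd$locus_name, table_rev$locus_name)
  if (length(shared)) {
    stop("locus present in both strand tables: '", shared[1L], "'")
  }
  rbind(table_fwd, table_rev)
}

#' Merge replicate locus tables
#'
#' Loci are kept when informative — total reads at or above
#' `min_total_reads` in all replicates (`"all_samples"`, the inbred-cross
#' rule) or in at least one (`"any_sample"`, the human cohort rule).
#' Merged totals and allelic ratios are replicate medians; the merged
#' allelic-score magnitude is the minimum across replicates (robust
#' calling), signed by the median allelic ratio. Replicates whose score
#' sign disagrees with that consensus are counted in the log attribute.
#'
#' @param tables List of locus tables over the identical locus set.
#' @param informative_rule `"all_samples"` or `"any_sample"`.
#' @param min_total_reads Informativeness cut-off (default 20).
#' @return Merged locus table with a `log` attribute.
#' @export
merge_replicates <- function(tables, informative_rule = c("all_samples", "any_sample"),
                             min_total_reads = 20L) {
  informative_rule <- match.arg(informative_rule)
  if (length(tables) == 0L) stop("no locus tables to merge")
  names0 <- tables[[1L]]$locus_name
  for (t in tables) {
    if (!identical(sort(t$locus_name), sort(names0)))
      stop("replicate locus tables must cover identical locus sets")
  }
  tables <- lapply(tables, function(t) t[match(names0, t$locus_name), ])

  col_matrix <- function(col) {
    vapply(tables, `[[`, numeric(length(names0)), col)
  }
  totals <- col_matrix("total_reads")
  ars <- col_matrix("allelic_ratio")
  ass <- col_matrix("allelic_score")
  if (is.null(dim(totals))) {                     # single locus edge case
    totals <- matrix(totals, nrow = 1L)
    ars <- matrix(ars, nrow = 1L)
    ass <- matrix(ass, nrow = 1L)
  }
  keep <- switch(informative_rule,
                 all_samples = rowSums(totals >= min_total_reads) == length(tables),
                 any_sample = rowSums(totals >= min_total_reads) >= 1L)

  merged <- tables[[1L]][keep, c("locus_name", "chrom", "start", "end",
                                 "strand", "biotype")]
  med_total <- apply(totals[keep, , drop = FALSE], 1L, stats::median)
  med_ar <- apply(ars[keep, , drop = FALSE], 1L, stats::median, na.rm = TRUE)
  min_abs_as <- apply(abs(ass[keep, , drop = FALSE]), 1L, min, na.rm = TRUE)
  min_abs_as[!is.finite(min_abs_as)] <- NA_real_
  sgn <- sign(med_ar - 0.5)
  merged$total_reads <- med_total
  merged$a1_reads <- rep(NA_integer_, nrow(merged))
  merged$a2_reads <- rep(NA_integer_, nrow(merged))
  nsnp <- col_matrix("n_snps")
  if (is.null(dim(nsnp))) nsnp <- matrix(nsnp, nrow = 1L)
  merged$n_snps <- apply(nsnp[keep, , drop = FALSE], 1L, stats::median)
  merged$allelic_ratio <- med_ar
  merged$allelic_score <- sgn * min_abs_as

  discord <- sum(sign(ass[keep, , drop = FALSE]) * sgn < 0, na.rm = TRUE)
  attr(merged, "log") <- c(
    sprintf("replicates merged: %d", length(tables)),
    sprintf("informative rule: %s (min_total_reads=%d)",
            informative_rule, min_total_reads),
    sprintf("loci retained: %d of %d", sum(keep), length(keep)),
    sprintf("replicate score-sign discordances: %d", discord))
  merged
}
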