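linkage_keys <- function(linkages) {
  paste(linkages$source_name, linkages$target_name, sep = "\t")
}

#' Confirm linkages against fine-mapped eQTLs
#'
#' A linkage is confirmed when at least one eQTL position falls inside
#' the source (ncRNA) gene body and that eQTL's target gene equals the
#' linkage's target. Confirmation in the linkage's own tissue takes
#' precedence over confirmation in any other tissue.
#'
#' @param linkages Linkage data.frame from [link_loci()].
#' @param eqtls eQTL data.frame (`chrom`, `pos`, `target_gene`,
#'   `tissue`), positions 0-based.
#' @param linkage_tissue Tissue label of the linkage run (scalar or one
#'   per linkage).
#' @return Character vector per linkage: `"confirmed_same_tissue"`,
#'   `"confirmed_other_tissue"` or `"unconfirmed"`.
#' @export
confirm_with_eqtl <- function(linkages, eqtls, linkage_tissue) {
  n <- nrow(linkages)
  if (n == 0L) return(character(0))
  tissue <- rep_len(linkage_tissue, n)
  status <- rep("unconfirmed", n)
  if (nrow(eqtls) == 0L) return(status)
  for (k in seq_len(n)) {
    inside <- eqtls$chrom == linkages$chrom[k] &
      eqtls$pos >= linkages$source_start[k] &
      eqtls$pos < linkages$source_end[k] &
      eqtls$target_gene == linkages$target_name[k]
    if (any(inside)) {
      status[k] <- if (any(eqtls$tissue[inside] == tissue[k]))
        "confirmed_same_tissue" else "confirmed_other_tissue"
    }
  }
  status
}

#' Intersect linkages with genome-wide-significant GWAS variants
#'
#' Variants below the significance threshold (strict `<`) are tested for
#' containment in the source and target gene bodies of every linkage.
#'
#' @param linkages Linkage data.frame.
#' @param variants GWAS data.frame (`rsid`, `chrom`, `pos`, `pvalue`,
#'   `trait`), positions 0-based.
#' @param p_threshold Genome-wide significance threshold, default 5e-8
#'   (strict less-than).
#' @return list with `category` (per linkage: `"ncRNA_only"`,
#'   `"pcGene_only"`, `"both"`, `"none"`) and `variants` (per linkage, a
#'   character vector of overlapping significant rsids).
#' @export
intersect_gwas <- function(linkages, variants, p_threshold = 5e-8) {
  sig <- variants[variants$pvalue < p_threshold, , drop = FALSE]
  n <- nrow(linkages)
  category <- character(n)
  hit_list <- vector("list", n)
  for (k in seq_len(n)) {
    on_chr <- sig[sig$chrom == linkages$chrom[k], , drop = FALSE]
    in_src <- on_chr$pos >= linkages$source_start[k] &
      on_chr$pos < linkages$source_end[k]
    in_tgt <- on_chr$pos >= linkages$target_start[k] &
      on_chr$pos < linkages$target_end[k]
    category[k] <- if (any(in_src) && any(in_tgt)) "both"
      else if (any(in_src)) "ncRNA_only"
      else if (any(in_tgt)) "pcGene_only"
      else "none"
    hit_list[[k]] <- unique(on_chr$rsid[in_src | in_tgt])
  }
  list(category = category, variants = hit_list)
}

#' TAD co-localization of linkages
#'
#' A linkage co-localizes when some TAD contains both gene bodies
#' entirely. TADs must be non-overlapping within a chromosome.
#'
#' @param linkages Linkage data.frame.
#' @param tads TAD data.frame (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @return list with `same_tad` (logical per linkage) and `fraction`.
#' @export
tad_colocalization <- function(linkages, tads) {
  for (chr in unique(tads$chrom)) {
    t <- tads[tads$chrom == chr, , drop = FALSE]
    t <- t[order(t$start), , drop = FALSE]
    if (nrow(t) > 1L && any(t$start[-1L] < t$end[-nrow(t)])) {
      stop("overlapping TADs on ", chr)
    }
  }
  n <- nrow(linkages)
  same <- logical(n)
  for (k in seq_len(n)) {
    lo <- min(linkages$source_start[k], linkages$target_start[k])
    hi <- max(linkages$source_end[k], linkages$target_end[k])
    same[k] <- any(tads$chrom == linkages$chrom[k] &
                     tads$start <= lo & tads$end >= hi)
  }
  list(same_tad = same,
       fraction = if (n) mean(same) else NA_real_)
}

#' Enhancer co-occurrence of ncRNA-pcGene linkages
#'
#' Interprets ncRNA-pcGene pairs in light of allele-specific enhancer
#' (peak) linkages: a pair is `enhancer_cooccurring` when at least one
#' enhancing peak linkage targets either member (suggesting a shared DNA
#' regulatory element), else `ncRNA_candidate` (consistent with a direct
#' ncRNA-mediated effect). Repressive peak linkages are ignored.
#'
#' @param gene_linkages ncRNA-to-pcGene linkage data.frame.
#' @param enhancer_linkages Peak-to-gene linkage data.frame (from
#'   [run_link()] with the `enhancing_peak_to_gene` filter; any
#'   repressive rows present are dropped here as a safeguard).
#' @return Character vector per gene linkage.
#' @export
enhancer_cooccurrence <- function(gene_linkages, enhancer_linkages) {
  enh <- enhancer_linkages[enhancer_linkages$mechanism == "enhancing", ,
                           drop = FALSE]
  covered <- unique(enh$target_name)
  ifelse(gene_linkages$source_name %in% covered |
           gene_linkages$target_name %in% covered,
         "enhancer_cooccurring", "ncRNA_candidate")
}

#' Mechanism consistency of a linkage across samples
#'
#' For each linkage key (source gene, target gene) observed across
#' samples, the fraction of samples calling it enhancing is computed and
#' the linkage is classified `enhancing` when that fraction meets the
#' consistency cut-off, `repressive` when the repressive fraction does,
#' and `unclassified` otherwise (e.g. an even split).
#'
#' @param calls data.frame with columns `source_name`, `target_name`,
#'   `mechanism` (one row per sample in which the linkage was detected).
#' @param cutoff Consistency cut-off, default 0.75 (inclusive).
#' @return data.frame per key: `source_name`, `target_name`,
#'   `n_samples`, `n_enhancing`, `fraction_enhancing`, `call`.
#' @export
mechanism_consistency <- function(calls, cutoff = 0.75) {
  key <- paste(calls$source_name, calls$target_name, sep = "\t")
  n <- tapply(rep(1L, nrow(calls)), key, sum)
  ne <- tapply(calls$mechanism == "enhancing", key, sum)
  keys <- names(n)
  frac <- as.numeric(ne[keys]) / as.numeric(n[keys])
  call <- ifelse(frac >= cutoff, "enhancing",
                 ifelse(1 - frac >= cutoff, "repressive", "unclassified"))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  data.frame(source_name = vapply(parts, `[`, "", 1L),
             target_name = vapply(parts, `[`, "", 2L),
             n_samples = as.integer(n[keys]),
             n_enhancing = as.integer(ne[keys]),
             fraction_enhancing = frac, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Linkage-discovery saturation curve
#'
#' For each cohort size n from 1 to the number of samples, draws random
#' n-subsets of samples without replacement and reports the mean and
#' standard deviation of the number of unique linkage keys in their
#' union. At n = N the full union is used directly (sd 0).
#'
#' @param sets Named list; each element is a character vector of linkage
#'   keys for one sample.
#' @param iterations Number of random subsets per n, default 1000.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return data.frame with columns `n`, `mean_unique`, `sd_unique`.
#' @export
saturation_curve <- function(sets, iterations = 1000L, seed) {
  if (iterations < 1L) stop("iterations must be >= 1")
  if (length(sets) == 0L) stop("need at least one sample")
  if (missing(seed)) stop("seed is required")
  N <- length(sets)
  withr::with_seed(as.integer(seed), {
    res <- lapply(seq_len(N), function(n) {
      if (n == N) {
        u <- length(unique(unlist(sets, use.names = FALSE)))
        return(data.frame(n = n, mean_unique = u, sd_unique = 0))
      }
      sizes <- vapply(seq_len(iterations), function(it) {
        pick <- sample.int(N, n)
        length(unique(unlist(sets[pick], use.names = FALSE)))
      }, numeric(1L))
      data.frame(n = n, mean_unique = mean(sizes), sd_unique = stats::sd(sizes))
    })
    do.call(rbind, res)
  })
}

#' Linkage sharing across groups
#'
#' Counts, for every linkage key, the number of groups (tissues,
#' individuals) in which it appears, and summarizes the histogram and
#' the group-specific fraction (keys seen in exactly one group).
#'
#' @param linkage_groups data.frame with columns `source_name`,
#'   `target_name`, `group`.
#' @return list with `per_key` (data.frame: key columns + `n_groups`),
#'   `histogram` (table over `n_groups`), `specific_fraction`.
#' @export
sharing_across_groups <- function(linkage_groups) {
  key <- paste(linkage_groups$source_name, linkage_groups$target_name,
               sep = "\t")
  per <- unique(data.frame(key = key, group = linkage_groups$group,
                           stringsAsFactors = FALSE))
  counts <- tapply(rep(1L, nrow(per)), per$key, sum)
  keys <- names(counts)
  parts <- strsplit(keys, "\t", fixed = TRUE)
  per_key <- data.frame(source_name = vapply(parts, `[`, "", 1L),
                        target_name = vapply(parts, `[`, "", 2L),
                        n_groups = as.integer(counts),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(per_key = per_key,
       histogram = table(per_key$n_groups),
       specific_fraction = mean(per_key$n_groups == 1L))
}

#' Precision and recall of predicted linkages against a truth set
#'
#' Keys are (source gene, target gene) pairs. An empty prediction set
#' has precision 1 by convention (no false positives) and recall 0.
#'
#' @param predicted,truth data.frames with `source_name` and
#'   `target_name` columns (or character vectors of `"src\ttgt"` keys);
#'   `truth` must be non-empty.
#' @return list with `precision`, `recall`, `n_true_positive`.
#' @export
evaluate_against_truth <- function(predicted, truth) {
  as_keys <- function(x) {
    if (is.data.frame(x)) unique(linkage_keys(x)) else unique(x)
  }
  pred <- as_keys(predicted)
  tr <- as_keys(truth)
  if (length(tr) == 0L) stop("truth set must be non-empty")
  tp <- length(intersect(pred, tr))
  list(precision = if (length(pred)) tp / length(pred) else 1,
       recall = tp / length(tr),
       n_true_positive = tp)
}

#' Binomial test on the enhancing/repressive balance
#'
#' Tests whether enhancing calls outnumber repressive ones beyond
#' chance: an exact binomial test of the enhancing count against a
#' balanced null of 0.5. The default one-sided (greater) alternative
#' asks specifically for an excess of enhancing linkages.
#'
#' @param n_enhancing Number of enhancing linkages.
#' @param n_total Total number of linkages.
#' @param alternative Passed to [stats::binom.test()]; default
#'   `"greater"`.
#' @return The `htest` object.
#' @export
mechanism_balance_test <- function(n_enhancing, n_total,
                                   alternative = "greater") {
  stats::binom.test(n_enhancing, n_total, p = 0.5,
                    alternative = alternative)
}
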