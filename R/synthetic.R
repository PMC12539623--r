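#' Configuration for the synthetic ASE cohort generator
#'
#' Defines a diploid genome emulating the statistical structure the
#' linkage method assumes: a biallelic background (allelic ratio 0.5),
#' rare strongly allele-specific loci, and planted cis-proximal pairs
#' whose members are placed within the linkage window. Planted pairs are
#' isolated from each other by more than the linkage window so that the
#' set of discoverable pairs equals the planted truth by construction.
#'
#' @param n_chromosomes Number of chromosomes (default 4).
#' @param chrom_length_bp Chromosome length (default 6e7).
#' @param n_loci Number of loci (default 200), distributed evenly.
#' @param ncRNA_fraction Fraction of loci tagged ncRNA (floor; default
#'   0.3); the rest are pcGene except planted sources/targets, which are
#'   forced to ncRNA/pcGene respectively.
#' @param snps_per_locus Poisson mean of phased SNPs per locus
#'   (default 3; a locus drawing 0 SNPs is uninformative, as in real
#'   data).
#' @param coverage_per_locus Poisson mean of SNP-overlapping reads per
#'   locus (default 50).
#' @param n_planted_links Number of planted source-target pairs
#'   (default 20), alternating enhancing and repressive.
#' @param planted_ar_high,planted_ar_low Allelic ratios planted at
#'   linked loci (defaults 0.85 / 0.15).
#' @param link_gap_bp Maximum interval gap between planted pair members
#'   (default 5e4, inside the default 100 kb window).
#' @param pair_isolation_bp Minimum distance separating a planted pair
#'   from any other locus (default 2e5, beyond the window).
#' @param concentration Beta-binomial concentration for allele sampling;
#'   `Inf` gives pure binomial (default 80, mild overdispersion as seen
#'   in real ASE counts).
#' @param read_length_bp Simulated read length (default 50, single-end).
#' @param seed Integer seed; every generator output is deterministic
#'   given the config.
#' @return list of class `truth_config`.
#' @export
truth_config <- function(n_chromosomes = 4L, chrom_length_bp = 6e7,
                         n_loci = 200L, ncRNA_fraction = 0.3,
                         snps_per_locus = 3, coverage_per_locus = 50,
                         n_planted_links = 20L,
                         planted_ar_high = 0.85, planted_ar_low = 0.15,
                         link_gap_bp = 5e4, pair_isolation_bp = 2e5,
                         concentration = 80, read_length_bp = 50L,
                         seed = 1L) {
  stopifnot(n_loci >= 2L * n_planted_links,
            planted_ar_high >= 0, planted_ar_high <= 1,
            planted_ar_low >= 0, planted_ar_low <= 1)
  structure(as.list(environment()), class = "truth_config")
}

rbetabinom <- function(n, size, prob, concentration) {
  if (is.infinite(concentration)) return(stats::rbinom(n, size, prob))
  p <- ifelse(prob <= 0, 0, ifelse(prob >= 1, 1,
              stats::rbeta(n, prob * concentration,
                           (1 - prob) * concentration)))
  stats::rbinom(n, size, p)
}

#' Simulate a genome: annotation, biotypes, phased SNPs and planted truth
#'
#' Loci are placed sequentially and non-overlapping; each planted pair
#' is placed with a gap of at most `link_gap_bp` between its members and
#' at least `pair_isolation_bp` from every other locus. SNP positions
#' are uniform within loci. Deterministic given the config seed.
#'
#' @param config A [truth_config()].
#' @return list with `annotation` (validated BED6-style data.frame with
#'   biotypes), `snps` (phased-SNP data.frame), and `truth` (data.frame
#'   of planted links: source/target names, mechanism, planted ARs).
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed, {
    n_chr <- config$n_chromosomes
    per_chr <- diff(round(seq(0, config$n_loci, length.out = n_chr + 1L)))
    chroms <- paste0("chr", seq_len(n_chr))

    # mark which loci are planted pair members: pairs occupy consecutive
    # slots, spread evenly over the locus sequence
    n_pairs <- config$n_planted_links
    slots <- integer(0)
    if (n_pairs > 0L) {
      src_slots <- floor(seq(1L, config$n_loci - 1L, length.out = n_pairs))
      src_slots <- unique(as.integer(src_slots))
      # avoid a pair straddling a chromosome boundary
      bounds <- cumsum(per_chr)
      src_slots[src_slots %in% bounds] <- src_slots[src_slots %in% bounds] - 1L
      src_slots <- unique(src_slots)
      while (length(src_slots) < n_pairs) {
        cand <- setdiff(seq_len(config$n_loci - 1L),
                        c(src_slots, src_slots + 1L, src_slots - 1L, bounds))
        src_slots <- sort(c(src_slots, cand[1L]))
      }
      slots <- src_slots[seq_len(n_pairs)]
    }
    is_source <- seq_len(config$n_loci) %in% slots
    is_target <- seq_len(config$n_loci) %in% (slots + 1L)

    chrom <- rep(chroms, per_chr)
    start <- integer(config$n_loci)
    end <- integer(config$n_loci)
    pos <- stats::setNames(rep(1000L, n_chr), chroms)
    for (k in seq_len(config$n_loci)) {
      len <- as.integer(round(stats::runif(1L, 2000, 8000)))
      gap <- if (is_target[k]) {
        as.integer(round(stats::runif(1L, 200, config$link_gap_bp)))
      } else if (is_source[k] || (k > 1L && is_target[k - 1L])) {
        as.integer(round(stats::runif(1L, config$pair_isolation_bp,
                                      config$pair_isolation_bp * 1.5)))
      } else {
        as.integer(round(stats::runif(1L, 2e4, 8e4)))
      }
      p <- pos[chrom[k]] + gap
      start[k] <- p
      end[k] <- p + len
      pos[chrom[k]] <- end[k]
    }
    if (any(end > config$chrom_length_bp)) {
      stop("loci cannot fit on the configured chromosomes without overlap")
    }

    n_nc <- as.integer(floor(config$ncRNA_fraction * config$n_loci))
    biotype <- rep("pcGene", config$n_loci)
    free <- which(!is_source & !is_target)
    n_free_nc <- max(0L, n_nc - sum(is_source))
    if (n_free_nc > 0L) biotype[sample(free, min(n_free_nc, length(free)))] <- "ncRNA"
    biotype[is_source] <- "ncRNA"
    biotype[is_target] <- "pcGene"

    name <- sprintf("%s_%s%04d",
                    ifelse(biotype == "ncRNA", "NC", "PC"),
                    chrom, seq_len(config$n_loci))
    strand <- sample(c("+", "-"), config$n_loci, replace = TRUE)
    ann <- data.frame(chrom = chrom, start = start, end = end, name = name,
                      score = 0, strand = strand, stringsAsFactors = FALSE)
    ann <- validate_annotation(ann,
                               biotype_map = stats::setNames(biotype, name))

    n_snps <- stats::rpois(config$n_loci, config$snps_per_locus)
    snp_rows <- lapply(seq_len(config$n_loci), function(k) {
      if (n_snps[k] == 0L) return(NULL)
      p <- sort(sample(seq.int(start[k], end[k] - 1L), n_snps[k]))
      alleles <- t(vapply(seq_along(p), function(i)
        sample(c("A", "C", "G", "T"), 2L), character(2L)))
      data.frame(chrom = chrom[k], pos = p, allele1 = alleles[, 1L],
                 allele2 = alleles[, 2L], stringsAsFactors = FALSE)
    })
    snps <- do.call(rbind, snp_rows)
    snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
    rownames(snps) <- NULL

    mech <- rep_len(c("enhancing", "repressive"), n_pairs)
    src_ar <- rep(config$planted_ar_high, n_pairs)
    tgt_ar <- ifelse(mech == "enhancing", config$planted_ar_high,
                     config$planted_ar_low)
    truth <- data.frame(source_name = name[slots],
                        target_name = name[slots + 1L],
                        mechanism = mech, source_ar = src_ar,
                        target_ar = tgt_ar, stringsAsFactors = FALSE)
    true_ar <- rep(0.5, config$n_loci)
    true_ar[slots] <- src_ar
    true_ar[slots + 1L] <- tgt_ar
    ann$true_ar <- true_ar
    list(annotation = ann, snps = snps, truth = truth)
  })
}

#' Simulate SNP-overlapping reads for one sample
#'
#' For every locus with at least one phased SNP, a Poisson number of
#' single-end, perfect-match, fixed-length reads is drawn; each read is
#' assigned to one haplotype (allele-1 count beta-binomial around the
#' locus's true allelic ratio) and anchored to cover a uniformly chosen
#' SNP of the locus, with haplotype-consistent bases at every SNP the
#' read covers. The emitted truth counts are exactly what
#' [quantify_sample()] recovers at `min_reads_per_snp = 1`.
#'
#' @param genome Output of [simulate_genome()].
#' @param config The same [truth_config()].
#' @param sam_path Path for the SAM output.
#' @param seed Optional seed overriding `config$seed` (to draw replicate
#'   samples from one genome).
#' @return Invisibly, a data.frame of per-locus truth counts:
#'   `locus_name`, `true_ar`, `a1_reads`, `a2_reads`.
#' @export
simulate_reads <- function(genome, config, sam_path,
                           seed = config$seed) {
  ann <- genome$annotation
  snps <- genome$snps
  rl <- config$read_length_bp
  withr::with_seed(as.integer(seed), {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:chr%d\tLN:%d", seq_len(config$n_chromosomes),
                        as.integer(config$chrom_length_bp)))
    lines <- character(0)
    truth <- data.frame(locus_name = ann$name, true_ar = ann$true_ar,
                        a1_reads = 0L, a2_reads = 0L,
                        stringsAsFactors = FALSE)
    qual <- strrep("I", rl)
    read_no <- 0L
    for (k in seq_len(nrow(ann))) {
      lsnp <- snps[snps$chrom == ann$chrom[k] & snps$pos >= ann$start[k] &
                     snps$pos < ann$end[k], , drop = FALSE]
      if (nrow(lsnp) == 0L) next
      n <- stats::rpois(1L, config$coverage_per_locus)
      if (n == 0L) next
      a1 <- rbetabinom(1L, n, ann$true_ar[k], config$concentration)
      truth$a1_reads[k] <- a1
      truth$a2_reads[k] <- n - a1
      hap <- c(rep(1L, a1), rep(2L, n - a1))
      anchor <- lsnp$pos[sample.int(nrow(lsnp), n, replace = TRUE)]
      lo <- pmax(ann$start[k], anchor - (rl - 1L))
      hi <- pmin(anchor, ann$end[k] - 1L)   # read must cover its anchor SNP
      hi <- pmax(hi, lo)
      rstart <- as.integer(lo + floor(stats::runif(n) * (hi - lo + 1L)))
      flag <- if (ann$strand[k] == "-") 16L else 0L
      for (r in seq_len(n)) {
        read_no <- read_no + 1L
        seq <- rep("A", rl)
        cov <- which(lsnp$pos >= rstart[r] & lsnp$pos < rstart[r] + rl)
        base <- if (hap[r] == 1L) lsnp$allele1 else lsnp$allele2
        seq[lsnp$pos[cov] - rstart[r] + 1L] <- base[cov]
        lines[read_no] <- paste(
          sprintf("read%07d", read_no), flag, ann$chrom[k], rstart[r] + 1L,
          60L, paste0(rl, "M"), "*", 0L, 0L,
          paste(seq, collapse = ""), qual, sep = "\t")
      }
    }
    writeLines(c(header, lines), sam_path)
    invisible(truth)
  })
}

#' Simulate a cohort of individuals with genotype-driven ASE
#'
#' Each planted link is active in a random subset of individuals
#' (emulating an ASE-inducing heterozygous variant that only some
#' individuals carry); where inactive, both loci revert to a balanced
#' allelic ratio. Per-individual locus tables are drawn directly
#' (Poisson totals, beta-binomial allele-1 counts). Toy integration
#' tables consistent with the truth accompany the cohort: eQTLs inside
#' every planted source pointing at the true target, GWAS variants
#' inside planted sources with p-values straddling genome-wide
#' significance, and TADs tiling each chromosome.
#'
#' @param config A [truth_config()].
#' @param n_individuals Cohort size (>= 1).
#' @param activation_prob Probability a planted link is active in an
#'   individual (default 0.6).
#' @param tissue Tissue label stamped on the toy eQTL table.
#' @return list with `genome`, `tables` (list of per-individual locus
#'   tables), `active` (links x individuals logical matrix), `eqtls`,
#'   `gwas`, `tads`, `truth`.
#' @export
simulate_cohort <- function(config, n_individuals,
                            activation_prob = 0.6,
                            tissue = "synthetic_tissue") {
  stopifnot(n_individuals >= 1L)
  genome <- simulate_genome(config)
  ann <- genome$annotation
  truth <- genome$truth
  withr::with_seed(config$seed + 1L, {
    n_links <- nrow(truth)
    active <- matrix(stats::runif(n_links * n_individuals) < activation_prob,
                     nrow = n_links,
                     dimnames = list(NULL, paste0("ind", seq_len(n_individuals))))
    tables <- lapply(seq_len(n_individuals), function(ind) {
      ar <- rep(0.5, nrow(ann))
      on <- which(active[, ind])
      ar[match(truth$source_name[on], ann$name)] <- truth$source_ar[on]
      ar[match(truth$target_name[on], ann$name)] <- truth$target_ar[on]
      total <- stats::rpois(nrow(ann), config$coverage_per_locus)
      a1 <- rbetabinom(nrow(ann), total, ar, config$concentration)
      defined <- total > 0L
      tab <- data.frame(locus_name = ann$name, chrom = ann$chrom,
                        start = ann$start, end = ann$end,
                        strand = ann$strand, biotype = ann$biotype,
                        total_reads = total, a1_reads = a1,
                        a2_reads = total - a1,
                        n_snps = pmin(total, 1L),
                        allelic_ratio = NA_real_,
                        allelic_score = NA_real_,
                        stringsAsFactors = FALSE)
      tab$allelic_ratio[defined] <- a1[defined] / total[defined]
      tab$allelic_score[defined] <- allelic_score(a1[defined],
                                                  total[defined] - a1[defined])
      tab
    })
    src <- match(truth$source_name, ann$name)
    eqtls <- data.frame(
      chrom = ann$chrom[src],
      pos = as.integer((ann$start[src] + ann$end[src]) %/% 2L),
      target_gene = truth$target_name, tissue = tissue,
      stringsAsFactors = FALSE)
    gwas <- data.frame(
      rsid = sprintf("rs%06d", seq_len(2L * n_links)),
      chrom = rep(ann$chrom[src], 2L),
      pos = rep(as.integer(ann$start[src] + 100L), 2L),
      pvalue = c(rep(1e-9, n_links), rep(1e-6, n_links)),
      trait = "synthetic_trait", stringsAsFactors = FALSE)
    tad_w <- 2e6
    tads <- do.call(rbind, lapply(paste0("chr", seq_len(config$n_chromosomes)),
      function(ch) {
        brk <- seq(0, config$chrom_length_bp, by = tad_w)
        data.frame(chrom = ch, start = as.integer(brk[-length(brk)]),
                   end = as.integer(brk[-1L]), stringsAsFactors = FALSE)
      }))
    list(genome = genome, tables = tables, active = active,
         eqtls = eqtls, gwas = gwas, tads = tads, truth = truth)
  })
}

#' Deterministic chromosome-wide repressor fixture
#'
#' Builds a locus table emulating chromosome-wide allelic silencing in
#' cis (the X-inactivation pattern): one strongly allele-specific ncRNA
#' regulator, `n_targets` genes biased toward the opposite allele along
#' the same chromosome, and `n_escape` biallelic escape genes. Counts
#' are deterministic so the expected linkage output is exact. Setting
#' `regulator_active = FALSE` models a regulator knockout: the regulator
#' and all its targets revert to biallelic expression.
#'
#' @param n_targets Number of silenced (opposite-allele) genes.
#' @param n_escape Number of biallelic escape genes.
#' @param coverage Total reads per locus (default 100).
#' @param regulator_ar Regulator allelic ratio (default 0.9).
#' @param target_ar Target allelic ratio (default 0.1).
#' @param regulator_active When `FALSE`, every locus is biallelic.
#' @return A locus table with the regulator named `"REG_ncRNA"`.
#' @export
repressor_domain_table <- function(n_targets = 40L, n_escape = 2L,
                                   coverage = 100L, regulator_ar = 0.9,
                                   target_ar = 0.1,
                                   regulator_active = TRUE) {
  n <- 1L + n_targets + n_escape
  start <- 1e5 + (seq_len(n) - 1L) * 3e6
  end <- start + 2e4
  ar <- c(if (regulator_active) regulator_ar else 0.5,
          rep(if (regulator_active) target_ar else 0.5, n_targets),
          rep(0.5, n_escape))
  name <- c("REG_ncRNA", sprintf("TGT_pc%03d", seq_len(n_targets)),
            sprintf("ESC_pc%02d", seq_len(n_escape)))
  biotype <- c("ncRNA", rep("pcGene", n_targets + n_escape))
  a1 <- as.integer(round(ar * coverage))
  data.frame(locus_name = name, chrom = "chrX", start = as.integer(start),
             end = as.integer(end), strand = "+", biotype = biotype,
             total_reads = coverage, a1_reads = a1,
             a2_reads = coverage - a1, n_snps = 3L,
             allelic_ratio = a1 / coverage,
             allelic_score = allelic_score(a1, coverage - a1),
             stringsAsFactors = FALSE)
}
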