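#' @importFrom utils read.delim write.table
NULL

LOCUS_TABLE_COLS <- c("locus_name", "chrom", "start", "end", "strand",
                      "biotype", "total_reads", "a1_reads", "a2_reads",
                      "n_snps", "allelic_ratio", "allelic_score")

BIOTYPES <- c("ncRNA", "pcGene", "peak", "other")

#' Read a BED6 locus annotation
#'
#' Loci are read as 0-based half-open intervals. The transcription start
#' site (TSS) is derived from the strand: `start` for `+` or `.` loci,
#' `end - 1` for `-` loci. Biotype (`ncRNA`, `pcGene`, `peak`, `other`)
#' is not part of BED6 and is supplied either as a named character vector
#' (`name -> biotype`) or as the path to a two-column tab-separated
#' sidecar file; unmapped loci default to `"other"`.
#'
#' @param path Path to a 6-column tab-separated BED file.
#' @param biotype_map Named character vector, two-column data.frame, or
#'   path to a two-column TSV mapping locus names to biotypes. Optional.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `biotype`, `tss`.
#' @export
read_annotation <- function(path, biotype_map = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    stop("malformed BED6 line ", which(nf != 6L)[1L], " in ", path,
         ": expected 6 tab-separated columns, got ", nf[nf != 6L][1L])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("non-numeric coordinates on line ", bad[1L], " in ", path)
  ann <- data.frame(chrom = m[, 1L], start = start, end = end,
                    name = m[, 4L],
                    score = suppressWarnings(as.numeric(m[, 5L])),
                    strand = m[, 6L], stringsAsFactors = FALSE)
  validate_annotation(ann, biotype_map = biotype_map)
}

#' Validate an annotation data.frame and attach biotype and TSS
#'
#' @param ann data.frame with columns chrom, start, end, name, score, strand.
#' @inheritParams read_annotation
#' @return The validated annotation with `biotype` and `tss` columns.
#' @export
validate_annotation <- function(ann, biotype_map = NULL) {
  if (any(ann$start >= ann$end)) {
    i <- which(ann$start >= ann$end)[1L]
    stop("locus '", ann$name[i], "': start (", ann$start[i],
         ") must be < end (", ann$end[i], ")")
  }
  if (anyDuplicated(ann$name)) {
    stop("duplicate locus name: '", ann$name[duplicated(ann$name)][1L], "'")
  }
  if (!all(ann$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  ann$biotype <- resolve_biotypes(ann$name, biotype_map)
  ann$tss <- ifelse(ann$strand == "-", ann$end - 1L, ann$start)
  ann
}

resolve_biotypes <- function(names, biotype_map) {
  if (is.null(biotype_map)) return(rep("other", length(names)))
  if (is.character(biotype_map) && is.null(names(biotype_map)) &&
      length(biotype_map) == 1L && file.exists(biotype_map)) {
    tab <- read.delim(biotype_map, header = FALSE, stringsAsFactors = FALSE)
    biotype_map <- stats::setNames(tab[[2L]], tab[[1L]])
  }
  if (is.data.frame(biotype_map)) {
    biotype_map <- stats::setNames(biotype_map[[2L]], biotype_map[[1L]])
  }
  bt <- unname(biotype_map[names])
  bt[is.na(bt)] <- "other"
  if (!all(bt %in% BIOTYPES)) {
    stop("unknown biotype(s): ", paste(unique(setdiff(bt, BIOTYPES)), collapse = ", "))
  }
  bt
}

#' Read a BED4 phased-SNP file
#'
#' Each record is a width-1 interval whose name field encodes the two
#' phased alleles as `"A1/A2"` with the haplotype-1 base first, e.g.
#' `"C/T"`. The returned table is sorted by chromosome and position for
#' fast indexed lookup.
#'
#' @param path Path to a 4-column tab-separated BED file.
#' @return A data.frame with columns `chrom`, `pos` (0-based), `allele1`,
#'   `allele2`, sorted by (`chrom`, `pos`).
#' @export
read_phased_snps <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    stop("malformed BED4 line ", which(nf != 4L)[1L], " in ", path)
  }
  m <- do.call(rbind, fields)
  start <- as.integer(m[, 2L])
  end <- as.integer(m[, 3L])
  if (any(end - start != 1L)) {
    i <- which(end - start != 1L)[1L]
    stop("SNP on line ", i, " has width ", end[i] - start[i], ", expected 1")
  }
  ok <- grepl("^[ACGT]/[ACGT]$", m[, 4L])
  if (!all(ok)) {
    stop("malformed allele string '", m[!ok, 4L][1L],
         "' on line ", which(!ok)[1L], " (expected e.g. 'C/T')")
  }
  a1 <- substr(m[, 4L], 1L, 1L)
  a2 <- substr(m[, 4L], 3L, 3L)
  if (any(a1 == a2)) {
    stop("identical alleles '", m[a1 == a2, 4L][1L], "' on line ",
         which(a1 == a2)[1L])
  }
  snps <- data.frame(chrom = m[, 1L], pos = start, allele1 = a1,
                     allele2 = a2, stringsAsFactors = FALSE)
  snps[order(snps$chrom, snps$pos), , drop = FALSE]
}

#' Read a locus table
#'
#' The locus table is the per-sample ASE quantification output: one row
#' per annotated locus with allele counts, total SNP-overlapping reads,
#' allelic ratio and signed allelic score. Loci without any
#' SNP-overlapping reads carry `NA` allelic ratio and score.
#'
#' @param path Path to a tab-separated locus table.
#' @return data.frame with the twelve canonical locus-table columns.
#' @export
read_locus_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(LOCUS_TABLE_COLS, names(tab))
  if (length(missing)) {
    stop("locus table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[, LOCUS_TABLE_COLS]
  for (col in c("start", "end", "total_reads", "a1_reads", "a2_reads", "n_snps"))
    tab[[col]] <- as.integer(tab[[col]])
  for (col in c("allelic_ratio", "allelic_score"))
    tab[[col]] <- as.numeric(tab[[col]])
  tab
}

#' Write a locus table
#'
#' @param loci Locus table data.frame (see [read_locus_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(loci, path) {
  missing <- setdiff(LOCUS_TABLE_COLS, names(loci))
  if (length(missing)) {
    stop("locus table is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- loci[, LOCUS_TABLE_COLS]
  for (col in c("allelic_ratio", "allelic_score")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 10, format = "g"))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an eQTL table
#'
#' Four tab-separated columns: `chrom`, `pos` (0-based), `target_gene`,
#' `tissue`.
#'
#' @param path Path to the table (with header).
#' @return data.frame with those four columns.
#' @export
read_eqtl_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "target_gene", "tissue")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("eQTL table missing column(s): ",
                            paste(missing, collapse = ", "))
  stopifnot(all(tab$pos >= 0))
  tab[, need]
}

#' Read a GWAS variant table
#'
#' Five tab-separated columns: `rsid`, `chrom`, `pos` (0-based),
#' `pvalue`, `trait`.
#'
#' @param path Path to the table (with header).
#' @return data.frame with those five columns.
#' @export
read_gwas_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos", "pvalue", "trait")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("GWAS table missing column(s): ",
                            paste(missing, collapse = ", "))
  if (any(tab$pvalue <= 0 | tab$pvalue > 1)) stop("GWAS p-values must be in (0, 1]")
  tab[, need]
}

#' Read a BED3 file of TAD intervals
#'
#' @param path Path to a 3+-column BED file (extra columns ignored).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_tad_bed <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("TAD BED needs at least 3 columns")
  tads <- data.frame(chrom = tab[[1L]], start = as.integer(tab[[2L]]),
                     end = as.integer(tab[[3L]]), stringsAsFactors = FALSE)
  if (any(tads$start >= tads$end)) stop("TAD with start >= end")
  tads
}

rank_linkages <- function(linkages) {
  linkages[order(-linkages$linkage_score, linkages$source_name,
                 linkages$target_name), , drop = FALSE]
}

linkage_rgb <- function(mechanism) {
  ifelse(mechanism == "enhancing", "0,128,0", "255,0,0")
}

#' Write ranked linkage outputs
#'
#' Writes four files under `out_prefix`: `<prefix>_linkage_table.tsv`
#' (ranked by linkage score descending, ties broken by source then
#' target name), `<prefix>.bedpe` (both intervals, mechanism, score and
#' an RGB colour column), `<prefix>.bed` (the spanning interval of each
#' pair with itemRgb colouring) and `<prefix>.log`. Enhancing linkages
#' are coloured green (0,128,0), repressive red (255,0,0). An empty
#' linkage set yields valid header-only outputs plus a log entry.
#'
#' @param linkages Linkage data.frame as produced by [link_loci()].
#' @param out_prefix Output path prefix.
#' @param log_lines Optional character vector of extra log lines
#'   (parameters, per-stage counts) prepended to the run log.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_linkage_outputs <- function(linkages, out_prefix, log_lines = character()) {
  linkages <- rank_linkages(linkages)
  paths <- c(table = paste0(out_prefix, "_linkage_table.tsv"),
             bedpe = paste0(out_prefix, ".bedpe"),
             bed = paste0(out_prefix, ".bed"),
             log = paste0(out_prefix, ".log"))
  tab_cols <- c("source_name", "target_name", "chrom", "mechanism",
                "delta_ar", "linkage_score", "distance_bp", "tss_distance_bp",
                "source_ar", "target_ar", "source_as", "target_as")
  tab_cols <- intersect(tab_cols, names(linkages))
  write.table(linkages[, tab_cols, drop = FALSE], paths["table"],
              sep = "\t", quote = FALSE, row.names = FALSE)

  rgb <- linkage_rgb(linkages$mechanism)
  if (nrow(linkages)) {
    bedpe <- data.frame(
      chrom1 = linkages$chrom, start1 = linkages$source_start,
      end1 = linkages$source_end,
      chrom2 = linkages$chrom, start2 = linkages$target_start,
      end2 = linkages$target_end,
      name = paste0(linkages$source_name, "|", linkages$target_name),
      score = linkages$linkage_score,
      strand1 = linkages$source_strand, strand2 = linkages$target_strand,
      mechanism = linkages$mechanism,
      linkage_score = linkages$linkage_score,
      rgb = rgb, stringsAsFactors = FALSE)
    span_start <- pmin(linkages$source_start, linkages$target_start)
    span_end <- pmax(linkages$source_end, linkages$target_end)
    bed <- data.frame(
      chrom = linkages$chrom, start = span_start, end = span_end,
      name = paste0(linkages$source_name, "|", linkages$target_name),
      score = pmin(1000L, as.integer(round(linkages$linkage_score * 100))),
      strand = ".", thickStart = span_start, thickEnd = span_end,
      rgb = rgb, stringsAsFactors = FALSE)
    write.table(bedpe, paths["bedpe"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    file.create(paths["bedpe"])
    file.create(paths["bed"])
  }
  writeLines(c(log_lines,
               sprintf("%d linkages written", nrow(linkages)),
               sprintf("output prefix: %s", out_prefix)),
             paths["log"])
  invisible(paths)
}

#' Convert an annotation or locus table to GRanges
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `strand`; other columns become metadata.
#' @return A [GenomicRanges::GRanges] object (1-based closed, as usual
#'   for GRanges; the shift is handled here so round-trips are exact).
#' @export
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
  meta <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  S4Vectors::mcols(gr) <- df[, meta, drop = FALSE]
  gr
}
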