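#' Read a SEG-style segmented copy-number file
#'
#' Tab-delimited with header; 5 columns (sample, chromosome, start, end,
#' seg_mean) or 6 (with num_markers third-from-last omitted or present —
#' i.e. sample, chromosome, start, end, n_markers, seg_mean). Coordinates
#' are 1-based inclusive. Rows violating the segment invariants raise a
#' parse error naming the offending line; rows on chromosomes absent from
#' an optional genome model are skipped with a warning.
#'
#' @param path file path.
#' @param genome optional \code{genome_model} used to screen chromosomes.
#' @param quiet suppress the record-count message.
#' @return data frame (sample, chrom, start, end, seg_mean) with attribute
#'   \code{value_kind = "log2_ratio"}.
#' @export
read_seg <- function(path, genome = NULL, quiet = FALSE) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!ncol(raw) %in% c(5, 6)) {
    stop("SEG file must have 5 or 6 columns, found ", ncol(raw))
  }
  nm <- if (ncol(raw) == 6) {
    c("sample", "chrom", "start", "end", "n_markers", "seg_mean")
  } else {
    c("sample", "chrom", "start", "end", "seg_mean")
  }
  names(raw) <- nm
  raw$chrom <- as.character(raw$chrom)
  for (col in c("start", "end", "seg_mean")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop(sprintf("parse error at line %d: non-numeric %s", bad[1] + 1, col))
    }
    raw[[col]] <- v
  }
  bad <- which(raw$start > raw$end)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: start > end", bad[1] + 1))
  }
  if (!is.null(genome)) {
    unknown <- !(raw$chrom %in% genome$chromosomes$chrom)
    if (any(unknown)) {
      warning(sprintf("skipping %d segment(s) on unknown chromosome(s): %s",
                      sum(unknown),
                      paste(unique(raw$chrom[unknown]), collapse = ", ")))
      raw <- raw[!unknown, , drop = FALSE]
    }
  }
  out <- raw[, c("sample", "chrom", "start", "end", "seg_mean")]
  rownames(out) <- NULL
  attr(out, "value_kind") <- "log2_ratio"
  if (!quiet) message(sprintf("read_seg: %d segments, %d samples from %s",
                              nrow(out), length(unique(out$sample)), path))
  out
}

#' Write segments in SEG format
#' @param segments data frame (sample, chrom, start, end, seg_mean).
#' @param path output path.
#' @return path, invisibly. Values are written to 6 decimals.
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(Sample = segments$sample, Chromosome = segments$chrom,
                    Start = segments$start, End = segments$end,
                    Num_Markers = if ("n_markers" %in% names(segments))
                      segments$n_markers else
                      pmax(1, round((segments$end - segments$start + 1) / 1000)),
                    Segment_Mean = sprintf("%.6f", segments$seg_mean))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read allele-specific integral copy-number segments (CSV)
#'
#' Comma-separated with header: sample, chromosome, start, end, total_cn,
#' minor_cn. Copy numbers must be non-negative integers with
#' minor <= total; violations raise a parse error naming the line.
#' @param path file path.
#' @param quiet suppress the record-count message.
#' @return data frame with attribute \code{value_kind = "allele_specific"}.
#' @export
read_allele_csv <- function(path, quiet = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  raw$chrom <- as.character(raw$chrom)
  bad <- which(raw$start > raw$end)
  if (length(bad)) stop(sprintf("parse error at line %d: start > end", bad[1] + 1))
  bad <- which(raw$total_cn < 0 | raw$minor_cn < 0 |
                 raw$total_cn != round(raw$total_cn) |
                 raw$minor_cn != round(raw$minor_cn))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: copy numbers must be non-negative integers",
                 bad[1] + 1))
  }
  bad <- which(raw$minor_cn > raw$total_cn)
  if (length(bad)) stop(sprintf("parse error at line %d: minor_cn > total_cn", bad[1] + 1))
  attr(raw, "value_kind") <- "allele_specific"
  if (!quiet) message(sprintf("read_allele_csv: %d segments, %d samples",
                              nrow(raw), length(unique(raw$sample))))
  raw
}

#' Write allele-specific segments as CSV
#' @param segments data frame (sample, chrom, start, end, total_cn, minor_cn).
#' @param path output path.
#' @export
write_allele_csv <- function(segments, path) {
  out <- segments[, c("sample", "chrom", "start", "end", "total_cn", "minor_cn")]
  names(out) <- c("sample", "chromosome", "start", "end", "total_cn", "minor_cn")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# controlled variant-class vocabulary
variant_classes <- function() {
  c("missense", "nonsense", "frameshift", "splice", "silent", "RNA",
    "intronic", "UTR", "flank", "intergenic")
}

#' Read a MAF-like mutation table (TSV)
#'
#' Columns: sample, gene, variant_class, protein_change, depth, vaf.
#' Variant classes outside the controlled vocabulary, negative depths or
#' VAFs outside [0,1] raise parse errors naming the line.
#' @param path file path.
#' @param quiet suppress the record-count message.
#' @return data frame of mutation records.
#' @export
read_maf <- function(path, quiet = FALSE) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(raw)[1:6] <- c("sample", "gene", "variant_class", "protein_change",
                       "depth", "vaf")
  bad <- which(!raw$variant_class %in% variant_classes())
  if (length(bad)) {
    stop(sprintf("parse error at line %d: unknown variant class '%s'",
                 bad[1] + 1, raw$variant_class[bad[1]]))
  }
  bad <- which(raw$depth < 0)
  if (length(bad)) stop(sprintf("parse error at line %d: negative depth", bad[1] + 1))
  bad <- which(raw$vaf < 0 | raw$vaf > 1)
  if (length(bad)) stop(sprintf("parse error at line %d: vaf outside [0,1]", bad[1] + 1))
  if (!quiet) message(sprintf("read_maf: %d records, %d samples",
                              nrow(raw), length(unique(raw$sample))))
  raw
}

#' Write a MAF-like mutation table
#' @param records mutation data frame.
#' @param path output path.
#' @export
write_maf <- function(records, path) {
  cols <- c("sample", "gene", "variant_class", "protein_change", "depth", "vaf")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GCT expression matrix
#' @param path file path; must start with a "#1.2" version line.
#' @param quiet suppress the record-count message.
#' @return genes x samples numeric matrix with attribute \code{kind}.
#' @export
read_gct <- function(path, quiet = FALSE) {
  lines <- readLines(path, n = 2)
  if (lines[1] != "#1.2") stop("not a GCT 1.2 file (missing #1.2 header)")
  dims <- as.integer(strsplit(lines[2], "\t")[[1]])
  tab <- utils::read.delim(path, skip = 2, stringsAsFactors = FALSE,
                           check.names = FALSE)
  mat <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(mat) <- tab[[1]]
  storage.mode(mat) <- "double"
  if (nrow(mat) != dims[1] || ncol(mat) != dims[2]) {
    stop("GCT dimension line disagrees with table body")
  }
  attr(mat, "kind") <- "expression"
  if (!quiet) message(sprintf("read_gct: %d genes x %d samples", nrow(mat), ncol(mat)))
  mat
}

#' Write a genes x samples matrix in GCT 1.2 format
#' @param mat numeric matrix with row (gene) and column (sample) names.
#' @param path output path.
#' @export
write_gct <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  tab <- data.frame(Name = rownames(mat), Description = rownames(mat),
                    mat, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene coordinate table (BED-like TSV, 1-based inclusive)
#' @param path file path; columns gene, chrom, start, end.
#' @return data frame of gene coordinates.
#' @export
read_gene_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(raw)[1:4] <- c("gene", "chrom", "start", "end")
  raw$chrom <- as.character(raw$chrom)
  bad <- which(raw$start > raw$end)
  if (length(bad)) stop(sprintf("parse error at line %d: start > end", bad[1] + 1))
  raw
}

#' Write a gene coordinate table
#' @param genes data frame (gene, chrom, start, end).
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("gene", "chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort truth ledger as JSON
#' @param truth truth list from the simulators.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a cohort truth ledger written by [write_truth_json()]
#' @param path file path.
#' @return truth list.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$samples)) x$samples <- as.data.frame(x$samples)
  x
}
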