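#' Convert integral total copy numbers to log2 ratios
#'
#' For each sample, computes the length-weighted average total copy number
#' A and transforms every segment to log2(total_cn / A), so a sample's
#' profile is expressed relative to its own average ploidy (a uniform
#' profile maps to identically zero). Zero-copy segments, whose log2 ratio
#' is -Inf, are floored at a configurable value with a warning.
#'
#' @param segments allele-specific or total-copy segment data frame with a
#'   \code{total_cn} column (sample, chrom, start, end, total_cn, ...).
#' @param floor_value log2 value substituted for zero-copy segments.
#' @return data frame (sample, chrom, start, end, seg_mean) with attribute
#'   \code{value_kind = "log2_ratio"}.
#' @export
integral_to_log2 <- function(segments, floor_value = -8) {
  if (!nrow(segments)) stop("empty profile")
  if (!"total_cn" %in% names(segments)) stop("no total_cn column")
  out <- lapply(split(segments, segments$sample), function(s) {
    len <- s$end - s$start + 1
    A <- sum(len * s$total_cn) / sum(len)
    if (A == 0) stop("degenerate input: all-zero copy number for sample ", s$sample[1])
    v <- log2(s$total_cn / A)
    if (any(s$total_cn == 0)) {
      warning(sprintf("sample %s: %d zero-copy segment(s) floored at %g",
                      s$sample[1], sum(s$total_cn == 0), floor_value))
      v[s$total_cn == 0] <- floor_value
    }
    data.frame(sample = s$sample, chrom = s$chrom, start = s$start,
               end = s$end, seg_mean = v, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "value_kind") <- "log2_ratio"
  res
}

#' Project segment values onto genes
#'
#' Each gene's value is the overlap-length-weighted mean of the segment
#' values intersecting it; genes with no overlapping segment are missing.
#'
#' @param segments log2-ratio segment data frame (sample, chrom, start,
#'   end, seg_mean).
#' @param genome a \code{genome_model} supplying gene coordinates, or a
#'   gene coordinate data frame (gene, chrom, start, end).
#' @return genes x samples numeric matrix, attribute \code{kind = "log2"}.
#' @export
segments_to_genes <- function(segments, genome) {
  genes <- if (inherits(genome, "genome_model")) genome$genes else genome
  if (!nrow(genes)) stop("empty genome")
  samples <- unique(segments$sample)
  mat <- matrix(NA_real_, nrow(genes), length(samples),
                dimnames = list(genes$gene, samples))
  seg_by <- split(segments, segments$sample)
  gene_by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  for (sid in samples) {
    ss <- seg_by[[sid]]
    for (c0 in intersect(names(gene_by_chrom), unique(ss$chrom))) {
      gi <- gene_by_chrom[[c0]]
      sc <- ss[ss$chrom == c0, , drop = FALSE]
      gs <- genes$start[gi]; ge <- genes$end[gi]
      wsum <- vsum <- numeric(length(gi))
      for (k in seq_len(nrow(sc))) {
        ov <- pmax(0, pmin(ge, sc$end[k]) - pmax(gs, sc$start[k]) + 1)
        wsum <- wsum + ov
        vsum <- vsum + ov * sc$seg_mean[k]
      }
      val <- ifelse(wsum > 0, vsum / wsum, NA_real_)
      mat[gi, sid] <- val
    }
  }
  attr(mat, "kind") <- "log2"
  mat
}

#' Discretize a log2 gene matrix into 5-valued GISTIC-like scores
#'
#' Maps each value v to +2 if v >= deep, +1 if shallow <= v < deep, -2 if
#' v <= -deep, -1 if -deep < v <= -shallow, and 0 otherwise (thresholds
#' inclusive). Missing values stay missing. The default thresholds are for
#' synthetic data; externally supplied GISTIC scores should be used as-is.
#'
#' @param mat genes x samples log2 matrix.
#' @param shallow_thresh,deep_thresh positive thresholds, shallow < deep.
#' @return integer matrix of scores in \{-2,-1,0,1,2\}, attribute
#'   \code{kind = "gistic5"}.
#' @export
discretize_gistic <- function(mat, shallow_thresh = 0.2, deep_thresh = 1.0) {
  if (!(shallow_thresh > 0 && shallow_thresh < deep_thresh)) {
    stop("need 0 < shallow_thresh < deep_thresh")
  }
  out <- mat
  out[] <- 0
  out[mat >= shallow_thresh] <- 1
  out[mat >= deep_thresh] <- 2
  out[mat <= -shallow_thresh] <- -1
  out[mat <= -deep_thresh] <- -2
  out[is.na(mat)] <- NA
  attr(out, "kind") <- "gistic5"
  out
}

#' Confidence-filter mutation records
#'
#' A record survives iff read depth >= \code{min_depth}, variant allele
#' fraction >= \code{min_vaf} (both inclusive) and its class is not in the
#' excluded set (by default the non-coding and silent classes: intronic,
#' UTR, flank, intergenic, silent, RNA). Filtering preserves record order
#' and is idempotent. A per-criterion audit of removed records is attached
#' as attribute \code{audit}.
#'
#' @param records mutation data frame (sample, gene, variant_class,
#'   protein_change, depth, vaf).
#' @param min_depth minimum read depth.
#' @param min_vaf minimum variant allele fraction.
#' @param excluded_classes variant classes to remove.
#' @return the surviving records, order preserved.
#' @export
filter_mutations <- function(records, min_depth = 15, min_vaf = 0.15,
                             excluded_classes = c("intronic", "UTR", "flank",
                                                  "intergenic", "silent", "RNA")) {
  if (!nrow(records)) {
    out <- records
    attr(out, "audit") <- list(n_in = 0L, fail_depth = 0L, fail_vaf = 0L,
                               fail_class = 0L, n_out = 0L)
    return(out)
  }
  fail_depth <- records$depth < min_depth
  fail_vaf <- records$vaf < min_vaf
  fail_class <- records$variant_class %in% excluded_classes
  keep <- !(fail_depth | fail_vaf | fail_class)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- list(n_in = nrow(records),
                             fail_depth = sum(fail_depth),
                             fail_vaf = sum(fail_vaf),
                             fail_class = sum(fail_class),
                             n_out = nrow(out))
  out
}

#' Restrict records or a gene matrix to a gene panel
#'
#' @param x a mutation record data frame (with a \code{gene} column) or a
#'   genes x samples matrix.
#' @param gene_list non-empty character vector of panel genes.
#' @param quiet suppress the intersection-size message.
#' @return object of the same type containing only panel genes; attribute
#'   \code{panel_intersection} records the intersection size.
#' @export
restrict_to_panel <- function(x, gene_list, quiet = TRUE) {
  if (!length(gene_list)) stop("gene_list must be non-empty")
  if (is.matrix(x)) {
    shared <- intersect(rownames(x), gene_list)
    out <- x[shared, , drop = FALSE]
    attr(out, "kind") <- attr(x, "kind")
  } else {
    keep <- x$gene %in% gene_list
    out <- x[keep, , drop = FALSE]
    rownames(out) <- NULL
    shared <- intersect(unique(x$gene), gene_list)
  }
  attr(out, "panel_intersection") <- length(shared)
  if (!quiet) message(sprintf("restrict_to_panel: %d genes in intersection",
                              length(shared)))
  out
}
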