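#' Fraction genome altered
#'
#' FGA for a segmented log2-ratio profile is the length-weighted fraction
#' of the profiled genome whose segment value exceeds the threshold in
#' absolute value: FGA = sum(L_i * 1[|CN_i| >= T]) / sum(L_i), with
#' segment length L_i = end - start + 1 and the threshold inclusive.
#'
#' @param segments log2-ratio segment data frame (sample, chrom, start,
#'   end, seg_mean), one or many samples.
#' @param threshold positive log2 threshold T (default 0.2; amplification
#'   at +T, deletion at -T).
#' @return data frame (sample, fga, threshold, total_length).
#' @export
fraction_genome_altered <- function(segments, threshold = 0.2) {
  if (!nrow(segments)) stop("degenerate input: empty profile")
  if (threshold <= 0) stop("threshold must be positive")
  out <- lapply(split(segments, segments$sample), function(s) {
    len <- s$end - s$start + 1
    data.frame(sample = s$sample[1],
               fga = sum(len[abs(s$seg_mean) >= threshold]) / sum(len),
               threshold = threshold, total_length = sum(len),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# clip segments of one sample to an arm interval; returns clipped df
clip_to_arm <- function(s, arm_row) {
  hit <- s$chrom == arm_row$chrom & s$end >= arm_row$start & s$start <= arm_row$end
  cs <- s[hit, , drop = FALSE]
  if (nrow(cs)) {
    cs$start <- pmax(cs$start, arm_row$start)
    cs$end <- pmin(cs$end, arm_row$end)
  }
  cs
}

#' Fraction of a chromosome arm lost (log2 view)
#'
#' The covered-length fraction of an arm whose segment value is at or
#' below the loss threshold. Segments are clipped to the arm; denominators
#' use covered (clipped) length, so uncovered regions carry no evidence.
#' A sample with no segment overlapping the arm is flagged indeterminate
#' (NA fraction) rather than reported as 0.
#'
#' @param segments log2-ratio segment data frame.
#' @param genome a \code{genome_model}.
#' @param arm arm id such as "3p".
#' @param loss_thresh inclusive log2 loss threshold (default -0.2).
#' @return data frame (sample, arm, loss_fraction, covered_length).
#' @export
arm_loss_fraction <- function(segments, genome, arm = "3p",
                              loss_thresh = -0.2) {
  a <- genome$arms[genome$arms$arm_id == arm, ]
  if (!nrow(a)) stop(sprintf("unknown arm '%s'", arm))
  out <- lapply(split(segments, segments$sample), function(s) {
    cs <- clip_to_arm(s, a)
    if (!nrow(cs)) {
      return(data.frame(sample = s$sample[1], arm = arm,
                        loss_fraction = NA_real_, covered_length = 0,
                        stringsAsFactors = FALSE))
    }
    len <- cs$end - cs$start + 1
    data.frame(sample = s$sample[1], arm = arm,
               loss_fraction = sum(len[cs$seg_mean <= loss_thresh]) / sum(len),
               covered_length = sum(len), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Minor-allele and ploidy-relative arm loss from allele-specific data
#'
#' Two loss estimators that total-copy log2 ratios cannot provide:
#' \itemize{
#'   \item \code{zero_minor_fraction}: covered-length fraction of the arm
#'     where the minor allele has copy number 0 (LOH) — detects losses
#'     masked by amplification of the remaining (major) allele.
#'   \item \code{relative_loss_fraction}: covered-length fraction where the
#'     total copy number is at least \code{relative_margin} below the
#'     sample's length-weighted genome-average copy number — detects arms
#'     that are diploid in absolute terms but lost relative to a
#'     hyperploid background.
#' }
#'
#' @param segments allele-specific data frame (sample, chrom, start, end,
#'   total_cn, minor_cn).
#' @param genome a \code{genome_model}.
#' @param arm arm id such as "3p".
#' @param relative_margin copy-number margin below the sample mean that
#'   counts as relative loss (default 0.5, separating integer states
#'   around a fractional mean).
#' @return data frame (sample, arm, zero_minor_fraction,
#'   relative_loss_fraction, sample_mean_total_cn, covered_length);
#'   fractions are NA (indeterminate) when the arm is uncovered.
#' @export
arm_loh_fraction <- function(segments, genome, arm = "3p",
                             relative_margin = 0.5) {
  a <- genome$arms[genome$arms$arm_id == arm, ]
  if (!nrow(a)) stop(sprintf("unknown arm '%s'", arm))
  out <- lapply(split(segments, segments$sample), function(s) {
    len_all <- s$end - s$start + 1
    mean_total <- sum(len_all * s$total_cn) / sum(len_all)
    cs <- clip_to_arm(s, a)
    if (!nrow(cs)) {
      return(data.frame(sample = s$sample[1], arm = arm,
                        zero_minor_fraction = NA_real_,
                        relative_loss_fraction = NA_real_,
                        sample_mean_total_cn = mean_total,
                        covered_length = 0, stringsAsFactors = FALSE))
    }
    len <- cs$end - cs$start + 1
    data.frame(sample = s$sample[1], arm = arm,
               zero_minor_fraction = sum(len[cs$minor_cn == 0]) / sum(len),
               relative_loss_fraction =
                 sum(len[cs$total_cn <= mean_total - relative_margin]) / sum(len),
               sample_mean_total_cn = mean_total,
               covered_length = sum(len), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Combine the log2 and minor-allele 3p loss estimators into one call
#'
#' Either-method rule: an arm is called \code{lost} if the maximum of the
#' available fractions reaches the cutoff, \code{negligible} if all
#' available fractions fall below it, and \code{indeterminate} if neither
#' estimator is available.
#'
#' @param log2_fraction,zero_minor_fraction numeric vectors (NA = missing),
#'   recycled to common length.
#' @param lost_cutoff fraction at or above which the arm counts as lost
#'   (default 0.8).
#' @return character vector of calls.
#' @export
combined_3p_call <- function(log2_fraction, zero_minor_fraction,
                             lost_cutoff = 0.8) {
  n <- max(length(log2_fraction), length(zero_minor_fraction))
  lf <- rep_len(log2_fraction, n)
  zf <- rep_len(zero_minor_fraction, n)
  vapply(seq_len(n), function(i) {
    avail <- c(lf[i], zf[i])
    avail <- avail[!is.na(avail)]
    if (!length(avail)) return("indeterminate")
    if (max(avail) >= lost_cutoff) "lost" else "negligible"
  }, character(1))
}
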