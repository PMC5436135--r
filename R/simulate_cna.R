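#' Simulate a segmented copy-number cohort with subtype structure
#'
#' Draws tumour and cell-line samples from arm-level subtype archetypes.
#' Each sample carries each archetype event with its stated penetrance as a
#' whole-arm (or whole-chromosome) segment of the stated log2 magnitude,
#' plus Poisson-distributed focal events of exponential length, plus
#' per-segment Gaussian noise. Cell lines receive an elevated alteration
#' burden — doubled penetrance of the archetype's secondary events and a
#' doubled focal-event rate — so that their fraction-genome-altered
#' distribution stochastically dominates the tumours'.
#'
#' Segments partition every chromosome exactly once per sample (no gaps,
#' no overlaps). RNG streams are split per sample via a deterministic hash,
#' so output is invariant to group ordering.
#'
#' @param genome a \code{genome_model}.
#' @param archetypes named list of archetypes (see [default_archetypes()]).
#' @param n_per_group tumours per archetype.
#' @param n_cell_lines_per_group cell lines per archetype.
#' @param segment_noise_sd Gaussian noise sd on per-segment log2 values.
#' @param seed integer seed.
#' @param focal_magnitude absolute log2 magnitude of focal events.
#' @param baseline_segments_per_arm number of baseline segments each arm is
#'   divided into (independent noise draws), emulating the granularity of
#'   array segmentation; arm-level events still span the whole arm.
#' @return list with \code{segments} (data frame: sample, chrom, start, end,
#'   seg_mean; attribute \code{value_kind = "log2_ratio"}) and \code{truth}
#'   (list: \code{samples} data frame with sample/group/is_cell_line,
#'   \code{events} per-sample applied-event tables, \code{mutated_genes}
#'   per-sample character vectors).
#' @export
simulate_cna_cohort <- function(genome, archetypes = default_archetypes(genome),
                                n_per_group = 100, n_cell_lines_per_group = 10,
                                segment_noise_sd = 0.1, seed = 1,
                                focal_magnitude = 0.8,
                                baseline_segments_per_arm = 5) {
  if (!length(archetypes)) stop("at least one archetype required")
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (segment_noise_sd < 0) stop("segment_noise_sd must be >= 0")
  for (a in archetypes) validate_archetype(a, genome)

  samples <- do.call(rbind, lapply(archetypes, function(a) {
    rbind(
      data.frame(sample = sprintf("T_%s_%03d", a$name, seq_len(n_per_group)),
                 group = a$name, is_cell_line = FALSE,
                 stringsAsFactors = FALSE),
      if (n_cell_lines_per_group > 0) {
        data.frame(sample = sprintf("CL_%s_%02d", a$name,
                                    seq_len(n_cell_lines_per_group)),
                   group = a$name, is_cell_line = TRUE,
                   stringsAsFactors = FALSE)
      }
    )
  }))
  rownames(samples) <- NULL

  seg_list <- vector("list", nrow(samples))
  event_list <- vector("list", nrow(samples))
  mut_list <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    arch <- archetypes[[s$group]]
    set.seed(hash_seed(s$sample, seed))
    drawn <- draw_sample_events(genome, arch, s$is_cell_line, focal_magnitude)
    seg <- events_to_segments(genome, drawn, segment_noise_sd,
                              baseline_segments_per_arm)
    seg$sample <- s$sample
    seg_list[[i]] <- seg[, c("sample", "chrom", "start", "end", "seg_mean")]
    event_list[[i]] <- drawn
    mu <- arch$mutation_rates
    mut_list[[i]] <- if (length(mu)) {
      names(mu)[stats::runif(length(mu)) < mu]
    } else character(0)
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  attr(segments, "value_kind") <- "log2_ratio"

  names(event_list) <- samples$sample
  names(mut_list) <- samples$sample
  list(segments = segments,
       truth = list(samples = samples, events = event_list,
                    mutated_genes = mut_list))
}

# Draw the realized event set for one sample (arm + focal); uses the
# current RNG stream. Secondary (non-defining) archetype events get doubled
# penetrance in cell lines; the focal rate is doubled too.
draw_sample_events <- function(genome, arch, is_cell_line, focal_magnitude) {
  ev <- arch$events
  pen <- ev$penetrance
  if (is_cell_line && nrow(ev) > 1) {
    pen[-1] <- pmin(1, 2 * pen[-1])
  }
  hit <- stats::runif(nrow(ev)) < pen
  applied <- ev[hit, , drop = FALSE]
  arm_rows <- if (nrow(applied)) {
    do.call(rbind, lapply(seq_len(nrow(applied)), function(k) {
      iv <- resolve_target(genome, applied$target[k])
      data.frame(kind = "arm", target = applied$target[k],
                 chrom = iv$chrom, start = iv$start, end = iv$end,
                 magnitude = applied$magnitude[k], stringsAsFactors = FALSE)
    }))
  }
  rate <- arch$focal_event_rate * if (is_cell_line) 2 else 1
  nf <- stats::rpois(1, rate)
  focal_rows <- if (nf > 0) {
    ch <- genome$chromosomes
    idx <- sample.int(nrow(ch), nf, replace = TRUE, prob = ch$length)
    do.call(rbind, lapply(seq_len(nf), function(k) {
      L <- ch$length[idx[k]]
      st <- ceiling(stats::runif(1) * (L - 1))
      w <- max(50, round(stats::rexp(1, rate = 1 / (0.03 * L))))
      en <- min(L, st + w - 1)
      data.frame(kind = "focal", target = ch$chrom[idx[k]],
                 chrom = ch$chrom[idx[k]], start = st, end = en,
                 magnitude = sample(c(-1, 1), 1) * focal_magnitude,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(arm_rows, focal_rows)
  if (is.null(out)) {
    out <- data.frame(kind = character(0), target = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), magnitude = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out
}

# Turn a sample's event table into segments partitioning every chromosome.
# Segment value = sum of overlapping event magnitudes + N(0, noise_sd).
# Arms are pre-divided into `baseline_k` equal baseline segments so that
# noise granularity resembles array segmentation output.
events_to_segments <- function(genome, events, noise_sd, baseline_k = 5) {
  arms <- genome$arms
  out <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    c0 <- genome$chromosomes$chrom[i]
    L <- genome$chromosomes$length[i]
    ev <- events[events$chrom == c0, , drop = FALSE]
    ar <- arms[arms$chrom == c0, , drop = FALSE]
    base_bp <- unlist(lapply(seq_len(nrow(ar)), function(k) {
      round(seq(ar$start[k], ar$end[k] + 1, length.out = baseline_k + 1))
    }))
    bp <- sort(unique(c(1, L + 1, base_bp, ev$start, ev$end + 1)))
    bp <- bp[bp >= 1 & bp <= L + 1]
    st <- bp[-length(bp)]
    en <- bp[-1] - 1
    mid <- (st + en) / 2
    val <- vapply(mid, function(m) {
      sum(ev$magnitude[ev$start <= m & ev$end >= m])
    }, numeric(1))
    if (noise_sd > 0) val <- val + stats::rnorm(length(val), 0, noise_sd)
    data.frame(chrom = c0, start = st, end = en, seg_mean = val,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate allele-specific integral copy-number profiles
#'
#' Produces PICNIC-style (total, minor) integer copy numbers, one segment
#' per chromosome arm, for named loss-of-heterozygosity scenarios:
#' \describe{
#'   \item{balanced_diploid}{(total 2, minor 1) everywhere.}
#'   \item{classic_loss}{3p at (total 1, minor 0); balanced elsewhere —
#'     a loss visible in both total and minor allele.}
#'   \item{masked_loss}{3p at (total 3, minor 0); balanced elsewhere. The
#'     minor allele is lost but the major allele's amplification hides the
#'     loss from the total-copy log2 view.}
#'   \item{ploidy_relative}{3p at (total 2, minor 1) in a hyperploid genome
#'     (length-weighted mean total copy number well above 2.5), so 3p is
#'     lost relative to the sample's average copy number although its
#'     absolute copy number is diploid.}
#' }
#' Custom scenarios supply per-arm (total, minor) pairs directly.
#'
#' @param genome a \code{genome_model}.
#' @param scenarios named list: each element is a scenario name string, or a
#'   list with \code{arms} (data frame: arm_id, total_cn, minor_cn) and
#'   optional \code{default_total}/\code{default_minor} for unlisted arms.
#'   Names are sample ids.
#' @param seed integer seed (scenarios are deterministic; the seed feeds
#'   only custom extensions).
#' @return data frame (sample, chrom, start, end, total_cn, minor_cn) with
#'   attribute \code{value_kind = "allele_specific"}.
#' @export
simulate_allele_specific <- function(genome, scenarios, seed = 1) {
  set.seed(as.integer(seed))
  arms <- genome$arms
  one <- function(sample_id, spec) {
    base <- data.frame(sample = sample_id, chrom = arms$chrom,
                       start = arms$start, end = arms$end,
                       arm_id = arms$arm_id,
                       total_cn = 2L, minor_cn = 1L,
                       stringsAsFactors = FALSE)
    if (is.character(spec) && length(spec) == 1) {
      if (spec == "balanced_diploid") {
        # defaults already balanced
      } else if (spec == "classic_loss") {
        on3p <- base$arm_id == "3p"
        base$total_cn[on3p] <- 1L; base$minor_cn[on3p] <- 0L
      } else if (spec == "masked_loss") {
        on3p <- base$arm_id == "3p"
        base$total_cn[on3p] <- 3L; base$minor_cn[on3p] <- 0L
      } else if (spec == "ploidy_relative") {
        # hyperploid background: arms cycle through totals 3,3,4 so the
        # genome mean lands near 3.2 while 3p stays at absolute total 2
        idx <- seq_len(nrow(base))
        base$total_cn <- 3L + as.integer(idx %% 3 == 0)
        base$minor_cn <- 1L
        on3p <- base$arm_id == "3p"
        base$total_cn[on3p] <- 2L; base$minor_cn[on3p] <- 1L
      } else {
        stop(sprintf("unknown scenario '%s'", spec))
      }
    } else if (is.list(spec)) {
      if (!is.null(spec$default_total)) base$total_cn <- as.integer(spec$default_total)
      if (!is.null(spec$default_minor)) base$minor_cn <- as.integer(spec$default_minor)
      if (!is.null(spec$arms)) {
        for (k in seq_len(nrow(spec$arms))) {
          row <- spec$arms[k, ]
          hit <- base$arm_id == row$arm_id
          if (!any(hit)) stop(sprintf("unknown arm '%s'", row$arm_id))
          base$total_cn[hit] <- as.integer(row$total_cn)
          base$minor_cn[hit] <- as.integer(row$minor_cn)
        }
      }
    } else {
      stop("scenario must be a name string or a list spec")
    }
    if (any(base$minor_cn > base$total_cn)) stop("minor_cn > total_cn")
    if (any(base$minor_cn < 0 | base$total_cn < 0)) {
      stop("copy numbers must be non-negative")
    }
    base$arm_id <- NULL
    base
  }
  out <- do.call(rbind, Map(one, names(scenarios), scenarios))
  rownames(out) <- NULL
  attr(out, "value_kind") <- "allele_specific"
  out
}
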