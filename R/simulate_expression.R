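#' Simulate two-class expression data with batch effects
#'
#' Generates a genes x samples log2-scale expression matrix with the
#' structure the ccA/ccB centroid classifier assumes: per-gene baseline
#' abundances (heterogeneous across genes, as in real microarray data —
#' this baseline is what makes centroid correlations of all samples high
#' and the between-class correlation margin small), a two-class effect of
#' size \code{class_effect_size} confined to \code{n_marker_genes} marker
#' genes (half up in ccA, half down), intermediate samples sitting at the
#' class midpoint, and per-batch location/scale effects applied on top.
#'
#' @param gene_list character vector of gene ids (non-empty).
#' @param n_per_class samples per class (ccA and ccB).
#' @param n_intermediate samples at the class midpoint.
#' @param class_effect_size mean log2 separation between classes on markers.
#' @param n_marker_genes number of marker genes (<= length(gene_list)).
#' @param batch_assignment either the number of batches (samples assigned
#'   round-robin, so batches are class-balanced) or an integer vector of
#'   batch labels, one per sample.
#' @param batch_shift mean location offset added per extra batch; per-gene
#'   offsets are jittered around it (exact zero when \code{batch_shift = 0}).
#' @param batch_scale variance inflation factor per extra batch (> 0).
#' @param noise_sd residual Gaussian noise sd.
#' @param baseline_sd sd of per-gene baseline means (log2 units).
#' @param seed integer seed.
#' @return list with \code{expr} (genes x samples matrix, attribute
#'   \code{kind = "expression"}) and \code{truth} (list: \code{samples}
#'   data frame with sample/class/batch, \code{markers} marker gene ids,
#'   \code{marker_direction} named +1/-1 vector of the ccA direction).
#' @export
simulate_expression <- function(gene_list, n_per_class = 100,
                                n_intermediate = 40, class_effect_size = 2,
                                n_marker_genes = 200, batch_assignment = 2,
                                batch_shift = 1, batch_scale = 1.2,
                                noise_sd = 0.5, baseline_sd = 3, seed = 1) {
  if (!length(gene_list)) stop("gene_list must be non-empty")
  if (n_marker_genes > length(gene_list)) {
    stop("n_marker_genes exceeds gene list size")
  }
  if (batch_scale <= 0 || noise_sd < 0) stop("scales must be positive")
  set.seed(as.integer(seed))

  G <- length(gene_list)
  # interleave classes so round-robin batches are class-balanced
  cls <- c(rep(c("ccA", "ccB"), n_per_class),
           rep("intermediate", n_intermediate))
  ids <- c(sprintf("S_%s_%03d", rep(c("ccA", "ccB"), n_per_class),
                   rep(seq_len(n_per_class), each = 2)),
           if (n_intermediate > 0) sprintf("S_int_%03d", seq_len(n_intermediate)))
  n <- length(ids)
  batch <- if (length(batch_assignment) == 1) {
    # round-robin within class, so batches are class-balanced (never
    # confounded with class regardless of sample ordering)
    b <- integer(n)
    for (lv in unique(cls)) {
      i <- which(cls == lv)
      b[i] <- rep_len(seq_len(as.integer(batch_assignment)), length(i))
    }
    b
  } else {
    if (length(batch_assignment) != n) stop("batch_assignment length mismatch")
    as.integer(batch_assignment)
  }

  baseline <- stats::rnorm(G, 7, baseline_sd)
  markers <- gene_list[seq_len(n_marker_genes)]
  direction <- stats::setNames(rep_len(c(1, -1), n_marker_genes), markers)
  class_shift <- matrix(0, G, n)
  mi <- seq_len(n_marker_genes)
  half <- class_effect_size / 2
  class_shift[mi, cls == "ccA"] <- direction * half
  class_shift[mi, cls == "ccB"] <- -direction * half

  batches <- sort(unique(batch))
  gamma <- matrix(0, G, n)
  sdmat <- matrix(noise_sd, G, n)
  for (b in batches) {
    inb <- batch == b
    off <- batch_shift * (match(b, batches) - 1)
    g_b <- if (off != 0) stats::rnorm(G, off, 0.1 * abs(batch_shift)) else rep(0, G)
    gamma[, inb] <- g_b
    sdmat[, inb] <- noise_sd * sqrt(batch_scale^(match(b, batches) - 1))
  }

  eps <- matrix(stats::rnorm(G * n), G, n) * sdmat
  expr <- baseline + class_shift + gamma + eps
  dimnames(expr) <- list(gene_list, ids)
  attr(expr, "kind") <- "expression"

  list(expr = expr,
       truth = list(samples = data.frame(sample = ids, class = cls,
                                         batch = batch,
                                         stringsAsFactors = FALSE),
                    markers = markers, marker_direction = direction))
}

#' Simulate stage/grade covariates tied to copy-number burden
#'
#' Tumour stage and grade are drawn so the probability of advanced disease
#' (stage 3/4, grade G3/G4) increases monotonically with the sample's
#' fraction genome altered (FGA) through a logistic link centred at the
#' cohort mean FGA.
#'
#' @param truth truth component of [simulate_cna_cohort()]; only tumour
#'   samples receive covariates.
#' @param fga_values named numeric vector of FGA per tumour sample.
#' @param stage_logit_slope,grade_logit_slope logistic slopes on centred FGA.
#' @param base_stage_high,base_grade_high baseline advanced-disease rates.
#' @param seed integer seed.
#' @return data frame (sample, stage in 1..4, grade in "G1".."G4").
#' @export
simulate_clinical <- function(truth, fga_values, stage_logit_slope = 8,
                              grade_logit_slope = 6, base_stage_high = 0.45,
                              base_grade_high = 0.5, seed = 1) {
  tum <- truth$samples$sample[!truth$samples$is_cell_line]
  missing <- setdiff(tum, names(fga_values))
  if (length(missing)) {
    stop("missing FGA for samples: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  fga <- fga_values[tum]
  ctr <- fga - mean(fga)
  rows <- lapply(seq_along(tum), function(i) {
    set.seed(hash_seed(paste0("clin:", tum[i]), seed))
    p_s <- stats::plogis(stats::qlogis(base_stage_high) + stage_logit_slope * ctr[i])
    p_g <- stats::plogis(stats::qlogis(base_grade_high) + grade_logit_slope * ctr[i])
    stage <- if (stats::runif(1) < p_s) sample(3:4, 1) else sample(1:2, 1)
    grade <- if (stats::runif(1) < p_g) sample(3:4, 1) else sample(1:2, 1)
    data.frame(sample = tum[i], stage = stage,
               grade = paste0("G", grade), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
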