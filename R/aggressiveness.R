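#' Split tumours by whether they co-cluster with cell lines
#'
#' Identifies the cluster holding the most cell lines (the dominant
#' cell-line cluster) and any other cluster that mixes tumours with cell
#' lines from it, then splits the focal tumours into those sharing a
#' cluster with those cell lines (\code{with_group}) and the rest
#' (\code{away_group}).
#'
#' @param cut a \code{cluster_cut} over tumours and cell lines together.
#' @param tumour_ids ids of the tumours to split (e.g. the ccRCC tumours).
#' @param cell_line_ids ids of the cell lines.
#' @return list with \code{with_group}, \code{away_group} and
#'   \code{dominant_cluster}.
#' @export
split_by_coclustering <- function(cut, tumour_ids, cell_line_ids) {
  labels <- cut$labels
  cl_clusters <- labels[intersect(names(labels), cell_line_ids)]
  tum_clusters <- labels[intersect(names(labels), tumour_ids)]
  mixed <- intersect(unique(cl_clusters), unique(tum_clusters))
  if (!length(mixed)) {
    stop("no cluster contains both tumours and cell lines; ",
         "consider the quartile-based split instead")
  }
  dom <- as.integer(names(sort(table(cl_clusters), decreasing = TRUE))[1])
  if (!dom %in% tum_clusters) {
    dom <- mixed[which.max(vapply(mixed, function(k) sum(cl_clusters == k),
                                  numeric(1)))]
  }
  with_group <- names(tum_clusters)[tum_clusters == dom]
  away_group <- setdiff(names(tum_clusters), with_group)
  list(with_group = with_group, away_group = away_group,
       dominant_cluster = dom)
}

#' Split tumours into top and bottom quartiles of cell-line similarity
#'
#' Ranks tumours by their mean correlation with all cell lines and returns
#' the top and bottom 25\% (quartile size floor(n/4); ties resolved by
#' stable input order, flagged when present).
#'
#' @param sim tumours x cell-lines similarity matrix.
#' @return list with \code{top_quartile}, \code{bottom_quartile},
#'   \code{mean_similarity} (named vector) and \code{tie_degenerate} flag.
#' @export
split_by_quartile <- function(sim) {
  n <- nrow(sim)
  if (n < 8) stop("need at least 8 tumours for a quartile split")
  m <- rowMeans(sim, na.rm = TRUE)
  k <- floor(n / 4)
  ord <- order(-m)  # stable for ties: preserves input order
  list(top_quartile = rownames(sim)[ord[seq_len(k)]],
       bottom_quartile = rownames(sim)[rev(ord)[seq_len(k)]],
       mean_similarity = m,
       tie_degenerate = anyDuplicated(m) > 0)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities no
#' larger than that of the observed table; the reported odds ratio is the
#' conditional maximum-likelihood estimate. A table with a zero margin is
#' degenerate: p = 1 with a flag.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with \code{odds_ratio}, \code{p_value},
#'   \code{or_type = "conditional_mle"} and \code{zero_margin} flag.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1,
                or_type = "conditional_mle", zero_margin = TRUE))
  }
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       or_type = "conditional_mle", zero_margin = FALSE)
}

#' Compare two tumour groups on stage, grade, FGA and panel-gene mutations
#'
#' Builds 2x2 tables for advanced stage (1-2 vs 3-4) and grade (G1-2 vs
#' G3-4), a 2x2 mutated-vs-not table per panel gene, Fisher's exact test
#' for each, and group FGA summaries. Gene p-values are reported
#' unadjusted for multiplicity, as flagged in the output.
#'
#' @param group_a,group_b character vectors of sample ids.
#' @param clinical data frame (sample, stage, grade).
#' @param mutation_profiles named list of mutated-gene sets
#'   (see [binarize_mutations()]).
#' @param fga_results data frame from [fraction_genome_altered()].
#' @param gene_panel genes to test for differential mutation frequency.
#' @return object of class \code{group_comparison}: stage/grade tests,
#'   per-gene table, FGA summaries, group sizes.
#' @export
compare_groups <- function(group_a, group_b, clinical, mutation_profiles,
                           fga_results, gene_panel = character(0)) {
  fga <- stats::setNames(fga_results$fga, fga_results$sample)
  covered <- intersect(c(group_a, group_b),
                       intersect(clinical$sample, names(fga)))
  miss <- setdiff(c(group_a, group_b), covered)
  if (length(miss)) {
    warning("excluding samples with missing covariates: ",
            paste(utils::head(miss, 5), collapse = ", "))
    group_a <- intersect(group_a, covered)
    group_b <- intersect(group_b, covered)
  }
  cl <- clinical[match(c(group_a, group_b), clinical$sample), ]
  in_a <- cl$sample %in% group_a

  tab2 <- function(high) {
    m <- rbind(a = c(sum(!high[in_a]), sum(high[in_a])),
               b = c(sum(!high[!in_a]), sum(high[!in_a])))
    colnames(m) <- c("low", "high")
    m
  }
  stage_tab <- tab2(cl$stage >= 3)
  grade_num <- as.integer(sub("^G", "", cl$grade))
  grade_tab <- tab2(grade_num >= 3)

  gene_rows <- lapply(gene_panel, function(g) {
    mut <- vapply(cl$sample, function(s) {
      g %in% mutation_profiles[[s]]
    }, logical(1))
    m <- rbind(c(sum(mut[in_a]), sum(!mut[in_a])),
               c(sum(mut[!in_a]), sum(!mut[!in_a])))
    ft <- fisher_exact_2x2(m)
    data.frame(gene = g,
               freq_a = mean(mut[in_a]), freq_b = mean(mut[!in_a]),
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               significant_unadjusted = ft$p_value < 0.05,
               stringsAsFactors = FALSE)
  })
  gene_table <- if (length(gene_rows)) do.call(rbind, gene_rows)

  fs <- fisher_exact_2x2(stage_tab)
  fg <- fisher_exact_2x2(grade_tab)
  structure(list(
    n_a = length(group_a), n_b = length(group_b),
    stage_table = stage_tab, stage_test = fs,
    grade_table = grade_tab, grade_test = fg,
    fga = data.frame(group = c("a", "b"),
                     mean = c(mean(fga[group_a]), mean(fga[group_b])),
                     median = c(stats::median(fga[group_a]),
                                stats::median(fga[group_b]))),
    gene_table = gene_table,
    p_values_adjusted = FALSE
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: n = %d vs %d\n", x$n_a, x$n_b))
  cat(sprintf("  stage 3/4: p = %.4g; grade G3/G4: p = %.4g\n",
              x$stage_test$p_value, x$grade_test$p_value))
  cat(sprintf("  mean FGA: %.3f vs %.3f\n", x$fga$mean[1], x$fga$mean[2]))
  if (!is.null(x$gene_table)) {
    cat(sprintf("  %d panel gene(s) tested (p-values unadjusted)\n",
                nrow(x$gene_table)))
  }
  invisible(x)
}
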