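#' Collapse mutation records into per-sample binary profiles
#'
#' A gene belongs to a sample's profile iff at least one (already filtered)
#' record survives for that sample; genes outside the declared universe are
#' dropped.
#'
#' @param records filtered mutation records.
#' @param gene_universe character vector of genes the profiles live over.
#' @param samples optional sample ids to include (defaults to the samples
#'   present in the records); samples with no records get empty sets.
#' @return named list of character vectors (mutated gene sets), with
#'   attribute \code{gene_universe}.
#' @export
binarize_mutations <- function(records, gene_universe,
                               samples = unique(records$sample)) {
  recs <- records[records$gene %in% gene_universe, , drop = FALSE]
  sets <- lapply(stats::setNames(samples, samples), function(s) {
    sort(unique(recs$gene[recs$sample == s]))
  })
  attr(sets, "gene_universe") <- gene_universe
  sets
}

#' Jaccard similarity of two gene sets
#'
#' |A intersect B| / |A union B|. Two empty sets are defined to have
#' similarity 0 (an all-empty pair carries no evidence of similarity);
#' the result then carries attribute \code{both_empty = TRUE}.
#'
#' @param a,b character vectors (sets).
#' @return numeric in [0,1].
#' @export
jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) {
    return(structure(0, both_empty = TRUE))
  }
  length(intersect(a, b)) / length(u)
}

#' Pairwise Jaccard similarity matrix between two profile lists
#' @param profiles_a,profiles_b named lists of gene sets.
#' @return |A| x |B| matrix, attribute \code{metric = "jaccard"}.
#' @export
jaccard_matrix <- function(profiles_a, profiles_b) {
  m <- matrix(NA_real_, length(profiles_a), length(profiles_b),
              dimnames = list(names(profiles_a), names(profiles_b)))
  for (i in seq_along(profiles_a)) {
    for (j in seq_along(profiles_b)) {
      m[i, j] <- jaccard(profiles_a[[i]], profiles_b[[j]])
    }
  }
  attr(m, "metric") <- "jaccard"
  m
}

#' Cross-dataset sample-sample correlation matrix
#'
#' Correlates every sample of one matrix with every sample of another over
#' their shared genes, excluding missing values pairwise. Pairs with fewer
#' than \code{min_features} shared non-missing genes, or with a
#' zero-variance vector, are flagged missing (NA) rather than propagating
#' NaN.
#'
#' @param mat_a,mat_b genes x samples matrices (shared gene ids matched by
#'   row name).
#' @param method "pearson" or "spearman" (ties get average ranks).
#' @param min_features minimum shared non-missing genes per pair.
#' @return samples_a x samples_b matrix, attribute \code{metric}.
#' @export
profile_correlation <- function(mat_a, mat_b,
                                method = c("pearson", "spearman"),
                                min_features = 3) {
  method <- match.arg(method)
  shared <- intersect(rownames(mat_a), rownames(mat_b))
  if (length(shared) < min_features) stop("fewer than min_features shared genes")
  a <- mat_a[shared, , drop = FALSE]
  b <- mat_b[shared, , drop = FALSE]
  r <- suppressWarnings(stats::cor(a, b, use = "pairwise.complete.obs",
                                   method = method))
  nshared <- crossprod(!is.na(a), !is.na(b))
  r[nshared < min_features] <- NA
  r[is.nan(r)] <- NA
  attr(r, "metric") <- method
  r
}

#' Compare matched-pair similarity against the unmatched background
#'
#' For each declared matched pair (a sample in the rows matched to one in
#' the columns), reports the matched similarity, the mean similarity to all
#' unmatched columns, and the rank of the matched value within its row
#' (descending; ties as average ranks). Also reports the fraction of
#' matched pairs ranked first in their row.
#'
#' @param sim similarity matrix (rows source A, columns source B).
#' @param pairs data frame with columns \code{row} and \code{col} naming
#'   matched samples.
#' @return list with \code{table} (per-pair summary) and
#'   \code{fraction_first}.
#' @export
matched_vs_unmatched <- function(sim, pairs) {
  if (!all(pairs$row %in% rownames(sim)) || !all(pairs$col %in% colnames(sim))) {
    stop("matched pair absent from similarity matrix")
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- pairs$row[i]; c0 <- pairs$col[i]
    v <- sim[r, ]
    rk <- rank(-v, ties.method = "average", na.last = "keep")
    data.frame(row = r, col = c0, matched = sim[r, c0],
               mean_unmatched = mean(v[setdiff(names(v), c0)], na.rm = TRUE),
               rank = unname(rk[c0]), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, fraction_first = mean(tab$rank == 1))
}
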