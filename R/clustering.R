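#' Hierarchically cluster copy-number profiles
#'
#' Agglomerative clustering of samples on gene-level copy number using
#' (1 - Spearman correlation) as the distance and average inter-cluster
#' linkage. Correlations use pairwise-complete observations; samples with
#' all-missing values are excluded with a warning.
#'
#' @param mat genes x samples numeric matrix (tumours and cell lines
#'   together).
#' @param min_shared minimum shared non-missing genes required per pair.
#' @return an \code{hclust} tree.
#' @export
cluster_profiles <- function(mat, min_shared = 3) {
  if (ncol(mat) < 2) stop("need at least 2 samples")
  allna <- colSums(!is.na(mat)) == 0
  if (any(allna)) {
    warning("excluding sample(s) with all-missing genes: ",
            paste(colnames(mat)[allna], collapse = ", "))
    mat <- mat[, !allna, drop = FALSE]
  }
  nshared <- crossprod(!is.na(mat))
  if (any(nshared < min_shared)) {
    stop("a sample pair shares fewer than min_shared non-missing genes")
  }
  rho <- stats::cor(mat, method = "spearman", use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - rho)
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram and summarize cluster composition
#'
#' Clusters are the connected components obtained by severing all merges
#' above height \code{h} (merges at exactly \code{h} are kept). The
#' composition table cross-tabulates clusters against supplied group
#' labels (e.g. tumour subtype or cell-line source).
#'
#' @param tree an \code{hclust} tree.
#' @param h cut height (default 0.9).
#' @param group_labels named character vector, one label per sample.
#' @return object of class \code{cluster_cut}: list with \code{tree},
#'   \code{h}, \code{labels} (named integer cluster ids) and
#'   \code{composition} (cluster x group table).
#' @export
cut_and_summarize <- function(tree, h = 0.9, group_labels = NULL) {
  if (h < 0) stop("h must be >= 0")
  labels <- stats::cutree(tree, h = h)
  composition <- if (!is.null(group_labels)) {
    table(cluster = labels, group = group_labels[names(labels)])
  }
  structure(list(tree = tree, h = h, labels = labels,
                 composition = composition),
            class = "cluster_cut")
}

#' @export
print.cluster_cut <- function(x, ...) {
  cat(sprintf("cluster_cut: %d samples, %d clusters at h = %g\n",
              length(x$labels), length(unique(x$labels)), x$h))
  if (!is.null(x$composition)) print(x$composition)
  invisible(x)
}

#' Call a subtype for each cell line from its co-clustering neighbourhood
#'
#' A cell line inherits the majority tumour subtype of its cluster,
#' provided the cluster contains at least \code{min_tumours} tumours; a
#' cell line in a cluster with fewer tumours, or with a tied majority, is
#' an \code{outlier} (the behaviour of lines that cluster on their own).
#'
#' @param cut a \code{cluster_cut}.
#' @param tumour_subtypes named character vector of subtype labels for the
#'   tumour samples; samples absent from it are treated as cell lines.
#' @param min_tumours minimum tumours a cluster needs to vote.
#' @return data frame (cell_line, cluster, call) where call is a subtype
#'   label or "outlier".
#' @export
assign_cell_line_subtype <- function(cut, tumour_subtypes, min_tumours = 5) {
  labels <- cut$labels
  cell_lines <- setdiff(names(labels), names(tumour_subtypes))
  rows <- lapply(cell_lines, function(cl) {
    k <- labels[[cl]]
    members <- names(labels)[labels == k]
    tum <- intersect(members, names(tumour_subtypes))
    call <- "outlier"
    if (length(tum) >= min_tumours) {
      counts <- sort(table(tumour_subtypes[tum]), decreasing = TRUE)
      if (length(counts) == 1 || counts[1] > counts[2]) {
        call <- names(counts)[1]
      }
    }
    data.frame(cell_line = cl, cluster = k, call = call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a dendrogram as a Newick tree with branch heights
#' @param tree an \code{hclust} tree.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
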