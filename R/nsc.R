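#' Train a nearest-shrunken-centroid classifier
#'
#' For classes k and genes j with class centroids xbar_kj, overall centroid
#' xbar_j, pooled within-class standard deviation s_j, fudge constant
#' s0 = median(s_j) and class-size normalizer m_k, the standardized
#' centroid difference is d_kj = (xbar_kj - xbar_j) / (m_k (s_j + s0)).
#' Soft-thresholding at Delta gives d'_kj = sign(d_kj)(|d_kj| - Delta)+ and
#' shrunken centroids xbar'_kj = xbar_j + m_k (s_j + s0) d'_kj; genes whose
#' d'_kj vanish for every class drop out of the classifier. Cross-validated
#' per-class error is computed for every Delta on a grid using seeded,
#' class-stratified folds.
#'
#' @param mat genes x samples training matrix.
#' @param labels class labels, one per sample (exactly 2 classes).
#' @param threshold_grid increasing vector of shrinkage thresholds.
#' @param folds cross-validation folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param m_formula "minus" for m_k = sqrt(1/n_k - 1/n) (the exact standard
#'   error of centroid minus grand mean under equal variance) or "plus"
#'   for the sqrt(1/n_k + 1/n) variant used by some implementations.
#' @param priors class prior probabilities (default uniform).
#' @return object of class \code{nsc_model}: centroid statistics, the CV
#'   error table (\code{cv}), the selected threshold (\code{delta}, via
#'   [select_threshold()]) and the surviving genes at that threshold.
#' @export
train_nsc <- function(mat, labels, threshold_grid = seq(0, 6, by = 0.5),
                      folds = 10, seed = 1,
                      m_formula = c("minus", "plus"), priors = NULL) {
  m_formula <- match.arg(m_formula)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly 2 classes required")
  if (!length(threshold_grid)) stop("threshold grid must be non-empty")
  if (any(table(labels) < folds)) {
    stop("every class needs at least `folds` samples")
  }
  if (is.null(priors)) priors <- rep(1 / nlevels(labels), nlevels(labels))

  fit <- nsc_fit(mat, labels, m_formula, priors)

  set.seed(as.integer(seed))
  fold_of <- integer(ncol(mat))
  for (lv in levels(labels)) {
    i <- which(labels == lv)
    fold_of[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  err <- matrix(0, length(threshold_grid), nlevels(labels),
                dimnames = list(NULL, levels(labels)))
  cnt <- table(labels)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    sub <- nsc_fit(mat[, tr, drop = FALSE], droplevels(labels[tr]),
                   m_formula, priors)
    pred <- vapply(threshold_grid, function(d) {
      nsc_predict(sub, mat[, !tr, drop = FALSE], d)
    }, character(sum(!tr)))
    truth <- as.character(labels[!tr])
    for (ti in seq_along(threshold_grid)) {
      wrong <- pred[, ti] != truth
      for (lv in levels(labels)) {
        err[ti, lv] <- err[ti, lv] + sum(wrong[truth == lv])
      }
    }
  }
  cv <- data.frame(threshold = threshold_grid,
                   n_genes = vapply(threshold_grid, function(d) {
                     length(nsc_surviving(fit, d))
                   }, integer(1)))
  for (lv in levels(labels)) cv[[paste0("err_", lv)]] <- err[, lv] / cnt[[lv]]
  cv$err_mean <- rowMeans(err %*% diag(1 / as.numeric(cnt)))

  fit$cv <- cv
  fit$delta <- select_threshold(cv)
  fit$surviving <- nsc_surviving(fit, fit$delta)
  class(fit) <- "nsc_model"
  fit
}

# core centroid statistics; shared by training and CV refits
nsc_fit <- function(mat, labels, m_formula, priors) {
  classes <- levels(labels)
  n <- ncol(mat)
  n_k <- table(labels)
  centroids <- vapply(classes, function(k) {
    rowMeans(mat[, labels == k, drop = FALSE])
  }, numeric(nrow(mat)))
  overall <- rowMeans(mat)
  ss <- 0
  for (k in classes) {
    ss <- ss + rowSums((mat[, labels == k, drop = FALSE] - centroids[, k])^2)
  }
  s_j <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(s_j)
  m_k <- if (m_formula == "minus") {
    sqrt(1 / as.numeric(n_k) - 1 / n)
  } else {
    sqrt(1 / as.numeric(n_k) + 1 / n)
  }
  names(m_k) <- classes
  d_kj <- vapply(classes, function(k) {
    (centroids[, k] - overall) / (m_k[k] * (s_j + s0))
  }, numeric(nrow(mat)))
  list(classes = classes, centroids = centroids, overall = overall,
       s_j = s_j, s0 = s0, m_k = m_k, d_kj = d_kj, priors = priors,
       genes = rownames(mat), m_formula = m_formula)
}

# soft-thresholded statistics at a given Delta
nsc_shrink <- function(fit, delta) {
  d <- fit$d_kj
  dprime <- sign(d) * pmax(abs(d) - delta, 0)
  shrunk <- fit$overall +
    sweep(dprime, 2, fit$m_k, "*") * (fit$s_j + fit$s0)
  list(dprime = dprime, shrunken_centroids = shrunk,
       surviving = which(rowSums(dprime != 0) > 0))
}

nsc_surviving <- function(fit, delta) {
  nsc_shrink(fit, delta)$surviving
}

# discriminant-score prediction (diagonal-covariance); degenerates to the
# prior-preferred class when no gene survives
nsc_predict <- function(fit, newmat, delta) {
  sh <- nsc_shrink(fit, delta)
  j <- sh$surviving
  if (!length(j)) {
    return(rep(fit$classes[which.max(fit$priors)], ncol(newmat)))
  }
  scores <- vapply(seq_along(fit$classes), function(ki) {
    colSums((newmat[j, , drop = FALSE] - sh$shrunken_centroids[j, ki])^2 /
              (fit$s_j[j] + fit$s0)^2) - 2 * log(fit$priors[ki])
  }, numeric(ncol(newmat)))
  scores <- matrix(scores, ncol = length(fit$classes))
  fit$classes[max.col(-scores, ties.method = "first")]
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf("nsc_model: classes %s; delta = %g, %d surviving genes\n",
              paste(x$classes, collapse = "/"), x$delta,
              length(x$surviving)))
  invisible(x)
}

#' Pick the shrinkage threshold from a cross-validation table
#'
#' Minimizes the mean per-class CV error; exact ties are broken toward the
#' larger threshold (fewer genes).
#'
#' @param cv_table data frame with columns \code{threshold} and
#'   \code{err_mean} (as produced by [train_nsc()]).
#' @return the selected threshold.
#' @export
select_threshold <- function(cv_table) {
  if (!nrow(cv_table)) stop("empty CV table")
  best <- which(cv_table$err_mean == min(cv_table$err_mean))
  cv_table$threshold[best[which.max(cv_table$threshold[best])]]
}

#' Call subtypes by correlation with shrunken centroids under a margin rule
#'
#' Each sample's Spearman correlation with both class centroids is
#' computed over the genes surviving shrinkage at \code{delta}; the sample
#' is called for the class whose correlation exceeds the other's by at
#' least \code{margin} (inclusive), and left \code{unclassified} when the
#' correlations differ by less than the margin. Samples usable on fewer
#' than 3 surviving genes are unclassified with a flag.
#'
#' @param model an \code{nsc_model}.
#' @param mat genes x samples matrix of new samples (missing genes are
#'   dropped pairwise).
#' @param margin correlation margin (default 0.05).
#' @param delta shrinkage threshold (default: the model's selected one).
#' @param use_shrunken correlate against shrunken centroids (default) or
#'   raw class means over the surviving genes.
#' @return data frame (sample, corr_A, corr_B named by class, call,
#'   margin, flag).
#' @export
classify_margin <- function(model, mat, margin = 0.05, delta = model$delta,
                            use_shrunken = TRUE) {
  sh <- nsc_shrink(model, delta)
  j <- sh$surviving
  genes <- model$genes[j]
  cent <- if (use_shrunken) sh$shrunken_centroids[j, , drop = FALSE] else
    model$centroids[j, , drop = FALSE]
  rownames(cent) <- genes
  usable <- intersect(genes, rownames(mat))
  cls <- model$classes
  rows <- lapply(seq_len(ncol(mat)), function(i) {
    x <- mat[usable, i]
    keep <- !is.na(x)
    flag <- ""
    if (sum(keep) < 3) {
      return(data.frame(sample = colnames(mat)[i], corr_a = NA_real_,
                        corr_b = NA_real_, call = "unclassified",
                        margin = NA_real_, flag = "too_few_genes",
                        stringsAsFactors = FALSE))
    }
    ca <- stats::cor(x[keep], cent[usable[keep], 1], method = "spearman")
    cb <- stats::cor(x[keep], cent[usable[keep], 2], method = "spearman")
    call <- if (is.na(ca) || is.na(cb)) "unclassified"
    else if (ca - cb >= margin) cls[1]
    else if (cb - ca >= margin) cls[2]
    else "unclassified"
    data.frame(sample = colnames(mat)[i], corr_a = ca, corr_b = cb,
               call = call, margin = abs(ca - cb), flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("corr_", cls)
  rownames(out) <- NULL
  out
}

#' Serialize an NSC model to JSON
#' @param model an \code{nsc_model}.
#' @param path output path.
#' @export
write_nsc_json <- function(model, path) {
  sh <- nsc_shrink(model, model$delta)
  obj <- list(classes = model$classes, delta = model$delta,
              s0 = model$s0, m_formula = model$m_formula,
              genes = model$genes[model$surviving],
              shrunken_centroids = sh$shrunken_centroids[model$surviving, ,
                                                         drop = FALSE])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
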