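# Independent brute-force oracles used to check the fast implementations.
# These deliberately enumerate per base pair / per table and share no code
# with the package internals.

# tiny genome for per-bp enumeration (chromosomes of a few kb)
tiny_genome <- function(seed = 1, n_chromosomes = 6, genes_per_arm = 3) {
  make_genome(n_chromosomes = n_chromosomes, genes_per_arm = genes_per_arm,
              scale = 1e-5, seed = seed)
}

# random segment profile partitioning each chromosome of a genome
random_profile <- function(genome, sample_id = "S1", max_breaks = 4) {
  segs <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    L <- genome$chromosomes$length[i]
    nb <- sample(0:max_breaks, 1)
    bp <- sort(unique(c(1, L + 1, sample(2:L, nb))))
    data.frame(sample = sample_id,
               chrom = genome$chromosomes$chrom[i],
               start = bp[-length(bp)], end = bp[-1] - 1,
               seg_mean = round(stats::rnorm(length(bp) - 1, 0, 0.5), 3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}

# expand a profile to one value per base pair (list per chromosome)
per_bp_values <- function(segs, genome) {
  vals <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    c0 <- genome$chromosomes$chrom[i]
    L <- genome$chromosomes$length[i]
    v <- rep(NA_real_, L)
    s <- segs[segs$chrom == c0, , drop = FALSE]
    for (k in seq_len(nrow(s))) v[s$start[k]:s$end[k]] <- s$seg_mean[k]
    v
  })
  names(vals) <- genome$chromosomes$chrom
  vals
}

# FGA by per-bp counting
fga_bp_oracle <- function(segs, genome, threshold = 0.2) {
  v <- unlist(per_bp_values(segs, genome))
  v <- v[!is.na(v)]
  mean(abs(v) >= threshold)
}

# arm loss fraction by per-bp counting
arm_loss_bp_oracle <- function(segs, genome, arm, loss_thresh = -0.2) {
  a <- genome$arms[genome$arms$arm_id == arm, ]
  v <- per_bp_values(segs, genome)[[a$chrom]][a$start:a$end]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v <= loss_thresh)
}

# gene value by per-bp averaging
gene_bp_oracle <- function(segs, genome) {
  bp <- per_bp_values(segs, genome)
  vapply(seq_len(nrow(genome$genes)), function(j) {
    g <- genome$genes[j, ]
    v <- bp[[g$chrom]][g$start:g$end]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
}

# two-sided Fisher p by direct hypergeometric enumeration
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# plain (unshrunken) nearest-centroid classifier with diagonal pooled
# within-class variance, for the zero-shrinkage equivalence check
nearest_centroid_oracle <- function(train, labels, newdata) {
  labels <- factor(labels)
  cents <- vapply(levels(labels), function(k) {
    rowMeans(train[, labels == k, drop = FALSE])
  }, numeric(nrow(train)))
  ss <- 0
  for (k in levels(labels)) {
    ss <- ss + rowSums((train[, labels == k, drop = FALSE] - cents[, k])^2)
  }
  s_j <- sqrt(ss / (ncol(train) - nlevels(labels)))
  s0 <- stats::median(s_j)
  scores <- vapply(levels(labels), function(k) {
    colSums((newdata - cents[, k])^2 / (s_j + s0)^2)
  }, numeric(ncol(newdata)))
  levels(labels)[max.col(-matrix(scores, ncol = nlevels(labels)),
                         ties.method = "first")]
}

# cluster count from an hclust tree by counting merges above a height
clusters_above_oracle <- function(tree, h) {
  1 + sum(tree$height > h)
}
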