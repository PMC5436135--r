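#' Expand truth mutated-gene sets into MAF-like records
#'
#' Each truly mutated gene yields exactly one coding variant record with a
#' plausible class, protein change, read depth and variant allele fraction.
#' Optionally adds decoy records that the standard confidence filters should
#' remove (low depth, low VAF, or non-coding/silent classes), drawn in genes
#' outside the truth set so filter recovery can be scored exactly.
#'
#' @param truth truth component of [simulate_cna_cohort()].
#' @param genome a \code{genome_model} (decoy genes are drawn from it).
#' @param seed integer seed.
#' @param decoy_rate expected decoy (filter-removable) records per sample.
#' @return data frame (sample, gene, variant_class, protein_change, depth,
#'   vaf, source) — one row per variant.
#' @export
simulate_mutation_records <- function(truth, genome, seed = 1, decoy_rate = 1) {
  aa <- c("A", "R", "N", "D", "C", "E", "G", "H", "L", "K", "P", "S", "T", "V")
  classes <- c("missense", "nonsense", "frameshift", "splice")
  bad_classes <- c("silent", "intronic", "UTR", "flank", "intergenic", "RNA")
  rows <- lapply(truth$samples$sample, function(sid) {
    set.seed(hash_seed(paste0("mut:", sid), seed))
    genes <- truth$mutated_genes[[sid]]
    real <- if (length(genes)) {
      data.frame(sample = sid, gene = genes,
                 variant_class = sample(classes, length(genes), replace = TRUE,
                                        prob = c(0.6, 0.15, 0.15, 0.1)),
                 protein_change = sprintf("p.%s%d%s",
                                          sample(aa, length(genes), TRUE),
                                          sample(30:800, length(genes), TRUE),
                                          sample(aa, length(genes), TRUE)),
                 depth = 30L + stats::rpois(length(genes), 40),
                 vaf = round(stats::rbeta(length(genes), 8, 12), 3),
                 stringsAsFactors = FALSE)
    }
    nd <- stats::rpois(1, decoy_rate)
    decoy <- if (nd > 0) {
      pool <- setdiff(genome$genes$gene, genes)
      dg <- sample(pool, min(nd, length(pool)))
      mode <- sample(c("class", "depth", "vaf"), length(dg), replace = TRUE)
      data.frame(sample = sid, gene = dg,
                 variant_class = ifelse(mode == "class",
                                        sample(bad_classes, length(dg), TRUE),
                                        sample(classes, length(dg), TRUE)),
                 protein_change = sprintf("p.%s%d%s",
                                          sample(aa, length(dg), TRUE),
                                          sample(30:800, length(dg), TRUE),
                                          sample(aa, length(dg), TRUE)),
                 depth = ifelse(mode == "depth", sample(1:14, length(dg), TRUE),
                                30L + stats::rpois(length(dg), 40)),
                 vaf = ifelse(mode == "vaf",
                              round(stats::runif(length(dg), 0.01, 0.14), 3),
                              round(stats::rbeta(length(dg), 8, 12), 3)),
                 stringsAsFactors = FALSE)
    }
    rbind(real, decoy)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample = character(0), gene = character(0),
                      variant_class = character(0),
                      protein_change = character(0),
                      depth = integer(0), vaf = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out$source <- "truth"
  rownames(out) <- NULL
  out
}

#' Simulate two database views of the same cell lines with injected discrepancies
#'
#' Emulates the situation where two cell-line resources profile the same
#' lines but disagree: \code{drop} removes a mutation call from one randomly
#' chosen view (a present-in-one-only case), \code{alter} perturbs the
#' protein change in one view (same gene, non-identical variant), and
#' \code{extent_shift} moves a GISTIC-like score of magnitude 2 to 1 (or 1
#' to 2) in one view (same direction, different extent). With all rates 0
#' the two views are identical. An injection ledger records every applied
#' discrepancy with its expected concordance tier, assuming at most one
#' variant per (sample, gene) in the truth table.
#'
#' @param truth_mutations MAF-like data frame (one variant per sample/gene).
#' @param truth_gistic genes x samples matrix of scores in \{-2,-1,0,1,2\}.
#' @param rates list with elements \code{drop}, \code{alter},
#'   \code{extent_shift}, all in [0,1].
#' @param seed integer seed.
#' @return list: \code{mut_a}, \code{mut_b} (mutation tables), \code{cna_a},
#'   \code{cna_b} (score matrices), \code{ledger} (data frame: data_kind,
#'   sample, gene, injection, expected_tier).
#' @export
simulate_two_source_views <- function(truth_mutations, truth_gistic,
                                      rates = list(drop = 0.1, alter = 0.1,
                                                   extent_shift = 0.1),
                                      seed = 1) {
  r <- lapply(c(drop = "drop", alter = "alter", extent_shift = "extent_shift"),
              function(k) if (is.null(rates[[k]])) 0 else rates[[k]])
  if (any(unlist(r) < 0 | unlist(r) > 1)) stop("rates must be in [0,1]")
  set.seed(as.integer(seed))

  mut_a <- truth_mutations
  mut_b <- truth_mutations
  mut_a$source <- rep("A", nrow(mut_a))
  mut_b$source <- rep("B", nrow(mut_b))
  ledger <- list()
  n <- nrow(truth_mutations)
  if (n > 0) {
    u <- stats::runif(n)
    which_view <- sample(c("A", "B"), n, replace = TRUE)
    drop_a <- drop_b <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (u[i] < r$drop) {
        if (which_view[i] == "A") drop_a[i] <- TRUE else drop_b[i] <- TRUE
        ledger[[length(ledger) + 1]] <- data.frame(
          data_kind = "mutation", sample = truth_mutations$sample[i],
          gene = truth_mutations$gene[i], injection = "drop",
          expected_tier = "3", stringsAsFactors = FALSE)
      } else if (u[i] < r$drop + r$alter * (1 - r$drop)) {
        pc <- truth_mutations$protein_change[i]
        num <- suppressWarnings(as.integer(gsub("\\D", "", pc)))
        new_pc <- if (!is.na(num)) {
          sub(as.character(num), as.character(num + 1), pc, fixed = TRUE)
        } else paste0(pc, "alt")
        if (which_view[i] == "A") {
          mut_a$protein_change[i] <- new_pc
        } else {
          mut_b$protein_change[i] <- new_pc
        }
        ledger[[length(ledger) + 1]] <- data.frame(
          data_kind = "mutation", sample = truth_mutations$sample[i],
          gene = truth_mutations$gene[i], injection = "alter",
          expected_tier = "2", stringsAsFactors = FALSE)
      }
    }
    mut_a <- mut_a[!drop_a, , drop = FALSE]
    mut_b <- mut_b[!drop_b, , drop = FALSE]
  }

  cna_a <- truth_gistic
  cna_b <- truth_gistic
  nz <- which(!is.na(truth_gistic) & truth_gistic != 0)
  if (length(nz) && r$extent_shift > 0) {
    hit <- nz[stats::runif(length(nz)) < r$extent_shift]
    for (idx in hit) {
      v <- truth_gistic[idx]
      shifted <- if (abs(v) == 2) sign(v) * 1 else sign(v) * 2
      if (stats::runif(1) < 0.5) cna_a[idx] <- shifted else cna_b[idx] <- shifted
      rc <- arrayInd(idx, dim(truth_gistic))
      ledger[[length(ledger) + 1]] <- data.frame(
        data_kind = "cna", sample = colnames(truth_gistic)[rc[2]],
        gene = rownames(truth_gistic)[rc[1]], injection = "extent_shift",
        expected_tier = "2", stringsAsFactors = FALSE)
    }
  }

  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(data_kind = character(0), sample = character(0),
               gene = character(0), injection = character(0),
               expected_tier = character(0), stringsAsFactors = FALSE)
  rownames(mut_a) <- rownames(mut_b) <- rownames(ledger) <- NULL
  list(mut_a = mut_a, mut_b = mut_b, cna_a = cna_a, cna_b = cna_b,
       ledger = ledger)
}
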