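#' Normalize a variant for cross-database identity comparison
#'
#' Variant identity is equality of (normalized protein-change string,
#' variant class): whitespace and case are normalized and a leading "p."
#' prefix stripped, so alignment-style formatting differences do not break
#' identity.
#'
#' @param protein_change character vector of protein changes.
#' @param variant_class character vector of classes.
#' @return character vector of normalized variant keys.
#' @export
normalize_variant <- function(protein_change, variant_class) {
  pc <- tolower(gsub("\\s+", "", protein_change))
  pc <- sub("^p\\.", "", pc)
  paste(tolower(variant_class), pc, sep = ":")
}

#' Concordance tier for one gene's mutations in two sources
#'
#' Both sets empty: \code{concordant_null}. Both non-empty with equal
#' normalized variant sets: Tier 1 (identical mutations). Both non-empty
#' but unequal: Tier 2 (mutations in the same gene that differ). Exactly
#' one non-empty: Tier 3 (reported in one source only).
#'
#' @param calls_a,calls_b character vectors of normalized variant keys for
#'   one (gene, cell line) in each source (possibly empty).
#' @return one of "1", "2", "3", "concordant_null".
#' @export
mutation_tier <- function(calls_a, calls_b) {
  a <- sort(unique(calls_a))
  b <- sort(unique(calls_b))
  if (!length(a) && !length(b)) return("concordant_null")
  if (!length(a) || !length(b)) return("3")
  if (identical(a, b)) "1" else "2"
}

#' Concordance tier for one gene's GISTIC-like scores in two sources
#'
#' (0,0): \code{concordant_null}. Equal nonzero scores: Tier 1 (agree on
#' nature and extent). Same sign, different magnitude: Tier 2 (agree on
#' nature, disagree on extent). One zero and one nonzero, or opposite
#' signs: Tier 3. Vectorized over score pairs.
#'
#' @param score_a,score_b scores in \{-2,-1,0,1,2\}.
#' @return character vector of tiers.
#' @export
cna_tier <- function(score_a, score_b) {
  if (any(!score_a %in% -2:2) || any(!score_b %in% -2:2)) {
    stop("scores must be in {-2,-1,0,1,2}")
  }
  n <- max(length(score_a), length(score_b))
  a <- rep_len(score_a, n)
  b <- rep_len(score_b, n)
  out <- character(n)
  out[a == 0 & b == 0] <- "concordant_null"
  out[a == b & a != 0] <- "1"
  out[sign(a) == sign(b) & a != b & a != 0 & b != 0] <- "2"
  out[(a == 0) != (b == 0) | (sign(a) * sign(b) == -1)] <- "3"
  out
}

#' Tier every (cell line, gene) pair across two sources
#'
#' Builds the full tier table over a gene panel for the cell lines shared
#' by two mutation tables and two score matrices.
#'
#' @param mut_a,mut_b mutation record tables from the two sources.
#' @param cna_a,cna_b genes x cell-lines score matrices from the two
#'   sources.
#' @param panel gene panel (character vector).
#' @param cell_lines cell lines to tier; defaults to those shared by both
#'   score matrices.
#' @return data frame (cell_line, gene, data_kind, tier, detail_a,
#'   detail_b).
#' @export
tier_table <- function(mut_a, mut_b, cna_a, cna_b, panel,
                       cell_lines = intersect(colnames(cna_a), colnames(cna_b))) {
  panel_cna <- intersect(panel, intersect(rownames(cna_a), rownames(cna_b)))
  key <- function(recs, cl, g) {
    hit <- recs$sample == cl & recs$gene == g
    normalize_variant(recs$protein_change[hit], recs$variant_class[hit])
  }
  rows <- list()
  for (cl in cell_lines) {
    for (g in panel) {
      va <- key(mut_a, cl, g)
      vb <- key(mut_b, cl, g)
      rows[[length(rows) + 1]] <- data.frame(
        cell_line = cl, gene = g, data_kind = "mutation",
        tier = mutation_tier(va, vb),
        detail_a = paste(sort(va), collapse = ";"),
        detail_b = paste(sort(vb), collapse = ";"),
        stringsAsFactors = FALSE)
    }
    for (g in panel_cna) {
      sa <- cna_a[g, cl]; sb <- cna_b[g, cl]
      rows[[length(rows) + 1]] <- data.frame(
        cell_line = cl, gene = g, data_kind = "cna",
        tier = if (is.na(sa) || is.na(sb)) "indeterminate" else cna_tier(sa, sb),
        detail_a = as.character(sa), detail_b = as.character(sb),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank cell lines by cross-database reliability
#'
#' Counts tier calls per cell line and data kind over a gene panel. A cell
#' line is flagged \code{all_tier1_mutations} (resp. \code{all_tier1_cna})
#' if it has no Tier 2 or Tier 3 call of that kind — i.e. every reported
#' alteration in the panel is confirmed by both sources. Ranking orders by
#' total discordant calls (Tier 2 + Tier 3) ascending, ties broken by
#' Tier 1 count descending. Silent agreement (both sources report
#' nothing/zero) is counted as \code{concordant_null}, not Tier 1.
#'
#' @param tier_calls data frame from [tier_table()].
#' @param panel gene panel the calls should cover.
#' @return data frame, one row per cell line, with per-tier counts per
#'   data kind, the two flags, and \code{rank}.
#' @export
reliability_report <- function(tier_calls, panel) {
  need_mut <- length(panel)
  by_cl <- split(tier_calls, tier_calls$cell_line)
  rows <- lapply(by_cl, function(tc) {
    mut <- tc[tc$data_kind == "mutation", ]
    cna <- tc[tc$data_kind == "cna", ]
    missing <- setdiff(panel, mut$gene)
    if (length(missing)) {
      stop("incomplete coverage for ", tc$cell_line[1], ": missing ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    cnt <- function(x, t) sum(x$tier == t)
    data.frame(cell_line = tc$cell_line[1],
               mut_tier1 = cnt(mut, "1"), mut_tier2 = cnt(mut, "2"),
               mut_tier3 = cnt(mut, "3"),
               mut_null = cnt(mut, "concordant_null"),
               cna_tier1 = cnt(cna, "1"), cna_tier2 = cnt(cna, "2"),
               cna_tier3 = cnt(cna, "3"),
               cna_null = cnt(cna, "concordant_null"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$all_tier1_mutations <- out$mut_tier2 + out$mut_tier3 == 0
  out$all_tier1_cna <- out$cna_tier2 + out$cna_tier3 == 0
  discord <- out$mut_tier2 + out$mut_tier3 + out$cna_tier2 + out$cna_tier3
  tier1 <- out$mut_tier1 + out$cna_tier1
  ord <- order(discord, -tier1, out$cell_line)
  out <- out[ord, ]
  out$rank <- rank(discord[ord], ties.method = "min")
  out <- out[, c("cell_line", "mut_tier1", "mut_tier2", "mut_tier3",
                 "mut_null", "cna_tier1", "cna_tier2", "cna_tier3",
                 "cna_null", "all_tier1_mutations", "all_tier1_cna", "rank")]
  rownames(out) <- NULL
  out
}
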