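test_that("SEG files round-trip through write and read", {
  g <- tiny_genome(seed = 3)
  set.seed(41)
  profs <- do.call(rbind, lapply(1:50, function(i) {
    random_profile(g, sprintf("S%02d", i))
  }))
  path <- withr::local_tempfile(fileext = ".seg")
  write_seg(profs, path)
  back <- read_seg(path, quiet = TRUE)
  expect_equal(back$seg_mean, profs$seg_mean, tolerance = 1e-6)
  expect_identical(back$sample, profs$sample)
  expect_identical(back$start, as.numeric(profs$start))
})

test_that("SEG reader rejects malformed rows and skips unknown chromosomes", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Markers\tSegment_Mean",
               "S1\t1\t100\t50\t10\t0.3"), path)
  expect_error(read_seg(path, quiet = TRUE), "line 2.*start > end")

  writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Markers\tSegment_Mean",
               "S1\t1\t1\t50\t10\t0.3",
               "S1\tweird\t1\t50\t10\t0.1"), path)
  g <- tiny_genome(seed = 3)
  expect_warning(out <- read_seg(path, genome = g, quiet = TRUE), "unknown")
  expect_equal(nrow(out), 1)
})

test_that("integral copy numbers convert to self-normalized log2 ratios", {
  uni <- data.frame(sample = "S", chrom = c("1", "1", "2"),
                    start = c(1, 51, 1), end = c(50, 100, 80),
                    total_cn = c(2, 2, 2))
  expect_true(all(integral_to_log2(uni)$seg_mean == 0))
  uni$total_cn <- 4
  expect_true(all(integral_to_log2(uni)$seg_mean == 0))

  two <- data.frame(sample = "S", chrom = "1", start = c(1, 101),
                    end = c(100, 200), total_cn = c(2, 4))
  out <- integral_to_log2(two)
  expect_equal(out$seg_mean, c(log2(2 / 3), log2(4 / 3)), tolerance = 1e-3)

  zero <- data.frame(sample = "S", chrom = "1", start = c(1, 101),
                     end = c(100, 200), total_cn = c(0, 4))
  expect_warning(fz <- integral_to_log2(zero), "floored")
  expect_equal(fz$seg_mean[1], -8)

  allz <- data.frame(sample = "S", chrom = "1", start = 1, end = 10,
                     total_cn = 0)
  expect_error(suppressWarnings(integral_to_log2(allz)), "degenerate")
})

test_that("segment-to-gene projection matches per-base-pair averaging", {
  g <- tiny_genome(seed = 5)
  one <- data.frame(sample = "S", chrom = g$genes$chrom[1],
                    start = 1, end = g$chromosomes$length[1], seg_mean = 0.3)
  m <- segments_to_genes(one, g)
  expect_equal(unname(m[g$genes$gene[1], "S"]), 0.3)

  # gene split 50/50 across -0.2 / +0.2 averages to 0
  gn <- g$genes[1, ]
  mid <- (gn$start + gn$end - 1) %/% 2
  two <- data.frame(sample = "S", chrom = gn$chrom,
                    start = c(1, mid + 1),
                    end = c(mid, g$chromosomes$length[1]),
                    seg_mean = c(-0.2, 0.2))
  m2 <- segments_to_genes(two, g)
  ov_left <- mid - gn$start + 1
  ov_right <- gn$end - mid
  expect_equal(unname(m2[gn$gene, "S"]),
               (-0.2 * ov_left + 0.2 * ov_right) / (ov_left + ov_right))

  set.seed(17)
  for (rep in 1:25) {
    p <- random_profile(g, "S")
    got <- segments_to_genes(p, g)[, "S"]
    want <- gene_bp_oracle(p, g)
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("GISTIC-like discretization matches its piecewise definition", {
  v <- c(-2, -1.01, -1, -0.5, -0.2, -0.19, 0, 0.19, 0.2, 0.5, 1, 1.5, NA)
  m <- matrix(v, ncol = 1, dimnames = list(sprintf("g%d", seq_along(v)), "s"))
  got <- discretize_gistic(m)[, 1]
  piecewise <- function(x) {
    if (is.na(x)) return(NA_real_)
    if (x >= 1) return(2)
    if (x >= 0.2) return(1)
    if (x <= -1) return(-2)
    if (x <= -0.2) return(-1)
    0
  }
  expect_equal(unname(got), vapply(v, piecewise, numeric(1)))
  expect_error(discretize_gistic(m, shallow_thresh = 1, deep_thresh = 0.5),
               "shallow")
})

test_that("mutation filtering applies depth, VAF and class rules inclusively", {
  recs <- data.frame(
    sample = "S", gene = c("a", "b", "c", "d"),
    variant_class = c("missense", "missense", "silent", "missense"),
    protein_change = "p.A1B",
    depth = c(14, 20, 100, 50),
    vaf = c(0.5, 0.15, 0.4, 0.149),
    stringsAsFactors = FALSE)
  out <- filter_mutations(recs)
  expect_identical(out$gene, "b")  # depth 14 out, VAF 0.15 in, silent out
  audit <- attr(out, "audit")
  expect_equal(audit$fail_depth, 1)
  expect_equal(audit$fail_class, 1)
  expect_equal(audit$fail_vaf, 1)
  # idempotent
  again <- filter_mutations(out)
  expect_identical(again$gene, out$gene)
  # empty in, empty out
  expect_equal(nrow(filter_mutations(recs[0, ])), 0)
})

test_that("panel restriction behaves as a set filter", {
  g <- tiny_genome(seed = 1)
  co <- simulate_cna_cohort(g, default_archetypes(g), 3, 0, seed = 1)
  muts <- simulate_mutation_records(co$truth, g, seed = 1)
  all_genes <- g$genes$gene
  expect_identical(restrict_to_panel(muts, all_genes)$gene, muts$gene)
  none <- restrict_to_panel(muts, "not_a_gene")
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "panel_intersection"), 0)
  set.seed(8)
  for (rep in 1:10) {
    panel <- sample(all_genes, 5)
    out <- restrict_to_panel(muts, panel)
    expect_identical(out$gene, muts$gene[muts$gene %in% panel])
  }
  m <- segments_to_genes(co$segments, g)
  sub <- restrict_to_panel(m, all_genes[1:4])
  expect_identical(rownames(sub), intersect(rownames(m), all_genes[1:4]))
})

test_that("GCT, MAF and allele-specific CSV round-trip", {
  mat <- matrix(rnorm(12), 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  p <- withr::local_tempfile(fileext = ".gct")
  write_gct(mat, p)
  expect_equal(read_gct(p, quiet = TRUE), mat, ignore_attr = TRUE)

  g <- tiny_genome(seed = 2)
  as <- simulate_allele_specific(g, list(A = "masked_loss"), seed = 1)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_allele_csv(as, p2)
  back <- read_allele_csv(p2, quiet = TRUE)
  expect_equal(back$total_cn, as$total_cn)
  expect_equal(back$minor_cn, as$minor_cn)

  co <- simulate_cna_cohort(g, default_archetypes(g), 2, 0, seed = 1)
  muts <- simulate_mutation_records(co$truth, g, seed = 1)
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_maf(muts, p3)
  back3 <- read_maf(p3, quiet = TRUE)
  expect_equal(back3$protein_change, muts$protein_change)
  expect_equal(back3$vaf, muts$vaf)
})
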