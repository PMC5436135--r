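small_genome <- make_genome(10, 5, seed = 11)
small_arch <- default_archetypes(small_genome)

test_that("cohort simulation is deterministic and order-insensitive", {
  a <- simulate_cna_cohort(small_genome, small_arch, 5, 2, seed = 4)
  b <- simulate_cna_cohort(small_genome, small_arch, 5, 2, seed = 4)
  expect_identical(a$segments, b$segments)
  # reversing archetype order must not change any sample's profile
  c0 <- simulate_cna_cohort(small_genome, rev(small_arch), 5, 2, seed = 4)
  key <- function(x) x[order(x$sample, x$chrom, x$start), ]
  expect_equal(key(a$segments), key(c0$segments), ignore_attr = TRUE)
})

test_that("segments partition every chromosome per sample", {
  co <- simulate_cna_cohort(small_genome, small_arch, 4, 2, seed = 9)
  len <- stats::setNames(small_genome$chromosomes$length,
                         small_genome$chromosomes$chrom)
  for (sid in unique(co$segments$sample)) {
    s <- co$segments[co$segments$sample == sid, ]
    for (c0 in names(len)) {
      sc <- s[s$chrom == c0, ]
      sc <- sc[order(sc$start), ]
      expect_equal(sc$start[1], 1)
      expect_equal(sc$end[nrow(sc)], unname(len[c0]))
      if (nrow(sc) > 1) expect_equal(sc$start[-1], sc$end[-nrow(sc)] + 1)
    }
  }
})

test_that("noiseless single-event archetype gives exact segment values", {
  arch <- list(cc = list(name = "cc",
                         events = data.frame(target = "3p", direction = "loss",
                                             penetrance = 1, magnitude = -0.5),
                         focal_event_rate = 0, mutation_rates = numeric(0)))
  co <- simulate_cna_cohort(small_genome, arch, 5, 0, segment_noise_sd = 0,
                            seed = 2)
  arm <- small_genome$arms[small_genome$arms$arm_id == "3p", ]
  on3p <- co$segments$chrom == arm$chrom & co$segments$end <= arm$end
  expect_true(all(co$segments$seg_mean[on3p] == -0.5))
  expect_true(all(co$segments$seg_mean[!on3p] == 0))

  # no events, no noise: identically zero
  arch0 <- list(z = list(name = "z",
                         events = data.frame(target = character(0),
                                             direction = character(0),
                                             penetrance = numeric(0),
                                             magnitude = numeric(0)),
                         focal_event_rate = 0, mutation_rates = numeric(0)))
  co0 <- simulate_cna_cohort(small_genome, arch0, 3, 0,
                             segment_noise_sd = 0, seed = 2)
  expect_true(all(co0$segments$seg_mean == 0))
})

test_that("ccRCC group mean 3p value is well below zero at defaults", {
  co <- simulate_cna_cohort(small_genome, small_arch["ccRCC"], 100, 0, seed = 5)
  arm <- small_genome$arms[small_genome$arms$arm_id == "3p", ]
  s <- co$segments
  on3p <- s$chrom == arm$chrom & s$start >= arm$start & s$end <= arm$end
  len <- s$end[on3p] - s$start[on3p] + 1
  expect_lt(sum(s$seg_mean[on3p] * len) / sum(len), -0.2)
})

test_that("cell-line copy-number burden dominates tumours", {
  co <- simulate_cna_cohort(small_genome, small_arch, 40, 15, seed = 3)
  fga <- fraction_genome_altered(co$segments)
  s <- co$truth$samples
  f <- stats::setNames(fga$fga, fga$sample)
  expect_gt(stats::median(f[s$sample[s$is_cell_line]]),
            stats::median(f[s$sample[!s$is_cell_line]]))
})

test_that("archetypes referencing unknown arms are rejected", {
  arch <- list(x = list(name = "x",
                        events = data.frame(target = "zz", direction = "loss",
                                            penetrance = 1, magnitude = -0.5),
                        focal_event_rate = 0, mutation_rates = numeric(0)))
  expect_error(simulate_cna_cohort(small_genome, arch, 2, 0, seed = 1),
               "unknown arm")
})

test_that("allele-specific scenarios produce the stated copy numbers", {
  as <- simulate_allele_specific(
    small_genome,
    list(A = "masked_loss", B = "balanced_diploid", C = "ploidy_relative"),
    seed = 1)
  arm3p <- small_genome$arms[small_genome$arms$arm_id == "3p", ]
  seg_of <- function(sid) as[as$sample == sid, ]
  on3p <- function(s) s$chrom == arm3p$chrom & s$start >= arm3p$start &
    s$end <= arm3p$end

  a <- seg_of("A")
  expect_true(all(a$minor_cn[on3p(a)] == 0) && all(a$total_cn[on3p(a)] == 3))
  expect_true(all(a$minor_cn[!on3p(a)] == 1) && all(a$total_cn[!on3p(a)] == 2))

  b <- seg_of("B")
  expect_true(all(b$total_cn == 2) && all(b$minor_cn == 1))

  c0 <- seg_of("C")
  len <- c0$end - c0$start + 1
  mean_total <- sum(len * c0$total_cn) / sum(len)
  expect_gt(mean_total, 2.5)   # hyperploid background
  expect_lt(abs(mean_total - 3.2), 0.35)
  expect_true(all(c0$total_cn[on3p(c0)] == 2) &&
                all(c0$minor_cn[on3p(c0)] == 1))

  expect_error(simulate_allele_specific(
    small_genome,
    list(X = list(arms = data.frame(arm_id = "3p", total_cn = 1,
                                    minor_cn = 2)))),
    "minor_cn > total_cn")
})

test_that("clinical covariates follow the FGA-linked logistic model", {
  co <- simulate_cna_cohort(small_genome, small_arch["ccRCC"], 200, 0, seed = 8)
  tum <- co$truth$samples$sample
  # bimodal FGA with a steep slope: high-FGA group should be mostly stage 3/4
  fga <- stats::setNames(rep(c(0.05, 0.5), length.out = length(tum)), tum)
  cl <- simulate_clinical(co$truth, fga, stage_logit_slope = 10,
                          grade_logit_slope = 10, seed = 1)
  hi <- cl$sample %in% tum[fga[cl$sample] > 0.2]
  expect_gt(mean(cl$stage[hi] >= 3), 0.5)
  expect_lt(mean(cl$stage[!hi] >= 3), 0.5)

  # zero slope: stage unrelated to FGA
  cl0 <- simulate_clinical(co$truth, fga, stage_logit_slope = 0,
                           grade_logit_slope = 0, seed = 1)
  tab <- table(cl0$sample %in% tum[fga[cl0$sample] > 0.2], cl0$stage >= 3)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)

  expect_identical(cl, simulate_clinical(co$truth, fga, 10, 10, seed = 1))
  expect_error(simulate_clinical(co$truth, fga[-1], seed = 1), "missing FGA")
})

test_that("expression simulator produces the declared class structure", {
  genes <- sprintf("g%03d", 1:120)
  ex <- simulate_expression(genes, n_per_class = 30, n_intermediate = 10,
                            class_effect_size = 2, n_marker_genes = 40,
                            batch_assignment = 2, batch_shift = 0,
                            batch_scale = 1, noise_sd = 0.1, seed = 3)
  lab <- ex$truth$samples$class
  d <- rowMeans(ex$expr[1:40, lab == "ccA"]) -
    rowMeans(ex$expr[1:40, lab == "ccB"])
  expect_equal(mean(abs(d)), 2, tolerance = 0.05)
  mid <- rowMeans(ex$expr[1:40, lab == "intermediate"])
  grand <- (rowMeans(ex$expr[1:40, lab == "ccA"]) +
              rowMeans(ex$expr[1:40, lab == "ccB"])) / 2
  expect_equal(mid, grand, tolerance = 0.15)
  # batches are class-balanced by construction
  expect_true(all(table(lab, ex$truth$samples$batch) > 0))

  ex0 <- simulate_expression(genes, 30, 0, class_effect_size = 0,
                             n_marker_genes = 40, batch_assignment = 1,
                             batch_shift = 0, batch_scale = 1,
                             noise_sd = 0.3, seed = 4)
  lab0 <- ex0$truth$samples$class
  d0 <- rowMeans(ex0$expr[1:40, lab0 == "ccA"]) -
    rowMeans(ex0$expr[1:40, lab0 == "ccB"])
  expect_lt(mean(abs(d0)), 0.3)

  expect_error(simulate_expression(character(0)), "non-empty")
})

test_that("two-source views honour the injection rates and ledger", {
  co <- simulate_cna_cohort(small_genome, small_arch, 6, 4, seed = 12)
  muts <- simulate_mutation_records(co$truth, small_genome, seed = 12,
                                    decoy_rate = 0)
  gm <- segments_to_genes(co$segments, small_genome)
  gistic <- discretize_gistic(gm)

  v0 <- simulate_two_source_views(muts, gistic,
                                  rates = list(drop = 0, alter = 0,
                                               extent_shift = 0), seed = 1)
  expect_equal(v0$mut_a$protein_change, v0$mut_b$protein_change)
  expect_identical(v0$cna_a, v0$cna_b)
  expect_equal(nrow(v0$ledger), 0)

  v1 <- simulate_two_source_views(muts, gistic,
                                  rates = list(drop = 1, alter = 0,
                                               extent_shift = 0), seed = 1)
  expect_equal(sum(v1$ledger$injection == "drop"), nrow(muts))
  expect_equal(nrow(v1$mut_a) + nrow(v1$mut_b), nrow(muts))

  m2 <- matrix(c(2L, 0L, 0L, 0L), 2, 2,
               dimnames = list(c("gA", "gB"), c("s1", "s2")))
  v2 <- simulate_two_source_views(muts[0, ], m2,
                                  rates = list(extent_shift = 1), seed = 2)
  pair <- sort(c(v2$cna_a["gA", "s1"], v2$cna_b["gA", "s1"]))
  expect_equal(pair, c(1, 2))

  expect_error(simulate_two_source_views(muts, gistic,
                                         rates = list(drop = 2), seed = 1),
               "rates")
})
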