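test_that("FGA follows its length-weighted definition", {
  quiet_prof <- data.frame(sample = "S", chrom = "1",
                           start = c(1, 101), end = c(100, 400),
                           seg_mean = c(0.1, -0.15))
  expect_equal(fraction_genome_altered(quiet_prof)$fga, 0)
  loud_prof <- within(quiet_prof, seg_mean <- c(0.2, -0.3))
  expect_equal(fraction_genome_altered(loud_prof)$fga, 1)

  # 100 bp at 0.5 over 400 bp total
  mix <- data.frame(sample = "S", chrom = "1", start = c(1, 101),
                    end = c(100, 400), seg_mean = c(0.5, 0))
  expect_equal(fraction_genome_altered(mix)$fga, 0.25)

  expect_error(fraction_genome_altered(mix[0, ]), "empty")
  expect_error(fraction_genome_altered(mix, threshold = 0), "positive")
})

test_that("FGA matches the per-base-pair oracle and is monotone in T", {
  g <- tiny_genome(seed = 4)
  set.seed(13)
  for (rep in 1:40) {
    p <- random_profile(g, "S")
    expect_equal(fraction_genome_altered(p)$fga, fga_bp_oracle(p, g))
    ts <- c(0.1, 0.2, 0.4, 0.8)
    fgas <- vapply(ts, function(t) {
      fraction_genome_altered(p, t)$fga
    }, numeric(1))
    expect_true(all(diff(fgas) <= 0))
  }
})

test_that("arm loss fraction clips to the arm and uses covered length", {
  g <- tiny_genome(seed = 4)
  arm <- g$arms[g$arms$arm_id == "3p", ]
  whole <- data.frame(sample = "S", chrom = arm$chrom, start = arm$start,
                      end = arm$end, seg_mean = -0.5)
  expect_equal(arm_loss_fraction(whole, g, "3p")$loss_fraction, 1)
  whole$seg_mean <- 0
  expect_equal(arm_loss_fraction(whole, g, "3p")$loss_fraction, 0)

  half_end <- arm$start + (arm$end - arm$start + 1) %/% 2 - 1
  half <- data.frame(sample = "S", chrom = arm$chrom,
                     start = c(arm$start, half_end + 1),
                     end = c(half_end, arm$end),
                     seg_mean = c(-0.3, 0))
  got <- arm_loss_fraction(half, g, "3p")$loss_fraction
  expect_equal(got, arm_loss_bp_oracle(half, g, "3p"))
  expect_equal(got, (half_end - arm$start + 1) / (arm$end - arm$start + 1))

  set.seed(6)
  for (rep in 1:25) {
    p <- random_profile(g, "S")
    expect_equal(arm_loss_fraction(p, g, "3p")$loss_fraction,
                 arm_loss_bp_oracle(p, g, "3p"))
  }

  # uncovered arm is indeterminate, not zero
  off <- data.frame(sample = "S", chrom = "5", start = 1, end = 100,
                    seg_mean = -0.5)
  res <- arm_loss_fraction(off, g, "3p")
  expect_true(is.na(res$loss_fraction))
  expect_equal(res$covered_length, 0)
  expect_error(arm_loss_fraction(off, g, "99z"), "unknown arm")
})

test_that("minor-allele estimator detects masked and relative losses", {
  g <- tiny_genome(seed = 2)
  as <- simulate_allele_specific(
    g, list(M = "masked_loss", B = "balanced_diploid", P = "ploidy_relative",
            C = "classic_loss"), seed = 1)
  loh <- arm_loh_fraction(as, g, "3p")
  row <- function(s) loh[loh$sample == s, ]

  expect_equal(row("M")$zero_minor_fraction, 1)
  expect_equal(row("B")$zero_minor_fraction, 0)
  expect_equal(row("P")$relative_loss_fraction, 1)
  expect_gt(row("P")$sample_mean_total_cn, 2.5)

  # masked loss: log2 view sees (almost) nothing, minor view sees all
  lg <- integral_to_log2(as[as$sample == "M", ])
  expect_lt(arm_loss_fraction(lg, g, "3p")$loss_fraction, 0.01)

  # agreement when there is no allelic imbalance trickery: classic loss
  lg_c <- integral_to_log2(as[as$sample == "C", ])
  expect_equal(arm_loss_fraction(lg_c, g, "3p")$loss_fraction,
               row("C")$zero_minor_fraction, tolerance = 0.01)
})

test_that("the combined 3p call applies the either-method rule", {
  expect_equal(combined_3p_call(0.95, 0.9), "lost")
  expect_equal(combined_3p_call(0.05, NA), "negligible")
  expect_equal(combined_3p_call(0.1, 0.9), "lost")
  expect_equal(combined_3p_call(NA, NA), "indeterminate")
  expect_equal(combined_3p_call(0.8, 0.1), "lost")  # inclusive cutoff
  expect_equal(combined_3p_call(c(0.95, 0.05), c(0.9, NA)),
               c("lost", "negligible"))
})

test_that("average-linkage clustering reproduces a hand agglomeration", {
  # three samples with controlled pairwise Spearman correlations
  base <- 1:20
  m <- cbind(s1 = base,
             s2 = c(2, 1, 3:20),          # nearly identical ranks to s1
             s3 = rev(base))              # anti-correlated
  rownames(m) <- paste0("g", 1:20)
  tree <- cluster_profiles(m)
  rho <- stats::cor(m, method = "spearman")
  d12 <- 1 - rho["s1", "s2"]
  d13 <- 1 - rho["s1", "s3"]
  d23 <- 1 - rho["s2", "s3"]
  # s1,s2 merge first at d12; then (s1,s2) joins s3 at mean(d13, d23)
  expect_equal(tree$height, c(d12, mean(c(d13, d23))))
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))

  dup <- cbind(a = base, b = base)
  rownames(dup) <- paste0("g", 1:20)
  tdup <- cluster_profiles(dup)
  expect_equal(tdup$height, 0)
})

test_that("dendrogram cuts count components exactly", {
  set.seed(7)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  tree <- cluster_profiles(m)
  expect_equal(length(unique(cut_and_summarize(tree, 0)$labels)), 10)
  expect_equal(length(unique(cut_and_summarize(tree,
                                               max(tree$height))$labels)), 1)
  for (h in c(0.2, 0.5, 0.8, 1, 1.3)) {
    cut <- cut_and_summarize(tree, h)
    expect_equal(length(unique(cut$labels)), clusters_above_oracle(tree, h))
  }
  hs <- seq(0, 2, by = 0.1)
  ks <- vapply(hs, function(h) {
    length(unique(cut_and_summarize(tree, h)$labels))
  }, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("cell-line subtype calls follow the majority rule with outliers", {
  labels <- c(T1 = 1L, T2 = 1L, T3 = 1L, T4 = 1L, T5 = 1L, T6 = 1L,
              P1 = 1L, CL1 = 1L, CL2 = 2L, CL3 = 3L, T7 = 3L, T8 = 3L)
  cut <- structure(list(labels = labels, h = 0.9), class = "cluster_cut")
  tum <- c(T1 = "ccRCC", T2 = "ccRCC", T3 = "ccRCC", T4 = "ccRCC",
           T5 = "ccRCC", T6 = "ccRCC", P1 = "pRCC",
           T7 = "chRCC", T8 = "chRCC")
  calls <- assign_cell_line_subtype(cut, tum, min_tumours = 5)
  got <- stats::setNames(calls$call, calls$cell_line)
  expect_equal(unname(got["CL1"]), "ccRCC")   # majority of 7 tumours
  expect_equal(unname(got["CL2"]), "outlier") # cell-line-only cluster
  expect_equal(unname(got["CL3"]), "outlier") # only 2 tumours < min_tumours

  # tie between subtypes is an outlier
  labels2 <- c(A1 = 1L, A2 = 1L, A3 = 1L, B1 = 1L, B2 = 1L, B3 = 1L,
               CLX = 1L)
  cut2 <- structure(list(labels = labels2, h = 0.9), class = "cluster_cut")
  tum2 <- c(A1 = "ccRCC", A2 = "ccRCC", A3 = "ccRCC",
            B1 = "pRCC", B2 = "pRCC", B3 = "pRCC")
  expect_equal(assign_cell_line_subtype(cut2, tum2, min_tumours = 5)$call,
               "outlier")
})
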