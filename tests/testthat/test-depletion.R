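# a small hand-checkable count tibble
toy_counts <- function() {
  tibble::tibble(
    sample = rep(c("s1", "s2"), each = 5),
    condition = rep(c("control", "treated"), each = 5),
    gene = rep(c("a_glob", "b_glob", "sp1", "g1", "g2"), 2),
    class = rep(c("globin_alpha", "globin_beta", "spikein", "other", "other"), 2),
    count = c(214, 422, 14, 250, 100, 10, 20, 14, 800, 156)
  )
}

test_that("class prevalence is additive over the disjoint class partition", {
  tbl <- toy_counts()
  # s1 totals 1000 by construction: 214 alpha, 422 beta
  expect_equal(class_prevalence(tbl, "s1", "globin_alpha"), 0.214)
  expect_equal(class_prevalence(tbl, "s1", "globin_beta"), 0.422)
  expect_equal(class_prevalence(tbl, "s1", c("globin_alpha", "globin_beta")),
               0.636)
  expect_equal(class_prevalence(tbl, "s1", "other"), 0.35)
  classes <- unique(tbl$class)
  for (s in c("s1", "s2")) {
    expect_equal(sum(vapply(classes, function(cl) class_prevalence(tbl, s, cl),
                            numeric(1))), 1)
  }
  # zero-globin sample
  zg <- tbl
  zg$count[zg$class %in% c("globin_alpha", "globin_beta")] <- 0
  expect_equal(class_prevalence(zg, "s1", "globin_alpha"), 0)
  expect_error(class_prevalence(tbl, "nope", "other"), "not found")
  zz <- tbl; zz$count <- 0
  expect_error(class_prevalence(zz, "s1", "other"), "zero total")
})

test_that("reduction folds reproduce the printed prevalence arithmetic", {
  expect_gte(reduction_fold(0.636, 0.052), 10)
  expect_equal(reduction_fold(0.636, 0.052), 0.636 / 0.052)
  expect_equal(reduction_fold(0.3, 0.3), 1)
  expect_equal(reduction_fold(0.422, 0.005), 84.4)
  expect_identical(reduction_fold(0.5, 0), Inf)
  expect_error(reduction_fold(0, 0.1))
  expect_error(reduction_fold(0.5, -0.1))
  set.seed(61)
  for (i in 1:20) {
    a <- runif(1, 0.01, 1); b <- runif(1, 0.01, 1)
    expect_equal(reduction_fold(a, b) * reduction_fold(b, a), 1,
                 tolerance = 1e-12)
  }
})

test_that("spike-in correlation is 1 for self and scaled counts", {
  set.seed(62)
  counts <- round(10^runif(20, 0.5, 4))
  tbl <- tibble::tibble(
    sample = rep(c("x", "y"), each = 20),
    condition = rep(c("control", "treated"), each = 20),
    gene = rep(sprintf("sp%02d", 1:20), 2),
    class = "spikein",
    count = c(counts, counts * 8)
  )
  expect_equal(spikein_correlation(tbl, "x", "x"), 1)
  # multiplicative scaling is an additive shift under a pure log transform
  expect_equal(spikein_correlation(tbl, "x", "y", transform = log10), 1,
               tolerance = 1e-12)
  expect_error(spikein_correlation(tbl[c(1, 21), ], "x", "y"), "at least 3")
})

test_that("correlation under log-normal noise matches its expectation", {
  set.seed(63)
  n <- 4000
  sd_u <- 1.2; sd_e <- 0.5
  u <- rnorm(n, 3, sd_u)
  la <- u + rnorm(n, 0, sd_e)
  lb <- u + rnorm(n, 0, sd_e)
  tbl <- tibble::tibble(
    sample = rep(c("x", "y"), each = n),
    condition = rep(c("control", "treated"), each = n),
    gene = rep(sprintf("sp%04d", 1:n), 2),
    class = "spikein",
    count = c(10^la, 10^lb)
  )
  r <- spikein_correlation(tbl, "x", "y", transform = log10)
  expected <- sd_u^2 / (sd_u^2 + sd_e^2)
  expect_equal(r, expected, tolerance = 0.03)
})

test_that("detection sets split genes by pooled-count threshold", {
  tbl <- toy_counts()
  same <- tbl
  same$count[same$sample == "s2"] <- same$count[same$sample == "s1"]
  ds <- detection_sets(same, "control", "treated")
  expect_length(ds$only_a, 0)
  expect_length(ds$only_b, 0)
  expect_setequal(ds$shared, unique(tbl$gene))

  excl <- tbl
  excl$count[excl$sample == "s1" & excl$gene == "g1"] <- 0
  excl$count[excl$sample == "s2" & excl$gene == "g2"] <- 0
  ds2 <- detection_sets(excl, "control", "treated")
  expect_equal(ds2$only_a, "g2")
  expect_equal(ds2$only_b, "g1")

  ds3 <- detection_sets(tbl, "control", "treated", min_count = 1e9)
  expect_length(ds3$shared, 0)
  expect_length(ds3$only_a, 0)
  expect_length(ds3$only_b, 0)
})

test_that("normalized counts carry Wilson intervals", {
  tbl <- tibble::tibble(
    sample = "s", condition = "control",
    gene = c("g1", "g2", "g3"),
    class = c("other", "other", "other"),
    count = c(50, 950, 0)
  )
  nc <- normalized_counts_ci(tbl, "s")
  expect_equal(nc$fraction, c(0.05, 0.95, 0))
  # closed-form Wilson score interval for 50/1000 at 95%
  z <- qnorm(0.975)
  n <- 1000; p <- 0.05
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  expect_equal(nc$ci_low[1], center - half, tolerance = 1e-12)
  expect_equal(nc$ci_high[1], center + half, tolerance = 1e-12)
  # independent route: stats::prop.test without continuity correction
  pt <- prop.test(50, 1000, correct = FALSE)$conf.int
  expect_equal(nc$ci_low[1], pt[1], tolerance = 1e-9)
  expect_equal(nc$ci_high[1], pt[2], tolerance = 1e-9)
  # edge cases
  expect_equal(nc$ci_low[3], 0)
  all_one <- tbl; all_one$count <- c(1000, 0, 0)
  nc1 <- normalized_counts_ci(all_one, "s")
  expect_equal(nc1$fraction[1], 1)
  expect_equal(nc1$ci_high[1], 1)
})

test_that("qPCR fold changes follow the efficiency model and range cap", {
  q0 <- simulate_ct(seed = 1, efficiency = 2, true_fold = 1, noise_sd = 0)
  fc0 <- qpcr_fold_change(q0, "globin_alpha_like", efficiency = 2)
  expect_equal(fc0$fold, 1)
  expect_true(fc0$in_range)

  q8 <- simulate_ct(seed = 1, efficiency = 2, true_fold = 8, noise_sd = 0)
  fc8 <- qpcr_fold_change(q8, "globin_alpha_like", efficiency = 2)
  expect_equal(fc8$delta_ct, 3)
  expect_equal(fc8$fold, 8)
  expect_true(fc8$in_range)

  q16 <- simulate_ct(seed = 1, efficiency = 2, true_fold = 16,
                     dilution_factor = 10, noise_sd = 0)
  fc16 <- qpcr_fold_change(q16, "globin_alpha_like", efficiency = 2)
  expect_equal(fc16$fold, 16)
  expect_false(fc16$in_range)

  expect_error(qpcr_fold_change(q8, "nope"), "not found")
  only_ctl <- q8[q8$condition == "control", ]
  expect_error(qpcr_fold_change(only_ctl, "globin_alpha_like"), "treated")
  expect_error(qpcr_fold_change(q8, "globin_alpha_like", efficiency = 2.5))
})

test_that("amplification efficiency is recovered from dilution series", {
  # perfect doubling: 10x dilution shifts Ct by log2(10) = 3.3219
  d <- data.frame(dilution_factor = c(1, 10, 100),
                  ct = 20 + log2(c(1, 10, 100)))
  expect_equal(qpcr_efficiency(d), 2, tolerance = 1e-3)
  # two-point series by hand: dCt = 4 over one 10x step
  # slope = -4, efficiency = 10^(1/4)
  d2 <- data.frame(dilution_factor = c(1, 10), ct = c(18, 22))
  expect_equal(qpcr_efficiency(d2), 10^(1 / 4), tolerance = 1e-12)
  # slope -3.6
  d3 <- data.frame(dilution_factor = c(1, 10, 100), ct = 20 + 3.6 * c(0, 1, 2))
  expect_equal(qpcr_efficiency(d3), 10^(1 / 3.6), tolerance = 1e-9)
  expect_error(qpcr_efficiency(data.frame(dilution_factor = c(10, 10),
                                          ct = c(20, 21))), "distinct")
})

test_that("depletion reports bundle the pairwise statistics", {
  tbl <- simulate_counts(sim_spec(seed = 64, depth = 2e5, n_other_genes = 200))
  rep <- depletion_report(tbl, "ctrl_1", "trt_1")
  expect_s3_class(rep, "depletion_report")
  g <- glance(rep)
  expect_gt(g$globin_reduction_fold, 5)
  expect_gt(g$spikein_r, 0.95)
  td <- tidy(rep)
  expect_setequal(td$class, c("globin_alpha", "globin_beta", "other", "spikein"))
  expect_s3_class(autoplot(rep), "ggplot")
  expect_output(print(rep), "globin prevalence")
})

test_that("count tables round-trip through the TSV reader", {
  tbl <- toy_counts()
  wide <- tidyr::pivot_wider(tbl[, c("gene", "sample", "count")],
                             names_from = "sample", values_from = "count")
  d <- withr::local_tempdir()
  write.table(wide, file.path(d, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(unique(tbl[, c("gene", "class")]), file.path(d, "annot.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(unique(tbl[, c("sample", "condition")]),
              file.path(d, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_counts(file.path(d, "counts.tsv"), file.path(d, "annot.tsv"),
                      file.path(d, "samples.tsv"))
  expect_equal(class_prevalence(back, "s1", "globin_beta"), 0.422)
  expect_equal(sum(back$count), sum(tbl$count))
})
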