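test_that("all generators are reproducible for a fixed seed", {
  expect_identical(make_globin_like(5, "beta_like"),
                   make_globin_like(5, "beta_like"))
  expect_identical(make_globin_like(5, "alpha_like"),
                   make_globin_like(5, "alpha_like"))
  expect_identical(make_spikein_set(5, n = 10), make_spikein_set(5, n = 10))
  expect_identical(simulate_counts(sim_spec(seed = 5, depth = 1e4,
                                            n_other_genes = 50)),
                   simulate_counts(sim_spec(seed = 5, depth = 1e4,
                                            n_other_genes = 50)))
  expect_identical(simulate_ct(5, noise_sd = 0.3), simulate_ct(5, noise_sd = 0.3))
  # and different seeds differ
  expect_false(identical(make_globin_like(5, "beta_like")$seq,
                         make_globin_like(6, "beta_like")$seq))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(make_globin_like(1, "beta_like"))
  invisible(simulate_counts(sim_spec(seed = 2, depth = 1e3, n_other_genes = 10)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("globin-like transcripts have the engineered accessibility", {
  for (seed in 1:5) {
    expect_true(assess_accessibility(make_globin_like(seed, "beta_like"))$accessible)
    expect_false(assess_accessibility(make_globin_like(seed, "alpha_like"))$accessible)
  }
  expect_error(make_globin_like(1, "beta_like", length = 80), ">= 100")
})

test_that("spike-in sets are poly-adenylated, laddered and arm-orthogonal", {
  b <- make_globin_like(71, "beta_like")
  d <- design_linear(b)
  sp <- make_spikein_set(71, n = 92, arm_seqs = d$arm3$arm_seq)
  expect_equal(nrow(sp), 92L)
  expect_true(all(substr(sp$seq, nchar(sp$seq) - 29, nchar(sp$seq)) ==
                    strrep("A", 30)))
  expect_equal(length(unique(sp$concentration)), 23L)
  expect_equal(nrow(screen_offtargets(d, sp)), 0L)
  # an impossible orthogonality constraint errors after bounded retries:
  # a poly-T arm's binding site is poly-A, which every tail contains
  expect_error(make_spikein_set(71, n = 2, arm_seqs = strrep("T", 12),
                                max_tries = 5), "orthogonal")
})

test_that("simulated counts hit the programmed globin fractions", {
  # no depletion: both conditions at the control fraction
  s0 <- sim_spec(seed = 72, depletion_efficiency = 0, depth = 1e5,
                 n_other_genes = 300)
  tbl0 <- simulate_counts(s0)
  for (smp in c("ctrl_1", "trt_1")) {
    p <- class_prevalence(tbl0, smp, c("globin_alpha", "globin_beta"))
    expect_lt(abs(p - 0.636), 0.01)
  }
  # default efficiency targets the measured treated prevalence
  tbl <- simulate_counts(sim_spec(seed = 72, depth = 1e6))
  p_ctl <- class_prevalence(tbl, "ctrl_1", c("globin_alpha", "globin_beta"))
  p_trt <- class_prevalence(tbl, "trt_1", c("globin_alpha", "globin_beta"))
  expect_lt(abs(p_ctl - 0.636), 0.01)
  expect_lt(abs(p_trt - 0.052), 0.01)
  expect_gt(reduction_fold(p_ctl, p_trt), 10)
  # alpha:beta split follows the configured share
  p_alpha <- class_prevalence(tbl, "ctrl_1", "globin_alpha")
  expect_lt(abs(p_alpha - 0.214), 0.01)
  expect_error(sim_spec(globin_fraction = 1.2))
  expect_error(sim_spec(depth = 0))
})

test_that("estimated prevalence falls inside its own Wilson interval at the
           nominal rate", {
  hits <- 0L
  n_rep <- 100L
  depth <- 1e5
  for (seed in seq_len(n_rep)) {
    tbl <- simulate_counts(sim_spec(seed = seed, depth = depth,
                                    n_other_genes = 100))
    x <- sum(tbl$count[tbl$sample == "ctrl_1" &
                         tbl$class %in% c("globin_alpha", "globin_beta")])
    ci <- wilson_interval(x, depth)
    if (ci[, "low"] <= 0.636 && 0.636 <= ci[, "high"]) hits <- hits + 1L
  }
  expect_gte(hits, 93L)
})

test_that("noiseless Ct tables invert exactly; noisy ones approximately", {
  q <- simulate_ct(seed = 73, efficiency = 1.9, true_fold = 6.5, noise_sd = 0)
  fc <- qpcr_fold_change(q, "globin_alpha_like", efficiency = 1.9)
  expect_equal(fc$fold, 6.5, tolerance = 1e-9)
  eff <- qpcr_efficiency(q[q$condition == "control", ])
  expect_equal(eff, 1.9, tolerance = 1e-9)

  qn <- simulate_ct(seed = 73, efficiency = 2, true_fold = 4, noise_sd = 0.1,
                    replicates = 8)
  fcn <- qpcr_fold_change(qn, "globin_alpha_like", efficiency = 2)
  expect_lt(abs(log2(fcn$fold) - 2), 0.5)
})

test_that("the full design-screen-simulate-evaluate pipeline runs from one seed", {
  seed <- 74
  beta <- make_globin_like(seed, "beta_like")
  alpha <- make_globin_like(seed, "alpha_like")
  designs <- list(design_linear(beta), design_linear(alpha),
                  design_circular(beta))
  for (d in designs) expect_true(design_passes(validate_design(d)))
  arms <- unlist(lapply(designs, function(d) {
    c(d$arm3$arm_seq, if (!is.null(d$arm5)) d$arm5$arm_seq)
  }))
  sp <- make_spikein_set(seed, n = 92, arm_seqs = arms)
  expect_true(check_spikein_compatibility(designs, sp)$pass)
  tbl <- simulate_counts(sim_spec(seed = seed, depth = 2e5, n_other_genes = 300))
  rep <- depletion_report(tbl, "ctrl_1", "trt_1")
  expect_gt(rep$globin_reduction_fold, 10)
  expect_gt(rep$spikein_r, 0.98)
  q <- simulate_ct(seed, true_fold = 8)
  expect_equal(qpcr_fold_change(q, "globin_alpha_like")$fold, 8)
})
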