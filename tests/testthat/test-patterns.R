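test_that("template encoding follows the 0:1:0 / 1:1:0 group assignment", {
  samples <- make_sample_table(reps = 2)
  tr <- encode_template(samples, "B", "TRANSIENT")
  expect_equal(unname(tr), c(0L, 0L, 1L, 1L, 0L, 0L))
  expect_equal(names(tr),
               c("B_CMS_1", "B_CMS_2", "B_CMS-R_1", "B_CMS-R_2",
                 "B_NH-R_1", "B_NH-R_2"))
  su <- encode_template(samples, "B", "SUSTAINED")
  expect_equal(unname(su), c(1L, 1L, 1L, 1L, 0L, 0L))
  # NH samples never enter the template design
  expect_false(any(grepl("_NH_", names(tr))))
})

test_that("template encoding errors name the missing strain and group", {
  samples <- make_sample_table(reps = 2)
  samples <- samples[!(samples$strain == "N" & samples$treatment == "CMS-R"), ]
  expect_error(encode_template(samples, "N", "TRANSIENT"), "N.*CMS-R")
  expect_error(encode_template(samples, "Z", "TRANSIENT"), "not present")
})

test_that("template fit matches the pooled two-sample t-test oracle", {
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(1, 2, 3, 7, 8, 9)
  fit <- fit_template(y, x)
  orc <- oracle_pooled_t(y, x)
  expect_equal(fit$p, orc$p, tolerance = 1e-10)
  expect_equal(fit$t, orc$t, tolerance = 1e-10)
  expect_equal(fit$df, orc$df)
  expect_equal(fit$beta, mean(y[x == 1]) - mean(y[x == 0]), tolerance = 1e-12)
})

test_that("template fit degenerates and symmetrizes correctly", {
  x <- c(0, 0, 1, 1, 0, 0)
  flat <- fit_template(rep(3.2, 6), x)
  expect_equal(flat$beta, 0)
  expect_equal(flat$p, 1)

  y <- c(5.1, 4.8, 6.2, 6.5, 5.0, 5.2)
  up <- fit_template(y, x)
  down <- fit_template(y, 1 - x)
  expect_equal(up$p, down$p, tolerance = 1e-12)
  expect_equal(up$beta, -down$beta, tolerance = 1e-12)
  expect_equal(sign(up$t), sign(up$beta))

  expect_error(fit_template(y, rep(1, 6)), "both 0 and 1")
  expect_error(fit_template(y[1:3], x[1:3]), "length")
})

test_that("template fit p-values equal the pooled t oracle on random designs", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    n1 <- sample(2:(n - 2), 1)
    x <- sample(c(rep(1, n1), rep(0, n - n1)))
    y <- rnorm(n, sd = runif(1, 0.1, 3))
    fit <- fit_template(y, x)
    orc <- oracle_pooled_t(y, x)
    expect_equal(fit$p, orc$p, tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # q-values never fall below the nominal p-values
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("NH-R vs CMS-R contrast computes linear-scale relative change", {
  same <- contrast_nhr_cmsr(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p, 1)
  expect_equal(same$rel_change, 0)

  doubled <- contrast_nhr_cmsr(c(5, 5.1, 4.9), c(6, 6.1, 5.9))
  expect_equal(doubled$rel_change, 1.0, tolerance = 1e-12)

  ten <- suppressWarnings(
    contrast_nhr_cmsr(c(5, 5), c(5 + log2(1.1), 5 + log2(1.1)))
  )
  expect_equal(ten$rel_change, 0.10, tolerance = 1e-12)

  expect_error(contrast_nhr_cmsr(5, c(5, 6)), "2 values per group")
})

test_that("the 10% filter is a strict inequality at the boundary", {
  samples <- make_sample_table(strains = "B", reps = 3)
  set.seed(55)
  mat <- matrix(8, nrow = 2, ncol = nrow(samples),
                dimnames = list(c("t_border", "t_small"),
                                samples$sample_id))
  cmsr <- samples$sample_id[samples$treatment == "CMS-R"]
  mat["t_border", cmsr] <- 8 + log2(1.1)
  mat["t_small", cmsr] <- 8 + log2(1.09)
  mat <- mat + matrix(rnorm(length(mat), sd = 1e-4), nrow = 2)

  # setting the threshold to the transcript's own realized relative
  # change pins the boundary exactly: strict ">" must fail there and a
  # hair below must pass
  calls0 <- call_stress_transcripts(mat, samples, fc_threshold = 0)
  border_rel <- calls0$rel_change[calls0$transcript == "t_border"]
  at <- call_stress_transcripts(mat, samples, fc_threshold = border_rel)
  expect_false(at$passes[at$transcript == "t_border"])
  below <- call_stress_transcripts(mat, samples,
                                   fc_threshold = border_rel - 1e-9)
  expect_true(below$passes[below$transcript == "t_border"])
  # a 9% true change fails the default 10% threshold regardless of p
  calls10 <- call_stress_transcripts(mat, samples, fc_threshold = 0.10)
  expect_false(calls10$passes[calls10$transcript == "t_small"])
})

test_that("planted transcripts are called with the planted direction", {
  cfg <- sim_config(n_transcripts = 200, seed = 5,
                    planted_fraction = c(B = 0.1, N = 0.1, D = 0.1),
                    overlap_spec = c("B:N" = 5, "B:D" = 5, "N:D" = 5,
                                     "B:N:D" = 3))
  sim <- simulate_expression(cfg)
  calls <- call_stress_transcripts(sim$matrix, sim$samples)
  merged <- merge(sim$truth, calls, by = c("transcript", "strain"),
                  suffixes = c("_true", "_called"))
  expect_gt(mean(merged$passes), 0.9)
  rec <- merged[merged$passes, ]
  expect_true(all(rec$direction_true == rec$direction_called))
})

test_that("raising the fold-change threshold never adds passing calls", {
  cfg <- sim_config(n_transcripts = 300, seed = 9,
                    effect_size = 0.3, residual_sd = 0.4,
                    planted_fraction = c(B = 0.2, N = 0.2, D = 0.2),
                    overlap_spec = null_overlap_spec())
  sim <- simulate_expression(cfg)
  thresholds <- c(0, 0.05, 0.10, 0.20, 0.50)
  n_pass <- vapply(thresholds, function(th) {
    sum(call_stress_transcripts(sim$matrix, sim$samples,
                                fc_threshold = th)$passes)
  }, numeric(1))
  expect_true(all(diff(n_pass) <= 0))
})

test_that("direction bias test is the 1-df goodness-of-fit chi-square", {
  calls <- region_calls(sprintf("t%03d", 1:100), "B",
                        list(rep(c("UP", "DOWN"), each = 50)))
  even <- direction_bias_test(calls, "B")
  expect_equal(even$chisq, 0)
  expect_equal(even$p, 1)

  calls2 <- region_calls(sprintf("t%03d", 1:40), "N",
                         list(rep(c("UP", "DOWN"), times = c(30, 10))))
  skewed <- direction_bias_test(calls2, "N")
  expect_equal(skewed$n_up, 30)
  expect_equal(skewed$n_down, 10)
  expect_equal(skewed$chisq, 10.0)
  # independent upper-tail form for a 1-df chi-square: 2*P(Z > sqrt(x))
  expect_equal(skewed$p, 2 * pnorm(-sqrt(10)), tolerance = 1e-12)

  expect_error(direction_bias_test(calls2, "D"), "no passing calls")
})
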