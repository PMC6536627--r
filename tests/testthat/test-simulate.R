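test_that("expression generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_transcripts = 100, seed = 7,
                    overlap_spec = c("B:N" = 2, "B:D" = 2, "N:D" = 2,
                                     "B:N:D" = 1))
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  expect_identical(a$samples, b$samples)
})

test_that("matrix dimensions follow the design and NH stays at baseline", {
  cfg <- sim_config(n_transcripts = 50, replicates_per_cell = 3, seed = 2,
                    residual_sd = 1e-9, effect_size = 1,
                    planted_fraction = c(B = 0.2, N = 0, D = 0),
                    overlap_spec = null_overlap_spec())
  sim <- simulate_expression(cfg)
  expect_equal(dim(sim$matrix), c(50, 3 * 4 * 3))
  expect_equal(nrow(sim$samples), ncol(sim$matrix))
  # with vanishing noise, NH samples sit at the per-transcript baseline
  nh <- sim$samples$sample_id[sim$samples$treatment == "NH"]
  planted <- unique(sim$truth$transcript)
  baseline <- rowMeans(sim$matrix[, nh, drop = FALSE])
  all_cols <- sim$matrix[setdiff(rownames(sim$matrix), planted), , drop = FALSE]
  expect_lt(max(abs(all_cols - rowMeans(all_cols))), 1e-6)
  # planted template shifts appear only in the planted strain's CMS-R /
  # CMS columns, in the planted direction
  for (j in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[j, ]
    grp <- if (tr$template == "TRANSIENT") "CMS-R" else c("CMS", "CMS-R")
    cols <- sim$samples$sample_id[sim$samples$strain == tr$strain &
                                    sim$samples$treatment %in% grp]
    shift <- mean(sim$matrix[tr$transcript, cols]) - baseline[tr$transcript]
    expect_equal(unname(shift), ifelse(tr$direction == "UP", 1, -1),
                 tolerance = 1e-6)
  }
})

test_that("degenerate noise with no effect collapses to the baseline", {
  cfg <- sim_config(n_transcripts = 20, seed = 3, effect_size = 0,
                    residual_sd = 1e-12,
                    planted_fraction = c(B = 0.5, N = 0, D = 0),
                    overlap_spec = null_overlap_spec())
  sim <- simulate_expression(cfg)
  spread <- apply(sim$matrix, 1, function(r) diff(range(r)))
  expect_lt(max(spread), 1e-9)
})

test_that("empirical planted effect matches the configured size at large n", {
  cfg <- sim_config(n_transcripts = 1, strains = "B",
                    replicates_per_cell = 1e4, seed = 11,
                    planted_fraction = c(B = 1), up_fraction = c(B = 1),
                    overlap_spec = null_overlap_spec())
  sim <- simulate_expression(cfg)
  cmsr <- sim$samples$sample_id[sim$samples$treatment == "CMS-R"]
  nhr <- sim$samples$sample_id[sim$samples$treatment == "NH-R"]
  diff_hat <- mean(sim$matrix[1, cmsr]) - mean(sim$matrix[1, nhr])
  expect_equal(diff_hat, 1.0, tolerance = 0.02)
})

test_that("config validation rejects infeasible and invalid settings", {
  expect_error(sim_config(replicates_per_cell = 1), "replicates")
  expect_error(sim_config(residual_sd = 0), "residual_sd")
  expect_error(sim_config(planted_fraction = c(B = 1.2, N = 0, D = 0)),
               "\\[0, 1\\]")
  expect_error(sim_config(n_transcripts = 100,
                          overlap_spec = c("B:N" = 90, "B:D" = 90,
                                           "N:D" = 0, "B:N:D" = 0)),
               "exceed")
  expect_error(sim_config(overlap_spec = c("B" = 5)), "multi-strain")
  expect_error(pheno_config(heart_sd = -1), "positive")
  expect_error(pheno_config(fcort_return_week = 9), "return_week")
})

test_that("planted membership blocks hit the configured region counts", {
  cfg <- sim_config(n_transcripts = 1000, seed = 4,
                    planted_fraction = c(B = 0.02, N = 0.01, D = 0.05),
                    overlap_spec = c("B:N" = 3, "B:D" = 4, "N:D" = 5,
                                     "B:N:D" = 2))
  sim <- simulate_expression(cfg)
  per_tx <- split(sim$truth$strain, sim$truth$transcript)
  regions <- table(vapply(per_tx, function(s) {
    paste(intersect(c("B", "N", "D"), s), collapse = ":")
  }, character(1)))
  expect_equal(unname(regions[c("B:N", "B:D", "N:D", "B:N:D")]),
               c(3, 4, 5, 2), ignore_attr = TRUE)
  expect_equal(unname(regions[c("B", "N", "D")]), c(20, 10, 50),
               ignore_attr = TRUE)
})

test_that("phenotype generator reproduces the configured heart deficit", {
  cfg <- pheno_config(seed = 21,
                      group_sizes = c("NH" = 2500, "NH-R" = 2500,
                                      "CMS" = 2500, "CMS-R" = 2500))
  tab <- simulate_phenotypes(cfg)
  tab <- pool_groups(tab)
  d <- mean(tab$heart_mg[tab$pooled_group == "NHgroup"]) -
    mean(tab$heart_mg[tab$pooled_group == "CMSgroup"])
  expect_equal(d, 10.4, tolerance = 0.5)
})

test_that("phenotype generator degenerates cleanly and is deterministic", {
  cfg <- pheno_config(seed = 5, heart_cms_deficit_mg = 0, heart_sd = 1e-9)
  tab <- pool_groups(simulate_phenotypes(cfg))
  for (s in c("B", "N", "D")) {
    sub <- tab[tab$strain == s, ]
    expect_equal(mean(sub$heart_mg[sub$pooled_group == "NHgroup"]),
                 mean(sub$heart_mg[sub$pooled_group == "CMSgroup"]),
                 tolerance = 1e-8)
  }
  expect_identical(simulate_phenotypes(cfg), simulate_phenotypes(cfg))
  # printed strain orderings hold in expectation
  hm <- tapply(tab$heart_mg, tab$strain, mean)
  expect_true(hm["D"] > hm["N"] && hm["N"] >= hm["B"] - 1)
})

test_that("fecal CORT trajectory rises at week 1 and habituates by the return week", {
  cfg <- pheno_config(seed = 13, fcort_n = c(B = 4000, N = 4000, D = 4000))
  fc <- simulate_fcort_timecourse(cfg)
  wk <- tapply(fc$fcort[fc$strain == "D"], fc$week[fc$strain == "D"], mean)
  expect_equal(unname(wk["0"]), 1.93, tolerance = 0.02)
  expect_gt(wk["1"], wk["0"] + 0.5 * (cfg$fcort_week1_elevation - 1) * 1.93)
  # from the return week (4) onward the expectation is back at baseline
  for (w in as.character(4:7)) {
    expect_equal(unname(wk[w]), unname(wk["0"]), tolerance = 0.02)
  }
  # intermediate weeks decline monotonically toward baseline
  expect_true(wk["1"] > wk["2"] && wk["2"] > wk["3"] && wk["3"] > wk["4"] - 0.02)
})

test_that("an elevation of 1 yields a flat expected trajectory", {
  cfg <- pheno_config(seed = 13, fcort_week1_elevation = 1,
                      fcort_baseline_sd = c(B = 1e-9, N = 1e-9, D = 1e-9))
  fc <- simulate_fcort_timecourse(cfg)
  wk <- tapply(fc$fcort[fc$strain == "B"], fc$week[fc$strain == "B"], mean)
  expect_lt(diff(range(wk)), 1e-7)
  expect_identical(simulate_fcort_timecourse(cfg),
                   simulate_fcort_timecourse(cfg))
})
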