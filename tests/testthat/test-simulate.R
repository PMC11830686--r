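test_that("identical truth and seed give bit-identical cohorts", {
  t1 <- default_sim_truth(n_markers = 30, n_signal = 4, seed = 5)
  t2 <- default_sim_truth(n_markers = 30, n_signal = 4, seed = 5)
  a <- simulate_cohort(t1, c(SjD = 40, HC = 20))
  b <- simulate_cohort(t2, c(SjD = 40, HC = 20))
  expect_identical(a$mfi$values, b$mfi$values)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$delta, b$truth$delta)

  c3 <- simulate_cohort(default_sim_truth(30, 4, seed = 6), c(SjD = 40, HC = 20))
  expect_false(identical(a$mfi$values, c3$mfi$values))
})

test_that("the generator rejects inconsistent requests", {
  truth <- planted_panel_truth(n_null = 4, seed = 1)
  expect_error(simulate_cohort(truth, c(SjD = 10, RA = 5)),
               "absent from the prevalence map")
  expect_error(simulate_cohort(truth, c(10, 5)), "named")
  expect_error(attach_clinical_outcomes(simulate_cohort(truth, c(SjD = 10, HC = 12))),
               "no association ledger")
  bad_assoc <- data.frame(marker_key = "NOPE|IgG", outcome = "x",
                          beta = 1, beta0 = 0)
  expect_error(sim_truth(truth$markers, truth$prevalence,
                         associations = bad_assoc),
               "unknown marker")
})

test_that("separation limit: certain responders are always called", {
  # prevalence 1 in SjD, 0 in HC, effect 10 sigma
  markers <- data.frame(marker_id = c("HIT", "BG1", "BG2"), isotype = "IgG",
                        mu = 11, sigma = 0.5, effect = c(5, 0, 0),
                        source = "discovery")
  prev <- matrix(0, 3, 2, dimnames = list(NULL, c("SjD", "HC")))
  prev[1, "SjD"] <- 1
  truth <- sim_truth(markers, prev, rng_seed = 9)
  sim <- simulate_cohort(truth, c(SjD = 50, HC = 40))
  m <- median_center(log2_transform(sim$mfi))
  cuts <- build_cutoff_table(m, sim$meta, q = 0.98)
  calls <- binarize(m, cuts)$calls[, "HIT|IgG"]
  expect_true(all(calls[sim$meta$group == "SjD"]))
  expect_false(any(calls[sim$meta$group == "HC"]))
})

test_that("planted prevalence is recovered within the binomial envelope", {
  truth <- planted_panel_truth(n_null = 10, prevalences = c(0.15, 0.1, 0.05),
                               seed = 23)
  sim <- simulate_cohort(truth, c(SjD = 400, HC = 20))
  frac <- mean(sim$truth$delta[sim$meta$group == "SjD", "AG001|IgG"])
  env <- qbinom(c(0.005, 0.995), 400, 0.15) / 400
  expect_gte(frac, env[1])
  expect_lte(frac, env[2])
})

test_that("median centering removes the planted sample offsets", {
  truth <- planted_panel_truth(n_null = 30, prevalences = c(0, 0, 0), seed = 77)
  sim <- simulate_cohort(truth, c(SjD = 80, HC = 40))
  m <- median_center(log2_transform(sim$mfi))
  resid <- apply(m$values, 1, median)           # exactly zero after centering
  expect_true(all(abs(resid) < 1e-12))
  # residual row means no longer track the planted offsets
  offs <- sim$truth$sample_offsets
  expect_lt(abs(cor(rowMeans(m$values), offs)), 0.2)
})

test_that("Ro/SSA status mirrors the designated RO60 channel", {
  truth <- default_sim_truth(n_markers = 20, n_signal = 3, seed = 3)
  sim <- simulate_cohort(truth, c(SjD = 60, HC = 30))
  expect_equal(sim$meta$ro_ssa_positive,
               sim$truth$delta[, "RO60|IgG"] == 1L,
               ignore_attr = TRUE)
  sjd_rate <- mean(sim$meta$ro_ssa_positive[sim$meta$group == "SjD"])
  expect_gt(sjd_rate, 0.35)
  expect_lt(sjd_rate, 0.85)
})

test_that("clinical outcomes honour the ledger and missingness bookkeeping", {
  truth <- planted_assoc_truth(n_null = 5, beta = 0, beta0 = 0,
                               missing_frac = 0.3, seed = 41)
  sim <- attach_clinical_outcomes(simulate_cohort(truth, c(SjD = 500, HC = 12)))
  y <- sim$meta$pulmonary[sim$meta$group == "SjD"]
  expect_true(all(is.na(sim$meta$pulmonary[sim$meta$group == "HC"])))
  # with beta = 0 and beta0 = 0 the outcome is a fair coin
  expect_gt(mean(y, na.rm = TRUE), 0.40)
  expect_lt(mean(y, na.rm = TRUE), 0.60)
  # missingness is in the requested ballpark and complete cases count exactly
  expect_gt(mean(is.na(y)), 0.2)
  expect_lt(mean(is.na(y)), 0.4)
  m <- median_center(log2_transform(sim$mfi))
  res <- association_screen(m, sim$meta, "pulmonary")
  expect_true(all(res$n_complete == sum(!is.na(y))))
})

test_that("disjoint planting keeps marginals and removes overlap", {
  truth <- planted_panel_truth(seed = 13)
  sim <- simulate_disjoint_cohort(truth, c(SjD = 200, HC = 118))
  d <- sim$truth$delta[sim$meta$group == "SjD", 1:3]
  expect_true(all(rowSums(d) <= 1))             # pairwise disjoint
  expect_true(all(colMeans(d) > 0.02))          # all three actually planted
  # values are consistent with the recorded indicators
  m <- log2(sim$mfi$values[sim$meta$group == "SjD", 1])
  expect_gt(median(m[d[, 1] == 1]), median(m[d[, 1] == 0]) + 1.5)
})
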