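test_that("cutoff calibration follows the nearest-rank and escalation rules", {
  # 98% quantile of 1..10 is the maximum: nobody above, no escalation
  r <- calibrate_cutoff(1:10, c(15, 20), q = 0.98)
  expect_equal(r$cutoff, 10)
  expect_false(r$escalated)
  expect_equal(r$n_hc_pos, 0)

  # base cutoff already excludes every control: nothing to escalate
  r <- calibrate_cutoff(c(1:9, 12), c(15, 20), q = 0.98)
  expect_equal(r$cutoff, 12)
  expect_false(r$escalated)

  # q = 0.9 leaves one control positive; raising to 12 removes it while
  # both cases stay positive
  r <- calibrate_cutoff(c(1:9, 12), c(15, 20), q = 0.9)
  expect_equal(r$base_cutoff, 9)
  expect_equal(r$cutoff, 12)
  expect_true(r$escalated)
  expect_equal(r$n_case_pos, 2)
  expect_equal(r$n_hc_pos, 0)

  expect_error(calibrate_cutoff(1:5, 1:3), "at least 10 HC")
})

test_that("calibration and escalation match the brute-force scan oracle", {
  set.seed(77)
  for (i in 1:150) {
    hc <- sample(0:30, sample(10:25, 1), replace = TRUE)
    case <- sample(0:40, sample(5:20, 1), replace = TRUE)
    q <- sample(c(0.8, 0.9, 0.95, 0.98), 1)
    got <- calibrate_cutoff(hc, case, q)
    want <- cutoff_scan_oracle(hc, case, q)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$base_cutoff, want$base)
    expect_equal(got$escalated, want$escalated)
    # escalation never changes case sensitivity, never lowers HC specificity
    expect_equal(sum(case > got$cutoff), sum(case > want$base))
    expect_lte(sum(hc > got$cutoff), sum(hc > want$base))
  }
})

test_that("binarization is strict and recomputable from a persisted table", {
  cohort <- panel_study(3, n_sjd = 40, n_hc = 15, n_null = 4)
  m <- cohort$m
  # boundary rule: a value equal to its cutoff is negative
  j <- 1L
  cut <- cohort$cutoffs$cutoff[j]
  m$values[1, j] <- cut
  b <- binarize(m, cohort$cutoffs)
  expect_false(b$calls[1, j])

  path <- tempfile(fileext = ".csv")
  write_results(cohort$cutoffs, path)
  b2 <- binarize(m, read_cutoff_table(path))
  expect_identical(b2$calls, b$calls)

  low <- m
  low$values[] <- min(cohort$cutoffs$cutoff) - 1
  expect_false(any(binarize(low, cohort$cutoffs)$calls))

  expect_error(binarize(m, cohort$cutoffs[-1, ]), "no cutoff for marker")
  expect_true(all(cohort$cutoffs$cutoff >= cohort$cutoffs$base_cutoff))
})

test_that("Fisher exact p matches hand enumeration and known tables", {
  # [[3,0],[0,3]]: only the two extreme tables, each 1/20
  expect_equal(fisher_exact_table(matrix(c(3, 0, 0, 3), 2, byrow = TRUE)), 0.1)
  expect_equal(fisher_exact_table(matrix(c(1, 1, 1, 1), 2, byrow = TRUE)), 1)
  expect_warning(p <- fisher_exact(c(FALSE, FALSE), c(FALSE, FALSE)),
                 "degenerate")
  expect_equal(p, 1)
  expect_equal(fisher_exact(c(TRUE, TRUE, TRUE, FALSE), c(FALSE, FALSE, FALSE)),
               fisher_enum_oracle(3, 1, 0, 3))
})

test_that("prevalence table counts, conserves and reports percent", {
  cohort <- panel_study(9, n_sjd = 16, n_hc = 12, n_null = 3)
  b <- cohort$binary
  b$calls[] <- FALSE
  b$calls[1:3, 1] <- TRUE                     # 3 of 16 SjD positive
  pt <- prevalence_table(b, cohort$meta)
  row <- pt[pt$marker_key == colnames(b$calls)[1] & pt$group == "SjD", ]
  expect_equal(row$percent, 18.75)
  expect_equal(row$n_pos, 3L)
  expect_true(all(pt$n_pos + (pt$n - pt$n_pos) == pt$n))
  expect_true(all(pt$prevalence >= 0 & pt$prevalence <= 1))
})

test_that("co-prevalence is a symmetric set-intersection summary", {
  calls <- matrix(FALSE, 10, 2,
                  dimnames = list(sprintf("s%d", 1:10), c("A|IgG", "B|IgG")))
  calls[1:3, 1] <- TRUE
  calls[2:4, 2] <- TRUE
  b <- structure(list(calls = calls,
                      markers = seropanel:::parse_marker_keys(colnames(calls))),
                 class = "binary_matrix")
  cp <- coprevalence_matrix(b)
  expect_equal(unname(diag(cp)), c(0.3, 0.3))
  expect_equal(cp["A|IgG", "B|IgG"], 0.2)
  expect_equal(cp["B|IgG", "A|IgG"], cp["A|IgG", "B|IgG"])

  # off-diagonal bounded by the smaller diagonal, for random calls
  set.seed(12)
  calls2 <- matrix(runif(200) < 0.3, 20, 10,
                   dimnames = list(NULL, sprintf("M%d|IgA", 1:10)))
  b2 <- structure(list(calls = calls2,
                       markers = seropanel:::parse_marker_keys(colnames(calls2))),
                  class = "binary_matrix")
  cp2 <- coprevalence_matrix(b2)
  for (i in 1:9) for (j in (i + 1):10)
    expect_lte(cp2[i, j], min(cp2[i, i], cp2[j, j]))
})
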