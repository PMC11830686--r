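# small hand-built binary cohort: explicit positives per marker
hand_binary <- function(positives, n, keys = names(positives)) {
  calls <- matrix(FALSE, n, length(positives),
                  dimnames = list(sprintf("t%02d", seq_len(n)), keys))
  for (k in seq_along(positives)) calls[positives[[k]], k] <- TRUE
  structure(list(calls = calls,
                 markers = seropanel:::parse_marker_keys(keys)),
            class = "binary_matrix")
}

test_that("OR-rule prediction and counting metrics", {
  b <- hand_binary(list("A|IgG" = 1, "B|IgG" = integer(0), "C|IgG" = 1:3), 10)
  p3 <- panel_model(c("A|IgG", "B|IgG", "C|IgG"))
  expect_identical(unname(predict_panel(p3, b)),
                   c(rep(TRUE, 3), rep(FALSE, 7)))
  p1 <- panel_model("C|IgG")
  expect_identical(predict_panel(p1, b), b$calls[, "C|IgG"])
  expect_error(predict_panel(panel_model("Z|IgG"), b), "absent")

  meta <- data.frame(sample_id = rownames(b$calls),
                     group = c(rep("SjD", 6), rep("HC", 4)),
                     ro_ssa_positive = NA)
  m <- evaluate_panel(p3, b, meta, target = "SjD")
  expect_equal(m$sensitivity, 0.5)       # 3 of 6 SjD covered
  expect_equal(m$specificity_hc, 1)
  expect_equal(unname(m$sensitivity_ci),
               unname(binom.test(3, 6)$conf.int[1:2]))
})

test_that("adding a marker never hurts sensitivity nor helps specificity", {
  cohort <- panel_study(21, n_sjd = 60, n_hc = 30, n_null = 8)
  keys <- colnames(cohort$binary$calls)
  base <- panel_model(keys[1:2])
  bigger <- panel_model(keys[1:3])
  mb <- evaluate_panel(base, cohort$binary, cohort$meta, target = "SjD")
  mB <- evaluate_panel(bigger, cohort$binary, cohort$meta, target = "SjD")
  expect_gte(mB$sensitivity, mb$sensitivity)
  expect_lte(mB$specificity_hc, mb$specificity_hc)
})

test_that("forward selection picks complementary markers greedily", {
  b <- hand_binary(list("A|IgG" = 1:4, "B|IgG" = 1:3, "C|IgG" = 5:6), 10)
  meta <- data.frame(sample_id = rownames(b$calls), group = "SjD",
                     ro_ssa_positive = NA)
  hc <- hand_binary(list("A|IgG" = integer(0), "B|IgG" = integer(0),
                         "C|IgG" = integer(0)), 20)
  rownames(hc$calls) <- sprintf("h%02d", 1:20)
  all_b <- structure(list(calls = rbind(b$calls, hc$calls), markers = b$markers),
                     class = "binary_matrix")
  all_meta <- rbind(meta, data.frame(sample_id = rownames(hc$calls),
                                     group = "HC", ro_ssa_positive = NA))

  panel <- forward_select_panel(all_b, all_meta, target = "SjD", max_k = 2)
  expect_identical(panel$markers, c("A|IgG", "C|IgG"))
  expect_equal(panel$metrics$sensitivity, 0.6)
  expect_equal(panel$gains, c(4, 2))

  seed_only <- forward_select_panel(all_b, all_meta, target = "SjD", max_k = 1)
  expect_identical(seed_only$markers, "A|IgG")

  # B is nested in A: it must not be chosen while C still adds coverage
  p3 <- forward_select_panel(all_b, all_meta, target = "SjD", max_k = 3)
  expect_identical(p3$markers[1:2], c("A|IgG", "C|IgG"))
})

test_that("the specificity floor is enforced and reported", {
  b <- hand_binary(list("A|IgG" = 1:5), 10)
  meta <- data.frame(sample_id = rownames(b$calls), group = "SjD",
                     ro_ssa_positive = NA)
  hc <- matrix(TRUE, 10, 1, dimnames = list(sprintf("h%d", 1:10), "A|IgG"))
  all_b <- structure(list(calls = rbind(b$calls, hc), markers = b$markers),
                     class = "binary_matrix")
  all_meta <- rbind(meta, data.frame(sample_id = rownames(hc),
                                     group = "HC", ro_ssa_positive = NA))
  expect_error(forward_select_panel(all_b, all_meta, target = "SjD",
                                    min_spec_hc = 0.95),
               "specificity floor \\(min_spec_hc = 0.95\\)")
})

test_that("greedy selection matches brute force on small instances", {
  set.seed(55)
  agree <- 0L
  for (i in 1:30) {
    n_t <- 25; n_h <- 40; p <- sample(6:10, 1)
    keys <- sprintf("M%02d|IgG", seq_len(p))
    tc <- matrix(runif(n_t * p) < runif(p, 0.05, 0.4)[col(matrix(0, n_t, p))],
                 n_t, p, dimnames = list(sprintf("t%d", 1:n_t), keys))
    hcp <- matrix(runif(n_h * p) < 0.02, n_h, p,
                  dimnames = list(sprintf("h%d", 1:n_h), keys))
    b <- structure(list(calls = rbind(tc, hcp),
                        markers = seropanel:::parse_marker_keys(keys)),
                   class = "binary_matrix")
    meta <- data.frame(sample_id = rownames(b$calls),
                       group = c(rep("SjD", n_t), rep("HC", n_h)),
                       ro_ssa_positive = NA)
    k <- sample(2:3, 1)
    panel <- tryCatch(
      forward_select_panel(b, meta, target = "SjD", max_k = k,
                           min_spec_hc = 0.9),
      error = function(e) NULL)
    if (is.null(panel)) next
    got <- sum(rowSums(tc[, panel$markers, drop = FALSE]) > 0)
    opt <- best_panel_oracle(tc, hcp, min(k, length(panel$markers)), 0.9)
    # submodular union coverage: greedy is within (1 - 1/e) of optimal
    expect_gte(got, ceiling((1 - exp(-1)) * opt))
    if (got == opt) agree <- agree + 1L
  }
  expect_gt(agree, 20L)   # and usually exactly optimal

  # disjoint responder sets: greedy is exactly optimal
  b <- hand_binary(list("A|IgG" = 1:4, "B|IgG" = 5:7, "C|IgG" = 8:9,
                        "D|IgG" = 10), 12)
  meta <- data.frame(sample_id = rownames(b$calls), group = "SjD",
                     ro_ssa_positive = NA)
  hcp <- matrix(FALSE, 15, 4, dimnames = list(sprintf("h%d", 1:15),
                                              colnames(b$calls)))
  all_b <- structure(list(calls = rbind(b$calls, hcp), markers = b$markers),
                     class = "binary_matrix")
  all_meta <- rbind(meta, data.frame(sample_id = rownames(hcp), group = "HC",
                                     ro_ssa_positive = NA))
  p3 <- forward_select_panel(all_b, all_meta, target = "SjD", max_k = 3)
  expect_identical(p3$markers, c("A|IgG", "B|IgG", "C|IgG"))
  expect_equal(sum(rowSums(b$calls[, p3$markers]) > 0),
               best_panel_oracle(b$calls, hcp, 3, 0.95))
})

test_that("PCA diagnostics expose geometry and are order-equivariant", {
  # collinear cloud: one component carries all variance
  x <- cbind(seq(0, 1, length.out = 10), 2 * seq(0, 1, length.out = 10))
  colnames(x) <- c("A|IgG", "B|IgG"); rownames(x) <- sprintf("s%d", 1:10)
  m <- mfi_matrix(x, scale = "log2_centered")
  qc <- pca_qc(m)
  expect_equal(qc$explained[1], 1)

  set.seed(8)
  y <- matrix(rnorm(60), 12, 5,
              dimnames = list(sprintf("s%d", 1:12), sprintf("M%d|IgA", 1:5)))
  m2 <- mfi_matrix(y, scale = "log2_centered")
  qc2 <- pca_qc(m2)
  expect_true(all(diff(qc2$explained) <= 1e-12))
  expect_lte(sum(qc2$explained), 1 + 1e-12)

  perm <- sample(12)
  qc3 <- pca_qc(mfi_matrix(y[perm, ], scale = "log2_centered"))
  for (pc in 1:2) {
    a <- qc2$scores[perm, pc]; bb <- qc3$scores[, pc]
    expect_true(max(abs(a - bb)) < 1e-8 || max(abs(a + bb)) < 1e-8)
  }

  flat <- mfi_matrix(matrix(1, 5, 3, dimnames = list(sprintf("s%d", 1:5),
                                                     sprintf("K%d|IgG", 1:3))),
                     scale = "log2_centered")
  expect_error(pca_qc(flat), "rank")
})
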