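# Independent brute-force oracles. Each re-derives its statistic from
# first principles, sharing no code with the implementation under test.

# two-sided Mann-Whitney p by full enumeration of group labelings
mw_perm_oracle <- function(case, control) {
  x <- c(case, control)
  n1 <- length(case); n <- length(x)
  u_stat <- function(idx) {
    a <- x[idx]; b <- x[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  labelings <- combn(n, n1)
  u_all <- apply(labelings, 2L, u_stat)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# two-sided Fisher p by direct enumeration over the hypergeometric
# support, with probabilities from factorials (no dhyper)
fisher_enum_oracle <- function(a, b, c, d) {
  k <- a + b; m <- a + c
  total <- a + b + c + d
  if (k == 0 || c + d == 0 || m == 0 || total - m == 0) return(1)
  lp <- function(x) {
    lchoose(m, x) + lchoose(total - m, k - x) - lchoose(total, k)
  }
  support <- max(0, k - (total - m)):min(k, m)
  probs <- exp(vapply(support, lp, 0))
  sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
}

# SAM permutation p by full enumeration, d re-derived from scratch
sam_perm_oracle <- function(case, control, s0) {
  x <- c(case, control)
  n1 <- length(case); n <- length(x)
  d_stat <- function(idx) {
    a <- x[idx]; b <- x[-idx]
    sp <- sqrt((1 / length(a) + 1 / length(b)) *
                 (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp + s0)
  }
  d_obs <- d_stat(seq_len(n1))
  d_all <- apply(combn(n, n1), 2L, d_stat)
  mean(abs(d_all) >= abs(d_obs) - 1e-12)
}

# Benjamini-Hochberg step-up from its closed-form definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# logistic regression by explicit Newton-Raphson on the log-likelihood
nr_logistic_oracle <- function(y, x, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- crossprod(X, y - p)
    H <- crossprod(X * (p * (1 - p)), X)
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  z <- beta / se
  list(coefficient = unname(beta[2L]), se = unname(se[2L]),
       p_value = unname(2 * pnorm(-abs(z[2L]))))
}

# exhaustive best k-subset OR-panel by union coverage under an HC
# specificity floor; returns the best coverage count
best_panel_oracle <- function(target_calls, hc_calls, k, min_spec_hc) {
  p <- ncol(target_calls)
  best <- -1L
  for (cols in as.data.frame(combn(p, k))) {
    spec <- mean(rowSums(hc_calls[, cols, drop = FALSE]) == 0)
    if (spec < min_spec_hc) next
    cov <- sum(rowSums(target_calls[, cols, drop = FALSE]) > 0)
    if (cov > best) best <- cov
  }
  best
}

# fast exhaustive 3-subset optimum (coverage count) under the floor,
# via 3-way uncovered-count tensors
best_triple_oracle <- function(target_calls, hc_calls, min_spec_hc) {
  Mt <- 1 - target_calls; Mh <- 1 - hc_calls
  storage.mode(Mt) <- "double"; storage.mode(Mh) <- "double"
  p <- ncol(Mt); n_t <- nrow(Mt); n_h <- nrow(Mh)
  max_hc_pos <- floor(n_h * (1 - min_spec_hc) + 1e-9)
  best <- -1L
  for (k in seq_len(p)) {
    unc_t <- crossprod(Mt * Mt[, k], Mt)   # uncovered target counts (i,j | k)
    unc_h <- crossprod(Mh * Mh[, k], Mh)
    ok <- (n_h - unc_h) <= max_hc_pos
    cov <- n_t - unc_t
    cov[!ok] <- -1L
    best <- max(best, max(cov))
  }
  best
}

# brute-force cutoff calibration: try every observed value as cutoff
cutoff_scan_oracle <- function(hc, case, q) {
  base <- sort(hc)[ceiling(q * length(hc))]
  sens0 <- sum(case > base); spec0 <- sum(hc > base)
  best <- base
  for (cand in sort(unique(c(hc, case)))) {
    if (cand <= base) next
    if (sum(case > cand) == sens0 && sum(hc > cand) < spec0 && cand > best)
      best <- cand
  }
  list(cutoff = best, escalated = best > base, base = base)
}
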