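# Shared cohort builders for recovery / calibration studies.

# planted-panel study: 200 Ro/SSA-negative SjD + 118 HC, 3 complementary
# planted markers among 50 nulls, preprocessed to the analysis scale,
# with calibrated cutoffs and binarized calls
panel_study <- function(seed, n_sjd = 200, n_hc = 118, n_null = 50,
                        prevalences = c(0.12, 0.10, 0.08)) {
  truth <- planted_panel_truth(n_null = n_null, prevalences = prevalences,
                               seed = seed)
  sim <- simulate_disjoint_cohort(truth, c(SjD = n_sjd, HC = n_hc))
  m <- median_center(log2_transform(sim$mfi))
  cutoffs <- build_cutoff_table(m, sim$meta, case_group = "SjD", q = 0.98)
  binary <- binarize(m, cutoffs)
  list(sim = sim, m = m, cutoffs = cutoffs, binary = binary,
       meta = sim$meta, planted = marker_key(truth$markers)[1:3])
}

# apply an existing cutoff table to a freshly simulated cohort
binarize_fresh <- function(truth, n_per_group, cutoffs) {
  sim <- simulate_cohort(truth, n_per_group)
  m <- median_center(log2_transform(sim$mfi))
  list(binary = binarize(m, cutoffs), meta = sim$meta)
}
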