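# Shared fixtures and independent oracles used across test files.

summ <- function(n, m, v) arm_summary(n = n, mean_change = m, var_change = v)

# Construct the named posterior list decide_interim() expects.
post_list <- function(p_f3 = NULL, p_rs = NULL, p12 = NULL) {
  out <- list()
  if (!is.null(p_f3)) out$p_active_F3_vs_sham <- p_f3
  if (!is.null(p_rs)) out$p_active_rsfMRI_vs_sham <- p_rs
  if (!is.null(p12)) out$p_active_F3_vs_active_rsfMRI <- p12
  out
}

# Independent Pearson chi-squared oracle: sum (O-E)^2 / E over the 2x2.
pearson_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Independent brute-force BH step-up: largest k with p_(k) <= k q / m.
bh_oracle_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(k)) reject[ord[seq_len(max(k))]] <- TRUE
  reject
}
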