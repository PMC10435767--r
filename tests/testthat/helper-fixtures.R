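# small fixtures built in code

# a peak table with given values recycled over 24 peaks
toy_peaks <- function(values, n = 1, stage = NULL) {
  mat <- matrix(rep_len(values, 24 * n), nrow = n, byrow = TRUE)
  colnames(mat) <- glycan_peak_names()
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("S", seq_len(n))),
    tibble::as_tibble(mat)
  )
  if (!is.null(stage)) peak_stage(out) <- stage
  out
}

# small cohort spec for fast simulations
tiny_spec <- function(n_control = 30, n_ds = 30, sibling_pairs = 0,
                      n_plates = 2, name = "TST") {
  cohort_spec(name, n_control = n_control, n_ds = n_ds,
              age_range_control = c(22, 67), age_range_ds = c(22, 67),
              n_plates = n_plates, sibling_pairs = sibling_pairs)
}

# noise-free trend parameters
quiet_trends <- function(...) {
  default_trend_params("FRA", noise_sd = c(G0 = 0, G1 = 0, G2 = 0),
                       batch_sd = 0, peak_noise_sd = 0, family_sd = 0, ...)
}

# brute-force BH step-up from the definition: find the largest k with
# p_(k) <= k q / m for each candidate q = p_i * m / rank_i, then
# q_i = min over j with p_j >= p_i of p_(j) * m / j (monotone envelope)
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p[ord][i:m] * m / seq(i, m)
    q[ord[i]] <- min(1, min(cand))
  }
  q
}
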