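# Independent oracles used across tests.

# Two-sided Fisher exact p for the 2x2 table [[a, b], [c, d]] by direct
# enumeration of the hypergeometric distribution with fixed margins.
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b   # row-1 total
  n <- c + d   # row-2 total
  k <- a + c   # column-1 total
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A tiny manually built registry in the long format produced by
# generate_registry(): each control has measurements at days 730 and 1460
# after diagnosis, so day 730 is the only admissible index date.
toy_registry <- function(ids, sex, age_at_index, bmi, hba1c_at_index) {
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(
      id = ids[i], sex = sex[i], age = age_at_index[i] - 730 / 365.25,
      bmi = bmi[i], diagnosis_day = 0L, day = c(730L, 1460L),
      hba1c = c(hba1c_at_index[i], hba1c_at_index[i] + 3),
      med_change = FALSE, stringsAsFactors = FALSE
    )
  }))
}

small_config <- function(...) {
  cohort_config(n_participants = 50, n_registry = 250, seed = 42, ...)
}
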