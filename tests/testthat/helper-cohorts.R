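# seeded synthetic feature cohorts for classifier-level tests:
# features f1..fk, the first two shifted by `shift` SDs in malignant rows
sep_cohort <- function(n = 80, k = 6, shift = 3, seed = 1, split = TRUE) {
  set.seed(seed)
  lab <- rep(c("benign", "malignant"), each = n / 2)
  df <- data.frame(id = seq_len(n), label = lab, stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    df[[paste0("f", j)]] <- stats::rnorm(n) +
      if (j <= 2) shift * (lab == "malignant") else 0
  }
  if (split) df$split <- duotomo:::split_cohort(df$label, 0.5, seed)
  df
}
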