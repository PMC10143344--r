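# brute-force normal-equations OLS, kept independent of stats::lm
ols_oracle <- function(x, y) {
  Sxx <- sum((x - mean(x))^2)
  Sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- Sxy / Sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# small hand-built record table: 2 conforming fish, 1 conforming daphnid,
# 1 NOEC, 1 24 h fish, 1 168 h mollusk
toy_records <- function() {
  tibble::tibble(
    species = c("Danio rerio", "Cyprinus carpio", "Daphnia magna",
                "Danio rerio", "Oryzias latipes", "Lymnaea stagnalis"),
    taxon_group = c("fish", "fish", "daphnid", "fish", "fish", "mollusk"),
    native = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    chemical = "Zn",
    endpoint = c("LC50", "EC50", "LC50", "NOEC", "LC50", "LC50"),
    duration_h = c(96, 96, 48, 96, 24, 168),
    value = c(200, 400, 120, 50, 300, 800),
    source_id = paste0("src", 1:6)
  )
}

# long SMAV table across chemicals with a guaranteed overlap
toy_smav_long <- function(n_species = 10, chemicals = c("A", "B"),
                          slope = 0.8, intercept = 0.3, noise_sd = 0,
                          seed = 1) {
  set.seed(seed)
  x <- seq(1, 3, length.out = n_species)
  out <- list()
  for (i in seq_along(chemicals)) {
    lv <- if (i == 1) x else slope * x + intercept + stats::rnorm(n_species, 0, noise_sd)
    out[[i]] <- tibble::tibble(
      species = sprintf("Sp%02d", seq_len(n_species)),
      chemical = chemicals[i],
      smav = 10^lv,
      n_records = 1L,
      native = TRUE
    )
  }
  dplyr::bind_rows(out)
}
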