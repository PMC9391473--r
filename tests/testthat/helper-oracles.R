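# Brute-force oracles for the variance-decomposition statistics:
# explicit loops, independent of the package's implementations.

oracle_var <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / (length(x) - 1)
}

oracle_intra <- function(values, subject) {
  ids <- unique(subject)
  tot <- 0
  for (id in ids) tot <- tot + oracle_var(values[subject == id])
  tot / length(ids)
}

oracle_inter <- function(values, subject) {
  ids <- unique(subject)
  means <- numeric(0)
  for (id in ids) {
    x <- values[subject == id]
    means <- c(means, sum(x) / length(x))
  }
  oracle_var(means)
}

oracle_cv <- function(values, subject) {
  ids <- unique(subject)
  tot <- 0
  for (id in ids) {
    x <- values[subject == id]
    m <- sum(x) / length(x)
    tot <- tot + sqrt(oracle_var(x)) / m
  }
  100 * tot / length(ids)
}

random_grouped_data <- function(n_subjects, n_scans) {
  list(values = 50 + rnorm(n_subjects * n_scans, 0, 5),
       subject = rep(seq_len(n_subjects), each = n_scans))
}

# small shared fixtures
short_train <- function(n = 48L) make_pulse_train(n_pulses = n, n_segments = 6L)

tiny_grid <- function() dictionary_grid(t1_min = 400, t1_max = 1200,
                                        t2_min = 30, t2_max = 120,
                                        b1_deg = c(60, 70, 80))

zero_noise_dist <- function() tissue_distribution(noise_rel = 0,
                                                  epg_noise_sd = 0,
                                                  na_noise_rel = 0)
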