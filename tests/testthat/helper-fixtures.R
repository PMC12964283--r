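# shared test helpers: small generators and independent oracles

total_supply <- function(panel) panel$institutions + panel$beds + panel$doctors

# independent OLS oracle (stats::lm, separate from fit_allometry's lm.fit path)
ols_slope <- function(p, m) unname(stats::coef(stats::lm(log(m) ~ log(p)))[2])

# literal transcription of the entropy-weight formulas, used as oracle
entropy_oracle <- function(z) {
  n <- nrow(z)
  w <- numeric(ncol(z))
  e <- numeric(ncol(z))
  for (j in seq_len(ncol(z))) {
    p <- z[, j] / sum(z[, j])
    s <- 0
    for (i in seq_len(n)) if (p[i] > 0) s <- s + p[i] * log(p[i])
    e[j] <- -s / log(n)
  }
  d <- 1 - e
  d / sum(d)
}

# exhaustive-search Jenks oracle: minimal within-class SSE over all
# contiguous k-partitions of the sorted values
jenks_oracle_wss <- function(values, k) {
  x <- sort(values); n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(sse(x))
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    cut <- c(0, splits[, j], n)
    tot <- 0
    for (g in seq_len(k)) tot <- tot + sse(x[(cut[g] + 1):cut[g + 1]])
    if (tot < best) best <- tot
  }
  best
}

# ground-truth response table for driver-recovery experiments
truth_fits <- function(dp) {
  data.frame(city_id = dp$truth$city_id, exponent_b = dp$truth$b_true,
             stringsAsFactors = FALSE)
}

no_active_drivers <- function(baseline = 0.8, noise_sd = 0.08) {
  driver_spec(active = stats::setNames(numeric(0), character(0)),
              baseline = baseline, noise_sd = noise_sd)
}
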