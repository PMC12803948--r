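# Independent oracles and fixture builders used across the test files.

# ICC(2,1) through R's two-way ANOVA fit (independent of the package's
# direct mean-squares computation).
icc_oracle_aov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   sess = factor(rep(seq_len(k), each = n)))
  # degenerate (zero-MSE) fixtures make aov's F machinery complain
  ms <- suppressWarnings(
    stats::anova(stats::aov(y ~ subj + sess, data = df))
  )[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# random small trial set with both outcome classes present
random_trialset <- function(n_min = 5, n_max = 25) {
  n <- sample(n_min:n_max, 1)
  x <- sample(20:80, n, replace = TRUE)
  t_true <- runif(1, 35, 65)
  y <- runif(n) < pnorm((x - t_true) / 3.5)
  list(intensity = x, outcome = y)
}

# a session log skeleton carrying a given running-estimate series
make_fake_log <- function(estimates, intensity = NULL, outcome = NULL,
                          config = session_config()) {
  n <- length(estimates)
  if (is.null(intensity)) intensity <- pmin(pmax(round(estimates), 1), 100)
  if (is.null(outcome)) outcome <- rep(c(TRUE, FALSE), length.out = n)
  structure(list(
    trials = data.frame(trial = seq_len(n), intensity = intensity,
                        outcome = outcome,
                        rejected_repeats = rep(0L, n),
                        estimate = estimates),
    config = config, seed = config$seed, truncated = FALSE
  ), class = "rmt_session")
}
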