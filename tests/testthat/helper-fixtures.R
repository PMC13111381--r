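# Shared fixtures for the test suite.  Everything is generated in code.

# a noiseless straight stride (exact ground truth)
clean_config <- function(...) {
  sim_config(marker_noise_sd = 0, cm_noise_sd = 0, joint_artifact_sd = 0,
             direction_perturbation_deg = 0, ...)
}

# paired-sample frame with an exact linear relation per component,
# spread over participants/trials, for correction-fitting tests
linear_pairs <- function(model, n_participants = 4, n_trials = 5,
                         grid = seq(5, 95, by = 10), seed = 42) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (tr in seq_len(n_trials)) {
      for (co in c("X", "Y", "Z")) {
        est <- runif(length(grid), -0.5, 1.5)
        true <- model$slope[co] * est + model$intercept[co]
        rows[[length(rows) + 1L]] <- data.frame(
          participant = sprintf("P%02d", p), trial = tr,
          motion = "curve-left", component = co, pct = grid,
          true_bw = true, est_bw = est, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# run both estimators on a cohort, filtering each trial once, and
# return the pooled paired samples per method
cohort_pairs_both <- function(trials, grid = 0:100) {
  p1 <- list(); p2 <- list()
  for (i in seq_along(trials)) {
    f <- filter_trial(trials[[i]])
    for (m in c("est1", "est2")) {
      te <- estimate_trial(f, m, filter = FALSE)
      d <- evaluate_trial(te, grid = grid)
      if (!nrow(d)) next
      d$participant <- trials[[i]]$participant
      d$trial <- i
      if (m == "est1") p1[[length(p1) + 1L]] <- d
      else p2[[length(p2) + 1L]] <- d
    }
  }
  list(est1 = do.call(rbind, p1), est2 = do.call(rbind, p2))
}

# independent ICC(2,1) oracle through R's ANOVA machinery
icc21_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  row = factor(rep(seq_len(n), k)),
                  col = factor(rep(seq_len(k), each = n)))
  a <- stats::anova(stats::lm(y ~ row + col, data = d))
  MSR <- a["row", "Mean Sq"]
  MSC <- a["col", "Mean Sq"]
  MSE <- a["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}
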