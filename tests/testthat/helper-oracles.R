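# Independent brute-force oracles and fixture builders used across tests.
# These re-derive the model equations step by step and must stay independent
# of the package's vectorised/compiled implementations.

# plain-R Rescorla-Wagner recursion: value, prediction error and predicted
# rating per trial, with group- and valence-specific learning rates
rw_oracle <- function(group, outcome, alpha4, beta, v0_in, v0_out) {
  # alpha4 named: pos_ingroup, neg_ingroup, pos_outgroup, neg_outgroup
  n <- length(outcome)
  v <- c(ingroup = v0_in, outgroup = v0_out)
  V <- delta <- pred <- numeric(n)
  for (t in seq_len(n)) {
    g <- group[t]
    V[t] <- v[[g]]
    pred[t] <- beta * v[[g]]
    delta[t] <- outcome[t] - v[[g]]
    cell <- paste0(if (delta[t] >= 0) "pos_" else "neg_",
                   if (g == "ingroup") "ingroup" else "outgroup")
    v[[g]] <- v[[g]] + alpha4[[cell]] * delta[t]
  }
  list(V = V, delta = delta, predicted = pred)
}

# brute-force discounted PE sum: explicit double loop over trials
disc_sum_oracle <- function(pe, gamma, valence, t) {
  total <- 0
  for (j in seq_len(t)) {
    d <- switch(valence,
                positive = max(pe[j], 0),
                negative = min(pe[j], 0),
                all = pe[j])
    total <- total + gamma^(t - j) * d
  }
  total
}

# hand-built trial schedule (bypasses make_schedule for bespoke sequences)
manual_schedule <- function(group, outcome, frame = "gain") {
  n <- length(group)
  structure(
    data.frame(block = 1L, trial = seq_len(n), group = group,
               outcome = outcome, stringsAsFactors = FALSE),
    class = c("trial_schedule", "data.frame"),
    frame = frame_spec(frame), n_blocks = 1L, block_length = n,
    positive_rate = mean(outcome), seed = NA_integer_)
}

# hand-built latent trajectory carrying arbitrary prediction errors
manual_trajectory <- function(group, delta, beta = 1) {
  n <- length(group)
  structure(
    data.frame(trial = seq_len(n), group = group, V = rep(0.5, n),
               delta = delta, predicted_rating = rep(0.5 * beta, n),
               stringsAsFactors = FALSE),
    class = c("latent_trajectory", "data.frame"), beta = beta)
}

# expectancy observations under the fitting convention: first rating per
# group is the initial value, later ratings are beta * V (+ noise)
make_expectancy_obs <- function(schedule, params, noise_sd = 0) {
  traj <- simulate_learning(schedule, params)
  r <- predict_expectancy(traj)
  if (noise_sd > 0) r <- r + rnorm(length(r), 0, noise_sd)
  r[match("ingroup", schedule$group)] <- params$v0_ingroup
  r[match("outgroup", schedule$group)] <- params$v0_outgroup
  r
}
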