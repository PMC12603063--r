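test_that("noise-free learning data are recovered to optimizer tolerance", {
  sched <- make_schedule(seed = 31)
  truth <- learning_params(0.4, beta = 1, v0_ingroup = 0.6,
                           v0_outgroup = 0.45)
  obs <- make_expectancy_obs(sched, truth)
  fit <- fit_learning(session_data(sched, obs), "M1", n_restarts = 5,
                      seed = 2)
  expect_equal(unname(fit$estimates["alpha"]), 0.4, tolerance = 1e-4)
  expect_equal(unname(fit$estimates["beta"]), 1, tolerance = 1e-4)
  expect_lt(fit$sse, 1e-8)
  expect_true(fit$converged)
})

test_that("the optimizer beats a dense grid on a small M1 problem", {
  sched <- make_schedule(1, 8, 0.5, seed = 33)
  truth <- learning_params(0.55, beta = 1.4, v0_ingroup = 0.5,
                           v0_outgroup = 0.5)
  set.seed(8)
  obs <- make_expectancy_obs(sched, truth, noise_sd = 0.2)
  sess <- session_data(sched, obs)
  fit <- fit_learning(sess, "M1", n_restarts = 10, seed = 3)

  # independent grid evaluation of the same SSE surface
  first <- c(match("ingroup", sched$group), match("outgroup", sched$group))
  include <- setdiff(seq_len(nrow(sched)), first)
  sse_at <- function(a, b) {
    o <- rw_oracle(sched$group, sched$outcome,
                   setNames(rep(a, 4), c("pos_ingroup", "neg_ingroup",
                                         "pos_outgroup", "neg_outgroup")),
                   b, obs[first[1]], obs[first[2]])
    sum((o$predicted[include] - obs[include])^2)
  }
  grid <- expand.grid(a = seq(0, 1, length.out = 50),
                      b = seq(0.01, 3, length.out = 50))
  grid_min <- min(mapply(sse_at, grid$a, grid$b))
  expect_lte(fit$sse, grid_min + 1e-10)
})

test_that("best-of-restarts SSE is non-increasing in the restart count", {
  sched <- make_schedule(seed = 35)
  truth <- learning_params(c(0.7, 0.1, 0.5, 0.3), beta = 1.6,
                           v0_ingroup = 0.6, v0_outgroup = 0.4)
  set.seed(9)
  obs <- make_expectancy_obs(sched, truth, noise_sd = 0.15)
  sess <- session_data(sched, obs)
  sses <- vapply(c(1, 3, 10), function(k)
    fit_learning(sess, "M3", n_restarts = k, seed = 77)$sse, numeric(1))
  expect_true(all(diff(sses) <= 1e-10))
})

test_that("AIC equals -2 loglik + 2k and k counts structural parameters", {
  sched <- make_schedule(2, 8, 0.5, seed = 36)
  set.seed(10)
  obs <- make_expectancy_obs(sched, learning_params(0.3), noise_sd = 0.1)
  sess <- session_data(sched, obs)
  for (variant in c("M1", "M2", "M3")) {
    fit <- fit_learning(sess, variant, n_restarts = 3, seed = 1)
    expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$k)
    expect_equal(fit$k, c(M1 = 2, M2 = 3, M3 = 5)[[variant]])
  }
})

test_that("constant rating series triggers an identifiability warning", {
  sched <- make_schedule(1, 8, 0.5, seed = 37)
  w <- capture_warnings(fit_learning(session_data(sched, rep(0.5, 8)), "M1",
                                     n_restarts = 2, seed = 1))
  expect_true(any(grepl("unidentifiable", w)))
})

test_that("noise-free closeness data are recovered to 1e-4", {
  sched <- make_schedule(seed = 41)
  traj <- simulate_learning(sched, learning_params(c(0.6, 0.2, 0.5, 0.15),
                                                   v0_ingroup = 0.7,
                                                   v0_outgroup = 0.4))
  cp <- closeness_params(W0 = 0, W_pos = 2, W_neg = -3, gamma = 0.5)
  pred <- predict_closeness_change(traj, cp, "ingroup")$predicted_delta
  series <- cumsum(c(5, pred[-length(pred)]))
  sess <- session_data(sched, rep(0.5, 96), closeness_in = series)
  fit <- fit_closeness(sess, traj, "C2", "ingroup", n_restarts = 5, seed = 4)
  expect_equal(unname(fit$estimates),
               c(0, 2, -3, 0.5), tolerance = 1e-4)
  expect_equal(fit$k, 4)
})

test_that("fitted weights are the OLS solution at the fitted gamma", {
  sched <- make_schedule(seed = 43)
  traj <- simulate_learning(sched, learning_params(c(0.5, 0.25, 0.6, 0.1),
                                                   v0_ingroup = 0.6,
                                                   v0_outgroup = 0.5))
  cp <- closeness_params(W0 = 0.5, W_pos = 1.5, W_neg = -2.5, gamma = 0.4)
  pred <- predict_closeness_change(traj, cp, "ingroup")$predicted_delta
  set.seed(11)
  changes <- pred[1:95] + rnorm(95, 0, 0.8)
  sess <- session_data(sched, rep(0.5, 96),
                       closeness_in = cumsum(c(5, changes)))
  fit <- fit_closeness(sess, traj, "C2", "ingroup", n_restarts = 5, seed = 5)

  # normal-equations oracle on brute-force discounted-sum regressors
  g <- unname(fit$estimates["gamma"])
  d <- ifelse(traj$group == "ingroup", traj$delta, 0)
  spos <- vapply(1:95, function(t) disc_sum_oracle(d, g, "positive", t),
                 numeric(1))
  sneg <- vapply(1:95, function(t) disc_sum_oracle(d, g, "negative", t),
                 numeric(1))
  ols <- coef(lm(changes ~ spos + sneg))
  expect_equal(unname(fit$estimates[c("W0", "W_pos", "W_neg")]),
               unname(ols), tolerance = 1e-4)
})

test_that("goodness of fit matches textbook definitions", {
  gof <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(gof$r2, 1)
  expect_equal(gof$mse, 0)

  gof2 <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3) + 2)
  expect_equal(gof2$r2, 1)
  expect_equal(gof2$mse, 4)

  obs <- c(1, 2, 3, 4); pred <- c(1.1, 1.9, 3.2, 3.8)
  gof3 <- goodness_of_fit(obs, pred)
  num <- sum((obs - mean(obs)) * (pred - mean(pred)))
  den <- sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(gof3$r2, (num / den)^2)
  expect_equal(gof3$mse, mean((obs - pred)^2))

  expect_warning(g4 <- goodness_of_fit(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_true(is.na(g4$r2))
  expect_equal(goodness_of_fit(obs, pred, method = "ss")$r2,
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
})

test_that("fit tables collect parameters, AIC and fit quality", {
  sched <- make_schedule(2, 8, 0.5, seed = 44)
  set.seed(12)
  obs <- make_expectancy_obs(sched, learning_params(0.4), noise_sd = 0.1)
  sess <- session_data(sched, obs, participant = "p1")
  fits <- list(fit_learning(sess, "M1", 2, 1), fit_learning(sess, "M2", 2, 1))
  tab <- fits_to_table(fits)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("participant", "model", "aic", "r2") %in% names(tab)))
  expect_equal(tab$model, c("M1", "M2"))
})
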