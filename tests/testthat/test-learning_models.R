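test_that("forward recursion matches the brute-force oracle to 1e-12", {
  # spec-style 6-trial ingroup-only case, alpha = 0.3, v0 = 0.5
  sched <- manual_schedule(rep("ingroup", 6), c(1, 1, 0, 1, 0, 1))
  params <- learning_params(0.3, beta = 1, v0_ingroup = 0.5,
                            v0_outgroup = 0.5)
  traj <- simulate_learning(sched, params)
  oracle <- rw_oracle(sched$group, sched$outcome,
                      setNames(rep(0.3, 4),
                               c("pos_ingroup", "neg_ingroup",
                                 "pos_outgroup", "neg_outgroup")),
                      1, 0.5, 0.5)
  expect_equal(traj$V, oracle$V, tolerance = 1e-12)
  expect_equal(traj$delta, oracle$delta, tolerance = 1e-12)
  expect_equal(predict_expectancy(traj), oracle$predicted, tolerance = 1e-12)

  # property: random schedules and parameters, all three variants
  set.seed(42)
  for (i in 1:15) {
    sched <- make_schedule(2, 8, 0.5, seed = i)
    a4 <- runif(4)
    params <- learning_params(a4, beta = runif(1, 0.1, 3),
                              v0_ingroup = runif(1), v0_outgroup = runif(1),
                              variant = "M3")
    traj <- simulate_learning(sched, params)
    oracle <- rw_oracle(sched$group, sched$outcome,
                        as.list(params$alpha), params$beta,
                        params$v0_ingroup, params$v0_outgroup)
    expect_equal(traj$V, oracle$V, tolerance = 1e-12)
    expect_equal(traj$predicted_rating, oracle$predicted, tolerance = 1e-12)
  }
})

test_that("alpha = 0 freezes values and alpha = 1 tracks the last outcome", {
  sched <- make_schedule(1, 8, 0.5, seed = 5)
  flat <- simulate_learning(sched, learning_params(0, beta = 1.4,
                                                   v0_ingroup = 0.3,
                                                   v0_outgroup = 0.8))
  expect_equal(flat$V[sched$group == "ingroup"],
               rep(0.3, 4))
  expect_equal(unique(flat$predicted_rating[sched$group == "outgroup"]),
               1.4 * 0.8)

  full <- simulate_learning(sched, learning_params(1, v0_ingroup = 0.5,
                                                   v0_outgroup = 0.5))
  for (g in c("ingroup", "outgroup")) {
    idx <- which(sched$group == g)
    expect_equal(full$V[idx[-1]], sched$outcome[idx[-length(idx)]])
  }
})

test_that("values contract geometrically toward a constant outcome", {
  sched <- manual_schedule(rep("ingroup", 10), rep(1, 10))
  alpha <- 0.35
  v0 <- 0.2
  traj <- simulate_learning(sched, learning_params(alpha, v0_ingroup = v0,
                                                   v0_outgroup = 0.5))
  k <- seq_len(10) - 1
  expect_equal(abs(traj$V - 1), (1 - alpha)^k * abs(v0 - 1),
               tolerance = 1e-12)
})

test_that("a group's trajectory ignores the other group's outcomes", {
  sched <- make_schedule(2, 12, 0.5, seed = 9)
  params <- learning_params(c(0.5, 0.2, 0.7, 0.1), beta = 1.2,
                            v0_ingroup = 0.6, v0_outgroup = 0.4)
  base <- simulate_learning(sched, params)
  flipped <- sched
  out_idx <- which(sched$group == "outgroup")
  flipped$outcome[out_idx] <- rev(sched$outcome[out_idx])
  alt <- simulate_learning(flipped, params)
  in_idx <- which(sched$group == "ingroup")
  expect_equal(base$V[in_idx], alt$V[in_idx])
  expect_equal(base$delta[in_idx], alt$delta[in_idx])
})

test_that("variants nest: tied parameters give identical trajectories", {
  sched <- make_schedule(2, 10, 0.6, seed = 11)
  a <- 0.45
  t1 <- simulate_learning(sched, learning_params(a, beta = 2,
                                                 v0_ingroup = 0.5,
                                                 v0_outgroup = 0.3))
  t2 <- simulate_learning(sched, learning_params(c(a, a), beta = 2,
                                                 v0_ingroup = 0.5,
                                                 v0_outgroup = 0.3))
  t3 <- simulate_learning(sched, learning_params(rep(a, 4), beta = 2,
                                                 v0_ingroup = 0.5,
                                                 v0_outgroup = 0.3))
  expect_equal(t1$V, t2$V)
  expect_equal(t2$V, t3$V)
  expect_equal(t1$predicted_rating, t3$predicted_rating)
})

test_that("predicted expectancy is beta times the latent value", {
  sched <- manual_schedule(c("ingroup", "outgroup"), c(1, 0))
  t1 <- simulate_learning(sched, learning_params(0, beta = 1,
                                                 v0_ingroup = 0.75,
                                                 v0_outgroup = 0.4))
  expect_equal(predict_expectancy(t1)[1], 0.75)
  t2 <- simulate_learning(sched, learning_params(0, beta = 2,
                                                 v0_ingroup = 0.4,
                                                 v0_outgroup = 0.4))
  expect_equal(predict_expectancy(t2)[1], 0.8)
  expect_equal(predict_expectancy(t2), 2 * t2$V)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(learning_params(1.2), "\\[0, 1\\]")
  expect_error(learning_params(0.5, beta = 0), "positive")
  expect_error(learning_params(0.5, v0_ingroup = 1.5), "\\[0, 1\\]")
  expect_error(learning_params(c(0.2, 0.3, 0.4)), "length")
  expect_equal(normalize_expectancy(c(1, 10)), c(0, 1))
  expect_error(normalize_expectancy(0.4), "\\[1, 10\\]")
})
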