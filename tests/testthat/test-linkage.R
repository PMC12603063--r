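test_that("stepwise selection finds a strong single predictor", {
  set.seed(91)
  cand <- as.data.frame(matrix(rnorm(50 * 8), 50, 8,
                               dimnames = list(NULL, paste0("x", 1:8))))
  outcome <- 2 * cand$x1 + rnorm(50, 0, 0.5)
  res <- stepwise_regression(cand, outcome)
  expect_equal(res$selected_predictors, "x1")
  expect_equal(res$coefficients$estimate[res$coefficients$term == "x1"], 2,
               tolerance = 0.2)
})

test_that("a candidate identical to the outcome is selected with slope 1", {
  set.seed(92)
  x <- rnorm(30)
  res <- suppressWarnings(stepwise_regression(data.frame(x = x), x))
  expect_equal(res$selected_predictors, "x")
  row <- res$coefficients[res$coefficients$term == "x", ]
  expect_equal(row$estimate, 1, tolerance = 1e-10)
  expect_lt(row$p, 1e-12)
})

test_that("threshold limits give the full and the empty model", {
  set.seed(93)
  cand <- as.data.frame(matrix(rnorm(40 * 4), 40, 4,
                               dimnames = list(NULL, paste0("x", 1:4))))
  y <- rnorm(40)
  full <- stepwise_regression(cand, y, entry_p = 1, removal_p = 1)
  expect_setequal(full$selected_predictors, names(cand))
  empty <- stepwise_regression(cand, y, entry_p = 0, removal_p = 0)
  expect_length(empty$selected_predictors, 0)
})

test_that("null outcomes select nothing at the nominal forward rate", {
  # with entry_p = 0.05 and 8 near-independent candidates the chance of an
  # empty model is about (1 - 0.05)^8
  set.seed(94)
  n_sims <- 400
  empty <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    cand <- as.data.frame(matrix(rnorm(50 * 8), 50, 8,
                                 dimnames = list(NULL, paste0("x", 1:8))))
    res <- stepwise_regression(cand, rnorm(50))
    empty[i] <- length(res$selected_predictors) == 0
  }
  expect_lt(abs(mean(empty) - 0.95^8), 0.08)
})

test_that("collinear duplicates are dropped with a warning", {
  set.seed(95)
  x <- rnorm(40)
  cand <- data.frame(a = x, b = x, c = rnorm(40))
  expect_warning(res <- stepwise_regression(cand, 2 * x + rnorm(40, 0, 0.3)),
                 "collinear")
  expect_true("a" %in% res$selected_predictors)
  expect_false("b" %in% res$selected_predictors)
})

test_that("a pure interaction outcome yields coefficient 1 and tiny p", {
  set.seed(96)
  x <- rnorm(60); m <- rnorm(60)
  res <- suppressWarnings(moderation(x, m, x * m))
  expect_equal(res$interaction$estimate, 1, tolerance = 1e-10)
  expect_lt(res$interaction$p, 1e-12)
})

test_that("binary moderators give per-level simple slopes", {
  set.seed(97)
  x <- rnorm(80)
  frame <- rep(c("gain", "loss"), 40)
  y <- ifelse(frame == "loss", -1.5 * x, 0.2 * x) + rnorm(80, 0, 0.3)
  res <- moderation(x, frame, y)
  expect_true(res$moderator_binary)
  sl <- res$simple_slopes
  expect_equal(sl$slope[sl$moderator_level == "level 0"], 0.2,
               tolerance = 0.2)
  expect_equal(sl$slope[sl$moderator_level == "level 1"], -1.5,
               tolerance = 0.2)
  expect_lt(res$interaction$p, 0.001)
})

test_that("the interaction is null-calibrated at the nominal 5% level", {
  set.seed(98)
  n_sims <- 400
  sig <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    x <- rnorm(50); m <- rnorm(50); cov1 <- rnorm(50)
    y <- 0.8 * cov1 + rnorm(50)
    res <- moderation(x, m, y, covariates = data.frame(cov1 = cov1))
    sig[i] <- res$interaction$p < 0.05
  }
  expect_lt(abs(mean(sig) - 0.05), 0.035)
})

test_that("moderation rejects degenerate moderators and scales sanely", {
  x <- rnorm(20); y <- rnorm(20)
  expect_error(moderation(x, rep(1, 20), y), "zero variance")
  # affine rescaling of x scales the interaction coefficient by 1/c
  set.seed(99)
  x <- rnorm(60); m <- rnorm(60); y <- x * m + rnorm(60, 0, 0.2)
  r1 <- moderation(x, m, y)
  r2 <- moderation(10 * x, m, y)
  expect_equal(r2$interaction$estimate, r1$interaction$estimate / 10,
               tolerance = 1e-8)
})

test_that("influence flags match the cutoff definitions exactly", {
  set.seed(100)
  for (i in 1:20) {
    x <- rnorm(40)
    y <- 1 + 0.5 * x + rnorm(40)
    fit <- lm(y ~ x, data = data.frame(x = x, y = y))
    res <- influence_filter(fit)
    n <- 40; k <- 2
    oracle <- which(abs(dffits(fit)) > 2 * sqrt(k / n) |
                      cooks.distance(fit) > 4 / n |
                      hatvalues(fit) > 2 * k / n |
                      apply(abs(dfbetas(fit)) > 1, 1, any))
    expect_equal(res$flagged, unname(oracle))
  }
})

test_that("a gross outlier is flagged and the refit recovers the slope", {
  set.seed(101)
  x <- rnorm(40)
  y <- 1 + 0.5 * x + rnorm(40, 0, 0.2)
  y[7] <- y[7] + 25
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  res <- influence_filter(fit)
  expect_true(7 %in% res$flagged)
  expect_equal(unname(coef(res$refit)["x"]), 0.5, tolerance = 0.15)
})

test_that("zero flags return the original fit object unchanged", {
  # evenly spaced x with tiny noise keeps every diagnostic under its cutoff
  x <- seq(-1, 1, length.out = 20)
  y <- 2 + x + rep(c(0.08, -0.08), 10)
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  res <- influence_filter(fit)
  expect_length(res$flagged, 0)
  expect_identical(res$refit, res$fit)
})

test_that("minimal n = k + 3 datasets run without numerical failure", {
  set.seed(103)
  d <- data.frame(x1 = rnorm(6), x2 = rnorm(6))
  d$y <- d$x1 + rnorm(6)
  fit <- lm(y ~ x1 + x2, data = d)
  expect_no_error(influence_filter(fit))
})

test_that("bias-identification correlation matches hand computation", {
  tab <- data.frame(identification = c(2, 3, 4, 5, 6),
                    impression_pre_in = c(5, 6, 6, 7, 8),
                    impression_pre_out = c(5, 5, 4, 5, 5))
  res <- bias_identification_correlation(tab)
  bias <- tab$impression_pre_in - tab$impression_pre_out
  expect_equal(res$pearson_r, cor(tab$identification, bias))
  expect_equal(res$n, 5)

  expect_warning(
    flat <- bias_identification_correlation(
      transform(tab, identification = 3)), "undefined")
  expect_equal(flat$flag, "degenerate")
  expect_error(bias_identification_correlation(tab[1:3, ]), "at least 4")
})

test_that("synthetic western populations show the reported bias correlation", {
  study <- simulate_study(112, seed = 104)
  res <- bias_identification_correlation(study$participants)
  expect_gt(res$pearson_r, 0)
  expect_lt(abs(res$pearson_r - 0.26), 0.2)
})

test_that("moderation on synthetic loss-frame data shows the Fig.-7 pattern", {
  study <- simulate_study(100, culture_profile = "east_asian",
                          frame_split = 0, seed = 105)
  p <- study$participants
  res <- moderation(p$W_neg_in, p$identification, p$intergroup_change)
  sl <- res$simple_slopes
  low <- sl$slope[sl$moderator_level == "mean - 1sd"]
  high <- sl$slope[sl$moderator_level == "mean + 1sd"]
  expect_lt(low, 0)           # strong negative link at low identification
  expect_gt(high, low)        # attenuated at high identification
  expect_gt(res$interaction$estimate, 0)
})
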