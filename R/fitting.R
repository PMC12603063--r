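# parameter-vector layouts used by the optimiser
learning_layout <- function(variant) {
  switch(variant,
    M1 = list(names = c("alpha", "beta"),
              lower = c(0, 1e-6), upper = c(1, 3)),
    M2 = list(names = c("alpha_ingroup", "alpha_outgroup", "beta"),
              lower = c(0, 0, 1e-6), upper = c(1, 1, 3)),
    M3 = list(names = c("alpha_pos_ingroup", "alpha_neg_ingroup",
                        "alpha_pos_outgroup", "alpha_neg_outgroup", "beta"),
              lower = c(0, 0, 0, 0, 1e-6), upper = c(1, 1, 1, 1, 3)))
}

par_to_learning_params <- function(par, variant, v0_in, v0_out) {
  k <- length(par)
  learning_params(alpha = par[-k], beta = par[k], v0_ingroup = v0_in,
                  v0_outgroup = v0_out, variant = variant)
}

closeness_layout <- function(variant) {
  switch(variant,
    C1 = list(names = c("W0", "W", "gamma"),
              lower = c(0, -10, 0), upper = c(10, 10, 1)),
    C2 = list(names = c("W0", "W_pos", "W_neg", "gamma"),
              lower = c(0, -10, -10, 0), upper = c(10, 10, 10, 1)))
}

# Gaussian log-likelihood at the profiled MLE sigma^2 = SSE / n.
# sigma^2 is floored to keep the likelihood finite on perfect fits.
gaussian_loglik <- function(sse, n) {
  sigma2 <- max(sse / n, 1e-12)
  -0.5 * n * (log(2 * pi * sigma2) + 1)
}

new_fit_result <- function(participant, model, estimates, sse, n_obs, k,
                           r2, mse, n_restarts_used, converged,
                           flags = character(0)) {
  loglik <- gaussian_loglik(sse, n_obs)
  structure(list(participant = participant, model = model,
                 estimates = estimates, sse = sse, loglik = loglik, k = k,
                 aic = -2 * loglik + 2 * k, r2 = r2, mse = mse,
                 n_obs = n_obs, n_restarts_used = n_restarts_used,
                 converged = converged, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> participant %s, model %s (k = %d)\n",
              x$participant, x$model, x$k))
  cat("  ", paste(sprintf("%s=%.4f", names(x$estimates), x$estimates),
                  collapse = ", "), "\n")
  cat(sprintf("  sse=%.4f, loglik=%.2f, AIC=%.2f, r2=%.3f, converged=%s\n",
              x$sse, x$loglik, x$aic,
              if (is.na(x$r2)) NA else x$r2, x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# Multi-start bounded quasi-Newton minimisation (L-BFGS-B). Start values are
# drawn uniformly within the bounds from a seeded stream; the best restart
# wins, so the attained SSE is non-increasing in the number of restarts for
# a given seed.
multistart_optim <- function(objective, lower, upper, n_restarts, seed) {
  stopifnot(n_restarts >= 1)
  k <- length(lower)
  # one draw per restart, in order, so restarts 1..m are a prefix of
  # restarts 1..n for m < n under the same seed
  starts <- with_local_seed(seed, t(vapply(seq_len(n_restarts),
    function(i) runif(k, lower, upper), numeric(k))))
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(n_restarts)) {
    res <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = lower, upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(list(par = (lower + upper) / 2, value = objective((lower + upper) / 2),
                converged = FALSE, n_conv = 0L))
  list(par = best$par, value = best$value, converged = n_conv > 0L,
       n_conv = n_conv)
}

#' Fit a Rescorla-Wagner expectancy model to one session
#'
#' Maximum-likelihood estimation by least squares under a Gaussian
#' observation model: the sum of squared differences between the predicted
#' (`beta * V`, computed before each outcome) and observed normalised
#' expectancy ratings is minimised over bounded parameters (learning rates
#' in \[0, 1\], `beta` in (0, 3\]) with multi-start bounded quasi-Newton
#' (L-BFGS-B) optimisation. Each group's initial value is set to its first
#' observed rating, which therefore serves as the prior rather than as data
#' and is excluded from the residuals. The Gaussian log-likelihood is
#' evaluated at the profiled noise variance `SSE / n`; `k` counts the
#' structural parameters only (2, 3 and 5 for `M1`, `M2`, `M3`).
#'
#' @param session A [session_data()] object with expectancy ratings.
#' @param model_variant `"M1"`, `"M2"` or `"M3"`.
#' @param n_restarts Number of random restarts (>= 1, default 10).
#' @param seed Seed for the restart stream; identical seeds give identical
#'   results.
#' @return A `fit_result` with the estimates, `sse`, `loglik`,
#'   `aic = -2 loglik + 2k`, squared-correlation `r2`, `mse`, restart count
#'   and convergence flag.
#' @examples
#' sched <- make_schedule(seed = 4)
#' truth <- learning_params(0.4, beta = 1, v0_ingroup = 0.6, v0_outgroup = 0.5)
#' traj <- simulate_learning(sched, truth)
#' exp_r <- predict_expectancy(traj)
#' exp_r[match(c("ingroup", "outgroup"), sched$group)] <- c(0.6, 0.5)
#' fit <- fit_learning(session_data(sched, exp_r), "M1")
#' fit$estimates
#' @export
fit_learning <- function(session, model_variant = c("M3", "M1", "M2"),
                         n_restarts = 10, seed = 1L) {
  stopifnot(inherits(session, "session_data"))
  model_variant <- match.arg(model_variant)
  sched <- session$schedule
  ratings <- session$expectancy
  flags <- character(0)
  if (anyNA(ratings)) stop("expectancy ratings contain NA", call. = FALSE)
  if (sd(ratings) == 0) {
    warning("constant expectancy ratings: learning rate unidentifiable")
    flags <- c(flags, "constant_ratings")
  }

  first_in <- match("ingroup", sched$group)
  first_out <- match("outgroup", sched$group)
  v0_in <- clamp(ratings[first_in], 0, 1)
  v0_out <- clamp(ratings[first_out], 0, 1)
  include <- setdiff(seq_len(nrow(sched)), c(first_in, first_out))
  obs <- ratings[include]

  is_in <- as.integer(sched$group == "ingroup")
  outc <- as.numeric(sched$outcome)
  lay <- learning_layout(model_variant)
  nk <- length(lay$names)

  expand_alpha <- switch(model_variant,
    M1 = function(p) rep(p[1], 4),
    M2 = function(p) p[c(1, 1, 2, 2)],
    M3 = function(p) p[1:4])

  objective <- function(par) {
    tr <- rw_forward(is_in, outc, expand_alpha(par), par[nk], v0_in, v0_out)
    sum((tr$predicted[include] - obs)^2)
  }

  opt <- multistart_optim(objective, lay$lower, lay$upper, n_restarts, seed)
  est <- setNames(opt$par, lay$names)
  tr <- rw_forward(is_in, outc, expand_alpha(opt$par), opt$par[nk],
                   v0_in, v0_out)
  gof <- goodness_of_fit(obs, tr$predicted[include])
  if (!opt$converged) flags <- c(flags, "no_restart_converged")
  new_fit_result(session$participant, model_variant, est, opt$value,
                 length(obs), nk, gof$r2, gof$mse, n_restarts,
                 opt$converged, flags)
}

#' Fit a closeness-update model to one session and group
#'
#' Least-squares estimation of the closeness model on the observed
#' trial-to-trial closeness changes (`rating(t + 1) - rating(t)`, the final
#' trial's prediction error being unobservable). Prediction errors come
#' from the supplied learning trajectory (normally the participant's
#' winning learning-model fit). For fixed `gamma` the model is linear in
#' the weights, so the fit profiles `gamma` on a grid (ordinary least
#' squares at each knot, estimates projected into the bounds), then
#' polishes jointly with multi-start bounded L-BFGS-B. Bounds: `W` in
#' \[-10, 10\], `W0` in \[0, 10\], `gamma` in \[0, 1\]. `k` is 3 (`C1`) or
#' 4 (`C2`).
#'
#' @param session A [session_data()] with closeness ratings for `group`.
#' @param trajectory A [simulate_learning()] trajectory supplying the
#'   prediction errors.
#' @param model_variant `"C1"` or `"C2"`.
#' @param group `"ingroup"` or `"outgroup"`: which closeness series to fit.
#' @param n_restarts Random restarts for the polish stage (default 10).
#' @param seed Seed for the restart stream.
#' @param gamma_grid Number of grid knots on \[0, 1\] for the profile search
#'   (default 201).
#' @return A `fit_result`.
#' @export
fit_closeness <- function(session, trajectory,
                          model_variant = c("C2", "C1"),
                          group = c("ingroup", "outgroup"),
                          n_restarts = 10, seed = 1L, gamma_grid = 201) {
  stopifnot(inherits(session, "session_data"),
            inherits(trajectory, "latent_trajectory"))
  model_variant <- match.arg(model_variant)
  group <- match.arg(group)
  series <- if (group == "ingroup") session$closeness_in
            else session$closeness_out
  if (is.null(series))
    stop("session has no closeness ratings for the ", group, call. = FALSE)
  if (length(series) != nrow(trajectory))
    stop("closeness series and trajectory lengths differ", call. = FALSE)
  obs <- observed_closeness_change(series)
  n <- length(obs)
  flags <- character(0)
  if (sd(obs) == 0) {
    warning("constant closeness changes: weights weakly identifiable")
    flags <- c(flags, "constant_changes")
  }

  d <- as.numeric(ifelse(trajectory$group == group, trajectory$delta, 0))
  lay <- closeness_layout(model_variant)
  nk <- length(lay$names)

  design <- function(gamma) {
    s <- discount_sums(d, gamma)
    if (model_variant == "C1") cbind(1, s$S_all[seq_len(n)])
    else cbind(1, s$S_pos[seq_len(n)], s$S_neg[seq_len(n)])
  }
  sse_par <- function(par) {
    X <- design(par[nk])
    sum((X %*% par[-nk] - obs)^2)
  }

  # profile-gamma grid: OLS weights at each knot, projected into bounds
  best_grid <- NULL
  for (g in seq(0, 1, length.out = gamma_grid)) {
    X <- design(g)
    cf <- tryCatch(lm.fit(X, obs)$coefficients, error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) cf <- rep(0, nk - 1)
    cf <- clamp(cf, lay$lower[-nk], lay$upper[-nk])
    val <- sum((X %*% cf - obs)^2)
    if (is.null(best_grid) || val < best_grid$value)
      best_grid <- list(par = c(cf, g), value = val)
  }

  opt <- multistart_optim(sse_par, lay$lower, lay$upper, n_restarts, seed)
  polish <- tryCatch(
    optim(best_grid$par, sse_par, method = "L-BFGS-B", lower = lay$lower,
          upper = lay$upper, control = list(maxit = 500)),
    error = function(e) list(par = best_grid$par, value = best_grid$value,
                             convergence = 1L))
  cand <- list(list(par = opt$par, value = opt$value),
               list(par = polish$par, value = polish$value), best_grid)
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]

  est <- setNames(best$par, lay$names)
  gof <- goodness_of_fit(obs, drop(design(best$par[nk]) %*% best$par[-nk]))
  new_fit_result(session$participant, model_variant, est, best$value, n, nk,
                 gof$r2, gof$mse, n_restarts,
                 opt$converged || polish$convergence == 0, flags)
}

#' Goodness of fit of a predicted rating series
#'
#' `r2` is the squared Pearson correlation between observed and predicted
#' series (so it stays positive under weak but directionally correct fits);
#' set `method = "ss"` for the 1 - SSE/SST definition. `mse` is the mean
#' squared residual.
#'
#' @param observed,predicted Equal-length numeric series (>= 2 points).
#' @param method `"cor"` (squared Pearson correlation, default) or `"ss"`.
#' @return A list with elements `r2` and `mse`; `r2` is `NA` (with a
#'   warning) when either series has zero variance under `"cor"`.
#' @examples
#' goodness_of_fit(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
goodness_of_fit <- function(observed, predicted, method = c("cor", "ss")) {
  method <- match.arg(method)
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  mse <- mean((observed - predicted)^2)
  r2 <- if (method == "cor") {
    if (sd(observed) == 0 || sd(predicted) == 0) {
      warning("zero-variance series: r2 undefined")
      NA_real_
    } else cor(observed, predicted)^2
  } else {
    sst <- sum((observed - mean(observed))^2)
    if (sst == 0) {
      warning("zero-variance observations: r2 undefined")
      NA_real_
    } else 1 - sum((observed - predicted)^2) / sst
  }
  list(r2 = r2, mse = mse)
}

#' Tabulate fit results
#'
#' @param fits A list of `fit_result` objects.
#' @return Data frame with `participant`, `model`, one column per parameter
#'   (union across fits), `sse`, `loglik`, `k`, `aic`, `r2`.
#' @export
fits_to_table <- function(fits) {
  stopifnot(length(fits) > 0, all(vapply(fits, inherits, TRUE, "fit_result")))
  par_names <- unique(unlist(lapply(fits, function(f) names(f$estimates))))
  rows <- lapply(fits, function(f) {
    p <- setNames(rep(NA_real_, length(par_names)), par_names)
    p[names(f$estimates)] <- f$estimates
    cbind(data.frame(participant = f$participant, model = f$model,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(p)),
          data.frame(sse = f$sse, loglik = f$loglik, k = f$k, aic = f$aic,
                     r2 = f$r2))
  })
  do.call(rbind, rows)
}
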