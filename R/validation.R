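# Parameter ranges used by the validation protocols: the full fitting
# bounds, matching the recovery/identifiability simulations.
default_learning_ranges <- list(alpha = c(0, 1), beta = c(0.001, 3),
                                v0 = c(0, 1))
default_closeness_ranges <- list(W0 = c(0, 10), W = c(-10, 10),
                                 gamma = c(0, 1))

# default observation noise: sd 0.15 on the [0,1] expectancy scale and 1.0
# on the 0-10 closeness-change scale, calibrated so simulated fit quality
# brackets typical empirical r2 values (~0.26-0.38)
default_noise_sd <- function(model_variant)
  if (model_variant %in% c("M1", "M2", "M3")) 0.15 else 1.0

draw_learning_truth <- function(variant, ranges) {
  n_alpha <- switch(variant, M1 = 1, M2 = 2, M3 = 4)
  list(alpha = runif(n_alpha, ranges$alpha[1], ranges$alpha[2]),
       beta = runif(1, ranges$beta[1], ranges$beta[2]),
       v0_in = runif(1, ranges$v0[1], ranges$v0[2]),
       v0_out = runif(1, ranges$v0[1], ranges$v0[2]))
}

# Simulated expectancy under the fitting convention: each group's first
# rating is the initial value itself (the prior the fit conditions on);
# later ratings are beta * V plus Gaussian noise, unclipped so the
# observation model matches the Gaussian likelihood of the estimator.
simulate_expectancy_obs <- function(schedule, params, noise_sd) {
  traj <- simulate_learning(schedule, params)
  ratings <- predict_expectancy(traj) + rnorm(nrow(schedule), 0, noise_sd)
  ratings[match("ingroup", schedule$group)] <- params$v0_ingroup
  ratings[match("outgroup", schedule$group)] <- params$v0_outgroup
  ratings
}

truth_vector_learning <- function(truth, variant) {
  lay <- learning_layout(variant)
  setNames(c(truth$alpha, truth$beta), lay$names)
}

draw_closeness_truth <- function(variant, ranges) {
  if (variant == "C1")
    closeness_params(W0 = runif(1, ranges$W0[1], ranges$W0[2]),
                     W = runif(1, ranges$W[1], ranges$W[2]),
                     gamma = runif(1, ranges$gamma[1], ranges$gamma[2]))
  else
    closeness_params(W0 = runif(1, ranges$W0[1], ranges$W0[2]),
                     W_pos = runif(1, ranges$W[1], ranges$W[2]),
                     W_neg = runif(1, ranges$W[1], ranges$W[2]),
                     gamma = runif(1, ranges$gamma[1], ranges$gamma[2]))
}

truth_vector_closeness <- function(params) {
  if (params$variant == "C1")
    c(W0 = params$W0, W = params$W, gamma = params$gamma)
  else
    c(W0 = params$W0, W_pos = params$W_pos, W_neg = params$W_neg,
      gamma = params$gamma)
}

# a driving learning agent for closeness simulations: prediction errors
# need realistic structure, the exact values are nuisance
draw_driver_params <- function() {
  learning_params(alpha = runif(4, 0.1, 0.9), beta = 1,
                  v0_ingroup = runif(1, 0.2, 0.8),
                  v0_outgroup = runif(1, 0.2, 0.8), variant = "M3")
}

# closeness series whose successive differences equal pred + noise
closeness_series_from_changes <- function(changes, start = 5)
  cumsum(c(start, changes))

simulate_closeness_session <- function(schedule, traj, params, noise_sd) {
  pred <- predict_closeness_change(traj, params, "ingroup")$predicted_delta
  n <- nrow(schedule)
  changes <- pred[seq_len(n - 1)] + rnorm(n - 1, 0, noise_sd)
  session_data(schedule, expectancy = rep(0.5, n),
               closeness_in = closeness_series_from_changes(changes))
}

#' Parameter recovery by simulation
#'
#' Simulates `n_simulations` agents with parameters drawn uniformly within
#' the stated ranges on fresh trial schedules, refits each simulated
#' dataset with the same estimation procedure used for real data, and
#' reports the Pearson correlation between generating and recovered values
#' for every parameter. High correlations indicate a reliable fitting
#' procedure.
#'
#' For learning variants the observed ratings are `beta * V` plus Gaussian
#' noise (each group's first rating carries the initial value, as in the
#' fitting convention). For closeness variants the observed trial-wise
#' changes are the model predictions plus Gaussian noise, driven by
#' prediction errors from a known learning trajectory (as in the real
#' pipeline, where closeness fits consume the winning learning model's
#' prediction errors).
#'
#' @param model_variant `"M1"`/`"M2"`/`"M3"` or `"C1"`/`"C2"`.
#' @param ranges Per-parameter sampling ranges; defaults to the fitting
#'   bounds (learning: `alpha` in \[0, 1\], `beta` in (0, 3\]; closeness:
#'   `W` in \[-10, 10\], `W0` in \[0, 10\], `gamma` in \[0, 1\]).
#' @param n_simulations Number of simulated datasets (default 100).
#' @param noise_sd Observation noise; defaults to 0.15 (expectancy scale)
#'   or 1.0 (closeness-change scale).
#' @param seed Master seed; the report is fully deterministic given it.
#' @param n_restarts Restarts per fit (default 10).
#' @param n_blocks,block_length,positive_rate Schedule settings.
#' @return A `recovery_report`: list with `model`, `n_simulations`,
#'   `correlations` (named per parameter), `min_r`, `ranges`, `noise_sd`
#'   and the `truth`/`estimates` tables.
#' @examples
#' rep0 <- run_parameter_recovery("M1", n_simulations = 5, noise_sd = 0,
#'                                n_restarts = 2, seed = 1)
#' rep0$min_r
#' @export
run_parameter_recovery <- function(model_variant, ranges = NULL,
                                   n_simulations = 100, noise_sd = NULL,
                                   seed = 1L, n_restarts = 10, n_blocks = 4,
                                   block_length = 24, positive_rate = 0.75) {
  model_variant <- match.arg(model_variant, c("M1", "M2", "M3", "C1", "C2"))
  is_learning <- model_variant %in% c("M1", "M2", "M3")
  ranges <- ranges %||% if (is_learning) default_learning_ranges
                        else default_closeness_ranges
  noise_sd <- noise_sd %||% default_noise_sd(model_variant)

  res <- with_local_seed(seed, {
    seeds <- matrix(spawn_seeds(3 * n_simulations), ncol = 3)
    truth <- list(); est <- list()
    for (i in seq_len(n_simulations)) {
      sched <- make_schedule(n_blocks, block_length, positive_rate,
                             seed = seeds[i, 1])
      if (is_learning) {
        tr <- draw_learning_truth(model_variant, ranges)
        params <- learning_params(tr$alpha, tr$beta, tr$v0_in, tr$v0_out,
                                  variant = model_variant)
        ratings <- simulate_expectancy_obs(sched, params, noise_sd)
        fit <- fit_learning(session_data(sched, ratings), model_variant,
                            n_restarts = n_restarts, seed = seeds[i, 2])
        truth[[i]] <- truth_vector_learning(tr, model_variant)
      } else {
        driver <- with_local_seed(seeds[i, 3], draw_driver_params())
        traj <- simulate_learning(sched, driver)
        params <- draw_closeness_truth(model_variant, ranges)
        sess <- simulate_closeness_session(sched, traj, params, noise_sd)
        fit <- fit_closeness(sess, traj, model_variant, "ingroup",
                             n_restarts = n_restarts, seed = seeds[i, 2])
        truth[[i]] <- truth_vector_closeness(params)
      }
      est[[i]] <- fit$estimates
    }
    list(truth = do.call(rbind, truth), est = do.call(rbind, est))
  })

  correlations <- vapply(colnames(res$truth), function(p) {
    if (sd(res$truth[, p]) == 0) NA_real_
    else cor(res$truth[, p], res$est[, p])
  }, numeric(1))
  flags <- names(correlations)[is.na(correlations)]
  structure(list(model = model_variant, n_simulations = n_simulations,
                 correlations = correlations,
                 min_r = if (all(is.na(correlations))) NA_real_
                         else min(correlations, na.rm = TRUE),
                 ranges = ranges, noise_sd = noise_sd, seed = seed,
                 truth = as.data.frame(res$truth),
                 estimates = as.data.frame(res$est),
                 degenerate_parameters = flags),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> model %s, %d simulations (noise sd %.3g)\n",
              x$model, x$n_simulations, x$noise_sd))
  print(round(x$correlations, 4))
  cat(sprintf("min r = %.4f\n", x$min_r))
  if (length(x$degenerate_parameters))
    cat("degenerate (zero-width range):",
        paste(x$degenerate_parameters, collapse = ", "), "\n")
  invisible(x)
}

#' Model identifiability by confusion matrix
#'
#' For each generating model, simulates `n_agents` sessions with parameters
#' drawn across the full ranges, fits every candidate model to every agent,
#' and records which candidate wins the group-level comparison; the whole
#' procedure is repeated `n_repetitions` times. A diagonal-dominant
#' confusion matrix shows the candidate set is identifiable under the task
#' design.
#'
#' @param model_set `"learning"` (candidates M1, M2, M3) or `"closeness"`
#'   (candidates C1, C2), or a character vector of candidate model ids from
#'   one family.
#' @param n_agents Simulated participants per repetition (default 30).
#' @param n_repetitions Repetitions per generating model (default 10).
#' @param seed Master seed.
#' @param n_restarts Restarts per fit.
#' @param noise_sd Observation noise (defaults as in
#'   [run_parameter_recovery()]).
#' @param winner `"aic"` (group-summed AIC, default) or `"xp"` (exceedance
#'   probability).
#' @param n_blocks,block_length,positive_rate Schedule settings.
#' @return A `confusion_matrix`: generating-model x winning-model counts
#'   with rows summing to `n_repetitions`.
#' @export
run_identifiability <- function(model_set = c("learning", "closeness"),
                                n_agents = 30, n_repetitions = 10,
                                seed = 1L, n_restarts = 10, noise_sd = NULL,
                                winner = c("aic", "xp"), n_blocks = 4,
                                block_length = 24, positive_rate = 0.75) {
  winner <- match.arg(winner)
  candidates <- if (length(model_set) == 1 &&
                    model_set %in% c("learning", "closeness")) {
    if (model_set == "learning") c("M1", "M2", "M3") else c("C1", "C2")
  } else model_set
  if (length(candidates) < 2)
    stop("need at least two candidate models", call. = FALSE)
  is_learning <- all(candidates %in% c("M1", "M2", "M3"))
  if (!is_learning && !all(candidates %in% c("C1", "C2")))
    stop("candidates must all come from one model family", call. = FALSE)
  noise_sd <- noise_sd %||% default_noise_sd(candidates[1])
  ranges <- if (is_learning) default_learning_ranges
            else default_closeness_ranges

  cm <- matrix(0L, length(candidates), length(candidates),
               dimnames = list(generating = candidates, winner = candidates))
  with_local_seed(seed, {
    for (gen in candidates) {
      for (rep_i in seq_len(n_repetitions)) {
        aics <- matrix(NA_real_, n_agents, length(candidates),
                       dimnames = list(NULL, candidates))
        for (a in seq_len(n_agents)) {
          seeds <- spawn_seeds(3)
          sched <- make_schedule(n_blocks, block_length, positive_rate,
                                 seed = seeds[1])
          if (is_learning) {
            tr <- draw_learning_truth(gen, ranges)
            params <- learning_params(tr$alpha, tr$beta, tr$v0_in, tr$v0_out,
                                      variant = gen)
            sess <- session_data(sched,
                                 simulate_expectancy_obs(sched, params,
                                                         noise_sd))
            for (cand in candidates)
              aics[a, cand] <- fit_learning(sess, cand, n_restarts,
                                            seed = seeds[2])$aic
          } else {
            driver <- draw_driver_params()
            traj <- simulate_learning(sched, driver)
            params <- draw_closeness_truth(gen, ranges)
            sess <- simulate_closeness_session(sched, traj, params, noise_sd)
            for (cand in candidates)
              aics[a, cand] <- fit_closeness(sess, traj, cand, "ingroup",
                                             n_restarts,
                                             seed = seeds[2])$aic
          }
        }
        win <- if (winner == "aic") candidates[which.min(colSums(aics))]
               else compare_models(aics, n_samples = 1e5,
                                   seed = spawn_seeds(1))$winner
        cm[gen, win] <- cm[gen, win] + 1L
      }
    }
  })
  structure(cm, class = c("confusion_matrix", class(cm)),
            n_agents = n_agents, n_repetitions = n_repetitions,
            winner = winner, noise_sd = noise_sd, seed = seed)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf(
    "<confusion_matrix> %d agents x %d repetitions (winner by %s)\n",
    attr(x, "n_agents"), attr(x, "n_repetitions"), attr(x, "winner")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}
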