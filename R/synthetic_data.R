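# Descriptive anchors for the two culture profiles (questionnaire scales:
# identification 1-7, impressions 1-9, closeness 0-10, expectancy 0-1).
culture_profiles <- list(
  western = list(
    identification_mean = 4.57, identification_sd = 1.15,
    impression_in_mean = 5.99, impression_in_sd = 1.12,
    impression_out_mean = 5.68, impression_out_sd = 1.14,
    closeness_in_mean = 4.24, closeness_in_sd = 2.43,
    closeness_out_mean = 4.76, closeness_out_sd = 2.41,
    expectancy_in_mean = 0.63, expectancy_out_mean = 0.57,
    bias_identification_r = 0.26),
  east_asian = list(
    identification_mean = 5.75, identification_sd = 0.91,
    impression_in_mean = 6.69, impression_in_sd = 1.14,
    impression_out_mean = 5.04, impression_out_sd = 1.08,
    closeness_in_mean = 7.04, closeness_in_sd = 2.03,
    closeness_out_mean = 4.17, closeness_out_sd = 2.16,
    expectancy_in_mean = 0.57, expectancy_out_mean = 0.44,
    bias_identification_r = 0.25)
)

# Impression change is measured, not modelled: the generator couples
# post-learning impressions to the net closeness change through a
# transparent linear rule (a synthetic convention). The coupling is larger
# in the loss frame and attenuated by ingroup identification, so generated
# populations carry the negative-ingroup-weight association and its
# identification moderation that the linkage analyses are built to detect.
default_coupling <- c(gain = 0.08, loss = 0.60)

identification_attenuation <- function(identification)
  clamp((7 - identification) / 4, 0, 1)

#' Sample a population of synthetic agents
#'
#' Draws agent profiles whose questionnaire descriptives match the culture
#' profile (identification and impression means/SDs; the east_asian profile
#' has higher identification and a larger initial ingroup bias) and whose
#' generative parameters lie in realistic sub-ranges of the fitting bounds:
#' positive learning rates exceed negative ones on average, closeness
#' weights make negative prediction errors reduce closeness, and the
#' initial impression bias correlates positively with identification
#' (population r around 0.25).
#'
#' @param n_agents Number of agents (>= 2).
#' @param frame_split Proportion of agents assigned to the gain frame.
#' @param culture_profile `"western"`, `"east_asian"`, or a custom list with
#'   the same fields as `intergroupRL:::culture_profiles$western`.
#' @param seed Integer seed; identical seeds give identical populations.
#' @return A list of `agent_profile` objects.
#' @examples
#' pop <- sample_population(10, seed = 1)
#' pop[[1]]$identification
#' @export
sample_population <- function(n_agents, frame_split = 0.5,
                              culture_profile = "western", seed = 1L) {
  stopifnot(n_agents >= 2)
  stop_if_not_scalar_prob(frame_split, "frame_split")
  prof <- if (is.character(culture_profile)) {
    culture_profile <- match.arg(culture_profile, names(culture_profiles))
    culture_profiles[[culture_profile]]
  } else culture_profile

  with_local_seed(seed, {
    n_gain <- round(n_agents * frame_split)
    frames <- sample(rep(c("gain", "loss"), c(n_gain, n_agents - n_gain)))

    identification <- clamp(rnorm(n_agents, prof$identification_mean,
                                  prof$identification_sd), 1, 7)
    # initial ingroup bias correlated with identification
    r <- prof$bias_identification_r
    sd_bias <- 1.1
    bias_mean <- prof$impression_in_mean - prof$impression_out_mean
    id_z <- (identification - prof$identification_mean) /
      prof$identification_sd
    bias <- bias_mean + sd_bias * (r * id_z + sqrt(1 - r^2) * rnorm(n_agents))
    mid <- rnorm(n_agents, (prof$impression_in_mean +
                              prof$impression_out_mean) / 2, 0.9)
    imp_in <- clamp(mid + bias / 2, 1, 9)
    imp_out <- clamp(mid - bias / 2, 1, 9)

    lapply(seq_len(n_agents), function(i) {
      lp <- learning_params(
        alpha = c(runif(1, 0.2, 0.8), runif(1, 0.05, 0.5),
                  runif(1, 0.2, 0.8), runif(1, 0.05, 0.5)),
        beta = runif(1, 0.8, 1.3),
        v0_ingroup = clamp(rnorm(1, prof$expectancy_in_mean, 0.15), 0.05, 0.95),
        v0_outgroup = clamp(rnorm(1, prof$expectancy_out_mean, 0.15),
                            0.05, 0.95),
        variant = "M3")
      # Weight ranges sized so per-trial predicted changes are a visible
      # fraction of the report noise while cumulative drives stay of the
      # order of the 0-10 scale over 96 trials (the positive/negative
      # cumulative PE drives roughly balance at these means under the 3:1
      # outcome ratio). Negative weights positive: worse-than-expected
      # outcomes reduce closeness.
      cp <- list(
        ingroup = closeness_params(W0 = runif(1, 0, 0.02),
                                   W_pos = runif(1, 0.4, 1.8),
                                   W_neg = runif(1, 0, 1.4),
                                   gamma = runif(1, 0.2, 0.7)),
        outgroup = closeness_params(W0 = runif(1, 0, 0.02),
                                    W_pos = runif(1, 0.4, 1.8),
                                    W_neg = runif(1, 0, 1.0),
                                    gamma = runif(1, 0.2, 0.7)))
      structure(list(
        participant = i, frame = frames[i], learning = lp, closeness = cp,
        closeness0 = c(
          ingroup = clamp(rnorm(1, prof$closeness_in_mean,
                                prof$closeness_in_sd), 0.5, 9.5),
          outgroup = clamp(rnorm(1, prof$closeness_out_mean,
                                 prof$closeness_out_sd), 0.5, 9.5)),
        identification = identification[i],
        impression_pre = c(ingroup = imp_in[i], outgroup = imp_out[i]),
        noise_sd_expectancy = 0.15, noise_sd_closeness = 0.7,
        coupling = unname(default_coupling[frames[i]])),
        class = "agent_profile")
    })
  })
}

#' @export
print.agent_profile <- function(x, ...) {
  cat(sprintf(
    "<agent_profile> participant %s (%s frame), identification %.2f\n",
    x$participant, x$frame, x$identification))
  invisible(x)
}

#' Generate one synthetic session from an agent profile
#'
#' Runs the agent's learning and closeness models generatively on the
#' schedule. Expectancy ratings are `beta * V` plus Gaussian noise, clipped
#' to \[0, 1\]; each group's first rating equals the agent's initial value
#' (it is the prior the fitting procedure conditions on, not data).
#' Closeness ratings integrate the predicted trial-wise changes plus noise,
#' clipped to \[0, 10\] (clipped trials are retained, as in real rating
#' data). Post-learning impressions couple linearly to the net closeness
#' change (synthetic convention, see [sample_population()]).
#'
#' @param profile An `agent_profile`.
#' @param schedule A [make_schedule()] trial schedule.
#' @param seed Integer seed for the observation noise.
#' @return A [session_data()] object; the profile is attached as attribute
#'   `profile`.
#' @export
generate_session <- function(profile, schedule, seed = 1L) {
  stopifnot(inherits(profile, "agent_profile"),
            inherits(schedule, "trial_schedule"))
  traj <- simulate_learning(schedule, profile$learning)
  n <- nrow(schedule)

  with_local_seed(seed, {
    expectancy <- clamp(predict_expectancy(traj) +
                          rnorm(n, 0, profile$noise_sd_expectancy), 0, 1)
    first_in <- match("ingroup", schedule$group)
    first_out <- match("outgroup", schedule$group)
    expectancy[first_in] <- profile$learning$v0_ingroup
    expectancy[first_out] <- profile$learning$v0_outgroup

    # Ratings are noisy, scale-censored reports of the latent closeness
    # state (the latent state integrates the predicted changes; report
    # noise does not accumulate); noise_sd_closeness is the sd on the
    # trial-to-trial change scale. Impressions couple to the latent net
    # change: the attitude shift, of which the clipped rating is only a
    # censored readout.
    closeness <- list()
    net_change <- c(ingroup = 0, outgroup = 0)
    for (g in c("ingroup", "outgroup")) {
      pred <- predict_closeness_change(traj, profile$closeness[[g]],
                                       g)$predicted_delta
      latent <- profile$closeness0[[g]] + cumsum(c(0, pred[-n]))
      eps <- c(0, rnorm(n - 1, 0, profile$noise_sd_closeness / sqrt(2)))
      closeness[[g]] <- clamp(latent + eps, 0, 10)
      net_change[[g]] <- latent[n] - latent[1]
    }

    couple <- profile$coupling *
      identification_attenuation(profile$identification)
    impression_post <- clamp(
      profile$impression_pre + couple * net_change + rnorm(2, 0, 0.3), 1, 9)

    out <- session_data(schedule, expectancy,
                        closeness_in = closeness$ingroup,
                        closeness_out = closeness$outgroup,
                        impression_pre = profile$impression_pre,
                        impression_post = impression_post,
                        identification = profile$identification,
                        participant = profile$participant)
    attr(out, "profile") <- profile
    out
  })
}

#' Generate a complete synthetic study
#'
#' Samples a population, builds one trial schedule per frame (identical
#' group/outcome sequences in both frames - the frames differ only in
#' payoff presentation, exactly as every participant of the original task
#' received the same feedback sequence) and generates every agent's session.
#'
#' @param n_agents Number of agents.
#' @param culture_profile See [sample_population()].
#' @param frame_split Proportion of agents in the gain frame.
#' @param seed Master seed.
#' @param n_blocks,block_length,positive_rate Schedule settings, see
#'   [make_schedule()].
#' @return A list with `trials` (long-format trial table), `participants`
#'   (per-participant impressions, identification and generating
#'   parameters), `sessions` (list of [session_data()]) and `schedules`
#'   (per frame).
#' @examples
#' study <- simulate_study(6, seed = 1)
#' head(study$participants)
#' @export
simulate_study <- function(n_agents, culture_profile = "western",
                           frame_split = 0.5, seed = 1L, n_blocks = 4,
                           block_length = 24, positive_rate = 0.75) {
  pop <- sample_population(n_agents, frame_split, culture_profile, seed)
  seeds <- with_local_seed(seed + 1L, spawn_seeds(n_agents + 1L))
  schedules <- list(
    gain = make_schedule(n_blocks, block_length, positive_rate,
                         seed = seeds[1], frame = "gain"),
    loss = make_schedule(n_blocks, block_length, positive_rate,
                         seed = seeds[1], frame = "loss"))
  sessions <- lapply(seq_along(pop), function(i)
    generate_session(pop[[i]], schedules[[pop[[i]]$frame]],
                     seed = seeds[i + 1L]))
  trials <- do.call(rbind, lapply(sessions, as.data.frame))
  participants <- do.call(rbind, lapply(pop, function(p) {
    ci <- p$closeness$ingroup; co <- p$closeness$outgroup
    data.frame(
      participant = p$participant, frame = p$frame,
      identification = p$identification,
      impression_pre_in = p$impression_pre[["ingroup"]],
      impression_pre_out = p$impression_pre[["outgroup"]],
      alpha_pos_in = p$learning$alpha[["pos_ingroup"]],
      alpha_neg_in = p$learning$alpha[["neg_ingroup"]],
      alpha_pos_out = p$learning$alpha[["pos_outgroup"]],
      alpha_neg_out = p$learning$alpha[["neg_outgroup"]],
      beta = p$learning$beta,
      W_pos_in = ci$W_pos, W_neg_in = ci$W_neg, gamma_in = ci$gamma,
      W_pos_out = co$W_pos, W_neg_out = co$W_neg, gamma_out = co$gamma,
      stringsAsFactors = FALSE)
  }))
  participants$impression_post_in <- vapply(
    sessions, function(s) s$impression_post[["ingroup"]], numeric(1))
  participants$impression_post_out <- vapply(
    sessions, function(s) s$impression_post[["outgroup"]], numeric(1))
  # intergroup impression change: (in - out)_after - (in - out)_before;
  # negative values mean the initial ingroup bias shrank
  participants$intergroup_change <-
    (participants$impression_post_in - participants$impression_post_out) -
    (participants$impression_pre_in - participants$impression_pre_out)
  list(trials = trials, participants = participants, sessions = sessions,
       schedules = schedules)
}
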