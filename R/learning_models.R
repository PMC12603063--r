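alpha_cells <- c("pos_ingroup", "neg_ingroup", "pos_outgroup", "neg_outgroup")

#' Parameters of the Rescorla-Wagner expectancy models
#'
#' Three nested variants are supported, differing only in how the learning
#' rate is structured:
#' * `M1` - a single learning rate for all trials;
#' * `M2` - one learning rate per partner group (ingroup/outgroup);
#' * `M3` - one learning rate per group x prediction-error valence
#'   (four free rates).
#'
#' Internally every variant is stored as a full four-cell rate map
#' (`pos_ingroup`, `neg_ingroup`, `pos_outgroup`, `neg_outgroup`) with the
#' appropriate ties, so tied parameters make the variants produce identical
#' trajectories. The response parameter `beta` linearly maps the latent
#' value V onto the expectancy-rating scale; initial values `v0_*` are the
#' participant's first observed (normalised) expectancy rating per group.
#'
#' @param alpha Learning rate(s) in \[0, 1\]: length 1 (`M1`), length 2 as
#'   `c(ingroup, outgroup)` (`M2`), or length 4 in the cell order
#'   `pos_ingroup, neg_ingroup, pos_outgroup, neg_outgroup` (`M3`).
#' @param beta Response scaling, > 0 (fitted on (0, 3\]).
#' @param v0_ingroup,v0_outgroup Initial values in \[0, 1\].
#' @param variant Optional `"M1"`/`"M2"`/`"M3"`; inferred from
#'   `length(alpha)` when omitted.
#' @return An object of class `learning_params`.
#' @examples
#' learning_params(alpha = c(0.6, 0.2, 0.4, 0.1), beta = 1.2)
#' @export
learning_params <- function(alpha, beta = 1, v0_ingroup = 0.5,
                            v0_outgroup = 0.5, variant = NULL) {
  variant <- variant %||% switch(as.character(length(alpha)),
                                 "1" = "M1", "2" = "M2", "4" = "M3",
                                 stop("`alpha` must have length 1, 2 or 4",
                                      call. = FALSE))
  variant <- match.arg(variant, c("M1", "M2", "M3"))
  a <- switch(variant,
    M1 = {
      stopifnot(length(alpha) == 1L)
      rep(unname(alpha), 4)
    },
    M2 = {
      stopifnot(length(alpha) == 2L)
      rep(unname(alpha), each = 2)
    },
    M3 = {
      stopifnot(length(alpha) == 4L)
      unname(alpha)
    })
  names(a) <- alpha_cells
  if (any(a < 0 | a > 1))
    stop("learning rates must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("`beta` must be a single positive number", call. = FALSE)
  if (v0_ingroup < 0 || v0_ingroup > 1 || v0_outgroup < 0 || v0_outgroup > 1)
    stop("initial values must lie in [0, 1]", call. = FALSE)
  structure(list(alpha = a, beta = beta, v0_ingroup = v0_ingroup,
                 v0_outgroup = v0_outgroup, variant = variant),
            class = "learning_params")
}

#' @export
print.learning_params <- function(x, ...) {
  cat(sprintf("<learning_params> %s\n", x$variant))
  cat("  alpha:", paste(sprintf("%s=%.3f", names(x$alpha), x$alpha),
                        collapse = ", "), "\n")
  cat(sprintf("  beta=%.3f, v0_ingroup=%.3f, v0_outgroup=%.3f\n",
              x$beta, x$v0_ingroup, x$v0_outgroup))
  invisible(x)
}

#' Simulate the latent learning trajectory for a schedule
#'
#' Runs the deterministic forward recursion: on each trial the predicted
#' expectancy rating is `beta * V` of the active group *before* the outcome
#' is seen; the prediction error `delta = R - V` then updates that group's
#' value with the learning-rate cell selected by the active group and the
#' sign of `delta` (positive valence for `delta >= 0`). Values of the
#' inactive group are untouched, so its trajectory is independent of the
#' other group's outcomes.
#'
#' @param schedule A [make_schedule()] trial schedule.
#' @param params A [learning_params()] object.
#' @return A `latent_trajectory`: data frame with `trial`, `group`, `V`
#'   (value before update), `delta` and `predicted_rating = beta * V`, with
#'   `beta` and the generating parameters stored as attributes.
#' @examples
#' sched <- make_schedule(seed = 2)
#' traj <- simulate_learning(sched, learning_params(0.3, beta = 1))
#' head(traj)
#' @export
simulate_learning <- function(schedule, params) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(params, "learning_params"))
  res <- rw_forward(as.integer(schedule$group == "ingroup"),
                    as.numeric(schedule$outcome),
                    as.numeric(params$alpha), params$beta,
                    params$v0_ingroup, params$v0_outgroup)
  structure(data.frame(trial = schedule$trial, group = schedule$group,
                       V = res$V, delta = res$delta,
                       predicted_rating = res$predicted,
                       stringsAsFactors = FALSE),
            class = c("latent_trajectory", "data.frame"),
            beta = params$beta, params = params)
}

#' Model-predicted expectancy ratings
#'
#' Returns the per-trial predicted expectancy `beta * V` on the normalised
#' \[0, 1\] rating scale. Predictions are not clipped: out-of-range values
#' are penalised through the residuals during fitting rather than masked.
#'
#' @param trajectory A [simulate_learning()] trajectory.
#' @return Numeric vector of predicted ratings.
#' @export
predict_expectancy <- function(trajectory) {
  stopifnot(inherits(trajectory, "latent_trajectory"))
  trajectory$predicted_rating
}

#' Export a latent trajectory in long CSV-ready format
#'
#' @param trajectory A `latent_trajectory`.
#' @param participant Participant identifier.
#' @return Data frame with `participant`, `trial`, `group`, `V`, `delta`,
#'   `predicted_rating`.
#' @export
trajectory_to_long <- function(trajectory, participant = 1L) {
  cbind(participant = participant, as.data.frame(trajectory))
}

#' Convert raw 1-10 expectancy ratings to the normalised scale
#'
#' Expectancy is modelled as a subjective probability on \[0, 1\]; raw
#' 10-step ratings are mapped by `(rating - 1) / 9`.
#'
#' @param rating Numeric vector of raw ratings in \[1, 10\].
#' @return Ratings on \[0, 1\].
#' @export
normalize_expectancy <- function(rating) {
  if (any(rating < 1 | rating > 10, na.rm = TRUE))
    stop("raw expectancy ratings must lie in [1, 10]", call. = FALSE)
  (rating - 1) / 9
}
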