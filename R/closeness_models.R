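#' Parameters of the closeness-update models
#'
#' Trial-wise changes in closeness toward a group are modelled as a linear
#' function of exponentially time-discounted sums of that group's past
#' prediction errors:
#' * `C1` - one weight `W` on the discounted sum of all (signed) prediction
#'   errors;
#' * `C2` - separate weights `W_pos` / `W_neg` on discounted sums of
#'   positive and negative prediction errors.
#'
#' `gamma` controls the exponential decay of past prediction errors: near 1
#' all preceding errors weigh equally, near 0 only the most recent error
#' drives the update. `W0` is a nuisance intercept (drift in closeness
#' unrelated to prediction errors). Fitting bounds are `W` in \[-10, 10\]
#' (10 is the closeness-scale maximum), `W0` in \[0, 10\], `gamma` in
#' \[0, 1\].
#'
#' @param W0 Intercept, in \[0, 10\].
#' @param W Single weight (variant `C1`).
#' @param W_pos,W_neg Valence-specific weights (variant `C2`), in
#'   \[-10, 10\].
#' @param gamma Exponential decay in \[0, 1\].
#' @param variant Optional `"C1"`/`"C2"`; inferred from which weights are
#'   supplied.
#' @return An object of class `closeness_params`.
#' @examples
#' closeness_params(W0 = 0, W_pos = 2, W_neg = -3, gamma = 0.5)
#' @export
closeness_params <- function(W0 = 0, W = NULL, W_pos = NULL, W_neg = NULL,
                             gamma = 0.5, variant = NULL) {
  variant <- variant %||% if (!is.null(W)) "C1" else "C2"
  variant <- match.arg(variant, c("C1", "C2"))
  if (variant == "C1") {
    if (is.null(W)) stop("variant C1 requires `W`", call. = FALSE)
    ws <- c(W = unname(W))
  } else {
    if (is.null(W_pos) || is.null(W_neg))
      stop("variant C2 requires `W_pos` and `W_neg`", call. = FALSE)
    ws <- c(W_pos = unname(W_pos), W_neg = unname(W_neg))
  }
  if (any(ws < -10 | ws > 10))
    stop("weights must lie in [-10, 10]", call. = FALSE)
  if (W0 < 0 || W0 > 10) stop("`W0` must lie in [0, 10]", call. = FALSE)
  if (gamma < 0 || gamma > 1)
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  structure(c(list(W0 = W0, gamma = gamma, variant = variant), as.list(ws)),
            class = "closeness_params")
}

#' @export
print.closeness_params <- function(x, ...) {
  w <- if (x$variant == "C1") sprintf("W=%.3f", x$W)
       else sprintf("W_pos=%.3f, W_neg=%.3f", x$W_pos, x$W_neg)
  cat(sprintf("<closeness_params> %s: W0=%.3f, %s, gamma=%.3f\n",
              x$variant, x$W0, w, x$gamma))
  invisible(x)
}

#' Time-discounted sum of prediction errors up to a trial
#'
#' Computes `sum_{j <= t} gamma^(t - j) * delta_valence(j)` where positive
#' valence keeps `max(delta, 0)`, negative keeps `min(delta, 0)` and `all`
#' keeps the signed error. The series must be aligned to absolute trial
#' time with zeros on trials where the group is inactive: those trials
#' contribute nothing themselves, but still advance the discount clock.
#' With `gamma = 0` only trial `t`'s error survives; with `gamma = 1` all
#' preceding errors weigh equally.
#'
#' @param pe Numeric vector of signed prediction errors indexed by trial.
#' @param gamma Decay in \[0, 1\].
#' @param valence `"positive"`, `"negative"` or `"all"`.
#' @param t Trial at which the sum is evaluated (default: last).
#' @return A single number.
#' @examples
#' discounted_pe_sum(c(0.5, -0.25, 0.1), gamma = 0.5, valence = "positive")
#' @export
discounted_pe_sum <- function(pe, gamma,
                              valence = c("all", "positive", "negative"),
                              t = length(pe)) {
  valence <- match.arg(valence)
  stopifnot(is.numeric(pe), gamma >= 0, gamma <= 1,
            t >= 1, t <= length(pe))
  d <- pe[seq_len(t)]
  d <- switch(valence,
              positive = pmax(d, 0),
              negative = pmin(d, 0),
              all = d)
  sum(gamma^(t - seq_len(t)) * d)  # 0^0 == 1 keeps the gamma = 0 limit exact
}

# Discounted sums for one group over the whole session (C++ recursion).
# Returns a data frame of S_pos, S_neg, S_all aligned to trials.
group_discounted_sums <- function(trajectory, group, gamma) {
  d <- ifelse(trajectory$group == group, trajectory$delta, 0)
  as.data.frame(discount_sums(as.numeric(d), gamma))
}

#' Predicted trial-wise closeness changes for one group
#'
#' Applies the closeness model to the prediction errors of a learning
#' trajectory. The predicted change on trial `t` is
#' `W0 + W * S_all(t)` (`C1`) or `W0 + W_pos * S_pos(t) + W_neg * S_neg(t)`
#' (`C2`), where the `S` terms are gamma-discounted sums of the group's
#' prediction errors running in absolute trial time (trials where the other
#' group acts add a prediction error of zero, so cross-group outcomes never
#' leak into a group's closeness updates). The observable counterpart of
#' the trial-`t` prediction is `rating(t + 1) - rating(t)`: closeness is
#' rated before the outcome, so the final trial's prediction has no
#' observable change.
#'
#' @param trajectory A [simulate_learning()] trajectory.
#' @param params A [closeness_params()] object.
#' @param group `"ingroup"` or `"outgroup"`.
#' @return A `closeness_trajectory`: data frame with `trial`, `group`,
#'   `S_pos`, `S_neg`, `S_all` and `predicted_delta`.
#' @examples
#' sched <- make_schedule(seed = 3)
#' traj <- simulate_learning(sched, learning_params(0.3))
#' cp <- closeness_params(W0 = 0, W_pos = 2, W_neg = -1, gamma = 0.5)
#' head(predict_closeness_change(traj, cp, "ingroup"))
#' @export
predict_closeness_change <- function(trajectory, params,
                                     group = c("ingroup", "outgroup")) {
  stopifnot(inherits(trajectory, "latent_trajectory"),
            inherits(params, "closeness_params"))
  group <- match.arg(group)
  s <- group_discounted_sums(trajectory, group, params$gamma)
  pred <- if (params$variant == "C1") params$W0 + params$W * s$S_all
          else params$W0 + params$W_pos * s$S_pos + params$W_neg * s$S_neg
  structure(data.frame(trial = trajectory$trial, group = group,
                       S_pos = s$S_pos, S_neg = s$S_neg, S_all = s$S_all,
                       predicted_delta = pred, stringsAsFactors = FALSE),
            class = c("closeness_trajectory", "data.frame"),
            params = params)
}

#' Observed closeness changes aligned to prediction errors
#'
#' Closeness toward both groups is rated at the start of every trial, so
#' the change attributable to the prediction error realised on trial `t` is
#' `rating(t + 1) - rating(t)`. The final trial's prediction error has no
#' observable consequence and is dropped.
#'
#' @param closeness Per-trial closeness ratings (0-10) for one group.
#' @return Numeric vector of length `length(closeness) - 1`, aligned to
#'   trials `1 .. n - 1`.
#' @export
observed_closeness_change <- function(closeness) {
  stopifnot(is.numeric(closeness), length(closeness) >= 2)
  diff(closeness)
}
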