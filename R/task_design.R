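#' Frame specification for the intergroup learning task
#'
#' The task presents mathematically identical payoffs either as money given
#' (gain frame: endowment 0 MU, the partner gives 5 or 0 MU) or as money
#' taken from an endowment (loss frame: endowment 10 MU, the partner takes
#' 5 or 10 MU). Both frames end every positive trial at 5 MU and every
#' negative trial at 0 MU.
#'
#' @param frame `"gain"` or `"loss"`.
#' @return An object of class `frame_spec`: a list with `frame_label`,
#'   `endowment`, `positive_transfer` and `negative_transfer` (all in
#'   monetary units, MU).
#' @examples
#' frame_spec("gain")
#' payoff(frame_spec("loss"), c(0, 1))
#' @export
frame_spec <- function(frame = c("gain", "loss")) {
  frame <- match.arg(frame)
  spec <- if (frame == "gain") {
    list(frame_label = "gain", endowment = 0,
         positive_transfer = 5, negative_transfer = 0)
  } else {
    list(frame_label = "loss", endowment = 10,
         positive_transfer = 5, negative_transfer = 10)
  }
  structure(spec, class = "frame_spec")
}

#' @export
print.frame_spec <- function(x, ...) {
  cat(sprintf("<frame_spec> %s: endowment %g MU, transfers %g/%g MU (pos/neg)\n",
              x$frame_label, x$endowment, x$positive_transfer,
              x$negative_transfer))
  invisible(x)
}

#' Final payoff of a trial
#'
#' In the gain frame the partner adds the transfer to a zero endowment; in
#' the loss frame the partner removes the transfer from a 10 MU endowment.
#' Final payoffs are identical across frames: 5 MU for a positive outcome,
#' 0 MU for a negative one.
#'
#' @param frame A [frame_spec()] or the string `"gain"`/`"loss"`.
#' @param outcome Binary outcome(s), 1 = positive event, 0 = negative event.
#' @return Numeric payoff(s) in MU.
#' @export
payoff <- function(frame, outcome) {
  if (is.character(frame)) frame <- frame_spec(frame)
  stopifnot(inherits(frame, "frame_spec"))
  if (!all(outcome %in% c(0, 1)))
    stop("`outcome` must be 0 or 1", call. = FALSE)
  transfer <- ifelse(outcome == 1, frame$positive_transfer,
                     frame$negative_transfer)
  if (frame$frame_label == "gain") frame$endowment + transfer
  else frame$endowment - transfer
}

#' Construct a pseudo-random trial schedule
#'
#' Builds the experimenter-controlled sequence of partner groups and binary
#' outcomes. Group identity is balanced within every block (half ingroup,
#' half outgroup) and the positive-outcome rate is met exactly within each
#' group condition at the session level, so all participants receive
#' equalised experiences with both groups. Defaults reproduce the task
#' structure: 4 blocks of 24 trials (96 total) with 75% positive events,
#' i.e. 36 positive of 48 trials per group.
#'
#' @param n_blocks Number of blocks (default 4).
#' @param block_length Trials per block (default 24; must be even so the
#'   group split is possible within block).
#' @param positive_rate Proportion of positive outcomes per group condition,
#'   in (0, 1]. `positive_rate * n_trials / 2` must be an integer; there is
#'   no rounding rule, off-grid configurations are rejected.
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param frame A [frame_spec()] or `"gain"`/`"loss"`; framing metadata only,
#'   the group/outcome sequences do not depend on it.
#' @return A `trial_schedule`: a data frame with columns `block`, `trial`
#'   (1-based), `group` (`"ingroup"`/`"outgroup"`) and `outcome` (0/1), with
#'   the frame spec and design settings stored as attributes.
#' @examples
#' sched <- make_schedule(seed = 1)
#' table(sched$group, sched$outcome)
#' @export
make_schedule <- function(n_blocks = 4, block_length = 24,
                          positive_rate = 0.75, seed = 1L,
                          frame = frame_spec("gain")) {
  stopifnot(n_blocks >= 1, block_length >= 1)
  if (is.character(frame)) frame <- frame_spec(frame)
  stop_if_not_scalar_prob(positive_rate, "positive_rate")
  if (positive_rate <= 0)
    stop("`positive_rate` must be in (0, 1]", call. = FALSE)
  if (block_length %% 2 != 0)
    stop("`block_length` must be even for an equal group split per block",
         call. = FALSE)
  n_trials <- n_blocks * block_length
  per_group <- n_trials / 2
  n_pos <- positive_rate * per_group
  if (abs(n_pos - round(n_pos)) > 1e-9)
    stop(sprintf(paste0("positive_rate * per-group trial count = %g is not ",
                        "an integer; no rounding rule is configured"), n_pos),
         call. = FALSE)
  n_pos <- as.integer(round(n_pos))

  with_local_seed(seed, {
    group <- unlist(lapply(seq_len(n_blocks), function(b)
      sample(rep(c("ingroup", "outgroup"), block_length / 2))))
    outcome <- integer(n_trials)
    for (g in c("ingroup", "outgroup")) {
      idx <- which(group == g)
      outcome[idx] <- sample(rep(c(1L, 0L), c(n_pos, per_group - n_pos)))
    }
    sched <- data.frame(
      block = rep(seq_len(n_blocks), each = block_length),
      trial = seq_len(n_trials),
      group = group,
      outcome = outcome,
      stringsAsFactors = FALSE
    )
    structure(sched,
              class = c("trial_schedule", "data.frame"),
              frame = frame, n_blocks = n_blocks,
              block_length = block_length,
              positive_rate = positive_rate, seed = seed)
  })
}

#' Check the structural invariants of a trial schedule
#'
#' Verifies trial count, the equal ingroup/outgroup split, within-block
#' group balance and the exact per-group positive-outcome counts.
#'
#' @param schedule A `trial_schedule`.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  nb <- attr(schedule, "n_blocks"); bl <- attr(schedule, "block_length")
  pr <- attr(schedule, "positive_rate")
  if (nrow(schedule) != nb * bl)
    stop("trial count does not equal n_blocks * block_length")
  tab <- table(schedule$group)
  if (length(tab) != 2L || tab[["ingroup"]] != tab[["outgroup"]])
    stop("ingroup and outgroup trial counts differ")
  for (b in unique(schedule$block)) {
    gb <- schedule$group[schedule$block == b]
    if (sum(gb == "ingroup") != bl / 2)
      stop("group identity is not balanced within block ", b)
  }
  for (g in c("ingroup", "outgroup")) {
    r <- schedule$outcome[schedule$group == g]
    if (sum(r) != pr * length(r))
      stop("positive rate is not exact for the ", g, " condition")
  }
  invisible(TRUE)
}

#' Export a schedule (or sessions) in the long trials format
#'
#' @param schedule A `trial_schedule`.
#' @param participant Participant identifier recorded in the output.
#' @return A data frame with columns `participant`, `frame`, `block`,
#'   `trial`, `group`, `outcome`.
#' @export
schedule_to_long <- function(schedule, participant = 1L) {
  stopifnot(inherits(schedule, "trial_schedule"))
  data.frame(participant = participant,
             frame = attr(schedule, "frame")$frame_label,
             block = schedule$block, trial = schedule$trial,
             group = schedule$group, outcome = schedule$outcome,
             stringsAsFactors = FALSE)
}
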