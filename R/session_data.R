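#' One participant's session: ratings aligned to a trial schedule
#'
#' Bundles the trial schedule with the participant's per-trial ratings and
#' the pre/post questionnaire measures used downstream.
#'
#' @param schedule A [make_schedule()] trial schedule.
#' @param expectancy Per-trial expectancy ratings on the normalised \[0, 1\]
#'   scale (use [normalize_expectancy()] for raw 1-10 ratings).
#' @param closeness_in,closeness_out Per-trial 0-10 closeness ratings toward
#'   the ingroup and outgroup.
#' @param impression_pre,impression_post Named numeric vectors
#'   `c(ingroup = , outgroup = )` of impression ratings (1-9 scale) before
#'   and after learning; may be `NULL` for purely trial-level analyses.
#' @param identification Ingroup-identification score (1-7 scale), optional.
#' @param participant Participant identifier.
#' @return An object of class `session_data`.
#' @export
session_data <- function(schedule, expectancy, closeness_in = NULL,
                         closeness_out = NULL, impression_pre = NULL,
                         impression_post = NULL, identification = NA_real_,
                         participant = 1L) {
  stopifnot(inherits(schedule, "trial_schedule"))
  n <- nrow(schedule)
  if (length(expectancy) != n)
    stop("`expectancy` must have one rating per trial", call. = FALSE)
  for (nm in c("closeness_in", "closeness_out")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n)
      stop(sprintf("`%s` must have one rating per trial", nm), call. = FALSE)
  }
  structure(list(schedule = schedule, expectancy = expectancy,
                 closeness_in = closeness_in, closeness_out = closeness_out,
                 impression_pre = impression_pre,
                 impression_post = impression_post,
                 identification = identification,
                 participant = participant),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data> participant %s: %d trials (%s frame)\n",
              x$participant, nrow(x$schedule),
              attr(x$schedule, "frame")$frame_label))
  invisible(x)
}

#' Long-format trial table for one session
#'
#' @param x A `session_data` object.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return Data frame with columns `participant`, `frame`, `block`, `trial`,
#'   `group`, `outcome`, `expectancy`, `closeness_in`, `closeness_out`.
#' @export
as.data.frame.session_data <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  out <- schedule_to_long(x$schedule, x$participant)
  out$expectancy <- x$expectancy
  out$closeness_in <- x$closeness_in %||% NA_real_
  out$closeness_out <- x$closeness_out %||% NA_real_
  out
}
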