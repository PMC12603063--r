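coef_table <- function(fit) {
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             t = s[, 3], p = s[, 4], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Forward/backward stepwise regression on model parameters
#'
#' Data-driven selection of which learning/weight parameters explain an
#' outcome (typically the post- vs pre-learning change in intergroup
#' impressions). Forward steps add the candidate with the smallest
#' coefficient p-value below `entry_p`; backward steps drop any retained
#' predictor whose p-value exceeds `removal_p`; the two alternate until a
#' fixed point. Ties are broken by smaller p-value, then lexical predictor
#' name.
#'
#' @param candidates Data frame of numeric candidate predictors.
#' @param outcome Numeric outcome vector.
#' @param entry_p Forward entry threshold (default 0.05).
#' @param removal_p Backward removal threshold (default 0.10).
#' @return A `linkage_result` list with `selected_predictors`,
#'   `coefficients` (term/estimate/se/t/p of the final model), `fit` (the
#'   final `lm`; intercept-only when nothing enters) and the thresholds.
#' @examples
#' set.seed(1)
#' x <- data.frame(a = rnorm(60), b = rnorm(60))
#' stepwise_regression(x, 2 * x$a + rnorm(60, 0, 0.5))$selected_predictors
#' @export
stepwise_regression <- function(candidates, outcome, entry_p = 0.05,
                                removal_p = 0.10) {
  stopifnot(is.data.frame(candidates), nrow(candidates) == length(outcome))
  if (nrow(candidates) <= ncol(candidates) + 2)
    stop("need more observations than candidates + 2", call. = FALSE)
  stop_if_not_scalar_prob(entry_p, "entry_p")
  stop_if_not_scalar_prob(removal_p, "removal_p")

  # drop later members of (near-)duplicate candidate pairs
  if (ncol(candidates) > 1) {
    cc <- abs(cor(candidates))
    dup <- character(0)
    nms <- names(candidates)
    for (j in 2:ncol(cc)) if (any(cc[seq_len(j - 1), j] > 0.999))
      dup <- c(dup, nms[j])
    if (length(dup)) {
      warning("dropping collinear candidate(s): ",
              paste(dup, collapse = ", "))
      candidates <- candidates[setdiff(nms, dup)]
    }
  }

  dat <- cbind(.outcome = outcome, candidates)
  fit_with <- function(preds) {
    rhs <- if (length(preds)) paste(preds, collapse = " + ") else "1"
    lm(as.formula(paste(".outcome ~", rhs)), data = dat)
  }
  term_p <- function(fit, term) {
    s <- summary(fit)$coefficients
    if (!term %in% rownames(s)) return(NA_real_)
    s[term, 4]
  }

  selected <- character(0)
  for (iter in seq_len(2 * ncol(candidates) + 10)) {
    changed <- FALSE
    remaining <- setdiff(names(candidates), selected)
    if (length(remaining)) {
      ps <- vapply(remaining, function(cand)
        term_p(fit_with(c(selected, cand)), cand), numeric(1))
      ps[is.na(ps)] <- Inf
      ord <- order(ps, remaining)
      if (ps[ord[1]] < entry_p) {
        selected <- c(selected, remaining[ord[1]])
        changed <- TRUE
      }
    }
    if (length(selected)) {
      fit <- fit_with(selected)
      ps <- vapply(selected, function(s) term_p(fit, s), numeric(1))
      worst <- which.max(ps)
      if (ps[worst] > removal_p) {
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  fit <- fit_with(selected)
  structure(list(analysis = "stepwise", selected_predictors = selected,
                 coefficients = coef_table(fit), fit = fit,
                 entry_p = entry_p, removal_p = removal_p),
            class = "linkage_result")
}

#' Moderation analysis with simple slopes
#'
#' Ordinary least squares of the outcome on a mean-centered predictor, the
#' moderator (mean-centered when numeric, coded 0/1 when binary), their
#' product and optional covariates. Reports the interaction coefficient and
#' simple slopes of the predictor at moderator levels (mean +/- 1 SD for a
#' numeric moderator, each level for a binary one).
#'
#' @param x Numeric predictor (e.g. a fitted weight parameter).
#' @param moderator Numeric or two-level moderator (e.g. frame or
#'   identification score).
#' @param outcome Numeric outcome (e.g. intergroup impression change).
#' @param covariates Optional data frame of covariates.
#' @return A `linkage_result` with the full coefficient table, the
#'   `interaction` row and a `simple_slopes` data frame.
#' @examples
#' set.seed(1)
#' x <- rnorm(60); m <- rnorm(60)
#' moderation(x, m, x * m + rnorm(60, 0, 0.1))$interaction
#' @export
moderation <- function(x, moderator, outcome, covariates = NULL) {
  n <- length(outcome)
  stopifnot(length(x) == n, length(moderator) == n, n > 10)
  if (is.character(moderator) || is.factor(moderator))
    moderator <- as.integer(factor(moderator)) - 1L
  lv <- unique(moderator)
  if (length(lv) < 2) stop("moderator has zero variance", call. = FALSE)
  binary <- length(lv) == 2L
  m <- if (binary) as.numeric(moderator == max(lv))
       else moderator - mean(moderator)
  xc <- x - mean(x)

  dat <- data.frame(.outcome = outcome, .x = xc, .m = m)
  rhs <- ".x * .m"
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == n)
    dat <- cbind(dat, covariates)
    rhs <- paste(c(rhs, names(covariates)), collapse = " + ")
  }
  fit <- lm(as.formula(paste(".outcome ~", rhs)), data = dat)
  ct <- coef_table(fit)
  inter <- ct[ct$term == ".x:.m", ]

  levels_at <- if (binary) c(0, 1) else c(-sd(m), sd(m))
  level_lab <- if (binary) c("level 0", "level 1")
               else c("mean - 1sd", "mean + 1sd")
  V <- vcov(fit)
  b <- coef(fit)
  slopes <- do.call(rbind, lapply(seq_along(levels_at), function(i) {
    mv <- levels_at[i]
    est <- b[".x"] + mv * b[".x:.m"]
    se <- sqrt(V[".x", ".x"] + mv^2 * V[".x:.m", ".x:.m"] +
                 2 * mv * V[".x", ".x:.m"])
    tval <- est / se
    data.frame(moderator_level = level_lab[i], at = mv, slope = est,
               se = se, t = tval,
               p = 2 * pt(-abs(tval), df = fit$df.residual),
               row.names = NULL)
  }))
  structure(list(analysis = "moderation", coefficients = ct,
                 interaction = inter, simple_slopes = slopes, fit = fit,
                 moderator_binary = binary),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("<linkage_result> %s\n", x$analysis))
  if (x$analysis == "stepwise")
    cat("selected:", if (length(x$selected_predictors))
      paste(x$selected_predictors, collapse = ", ") else "(none)", "\n")
  print(x$coefficients, row.names = FALSE)
  if (!is.null(x$simple_slopes)) {
    cat("simple slopes:\n")
    print(x$simple_slopes, row.names = FALSE)
  }
  invisible(x)
}

#' Influence diagnostics and robustness refit
#'
#' Flags observations exceeding any of the standard influence cutoffs for a
#' fitted OLS model with `k` coefficients and `n` observations:
#' `|DFFITS| > 2 * sqrt(k / n)`, Cook's distance `> 4 / n`, leverage
#' `> 2k / n`, or any standardised `|DFBETA| > 1`; then refits the model
#' without the flagged cases. With no flags the refit is the original fit.
#'
#' @param fit An `lm` fit with `n > k + 2`.
#' @return A list with `flagged` (row indices), `criteria` (logical matrix
#'   of which cutoff fired per observation), `fit` (original) and `refit`
#'   (model excluding flagged cases).
#' @export
influence_filter <- function(fit) {
  stopifnot(inherits(fit, "lm"))
  n <- nrow(fit$model)
  k <- length(coef(fit))
  if (n <= k + 2) stop("need n > k + 2 observations", call. = FALSE)
  criteria <- cbind(
    dffits = abs(dffits(fit)) > 2 * sqrt(k / n),
    cooks = cooks.distance(fit) > 4 / n,
    leverage = hatvalues(fit) > 2 * k / n,
    dfbetas = apply(abs(dfbetas(fit)) > 1, 1, any))
  flagged <- which(apply(criteria, 1, any))
  refit <- if (length(flagged)) {
    lm(formula(fit), data = fit$model[-flagged, , drop = FALSE])
  } else fit
  list(flagged = unname(flagged), criteria = criteria, fit = fit,
       refit = refit)
}

#' Correlation between ingroup identification and initial ingroup bias
#'
#' The initial ingroup bias is the pre-learning ingroup-minus-outgroup
#' impression difference. Reports the Pearson correlation with the
#' identification score (and Spearman as robustness).
#'
#' @param participants Data frame with columns `identification`,
#'   `impression_pre_in`, `impression_pre_out` (as produced by
#'   [simulate_study()]).
#' @return A list with `n`, `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p` and `flag` (`"degenerate"` when either variable is
#'   constant).
#' @export
bias_identification_correlation <- function(participants) {
  need <- c("identification", "impression_pre_in", "impression_pre_out")
  if (!all(need %in% names(participants)))
    stop("`participants` must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  n <- nrow(participants)
  if (n < 4) stop("need at least 4 participants", call. = FALSE)
  bias <- participants$impression_pre_in - participants$impression_pre_out
  id <- participants$identification
  if (sd(id) == 0 || sd(bias) == 0) {
    warning("constant identification or bias: correlation undefined")
    return(list(n = n, pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                flag = "degenerate"))
  }
  pe <- cor.test(id, bias, method = "pearson")
  sp <- suppressWarnings(cor.test(id, bias, method = "spearman"))
  list(n = n, pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       flag = "ok")
}
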