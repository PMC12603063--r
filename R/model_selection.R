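#' Build a participants x models AIC matrix from fit results
#'
#' @param fits List of `fit_result` objects covering every participant x
#'   model combination.
#' @return Numeric matrix with participants as rows and models as columns.
#' @export
aic_matrix <- function(fits) {
  tab <- fits_to_table(fits)
  participants <- unique(tab$participant)
  models <- unique(tab$model)
  m <- matrix(NA_real_, length(participants), length(models),
              dimnames = list(as.character(participants), models))
  for (i in seq_len(nrow(tab)))
    m[as.character(tab$participant[i]), tab$model[i]] <- tab$aic[i]
  m
}

#' Random-effects Bayesian model selection with exceedance probabilities
#'
#' Compares candidate models across participants. Per-participant AIC values
#' are converted to approximate log model evidence (`-AIC/2`) and fed to the
#' standard variational random-effects scheme: model frequencies in the
#' population carry a Dirichlet prior (uniform, `alpha0 = 1`) and
#' per-participant model assignments are updated in closed form until the
#' posterior Dirichlet concentration converges. The exceedance probability
#' (XP) of a model - the posterior probability that it is the most frequent
#' model in the population - is estimated by Monte-Carlo sampling from the
#' posterior Dirichlet. An XP above 0.95 is conventionally read as
#' significant evidence for a model. A fixed-effects summary (summed AIC) is
#' reported alongside.
#'
#' Because only evidence differences matter, adding a constant to every
#' model's AIC within a participant leaves the result unchanged.
#'
#' @param aic Participants x models matrix of AIC values (see
#'   [aic_matrix()]), or a list of `fit_result`s.
#' @param alpha0 Dirichlet prior concentration per model (default 1).
#' @param n_samples Monte-Carlo draws for the XP estimate (default 1e6).
#' @param seed Seed for the Monte-Carlo draws.
#' @param tol,max_iter Convergence controls of the variational loop.
#' @return A `comparison_result`: list with `aic_matrix`, `evidence_matrix`,
#'   `dirichlet_alpha`, `expected_frequencies`, `exceedance_probability`,
#'   `summed_aic`, `winner` and `unresolved` (TRUE when the top two XPs are
#'   within 0.01).
#' @examples
#' aics <- cbind(M1 = c(110, 120, 115), M2 = c(100, 104, 98))
#' compare_models(aics, n_samples = 1e4, seed = 1)
#' @export
compare_models <- function(aic, alpha0 = 1, n_samples = 1e6, seed = 1L,
                           tol = 1e-8, max_iter = 1000) {
  if (is.list(aic) && !is.matrix(aic)) aic <- aic_matrix(aic)
  stopifnot(is.matrix(aic), ncol(aic) >= 2)
  if (anyNA(aic)) {
    bad <- which(is.na(aic), arr.ind = TRUE)[1, ]
    stop(sprintf("missing fit: participant %s, model %s",
                 rownames(aic)[bad[1]] %||% bad[1],
                 colnames(aic)[bad[2]] %||% bad[2]), call. = FALSE)
  }
  models <- colnames(aic) %||% paste0("model", seq_len(ncol(aic)))
  lme <- -aic / 2
  M <- ncol(lme)

  alpha <- rep(alpha0, M)
  for (it in seq_len(max_iter)) {
    lnu <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lnu <- lnu - apply(lnu, 1, max)
    g <- exp(lnu)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  xp <- with_local_seed(seed, {
    draws <- matrix(rgamma(n_samples * M, shape = rep(alpha, each = n_samples)),
                    nrow = n_samples)
    tabulate(max.col(draws, ties.method = "first"), M) / n_samples
  })
  names(xp) <- models
  ef <- setNames(alpha / sum(alpha), models)

  ord <- order(xp, decreasing = TRUE)
  unresolved <- (xp[ord[1]] - xp[ord[2]]) < 0.01
  structure(list(aic_matrix = aic, evidence_matrix = lme,
                 dirichlet_alpha = setNames(alpha, models),
                 expected_frequencies = ef,
                 exceedance_probability = xp,
                 summed_aic = setNames(colSums(aic), models),
                 winner = models[ord[1]], unresolved = unresolved,
                 n_samples = n_samples, seed = seed),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d participants, %d models\n",
              nrow(x$aic_matrix), ncol(x$aic_matrix)))
  tab <- data.frame(model = names(x$exceedance_probability),
                    xp = round(x$exceedance_probability, 4),
                    expected_freq = round(x$expected_frequencies, 4),
                    summed_aic = round(x$summed_aic, 2))
  print(tab, row.names = FALSE)
  cat(sprintf("winner: %s%s\n", x$winner,
              if (x$unresolved) " (unresolved: top models within 0.01 XP)"
              else ""))
  invisible(x)
}

#' Comparison report as a data frame
#'
#' @param comparison A [compare_models()] result.
#' @return Data frame with one row per model: XP, expected frequency,
#'   Dirichlet concentration and summed AIC.
#' @export
comparison_to_table <- function(comparison) {
  stopifnot(inherits(comparison, "comparison_result"))
  data.frame(model = names(comparison$exceedance_probability),
             exceedance_probability = comparison$exceedance_probability,
             expected_frequency = comparison$expected_frequencies,
             dirichlet_alpha = comparison$dirichlet_alpha,
             summed_aic = comparison$summed_aic,
             row.names = NULL, stringsAsFactors = FALSE)
}
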