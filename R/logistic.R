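#' Multivariable logistic regression by iteratively reweighted least squares
#'
#' The comparison model of the pipeline: the binary multimorbidity outcome
#' is regressed on the integer-scored predictors, one coefficient per
#' variable (each code treated as a score, matching a one-row-per-variable
#' forest plot; set `dummy = TRUE` for indicator coding of every non-binary
#' predictor instead). The Bernoulli log-likelihood is maximized by
#' Newton-Raphson / IRLS; standard errors come from the inverse observed
#' information and Wald 95% intervals are `exp(beta +/- 1.96 se)`.
#'
#' Perfect (quasi-)separation makes the MLE diverge; it is detected by
#' runaway coefficients or a singular information matrix, flagged in the
#' returned object and warned about, and the partial result is returned.
#'
#' @param data Data frame holding the outcome and predictors, complete for
#'   the used columns.
#' @param outcome Name of the 0/1 outcome column (default `"mmd"`).
#' @param predictors Predictor column names; default all other study
#'   variables present in `data`.
#' @param dummy Use indicator (dummy) coding for predictors with more than
#'   two codes instead of integer scores (default `FALSE`).
#' @param tol Convergence tolerance on the maximum absolute score-equation
#'   component (default `1e-10`).
#' @param max_iter Newton iteration cap (default 50).
#' @return An object of class `mmd_logit` with fields `coefficients`,
#'   `std_errors`, `vcov`, `log_likelihood`, `converged`, `separation`,
#'   `iterations`, `n`, plus the model frame metadata. Use [tidy()] /
#'   [odds_ratio_table()] for reporting.
#' @export
#' @examples
#' d <- ancestral_sample(charls_like_network(), 2000, seed = 3)
#' fit <- fit_logistic_irls(d)
#' tidy(fit)
fit_logistic_irls <- function(data, outcome = "mmd", predictors = NULL,
                              dummy = FALSE, tol = 1e-10, max_iter = 50) {
  data <- tibble::as_tibble(data)
  predictors <- predictors %||% setdiff(intersect(mmd_variables(), names(data)), outcome)
  if (!length(predictors)) stop_contract("no predictors available")
  used <- c(outcome, predictors)
  if (anyNA(data[used])) stop_contract("model columns must be complete; impute first")
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop_contract("outcome must be coded 0/1")
  X <- if (dummy) {
    mf <- data[predictors]
    for (v in predictors) {
      if (length(unique(mf[[v]])) > 2) mf[[v]] <- factor(mf[[v]])
    }
    stats::model.matrix(~ ., data = mf)
  } else {
    cbind(`(Intercept)` = 1, as.matrix(data[predictors]))
  }
  beta <- rep(0, ncol(X))
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  H <- diag(ncol(X))
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- as.numeric(X %*% beta)
    p <- plogis(eta)
    score <- as.numeric(crossprod(X, y - p))
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) {
      separation <- TRUE
      break
    }
    beta <- beta + step
    if (max(abs(beta)) > 20) {
      separation <- TRUE
      break
    }
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
  }
  # recompute at the final beta so reported quantities are self-consistent
  eta <- as.numeric(X %*% beta)
  p <- plogis(eta)
  score <- as.numeric(crossprod(X, y - p))
  if (max(abs(score)) < tol) converged <- TRUE
  if (separation) {
    warn("possible perfect separation: coefficients diverged; partial result returned")
  } else if (!converged) {
    warn("IRLS did not converge within `max_iter`")
  }
  w <- pmax(p * (1 - p), 1e-12)
  H <- crossprod(X * w, X)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(pmax(diag(vc), 0))
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  structure(list(
    coefficients = setNames(beta, colnames(X)),
    std_errors = setNames(se, colnames(X)),
    vcov = vc,
    log_likelihood = ll,
    converged = converged,
    separation = separation,
    iterations = iter,
    max_score = max(abs(score)),
    n = length(y),
    outcome = outcome,
    predictors = predictors,
    dummy = dummy
  ), class = "mmd_logit")
}

#' @export
print.mmd_logit <- function(x, ...) {
  cat(sprintf("<mmd_logit> n = %d, logLik = %.2f, %s in %d iteration(s)%s\n",
              x$n, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$iterations,
              if (x$separation) " [separation flagged]" else ""))
  print(tidy(x))
  invisible(x)
}

#' Tidy coefficient table of a logistic fit
#'
#' @param x An `mmd_logit`.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std_error`, `statistic` (Wald z), `p_value`, `odds_ratio`, `ci_low`,
#'   `ci_high` (95% Wald limits on the odds-ratio scale).
#' @method tidy mmd_logit
#' @export
tidy.mmd_logit <- function(x, ...) {
  z <- x$coefficients / x$std_errors
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = unname(x$std_errors),
    statistic = unname(z),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    odds_ratio = exp(unname(x$coefficients)),
    ci_low = exp(unname(x$coefficients - qnorm(0.975) * x$std_errors)),
    ci_high = exp(unname(x$coefficients + qnorm(0.975) * x$std_errors))
  )
}

#' @method glance mmd_logit
#' @export
glance.mmd_logit <- function(x, ...) {
  tibble::tibble(
    n = x$n, log_likelihood = x$log_likelihood, iterations = x$iterations,
    converged = x$converged, separation = x$separation, max_score = x$max_score
  )
}

#' Odds-ratio report of the logistic baseline
#'
#' One row per predictor (the intercept is dropped), with the odds ratio
#' and its Wald 95% interval rounded to two decimals in the style of
#' published forest plots; the Wald p-value is kept at full precision.
#'
#' @param fit An `mmd_logit`.
#' @return A tibble `(variable, odds_ratio, ci_low, ci_high, p_value)`.
#' @export
odds_ratio_table <- function(fit) {
  stopifnot(inherits(fit, "mmd_logit"))
  td <- tidy(fit)
  td <- td[td$term != "(Intercept)", ]
  tibble::tibble(
    variable = td$term,
    odds_ratio = round_half_up(td$odds_ratio, 2),
    ci_low = round_half_up(td$ci_low, 2),
    ci_high = round_half_up(td$ci_high, 2),
    p_value = td$p_value
  )
}

#' Forest-plot data for an odds-ratio table
#'
#' Prepares the plotting specification behind the forest plot: ordered
#' rows with the point estimate, interval ends, the reference line at odds
#' ratio 1, and an `associated` flag that is `FALSE` whenever the interval
#' crosses 1 (an interval through the reference line means the predictor is
#' not associated with the outcome at the 5% level).
#'
#' @param table An odds-ratio table from [odds_ratio_table()] (or any tibble
#'   with `variable`, `odds_ratio`, `ci_low`, `ci_high`).
#' @return A tibble with `variable`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `reference` (always 1) and `associated`.
#' @export
forest_plot_data <- function(table) {
  table <- tibble::as_tibble(table)
  if (nrow(table) == 0) {
    return(tibble::tibble(variable = character(0), odds_ratio = numeric(0),
                          ci_low = numeric(0), ci_high = numeric(0),
                          reference = numeric(0), associated = logical(0)))
  }
  tibble::tibble(
    variable = table$variable,
    odds_ratio = table$odds_ratio,
    ci_low = table$ci_low,
    ci_high = table$ci_high,
    reference = 1,
    associated = table$ci_low > 1 | table$ci_high < 1
  )
}

#' Forest plot of a logistic fit
#'
#' @param object An `mmd_logit`.
#' @param ... Unused.
#' @return A ggplot: odds ratios with 95% Wald intervals on a log scale and
#'   a dashed reference line at 1.
#' @method autoplot mmd_logit
#' @export
autoplot.mmd_logit <- function(object, ...) {
  fp <- forest_plot_data(odds_ratio_table(object))
  ggplot2::ggplot(fp, ggplot2::aes(x = .data$odds_ratio,
                                   y = stats::reorder(.data$variable, .data$odds_ratio))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high,
                                          colour = .data$associated)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL, colour = "Associated") +
    ggplot2::theme_minimal()
}
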