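#' Mode-fill initialization for missing categorical cells
#'
#' Replaces every missing cell by its column's most frequent observed code,
#' breaking ties toward the smallest code. This is both the starting point
#' of [rf_impute()] and the naive baseline that the forest imputer must
#' beat.
#'
#' @param data Data frame of integer codes, possibly with `NA`s.
#' @return A complete tibble.
#' @export
initialize_fill <- function(data) {
  data <- tibble::as_tibble(data)
  for (v in names(data)) {
    x <- data[[v]]
    if (!anyNA(x)) next
    obs <- x[!is.na(x)]
    if (!length(obs)) {
      stop_contract(sprintf("column `%s` is fully missing; cannot initialize", v))
    }
    tab <- table(obs)
    mode <- sort(as.numeric(names(tab)[tab == max(tab)]))[1]
    x[is.na(x)] <- if (is.integer(x)) as.integer(mode) else mode
    data[[v]] <- x
  }
  data
}

#' Iterative random-forest imputation for categorical data
#'
#' missForest-style scheme for integer-coded categorical tables: missing
#' cells are mode-filled, then columns are revisited in order of increasing
#' missingness; for each, a classification random forest is trained on the
#' rows where the column is observed (all other columns as predictors) and
#' its missing cells are re-predicted. Sweeps repeat until the fraction of
#' imputed cells that changed stops decreasing (the previous iterate is
#' returned) or `max_iter` is reached. Observed cells are never touched.
#'
#' @param data Data frame of integer codes with `NA` for missing.
#' @param max_iter Maximum number of column sweeps (default 10).
#' @param trees Trees per forest (default 100).
#' @param mtry Predictors tried per split; default `ceiling(sqrt(p))`.
#' @param seed Integer seed; forests are seeded per (sweep, column) so runs
#'   are reproducible.
#' @return An object of class `mmd_imputation`: list with `completed`
#'   (complete tibble), `iterations`, `disagreement` (per-sweep fraction of
#'   imputed cells changed) and `mask` (logical tibble of originally
#'   missing cells).
#' @export
rf_impute <- function(data, max_iter = 10, trees = 100, mtry = NULL, seed = 1) {
  data <- tibble::as_tibble(data)
  stopifnot(max_iter >= 1)
  miss <- is.na(as.matrix(data))
  mask <- tibble::as_tibble(as.data.frame(miss))
  n_miss <- sum(miss)
  if (n_miss == 0) {
    return(structure(list(completed = data, iterations = 1L,
                          disagreement = 0, mask = mask),
                     class = "mmd_imputation"))
  }
  levels_all <- default_levels(data)
  cols <- names(data)[colSums(miss) > 0]
  cols <- cols[order(colSums(miss)[match(cols, names(data))], cols)]
  mtry <- mtry %||% ceiling(sqrt(ncol(data) - 1))
  current <- initialize_fill(data)
  disagreement <- numeric(0)
  best <- current
  withr::with_seed(sub_seed(seed, "rf_impute"), {
    for (sweep in seq_len(max_iter)) {
      previous <- current
      for (v in cols) {
        obs_rows <- !miss[, v]
        train <- as_factor_frame(current[obs_rows, , drop = FALSE], levels_all)
        test <- as_factor_frame(current[miss[, v], , drop = FALSE], levels_all)
        fit <- ranger::ranger(
          x = train[setdiff(names(train), v)], y = train[[v]],
          num.trees = trees, mtry = min(mtry, ncol(train) - 1),
          seed = sub_seed(seed, paste0(sweep, ":", v)),
          num.threads = 1, verbose = FALSE, respect.unordered.factors = "order"
        )
        pred <- stats::predict(fit, data = test[setdiff(names(test), v)],
                               num.threads = 1,
                               seed = sub_seed(seed, paste0("p", sweep, ":", v)))$predictions
        filled <- current[[v]]
        new_vals <- as.numeric(as.character(pred))
        filled[miss[, v]] <- if (is.integer(filled)) as.integer(new_vals) else new_vals
        current[[v]] <- filled
      }
      changed <- sum(as.matrix(current)[miss] != as.matrix(previous)[miss])
      disagreement <- c(disagreement, changed / n_miss)
      if (sweep > 1 && disagreement[sweep] >= disagreement[sweep - 1]) {
        best <- previous  # convergence criterion: return the previous iterate
        break
      }
      best <- current
      if (disagreement[sweep] == 0) break
    }
  })
  structure(list(completed = best, iterations = length(disagreement),
                 disagreement = disagreement, mask = mask),
            class = "mmd_imputation")
}

as_factor_frame <- function(data, levels_all) {
  out <- data
  for (v in names(out)) {
    out[[v]] <- factor(out[[v]], levels = levels_all[[v]])
  }
  as.data.frame(out)
}

#' @export
print.mmd_imputation <- function(x, ...) {
  cat(sprintf("<mmd_imputation> %d masked cell(s), %d sweep(s); disagreement: %s\n",
              sum(as.matrix(x$mask)), x$iterations,
              paste(signif(x$disagreement, 3), collapse = ", ")))
  invisible(x)
}

#' Accuracy of imputed cells against the ground truth
#'
#' @param truth Complete data frame holding the true codes.
#' @param result An `mmd_imputation`, or any complete data frame of the same
#'   shape.
#' @param mask Logical data frame / matrix marking the cells that were
#'   missing; defaults to the result's own mask.
#' @return Fraction of masked cells imputed correctly, or `NA` (with a
#'   message) when the mask is empty.
#' @export
imputation_accuracy <- function(truth, result, mask = NULL) {
  completed <- if (inherits(result, "mmd_imputation")) result$completed else result
  mask <- mask %||% (if (inherits(result, "mmd_imputation")) result$mask else NULL)
  if (is.null(mask)) stop_contract("`mask` is required when `result` is a plain table")
  truth <- as.matrix(truth)
  completed <- as.matrix(completed)
  mask <- as.matrix(mask)
  if (!all(dim(truth) == dim(completed)) || !all(dim(truth) == dim(mask))) {
    stop_contract("`truth`, imputed data and `mask` must share one shape")
  }
  if (!any(mask)) {
    inform("empty mask: no imputed cells to score")
    return(NA_real_)
  }
  mean(completed[mask] == truth[mask])
}
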