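#' G-squared conditional-independence test
#'
#' Likelihood-ratio test of `x` independent of `y` given the variable set
#' `z` on complete categorical data. Within each stratum of `z` the observed
#' `x` by `y` table is compared with its independence expectation:
#' `G2 = 2 * sum O * ln(O / E)` summed over all cells and strata (empty
#' cells contribute 0), referred to a chi-square distribution with
#' `(|x|-1) * (|y|-1) * prod(|z_i|)` degrees of freedom.
#'
#' Two guards make high-order tests honest rather than noisy: a test whose
#' conditioning set exceeds `max_condition_size`, or whose sample size falls
#' below `adequacy_k` observations per degree of freedom, is skipped and
#' reported with `performed = FALSE` and `p_value = 1` (treated as
#' independence by callers).
#'
#' @param data Complete data frame of categorical codes.
#' @param x,y Column names to test.
#' @param z Character vector of conditioning columns (default none).
#' @param levels Optional named list of code domains; defaults to the study
#'   codebook / observed codes.
#' @param statistic `"g2"` (default, likelihood ratio) or `"x2"` (Pearson).
#' @param max_condition_size Skip tests conditioning on more than this many
#'   variables (default `Inf`).
#' @param adequacy_k Skip tests with fewer than `adequacy_k * df`
#'   observations (default 5).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `performed`, `n`.
#' @export
#' @examples
#' d <- data.frame(a = rep(0:1, each = 40), b = rep(c(0, 1, 0, 1), c(30, 10, 10, 30)))
#' g2_test(d, "a", "b")
g2_test <- function(data, x, y, z = character(0), levels = NULL,
                    statistic = c("g2", "x2"),
                    max_condition_size = Inf, adequacy_k = 5) {
  statistic <- match.arg(statistic)
  if (x == y || x %in% z || y %in% z) {
    stop_contract("`x`, `y` and `z` must be distinct")
  }
  data <- tibble::as_tibble(data)
  cols <- c(x, y, z)
  if (anyNA(data[cols])) stop_contract("data must be complete for CI testing")
  levels <- default_levels(data[cols], levels)
  card <- vapply(levels, length, integer(1))
  df <- (card[[x]] - 1) * (card[[y]] - 1) * prod(card[z])
  n <- nrow(data)
  skipped <- tibble::tibble(statistic = NA_real_, df = as.integer(df),
                            p_value = 1, performed = FALSE, n = n)
  if (length(z) > max_condition_size || n < adequacy_k * df) return(skipped)
  idx <- code_index_matrix(data, cols, levels)
  cfg <- rep(1L, n)
  mult <- 1L
  for (v in z) {
    cfg <- cfg + (idx[, v] - 1L) * mult
    mult <- mult * card[[v]]
  }
  kx <- card[[x]]; ky <- card[[y]]; j <- prod(card[z])
  counts <- tabulate(idx[, x] + kx * (idx[, y] - 1L) + kx * ky * (cfg - 1L),
                     nbins = kx * ky * j)
  counts <- array(counts, dim = c(kx, ky, j))
  stat <- 0
  for (s in seq_len(j)) {
    o <- counts[, , s]
    ns <- sum(o)
    if (ns == 0) next
    e <- outer(rowSums(o), colSums(o)) / ns
    if (statistic == "g2") {
      pos <- o > 0
      stat <- stat + 2 * sum(o[pos] * log(o[pos] / e[pos]))
    } else {
      pos <- e > 0
      stat <- stat + sum((o[pos] - e[pos])^2 / e[pos])
    }
  }
  tibble::tibble(
    statistic = stat, df = as.integer(df),
    p_value = pchisq(stat, df = df, lower.tail = FALSE),
    performed = TRUE, n = n
  )
}

# association p-value used by MMPC (smaller p = stronger association);
# skipped tests count as independence
assoc_pvalue <- function(data, x, y, z, levels, max_condition_size, adequacy_k) {
  g2_test(data, x, y, z, levels = levels,
          max_condition_size = max_condition_size,
          adequacy_k = adequacy_k)$p_value
}
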