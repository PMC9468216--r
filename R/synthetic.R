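#' Published baseline frequency table of the study cohort
#'
#' Per-variable category counts of the 19,752-subject cohort, stratified by
#' multimorbidity status (9,129 without, 10,623 with), as shipped in
#' `extdata/table1_counts.csv`. These printed counts are the calibration
#' input for the synthetic ground-truth network and the reference for
#' summary-table checks.
#'
#' @return A tibble with columns `variable`, `code`, `label`,
#'   `n_without_mmd`, `n_with_mmd`.
#' @export
table1_counts <- function() {
  path <- system.file("extdata", "table1_counts.csv", package = "mmdbn")
  readr::read_csv(path, col_types = readr::cols(
    variable = readr::col_character(), code = readr::col_integer(),
    label = readr::col_character(), n_without_mmd = readr::col_double(),
    n_with_mmd = readr::col_double()
  ))
}

# pooled single-variable marginal targets implied by the baseline table,
# including the outcome prevalence from the stratum sizes
table1_marginals <- function(counts = table1_counts()) {
  tot <- dplyr::summarise(
    dplyr::group_by(counts, .data$variable),
    n_without = sum(.data$n_without_mmd), n_with = sum(.data$n_with_mmd)
  )
  stopifnot(length(unique(tot$n_without)) == 1, length(unique(tot$n_with)) == 1)
  n0 <- tot$n_without[1]; n1 <- tot$n_with[1]
  pooled <- lapply(split(counts, counts$variable), function(d) {
    d <- d[order(d$code), ]
    setNames((d$n_without_mmd + d$n_with_mmd) / (n0 + n1), d$code)
  })
  pooled$mmd <- setNames(c(n0, n1) / (n0 + n1), 0:1)
  pooled
}

# ground-truth edges with signed ordinal association strengths (log-linear
# tilt per unit of the centred category scores). The prose-documented edges
# are: age/sleep/physical activity into mmd; age into physical activity;
# sex and age into education and marital status; education into residence;
# residence into sleep (so education and residence reach mmd through sleep);
# residence into physical activity. The remaining edges complete the
# 18-edge graph with demographically plausible lifestyle links and are
# frozen here as the package's simulation truth.
charls_edge_effects <- function() {
  tibble::tribble(
    ~from,               ~to,                 ~beta,
    "sex",               "education",         -0.8,
    "sex",               "marital_status",     0.9,
    "sex",               "smoking",           -2.2,
    "sex",               "alcohol",           -1.2,
    "sex",               "physical_activity", -0.8,
    "age",               "education",         -0.8,
    "age",               "marital_status",     1.1,
    "age",               "nap",                0.6,
    "age",               "physical_activity", -1.0,
    "age",               "sleep_duration",    -0.8,
    "age",               "smoking",           -1.4,
    "age",               "mmd",                0.9,
    "education",         "residence",         -1.0,
    "residence",         "sleep_duration",    -0.45,
    "residence",         "physical_activity",  0.5,
    "smoking",           "alcohol",            1.2,
    "physical_activity", "mmd",               -0.5,
    "sleep_duration",    "mmd",               -0.45
  )
}

# centred category scores in [-1, 1] used for the ordinal tilts
centred_scores <- function(k) {
  if (k == 1) return(0)
  s <- seq_len(k) - (k + 1) / 2
  s / max(abs(s))
}

.mmdbn_cache <- new.env(parent = emptyenv())

#' Ground-truth survey-like Bayesian network
#'
#' The 11-node, 18-edge network the synthetic cohorts are sampled from. Its
#' structure hard-codes the dependence pattern reported for the study
#' cohort — age, sleep duration and physical activity are the parents of
#' multimorbidity; sex and age feed education and marital status; education
#' feeds residence, which reaches multimorbidity through sleep duration —
#' completed with plausible lifestyle edges to 18 (see the package source
#' for the frozen list). Conditional probability tables start from ordinal
#' log-linear tilts along each edge and are calibrated by iterative
#' proportional fitting so that every single-variable marginal matches the
#' pooled published baseline frequencies (multimorbidity prevalence 0.538)
#' to within 1e-8.
#'
#' @param effects Optional edge/effect tibble like the default (columns
#'   `from`, `to`, `beta`) to generate variant ground truths.
#' @return A `bn_fit` over the eleven study variables.
#' @export
#' @examples
#' gt <- charls_like_network()
#' glance(gt)
charls_like_network <- function(effects = NULL) {
  default <- is.null(effects)
  if (default && !is.null(.mmdbn_cache$charls_bn)) return(.mmdbn_cache$charls_bn)
  effects <- effects %||% charls_edge_effects()
  dag <- bn_dag(mmd_variables(), effects[, c("from", "to")])
  levels <- mmd_levels()
  card <- vapply(levels, length, integer(1))
  targets <- table1_marginals()
  joint <- f_new(character(0), integer(0), 1)  # joint over processed nodes
  cpts <- list()
  for (v in topological_order(dag)) {
    pa <- dag_parents(dag, v)
    k <- card[[v]]
    m <- unname(targets[[v]])
    if (!length(pa)) {
      tab <- matrix(m, ncol = 1)
    } else {
      # parent-configuration distribution implied by the network so far
      qf <- joint
      for (drop in setdiff(qf$vars, pa)) qf <- f_sum_out(qf, drop)
      perm <- f_new(pa, card[pa], numeric(prod(card[pa])))
      q <- qf$val[f_map_index(qf, perm$vars, perm$card)]
      # ordinal tilt: row j gets child log-odds shifted by sum of parent scores
      tilt <- rep(0, length(q))
      for (i in seq_along(pa)) {
        b <- effects$beta[effects$from == pa[i] & effects$to == v]
        tilt <- tilt + b * centred_scores(card[[pa[i]]])[grid_coord(perm$card, i) + 1]
      }
      tab <- exp(outer(centred_scores(k), tilt)) * m
      tab <- sweep(tab, 2, colSums(tab), "/")
      # IPF: rescale child categories toward the target marginal, renormalize
      for (iter in 1:500) {
        cur <- as.numeric(tab %*% q)
        if (max(abs(cur - m)) < 1e-12) break
        tab <- tab * (m / cur)
        tab <- sweep(tab, 2, colSums(tab), "/")
      }
    }
    cpts[[v]] <- matrix(as.numeric(tab), nrow = k)
    joint <- f_product(joint, f_new(c(v, pa), c(k, unname(card[pa])),
                                    as.numeric(tab)))
  }
  bn <- bn_custom(dag, levels, cpts)
  if (default) .mmdbn_cache$charls_bn <- bn
  bn
}

#' Forward (ancestral) sampling from a fitted network
#'
#' Draws complete records node by node in topological order, each node from
#' its CPT row selected by the already-sampled parent values. Fully
#' deterministic given `seed`.
#'
#' @param bn A `bn_fit`.
#' @param n Number of rows (0 gives an empty, correctly-typed tibble).
#' @param seed Integer seed.
#' @return A tibble of integer codes with one column per node, in the
#'   network's node order.
#' @export
ancestral_sample <- function(bn, n, seed = 1) {
  stopifnot(inherits(bn, "bn_fit"), n >= 0)
  nodes <- bn$dag$nodes
  card <- vapply(bn$levels, length, integer(1))
  if (n == 0) {
    return(tibble::as_tibble(setNames(
      lapply(nodes, function(v) integer(0)), nodes)))
  }
  idx <- matrix(0L, n, length(nodes), dimnames = list(NULL, nodes))
  withr::with_seed(seed, {
    for (v in topological_order(bn$dag)) {
      f <- bn$cpts[[v]]
      pa <- f$vars[-1]
      cfg <- rep(1L, n)
      mult <- 1L
      for (i in seq_along(pa)) {
        cfg <- cfg + (idx[, pa[i]] - 1L) * mult
        mult <- mult * f$card[i + 1]
      }
      cum <- apply(matrix(f$val, nrow = f$card[1]), 2, cumsum)
      u <- runif(n)
      idx[, v] <- 1L + rowSums(u > t(cum)[cfg, , drop = FALSE])
    }
  })
  cols <- lapply(nodes, function(v) bn$levels[[v]][idx[, v]])
  tibble::as_tibble(setNames(cols, nodes))
}

#' Mask cells to emulate survey missingness
#'
#' Produces a partially observed copy of a complete dataset. Under MCAR
#' every maskable cell is hidden independently with probability `rate`.
#' Under MAR the per-row masking probability follows a logistic link on the
#' (standardized) value of an always-observed `driver` column,
#' `plogis(a + slope * score)`, with the intercept `a` solved so the overall
#' expected rate equals `rate`.
#'
#' @param data Complete data frame.
#' @param rate Target missingness fraction in `[0, 0.5]`.
#' @param mechanism `"MCAR"` (default) or `"MAR"`.
#' @param driver Column driving MAR missingness; required for MAR and never
#'   masked itself.
#' @param slope MAR log-odds slope per unit of the driver's centred score
#'   (default 1.5).
#' @param seed Integer seed.
#' @return A list with `data` (masked tibble, hidden cells `NA`) and `mask`
#'   (logical tibble, `TRUE` where hidden).
#' @export
inject_missingness <- function(data, rate, mechanism = c("MCAR", "MAR"),
                               driver = NULL, slope = 1.5, seed = 1) {
  mechanism <- match.arg(mechanism)
  data <- tibble::as_tibble(data)
  if (anyNA(data)) stop_contract("`data` must be complete before masking")
  if (!(rate >= 0 && rate <= 0.5)) stop_contract("`rate` must lie in [0, 0.5]")
  maskable <- names(data)
  if (mechanism == "MAR") {
    if (is.null(driver) || !driver %in% names(data)) {
      stop_contract("MAR requires a `driver` column present in `data`")
    }
    maskable <- setdiff(maskable, driver)
  }
  n <- nrow(data)
  mask <- matrix(FALSE, n, ncol(data), dimnames = list(NULL, names(data)))
  if (rate > 0 && n > 0) {
    p_row <- if (mechanism == "MCAR") {
      rep(rate, n)
    } else {
      x <- data[[driver]]
      s <- (x - mean(x)) / max(stats::sd(x), 1e-12)
      a <- uniroot(function(a) mean(plogis(a + slope * s)) - rate,
                   interval = c(-30, 30))$root
      plogis(a + slope * s)
    }
    withr::with_seed(seed, {
      for (v in maskable) mask[, v] <- runif(n) < p_row
    })
  }
  masked <- data
  for (v in maskable) masked[[v]][mask[, v]] <- NA
  list(data = masked, mask = tibble::as_tibble(mask))
}

#' Small fixed benchmark networks
#'
#' Hand-specified networks with printed CPTs used by the structure-learning
#' and inference tests: a three-node chain, fork and collider over binary
#' variables, and the five-node sprinkler network.
#'
#' @return Named list of `bn_fit` objects: `chain` (`A->B->C`), `fork`
#'   (`A<-C->B`), `collider` (`A->C<-B`), `sprinkler`.
#' @export
benchmark_networks <- function() {
  lv2 <- function(nodes) setNames(rep(list(0:1), length(nodes)), nodes)
  chain <- bn_custom(
    bn_dag(c("A", "B", "C"), c("A->B", "B->C")),
    lv2(c("A", "B", "C")),
    list(A = c(0.6, 0.4),
         B = matrix(c(0.8, 0.2, 0.2, 0.8), nrow = 2),   # columns: A=0, A=1
         C = matrix(c(0.75, 0.25, 0.3, 0.7), nrow = 2))
  )
  fork <- bn_custom(
    bn_dag(c("A", "B", "C"), c("C->A", "C->B")),
    lv2(c("A", "B", "C")),
    list(C = c(0.5, 0.5),
         A = matrix(c(0.85, 0.15, 0.25, 0.75), nrow = 2),
         B = matrix(c(0.2, 0.8, 0.7, 0.3), nrow = 2))
  )
  collider <- bn_custom(
    bn_dag(c("A", "B", "C"), c("A->C", "B->C")),
    lv2(c("A", "B", "C")),
    list(A = c(0.45, 0.55),
         B = c(0.6, 0.4),
         # columns (A,B): (0,0), (1,0), (0,1), (1,1)
         C = matrix(c(0.9, 0.1, 0.55, 0.45, 0.5, 0.5, 0.1, 0.9), nrow = 2))
  )
  sprinkler <- bn_custom(
    bn_dag(c("cloudy", "sprinkler", "rain", "wet", "slippery"),
           c("cloudy->sprinkler", "cloudy->rain", "sprinkler->wet",
             "rain->wet", "wet->slippery")),
    lv2(c("cloudy", "sprinkler", "rain", "wet", "slippery")),
    list(cloudy = c(0.5, 0.5),
         sprinkler = matrix(c(0.5, 0.5, 0.9, 0.1), nrow = 2),
         rain = matrix(c(0.8, 0.2, 0.2, 0.8), nrow = 2),
         # columns (rain, sprinkler): (0,0), (1,0), (0,1), (1,1)
         wet = matrix(c(1.0, 0.0, 0.1, 0.9, 0.1, 0.9, 0.01, 0.99), nrow = 2),
         slippery = matrix(c(1.0, 0.0, 0.3, 0.7), nrow = 2))
  )
  list(chain = chain, fork = fork, collider = collider, sprinkler = sprinkler)
}
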