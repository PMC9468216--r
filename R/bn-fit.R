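#' Build a discrete Bayesian network from explicit probability tables
#'
#' A Bayesian network couples a DAG with one conditional probability table
#' (CPT) per node and represents the joint distribution as the product of
#' `P(node | parents(node))` over all nodes. This constructor is used for
#' hand-specified networks (benchmarks, simulation ground truths); networks
#' estimated from data come from [fit_mle()].
#'
#' @param dag A [bn_dag()].
#' @param levels Named list: for each node, the vector of its category codes
#'   (in table order).
#' @param cpts Named list: for each node, a matrix with one row per child
#'   category and one column per joint parent configuration. Parents are
#'   taken in sorted name order with the first parent varying fastest
#'   across columns; a parentless node takes a single-column matrix (or a
#'   probability vector). Every column must sum to 1.
#' @return An object of class `bn_fit`.
#' @export
bn_custom <- function(dag, levels, cpts) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!setequal(names(levels), dag$nodes) || !setequal(names(cpts), dag$nodes)) {
    stop_contract("`levels` and `cpts` must name every DAG node")
  }
  card <- vapply(levels, length, integer(1))
  fitted <- list()
  for (v in dag$nodes) {
    pa <- dag_parents(dag, v)
    tab <- cpts[[v]]
    if (is.null(dim(tab))) tab <- matrix(tab, ncol = 1)
    j <- prod(card[pa])
    if (nrow(tab) != card[v] || ncol(tab) != j) {
      stop_contract(sprintf("CPT for `%s` must be %d x %d", v, card[v], j))
    }
    if (any(tab < 0) || any(abs(colSums(tab) - 1) > 1e-9)) {
      stop_contract(sprintf("CPT columns for `%s` must be probability vectors", v))
    }
    fitted[[v]] <- f_new(c(v, pa), c(card[v], unname(card[pa])), as.numeric(tab))
  }
  structure(list(dag = dag, levels = levels[dag$nodes], cpts = fitted),
            class = "bn_fit")
}

#' @export
print.bn_fit <- function(x, ...) {
  cat(sprintf("<bn_fit> %d nodes, %d edges, state space %s\n",
              length(x$dag$nodes), nrow(x$dag$edges),
              format(prod(vapply(x$levels, length, integer(1))), big.mark = ",")))
  invisible(x)
}

# integer (1-based) category index matrix for `cols`, validating codes
code_index_matrix <- function(data, cols, levels) {
  out <- matrix(0L, nrow(data), length(cols), dimnames = list(NULL, cols))
  for (v in cols) {
    idx <- match(data[[v]], levels[[v]])
    if (anyNA(idx)) {
      stop_contract(sprintf("column `%s` contains missing or out-of-domain codes", v))
    }
    out[, v] <- idx
  }
  out
}

default_levels <- function(data, levels = NULL) {
  known <- mmd_levels()
  out <- lapply(names(data), function(v) {
    if (!is.null(levels[[v]])) levels[[v]]
    else if (v %in% names(known)) known[[v]]
    else sort(unique(data[[v]]))
  })
  setNames(out, names(data))
}

#' Maximum-likelihood parameter learning for a discrete Bayesian network
#'
#' Estimates every conditional probability table from complete integer-coded
#' data: the probability of child category `k` given parent configuration
#' `j` is `(N_jk + pseudo_count) / (N_j + pseudo_count * K)`. With
#' `pseudo_count = 0` this is the pure maximum-likelihood estimate; parent
#' configurations never observed are then set to the uniform distribution
#' (and reported via a message), since the likelihood leaves them free.
#'
#' @param dag A [bn_dag()] whose nodes are columns of `data`.
#' @param data Complete data frame of integer codes (no `NA`).
#' @param levels Optional named list of code domains per column; defaults to
#'   the study codebook for study variables and the observed codes
#'   otherwise.
#' @param pseudo_count Non-negative Laplace smoothing constant; default 0.
#' @return A `bn_fit` object.
#' @export
#' @examples
#' d <- data.frame(a = c(0, 0, 1, 1), b = c(0, 1, 1, 1))
#' fit <- fit_mle(bn_dag(c("a", "b"), c("a->b")), d)
fit_mle <- function(dag, data, levels = NULL, pseudo_count = 0) {
  stopifnot(inherits(dag, "bn_dag"), pseudo_count >= 0)
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    stop_contract("cannot estimate parameters from an empty dataset",
                  "mmdbn_estimation_error")
  }
  missing_cols <- setdiff(dag$nodes, names(data))
  if (length(missing_cols)) {
    stop_contract(paste("data lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(data[dag$nodes])) {
    stop_contract("data must be complete (no missing values); impute first")
  }
  levels <- default_levels(data[dag$nodes], levels)
  card <- vapply(levels, length, integer(1))
  idx <- code_index_matrix(data, dag$nodes, levels)
  cpts <- list()
  for (v in dag$nodes) {
    pa <- dag_parents(dag, v)
    k <- card[v]
    j <- prod(card[pa])
    cfg <- rep(1L, nrow(data))
    mult <- 1L
    for (p in pa) {
      cfg <- cfg + (idx[, p] - 1L) * mult
      mult <- mult * card[p]
    }
    counts <- matrix(tabulate(idx[, v] + (cfg - 1L) * k, nbins = k * j), nrow = k)
    tab <- counts + pseudo_count
    tot <- colSums(tab)
    empty <- tot == 0
    if (any(empty)) {
      inform(sprintf("node `%s`: %d unobserved parent configuration(s) set uniform",
                     v, sum(empty)))
      tab[, empty] <- 1
      tot[empty] <- k
    }
    tab <- sweep(tab, 2, tot, "/")
    cpts[[v]] <- f_new(c(v, pa), c(k, unname(card[pa])), as.numeric(tab))
  }
  structure(list(dag = dag, levels = levels, cpts = cpts), class = "bn_fit")
}

# 1-based category indices for a full or partial assignment given as a
# named vector/list of codes
assignment_index <- function(bn, assignment) {
  vars <- names(assignment)
  unknown <- setdiff(vars, bn$dag$nodes)
  if (length(unknown)) {
    stop_contract(paste("unknown node(s):", paste(unknown, collapse = ", ")))
  }
  out <- integer(length(vars))
  for (i in seq_along(vars)) {
    out[i] <- match(assignment[[i]], bn$levels[[vars[i]]])
    if (is.na(out[i])) {
      stop_contract(sprintf("code %s is not valid for node `%s`",
                            format(assignment[[i]]), vars[i]))
    }
  }
  setNames(out, vars)
}

#' Joint probability of one full assignment
#'
#' Evaluates the factorization of the joint distribution — the product over
#' nodes of the CPT entry selected by the assignment. Computed in log space
#' for underflow safety and returned on the linear scale.
#'
#' @param bn A `bn_fit`.
#' @param assignment Named vector or list giving a code for every node.
#' @return A probability in `[0, 1]`.
#' @export
joint_probability <- function(bn, assignment) {
  if (!setequal(names(assignment), bn$dag$nodes)) {
    stop_contract("`assignment` must cover every node exactly once")
  }
  idx <- assignment_index(bn, assignment)
  lp <- 0
  for (v in bn$dag$nodes) {
    f <- bn$cpts[[v]]
    lin <- 1
    stride <- 1
    for (k in seq_along(f$vars)) {
      lin <- lin + (idx[f$vars[k]] - 1L) * stride
      stride <- stride * f$card[k]
    }
    lp <- lp + log(f$val[lin])
  }
  exp(lp)
}

#' Exhaustive joint distribution of a network
#'
#' Multiplies all CPTs into one factor over every node. Exponential in the
#' number of variables, so guarded by a state-space cap; intended as the
#' brute-force oracle against which [eliminate_query()] is checked, and
#' usable directly on the 11-variable study network (245,760 states).
#'
#' @param bn A `bn_fit`.
#' @param cap Maximum admissible number of joint states (default `1e7`).
#' @return A tibble with one row per joint configuration: one code column
#'   per node plus `probability`.
#' @export
enumerate_joint <- function(bn, cap = 1e7) {
  card <- vapply(bn$levels, length, integer(1))
  size <- prod(card)
  if (size > cap) {
    stop_contract(sprintf(
      "state space %s exceeds cap %s; refusing to enumerate",
      format(size, big.mark = ","), format(cap, big.mark = ",")),
      "mmdbn_statespace_error")
  }
  f <- f_new(character(0), integer(0), 1)
  for (v in bn$dag$nodes) f <- f_product(f, bn$cpts[[v]])
  cols <- lapply(seq_along(f$vars), function(p) {
    bn$levels[[f$vars[p]]][grid_coord(f$card, p) + 1L]
  })
  out <- tibble::as_tibble(setNames(cols, f$vars))
  out$probability <- f$val
  out
}

#' Prior marginal distribution of every node
#'
#' @param bn A `bn_fit`.
#' @return A tibble `(variable, code, probability)`; within each variable
#'   the probabilities sum to 1.
#' @export
prior_marginals <- function(bn) {
  purrr::map_dfr(bn$dag$nodes, function(v) {
    post <- eliminate_query(bn, v)
    tibble::tibble(variable = v, code = post$code, probability = post$probability)
  })
}

#' Tidy a fitted Bayesian network into one row per CPT entry
#'
#' @param x A `bn_fit`.
#' @param ... Unused.
#' @return A tibble with columns `child`, `parent_config` (a
#'   `"name=code"` comma-joined string, empty for parentless nodes),
#'   `category` (child code) and `probability`.
#' @method tidy bn_fit
#' @export
tidy.bn_fit <- function(x, ...) {
  purrr::map_dfr(x$dag$nodes, function(v) {
    f <- x$cpts[[v]]
    pa <- f$vars[-1]
    n <- prod(f$card)
    cfg <- if (length(pa)) {
      parts <- lapply(seq_along(pa), function(k) {
        codes <- x$levels[[pa[k]]][grid_coord(f$card, k + 1) + 1L]
        paste0(pa[k], "=", codes)
      })
      do.call(paste, c(parts, sep = ","))
    } else rep("", n)
    tibble::tibble(
      child = v,
      parent_config = cfg,
      category = x$levels[[v]][grid_coord(f$card, 1) + 1L],
      probability = f$val
    )
  })
}

#' One-row summary of a fitted Bayesian network
#'
#' @param x A `bn_fit`.
#' @param ... Unused.
#' @return A tibble with node, edge, free-parameter and state-space counts.
#' @method glance bn_fit
#' @export
glance.bn_fit <- function(x, ...) {
  card <- vapply(x$levels, length, integer(1))
  n_par <- sum(vapply(x$dag$nodes, function(v) {
    pa <- dag_parents(x$dag, v)
    (card[v] - 1) * prod(card[pa])
  }, numeric(1)))
  tibble::tibble(
    n_nodes = length(x$dag$nodes),
    n_edges = nrow(x$dag$edges),
    n_parameters = n_par,
    state_space = prod(card)
  )
}
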