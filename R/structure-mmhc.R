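#' Max-min association heuristic for one candidate selection
#'
#' The forward step of Max-Min Parents-and-Children: the association of a
#' candidate `X` with the target is its weakest showing — the largest
#' G-squared p-value of `X` vs. the target over all conditioning subsets of
#' the current candidate parent-children set. The heuristic returns the
#' candidate whose weakest association is strongest (smallest max-p).
#'
#' @param data Complete data frame.
#' @param target Target node.
#' @param cpc Current candidate parent-children set of `target`.
#' @param candidates Nodes still in play (disjoint from `cpc` and `target`).
#' @param levels Optional named list of code domains.
#' @param max_condition_size,adequacy_k Test guards, see [g2_test()].
#' @return A list with `candidate` (name or `NA` when `candidates` is
#'   empty) and `p_value` (its max-association p).
#' @export
max_min_heuristic <- function(data, target, cpc, candidates, levels = NULL,
                              max_condition_size = 3, adequacy_k = 5) {
  if (any(candidates %in% c(cpc, target))) {
    stop_contract("`candidates` must be disjoint from `cpc` and `target`")
  }
  if (!length(candidates)) return(list(candidate = NA_character_, p_value = NA_real_))
  levels <- default_levels(data[c(target, cpc, candidates)], levels)
  maxp <- vapply(sort(candidates), function(x) {
    max(vapply(cond_subsets(cpc, max_condition_size), function(s) {
      assoc_pvalue(data, x, target, s, levels, max_condition_size, adequacy_k)
    }, numeric(1)))
  }, numeric(1))
  best <- names(maxp)[which.min(maxp)]
  list(candidate = best, p_value = unname(maxp[best]))
}

# all subsets of `set` up to size `max_size`, empty set first, in a
# deterministic order
cond_subsets <- function(set, max_size = Inf) {
  set <- sort(set)
  out <- list(character(0))
  for (k in seq_len(min(length(set), max_size))) {
    out <- c(out, utils::combn(set, k, simplify = FALSE))
  }
  out
}

#' Max-Min Parents-and-Children skeleton discovery
#'
#' Constraint phase of the hybrid structure learner. For each target node, a
#' forward phase grows the candidate parent-children (CPC) set by repeatedly
#' adding the max-min-association candidate while it is dependent at level
#' `alpha`; candidates whose max-association p-value exceeds `alpha` are
#' discarded permanently. A backward phase then removes any member that some
#' subset of the remaining CPC renders independent of the target. Finally a
#' symmetry (AND) correction keeps the undirected pair only when each node
#' is in the other's CPC.
#'
#' @param data Complete data frame of categorical codes.
#' @param alpha Significance level of the G-squared tests (default 0.05).
#' @param levels Optional named list of code domains.
#' @param max_condition_size Largest conditioning-set size attempted
#'   (default 3); larger tests are treated as uninformative.
#' @param adequacy_k Sample-adequacy multiplier: a test needs at least
#'   `adequacy_k * df` rows, else it is skipped (default 5).
#' @return A `bn_skeleton`: list with `nodes`, `edges` (tibble of unordered
#'   pairs, `from < to`) and `cpc` (named list of per-node neighbour sets
#'   after correction).
#' @export
mmpc <- function(data, alpha = 0.05, levels = NULL,
                 max_condition_size = 3, adequacy_k = 5) {
  data <- tibble::as_tibble(data)
  if (anyNA(data)) stop_contract("data must be complete; impute first")
  if (!(alpha > 0 && alpha < 1)) stop_contract("`alpha` must lie in (0, 1)")
  non_cat <- names(data)[!vapply(data, function(col) {
    is.numeric(col) && all(is_whole(col))
  }, logical(1))]
  if (length(non_cat)) {
    stop_contract(paste("non-categorical column(s):", paste(non_cat, collapse = ", ")))
  }
  nodes <- names(data)
  levels <- default_levels(data, levels)
  cpc_raw <- lapply(setNames(nodes, nodes), function(target) {
    mmpc_one(data, target, setdiff(nodes, target), alpha, levels,
             max_condition_size, adequacy_k)
  })
  # symmetry correction: keep {x, t} only if each is in the other's CPC
  cpc <- lapply(setNames(nodes, nodes), function(target) {
    sort(Filter(function(x) target %in% cpc_raw[[x]], cpc_raw[[target]]))
  })
  pairs <- unique(do.call(rbind, lapply(nodes, function(t) {
    if (!length(cpc[[t]])) return(NULL)
    cbind(pmin(t, cpc[[t]]), pmax(t, cpc[[t]]))
  })))
  edges <- if (is.null(pairs)) {
    tibble::tibble(from = character(0), to = character(0))
  } else {
    tibble::tibble(from = pairs[, 1], to = pairs[, 2])[order(pairs[, 1], pairs[, 2]), ]
  }
  structure(list(nodes = nodes, edges = edges, cpc = cpc), class = "bn_skeleton")
}

mmpc_one <- function(data, target, candidates, alpha, levels,
                     max_condition_size, adequacy_k) {
  cpc <- character(0)
  # incremental max-p bookkeeping: only subsets containing the newest CPC
  # member need testing after an addition
  maxp <- setNames(rep(-Inf, length(candidates)), sort(candidates))
  new_subsets <- list(character(0))
  repeat {
    for (x in names(maxp)) {
      for (s in new_subsets) {
        p <- assoc_pvalue(data, x, target, s, levels, max_condition_size, adequacy_k)
        if (p > maxp[x]) maxp[x] <- p
      }
    }
    maxp <- maxp[maxp <= alpha]
    if (!length(maxp)) break
    best <- names(maxp)[which.min(maxp)]
    cpc <- c(cpc, best)
    maxp <- maxp[names(maxp) != best]
    if (!length(maxp)) break
    others <- setdiff(cpc, best)
    new_subsets <- lapply(cond_subsets(others, max_condition_size - 1),
                          function(s) sort(c(s, best)))
    new_subsets <- Filter(function(s) length(s) <= max_condition_size, new_subsets)
  }
  # backward phase: drop members made independent by some subset of the rest
  repeat {
    dropped <- FALSE
    for (x in sort(cpc)) {
      rest <- setdiff(cpc, x)
      for (s in cond_subsets(rest, max_condition_size)) {
        if (assoc_pvalue(data, x, target, s, levels,
                         max_condition_size, adequacy_k) > alpha) {
          cpc <- rest
          dropped <- TRUE
          break
        }
      }
      if (dropped) break
    }
    if (!dropped) break
  }
  sort(cpc)
}

#' @export
print.bn_skeleton <- function(x, ...) {
  cat(sprintf("<bn_skeleton> %d nodes, %d undirected edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges$from, " - ", x$edges$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' BIC score of a DAG on complete categorical data
#'
#' Decomposable Bayesian information criterion: the maximized multinomial
#' log-likelihood of each node given its parents minus `(ln n)/2` per free
#' parameter, summed over node families. Larger is better.
#'
#' @param dag A [bn_dag()] over the columns of `data`.
#' @param data Complete data frame.
#' @param levels Optional named list of code domains.
#' @param by_node Return the per-family scores instead of their sum.
#' @return A single number, or a named numeric vector when `by_node = TRUE`.
#' @export
bic_score <- function(dag, data, levels = NULL, by_node = FALSE) {
  data <- tibble::as_tibble(data)
  levels <- default_levels(data[dag$nodes], levels)
  card <- vapply(levels, length, integer(1))
  idx <- code_index_matrix(data, dag$nodes, levels)
  fam <- vapply(dag$nodes, function(v) {
    family_bic(v, dag_parents(dag, v), idx, card, nrow(data))
  }, numeric(1))
  if (by_node) fam else sum(fam)
}

family_bic <- function(node, parents, idx, card, n) {
  k <- card[[node]]
  j <- prod(card[parents])
  cfg <- rep(1L, n)
  mult <- 1L
  for (p in parents) {
    cfg <- cfg + (idx[, p] - 1L) * mult
    mult <- mult * card[[p]]
  }
  counts <- matrix(tabulate(idx[, node] + (cfg - 1L) * k, nbins = k * j), nrow = k)
  tot <- colSums(counts)
  pos <- counts > 0
  ll <- sum(counts[pos] * log(counts[pos] / rep(tot, each = k)[pos]))
  ll - log(n) / 2 * (k - 1) * j
}

#' BIC hill climbing with deterministic tabu escape, restricted to a skeleton
#'
#' Score-and-search phase of the hybrid learner. Starting from the empty
#' graph, the single best score-improving move is applied per iteration,
#' where the legal moves are: add a directed edge between a skeleton-adjacent
#' pair, delete an existing edge, or reverse an existing edge — always
#' keeping the graph acyclic. When no move improves the (decomposable,
#' cached) BIC score, the search may take up to `tabu` consecutive
#' non-improving best moves — never revisiting a recently seen structure —
#' to escape orientation local optima, and finally returns the best-scoring
#' structure encountered. The escape is entirely deterministic (no
#' randomness); tie-breaks are lexicographic on the move's `(from, to)`
#' pair, so runs are bit-reproducible. Set `tabu = 0` for plain greedy
#' ascent.
#'
#' @param data Complete data frame.
#' @param skeleton A `bn_skeleton` from [mmpc()], or a tibble of undirected
#'   pairs (`from`/`to`).
#' @param levels Optional named list of code domains.
#' @param max_iter Iteration cap (default 500).
#' @param tabu Number of consecutive non-improving moves allowed before
#'   stopping (default 10); the visited-structure memory holds
#'   `tabu_memory` structures.
#' @param tabu_memory Size of the visited-structure list (default 100).
#' @return A list with `dag` (the best [bn_dag()] found), `score` (its BIC)
#'   and `trace`, a tibble of applied moves
#'   `(iteration, operator, from, to, delta, improving)`; moves with
#'   `improving = TRUE` (those advancing the best score) have strictly
#'   positive deltas.
#' @export
hill_climb <- function(data, skeleton, levels = NULL, max_iter = 500,
                       tabu = 10, tabu_memory = 100) {
  data <- tibble::as_tibble(data)
  nodes <- if (inherits(skeleton, "bn_skeleton")) skeleton$nodes else names(data)
  skel_edges <- if (inherits(skeleton, "bn_skeleton")) skeleton$edges else
    tibble::as_tibble(skeleton)
  levels <- default_levels(data[nodes], levels)
  card <- vapply(levels, length, integer(1))
  idx <- code_index_matrix(data, nodes, levels)
  n <- nrow(data)

  cache <- new.env(parent = emptyenv())
  fam <- function(v, parents) {
    key <- paste(v, paste(sort(parents), collapse = ","), sep = "|")
    if (is.null(cache[[key]])) cache[[key]] <- family_bic(v, sort(parents), idx, card, n)
    cache[[key]]
  }

  parents <- lapply(setNames(nodes, nodes), function(v) character(0))
  adj_ok <- function(a, b) {
    any((skel_edges$from == a & skel_edges$to == b) |
        (skel_edges$from == b & skel_edges$to == a))
  }
  has_path <- function(from, to) {  # directed path in the current graph
    frontier <- from
    seen <- character(0)
    while (length(frontier)) {
      if (to %in% frontier) return(TRUE)
      seen <- c(seen, frontier)
      frontier <- setdiff(
        unique(unlist(lapply(names(parents), function(v) {
          if (any(parents[[v]] %in% frontier)) v else NULL
        }))), seen)
    }
    FALSE
  }

  signature <- function(p) {
    paste(unlist(lapply(sort(names(p)), function(v) {
      if (length(p[[v]])) paste0(p[[v]], ">", v) else NULL
    })), collapse = ";")
  }
  score_of <- function(p) sum(vapply(nodes, function(v) fam(v, p[[v]]), numeric(1)))
  visited <- signature(parents)
  best_parents <- parents
  best_score <- score_of(parents)
  current_score <- best_score
  escapes_left <- tabu

  trace <- list()
  for (iter in seq_len(max_iter)) {
    moves <- list()
    for (i in seq_len(nrow(skel_edges))) {
      a <- skel_edges$from[i]; b <- skel_edges$to[i]
      linked <- a %in% parents[[b]] || b %in% parents[[a]]
      if (!linked) {
        for (pair in list(c(a, b), c(b, a))) {
          u <- pair[1]; v <- pair[2]
          if (!has_path(v, u)) {
            delta <- fam(v, c(parents[[v]], u)) - fam(v, parents[[v]])
            moves[[length(moves) + 1]] <- list(op = "add", from = u, to = v, delta = delta)
          }
        }
      }
    }
    for (v in nodes) {
      for (u in parents[[v]]) {
        delta <- fam(v, setdiff(parents[[v]], u)) - fam(v, parents[[v]])
        moves[[length(moves) + 1]] <- list(op = "delete", from = u, to = v, delta = delta)
        # reverse u->v: legal if removing it leaves no other u..v path
        parents_v_wo <- setdiff(parents[[v]], u)
        saved <- parents[[v]]; parents[[v]] <- parents_v_wo
        legal <- !has_path(u, v)
        parents[[v]] <- saved
        if (legal) {
          delta_rev <- (fam(v, parents_v_wo) - fam(v, parents[[v]])) +
            (fam(u, c(parents[[u]], v)) - fam(u, parents[[u]]))
          moves[[length(moves) + 1]] <- list(op = "reverse", from = u, to = v,
                                             delta = delta_rev)
        }
      }
    }
    if (!length(moves)) break
    apply_move <- function(p, m) {
      if (m$op == "add") {
        p[[m$to]] <- sort(c(p[[m$to]], m$from))
      } else if (m$op == "delete") {
        p[[m$to]] <- setdiff(p[[m$to]], m$from)
      } else {
        p[[m$to]] <- setdiff(p[[m$to]], m$from)
        p[[m$from]] <- sort(c(p[[m$from]], m$to))
      }
      p
    }
    candidates_p <- lapply(moves, function(m) apply_move(parents, m))
    fresh <- !vapply(candidates_p, function(p) signature(p) %in% visited, logical(1))
    if (!any(fresh)) break
    moves <- moves[fresh]
    candidates_p <- candidates_p[fresh]
    deltas <- vapply(moves, `[[`, numeric(1), "delta")
    best_delta <- max(deltas)
    if (best_delta <= 1e-9 && escapes_left <= 0) break
    tied <- which(deltas >= best_delta - 1e-12)
    keys <- vapply(moves[tied], function(m) paste(m$from, m$to, m$op), character(1))
    pick <- tied[order(keys)[1]]
    mv <- moves[[pick]]
    parents <- candidates_p[[pick]]
    current_score <- current_score + mv$delta
    visited <- utils::tail(c(visited, signature(parents)), tabu_memory)
    if (current_score > best_score + 1e-9) {
      best_score <- current_score
      best_parents <- parents
      escapes_left <- tabu
    } else {
      escapes_left <- escapes_left - 1
    }
    trace[[length(trace) + 1]] <- tibble::tibble(
      iteration = iter, operator = mv$op, from = mv$from, to = mv$to,
      delta = mv$delta, improving = mv$delta > 1e-9
    )
  }
  parents <- best_parents
  edges <- dplyr::bind_rows(lapply(nodes, function(v) {
    if (!length(parents[[v]])) return(NULL)
    tibble::tibble(from = parents[[v]], to = v)
  }))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(0), to = character(0))
  }
  dag <- bn_dag(nodes, edges[order(edges$from, edges$to), ])
  list(
    dag = dag,
    score = sum(vapply(nodes, function(v) fam(v, parents[[v]]), numeric(1))),
    trace = if (length(trace)) dplyr::bind_rows(trace) else
      tibble::tibble(iteration = integer(0), operator = character(0),
                     from = character(0), to = character(0), delta = numeric(0),
                     improving = logical(0))
  )
}

#' Max-Min Hill-Climbing hybrid structure learning
#'
#' Learns a Bayesian-network structure in two stages: [mmpc()] restricts the
#' search space to a conditional-independence-backed skeleton, then
#' [hill_climb()] orients and prunes edges by greedy BIC search inside that
#' skeleton. Deterministic for a fixed dataset and row order.
#'
#' @inheritParams mmpc
#' @inheritParams hill_climb
#' @return An object of class `mmhc_result`: list with `dag`, `skeleton`,
#'   `trace` and `score`.
#' @export
#' @examples
#' truth <- benchmark_networks()$chain
#' d <- ancestral_sample(truth, n = 2000, seed = 7)
#' mmhc(d)$dag
mmhc <- function(data, alpha = 0.05, levels = NULL,
                 max_condition_size = 3, adequacy_k = 5, max_iter = 500) {
  skeleton <- mmpc(data, alpha = alpha, levels = levels,
                   max_condition_size = max_condition_size, adequacy_k = adequacy_k)
  hc <- hill_climb(data, skeleton, levels = levels, max_iter = max_iter)
  structure(list(dag = hc$dag, skeleton = skeleton, trace = hc$trace,
                 score = hc$score),
            class = "mmhc_result")
}

#' @export
print.mmhc_result <- function(x, ...) {
  cat(sprintf("<mmhc_result> %d nodes, %d skeleton edges, %d directed edges, BIC %.2f\n",
              length(x$dag$nodes), nrow(x$skeleton$edges), nrow(x$dag$edges), x$score))
  print(x$dag)
  invisible(x)
}
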