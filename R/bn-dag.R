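#' Directed acyclic graph over named variables
#'
#' Constructs the graph object used throughout the package: nodes are study
#' variables, a directed edge `parent -> child` states a direct
#' probabilistic dependence. Acyclicity is checked at construction.
#'
#' @param nodes Character vector of node names. May be omitted when every
#'   node appears in `edges`.
#' @param edges Either a data frame with columns `from` and `to`, or a
#'   character vector of `"A->B"` strings. Duplicate edges and self-loops
#'   are rejected.
#' @return An object of class `bn_dag` with fields `nodes` and `edges` (a
#'   tibble of `from`/`to` pairs).
#' @export
#' @examples
#' bn_dag(edges = c("age->mmd", "sleep->mmd"))
bn_dag <- function(nodes = NULL, edges = NULL) {
  if (is.character(edges)) {
    parts <- strsplit(gsub("\\s", "", edges), "->", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop_contract("edge strings must look like \"A->B\"")
    edges <- tibble::tibble(from = purrr::map_chr(parts, 1),
                            to = purrr::map_chr(parts, 2))
  }
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(0), to = character(0))
  }
  edges <- tibble::as_tibble(edges)[, c("from", "to")]
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_contract("duplicate node names")
  unknown <- setdiff(c(edges$from, edges$to), nodes)
  if (length(unknown)) {
    stop_contract(paste("edge endpoints not in `nodes`:", paste(unknown, collapse = ", ")))
  }
  if (any(edges$from == edges$to)) stop_contract("self-loops are not allowed")
  if (anyDuplicated(paste(edges$from, edges$to))) stop_contract("duplicate edges")
  dag <- structure(list(nodes = nodes, edges = edges), class = "bn_dag")
  topological_order(dag)  # raises on cycles
  dag
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("<bn_dag> %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Parents of a node
#' @param dag A [bn_dag()].
#' @param node Node name.
#' @return Character vector of parent names (sorted).
#' @export
dag_parents <- function(dag, node) {
  sort(dag$edges$from[dag$edges$to == node])
}

dag_children <- function(dag, node) {
  sort(dag$edges$to[dag$edges$from == node])
}

#' Deterministic topological order of a DAG
#'
#' Kahn's algorithm with lexicographic tie-breaks, so the order is unique
#' and reproducible. A cycle aborts with one offending cycle named.
#'
#' @param dag A [bn_dag()], or a bare list with `nodes`/`edges` fields (used
#'   internally during construction).
#' @return Character vector of node names, every parent before its children.
#' @export
topological_order <- function(dag) {
  nodes <- dag$nodes
  edges <- dag$edges
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(factor(edges$to, levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  remaining <- nodes
  active <- edges
  while (length(remaining)) {
    free <- sort(remaining[indeg[remaining] == 0L])
    if (!length(free)) {
      cyc <- find_cycle(remaining, active)
      abort(paste0("graph contains a directed cycle: ", paste(cyc, collapse = " -> ")),
            class = c("mmdbn_cycle_error", "mmdbn_error"))
    }
    nxt <- free[1]
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    hit <- active$from == nxt
    indeg[active$to[hit]] <- indeg[active$to[hit]] - 1L
    active <- active[!hit, ]
  }
  out
}

# walk successors until a node repeats; only called when a cycle exists
find_cycle <- function(nodes, edges) {
  cur <- nodes[1]
  path <- cur
  repeat {
    nxt <- edges$to[edges$from == cur][1]
    if (is.na(nxt)) {  # dead end: restart from an unvisited node
      cur <- setdiff(nodes, path)[1]
      path <- cur
      next
    }
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(c(path[i:length(path)], nxt))
    }
    path <- c(path, nxt)
    cur <- nxt
  }
}

# adjacency helper: symmetric logical matrix of the skeleton
skeleton_amat <- function(dag) {
  n <- length(dag$nodes)
  m <- matrix(FALSE, n, n, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$edges)) {
    idx <- cbind(match(dag$edges$from, dag$nodes), match(dag$edges$to, dag$nodes))
    m[idx] <- TRUE
    m[idx[, 2:1, drop = FALSE]] <- TRUE
  }
  m
}

#' Completed partially directed graph (Markov-equivalence class) of a DAG
#'
#' Labels every edge of the DAG as compelled (directed in every member of
#' the equivalence class) or reversible, using Chickering's edge-ordering
#' algorithm. Two DAGs are Markov equivalent iff their CPDAGs are equal:
#' same skeleton and same compelled orientations (equivalently, same
#' v-structures).
#'
#' @param dag A [bn_dag()].
#' @return An object of class `bn_cpdag`: `nodes` plus an edge tibble with
#'   columns `from`, `to`, `directed`. Undirected edges are stored once with
#'   `from < to`.
#' @export
cpdag <- function(dag) {
  stopifnot(inherits(dag, "bn_dag"))
  topo <- topological_order(dag)
  ord <- setNames(seq_along(topo), topo)
  ed <- dag$edges
  if (nrow(ed) == 0) {
    return(structure(list(nodes = dag$nodes,
                          edges = tibble::tibble(from = character(0), to = character(0),
                                                 directed = logical(0))),
                     class = "bn_cpdag"))
  }
  # Chickering's ordering: ascending head order, then descending tail order
  ed <- ed[order(ord[ed$to], -ord[ed$from]), ]
  lab <- rep(NA_character_, nrow(ed))  # "compelled" / "reversible"
  parent_idx <- function(y) which(ed$to == y)
  is_parent <- function(w, y) any(ed$from == w & ed$to == y)
  for (k in seq_len(nrow(ed))) {
    if (!is.na(lab[k])) next
    x <- ed$from[k]; y <- ed$to[k]
    done <- FALSE
    comp_into_x <- which(ed$to == x & lab == "compelled")
    for (j in comp_into_x) {
      w <- ed$from[j]
      if (!is_parent(w, y)) {
        lab[parent_idx(y)] <- "compelled"
        done <- TRUE
        break
      } else {
        lab[which(ed$from == w & ed$to == y)] <- "compelled"
      }
    }
    if (!done) {
      zs <- ed$from[ed$to == y & ed$from != x]
      if (any(vapply(zs, function(z) !is_parent(z, x), logical(1)))) {
        idx <- parent_idx(y)
        lab[idx][is.na(lab[idx])] <- "compelled"
      } else {
        idx <- parent_idx(y)
        lab[idx][is.na(lab[idx])] <- "reversible"
      }
    }
  }
  out <- tibble::tibble(from = ed$from, to = ed$to, directed = lab == "compelled")
  und <- !out$directed
  swap <- und & out$from > out$to
  tmp <- out$from[swap]; out$from[swap] <- out$to[swap]; out$to[swap] <- tmp
  out <- out[order(out$from, out$to), ]
  structure(list(nodes = dag$nodes, edges = out), class = "bn_cpdag")
}

#' @export
print.bn_cpdag <- function(x, ...) {
  cat(sprintf("<bn_cpdag> %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    arrow <- ifelse(x$edges$directed, " -> ", " - ")
    cat(paste0("  ", x$edges$from, arrow, x$edges$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

# pairwise state code per unordered node pair: "none", "i->j", "j->i", "undir"
pair_states <- function(g) {
  nodes <- g$nodes
  ed <- g$edges
  directed <- if (inherits(g, "bn_dag")) rep(TRUE, nrow(ed)) else ed$directed
  states <- new.env(parent = emptyenv())
  key <- function(a, b) paste(min(a, b), max(a, b), sep = "|")
  for (i in seq_len(nrow(ed))) {
    a <- ed$from[i]; b <- ed$to[i]
    assign(key(a, b),
           if (!directed[i]) "undir" else paste0(a, ">", b),
           envir = states)
  }
  states
}

#' Structural Hamming distance between two graphs
#'
#' Counts the unordered node pairs whose edge state differs: an edge present
#' in one graph and absent in the other, or present in both with a
#' different orientation (including directed vs. undirected), each costs 1.
#' Both arguments may be DAGs or CPDAGs; comparing the CPDAGs of two learned
#' structures gives an equivalence-aware recovery metric.
#'
#' @param a,b Two [bn_dag()] or [cpdag()] objects over the same node set.
#' @return A non-negative integer.
#' @export
shd <- function(a, b) {
  if (!setequal(a$nodes, b$nodes)) stop_contract("graphs must share one node set")
  sa <- pair_states(a); sb <- pair_states(b)
  keys <- union(ls(sa), ls(sb))
  sum(vapply(keys, function(k) {
    va <- if (exists(k, envir = sa)) get(k, envir = sa) else "none"
    vb <- if (exists(k, envir = sb)) get(k, envir = sb) else "none"
    va != vb
  }, logical(1)))
}
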