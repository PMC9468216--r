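# shared fixtures: all built in code at test time

# brute-force conditional P(target | evidence) from the enumerated joint;
# independent of the variable-elimination path
enum_conditional <- function(bn, target, evidence = NULL) {
  ej <- enumerate_joint(bn)
  keep <- rep(TRUE, nrow(ej))
  for (v in names(evidence)) keep <- keep & ej[[v]] == evidence[[v]]
  sub <- ej[keep, ]
  agg <- tapply(sub$probability, sub[[target]], sum)
  out <- rep(0, length(bn$levels[[target]]))
  names(out) <- bn$levels[[target]]
  out[names(agg)] <- agg
  unname(out / sum(out))
}

# random small binary-node network for property-style inference checks
random_binary_network <- function(n_nodes, seed) {
  withr::with_seed(seed, {
    nodes <- LETTERS[seq_len(n_nodes)]
    edges <- NULL
    for (j in 2:n_nodes) {
      pa <- nodes[seq_len(j - 1)][runif(j - 1) < 0.5]
      if (length(pa) > 3) pa <- pa[1:3]
      if (length(pa)) edges <- rbind(edges, cbind(from = pa, to = nodes[j]))
    }
    dag <- bn_dag(nodes, tibble::as_tibble(edges %||%
      matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))))
    cpts <- lapply(stats::setNames(nodes, nodes), function(v) {
      k <- 2L
      j <- 2L^length(dag_parents(dag, v))
      p1 <- runif(j, 0.05, 0.95)
      matrix(rbind(1 - p1, p1), nrow = 2)
    })
    bn_custom(dag, stats::setNames(rep(list(0:1), n_nodes), nodes), cpts)
  })
}

# expand one variable's published stratified counts into per-subject rows
expand_table1_variable <- function(variable) {
  counts <- table1_counts()
  d <- counts[counts$variable == variable, ]
  tibble::tibble(
    !!variable := rep(rep(d$code, 2), c(d$n_without_mmd, d$n_with_mmd)),
    mmd = rep(rep(0:1, each = nrow(d)), c(d$n_without_mmd, d$n_with_mmd))
  )
}
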