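test_that("topological order is deterministic and rejects cycles", {
  expect_equal(topological_order(bn_dag(c("A", "B", "C"), c("A->B", "B->C"))),
               c("A", "B", "C"))
  expect_equal(topological_order(bn_dag(c("B", "A"))), c("A", "B"))
  expect_error(bn_dag(c("A", "B"), c("A->B", "B->A")),
               class = "mmdbn_cycle_error")
})

test_that("bn_dag rejects malformed graphs", {
  expect_error(bn_dag(c("A", "A")), "duplicate node")
  expect_error(bn_dag(c("A", "B"), c("A->A")), "self-loops")
  expect_error(bn_dag(c("A", "B"), c("A->B", "A->B")), "duplicate edges")
  expect_error(bn_dag(c("A"), c("A->B")), "not in")
})

test_that("maximum-likelihood CPTs are the conditional count ratios", {
  dag <- bn_dag(c("a", "b"), c("a->b"))
  d <- tibble::tibble(a = c(1, 1, 1, 1, 0, 0), b = c(0, 1, 1, 1, 0, 0))
  fit <- fit_mle(dag, d)
  tab <- matrix(fit$cpts$b$val, nrow = 2)  # columns a=0, a=1
  expect_equal(tab[, 2], c(0.25, 0.75))
  expect_equal(tab[, 1], c(1, 0))
  # Laplace smoothing turns an unobserved row uniform
  d2 <- tibble::tibble(a = c(0, 0), b = c(0, 1))
  fit2 <- fit_mle(bn_dag(c("a", "b"), c("a->b")), d2,
                  levels = list(a = 0:1, b = 0:1), pseudo_count = 1)
  tab2 <- matrix(fit2$cpts$b$val, nrow = 2)
  expect_equal(tab2[, 2], c(0.5, 0.5))
  # unobserved rows under pure MLE are set uniform with a message
  expect_message(
    fit3 <- fit_mle(bn_dag(c("a", "b"), c("a->b")), d2, levels = list(a = 0:1, b = 0:1)),
    "unobserved"
  )
  expect_equal(matrix(fit3$cpts$b$val, nrow = 2)[, 2], c(0.5, 0.5))
  expect_error(fit_mle(dag, d[0, ]), class = "mmdbn_estimation_error")
  expect_error(fit_mle(dag, tibble::tibble(a = c(1, NA), b = c(0, 1))), "complete")
})

test_that("parentless outcome MLE reproduces the published prevalence", {
  d <- expand_table1_variable("sex")["mmd"]
  fit <- fit_mle(bn_dag("mmd"), d)
  p1 <- fit$cpts$mmd$val[2]
  expect_equal(round(p1, 3), 0.538)
})

test_that("joint probability is the factorized product", {
  coins <- bn_custom(
    bn_dag(c("A", "B")), list(A = 0:1, B = 0:1),
    list(A = c(0.5, 0.5), B = c(0.5, 0.5))
  )
  expect_equal(joint_probability(coins, c(A = 1, B = 0)), 0.25)
  chain2 <- bn_custom(
    bn_dag(c("A", "B"), c("A->B")), list(A = 0:1, B = 0:1),
    list(A = c(0.4, 0.6), B = matrix(c(0.9, 0.1, 0.5, 0.5), nrow = 2))
  )
  expect_equal(joint_probability(chain2, c(A = 1, B = 1)), 0.6 * 0.5)
  expect_error(joint_probability(chain2, c(A = 1)), "every node")
  # total mass over all assignments is 1
  ej <- enumerate_joint(benchmark_networks()$chain)
  expect_equal(sum(ej$probability), 1, tolerance = 1e-12)
  probs <- apply(ej, 1, function(r) {
    joint_probability(benchmark_networks()$chain,
                      as.list(r[c("A", "B", "C")]))
  })
  expect_equal(unname(probs), ej$probability, tolerance = 1e-12)
})

test_that("joint enumeration refuses oversized state spaces", {
  single <- bn_custom(bn_dag("A"), list(A = 0:1), list(A = c(0.4, 0.6)))
  ej <- enumerate_joint(single)
  expect_equal(ej$probability, c(0.4, 0.6))
  expect_error(enumerate_joint(benchmark_networks()$sprinkler, cap = 10),
               class = "mmdbn_statespace_error")
})

test_that("variable elimination matches hand-derived Bayes inversion", {
  chain2 <- bn_custom(
    bn_dag(c("A", "B"), c("A->B")), list(A = 0:1, B = 0:1),
    list(A = c(0.5, 0.5), B = matrix(c(0.9, 0.1, 0.1, 0.9), nrow = 2))
  )
  post <- eliminate_query(chain2, "A", c(B = 1))
  expect_equal(post$probability[2], 0.9)
  expect_equal(sum(post$probability), 1, tolerance = 1e-12)
  # empty evidence returns the prior marginal
  prior <- eliminate_query(chain2, "A")
  expect_equal(prior$probability, c(0.5, 0.5))
  expect_error(eliminate_query(chain2, "A", c(A = 1)), "must not appear")
  expect_error(eliminate_query(chain2, "A", c(B = 7)), "not valid")
})

test_that("zero-probability evidence raises an explicit error", {
  degenerate <- bn_custom(
    bn_dag(c("A", "B"), c("A->B")), list(A = 0:1, B = 0:1),
    list(A = c(1, 0), B = matrix(c(1, 0, 0.5, 0.5), nrow = 2))
  )
  expect_error(eliminate_query(degenerate, "B", c(A = 1)),
               class = "mmdbn_zero_evidence_error")
})

test_that("elimination agrees with brute-force enumeration everywhere", {
  nets <- c(benchmark_networks(),
            list(r1 = random_binary_network(5, 101),
                 r2 = random_binary_network(6, 202),
                 r3 = random_binary_network(5, 303)))
  for (nm in names(nets)) {
    bn <- nets[[nm]]
    nodes <- bn$dag$nodes
    queries <- c(
      lapply(nodes, function(v) list(target = v, evidence = NULL)),
      list(list(target = nodes[1], evidence = stats::setNames(list(1), nodes[2])),
           list(target = nodes[2],
                evidence = stats::setNames(list(0, 1), nodes[c(1, 3)])))
    )
    for (q in queries) {
      ve <- eliminate_query(bn, q$target, q$evidence)
      oracle <- enum_conditional(bn, q$target, q$evidence)
      expect_lt(max(abs(ve$probability - oracle)), 1e-10)
    }
  }
})

test_that("d-separated evidence leaves the posterior unchanged", {
  chain <- benchmark_networks()$chain   # A -> B -> C: A independent of C given B
  base <- eliminate_query(chain, "A", c(B = 1))
  extended <- eliminate_query(chain, "A", c(B = 1, C = 1))
  expect_equal(base$probability, extended$probability, tolerance = 1e-12)
  fork <- benchmark_networks()$fork     # A <- C -> B: A independent of B given C
  expect_equal(eliminate_query(fork, "A", c(C = 0))$probability,
               eliminate_query(fork, "A", c(C = 0, B = 1))$probability,
               tolerance = 1e-12)
})

test_that("prior marginals behave like marginals", {
  nets <- benchmark_networks()
  m <- prior_marginals(nets$chain)
  expect_equal(m$probability[m$variable == "A"], c(0.6, 0.4))
  for (v in unique(m$variable)) {
    expect_equal(sum(m$probability[m$variable == v]), 1, tolerance = 1e-12)
  }
  # a degenerate CPT yields a point mass
  point <- bn_custom(bn_dag("A"), list(A = 0:1), list(A = c(0, 1)))
  expect_equal(prior_marginals(point)$probability, c(0, 1))
})

test_that("fitting large samples from a balanced network recovers its CPTs", {
  truth <- benchmark_networks()$sprinkler
  d <- ancestral_sample(truth, 100000, seed = 31)
  fit <- suppressMessages(fit_mle(truth$dag, d, levels = truth$levels))
  err <- max(vapply(truth$dag$nodes, function(v) {
    max(abs(fit$cpts[[v]]$val - truth$cpts[[v]]$val))
  }, numeric(1)))
  expect_lt(err, 0.01)
})

test_that("tidy and glance summarise a fitted network", {
  bn <- benchmark_networks()$sprinkler
  td <- tidy(bn)
  expect_named(td, c("child", "parent_config", "category", "probability"))
  sums <- tapply(td$probability, paste(td$child, td$parent_config), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
  gl <- glance(bn)
  expect_equal(gl$n_nodes, 5)
  expect_equal(gl$n_edges, 5)
  expect_equal(gl$state_space, 32)
})

test_that("DOT and BIF exports write parseable structure text", {
  bn <- benchmark_networks()$chain
  dot <- file.path(tempdir(), "chain.dot")
  bif <- file.path(tempdir(), "chain.bif")
  write_dot(bn, dot)
  write_bif(bn, bif)
  dot_lines <- readLines(dot)
  expect_true(any(grepl("\"A\" -> \"B\"", dot_lines)))
  bif_lines <- readLines(bif)
  expect_true(any(grepl("probability \\( B \\| A \\)", bif_lines)))
  expect_true(any(grepl("type discrete \\[ 2 \\]", bif_lines)))
  out <- write_network_csv(bn,
                           edges_path = file.path(tempdir(), "e.csv"),
                           cpts_path = file.path(tempdir(), "c.csv"))
  expect_equal(nrow(readr::read_csv(file.path(tempdir(), "e.csv"),
                                    show_col_types = FALSE)), 2)
  expect_equal(nrow(out$cpts), 2 + 4 + 4)
})
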