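test_that("G-squared statistic matches hand-computed values", {
  balanced <- data.frame(x = rep(0:1, each = 50), y = rep(0:1, times = 50))
  r0 <- g2_test(balanced, "x", "y")
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  # 2x2 table (30,10,10,30): 2*sum(O*ln(O/E)) with E = 20 everywhere
  d <- data.frame(x = rep(0:1, each = 40), y = rep(c(0, 1, 0, 1), c(30, 10, 10, 30)))
  r <- g2_test(d, "x", "y")
  expect_equal(r$statistic, 2 * (60 * log(1.5) + 20 * log(0.5)), tolerance = 1e-12)
  expect_equal(round(r$statistic, 2), 20.93)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, pchisq(r$statistic, 1, lower.tail = FALSE))
  # Pearson variant on the same table: 4 * (10^2 / 20) = 20
  expect_equal(g2_test(d, "x", "y", statistic = "x2")$statistic, 20)
})

test_that("degrees of freedom multiply over conditioning strata", {
  d <- withr::with_seed(5, data.frame(
    x = sample(0:1, 300, TRUE), y = sample(0:1, 300, TRUE),
    z = sample(1:3, 300, TRUE)
  ))
  expect_equal(g2_test(d, "x", "y", "z")$df, 3L)
  # inadequate samples: n < 5 * df skips the test and reports independence
  small <- d[1:10, ]
  r <- g2_test(small, "x", "y", "z")
  expect_false(r$performed)
  expect_equal(r$p_value, 1)
  # conditioning-set size cap skips likewise
  r2 <- g2_test(d, "x", "y", "z", max_condition_size = 0)
  expect_false(r2$performed)
  expect_error(g2_test(d, "x", "x"), "distinct")
})

test_that("max-min heuristic prefers the direct neighbour", {
  chain <- benchmark_networks()$chain
  d <- ancestral_sample(chain, 10000, seed = 21)
  pick <- max_min_heuristic(d, "C", character(0), c("A", "B"))
  expect_equal(pick$candidate, "B")
  expect_lt(pick$p_value, 0.05)
  # an isolated candidate shows a weak max-association
  d$noise <- withr::with_seed(22, sample(0:1, nrow(d), TRUE))
  lone <- max_min_heuristic(d, "C", c("B"), "noise")
  expect_gt(lone$p_value, 0.05)
  single <- max_min_heuristic(d, "C", character(0), "A")
  expect_equal(single$candidate, "A")
  none <- max_min_heuristic(d, "C", character(0), character(0))
  expect_true(is.na(none$candidate))
  expect_error(max_min_heuristic(d, "C", c("A"), c("A")), "disjoint")
})

test_that("MMPC recovers benchmark skeletons and stays symmetric", {
  ind <- withr::with_seed(7, data.frame(
    a = sample(0:1, 5000, TRUE), b = sample(0:1, 5000, TRUE),
    c = sample(1:3, 5000, TRUE)
  ))
  expect_equal(nrow(mmpc(ind)$edges), 0)
  coll <- mmpc(ancestral_sample(benchmark_networks()$collider, 20000, seed = 8))
  expect_setequal(paste(coll$edges$from, coll$edges$to), c("A C", "B C"))
  frk <- mmpc(ancestral_sample(benchmark_networks()$fork, 20000, seed = 9))
  expect_setequal(paste(frk$edges$from, frk$edges$to), c("A C", "B C"))
  # symmetry of the corrected CPCs
  for (sk in list(coll, frk)) {
    for (v in sk$nodes) {
      for (w in sk$cpc[[v]]) expect_true(v %in% sk$cpc[[w]])
    }
  }
  expect_error(mmpc(data.frame(a = c(0.5, 1.2, 0.7))), "non-categorical")
})

test_that("BIC score matches its closed form and decomposes", {
  one <- tibble::tibble(x = rep(0:1, each = 5))
  expect_equal(bic_score(bn_dag("x"), one), 10 * log(0.5) - log(10) / 2,
               tolerance = 1e-12)
  gt <- charls_like_network()
  d <- ancestral_sample(gt, 2000, seed = 10)
  by_node <- bic_score(gt$dag, d, by_node = TRUE)
  expect_equal(sum(by_node), bic_score(gt$dag, d), tolerance = 1e-9)
  # an edge from an independent column lowers the penalized score
  ind <- withr::with_seed(11, tibble::tibble(a = sample(0:1, 5000, TRUE),
                                             b = sample(0:1, 5000, TRUE)))
  expect_lt(bic_score(bn_dag(c("a", "b"), c("a->b")), ind),
            bic_score(bn_dag(c("a", "b")), ind))
})

test_that("hill climbing respects the skeleton and only improves", {
  d <- ancestral_sample(benchmark_networks()$chain, 5000, seed = 12)
  empty <- hill_climb(d, tibble::tibble(from = character(0), to = character(0)))
  expect_equal(nrow(empty$dag$edges), 0)
  expect_equal(nrow(empty$trace), 0)
  two <- hill_climb(d[c("A", "B")], tibble::tibble(from = "A", to = "B"))
  expect_equal(nrow(two$dag$edges), 1)
  expect_setequal(unlist(two$dag$edges[1, ]), c("A", "B"))
  expect_true(all(two$trace$delta[two$trace$improving] > 0))
  expect_gte(two$score, bic_score(bn_dag(c("A", "B")), d[c("A", "B")]))
})

test_that("the full hybrid learner finds the chain's equivalence class", {
  chain <- benchmark_networks()$chain
  d <- ancestral_sample(chain, 20000, seed = 13)
  res <- mmhc(d)
  expect_setequal(with(res$skeleton$edges, paste(from, to)), c("A B", "B C"))
  expect_equal(shd(cpdag(res$dag), cpdag(chain$dag)), 0)
  # learned edges always lie inside the skeleton, and the DAG is acyclic
  gt <- charls_like_network()
  ds <- ancestral_sample(gt, 4000, seed = 14)
  rs <- mmhc(ds)
  skel_pairs <- with(rs$skeleton$edges, paste(from, to))
  got_pairs <- with(rs$dag$edges, paste(pmin(from, to), pmax(from, to)))
  expect_true(all(got_pairs %in% skel_pairs))
  expect_silent(topological_order(rs$dag))
  # deterministic under a fixed dataset and row order
  rs2 <- mmhc(ds)
  expect_identical(rs$dag$edges, rs2$dag$edges)
  expect_identical(rs$trace, rs2$trace)
})

test_that("CPDAGs encode Markov equivalence", {
  chain_cp <- cpdag(bn_dag(c("A", "B", "C"), c("A->B", "B->C")))
  expect_true(all(!chain_cp$edges$directed))
  coll_cp <- cpdag(bn_dag(c("A", "B", "C"), c("A->C", "B->C")))
  expect_true(all(coll_cp$edges$directed))
  single <- cpdag(bn_dag(c("A", "B"), c("A->B")))
  expect_false(single$edges$directed)
  # the three chain orientations share one CPDAG; the collider does not
  rev_chain <- cpdag(bn_dag(c("A", "B", "C"), c("C->B", "B->A")))
  expect_equal(shd(chain_cp, rev_chain), 0)
  # chain vs collider: A-B only in the chain, A-C only in the collider,
  # and B-C differs in orientation state
  expect_equal(shd(chain_cp, coll_cp), 3)
})

test_that("structural Hamming distance counts edits", {
  a <- bn_dag(c("A", "B", "C"), c("A->B"))
  expect_equal(shd(a, a), 0)
  expect_equal(shd(a, bn_dag(c("A", "B", "C"), c("A->B", "B->C"))), 1)
  expect_equal(shd(a, bn_dag(c("A", "B", "C"), c("B->A"))), 1)
  expect_error(shd(a, bn_dag(c("A", "B"))), "node set")
})
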