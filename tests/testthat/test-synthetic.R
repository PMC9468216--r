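test_that("the ground-truth network matches the published cohort structure", {
  gt <- charls_like_network()
  expect_equal(length(gt$dag$nodes), 11)
  expect_equal(nrow(gt$dag$edges), 18)
  documented <- c(
    "age->mmd", "sleep_duration->mmd", "physical_activity->mmd",
    "age->physical_activity", "sex->education", "age->education",
    "sex->marital_status", "age->marital_status",
    "education->residence", "residence->sleep_duration"
  )
  have <- paste0(gt$dag$edges$from, "->", gt$dag$edges$to)
  expect_true(all(documented %in% have))
  # mmd's parents are exactly age, physical activity and sleep duration
  expect_equal(dag_parents(gt$dag, "mmd"),
               c("age", "physical_activity", "sleep_duration"))
})

test_that("calibrated marginals reproduce the pooled baseline frequencies", {
  gt <- charls_like_network()
  marg <- prior_marginals(gt)
  targets <- mmdbn:::table1_marginals()
  for (v in unique(marg$variable)) {
    expect_lt(max(abs(marg$probability[marg$variable == v] - unname(targets[[v]]))),
              0.01, label = paste("marginal dev for", v))
  }
  p_mmd <- marg$probability[marg$variable == "mmd" & marg$code == 1]
  expect_equal(p_mmd, 0.538, tolerance = 0.001 / 0.538)
  # every CPT row is a proper distribution
  for (v in gt$dag$nodes) {
    tab <- matrix(gt$cpts[[v]]$val, nrow = length(gt$levels[[v]]))
    expect_equal(unname(colSums(tab)), rep(1, ncol(tab)), tolerance = 1e-9)
    expect_true(all(tab >= 0))
  }
})

test_that("ancestral sampling is seed-deterministic with correct shape", {
  gt <- charls_like_network()
  empty <- ancestral_sample(gt, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_named(empty, gt$dag$nodes)
  a <- ancestral_sample(gt, 500, seed = 99)
  b <- ancestral_sample(gt, 500, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, ancestral_sample(gt, 500, seed = 100)))
  ok <- validate_dataset(a)
  expect_equal(sum(ok$n_out_of_domain), 0)
})

test_that("sampled frequencies converge to the network marginals", {
  gt <- charls_like_network()
  marg <- prior_marginals(gt)
  # large-sample check on the outcome prevalence across 3 seeds
  for (s in 1:3) {
    d <- ancestral_sample(gt, 200000, seed = s)
    expect_lt(abs(mean(d$mmd) - 0.538), 0.005)
  }
  # all-category binomial concentration at n = 20,000
  d <- ancestral_sample(gt, 20000, seed = 4)
  for (v in gt$dag$nodes) {
    for (k in gt$levels[[v]]) {
      p <- marg$probability[marg$variable == v & marg$code == k]
      bound <- max(3 * sqrt(p * (1 - p) / 20000), 5 / 20000)
      expect_lt(abs(mean(d[[v]] == k) - p), bound,
                label = sprintf("frequency of %s=%d", v, k))
    }
  }
})

test_that("missingness injection hits its target rate and spares the driver", {
  gt <- charls_like_network()
  d <- ancestral_sample(gt, 10000, seed = 6)
  none <- inject_missingness(d, rate = 0)
  expect_identical(none$data, d)
  expect_equal(sum(as.matrix(none$mask)), 0)
  mcar <- inject_missingness(d, rate = 0.1, seed = 7)
  expect_equal(mean(as.matrix(mcar$mask)), 0.1, tolerance = 0.01 / 0.1)
  # observed cells unchanged
  keep <- !as.matrix(mcar$mask)
  expect_equal(as.matrix(mcar$data)[keep], as.matrix(d)[keep])
  mar <- inject_missingness(d, rate = 0.1, mechanism = "MAR", driver = "age", seed = 8)
  expect_equal(sum(is.na(mar$data$age)), 0)
  expect_equal(mean(as.matrix(mar$mask)[, setdiff(names(d), "age")]), 0.1,
               tolerance = 0.15)
  # masking probability rises with the driver under MAR
  rate_by_age <- tapply(rowMeans(as.matrix(mar$mask)[, setdiff(names(d), "age")]),
                        d$age, mean)
  expect_true(rate_by_age[["4"]] > rate_by_age[["1"]])
  expect_error(inject_missingness(d, rate = 0.7), "rate")
  expect_error(inject_missingness(d, rate = 0.1, mechanism = "MAR"), "driver")
})

test_that("benchmark networks are valid and structurally as announced", {
  nets <- benchmark_networks()
  expect_named(nets, c("chain", "fork", "collider", "sprinkler"))
  expect_equal(paste0(nets$chain$dag$edges$from, ">", nets$chain$dag$edges$to),
               c("A>B", "B>C"))
  expect_setequal(paste0(nets$collider$dag$edges$from, ">", nets$collider$dag$edges$to),
                  c("A>C", "B>C"))
  for (bn in nets) {
    expect_s3_class(bn, "bn_fit")
    expect_equal(sum(enumerate_joint(bn)$probability), 1, tolerance = 1e-9)
  }
})
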