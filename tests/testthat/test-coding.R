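test_that("multimorbidity flag is the >=2-conditions rule and is monotone", {
  expect_identical(derive_mmd(rep(0, 14)), 0L)
  one <- c(1, rep(0, 13))
  expect_identical(derive_mmd(one), 0L)
  expect_identical(derive_mmd(c(1, 1, rep(0, 12))), 1L)
  # monotone non-decreasing in the number of positive indicators
  flags <- t(vapply(0:14, function(k) c(rep(1, k), rep(0, 14 - k)), numeric(14)))
  expect_true(all(diff(derive_mmd(flags)) >= 0))
  expect_error(derive_mmd(rep(0, 13)), "14")
  expect_error(derive_mmd(c(2, rep(0, 13))), "0 or 1")
})

test_that("MET-minutes follow the IPAQ weight x frequency x duration rule", {
  expect_equal(met_minutes(data.frame(
    intensity = "moderate", days_per_week = 5, minutes_per_day = 30)), 600)
  expect_equal(met_minutes(data.frame(
    intensity = c("vigorous", "light"),
    days_per_week = c(3, 2), minutes_per_day = c(40, 10))), 8 * 3 * 40 + 3.3 * 2 * 10)
  expect_equal(met_minutes(data.frame(intensity = character(0),
                                      days_per_week = numeric(0),
                                      minutes_per_day = numeric(0))), 0)
  expect_error(met_minutes(data.frame(intensity = "light", days_per_week = 8,
                                      minutes_per_day = 10)), "0-7")
  expect_error(met_minutes(data.frame(intensity = "light", days_per_week = 2,
                                      minutes_per_day = -1)), "non-negative")
  # per-subject totals via the id column
  recs <- data.frame(id = c(1, 1, 2), intensity = c("moderate", "light", "vigorous"),
                     days_per_week = c(5, 2, 1), minutes_per_day = c(30, 10, 60))
  agg <- met_minutes(recs)
  expect_equal(agg$met_minutes, c(600 + 66, 480))
})

test_that("activity bands partition [0, Inf) with the stated boundaries", {
  expect_identical(categorize_activity(c(0, 599.9, 600, 2999.9, 3000, 1e6)),
                   c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(categorize_activity(-1), "non-negative")
  # exhaustive, no gaps: every non-negative value lands in exactly one band
  grid <- seq(0, 5000, by = 0.5)
  codes <- categorize_activity(grid)
  expect_true(all(codes %in% 1:3))
  expect_true(all(diff(codes) >= 0))
})

test_that("raw fields encode to the published integer codes", {
  raw <- data.frame(
    sex = c("Women", "Men", "woman"),
    smoking = c("No", "Yes", "No"),
    alcohol = c("Yes", "No", "No"),
    age_years = c(54.9, 65, 80),
    sleep_hours = c(6.5, 5, 9),
    nap_minutes = c(0, 30, 45),
    met_minutes = c(600, 100, 3000)
  )
  enc <- encode_records(raw)
  expect_equal(enc$sex, c(2L, 1L, 2L))
  expect_equal(enc$smoking, c(0L, 1L, 0L))
  expect_equal(enc$age, c(1L, 3L, 4L))
  expect_equal(enc$sleep_duration, c(3L, 1L, 5L))
  expect_equal(enc$nap, c(1L, 2L, 3L))
  expect_equal(enc$physical_activity, c(2L, 1L, 3L))
  expect_warning(
    bad <- encode_records(data.frame(sex = c("Men", "unknown"))),
    "unrecognized"
  )
  expect_equal(bad$sex, c(1L, NA))
})

test_that("mmd derives from 14 condition columns at encode time", {
  conds <- matrix(0, 3, 14, dimnames = list(NULL, paste0("c", 1:14)))
  conds[2, 1:2] <- 1
  conds[3, 1:5] <- 1
  raw <- cbind(data.frame(sex = c("Men", "Men", "Women")), as.data.frame(conds))
  enc <- encode_records(raw, condition_cols = paste0("c", 1:14))
  expect_equal(enc$mmd, c(0L, 1L, 1L))
  expect_error(encode_records(raw, condition_cols = paste0("z", 1:14)), "absent")
})

test_that("decoding then re-encoding every codebook label is the identity", {
  cb <- mmd_codebook()
  full <- tibble::as_tibble(lapply(
    split(cb$code, factor(cb$variable, unique(cb$variable))),
    function(codes) rep(codes, length.out = 5)
  ))
  roundtrip <- encode_records(decode_records(full))
  for (v in setdiff(names(full), "mmd")) {
    expect_equal(roundtrip[[v]], as.integer(full[[v]]), info = v)
  }
})

test_that("dataset validation reports issues without mutating data", {
  gt <- charls_like_network()
  d <- ancestral_sample(gt, 200, seed = 1)
  rep0 <- validate_dataset(d)
  expect_equal(sum(rep0$n_out_of_domain), 0)
  expect_length(attr(rep0, "issues"), 0)
  d_bad <- d
  d_bad$sex[1] <- 9
  d_bad$age[2] <- NA
  rep1 <- validate_dataset(d_bad)
  expect_equal(rep1$n_out_of_domain[rep1$variable == "sex"], 1)
  expect_equal(rep1$missing_fraction[rep1$variable == "age"], 1 / 200)
  expect_length(attr(rep1, "issues"), 1)
  expect_equal(d_bad$sex[1], 9)  # untouched
  expect_error(validate_dataset(d[setdiff(names(d), "mmd")]),
               class = "mmdbn_structure_error")
})

test_that("shipped JSON codebook mirrors the in-package codebook", {
  js <- read_codebook_json()
  cb <- mmd_codebook()
  expect_equal(js$variable, cb$variable)
  expect_equal(as.integer(js$code), cb$code)
  expect_equal(js$label, cb$label)
})
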