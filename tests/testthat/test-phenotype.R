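test_that("mean time to sterility averages observed failures only", {
  r <- mean_time_to_sterility(make_line(c(6, 6, 6)), horizon = 21)
  expect_equal(r$mean, 6)
  expect_equal(r$n_sterile, 3)
  expect_equal(r$n_censored, 0)

  r <- mean_time_to_sterility(make_line(c(12, 15, NA)), horizon = 21)
  expect_equal(r$mean, 13.5)
  expect_equal(r$n_sterile, 2)
  expect_equal(r$n_censored, 1)

  r <- mean_time_to_sterility(make_line(c(NA, NA, NA)), horizon = 21)
  expect_true(is.na(r$mean))
  expect_equal(r$n_censored, 3)

  # non-Mrt failures are excluded from the mean
  r <- mean_time_to_sterility(
    make_line(c(3, 10, 12), failure_mode = c("non_mrt_failure",
                                             "mrt_sterile", "mrt_sterile")),
    horizon = 21)
  expect_equal(r$mean, 11)
  expect_equal(r$n_excluded, 1)

  expect_error(mean_time_to_sterility(make_line(numeric(0)), horizon = 21),
               "no replicate")
})

test_that("worked assay lines are classified as in the study", {
  # a heat-sensitive sterile mutant: all 10 replicates sterile after the
  # first generation at 25 degrees
  expect_identical(classify_line(make_line(rep(1, 10)), 21), "ts_sterile")
  # the strong Mrt mutant: all 10 sterile by generation 10, mean 6.4
  l578 <- make_line(c(4, 5, 5, 6, 6, 6, 7, 7, 8, 10))
  expect_identical(classify_line(l578, 21), "strong")
  expect_equal(classify_table(l578, 21)$mean_tts, 6.4)
  # one early failure but 2/3 replicates fertile at 21: wild type
  expect_identical(classify_line(make_line(c(5, NA, NA)), 21), "wild_type")
  # mean 13.5 < 16 but one replicate fertile at 21: weak, not moderate
  expect_identical(classify_line(make_line(c(12, 15, NA)), 21), "weak")
})

test_that("class boundaries follow the strict threshold inequalities", {
  # mean exactly 10 fails the strong mean criterion
  expect_identical(classify_line(make_line(c(8, 10, 12)), 21), "moderate")
  # max exactly 15 fails the strong max criterion
  expect_identical(classify_line(make_line(c(5, 6, 15)), 21), "moderate")
  # mean exactly 16 fails moderate, all sterile so at least 2/3: weak
  expect_identical(classify_line(make_line(c(14, 16, 18)), 21), "weak")
  # strong when strictly inside both thresholds
  expect_identical(classify_line(make_line(c(5, 9, 14)), 21), "strong")
  # exactly 2/3 sterile by 21 is weak (the "at least 2 out of 3" rule)
  expect_identical(classify_line(make_line(c(18, 20, NA)), 21), "weak")
  # fewer than 2/3 sterile is wild type
  expect_identical(classify_line(make_line(c(18, NA, NA)), 21), "wild_type")
})

test_that("low-fitness annotation drives exclusion by strict majority", {
  # 6/10 non-Mrt failures: excluded
  l471 <- make_line(c(3, 4, 4, 5, 6, 6, NA, NA, NA, NA),
                    failure_mode = c(rep("non_mrt_failure", 6),
                                     rep("none", 4)))
  expect_identical(classify_line(l471, 21), "excluded_low_fitness")
  # 3/10 non-Mrt failures: the line is scored on its remaining
  # replicates, here wild type
  l516 <- make_line(c(3, 5, 9, rep(NA, 7)),
                    failure_mode = c(rep("non_mrt_failure", 3),
                                     rep("none", 7)))
  expect_identical(classify_line(l516, 21), "wild_type")
})

test_that("14-generation assays only admit ts_sterile, strong, wild_type", {
  expect_identical(classify_line(make_line(c(4, 5, 6, 7, 8)), 14), "strong")
  expect_identical(classify_line(make_line(rep(1, 10)), 14), "ts_sterile")
  # would be moderate at horizon 21; capped to wild_type at 14
  expect_identical(classify_line(make_line(c(10, 12, 13, 14, NA)), 14),
                   "wild_type")
  cls <- classify_table(make_line(c(4, 5, 6)), 14)
  expect_false(any(cls$class %in% c("moderate", "weak")))
  expect_match(attr(cls, "caveat"), "moderate and weak")
})

test_that("malformed tables are rejected", {
  bad <- make_line(c(25, 4, 5))
  expect_error(classify_table(bad, 21), "horizon")
  dup <- rbind(make_line(c(4, 5)), make_line(6)[1, ])
  dup$replicate_id <- c(1, 2, 1)
  expect_error(classify_table(dup, 21), "duplicate")
  cc <- make_line(c(4, NA))
  cc$censored <- c(1L, 1L) # censored but with a recorded generation
  expect_error(classify_table(cc, 21), "censored")
  expect_error(classify_table(make_line(4)), "horizon")
})

test_that("classify_table partitions lines and tallies counts", {
  empty <- classify_table(make_line(numeric(0)), 21)
  expect_identical(nrow(empty), 0L)
  expect_identical(sum(summary(empty)), 0L)

  tab <- rbind(make_line(rep(1, 3), "A"),
               make_line(c(4, 5, 6), "B"),
               make_line(c(NA, NA, NA), "C"))
  attr(tab, "horizon") <- 21
  cls <- classify_table(tab)
  expect_identical(nrow(cls), 3L)
  expect_identical(sum(summary(cls)), 3L)
  expect_identical(as.character(cls$class),
                   c("ts_sterile", "strong", "wild_type"))
  # every line receives exactly one class
  expect_false(anyNA(cls$class))
})

test_that("classification recovers the generating mixture", {
  mixture <- c(strong = 0.2, moderate = 0.25, weak = 0.25, wild_type = 0.3)
  n <- 10000
  cfg <- synthetic_config(assay_design(n, 10, 21, "mixture check"),
                          mixture = mixture, seed = 2024)
  cls <- classify_table(generate_assay_table(cfg))
  freq <- summary(cls) / n
  for (cl in names(mixture)) {
    se <- sqrt(mixture[[cl]] * (1 - mixture[[cl]]) / n)
    expect_lt(abs(freq[[cl]] - mixture[[cl]]), 3 * se + 0.005)
  }
})

test_that("strengthening outcomes never weakens the class", {
  set.seed(7)
  for (i in 1:200) {
    r <- sample(3:10, 1)
    gens <- ifelse(runif(r) < 0.4, NA, sample(2:21, r, replace = TRUE))
    before <- classify_line(make_line(gens), 21)
    if (before %in% c("excluded_low_fitness")) next
    # strengthen: shrink some times, convert some censored to sterile
    gens2 <- gens
    shrink <- !is.na(gens2) & runif(r) < 0.5
    gens2[shrink] <- pmax(1, gens2[shrink] - sample(1:6, sum(shrink),
                                                    replace = TRUE))
    convert <- is.na(gens2) & runif(r) < 0.5
    gens2[convert] <- sample(1:21, sum(convert), replace = TRUE)
    after <- classify_line(make_line(gens2), 21)
    expect_gte(class_rank(after), class_rank(before))
  }
})

test_that("identical failure distributions give D = 0 and p near 1", {
  tab <- make_failure_tab(c(4, 7, 9, NA, 12, NA, 6, 15))
  res <- compare_time_to_failure(tab, tab, n_permutations = 99, seed = 1)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
})

test_that("the KS distance matches stats::ks.test on tie-free data", {
  set.seed(31)
  x <- rnorm(40)
  y <- rnorm(35, 0.5)
  got <- mrtline:::ks_distance(x, y)
  want <- unname(suppressWarnings(ks.test(x, y)$statistic))
  expect_equal(got, want)
})

test_that("a large distribution shift is detected essentially always", {
  set.seed(55)
  rejected <- vapply(1:40, function(i) {
    a <- make_failure_tab(pmin(rnbinom(100, mu = 12, size = 8) + 1, 21))
    b <- make_failure_tab(pmin(rnbinom(100, mu = 4, size = 8) + 1, 21))
    compare_time_to_failure(a, b, n_permutations = 199,
                            seed = i)$p.value <= 0.05
  }, logical(1))
  expect_gt(mean(rejected), 0.95)
})

test_that("comparison rejects empty input and bad permutation counts", {
  tab <- make_failure_tab(c(4, 5))
  expect_error(compare_time_to_failure(tab[0, ], tab), "non-empty")
  expect_error(compare_time_to_failure(tab, tab, n_permutations = 0),
               "positive integer")
})
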