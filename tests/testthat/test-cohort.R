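test_that("aggregation reproduces hand-computed mean and SEM", {
  recs <- fake_cf_records(pair_cf_records(ab = c(5, 6, 7, 8, 9),
                                          ac = 1:5, bc = rep(2, 5)))
  agg <- aggregate_cells(recs)
  row <- agg[agg$region == "A & B w/o C", ]
  expect_equal(row$mean_cf, 7)
  expect_equal(row$sem, sqrt(2.5) / sqrt(5))  # ~0.707
  expect_identical(row$n, 5L)
  expect_identical(row$n_excluded, 0L)
})

test_that("undefined CFs are excluded and counted", {
  recs <- fake_cf_records(pair_cf_records(ab = c(1, 2, 3), ac = c(1, 1, 1),
                                          bc = c(2, 2, 2)))
  recs$defined[recs$region == "A & B w/o C" & recs$cell_id == "c2"] <- FALSE
  recs$cf[recs$region == "A & B w/o C" & recs$cell_id == "c2"] <- NaN
  agg <- aggregate_cells(recs)
  row <- agg[agg$region == "A & B w/o C", ]
  expect_equal(row$mean_cf, 2)
  expect_identical(row$n, 2L)
  expect_identical(row$n_excluded, 1L)
})

test_that("cohort validation rejects single cells and mismatched region sets", {
  recs <- fake_cf_records(pair_cf_records(ab = 1, ac = 1, bc = 1))
  expect_error(aggregate_cells(recs), class = "venncf_parameter_error")
  recs2 <- fake_cf_records(pair_cf_records(ab = 1:3, ac = 1:3, bc = 1:3))
  recs2 <- recs2[!(recs2$cell_id == "c3" & recs2$region == "A & B w/o C"), ]
  expect_error(aggregate_cells(recs2), "A & B w/o C",
               class = "venncf_parameter_error")
})

test_that("ANOVA against a reference handles the degenerate extremes", {
  # identical values within groups, different means: F = Inf, p = 0
  recs <- fake_cf_records(pair_cf_records(ab = rep(4, 4), ac = rep(3, 4),
                                          bc = rep(1, 4)))
  av <- anova_vs_reference(recs, reference = "B & C w/o A")
  expect_identical(av$anova$statistic, Inf)
  expect_identical(av$anova$p_value, 0)
  expect_true(all(av$comparisons$reject))
  # groups exactly equal to each other: F = 0, p = 1
  recs2 <- fake_cf_records(pair_cf_records(ab = 1:4, ac = 1:4, bc = 1:4))
  av2 <- anova_vs_reference(recs2, reference = "B & C w/o A")
  expect_equal(av2$anova$statistic, 0)
  expect_equal(av2$anova$p_value, 1)
  expect_false(any(av2$comparisons$reject))
  # every CF identical: degenerate
  recs3 <- fake_cf_records(pair_cf_records(ab = rep(1, 4), ac = rep(1, 4),
                                           bc = rep(1, 4)))
  expect_error(anova_vs_reference(recs3, reference = "B & C w/o A"),
               class = "venncf_degenerate_data")
})

test_that("ANOVA matches R's reference machinery on regular data", {
  set.seed(20)
  recs <- fake_cf_records(pair_cf_records(ab = rnorm(6, 4), ac = rnorm(6, 3),
                                          bc = rnorm(6, 1)))
  av <- anova_vs_reference(recs, reference = "B & C w/o A")
  fit <- stats::aov(cf ~ region, data = recs)
  tab <- summary(fit)[[1]]
  expect_equal(av$anova$statistic, tab[1, "F value"], tolerance = 1e-12)
  expect_equal(av$anova$p_value, tab[1, "Pr(>F)"], tolerance = 1e-12)
  w <- t.test(recs$cf[recs$region == "A & B w/o C"],
              recs$cf[recs$region == "B & C w/o A"])
  cmp <- av$comparisons[av$comparisons$region == "A & B w/o C", ]
  expect_equal(cmp$p_value, w$p.value, tolerance = 1e-12)
  expect_equal(av$comparisons$p_adj,
               p.adjust(av$comparisons$p_value, "holm"))
})

test_that("the reference region must exist", {
  recs <- fake_cf_records(pair_cf_records(ab = 1:3, ac = 2:4, bc = 3:5))
  expect_error(anova_vs_reference(recs, reference = "nope"),
               class = "venncf_parameter_error")
})

test_that("scaffold calls follow the minimum exclusive-pair CF", {
  set.seed(30)
  # pair regions containing C are high; A & B w/o C is at control level:
  # C bridges A and B
  recs <- fake_cf_records(pair_cf_records(ab = rnorm(5, 1, 0.1),
                                          ac = rnorm(5, 4, 0.3),
                                          bc = rnorm(5, 3, 0.3),
                                          triple = rnorm(5, 8, 1)))
  call <- call_scaffold(recs)
  expect_identical(call$scaffold, "C")
  expect_true(call$significant)
  expect_identical(call$ordering$excluded_channel[3], "C")
})

test_that("tied minima produce no call and report the ordering", {
  recs <- fake_cf_records(pair_cf_records(ab = c(1, 2, 3), ac = c(3, 2, 1),
                                          bc = c(2, 2, 2)))
  call <- call_scaffold(recs)
  expect_true(call$tie)
  expect_identical(call$scaffold, NA_character_)
  expect_identical(nrow(call$ordering), 3L)
})

test_that("an insignificant minimum yields candidate but no scaffold", {
  set.seed(31)
  recs <- fake_cf_records(pair_cf_records(ab = rnorm(5, 1.0, 2),
                                          ac = rnorm(5, 1.2, 2),
                                          bc = rnorm(5, 1.1, 2)))
  call <- call_scaffold(recs)
  expect_false(call$significant)
  expect_identical(call$scaffold, NA_character_)
  expect_false(is.na(call$candidate))
})

test_that("scaffold calls are equivariant under channel relabeling", {
  set.seed(32)
  ab <- rnorm(5, 1, 0.1); ac <- rnorm(5, 4, 0.3); bc <- rnorm(5, 3.5, 0.3)
  call1 <- call_scaffold(fake_cf_records(pair_cf_records(ab, ac, bc)))
  # swap roles: relabel A->X, B->Z, C->Y; pair values follow their channels
  # pairs of (X,Y,Z): XZ = ab, XY = ac, YZ = bc
  call2 <- call_scaffold(fake_cf_records(
    pair_cf_records(ab = ac, ac = ab, bc = bc, channels = c("X", "Y", "Z"))))
  expect_identical(call1$scaffold, "C")
  expect_identical(call2$scaffold, "Y")
  expect_equal(sort(call1$ordering$mean_cf), sort(call2$ordering$mean_cf))
})
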