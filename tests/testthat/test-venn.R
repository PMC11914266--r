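test_that("partition areas equal the per-pixel enumeration oracle", {
  for (seed in 1:6) {
    masks <- rand_masks(nr = 8, nc = 8, p = 0.4, seed = seed)
    pa <- partition_areas(masks)
    expect_identical(pa$areas, pixel_loop_areas(masks))
  }
  # with an ROI, and with k = 2 channels
  masks <- rand_masks(nr = 10, nc = 10, p = 0.3, seed = 7)
  roi <- matrix(runif(100) < 0.6, 10, 10)
  pa <- partition_areas(masks, roi)
  expect_identical(pa$areas, pixel_loop_areas(masks, roi))
  m2 <- rand_masks(channels = c("A", "B"), seed = 8)
  expect_identical(partition_areas(m2)$areas, pixel_loop_areas(m2))
})

test_that("conservation: exclusive areas sum to the union and rebuild marginals", {
  for (seed in 1:5) {
    masks <- rand_masks(nr = 16, nc = 16, p = 0.35, seed = seed)
    pa <- partition_areas(masks)
    union <- sum(Reduce(`|`, masks))
    expect_identical(sum(pa$areas), union)
    m <- venncf:::pattern_membership(pa)
    for (ch in names(masks)) {
      expect_identical(sum(pa$areas[m[, ch]]), sum(masks[[ch]]))
      expect_equal(pa$p[[ch]], sum(masks[[ch]]) / pa$roi_area)
    }
  }
})

test_that("degenerate mask geometries give pure patterns", {
  a <- matrix(FALSE, 10, 10); a[1:2, ] <- TRUE  # area 20
  pa <- partition_areas(list(A = a, B = a, C = a))
  expect_identical(pa$areas[7], 20L)
  expect_identical(sum(pa$areas), 20L)
  d1 <- matrix(FALSE, 10, 10); d1[1, ] <- TRUE
  d2 <- matrix(FALSE, 10, 10); d2[2, ] <- TRUE
  d3 <- matrix(FALSE, 10, 10); d3[3, ] <- TRUE
  pa2 <- partition_areas(list(A = d1, B = d2, C = d3))
  expect_identical(pa2$areas[c(1, 2, 4)], rep(10L, 3))
  expect_identical(sum(pa2$areas), 30L)
})

test_that("region_area matches the brute-force pixel count", {
  masks <- rand_masks(nr = 12, nc = 12, p = 0.4, seed = 10)
  pa <- partition_areas(masks)
  cases <- list(
    list(inc = c("A", "B", "C"), exc = character()),
    list(inc = c("A", "B"), exc = "C"),
    list(inc = "A", exc = character()),
    list(inc = "B", exc = c("A", "C")))
  for (cs in cases) {
    expect_identical(region_area(pa, region_spec(cs$inc, cs$exc)),
                     pixel_loop_region_area(masks, cs$inc, cs$exc))
  }
  # single included channel with no exclusions returns the marginal area
  expect_identical(region_area(pa, region_spec("C")), sum(masks$C))
  expect_error(region_area(pa, region_spec("Z")), "unknown channel",
               class = "venncf_parameter_error")
})

test_that("expected fractions follow the independence product rule", {
  p <- c(A = 0.5, B = 0.5, C = 0.5)
  triple <- region_spec(c("A", "B", "C"))
  pair <- region_spec(c("A", "B"), "C")
  expect_equal(expected_fraction(p, triple), 0.125)
  expect_equal(expected_fraction(p, triple, "paper_literal"), 0.125)
  expect_equal(expected_fraction(p, pair), 0.125)
  expect_equal(expected_fraction(p, pair, "paper_literal"), 0.25)
  p2 <- c(A = 0.1, B = 0.4, C = 0.3)
  expect_equal(expected_fraction(p2, pair), 0.1 * 0.4 * 0.7)
  expect_equal(expected_fraction(p2, region_spec("A", c("B", "C"))),
               0.1 * 0.6 * 0.7)
  expect_equal(expected_fraction(c(A = 0, B = 0.4, C = 0.3), triple), 0)
})

test_that("CF has the closed form p^(1-k) for identical masks", {
  for (p in c(0.1, 0.2, 0.5)) {
    m <- matrix(FALSE, 10, 10)
    m[seq_len(p * 100)] <- TRUE
    pa <- partition_areas(list(A = m, B = m, C = m))
    rec <- colocalization_factor(pa, region_spec(c("A", "B", "C")))
    expect_equal(rec$cf, p^(-2), tolerance = 1e-12)
    expect_equal(rec$actual_fraction, p)
    expect_equal(rec$expected_fraction, p^3)
  }
})

test_that("CF handles empty and undefined regions", {
  d1 <- matrix(FALSE, 10, 10); d1[1, ] <- TRUE
  d2 <- matrix(FALSE, 10, 10); d2[2, ] <- TRUE
  d3 <- matrix(FALSE, 10, 10); d3[3, ] <- TRUE
  pa <- partition_areas(list(A = d1, B = d2, C = d3))
  rec <- colocalization_factor(pa, region_spec(c("A", "B", "C")))
  expect_equal(rec$cf, 0)  # disjoint: actual 0, expected > 0
  # a channel with empty mask: expected 0 and actual 0 -> flagged NaN
  empty <- matrix(FALSE, 10, 10)
  pa2 <- partition_areas(list(A = d1, B = d2, C = empty))
  rec2 <- colocalization_factor(pa2, region_spec(c("A", "C")))
  expect_true(is.nan(rec2$cf))
  expect_false(rec2$defined)
})

test_that("venn_summary rows cover all patterns and sum to the union", {
  masks <- rand_masks(nr = 16, nc = 16, p = 0.3, seed = 12)
  pa <- partition_areas(masks)
  vs <- venn_summary(pa)
  expect_identical(nrow(vs), 7L)
  expect_equal(sum(vs$percent), 100 * sum(pa$areas) / pa$roi_area)
  # oracle check per row
  m <- venncf:::pattern_membership(pa)
  for (r in seq_len(nrow(vs))) {
    inc <- pa$channels[m[r, ]]
    exc <- pa$channels[!m[r, ]]
    expect_identical(vs$area[r],
                     pixel_loop_region_area(masks, inc, exc))
  }
  # identical masks: one nonzero row at p * 100
  mm <- matrix(FALSE, 10, 10); mm[1:20] <- TRUE
  vs2 <- venn_summary(partition_areas(list(A = mm, B = mm, C = mm)))
  expect_equal(sort(vs2$percent), c(rep(0, 6), 20))
})

test_that("CF is invariant under joint toroidal translation and relabeling", {
  masks <- rand_masks(nr = 16, nc = 16, p = 0.3, seed = 14)
  shift <- function(m, dr, dc)
    m[((seq_len(nrow(m)) - 1 - dr) %% nrow(m)) + 1,
      ((seq_len(ncol(m)) - 1 - dc) %% ncol(m)) + 1]
  shifted <- lapply(masks, shift, dr = 5, dc = 11)
  reg <- region_spec(c("A", "B"), "C")
  cf0 <- colocalization_factor(partition_areas(masks), reg)$cf
  cf1 <- colocalization_factor(partition_areas(shifted), reg)$cf
  expect_equal(cf0, cf1)
  # relabeling channels consistently with the region spec
  relabeled <- list(X = masks$B, Y = masks$C, Z = masks$A)
  cf2 <- colocalization_factor(partition_areas(relabeled),
                               region_spec(c("X", "Z"), "Y"))$cf
  expect_equal(cf0, cf2)
})

test_that("toroidal-shift Monte Carlo agrees with the analytic expectation", {
  masks <- rand_masks(nr = 32, nc = 32, p = 0.25, seed = 15)
  regions <- default_regions(names(masks))
  mc <- toroidal_null_fraction(masks, regions, n_shifts = 400, seed = 2)
  pa <- partition_areas(masks)
  for (i in seq_along(regions)) {
    analytic <- expected_fraction(pa$p, regions[[i]])
    expect_lt(abs(mc$mc_expected[i] - analytic), 3 * mc$mc_se[i] + 1e-12)
  }
})

test_that("region and mask validation errors are informative", {
  expect_error(region_spec(character()), class = "venncf_parameter_error")
  expect_error(region_spec("A", "A"), class = "venncf_parameter_error")
  bad <- list(A = matrix(TRUE, 4, 4), B = matrix(TRUE, 5, 5))
  expect_error(partition_areas(bad), "B", class = "venncf_shape_error")
  expect_error(partition_areas(list(A = matrix(TRUE, 4, 4))),
               class = "venncf_parameter_error")
})
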