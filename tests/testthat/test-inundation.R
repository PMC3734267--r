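test_that("bathtub mask thresholds elevation at the rise level", {
  g <- sivva_grid(matrix(2, 3, 3))
  expect_false(any(bathtub_mask(g, 1)))
  g0 <- sivva_grid(matrix(0, 3, 3))
  expect_true(all(bathtub_mask(g0, 1)))
  g2 <- sivva_grid(matrix(c(0.5, 0.9, 1.5, 2.0), 2, 2))
  expect_equal(sum(bathtub_mask(g2, 1)), 2)
  # missing cells never flood; an all-missing grid is rejected
  gna <- sivva_grid(matrix(c(NA, 0, 0, 0), 2, 2))
  expect_equal(sum(bathtub_mask(gna, 1)), 3)
  expect_error(bathtub_mask(sivva_grid(matrix(NA_real_, 2, 2)), 1), "missing")
  expect_error(bathtub_mask(g, -1), "non-negative")
})

test_that("inundation grows monotonically with rise and connectivity only removes", {
  set.seed(11)
  for (i in 1:10) {
    g <- sivva_grid(matrix(runif(400, -0.5, 3), 20, 20))
    r1 <- runif(1, 0, 1.5)
    r2 <- r1 + runif(1, 0, 1.5)
    m1 <- bathtub_mask(g, r1)
    m2 <- bathtub_mask(g, r2)
    expect_true(all(m2[m1])) # mask(rise1) subset of mask(rise2)
    mc <- bathtub_mask(g, r1, require_sea_connectivity = TRUE)
    expect_true(all(m1[mc]))
  }
})

test_that("sea connectivity removes enclosed depressions", {
  # low basin in the middle of high ground, sea on the west edge
  m <- matrix(5, 5, 7)
  m[, 1] <- 0
  m[, 2] <- 0.5
  m[3, 5] <- 0.2 # isolated depression
  g <- sivva_grid(m)
  plain <- bathtub_mask(g, 1)
  conn <- bathtub_mask(g, 1, require_sea_connectivity = TRUE)
  expect_true(plain[3, 5])
  expect_false(conn[3, 5])
  expect_true(all(conn[, 1:2]))
})

test_that("percent of range inundated counts overlap cells", {
  wet <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  all_in <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(percent_range_inundated(all_in, wet), 100)
  disjoint <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2)
  expect_equal(percent_range_inundated(disjoint, wet), 0)
  half <- matrix(TRUE, 2, 2)
  expect_equal(percent_range_inundated(half, wet), 50)
  expect_error(percent_range_inundated(matrix(FALSE, 2, 2), wet), "empty")
})

test_that("category scales map published example values", {
  expect_equal(slr_category(57), "High")
  expect_equal(slr_category(50), "Moderate")
  expect_equal(slr_category(0), "Low")
  expect_equal(criterion_category(3), "Neutral")
  expect_equal(criterion_category(6), "Very high")
  expect_equal(criterion_category(4), "Moderate")
  expect_error(slr_category(101), "0, 100")
  expect_error(criterion_category(2.9), "3, 6")
})

test_that("range centroid is the mean of occupied cell centres", {
  g <- sivva_grid(matrix(0, 3, 3))
  single <- matrix(FALSE, 3, 3); single[1, 1] <- TRUE
  expect_equal(range_centroid(single, g), c(x = 0.5, y = 0.5))
  block <- matrix(FALSE, 3, 3); block[1:2, 1:2] <- TRUE
  expect_equal(range_centroid(block, g), c(x = 1, y = 1))
  lshape <- matrix(FALSE, 3, 3); lshape[1, 1] <- lshape[2, 1] <- lshape[1, 2] <- TRUE
  expect_equal(range_centroid(lshape, g),
               c(x = mean(c(0.5, 0.5, 1.5)), y = mean(c(0.5, 1.5, 0.5))))
  expect_error(range_centroid(matrix(FALSE, 3, 3), g), "empty")
})

test_that("distance to coast equals the brute-force pairwise minimum", {
  set.seed(21)
  for (i in 1:8) {
    n <- 50
    g <- sivva_grid(matrix(0, n, n), cellsize = runif(1, 0.5, 2))
    coast <- matrix(runif(n * n) < 0.03, n, n)
    if (!any(coast)) coast[1, 1] <- TRUE
    pt <- c(runif(1, 0, n * g$cellsize), runif(1, 0, n * g$cellsize))
    cc <- which(coast, arr.ind = TRUE)
    xs <- (cc[, 2] - 0.5) * g$cellsize
    ys <- (cc[, 1] - 0.5) * g$cellsize
    brute <- min(sqrt((xs - pt[1])^2 + (ys - pt[2])^2))
    expect_equal(distance_to_coast(pt, coast, g), brute)
  }
  # unit-grid sanity: centroid one cell inland
  g1 <- sivva_grid(matrix(0, 3, 3))
  coast <- matrix(FALSE, 3, 3); coast[, 1] <- TRUE
  expect_equal(distance_to_coast(c(1.5, 0.5), coast, g1), 1)
  expect_error(distance_to_coast(c(1, 1), matrix(FALSE, 3, 3), g1), "empty")
})

test_that("log distance floors at half a cell", {
  g <- sivva_grid(matrix(0, 3, 3), cellsize = 2)
  coast <- matrix(FALSE, 3, 3); coast[2, 2] <- TRUE
  on_coast <- c(3, 3) # the coast-cell centre
  expect_equal(log_distance_to_coast(on_coast, coast, g), log(1))
  far <- c(3, 30)
  expect_equal(log_distance_to_coast(far, coast, g), log(27))
})
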