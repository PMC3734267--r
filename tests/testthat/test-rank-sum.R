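test_that("complete-separation cases reproduce known exact tails", {
  # 3 vs 3, first sample all larger: U = 9, one-sided p = 1/20
  r <- exact_rank_sum(c(7, 8, 9), c(1, 2, 3), sided = "one")
  expect_equal(r$statistic, 9)
  expect_equal(r$p_value, 1 / 20)
  # 3 vs 4, first sample all smaller: U = 0, one-sided p = 1/35
  r <- exact_rank_sum(c(1, 2, 3), c(4, 5, 6, 7), sided = "one")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 35)
  # 3 vs 8: U = 0, one-sided p = 1/165
  r <- exact_rank_sum(c(1, 2, 3), 4:11, sided = "one")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 165)
})

test_that("identical samples give two-sided p of 1", {
  x <- c(2, 5, 9)
  r <- exact_rank_sum(x, x, sided = "two")
  expect_equal(r$p_value, 1)
})

test_that("tie-free enumeration matches the closed-form Mann-Whitney null", {
  # stats::pwilcox is an independent closed-form route to the same null
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- runif(n1)
    y <- runif(n2)
    u <- sum(outer(x, y, ">"))
    r <- exact_rank_sum(x, y, sided = "one")
    expect_equal(r$statistic, u)
    p_ref <- min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    expect_equal(r$p_value, p_ref)
  }
})

test_that("tied data match brute-force counting over all labelings", {
  cases <- list(
    list(x = c(1, 2, 2), y = c(2, 3, 4)),
    list(x = c(5, 5, 7, 8), y = c(5, 6, 7)),
    list(x = c(1, 1, 1), y = c(1, 1, 2, 2))
  )
  for (cs in cases) {
    pooled <- c(cs$x, cs$y)
    u_dist <- brute_force_u_distribution(pooled, length(cs$x))
    u_obs <- sum(outer(cs$x, cs$y, ">")) + 0.5 * sum(outer(cs$x, cs$y, "=="))
    p_one <- min(mean(u_dist <= u_obs), mean(u_dist >= u_obs))
    r1 <- exact_rank_sum(cs$x, cs$y, sided = "one")
    r2 <- exact_rank_sum(cs$x, cs$y, sided = "two")
    expect_equal(r1$statistic, u_obs)
    expect_equal(r1$p_value, p_one)
    expect_equal(r2$p_value, min(1, 2 * p_one))
  }
})

test_that("large samples fall back to the normal approximation", {
  set.seed(8)
  x <- rnorm(15)
  y <- rnorm(15, 1)
  r <- exact_rank_sum(x, y, sided = "two")
  expect_match(r$method, "normal approximation")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(r$p_value, wt$p.value)
  expect_error(exact_rank_sum(numeric(0), y), "non-empty")
})
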