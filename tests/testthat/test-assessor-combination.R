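two_assessor_sheet <- function(s1, s2, u1 = FALSE, u2 = FALSE) {
  dplyr::bind_rows(
    make_sheet(s1, uncertain = u1, assessor_id = "A1"),
    make_sheet(s2, uncertain = u2, assessor_id = "A2")
  )
}

test_that("combining identical sheets is idempotent on scores", {
  sheet <- make_sheet(c(4, 2, 6))
  comb <- combine_assessors(dplyr::bind_rows(
    sheet, dplyr::mutate(sheet, assessor_id = "A2")
  ))
  expect_equal(comb$score, c(4, 2, 6))
  expect_equal(unique(comb$assessor_id), "combined")
})

test_that("scores are averaged and zeros excluded pairwise", {
  comb <- combine_assessors(two_assessor_sheet(c(4, 0, 0), c(6, 4, 0)))
  comb <- comb[order(comb$criterion_id), ]
  expect_equal(comb$score, c(5, 4, 0)) # mean; one-sided zero; both-zero stays 0
})

test_that("uncertainty flags take the union", {
  comb <- combine_assessors(two_assessor_sheet(
    c(4, 4), c(5, 5), u1 = c(TRUE, FALSE), u2 = c(FALSE, FALSE)
  ))
  comb <- comb[order(comb$criterion_id), ]
  expect_equal(comb$uncertain, c(TRUE, FALSE))
})

test_that("mismatched criterion sets abort and keep-separate passes through", {
  a <- make_sheet(c(4, 5), assessor_id = "A1")
  b <- make_sheet(c(4, 5, 6), assessor_id = "A2")
  expect_error(combine_assessors(dplyr::bind_rows(a, b)), "different")
  sheet <- two_assessor_sheet(c(4, 5), c(2, 3))
  expect_identical(
    combine_assessors(sheet, strategy = "keep_separate"),
    validate_scoresheet(sheet)
  )
})

test_that("interval disjointness follows the endpoint-overlap rule", {
  expect_true(ci_disjoint(0.2, 0.3, 0.5, 0.6))
  expect_true(ci_disjoint(0.5, 0.6, 0.2, 0.3))
  expect_false(ci_disjoint(0.2, 0.4, 0.3, 0.6))
  expect_false(ci_disjoint(0.2, 0.4, 0.2, 0.4))
  expect_false(ci_disjoint(0.2, 0.4, 0.4, 0.6)) # touching endpoints overlap
  expect_error(ci_disjoint(0.4, 0.2, 0.1, 0.3), "out of order")
})

test_that("pairwise differences join listed and nonlisted members", {
  ci <- tibble::tibble(
    taxon_id = c("a", "b"), pair_id = "P1",
    status = c("listed", "nonlisted"), module = "vulnerability",
    point = c(0.8, 0.4), ci_low = c(0.75, 0.35), ci_high = c(0.85, 0.45)
  )
  pw <- pairwise_ci_differences(ci)
  expect_equal(nrow(pw), 1)
  expect_true(pw$different)
  expect_equal(pw$point_listed, 0.8)
})
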