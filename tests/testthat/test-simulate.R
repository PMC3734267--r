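test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 77, n_pairs = 3)
  expect_identical(sim_scoresheets(cfg), sim_scoresheets(cfg))
  expect_identical(sim_traits(cfg), sim_traits(cfg))
  a <- sim_landscape(cfg)
  b <- sim_landscape(cfg)
  expect_identical(a$elevation$values, b$elevation$values)
  expect_identical(a$ranges, b$ranges)
  cfg2 <- sim_config(seed = 78, n_pairs = 3)
  expect_false(identical(sim_scoresheets(cfg), sim_scoresheets(cfg2)))
})

test_that("a null status shift produces no systematic module-score gap", {
  cfg <- sim_config(seed = 55, n_pairs = 100, status_score_shift = 0)
  sm <- score_modules(sim_scoresheets(cfg))
  gap <- mean(sm$score[sm$status == "listed"]) -
    mean(sm$score[sm$status == "nonlisted"])
  # 100 pairs x 2 assessors x 4 modules per group: the gap is noise-level
  expect_lt(abs(gap), 0.02)
})

test_that("flag_prob = 0 makes every MC interval degenerate", {
  cfg <- sim_config(seed = 56, n_pairs = 2, flag_prob = 0)
  ci <- mc_uncertainty_ci(sim_scoresheets(cfg), n_sims = 100, seed = 1)
  expect_equal(ci$ci_low, ci$point)
  expect_equal(ci$ci_high, ci$point)
})

test_that("scores honour the 1-6 scale and flags appear at the set rate", {
  cfg <- sim_config(seed = 57, n_pairs = 30, flag_prob = 0.3)
  sheets <- sim_scoresheets(cfg)
  expect_true(all(sheets$score >= 1 & sheets$score <= 6))
  expect_true(all(sheets$score == round(sheets$score)))
  expect_lt(abs(mean(sheets$uncertain) - 0.3), 0.02) # ~4 binomial sd at n = 7200
})

test_that("trait generator encodes the configured status ratios", {
  cfg <- sim_config(seed = 58, n_pairs = 60)
  tr <- sim_traits(cfg)
  ratio_of <- function(trait) {
    hr <- dplyr::filter(tr, trait == !!trait)
    exp(mean(log(hr$value[hr$status == "listed"])) -
          mean(log(hr$value[hr$status == "nonlisted"])))
  }
  expect_equal(ratio_of("home_range"), 2, tolerance = 0.15)
  expect_equal(ratio_of("dispersal"), 0.5, tolerance = 0.1)
  expect_equal(ratio_of("litter_clutch"), 1, tolerance = 0.1)
  surv <- dplyr::filter(tr, trait == "survival")
  expect_true(all(surv$value > 0 & surv$value < 1))
})

test_that("the landscape gradient floods column by column", {
  cfg <- sim_config(seed = 59, landscape = list(
    nx = 10, ny = 6, slope_m_per_cell = 1, coastal_fraction = 0.3
  ))
  land <- sim_landscape(cfg)
  wet <- bathtub_mask(land$elevation, rise = 1)
  expect_true(all(wet[, 1:2]))   # elevations 0 and 1
  expect_false(any(wet[, 3:10])) # elevation 2 upward
  far <- matrix(FALSE, 6, 10); far[2:4, 9:10] <- TRUE
  expect_equal(percent_range_inundated(far, wet), 0)
})

test_that("generated geography couples exposure to coast distance", {
  for (seed in c(1, 2, 3)) {
    cfg <- sim_config(seed = seed, n_pairs = 10)
    land <- sim_landscape(cfg)
    wet <- bathtub_mask(land$elevation, rise = 1)
    stats <- purrr::imap_dfr(land$ranges, function(r, tx) {
      ctr <- range_centroid(r, land$elevation)
      tibble::tibble(
        pct = percent_range_inundated(r, wet),
        logd = log(max(distance_to_coast(ctr, land$coast, land$elevation), 0.5))
      )
    })
    expect_lt(cor(stats$logd, stats$pct), 0)
    listed <- grepl("listed$", names(land$ranges)) & !grepl("nonlisted$", names(land$ranges))
    expect_gt(mean(stats$pct[listed]), mean(stats$pct[!listed]) - 1e-9)
  }
})
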