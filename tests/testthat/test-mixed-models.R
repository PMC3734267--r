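test_that("a constant response yields a null chi-square", {
  d <- tibble::tibble(
    y = 3, status = rep(c("listed", "nonlisted"), 12),
    pair_id = rep(sprintf("P%02d", 1:12), each = 2)
  )
  fit <- lrt_fixed_effect(d, "y", family = "poisson")
  expect_equal(fit$chisq, 0)
  expect_equal(fit$p_value, 1)
  expect_match(fit$convergence_notes, "constant")
})

test_that("a strong status effect is detected and reported tidily", {
  cfg <- sim_config(seed = 101, status_score_shift = 1.5)
  sm <- score_modules(sim_scoresheets(cfg))
  dat <- dplyr::filter(sm, module == "vulnerability")
  fit <- lrt_fixed_effect(dat, "score", random = c("pair_id", "assessor_id"))
  expect_lt(fit$p_value, 0.001)
  td <- tidy(fit)
  expect_equal(td$statistic, fit$chisq)
  gl <- glance(fit)
  expect_equal(gl$statistic,
               2 * (gl$logLik_full - gl$logLik_reduced), tolerance = 1e-8)
  expect_error(lrt_fixed_effect(dat, "nope"), "not found")
  one_level <- dplyr::filter(dat, status == "listed")
  expect_error(lrt_fixed_effect(one_level, "score"), "2 levels")
})

test_that("poisson family runs on integer criterion scores", {
  cfg <- sim_config(seed = 103, status_score_shift = 2)
  sheets <- sim_scoresheets(cfg)
  dat <- dplyr::filter(sheets, criterion_id == "V03")
  fit <- lrt_fixed_effect(dat, "score", random = c("pair_id", "assessor_id"),
                          family = "poisson")
  expect_s3_class(fit, "sivva_lrt")
  expect_true(fit$chisq >= 0)
  expect_true(fit$p_value >= 0 && fit$p_value <= 1)
})

test_that("one trait, two balanced groups: contrast equals the mean difference", {
  set.seed(23)
  d <- tidyr::expand_grid(
    pair_id = sprintf("P%02d", 1:10), status = c("listed", "nonlisted"),
    obs = 1:3
  ) |>
    dplyr::mutate(
      taxon_id = paste(pair_id, status, sep = "_"),
      trait = "home_range",
      logit_prop = rnorm(dplyr::n()) + ifelse(status == "listed", 0.8, 0)
    )
  ct <- status_trait_contrasts(d, seed = 2)
  mean_diff <- mean(d$logit_prop[d$status == "listed"]) -
    mean(d$logit_prop[d$status == "nonlisted"])
  expect_equal(nrow(ct), 1)
  expect_equal(ct$estimate, mean_diff, tolerance = 1e-6)
})

test_that("traits with a single status level are dropped with a warning", {
  set.seed(29)
  d <- tidyr::expand_grid(
    pair_id = sprintf("P%02d", 1:8), status = c("listed", "nonlisted"), obs = 1:2
  ) |>
    dplyr::mutate(taxon_id = paste(pair_id, status, sep = "_"),
                  trait = "dispersal", logit_prop = rnorm(dplyr::n()))
  lonely <- tibble::tibble(
    pair_id = "P01", taxon_id = "P01_listed", status = "listed", obs = 1:4,
    trait = "survival", logit_prop = rnorm(4)
  )
  expect_warning(
    ct <- status_trait_contrasts(dplyr::bind_rows(d, lonely), seed = 3),
    "survival"
  )
  expect_equal(ct$trait, "dispersal")
})

test_that("contrast p-values are reproducible given the seed", {
  cfg <- sim_config(seed = 41)
  tr <- proportion_of_max(dplyr::filter(sim_traits(cfg), independent))
  tr$logit_prop <- adjusted_logit(tr$prop_max, min_nonzero(tr$prop_max))
  a <- status_trait_contrasts(tr, seed = 11)
  b <- status_trait_contrasts(tr, seed = 11)
  expect_identical(a, b)
})
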