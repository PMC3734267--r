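#' Pipeline configuration
#'
#' Options for [run_pipeline()]. The four a priori vulnerability criteria
#' (sea-level rise, habitat fragmentation, altered temperature, altered
#' precipitation) are identified by criterion ids from the scoresheet
#' template; these four tests form one FDR family, and the trait-criterion
#' correlations another.
#'
#' @param seed Integer seed for all stochastic stages.
#' @param rise Sea-level-rise increment in metres.
#' @param n_sims Monte-Carlo draws for uncertainty intervals.
#' @param n_perm Weight permutations per taxon x module.
#' @param alpha Interval level complement (0.05 for 95% CIs).
#' @param fdr_q Benjamini-Hochberg level.
#' @param require_sea_connectivity Passed to [bathtub_mask()].
#' @param a_priori Named character vector mapping hypothesis names to
#'   criterion ids (`slr` is tested on percent inundation, not a criterion
#'   score, but keeps its id for Table-2 categorisation).
#' @return A list of class `sivva_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, rise = 1, n_sims = 1000, n_perm = 1000,
                            alpha = 0.05, fdr_q = 0.05,
                            require_sea_connectivity = FALSE,
                            a_priori = c(slr = "V01", fragmentation = "V03",
                                         temperature = "V04",
                                         precipitation = "V05")) {
  stopifnot(
    rise >= 0, n_sims >= 1, n_perm >= 1,
    alpha > 0, alpha < 1, fdr_q > 0, fdr_q < 1,
    all(c("slr", "fragmentation", "temperature", "precipitation") %in%
          names(a_priori))
  )
  structure(
    list(seed = seed, rise = rise, n_sims = n_sims, n_perm = n_perm,
         alpha = alpha, fdr_q = fdr_q,
         require_sea_connectivity = require_sea_connectivity,
         a_priori = a_priori),
    class = "sivva_pipeline_config"
  )
}

#' Run the full vulnerability-assessment analysis
#'
#' Orchestrates every stage on conforming inputs: (1) assessor combination
#' and module scoring with Monte-Carlo uncertainty intervals; (2)
#' within-pair module-score differences from interval overlap; (3) sea-level
#' rise exposure (bathtub inundation, percent of range lost, distance to
#' coast); (4) likelihood-ratio tests of listing status on each module score
#' (Gaussian mixed models with pair and assessor random intercepts) and on
#' the four a priori vulnerability criteria (Poisson models on criterion
#' scores; Gaussian on adjusted-logit percent inundation for sea-level
#' rise), BH-FDR corrected as one family; (5) trait normalisation
#' (proportion of pair maximum, adjusted logit), the global mixed-model
#' trait contrasts, and per-pair exact rank-sum tests where both taxa have
#' at least `min_obs` independent observations; (6) trait and
#' distance-to-coast correlations with module scores, FDR-corrected as a
#' second family; (7) the Table-2-style category table.
#'
#' @param scoresheets Scoresheet tibble with `pair_id` and `status`.
#' @param traits Trait tibble (see [read_trait_table()]).
#' @param landscape List with `elevation`, `coast`, `ranges` as produced by
#'   [sim_landscape()] (ranges named by taxon_id).
#' @param config A [pipeline_config()].
#' @param min_obs Minimum independent observations per taxon for a
#'   within-pair rank test (default 3).
#' @return A list of class `sivva_report`; see the elements described
#'   above, each a tibble.
#' @export
run_pipeline <- function(scoresheets, traits, landscape,
                         config = pipeline_config(), min_obs = 3) {
  stopifnot(inherits(config, "sivva_pipeline_config"))
  scoresheets <- validate_scoresheet(scoresheets)
  if (!all(c("pair_id", "status") %in% names(scoresheets))) {
    abort("`scoresheets` needs `pair_id` and `status` columns for the pipeline.")
  }
  traits <- validate_trait_table(traits)
  unpaired <- scoresheets |>
    dplyr::distinct(.data$pair_id, .data$status) |>
    dplyr::count(.data$pair_id) |>
    dplyr::filter(.data$n != 2)
  if (nrow(unpaired) > 0) {
    abort(paste0(
      "Every pair needs a listed and a nonlisted member; offending pair(s): ",
      paste(unpaired$pair_id, collapse = ", ")
    ))
  }

  # -- module scores, uncertainty intervals, pairwise differences ----------
  combined <- combine_assessors(scoresheets)
  ci <- mc_uncertainty_ci(combined, n_sims = config$n_sims,
                          alpha = config$alpha, seed = config$seed)
  pairwise <- pairwise_ci_differences(ci)

  # -- weight-permutation sensitivity --------------------------------------
  perm_summary <- combined |>
    dplyr::distinct(.data$taxon_id) |>
    dplyr::pull(.data$taxon_id) |>
    purrr::map_dfr(function(tx) {
      sheet <- dplyr::filter(combined, .data$taxon_id == tx)
      purrr::map_dfr(unique(sheet$module), function(m) {
        wp <- permute_weights(sheet, m, n_perm = config$n_perm,
                              seed = config$seed)
        tibble::tibble(
          taxon_id = tx, module = m, observed = wp$observed,
          perm_q025 = wp$quantiles[[1]], perm_median = wp$quantiles[[2]],
          perm_q975 = wp$quantiles[[3]], n_perm = wp$n_perm
        )
      })
    })

  # -- sea-level-rise exposure ---------------------------------------------
  exposure <- exposure_metrics(
    landscape$elevation, landscape$ranges, landscape$coast,
    rise = config$rise,
    require_sea_connectivity = config$require_sea_connectivity
  ) |>
    dplyr::left_join(
      dplyr::distinct(scoresheets, .data$taxon_id, .data$pair_id, .data$status),
      by = "taxon_id"
    )

  # -- status tests: module scores and a priori criteria -------------------
  per_assessor <- score_modules(scoresheets)
  module_tests <- purrr::map_dfr(SIVVA_MODULES, function(m) {
    dat <- dplyr::filter(per_assessor, .data$module == m)
    fit <- lrt_fixed_effect(dat, response = "score", fixed = "status",
                            random = c("pair_id", "assessor_id"),
                            family = "gaussian")
    dplyr::mutate(tidy(fit), response = m, .keep = "all")
  })

  crit <- config$a_priori
  crit_scores <- scoresheets |>
    dplyr::filter(.data$criterion_id %in% crit[c("fragmentation", "temperature",
                                                 "precipitation")])
  crit_tests <- purrr::map_dfr(
    c("fragmentation", "temperature", "precipitation"),
    function(h) {
      dat <- dplyr::filter(crit_scores, .data$criterion_id == crit[[h]])
      fit <- lrt_fixed_effect(dat, response = "score", fixed = "status",
                              random = c("pair_id", "assessor_id"),
                              family = "poisson")
      dplyr::mutate(tidy(fit), response = h)
    }
  )
  slr_dat <- exposure |>
    dplyr::mutate(prop = pmin(pmax(.data$pct_inundated / 100, 0), 1))
  eps_slr <- if (any(slr_dat$prop > 0)) min_nonzero(slr_dat$prop) else 0.5
  slr_dat$logit_prop <- log((slr_dat$prop + eps_slr) /
                              (1 - slr_dat$prop + eps_slr))
  slr_fit <- lrt_fixed_effect(slr_dat, response = "logit_prop",
                              fixed = "status", random = "pair_id",
                              family = "gaussian")
  a_priori_tests <- dplyr::bind_rows(
    dplyr::mutate(tidy(slr_fit), response = "slr"),
    crit_tests
  )
  a_priori_tests <- dplyr::bind_cols(
    a_priori_tests,
    bh_fdr(a_priori_tests$p_value, q = config$fdr_q)[, c("p_adjusted", "reject")]
  )

  # -- trait analyses ------------------------------------------------------
  indep <- dplyr::filter(traits, .data$independent)
  trait_norm <- proportion_of_max(indep)
  eps <- min_nonzero(trait_norm$prop_max)
  trait_norm$logit_prop <- adjusted_logit(trait_norm$prop_max, eps)
  contrasts <- status_trait_contrasts(trait_norm, response = "logit_prop",
                                      seed = config$seed)
  pair_tests <- trait_norm |>
    dplyr::group_by(.data$pair_id, .data$trait) |>
    dplyr::group_modify(function(d, key) {
      x <- d$value[d$status == "listed"]
      y <- d$value[d$status == "nonlisted"]
      if (length(x) < min_obs || length(y) < min_obs) {
        return(tibble::tibble())
      }
      exact_rank_sum(x, y, sided = "one")
    }) |>
    dplyr::ungroup()

  # -- correlations (traits and geography vs scores) -----------------------
  taxon_traits <- trait_norm |>
    dplyr::group_by(.data$taxon_id, .data$trait) |>
    dplyr::summarise(mean_logit = mean(.data$logit_prop), .groups = "drop")
  vuln_scores <- ci |>
    dplyr::select(dplyr::all_of(c("taxon_id", "module", "point"))) |>
    tidyr::pivot_wider(names_from = "module", values_from = "point")
  corr_dat <- dplyr::inner_join(taxon_traits, vuln_scores, by = "taxon_id")
  correlations <- purrr::map_dfr(
    intersect(unique(corr_dat$trait), TRAIT_LEVELS),
    function(tr) {
      d <- dplyr::filter(corr_dat, .data$trait == tr)
      purrr::map_dfr(c("vulnerability", "adaptive_capacity"), function(m) {
        if (nrow(d) < 3 || sd(d$mean_logit) == 0 || sd(d[[m]]) == 0) {
          return(tibble::tibble())
        }
        dplyr::mutate(pearson_r(d$mean_logit, d[[m]]),
                      trait = tr, score = m, .before = 1)
      })
    }
  )
  geo <- exposure |>
    dplyr::inner_join(vuln_scores, by = "taxon_id")
  geo_correlations <- dplyr::bind_rows(
    dplyr::mutate(
      pearson_r(geo$log_dist_coast, geo$vulnerability),
      trait = "log_dist_coast", score = "vulnerability", .before = 1
    ),
    dplyr::mutate(
      pearson_r(geo$log_dist_coast, geo$pct_inundated),
      trait = "log_dist_coast", score = "pct_inundated", .before = 1
    )
  )
  correlations <- dplyr::bind_rows(correlations, geo_correlations)
  if (nrow(correlations) > 0) {
    correlations <- dplyr::bind_cols(
      correlations,
      bh_fdr(correlations$p_value, q = config$fdr_q)[, c("p_adjusted", "reject")]
    )
  }

  # mean vs maximum dispersal across taxa (untransformed)
  disp <- indep |>
    dplyr::filter(.data$trait == "dispersal") |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(mean_disp = mean(.data$value),
                     max_disp = max(.data$value), .groups = "drop")
  dispersal_cor <- if (nrow(disp) >= 3 && sd(disp$mean_disp) > 0) {
    spearman_rho(disp$mean_disp, disp$max_disp)
  } else {
    tibble::tibble()
  }

  # -- Table-2-style categories --------------------------------------------
  table2 <- make_table2(
    combined, exposure,
    criteria = crit[c("fragmentation", "temperature", "precipitation")]
  )

  structure(
    list(
      module_scores = ci,
      pairwise_differences = pairwise,
      weight_permutations = perm_summary,
      exposure = exposure,
      module_tests = module_tests,
      a_priori_tests = a_priori_tests,
      trait_contrasts = contrasts,
      pair_trait_tests = pair_tests,
      correlations = correlations,
      dispersal_cor = dispersal_cor,
      table2 = table2,
      config = config
    ),
    class = "sivva_report"
  )
}

#' Table-2-style vulnerability category table
#'
#' One row per listed taxon: sea-level-rise vulnerability categorised from
#' percent of range inundated, and fragmentation / temperature /
#' precipitation vulnerability categorised from the assessor-combined
#' criterion scores. Criterion scores below 3 indicate a beneficial
#' response and are labelled `"Positive"`; a missing criterion yields `NA`
#' with a warning.
#'
#' @param combined Assessor-combined scoresheet tibble.
#' @param exposure Exposure tibble from [exposure_metrics()] (needs
#'   `taxon_id`, `pct_inundated`; rows with `status == "listed"` are kept if
#'   a `status` column is present).
#' @param criteria Named ids: `fragmentation`, `temperature`,
#'   `precipitation`.
#' @return Tibble: `taxon_id`, `slr`, `fragmentation`, `temperature`,
#'   `precipitation`.
#' @export
make_table2 <- function(combined, exposure,
                        criteria = c(fragmentation = "V03",
                                     temperature = "V04",
                                     precipitation = "V05")) {
  combined <- validate_scoresheet(combined)
  if ("status" %in% names(exposure)) {
    exposure <- dplyr::filter(exposure, .data$status == "listed")
  }
  categorise <- function(score) {
    out <- rep(NA_character_, length(score))
    pos <- !is.na(score) & score < 3
    out[pos] <- "Positive"
    rest <- !is.na(score) & score >= 3
    out[rest] <- criterion_category(score[rest])
    out
  }
  crit_tbl <- purrr::imap_dfr(as.list(criteria), function(id, hyp) {
    rows <- dplyr::filter(
      combined, .data$criterion_id == id,
      .data$taxon_id %in% exposure$taxon_id
    )
    miss <- setdiff(exposure$taxon_id, rows$taxon_id)
    if (length(miss) > 0) {
      warn(paste0("Criterion ", id, " missing for: ", paste(miss, collapse = ", ")))
    }
    tibble::tibble(
      taxon_id = exposure$taxon_id,
      hypothesis = hyp,
      category = categorise(rows$score[match(exposure$taxon_id, rows$taxon_id)])
    )
  })
  crit_wide <- tidyr::pivot_wider(crit_tbl, names_from = "hypothesis",
                                  values_from = "category")
  exposure |>
    dplyr::transmute(taxon_id = .data$taxon_id,
                     slr = slr_category(.data$pct_inundated)) |>
    dplyr::left_join(crit_wide, by = "taxon_id")
}

#' @exportS3Method base::print
print.sivva_report <- function(x, ...) {
  cat("<sivva_report>\n")
  cat(sprintf("  taxa: %d; modules scored with %d MC draws (alpha = %g)\n",
              length(unique(x$module_scores$taxon_id)),
              x$config$n_sims, x$config$alpha))
  ndiff <- sum(x$pairwise_differences$different)
  cat(sprintf("  pairwise module differences flagged: %d of %d\n",
              ndiff, nrow(x$pairwise_differences)))
  cat(sprintf("  a priori status tests rejected (BH q = %g): %s\n",
              x$config$fdr_q,
              paste(x$a_priori_tests$response[x$a_priori_tests$reject],
                    collapse = ", ")))
  sig <- x$trait_contrasts$trait[x$trait_contrasts$p_adjusted < 0.05]
  cat(sprintf("  trait contrasts significant at 0.05: %s\n",
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}

#' Write every report table to CSV
#'
#' @param report A `sivva_report`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sivva_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- report[vapply(report, is.data.frame, logical(1))]
  purrr::iwalk(tabs, function(tab, name) {
    readr::write_csv(tab, file.path(dir, paste0(name, ".csv")))
  })
  invisible(dir)
}
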