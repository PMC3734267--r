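#' Weighted SIVVA module summary score
#'
#' The module summary score is the total number of weighted points earned
#' divided by the total number of weighted points possible: with criterion
#' scores \eqn{s_i \in \{0\} \cup [1,6]} and weights \eqn{w_i \ge 0},
#' \deqn{S = \sum_i w_i s_i / \sum_i 6 w_i,}
#' the sums running over criteria with \eqn{s_i \ge 1}. A score of 0 means
#' "insufficient information" and is excluded from both numerator and
#' denominator, so missing knowledge neither raises nor lowers the summary.
#' When every criterion is scored the result lies in [1/6, 1].
#'
#' @param score Numeric vector of criterion scores (0 or in [1, 6]).
#' @param weight Numeric vector of non-negative weights (recycled if length 1).
#' @return A single number in [0, 1].
#' @export
#' @examples
#' module_score(c(6, 2, 4), c(2, 1, 1)) # 0.75
#' module_score(c(5, 0, 3))             # zero-scored criterion dropped: 8/12
module_score <- function(score, weight = 1) {
  if (length(score) == 0) abort("At least one criterion score is required.")
  weight <- rep_len(weight, length(score))
  validate_weights(weight)
  if (any(!is.finite(score)) || any(score < 0 | score > 6) || any(score > 0 & score < 1)) {
    abort("Scores must be 0 (insufficient information) or lie in [1, 6].")
  }
  keep <- score >= 1 & weight > 0
  if (!any(keep)) {
    abort("No information: every criterion is scored 0 or has zero weight.")
  }
  sum(weight[keep] * score[keep]) / sum(weight[keep] * 6)
}

#' Module summary scores for every taxon in a scoresheet table
#'
#' Applies [module_score()] per taxon x assessor x module.
#'
#' @param sheets Scoresheet tibble (see [validate_scoresheet()]).
#' @return A tibble with one row per taxon x assessor x module and a `score`
#'   column in [0, 1]; `status` and `pair_id` are carried through if present.
#' @export
score_modules <- function(sheets) {
  sheets <- validate_scoresheet(sheets)
  keep <- intersect(c("status", "pair_id"), names(sheets))
  sheets |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("taxon_id", "assessor_id", keep, "module")
    ))) |>
    dplyr::summarise(score = module_score(.data$score, .data$weight),
                     .groups = "drop")
}

# Simulate the module-score distribution under the +/-1 uncertainty model for
# one taxon x module. Flagged criteria receive independent perturbations drawn
# uniformly from {-1, 0, +1}, clipped to [1, 6]; unflagged criteria are fixed.
# Zero-scored criteria are never flagged (validated upstream), so the set of
# excluded criteria -- and hence the denominator -- is constant across draws.
simulate_module_scores <- function(score, weight, uncertain, n_sims) {
  keep <- score >= 1 & weight > 0
  s <- score[keep]; w <- weight[keep]; u <- uncertain[keep]
  denom <- sum(w * 6)
  base_num <- sum(w[!u] * s[!u])
  n_flag <- sum(u)
  if (n_flag == 0) {
    return(rep(sum(w * s) / denom, n_sims))
  }
  delta <- matrix(
    sample(c(-1, 0, 1), n_sims * n_flag, replace = TRUE),
    nrow = n_sims
  )
  perturbed <- sweep(delta, 2, s[u], "+")
  perturbed <- pmin(pmax(perturbed, 1), 6)
  (base_num + as.vector(perturbed %*% w[u])) / denom
}

#' Monte-Carlo uncertainty intervals around module scores
#'
#' Assessors mark low-confidence criteria with an uncertainty flag. To
#' propagate that uncertainty, each simulation adds an independent
#' perturbation of -1, 0 or +1 (equiprobable) to every flagged criterion's
#' score, clips the result to the 1-6 scale, and recomputes the module
#' summary score; the percentile interval of the simulated scores is the
#' reported confidence interval. Unflagged criteria never move, so a sheet
#' with no flags yields a degenerate interval equal to the point estimate.
#'
#' Percentiles use type-7 linear interpolation ([stats::quantile()]'s
#' default). Results are reproducible given `seed`.
#'
#' @param sheets Scoresheet tibble; typically one assessor per taxon (see
#'   [combine_assessors()]), but any table validated by
#'   [validate_scoresheet()] works, producing one row per taxon x assessor x
#'   module.
#' @param n_sims Number of Monte-Carlo draws (default 1000).
#' @param alpha Two-sided interval level complement (default 0.05 for 95% CI).
#' @param seed Integer seed.
#' @return A tibble with columns `taxon_id`, `assessor_id`, (`status`,
#'   `pair_id` if present), `module`, `point`, `ci_low`, `ci_high`,
#'   `n_sims`, `alpha`.
#' @export
mc_uncertainty_ci <- function(sheets, n_sims = 1000, alpha = 0.05, seed = 1) {
  if (n_sims < 1) abort("`n_sims` must be at least 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  sheets <- validate_scoresheet(sheets)
  keep <- intersect(c("status", "pair_id"), names(sheets))
  withr::with_seed(seed, {
    sheets |>
      dplyr::group_by(dplyr::across(dplyr::all_of(
        c("taxon_id", "assessor_id", keep, "module")
      ))) |>
      dplyr::summarise(
        res = list({
          point <- module_score(.data$score, .data$weight)
          sims <- simulate_module_scores(
            .data$score, .data$weight, .data$uncertain, n_sims
          )
          qs <- quantile(sims, c(alpha / 2, 1 - alpha / 2), names = FALSE)
          tibble::tibble(point = point, ci_low = qs[1], ci_high = qs[2])
        }),
        .groups = "drop"
      ) |>
      tidyr::unnest("res") |>
      dplyr::mutate(n_sims = n_sims, alpha = alpha)
  })
}

# All permutations of 1..n (n <= 8 guard; 8! = 40320 rows).
all_permutations <- function(n) {
  if (n > 8) abort("Exhaustive permutation limited to 8 criteria.")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Weight-permutation sensitivity of a module score
#'
#' To ask how much a module score owes to the weighting scheme, the weights
#' are randomly permuted across that module's criteria `n_perm` times
#' (default 1000) and the module score recomputed for each permutation. A
#' score that barely moves under permutation is insensitive to the scheme.
#' With equal weights every permutation reproduces the observed score
#' exactly.
#'
#' @param sheets Scoresheet tibble restricted to one taxon x assessor.
#' @param module One of the four SIVVA modules.
#' @param n_perm Number of random permutations.
#' @param seed Integer seed.
#' @param exhaustive If `TRUE`, enumerate all permutations instead of
#'   sampling (modules of at most 8 criteria).
#' @return A list of class `sivva_weight_perm` with elements `taxon_id`,
#'   `module`, `observed`, `permuted` (numeric vector), `n_perm`, and
#'   `quantiles` (2.5/50/97.5 percentiles of the permuted scores).
#' @export
permute_weights <- function(sheets, module, n_perm = 1000, seed = 1,
                            exhaustive = FALSE) {
  sheets <- validate_scoresheet(sheets)
  if (length(unique(sheets$taxon_id)) != 1 ||
      length(unique(sheets$assessor_id)) != 1) {
    abort("`sheets` must hold exactly one taxon x assessor sheet.")
  }
  rows <- sheets[sheets$module == module, ]
  if (sum(rows$weight > 0) < 2) {
    abort("Weight permutation needs at least 2 weighted criteria in the module.")
  }
  if (!exhaustive && n_perm < 1) abort("`n_perm` must be at least 1.")
  s <- rows$score
  w <- rows$weight
  observed <- module_score(s, w)
  perm_idx <- if (exhaustive) {
    all_permutations(length(w))
  } else {
    withr::with_seed(seed, t(replicate(n_perm, sample.int(length(w)))))
  }
  permuted <- apply(perm_idx, 1, function(idx) module_score(s, w[idx]))
  structure(
    list(
      taxon_id = rows$taxon_id[1], module = module,
      observed = observed, permuted = permuted, n_perm = length(permuted),
      quantiles = quantile(permuted, c(0.025, 0.5, 0.975))
    ),
    class = "sivva_weight_perm"
  )
}

#' @exportS3Method base::print
print.sivva_weight_perm <- function(x, ...) {
  cat(sprintf(
    "Weight permutation: %s / %s\n  observed %.4f; permuted median %.4f [%.4f, %.4f] (n = %d)\n",
    x$taxon_id, x$module, x$observed, x$quantiles[[2]],
    x$quantiles[[1]], x$quantiles[[3]], x$n_perm
  ))
  invisible(x)
}

#' Are two confidence intervals disjoint?
#'
#' Pairwise differences between taxa are called significant when their
#' module-score confidence intervals do not overlap. Intervals that merely
#' touch at an endpoint are conservatively treated as overlapping (not
#' different). Vectorized over all arguments.
#'
#' @param lo1,hi1,lo2,hi2 Interval bounds.
#' @return Logical vector: `TRUE` where the intervals are disjoint.
#' @export
#' @examples
#' ci_disjoint(0.2, 0.3, 0.5, 0.6) # TRUE
#' ci_disjoint(0.2, 0.4, 0.4, 0.6) # FALSE: shared endpoint overlaps
ci_disjoint <- function(lo1, hi1, lo2, hi2) {
  if (any(lo1 > hi1) || any(lo2 > hi2)) abort("Interval bounds out of order.")
  hi1 < lo2 | hi2 < lo1
}

#' Within-pair module-score differences from MC intervals
#'
#' Joins the listed and non-listed member of each taxon-pair and flags the
#' pair x module combinations whose confidence intervals are disjoint.
#'
#' @param ci A tibble from [mc_uncertainty_ci()] including `pair_id` and
#'   `status` columns (`status` in `listed`/`nonlisted`).
#' @return A tibble with one row per pair x module: point estimates and
#'   interval bounds for both members plus a logical `different`.
#' @export
pairwise_ci_differences <- function(ci) {
  needed <- c("pair_id", "status", "module", "point", "ci_low", "ci_high")
  missing <- setdiff(needed, names(ci))
  if (length(missing) > 0) {
    abort(paste0("`ci` is missing columns: ", paste(missing, collapse = ", ")))
  }
  listed <- dplyr::filter(ci, .data$status == "listed")
  nonlisted <- dplyr::filter(ci, .data$status == "nonlisted")
  out <- dplyr::inner_join(
    listed, nonlisted,
    by = c("pair_id", "module"), suffix = c("_listed", "_nonlisted")
  )
  unmatched <- setdiff(
    unique(ci$pair_id),
    unique(out$pair_id)
  )
  if (length(unmatched) > 0) {
    warn(paste0("Unpaired pair_id(s) dropped: ", paste(unmatched, collapse = ", ")))
  }
  out |>
    dplyr::mutate(different = ci_disjoint(
      .data$ci_low_listed, .data$ci_high_listed,
      .data$ci_low_nonlisted, .data$ci_high_nonlisted
    )) |>
    dplyr::select(dplyr::all_of(c(
      "pair_id", "module",
      "point_listed", "ci_low_listed", "ci_high_listed",
      "point_nonlisted", "ci_low_nonlisted", "ci_high_nonlisted",
      "different"
    )))
}
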