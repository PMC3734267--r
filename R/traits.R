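#' Read a trait-record table
#'
#' Literature-derived ecological trait observations, one row per independent
#' observation: columns `pair_id`, `taxon_id`, `status` (`listed` /
#' `nonlisted`), `trait` (`litter_clutch`, `home_range`, `dispersal`,
#' `survival`), `value` (positive, harmonized units within each pair x
#' trait), `unit`, `source_id`, `independent` (logical). Non-independent
#' records (overlapping individuals, sites or periods) are kept on read but
#' filtered out by the analysis functions.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_trait_table <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  validate_trait_table(tr)
}

TRAIT_LEVELS <- c("litter_clutch", "home_range", "dispersal", "survival")

#' @rdname read_trait_table
#' @param traits Data frame of trait records.
#' @export
validate_trait_table <- function(traits) {
  traits <- tibble::as_tibble(traits)
  needed <- c("pair_id", "taxon_id", "status", "trait", "value", "independent")
  missing <- setdiff(needed, names(traits))
  if (length(missing) > 0) {
    abort(paste0("Trait table is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(!traits$status %in% c("listed", "nonlisted"))) {
    abort("`status` must be 'listed' or 'nonlisted'.")
  }
  if (any(!traits$trait %in% TRAIT_LEVELS)) {
    abort(paste0("`trait` must be one of: ", paste(TRAIT_LEVELS, collapse = ", ")))
  }
  if (any(!is.finite(traits$value)) || any(traits$value <= 0)) {
    abort("Trait values must be positive (survival as a proportion in (0, 1]).")
  }
  surv <- traits$value[traits$trait == "survival"]
  if (any(surv > 1)) abort("Survival values must lie in (0, 1].")
  traits
}

#' Scale trait values to proportions of the pair-wise maximum
#'
#' Literature trait values differ in scale across taxon-pairs (a panther
#' home range and a beach-mouse home range are not comparable in km^2). To
#' pool pairs, each value is divided by the maximum value within its
#' `pair_id` x `trait` cell, so every cell's maximum maps to exactly 1 and
#' relative order within the cell is preserved. The scaling is invariant to
#' the unit the cell was recorded in.
#'
#' @param traits Trait tibble (see [read_trait_table()]).
#' @return The tibble with a new `prop_max` column.
#' @export
proportion_of_max <- function(traits) {
  traits <- validate_trait_table(traits)
  traits |>
    dplyr::group_by(.data$pair_id, .data$trait) |>
    dplyr::mutate(prop_max = .data$value / max(.data$value)) |>
    dplyr::ungroup()
}

#' Adjusted logit for proportions that reach 1
#'
#' The ordinary logit is infinite at p = 1. Following the standard
#' correction for proportion data, the minimum non-zero proportion in the
#' analysis data set (`eps`) is added to both numerator and denominator:
#' \deqn{\mathrm{logit}^*(p) = \ln\frac{p + \varepsilon}{1 - p + \varepsilon}.}
#' The transform is strictly increasing and finite on (0, 1], and maps
#' p = 0.5 to 0 for every `eps`.
#'
#' @param p Proportions in (0, 1].
#' @param eps Positive correction; by convention the minimum non-zero
#'   proportion over the whole data set being analysed (see
#'   [min_nonzero()]).
#' @return Numeric vector of adjusted logits.
#' @export
#' @examples
#' adjusted_logit(1, eps = 0.25) # log(5)
#' adjusted_logit(0.5, eps = 0.1) # 0
adjusted_logit <- function(p, eps) {
  if (!is.numeric(eps) || length(eps) != 1 || !is.finite(eps) || eps <= 0) {
    abort("`eps` must be a single positive number.")
  }
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    abort("`p` must lie in (0, 1].")
  }
  log((p + eps) / (1 - p + eps))
}

#' @rdname adjusted_logit
#' @param x Numeric vector.
#' @export
min_nonzero <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) == 0) abort("No positive values to take the minimum of.")
  min(x)
}
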