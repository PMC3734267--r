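#' Default 30-criterion scoresheet template
#'
#' SIVVA assessments score each taxon on 30 criteria split across four
#' modules: vulnerability (10 criteria), adaptive capacity (8), conservation
#' value (7), and information availability (5). The criterion texts are part
#' of the elicitation protocol, not of this package; here each criterion is
#' identified by a short id and a free-text `label` that users replace with
#' their own protocol wording. Weights default to 1 (equal weighting) and can
#' be overridden per criterion.
#'
#' The first vulnerability criterion (`V01`) is conventionally the
#' sea-level-rise criterion; `V03`, `V04` and `V05` are the habitat
#' fragmentation, altered temperature and altered precipitation criteria used
#' by the a priori hypothesis tests in [run_pipeline()].
#'
#' @param weights Optional named numeric vector of weights keyed by
#'   `criterion_id`; unnamed criteria keep weight 1.
#' @return A tibble with columns `criterion_id`, `module`, `label`, `weight`.
#' @export
#' @examples
#' criterion_template()
#' criterion_template(weights = c(V01 = 2, V03 = 1.5))
criterion_template <- function(weights = NULL) {
  n_per_module <- c(
    vulnerability = 10L, adaptive_capacity = 8L,
    conservation_value = 7L, information_availability = 5L
  )
  prefix <- c(
    vulnerability = "V", adaptive_capacity = "A",
    conservation_value = "C", information_availability = "I"
  )
  tmpl <- purrr::map_dfr(names(n_per_module), function(m) {
    n <- n_per_module[[m]]
    tibble::tibble(
      criterion_id = sprintf("%s%02d", prefix[[m]], seq_len(n)),
      module = m,
      label = sprintf("%s criterion %d (replace with protocol text)", m, seq_len(n)),
      weight = 1
    )
  })
  if (!is.null(weights)) {
    if (is.null(names(weights)) || any(!names(weights) %in% tmpl$criterion_id)) {
      abort("`weights` must be named by criterion_id from the template.")
    }
    idx <- match(names(weights), tmpl$criterion_id)
    tmpl$weight[idx] <- unname(weights)
  }
  validate_weights(tmpl$weight)
  tmpl
}

validate_weights <- function(w) {
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("Criterion weights must be finite and non-negative.")
  }
  invisible(w)
}

#' Validate a scoresheet table
#'
#' Checks the tidy scoresheet layout used throughout the package: one row per
#' taxon x assessor x criterion with columns `taxon_id`, `assessor_id`,
#' `status`, `module`, `criterion_id`, `score`, `uncertain`, `weight`
#' (optionally `pair_id`). Scores must be 0 (insufficient information) or lie
#' in [1, 6]; a flagged (`uncertain`) criterion must carry a score of at
#' least 1, since an unscored criterion has no value to perturb.
#'
#' @param sheets A data frame of scoresheet rows.
#' @return The input as a tibble, invisibly validated.
#' @export
validate_scoresheet <- function(sheets) {
  sheets <- tibble::as_tibble(sheets)
  needed <- c("taxon_id", "assessor_id", "module", "criterion_id",
              "score", "uncertain", "weight")
  missing <- setdiff(needed, names(sheets))
  if (length(missing) > 0) {
    abort(paste0("Scoresheet is missing columns: ", paste(missing, collapse = ", ")))
  }
  bad_mod <- setdiff(unique(sheets$module), SIVVA_MODULES)
  if (length(bad_mod) > 0) {
    abort(paste0("Unknown module(s): ", paste(bad_mod, collapse = ", ")))
  }
  s <- sheets$score
  if (any(!is.finite(s)) || any(s < 0 | s > 6) || any(s > 0 & s < 1)) {
    abort("Scores must be 0 (insufficient information) or lie in [1, 6].")
  }
  validate_weights(sheets$weight)
  if (any(sheets$uncertain & sheets$score == 0)) {
    abort("A criterion flagged uncertain must have a score of at least 1.")
  }
  dup <- sheets |>
    dplyr::count(.data$taxon_id, .data$assessor_id, .data$criterion_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("Duplicated criterion_id within a taxon x assessor sheet.")
  }
  sheets
}

#' Read and write scoresheet CSV files
#'
#' The on-disk format is the tidy layout checked by [validate_scoresheet()]:
#' `taxon_id,assessor_id,status,module,criterion_id,score,uncertain,weight`.
#'
#' @param path File path.
#' @param sheets Scoresheet tibble to write.
#' @return `read_scoresheets()` returns a validated tibble.
#' @export
read_scoresheets <- function(path) {
  sheets <- readr::read_csv(path, show_col_types = FALSE)
  validate_scoresheet(sheets)
}

#' @rdname read_scoresheets
#' @export
write_scoresheets <- function(sheets, path) {
  readr::write_csv(validate_scoresheet(sheets), path)
  invisible(path)
}

#' Combine two assessors' sheets into one per-taxon sheet
#'
#' Each taxon is assessed independently by (typically two) experts. For a
#' single per-taxon score the assessors' criterion scores are averaged, with
#' zeros excluded pairwise: a 0 means "insufficient information", so when one
#' assessor scored 0 the other assessor's score is used alone, and the
#' combined score is 0 only when every assessor scored 0. The uncertainty
#' flag is the union of the assessors' flags. Weights must agree across
#' assessors (they come from the weighting scheme, not the assessor).
#'
#' With `strategy = "keep_separate"` the input is validated and returned
#' unchanged, for analyses that treat assessor as a random effect instead.
#'
#' @param sheets Scoresheet tibble (any number of taxa, >= 1 assessor each).
#' @param strategy Either `"mean"` (default) or `"keep_separate"`.
#' @return A scoresheet tibble with one synthetic assessor `"combined"` per
#'   taxon (for `"mean"`), carrying `status` and `pair_id` columns through.
#' @export
combine_assessors <- function(sheets, strategy = c("mean", "keep_separate")) {
  strategy <- match.arg(strategy)
  sheets <- validate_scoresheet(sheets)
  if (strategy == "keep_separate") {
    return(sheets)
  }
  per_taxon_sets <- sheets |>
    dplyr::group_by(.data$taxon_id, .data$assessor_id) |>
    dplyr::summarise(set = paste(sort(.data$criterion_id), collapse = "|"),
                     .groups = "drop") |>
    dplyr::distinct(.data$taxon_id, .data$set)
  if (any(duplicated(per_taxon_sets$taxon_id))) {
    abort("Assessors for the same taxon cover different criterion sets.")
  }
  keep <- intersect(c("status", "pair_id"), names(sheets))
  grp_cols <- c("taxon_id", keep, "module", "criterion_id")
  out <- sheets |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(
      score = if (all(.data$score == 0)) 0 else mean(.data$score[.data$score > 0]),
      uncertain = any(.data$uncertain),
      weight = {
        if (length(unique(.data$weight)) > 1) {
          abort("Assessors disagree on criterion weights; weights are per-scheme.")
        }
        .data$weight[1]
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(assessor_id = "combined", .after = "taxon_id")
  validate_scoresheet(out)
}
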