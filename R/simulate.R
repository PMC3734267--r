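#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults encode
#' the study design the package is built around: 12 taxon-pairs (one
#' federally listed subspecies matched with a non-listed subspecies of the
#' same parent species), each taxon scored by the same two assessors on the
#' 30-criterion template, listed taxa scoring higher by
#' `status_score_shift` points on average, roughly a third of criteria
#' flagged uncertain, lognormal trait values with listed home ranges twice
#' as large and listed dispersal half as far, and a coastal-gradient
#' landscape with listed ranges placed nearer the coast.
#'
#' @param seed Integer seed; all generators are byte-reproducible given it.
#' @param n_pairs Number of taxon-pairs.
#' @param n_assessors Assessors per taxon (shared across taxa).
#' @param baseline_score Mean criterion score before effects (0-6 scale).
#' @param status_score_shift Additive criterion-score elevation for listed
#'   taxa (scores clipped to [1, 6] after rounding).
#' @param flag_prob Probability a criterion is flagged uncertain.
#' @param pair_sd,assessor_sd,residual_sd Standard deviations of the pair
#'   and assessor random intercepts and the residual criterion noise, on the
#'   score scale.
#' @param trait_effects Named multiplicative listed/nonlisted ratios per
#'   trait.
#' @param trait_pair_sd,trait_residual_sd Lognormal-scale standard
#'   deviations of the pair intercept and the observation noise for traits.
#' @param n_obs_per_taxon_trait Literature observations per taxon x trait.
#' @param non_independent_prob Probability an observation is marked
#'   non-independent (exercises the analysis-side filter).
#' @param landscape List: grid size `nx`, `ny`, inland elevation gain
#'   `slope_m_per_cell`, and `coastal_fraction` — the western fraction of
#'   the grid within which listed range centres are placed.
#' @return A list of class `sivva_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_pairs = 12,
                       n_assessors = 2,
                       baseline_score = 3.5,
                       status_score_shift = 1.5,
                       flag_prob = 0.3,
                       pair_sd = 0.4,
                       assessor_sd = 0.25,
                       residual_sd = 0.5,
                       trait_effects = c(litter_clutch = 1, home_range = 2,
                                         dispersal = 0.5, survival = 1),
                       trait_pair_sd = 0.5,
                       trait_residual_sd = 0.35,
                       n_obs_per_taxon_trait = 5,
                       non_independent_prob = 0.1,
                       landscape = list(nx = 60, ny = 40,
                                        slope_m_per_cell = 0.25,
                                        coastal_fraction = 0.3)) {
  stopifnot(
    n_pairs >= 1, n_assessors >= 1,
    flag_prob >= 0, flag_prob <= 1,
    pair_sd > 0, assessor_sd > 0, residual_sd > 0,
    trait_pair_sd > 0, trait_residual_sd > 0,
    all(trait_effects > 0),
    non_independent_prob >= 0, non_independent_prob <= 1,
    landscape$nx >= 5, landscape$ny >= 5, landscape$slope_m_per_cell > 0
  )
  structure(
    list(
      seed = seed, n_pairs = n_pairs, n_assessors = n_assessors,
      baseline_score = baseline_score,
      status_score_shift = status_score_shift, flag_prob = flag_prob,
      pair_sd = pair_sd, assessor_sd = assessor_sd, residual_sd = residual_sd,
      trait_effects = trait_effects, trait_pair_sd = trait_pair_sd,
      trait_residual_sd = trait_residual_sd,
      n_obs_per_taxon_trait = n_obs_per_taxon_trait,
      non_independent_prob = non_independent_prob,
      landscape = landscape
    ),
    class = "sivva_sim_config"
  )
}

sim_taxa <- function(cfg) {
  tidyr::expand_grid(
    pair_id = sprintf("P%02d", seq_len(cfg$n_pairs)),
    status = c("listed", "nonlisted")
  ) |>
    dplyr::mutate(taxon_id = paste(.data$pair_id, .data$status, sep = "_"))
}

#' Generate synthetic assessor scoresheets
#'
#' Criterion scores follow an additive model on the 0-6 scale: baseline +
#' pair intercept + assessor intercept + status shift (listed only) +
#' residual noise, rounded to the nearest integer and clipped to [1, 6].
#' Both assessors score every taxon; each criterion is independently
#' flagged uncertain with probability `flag_prob`. Weights come from
#' [criterion_template()].
#'
#' @param cfg A [sim_config()].
#' @param template Criterion template tibble (id, module, weight).
#' @return A validated scoresheet tibble with `pair_id` and `status`.
#' @export
sim_scoresheets <- function(cfg, template = criterion_template()) {
  stopifnot(inherits(cfg, "sivva_sim_config"))
  withr::with_seed(cfg$seed, {
    taxa <- sim_taxa(cfg)
    pair_eff <- setNames(rnorm(cfg$n_pairs, 0, cfg$pair_sd),
                         unique(taxa$pair_id))
    assessors <- sprintf("A%d", seq_len(cfg$n_assessors))
    ass_eff <- setNames(rnorm(cfg$n_assessors, 0, cfg$assessor_sd), assessors)
    sheets <- tidyr::expand_grid(
      taxa, assessor_id = assessors,
      template[, c("criterion_id", "module", "weight")]
    )
    raw <- cfg$baseline_score +
      pair_eff[sheets$pair_id] +
      ass_eff[sheets$assessor_id] +
      ifelse(sheets$status == "listed", cfg$status_score_shift, 0) +
      rnorm(nrow(sheets), 0, cfg$residual_sd)
    sheets |>
      dplyr::mutate(
        score = pmin(pmax(round(raw), 1), 6),
        uncertain = runif(dplyr::n()) < cfg$flag_prob
      ) |>
      dplyr::select(dplyr::all_of(c(
        "taxon_id", "assessor_id", "status", "pair_id",
        "module", "criterion_id", "score", "uncertain", "weight"
      ))) |>
      validate_scoresheet()
  })
}

TRAIT_BASELINES <- c(litter_clutch = 4, home_range = 5, dispersal = 10,
                     survival = 0.6)
TRAIT_UNITS <- c(litter_clutch = "count", home_range = "km2",
                 dispersal = "km", survival = "proportion")

#' Generate synthetic ecological trait records
#'
#' Size and distance traits are lognormal: log value = log(baseline) + pair
#' intercept + log(status ratio) for listed taxa + observation noise, so
#' status effects are multiplicative ratios (e.g. listed home ranges 2x).
#' Annual adult survival is generated on the logistic scale
#' (logistic-normal), keeping values in (0, 1). A fraction of records is
#' marked non-independent to exercise the analysis-side filter.
#'
#' @param cfg A [sim_config()].
#' @return A validated trait tibble.
#' @export
sim_traits <- function(cfg) {
  stopifnot(inherits(cfg, "sivva_sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    taxa <- sim_taxa(cfg)
    grid <- tidyr::expand_grid(
      taxa, trait = TRAIT_LEVELS,
      obs = seq_len(cfg$n_obs_per_taxon_trait)
    )
    pair_trait <- tidyr::expand_grid(
      pair_id = unique(taxa$pair_id), trait = TRAIT_LEVELS
    ) |>
      dplyr::mutate(pair_re = rnorm(dplyr::n(), 0, cfg$trait_pair_sd))
    grid <- dplyr::left_join(grid, pair_trait, by = c("pair_id", "trait"))
    ratio <- cfg$trait_effects[grid$trait]
    eta <- grid$pair_re +
      ifelse(grid$status == "listed", log(ratio), 0) +
      rnorm(nrow(grid), 0, cfg$trait_residual_sd)
    value <- ifelse(
      grid$trait == "survival",
      plogis(qlogis(TRAIT_BASELINES["survival"]) + eta),
      TRAIT_BASELINES[grid$trait] * exp(eta)
    )
    grid |>
      dplyr::mutate(
        value = value,
        unit = TRAIT_UNITS[.data$trait],
        source_id = sprintf("SRC_%s_%s_%02d", .data$taxon_id, .data$trait, .data$obs),
        independent = runif(dplyr::n()) >= cfg$non_independent_prob
      ) |>
      dplyr::select(dplyr::all_of(c(
        "pair_id", "taxon_id", "status", "trait", "value", "unit",
        "source_id", "independent"
      ))) |>
      validate_trait_table()
  })
}

#' Generate a synthetic coastal-gradient landscape
#'
#' Elevation rises inland from a western sea edge at `slope_m_per_cell` per
#' column: column j has elevation `(j - 1) * slope`, so column 1 sits at
#' current sea level and forms the coastline. Each taxon receives a
#' rectangular range; listed taxa are centred within the western
#' `coastal_fraction` of the grid (near the coast), non-listed taxa in the
#' remaining inland part, reproducing the geography in which exposure to
#' sea-level rise decreases with distance to coast.
#'
#' @param cfg A [sim_config()].
#' @return A list: `elevation` (`sivva_grid`), `coast` (logical matrix),
#'   `ranges` (named list of logical matrices), `taxa` (tibble of taxon
#'   metadata).
#' @export
sim_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sivva_sim_config"))
  ls <- cfg$landscape
  withr::with_seed(cfg$seed + 2L, {
    nx <- ls$nx; ny <- ls$ny
    elev <- matrix(rep((seq_len(nx) - 1) * ls$slope_m_per_cell, each = ny),
                   nrow = ny, ncol = nx)
    grid <- sivva_grid(elev, cellsize = 1)
    # coastline: sea-level cells with a higher 4-neighbour (here: column 1)
    coast <- matrix(FALSE, ny, nx)
    coast[, 1] <- TRUE
    taxa <- sim_taxa(cfg)
    half_w <- min(2L, (nx - 2L) %/% 4L)
    half_h <- min(3L, (ny - 2L) %/% 2L)
    coast_edge <- max(half_w + 2, floor(nx * ls$coastal_fraction))
    # centre columns evenly spaced within each band (jittered rows), so the
    # generated set always spans near-coast to band-edge distances
    spread <- function(lo, hi, n) round(seq(lo, hi, length.out = n))
    listed_cx <- spread(half_w + 1, coast_edge, cfg$n_pairs)
    nonlisted_cx <- spread(coast_edge + 1, nx - half_w, cfg$n_pairs)
    taxa <- taxa |>
      dplyr::mutate(cx = ifelse(
        .data$status == "listed",
        listed_cx[match(.data$pair_id, unique(.data$pair_id))],
        nonlisted_cx[match(.data$pair_id, unique(.data$pair_id))]
      ))
    ranges <- purrr::pmap(taxa, function(pair_id, status, taxon_id, cx) {
      cy <- sample((half_h + 1):(ny - half_h), 1)
      r <- matrix(FALSE, ny, nx)
      r[(cy - half_h):(cy + half_h), (cx - half_w):(cx + half_w)] <- TRUE
      r
    })
    names(ranges) <- taxa$taxon_id
    list(elevation = grid, coast = coast, ranges = ranges, taxa = taxa)
  })
}
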