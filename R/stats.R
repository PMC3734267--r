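#' Exact Wilcoxon rank-sum (Mann-Whitney) test by enumeration
#'
#' Small literature samples (often 3 observations per taxon) make the normal
#' approximation to the rank-sum null unreliable, so the null distribution
#' is enumerated exactly: under the null every assignment of the pooled
#' (mid)ranks to the first sample is equiprobable, giving
#' \eqn{\binom{n_1+n_2}{n_1}} equally likely values of the Mann-Whitney
#' statistic \eqn{U = R_1 - n_1(n_1+1)/2}. Ties are handled by enumerating
#' over the observed midranks. The reported statistic is U of the first
#' sample (what most software prints as "W").
#'
#' One-sided p is the smaller exact tail in the observed direction,
#' \eqn{\min(P(U \le u), P(U \ge u))}; two-sided p doubles it, capped at 1.
#' Enumeration is used when `n1 + n2 <= max_exact` (default 20, i.e. at most
#' 184756 assignments); larger samples fall back to the continuity-corrected
#' normal approximation of [stats::wilcox.test()].
#'
#' @param x,y Numeric samples (first and second group).
#' @param sided `"one"` or `"two"`.
#' @param max_exact Largest pooled size for exact enumeration.
#' @return A one-row tibble: `statistic` (U), `n1`, `n2`, `p_value`,
#'   `sided`, `method`.
#' @export
#' @examples
#' exact_rank_sum(c(7, 8, 9), c(1, 2, 3), sided = "one") # U = 9, p = 0.05
exact_rank_sum <- function(x, y, sided = c("one", "two"), max_exact = 20) {
  sided <- match.arg(sided)
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  if (any(!is.finite(c(x, y)))) abort("Samples must be finite.")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= max_exact) {
    picks <- combn(n, n1)
    u_all <- colSums(matrix(r[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    # guard floating midranks: compare on a half-rank grid
    u_all <- round(u_all * 2) / 2
    u_obs <- round(u_obs * 2) / 2
    p_le <- mean(u_all <= u_obs)
    p_ge <- mean(u_all >= u_obs)
    p_one <- min(p_le, p_ge)
    p <- if (sided == "one") p_one else min(1, 2 * p_one)
    method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      x, y, alternative = "two.sided", exact = FALSE, correct = TRUE
    ))
    p <- if (sided == "one") wt$p.value / 2 else wt$p.value
    method <- "normal approximation"
  }
  tibble::tibble(
    statistic = u_obs, n1 = n1, n2 = n2, p_value = p,
    sided = sided, method = paste("Wilcoxon rank sum,", method)
  )
}

#' Correlation tests in tidy form
#'
#' Thin wrappers around [stats::cor.test()] returning the package's tidy
#' test layout. `pearson_r()` computes the product-moment correlation with a
#' two-sided t-approximation p; `spearman_rho()` the rank correlation
#' (exact p for small tie-free samples, as `cor.test` provides).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return One-row tibble: `statistic` (r or rho), `n1`, `n2` (both n),
#'   `p_value`, `sided`, `method`.
#' @export
pearson_r <- function(x, y) {
  cor_tidy(x, y, method = "pearson")
}

#' @rdname pearson_r
#' @export
spearman_rho <- function(x, y) {
  cor_tidy(x, y, method = "spearman")
}

cor_tidy <- function(x, y, method) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Correlation needs at least 3 observations.")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("Values must be finite.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: one input has zero variance.")
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble::tibble(
    statistic = unname(ct$estimate), n1 = length(x), n2 = length(y),
    p_value = ct$p.value, sided = "two",
    method = if (method == "pearson") "Pearson product-moment" else "Spearman rank"
  )
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up FDR control at level `q`: with ordered p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, reject all hypotheses up to the
#' largest i with \eqn{p_{(i)} \le (i/m) q}. Adjusted p-values are the usual
#' BH step-up values (computed via [stats::p.adjust()]), and rejection is
#' equivalent to `p_adjusted <= q`.
#'
#' @param p_value Numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return Tibble: `p_value`, `p_adjusted`, `reject`.
#' @export
bh_fdr <- function(p_value, q = 0.05) {
  if (any(!is.finite(p_value)) || any(p_value < 0 | p_value > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  adj <- p.adjust(p_value, method = "BH")
  tibble::tibble(p_value = p_value, p_adjusted = adj, reject = adj <= q)
}

#' Likelihood-ratio test for a fixed effect in a mixed model
#'
#' Fits the full and reduced mixed models by maximum likelihood (REML off,
#' since likelihoods are compared across different fixed-effect structures)
#' and tests the dropped fixed effect with
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})} on 1 df. The Gaussian
#' family uses [lme4::lmer()], Poisson uses [lme4::glmer()] (integer
#' responses such as raw criterion scores). Convergence or singularity
#' messages from either fit are captured and reported in the result, never
#' silently dropped.
#'
#' @param data Data frame holding the response, the fixed effect and the
#'   grouping factors.
#' @param response Name of the response column.
#' @param fixed Name of the fixed-effect column to test (default
#'   `"status"`).
#' @param random Character vector of grouping-factor columns fitted as
#'   random intercepts (e.g. `c("pair_id", "assessor_id")`).
#' @param family `"gaussian"` or `"poisson"`.
#' @return An object of class `sivva_lrt`; see [tidy.sivva_lrt()].
#' @export
lrt_fixed_effect <- function(data, response, fixed = "status",
                             random = "pair_id",
                             family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  data <- tibble::as_tibble(data)
  for (col in c(response, fixed, random)) {
    if (!col %in% names(data)) abort(paste0("Column '", col, "' not found."))
  }
  if (length(unique(data[[fixed]])) < 2) {
    abort(paste0("Fixed effect '", fixed, "' needs at least 2 levels."))
  }
  if (sd(data[[response]]) == 0) {
    # a constant response carries no evidence either way; chi-square is 0
    return(structure(
      list(chisq = 0, df = 1L, p_value = 1, fixed = fixed,
           response = response, family = family, n = nrow(data),
           full = NULL, reduced = NULL,
           convergence_notes = "response is constant; models not fitted"),
      class = "sivva_lrt"
    ))
  }
  re <- paste(sprintf("(1 | %s)", random), collapse = " + ")
  f_full <- as.formula(paste(response, "~", fixed, "+", re))
  f_red <- as.formula(paste(response, "~ 1 +", re))
  notes <- character()
  fit_one <- function(f) {
    withCallingHandlers(
      {
        if (family == "gaussian") {
          lme4::lmer(f, data = data, REML = FALSE)
        } else {
          lme4::glmer(f, data = data, family = stats::poisson())
        }
      },
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        notes <<- c(notes, conditionMessage(m))
        invokeRestart("muffleMessage")
      }
    )
  }
  full <- fit_one(f_full)
  reduced <- fit_one(f_red)
  chisq <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced))))
  structure(
    list(
      chisq = chisq, df = 1L, p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
      fixed = fixed, response = response, family = family,
      n = nrow(data), full = full, reduced = reduced,
      convergence_notes = unique(notes)
    ),
    class = "sivva_lrt"
  )
}

#' @exportS3Method base::print
print.sivva_lrt <- function(x, ...) {
  cat(sprintf(
    "LRT for fixed effect '%s' on '%s' (%s): chisq = %.3f, df = %d, p = %.4g\n",
    x$fixed, x$response, x$family, x$chisq, x$df, x$p_value
  ))
  if (length(x$convergence_notes) > 0) {
    cat("  fit notes:", paste(x$convergence_notes, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tidy and glance methods for likelihood-ratio tests
#'
#' @param x A `sivva_lrt` object.
#' @param ... Unused.
#' @return `tidy()` returns a one-row tibble of the test (statistic, df,
#'   p-value); `glance()` adds model-level summaries (log-likelihoods, n,
#'   convergence notes).
#' @export
tidy.sivva_lrt <- function(x, ...) {
  tibble::tibble(
    term = x$fixed, response = x$response, family = x$family,
    statistic = x$chisq, df = x$df, p_value = x$p_value
  )
}

#' @rdname tidy.sivva_lrt
#' @export
glance.sivva_lrt <- function(x, ...) {
  tibble::tibble(
    logLik_full = if (is.null(x$full)) NA_real_ else as.numeric(logLik(x$full)),
    logLik_reduced = if (is.null(x$reduced)) NA_real_ else as.numeric(logLik(x$reduced)),
    statistic = x$chisq, df = x$df, p_value = x$p_value, nobs = x$n,
    notes = paste(x$convergence_notes, collapse = "; ")
  )
}

#' Per-trait listed-vs-nonlisted contrasts from a mixed model
#'
#' Fits a linear mixed model with trait nested within listing status
#' (cell-means parameterisation `response ~ 0 + trait:status`) and random
#' intercepts for taxon-pair and for taxon x trait, then tests the
#' listed-minus-nonlisted contrast within each trait with single-step
#' (max-t, Tukey-style) familywise adjustment via [multcomp::glht()]. The
#' taxon x trait intercept matters: repeated literature observations of one
#' taxon are pseudo-replicates, and the proportion-of-maximum scaling ties
#' every observation in a pair x trait cell to the same maximum, so
#' observation-level independence would understate the contrast variance.
#' The model is fitted by REML (no likelihoods are compared here). The
#' response should already be normalised and transformed
#' (proportion-of-maximum then adjusted logit; see [proportion_of_max()]
#' and [adjusted_logit()]).
#'
#' Traits observed for only one status level cannot be contrasted and are
#' excluded with a warning. The multivariate-t adjustment involves
#' quasi-random integration; `seed` fixes it for reproducibility.
#'
#' @param data Tibble with columns `pair_id`, `taxon_id`, `status`,
#'   `trait`, and the response.
#' @param response Name of the (transformed) response column.
#' @param seed Integer seed for the adjusted p-value computation.
#' @return Tibble: `trait`, `estimate` (listed minus nonlisted, on the
#'   transformed scale), `se`, `statistic`, `p_adjusted`.
#' @export
status_trait_contrasts <- function(data, response = "logit_prop", seed = 1) {
  data <- tibble::as_tibble(data)
  for (col in c("pair_id", "taxon_id", "status", "trait", response)) {
    if (!col %in% names(data)) abort(paste0("Column '", col, "' not found."))
  }
  ok_traits <- data |>
    dplyr::distinct(.data$trait, .data$status) |>
    dplyr::count(.data$trait) |>
    dplyr::filter(.data$n == 2) |>
    dplyr::pull(.data$trait)
  dropped <- setdiff(unique(data$trait), ok_traits)
  if (length(dropped) > 0) {
    warn(paste0(
      "Trait(s) with a single status level excluded from contrasts: ",
      paste(dropped, collapse = ", ")
    ))
  }
  if (length(ok_traits) == 0) abort("No trait has both status levels.")
  dat <- data |>
    dplyr::filter(.data$trait %in% ok_traits) |>
    dplyr::mutate(
      cell = factor(paste(.data$trait, .data$status, sep = ".")),
      pair_id = factor(.data$pair_id),
      taxon_trait = factor(paste(.data$taxon_id, .data$trait, sep = "."))
    )
  f <- as.formula(paste(response, "~ 0 + cell + (1 | pair_id) + (1 | taxon_trait)"))
  fit <- suppressMessages(lme4::lmer(f, data = dat, REML = TRUE))
  cells <- levels(dat$cell)
  traits <- sort(unique(sub("\\..*$", "", cells)))
  K <- t(vapply(traits, function(tr) {
    k <- numeric(length(cells))
    k[cells == paste0(tr, ".listed")] <- 1
    k[cells == paste0(tr, ".nonlisted")] <- -1
    k
  }, numeric(length(cells))))
  rownames(K) <- traits
  colnames(K) <- paste0("cell", cells)
  gl <- multcomp::glht(fit, linfct = K)
  smry <- withr::with_seed(seed, summary(gl))
  tibble::tibble(
    trait = traits,
    estimate = unname(smry$test$coefficients),
    se = unname(smry$test$sigma),
    statistic = unname(smry$test$tstat),
    p_adjusted = unname(as.numeric(smry$test$pvalues))
  )
}
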