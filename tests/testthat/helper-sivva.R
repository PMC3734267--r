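# Build a minimal one-taxon, one-assessor scoresheet tibble.
make_sheet <- function(score, weight = 1, uncertain = FALSE,
                       module = "vulnerability", taxon_id = "T1",
                       assessor_id = "A1") {
  n <- length(score)
  tibble::tibble(
    taxon_id = taxon_id, assessor_id = assessor_id,
    module = rep_len(module, n),
    criterion_id = sprintf("X%02d", seq_len(n)),
    score = score,
    uncertain = rep_len(uncertain, n),
    weight = rep_len(weight, n)
  )
}

# Exact perturbation distribution of a module score: enumerate every
# combination of deltas in {-1, 0, +1} over the flagged criteria (clipping
# to [1, 6]) and return the support with probabilities.
enumerate_mc_distribution <- function(score, weight, uncertain) {
  weight <- rep_len(weight, length(score))
  flagged <- which(uncertain & score >= 1)
  denom <- sum(weight[score >= 1] * 6)
  if (length(flagged) == 0) {
    s <- sum(weight[score >= 1] * score[score >= 1]) / denom
    return(data.frame(value = s, prob = 1))
  }
  deltas <- expand.grid(rep(list(c(-1, 0, 1)), length(flagged)))
  vals <- apply(deltas, 1, function(d) {
    s <- score
    s[flagged] <- pmin(pmax(s[flagged] + d, 1), 6)
    sum(weight[s >= 1] * s[s >= 1]) / denom
  })
  agg <- aggregate(
    list(prob = rep(1 / nrow(deltas), nrow(deltas))),
    by = list(value = round(vals, 12)), FUN = sum
  )
  agg[order(agg$value), ]
}

# Quantile of a discrete distribution as the large-sample limit of the
# type-7 sample quantile: F^{-1}(p).
discrete_quantile <- function(dist, p) {
  cum <- cumsum(dist$prob)
  vapply(p, function(pp) dist$value[which(cum >= pp - 1e-12)[1]], numeric(1))
}

# Brute-force Mann-Whitney U null distribution by direct counting:
# enumerate every split of the pooled values into groups of size n1/n2 and
# count pairs (x > y) plus half-ties. Independent of the rank-based route
# used by exact_rank_sum().
brute_force_u_distribution <- function(pooled, n1) {
  picks <- utils::combn(length(pooled), n1)
  apply(picks, 2, function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  })
}

# Textbook BH step-up: largest i with p_(i) <= (i/m) q.
bh_stepup_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ok <- which(p[ord] <= (seq_len(m) / m) * q)
  reject <- logical(m)
  if (length(ok) > 0) reject[ord[seq_len(max(ok))]] <- TRUE
  reject
}
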