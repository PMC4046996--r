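# Decision analytics on a PSA: expected outcomes, the cost-effectiveness
# frontier with dominance and extended dominance, ICERs, net monetary
# benefit, acceptability curves and the expected value of perfect
# information.

psa_outcomes <- function(psa) {
  if (inherits(psa, "psa_result")) psa$outcomes
  else as_tibble(psa)
}

#' Per-strategy expected outcomes
#'
#' Arithmetic means of QALYs and costs across all PSA draws, per strategy,
#' reported per household and — when the cohort size is known — scaled to
#' the simulated cohort.
#'
#' @param psa a `psa_result` or an outcomes tibble with columns
#'   `strategy_id`, `label`, `qalys`, `cost_total`.
#' @return A tibble with one row per strategy: mean `qalys` and `cost_total`
#'   (per household), itemised category means when present, and
#'   `qalys_cohort` / `cost_cohort` when a cohort size is recorded.
#' @export
mean_outcomes <- function(psa) {
  out <- psa_outcomes(psa)
  num <- intersect(c("qalys", "cost_total", "cost_intervention",
                     "cost_NHS_PSS", "cost_other_public", "cost_household",
                     "n_fires", "n_minor", "n_moderate", "n_severe",
                     "n_fatal", "life_years"), names(out))
  means <- out %>%
    group_by(.data$strategy_id, .data$label) %>%
    summarise(across(all_of(num), mean), .groups = "drop") %>%
    arrange(.data$strategy_id)
  cs <- if (inherits(psa, "psa_result")) psa$settings$cohort_size else NULL
  if (!is.null(cs) && is.finite(cs)) {
    means$qalys_cohort <- means$qalys * cs
    means$cost_cohort <- means$cost_total * cs
  }
  means
}

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost incremental cost.
#' @param delta_qaly incremental effect; a zero increment makes the ratio
#'   undefined and returns `NA` (dominance logic handles that case
#'   upstream).
#' @return `delta_cost / delta_qaly`; negative values indicate a dominance
#'   situation (more effect for less cost, or vice versa).
#' @examples
#' icer(777, 0.023)
#' @export
icer <- function(delta_cost, delta_qaly) {
  ifelse(delta_qaly == 0, NA_real_, delta_cost / delta_qaly)
}

#' Cost-effectiveness frontier with dominance and extended dominance
#'
#' Orders strategies by effectiveness, removes strictly dominated strategies
#' (at least as costly and no more effective than some alternative, with at
#' least one strict inequality; exact duplicates collapse to the earlier
#' id), then iteratively removes extendedly dominated strategies until the
#' ICER sequence along the remaining chain is strictly increasing.
#' Incremental QALYs, costs and ICERs are computed against the previous
#' frontier member.
#'
#' @param means a data frame with one row per strategy and columns `qalys`
#'   and `cost` (or `cost_total`); a `label` column is carried through. The
#'   output of [mean_outcomes()] works directly.
#' @return An object of class `cea_frontier`: a tibble sorted by
#'   effectiveness with columns `label`, `qalys`, `cost`, `status`
#'   (`"frontier"`, `"dominated"` or `"extendedly_dominated"`),
#'   `inc_qalys`, `inc_cost` and `icer` (populated on frontier rows only;
#'   the least effective frontier member is the reference with `NA`
#'   increments).
#' @examples
#' tab <- tibble::tibble(
#'   label = c("A", "B", "C"),
#'   qalys = c(10, 10.5, 10.6),
#'   cost  = c(100, 120, 500))
#' compute_frontier(tab)
#' @export
compute_frontier <- function(means) {
  means <- as_tibble(means)
  if (!"cost" %in% names(means) && "cost_total" %in% names(means))
    means$cost <- means$cost_total
  if (!all(c("qalys", "cost") %in% names(means)))
    abort("`means` must have columns qalys and cost (or cost_total)")
  if (!"label" %in% names(means))
    means$label <- paste0("S", seq_len(nrow(means)))
  n <- nrow(means)
  q <- means$qalys
  cost <- means$cost
  status <- rep("frontier", n)

  # strict dominance (pairwise, global); ties collapse to the earlier row
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if ((q[j] > q[i] && cost[j] <= cost[i]) ||
          (q[j] >= q[i] && cost[j] < cost[i]) ||
          (q[j] == q[i] && cost[j] == cost[i] && j < i)) {
        status[i] <- "dominated"
        break
      }
    }
  }

  # extended dominance: drop chain members until ICERs strictly increase
  cand <- which(status != "dominated")
  cand <- cand[order(q[cand], cost[cand])]
  repeat {
    if (length(cand) < 3L) break
    ic <- icer(diff(cost[cand]), diff(q[cand]))
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    drop <- cand[bad[1] + 1L]  # the member whose ICER breaks monotonicity
    status[drop] <- "extendedly_dominated"
    cand <- setdiff(cand, drop)
  }

  out <- means[order(q, cost), c("label", "qalys", "cost",
                                 intersect("strategy_id", names(means)))]
  out$status <- status[order(q, cost)]
  out$inc_qalys <- NA_real_
  out$inc_cost <- NA_real_
  out$icer <- NA_real_
  fr <- which(out$status == "frontier")
  if (length(fr) > 1L) {
    out$inc_qalys[fr[-1]] <- diff(out$qalys[fr])
    out$inc_cost[fr[-1]] <- diff(out$cost[fr])
    out$icer[fr[-1]] <- icer(out$inc_cost[fr[-1]], out$inc_qalys[fr[-1]])
  }
  structure(out, class = c("cea_frontier", class(out)))
}

#' Per-draw net monetary benefit
#'
#' @param psa a `psa_result` or outcomes tibble.
#' @param threshold willingness to pay per QALY (GBP), `>= 0`.
#' @return A tibble with one row per (draw, strategy): `draw`,
#'   `strategy_id`, `label`, `nmb = threshold * qalys - cost_total`.
#' @export
nmb <- function(psa, threshold) {
  if (any(threshold < 0)) abort("threshold must be >= 0")
  stopifnot(length(threshold) == 1)
  out <- psa_outcomes(psa)
  out %>%
    mutate(nmb = threshold * .data$qalys - .data$cost_total) %>%
    select(all_of(c("draw", "strategy_id", "label", "nmb")))
}

# draws x strategies matrices of QALYs and costs, strategies in id order
psa_matrices <- function(psa) {
  out <- psa_outcomes(psa)
  ids <- sort(unique(out$strategy_id))
  lab <- out$label[match(ids, out$strategy_id)]
  qm <- do.call(cbind, lapply(ids, function(i)
    out$qalys[out$strategy_id == i][order(out$draw[out$strategy_id == i])]))
  cm <- do.call(cbind, lapply(ids, function(i)
    out$cost_total[out$strategy_id == i][order(out$draw[out$strategy_id == i])]))
  colnames(qm) <- colnames(cm) <- lab
  list(q = qm, cost = cm, ids = ids, labels = lab)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws in which
#' each strategy attains the maximal net monetary benefit. Exact NMB ties
#' within a draw are awarded to the strategy with the lower cost in that
#' draw (then the lower id), so probabilities sum to one at every
#' threshold.
#'
#' @param psa a `psa_result` or outcomes tibble.
#' @param thresholds numeric grid of thresholds (GBP per QALY).
#' @return An object of class `cea_ceac`: a tibble with columns
#'   `threshold`, `strategy_id`, `label`, `probability`.
#' @export
ceac <- function(psa, thresholds) {
  if (!length(thresholds)) abort("threshold grid is empty")
  if (any(thresholds < 0)) abort("thresholds must be >= 0")
  m <- psa_matrices(psa)
  n <- nrow(m$q)
  k <- ncol(m$q)
  res <- purrr::map_dfr(thresholds, function(lam) {
    netb <- lam * m$q - m$cost
    best <- netb == matrixStats_rowMaxs(netb)
    cost_masked <- ifelse(best, m$cost, Inf)
    winner <- max.col(-cost_masked, ties.method = "first")
    tibble(threshold = lam, strategy_id = m$ids, label = m$labels,
           probability = tabulate(winner, nbins = k) / n)
  })
  structure(res, class = c("cea_ceac", class(res)))
}

# row maxima as a column-conformable matrix (base R, no extra deps)
matrixStats_rowMaxs <- function(x) {
  mx <- do.call(pmax, as.data.frame(x))
  matrix(mx, nrow = nrow(x), ncol = ncol(x))
}

#' Expected value of perfect information (per decision)
#'
#' `EVPI = E_draw[max_s NMB] - max_s E_draw[NMB]`: the expected gain from
#' resolving all parameter uncertainty before choosing a strategy. Always
#' non-negative; zero when one strategy is NMB-maximal in every draw.
#'
#' @param psa a `psa_result` or outcomes tibble.
#' @param threshold willingness to pay per QALY (GBP), `>= 0`.
#' @return An object of class `cea_evpi`: a one-row tibble with `threshold`
#'   and `evpi` (GBP per decision unit, i.e. per household at the model's
#'   scale).
#' @export
evpi <- function(psa, threshold) {
  if (any(threshold < 0)) abort("threshold must be >= 0")
  stopifnot(length(threshold) == 1)
  m <- psa_matrices(psa)
  netb <- threshold * m$q - m$cost
  val <- mean(do.call(pmax, as.data.frame(netb))) - max(colMeans(netb))
  structure(tibble(threshold = threshold, evpi = max(0, val)),
            class = c("cea_evpi", "tbl_df", "tbl", "data.frame"))
}

#' @rdname evpi
#' @param thresholds a grid of thresholds.
#' @export
evpi_curve <- function(psa, thresholds) {
  res <- purrr::map_dfr(thresholds, function(l) evpi(psa, l))
  structure(res, class = c("cea_evpi", class(tibble())))
}

#' Population expected value of perfect information
#'
#' Scales a per-decision EVPI to the population expected to benefit from
#' the decision over an intervention horizon:
#' `evpi_pd * sum_{t=0}^{horizon-1} annual_population / (1 + discount_rate)^t`.
#'
#' @param per_decision_evpi per-decision EVPI (GBP), e.g. `evpi(...)$evpi`.
#' @param annual_population decision units affected per year (default
#'   31,000, the approximate number of single-child under-5 households
#'   entering the decision each year).
#' @param horizon_years intervention relevance horizon (default 10).
#' @param discount_rate annual rate (default 3.5%); set `discounted =
#'   FALSE` to ignore discounting.
#' @param discounted logical.
#' @return Population EVPI in GBP.
#' @examples
#' population_evpi(1.5, annual_population = 31000)
#' @export
population_evpi <- function(per_decision_evpi, annual_population = 31000,
                            horizon_years = 10, discount_rate = 0.035,
                            discounted = TRUE) {
  stopifnot(per_decision_evpi >= 0, annual_population >= 0,
            horizon_years >= 0, discount_rate >= 0)
  t <- seq_len(horizon_years) - 1
  w <- if (discounted) (1 + discount_rate)^(-t) else rep(1, length(t))
  per_decision_evpi * sum(annual_population * w)
}
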