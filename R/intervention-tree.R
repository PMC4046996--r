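# Stage 1: the intervention decision tree. A household either (i) already
# has a functioning alarm; or does not and (ii) accepts the intervention and
# becomes enabled, (iii) accepts but is not enabled, or (iv) declines.
# Branches (i) and (ii) enter the pre-school model in the functioning-alarm
# state; (iii) and (iv) in the non-functioning state.

#' Per-household delivery cost of a strategy
#'
#' Sums the component delivery costs (`c_E`, `c_FE`, `c_F`, `c_HI`) over the
#' strategy's components; usual care costs nothing. Monotone non-decreasing
#' under component-set inclusion for non-negative costs.
#'
#' @param strategy a strategy id, label or [strategies()] row.
#' @param draws a parameter-draws tibble ([sample_draws()]); vectorised over
#'   rows.
#' @return Numeric vector (GBP per delivered household), one per draw row.
#' @examples
#' d <- sample_draws(parameter_fixture(), 1, seed = 1)
#' strategy_cost("E + FE", d)
#' @export
strategy_cost <- function(strategy, draws) {
  strat <- resolve_strategy(strategy)
  comps <- strat$components[[1]]
  if (length(comps) == 0L) return(rep(0, nrow(draws)))
  cost_cols <- paste0("c_", comps)
  miss <- setdiff(cost_cols, names(draws))
  if (length(miss))
    abort(paste0("draws missing component cost column(s): ",
                 paste(miss, collapse = ", ")))
  m <- as.matrix(draws[cost_cols])
  if (any(m < 0)) abort("negative component cost")
  rowSums(m)
}

#' Decision-tree branch probabilities
#'
#' The four mutually exclusive household situations: (i) already owns a
#' functioning alarm, (ii) non-owner, accepts and is enabled, (iii)
#' non-owner, accepts but not enabled, (iv) non-owner, declines. They sum to
#' one for any valid inputs.
#'
#' @inheritParams strategy_cost
#' @param pi_k enablement probability for the strategy (one value or one per
#'   draw row); 0 for usual care.
#' @return A tibble with columns `owns`, `enabled`, `accepts_not_enabled`,
#'   `declines`.
#' @export
tree_branches <- function(draws, pi_k) {
  p_prev <- draws$p_prev
  p_accept <- draws$p_accept
  tibble(
    owns = p_prev,
    enabled = (1 - p_prev) * p_accept * pi_k,
    accepts_not_enabled = (1 - p_prev) * p_accept * (1 - pi_k),
    declines = (1 - p_prev) * (1 - p_accept)
  )
}

#' Evaluate the stage-1 intervention tree
#'
#' Converts a strategy plus parameter draw(s) into the probability of
#' entering the pre-school model with a functioning alarm,
#' `p_prev + (1 - p_prev) * p_accept * pi_k`, and the expected per-household
#' intervention cost. By default delivery costs are incurred by the
#' non-owning households that accept — including those that accept but are
#' not enabled, since delivery still happened — i.e.
#' `(1 - p_prev) * p_accept * strategy_cost()`. Setting
#' `cost_basis = "offered"` instead charges the delivery cost for every
#' household offered the intervention.
#'
#' @inheritParams tree_branches
#' @param strategy a strategy id, label or [strategies()] row.
#' @param cost_basis `"accepters"` (default) or `"offered"`.
#' @return A tibble with columns `p_start_functioning` and
#'   `cost_intervention`, one row per draw.
#' @examples
#' d <- sample_draws(parameter_fixture(), 1, seed = 1)
#' evaluate_tree("E + FE", d, pi_k = 0.5)
#' @export
evaluate_tree <- function(strategy, draws, pi_k,
                          cost_basis = c("accepters", "offered")) {
  cost_basis <- match.arg(cost_basis)
  strat <- resolve_strategy(strategy)
  n <- nrow(draws)
  pi_k <- rep_len(pi_k, n)
  if (any(pi_k < 0 | pi_k > 1)) abort("pi_k must lie in [0, 1]")
  if (strat$id == 1L && any(pi_k != 0))
    abort("usual care must have pi_k = 0")
  p_prev <- draws$p_prev
  p_accept <- draws$p_accept
  p_start <- p_prev + (1 - p_prev) * p_accept * pi_k
  if (strat$id == 1L) {
    cost <- rep(0, n)
  } else {
    unit <- strategy_cost(strat, draws)
    cost <- switch(cost_basis,
                   accepters = (1 - p_prev) * p_accept * unit,
                   offered = unit)
  }
  tibble(p_start_functioning = p_start, cost_intervention = cost)
}
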