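# Stage 3: lifetime Markov projection, ages 5-99. Three states — healthy,
# post-severe, dead — with life-table mortality, age-specific utility norms,
# the lifelong post-severe utility decrement and ongoing annual care cost.
# Discounting continues on the birth clock: factor (1 + r)^-age.

#' Discount factor
#'
#' @param t years since birth (non-negative integer-valued).
#' @param r annual discount rate, `>= 0`.
#' @return `(1 + r)^(-t)`.
#' @examples
#' discount_factor(1, 0.035)
#' @export
discount_factor <- function(t, r) {
  if (any(r < 0)) abort("discount rate r must be >= 0")
  if (any(t < 0)) abort("t must be >= 0")
  (1 + r)^(-t)
}

as_start_distribution <- function(start, n) {
  if (is.data.frame(start)) {
    nm <- names(start)
    pick <- function(a, b) if (a %in% nm) start[[a]] else start[[b]]
    healthy <- pick("terminal_healthy", "healthy")
    post <- pick("terminal_postsevere", "postsevere")
    dead <- pick("terminal_dead", "dead")
  } else {
    stopifnot(length(start) == 3)
    healthy <- rep(start[1], n); post <- rep(start[2], n)
    dead <- rep(start[3], n)
  }
  if (any(healthy < -1e-12 | post < -1e-12 | dead < -1e-12))
    abort("negative start occupancy")
  if (any(abs(healthy + post + dead - 1) > 1e-10))
    abort("start distribution must sum to 1")
  list(healthy = pmax(healthy, 0), post = pmax(post, 0))
}

#' Run the lifetime (ages 5-99) projection
#'
#' Projects the terminal pre-school distribution to age 99 inclusive.
#' Healthy individuals accrue the age-specific utility norm; post-severe
#' individuals accrue the norm minus `du_severe` plus the annual ongoing
#' care cost `c_severe_annual` (an NHS/PSS cost). Mortality follows the
#' life table, applied equally to healthy and post-severe by default; an
#' optional hazard ratio on post-severe mortality is available. Rewards at
#' cycle start, no half-cycle correction; nothing accrues beyond age 99.
#'
#' @param start terminal distribution: a [run_preschool()] result (columns
#'   `terminal_healthy`, `terminal_postsevere`, `terminal_dead`), or a
#'   length-3 numeric `(healthy, postsevere, dead)`.
#' @param draws parameter draws, one row per start row.
#' @param life_table life table covering ages 5-99.
#' @param utility_norms age-band utility norms.
#' @param hr_postsevere hazard ratio on post-severe annual death
#'   probability (default 1: no excess mortality).
#' @return A tibble per draw: discounted `qalys` (ages 5-99), discounted
#'   `cost_severe_annual`, and undiscounted `life_years`.
#' @examples
#' d <- sample_draws(parameter_fixture(), 2, seed = 1)
#' run_lifetime(c(0.99, 0.005, 0.005), d, life_table_fixture(),
#'              utility_norms_fixture())
#' @export
run_lifetime <- function(start, draws, life_table, utility_norms,
                         hr_postsevere = 1) {
  draws <- check_draws(draws)
  n <- nrow(draws)
  life_table <- validate_life_table(life_table, ages = 5:99)
  if (any(life_table$qx < 0 | life_table$qx > 1))
    abort("life-table qx outside [0, 1]")
  u_age <- utility_by_age(utility_norms)
  s <- as_start_distribution(start, n)
  healthy <- s$healthy
  post <- s$post
  r <- draws$r
  du <- draws$du_severe
  c_ann <- draws$c_severe_annual
  qalys <- numeric(n)
  cost <- numeric(n)
  life_years <- numeric(n)
  for (a in 5:99) {
    disc <- discount_factor(a, r)
    qalys <- qalys + disc * (healthy * u_age[a + 1L] +
                               post * (u_age[a + 1L] - du))
    cost <- cost + disc * post * c_ann
    life_years <- life_years + healthy + post
    qx <- life_table$qx[match(a, life_table$age)]
    qx_post <- pmin(1, qx * hr_postsevere)
    healthy <- healthy * (1 - qx)
    post <- post * (1 - qx_post)
  }
  tibble(qalys = qalys, cost_severe_annual = cost, life_years = life_years)
}
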