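# Stage 2: the pre-school Markov cohort model (ages 0-4, yearly cycles).
# Joint state of the household alarm (functioning / non-functioning) and the
# child's severe-injury history (never-severe / post-severe), plus an
# absorbing dead state. Within a cycle events apply in a fixed order:
# fire -> injury -> severity -> background mortality -> alarm decay/repair;
# at most one fire (and hence one injury) per household per cycle by
# construction. Rewards follow a cycle-start convention with no half-cycle
# correction; newly severe children accrue the utility decrement and the
# ongoing annual cost from the event cycle onward.

#' Initial pre-school state occupancies
#'
#' @param p_start_functioning probability (vector) of entering stage 2 in
#'   the functioning-alarm state.
#' @return A state tibble with columns `func_never`, `nonfunc_never`,
#'   `func_post`, `nonfunc_post`, `dead` (occupancies summing to 1 per row).
#' @export
preschool_state <- function(p_start_functioning) {
  if (any(p_start_functioning < 0 | p_start_functioning > 1))
    abort("p_start_functioning must lie in [0, 1]")
  n <- length(p_start_functioning)
  tibble(func_never = p_start_functioning,
         nonfunc_never = 1 - p_start_functioning,
         func_post = rep(0, n), nonfunc_post = rep(0, n),
         dead = rep(0, n))
}

check_state <- function(state) {
  m <- as.matrix(state)
  if (any(m < -1e-12)) abort("negative state occupancy")
  if (any(abs(rowSums(m) - 1) > 1e-10))
    abort("state occupancies must sum to 1")
  invisible(state)
}

sev_cols <- function(draws, alarm) {
  m <- as.matrix(draws[paste0("severity_split_", alarm, "_", severity_labels)])
  dimnames(m) <- NULL
  m
}

#' One annual cycle of the pre-school model
#'
#' Advances the joint alarm-by-injury-history state through one cycle and
#' returns the cycle's (undiscounted) QALYs, itemised costs and expected
#' event counts. Vectorised over draw rows.
#'
#' @param state a state tibble from [preschool_state()], one row per draw.
#' @param draws parameter draws ([sample_draws()]), same number of rows.
#' @param qx annual background death probability at the child's current age.
#' @param u_age utility norm at the child's current age.
#' @return A list with elements `state` (next cycle's state), `qalys`,
#'   `costs` (tibble: `injury_nhs`, `fatality`, `fire_other_public`,
#'   `fire_household`, `severe_annual`) and `events` (tibble: `fires`,
#'   `minor`, `moderate`, `severe`, `fatal`), all per draw row and
#'   undiscounted.
#' @export
step_preschool <- function(state, draws, qx, u_age) {
  check_state(state)
  draws <- check_draws(draws)
  stopifnot(nrow(state) == nrow(draws), qx >= 0, qx <= 1)
  n <- nrow(draws)
  p_fire <- draws$p_fire
  p_inj <- list(func = draws$p_injury_func, nonfunc = draws$p_injury_nonfunc)
  split <- list(func = sev_cols(draws, "func"),
                nonfunc = sev_cols(draws, "nonfunc"))

  zero <- rep(0, n)
  ev <- list(fires = zero, minor = zero, moderate = zero, severe = zero,
             fatal = zero)
  new_severe <- zero     # never-severe -> severe transitions this cycle
  fatal_by <- list()     # fire fatality mass per state
  alive_after <- list()  # state mass surviving the fire stage

  for (st in c("func_never", "nonfunc_never", "func_post", "nonfunc_post")) {
    alarm <- if (grepl("^func", st)) "func" else "nonfunc"
    m <- state[[st]]
    fire <- m * p_fire
    inj <- fire * p_inj[[alarm]]
    sev <- inj * split[[alarm]]  # n x 4: minor, moderate, severe, fatal
    ev$fires <- ev$fires + fire
    ev$minor <- ev$minor + sev[, 1]
    ev$moderate <- ev$moderate + sev[, 2]
    ev$severe <- ev$severe + sev[, 3]
    ev$fatal <- ev$fatal + sev[, 4]
    if (grepl("never$", st)) new_severe <- new_severe + sev[, 3]
    fatal_by[[st]] <- sev[, 4]
    alive_after[[st]] <- m - sev[, 4]
  }

  # cycle-start rewards plus event-cycle accruals for the newly severe
  alive0 <- state$func_never + state$nonfunc_never +
    state$func_post + state$nonfunc_post
  post0 <- state$func_post + state$nonfunc_post
  qalys <- u_age * alive0 - draws$du_severe * (post0 + new_severe)
  costs <- tibble(
    injury_nhs = ev$minor * draws$c_minor + ev$moderate * draws$c_moderate +
      ev$severe * draws$c_severe_acute,
    fatality = ev$fatal * draws$c_fatal_event,
    fire_other_public = ev$fires * draws$c_fire_rescue,
    fire_household = ev$fires * draws$c_property,
    severe_annual = (post0 + new_severe) * draws$c_severe_annual
  )

  # background mortality, then the severity flag, then alarm decay/repair
  surv <- 1 - qx
  fn <- alive_after$func_never * surv
  nn <- alive_after$nonfunc_never * surv
  fp <- alive_after$func_post * surv
  np <- alive_after$nonfunc_post * surv
  dead <- state$dead + qx * (alive_after$func_never + alive_after$nonfunc_never +
    alive_after$func_post + alive_after$nonfunc_post) +
    fatal_by$func_never + fatal_by$nonfunc_never +
    fatal_by$func_post + fatal_by$nonfunc_post

  ns_func <- new_severe_split(state, draws, p_fire, p_inj, split, surv)
  fn <- fn - ns_func$from_func
  nn <- nn - ns_func$from_nonfunc
  fp <- fp + ns_func$from_func
  np <- np + ns_func$from_nonfunc

  d_decay <- draws$d_decay
  d_repair <- draws$d_repair
  nxt <- tibble(
    func_never = fn * (1 - d_decay) + nn * d_repair,
    nonfunc_never = nn * (1 - d_repair) + fn * d_decay,
    func_post = fp * (1 - d_decay) + np * d_repair,
    nonfunc_post = np * (1 - d_repair) + fp * d_decay,
    dead = dead
  )
  check_state(nxt)
  list(state = nxt, qalys = qalys, costs = costs,
       events = as_tibble(ev))
}

# severe-event mass leaving the never-severe states, after background
# mortality (they enter the post-severe states next cycle)
new_severe_split <- function(state, draws, p_fire, p_inj, split, surv) {
  list(
    from_func = state$func_never * p_fire * p_inj$func *
      split$func[, 3] * surv,
    from_nonfunc = state$nonfunc_never * p_fire * p_inj$nonfunc *
      split$nonfunc[, 3] * surv
  )
}

#' Run the five pre-school cycles
#'
#' Evaluates the stage-2 model from the stage-1 starting distribution:
#' five yearly cycles at ages 0-4, with QALYs and costs discounted to birth
#' at each draw's rate `r` (discount factor `(1 + r)^-t`, `t` = age,
#' rewards at cycle start).
#'
#' @param tree a [evaluate_tree()] result (or a numeric vector of
#'   `p_start_functioning`), one row/value per draw.
#' @param draws parameter draws, one row per tree row.
#' @param life_table life table covering ages 0-4 ([life_table_fixture()]).
#' @param utility_norms age-band utility norms ([utility_norms_fixture()]).
#' @return A tibble per draw with discounted QALYs (`qalys`), discounted
#'   itemised costs (`cost_injury_nhs`, `cost_severe_annual`,
#'   `cost_fatality`, `cost_fire_other_public`, `cost_fire_household`),
#'   expected (undiscounted) event counts `n_fires`, `n_minor`, `n_moderate`,
#'   `n_severe`, `n_fatal`, and the terminal distribution
#'   `terminal_healthy`, `terminal_postsevere`, `terminal_dead`.
#' @examples
#' d <- sample_draws(parameter_fixture(), 3, seed = 1)
#' tr <- evaluate_tree("UC", d, pi_k = 0)
#' run_preschool(tr, d, life_table_fixture(), utility_norms_fixture())
#' @export
run_preschool <- function(tree, draws, life_table, utility_norms) {
  p_start <- if (is.data.frame(tree)) tree$p_start_functioning else tree
  draws <- check_draws(draws)
  life_table <- validate_life_table(life_table, ages = 0:4)
  u_age <- utility_by_age(utility_norms)
  n <- nrow(draws)
  stopifnot(length(p_start) == n)
  state <- preschool_state(p_start)
  r <- draws$r
  qalys <- numeric(n)
  cost <- list(injury_nhs = numeric(n), severe_annual = numeric(n),
               fatality = numeric(n), fire_other_public = numeric(n),
               fire_household = numeric(n))
  ev <- list(fires = numeric(n), minor = numeric(n), moderate = numeric(n),
             severe = numeric(n), fatal = numeric(n))
  for (t in 0:4) {
    qx <- life_table$qx[match(t, life_table$age)]
    step <- step_preschool(state, draws, qx, u_age[t + 1L])
    disc <- (1 + r)^(-t)
    qalys <- qalys + disc * step$qalys
    cost$injury_nhs <- cost$injury_nhs + disc * step$costs$injury_nhs
    cost$severe_annual <- cost$severe_annual + disc * step$costs$severe_annual
    cost$fatality <- cost$fatality + disc * step$costs$fatality
    cost$fire_other_public <- cost$fire_other_public +
      disc * step$costs$fire_other_public
    cost$fire_household <- cost$fire_household +
      disc * step$costs$fire_household
    for (e in names(ev)) ev[[e]] <- ev[[e]] + step$events[[e]]
    state <- step$state
  }
  tibble(
    qalys = qalys,
    cost_injury_nhs = cost$injury_nhs,
    cost_severe_annual = cost$severe_annual,
    cost_fatality = cost$fatality,
    cost_fire_other_public = cost$fire_other_public,
    cost_fire_household = cost$fire_household,
    n_fires = ev$fires, n_minor = ev$minor, n_moderate = ev$moderate,
    n_severe = ev$severe, n_fatal = ev$fatal,
    terminal_healthy = state$func_never + state$nonfunc_never,
    terminal_postsevere = state$func_post + state$nonfunc_post,
    terminal_dead = state$dead
  )
}

#' Cycle-by-cycle occupancy trace of the pre-school model
#'
#' Diagnostic export: the state distribution at the start of each cycle
#' (ages 0-5; age 5 is the terminal distribution) for a single parameter
#' draw.
#'
#' @inheritParams run_preschool
#' @param draw a single-row parameter-draws tibble.
#' @param p_start_functioning starting functioning-alarm probability.
#' @return A tibble with columns `age` and the five state occupancies.
#' @export
preschool_trace <- function(p_start_functioning, draw, life_table,
                            utility_norms) {
  stopifnot(nrow(draw) == 1L)
  draw <- check_draws(draw)
  life_table <- validate_life_table(life_table, ages = 0:4)
  u_age <- utility_by_age(utility_norms)
  state <- preschool_state(p_start_functioning)
  out <- bind_cols(tibble(age = 0L), state)
  for (t in 0:4) {
    qx <- life_table$qx[match(t, life_table$age)]
    state <- step_preschool(state, draw, qx, u_age[t + 1L])$state
    out <- bind_rows(out, bind_cols(tibble(age = t + 1L), state))
  }
  out
}
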